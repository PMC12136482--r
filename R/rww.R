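## Reduced Wong-Wang whole-brain model on a weighted, delayed connectome.

#' Reduced Wong-Wang parameters
#'
#' Defaults are the canonical values of the reduced one-population model:
#' `a = 0.27` nC^-1, `b = 0.108` kHz, `d = 154` ms for the input-output
#' transfer `H`, kinetic parameters `gamma_kin = 0.641` and `tau_s = 100` ms,
#' NMDA synaptic coupling `J_N = 0.2609` nA, baseline input `I_0 = 0.33` nA,
#' local recurrence `omega = 1` and global coupling `G = 0.096`.
#'
#' @param a,b,d transfer-function parameters (nC^-1, kHz, ms).
#' @param gamma_kin kinetic rate scale (dimensionless).
#' @param tau_s gating decay time constant (ms).
#' @param J_N synaptic coupling (nA).
#' @param I_0 external baseline input (nA).
#' @param omega local excitatory recurrence.
#' @param G global coupling strength.
#' @return Object of class `rww_params`.
#' @export
rww_params <- function(a = 0.27, b = 0.108, d = 154, gamma_kin = 0.641,
                       tau_s = 100, J_N = 0.2609, I_0 = 0.33,
                       omega = 1, G = 0.096) {
  p <- list(a = a, b = b, d = d, gamma_kin = gamma_kin, tau_s = tau_s,
            J_N = J_N, I_0 = I_0, omega = omega, G = G)
  stopifnot(all(vapply(p, function(x) is.numeric(x) && x > 0 || identical(x, 0),
                       logical(1))))
  structure(p, class = "rww_params")
}

.rww_param_vector <- function(p) {
  unlist(p[c("a", "b", "d", "gamma_kin", "tau_s", "J_N", "I_0", "omega", "G")])
}

#' Population firing-rate transfer function
#'
#' `H(x) = (a x - b) / (1 - exp(-d (a x - b)))`, continuous, positive and
#' monotone increasing, with the removable singularity at `a x = b`
#' evaluated as the limit `1/d`.
#'
#' @param x total synaptic input (nA); any numeric vector.
#' @param params an [rww_params()].
#' @return Firing rate in kHz.
#' @export
#' @examples
#' p <- rww_params()
#' firing_rate(p$b / p$a, p) * p$d  # exactly 1 at the singularity
firing_rate <- function(x, params = rww_params()) {
  stopifnot(all(is.finite(x)))
  .rate_H_cpp(as.numeric(x), params$a, params$b, params$d)
}

#' Right-hand side of the mass model
#'
#' `dS_I/dt = -S_I/tau_s + (1 - S_I) gamma_kin H(x_I)` with
#' `x_I = omega J_N S_I + G J_N sum_K c_IK S_K(t - tau_IK) + I_0`.
#'
#' @param S current gating vector.
#' @param connectome a [connectome()] object.
#' @param params an [rww_params()].
#' @param S_delayed matrix of delayed gating, `S_delayed[I, K]` holding
#'   `S_K(t - tau_IK)`; defaults to the instantaneous `S` for all pairs.
#' @return List with `dS` (per ms), `x` (nA) and `nu = H(x)` (kHz).
#' @export
rww_rhs <- function(S, connectome, params = rww_params(), S_delayed = NULL) {
  N <- length(S)
  W <- connectome$weights
  stopifnot(nrow(W) == N)
  if (is.null(S_delayed)) S_delayed <- matrix(S, nrow = N, ncol = N, byrow = TRUE)
  coupl <- rowSums(W * S_delayed) - diag(W) * diag(S_delayed)
  x <- params$omega * params$J_N * S + params$G * params$J_N * coupl + params$I_0
  nu <- firing_rate(x, params)
  dS <- -S / params$tau_s + (1 - S) * params$gamma_kin * nu
  list(dS = dS, x = x, nu = nu)
}

#' Fixed point of an isolated region
#'
#' Solves `S/tau_s = (1 - S) gamma_kin H(omega J_N S + I_0)` for a single
#' region without network input, by bracketed root search on `[0, 1]`.
#'
#' @param params an [rww_params()].
#' @return The gating fixed point `S*` in `[0, 1]`.
#' @export
rww_fixed_point <- function(params = rww_params()) {
  f <- function(S) {
    -S / params$tau_s + (1 - S) * params$gamma_kin *
      firing_rate(params$omega * params$J_N * S + params$I_0, params)
  }
  stats::uniroot(f, c(0, 1), tol = 1e-12)$root
}

#' Fresh mass-model state
#'
#' Uniform initial gating with a constant pre-history filling the delay
#' buffer.
#'
#' @param connectome a [connectome()] object.
#' @param dt integration step (ms).
#' @param S0 initial gating (scalar or per-region vector); default 0.001.
#' @return Object of class `rww_state` with elements `S`, `hist`, `step`.
#' @export
rww_initial_state <- function(connectome, dt, S0 = 0.001) {
  N <- nrow(connectome$weights)
  S <- rep_len(S0, N)
  H <- max(.delay_steps(connectome, dt)) + 1L
  hist <- matrix(rep(S, each = H), nrow = H)
  structure(list(S = S, hist = hist, step = 0), class = "rww_state")
}

## delay matrix in integration steps; zero off-diagonal delays become one step
.delay_steps <- function(connectome, dt) {
  d <- round(connectome$delays / dt)
  d[d < 1] <- 1L
  diag(d) <- 1L
  storage.mode(d) <- "integer"
  d
}

#' Simulate the delayed Wong-Wang network
#'
#' Explicit Euler with a ring-buffer delay history; gating clamped to
#' `[0, 1]` after each step.  Deterministic.  Resuming from the returned
#' state is bit-identical to a single uninterrupted run.
#'
#' @param connectome a [connectome()] object.
#' @param params an [rww_params()].
#' @param T duration (ms).
#' @param dt step (ms); must evenly divide the smallest inter-region delay
#'   (checked, see [validate_schedule()]).
#' @param state optional `rww_state` to resume from; default fresh state.
#' @param proxy optional list `list(region = <index or label>, activity =
#'   <numeric>)` substituting the region's gating slot with the given
#'   activity (one value per step, length `T/dt + 1`).
#' @param record_every record every k-th step.
#' @param check_dt set `FALSE` to skip the divisibility check (used
#'   internally once a schedule has been validated).
#' @return List with `t_ms`, `S`, `nu` (matrices samples x regions),
#'   `nu_mean` (per-region mean rate over the call) and `state`.
#' @export
simulate_rww <- function(connectome, params = rww_params(), T, dt = 0.1,
                         state = NULL, proxy = NULL, record_every = 1L,
                         check_dt = TRUE) {
  stopifnot(inherits(connectome, "connectome"), dt > 0, T >= dt)
  if (check_dt) .check_dt_divides(connectome$tau_min, dt)
  if (is.null(state)) state <- rww_initial_state(connectome, dt)
  N <- nrow(connectome$weights)
  proxy_idx <- -1L
  proxy_vals <- numeric(0)
  if (!is.null(proxy)) {
    proxy_idx <- .region_index(connectome, proxy$region) - 1L
    proxy_vals <- as.numeric(proxy$activity)
  }
  out <- .simulate_rww_cpp(connectome$weights, .delay_steps(connectome, dt),
                           .rww_param_vector(params), state$S, state$hist,
                           state$step, T, dt, proxy_idx, proxy_vals,
                           as.integer(record_every), TRUE)
  colnames(out$S) <- colnames(out$nu) <- connectome$labels
  new_state <- structure(list(S = out$S_end, hist = out$hist, step = out$step),
                         class = "rww_state")
  list(t_ms = out$t_ms, S = out$S, nu = out$nu,
       nu_mean = setNames(out$nu_mean, connectome$labels), state = new_state)
}

.check_dt_divides <- function(tau_min, dt) {
  k <- tau_min / dt
  if (abs(k - round(k)) > 1e-9 * max(1, k)) {
    stop(sprintf("dt = %g ms does not evenly divide tau_min = %g ms", dt, tau_min))
  }
  invisible(as.integer(round(k)))
}

.region_index <- function(connectome, region) {
  if (is.character(region)) {
    i <- match(region, connectome$labels)
    if (is.na(i)) stop("unknown region label: ", region)
    return(i)
  }
  i <- as.integer(region)
  stopifnot(i >= 1, i <= length(connectome$labels))
  i
}
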