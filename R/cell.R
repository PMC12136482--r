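## Single-compartment potassium-bath neuron: Hodgkin-Huxley fast subsystem
## (V, n) coupled to slow ion-concentration bookkeeping (dKi, Kg).  The bath
## potassium concentration K_bath is the single control parameter that moves
## the cell through resting, spiking, bursting, seizure-like and
## depolarization-block regimes.

## Fixed column order used when flattening parameters for the C++ kernels.
.cell_par_names <- c(
  "cm", "tau_n", "g0_Cl", "g0_Na", "g0_K", "gl_Na", "gl_K", "rho",
  "gamma_ion", "epsilon", "beta_vol", "K0_i", "K0_o", "Na0_i", "Na0_o",
  "Cl0_i", "Cl0_o", "C_nernst", "K_bath", "v_m", "s_m", "f_pump"
)

#' Parameters of the potassium-bath neuron
#'
#' Returns the full parameter set of the single-compartment seizure neuron.
#' The defaults are a calibrated set for which a 10 s simulation reproduces
#' the core of the canonical regime progression under increasing bath
#' potassium: resting state (4 and 7.5 mM), tonic spiking (9.5 mM),
#' bursting (12.5 mM), seizure-like events (17 and 17.5 mM) and
#' depolarization block (first at 22.5 mM on a 0.5 mM grid).  The narrow
#' transient-spike-train and sustained-ictal border regimes are recognized
#' by [classify_regime()] but are not expressed at those reference values
#' by this parameter set (see the package vignette).
#'
#' Units are fixed package-wide: ms, mV, mM, uA/cm2, mS/cm2, uF/cm2.
#'
#' @param K_bath bath potassium concentration (mM); the control parameter.
#' @param ... overrides for any other parameter: `cm` (membrane capacitance),
#'   `tau_n` (gating time constant, ms), `g0_K`, `g0_Na`, `g0_Cl` (maximal
#'   conductances), `gl_K`, `gl_Na` (leaks), `rho` (Na/K pump strength),
#'   `gamma_ion` (current-to-flux factor), `epsilon` (bath exchange rate,
#'   1/ms), `beta_vol` (intra/extracellular volume ratio), `K0_i`, `K0_o`,
#'   `Na0_i`, `Na0_o`, `Cl0_i`, `Cl0_o` (baseline concentrations, mM),
#'   `C_nernst` (Nernst prefactor, mV), `v_m`, `s_m` (Na activation midpoint
#'   and slope, mV), `f_pump` (K-flux stoichiometry factor of the pump in the
#'   slow equation).
#' @return An object of class `cell_params` (named list).
#' @export
#' @examples
#' p <- cell_params(K_bath = 9.5)
#' p$g0_Na
cell_params <- function(K_bath = 5.5, ...) {
  p <- list(
    cm = 1.0,
    tau_n = 1.8114497281547524,
    g0_Cl = 10.179353867610967,
    g0_Na = 30.88781481866947,
    g0_K = 31.377464625505244,
    gl_Na = 0.04939342026624035,
    gl_K = 0.439098679509697,
    rho = 91.79266595362914,
    gamma_ion = 0.00018833811175003544,
    epsilon = 0.0015679777675383455,
    beta_vol = 5.463152597732632,
    K0_i = 123.62319912468159,
    K0_o = 10.619977962158577,
    Na0_i = 28.74231701412527,
    Na0_o = 63.677095591812,
    Cl0_i = 6.249080919890816,
    Cl0_o = 101.71838092637299,
    C_nernst = 26.64,
    K_bath = K_bath,
    v_m = 29.49831605325691,
    s_m = 11.599933990478469,
    f_pump = 2.0
  )
  dots <- list(...)
  unknown <- setdiff(names(dots), names(p))
  if (length(unknown)) {
    stop("unknown cell parameter(s): ", paste(unknown, collapse = ", "))
  }
  p[names(dots)] <- dots
  stopifnot(
    p$cm > 0, p$tau_n > 0, p$K_bath > 0,
    p$g0_K >= 0, p$g0_Na >= 0, p$g0_Cl >= 0, p$gl_K >= 0, p$gl_Na >= 0,
    p$K0_i > 0, p$K0_o > 0, p$Na0_i > 0, p$Na0_o > 0, p$Cl0_i > 0, p$Cl0_o > 0
  )
  structure(p, class = "cell_params")
}

.cell_param_vector <- function(params) {
  stopifnot(inherits(params, "cell_params"))
  v <- vapply(.cell_par_names, function(nm) params[[nm]], numeric(1))
  names(v) <- .cell_par_names
  v
}

#' Nernst reversal potential
#'
#' `E = C * log(X_o / X_i)` for an ion with external concentration `X_o` and
#' internal concentration `X_i`.  For chloride (negative valence) call with
#' the arguments swapped.
#'
#' @param X_o external concentration (mM), must be positive.
#' @param X_i internal concentration (mM), must be positive.
#' @param C_nernst prefactor in mV (default 26.64, RT/F at mammalian
#'   temperature).
#' @return Reversal potential in mV.
#' @export
#' @examples
#' nernst_potential(4, 140)   # potassium-like, strongly negative
nernst_potential <- function(X_o, X_i, C_nernst = 26.64) {
  if (any(X_o <= 0) || any(X_i <= 0)) {
    stop("ion concentrations must be positive")
  }
  C_nernst * log(X_o / X_i)
}

#' Cell state constructor
#'
#' @param V membrane potential (mV).
#' @param n potassium gating variable.
#' @param dKi internal potassium deviation from baseline (mM).
#' @param Kg bath-buffer variable (mM).
#' @return Named numeric vector of class `cell_state`.
#' @export
cell_state <- function(V, n, dKi = 0, Kg = 0) {
  structure(c(V = V, n = n, dKi = dKi, Kg = Kg), class = "cell_state")
}

#' Resting initial state of the cell
#'
#' Membrane potential at the resting value of the fast subsystem under
#' baseline concentrations (dKi = 0, Kg = 0), with `n = n_inf(V)`.  The rest
#' voltage is located by a bisection on the total membrane current with the
#' gating variable at its voltage equilibrium.
#'
#' @param params a [cell_params()] object.
#' @return A [cell_state()].
#' @export
cell_initial_state <- function(params) {
  total_current <- function(V) {
    st <- cell_state(V = V, n = .n_inf(V))
    cur <- ionic_currents(st, params)
    unname(cur["i_K"] + cur["i_Na"] + cur["i_Cl"] + cur["i_pump"])
  }
  ## search a hyperpolarized bracket; fall back to -70 mV if none found
  grid <- seq(-95, -40, by = 1)
  vals <- vapply(grid, total_current, numeric(1))
  sgn <- which(vals[-1] * vals[-length(vals)] < 0)
  if (length(sgn) == 0) {
    V0 <- -70
  } else {
    i <- sgn[1]
    V0 <- stats::uniroot(total_current, c(grid[i], grid[i + 1]))$root
  }
  cell_state(V = V0, n = .n_inf(V0))
}

.n_inf <- function(V) 1 / (1 + exp(-(19 + V) / 18))

#' Instantaneous ionic current densities
#'
#' Channel currents `i_X = g_X (V - E_X)` for X in {K, Na, Cl} and the
#' Na/K pump current, at the given state.  Conductances follow the reduced
#' Hodgkin-Huxley form: `g_K = g0_K n + gl_K`, `g_Na = g0_Na m_inf(V) h(n) +
#' gl_Na`, `g_Cl = g0_Cl`.  Sodium activation is instantaneous and
#' inactivation is slaved to the K gate, `h(n) = 1.1 - 1/(1 + exp(3.2 - 8 n))`.
#'
#' @param state a [cell_state()].
#' @param params a [cell_params()].
#' @return Named vector with `i_K`, `i_Na`, `i_Cl`, `i_pump` (uA/cm2) plus
#'   the reversal potentials and derived concentrations.
#' @export
ionic_currents <- function(state, params) {
  if (any(is.na(unclass(state)))) {
    stop("NaN/NA in cell state: ", paste(names(state), "=", unclass(state), collapse = ", "))
  }
  .cell_currents_cpp(unclass(state), .cell_param_vector(params))
}

#' Time derivative of the cell state
#'
#' Right-hand side of the potassium-bath neuron:
#' `dV/dt = (-(i_K + i_Na + i_Cl + i_pump) + i_syn)/cm`,
#' `dn/dt = (n_inf(V) - n)/tau_n`,
#' `d dKi/dt = -gamma_ion (i_K - f_pump * i_pump)`,
#' `d Kg/dt = epsilon (K_bath - K_o)`,
#' with concentration bookkeeping `K_i = K0_i + dKi`, `Na_i = Na0_i - dKi`,
#' `K_o = K0_o - beta_vol * dKi + Kg`, `Na_o = Na0_o + beta_vol * dKi`.
#'
#' @param state a [cell_state()].
#' @param params a [cell_params()].
#' @param i_syn synaptic current density (uA/cm2, positive depolarizes).
#' @return Named vector of derivatives (per ms).
#' @export
cell_rhs <- function(state, params, i_syn = 0) {
  .cell_rhs_cpp(unclass(state), .cell_param_vector(params), i_syn)
}

#' Simulate the single cell
#'
#' Fixed-step integration (first-order split: explicit Euler for the membrane
#' and slow subsystem, exact exponential relaxation for the gating variable).
#' Deterministic given its inputs.
#'
#' @param params a [cell_params()].
#' @param T duration (ms).
#' @param dt step (ms); default 0.025.
#' @param init initial [cell_state()]; default [cell_initial_state()].
#' @param i_syn optional synaptic drive: a function of time (ms) returning a
#'   current density, or a numeric vector with one value per step.
#' @param record_every record every k-th sample to keep traces small
#'   (default 1 = every step).
#' @return A data.frame with columns `t_ms`, `V_mV`, `n`, `dKi_mM`, `Kg_mM`.
#' @export
#' @examples
#' tr <- simulate_cell(cell_params(K_bath = 9.5), T = 500)
#' range(tr$V_mV)
simulate_cell <- function(params, T, dt = 0.025, init = NULL,
                          i_syn = NULL, record_every = 1L) {
  stopifnot(dt > 0, T >= dt)
  if (is.null(init)) init <- cell_initial_state(params)
  n_steps <- round(T / dt)
  drive <- numeric(0)
  if (!is.null(i_syn)) {
    if (is.function(i_syn)) {
      drive <- i_syn((seq_len(n_steps) - 1) * dt)
    } else {
      drive <- as.numeric(i_syn)
    }
    drive <- rep_len(drive, n_steps)
  }
  out <- .simulate_cell_cpp(.cell_param_vector(params), T, dt,
                            unclass(init), drive, as.integer(record_every))
  as.data.frame(out)
}

#' Spike detection on a membrane-potential trace
#'
#' Upward crossings of the threshold; one spike per crossing, re-arming only
#' after the trace falls back below threshold.
#'
#' @param trace data.frame with `t_ms` and `V_mV` (or a numeric vector of V
#'   with `t` supplied).
#' @param threshold spike threshold (mV); default -25.
#' @param t time vector when `trace` is a bare numeric vector.
#' @return Numeric vector of spike times (ms).
#' @export
detect_spikes <- function(trace, threshold = -25, t = NULL) {
  if (is.data.frame(trace)) {
    .detect_spikes_cpp(trace$t_ms, trace$V_mV, threshold)
  } else {
    stopifnot(!is.null(t), length(t) == length(trace))
    .detect_spikes_cpp(t, trace, threshold)
  }
}
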