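## Population of potassium-bath neurons with all-to-all (or explicit)
## connectivity through conductance-based single-exponential synapses.

#' Synapse parameters
#'
#' Conductance-based single-exponential synapse: each delivered event
#' increments the target's synaptic conductance by `weight * weight_scale`
#' (mS/cm2); the conductance then decays with time constant `tau_syn`.  The
#' synaptic current is `g_syn * (e_rev - V)`.
#'
#' @param weight dimensionless synaptic weight (default 0.5).
#' @param tau_syn decay time constant (ms).
#' @param e_rev reversal potential (mV); 0 for excitatory.
#' @param delay transmission delay (ms); must be at least one step.
#' @param weight_scale conductance increment per unit weight (mS/cm2).  The
#'   default is calibrated so that a mixed healthy/pathological population
#'   entrains to the pathological rhythm once fully connected.
#' @return Object of class `synapse_params`.
#' @export
synapse_params <- function(weight = 0.5, tau_syn = 2, e_rev = 0, delay = 1,
                           weight_scale = 0.1) {
  stopifnot(tau_syn > 0, delay > 0, weight_scale >= 0)
  structure(list(weight = weight, tau_syn = tau_syn, e_rev = e_rev,
                 delay = delay, weight_scale = weight_scale),
            class = "synapse_params")
}

#' Network configuration
#'
#' A population of `N` cells is split into `round(f * N)` healthy cells
#' (bath potassium `K_bath_healthy`) and the remainder pathological
#' (`K_bath_path`).  Healthy cells come first (ids `1..round(f*N)`).
#' Rounding is half-up.
#'
#' @param N number of cells.
#' @param f healthy fraction in `[0, 1]`.
#' @param K_bath_healthy bath potassium of healthy cells (mM).
#' @param K_bath_path bath potassium of pathological cells (mM).
#' @param synapse a [synapse_params()].
#' @param spike_threshold spike detection threshold (mV).
#' @param connectivity `"none"`, `"all_to_all"`, or an `N x N` 0/1 adjacency
#'   matrix (row = source, column = target; diagonal ignored).
#' @param seed RNG seed recorded in the config (the network build itself is
#'   deterministic).
#' @return Object of class `network_config`.
#' @export
network_config <- function(N, f, K_bath_healthy = 9.5, K_bath_path = 17.0,
                           synapse = synapse_params(), spike_threshold = -25,
                           connectivity = "all_to_all", seed = 1L) {
  stopifnot(N >= 1, f >= 0, f <= 1)
  if (is.character(connectivity)) {
    connectivity <- match.arg(connectivity, c("none", "all_to_all"))
  } else {
    connectivity <- as.matrix(connectivity)
    stopifnot(nrow(connectivity) == N, ncol(connectivity) == N)
  }
  structure(list(N = as.integer(N), f = f,
                 K_bath_healthy = K_bath_healthy, K_bath_path = K_bath_path,
                 synapse = synapse, spike_threshold = spike_threshold,
                 connectivity = connectivity, seed = as.integer(seed)),
            class = "network_config")
}

## round-half-up, documented rounding rule for f * N
.round_half_up <- function(x) floor(x + 0.5)

#' Build a spiking network
#'
#' Deterministic construction: the first `round(f N)` cells are healthy, the
#' rest pathological; adjacency per the connectivity mode with
#' self-connections excluded.
#'
#' @param config a [network_config()].
#' @param cell_overrides optional named list of cell parameter overrides
#'   applied to every cell (passed to [cell_params()]).
#' @return Object of class `spiking_network` with elements `config`,
#'   `n_healthy`, `cell_params` (list of per-cell [cell_params()]),
#'   `edges` (2-column matrix of directed edges, source/target ids).
#' @export
#' @examples
#' net <- build_network(network_config(N = 5, f = 0.2))
#' net$n_healthy          # 1
#' nrow(net$edges)        # 20 directed edges
build_network <- function(config, cell_overrides = list()) {
  N <- config$N
  n_healthy <- as.integer(.round_half_up(config$f * N))
  kb <- c(rep(config$K_bath_healthy, n_healthy),
          rep(config$K_bath_path, N - n_healthy))
  cells <- lapply(kb, function(k) {
    do.call(cell_params, c(list(K_bath = k), cell_overrides))
  })
  edges <- .adjacency_edges(config$connectivity, N)
  pm <- t(vapply(cells, .cell_param_vector, numeric(length(.cell_par_names))))
  structure(list(config = config, n_healthy = n_healthy,
                 cell_params = cells, edges = edges, param_matrix = pm),
            class = "spiking_network")
}

.adjacency_edges <- function(connectivity, N) {
  if (is.character(connectivity)) {
    if (connectivity == "none") {
      return(matrix(integer(0), ncol = 2,
                    dimnames = list(NULL, c("from", "to"))))
    }
    from <- rep(seq_len(N), each = N)
    to <- rep(seq_len(N), times = N)
    keep <- from != to
    return(cbind(from = from[keep], to = to[keep]))
  }
  idx <- which(connectivity != 0, arr.ind = TRUE)
  idx <- idx[idx[, 1] != idx[, 2], , drop = FALSE]
  cbind(from = as.integer(idx[, 1]), to = as.integer(idx[, 2]))
}

.conn_mode_code <- function(connectivity) {
  if (is.character(connectivity)) {
    switch(connectivity, none = 0L, all_to_all = 1L)
  } else {
    2L
  }
}

## CSR adjacency for explicit matrices (0-based for C++)
.adjacency_csr <- function(net) {
  N <- net$config$N
  if (is.character(net$config$connectivity)) {
    return(list(ptr = integer(N + 1), idx = integer(0)))
  }
  e <- net$edges
  ord <- order(e[, 1], e[, 2])
  e <- e[ord, , drop = FALSE]
  counts <- tabulate(e[, 1], nbins = N)
  list(ptr = as.integer(c(0, cumsum(counts))), idx = as.integer(e[, 2] - 1))
}

#' Fresh network state
#'
#' Per-cell resting initial conditions, zero synaptic conductances, armed
#' spike detectors, step counter zero.
#'
#' @param net a [build_network()] result.
#' @return Object of class `network_state`.
#' @export
network_initial_state <- function(net) {
  N <- net$config$N
  sts <- t(vapply(net$cell_params,
                  function(p) unclass(cell_initial_state(p)), numeric(4)))
  structure(list(state = sts, gsyn = numeric(N), armed = rep(TRUE, N),
                 step = 0, pending = matrix(numeric(0), ncol = 3),
                 conn_mode = .conn_mode_code(net$config$connectivity)),
            class = "network_state")
}

#' Simulate a spiking network
#'
#' Advances the network for `T` ms with step `dt`.  Spikes are upward
#' crossings of the configured threshold (re-armed below threshold) and are
#' delivered to all targets after the synaptic delay as conductance
#' increments.  Supports external events and timed connectivity switches,
#' and can be resumed from a returned state, in which case the chunked run
#' is bit-identical to an uninterrupted one.
#'
#' @param net a [build_network()] result.
#' @param T duration (ms).
#' @param dt step (ms).
#' @param external_events optional data.frame/matrix with columns (cell id,
#'   time ms, conductance increment mS/cm2); times are absolute.  Events
#'   beyond the end of this call are kept pending in the returned state.
#' @param switch_schedule optional data.frame with columns `time` (ms) and
#'   `mode` (`"none"`, `"all_to_all"`); connectivity changes when simulated
#'   time reaches each entry.
#' @param state optional `network_state` to resume from.
#' @param record_every record every k-th sample.
#' @param allow_future keep events beyond the end of this call as pending
#'   deliveries in the returned state (used by the co-simulation loop,
#'   where inbound events carry delays larger than one epoch) instead of
#'   rejecting them.
#' @return List with `t_ms`, `V` (samples x cells matrix), `raster`
#'   (data.frame gid/t_ms; gid 0 in `external_events` means every cell),
#'   and `state` for resumption.
#' @export
simulate_network <- function(net, T, dt = 0.025, external_events = NULL,
                             switch_schedule = NULL, state = NULL,
                             record_every = 1L, allow_future = FALSE) {
  stopifnot(inherits(net, "spiking_network"), dt > 0, T >= dt)
  if (is.null(state)) state <- network_initial_state(net)
  syn <- net$config$synapse
  pm <- net$param_matrix
  if (is.null(pm)) {
    pm <- t(vapply(net$cell_params, .cell_param_vector,
                   numeric(length(.cell_par_names))))
  }
  ev <- matrix(numeric(0), ncol = 3)
  if (!is.null(external_events) && NROW(external_events) > 0) {
    ev <- as.matrix(external_events)[, 1:3, drop = FALSE]
    if (!allow_future) {
      t_end <- state$step * dt + T
      late <- ev[, 2] > t_end
      if (any(late)) {
        warning(sum(late), " external event(s) beyond simulation end rejected")
        ev <- ev[!late, , drop = FALSE]
      }
    }
  }
  sw_t <- numeric(0); sw_m <- integer(0)
  if (!is.null(switch_schedule) && NROW(switch_schedule) > 0) {
    sw_t <- as.numeric(switch_schedule$time)
    sw_m <- vapply(as.character(switch_schedule$mode),
                   function(m) switch(m, none = 0L, all_to_all = 1L,
                                      stop("unknown connectivity mode: ", m)),
                   integer(1))
    stopifnot(all(sw_t >= state$step * dt), all(sw_t <= state$step * dt + T))
  }
  csr <- .adjacency_csr(net)
  out <- .simulate_network_cpp(
    pm, T, dt, state$state, state$gsyn, state$armed, state$step,
    ev, state$pending,
    syn$weight * syn$weight_scale, syn$tau_syn, syn$e_rev, syn$delay,
    net$config$spike_threshold, state$conn_mode, sw_t, sw_m,
    csr$ptr, csr$idx, as.integer(record_every))
  new_state <- structure(list(state = out$state, gsyn = out$gsyn,
                              armed = out$armed, step = out$step,
                              pending = out$pending,
                              conn_mode = out$conn_mode),
                         class = "network_state")
  list(t_ms = out$t_ms, V = out$V,
       raster = data.frame(gid = out$spike_cell, t_ms = out$spike_time),
       state = new_state)
}

#' Pairwise spike-train synchrony
#'
#' Mean pairwise Pearson correlation of binned spike counts; a simple
#' population synchrony index used to quantify entrainment after a
#' connectivity switch.
#'
#' @param raster data.frame with `gid`, `t_ms`.
#' @param N number of cells.
#' @param span time window `c(t0, t1)` (ms).
#' @param bin_width bin width (ms).
#' @return Scalar in `[-1, 1]` (NA when fewer than two cells spike).
#' @export
spike_synchrony <- function(raster, N, span, bin_width = 50) {
  breaks <- seq(span[1], span[2], by = bin_width)
  if (length(breaks) < 3) stop("span too short for the given bin width")
  keep <- raster$t_ms >= span[1] & raster$t_ms <= span[2]
  r <- raster[keep, , drop = FALSE]
  counts <- vapply(seq_len(N), function(g) {
    hist(r$t_ms[r$gid == g], breaks = breaks, plot = FALSE)$counts
  }, numeric(length(breaks) - 1))
  ## a cell with no rate variation shares no synchrony with anyone: pairs
  ## involving it contribute zero instead of being dropped, so a population
  ## with silent members scores low rather than NA
  active <- which(apply(counts, 2, stats::sd) > 0)
  if (length(active) < 2) return(0)
  cm <- stats::cor(counts[, active, drop = FALSE])
  total_pairs <- N * (N - 1) / 2
  sum(cm[upper.tri(cm)]) / total_pairs
}
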