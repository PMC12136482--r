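## Orchestrates the two scales: one connectome region is replaced by a
## spiking proxy population; both sides advance in lockstep over epochs of
## (at most) the smallest inter-region delay, exchanging activity only at
## epoch boundaries.  Because every inter-region influence is delayed by at
## least tau_min, events generated during an epoch cannot affect any other
## region before the next epoch begins.

#' Co-simulation configuration
#'
#' @param proxy_region label (or index) of the connectome region replaced by
#'   the spiking network.
#' @param network a [network_config()] for the proxy population.
#' @param rww an [rww_params()].
#' @param coupling a [coupling_config()].
#' @param T total duration (ms).
#' @param epoch exchange interval (ms); `NULL` uses the connectome's
#'   tau_min.  Must not exceed tau_min.
#' @param dt_micro spiking-network step (ms).
#' @param dt_macro mass-model step (ms); both must evenly divide the epoch.
#' @param seed base seed; every (source region, epoch) event draw uses a
#'   deterministic stream derived from it, so results are independent of
#'   evaluation order.
#' @return Object of class `cosim_config`.
#' @export
cosim_config <- function(proxy_region, network, rww = rww_params(),
                         coupling = coupling_config(), T = 20000,
                         epoch = NULL, dt_micro = 0.025, dt_macro = 0.1,
                         seed = 1L) {
  stopifnot(inherits(network, "network_config"), inherits(rww, "rww_params"),
            inherits(coupling, "coupling_config"), T > 0,
            dt_micro > 0, dt_macro > 0)
  structure(list(proxy_region = proxy_region, network = network, rww = rww,
                 coupling = coupling, T = T, epoch = epoch,
                 dt_micro = dt_micro, dt_macro = dt_macro,
                 seed = as.integer(seed)),
            class = "cosim_config")
}

#' Validate the exchange schedule
#'
#' The epoch is capped at the smallest inter-region delay tau_min; both time
#' steps must evenly divide the epoch (and hence tau_min when the epoch
#' equals it).  An epoch longer than tau_min is rejected: delayed influences
#' would arrive within the epoch and the exchange would no longer be causal.
#'
#' @param connectome a [connectome()].
#' @param config a [cosim_config()].
#' @return List with `epoch` (ms), `n_epochs`, `micro_steps`, `macro_steps`
#'   per epoch.
#' @export
validate_schedule <- function(connectome, config) {
  tau_min <- connectome$tau_min
  if (is.na(tau_min)) stop("connectome has no positive inter-region delay")
  epoch <- if (is.null(config$epoch)) tau_min else config$epoch
  if (epoch > tau_min + 1e-9) {
    stop(sprintf("epoch (%g ms) exceeds tau_min (%g ms): exchange would break causality",
                 epoch, tau_min))
  }
  epoch <- min(epoch, tau_min)
  macro_steps <- .check_dt_divides(epoch, config$dt_macro)
  micro_steps <- .check_dt_divides(epoch, config$dt_micro)
  n_epochs <- ceiling(config$T / epoch)
  list(epoch = epoch, n_epochs = n_epochs,
       micro_steps = micro_steps, macro_steps = macro_steps)
}

## deterministic sub-seed per (source region, epoch); kept below 2^31
.stream_seed <- function(base, region_idx, epoch_idx) {
  as.integer((as.double(base) * 1000003 + epoch_idx * 10007 + region_idx) %%
               2147483647)
}

#' Run an epoch-based co-simulation
#'
#' Per epoch: (1) synthetic events for the proxy cells are drawn from each
#' region with a positive inbound weight, using the previous epoch's mean
#' rate; (2) the spiking network advances one epoch; (3) its raster is
#' converted to a smooth activity trace (calcium filter by default);
#' (4) the mass model advances one epoch with the proxy's gating slot
#' substituted by `G_A * nu_P(t)`.  Deterministic given the seeds.
#'
#' @param config a [cosim_config()].
#' @param connectome a [connectome()].
#' @param record_every_macro,record_every_micro recording strides for the
#'   two sides.
#' @return List with `t_ms`, `S`, `nu` (macro samples x regions),
#'   `proxy` (list: `t_ms`, `V`, `raster`, `nu` data.frame of the proxy
#'   activity), `exchange_log` (one row per epoch), `schedule`, and the
#'   resolved `config`.
#' @export
run_cosim <- function(config, connectome, record_every_macro = 1L,
                      record_every_micro = 20L) {
  sched <- validate_schedule(connectome, config)
  P <- .region_index(connectome, config$proxy_region)
  W <- connectome$weights
  N_reg <- nrow(W)
  cpl <- config$coupling

  net <- build_network(config$network)
  net_state <- network_initial_state(net)
  rww_state <- rww_initial_state(connectome, config$dt_macro)

  ## previous-epoch mean rates; initialized from the initial state
  r0 <- rww_rhs(rww_state$S, connectome, config$rww)
  nu_prev <- r0$nu

  C_end <- numeric(config$network$N)
  inbound <- which(W[P, ] > 0 & seq_len(N_reg) != P)

  macro_t <- list(); macro_S <- list(); macro_nu <- list()
  micro_t <- list(); micro_V <- list(); proxy_nu <- list()
  sp_gid <- list(); sp_t <- list()
  log_events <- numeric(sched$n_epochs)
  log_spikes <- numeric(sched$n_epochs)
  log_nu <- numeric(sched$n_epochs)

  for (k in seq_len(sched$n_epochs) - 1L) {
    t0 <- k * sched$epoch
    t1 <- t0 + sched$epoch
    ## (1) rate -> events, one independent stream per (source, epoch);
    ## gid 0 = broadcast to every proxy cell
    evs <- lapply(inbound, function(I) {
      e <- rate_to_events(nu_I = max(0, nu_prev[I]), c_IP = W[P, I],
                          epoch = c(t0, t1), n_cells = config$network$N,
                          gain = cpl$rate_to_spike_gain,
                          delay = connectome$delays[P, I],
                          event_weight = cpl$event_weight,
                          seed = .stream_seed(config$seed, I, k),
                          broadcast = TRUE)
      if (nrow(e)) cbind(0, e$t_ms, e$weight) else NULL
    })
    evs <- do.call(rbind, evs)
    n_events_in <- if (is.null(evs)) 0L else nrow(evs)
    ## (2) advance the spiking network one epoch
    micro <- simulate_network(net, T = sched$epoch, dt = config$dt_micro,
                              external_events = evs, state = net_state,
                              record_every = record_every_micro,
                              allow_future = TRUE)
    net_state <- micro$state
    ## (3) spikes -> smooth proxy activity on the macro grid
    if (cpl$mode == "ca") {
      act <- ca_activity(micro$raster, N = config$network$N, params = cpl$ca,
                         dt = config$dt_macro, span = c(t0, t1), C0 = C_end)
      C_end <- attr(act, "C_end")
    } else {
      act <- spikes_to_rate_binned(micro$raster, N = config$network$N,
                                   bin_width = config$dt_macro,
                                   span = c(t0, t1))
      act <- rbind(act, act[nrow(act), ])  # one value per macro step incl. end
      act$t_ms <- seq(t0, t1, by = config$dt_macro)[seq_len(nrow(act))]
    }
    proxy_vals <- proxy_to_tvb(act, cpl$G_A)
    ## (4) advance the mass model with the substituted proxy slot
    macro <- simulate_rww(connectome, config$rww, T = sched$epoch,
                          dt = config$dt_macro, state = rww_state,
                          proxy = list(region = P, activity = proxy_vals),
                          record_every = record_every_macro, check_dt = FALSE)
    rww_state <- macro$state
    nu_prev <- macro$nu_mean

    drop_last <- k < sched$n_epochs - 1L
    keep_m <- if (drop_last) seq_len(length(macro$t_ms) - 1L) else seq_along(macro$t_ms)
    macro_t[[k + 1]] <- macro$t_ms[keep_m]
    macro_S[[k + 1]] <- macro$S[keep_m, , drop = FALSE]
    macro_nu[[k + 1]] <- macro$nu[keep_m, , drop = FALSE]
    keep_u <- if (drop_last) seq_len(length(micro$t_ms) - 1L) else seq_along(micro$t_ms)
    micro_t[[k + 1]] <- micro$t_ms[keep_u]
    micro_V[[k + 1]] <- micro$V[keep_u, , drop = FALSE]
    sp_gid[[k + 1]] <- micro$raster$gid
    sp_t[[k + 1]] <- micro$raster$t_ms
    proxy_nu[[k + 1]] <- if (drop_last) act[seq_len(nrow(act) - 1L), ] else act
    log_events[k + 1] <- n_events_in
    log_spikes[k + 1] <- nrow(micro$raster)
    log_nu[k + 1] <- mean(act$nu)
  }

  raster <- data.frame(gid = do.call(c, sp_gid), t_ms = do.call(c, sp_t))
  epochs <- seq_len(sched$n_epochs) - 1L
  list(t_ms = do.call(c, macro_t),
       S = do.call(rbind, macro_S),
       nu = do.call(rbind, macro_nu),
       proxy = list(t_ms = do.call(c, micro_t),
                    V = do.call(rbind, micro_V),
                    raster = raster,
                    nu = do.call(rbind, proxy_nu)),
       exchange_log = data.frame(epoch = epochs,
                                 t0 = epochs * sched$epoch,
                                 t1 = (epochs + 1) * sched$epoch,
                                 events_in = log_events,
                                 spikes_out = log_spikes,
                                 nu_P_mean = log_nu),
       schedule = sched,
       proxy_region = connectome$labels[P],
       config = config)
}
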