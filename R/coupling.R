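## Bidirectional translation between discrete spikes and continuous region
## activity.  Spike -> rate: simple binning or a calcium-like exponential
## filter; rate -> spike: Poisson event counts with uniform timing.

#' Calcium-filter parameters
#'
#' Per-cell trace `dC_p/dt = -C_p/tau_ca + beta_ca * sum delta(t - t_spike)`
#' with `C_p(0) = 0`; the population activity is the mean over cells.  With a
#' per-cell increment and a population mean, the converter is invariant under
#' the number of cells for per-cell-identical activity.
#'
#' @param tau_ca decay constant (ms), default 100.
#' @param beta_ca per-spike increment, default 0.1.
#' @return Object of class `ca_filter_params`.
#' @export
ca_filter_params <- function(tau_ca = 100, beta_ca = 0.1) {
  stopifnot(tau_ca > 0, beta_ca >= 0)
  structure(list(tau_ca = tau_ca, beta_ca = beta_ca), class = "ca_filter_params")
}

#' Coupling configuration
#'
#' @param mode spike-to-rate converter: `"ca"` (calcium filter, default) or
#'   `"binned"`.
#' @param bin_width bin width for the binned converter (ms).
#' @param G_A proxy-to-mass-model scaling (default 100): the substituted
#'   gating-slot value is `G_A * nu_P(t)`.
#' @param rate_to_spike_gain expected events per (weight x kHz x ms) when
#'   converting region activity to proxy input events.
#' @param event_weight conductance increment per inbound event (mS/cm2).
#' @param ca a [ca_filter_params()].
#' @param rng_seed base seed for the rate-to-event generator.
#' @return Object of class `coupling_config`.
#' @export
coupling_config <- function(mode = c("ca", "binned"), bin_width = 1,
                            G_A = 100, rate_to_spike_gain = 1,
                            event_weight = 0.05,
                            ca = ca_filter_params(), rng_seed = 1L) {
  mode <- match.arg(mode)
  stopifnot(bin_width > 0, G_A > 0, rate_to_spike_gain >= 0)
  structure(list(mode = mode, bin_width = bin_width, G_A = G_A,
                 rate_to_spike_gain = rate_to_spike_gain,
                 event_weight = event_weight, ca = ca,
                 rng_seed = as.integer(rng_seed)),
            class = "coupling_config")
}

#' Binned spike-to-rate conversion
#'
#' Spikes are sorted into bins of width `bin_width` and normalized by cell
#' count and bin width: `nu(bin) = count / (N * bin_width)`, a per-cell rate
#' in kHz (1/ms).
#'
#' @param raster data.frame with `gid`, `t_ms`.
#' @param N number of cells in the population.
#' @param bin_width bin width (ms).
#' @param span time window `c(t0, t1)` (ms).
#' @return data.frame with `t_ms` (bin centers) and `nu` (kHz per cell).
#' @export
spikes_to_rate_binned <- function(raster, N, bin_width, span) {
  stopifnot(N >= 1, bin_width > 0)
  if (span[2] <= span[1]) stop("empty time span")
  breaks <- seq(span[1], span[2], by = bin_width)
  if (breaks[length(breaks)] < span[2]) breaks <- c(breaks, span[2])
  keep <- raster$t_ms >= span[1] & raster$t_ms <= span[2]
  counts <- hist(raster$t_ms[keep], breaks = breaks, plot = FALSE)$counts
  widths <- diff(breaks)
  data.frame(t_ms = (breaks[-length(breaks)] + breaks[-1]) / 2,
             nu = counts / (N * widths))
}

#' Calcium-filter spike-to-rate conversion
#'
#' Per-cell exponentially decaying trace incremented by `beta_ca` at each of
#' the cell's spikes, averaged over the population.  Exact between-event
#' decay; sampled on a regular grid.
#'
#' @param raster data.frame with `gid`, `t_ms`.
#' @param N number of cells.
#' @param params a [ca_filter_params()].
#' @param dt sampling step (ms).
#' @param span time window `c(t0, t1)` (ms).
#' @param C0 initial per-cell filter values (default all zero).
#' @return data.frame with `t_ms`, `nu`, plus attribute `"C_end"` holding the
#'   final per-cell values (for continuation across epochs).
#' @export
ca_activity <- function(raster, N, params = ca_filter_params(), dt = 0.1,
                        span, C0 = NULL) {
  stopifnot(N >= 1, dt > 0)
  if (span[2] <= span[1]) stop("empty time span")
  if (is.null(C0)) C0 <- numeric(N)
  n_steps <- round((span[2] - span[1]) / dt)
  out <- .ca_filter_cpp(as.integer(raster$gid), as.numeric(raster$t_ms),
                        as.integer(N), params$tau_ca, params$beta_ca,
                        span[1], dt, n_steps, C0)
  res <- data.frame(t_ms = out$t_ms, nu = out$nu)
  attr(res, "C_end") <- out$C_end
  res
}

#' Scale proxy activity into the mass-model gating slot
#'
#' The proxy region's contribution to every other region's coupling sum is
#' `G_A * nu_P(t)` in place of the gating variable `S_P`.
#'
#' @param activity data.frame with `nu` (or bare numeric).
#' @param G_A scaling factor.
#' @return Numeric vector of substituted gating-slot values.
#' @export
proxy_to_tvb <- function(activity, G_A = 100) {
  nu <- if (is.data.frame(activity)) activity$nu else as.numeric(activity)
  G_A * nu
}

#' Generate proxy input events from region activity
#'
#' For a source region with mean activity `nu_I` (kHz) and connection weight
#' `c_IP` to the proxy, the event count over an epoch of length `epoch_len`
#' is Poisson with mean `gain * c_IP * nu_I * epoch_len`; event times are
#' i.i.d. uniform over the epoch and every event is dispatched to all proxy
#' cells after the per-connection delay.
#'
#' @param nu_I source-region activity (kHz), must be non-negative.
#' @param c_IP connectome weight from the source to the proxy region.
#' @param epoch `c(t0, t1)` (ms) over which events are placed.
#' @param n_cells number of proxy cells (events are dispatched to each).
#' @param gain events per (weight x kHz x ms).
#' @param delay per-connection delay (ms) added to each event time.
#' @param event_weight conductance increment carried by each event.
#' @param seed RNG seed for this (region, epoch) draw.
#' @param broadcast if `TRUE`, return one row per event with `gid = 0`,
#'   which the network simulator interprets as delivery to every cell
#'   (equivalent to, and much cheaper than, enumerating all cells).
#' @return data.frame with columns `gid`, `t_ms`, `weight` (possibly empty).
#' @export
rate_to_events <- function(nu_I, c_IP, epoch, n_cells, gain = 1, delay = 0,
                           event_weight = 0.05, seed = 1L, broadcast = FALSE) {
  if (nu_I < 0) stop("negative source activity")
  epoch_len <- epoch[2] - epoch[1]
  stopifnot(epoch_len > 0, n_cells >= 1)
  lambda <- gain * c_IP * nu_I * epoch_len
  .with_seed(seed, {
    k <- stats::rpois(1, lambda)
    if (k == 0) {
      return(data.frame(gid = integer(0), t_ms = numeric(0), weight = numeric(0)))
    }
    times <- sort(stats::runif(k, epoch[1], epoch[2])) + delay
    if (broadcast) {
      data.frame(gid = rep(0L, k), t_ms = times, weight = event_weight)
    } else {
      data.frame(gid = rep(seq_len(n_cells), each = k),
                 t_ms = rep(times, times = n_cells),
                 weight = event_weight)
    }
  })
}
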