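## Regime classification of single-cell voltage traces.  The seven labels
## follow the canonical potassium-bath sequence: RS (resting state), ST
## (transient spike train), TS (tonic spiking), BURSTING, SLE (seizure-like
## events), SIA (sustained ictal activity), DB (depolarization block).

#' Regime classifier settings
#'
#' Decision thresholds for [classify_regime()].  All times in ms, voltages
#' in mV.
#'
#' @param discard initial transient excluded from classification.
#' @param rest_v_max final-window mean V below this = hyperpolarized (RS).
#' @param db_v_min final-window mean V above this = depolarized plateau (DB).
#' @param st_frac spikes confined to this leading fraction of the trace = ST.
#' @param tonic_cv_max ISI coefficient-of-variation bound for tonic spiking.
#' @param tonic_gap_factor no ISI may exceed this multiple of the median ISI
#'   for tonic spiking.
#' @param burst_gap_factor cluster-splitting threshold as a multiple of the
#'   median intra-cluster ISI.
#' @param burst_max_dur maximal burst-cluster duration.
#' @param sle_min_event minimal duration of a seizure-like event.
#' @param sle_min_quiet minimal quiescence separating seizure-like events.
#' @param sia_v_min final-window mean V above this counts as elevated (SIA).
#' @param final_window length of the trailing window used for mean V.
#' @return Named list of class `regime_criteria`.
#' @export
regime_criteria <- function(discard = 1000, rest_v_max = -50, db_v_min = -40,
                            st_frac = 0.3, tonic_cv_max = 0.3,
                            tonic_gap_factor = 5, burst_gap_factor = 3,
                            burst_max_dur = 1000, sle_min_event = 1000,
                            sle_min_quiet = 1000, sia_v_min = -50,
                            final_window = 1000) {
  structure(as.list(environment()), class = "regime_criteria")
}

## split spike times into clusters wherever the gap exceeds `gap`
.spike_clusters <- function(st, gap) {
  if (length(st) == 0) return(list())
  breaks <- which(diff(st) > gap)
  idx <- rep(seq_len(length(breaks) + 1),
             diff(c(0, breaks, length(st))))
  unname(split(st, idx))
}

#' Classify the firing regime of a voltage trace
#'
#' Applies a fixed decision tree to the spike pattern and trailing membrane
#' potential of a single-cell trace.  The trace should cover at least 10 s
#' for a reliable classification; shorter traces raise an error.
#'
#' Decision rules (after discarding the initial transient):
#' * RS: no spikes and trailing mean V below `rest_v_max`.
#' * DB: no spikes in the final half and trailing mean V above `db_v_min`.
#' * ST: all spikes confined to the leading `st_frac` of the trace.
#' * SLE: recurrent spike clusters of duration at least `sle_min_event`,
#'   separated by quiescence of at least `sle_min_quiet`.
#' * BURSTING: bimodal inter-spike intervals; clusters split at
#'   `burst_gap_factor` times the median intra-cluster ISI, all shorter than
#'   `burst_max_dur`.
#' * TS: spiking persists to the end with ISI coefficient of variation below
#'   `tonic_cv_max` and no gap beyond `tonic_gap_factor` median ISIs.
#' * SIA: spiking persists with no quiescence of `sle_min_quiet` and an
#'   elevated trailing mean V.
#'
#' @param trace data.frame with `t_ms` and `V_mV` as from [simulate_cell()].
#' @param spike_threshold spike detection threshold (mV).
#' @param criteria a [regime_criteria()] object.
#' @return One of `"RS"`, `"ST"`, `"TS"`, `"BURSTING"`, `"SLE"`, `"SIA"`,
#'   `"DB"`.
#' @export
classify_regime <- function(trace, spike_threshold = -25,
                            criteria = regime_criteria()) {
  cr <- criteria
  t <- trace$t_ms
  V <- trace$V_mV
  T_end <- t[length(t)]
  if (T_end - t[1] < 10000) {
    stop("trace too short to classify reliably (need >= 10 s)")
  }
  st <- detect_spikes(trace, spike_threshold)
  st <- st[st > cr$discard]
  v_final <- mean(V[t > T_end - cr$final_window])

  if (length(st) == 0) {
    if (v_final < cr$rest_v_max) return("RS")
    if (v_final > cr$db_v_min) return("DB")
    return("SIA")
  }
  if (st[length(st)] < 0.5 * T_end && v_final > cr$db_v_min) return("DB")
  if (st[length(st)] < cr$st_frac * T_end) return("ST")
  if (length(st) < 3) return("ST")

  isi <- diff(st)
  med <- stats::median(isi)
  cv <- stats::sd(isi) / mean(isi)

  ## long depolarized events separated by long quiescence
  cl <- .spike_clusters(st, cr$sle_min_quiet)
  if (length(cl) >= 2) {
    durs <- vapply(cl, function(x) x[length(x)] - x[1], numeric(1))
    if (stats::median(durs) >= cr$sle_min_event) return("SLE")
    if (max(durs) < cr$burst_max_dur) return("BURSTING")
    return("SLE")
  }

  ## bimodal ISI: iterate the intra-cluster gap threshold to a fixed point
  g <- cr$burst_gap_factor * med
  for (i in 1:3) {
    intra <- isi[isi <= g]
    if (length(intra) == 0) break
    g_new <- cr$burst_gap_factor * stats::median(intra)
    if (abs(g_new - g) < 1e-9) break
    g <- g_new
  }
  cl2 <- .spike_clusters(st, g)
  if (length(cl2) >= 3) {
    durs2 <- vapply(cl2, function(x) x[length(x)] - x[1], numeric(1))
    sizes <- vapply(cl2, length, integer(1))
    if (max(durs2) < cr$burst_max_dur && any(sizes > 1)) return("BURSTING")
  }

  persists <- (T_end - st[length(st)]) < max(cr$tonic_gap_factor * med,
                                             cr$sle_min_quiet)
  if (persists && cv < cr$tonic_cv_max && max(isi) <= cr$tonic_gap_factor * med) {
    return("TS")
  }
  if (persists && cv >= cr$tonic_cv_max && v_final > cr$sia_v_min) return("SIA")
  if (persists) {
    return(if (v_final > cr$sia_v_min) "SIA" else "TS")
  }
  if (st[length(st)] < 0.5 * T_end) return("ST")
  if (v_final > cr$sia_v_min) "SIA" else "TS"
}

#' Sweep the bath potassium concentration and classify each regime
#'
#' Simulates one cell per `K_bath` value and applies [classify_regime()].
#'
#' @param k_bath vector of bath concentrations (mM).
#' @param T duration per point (ms); default 10000.
#' @param dt step (ms).
#' @param params_fn function mapping a `K_bath` value to a [cell_params()]
#'   object, by default `cell_params`.
#' @param spike_threshold detection threshold (mV).
#' @param criteria a [regime_criteria()].
#' @param record_every trace down-sampling for classification (default every
#'   20th step, i.e. 0.5 ms at dt = 0.025).
#' @return data.frame with `K_bath`, `regime`, `n_spikes`.
#' @export
regime_sweep <- function(k_bath, T = 10000, dt = 0.025,
                         params_fn = cell_params, spike_threshold = -25,
                         criteria = regime_criteria(), record_every = 20L) {
  res <- lapply(k_bath, function(kb) {
    tr <- simulate_cell(params_fn(K_bath = kb), T = T, dt = dt,
                        record_every = record_every)
    st <- detect_spikes(tr, spike_threshold)
    data.frame(K_bath = kb,
               regime = classify_regime(tr, spike_threshold, criteria),
               n_spikes = length(st))
  })
  do.call(rbind, res)
}
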