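## Seizure detection on region activity traces, onset timing and
## propagation-latency mapping.

#' Seizure detection criteria
#'
#' A region is recruited when its activity exceeds the baseline by at least
#' `rel_threshold` (default 0.55, i.e. a 55% increase over the resting
#' value); the onset is the first local maximum above that level.
#'
#' @param rel_threshold fractional increase over baseline.
#' @param baseline_window `c(t0, t1)` (ms) over which the baseline is
#'   averaged; must precede the detection window.
#' @param smooth_width optional moving-average width (ms); `NULL` = none.
#' @return Object of class `seizure_criteria`.
#' @export
seizure_criteria <- function(rel_threshold = 0.55, baseline_window = NULL,
                             smooth_width = NULL) {
  stopifnot(rel_threshold > 0)
  structure(list(rel_threshold = rel_threshold,
                 baseline_window = baseline_window,
                 smooth_width = smooth_width),
            class = "seizure_criteria")
}

#' Baseline activity of a trace
#'
#' Mean activity over a window, intended to lie after the simulation
#' transient and before any seizure.
#'
#' @param trace data.frame with `t_ms` and `nu` (or a bare numeric vector
#'   with `t` supplied).
#' @param window `c(t0, t1)` (ms).
#' @param t time vector for bare numeric traces.
#' @param transient start of valid data (ms); a window reaching into it
#'   triggers a warning.
#' @return Scalar baseline.
#' @export
baseline_activity <- function(trace, window, t = NULL, transient = 0) {
  if (is.data.frame(trace)) {
    t <- trace$t_ms
    v <- trace$nu
  } else {
    v <- trace
  }
  stopifnot(length(t) == length(v), window[2] > window[1])
  if (window[1] < t[1] || window[2] > t[length(t)]) {
    stop("baseline window outside trace")
  }
  if (window[1] < transient) {
    warning("baseline window overlaps the discarded transient")
  }
  mean(v[t >= window[1] & t <= window[2]])
}

## first local maximum (three-point comparison) at or above level, after the
## first crossing of the level
.first_peak_above <- function(t, v, level) {
  above <- which(v >= level)
  if (length(above) == 0) return(NA_real_)
  start <- above[1]
  n <- length(v)
  for (i in seq(max(start, 2), n - 1)) {
    if (v[i] >= level && v[i] >= v[i - 1] && v[i] > v[i + 1]) return(t[i])
    if (v[i] >= level && v[i] > v[i - 1] && v[i] >= v[i + 1]) return(t[i])
  }
  ## plateau or monotone to the end: take the maximum sample
  t[which.max(v)]
}

#' Detect a seizure on an activity trace
#'
#' A seizure is present when the trace reaches `(1 + rel_threshold) *
#' baseline`; its onset is the time of the first local maximum above that
#' level (three-point comparison on the sampled trace).
#'
#' @param trace data.frame with `t_ms`, `nu`.
#' @param baseline scalar baseline (see [baseline_activity()]).
#' @param criteria a [seizure_criteria()].
#' @param search_window optional `c(t0, t1)` restricting the detection.
#' @return Onset time (ms), or `NA` when no seizure is detected.
#' @export
detect_seizure <- function(trace, baseline, criteria = seizure_criteria(),
                           search_window = NULL) {
  stopifnot(baseline > 0)
  t <- trace$t_ms
  v <- trace$nu
  if (!is.null(criteria$smooth_width) && criteria$smooth_width > 0) {
    dt <- stats::median(diff(t))
    k <- max(1L, round(criteria$smooth_width / dt))
    v <- stats::filter(v, rep(1 / k, k), sides = 2)
    keep <- !is.na(v)
    t <- t[keep]; v <- as.numeric(v[keep])
  }
  if (!is.null(search_window)) {
    keep <- t >= search_window[1] & t <= search_window[2]
    t <- t[keep]; v <- v[keep]
  }
  level <- (1 + criteria$rel_threshold) * baseline
  if (length(v) == 0 || max(v) < level) return(NA_real_)
  .first_peak_above(t, v, level)
}

#' Per-region seizure onsets
#'
#' Applies [detect_seizure()] to every region of a mass-model activity
#' result, with region-specific baselines computed over a shared window.
#'
#' @param sim result of [simulate_rww()] / [run_cosim()] (`t_ms` + `nu`
#'   matrix).
#' @param baseline_window `c(t0, t1)` (ms).
#' @param criteria a [seizure_criteria()].
#' @param search_window optional detection window.
#' @param exclude region labels to skip (e.g. the proxy region itself).
#' @return Named numeric vector of onset times (NA = not recruited).
#' @export
seizure_onsets <- function(sim, baseline_window,
                           criteria = seizure_criteria(),
                           search_window = NULL, exclude = character(0)) {
  regions <- colnames(sim$nu)
  onsets <- vapply(regions, function(rg) {
    if (rg %in% exclude) return(NA_real_)
    tr <- data.frame(t_ms = sim$t_ms, nu = sim$nu[, rg])
    b <- baseline_activity(tr, baseline_window)
    detect_seizure(tr, b, criteria, search_window)
  }, numeric(1))
  onsets
}

#' Propagation-latency map
#'
#' Latency of seizure arrival in each region relative to the source:
#' `latency_J = onset_J - onset_source`.  Regions without a detected onset
#' are marked not recruited.
#'
#' @param onsets named vector of onset times (ms), NA = not recruited.
#' @param source name (or index) of the source region; must be recruited.
#' @return data.frame of class `propagation_map` with `region`,
#'   `latency_ms`, `recruited`.
#' @export
propagation_map <- function(onsets, source) {
  if (is.numeric(source)) source <- names(onsets)[source]
  if (!source %in% names(onsets)) stop("unknown source region: ", source)
  if (is.na(onsets[source])) stop("source region has no detected seizure onset")
  lat <- onsets - onsets[[source]]
  structure(data.frame(region = names(onsets),
                       latency_ms = unname(lat),
                       recruited = !is.na(lat),
                       row.names = NULL),
            class = c("propagation_map", "data.frame"),
            source = source)
}

#' Write a propagation map as CSV (region, latency_ms, recruited)
#' @param map a [propagation_map()].
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_propagation_csv <- function(map, path) {
  utils::write.csv(map, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
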