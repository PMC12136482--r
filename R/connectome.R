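## Structural connectome container and I/O: weights, tract lengths, derived
## delays.  Readers accept TVB-style directories/zips (whitespace-delimited
## weights.txt / tract_lengths.txt / centres.txt) and plain CSV matrix pairs.

#' Construct a connectome
#'
#' @param weights square non-negative matrix `c_IK` (row I receives from K).
#' @param tract_lengths square matrix of tract lengths (mm).
#' @param labels region names; default `R1..Rn`.
#' @param speed conduction speed (mm/ms); default 3.
#' @return Object of class `connectome` with derived `delays` (ms) and
#'   `tau_min`, the smallest positive inter-region delay after replacing
#'   zero-length connected tracts is left to the simulation step (zero
#'   delays are treated as one integration step).
#' @export
connectome <- function(weights, tract_lengths, labels = NULL, speed = 3) {
  weights <- as.matrix(weights)
  tract_lengths <- as.matrix(tract_lengths)
  n <- nrow(weights)
  if (ncol(weights) != n) stop("weights matrix must be square")
  if (!all(dim(tract_lengths) == c(n, n))) {
    stop("tract_lengths shape ", paste(dim(tract_lengths), collapse = "x"),
         " does not match weights ", n, "x", n)
  }
  if (any(weights < 0)) stop("negative connectome weights")
  if (any(tract_lengths < 0)) stop("negative tract lengths")
  if (is.null(labels)) labels <- paste0("R", seq_len(n))
  stopifnot(length(labels) == n, speed > 0)
  delays <- tract_lengths / speed
  off <- delays[row(delays) != col(delays)]
  conn <- weights[row(weights) != col(weights)] > 0
  pos <- off[conn & off > 0]
  tau_min <- if (length(pos)) min(pos) else NA_real_
  dimnames(weights) <- dimnames(tract_lengths) <- dimnames(delays) <-
    list(labels, labels)
  structure(list(labels = labels, weights = weights,
                 tract_lengths = tract_lengths, speed = speed,
                 delays = delays, tau_min = tau_min),
            class = "connectome")
}

#' @export
print.connectome <- function(x, ...) {
  cat("connectome:", length(x$labels), "regions,",
      sum(x$weights[row(x$weights) != col(x$weights)] > 0), "edges,",
      "tau_min =", signif(x$tau_min, 4), "ms\n")
  invisible(x)
}

#' Read a connectome from disk
#'
#' Accepts a TVB-style layout (directory or zip containing whitespace
#' delimited `weights.txt`, `tract_lengths.txt` and optional `centres.txt`)
#' or a pair of CSV matrices `weights.csv` / `tract_lengths.csv` (with
#' optional header row of region labels).
#'
#' @param path directory, zip file, or directory containing the CSV pair.
#' @param speed conduction speed (mm/ms) used to derive delays.
#' @return A [connectome()].
#' @export
read_connectome <- function(path, speed = 3) {
  if (grepl("\\.zip$", path)) {
    ex <- tempfile("conn")
    utils::unzip(path, exdir = ex)
    inner <- list.dirs(ex, recursive = FALSE)
    path <- if (length(inner) == 1 &&
                !file.exists(file.path(ex, "weights.txt"))) inner else ex
  }
  if (!dir.exists(path)) stop("no such connectome directory: ", path)
  txt_w <- file.path(path, "weights.txt")
  csv_w <- file.path(path, "weights.csv")
  if (file.exists(txt_w)) {
    w <- as.matrix(utils::read.table(txt_w))
    tl <- as.matrix(utils::read.table(file.path(path, "tract_lengths.txt")))
    labels <- NULL
    cfile <- file.path(path, "centres.txt")
    if (file.exists(cfile)) {
      labels <- utils::read.table(cfile, stringsAsFactors = FALSE)[, 1]
    }
  } else if (file.exists(csv_w)) {
    w <- as.matrix(utils::read.csv(csv_w, header = TRUE, row.names = NULL))
    tl <- as.matrix(utils::read.csv(file.path(path, "tract_lengths.csv"),
                                    header = TRUE, row.names = NULL))
    labels <- colnames(w)
  } else {
    stop("no weights.txt or weights.csv under ", path)
  }
  dimnames(w) <- dimnames(tl) <- NULL
  connectome(w, tl, labels = labels, speed = speed)
}

#' Write a connectome
#'
#' TVB-style directory with `weights.txt`, `tract_lengths.txt`,
#' `centres.txt`; round-trips losslessly through [read_connectome()] at full
#' double precision.
#'
#' @param conn a [connectome()].
#' @param path output directory (created if missing).
#' @return `path`, invisibly.
#' @export
write_connectome <- function(conn, path) {
  dir.create(path, showWarnings = FALSE, recursive = TRUE)
  fmt <- function(m) apply(m, 1, function(r) paste(sprintf("%.17g", r), collapse = " "))
  writeLines(fmt(conn$weights), file.path(path, "weights.txt"))
  writeLines(fmt(conn$tract_lengths), file.path(path, "tract_lengths.txt"))
  writeLines(paste(conn$labels, "0 0 0"), file.path(path, "centres.txt"))
  invisible(path)
}

#' Synthetic connectome generator
#'
#' Emulates a ~100-region mammalian whole-brain structural connectome:
#' log-normally distributed weights, uniformly distributed positive tract
#' lengths, optional mirrored left/right hemisphere blocks (regions `1..n/2`
#' left, `n/2+1..n` right, with both within- and cross-hemisphere blocks
#' copied between hemispheres).
#'
#' @param n_regions number of regions (default 98; forced even when
#'   `symmetric`).
#' @param density fraction of off-diagonal entries with a connection.
#' @param weight_meanlog,weight_sdlog log-normal weight parameters.
#' @param length_range tract-length range (mm).
#' @param symmetric mirror the hemisphere blocks.
#' @param speed conduction speed (mm/ms).
#' @param seed RNG seed; the generator is deterministic given the seed.
#' @return A [connectome()] with labels `L1..L<n/2>`, `R1..R<n/2>` when
#'   symmetric.
#' @export
synthetic_connectome <- function(n_regions = 98, density = 0.3,
                                 weight_meanlog = -2.5, weight_sdlog = 1,
                                 length_range = c(6, 60), symmetric = TRUE,
                                 speed = 3, seed = 1L) {
  stopifnot(n_regions >= 2, density >= 0, density <= 1)
  if (symmetric && n_regions %% 2 != 0) {
    stop("hemisphere symmetry requires an even region count")
  }
  rs <- .with_seed(seed, {
    n <- n_regions
    mask <- matrix(stats::runif(n * n) < density, n, n)
    w <- matrix(stats::rlnorm(n * n, weight_meanlog, weight_sdlog), n, n) * mask
    ## lengths snapped to a 0.3 mm grid so delays are exact multiples of
    ## 0.1 ms at the default conduction speed (the mass-model step must
    ## evenly divide tau_min)
    tl <- matrix(stats::runif(n * n, length_range[1], length_range[2]), n, n)
    tl <- round(tl / 0.3) * 0.3
    diag(w) <- 0
    diag(tl) <- 0
    if (symmetric) {
      h <- n / 2
      L <- seq_len(h); R <- h + L
      ## mirror the left-hemisphere blocks onto the right
      w[R, R] <- w[L, L]; tl[R, R] <- tl[L, L]
      w[R, L] <- w[L, R]; tl[R, L] <- tl[L, R]
    }
    tl[w > 0 & tl <= 0] <- mean(length_range)
    list(w = w, tl = tl)
  })
  labels <- if (symmetric) {
    h <- n_regions / 2
    c(paste0("L", seq_len(h)), paste0("R", seq_len(h)))
  } else {
    paste0("R", seq_len(n_regions))
  }
  connectome(rs$w, rs$tl, labels = labels, speed = speed)
}

## evaluate expr under a local RNG seed without disturbing the global stream
.with_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()), add = TRUE)
  }
  set.seed(seed)
  expr
}

#' Write a run manifest
#'
#' JSON record of the resolved configuration, seeds and package version from
#' which a stochastic run can be reproduced exactly.
#'
#' @param config named list of resolved configuration values.
#' @param seeds named list/vector of every RNG seed used; missing or NULL
#'   seeds are an error.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_manifest <- function(config, seeds, path) {
  if (length(seeds) == 0 || any(vapply(seeds, is.null, logical(1))) ||
      any(is.na(unlist(seeds)))) {
    stop("every seed must be recorded in the manifest")
  }
  manifest <- list(
    package = "braincosim",
    version = as.character(utils::packageVersion("braincosim")),
    created = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
    seeds = as.list(seeds),
    config = config
  )
  jsonlite::write_json(manifest, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, null = "null")
  invisible(path)
}

#' Read a run manifest
#' @param path manifest file written by [write_manifest()].
#' @return Named list.
#' @export
read_manifest <- function(path) {
  jsonlite::read_json(path, simplifyVector = TRUE)
}

#' Write an activity trace in long format
#'
#' Columns `t_ms`, `region`, `S`, `nu` — one row per time sample and region.
#'
#' @param sim result of [simulate_rww()] (or any list with `t_ms`, `S`, `nu`).
#' @param path output CSV.
#' @return `path`, invisibly.
#' @export
write_activity_csv <- function(sim, path) {
  regions <- colnames(sim$nu)
  if (is.null(regions)) regions <- paste0("R", seq_len(ncol(sim$nu)))
  long <- data.frame(
    t_ms = rep(sim$t_ms, times = length(regions)),
    region = rep(regions, each = length(sim$t_ms)),
    S = as.vector(sim$S),
    nu = as.vector(sim$nu)
  )
  utils::write.csv(long, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Write / read a spike raster as two-column text (gid, t_ms)
#' @param raster data.frame with `gid`, `t_ms`.
#' @param path output file.
#' @return `path` invisibly (writer); data.frame (reader).
#' @export
write_raster <- function(raster, path) {
  utils::write.table(raster[, c("gid", "t_ms")], path, row.names = FALSE,
                     col.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_raster
#' @export
read_raster <- function(path) {
  if (file.size(path) == 0) return(data.frame(gid = integer(0), t_ms = numeric(0)))
  r <- utils::read.table(path, col.names = c("gid", "t_ms"))
  r$gid <- as.integer(r$gid)
  r
}
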