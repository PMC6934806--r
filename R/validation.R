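#' Bootstrap surrogate threshold for directed connectivity
#'
#' Window-shuffling surrogates: the time series is divided into
#' non-overlapping windows (default one second) whose order is shuffled
#' independently per channel, destroying lagged cross-channel structure
#' while preserving per-channel marginal spectra. Per surrogate the MVAR is
#' refitted at the same order and the band-mean RPDC recomputed. The
#' threshold per connection is the mean over the surrogate values; the
#' empirical 95th percentile is stored alongside, as is the full surrogate
#' set (needed by the time-reversal noise floor).
#'
#' @param signals sources x samples matrix, 3-d array or `pooled_sources`.
#' @param order MVAR order used for the observed fit.
#' @param band band name or one-row band data.frame.
#' @param n_boot number of surrogates (default 100, >= 20 required).
#' @param window_len shuffle window in samples (default 1 s of samples).
#' @param seed integer seed.
#' @param fs sampling rate (Hz).
#' @param freqs frequency grid for RPDC (defaults to the band's bins at
#'   0.25 Hz).
#' @return object of class `surrogate_threshold` with `mean`, `p95`
#'   (d x d matrices), `surrogates` (d x d x n_boot), `band`, `window_len`.
#' @export
bootstrap_threshold <- function(signals, order, band, n_boot = 100L,
                                window_len = NULL, seed = NULL, fs = NULL,
                                freqs = NULL) {
  x <- as_signal_array(signals)
  if (is.null(fs)) fs <- attr(x, "fs")
  if (is.null(fs)) stop("sampling rate 'fs' is required")
  if (is.character(band)) band <- band_by_name(band)
  if (n_boot < 20L) stop("'n_boot' must be >= 20")
  d <- dim(x)[1L]
  y <- matrix(x, d, dim(x)[2L] * dim(x)[3L])
  if (is.null(window_len)) window_len <- round(fs)
  nwin <- floor(ncol(y) / window_len)
  if (nwin < 10L) stop("signal shorter than 10 shuffle windows")
  if (is.null(freqs)) freqs <- seq(band$lo, band$hi, by = 0.25)
  if (!is.null(seed)) set.seed(seed)
  y <- y[, seq_len(nwin * window_len), drop = FALSE]
  surr <- array(NA_real_, dim = c(d, d, n_boot))
  failures <- 0L
  for (b in seq_len(n_boot)) {
    ys <- y
    for (ch in seq_len(d)) {
      ord <- sample.int(nwin)
      idx <- as.vector(outer(seq_len(window_len), (ord - 1L) * window_len, `+`))
      ys[ch, ] <- y[ch, idx]
    }
    bm <- tryCatch(
      band_mean(rpdc(fit_var(ys, order), freqs = freqs, fs = fs), band),
      error = function(e) NULL)
    if (is.null(bm)) failures <- failures + 1L else surr[, , b] <- bm
  }
  if (failures > 0.2 * n_boot)
    stop("MVAR refit failed for more than 20% of surrogates")
  structure(list(mean = apply(surr, c(1L, 2L), mean, na.rm = TRUE),
                 p95 = apply(surr, c(1L, 2L), stats::quantile, probs = 0.95,
                             na.rm = TRUE, names = FALSE),
                 surrogates = surr, n_surrogates = n_boot,
                 window_len = window_len, band = band),
            class = "surrogate_threshold")
}

#' @export
print.surrogate_threshold <- function(x, ...) {
  cat(sprintf("Surrogate thresholds: %d surrogates, window %d samples, band [%g, %g] Hz\n",
              x$n_surrogates, x$window_len, x$band$lo, x$band$hi))
  invisible(x)
}

#' Apply surrogate thresholds to band-mean connectivity
#'
#' An edge passes when its observed band-mean strength exceeds its
#' threshold under the chosen rule (`"mean"` of the surrogate distribution
#' -- the default -- or its 95th percentile `"p95"`). Each unordered pair is
#' then classified: both directions pass = bidirectional, one =
#' unidirectional, none = none.
#'
#' @param conn_band_means d x d matrix of observed band-mean directed
#'   strengths (NA diagonal).
#' @param thresholds a `surrogate_threshold`.
#' @param rule `"mean"` or `"p95"`.
#' @return object of class `directed_network` with an `edges` data.frame
#'   (from, to, strength, threshold, surrogate_pass, trt_pass) and
#'   `pair_direction` (data.frame: node_a, node_b, direction).
#' @export
apply_thresholds <- function(conn_band_means, thresholds, rule = c("mean", "p95")) {
  rule <- match.arg(rule)
  thr <- thresholds[[rule]]
  if (!all(dim(conn_band_means) == dim(thr)))
    stop("connectivity and threshold dimensions do not match")
  d <- nrow(conn_band_means)
  from <- rep(seq_len(d), each = d); to <- rep(seq_len(d), d)
  keep <- from != to
  edges <- data.frame(from = from[keep], to = to[keep])
  edges$strength <- conn_band_means[cbind(edges$to, edges$from)]
  edges$threshold <- thr[cbind(edges$to, edges$from)]
  if (any(is.na(edges$threshold)))
    stop("missing surrogate threshold for a present edge")
  edges$surrogate_pass <- edges$strength > edges$threshold
  edges$trt_pass <- NA
  pairs <- unique(t(apply(cbind(edges$from, edges$to), 1L, sort)))
  dir <- character(nrow(pairs))
  for (r in seq_len(nrow(pairs))) {
    a <- pairs[r, 1L]; b <- pairs[r, 2L]
    fwd <- edges$surrogate_pass[edges$from == a & edges$to == b]
    rev <- edges$surrogate_pass[edges$from == b & edges$to == a]
    dir[r] <- if (fwd && rev) "bidirectional" else if (fwd || rev) "unidirectional" else "none"
  }
  structure(list(edges = edges,
                 pair_direction = data.frame(node_a = pairs[, 1L],
                                             node_b = pairs[, 2L],
                                             direction = dir),
                 rule = rule, band = thresholds$band),
            class = "directed_network")
}

#' @export
print.directed_network <- function(x, ...) {
  ns <- sum(x$edges$surrogate_pass)
  nt <- sum(x$edges$trt_pass %in% TRUE)
  cat(sprintf("Directed network (band [%g, %g] Hz, rule '%s'): %d/%d edges pass surrogates, %d pass TRT\n",
              x$band$lo, x$band$hi, x$rule, ns, nrow(x$edges), nt))
  print(x$pair_direction)
  invisible(x)
}

#' Time-reversal test (TRT) on surrogate-passing edges
#'
#' Genuinely lagged (causal) interactions reverse their direction when the
#' signals are time-reversed, while instantaneous (volume-conduction-like)
#' effects do not. The signals are reversed along time, the MVAR refitted,
#' and band-mean directed strengths recomputed. For each unordered pair
#' with at least one surrogate-passing edge, the asymmetry
#' `delta = strength(i <- j) - strength(j <- i)` is computed on the
#' original and the reversed data; the edge keeps `trt_pass = TRUE` iff the
#' reversed asymmetry flips sign and the original asymmetry exceeds a
#' noise floor. The floor is the larger of (a) the standard deviation of
#' the asymmetry across the surrogate set and (b) `floor_scale` times the
#' sampling standard deviation of the asymmetry implied by the
#' approximately noncentral-chi-squared distribution of the RPDC statistic
#' (`2 sqrt(s_ij + s_ji)`). Pairs whose original asymmetry is below the
#' floor are reported as indeterminate (`trt_pass = NA`), not failed.
#'
#' @param signals the original signals used for `network`.
#' @param network a `directed_network` from [apply_thresholds()].
#' @param order MVAR order.
#' @param band band name or data.frame (must match the network's band).
#' @param thresholds the `surrogate_threshold` used (contributes its
#'   surrogate-asymmetry spread to the noise floor); optional.
#' @param fs sampling rate.
#' @param freqs frequency grid for RPDC.
#' @param floor_scale multiplier on the sampling-noise floor (default 3).
#' @return the `directed_network` with `trt_pass` set and `pair_direction`
#'   recomputed from edges surviving both tests.
#' @export
time_reversal_test <- function(signals, network, order, band,
                               thresholds = NULL, fs = NULL, freqs = NULL,
                               floor_scale = 3) {
  stopifnot(inherits(network, "directed_network"))
  x <- as_signal_array(signals)
  if (is.null(fs)) fs <- attr(x, "fs")
  if (is.null(fs)) stop("sampling rate 'fs' is required")
  if (is.character(band)) band <- band_by_name(band)
  if (is.null(freqs)) freqs <- seq(band$lo, band$hi, by = 0.25)
  if (!any(network$edges$surrogate_pass)) {
    network$edges$trt_pass <- FALSE
    return(network)
  }
  fwd <- band_mean(rpdc(fit_var(x, order), freqs = freqs, fs = fs), band)
  xr <- x[, rev(seq_len(dim(x)[2L])), rev(seq_len(dim(x)[3L])), drop = FALSE]
  rev_bm <- band_mean(rpdc(fit_var(xr, order), freqs = freqs, fs = fs), band)
  edges <- network$edges
  floor_sd <- function(i, j) {
    samp <- floor_scale * 2 * sqrt(max(fwd[i, j] + fwd[j, i], 0))
    if (is.null(thresholds)) return(samp)
    dd <- thresholds$surrogates[i, j, ] - thresholds$surrogates[j, i, ]
    max(stats::sd(dd, na.rm = TRUE), samp)
  }
  for (r in seq_len(nrow(edges))) {
    if (!edges$surrogate_pass[r]) { edges$trt_pass[r] <- FALSE; next }
    i <- edges$to[r]; j <- edges$from[r]
    d_orig <- fwd[i, j] - fwd[j, i]
    d_rev <- rev_bm[i, j] - rev_bm[j, i]
    nf <- floor_sd(i, j)
    if (abs(d_orig) <= nf) {
      edges$trt_pass[r] <- NA              # indeterminate (symmetric pair)
    } else {
      edges$trt_pass[r] <- sign(d_rev) == -sign(d_orig)
    }
  }
  network$edges <- edges
  pd <- network$pair_direction
  for (r in seq_len(nrow(pd))) {
    a <- pd$node_a[r]; b <- pd$node_b[r]
    fwd_ok <- with(edges, surrogate_pass[from == a & to == b] &
                     (trt_pass[from == a & to == b] %in% c(TRUE, NA)))
    rev_ok <- with(edges, surrogate_pass[from == b & to == a] &
                     (trt_pass[from == b & to == a] %in% c(TRUE, NA)))
    pd$direction[r] <- if (fwd_ok && rev_ok) "bidirectional"
      else if (fwd_ok || rev_ok) "unidirectional" else "none"
  }
  network$pair_direction <- pd
  network
}

#' Export a directed network as an edge-list text table
#'
#' @param network a `directed_network`.
#' @param path file path; tab-separated text with a header row.
#' @return the path, invisibly.
#' @export
export_edges <- function(network, path) {
  stopifnot(inherits(network, "directed_network"))
  tab <- network$edges
  tab$band_lo <- network$band$lo
  tab$band_hi <- network$band$hi
  utils::write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
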