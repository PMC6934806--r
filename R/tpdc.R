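#' Dual extended Kalman filter configuration
#'
#' Filter tuning for [dekf_tvar()]. The coefficient dynamics are a random
#' walk with process-noise scale `q`, normalized internally by the regressor
#' power so that `q` sets the filter's effective averaging window (about
#' `1/sqrt(q)` samples) independently of the signal scale. `r_scale` scales
#' the coefficient-filter measurement noise and `r_state` the state-filter
#' observation noise, both relative to the innovation covariance of the
#' initial stationary fit.
#'
#' @param q coefficient random-walk process-noise scale (default 1e-5).
#' @param r_scale coefficient-filter measurement-noise scale, relative to
#'   the innovation covariance of the initial fit (default 1).
#' @param r_state state-filter observation-noise scale, relative to the
#'   innovation covariance (default 0.01; small values mean the recordings
#'   are trusted as near-noiseless observations of the state).
#' @param guard divergence guard on the trace of the coefficient covariance.
#' @return list of class `dekf_config`.
#' @export
dekf_config <- function(q = 1e-5, r_scale = 1, r_state = 0.01, guard = 1e8) {
  stopifnot(q > 0, r_scale > 0, r_state > 0)
  structure(list(q = q, r_scale = r_scale, r_state = r_state, guard = guard),
            class = "dekf_config")
}

#' Time-varying VAR coefficients via dual extended Kalman filtering
#'
#' Two coupled filters alternate at every sample: a state filter estimates
#' the current signal state conditioned on the current coefficient
#' estimates, and a coefficient filter (random-walk parameter model)
#' updates the stacked VAR coefficients conditioned on the filtered states.
#' Coefficients are initialized from a stationary least-squares fit on the
#' first second of data, and the first second is discarded as burn-in.
#'
#' @param signals sources x samples matrix (a continuous segment), 3-d array
#'   or `pooled_sources` (epochs are concatenated).
#' @param order VAR order p.
#' @param filter_cfg a [dekf_config()].
#' @param fs sampling rate in Hz (taken from `pooled_sources` when present);
#'   defines the 1-s initialization/burn-in span.
#' @param seed unused (the filter is deterministic); kept so pipeline stages
#'   share a uniform signature.
#' @return object of class `tvar` with `coeff_track` (time x p x d x d),
#'   `order`, `d`, `fs`, `burn_in`, `filter_cfg`.
#' @export
dekf_tvar <- function(signals, order, filter_cfg = dekf_config(), fs = NULL,
                      seed = NULL) {
  x <- as_signal_array(signals)
  if (is.null(fs)) fs <- attr(x, "fs")
  if (is.null(fs)) stop("sampling rate 'fs' is required")
  d <- dim(x)[1L]
  y <- matrix(x, d, dim(x)[2L] * dim(x)[3L])  # concatenate epochs
  p <- as.integer(order)
  n <- ncol(y)
  if (p < 1L) stop("'order' must be >= 1")
  if (n < 10L * p * d) stop("signal too short for DEKF (need >= 10 * order * d samples)")
  init_len <- min(max(round(fs), p * d * 4L), n - 1L)
  init <- fit_var(y[, seq_len(init_len), drop = FALSE], p)
  nw <- d * d * p
  # w stacks the coefficient rows: w[(i-1)*d*p + (k-1)*d + j] = A_k[i, j]
  w <- unlist(lapply(seq_len(d), function(i)
    unlist(lapply(seq_len(p), function(k) init$A[[k]][i, ]))))
  # Process noise is normalized by the regressor power so that `q` sets the
  # filter's effective averaging window (about 1/sqrt(q) samples) regardless
  # of the signal scale.
  rho <- mean(y[, seq_len(init_len)]^2)
  w0_var <- max(stats::var(w), 1e-4)
  Q <- filter_cfg$q * mean(diag(init$Sigma)) / max(rho, 1e-12) * diag(nw)
  Rw <- filter_cfg$r_scale * (init$Sigma + 1e-8 * diag(d))   # coefficient filter
  Rx <- filter_cfg$r_state * (init$Sigma + 1e-8 * diag(d))   # state filter
  Qx <- init$Sigma + 1e-8 * diag(d)          # innovations drive the state
  Pw <- diag(nw) * w0_var
  dp <- d * p
  Px <- Qx
  yf <- y                                    # filtered signal states
  Id <- diag(d)
  track <- array(NA_real_, dim = c(n, p, d, d))
  for (t in (p + 1L):n) {
    A <- w_to_A(w, d, p)
    z <- as.numeric(yf[, (t - 1L):(t - p)])  # lagged filtered states
    # --- state filter (EKF 1): predict the next signal value from the
    #     current coefficients, update with the observed sample
    y_pred <- numeric(d)
    for (k in seq_len(p)) y_pred <- y_pred + A[[k]] %*% yf[, t - k]
    Pp <- A[[1L]] %*% Px %*% t(A[[1L]]) + Qx
    Kx <- Pp %*% solve(Pp + Rx)
    yf[, t] <- as.numeric(y_pred + Kx %*% (y[, t] - y_pred))
    Px <- (Id - Kx) %*% Pp
    # --- coefficient filter (EKF 2): random-walk parameter model,
    #     regressors are the lagged filtered states
    Hw <- kronecker(Id, matrix(z, 1L))       # d x nw
    Pw <- Pw + Q
    Sw <- Hw %*% Pw %*% t(Hw) + Rw
    Kw <- Pw %*% t(Hw) %*% solve(Sw)
    w <- as.numeric(w + Kw %*% (y[, t] - Hw %*% w))
    Pw <- (diag(nw) - Kw %*% Hw) %*% Pw
    if (sum(diag(Pw)) > filter_cfg$guard)
      stop("DEKF coefficient covariance diverged at sample ", t)
    Af <- w_to_A(w, d, p)
    for (k in seq_len(p)) track[t, k, , ] <- Af[[k]]
  }
  burn <- min(round(fs), n - p - 1L)
  keep <- (burn + 1L):n
  keep <- keep[keep > p]
  structure(list(coeff_track = track[keep, , , , drop = FALSE],
                 time_index = keep, order = p, d = d, fs = fs,
                 burn_in = burn, filter_cfg = filter_cfg),
            class = "tvar")
}

w_to_A <- function(w, d, p) {
  W <- matrix(w, nrow = d * p, ncol = d)    # column i = row i of coefficients
  lapply(seq_len(p), function(k) t(W[(k - 1L) * d + seq_len(d), , drop = FALSE]))
}

#' @export
print.tvar <- function(x, ...) {
  cat(sprintf("Time-varying VAR(%d): %d signals, %d retained samples @ %g Hz (burn-in %d)\n",
              x$order, x$d, dim(x$coeff_track)[1L], x$fs, x$burn_in))
  invisible(x)
}

#' Time-resolved PDC from a time-varying VAR
#'
#' Applies the PDC formula to the coefficient matrices at each retained time
#' index (optionally strided), yielding a target x source x frequency x time
#' array, the per-connection band-mean time courses, and the per-connection
#' temporal standard deviation of those courses. Time points with a
#' degenerate column are marked missing; more than 10% missing raises an
#' error.
#'
#' @param tvar a `tvar` from [dekf_tvar()].
#' @param freqs frequency grid in Hz.
#' @param bands band table for the band summaries (default
#'   [canonical_bands()]).
#' @param stride evaluate every `stride`-th retained sample (default 1).
#' @return object of class `tpdc_array` with `values` (d x d x freq x time),
#'   `freqs`, `times` (sample indices), `band_summary` (named list of d x d
#'   x time arrays) and `temporal_sd` (named list of d x d matrices).
#' @export
tpdc_from_tvar <- function(tvar, freqs, bands = canonical_bands(), stride = 1L) {
  stopifnot(inherits(tvar, "tvar"))
  if (length(freqs) == 0L) stop("empty frequency grid")
  ti <- seq(1L, dim(tvar$coeff_track)[1L], by = stride)
  d <- tvar$d; p <- tvar$order
  nv <- array(NA_real_, dim = c(d, d, length(freqs), length(ti)))
  n_missing <- 0L
  for (s in seq_along(ti)) {
    A <- lapply(seq_len(p), function(k) tvar$coeff_track[ti[s], k, , ])
    Abar <- coeff_fourier_matrices(A, freqs, tvar$fs)
    denom <- sqrt(apply(abs(Abar)^2, c(2L, 3L), sum))
    bad <- denom < .Machine$double.eps
    if (any(bad)) { n_missing <- n_missing + 1L; denom[bad] <- NA_real_ }
    for (fi in seq_along(freqs))
      nv[, , fi, s] <- sweep(abs(Abar[, , fi, drop = FALSE][, , 1L]), 2L,
                             denom[, fi], `/`)
  }
  if (n_missing > 0.1 * length(ti))
    stop("more than 10% of time points have degenerate PDC columns")
  bands <- bands[bands$lo <= max(freqs) & bands$hi >= min(freqs), , drop = FALSE]
  band_summary <- list(); temporal_sd <- list()
  for (b in seq_len(nrow(bands))) {
    idx <- band_bins(freqs, bands$lo[b], bands$hi[b])
    if (length(idx) == 0L) next
    course <- apply(nv[, , idx, , drop = FALSE], c(1L, 2L, 4L), mean)
    sdmat <- apply(course, c(1L, 2L), sd_pop)
    diag(sdmat) <- NA_real_
    band_summary[[bands$name[b]]] <- course
    temporal_sd[[bands$name[b]]] <- sdmat
  }
  structure(list(values = nv, freqs = freqs, times = tvar$time_index[ti],
                 band_summary = band_summary, temporal_sd = temporal_sd,
                 fs = tvar$fs),
            class = "tpdc_array")
}

# Population (1/n) standard deviation, the convention used for temporal
# variability of band-mean courses.
sd_pop <- function(x) {
  x <- x[is.finite(x)]
  if (length(x) == 0L) return(NA_real_)
  sqrt(mean((x - mean(x))^2))
}

#' @export
print.tpdc_array <- function(x, ...) {
  d <- dim(x$values)
  cat(sprintf("tPDC array: %d x %d connections, %d frequencies x %d time points\n",
              d[1], d[2], d[3], d[4]))
  invisible(x)
}

#' Temporal variability of directed connectivity
#'
#' The standard deviation over time (population convention) of the
#' band-mean directed strength, per ordered source pair. This is the
#' quantity whose group contrast separates a high-modulation (patient-like)
#' cohort from a stable (control-like) one.
#'
#' @param tpdc_array a `tpdc_array`.
#' @param band band name or one-row band data.frame.
#' @return list with `sd` (d x d matrix, `NA` diagonal) and `table`
#'   (long-format data.frame: from, to, temporal_sd).
#' @export
temporal_variability <- function(tpdc_array, band) {
  stopifnot(inherits(tpdc_array, "tpdc_array"))
  if (!is.character(band)) band <- band$name
  course <- tpdc_array$band_summary[[band]]
  if (is.null(course)) stop("no band summary for band '", band, "'")
  if (dim(course)[3L] < 2L) stop("temporal variability needs more than one time point")
  sdmat <- apply(course, c(1L, 2L), sd_pop)
  diag(sdmat) <- NA_real_
  d <- nrow(sdmat)
  idx <- which(!is.na(sdmat), arr.ind = TRUE)
  tab <- data.frame(from = idx[, 2L], to = idx[, 1L],
                    temporal_sd = sdmat[idx])
  list(sd = sdmat, table = tab)
}
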