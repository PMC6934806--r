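#' Canonical frequency bands
#'
#' The five canonical resting-state oscillation bands: delta (1-3 Hz), theta
#' (4-7 Hz), alpha (8-13 Hz), beta (14-30 Hz) and gamma (30-49 Hz).
#'
#' @return data.frame with columns `name`, `lo`, `hi` (Hz).
#' @export
canonical_bands <- function() {
  data.frame(name = c("delta", "theta", "alpha", "beta", "gamma"),
             lo   = c(1, 4, 8, 14, 30),
             hi   = c(3, 7, 13, 30, 49),
             stringsAsFactors = FALSE)
}

band_by_name <- function(name, bands = canonical_bands()) {
  i <- match(name, bands$name)
  if (is.na(i)) stop("unknown band: ", name)
  bands[i, , drop = FALSE]
}

# Cosine-tapered (Tukey) window; `alpha` is the total taper fraction.
tukey_window <- function(n, alpha = 0.1) {
  if (alpha <= 0) return(rep(1, n))
  if (alpha >= 1) return(0.5 * (1 - cos(2 * pi * seq(0, n - 1) / (n - 1))))
  w <- rep(1, n)
  k <- seq(0, n - 1) / (n - 1)
  lo <- k < alpha / 2
  hi <- k > 1 - alpha / 2
  w[lo] <- 0.5 * (1 + cos(pi * (2 * k[lo] / alpha - 1)))
  w[hi] <- 0.5 * (1 + cos(pi * (2 * k[hi] / alpha - 2 / alpha + 1)))
  w
}

make_taper <- function(n, taper = c("tukey01", "hann")) {
  taper <- match.arg(taper)
  if (taper == "tukey01") tukey_window(n, 0.1) else tukey_window(n, 1)
}

# Tapered, zero-padded FFT of every channel x epoch; the workhorse shared by
# power spectra and cross-spectral densities. Returns the one-sided complex
# coefficients (channels x frequencies x epochs) plus the frequency grid and
# the taper used.
epoch_ffts <- function(recording, resolution_hz = 0.25, taper = "tukey01") {
  stopifnot(inherits(recording, "epoched_recording"))
  x <- recording$data
  fs <- recording$fs
  n <- dim(x)[2L]
  nfft <- round(fs / resolution_hz)
  if (abs(nfft * resolution_hz - fs) > 1e-9)
    stop("'resolution_hz' must divide the sampling rate")
  if (nfft < n)
    stop(sprintf("resolution %.3g Hz needs %d-point support but epochs have %d samples",
                 resolution_hz, nfft, n))
  w <- make_taper(n, taper)
  nf <- floor(nfft / 2) + 1L
  freqs <- (seq_len(nf) - 1L) * resolution_hz
  out <- array(0i, dim = c(dim(x)[1L], nf, dim(x)[3L]))
  for (e in seq_len(dim(x)[3L])) {
    xe <- x[, , e, drop = FALSE]
    dim(xe) <- dim(x)[1:2]
    xe <- sweep(xe, 1L, rowMeans(xe))
    xe <- sweep(xe, 2L, w, `*`)
    pad <- cbind(xe, matrix(0, nrow(xe), nfft - n))
    X <- t(apply(pad, 1L, stats::fft))
    if (nrow(xe) == 1L) X <- matrix(X, nrow = 1L)
    out[, , e] <- X[, seq_len(nf), drop = FALSE]
  }
  list(coef = out, freqs = freqs, window = w, fs = fs, n = n, nfft = nfft)
}

#' Epoch-averaged power spectrum
#'
#' Per-epoch tapered periodograms, averaged over epochs. Each 1-s epoch is
#' demeaned, multiplied by a 10% cosine-tapered (Tukey) window and
#' zero-padded so that the FFT grid has the requested frequency resolution
#' (default 0.25 Hz, i.e. 4x padding for 1-s epochs). Power is returned as a
#' one-sided power spectral density,
#' `P(f) = 2 |X(f)|^2 / (fs * sum(w^2))` (no doubling at DC/Nyquist).
#'
#' @param recording an [epoched_recording].
#' @param resolution_hz frequency-bin spacing in Hz (default 0.25).
#' @param taper `"tukey01"` (10% cosine taper, default) or `"hann"`.
#' @return object of class `spectrum_est` with fields `freqs` (Hz) and
#'   `power` (channels x frequencies).
#' @export
power_spectrum <- function(recording, resolution_hz = 0.25, taper = "tukey01") {
  ef <- epoch_ffts(recording, resolution_hz, taper)
  scale <- 2 / (ef$fs * sum(ef$window^2))
  p <- apply(abs(ef$coef)^2, c(1L, 2L), mean) * scale
  p[, 1L] <- p[, 1L] / 2                       # DC not doubled
  if (ef$nfft %% 2L == 0L) p[, ncol(p)] <- p[, ncol(p)] / 2  # Nyquist
  structure(list(freqs = ef$freqs, power = p, fs = ef$fs,
                 resolution = resolution_hz, taper = taper,
                 channel_labels = recording$channel_labels),
            class = "spectrum_est")
}

#' @export
print.spectrum_est <- function(x, ...) {
  cat(sprintf("Power spectrum: %d channels, %d bins (%g-%g Hz @ %g Hz)\n",
              nrow(x$power), length(x$freqs), min(x$freqs), max(x$freqs),
              x$resolution))
  invisible(x)
}

#' @export
plot.spectrum_est <- function(x, channel = 1L, ...) {
  graphics::plot(x$freqs, x$power[channel, ], type = "l",
                 xlab = "Frequency (Hz)", ylab = "Power", ...)
  invisible(x)
}

band_bins <- function(freqs, lo, hi) which(freqs >= lo & freqs <= hi)

#' Mean band power per channel
#'
#' The integrated power inside a band divided by the number of frequency
#' bins it spans, i.e. the arithmetic mean of the power values at all bins
#' with `lo <= f <= hi` (both edges included).
#'
#' @param spectrum a `spectrum_est` from [power_spectrum()].
#' @param band a one-row data.frame with `lo`/`hi` in Hz, or a band name from
#'   [canonical_bands()].
#' @return named numeric vector, one value per channel.
#' @export
band_power <- function(spectrum, band) {
  stopifnot(inherits(spectrum, "spectrum_est"))
  if (is.character(band)) band <- band_by_name(band)
  idx <- band_bins(spectrum$freqs, band$lo, band$hi)
  if (length(idx) == 0L)
    stop(sprintf("band [%g, %g] Hz contains no frequency bins", band$lo, band$hi))
  out <- rowMeans(spectrum$power[, idx, drop = FALSE])
  names(out) <- spectrum$channel_labels
  out
}

#' Individual alpha frequency (IAF)
#'
#' The frequency of maximal channel-mean power inside the alpha search range.
#' A strict local maximum (larger than both spectral neighbours) is required;
#' if none exists in the range the global maximum within the range is
#' returned with `fallback = TRUE`. Ties are broken towards the lower
#' frequency.
#'
#' @param spectrum a `spectrum_est`.
#' @param search_lo,search_hi search range in Hz (default 8-13).
#' @return list with `iaf` (Hz) and `fallback` (logical).
#' @export
estimate_iaf <- function(spectrum, search_lo = 8, search_hi = 13) {
  stopifnot(inherits(spectrum, "spectrum_est"))
  freqs <- spectrum$freqs
  idx <- band_bins(freqs, search_lo, search_hi)
  if (length(idx) == 0L) stop("search range contains no frequency bins")
  m <- colMeans(spectrum$power)
  is_peak <- vapply(idx, function(i) {
    i > 1L && i < length(m) && m[i] > m[i - 1L] && m[i] > m[i + 1L]
  }, logical(1L))
  cand <- idx[is_peak]
  if (length(cand) > 0L) {
    best <- cand[which.max(m[cand])]    # which.max takes the first = lowest f
    list(iaf = freqs[best], fallback = FALSE)
  } else {
    best <- idx[which.max(m[idx])]
    list(iaf = freqs[best], fallback = TRUE)
  }
}

#' IAF-individualized frequency bands
#'
#' Rescales every canonical band edge by the individual alpha frequency:
#' each edge `e` maps to `(0.1 * e) * iaf`, so that an IAF of exactly 10 Hz
#' reproduces the canonical bands, a faster alpha rhythm widens and shifts
#' all bands up, and a slower one compresses them. For example, an IAF of
#' 10.1 Hz gives delta edges 1.01 and 3.03 Hz. The individualized gamma
#' upper edge is capped at the canonical 49 Hz and, when `fs` is supplied,
#' at `fs/2 - resolution`.
#'
#' @param iaf individual alpha frequency in Hz (> 0).
#' @param bands canonical band table (defaults to [canonical_bands()]).
#' @param fs optional sampling rate in Hz used to cap the gamma band.
#' @param resolution frequency resolution used with `fs` for the cap.
#' @return data.frame like [canonical_bands()] with rescaled edges.
#' @export
individualized_bands <- function(iaf, bands = canonical_bands(),
                                 fs = NULL, resolution = 0.25) {
  if (!is.numeric(iaf) || length(iaf) != 1L || iaf <= 0)
    stop("'iaf' must be a positive scalar (Hz)")
  out <- bands
  out$lo <- 0.1 * bands$lo * iaf
  out$hi <- 0.1 * bands$hi * iaf
  g <- which(out$name == "gamma")
  if (length(g) == 1L) {
    cap <- 49
    if (!is.null(fs)) cap <- min(cap, fs / 2 - resolution)
    out$hi[g] <- min(out$hi[g], cap)
  }
  if (any(out$lo >= out$hi))
    stop("individualization produced a degenerate band (lo >= hi)")
  out
}
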