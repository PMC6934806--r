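#' Fourier transform of VAR coefficients
#'
#' `Abar(f) = I - sum_k A_k exp(-i 2 pi f k / fs)`, the frequency-domain
#' coefficient matrix underlying partial directed coherence.
#'
#' @param model an `mvar` fit (a list of coefficient matrices also works via
#'   `coeff_fourier_matrices`).
#' @param freqs frequency grid in Hz.
#' @param fs sampling rate; taken from the model when available.
#' @return complex array d x d x length(freqs).
#' @export
coeff_fourier <- function(model, freqs, fs = NULL) {
  if (inherits(model, "mvar")) {
    if (is.null(fs)) fs <- model$fs
    if (!model$stable) warning("model is unstable; frequency response may be misleading")
    A <- model$A
  } else A <- model
  if (is.null(fs)) stop("sampling rate 'fs' is required")
  coeff_fourier_matrices(A, freqs, fs)
}

coeff_fourier_matrices <- function(A, freqs, fs) {
  if (length(freqs) == 0L) stop("empty frequency grid")
  d <- nrow(A[[1L]])
  out <- array(0i, dim = c(d, d, length(freqs)))
  for (fi in seq_along(freqs)) {
    Abar <- diag(d) + 0i
    for (k in seq_along(A))
      Abar <- Abar - A[[k]] * exp(-2i * pi * freqs[fi] * k / fs)
    out[, , fi] <- Abar
  }
  out
}

new_pdc_spectrum <- function(values, freqs, kind, fs) {
  structure(list(values = values, freqs = freqs, kind = kind, fs = fs),
            class = "pdc_spectrum")
}

#' @export
print.pdc_spectrum <- function(x, ...) {
  d <- dim(x$values)[1L]
  cat(sprintf("%s spectrum: %d x %d connections, %d frequency bins (%g-%g Hz)\n",
              toupper(x$kind), d, d, length(x$freqs), min(x$freqs), max(x$freqs)))
  invisible(x)
}

#' Partial directed coherence (PDC)
#'
#' `pi(i <- j, f) = |Abar_ij(f)| / sqrt(sum_m |Abar_mj(f)|^2)`: the
#' column-normalized magnitude of the Fourier-transformed VAR coefficients.
#' By construction the squared values sum to one over all targets (diagonal
#' included) for every source column and frequency.
#'
#' @param model an `mvar` fit.
#' @param freqs frequency grid in Hz; defaults to 0..fs/2 at 0.25 Hz.
#' @param fs sampling rate override.
#' @return `pdc_spectrum` with `kind = "pdc"`; `values[i, j, f]` is the
#'   directed influence of source j on target i.
#' @export
pdc <- function(model, freqs = NULL, fs = NULL) {
  if (is.null(fs)) fs <- model$fs
  if (is.null(freqs)) freqs <- seq(0, fs / 2, by = 0.25)
  Abar <- coeff_fourier(model, freqs, fs)
  denom <- sqrt(apply(abs(Abar)^2, c(2L, 3L), sum))
  if (any(denom < .Machine$double.eps))
    stop("degenerate coefficient column: zero PDC normalization denominator")
  vals <- abs(Abar)
  for (fi in seq_along(freqs)) vals[, , fi] <- sweep(vals[, , fi, drop = FALSE][, , 1L],
                                                     2L, denom[, fi], `/`)
  new_pdc_spectrum(vals, freqs, "pdc", fs)
}

# Indices of source j's lags inside the stacked regressor vector.
lag_indices <- function(j, d, p) (seq_len(p) - 1L) * d + j

#' Renormalized partial directed coherence (RPDC)
#'
#' For every connection (i <- j) and frequency, the two-vector of real and
#' imaginary parts of `Abar_ij(f)` is standardized by its estimated
#' covariance, propagated from the least-squares coefficient-estimator
#' covariance (inverse regressor cross-product x innovation variance) via
#' the lag cosine/sine loading vectors. The returned statistic is the
#' resulting quadratic form: under the null of no coupling it is
#' approximately chi-squared with 2 degrees of freedom, and it is invariant
#' to uniform rescaling of the data.
#'
#' @param model an `mvar` fit carrying `xtx_inv` (from [fit_var()]).
#' @param signals unused placeholder kept for call-site symmetry (the fit
#'   already stores the regressor second moments); may be `NULL`.
#' @param freqs frequency grid in Hz; defaults to 0..fs/2 at 0.25 Hz.
#' @param fs sampling rate override.
#' @return `pdc_spectrum` with `kind = "rpdc"`; diagonal entries are `NA`.
#' @export
rpdc <- function(model, signals = NULL, freqs = NULL, fs = NULL) {
  stopifnot(inherits(model, "mvar"))
  if (is.null(model$xtx_inv)) stop("model lacks regressor second moments; refit with fit_var()")
  if (is.null(fs)) fs <- model$fs
  if (is.null(freqs)) freqs <- seq(0, fs / 2, by = 0.25)
  d <- model$d; p <- model$order
  vals <- array(NA_real_, dim = c(d, d, length(freqs)))
  omega <- 2 * pi * freqs / fs
  for (j in seq_len(d)) {
    idx <- lag_indices(j, d, p)
    Rj <- model$xtx_inv[idx, idx, drop = FALSE]
    for (i in seq_len(d)) {
      if (i == j) next
      a <- vapply(seq_len(p), function(k) model$A[[k]][i, j], numeric(1L))
      cov_a <- model$Sigma[i, i] * Rj
      for (fi in seq_along(freqs)) {
        ck <- cos(omega[fi] * seq_len(p))
        sk <- sin(omega[fi] * seq_len(p))
        v <- c(-sum(a * ck), sum(a * sk))
        C <- rbind(-ck, sk)
        V <- C %*% cov_a %*% t(C)
        V <- V + diag(2) * 1e-14 * (sum(diag(V)) + 1e-300)
        sol <- tryCatch(solve(V, v), error = function(e)
          stop(sprintf("singular RPDC covariance for connection %d <- %d", i, j)))
        vals[i, j, fi] <- sum(v * sol)
      }
    }
  }
  new_pdc_spectrum(vals, freqs, "rpdc", fs)
}

#' Coherence matrix from a cross-spectral density
#'
#' `C_ij = |S_ij|^2 / (S_ii S_jj)`; symmetric with unit diagonal, values in
#' [0, 1] by the Cauchy-Schwarz inequality.
#'
#' @param csd a `csd` object (see [csd_matrix()]) or a Hermitian matrix.
#' @return d x d real matrix.
#' @export
coherence_matrix <- function(csd) {
  S <- if (inherits(csd, "csd")) csd$matrix else csd
  auto <- Re(diag(S))
  if (any(auto <= 0)) stop("zero auto-spectrum; coherence undefined")
  C <- abs(S)^2 / (auto %o% auto)
  C <- Re((C + t(C)) / 2)
  diag(C) <- 1
  pmin(pmax(C, 0), 1)
}

#' Band mean of a connectivity spectrum
#'
#' Arithmetic mean over the frequency bins inside a band, per connection.
#' Self-connections are reported as `NA` (the analysis is between-source
#' only).
#'
#' @param x a `pdc_spectrum` (PDC or RPDC).
#' @param band one-row band data.frame or band name.
#' @return d x d matrix of band means with `NA` diagonal.
#' @export
band_mean <- function(x, band) {
  stopifnot(inherits(x, "pdc_spectrum"))
  if (is.character(band)) band <- band_by_name(band)
  idx <- band_bins(x$freqs, band$lo, band$hi)
  if (length(idx) == 0L)
    stop(sprintf("band [%g, %g] Hz has no bins on the frequency grid", band$lo, band$hi))
  out <- apply(x$values[, , idx, drop = FALSE], c(1L, 2L), mean)
  diag(out) <- NA_real_
  out
}
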