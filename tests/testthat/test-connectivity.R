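# Independent brute-force PDC oracle: evaluates the defining ratio with
# explicit elementwise sums, sharing no code with the implementation.
brute_pdc <- function(A, f, fs) {
  d <- nrow(A[[1]])
  Abar <- matrix(0i, d, d)
  for (i in 1:d) for (j in 1:d) {
    val <- if (i == j) 1 + 0i else 0i
    for (k in seq_along(A))
      val <- val - A[[k]][i, j] * complex(modulus = 1,
                                          argument = -2 * pi * f * k / fs)
    Abar[i, j] <- val
  }
  out <- matrix(0, d, d)
  for (j in 1:d) {
    den <- 0
    for (m in 1:d) den <- den + Mod(Abar[m, j])^2
    for (i in 1:d) out[i, j] <- Mod(Abar[i, j]) / sqrt(den)
  }
  out
}

mvar_from_A <- function(A, fs = 100) {
  structure(list(A = A, d = nrow(A[[1]]), order = length(A),
                 stable = spectral_radius(A) < 1, fs = fs),
            class = "mvar")
}

test_that("coefficient Fourier transform matches closed forms", {
  fs <- 100
  A0 <- list(matrix(0, 2, 2))
  out <- coeff_fourier(A0, c(0, 10, 25), fs = fs)
  for (k in 1:3) expect_equal(out[, , k], diag(2) + 0i)

  A <- list(matrix(c(0.5, 0.1, 0.2, 0.3), 2, 2))
  at0 <- coeff_fourier(A, 0, fs = fs)
  expect_equal(at0[, , 1], diag(2) - A[[1]] + 0i, tolerance = 1e-12)

  a <- list(matrix(0.5, 1, 1))
  at_quarter <- coeff_fourier(a, fs / 4, fs = fs)
  expect_equal(at_quarter[1, 1, 1], 1 + 0.5i, tolerance = 1e-12)

  expect_error(coeff_fourier(A, numeric(0), fs = fs), "empty")
})

test_that("PDC matches the brute-force oracle on 2- and 3-node systems", {
  fs <- 100
  set.seed(1)
  systems <- list(
    list(matrix(c(0.5, 0, 0.3, 0.5), 2, 2, byrow = TRUE)),
    list(matrix(c(0.4, 0.2, 0, 0, 0.3, 0.1, 0.2, 0, 0.5), 3, 3, byrow = TRUE)),
    list(matrix(rnorm(9, sd = 0.2), 3, 3))
  )
  for (A in systems) {
    m <- mvar_from_A(A, fs)
    freqs <- c(1, 7.5, 20, 40)
    got <- pdc(m, freqs, fs)
    for (fi in seq_along(freqs))
      expect_equal(got$values[, , fi], brute_pdc(A, freqs[fi], fs),
                   tolerance = 1e-10)
  }
})

test_that("PDC of the triangular 2-node system is one-way and normalized", {
  A <- list(matrix(c(0.5, 0, 0.3, 0.5), 2, 2, byrow = TRUE))
  m <- mvar_from_A(A)
  freqs <- seq(0, 50, by = 0.5)
  p <- pdc(m, freqs, 100)
  expect_true(all(p$values[1, 2, ] == 0))       # no 2 -> 1 influence
  expect_true(all(p$values[2, 1, ] > 0))        # 1 -> 2 present everywhere
  norms <- apply(p$values^2, c(2, 3), sum)
  expect_lt(max(abs(norms - 1)), 1e-10)

  diag_m <- mvar_from_A(list(diag(0.5, 3)))
  pd <- pdc(diag_m, freqs, 100)
  offdiag <- pd$values; for (i in 1:3) offdiag[i, i, ] <- 0
  expect_true(all(offdiag == 0))
})

test_that("RPDC null statistic is approximately chi-squared(2) and scale invariant", {
  set.seed(2)
  fs <- 100
  # order >= 2 so the real/imaginary loading pair spans two dimensions
  stats_null <- vapply(1:150, function(i) {
    y <- matrix(rnorm(2 * 500), 2)
    m <- fit_var(y, 2); m$fs <- fs
    rpdc(m, freqs = 10, fs = fs)$values[1, 2, 1]
  }, numeric(1))
  qs <- seq(0.1, 0.9, by = 0.1)
  slope <- unname(coef(lm(quantile(stats_null, qs) ~ qchisq(qs, df = 2)))[2])
  expect_gt(slope, 0.85); expect_lt(slope, 1.15)

  y <- sim_chain_var1(1000, seed = 3)
  m1 <- fit_var(y, 1); m1$fs <- fs
  m2 <- fit_var(y * 10, 1); m2$fs <- fs
  r1 <- rpdc(m1, freqs = c(5, 10, 20), fs = fs)
  r2 <- rpdc(m2, freqs = c(5, 10, 20), fs = fs)
  expect_equal(r1$values, r2$values, tolerance = 1e-8)
})

test_that("stronger coupling yields larger band-mean RPDC", {
  fs <- 100
  wins <- vapply(1:20, function(i) {
    y_hi <- sim_chain_var1(1500, coupling = 0.3, seed = 400 + i)
    y_lo <- sim_chain_var1(1500, coupling = 0.15, seed = 400 + i)
    m_hi <- fit_var(y_hi, 1); m_hi$fs <- fs
    m_lo <- fit_var(y_lo, 1); m_lo$fs <- fs
    f <- seq(8, 13, 0.5)
    band_mean(rpdc(m_hi, f, fs = fs), "alpha")[2, 1] >
      band_mean(rpdc(m_lo, f, fs = fs), "alpha")[2, 1]
  }, logical(1))
  expect_gte(mean(wins), 0.95)
})

test_that("coherence is bounded, symmetric, unity for duplicated channels, small for independent ones", {
  set.seed(4)
  fs <- 256
  x <- array(rnorm(3 * fs * 60), c(3, fs, 60))
  x[2, , ] <- x[1, , ]                         # duplicated pair
  rec <- epoched_recording(x, fs)
  cs <- csd_matrix(rec, "alpha")
  C <- coherence_matrix(cs)
  expect_true(isSymmetric(C))
  expect_true(all(C >= 0 & C <= 1))
  expect_equal(C[1, 2], 1, tolerance = 1e-10)
  expect_lt(C[1, 3], 0.2)                      # independent -> near zero
  expect_equal(diag(C), rep(1, 3))
})

test_that("band means average in-band bins and reject empty bands", {
  A <- list(matrix(c(0.5, 0, 0.3, 0.5), 2, 2, byrow = TRUE))
  m <- mvar_from_A(A)
  freqs <- c(8, 9, 10, 11)
  p <- pdc(m, freqs, 100)
  bm <- band_mean(p, data.frame(lo = 8, hi = 11))
  expect_equal(bm[2, 1], mean(p$values[2, 1, ]))
  expect_true(is.na(bm[1, 1]))

  const <- p; const$values[] <- 0.42
  expect_equal(band_mean(const, data.frame(lo = 8, hi = 11))[2, 1], 0.42)
  expect_error(band_mean(p, data.frame(lo = 30, hi = 40)), "no bins")
})
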