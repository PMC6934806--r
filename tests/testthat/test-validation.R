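test_that("bootstrap thresholds are deterministic and preserve per-channel spectra", {
  y <- sim_chain_var1(4000, coupling = 0.3, seed = 1)
  thr1 <- bootstrap_threshold(y, 1, "alpha", n_boot = 25, seed = 2, fs = 256)
  thr2 <- bootstrap_threshold(y, 1, "alpha", n_boot = 25, seed = 2, fs = 256)
  expect_identical(thr1$surrogates, thr2$surrogates)
  expect_true(all(thr1$mean[!diag(2)] >= 0))
  expect_error(bootstrap_threshold(y, 1, "alpha", n_boot = 5, fs = 256), "n_boot")

  # window shuffling preserves each channel's marginal band power
  set.seed(3)
  fs <- 256
  win <- fs
  nwin <- 15
  yy <- matrix(sim_chain_var1(win * nwin, coupling = 0, seed = 4)[1, ], 1)
  ord <- sample(nwin)
  idx <- as.vector(outer(seq_len(win), (ord - 1) * win, `+`))
  ys <- yy[, idx, drop = FALSE]
  bp0 <- band_power(power_spectrum(epoched_recording(
    array(yy, c(1, win, nwin)), fs)), "alpha")
  bp1 <- band_power(power_spectrum(epoched_recording(
    array(ys, c(1, win, nwin)), fs)), "alpha")
  expect_lt(abs(bp1 - bp0) / bp0, 0.1)
})

test_that("a genuinely coupled edge exceeds its surrogate threshold", {
  hits <- vapply(1:8, function(i) {
    y <- sim_chain_var1(4000, coupling = 0.3, seed = 10 + i)
    m <- fit_var(y, 1); m$fs <- 256
    f <- seq(8, 13, 0.5)
    bm <- band_mean(rpdc(m, f, fs = 256), "alpha")
    thr <- bootstrap_threshold(y, 1, "alpha", n_boot = 30, seed = 20 + i,
                               fs = 256, freqs = f)
    bm[2, 1] > thr$mean[2, 1]
  }, logical(1))
  expect_gte(mean(hits), 0.95)
})

test_that("thresholding labels pair directionality correctly", {
  bm <- matrix(c(NA, 80, 5, NA), 2, 2)       # strong 1->2 (bm[2,1]), weak 2->1
  thr <- structure(list(mean = matrix(10, 2, 2), p95 = matrix(20, 2, 2),
                        surrogates = array(10, c(2, 2, 30)),
                        n_surrogates = 30L, window_len = 256L,
                        band = canonical_bands()[3, ]),
                   class = "surrogate_threshold")
  nw <- apply_thresholds(bm, thr, "mean")
  expect_equal(nw$pair_direction$direction, "unidirectional")
  expect_true(nw$edges$surrogate_pass[nw$edges$from == 1 & nw$edges$to == 2])

  both <- matrix(c(NA, 50, 80, NA), 2, 2)
  expect_equal(apply_thresholds(both, thr, "mean")$pair_direction$direction,
               "bidirectional")
  none <- matrix(c(NA, 1, 2, NA), 2, 2)
  nw0 <- apply_thresholds(none, thr, "mean")
  expect_equal(nw0$pair_direction$direction, "none")
  expect_false(any(nw0$edges$surrogate_pass))
})

test_that("time reversal keeps genuine lagged edges and flags symmetric pairs", {
  keep <- vapply(1:6, function(i) {
    y <- sim_chain_var1(4000, coupling = 0.3, seed = 30 + i)
    m <- fit_var(y, 1); m$fs <- 256
    f <- seq(8, 13, 0.5)
    bm <- band_mean(rpdc(m, f, fs = 256), "alpha")
    thr <- bootstrap_threshold(y, 1, "alpha", n_boot = 25, seed = 40 + i,
                               fs = 256, freqs = f)
    nw <- apply_thresholds(bm, thr, "mean")
    nw <- time_reversal_test(y, nw, 1, "alpha", thr, fs = 256, freqs = f)
    isTRUE(nw$edges$trt_pass[nw$edges$from == 1 & nw$edges$to == 2])
  }, logical(1))
  expect_gte(mean(keep), 0.8)

  # symmetric equal coupling: asymmetry below the noise floor -> indeterminate
  set.seed(50)
  n <- 4000
  y <- matrix(0, 2, n)
  for (t in 2:n) {
    y[, t] <- 0.4 * y[, t - 1] + rnorm(2)
    y[1, t] <- y[1, t] + 0.25 * y[2, t - 1]
    y[2, t] <- y[2, t] + 0.25 * y[1, t - 1]
  }
  m <- fit_var(y, 1); m$fs <- 256
  f <- seq(8, 13, 0.5)
  bm <- band_mean(rpdc(m, f, fs = 256), "alpha")
  thr <- bootstrap_threshold(y, 1, "alpha", n_boot = 25, seed = 51, fs = 256,
                             freqs = f)
  nw <- apply_thresholds(bm, thr, "mean")
  nw <- time_reversal_test(y, nw, 1, "alpha", thr, fs = 256, freqs = f)
  passing <- nw$edges[nw$edges$surrogate_pass, ]
  expect_true(all(is.na(passing$trt_pass)))
})

test_that("instantaneous mixing edges are rejected by the time-reversal test", {
  rejected <- vapply(1:6, function(i) {
    set.seed(60 + i)
    src <- rbind(sim_chain_var1(4000, coupling = 0, d = 1, a = 0.6),
                 sim_chain_var1(4000, coupling = 0, d = 1, a = -0.3))
    M <- matrix(c(0.8, 0.35, 0.35, 0.8), 2, 2)  # zero-lag mixing only
    y <- M %*% src
    m <- fit_var(y, 1); m$fs <- 256
    f <- seq(8, 13, 0.5)
    bm <- band_mean(rpdc(m, f, fs = 256), "alpha")
    thr <- bootstrap_threshold(y, 1, "alpha", n_boot = 25, seed = 70 + i,
                               fs = 256, freqs = f)
    nw <- apply_thresholds(bm, thr, "mean")
    nw <- time_reversal_test(y, nw, 1, "alpha", thr, fs = 256, freqs = f)
    sp <- nw$edges$surrogate_pass
    if (!any(sp)) return(NA)                   # nothing spurious to reject
    !any(nw$edges$trt_pass[sp] %in% TRUE)
  }, logical(1))
  rejected <- rejected[!is.na(rejected)]
  expect_gte(mean(rejected), 0.8)
})

test_that("edge export writes a readable tab-separated table", {
  bm <- matrix(c(NA, 5, 80, NA), 2, 2)
  thr <- structure(list(mean = matrix(10, 2, 2), p95 = matrix(20, 2, 2),
                        surrogates = array(10, c(2, 2, 30)),
                        n_surrogates = 30L, window_len = 256L,
                        band = canonical_bands()[3, ]),
                   class = "surrogate_threshold")
  nw <- apply_thresholds(bm, thr)
  path <- tempfile(fileext = ".tsv")
  export_edges(nw, path)
  back <- read.delim(path)
  expect_equal(nrow(back), 2)
  expect_true(all(c("from", "to", "strength", "surrogate_pass") %in% names(back)))
  unlink(path)
})
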