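# Recording with sources planted at known voxels of a synthetic lead field.
planted_recording <- function(lf, voxels, fs = 256, n_epochs = 40L,
                              snr_db = 10, seed = 1L) {
  set.seed(seed)
  n <- fs * n_epochs
  src <- t(vapply(seq_along(voxels), function(i) ar2_source(n, fs), numeric(n)))
  sens <- lf$gain[, voxels, drop = FALSE] %*% src
  sens <- add_noise_snr(sens, snr_db)
  preprocess(epoched_recording(array(sens, c(nrow(lf$gain), fs, n_epochs)), fs))
}

test_that("CSD is Hermitian with nonnegative diagonal and decaying off-diagonals", {
  rec <- white_recording(n_epochs = 100, n_ch = 4, seed = 1)
  cs <- csd_matrix(rec, "alpha")
  expect_lt(max(abs(cs$matrix - Conj(t(cs$matrix)))), 1e-12)
  expect_true(all(Re(diag(cs$matrix)) >= 0))
  expect_lt(max(abs(Im(diag(cs$matrix)))), 1e-12)
  off <- abs(cs$matrix[upper.tri(cs$matrix)])
  expect_lt(max(off), 0.2 * min(Re(diag(cs$matrix))))

  few <- white_recording(n_epochs = 30, n_ch = 4, seed = 2)
  expect_false(csd_matrix(few, "alpha")$rank_warning)
})

test_that("beamformer weights satisfy the unit-gain constraint at every voxel", {
  lf <- make_leadfield(16, c(4, 4, 4), 5, seed = 3)
  rec <- planted_recording(lf, c(10, 50), seed = 4)
  fl <- dics_filter(lf, csd_matrix(rec, "alpha"))
  gains <- rowSums(fl$weights * t(lf$gain))
  expect_lt(max(abs(gains - 1)), 1e-10)
})

test_that("high regularization drives weights towards the pseudoinverse", {
  lf <- make_leadfield(16, c(3, 3, 3), 5, seed = 5)
  rec <- planted_recording(lf, 14, seed = 6)
  cs <- csd_matrix(rec, "alpha")
  fl <- dics_filter(lf, cs, reg_lambda = 1e8)
  # in the lambda -> infinity limit C is a scaled identity, so
  # w_v -> l_v' / (l_v' l_v), the row-wise pseudoinverse of unit-norm gains
  expected <- t(lf$gain) / colSums(lf$gain^2)
  expect_equal(fl$weights, expected, tolerance = 1e-4)
})

test_that("a planted source maps to its voxel and flagged peaks recover the truth", {
  lf <- make_leadfield(24, c(5, 5, 5), 5, seed = 7)
  rec <- planted_recording(lf, 62, seed = 8, snr_db = 10)
  cs <- csd_matrix(rec, "alpha")
  fl <- dics_filter(lf, cs)
  sm <- source_power_map(fl, cs)
  expect_true(all(sm$voxel_power >= 0))
  expect_equal(sm$peaks$voxel[1], 62)
  expect_false(any(sm$peaks$flagged))

  ps <- peak_selection_surrogate(rec, "alpha", lf, n_perm = 40, seed = 9)
  expect_true(62 %in% ps$peaks$voxel[ps$peaks$flagged])
  ps2 <- peak_selection_surrogate(rec, "alpha", lf, n_perm = 40, seed = 9)
  expect_identical(ps$peaks$flagged, ps2$peaks$flagged)
  expect_error(peak_selection_surrogate(rec, "alpha", lf, n_perm = 5), "n_perm")
})

test_that("two well-separated sources give two flagged peaks near truth", {
  lf <- make_leadfield(24, c(5, 5, 5), 5, seed = 10)
  rec <- planted_recording(lf, c(32, 94), seed = 11, snr_db = 10)
  ps <- peak_selection_surrogate(rec, "alpha", lf, n_perm = 40, seed = 12)
  flagged <- ps$peaks$voxel[ps$peaks$flagged]
  co <- lf$voxel_coords
  for (v in c(32, 94)) {
    dd <- sqrt(rowSums(sweep(co[flagged, , drop = FALSE], 2, co[v, ])^2))
    expect_lte(min(dd), sqrt(3) * 5)           # within one grid step
  }
})

test_that("pooled signals reproduce a rank-1 region and recover the source", {
  lf <- make_leadfield(24, c(4, 4, 4), 5, seed = 13)
  n_epochs <- 30L; fs <- 256
  set.seed(14)
  src <- matrix(ar2_source(fs * n_epochs, fs), 1)
  sens <- add_noise_snr(lf$gain[, 30, drop = FALSE] %*% src, 10, seed = 15)
  rec <- preprocess(epoched_recording(array(sens, c(24, fs, n_epochs)), fs))
  cs <- csd_matrix(rec, "alpha")
  fl <- dics_filter(lf, cs)
  sm <- source_power_map(fl, cs)
  sm$peaks$flagged <- sm$peaks$voxel == 30
  pooled <- pooled_source_signal(rec, fl, sm)
  expect_equal(dim(pooled$signals), c(1L, fs, n_epochs))
  r <- cor(as.numeric(pooled$signals[1, , ]), as.numeric(src))
  expect_gte(abs(r), 0.8)
  # sign convention: positive correlation with the peak-voxel series
  peak_series <- as.numeric(fl$weights[30, ] %*% matrix(rec$data, 24))
  expect_gt(cor(as.numeric(pooled$signals[1, , ]), peak_series), 0)
})

test_that("peak distances follow grid geometry and greedy matching", {
  lf <- make_leadfield(16, c(4, 4, 4), 5, seed = 16)
  mk <- function(voxels) {
    structure(list(voxel_power = rep(1, 64),
                   peaks = data.frame(voxel = voxels, power = 1, flagged = TRUE),
                   leadfield = lf, band = canonical_bands()[3, ]),
              class = "source_map")
  }
  same <- peak_distance(mk(c(1, 22)), mk(c(1, 22)))
  expect_equal(same$distance_mm, c(0, 0))
  # one step along x on a 5-mm grid
  expect_equal(peak_distance(mk(1), mk(2))$distance_mm, 5)
  # diagonal neighbour: voxel 1 -> (1+1, 1+4, 1+16)
  expect_equal(peak_distance(mk(1), mk(22))$distance_mm, 5 * sqrt(3))
  # unequal counts: surplus matched greedily and reported
  um <- peak_distance(mk(c(1, 2)), mk(1))
  expect_equal(um$unmatched, 1)
  expect_length(um$distance_mm, 2)
})
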