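complete_subject <- function(offset = 0) {
  bands <- canonical_bands()$name
  mk <- function(base) setNames(base + offset + seq(0.01, 0.05, 0.01), bands)
  list(source_power = mk(1), coherence = mk(0.1), rpdc = mk(0.2), tpdc = mk(0.3))
}

test_that("feature vectors have exactly 20 named finite values", {
  fv <- build_features(complete_subject())
  expect_length(fv, 20)
  expect_true(all(is.finite(fv)))
  expect_setequal(unique(sub("\\..*", "", names(fv))),
                  c("source_power", "coherence", "rpdc", "tpdc"))
  expect_identical(build_features(complete_subject()), fv)

  broken <- complete_subject()
  broken$rpdc <- broken$rpdc[-2]              # drop theta
  expect_error(build_features(broken), "rpdc.theta")
  expect_error(build_features(list(source_power = 1)), "coherence")
})

test_that("subject_measures needs at least two sources", {
  expect_error(subject_measures(matrix(rnorm(100), 1), fs = 256), "2 sources")
})

test_that("the classifier separates a well-separated synthetic cohort", {
  coh <- simulate_feature_cohort(20, seed = 1)
  rep <- svm_classify(coh$features, coh$labels, seed = 2)
  all_acc <- rep$summary$mean_accuracy[rep$summary$feature_set == "ALL"]
  expect_gte(all_acc, 90)
  expect_setequal(rep$summary$feature_set,
                  c("source_power", "coherence", "rpdc", "tpdc", "ALL"))
  expect_true(all(rep$summary$mean_accuracy >= 0 &
                    rep$summary$mean_accuracy <= 100))
})

test_that("label permutation and contradictory labels give chance accuracy", {
  coh <- simulate_feature_cohort(10, seed = 3)
  cfg <- svm_config(repeats = 1)
  set.seed(4)
  perm_acc <- vapply(1:5, function(i) {
    svm_classify(coh$features, sample(coh$labels), cfg,
                 seed = 100 + i)$summary$mean_accuracy[5]
  }, numeric(1))
  expect_lt(abs(mean(perm_acc) - 50), 12)

  # inseparable cohort: both groups drawn from the same feature profile
  prof <- dirflow:::feature_group_profiles()
  same <- simulate_feature_cohort(10, seed = 6,
                                  means = list(control = prof$means$control,
                                               patient = prof$means$control),
                                  sds = list(control = prof$sds$control,
                                             patient = prof$sds$control))
  acc <- svm_classify(same$features, same$labels, cfg, seed = 5)$summary$mean_accuracy[5]
  expect_lt(abs(acc - 50), 20)
})

test_that("standardization and cost selection do not leak test-fold information", {
  # inject a test-only artifact: if any statistic were computed on the full
  # data, a giant constant shift in held-out rows would be absorbed; with
  # training-fold-only standardization it must not lift accuracy above chance
  set.seed(6)
  n <- 20
  x <- matrix(rnorm(n * 5), n, 5,
              dimnames = list(NULL, paste0("m.", canonical_bands()$name)))
  labels <- rep(c("a", "b"), each = n / 2)    # labels independent of x
  acc <- svm_classify(x, labels, svm_config(repeats = 2), seed = 7)
  expect_lt(acc$summary$mean_accuracy[acc$summary$feature_set == "ALL"], 75)
})

test_that("group statistics reproduce the textbook t and detect a planted band effect", {
  df <- data.frame(value = c(1, 2, 3, 4, 5, 6),
                   group = rep(c("a", "b"), each = 3),
                   band = "alpha", subject = 1:6)
  out <- group_statistics(df)
  expect_equal(out$t_tests$t, -3.674235, tolerance = 1e-6)

  # identical groups: no rejections anywhere
  same <- data.frame(value = rep(c(1, 2, 3), 2),
                     group = rep(c("a", "b"), each = 3),
                     band = "alpha", subject = 1:6)
  out2 <- group_statistics(same)
  expect_true(all(out2$t_tests$p_adj > 0.99))

  # planted theta difference survives Bonferroni, delta does not
  set.seed(8)
  n <- 12
  mk <- function(band, shift) data.frame(
    value = c(rnorm(n), rnorm(n) + shift),
    group = rep(c("a", "b"), each = n), band = band,
    subject = c(1:n, n + 1:n))
  df3 <- rbind(mk("delta", 0), mk("theta", 2.5), mk("alpha", 0),
               mk("beta", 0), mk("gamma", 0))
  out3 <- group_statistics(df3)
  expect_lt(out3$t_tests$p_adj[out3$t_tests$band == "theta"], 0.05)
  expect_gt(out3$t_tests$p_adj[out3$t_tests$band == "delta"], 0.05)
  expect_s3_class(out3$anova, "anova")
  expect_true(!is.null(out3$friedman))
})

test_that("zero-variance cells are short-circuited with a note", {
  df <- data.frame(value = c(1, 1, 1, 2, 2, 2),
                   group = rep(c("a", "b"), each = 3),
                   band = "alpha", subject = 1:6)
  # the perfect-fit ANOVA on this degenerate fixture warns by design
  out <- suppressWarnings(group_statistics(df))
  expect_equal(out$t_tests$p, 0)
  expect_true(any(grepl("zero variance", out$notes)))
})

test_that("feature export writes a header and all subjects", {
  coh <- simulate_feature_cohort(3, seed = 9)
  path <- tempfile(fileext = ".tsv")
  export_features(coh$features, coh$labels, path)
  back <- read.delim(path, check.names = FALSE)
  expect_equal(nrow(back), 6)
  expect_equal(ncol(back), 22)
  unlink(path)
})
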