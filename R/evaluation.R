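#' Assemble the 20-feature subject vector
#'
#' Four measures (first-source band power, mean pairwise source coherence,
#' mean RPDC, mean tPDC over all ordered source pairs) at each of the five
#' canonical frequency bands, giving exactly 20 named values per subject.
#'
#' @param subject_results list with elements `source_power`, `coherence`,
#'   `rpdc`, `tpdc`, each a numeric vector named by band (all five bands
#'   required).
#' @return named numeric vector of length 20 (names `measure.band`).
#' @export
build_features <- function(subject_results) {
  measures <- c("source_power", "coherence", "rpdc", "tpdc")
  bands <- canonical_bands()$name
  missing <- character(0)
  out <- numeric(0)
  for (m in measures) {
    v <- subject_results[[m]]
    for (b in bands) {
      val <- if (is.null(v)) NA_real_ else unname(v[b])
      if (is.null(val) || length(val) != 1L || !is.finite(val))
        missing <- c(missing, paste(m, b, sep = "."))
      out[paste(m, b, sep = ".")] <- if (length(val) == 1L) val else NA_real_
    }
  }
  if (length(missing) > 0L)
    stop("missing or non-finite features: ", paste(missing, collapse = ", "))
  out
}

#' Compute a subject's connectivity measures from source signals
#'
#' Convenience wrapper producing the four band-resolved measures feeding
#' [build_features()]: band power of the strongest source, mean pairwise
#' band coherence across sources, and band-mean RPDC and tPDC over all
#' ordered source pairs. A single broadband MVAR (and DEKF track) is fitted
#' and evaluated at each band's frequencies.
#'
#' @param signals sources x samples x epochs array or `pooled_sources`
#'   (>= 2 sources).
#' @param fs sampling rate.
#' @param order MVAR order (default selected by AIC up to `max_order`).
#' @param max_order AIC search bound when `order` is missing.
#' @param bands band table (default [canonical_bands()]).
#' @param tpdc_stride time stride for the tPDC evaluation.
#' @return list with `source_power`, `coherence`, `rpdc`, `tpdc` (band-named
#'   vectors) and `temporal_sd` (band-named vectors of mean temporal SD).
#' @export
subject_measures <- function(signals, fs, order = NULL, max_order = 10L,
                             bands = canonical_bands(), tpdc_stride = 4L) {
  x <- as_signal_array(signals)
  if (inherits(signals, "pooled_sources")) fs <- signals$fs
  d <- dim(x)[1L]
  if (d < 2L) stop("at least 2 sources are required for connectivity measures")
  rec <- epoched_recording(x, fs)
  spec <- power_spectrum(rec)
  if (is.null(order)) order <- select_order_aic(x, max_order)$order
  model <- fit_var(x, order)
  model$fs <- fs
  rp <- rpdc(model, freqs = seq(0.25, fs / 2 - 0.25, by = 0.25), fs = fs)
  tv <- dekf_tvar(x, order, fs = fs)
  band_freqs <- unlist(lapply(seq_len(nrow(bands)), function(b)
    seq(bands$lo[b], bands$hi[b], by = 0.5)))
  tp <- tpdc_from_tvar(tv, freqs = sort(unique(band_freqs)), bands = bands,
                       stride = tpdc_stride)
  src_pow <- coh <- rpdc_m <- tpdc_m <- tsd <- stats::setNames(numeric(nrow(bands)), bands$name)
  for (b in seq_len(nrow(bands))) {
    bd <- bands[b, , drop = FALSE]
    bp <- band_power(spec, bd)
    src_pow[b] <- max(bp)                   # strongest ("first") source
    cs <- csd_matrix(rec, bd)
    cm <- coherence_matrix(cs)
    coh[b] <- mean(cm[upper.tri(cm)])
    rpdc_m[b] <- mean(band_mean(rp, bd), na.rm = TRUE)
    course <- tp$band_summary[[bd$name]]
    tpdc_m[b] <- {
      m <- apply(course, c(1L, 2L), mean)
      diag(m) <- NA_real_
      mean(m, na.rm = TRUE)
    }
    tsd[b] <- mean(tp$temporal_sd[[bd$name]], na.rm = TRUE)
  }
  list(source_power = src_pow, coherence = coh, rpdc = rpdc_m,
       tpdc = tpdc_m, temporal_sd = tsd, order = order)
}

#' Simulate a feature-level cohort with group contrasts
#'
#' Draws per-subject 20-feature vectors from independent Gaussians whose
#' group means and standard deviations default to the group-level contrast
#' pattern the pipeline is designed to detect (strong theta/alpha/gamma
#' separation in coherence, RPDC and tPDC; overlapping delta and beta).
#' Useful for exercising the classifier at a known separability.
#'
#' @param n_per_group subjects per group.
#' @param seed integer seed.
#' @param means,sds optional lists (`control`, `patient`) of 20-vectors
#'   overriding the built-in group profiles.
#' @return list with `features` (matrix subjects x 20) and `labels`.
#' @export
simulate_feature_cohort <- function(n_per_group = 20L, seed = 1L,
                                    means = NULL, sds = NULL) {
  prof <- feature_group_profiles()
  if (is.null(means)) means <- prof$means
  if (is.null(sds)) sds <- prof$sds
  set.seed(seed)
  labels <- rep(c("control", "patient"), each = n_per_group)
  nm <- names(means$control)
  feats <- t(vapply(labels, function(g) {
    stats::rnorm(length(nm), mean = means[[g]], sd = sds[[g]])
  }, numeric(length(nm))))
  colnames(feats) <- nm
  rownames(feats) <- paste0("s", seq_along(labels))
  list(features = feats, labels = labels)
}

# Built-in group feature profiles: log band power of the first source, mean
# source coherence, mean RPDC and mean tPDC per band, for a control-like
# and a patient-like group. The contrast pattern (theta reversed, alpha and
# gamma reduced in the patient-like group, delta/beta overlapping) mirrors
# the group structure the synthetic cohorts are built to produce.
feature_group_profiles <- function() {
  bands <- canonical_bands()$name
  nm <- as.vector(outer(bands, c("source_power", "coherence", "rpdc", "tpdc"),
                        function(b, m) paste(m, b, sep = ".")))
  ctrl_mean <- c(4.26, 1.24, 3.74, 0.29, 0.71,      # power
                 0.19, 0.17, 0.19, 0.13, 0.14,      # coherence
                 0.16, 0.24, 0.24, 0.16, 0.24,      # rpdc
                 0.16, 0.24, 0.24, 0.16, 0.24)      # tpdc
  ctrl_sd   <- c(0.14, 0.13, 0.13, 0.18, 0.16,
                 0.03, 0.05, 0.02, 0.03, 0.01,
                 0.01, 0.02, 0.02, 0.01, 0.02,
                 0.03, 0.04, 0.03, 0.03, 0.03)
  pat_mean  <- c(4.26, 1.75, 3.45, 0.17, 0.31,
                 0.19, 0.22, 0.11, 0.13, 0.09,
                 0.16, 0.13, 0.14, 0.16, 0.11,
                 0.16, 0.13, 0.14, 0.16, 0.11)
  pat_sd    <- c(0.15, 0.12, 0.65, 0.10, 0.13,
                 0.03, 0.03, 0.02, 0.02, 0.02,
                 0.01, 0.02, 0.03, 0.01, 0.02,
                 0.03, 0.07, 0.06, 0.03, 0.06)
  names(ctrl_mean) <- names(ctrl_sd) <- names(pat_mean) <- names(pat_sd) <- nm
  list(means = list(control = ctrl_mean, patient = pat_mean),
       sds = list(control = ctrl_sd, patient = pat_sd))
}

#' SVM classification configuration
#'
#' @param degree polynomial kernel degree (default 3).
#' @param gamma kernel scale coefficient (default 0.25).
#' @param coef0 kernel offset (default 1).
#' @param cost_grid soft-margin penalties searched (default 1..10).
#' @param folds outer cross-validation folds (default 10).
#' @param repeats whole-CV repetitions with reshuffling (default 3).
#' @param inner_folds folds of the inner CV used to pick the cost inside
#'   each training fold (default 5).
#' @return list of class `svm_config`.
#' @export
svm_config <- function(degree = 3L, gamma = 0.25, coef0 = 1,
                       cost_grid = 1:10, folds = 10L, repeats = 3L,
                       inner_folds = 5L) {
  structure(list(degree = degree, gamma = gamma, coef0 = coef0,
                 cost_grid = cost_grid, folds = folds, repeats = repeats,
                 inner_folds = inner_folds),
            class = "svm_config")
}

stratified_folds <- function(labels, k) {
  folds <- integer(length(labels))
  for (g in unique(labels)) {
    idx <- sample(which(labels == g))
    folds[idx] <- rep_len(sample(seq_len(k)), length(idx))
  }
  folds
}

fit_predict_svm <- function(xtr, ytr, xte, cfg, cost) {
  fit <- e1071::svm(xtr, factor(ytr), kernel = "polynomial",
                    degree = cfg$degree, gamma = cfg$gamma,
                    coef0 = cfg$coef0, cost = cost, scale = FALSE)
  as.character(stats::predict(fit, xte))
}

# One repeat of stratified k-fold CV: per fold, standardize with training
# statistics only, pick the cost by an inner CV on the training data, train
# and score the held-out fold.
cv_accuracy <- function(x, labels, cfg) {
  k <- cfg$folds
  folds <- stratified_folds(labels, k)
  acc <- numeric(k)
  chosen <- numeric(k)
  for (f in seq_len(k)) {
    tr <- folds != f; te <- !tr
    if (length(unique(labels[te])) < 1L || length(unique(labels[tr])) < 2L) {
      folds <- stratified_folds(labels, k)
      tr <- folds != f; te <- !tr
      if (length(unique(labels[tr])) < 2L) stop("cannot stratify folds with two classes")
    }
    mu <- colMeans(x[tr, , drop = FALSE])
    sdv <- apply(x[tr, , drop = FALSE], 2L, stats::sd)
    sdv[sdv < 1e-12] <- 1
    xz <- sweep(sweep(x, 2L, mu), 2L, sdv, `/`)
    best_cost <- cfg$cost_grid[1L]
    if (length(cfg$cost_grid) > 1L) {
      inner <- stratified_folds(labels[tr], cfg$inner_folds)
      xin <- xz[tr, , drop = FALSE]; yin <- labels[tr]
      inner_acc <- vapply(cfg$cost_grid, function(cost) {
        ok <- 0L; tot <- 0L
        for (g in seq_len(cfg$inner_folds)) {
          itr <- inner != g
          if (length(unique(yin[itr])) < 2L || !any(!itr)) next
          pr <- fit_predict_svm(xin[itr, , drop = FALSE], yin[itr],
                                xin[!itr, , drop = FALSE], cfg, cost)
          ok <- ok + sum(pr == yin[!itr]); tot <- tot + sum(!itr)
        }
        if (tot == 0L) 0 else ok / tot
      }, numeric(1L))
      best_cost <- cfg$cost_grid[which.max(inner_acc)]
    }
    pr <- fit_predict_svm(xz[tr, , drop = FALSE], labels[tr],
                          xz[te, , drop = FALSE], cfg, best_cost)
    acc[f] <- mean(pr == labels[te])
    chosen[f] <- best_cost
  }
  list(acc = acc, cost = chosen)
}

#' SVM classification of connectivity features
#'
#' Third-degree polynomial-kernel SVM with kernel scale 0.25, soft-margin
#' cost selected from 1..10 by an inner cross-validation inside each
#' training fold, stratified 10-fold outer cross-validation repeated three
#' times with reshuffling. Features are standardized using training-fold
#' statistics only. Accuracy is reported per feature block (each measure's
#' five band values) and for the full 20-feature vector (`ALL`).
#'
#' @param features subjects x features numeric matrix with `measure.band`
#'   column names (as from [build_features()] rows).
#' @param labels group label per subject (two classes).
#' @param cfg an [svm_config()].
#' @param seed integer seed for fold shuffling.
#' @param feature_sets optional named list of column selections; defaults to
#'   one block per measure plus `ALL`.
#' @return object of class `classifier_report`: data.frame `summary`
#'   (feature_set, mean_accuracy in percent), list `folds` of per-repeat
#'   fold accuracies, and the config.
#' @export
svm_classify <- function(features, labels, cfg = svm_config(), seed = 1L,
                         feature_sets = NULL) {
  features <- as.matrix(features)
  labels <- as.character(labels)
  if (length(unique(labels)) != 2L) stop("exactly two classes are required")
  if (nrow(features) < cfg$folds) stop("fewer subjects than folds")
  if (is.null(feature_sets)) {
    prefixes <- unique(sub("\\..*$", "", colnames(features)))
    feature_sets <- lapply(prefixes, function(p)
      grep(paste0("^", p, "\\."), colnames(features), value = TRUE))
    names(feature_sets) <- prefixes
    feature_sets$ALL <- colnames(features)
  }
  set.seed(seed)
  summary_rows <- list()
  fold_acc <- list()
  for (fs_name in names(feature_sets)) {
    x <- features[, feature_sets[[fs_name]], drop = FALSE]
    accs <- costs <- numeric(0)
    for (rep in seq_len(cfg$repeats)) {
      cv <- cv_accuracy(x, labels, cfg)
      accs <- c(accs, cv$acc)
      costs <- c(costs, cv$cost)
    }
    summary_rows[[fs_name]] <- data.frame(
      feature_set = fs_name,
      mean_accuracy = 100 * mean(accs),
      modal_cost = as.numeric(names(sort(table(costs), decreasing = TRUE))[1L]),
      stringsAsFactors = FALSE)
    fold_acc[[fs_name]] <- accs
  }
  structure(list(summary = do.call(rbind, summary_rows), folds = fold_acc,
                 cfg = cfg, n_subjects = nrow(features)),
            class = "classifier_report")
}

#' @export
print.classifier_report <- function(x, ...) {
  cat(sprintf("SVM classification (%d subjects, %d-fold CV x %d repeats):\n",
              x$n_subjects, x$cfg$folds, x$cfg$repeats))
  df <- x$summary
  df$mean_accuracy <- sprintf("%.1f%%", df$mean_accuracy)
  print(df, row.names = FALSE)
  invisible(x)
}

#' Group statistics on band-resolved measures
#'
#' Per band (and modality, when present): a two-tailed two-sample t-test
#' between groups with Bonferroni adjustment across tests; a three-factor
#' ANOVA (group x band x modality) with main effects and interactions; and
#' a Friedman rank test across bands using subjects as blocks. Cells with
#' zero variance short-circuit to an exact-equality comparison and are
#' flagged.
#'
#' @param data data.frame with columns `value`, `group`, `band`, `subject`
#'   and optionally `modality`.
#' @return list with `t_tests` (data.frame), `anova` (table), `friedman`
#'   (htest), `notes` (character).
#' @export
group_statistics <- function(data) {
  req <- c("value", "group", "band", "subject")
  if (!all(req %in% names(data))) stop("data needs columns: ", paste(req, collapse = ", "))
  if (!"modality" %in% names(data)) data$modality <- "single"
  notes <- character(0)
  combos <- unique(data[, c("band", "modality")])
  tt <- lapply(seq_len(nrow(combos)), function(r) {
    d <- data[data$band == combos$band[r] & data$modality == combos$modality[r], ]
    g <- split(d$value, d$group)
    if (length(g) != 2L) stop("exactly two groups are required")
    if (stats::sd(g[[1L]]) < 1e-12 && stats::sd(g[[2L]]) < 1e-12) {
      eq <- isTRUE(all.equal(mean(g[[1L]]), mean(g[[2L]])))
      notes <<- c(notes, sprintf("zero variance in %s/%s: exact comparison used",
                                 combos$band[r], combos$modality[r]))
      data.frame(band = combos$band[r], modality = combos$modality[r],
                 t = NA_real_, df = NA_real_, p = if (eq) 1 else 0)
    } else {
      ht <- stats::t.test(g[[1L]], g[[2L]], var.equal = TRUE)
      data.frame(band = combos$band[r], modality = combos$modality[r],
                 t = unname(ht$statistic), df = unname(ht$parameter),
                 p = ht$p.value)
    }
  })
  tt <- do.call(rbind, tt)
  tt$p_adj <- stats::p.adjust(tt$p, method = "bonferroni")
  data$group <- factor(data$group); data$band <- factor(data$band)
  data$modality <- factor(data$modality)
  terms <- c("group", "band", "modality")
  terms <- terms[vapply(terms, function(v) nlevels(data[[v]]) > 1L, logical(1L))]
  an <- NULL
  if (length(terms) > 0L) {
    form <- stats::as.formula(paste("value ~", paste(terms, collapse = " * ")))
    an <- stats::anova(stats::aov(form, data = data))
  }
  fr <- tryCatch({
    wide <- stats::aggregate(value ~ subject + band, data = data, FUN = mean)
    m <- stats::reshape(wide, idvar = "subject", timevar = "band",
                        direction = "wide")
    stats::friedman.test(as.matrix(m[, -1L, drop = FALSE]))
  }, error = function(e) { notes <<- c(notes, paste("friedman:", conditionMessage(e))); NULL })
  list(t_tests = tt, anova = an, friedman = fr, notes = notes)
}

#' Export a feature table as tab-separated text
#'
#' @param features subjects x features matrix.
#' @param labels group labels.
#' @param path output path.
#' @return the path, invisibly.
#' @export
export_features <- function(features, labels, path) {
  df <- data.frame(subject = rownames(features), group = labels,
                   as.data.frame(features), check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
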