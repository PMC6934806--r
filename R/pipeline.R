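#' Pipeline configuration
#'
#' Validated settings for [run_pipeline()]. Every stage draws its
#' randomness from a named substream derived from the single top-level
#' seed, so stages are independently re-runnable.
#'
#' @param cohort a [cohort_spec()].
#' @param bands band table (default [canonical_bands()]).
#' @param source_band band used for beamformer source selection (the
#'   pooled source signals are broadband; connectivity is evaluated at every
#'   band's frequencies afterwards).
#' @param n_sources_max cap on pooled sources per subject.
#' @param reg_lambda beamformer regularization.
#' @param n_perm source-peak surrogate permutations.
#' @param var_max_order AIC search bound.
#' @param n_boot connectivity surrogate count.
#' @param threshold_rule `"mean"` or `"p95"`.
#' @param svm an [svm_config()] or `NULL` to skip classification.
#' @param tpdc_stride time stride of the tPDC evaluation.
#' @param seed top-level integer seed.
#' @return list of class `pipeline_config`.
#' @export
pipeline_config <- function(cohort = cohort_spec(),
                            bands = canonical_bands(),
                            source_band = "alpha",
                            n_sources_max = 4L,
                            reg_lambda = 0.05,
                            n_perm = 50L,
                            var_max_order = 10L,
                            n_boot = 50L,
                            threshold_rule = "mean",
                            svm = svm_config(),
                            tpdc_stride = 4L,
                            seed = 1L) {
  stopifnot(inherits(cohort, "cohort_spec"))
  if (any(bands$hi > cohort$fs / 2))
    stop("band upper edge exceeds the Nyquist frequency of the cohort")
  if (any(bands$lo <= 0) || any(bands$lo >= bands$hi)) stop("invalid band table")
  if (!threshold_rule %in% c("mean", "p95")) stop("unknown threshold rule")
  structure(list(cohort = cohort, bands = bands, source_band = source_band,
                 n_sources_max = as.integer(n_sources_max),
                 reg_lambda = reg_lambda, n_perm = as.integer(n_perm),
                 var_max_order = as.integer(var_max_order),
                 n_boot = as.integer(n_boot), threshold_rule = threshold_rule,
                 svm = svm, tpdc_stride = as.integer(tpdc_stride),
                 seed = as.integer(seed)),
            class = "pipeline_config")
}

# Named substream seed derived from the top-level seed; stable across runs.
substream_seed <- function(seed, stage) {
  h <- sum(utf8ToInt(stage) * seq_along(utf8ToInt(stage)))
  (seed * 10007L + h) %% 2147483647L
}

#' Run the full analysis pipeline on a synthetic cohort
#'
#' Executes, in order: cohort simulation, per-subject preprocessing and
#' spectral analysis (including IAF estimation), beamformer source
#' selection with surrogate-flagged peaks, pooled source extraction, MVAR
#' fitting with AIC order selection, RPDC and tPDC, surrogate plus
#' time-reversal edge validation in the source band, feature assembly, and
#' (when at least 10 subjects are available and `svm` is configured) group
#' statistics and SVM classification. All randomness derives from the
#' config seed through named substreams; a failed stage aborts with the
#' stage name while partial per-subject results are returned.
#'
#' @param config a [pipeline_config()].
#' @param verbose print per-stage progress.
#' @return object of class `pipeline_result` with `cohort`, `subjects`
#'   (per-subject lists: iaf, source_map, measures, network), `features`,
#'   `labels`, `stats`, `svm`, `timing`, `config`.
#' @export
run_pipeline <- function(config, verbose = FALSE) {
  stopifnot(inherits(config, "pipeline_config"))
  t0 <- proc.time()[3L]
  timing <- c()
  say <- function(...) if (verbose) message(sprintf(...))
  stage <- function(name, expr) {
    st <- proc.time()[3L]
    out <- tryCatch(expr, error = function(e)
      stop(sprintf("pipeline stage '%s' failed: %s", name, conditionMessage(e)),
           call. = FALSE))
    timing[name] <<- proc.time()[3L] - st
    say("stage %-12s %6.1f s", name, timing[name])
    out
  }
  spec <- config$cohort
  spec$seed <- substream_seed(config$seed, "cohort")
  ctrl <- make_group_network("control", band_assignment = config$source_band,
                             fs = spec$fs)
  pat <- make_group_network("patient", band_assignment = config$source_band,
                            fs = spec$fs)
  cohort <- stage("simulate", make_cohort(spec, ctrl, pat))
  subjects <- vector("list", length(cohort$labels))
  feats <- list()
  for (s in seq_along(cohort$labels)) {
    rec <- stage("preprocess", preprocess(cohort$recordings[[s]]))
    spect <- power_spectrum(rec)
    iaf <- estimate_iaf(spect)
    smap <- stage("source", peak_selection_surrogate(
      rec, config$source_band, cohort$leadfield, n_perm = config$n_perm,
      seed = substream_seed(config$seed, paste0("peaks", s)),
      reg_lambda = config$reg_lambda))
    csd <- csd_matrix(rec, config$source_band)
    filt <- dics_filter(cohort$leadfield, csd, config$reg_lambda)
    if (!any(smap$peaks$flagged)) {
      # fall back to the strongest unflagged peaks so downstream stages run
      smap$peaks$flagged[seq_len(min(2L, nrow(smap$peaks)))] <- TRUE
    }
    pooled <- stage("pool", pooled_source_signal(rec, filt, smap,
                                                 max_sources = config$n_sources_max))
    if (dim(pooled$signals)[1L] < 2L) {
      smap$peaks$flagged[seq_len(min(2L, nrow(smap$peaks)))] <- TRUE
      pooled <- pooled_source_signal(rec, filt, smap,
                                     max_sources = max(2L, config$n_sources_max))
    }
    meas <- stage("connectivity", subject_measures(
      pooled, fs = spec$fs, max_order = config$var_max_order,
      bands = config$bands, tpdc_stride = config$tpdc_stride))
    net <- stage("validate", {
      bsig <- pooled
      thr <- bootstrap_threshold(bsig, meas$order, config$source_band,
                                 n_boot = config$n_boot,
                                 seed = substream_seed(config$seed, paste0("boot", s)),
                                 fs = spec$fs)
      model <- fit_var(bsig, meas$order); model$fs <- spec$fs
      bm <- band_mean(rpdc(model, fs = spec$fs), config$source_band)
      nw <- apply_thresholds(bm, thr, config$threshold_rule)
      time_reversal_test(bsig, nw, meas$order, config$source_band,
                         thresholds = thr, fs = spec$fs)
    })
    subjects[[s]] <- list(iaf = iaf, source_map = smap, measures = meas,
                          network = net)
    feats[[s]] <- build_features(meas)
  }
  features <- do.call(rbind, feats)
  rownames(features) <- paste0("s", seq_along(cohort$labels))
  long <- do.call(rbind, lapply(seq_along(feats), function(s) {
    data.frame(subject = s, group = cohort$labels[s],
               band = canonical_bands()$name,
               value = unname(feats[[s]][paste0("rpdc.", canonical_bands()$name)]))
  }))
  stats <- stage("stats", group_statistics(long))
  svm_rep <- NULL
  if (!is.null(config$svm) && length(cohort$labels) >= config$svm$folds) {
    svm_rep <- stage("classify", svm_classify(
      features, cohort$labels, config$svm,
      seed = substream_seed(config$seed, "svm")))
  }
  timing["total"] <- proc.time()[3L] - t0
  structure(list(cohort = cohort, subjects = subjects, features = features,
                 labels = cohort$labels, stats = stats, svm = svm_rep,
                 timing = timing, config = config),
            class = "pipeline_result")
}

#' @export
print.pipeline_result <- function(x, ...) {
  cat(sprintf("Pipeline run: %d subjects, %.1f s total\n",
              length(x$labels), x$timing["total"]))
  if (!is.null(x$svm)) print(x$svm)
  invisible(x)
}
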