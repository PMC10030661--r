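# Evaluation metrics: ME, SD of differences, MAE, MASE against the naive
# (training-mean) predictor, pooled-across-folds computation, label
# extraction from predicted pressure waveforms, and paired-bootstrap model
# comparison with Bonferroni-corrected intervals.

#' Prediction set constructor
#'
#' One row per segment: predicted value, reference value, the per-fold naive
#' prediction (the fold's training mean), subject and fold ids.
#'
#' @param pred,ref Numeric vectors in mmHg.
#' @param naive Per-segment naive predictions (each fold's training mean).
#' @param subject_id,fold Identifier vectors.
#' @param segment_id Optional unique segment keys (used for pairing).
#' @return Data frame of class `prediction_set` with a `diff` column
#'   (`pred - ref`).
#' @export
prediction_set <- function(pred, ref, naive = NA_real_, subject_id = NA,
                           fold = NA, segment_id = seq_along(pred)) {
  if (length(pred) != length(ref)) stop_spec("pred and ref lengths differ")
  if (length(pred) < 1L) stop_spec("empty prediction set")
  if (any(!is.finite(pred)) || any(!is.finite(ref))) {
    stop_spec("prediction_set: non-finite values")
  }
  df <- data.frame(segment_id = segment_id, subject_id = subject_id,
                   fold = fold, pred = pred, ref = ref, naive = naive,
                   diff = pred - ref)
  class(df) <- c("prediction_set", class(df))
  df
}

#' Mean error (bias) of a prediction set
#' @param preds A [prediction_set()] or numeric vector of differences.
#' @return Mean of `pred - ref` in mmHg.
#' @export
mean_error <- function(preds) {
  d <- if (is.data.frame(preds)) preds$diff else preds
  if (length(d) < 1L) stop_spec("mean_error: empty input")
  mean(d)
}

#' Standard deviation of the prediction differences
#'
#' Sample SD with the n-1 denominator.
#' @inheritParams mean_error
#' @return SD in mmHg.
#' @export
sd_of_differences <- function(preds) {
  d <- if (is.data.frame(preds)) preds$diff else preds
  if (length(d) < 2L) stop_spec("sd_of_differences: need n >= 2")
  sd(d)
}

#' Mean absolute error of a prediction set
#' @inheritParams mean_error
#' @return MAE in mmHg.
#' @export
mean_absolute_error <- function(preds) {
  d <- if (is.data.frame(preds)) preds$diff else preds
  if (length(d) < 1L) stop_spec("mean_absolute_error: empty input")
  mean(abs(d))
}

#' Naive (training-mean) predictor
#'
#' Predicts the mean of the training labels for every test segment.
#'
#' @param train_labels Numeric training labels in mmHg.
#' @return A function `f(n)` returning `n` identical predictions (and
#'   carrying the mean as attribute `level`).
#' @export
naive_predictor <- function(train_labels) {
  if (length(train_labels) < 1L) stop_spec("naive_predictor: empty training set")
  level <- mean(train_labels)
  structure(function(n) rep(level, n), level = level)
}

#' Mean absolute scaled error, in percent
#'
#' `100 * MAE(preds) / MAE(naive_preds)`, both against the same references.
#' 100 means no better than the training-mean predictor; the metric is
#' scale-free so it compares across datasets with different BP ranges.
#'
#' @param preds A [prediction_set()] (its `naive` column supplies the naive
#'   predictions unless `naive_preds` is given).
#' @param naive_preds Optional explicit naive predictions.
#' @return MASE in percent.
#' @export
mase <- function(preds, naive_preds = NULL) {
  if (is.null(naive_preds)) {
    if (!is.data.frame(preds) || anyNA(preds$naive)) {
      stop_spec("mase: naive predictions required")
    }
    naive_preds <- preds$naive
  }
  mae_model <- mean_absolute_error(preds)
  ref <- if (is.data.frame(preds)) preds$ref else stop_spec("mase: need references")
  mae_naive <- mean(abs(naive_preds - ref))
  if (mae_naive == 0) {
    stop_spec("mase: undefined — the naive predictor is exact (constant labels)")
  }
  100 * mae_model / mae_naive
}

#' Pooled-across-folds evaluation report
#'
#' Concatenates the per-fold prediction sets first and computes ME/SD/MAE
#' once on the pooled set (never averaging per-fold metrics); MASE pools the
#' per-fold naive predictions (each fold's training mean) the same way.
#'
#' @param fold_preds A single [prediction_set()] or a list of per-fold
#'   prediction sets; each test segment must appear exactly once.
#' @return List with `me`, `sd`, `mae`, `mae_naive`, `mase` (percent), `n`.
#' @export
pooled_metrics <- function(fold_preds) {
  if (is.data.frame(fold_preds)) fold_preds <- list(fold_preds)
  pooled <- do.call(rbind, fold_preds)
  if (anyDuplicated(pooled$segment_id)) {
    stop_spec("pooled_metrics: segment predicted more than once across folds")
  }
  list(me = mean_error(pooled),
       sd = sd_of_differences(pooled),
       mae = mean_absolute_error(pooled),
       mae_naive = mean(abs(pooled$naive - pooled$ref)),
       mase = mase(pooled),
       n = nrow(pooled))
}

#' Extract SBP/DBP labels from a predicted pressure waveform
#'
#' Runs the same cycle detection and label extraction used on reference ABP
#' on a model's predicted waveform; undetectable cycles yield a missing
#' result rather than an error so coverage can be reported.
#'
#' @param abp Predicted pressure waveform in mmHg.
#' @param fs Sampling rate in Hz.
#' @param ... Detector settings passed to [detect_cycles()].
#' @return Named vector `c(sbp=, dbp=)`, or `NA`s with attribute
#'   `missing_reason` when no cycle is detectable.
#' @export
labels_from_predicted_abp <- function(abp, fs, ...) {
  cyc <- detect_cycles(abp, fs, ...)
  if (is_fail(cyc)) {
    return(structure(c(sbp = NA_real_, dbp = NA_real_),
                     missing_reason = cyc$reason))
  }
  extract_bp_labels(abp, cyc)
}

#' Paired bootstrap comparison of two models' MASE
#'
#' Resamples segment indices with replacement (paired across models),
#' recomputes each model's MASE and their difference per replicate, and
#' reports percentile intervals at Bonferroni-corrected levels
#' `1 - alpha / n_comparisons`. The significance mark is the smallest alpha
#' whose corrected interval excludes zero.
#'
#' @param preds_a,preds_b [prediction_set()]s over the same segments (same
#'   `segment_id`s, same references).
#' @param n_boot Number of bootstrap replicates.
#' @param alphas Significance levels to test, decreasing stringency.
#' @param n_comparisons Bonferroni divisor (number of pairwise tests drawn
#'   together).
#' @param seed Integer seed.
#' @return List with `mark` (`"***"`, `"**"`, `"*"` or `"ns"`),
#'   `diff_ci` (per-alpha intervals of MASE_A - MASE_B), `mase_a_ci`,
#'   `mase_b_ci` (95% own-model intervals), and the observed MASEs.
#' @export
bootstrap_compare <- function(preds_a, preds_b, n_boot = 2000,
                              alphas = c(0.05, 0.01, 0.001),
                              n_comparisons = 1, seed = 1L) {
  a <- preds_a[order(preds_a$segment_id), ]
  b <- preds_b[order(preds_b$segment_id), ]
  if (nrow(a) != nrow(b) || !all(a$segment_id == b$segment_id) ||
      !all(a$ref == b$ref)) {
    stop_spec("bootstrap_compare: models must predict the same segments")
  }
  n <- nrow(a)
  boot <- with_seed(seed, {
    t(vapply(seq_len(n_boot), function(r) {
      idx <- sample.int(n, n, replace = TRUE)
      mn <- mean(abs(a$naive[idx] - a$ref[idx]))
      if (mn == 0) return(c(NA_real_, NA_real_))
      ma <- 100 * mean(abs(a$pred[idx] - a$ref[idx])) / mn
      mb <- 100 * mean(abs(b$pred[idx] - b$ref[idx])) / mn
      c(ma, mb)
    }, numeric(2)))
  })
  boot <- boot[stats::complete.cases(boot), , drop = FALSE]
  diffs <- boot[, 1] - boot[, 2]
  alphas <- sort(alphas, decreasing = TRUE)
  diff_ci <- lapply(alphas, function(al) {
    al_c <- min(al / n_comparisons, 1)
    unname(quantile(diffs, c(al_c / 2, 1 - al_c / 2)))
  })
  names(diff_ci) <- paste0("alpha_", alphas)
  sig <- vapply(diff_ci, function(ci) ci[1] > 0 || ci[2] < 0, logical(1))
  mark <- if (all(sig)) "***"
          else if (all(sig[1:2])) "**"
          else if (sig[1]) "*"
          else "ns"
  list(mark = mark, diff_ci = diff_ci,
       mase_a = mase(a), mase_b = mase(b),
       mase_a_ci = unname(quantile(boot[, 1], c(0.025, 0.975))),
       mase_b_ci = unname(quantile(boot[, 2], c(0.025, 0.975))))
}
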