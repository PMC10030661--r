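# Benchmark harness: tree-ensemble feature ranking and selection, nested-CV
# grid tuning, experiment orchestration (cohort -> pipeline -> features ->
# split -> fit/predict -> pooled evaluation -> bootstrap comparison), and
# the leakage experiment.

feature_columns <- function(features_df) {
  setdiff(names(features_df),
          c("subject_id", "record_id", "segment_index", "sbp", "dbp"))
}

#' Rank features by tree-ensemble impurity importance
#'
#' Fits two fully grown 500-tree ensembles — a bagged random forest and an
#' extremely-randomized (random-split) variant — on the training data and
#' averages their impurity-decrease importances (the regression analogue of
#' Gini importance), normalized to sum to 1 and sorted descending.
#'
#' @param x Feature matrix / data frame (training partition only).
#' @param y Numeric target (SBP or DBP labels).
#' @param n_trees Trees per ensemble.
#' @param seed Integer seed.
#' @return A `feature_ranking`: data frame with `feature`, `importance`
#'   (descending, summing to 1).
#' @export
rank_features <- function(x, y, n_trees = 500, seed = 1L) {
  x <- as.matrix(x)
  if (ncol(x) < 2L) stop_spec("rank_features: need at least 2 features")
  if (nrow(x) < 10L) stop_spec("rank_features: need at least 10 segments")
  if (sd(y) == 0) stop_spec("rank_features: constant target")
  df <- data.frame(x, check.names = FALSE)
  df$.y <- y
  imp <- function(splitrule, s) {
    fit <- ranger::ranger(dependent.variable.name = ".y", data = df,
                          num.trees = n_trees, importance = "impurity",
                          min.node.size = 1, splitrule = splitrule,
                          seed = s, num.threads = 1)
    v <- fit$variable.importance
    v <- pmax(v, 0)
    if (sum(v) == 0) v else v / sum(v)
  }
  avg <- (imp("variance", seed) + imp("extratrees", child_seed(seed, 1L))) / 2
  avg <- avg / sum(avg)
  out <- data.frame(feature = names(avg), importance = unname(avg))
  out <- out[order(-out$importance, out$feature), ]
  rownames(out) <- NULL
  class(out) <- c("feature_ranking", class(out))
  out
}

#' Select the top fraction of ranked features
#'
#' @param ranking A [rank_features()] result.
#' @param rate Fraction of features to keep, in (0, 1]; `ceil(rate * n)`
#'   features are returned in ranking order.
#' @return Character vector of feature names.
#' @export
select_features <- function(ranking, rate) {
  if (!is.numeric(rate) || rate <= 0 || rate > 1) {
    stop_spec("select_features: rate must be in (0, 1]")
  }
  head(ranking$feature, ceiling(rate * nrow(ranking)))
}

expand_param_grid <- function(grid) {
  if (length(grid) == 0L) return(list(list()))
  combos <- expand.grid(grid, KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  lapply(seq_len(nrow(combos)), function(i) as.list(combos[i, , drop = FALSE]))
}

#' Tune and fit a model by nested subject-stratified cross-validation
#'
#' Builds inner folds with [stratified_subject_kfold()] on the training
#' subjects only, grid-searches the model's hyperparameters jointly with the
#' feature-selection rate by mean inner-validation MAE (ties broken by fewer
#' features, then grid order), re-ranks and refits on the full training
#' partition with the winning configuration.
#'
#' @param spec A [bp_model_spec()].
#' @param train_df Training slice of the feature table (columns
#'   `subject_id`, `sbp`, `dbp` + features).
#' @param target `"sbp"` or `"dbp"`.
#' @param K_inner Inner folds (reduced with a warning when there are too
#'   few subjects).
#' @param rank_trees Trees per ranking ensemble.
#' @param seed Integer seed.
#' @return List with `model` (fitted), `params`, `rate`, `features`,
#'   `ranking`, `inner_mae` (winning mean inner MAE).
#' @export
tune_and_fit <- function(spec, train_df, target = "sbp", K_inner = 5,
                         rank_trees = 100, seed = 1L) {
  stopifnot(inherits(spec, "bp_model_spec"))
  cols <- feature_columns(train_df)
  y <- train_df[[target]]
  combos <- expand_param_grid(spec$grid)
  rates <- spec$selection_rates
  n_sub <- length(unique(train_df$subject_id))
  while (K_inner > n_sub && K_inner > 2L) {
    warning(sprintf("too few subjects (%d) for %d inner folds; using %d",
                    n_sub, K_inner, K_inner - 1L))
    K_inner <- K_inner - 1L
  }
  inner_mae <- NULL
  best <- NULL
  if (length(combos) * length(rates) > 1L && n_sub >= 2L) {
    m <- build_subject_matrix(train_df)
    fa <- stratified_subject_kfold(m, K_inner, seed = seed)
    fold_of <- fa$assignment[train_df$subject_id]
    # rank once per inner fold (independent of the candidate configuration)
    fold_ranks <- lapply(seq_len(K_inner), function(f) {
      tr <- fold_of != f
      rank_features(train_df[tr, cols, drop = FALSE], y[tr],
                    n_trees = rank_trees, seed = child_seed(seed, f))
    })
    score <- function(params, rate) {
      maes <- vapply(seq_len(K_inner), function(f) {
        tr <- which(fold_of != f)
        te <- which(fold_of == f)
        if (length(te) == 0L) return(NA_real_)
        feats <- select_features(fold_ranks[[f]], rate)
        mdl <- fit_bp_model(spec, train_df[tr, feats, drop = FALSE], y[tr],
                            params, seed = child_seed(seed, 100L + f))
        mean(abs(predict_bp_model(mdl, train_df[te, feats, drop = FALSE]) - y[te]))
      }, numeric(1))
      mean(maes, na.rm = TRUE)
    }
    results <- expand.grid(combo = seq_along(combos), rate = rates)
    results$mae <- mapply(function(ci, r) score(combos[[ci]], r),
                          results$combo, results$rate)
    # lowest MAE; ties -> fewer features (smaller rate), then grid order
    ord <- order(results$mae, results$rate, results$combo)
    best <- results[ord[1], ]
    inner_mae <- best$mae
  } else {
    best <- data.frame(combo = 1L, rate = rates[1])
  }
  params <- combos[[best$combo]]
  rate <- best$rate
  if (spec$name == "naive" || length(cols) < 2L || rate >= 1) {
    feats <- cols
    ranking <- NULL
  } else {
    ranking <- rank_features(train_df[, cols, drop = FALSE], y,
                             n_trees = rank_trees, seed = seed)
    feats <- select_features(ranking, rate)
  }
  model <- fit_bp_model(spec, train_df[, feats, drop = FALSE], y, params,
                        seed = seed)
  list(model = model, params = params, rate = rate, features = feats,
       ranking = ranking, inner_mae = inner_mae)
}

#' Benchmark experiment configuration
#'
#' @param cohort A [cohort_spec()] (or a list of `bp_record`s under
#'   `records`).
#' @param records Optional pre-generated records (overrides `cohort`).
#' @param pipeline A [pipeline_config()].
#' @param models Named list of [bp_model_spec()]s.
#' @param split_mode `"stratified"` (subject-grouped) or `"leaked"`
#'   (uniform segment assignment).
#' @param K Number of folds.
#' @param targets Targets to evaluate.
#' @param tune Run nested-CV tuning (otherwise first grid point + first
#'   selection rate).
#' @param K_inner Inner folds for tuning.
#' @param n_boot Bootstrap replicates for pairwise comparison (0 disables).
#' @param seed Integer seed for splitting/fitting/bootstrap.
#' @return A `benchmark_config` list.
#' @export
benchmark_config <- function(cohort = NULL, records = NULL,
                             pipeline = pipeline_config(),
                             models = list(naive = bp_model_spec("naive")),
                             split_mode = c("stratified", "leaked"),
                             K = 5, targets = c("sbp", "dbp"),
                             tune = FALSE, K_inner = 5, n_boot = 0,
                             seed = 1L) {
  split_mode <- match.arg(split_mode)
  structure(list(cohort = cohort, records = records, pipeline = pipeline,
                 models = models, split_mode = split_mode, K = K,
                 targets = targets, tune = tune, K_inner = K_inner,
                 n_boot = n_boot, seed = as.integer(seed)),
            class = "benchmark_config")
}

#' Run a full benchmark experiment
#'
#' Generates (or takes) the cohort, cleans it, extracts features, splits by
#' the configured mode, per fold fits each model on the training partition
#' (with optional nested tuning) and predicts the test fold, pools the
#' predictions across folds and reports ME/SD/MAE/MASE per model and
#' target, plus Bonferroni-corrected pairwise bootstrap comparisons.
#'
#' @param config A [benchmark_config()].
#' @return An `evaluation_report`: list with `metrics` (data frame),
#'   `predictions`, `comparisons`, `fold_assignment`, `audit`, `features`.
#' @export
run_benchmark <- function(config) {
  stopifnot(inherits(config, "benchmark_config"))
  records <- config$records %||% generate_cohort(config$cohort)
  pipe <- run_pipeline(records, config$pipeline)
  features <- pipe$features
  if (is.null(features) || nrow(features) < 2L) {
    stop_spec("run_benchmark: pipeline kept too few segments (stage: pipeline)")
  }
  cols <- feature_columns(features)
  if (config$split_mode == "stratified") {
    m <- build_subject_matrix(features)
    fa <- stratified_subject_kfold(m, config$K, seed = config$seed)
    fold_of <- unname(fa$assignment[features$subject_id])
  } else {
    fa <- leaked_split(features, config$K, seed = config$seed)
    fold_of <- fa$assignment
  }
  preds <- list()
  tuning <- list()
  for (target in config$targets) {
    y <- features[[target]]
    for (mn in names(config$models)) {
      spec <- config$models[[mn]]
      fold_sets <- lapply(seq_len(config$K), function(f) {
        tr <- which(fold_of != f)
        te <- which(fold_of == f)
        if (length(te) == 0L) return(NULL)
        naive_level <- mean(y[tr])
        if (config$tune) {
          tf <- tune_and_fit(spec, features[tr, , drop = FALSE], target,
                             K_inner = config$K_inner,
                             seed = child_seed(config$seed, f))
          mdl <- tf$model
          feats <- tf$features
          tuning[[paste(target, mn, f, sep = ".")]] <<- tf[c("params", "rate", "inner_mae")]
        } else {
          feats <- cols
          if (spec$selection_rates[1] < 1 && spec$name != "naive") {
            rk <- rank_features(features[tr, cols, drop = FALSE], y[tr],
                                n_trees = 100,
                                seed = child_seed(config$seed, f))
            feats <- select_features(rk, spec$selection_rates[1])
          }
          mdl <- fit_bp_model(spec, features[tr, feats, drop = FALSE], y[tr],
                              seed = child_seed(config$seed, f))
        }
        p <- predict_bp_model(mdl, features[te, feats, drop = FALSE])
        prediction_set(p, y[te], naive = naive_level,
                       subject_id = features$subject_id[te], fold = f,
                       segment_id = te)
      })
      preds[[paste(mn, target, sep = ".")]] <-
        do.call(rbind, fold_sets[!vapply(fold_sets, is.null, logical(1))])
    }
  }
  metrics <- do.call(rbind, lapply(names(preds), function(key) {
    parts <- strsplit(key, ".", fixed = TRUE)[[1]]
    pm <- pooled_metrics(preds[[key]])
    data.frame(model = parts[1], target = toupper(parts[2]),
               me = pm$me, sd = pm$sd, mae = pm$mae,
               mae_naive = pm$mae_naive, mase = pm$mase, n = pm$n)
  }))
  comparisons <- list()
  model_names <- names(config$models)
  if (config$n_boot > 0 && length(model_names) > 1L) {
    pairs <- utils::combn(model_names, 2, simplify = FALSE)
    for (target in config$targets) {
      for (pr in pairs) {
        key <- paste(pr[1], pr[2], target, sep = ".")
        comparisons[[key]] <- bootstrap_compare(
          preds[[paste(pr[1], target, sep = ".")]],
          preds[[paste(pr[2], target, sep = ".")]],
          n_boot = config$n_boot, n_comparisons = length(pairs),
          seed = child_seed(config$seed, 999L))
      }
    }
  }
  structure(list(metrics = metrics, predictions = preds,
                 comparisons = comparisons, fold_assignment = fa,
                 audit = pipe$audit, features = features,
                 tuning = tuning, config = config),
            class = "evaluation_report")
}

#' @export
print.evaluation_report <- function(x, ...) {
  cat("Benchmark evaluation (pooled across folds)\n")
  df <- x$metrics
  df$me <- sprintf("%.2f", df$me); df$sd <- sprintf("%.2f", df$sd)
  df$mae <- sprintf("%.2f", df$mae); df$mase <- sprintf("%.2f", df$mase)
  print(df[, c("model", "target", "mae", "me", "sd", "mase", "n")],
        row.names = FALSE)
  invisible(x)
}

#' Compare subject-grouped and leaked splitting on the same cohort
#'
#' Runs the same models under the subject-grouped stratified split and under
#' the uniform segment-level (leaky) split, reporting both pooled MASEs and
#' the measured leakage fractions — the mechanism by which subject leakage
#' inflates apparent accuracy for models that can memorize subjects.
#'
#' @param config A [benchmark_config()] (its `split_mode` is overridden).
#' @return List with `grouped` and `leaked` evaluation reports and a
#'   `summary` data frame (model, target, MASE under both splits, leakage
#'   fractions).
#' @export
leakage_experiment <- function(config) {
  config$records <- config$records %||% generate_cohort(config$cohort)
  cfg_g <- config; cfg_g$split_mode <- "stratified"
  cfg_l <- config; cfg_l$split_mode <- "leaked"
  rep_g <- run_benchmark(cfg_g)
  rep_l <- run_benchmark(cfg_l)
  s <- merge(rep_g$metrics[, c("model", "target", "mase")],
             rep_l$metrics[, c("model", "target", "mase")],
             by = c("model", "target"), suffixes = c("_grouped", "_leaked"))
  s$leakage_grouped <- rep_g$fold_assignment$leakage_fraction
  s$leakage_leaked <- rep_l$fold_assignment$leakage_fraction
  list(grouped = rep_g, leaked = rep_l, summary = s)
}
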