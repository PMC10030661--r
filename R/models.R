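# Reference Feat2Lab model zoo behind one fit/predict contract: the naive
# training-mean baseline, a k-nearest-neighbour regressor (deliberately
# subject-memorizing, used in leakage experiments), random forest, support
# vector regression, gradient-boosted trees, boosted stumps and a single-
# hidden-layer feed-forward net.

bp_model_names <- function() {
  c("naive", "knn", "rf", "svr", "gbt", "stump_boost", "mlp")
}

#' Model specification for the benchmark harness
#'
#' @param name One of `naive`, `knn`, `rf`, `svr`, `gbt`, `stump_boost`,
#'   `mlp`.
#' @param grid Named list of hyperparameter value vectors to grid-search
#'   (defaults to a single sensible point per model; see
#'   [feat2lab_grid()] for the full published-style search space).
#' @param selection_rates Feature-selection rate values in (0, 1] to search.
#' @return A `bp_model_spec`.
#' @export
bp_model_spec <- function(name, grid = NULL, selection_rates = 1.0) {
  if (!name %in% bp_model_names()) {
    stop_spec("unknown model '%s'; available: %s", name,
              paste(bp_model_names(), collapse = ", "))
  }
  if (any(selection_rates <= 0 | selection_rates > 1)) {
    stop_spec("selection_rates must be in (0, 1]")
  }
  if (is.null(grid)) grid <- default_model_grid(name)
  structure(list(name = name, grid = grid,
                 selection_rates = selection_rates),
            class = "bp_model_spec")
}

default_model_grid <- function(name) {
  switch(name,
    naive = list(),
    knn = list(k = 3),
    rf = list(num_trees = 200, min_node_size = 5, sample_fraction = 0.9,
              mtry_frac = 0.7),
    svr = list(cost = 10, gamma = 0.1, epsilon = 0.1),
    gbt = list(nrounds = 150, max_depth = 5, eta = 0.1,
               min_child_weight = 5, subsample = 0.9),
    stump_boost = list(nrounds = 150, eta = 0.1, min_child_weight = 5),
    mlp = list(size = 32, decay = 1e-3))
}

#' Full hyperparameter search spaces for the Feat2Lab families
#'
#' The published-style grids: feature-selection rates 0.05-1.0; SVR
#' cost/gamma/epsilon ranges; tree counts, depths and leaf sizes for the
#' forest and boosting families; hidden sizes for the feed-forward net
#' (single hidden layer in this implementation).
#'
#' @param name Model name as in [bp_model_spec()].
#' @return Named list of value vectors.
#' @export
feat2lab_grid <- function(name) {
  switch(name,
    svr = list(cost = c(1, 5.4, 10, 100, 170, 1001),
               gamma = c(0.001, 0.008, 0.1, 0.7, 1),
               epsilon = c(0.0003, 0.007, 0.01, 0.05, 0.1, 0.15, 0.2)),
    rf = list(num_trees = c(10, 50, 100, 150, 200, 300, 400),
              min_node_size = c(5, 25, 50),
              sample_fraction = c(0.5, 0.7, 0.9),
              mtry_frac = c(0.3, 0.7, 1)),
    gbt = list(nrounds = c(10, 50, 100, 150, 200, 300, 400),
               eta = c(0.01, 0.05, 0.1),
               max_depth = c(1, 3, 5, 8),
               min_child_weight = c(5, 25, 50),
               subsample = c(0.5, 0.7, 1)),
    stump_boost = list(nrounds = c(5, 10, 50, 100, 150, 200),
                       eta = c(0.05, 0.1),
                       min_child_weight = c(5, 25, 50)),
    mlp = list(size = c(32, 64, 256), decay = c(1e-4, 1e-3)),
    knn = list(k = c(1, 3, 5, 9)),
    naive = list(),
    stop_spec("unknown model '%s'", name))
}

#' Published-style feature-selection rate grid
#' @return Numeric vector of selection rates.
#' @export
selection_rate_grid <- function() {
  c(0.05, 0.1, 0.15, 0.2, 0.25, 0.3, 0.4, 0.5, 0.7, 0.9, 1.0)
}

drop_constant_columns <- function(x) {
  keep <- vapply(seq_len(ncol(x)), function(j) {
    v <- x[, j]
    is.finite(sd(v)) && sd(v) > 0
  }, logical(1))
  x[, keep, drop = FALSE]
}

#' Fit a reference model
#'
#' @param spec A [bp_model_spec()] (or model name).
#' @param x Numeric feature matrix / data frame (rows = segments).
#' @param y Numeric target labels (mmHg).
#' @param params Named list of hyperparameter values (one value each);
#'   defaults to the first value of each grid entry.
#' @param seed Integer seed (models with internal randomness).
#' @return A `bp_fitted_model`; use [predict_bp_model()] on new data.
#' @export
fit_bp_model <- function(spec, x, y, params = NULL, seed = 1L) {
  if (is.character(spec)) spec <- bp_model_spec(spec)
  x <- as.matrix(x)
  storage.mode(x) <- "double"
  if (is.null(params)) params <- lapply(spec$grid, `[`, 1)
  x <- drop_constant_columns(x)
  cols <- colnames(x)
  fit <- switch(spec$name,
    naive = list(level = mean(y)),
    knn = {
      mu <- colMeans(x); sg <- apply(x, 2, sd)
      list(x = scale(x, mu, sg), y = y, mu = mu, sg = sg,
           k = params$k %||% 3)
    },
    rf = {
      df <- data.frame(x, check.names = FALSE)
      df$.y <- y
      ranger::ranger(
        dependent.variable.name = ".y", data = df,
        num.trees = params$num_trees %||% 200,
        min.node.size = params$min_node_size %||% 5,
        sample.fraction = params$sample_fraction %||% 0.9,
        mtry = max(1L, floor((params$mtry_frac %||% 0.7) * ncol(x))),
        seed = seed, num.threads = 1)
    },
    svr = e1071::svm(x, y, type = "eps-regression", kernel = "radial",
                     cost = params$cost %||% 10,
                     gamma = params$gamma %||% (1 / ncol(x)),
                     epsilon = params$epsilon %||% 0.1),
    gbt = xgboost::xgboost(
      x, y, objective = "reg:squarederror",
      nrounds = params$nrounds %||% 150,
      max_depth = params$max_depth %||% 5,
      learning_rate = params$eta %||% 0.1,
      min_child_weight = params$min_child_weight %||% 5,
      subsample = params$subsample %||% 0.9,
      verbosity = 0, nthreads = 1, seed = seed),
    stump_boost = xgboost::xgboost(
      x, y, objective = "reg:squarederror",
      nrounds = params$nrounds %||% 150,
      max_depth = 1, learning_rate = params$eta %||% 0.1,
      min_child_weight = params$min_child_weight %||% 5,
      verbosity = 0, nthreads = 1, seed = seed),
    mlp = {
      mu <- colMeans(x); sg <- apply(x, 2, sd)
      ym <- mean(y); ys <- sd(y)
      net <- with_seed(seed, nnet::nnet(
        scale(x, mu, sg), (y - ym) / ys, size = params$size %||% 32,
        decay = params$decay %||% 1e-3, linout = TRUE, maxit = 300,
        trace = FALSE, MaxNWts = 100000))
      list(net = net, mu = mu, sg = sg, ym = ym, ys = ys)
    })
  structure(list(name = spec$name, fit = fit, columns = cols,
                 params = params),
            class = "bp_fitted_model")
}

#' Predict from a fitted reference model
#'
#' @param model A `bp_fitted_model`.
#' @param x New feature matrix / data frame.
#' @return Numeric predictions in mmHg.
#' @export
predict_bp_model <- function(model, x) {
  x <- as.matrix(x)
  storage.mode(x) <- "double"
  x <- x[, model$columns, drop = FALSE]
  n <- nrow(x)
  switch(model$name,
    naive = rep(model$fit$level, n),
    knn = {
      f <- model$fit
      xs <- scale(x, f$mu, f$sg)
      tr <- f$x
      d2 <- outer(rowSums(xs^2), rep(1, nrow(tr))) +
        outer(rep(1, n), rowSums(tr^2)) - 2 * xs %*% t(tr)
      apply(d2, 1, function(row) {
        mean(f$y[order(row)[seq_len(min(f$k, length(row)))]])
      })
    },
    rf = predict(model$fit, data.frame(x, check.names = FALSE),
                 num.threads = 1)$predictions,
    svr = as.numeric(predict(model$fit, x)),
    gbt = ,
    stump_boost = predict(model$fit, x),
    mlp = {
      f <- model$fit
      as.numeric(predict(f$net, scale(x, f$mu, f$sg))) * f$ys + f$ym
    })
}
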