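## Fitting, prediction and tuning behind the uniform learner contract.
## Every downstream module (transformation, stacking, evaluation) talks to
## models only through fit_learner() / predict(), so it never needs to know
## which backend package implements a family.

resolve_params <- function(spec, p) {
  pr <- spec$params
  if (spec$family == "forest") {
    if (is.na(pr$mtry)) pr$mtry <- max(1, floor(sqrt(p)))
    else if (pr$mtry < 0) pr$mtry <- max(1, floor(p / 3))
    pr$mtry <- min(pr$mtry, p)
  }
  if (spec$family == "svm" && is.na(pr$gamma)) pr$gamma <- 1 / p
  pr
}

## Column standardization for families that are scale-sensitive (knn, nn).
## Constant columns get scale 1 so binary fingerprints with dead bits pass
## through unchanged.
make_scaler <- function(X) {
  center <- colMeans(X)
  scale <- apply(X, 2, stats::sd)
  scale[!is.finite(scale) | scale == 0] <- 1
  list(center = center, scale = scale)
}

apply_scaler <- function(scaler, X) {
  scale(X, center = scaler$center, scale = scaler$scale)
}

#' Fit a baseline learner
#'
#' Trains one model of the requested family. The fit is deterministic given
#' `(spec$seed, X, y)`: single-threaded backends with fixed seeds. A
#' zero-variance target is not an error; the model degenerates to the
#' constant predictor and the degeneracy is flagged in `fit_metadata`.
#'
#' @param spec A [learner_spec()].
#' @param X Numeric feature matrix with column names (at least 2 rows).
#' @param y Numeric target vector.
#' @return An object of class `tml_model` carrying the spec, the expected
#'   feature schema, fit metadata and (for forest/boosting) native
#'   importance scores.
#' @export
fit_learner <- function(spec, X, y) {
  stopifnot(inherits(spec, "tml_learner_spec"))
  X <- as_feature_matrix(X)
  y <- as.numeric(y)
  tml_assert(nrow(X) == length(y), "tml_integrity_error",
             "X has %d rows but y has %d values", nrow(X), length(y))
  tml_assert(nrow(X) >= 2, "tml_config_error",
             "need at least 2 training rows, got %d", nrow(X))
  tml_assert(all(is.finite(y)), "tml_integrity_error",
             "target contains non-finite values")
  params <- resolve_params(spec, ncol(X))
  zero_var <- stats::var(y) == 0
  meta <- list(n_train = nrow(X), seed = spec$seed, params = params,
               zero_variance_target = zero_var)
  model <- structure(list(spec = spec, feature_schema = colnames(X),
                          fit_metadata = meta, importance_scores = NULL),
                     class = "tml_model")
  if (zero_var) {
    model$backend <- "constant"
    model$constant <- y[1]
    return(model)
  }
  if (spec$family == "knn") {
    tml_assert(params$k <= nrow(X), "tml_config_error",
               "knn with k=%d needs at least k training rows (have %d)",
               params$k, nrow(X))
  }
  model$backend <- spec$family
  if (spec$family %in% c("knn", "nn")) {
    model$scaler <- make_scaler(X)
    Xs <- apply_scaler(model$scaler, X)
  }
  model$fit <- switch(spec$family,
    forest = {
      rf <- ranger::ranger(x = as.data.frame(X, check.names = FALSE), y = y,
                           num.trees = params$num_trees, mtry = params$mtry,
                           min.node.size = params$min_node_size,
                           importance = "impurity",
                           seed = spec$seed, num.threads = 1)
      imp <- rf$variable.importance
      model$importance_scores <- pmax(imp, 0)[colnames(X)]
      rf
    },
    boosting = {
      bst <- xgboost::xgboost(x = X, y = y, nrounds = params$nrounds,
                              max_depth = params$max_depth,
                              learning_rate = params$eta,
                              subsample = params$subsample,
                              nthreads = 1, verbosity = 0, seed = spec$seed)
      imp <- tryCatch(xgboost::xgb.importance(model = bst),
                      error = function(e) NULL)
      sc <- stats::setNames(rep(0, ncol(X)), colnames(X))
      if (!is.null(imp)) sc[imp$Feature] <- imp$Gain
      model$importance_scores <- sc
      bst
    },
    svm = {
      sds <- apply(X, 2, stats::sd)
      withr::with_seed(spec$seed,
        e1071::svm(x = X, y = y, type = "eps-regression", kernel = "radial",
                   cost = params$cost, gamma = params$gamma,
                   epsilon = params$epsilon, scale = sds > 0))
    },
    knn = caret::knnreg(Xs, y, k = params$k),
    nn = withr::with_seed(spec$seed,
      nnet::nnet(x = Xs, y = y, size = params$size, decay = params$decay,
                 maxit = params$maxit, linout = TRUE, trace = FALSE,
                 MaxNWts = 1e6))
  )
  ## retain zero-importance entries so schemas stay aligned
  if (!is.null(model$importance_scores)) {
    model$importance_scores <- model$importance_scores[colnames(X)]
    names(model$importance_scores) <- colnames(X)
  }
  model
}

#' @export
print.tml_model <- function(x, ...) {
  cat(sprintf("<tml_model> %s on %d features (n_train=%d%s)\n",
              x$spec$family, length(x$feature_schema),
              x$fit_metadata$n_train,
              if (isTRUE(x$fit_metadata$zero_variance_target))
                ", zero-variance target" else ""))
  invisible(x)
}

align_schema <- function(schema, X, what = "model") {
  tml_assert(!is.null(colnames(X)), "tml_schema_error",
             "prediction matrix must have column names")
  missing <- setdiff(schema, colnames(X))
  extra <- setdiff(colnames(X), schema)
  if (length(missing) || length(extra)) {
    tml_stop("tml_schema_error",
             "%s schema mismatch: missing [%s], unexpected [%s]", what,
             paste(missing, collapse = ", "), paste(extra, collapse = ", "))
  }
  X[, schema, drop = FALSE]
}

#' Predict from a fitted learner
#'
#' Columns of `newdata` are realigned to the model's feature schema by name,
#' so column order is irrelevant; missing or unexpected columns raise a
#' schema error naming them. Repeated calls return identical values.
#'
#' @param object A `tml_model` from [fit_learner()].
#' @param newdata Numeric feature matrix.
#' @param ... Unused.
#' @return Numeric prediction vector of length `nrow(newdata)` (empty for a
#'   0-row matrix), all values finite.
#' @export
predict.tml_model <- function(object, newdata, ...) {
  X <- align_schema(object$feature_schema, as_feature_matrix(newdata))
  if (nrow(X) == 0) return(numeric(0))
  if (object$backend == "constant") return(rep(object$constant, nrow(X)))
  if (!is.null(object$scaler)) X <- apply_scaler(object$scaler, X)
  out <- switch(object$backend,
    forest = predict(object$fit, data = as.data.frame(X, check.names = FALSE),
                     num.threads = 1)$predictions,
    boosting = predict(object$fit, X),
    svm = as.numeric(predict(object$fit, X)),
    knn = as.numeric(predict(object$fit, X)),
    nn = as.numeric(predict(object$fit, X)))
  tml_assert(all(is.finite(out)), "tml_integrity_error",
             "model produced non-finite predictions")
  as.numeric(out)
}

#' Tune a learner spec by cross-validated RMSE
#'
#' Full grid search over `spec$grid`: each grid point is scored by mean
#' out-of-fold RMSE over a seeded k-fold split; the minimizing point is
#' returned, with ties broken by grid order. A grid point whose fit fails is
#' scored as `+Inf`, never aborting the search.
#'
#' @param spec A [learner_spec()] with a non-empty `grid`.
#' @param X,y Training data.
#' @param n_folds Number of CV folds (>= 2).
#' @param metric Only `"rmse"` is supported.
#' @return The winning `tml_learner_spec` (grid dropped), with the score
#'   table attached as attribute `"tuning"`.
#' @export
tune_learner <- function(spec, X, y, n_folds = 5, metric = "rmse") {
  stopifnot(inherits(spec, "tml_learner_spec"))
  tml_assert(identical(metric, "rmse"), "tml_config_error",
             "unsupported tuning metric '%s'", metric)
  tml_assert(length(spec$grid) > 0, "tml_config_error",
             "learner spec has an empty tuning grid")
  X <- as_feature_matrix(X)
  grid <- expand.grid(spec$grid, KEEP.OUT.ATTRS = FALSE,
                      stringsAsFactors = FALSE)
  folds <- make_folds(nrow(X), n_folds, spec$seed)
  scores <- vapply(seq_len(nrow(grid)), function(i) {
    cand <- learner_spec(spec$family,
                         params = utils::modifyList(spec$params,
                                                    as.list(grid[i, , drop = FALSE])),
                         grid = spec$grid, seed = spec$seed)
    fold_rmse <- vapply(seq_len(n_folds), function(f) {
      tr <- folds != f
      tryCatch({
        m <- fit_learner(cand, X[tr, , drop = FALSE], y[tr])
        rmse(predict(m, X[!tr, , drop = FALSE]), y[!tr])
      }, error = function(e) Inf)
    }, numeric(1))
    mean(fold_rmse)
  }, numeric(1))
  best <- which.min(scores)  # ties -> first in grid order
  out <- learner_spec(spec$family,
                      params = utils::modifyList(spec$params,
                                                 as.list(grid[best, , drop = FALSE])),
                      grid = spec$grid, seed = spec$seed)
  attr(out, "tuning") <- cbind(grid, cv_rmse = scores)
  out
}

#' Train baseline models for every task in a collection
#'
#' Fits one model per task on that task's full data (the source models the
#' transformed representation is built from) and registers them under tag
#' `"baseline"`.
#'
#' @param collection A `tml_collection`.
#' @param spec A [learner_spec()].
#' @param registry Registry to add to; a fresh one by default.
#' @return The populated `tml_registry`, invisibly usable for
#'   [tml_transform()].
#' @export
train_baselines <- function(collection, spec, registry = model_registry()) {
  digest <- learner_digest(spec)
  for (tid in task_ids(collection)) {
    tk <- collection$tasks[[tid]]
    model <- fit_learner(spec, tk$features, tk$target)
    registry_add(registry, tid, digest, "baseline", model,
                 meta = list(seed = spec$seed, n_train = n_examples(tk)))
  }
  registry
}
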