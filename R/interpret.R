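## Interpretation: which source-task models carry the predictive weight of a
## transformational model, and hierarchical clustering of prediction
## profiles (examples by their predicted values across tasks, or tasks by
## their predicted values across a probe set of examples).

#' Rank source-task models by importance
#'
#' For a model fitted on a transformed representation, ranks the
#' attribute-model columns by how much each contributes to the prediction.
#' `method = "native"` uses the learner's own per-column scores (impurity
#' importance for forests, gain for boosting); families without native
#' scores fall back to permutation importance automatically (recorded in
#' the result). Permutation importance is the mean increase in RMSE over
#' `n_perm` seeded permutations of each column.
#'
#' @param model A `tml_model` (or the `inner` model of a `tml_phi_model`)
#'   fitted on a transformed representation.
#' @param X_tml The transformed feature matrix the model was fitted on (or a
#'   `tml_representation`).
#' @param y Observed targets aligned with `X_tml`.
#' @param method `"native"` or `"permutation"`.
#' @param top_k Number of rows to keep (default: all).
#' @param n_perm Permutations per column (permutation method).
#' @param seed Seed for the permutations.
#' @param normalization `"percent"` (weights rescaled to sum to 100) or
#'   `"raw"`.
#' @return An object of class `tml_importance`: a data.frame with columns
#'   `rank`, `source_task_id`, `weight`, sorted by decreasing weight (ties
#'   broken by task id), plus attributes `method` and `normalization`.
#' @export
attribute_importance <- function(model, X_tml, y,
                                 method = c("native", "permutation"),
                                 top_k = NULL, n_perm = 20, seed = 1L,
                                 normalization = c("percent", "raw")) {
  if (inherits(model, "tml_phi_model")) model <- model$inner
  stopifnot(inherits(model, "tml_model"))
  method <- match.arg(method)
  normalization <- match.arg(normalization)
  M <- if (inherits(X_tml, "tml_representation")) X_tml$matrix
       else as_feature_matrix(X_tml)
  M <- align_schema(model$feature_schema, M)
  fell_back <- FALSE
  if (method == "native" && is.null(model$importance_scores)) {
    method <- "permutation"
    fell_back <- TRUE
  }
  if (method == "native") {
    weights <- model$importance_scores
  } else {
    base_rmse <- rmse(predict(model, M), y)
    weights <- withr::with_seed(seed, vapply(seq_len(ncol(M)), function(j) {
      incr <- vapply(seq_len(n_perm), function(r) {
        Mp <- M
        Mp[, j] <- sample(Mp[, j])
        rmse(predict(model, Mp), y) - base_rmse
      }, numeric(1))
      mean(incr)
    }, numeric(1)))
    names(weights) <- colnames(M)
  }
  weights <- pmax(weights, 0)
  if (normalization == "percent" && sum(weights) > 0) {
    weights <- 100 * weights / sum(weights)
  }
  ids <- sub("^tml:", "", names(weights))
  ord <- order(-weights, ids)
  out <- data.frame(rank = seq_along(ord), source_task_id = ids[ord],
                    weight = unname(weights[ord]), stringsAsFactors = FALSE)
  if (!is.null(top_k)) {
    tml_assert(top_k >= 1, "tml_config_error", "top_k must be >= 1")
    out <- out[seq_len(min(top_k, nrow(out))), ]
  }
  structure(out, class = c("tml_importance", "data.frame"),
            method = method, normalization = normalization,
            native_fallback = fell_back)
}

profile_matrix <- function(matrix, axis) {
  structure(list(matrix = matrix, axis = axis,
                 row_ids = rownames(matrix), column_ids = colnames(matrix)),
            class = "tml_profiles")
}

#' @export
print.tml_profiles <- function(x, ...) {
  cat(sprintf("<tml_profiles> %s: %d x %d\n", x$axis, nrow(x$matrix),
              ncol(x$matrix)))
  invisible(x)
}

#' Example profiles: predicted values of each example across all task models
#'
#' Row = example, column `j` = predictions of source task `j`'s model on all
#' examples (columns sorted by task id). For drugs scored by QSAR models
#' this is the drug's predicted-activity profile across targets.
#'
#' @param registry A populated `tml_registry`.
#' @param digest Learner digest selecting the models.
#' @param X Examples to profile (intrinsic schema).
#' @param tag Registry tag of the models used (`"baseline"` or `"tml"`).
#' @return A `tml_profiles` object with `axis = "example_profiles"`.
#' @export
example_profiles <- function(registry, digest, X, tag = "baseline") {
  ids <- registry_tasks(registry, digest, tag)
  tml_assert(length(ids) >= 2, "tml_dependency_error",
             "profiles need models for at least 2 tasks")
  X <- as_feature_matrix(X)
  cols <- lapply(ids, function(tid) {
    model <- registry_get(registry, tid, digest, tag)
    if (inherits(model, "tml_phi_model")) predict(model, X, registry = registry)
    else predict(model, X)
  })
  M <- matrix(unlist(cols), nrow = nrow(X),
              dimnames = list(rownames(X) %||%
                                paste0("ex_", seq_len(nrow(X))), ids))
  profile_matrix(M, "example_profiles")
}

#' Problem profiles: predicted values of each task model across probe examples
#'
#' The transpose orientation of [example_profiles()]: row = task, column =
#' probe example. Equals `t(example_profiles(...)$matrix)` exactly on the
#' same inputs.
#'
#' @inheritParams example_profiles
#' @param probe_examples Probe feature matrix (e.g. a held-out compound set).
#' @return A `tml_profiles` object with `axis = "problem_profiles"`.
#' @export
problem_profiles <- function(registry, digest, probe_examples,
                             tag = "baseline") {
  ep <- example_profiles(registry, digest, probe_examples, tag = tag)
  profile_matrix(t(ep$matrix), "problem_profiles")
}
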