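## The core computation: re-represent examples by the predictions of models
## trained on the *other* tasks (the extrinsic representation).

new_representation <- function(matrix, column_task_ids, excluded_task_id,
                               order_tag, digest) {
  colnames(matrix) <- paste0("tml:", column_task_ids)
  structure(list(matrix = matrix, column_task_ids = column_task_ids,
                 excluded_task_id = excluded_task_id, order_tag = order_tag,
                 learner_digest = digest),
            class = "tml_representation")
}

#' @export
print.tml_representation <- function(x, ...) {
  cat(sprintf("<tml_representation> %s-order: %d examples x %d source models%s\n",
              x$order_tag, nrow(x$matrix), length(x$column_task_ids),
              if (!is.null(x$excluded_task_id))
                sprintf(" (excluding '%s')", x$excluded_task_id) else ""))
  invisible(x)
}

#' Build the transformed (extrinsic) representation
#'
#' Applies every registered source model of one learner spec to the examples
#' in `X` and collects the predictions as columns: column `j` holds the
#' predictions of the model trained on source task `j`. Columns are ordered
#' by sorted source task id, so the output is invariant to registry
#' insertion order. For an in-collection task its own model is excluded via
#' `exclude_task` (the leave-own-model-out convention); for a genuinely new
#' task leave `exclude_task` unset so all n source models contribute.
#'
#' @param registry A populated `tml_registry` (see [train_baselines()]).
#' @param digest Learner digest selecting the source models (see
#'   [learner_digest()]).
#' @param X Feature matrix in the source models' intrinsic schema.
#' @param exclude_task Optional task id whose model must not contribute a
#'   column.
#' @param tag Registry tag of the source models: `"baseline"` (first-order)
#'   or `"tml"` (used internally for second-order transforms).
#' @return A `tml_representation`; its `matrix` has one column per
#'   non-excluded source model, named `tml:<task_id>`.
#' @export
tml_transform <- function(registry, digest, X, exclude_task = NULL,
                          tag = "baseline") {
  ids <- registry_tasks(registry, digest, tag)
  tml_assert(length(ids) >= 2, "tml_dependency_error",
             "registry holds %d model(s) for this learner spec; need at least 2",
             length(ids))
  keep <- setdiff(ids, exclude_task)
  tml_assert(length(keep) >= 1, "tml_config_error",
             "excluding task '%s' leaves no source models", exclude_task)
  X <- as_feature_matrix(X)
  cols <- lapply(keep, function(tid) {
    model <- registry_get(registry, tid, digest, tag)
    pred <- if (inherits(model, "tml_phi_model")) {
      predict(model, X, registry = registry)
    } else {
      predict(model, X)
    }
    tml_assert(length(pred) == nrow(X) && all(is.finite(pred)),
               "tml_schema_error",
               "source model for task '%s' returned invalid predictions", tid)
    pred
  })
  mat <- matrix(unlist(cols, use.names = FALSE), nrow = nrow(X),
                dimnames = list(rownames(X), NULL))
  new_representation(mat, keep, exclude_task,
                     if (tag == "tml") "second" else "first", digest)
}

#' Concatenate intrinsic and transformed features
#'
#' The combined (augmented) representation: baseline columns first, then the
#' transformed columns, with namespaced names (`base:*`, `tml:<task_id>`).
#'
#' @param X_baseline Intrinsic feature matrix.
#' @param representation A `tml_representation` with the same row count.
#' @return A numeric matrix with `p + m` named columns.
#' @export
combined_representation <- function(X_baseline, representation) {
  stopifnot(inherits(representation, "tml_representation"))
  X <- as_feature_matrix(X_baseline)
  tml_assert(nrow(X) == nrow(representation$matrix), "tml_integrity_error",
             "row mismatch: %d intrinsic vs %d transformed rows",
             nrow(X), nrow(representation$matrix))
  colnames(X) <- paste0("base:", colnames(X))
  cbind(X, representation$matrix)
}

#' Train transformational models for every task
#'
#' For each task the first-order transformed representation is built from
#' the other tasks' baseline models and a meta-learner is fitted on it. The
#' fitted models are registered under tag `"tml"`, wrapped so that
#' prediction on new intrinsic examples internally re-derives the
#' transformed features from the baseline registry (which is what makes
#' second-order transforms possible).
#'
#' @param collection A `tml_collection`.
#' @param registry Registry already holding baseline models for `spec`.
#' @param spec Learner spec of the baseline source models.
#' @param phi_spec Learner spec of the meta-learner; defaults to `spec`
#'   (same method at both levels).
#' @param include_self If `TRUE`, a task's own baseline model contributes a
#'   column to its own representation (off by default).
#' @return The registry, now also holding the `"tml"`-tagged models.
#' @export
train_tml_models <- function(collection, registry, spec, phi_spec = spec,
                             include_self = FALSE) {
  digest <- learner_digest(spec)
  phi_digest <- learner_digest(phi_spec)
  for (tid in task_ids(collection)) {
    tk <- collection$tasks[[tid]]
    rep_i <- tml_transform(registry, digest, tk$features,
                           exclude_task = if (include_self) NULL else tid)
    inner <- fit_learner(phi_spec, rep_i$matrix, tk$target)
    wrapper <- structure(list(inner = inner, base_digest = digest,
                              excluded_task_id = rep_i$excluded_task_id,
                              task_id = tid),
                         class = "tml_phi_model")
    registry_add(registry, tid, phi_digest, "tml", wrapper,
                 meta = list(base_digest = digest))
  }
  registry
}

#' @export
predict.tml_phi_model <- function(object, newdata, registry, ...) {
  tml_assert(inherits(registry, "tml_registry"), "tml_dependency_error",
             "predicting from a transformational model needs the baseline registry")
  rep_new <- tml_transform(registry, object$base_digest, newdata,
                           exclude_task = object$excluded_task_id)
  predict(object$inner, rep_new$matrix)
}

#' Second-order transformed representations
#'
#' Re-applies the transformation one level up: for each task the columns are
#' the predictions of the *other* tasks' first-order transformational
#' models (each of which internally re-derives its own first-order features
#' from the baseline registry). The own-model exclusion rule is identical to
#' first order.
#'
#' @param registry Registry holding `"tml"`-tagged models for `phi_digest`
#'   (see [train_tml_models()]).
#' @param phi_digest Learner digest of the first-order meta-learners.
#' @param collection The task collection.
#' @param include_self Include each task's own first-order model.
#' @return Named list of `tml_representation` objects (`order_tag =
#'   "second"`), one per task.
#' @export
second_order_transform <- function(registry, phi_digest, collection,
                                   include_self = FALSE) {
  have <- registry_tasks(registry, phi_digest, "tml")
  missing <- setdiff(task_ids(collection), have)
  tml_assert(length(missing) == 0, "tml_dependency_error",
             "missing first-order transformational models for: %s",
             paste(missing, collapse = ", "))
  out <- lapply(task_ids(collection), function(tid) {
    tml_transform(registry, phi_digest, collection$tasks[[tid]]$features,
                  exclude_task = if (include_self) NULL else tid,
                  tag = "tml")
  })
  stats::setNames(out, task_ids(collection))
}

#' Data-driven selection of transformed feature columns
#'
#' Keeps the `m_keep` source-model columns scoring highest by absolute
#' Pearson correlation with the target (`method = "correlation"`) or by
#' random-forest impurity importance (`method = "importance"`). Ties are
#' broken by column order. With a constant target the correlation score is
#' undefined; the importance method is used instead and a warning is
#' recorded in the result's metadata.
#'
#' @param representation A `tml_representation`.
#' @param y Target vector aligned with the representation rows.
#' @param m_keep Number of columns to keep (between 1 and m).
#' @param method `"correlation"` (default) or `"importance"`.
#' @param seed Seed for the importance fit.
#' @return A `tml_representation` restricted to the selected columns, with a
#'   `selection` attribute recording scores and any fallback.
#' @export
select_tml_features <- function(representation, y, m_keep,
                                method = c("correlation", "importance"),
                                seed = 1L) {
  stopifnot(inherits(representation, "tml_representation"))
  method <- match.arg(method)
  M <- representation$matrix
  m <- ncol(M)
  tml_assert(m_keep >= 1 && m_keep <= m, "tml_config_error",
             "m_keep must lie in [1, %d], got %s", m, format(m_keep))
  fallback <- FALSE
  if (method == "correlation" && stats::var(y) == 0) {
    method <- "importance"
    fallback <- TRUE
  }
  scores <- if (method == "correlation") {
    s <- abs(suppressWarnings(stats::cor(M, y)))[, 1]
    s[!is.finite(s)] <- 0  # constant columns carry no signal
    s
  } else {
    rf <- fit_learner(learner_spec("forest", params = list(num_trees = 200),
                                   seed = seed), M, y)
    imp <- rf$importance_scores %||% stats::setNames(rep(0, m), colnames(M))
    imp[colnames(M)]
  }
  keep_idx <- sort(order(-scores, seq_len(m))[seq_len(m_keep)])
  out <- new_representation(M[, keep_idx, drop = FALSE],
                            representation$column_task_ids[keep_idx],
                            representation$excluded_task_id,
                            representation$order_tag,
                            representation$learner_digest)
  attr(out, "selection") <- list(method = method, scores = scores,
                                 kept = representation$column_task_ids[keep_idx],
                                 constant_target_fallback = fallback)
  out
}
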