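#' Construct a regression task
#'
#' A task is one learning problem in a multi-task collection: a numeric
#' feature matrix over the shared attribute schema, a real-valued target
#' vector, and per-example identifiers. Binary (fingerprint) features are
#' stored as doubles so fingerprint and continuous features share one code
#' path.
#'
#' @param task_id Unique task identifier (string).
#' @param features Numeric examples-by-features matrix with column names.
#' @param target Numeric target vector, one value per row of `features`.
#' @param example_ids Character vector of per-row identifiers; defaults to
#'   rownames of `features` or `ex_1 ... ex_n`.
#' @param metadata Free-form named list (e.g. target protein name, species).
#' @return An object of class `tml_task`.
#' @examples
#' X <- matrix(rbinom(20, 1, 0.3), 5, 4,
#'             dimnames = list(NULL, paste0("fp_", 1:4)))
#' task("t1", X, rnorm(5))
#' @export
task <- function(task_id, features, target, example_ids = NULL,
                 metadata = list()) {
  tml_assert(is.character(task_id) && length(task_id) == 1 && nzchar(task_id),
             "tml_config_error", "task_id must be a non-empty string")
  X <- as_feature_matrix(features)
  y <- as.numeric(target)
  ids <- as.character(example_ids %||% rownames(X) %||%
                        paste0("ex_", seq_len(nrow(X))))
  tml_assert(nrow(X) == length(y) && nrow(X) == length(ids),
             "tml_integrity_error",
             "task '%s': features (%d rows), target (%d) and example_ids (%d) disagree",
             task_id, nrow(X), length(y), length(ids))
  tml_assert(!anyNA(y) && all(is.finite(y)), "tml_integrity_error",
             "task '%s': target vector contains missing or non-finite values",
             task_id)
  tml_assert(is_finite_matrix(X), "tml_integrity_error",
             "task '%s': feature matrix contains missing or non-finite values",
             task_id)
  tml_assert(!anyDuplicated(ids), "tml_integrity_error",
             "task '%s': duplicated example_ids", task_id)
  rownames(X) <- ids
  structure(list(task_id = task_id, features = X, target = y,
                 example_ids = ids, metadata = metadata),
            class = "tml_task")
}

#' @export
print.tml_task <- function(x, ...) {
  cat(sprintf("<tml_task> '%s': %d examples x %d features\n",
              x$task_id, nrow(x$features), ncol(x$features)))
  invisible(x)
}

n_examples <- function(task) nrow(task$features)

#' Construct a task collection
#'
#' The unit the transformational learner operates on: `n` tasks sharing one
#' ordered feature schema of `p` attributes. Tasks are stored sorted by
#' `task_id`, so iteration order is deterministic and independent of input
#' discovery order.
#'
#' @param tasks List of [task()] objects.
#' @param collection_id Identifier for the collection.
#' @return An object of class `tml_collection`.
#' @export
task_collection <- function(tasks, collection_id = "collection") {
  tml_assert(length(tasks) >= 1, "tml_config_error",
             "a collection needs at least one task")
  tml_assert(all(vapply(tasks, inherits, logical(1), "tml_task")),
             "tml_config_error", "all elements must be tml_task objects")
  ids <- vapply(tasks, `[[`, character(1), "task_id")
  tml_assert(!anyDuplicated(ids), "tml_integrity_error",
             "duplicated task ids: %s",
             paste(unique(ids[duplicated(ids)]), collapse = ", "))
  tasks <- tasks[order(ids)]
  names(tasks) <- sort(ids)
  schema <- colnames(tasks[[1]]$features)
  for (tk in tasks) {
    tml_assert(identical(colnames(tk$features), schema), "tml_schema_error",
               "task '%s' does not match the collection feature schema",
               tk$task_id)
  }
  structure(list(tasks = tasks, feature_schema = schema,
                 collection_id = collection_id),
            class = "tml_collection")
}

#' @export
print.tml_collection <- function(x, ...) {
  cat(sprintf("<tml_collection> '%s': %d tasks, %d shared features\n",
              x$collection_id, length(x$tasks), length(x$feature_schema)))
  invisible(x)
}

#' @rdname task_collection
#' @param collection A `tml_collection`.
#' @export
task_ids <- function(collection) names(collection$tasks)

#' @rdname task_collection
#' @param task_id Task identifier to extract.
#' @export
get_task <- function(collection, task_id) {
  tml_assert(task_id %in% names(collection$tasks), "tml_config_error",
             "no task '%s' in collection '%s'", task_id,
             collection$collection_id)
  collection$tasks[[task_id]]
}

#' @export
length.tml_collection <- function(x) length(x$tasks)
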