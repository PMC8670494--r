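## Model registry: fitted baseline (and transformational) models keyed by
## (task_id, learner digest, representation tag). Backed by an environment so
## training loops can add entries without copying.

REGISTRY_FORMAT_VERSION <- 1L

#' Create an empty model registry
#'
#' Holds the per-task fitted models the transformed representation is built
#' from. Each entry is keyed by the task id, the learner digest (see
#' [learner_digest()]) and a representation tag (`"baseline"` or `"tml"`);
#' at most one model per key triple.
#'
#' @return An object of class `tml_registry`.
#' @export
model_registry <- function() {
  structure(list(env = new.env(parent = emptyenv())), class = "tml_registry")
}

registry_key <- function(task_id, digest, tag) {
  paste(task_id, digest, tag, sep = "\r")
}

#' @rdname model_registry
#' @param registry A `tml_registry`.
#' @param task_id Task the model was trained on.
#' @param digest Learner digest string.
#' @param tag Representation tag, `"baseline"` or `"tml"`.
#' @param model Fitted model object.
#' @param meta Named list of training metadata (seed, fold digest, ...).
#' @param overwrite Replace an existing entry instead of erroring.
#' @export
registry_add <- function(registry, task_id, digest, tag, model,
                         meta = list(), overwrite = FALSE) {
  tml_assert(tag %in% c("baseline", "tml", "combined"), "tml_config_error",
             "unknown representation tag '%s'", tag)
  key <- registry_key(task_id, digest, tag)
  if (!overwrite && !is.null(registry$env[[key]])) {
    tml_stop("tml_integrity_error",
             "registry already holds a model for (%s, %s, %s)",
             task_id, digest, tag)
  }
  registry$env[[key]] <- list(task_id = task_id, digest = digest, tag = tag,
                              model = model,
                              meta = c(meta, list(stored = Sys.time())))
  invisible(registry)
}

registry_get <- function(registry, task_id, digest, tag) {
  entry <- registry$env[[registry_key(task_id, digest, tag)]]
  tml_assert(!is.null(entry), "tml_dependency_error",
             "no registered model for task '%s' (digest '%s', tag '%s')",
             task_id, digest, tag)
  entry$model
}

registry_has <- function(registry, task_id, digest, tag) {
  !is.null(registry$env[[registry_key(task_id, digest, tag)]])
}

#' Enumerate registry entries
#'
#' @param registry A `tml_registry`.
#' @return A data.frame with one row per entry (task_id, digest, tag), sorted.
#' @export
registry_entries <- function(registry) {
  keys <- sort(ls(registry$env))
  parts <- strsplit(keys, "\r", fixed = TRUE)
  data.frame(task_id = vapply(parts, `[[`, character(1), 1),
             digest = vapply(parts, `[[`, character(1), 2),
             tag = vapply(parts, `[[`, character(1), 3),
             stringsAsFactors = FALSE)
}

## Task ids holding a model for a given digest/tag, sorted (the deterministic
## column order of transformed representations).
registry_tasks <- function(registry, digest, tag) {
  e <- registry_entries(registry)
  sort(e$task_id[e$digest == digest & e$tag == tag])
}

#' @export
print.tml_registry <- function(x, ...) {
  e <- registry_entries(x)
  cat(sprintf("<tml_registry> %d entries (%d tasks, %d learner specs)\n",
              nrow(e), length(unique(e$task_id)), length(unique(e$digest))))
  invisible(x)
}

#' Persist / restore a model registry
#'
#' The registry is written as a directory: a JSON metadata index plus one
#' opaque serialized blob per model. Reloading reproduces each model's
#' predictions bit-for-bit for deterministic learners. A serialized format
#' version is checked on load; a mismatch raises an explicit incompatibility
#' error rather than risking silent misprediction.
#'
#' @param registry A `tml_registry`.
#' @param path Directory to write to / read from.
#' @return `save_registry` returns `path` invisibly; `load_registry` returns
#'   the restored `tml_registry`.
#' @export
save_registry <- function(registry, path) {
  dir.create(path, showWarnings = FALSE, recursive = TRUE)
  keys <- sort(ls(registry$env))
  index <- list(format_version = REGISTRY_FORMAT_VERSION, entries = list())
  for (i in seq_along(keys)) {
    entry <- registry$env[[keys[i]]]
    blob <- sprintf("model_%04d.rds", i)
    saveRDS(entry$model, file.path(path, blob))
    index$entries[[i]] <- list(task_id = entry$task_id, digest = entry$digest,
                               tag = entry$tag, blob = blob)
  }
  jsonlite::write_json(index, file.path(path, "index.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(path)
}

#' @rdname save_registry
#' @export
load_registry <- function(path) {
  index_path <- file.path(path, "index.json")
  tml_assert(file.exists(index_path), "tml_format_error",
             "'%s' is not a saved registry (no index.json)", path)
  index <- tryCatch(jsonlite::read_json(index_path),
                    error = function(e) tml_stop("tml_format_error",
                      "could not parse registry index at '%s': %s",
                      index_path, conditionMessage(e)))
  ver <- index$format_version
  tml_assert(identical(as.integer(ver), REGISTRY_FORMAT_VERSION),
             "tml_format_error",
             "registry format version %s is incompatible with this package (expects %d)",
             as.character(ver %||% "<missing>"), REGISTRY_FORMAT_VERSION)
  registry <- model_registry()
  for (entry in index$entries) {
    model <- readRDS(file.path(path, entry$blob))
    registry_add(registry, entry$task_id, entry$digest, entry$tag, model)
  }
  registry
}
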