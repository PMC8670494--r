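## Collection file I/O.
##
## Two on-disk layouts are accepted:
##   * directory-of-tasks: one delimited file per task named <task_id>.csv
##     (or .tsv); first column = example id, last column = target, middle
##     columns = features.
##   * wide single file: columns task_id, example_id, target plus the shared
##     feature columns.
## A character column holding fingerprint bitstrings (name prefixed "fp:" or
## named via `fingerprint_col`) is expanded to one binary column per bit.

infer_delim <- function(path, delim = NULL) {
  if (!is.null(delim)) return(delim)
  if (grepl("\\.tsv$", path, ignore.case = TRUE)) "\t" else ","
}

read_delim_file <- function(path, delim = NULL, char_cols = NULL) {
  sep <- infer_delim(path, delim)
  ## fingerprint bitstring columns must be read as character so leading
  ## zeros survive; peek at the header to build colClasses
  hdr <- as.character(unlist(utils::read.table(path, header = FALSE,
                                               sep = sep, nrows = 1,
                                               stringsAsFactors = FALSE)))
  classes <- ifelse(grepl("^fp:", hdr) | hdr %in% (char_cols %||%
                                                     character(0)),
                    "character", NA)
  utils::read.table(path, header = TRUE, sep = sep, colClasses = classes,
                    stringsAsFactors = FALSE, check.names = FALSE)
}

## Expand any fingerprint columns of a data.frame in place.
expand_fingerprints <- function(df, fingerprint_col = NULL) {
  fp_cols <- union(grep("^fp:", names(df), value = TRUE),
                   intersect(fingerprint_col %||% character(0), names(df)))
  if (length(fp_cols) == 0) return(df)
  keep <- df[, setdiff(names(df), fp_cols), drop = FALSE]
  mats <- lapply(fp_cols, function(cn) {
    prefix <- sub("^fp:", "", cn)
    if (!nzchar(prefix) || prefix == cn) prefix <- "fp"
    expand_fingerprint_column(as.character(df[[cn]]), prefix = prefix)
  })
  cbind(keep, do.call(cbind, mats))
}

task_from_frame <- function(df, task_id, source,
                            id_col = NULL, target_col = NULL) {
  id_col <- id_col %||% names(df)[1]
  target_col <- target_col %||% names(df)[ncol(df)]
  tml_assert(target_col %in% names(df), "tml_format_error",
             "%s: missing target column '%s'", source, target_col)
  feat_cols <- setdiff(names(df), c(id_col, target_col))
  tml_assert(length(feat_cols) >= 1, "tml_format_error",
             "%s: no feature columns found", source)
  X <- df[, feat_cols, drop = FALSE]
  bad <- names(X)[!vapply(X, is.numeric, logical(1))]
  tml_assert(length(bad) == 0, "tml_format_error",
             "%s: non-numeric feature columns: %s", source,
             paste(bad, collapse = ", "))
  tml_assert(!anyNA(X), "tml_integrity_error",
             "%s: missing feature values are not supported", source)
  task(task_id, as_feature_matrix(X), df[[target_col]],
       example_ids = as.character(df[[id_col]]))
}

#' Load a multi-task collection from disk
#'
#' @param path A directory with one delimited file per task, or a single wide
#'   delimited file with `task_id`, `example_id` and `target` columns.
#' @param delim Field delimiter; inferred from the file extension (`.tsv` =
#'   tab, otherwise comma) when `NULL`.
#' @param fingerprint_col Optional name of a character column holding
#'   fingerprint bitstrings to expand into binary feature columns. Columns
#'   whose names start with `fp:` are always expanded.
#' @param collection_id Identifier for the returned collection; defaults to
#'   the path's base name.
#' @return A validated [task_collection()] with deterministic (sorted) task
#'   order and the feature schema taken from the file header(s).
#' @seealso [save_collection()]
#' @export
load_collection <- function(path, delim = NULL, fingerprint_col = NULL,
                            collection_id = NULL) {
  tml_assert(file.exists(path), "tml_format_error", "path '%s' not found", path)
  collection_id <- collection_id %||% sub("\\.(csv|tsv)$", "", basename(path))
  if (dir.exists(path)) {
    files <- list.files(path, pattern = "\\.(csv|tsv)$", full.names = TRUE)
    tml_assert(length(files) >= 1, "tml_format_error",
               "no .csv/.tsv task files under '%s'", path)
    tasks <- lapply(files, function(f) {
      df <- expand_fingerprints(read_delim_file(f, delim, fingerprint_col),
                                fingerprint_col)
      task_from_frame(df, sub("\\.(csv|tsv)$", "", basename(f)), basename(f))
    })
    schema <- colnames(tasks[[1]]$features)
    for (i in seq_along(tasks)) {
      tml_assert(identical(colnames(tasks[[i]]$features), schema),
                 "tml_schema_error",
                 "file '%s' does not match the feature schema of '%s'",
                 basename(files[i]), basename(files[1]))
    }
    return(task_collection(tasks, collection_id))
  }
  df <- read_delim_file(path, delim, fingerprint_col)
  for (cn in c("task_id", "example_id", "target")) {
    tml_assert(cn %in% names(df), "tml_format_error",
               "wide table '%s' lacks required column '%s'", path, cn)
  }
  key <- paste(df$task_id, df$example_id, sep = "\r")
  tml_assert(!anyDuplicated(key), "tml_integrity_error",
             "duplicate (task_id, example_id) pairs in '%s': %s", path,
             paste(utils::head(sub("\r", "/", key[duplicated(key)]), 3),
                   collapse = ", "))
  df <- expand_fingerprints(df, fingerprint_col)
  tasks <- lapply(split(df, df$task_id), function(part) {
    tid <- part$task_id[1]
    part$task_id <- NULL
    ## reorder so example_id is first and target last
    feat <- setdiff(names(part), c("example_id", "target"))
    task_from_frame(part[, c("example_id", feat, "target")], tid,
                    sprintf("task '%s' in '%s'", tid, path))
  })
  task_collection(tasks, collection_id)
}

#' Save a collection as a directory of per-task CSV files
#'
#' Inverse of [load_collection()]: writes `<task_id>.csv` files (example id
#' first, target last) such that reloading reproduces the collection content
#' exactly (values, ordering, ids).
#'
#' @param collection A `tml_collection`.
#' @param path Output directory (created if needed).
#' @return `path`, invisibly.
#' @export
save_collection <- function(collection, path) {
  dir.create(path, showWarnings = FALSE, recursive = TRUE)
  for (tk in collection$tasks) {
    df <- data.frame(example_id = tk$example_ids, check.names = FALSE)
    df <- cbind(df, as.data.frame(tk$features, check.names = FALSE))
    df$target <- tk$target
    utils::write.csv(df, file.path(path, paste0(tk$task_id, ".csv")),
                     row.names = FALSE)
  }
  invisible(path)
}
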