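## Internal helpers shared across modules.

`%||%` <- function(a, b) if (is.null(a)) b else a

## Classed conditions so callers can distinguish schema/format/config failures.
tml_stop <- function(class, fmt, ...) {
  stop(errorCondition(sprintf(fmt, ...), class = c(class, "tml_error")))
}

tml_assert <- function(ok, class, fmt, ...) {
  if (!isTRUE(ok)) tml_stop(class, fmt, ...)
  invisible(TRUE)
}

## Canonical, human-readable string form of a (possibly nested) named list.
## Used for learner digests and config provenance: stable across sessions,
## independent of element order.
canonical_string <- function(x) {
  if (is.null(x)) return("NULL")
  if (is.list(x)) {
    nm <- names(x) %||% rep("", length(x))
    ord <- order(nm)
    parts <- vapply(ord, function(i) {
      paste0(nm[i], "=", canonical_string(x[[i]]))
    }, character(1))
    return(paste0("{", paste(parts, collapse = ","), "}"))
  }
  if (is.numeric(x)) return(paste(format(x, digits = 15, trim = TRUE),
                                  collapse = ";"))
  paste(as.character(x), collapse = ";")
}

## Deterministic 31-bit integer seed derived from a base seed and a string id.
## Keeps every derived seed below 2^31 - 1 so set.seed() accepts it.
derive_seed <- function(seed, id) {
  h <- as.double(seed) %% 2147483647
  for (ch in utf8ToInt(as.character(id))) {
    h <- (h * 31 + ch) %% 2147483647
  }
  as.integer(h)
}

## Balanced k-fold assignment, seeded. Returns integer vector of fold labels.
make_folds <- function(n, k, seed) {
  tml_assert(k >= 2, "tml_config_error", "need at least 2 folds, got %d", k)
  tml_assert(n >= k, "tml_config_error",
             "cannot split %d rows into %d folds", n, k)
  withr::with_seed(seed, sample(rep_len(seq_len(k), n)))
}

fold_digest <- function(folds) paste(folds, collapse = "")

is_finite_matrix <- function(m) all(is.finite(m))

## Coerce a data.frame / matrix of features to a double matrix with colnames.
as_feature_matrix <- function(x) {
  m <- as.matrix(x)
  storage.mode(m) <- "double"
  tml_assert(!is.null(colnames(m)), "tml_schema_error",
             "feature matrix must have column names")
  m
}
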