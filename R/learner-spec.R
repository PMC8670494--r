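## Learner specifications: a uniform, learner-agnostic description of the five
## baseline model families (random forest, gradient boosting, RBF support
## vector regression, k-nearest neighbours, single-hidden-layer neural net).

LEARNER_FAMILIES <- c("forest", "boosting", "svm", "knn", "nn")

## Allowed hyperparameter keys per family; unknown keys are rejected.
LEARNER_PARAM_KEYS <- list(
  forest = c("num_trees", "mtry", "min_node_size"),
  boosting = c("nrounds", "max_depth", "eta", "subsample"),
  svm = c("cost", "gamma", "epsilon"),
  knn = c("k"),
  nn = c("size", "decay", "maxit")
)

## Shipped defaults. Benchmark studies in this area tend to tune baselines
## without stating the grids; ours are explicit, conventional stand-ins and
## fully overridable (also available as YAML in inst/extdata).
default_params <- function(family) {
  switch(family,
    forest = list(num_trees = 500, mtry = NA_real_, min_node_size = 5),
    boosting = list(nrounds = 200, max_depth = 3, eta = 0.1, subsample = 1),
    svm = list(cost = 1, gamma = NA_real_, epsilon = 0.1),
    knn = list(k = 5),
    nn = list(size = 64, decay = 0.01, maxit = 200))
}

default_grid <- function(family) {
  switch(family,
    forest = list(mtry = c(NA_real_, -1)),  # NA = sqrt(p), -1 = p/3
    boosting = list(max_depth = c(3, 6)),
    svm = list(cost = c(0.1, 1, 10)),
    knn = list(k = c(1, 3, 5, 11, 25)),
    nn = list(size = c(64, 256)))
}

#' Describe a baseline learner
#'
#' @param family One of `"forest"`, `"boosting"`, `"svm"`, `"knn"`, `"nn"`.
#' @param params Named list of hyperparameters overriding the family
#'   defaults. Unknown keys are rejected. `mtry = NA` means `sqrt(p)` and
#'   `mtry = -1` means `p/3`, resolved at fit time; `gamma = NA` means
#'   `1 / p`.
#' @param grid Optional named list of candidate hyperparameter values for
#'   [tune_learner()]; defaults to a small family-specific grid.
#' @param seed Integer seed making fit/predict deterministic.
#' @return An object of class `tml_learner_spec`.
#' @examples
#' learner_spec("knn", params = list(k = 3), seed = 7)
#' @export
learner_spec <- function(family, params = list(), grid = NULL, seed = 1L) {
  tml_assert(length(family) == 1 && family %in% LEARNER_FAMILIES,
             "tml_config_error",
             "unknown learner family '%s' (expected one of %s)",
             paste(family, collapse = ","),
             paste(LEARNER_FAMILIES, collapse = ", "))
  allowed <- LEARNER_PARAM_KEYS[[family]]
  bad <- setdiff(names(params), allowed)
  tml_assert(length(bad) == 0, "tml_config_error",
             "unknown hyperparameters for family '%s': %s", family,
             paste(bad, collapse = ", "))
  bad_grid <- setdiff(names(grid %||% list()), allowed)
  tml_assert(length(bad_grid) == 0, "tml_config_error",
             "unknown grid keys for family '%s': %s", family,
             paste(bad_grid, collapse = ", "))
  full <- utils::modifyList(default_params(family), as.list(params))
  structure(list(family = family, params = full,
                 grid = grid %||% default_grid(family),
                 seed = as.integer(seed)),
            class = "tml_learner_spec")
}

#' @rdname learner_spec
#' @param spec A `tml_learner_spec`.
#' @return `learner_digest` returns a deterministic string identifying the
#'   family plus its (sorted) hyperparameters and seed; registries key their
#'   entries by it.
#' @export
learner_digest <- function(spec) {
  stopifnot(inherits(spec, "tml_learner_spec"))
  paste0(spec$family, canonical_string(spec$params), "#", spec$seed)
}

#' @export
print.tml_learner_spec <- function(x, ...) {
  cat(sprintf("<tml_learner_spec> %s (%s), seed %d\n", x$family,
              paste(names(x$params), unlist(x$params), sep = "=",
                    collapse = ", "), x$seed))
  invisible(x)
}

#' Read learner specs from a YAML config
#'
#' Accepts either a single mapping (`family:`, optional `params:`, `grid:`,
#' `seed:`) or a sequence of such mappings.
#'
#' @param path Path to a YAML file.
#' @return A list of `tml_learner_spec` objects.
#' @export
read_learner_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  if (!is.null(cfg$family)) cfg <- list(cfg)
  lapply(cfg, function(item) {
    learner_spec(item$family, params = item$params %||% list(),
                 grid = item$grid, seed = item$seed %||% 1L)
  })
}
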