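## Synthetic multi-task benchmark generator.
##
## Emulates the structure the transformational approach assumes: many small
## regression tasks whose true functions share latent structure. Features x
## (binary fingerprint-like or Gaussian) load onto a k-dimensional latent
## signal z = x B shared by all tasks; each task's target is a (possibly
## squashed) linear function of z with task coefficients
##   w_i = sqrt(rho) * w_bar + sqrt(1 - rho) * u_i,
## so Corr(w_i, w_j) = rho controls function relatedness, plus additive
## Gaussian noise. A fraction of each task's examples is drawn from a shared
## pool, the second relatedness channel (shared molecules across assays).

#' Configure the synthetic task generator
#'
#' @param n_tasks Number of tasks.
#' @param n_examples Examples per task.
#' @param p_features Number of intrinsic features.
#' @param latent_dim Latent dimension k (<= p).
#' @param relatedness rho in `[0, 1]`: expected correlation between any two
#'   tasks' true coefficient vectors.
#' @param group_structure Optional list with `sizes` (task-group sizes
#'   summing to `n_tasks`), `rho_within` and `rho_between`, planting block
#'   relatedness (within-group vs between-group coefficient correlation).
#'   Overrides `relatedness`.
#' @param noise_sd Additive noise standard deviation; `NULL` (default)
#'   means `0.5 * sd(signal)` per task.
#' @param feature_kind `"binary_fingerprint"` (each bit Bernoulli with
#'   per-bit frequency drawn from Beta(0.3, 1), sparse and
#'   fingerprint-like) or `"gaussian"` (standard normal).
#' @param nonlinearity `"none"`, `"squash"` (tanh of the standardized
#'   linear index) or `"interactions"` (adds a product of the first two
#'   latent coordinates).
#' @param overlap_fraction Fraction of each task's examples drawn from a
#'   shared example pool.
#' @param seed Integer seed; generation is fully reproducible from it.
#' @return An object of class `tml_generator_config`.
#' @export
generator_config <- function(n_tasks = 60, n_examples = 100,
                             p_features = 128, latent_dim = 10,
                             relatedness = 0.9, group_structure = NULL,
                             noise_sd = NULL,
                             feature_kind = c("binary_fingerprint",
                                              "gaussian"),
                             nonlinearity = c("squash", "none",
                                              "interactions"),
                             overlap_fraction = 0.3, seed = 20211129) {
  feature_kind <- match.arg(feature_kind)
  nonlinearity <- match.arg(nonlinearity)
  tml_assert(n_tasks >= 1 && n_examples >= 2 && p_features >= 1,
             "tml_config_error", "invalid collection dimensions")
  tml_assert(latent_dim >= 1 && latent_dim <= p_features,
             "tml_config_error", "latent_dim must lie in [1, p_features]")
  tml_assert(relatedness >= 0 && relatedness <= 1, "tml_config_error",
             "relatedness must lie in [0, 1]")
  tml_assert(overlap_fraction >= 0 && overlap_fraction <= 1,
             "tml_config_error", "overlap_fraction must lie in [0, 1]")
  tml_assert(is.null(noise_sd) || noise_sd >= 0, "tml_config_error",
             "noise_sd must be nonnegative")
  if (!is.null(group_structure)) {
    tml_assert(is.list(group_structure) &&
                 !is.null(group_structure$sizes) &&
                 sum(group_structure$sizes) == n_tasks,
               "tml_config_error",
               "group_structure$sizes must sum to n_tasks")
    for (fld in c("rho_within", "rho_between")) {
      val <- group_structure[[fld]] %||% relatedness
      tml_assert(val >= 0 && val <= 1, "tml_config_error",
                 "group_structure$%s must lie in [0, 1]", fld)
      group_structure[[fld]] <- val
    }
  }
  structure(list(n_tasks = as.integer(n_tasks),
                 n_examples = as.integer(n_examples),
                 p_features = as.integer(p_features),
                 latent_dim = as.integer(latent_dim),
                 relatedness = relatedness,
                 group_structure = group_structure,
                 noise_sd = noise_sd, feature_kind = feature_kind,
                 nonlinearity = nonlinearity,
                 overlap_fraction = overlap_fraction,
                 seed = as.integer(seed %% 2147483647)),
            class = "tml_generator_config")
}

## Per-bit frequencies live in their own seed substream so probe sets can
## reproduce the feature distribution without replaying task generation.
feature_distribution <- function(config) {
  if (config$feature_kind != "binary_fingerprint") return(NULL)
  withr::with_seed(config$seed, stats::rbeta(config$p_features, 0.3, 1))
}

draw_features <- function(config, n, freq) {
  p <- config$p_features
  m <- if (config$feature_kind == "binary_fingerprint") {
    matrix(stats::rbinom(n * p, 1, rep(freq, each = n)), nrow = n)
  } else {
    matrix(stats::rnorm(n * p), nrow = n)
  }
  colnames(m) <- sprintf("f_%04d", seq_len(p) - 1)
  storage.mode(m) <- "double"
  m
}

## True response surface: latent index through the configured nonlinearity.
task_signal <- function(X, B, w, nonlinearity) {
  z <- X %*% B
  s <- as.numeric(z %*% w)
  switch(nonlinearity,
    none = s,
    squash = {
      sds <- stats::sd(s)
      if (sds == 0) s else tanh((s - mean(s)) / sds)
    },
    interactions = {
      sds <- stats::sd(s)
      s_std <- if (sds == 0) s else (s - mean(s)) / sds
      z1 <- scale(z[, 1])[, 1]
      z2 <- if (ncol(z) >= 2) scale(z[, 2])[, 1] else z1
      s_std + 0.5 * z1 * z2
    })
}

## Task coefficient vectors with the requested correlation structure.
draw_task_coefficients <- function(config) {
  k <- config$latent_dim
  n <- config$n_tasks
  gs <- config$group_structure
  w_bar <- stats::rnorm(k)
  if (is.null(gs)) {
    rho <- config$relatedness
    W <- vapply(seq_len(n), function(i) {
      sqrt(rho) * w_bar + sqrt(1 - rho) * stats::rnorm(k)
    }, numeric(k))
    group <- rep(1L, n)
  } else {
    rho_w <- gs$rho_within
    rho_b <- gs$rho_between
    group <- rep(seq_along(gs$sizes), gs$sizes)
    centers <- vapply(seq_along(gs$sizes), function(g) {
      sqrt(rho_b) * w_bar + sqrt(1 - rho_b) * stats::rnorm(k)
    }, numeric(k))
    W <- vapply(seq_len(n), function(i) {
      sqrt(rho_w) * centers[, group[i]] +
        sqrt(1 - rho_w) * stats::rnorm(k)
    }, numeric(k))
  }
  W <- matrix(W, nrow = k)
  list(W = W, w_bar = w_bar, group = group)
}

#' Generate a synthetic multi-task collection
#'
#' @param config A [generator_config()].
#' @return List with `collection` (a `tml_collection`) and `truth` (a
#'   `tml_ground_truth` holding the latent loadings `B`, the task
#'   coefficient matrix `W` (k x n), the shared component `w_bar`, group
#'   assignments, per-task noise SDs and realized signal-variance fractions
#'   `r2`).
#' @examples
#' sim <- generate_tasks(generator_config(n_tasks = 4, n_examples = 20,
#'                                        p_features = 16, latent_dim = 3,
#'                                        seed = 1))
#' sim$collection
#' @export
generate_tasks <- function(config) {
  stopifnot(inherits(config, "tml_generator_config"))
  freq <- feature_distribution(config)
  n <- config$n_examples
  structure_seed <- derive_seed(config$seed, "structure")
  examples_seed <- derive_seed(config$seed, "examples")
  str_draw <- withr::with_seed(structure_seed, {
    B <- matrix(stats::rnorm(config$p_features * config$latent_dim),
                nrow = config$p_features)
    c(list(B = B), draw_task_coefficients(config))
  })
  id_width <- max(2, nchar(config$n_tasks))
  withr::with_seed(examples_seed, {
    n_pool_per_task <- floor(config$overlap_fraction * n)
    pool_size <- max(2 * n_pool_per_task, n_pool_per_task)
    pool <- if (pool_size > 0) draw_features(config, pool_size, freq)
    pool_ids <- if (pool_size > 0) sprintf("pool_%05d", seq_len(pool_size))
    sigma <- numeric(config$n_tasks)
    r2 <- numeric(config$n_tasks)
    tasks <- lapply(seq_len(config$n_tasks), function(i) {
      tid <- sprintf("T%0*d", id_width, i)
      n_fresh <- n - n_pool_per_task
      X_fresh <- draw_features(config, n_fresh, freq)
      ids_fresh <- sprintf("%s_ex%04d", tid, seq_len(n_fresh))
      if (n_pool_per_task > 0) {
        take <- sample(pool_size, n_pool_per_task)
        X <- rbind(pool[take, , drop = FALSE], X_fresh)
        ids <- c(pool_ids[take], ids_fresh)
      } else {
        X <- X_fresh
        ids <- ids_fresh
      }
      signal <- task_signal(X, str_draw$B, str_draw$W[, i],
                            config$nonlinearity)
      s_i <- config$noise_sd %||% (0.5 * stats::sd(signal))
      if (!is.finite(s_i)) s_i <- 0
      y <- signal + stats::rnorm(n, sd = s_i)
      sigma[i] <<- s_i
      r2[i] <<- if (stats::var(y) > 0) stats::var(signal) / stats::var(y)
                else 1
      task(tid, X, y, example_ids = ids,
           metadata = list(group = str_draw$group[i]))
    })
    truth <- structure(list(B = str_draw$B, W = str_draw$W,
                            w_bar = str_draw$w_bar,
                            group = str_draw$group, sigma = sigma, r2 = r2,
                            config = config),
                       class = "tml_ground_truth")
    list(collection = task_collection(tasks,
                                      sprintf("synthetic_%d", config$seed)),
         truth = truth)
  })
}

#' @export
print.tml_ground_truth <- function(x, ...) {
  cat(sprintf("<tml_ground_truth> %d tasks, latent dim %d, mean signal R^2 %.2f\n",
              ncol(x$W), ncol(x$B), mean(x$r2)))
  invisible(x)
}

#' Generate a probe example set
#'
#' Fresh examples from the same feature distribution as [generate_tasks()]
#' under the same config, disjoint from every task's training examples
#' (their ids are namespaced `probe_*`). Used as the probe set for problem
#' profiles.
#'
#' @param config The same [generator_config()] used for the collection.
#' @param n_probe Number of probe examples (0 gives an empty matrix with p
#'   columns).
#' @return Feature matrix with rownames `probe_0001, ...`.
#' @export
make_probe_set <- function(config, n_probe) {
  stopifnot(inherits(config, "tml_generator_config"))
  tml_assert(n_probe >= 0, "tml_config_error", "n_probe must be >= 0")
  freq <- feature_distribution(config)
  if (n_probe == 0) {
    m <- matrix(numeric(0), nrow = 0, ncol = config$p_features)
    colnames(m) <- sprintf("f_%04d", seq_len(config$p_features) - 1)
    return(m)
  }
  X <- withr::with_seed(derive_seed(config$seed, "probe"),
                        draw_features(config, n_probe, freq))
  rownames(X) <- sprintf("probe_%05d", seq_len(n_probe))
  X
}
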