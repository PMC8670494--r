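## Stacking: combine the predicted outputs of the baseline and
## transformational models (or more streams) per task, via nonnegative least
## squares ("convex") or ridge regression.

#' Bundle out-of-fold prediction streams for stacking
#'
#' @param matrix Examples-by-streams matrix of out-of-fold predictions.
#' @param labels Column labels (e.g. `c("baseline:forest", "tml:forest")`).
#' @param target Observed target aligned with the rows.
#' @return An object of class `tml_panel`.
#' @export
prediction_panel <- function(matrix, labels = colnames(matrix), target) {
  P <- as.matrix(matrix)
  storage.mode(P) <- "double"
  tml_assert(!is.null(labels) && length(labels) == ncol(P),
             "tml_config_error", "panel needs one label per column")
  colnames(P) <- labels
  tml_assert(nrow(P) == length(target), "tml_integrity_error",
             "panel has %d rows but target has %d values", nrow(P),
             length(target))
  tml_assert(all(is.finite(P)) && all(is.finite(target)),
             "tml_integrity_error", "panel entries and target must be finite")
  structure(list(matrix = P, labels = labels, target = as.numeric(target)),
            class = "tml_panel")
}

new_stack_weights <- function(weights, intercept, method, labels,
                              ridge_lambda = NULL, nonunique = FALSE) {
  structure(list(weights = stats::setNames(as.numeric(weights), labels),
                 intercept = intercept, method = method,
                 ridge_lambda = ridge_lambda, nonunique = nonunique),
            class = "tml_stack_weights")
}

#' @export
print.tml_stack_weights <- function(x, ...) {
  cat(sprintf("<tml_stack_weights> %s: %s; intercept %.4g%s\n", x$method,
              paste(names(x$weights), round(x$weights, 4), sep = "=",
                    collapse = ", "),
              x$intercept,
              if (isTRUE(x$nonunique)) " [non-unique optimum]" else ""))
  invisible(x)
}

#' Convex (nonnegative least squares) stacking
#'
#' Solves `min ||y - P w||^2` subject to `w >= 0` (no intercept, no
#' sum-to-one constraint) with the Lawson-Hanson active-set algorithm, so
#' the training RMSE of the stack can never exceed that of any single
#' stream (the unit vector on that stream is feasible). With
#' `simplex = TRUE` the weights are additionally renormalized to sum to one
#' (sensitivity-analysis mode). A rank-deficient panel has multiple optima;
#' the deterministic active-set solution is returned and flagged
#' `nonunique`.
#'
#' @param panel A [prediction_panel()] with at least two streams.
#' @param simplex Renormalize weights to the simplex.
#' @return A `tml_stack_weights` object.
#' @export
fit_convex <- function(panel, simplex = FALSE) {
  stopifnot(inherits(panel, "tml_panel"))
  tml_assert(ncol(panel$matrix) >= 2, "tml_config_error",
             "stacking needs at least 2 prediction streams")
  sol <- pracma::lsqnonneg(panel$matrix, panel$target)
  w <- sol$x
  nonunique <- qr(panel$matrix)$rank < ncol(panel$matrix)
  if (simplex && sum(w) > 0) w <- w / sum(w)
  new_stack_weights(w, 0, "convex", colnames(panel$matrix),
                    nonunique = nonunique)
}

ridge_solve <- function(P, y, lambda) {
  mu_p <- colMeans(P)
  mu_y <- mean(y)
  Pc <- sweep(P, 2, mu_p)
  yc <- y - mu_y
  A <- crossprod(Pc) + diag(lambda, ncol(P))
  w <- solve(A, crossprod(Pc, yc))[, 1]
  list(weights = w, intercept = mu_y - sum(mu_p * w))
}

#' Ridge stacking with cross-validated penalty
#'
#' Closed-form ridge on the column-centered panel, `w = (P'P + lambda I)^-1
#' P'y`, intercept recovered from the means. The penalty is chosen from
#' `lambda_grid` by out-of-fold RMSE; ties go to the smallest lambda. A
#' `lambda = 0` entry is dropped automatically (and recorded) when `P'P` is
#' numerically singular.
#'
#' @param panel A [prediction_panel()].
#' @param lambda_grid Nonnegative candidate penalties.
#' @param n_folds CV folds for the lambda choice.
#' @param seed Fold-assignment seed.
#' @return A `tml_stack_weights` with `ridge_lambda` set; the per-lambda CV
#'   table is attached as attribute `"cv"`.
#' @export
fit_ridge <- function(panel, lambda_grid = c(0.01, 0.1, 1, 10, 100),
                      n_folds = 5, seed = 1L) {
  stopifnot(inherits(panel, "tml_panel"))
  tml_assert(ncol(panel$matrix) >= 2, "tml_config_error",
             "stacking needs at least 2 prediction streams")
  tml_assert(length(lambda_grid) >= 1 && all(lambda_grid >= 0),
             "tml_config_error", "lambda grid must be nonempty and nonnegative")
  lambda_grid <- sort(unique(lambda_grid))
  dropped_zero <- FALSE
  if (0 %in% lambda_grid) {
    Pc <- sweep(panel$matrix, 2, colMeans(panel$matrix))
    if (kappa(crossprod(Pc)) > 1e10) {
      lambda_grid <- setdiff(lambda_grid, 0)
      dropped_zero <- TRUE
      tml_assert(length(lambda_grid) > 0, "tml_config_error",
                 "lambda grid only contained 0, which is singular here")
    }
  }
  P <- panel$matrix
  y <- panel$target
  if (length(lambda_grid) == 1) {
    cv <- NA_real_
    best <- lambda_grid
  } else {
    n_folds <- min(n_folds, nrow(P))
    folds <- make_folds(nrow(P), n_folds, seed)
    cv <- vapply(lambda_grid, function(l) {
      errs <- vapply(seq_len(n_folds), function(f) {
        tr <- folds != f
        fit <- ridge_solve(P[tr, , drop = FALSE], y[tr], l)
        rmse(P[!tr, , drop = FALSE] %*% fit$weights + fit$intercept, y[!tr])
      }, numeric(1))
      mean(errs)
    }, numeric(1))
    best <- lambda_grid[which.min(cv)]  # grid sorted: ties -> smallest lambda
  }
  fit <- ridge_solve(P, y, best)
  out <- new_stack_weights(fit$weights, fit$intercept, "ridge", colnames(P),
                           ridge_lambda = best)
  attr(out, "cv") <- data.frame(lambda = lambda_grid, cv_rmse = cv)
  attr(out, "dropped_zero_lambda") <- dropped_zero
  out
}

#' Apply stacking weights to new prediction streams
#'
#' @param weights A `tml_stack_weights`.
#' @param new_panel A `tml_panel` or a labeled matrix whose column labels
#'   match the weights.
#' @return Numeric vector `P w + intercept`.
#' @export
stack_predict <- function(weights, new_panel) {
  stopifnot(inherits(weights, "tml_stack_weights"))
  P <- if (inherits(new_panel, "tml_panel")) new_panel$matrix
       else as.matrix(new_panel)
  tml_assert(!is.null(colnames(P)), "tml_schema_error",
             "new panel must have column labels")
  P <- align_schema(names(weights$weights), P, what = "stacking panel")
  as.numeric(P %*% weights$weights + weights$intercept)
}
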