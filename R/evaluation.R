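## The benchmark protocol: per-task cross-validated RMSE for the baseline /
## transformed / combined / stacked variants, aggregated over tasks, with
## paired sign and Wilcoxon signed-rank tests against the baseline.

BENCHMARK_VARIANTS <- c("baseline", "transformed", "combined",
                        "stacked_convex", "stacked_ridge")

#' Configure a benchmark run
#'
#' @param n_folds Cross-validation folds per task (default 10).
#' @param seed Global seed; per-task fold assignments are derived from
#'   `(seed, task_id)` and shared across variants so paired tests compare
#'   identical splits.
#' @param variants Subset of `c("baseline", "transformed", "combined",
#'   "stacked_convex", "stacked_ridge")`.
#' @param include_self Let each task's own source model contribute to its
#'   transformed representation (off by default: leave-own-model-out).
#' @param ridge_lambda_grid Penalty grid for the ridge stack.
#' @return An object of class `tml_eval_config`.
#' @export
evaluation_config <- function(n_folds = 10, seed = 1L,
                              variants = c("baseline", "transformed",
                                           "stacked_convex", "stacked_ridge"),
                              include_self = FALSE,
                              ridge_lambda_grid = c(0.01, 0.1, 1, 10, 100)) {
  tml_assert(n_folds >= 2, "tml_config_error", "n_folds must be >= 2")
  bad <- setdiff(variants, BENCHMARK_VARIANTS)
  tml_assert(length(bad) == 0, "tml_config_error",
             "unknown variants: %s", paste(bad, collapse = ", "))
  tml_assert(length(variants) > 0, "tml_config_error",
             "at least one variant required")
  structure(list(n_folds = as.integer(n_folds), seed = as.integer(seed),
                 variants = variants, include_self = isTRUE(include_self),
                 ridge_lambda_grid = ridge_lambda_grid),
            class = "tml_eval_config")
}

## Out-of-fold predictions of `spec` fitted on representation matrix M.
oof_predictions <- function(spec, M, y, folds) {
  out <- rep(NA_real_, length(y))
  for (f in sort(unique(folds))) {
    tr <- folds != f
    model <- fit_learner(spec, M[tr, , drop = FALSE], y[tr])
    out[!tr] <- predict(model, M[!tr, , drop = FALSE])
  }
  out
}

## Second-level CV over an out-of-fold prediction panel: stacking weights are
## fit on the other folds' OOF rows and applied to the held-out fold, so no
## evaluated row ever contributes to the weights that score it.
stack_oof <- function(P, y, folds, method, config) {
  out <- rep(NA_real_, length(y))
  for (f in sort(unique(folds))) {
    tr <- folds != f
    panel <- prediction_panel(P[tr, , drop = FALSE], colnames(P), y[tr])
    w <- if (method == "stacked_convex") {
      fit_convex(panel)
    } else {
      fit_ridge(panel, lambda_grid = config$ridge_lambda_grid,
                seed = config$seed)
    }
    out[!tr] <- stack_predict(w, P[!tr, , drop = FALSE])
  }
  out
}

## All requested variant OOF vectors for one task, sharing one fold split.
eval_task_variants <- function(task, registry, spec, config,
                               phi_spec = spec) {
  y <- task$target
  n <- length(y)
  k <- config$n_folds
  if (n < k || n - max(tabulate(rep_len(seq_len(k), n))) < 2) {
    return(list(skipped = sprintf(
      "task '%s': %d examples leave folds with < 2 training rows",
      task$task_id, n)))
  }
  ## fold assignment depends on the config seed and the task's size only, so
  ## identical tasks receive identical splits (and hence identical RMSEs) and
  ## every variant of one task is scored on the same partition
  folds <- make_folds(n, k, derive_seed(config$seed, sprintf("folds_%d", n)))
  digest <- learner_digest(spec)
  need_base <- any(c("baseline", "stacked_convex", "stacked_ridge") %in%
                     config$variants)
  need_tml <- any(c("transformed", "stacked_convex", "stacked_ridge") %in%
                    config$variants)
  oof <- list()
  if (need_base) {
    oof$baseline <- oof_predictions(spec, task$features, y, folds)
  }
  rep_i <- NULL
  if (need_tml || "combined" %in% config$variants) {
    rep_i <- tml_transform(registry, digest, task$features,
                           exclude_task = if (config$include_self) NULL
                                          else task$task_id)
  }
  if (need_tml) {
    oof$transformed <- oof_predictions(phi_spec, rep_i$matrix, y, folds)
  }
  if ("combined" %in% config$variants) {
    M <- combined_representation(task$features, rep_i)
    oof$combined <- oof_predictions(phi_spec, M, y, folds)
  }
  panel_mat <- NULL
  if (any(c("stacked_convex", "stacked_ridge") %in% config$variants)) {
    panel_mat <- cbind(baseline = oof$baseline, transformed = oof$transformed)
    for (m in intersect(c("stacked_convex", "stacked_ridge"),
                        config$variants)) {
      oof[[m]] <- stack_oof(panel_mat, y, folds, m, config)
    }
  }
  list(folds = folds, fold_digest = fold_digest(folds),
       oof = oof[intersect(BENCHMARK_VARIANTS, names(oof))],
       panel = panel_mat, target = y)
}

#' Cross-validate one task under one variant
#'
#' Seeded k-fold CV: for each fold the variant-specific representation is
#' built, a model is fitted on the training rows and applied to the test
#' rows; the out-of-fold predictions are concatenated in original row order
#' and a single RMSE is computed on the full vector. Stacked variants are
#' scored by second-level CV over the (baseline, transformed) out-of-fold
#' panel using the same fold split.
#'
#' @param task A `tml_task` belonging to the registry's collection.
#' @param registry Registry holding the baseline source models for `spec`.
#' @param variant One of `"baseline"`, `"transformed"`, `"combined"`,
#'   `"stacked_convex"`, `"stacked_ridge"`.
#' @param spec Learner spec (also used as the meta-learner unless
#'   `phi_spec` differs).
#' @param config An [evaluation_config()].
#' @param phi_spec Meta-learner spec for the transformed representation.
#' @return List with `predictions` (out-of-fold, original row order),
#'   `rmse`, `folds` and `fold_digest`; or `skipped` with a reason.
#' @export
cross_validate_task <- function(task, registry, variant, spec, config,
                                phi_spec = spec) {
  tml_assert(variant %in% BENCHMARK_VARIANTS, "tml_config_error",
             "unknown variant '%s'", variant)
  cfg <- config
  cfg$variants <- variant
  res <- eval_task_variants(task, registry, spec, cfg, phi_spec)
  if (!is.null(res$skipped)) return(list(skipped = res$skipped))
  pred <- res$oof[[variant]]
  list(predictions = pred, rmse = rmse(pred, task$target),
       folds = res$folds, fold_digest = res$fold_digest, variant = variant)
}

#' Run the multi-task benchmark
#'
#' For each learner spec: trains the per-task source models, scores every
#' requested variant on every task by cross-validated RMSE (shared fold
#' splits), aggregates means and medians over tasks, and runs paired sign
#' and Wilcoxon signed-rank tests of every non-baseline variant against the
#' baseline. Percentage improvement is reported as
#' `100 * (1 - mean_variant / mean_baseline)`.
#'
#' @param collection A `tml_collection`.
#' @param config An [evaluation_config()].
#' @param learner_specs A single [learner_spec()] or a list of them.
#' @param max_failure_fraction Abort if any variant fails on more than this
#'   fraction of tasks.
#' @return An object of class `tml_benchmark` with elements `per_task`,
#'   `summary`, `tests`, `skipped`, `details` (per-family fold digests and
#'   OOF panels) and `provenance` (config digest).
#' @export
run_benchmark <- function(collection, config, learner_specs,
                          max_failure_fraction = 0.2) {
  if (inherits(learner_specs, "tml_learner_spec")) {
    learner_specs <- list(learner_specs)
  }
  fams <- vapply(learner_specs, `[[`, character(1), "family")
  names(learner_specs) <- names(learner_specs) %||% fams
  per_task <- list()
  skipped <- list()
  details <- list()
  for (fam in names(learner_specs)) {
    spec <- learner_specs[[fam]]
    registry <- train_baselines(collection, spec)
    fam_detail <- list()
    failures <- character(0)
    for (tid in task_ids(collection)) {
      res <- tryCatch(
        eval_task_variants(collection$tasks[[tid]], registry, spec, config),
        error = function(e) list(failed = conditionMessage(e)))
      if (!is.null(res$skipped)) {
        skipped[[length(skipped) + 1]] <-
          data.frame(family = fam, task_id = tid, reason = res$skipped)
        next
      }
      if (!is.null(res$failed)) {
        failures <- c(failures, sprintf("%s: %s", tid, res$failed))
        next
      }
      for (v in names(res$oof)) {
        per_task[[length(per_task) + 1]] <- data.frame(
          family = fam, task_id = tid, variant = v,
          rmse = rmse(res$oof[[v]], res$target),
          fold_digest = res$fold_digest, stringsAsFactors = FALSE)
      }
      fam_detail[[tid]] <- list(panel = res$panel, target = res$target,
                                folds = res$folds, oof = res$oof)
    }
    if (length(failures) > max_failure_fraction * length(collection)) {
      tml_stop("tml_stage_error",
               "family '%s' failed on %d/%d tasks:\n%s", fam,
               length(failures), length(collection),
               paste(failures, collapse = "\n"))
    }
    details[[fam]] <- fam_detail
  }
  per_task <- do.call(rbind, per_task)
  tml_assert(!is.null(per_task) && nrow(per_task) > 0, "tml_stage_error",
             "benchmark produced no results (all tasks skipped?)")
  summary_df <- do.call(rbind, lapply(split(
    per_task, list(per_task$family, per_task$variant), drop = TRUE),
    function(part) {
      data.frame(family = part$family[1], variant = part$variant[1],
                 mean_rmse = mean(part$rmse),
                 median_rmse = stats::median(part$rmse),
                 n_tasks = nrow(part), stringsAsFactors = FALSE)
    }))
  rownames(summary_df) <- NULL
  ## percentage improvement over baseline, per family
  summary_df$pct_improvement <- NA_real_
  tests <- list()
  for (fam in unique(summary_df$family)) {
    base_rows <- per_task[per_task$family == fam &
                            per_task$variant == "baseline", ]
    if (nrow(base_rows) == 0) next
    base_mean <- mean(base_rows$rmse)
    for (v in setdiff(unique(per_task$variant[per_task$family == fam]),
                      "baseline")) {
      rows <- per_task[per_task$family == fam & per_task$variant == v, ]
      merged <- merge(base_rows[, c("task_id", "rmse", "fold_digest")],
                      rows[, c("task_id", "rmse", "fold_digest")],
                      by = "task_id", suffixes = c("_base", "_var"))
      tml_assert(all(merged$fold_digest_base == merged$fold_digest_var),
                 "tml_integrity_error",
                 "pairing integrity violated: fold assignments differ between variants")
      diffs <- merged$rmse_base - merged$rmse_var
      st <- sign_test(diffs)
      wt <- wilcoxon_signed_rank(diffs)
      tests[[length(tests) + 1]] <- data.frame(
        family = fam, variant = v, sign_p = st$p_value,
        wilcoxon_p = wt$p_value, n_pairs = length(diffs),
        n_pos = st$n_pos, n_neg = st$n_neg, n_ties = st$n_ties,
        stringsAsFactors = FALSE)
      idx <- summary_df$family == fam & summary_df$variant == v
      summary_df$pct_improvement[idx] <-
        100 * (1 - summary_df$mean_rmse[idx] / base_mean)
    }
  }
  structure(list(per_task = per_task, summary = summary_df,
                 tests = do.call(rbind, tests),
                 skipped = if (length(skipped)) do.call(rbind, skipped)
                           else NULL,
                 details = details, config = config,
                 provenance = canonical_string(unclass(config))),
            class = "tml_benchmark")
}

#' @export
print.tml_benchmark <- function(x, ...) {
  cat("<tml_benchmark>\n")
  s <- x$summary
  s$mean_rmse <- round(s$mean_rmse, 4)
  s$median_rmse <- round(s$median_rmse, 4)
  s$pct_improvement <- round(s$pct_improvement, 2)
  print(s, row.names = FALSE)
  if (!is.null(x$tests)) {
    cat("\nPaired tests vs baseline:\n")
    t <- x$tests
    t$sign_p <- signif(t$sign_p, 3)
    t$wilcoxon_p <- signif(t$wilcoxon_p, 3)
    print(t[, c("family", "variant", "sign_p", "wilcoxon_p", "n_pairs")],
          row.names = FALSE)
  }
  invisible(x)
}
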