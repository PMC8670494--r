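## End-to-end pipeline driver: generate (or load) -> train source models ->
## benchmark -> interpret. Thin orchestration over the exported functions;
## the CLI script in inst/scripts wraps this.

PIPELINE_KEYS <- c("seed", "output_dir", "generator", "collection_path",
                   "learners", "evaluation", "cluster", "importance")

#' Run the full pipeline
#'
#' Wires the stages together: obtain a task collection (synthetic generator
#' or a directory/file on disk), run the cross-validated benchmark over the
#' configured learner families and variants, cluster problem profiles, and
#' rank attribute-model importances for the first task. All artifacts are
#' written under `output_dir` together with a manifest embedding the config
#' digest; rerunning the same config reproduces identical benchmark numbers
#' for deterministic learner families.
#'
#' @param config Named list (or path to a YAML file) with entries:
#'   `seed`; `output_dir`; `generator` (arguments to [generator_config()])
#'   or `collection_path`; `learners` (list of [learner_spec()] argument
#'   lists); `evaluation` (arguments to [evaluation_config()]); optional
#'   `cluster` (`n_probe`, `distance`, `linkage`, `k`) and `importance`
#'   (`task_id`, `top_k`). Unknown keys are rejected.
#' @return Invisibly, a manifest list: output paths, the config digest and
#'   the benchmark summary.
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  bad <- setdiff(names(config), PIPELINE_KEYS)
  tml_assert(length(bad) == 0, "tml_config_error",
             "unknown pipeline config keys: %s", paste(bad, collapse = ", "))
  seed <- as.integer(config$seed %||% 1L)
  out_dir <- config$output_dir %||% stop("config$output_dir is required")
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  digest <- canonical_string(config)
  manifest <- list(config_digest = digest, outputs = character(0))
  add_output <- function(path) {
    manifest$outputs <<- c(manifest$outputs, path)
    path
  }

  ## stage: collection
  if (!is.null(config$collection_path)) {
    collection <- load_collection(config$collection_path)
    gen_cfg <- NULL
  } else {
    gen_args <- config$generator %||% list()
    gen_args$seed <- gen_args$seed %||% seed
    gen_cfg <- do.call(generator_config, gen_args)
    sim <- generate_tasks(gen_cfg)
    collection <- sim$collection
    save_collection(collection, add_output(file.path(out_dir, "collection")))
  }

  ## stage: learners + benchmark
  learner_args <- config$learners %||% list(list(family = "forest"))
  specs <- lapply(learner_args, function(a) {
    learner_spec(a$family, params = a$params %||% list(), grid = a$grid,
                 seed = a$seed %||% seed)
  })
  eval_args <- config$evaluation %||% list()
  eval_args$seed <- eval_args$seed %||% seed
  eval_cfg <- do.call(evaluation_config, eval_args)
  bench <- run_benchmark(collection, eval_cfg, specs)
  utils::write.csv(bench$per_task,
                   add_output(file.path(out_dir, "per_task.csv")),
                   row.names = FALSE)
  utils::write.csv(bench$summary,
                   add_output(file.path(out_dir, "summary.csv")),
                   row.names = FALSE)
  if (!is.null(bench$tests)) {
    utils::write.csv(bench$tests,
                     add_output(file.path(out_dir, "tests.csv")),
                     row.names = FALSE)
  }

  ## stage: interpretation (first learner spec)
  spec <- specs[[1]]
  registry <- train_baselines(collection, spec)
  cl_cfg <- config$cluster %||% list()
  if (!identical(cl_cfg$enabled %||% TRUE, FALSE)) {
    n_probe <- cl_cfg$n_probe %||% 50
    probe <- if (!is.null(gen_cfg)) make_probe_set(gen_cfg, n_probe)
             else collection$tasks[[1]]$features
    prof <- problem_profiles(registry, learner_digest(spec), probe)
    tree <- hierarchical_cluster(prof,
                                 distance = cl_cfg$distance %||% "correlation",
                                 linkage = cl_cfg$linkage %||% "average")
    as_newick(tree, add_output(file.path(out_dir, "problem_tree.nwk")))
    k <- cl_cfg$k %||% min(2, length(collection))
    labels <- cut_clusters(tree, k = k)
    utils::write.csv(data.frame(task_id = names(labels), cluster = labels),
                     add_output(file.path(out_dir, "problem_clusters.csv")),
                     row.names = FALSE)
  }
  imp_cfg <- config$importance %||% list()
  if (!identical(imp_cfg$enabled %||% TRUE, FALSE)) {
    tid <- imp_cfg$task_id %||% task_ids(collection)[1]
    tk <- get_task(collection, tid)
    rep_i <- tml_transform(registry, learner_digest(spec), tk$features,
                           exclude_task = tid)
    phi <- fit_learner(spec, rep_i$matrix, tk$target)
    imp <- attribute_importance(phi, rep_i, tk$target,
                                top_k = imp_cfg$top_k %||% 10)
    utils::write.csv(as.data.frame(imp),
                     add_output(file.path(out_dir, "importance.csv")),
                     row.names = FALSE)
  }

  manifest$summary <- bench$summary
  jsonlite::write_json(
    list(config_digest = digest, outputs = manifest$outputs),
    file.path(out_dir, "manifest.json"), auto_unbox = TRUE, pretty = TRUE)
  invisible(manifest)
}
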