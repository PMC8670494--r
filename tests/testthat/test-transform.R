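coll <- make_tiny_collection(n_tasks = 4, n = 30, p = 5, seed = 13)
spec <- learner_spec("knn", params = list(k = 3), seed = 1)
reg <- train_baselines(coll, spec)
dg <- learner_digest(spec)

test_that("transform produces one sorted column per non-excluded source model", {
  X <- coll$tasks[["task01"]]$features
  rep_all <- tml_transform(reg, dg, X)
  expect_equal(dim(rep_all$matrix), c(30, 4))
  expect_equal(rep_all$column_task_ids, sort(task_ids(coll)))
  expect_equal(colnames(rep_all$matrix), paste0("tml:", task_ids(coll)))

  rep_excl <- tml_transform(reg, dg, X, exclude_task = "task01")
  expect_equal(ncol(rep_excl$matrix), 3)
  expect_false("task01" %in% rep_excl$column_task_ids)

  ## composability: exclusion == column drop of the full transform, exactly
  expect_identical(rep_excl$matrix,
                   rep_all$matrix[, colnames(rep_all$matrix) != "tml:task01"])

  ## columns are the source models' predictions
  m2 <- tmlearn:::registry_get(reg, "task02", dg, "baseline")
  expect_identical(rep_all$matrix[, "tml:task02"],
                   stats::setNames(predict(m2, X), rownames(X)))
})

test_that("a task's own model never leaks into its representation", {
  ## spike task03's model with a recognizable constant
  reg2 <- train_baselines(coll, spec)
  spiked <- fit_learner(spec, coll$tasks[["task03"]]$features,
                        rep(123.456, 30))
  registry_add(reg2, "task03", dg, "baseline", spiked, overwrite = TRUE)
  rep3 <- tml_transform(reg2, dg, coll$tasks[["task03"]]$features,
                        exclude_task = "task03")
  expect_false(any(rep3$matrix == 123.456))
  ## but it does appear in other tasks' representations
  rep1 <- tml_transform(reg2, dg, coll$tasks[["task01"]]$features,
                        exclude_task = "task01")
  expect_true(all(rep1$matrix[, "tml:task03"] == 123.456))
})

test_that("transform is invariant to registry insertion order", {
  reg_rev <- model_registry()
  for (tid in rev(task_ids(coll))) {
    registry_add(reg_rev, tid, dg, "baseline",
                 tmlearn:::registry_get(reg, tid, dg, "baseline"))
  }
  X <- coll$tasks[["task02"]]$features
  expect_identical(tml_transform(reg_rev, dg, X)$matrix,
                   tml_transform(reg, dg, X)$matrix)
})

test_that("constant source models pass through as constant columns", {
  cc <- withr::with_seed(31, {
    X <- matrix(rnorm(40), 10, 4, dimnames = list(NULL, paste0("f", 1:4)))
    task_collection(list(task("flat1", X, rep(1, 10)),
                         task("flat2", X, rep(2, 10)),
                         task("live", X, rnorm(10))))
  })
  regc <- train_baselines(cc, spec)
  rp <- tml_transform(regc, dg, cc$tasks[["live"]]$features,
                      exclude_task = "live")
  expect_equal(ncol(rp$matrix), 2)  # no silent column dropping
  expect_true(all(rp$matrix[, "tml:flat1"] == 1))
  expect_true(all(rp$matrix[, "tml:flat2"] == 2))
})

test_that("transform errors are informative", {
  expect_error(tml_transform(model_registry(), dg,
                             coll$tasks[[1]]$features),
               class = "tml_dependency_error")
  two <- task_collection(coll$tasks[1:2], "two")
  reg_two <- train_baselines(two, spec)
  expect_error(tml_transform(reg_two, dg, two$tasks[[1]]$features[, 1:3]),
               class = "tml_schema_error")
})

test_that("combined representation concatenates with namespaced columns", {
  X <- coll$tasks[["task01"]]$features
  rp <- tml_transform(reg, dg, X, exclude_task = "task01")
  M <- combined_representation(X, rp)
  expect_equal(ncol(M), 5 + 3)
  expect_equal(colnames(M),
               c(paste0("base:f", 1:5), paste0("tml:", c("task02", "task03",
                                                         "task04"))))
  expect_identical(unname(M[, 1:5]), unname(X))
  expect_error(combined_representation(X[1:10, ], rp),
               class = "tml_integrity_error")
})

test_that("second-order transform has the right shape and dependency checks", {
  reg_so <- train_baselines(coll, spec)
  expect_error(second_order_transform(reg_so, dg, coll),
               class = "tml_dependency_error")
  train_tml_models(coll, reg_so, spec)
  so <- second_order_transform(reg_so, dg, coll)
  expect_equal(names(so), task_ids(coll))
  for (tid in task_ids(coll)) {
    expect_equal(ncol(so[[tid]]$matrix), 3)
    expect_equal(so[[tid]]$order_tag, "second")
    expect_false(tid %in% so[[tid]]$column_task_ids)
  }
})

test_that("feature selection keeps the highest-scoring columns", {
  withr::with_seed(17, {
    y <- rnorm(50)
    M <- cbind(n1 = rnorm(50), sig = y, n2 = rnorm(50), n3 = rnorm(50))
  })
  rp <- tmlearn:::new_representation(M, c("n1", "sig", "n2", "n3"),
                                     NULL, "first", dg)
  ## m_keep = m is the identity
  expect_identical(select_tml_features(rp, y, 4)$matrix, rp$matrix)
  ## the perfect predictor survives m_keep = 1
  kept <- select_tml_features(rp, y, 1)
  expect_equal(kept$column_task_ids, "sig")
  ## importance method agrees here
  kept_imp <- select_tml_features(rp, y, 1, method = "importance")
  expect_equal(kept_imp$column_task_ids, "sig")
  ## constant target falls back to importance with a record
  kept_const <- select_tml_features(rp, rep(1, 50), 2)
  expect_true(attr(kept_const, "selection")$constant_target_fallback)
  expect_equal(attr(kept_const, "selection")$method, "importance")
  expect_error(select_tml_features(rp, y, 0), class = "tml_config_error")
  expect_error(select_tml_features(rp, y, 5), class = "tml_config_error")
})
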