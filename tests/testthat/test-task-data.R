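test_that("task and collection validation enforce the data contract", {
  X <- matrix(rnorm(12), 4, 3, dimnames = list(NULL, c("a", "b", "c")))
  tk <- task("t1", X, 1:4)
  expect_s3_class(tk, "tml_task")
  expect_equal(tk$example_ids, paste0("ex_", 1:4))

  expect_error(task("t1", X, 1:3), class = "tml_integrity_error")
  expect_error(task("t1", X, c(1, 2, NA, 4)), class = "tml_integrity_error")
  expect_error(task("t1", X, 1:4, example_ids = c("a", "a", "b", "c")),
               class = "tml_integrity_error")
  Xbad <- X
  Xbad[2, 2] <- Inf
  expect_error(task("t1", Xbad, 1:4), class = "tml_integrity_error")

  ## mismatched schema across tasks is rejected, naming the offender
  X2 <- X
  colnames(X2) <- c("a", "b", "zzz")
  expect_error(task_collection(list(tk, task("t2", X2, 1:4))),
               "t2", class = "tml_schema_error")
})

test_that("collections iterate in sorted task order regardless of input order", {
  X <- matrix(rnorm(8), 4, 2, dimnames = list(NULL, c("a", "b")))
  coll <- task_collection(list(task("zebra", X, 1:4), task("ant", X, 1:4),
                               task("mouse", X, 1:4)))
  expect_equal(task_ids(coll), c("ant", "mouse", "zebra"))
})

test_that("fingerprint parsing preserves order and reports bad positions", {
  expect_equal(parse_fingerprint("0000"), c(0, 0, 0, 0))
  expect_equal(parse_fingerprint("1011"), c(1, 0, 1, 1))
  expect_error(parse_fingerprint("10a1"), "position 3",
               class = "tml_format_error")
  expect_error(parse_fingerprint(""), class = "tml_format_error")
})

test_that("directory round-trip is the identity on collection content", {
  coll <- make_tiny_collection(n_tasks = 3, n = 10, p = 4)
  dir <- withr::local_tempdir()
  save_collection(coll, dir)
  coll2 <- load_collection(dir, collection_id = "tiny")
  expect_equal(task_ids(coll2), task_ids(coll))
  expect_equal(coll2$feature_schema, coll$feature_schema)
  for (tid in task_ids(coll)) {
    expect_equal(coll2$tasks[[tid]]$features, coll$tasks[[tid]]$features)
    expect_equal(coll2$tasks[[tid]]$target, coll$tasks[[tid]]$target)
    expect_equal(coll2$tasks[[tid]]$example_ids, coll$tasks[[tid]]$example_ids)
  }
})

test_that("directory loading rejects a file with extra feature columns", {
  coll <- make_tiny_collection(n_tasks = 3, n = 10, p = 4)
  dir <- withr::local_tempdir()
  save_collection(coll, dir)
  ## corrupt one task file with a 5th feature column
  f <- file.path(dir, "task02.csv")
  df <- read.csv(f, check.names = FALSE)
  df$extra <- 1
  df <- df[, c("example_id", "f1", "f2", "f3", "f4", "extra", "target")]
  write.csv(df, f, row.names = FALSE)
  expect_error(load_collection(dir), "task02", class = "tml_schema_error")
})

test_that("wide single-file layout loads with fingerprint expansion", {
  withr::with_seed(11, {
    bits <- vapply(1:12, function(i) {
      paste(sample(c("0", "1"), 8, replace = TRUE), collapse = "")
    }, character(1))
  })
  df <- data.frame(task_id = rep(c("tA", "tB"), each = 6),
                   example_id = rep(sprintf("e%d", 1:6), 2),
                   `fp:fp` = bits, target = rnorm(12),
                   check.names = FALSE)
  f <- withr::local_tempfile(fileext = ".csv")
  write.csv(df, f, row.names = FALSE)
  coll <- load_collection(f)
  expect_equal(length(coll), 2)
  expect_equal(length(coll$feature_schema), 8)
  expect_true(all(grepl("^fp_", coll$feature_schema)))
  expect_true(all(coll$tasks[["tA"]]$features %in% c(0, 1)))
  ## first row of tA matches its bitstring
  expect_equal(unname(coll$tasks[["tA"]]$features[1, ]),
               parse_fingerprint(bits[1]))

  ## duplicate (task_id, example_id) is an integrity error
  df2 <- rbind(df, df[1, ])
  write.csv(df2, f, row.names = FALSE)
  expect_error(load_collection(f), class = "tml_integrity_error")
})

test_that("wide table without a target column is a format error", {
  df <- data.frame(task_id = "a", example_id = "e1", f1 = 1)
  f <- withr::local_tempfile(fileext = ".csv")
  write.csv(df, f, row.names = FALSE)
  expect_error(load_collection(f), "target", class = "tml_format_error")
})

test_that("registry round-trips models with identical predictions", {
  coll <- make_tiny_collection(n_tasks = 3, n = 15, p = 4)
  spec <- learner_spec("knn", params = list(k = 1), seed = 1)
  reg <- train_baselines(coll, spec)
  expect_equal(nrow(registry_entries(reg)), 3)

  dir <- withr::local_tempdir()
  save_registry(reg, dir)
  reg2 <- load_registry(dir)
  expect_equal(registry_entries(reg2), registry_entries(reg))
  Xnew <- coll$tasks[[1]]$features[1:5, , drop = FALSE]
  dg <- learner_digest(spec)
  for (tid in task_ids(coll)) {
    m1 <- tmlearn:::registry_get(reg, tid, dg, "baseline")
    m2 <- tmlearn:::registry_get(reg2, tid, dg, "baseline")
    expect_identical(predict(m1, Xnew), predict(m2, Xnew))
  }

  ## two learner specs x 3 tasks -> 6 entries
  reg3 <- train_baselines(coll, learner_spec("knn", params = list(k = 3)),
                          registry = reg)
  expect_equal(nrow(registry_entries(reg3)), 6)

  ## version mismatch is an explicit incompatibility error
  idx <- jsonlite::read_json(file.path(dir, "index.json"))
  idx$format_version <- 999
  jsonlite::write_json(idx, file.path(dir, "index.json"), auto_unbox = TRUE)
  expect_error(load_registry(dir), "version", class = "tml_format_error")

  ## empty / garbage file is a format error
  dir2 <- withr::local_tempdir()
  expect_error(load_registry(dir2), class = "tml_format_error")
  writeLines("not json {", file.path(dir2, "index.json"))
  expect_error(load_registry(dir2), class = "tml_format_error")
})
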