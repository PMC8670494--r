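test_that("learner specs validate family and hyperparameter keys", {
  expect_error(learner_spec("deepnet"), class = "tml_config_error")
  expect_error(learner_spec("knn", params = list(k = 3, bogus = 1)),
               "bogus", class = "tml_config_error")
  s1 <- learner_spec("forest", params = list(num_trees = 100), seed = 5)
  s2 <- learner_spec("forest", params = list(num_trees = 100), seed = 5)
  expect_identical(learner_digest(s1), learner_digest(s2))
  expect_false(learner_digest(s1) ==
                 learner_digest(learner_spec("forest", seed = 5)))
})

test_that("1-NN memorizes training points and matches the brute-force oracle", {
  withr::with_seed(2, {
    X <- matrix(rnorm(50 * 3), 50, 3, dimnames = list(NULL, c("a", "b", "c")))
    y <- rnorm(50)
    Xte <- matrix(rnorm(20 * 3), 20, 3,
                  dimnames = list(NULL, c("a", "b", "c")))
  })
  m <- fit_learner(learner_spec("knn", params = list(k = 1)), X, y)
  expect_equal(predict(m, X[4, , drop = FALSE]), y[4])
  ## oracle works in the same standardized space the adapter uses
  ctr <- colMeans(X)
  scl <- apply(X, 2, sd)
  Xs <- scale(X, ctr, scl)
  Xtes <- scale(Xte, ctr, scl)
  expect_equal(predict(m, Xte), unname(oracle_1nn(Xs, y, Xtes)),
               tolerance = 1e-12)
})

test_that("every family fits, predicts finite values, and is seed-deterministic", {
  withr::with_seed(3, {
    X <- matrix(rnorm(40 * 6), 40, 6, dimnames = list(NULL, paste0("f", 1:6)))
    y <- as.numeric(X %*% rnorm(6)) + rnorm(40, sd = 0.2)
    Xte <- matrix(rnorm(10 * 6), 10, 6, dimnames = list(NULL, paste0("f", 1:6)))
  })
  for (fam in c("forest", "boosting", "svm", "knn", "nn")) {
    params <- switch(fam, forest = list(num_trees = 50),
                     boosting = list(nrounds = 20),
                     nn = list(size = 4, maxit = 50), list())
    spec <- learner_spec(fam, params = params, seed = 11)
    m1 <- fit_learner(spec, X, y)
    m2 <- fit_learner(spec, X, y)
    p1 <- predict(m1, Xte)
    expect_length(p1, 10)
    expect_true(all(is.finite(p1)), info = fam)
    expect_identical(p1, predict(m2, Xte), info = fam)
    expect_identical(p1, predict(m1, Xte), info = fam)
    ## empty prediction matrix -> empty vector
    expect_identical(predict(m1, Xte[0, , drop = FALSE]), numeric(0))
    ## identical rows -> identical predictions
    Xdup <- Xte[c(1, 1), , drop = FALSE]
    pd <- predict(m1, Xdup)
    expect_equal(pd[1], pd[2], info = fam)
    ## column order is realigned by name
    perm <- sample(ncol(Xte))
    expect_equal(predict(m1, Xte[, perm, drop = FALSE]), p1, info = fam)
    ## schema mismatch errors name the columns
    Xbad <- Xte
    colnames(Xbad)[2] <- "other"
    expect_error(predict(m1, Xbad), "other", class = "tml_schema_error")
  }
})

test_that("constant targets are flagged and served by a constant predictor", {
  X <- matrix(rnorm(20), 10, 2, dimnames = list(NULL, c("a", "b")))
  m <- fit_learner(learner_spec("svm"), X, rep(3.5, 10))
  expect_true(m$fit_metadata$zero_variance_target)
  expect_equal(predict(m, X), rep(3.5, 10))
})

test_that("undersized training sets raise configuration errors", {
  X <- matrix(rnorm(10), 5, 2, dimnames = list(NULL, c("a", "b")))
  expect_error(fit_learner(learner_spec("knn", params = list(k = 10)),
                           X, rnorm(5)),
               class = "tml_config_error")
  ## svm is fine on the same data
  expect_length(predict(fit_learner(learner_spec("svm"), X, rnorm(5)), X), 5)
  expect_error(fit_learner(learner_spec("svm"), X[1, , drop = FALSE],
                           rnorm(1)),
               class = "tml_config_error")
})

test_that("forest importance ranks an informative feature above pure noise", {
  withr::with_seed(21, {
    x1 <- rnorm(500)
    x2 <- rnorm(500)
    X <- cbind(x1 = x1, x2 = x2)
    y <- x1 + rnorm(500, sd = 0.1)
  })
  m <- fit_learner(learner_spec("forest", params = list(num_trees = 200),
                                seed = 4), X, y)
  expect_gt(m$importance_scores["x1"], m$importance_scores["x2"])
})

test_that("tuning minimizes cross-validated RMSE with deterministic ties", {
  ## singleton grid -> that point
  withr::with_seed(5, {
    X <- matrix(rnorm(60), 30, 2, dimnames = list(NULL, c("a", "b")))
    y <- rnorm(30)
  })
  spec <- learner_spec("knn", grid = list(k = 3))
  expect_equal(tune_learner(spec, X, y, n_folds = 3)$params$k, 3)

  ## smooth low-noise 1-d signal: small k beats k = 50 at n = 200
  withr::with_seed(6, {
    x <- runif(200, -3, 3)
    Xs <- cbind(x = x, junk = rnorm(200))
    ys <- sin(x) + rnorm(200, sd = 0.01)
  })
  tuned <- tune_learner(learner_spec("knn", grid = list(k = c(1, 50)),
                                     seed = 2), Xs, ys, n_folds = 5)
  expect_lt(tuned$params$k, 50)
  tab <- attr(tuned, "tuning")
  expect_lt(tab$cv_rmse[tab$k == 1], tab$cv_rmse[tab$k == 50])

  ## exact tie -> first grid point wins (duplicate candidate values)
  tie <- tune_learner(learner_spec("knn", grid = list(k = c(7, 7))),
                      X, y, n_folds = 3)
  expect_equal(tie$params$k, 7)
  expect_equal(which.min(attr(tie, "tuning")$cv_rmse), 1L)

  ## failing grid points score +Inf but never abort the search
  bad <- tune_learner(learner_spec("knn", grid = list(k = c(100, 3))),
                      X, y, n_folds = 3)
  expect_equal(bad$params$k, 3)
  expect_true(is.infinite(attr(bad, "tuning")$cv_rmse[1]))
})
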