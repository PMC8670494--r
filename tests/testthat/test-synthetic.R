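test_that("generation is byte-identical under one seed and validates config", {
  cfg <- generator_config(n_tasks = 4, n_examples = 20, p_features = 16,
                          latent_dim = 4, seed = 9)
  s1 <- generate_tasks(cfg)
  s2 <- generate_tasks(cfg)
  expect_identical(s1$collection, s2$collection)
  expect_identical(s1$truth$W, s2$truth$W)
  ## a different seed changes the data
  s3 <- generate_tasks(generator_config(n_tasks = 4, n_examples = 20,
                                        p_features = 16, latent_dim = 4,
                                        seed = 10))
  expect_false(identical(s1$collection, s3$collection))

  expect_error(generator_config(latent_dim = 200, p_features = 100),
               class = "tml_config_error")
  expect_error(generator_config(relatedness = 1.2),
               class = "tml_config_error")
  expect_error(generator_config(overlap_fraction = -0.1),
               class = "tml_config_error")
  expect_error(generator_config(group_structure = list(sizes = c(2, 3)),
                                n_tasks = 4),
               class = "tml_config_error")
})

test_that("fully related noiseless linear tasks agree on shared-pool examples", {
  cfg <- generator_config(n_tasks = 6, n_examples = 30, p_features = 24,
                          latent_dim = 5, relatedness = 1, noise_sd = 0,
                          nonlinearity = "none", overlap_fraction = 0.5,
                          seed = 15)
  sim <- generate_tasks(cfg)
  ## every pair of tasks: identical targets on common pool examples
  ids <- task_ids(sim$collection)
  n_shared_pairs <- 0
  for (i in seq_along(ids)) {
    for (j in seq_len(i - 1)) {
      ti <- sim$collection$tasks[[ids[i]]]
      tj <- sim$collection$tasks[[ids[j]]]
      common <- intersect(ti$example_ids, tj$example_ids)
      common <- grep("^pool_", common, value = TRUE)
      if (length(common) == 0) next
      n_shared_pairs <- n_shared_pairs + 1
      expect_equal(ti$target[match(common, ti$example_ids)],
                   tj$target[match(common, tj$example_ids)],
                   tolerance = 1e-12)
    }
  }
  expect_gt(n_shared_pairs, 0)
})

test_that("task coefficient correlations recover the configured relatedness", {
  ## 200 pairs drawn from 20 independent collections so the shared latent
  ## component w_bar averages out across replicates
  for (rho in c(0, 0.5, 0.9)) {
    cors <- unlist(lapply(1:20, function(rep_i) {
      cfg <- generator_config(n_tasks = 20, n_examples = 2,
                              p_features = 256, latent_dim = 128,
                              relatedness = rho,
                              seed = 400 + round(100 * rho) + rep_i)
      W <- generate_tasks(cfg)$truth$W
      pairs <- withr::with_seed(50 + rep_i,
                                t(replicate(10, sample(ncol(W), 2))))
      vapply(seq_len(nrow(pairs)), function(r) {
        stats::cor(W[, pairs[r, 1]], W[, pairs[r, 2]])
      }, numeric(1))
    }))
    expect_length(cors, 200)
    expect_lt(abs(mean(cors) - rho), 0.05)
  }
})

test_that("planted group structure yields block-correlated coefficients", {
  cfg <- generator_config(n_tasks = 12, n_examples = 10, p_features = 64,
                          latent_dim = 48,
                          group_structure = list(sizes = c(6, 6),
                                                 rho_within = 1,
                                                 rho_between = 0),
                          seed = 77)
  sim <- generate_tasks(cfg)
  W <- sim$truth$W
  g <- sim$truth$group
  within <- stats::cor(W[, g == 1])[upper.tri(diag(6))]
  expect_true(all(abs(within - 1) < 1e-12))
  between <- stats::cor(W[, g == 1][, 1], W[, g == 2][, 1])
  expect_lt(abs(between), 0.5)
})

test_that("noiseless linear truth is recoverable from the latent index", {
  cfg <- generator_config(n_tasks = 3, n_examples = 50, p_features = 32,
                          latent_dim = 6, noise_sd = 0,
                          nonlinearity = "none", seed = 21)
  sim <- generate_tasks(cfg)
  for (tid in task_ids(sim$collection)) {
    tk <- sim$collection$tasks[[tid]]
    i <- match(tid, task_ids(sim$collection))
    z <- tk$features %*% sim$truth$B
    pred <- as.numeric(z %*% sim$truth$W[, i])
    expect_equal(pred, tk$target, tolerance = 1e-10)
  }
  expect_true(all(sim$truth$r2 == 1))
  ## generator-reported signal fraction matches realized variance ratio
  cfg2 <- generator_config(n_tasks = 3, n_examples = 400, p_features = 32,
                           latent_dim = 6, seed = 22)
  sim2 <- generate_tasks(cfg2)
  for (i in 1:3) {
    tk <- sim2$collection$tasks[[i]]
    expect_lt(abs(sim2$truth$r2[i] -
                    (1 - sim2$truth$sigma[i]^2 / stats::var(tk$target))),
              0.05)
  }
})

test_that("probe sets share the feature distribution but not the examples", {
  cfg <- generator_config(n_tasks = 5, n_examples = 60, p_features = 40,
                          latent_dim = 5, seed = 31)
  sim <- generate_tasks(cfg)
  probe0 <- make_probe_set(cfg, 0)
  expect_equal(dim(probe0), c(0, 40))
  probe <- make_probe_set(cfg, 500)
  expect_equal(dim(probe), c(500, 40))
  train_ids <- unlist(lapply(sim$collection$tasks, `[[`, "example_ids"))
  expect_length(intersect(rownames(probe), train_ids), 0)
  ## per-bit means agree with training within 3 standard errors
  train_X <- do.call(rbind, lapply(sim$collection$tasks, `[[`, "features"))
  p_hat <- colMeans(train_X)
  se <- sqrt(p_hat * (1 - p_hat) / nrow(train_X)) +
    sqrt(colMeans(probe) * (1 - colMeans(probe)) / nrow(probe)) + 1e-6
  frac_within <- mean(abs(colMeans(probe) - p_hat) <= 3 * se)
  expect_gt(frac_within, 0.95)
})
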