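## Shared fixtures and independent oracles for the test suite.
## Fixtures are built in code; oracles are deliberately naive implementations
## kept separate from the package code paths they check.

## A tiny hand-built collection: n_tasks linear tasks over p shared features.
make_tiny_collection <- function(n_tasks = 3, n = 20, p = 4, seed = 42,
                                 noise = 0.1) {
  withr::with_seed(seed, {
    tasks <- lapply(seq_len(n_tasks), function(i) {
      X <- matrix(rnorm(n * p), n, p, dimnames = list(NULL, paste0("f", 1:p)))
      beta <- rnorm(p)
      task(sprintf("task%02d", i), X,
           as.numeric(X %*% beta) + rnorm(n, sd = noise))
    })
    task_collection(tasks, "tiny")
  })
}

## A collection of identical task copies (same X, same y, distinct ids).
make_identical_collection <- function(n_copies = 4, n = 60, p = 6,
                                      seed = 7, noise = 0.05) {
  withr::with_seed(seed, {
    X <- matrix(rnorm(n * p), n, p, dimnames = list(NULL, paste0("f", 1:p)))
    y <- as.numeric(tanh(X[, 1]) + 0.5 * X[, 2]) + rnorm(n, sd = noise)
    tasks <- lapply(seq_len(n_copies), function(i) {
      task(sprintf("copy%02d", i), X, y)
    })
    task_collection(tasks, "identical")
  })
}

## Brute-force 1-nearest-neighbour regression (Euclidean), the adapter oracle.
oracle_1nn <- function(Xtr, ytr, Xte) {
  apply(Xte, 1, function(row) {
    d2 <- colSums((t(Xtr) - row)^2)
    ytr[which.min(d2)]
  })
}

## Projected-gradient NNLS oracle: minimize ||y - P w||^2 s.t. w >= 0.
oracle_nnls <- function(P, y, iters = 1e5) {
  L <- 2 * norm(crossprod(P), "2")
  w <- rep(0, ncol(P))
  for (i in seq_len(iters)) {
    grad <- 2 * crossprod(P, P %*% w - y)
    w_new <- pmax(0, w - grad / L)
    if (max(abs(w_new - w)) < 1e-12) {
      w <- w_new
      break
    }
    w <- w_new
  }
  w
}

nnls_objective <- function(P, y, w) sum((y - P %*% w)^2)

## Exact binomial sign-test oracle (doubled tail, zeros dropped, capped).
oracle_sign_test <- function(diffs) {
  d <- diffs[diffs != 0]
  n <- length(d)
  if (n == 0) return(1)
  m <- min(sum(d > 0), sum(d < 0))
  min(1, 2 * sum(choose(n, 0:m)) / 2^n)
}

## Adjusted Rand index between two partitions (hand-rolled so cluster
## recovery checks do not lean on the clustering stack under test).
ari <- function(a, b) {
  tab <- table(a, b)
  sr <- rowSums(tab)
  sc <- colSums(tab)
  n <- sum(tab)
  si <- sum(choose(tab, 2))
  sa <- sum(choose(sr, 2))
  sb <- sum(choose(sc, 2))
  exp_i <- sa * sb / choose(n, 2)
  (si - exp_i) / ((sa + sb) / 2 - exp_i)
}

## Full 2^n enumeration oracle for the Wilcoxon signed-rank test (handles
## ties via average ranks). Only sensible for n <= about 14.
oracle_wilcoxon <- function(diffs) {
  d <- diffs[diffs != 0]
  n <- length(d)
  if (n == 0) return(1)
  r <- rank(abs(d))
  w_obs <- sum(r[d > 0])
  all_w <- vapply(0:(2^n - 1), function(mask) {
    signs <- bitwAnd(bitwShiftR(mask, 0:(n - 1)), 1L) == 1L
    sum(r[signs])
  }, numeric(1))
  min(1, 2 * min(mean(all_w <= w_obs + 1e-9), mean(all_w >= w_obs - 1e-9)))
}
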