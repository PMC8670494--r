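#' Root-mean-squared error
#'
#' @param pred,obs Numeric vectors of equal, nonzero length.
#' @return `sqrt(mean((pred - obs)^2))`.
#' @examples
#' rmse(c(1, 2), c(3, 2))  # sqrt(2)
#' @export
rmse <- function(pred, obs) {
  tml_assert(length(pred) == length(obs), "tml_integrity_error",
             "pred (%d) and obs (%d) differ in length", length(pred),
             length(obs))
  tml_assert(length(pred) > 0, "tml_integrity_error",
             "cannot compute RMSE of empty vectors")
  tml_assert(all(is.finite(pred)) && all(is.finite(obs)),
             "tml_integrity_error", "RMSE inputs must be finite")
  sqrt(mean((as.numeric(pred) - as.numeric(obs))^2))
}

#' Paired sign test
#'
#' Two-sided exact binomial test on the signs of paired differences
#' (classical doubled-tail convention, capped at 1). Zero differences are
#' discarded, the classical convention; the discarded count is reported so
#' the choice is auditable. Tests whether the paired medians differ.
#'
#' @param diffs Numeric vector of paired differences (e.g. per-task
#'   baseline RMSE minus variant RMSE).
#' @return A list of class `tml_test` with `p_value` in (0, 1], `n_pos`,
#'   `n_neg`, `n_ties`, `statistic` (the positive count).
#' @examples
#' sign_test(rep(1, 10))$p_value  # 2 * (1/2)^10
#' @export
sign_test <- function(diffs) {
  tml_assert(length(diffs) >= 1, "tml_config_error",
             "sign test needs at least one difference")
  tml_assert(all(is.finite(diffs)), "tml_integrity_error",
             "differences must be finite")
  n_pos <- sum(diffs > 0)
  n_neg <- sum(diffs < 0)
  n_ties <- sum(diffs == 0)
  n <- n_pos + n_neg
  p <- if (n == 0) 1 else min(1, 2 * stats::pbinom(min(n_pos, n_neg), n, 0.5))
  structure(list(method = "sign", p_value = p, statistic = n_pos,
                 n_pos = n_pos, n_neg = n_neg, n_ties = n_ties,
                 degenerate = n == 0),
            class = "tml_test")
}

## Exact null distribution of the signed-rank statistic W+ over all 2^n sign
## assignments, via generating-function convolution on doubled ranks (so
## tied, half-integer average ranks stay integral). O(n * sum(ranks)).
signed_rank_null_cdf <- function(ranks2, w2) {
  total <- sum(ranks2)
  f <- c(1, numeric(total))  # f[s + 1] = P(W2 = s)
  for (r in ranks2) {
    shifted <- c(numeric(r), f[seq_len(total + 1 - r)])
    f <- 0.5 * (f + shifted)
  }
  c(lower = sum(f[seq_len(w2 + 1)]),
    upper = sum(f[seq(w2 + 1, total + 1)]))
}

#' Paired Wilcoxon signed-rank test
#'
#' Two-sided test on the ranks of paired differences; tests whether the
#' paired means differ. Zeros are discarded; tied absolute differences get
#' average ranks. The null distribution is exact (full sign-assignment
#' enumeration, computed by convolution, valid under ties) for `n <=
#' exact_limit`, and a tie-corrected normal approximation with continuity
#' correction beyond.
#'
#' @param diffs Numeric vector of paired differences.
#' @param exact_limit Largest n for which the exact distribution is used.
#' @return A list of class `tml_test` with `p_value`, `statistic` (W+, the
#'   positive-rank sum), `n` (nonzero pairs), `n_ties` (discarded zeros) and
#'   `exact` flag.
#' @examples
#' wilcoxon_signed_rank(1:5)$p_value  # 2 / 2^5
#' @export
wilcoxon_signed_rank <- function(diffs, exact_limit = 25) {
  tml_assert(length(diffs) >= 1, "tml_config_error",
             "signed-rank test needs at least one difference")
  tml_assert(all(is.finite(diffs)), "tml_integrity_error",
             "differences must be finite")
  n_zero <- sum(diffs == 0)
  d <- diffs[diffs != 0]
  n <- length(d)
  if (n == 0) {
    return(structure(list(method = "wilcoxon", p_value = 1,
                          statistic = NA_real_, n = 0, n_ties = n_zero,
                          exact = TRUE, degenerate = TRUE),
                     class = "tml_test"))
  }
  r <- rank(abs(d))  # average ranks for ties
  w_pos <- sum(r[d > 0])
  if (n <= exact_limit) {
    ranks2 <- as.integer(round(2 * r))
    w2 <- as.integer(round(2 * w_pos))
    tails <- signed_rank_null_cdf(ranks2, w2)
    p <- min(1, 2 * min(tails))
    exact <- TRUE
  } else {
    mu <- n * (n + 1) / 4
    tie_tab <- table(r)
    sigma2 <- n * (n + 1) * (2 * n + 1) / 24 -
      sum(tie_tab^3 - tie_tab) / 48
    z <- (w_pos - mu - 0.5 * sign(w_pos - mu)) / sqrt(sigma2)
    p <- min(1, 2 * stats::pnorm(-abs(z)))
    exact <- FALSE
  }
  structure(list(method = "wilcoxon", p_value = p, statistic = w_pos, n = n,
                 n_ties = n_zero, exact = exact, degenerate = FALSE),
            class = "tml_test")
}

#' @export
print.tml_test <- function(x, ...) {
  cat(sprintf("<tml_test> %s: p = %.6g (statistic = %s)\n", x$method,
              x$p_value, format(x$statistic)))
  invisible(x)
}
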