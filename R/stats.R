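#' Two-sided permutation test for a difference in means
#'
#' Unpaired: the group labels are permuted (a random size-`nx` subset of the
#' pooled sample is relabeled as x) `n_iterations` times. Paired: the signs
#' of the paired differences are flipped at random. The two-sided p-value is
#' `max(#(|null| >= |observed|), 1) / n_iterations`, so the smallest
#' attainable p is `1 / n_iterations` (0.0001 at the default 10,000
#' iterations). The effect size is Cohen's d: the observed mean difference
#' divided by the pooled standard deviation.
#'
#' @param x,y numeric samples (equal length when `paired`).
#' @param paired logical.
#' @param n_iterations Monte-Carlo iterations.
#' @param seed RNG seed.
#' @return a `pm_permutation` list: `p`, `observed_diff`, `effect_size`,
#'   `n_iterations`, `paired`, `seed`.
#' @examples
#' permutation_test(rnorm(10), rnorm(10), n_iterations = 1000, seed = 1)
#' @export
permutation_test <- function(x, y, paired = FALSE, n_iterations = 10000,
                             seed = 1) {
  x <- as.numeric(x); y <- as.numeric(y)
  if (length(x) == 0 || length(y) == 0) stop("empty input sample")
  if (paired) {
    if (length(x) != length(y)) stop("paired samples must have equal length")
    if (length(x) < 2) stop("paired test needs at least 2 pairs")
  }
  obs <- mean(x) - mean(y)
  nx <- length(x); ny <- length(y)
  pooled_sd <- sqrt(((nx - 1) * var(x) + (ny - 1) * var(y)) / (nx + ny - 2))
  eff <- if (is.finite(pooled_sd) && pooled_sd > 0) obs / pooled_sd else
    ifelse(obs == 0, 0, sign(obs) * Inf)
  set.seed(seed)
  if (paired) {
    d <- x - y
    signs <- matrix(sample(c(-1, 1), length(d) * n_iterations, replace = TRUE),
                    length(d), n_iterations)
    null <- as.numeric(crossprod(d, signs)) / length(d)
  } else {
    pool <- c(x, y)
    tot <- sum(pool)
    null <- vapply(seq_len(n_iterations), function(b) {
      sx <- sum(pool[sample.int(nx + ny, nx)])
      sx / nx - (tot - sx) / ny
    }, 0)
  }
  p <- max(sum(abs(null) >= abs(obs)), 1) / n_iterations
  structure(list(p = p, observed_diff = obs, effect_size = eff,
                 n_iterations = n_iterations, paired = paired, seed = seed),
            class = "pm_permutation")
}

#' @export
print.pm_permutation <- function(x, ...) {
  cat("<pm_permutation> ", if (x$paired) "paired" else "unpaired",
      ": diff = ", signif(x$observed_diff, 4),
      ", effect size = ", signif(x$effect_size, 4),
      ", p = ", signif(x$p, 4), " (", x$n_iterations, " iterations)\n",
      sep = "")
  invisible(x)
}

#' Bonferroni-corrected significance decisions
#'
#' A comparison is significant at family level `alpha` iff its raw p-value
#' is below `alpha / m`.
#'
#' @param p_values raw p-values.
#' @param m number of comparisons in the family (default
#'   `length(p_values)`).
#' @param alpha family-wise level.
#' @return list: `significant` (logical vector), `threshold` (`alpha / m`),
#'   `m`, `alpha`.
#' @export
bonferroni <- function(p_values, m = length(p_values), alpha = 0.05) {
  if (m < 1) stop("m must be >= 1")
  list(significant = p_values < alpha / m, threshold = alpha / m,
       m = m, alpha = alpha)
}
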