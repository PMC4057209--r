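#' Exact Wilcoxon signed-rank test for paired samples
#'
#' Paired signed-rank test with an exact permutation null for small
#' samples: zero differences are dropped (Wilcoxon's original
#' convention), absolute differences are mid-ranked, and for
#' `n <= exact_limit` the null distribution of the positive rank sum is
#' obtained by exact enumeration of all `2^n` sign assignments (computed
#' by dynamic programming over doubled mid-ranks, so ties are handled
#' exactly). The two-sided p-value doubles the smaller tail, capped at 1.
#' For larger samples a normal approximation with tie and continuity
#' corrections is used.
#'
#' @param a Values under condition A, or the paired differences if `b`
#'   is `NULL`.
#' @param b Optional values under condition B, paired with `a`.
#' @param alternative `"two.sided"` (default), `"greater"` (A tends to
#'   exceed B) or `"less"`.
#' @param exact_limit Largest effective n for which the exact
#'   distribution is enumerated (default 20).
#' @return An object of class `wilcoxon_signed_rank`: list with
#'   `statistic` (positive rank sum W+), `p_value`, `method`
#'   (`"exact"` or `"normal-approximation"`), `alternative`,
#'   `n_effective` and `n_zero_dropped`.
#' @export
wilcoxon_signed_rank <- function(a, b = NULL,
                                 alternative = c("two.sided", "greater", "less"),
                                 exact_limit = 20L) {
  alternative <- match.arg(alternative)
  d <- if (is.null(b)) as.double(a) else {
    if (length(a) != length(b)) {
      stop_dcar("Paired samples must have equal length.", "dcar_validation_error")
    }
    as.double(a) - as.double(b)
  }
  if (length(d) < 1L || anyNA(d)) {
    stop_dcar("Differences must be non-empty and free of missing values.",
              "dcar_validation_error")
  }
  n_zero <- sum(d == 0)
  d <- d[d != 0]
  n <- length(d)
  if (n == 0L) {
    stop_dcar("All paired differences are zero; the test is degenerate.",
              "dcar_degenerate_sample")
  }
  r <- rank(abs(d))
  w_pos <- sum(r[d > 0])

  if (n <= exact_limit) {
    # exact null: counts of the doubled rank sum over all 2^n sign patterns
    r2 <- as.integer(round(2 * r))
    total <- sum(r2)
    counts <- numeric(total + 1L)
    counts[1L] <- 1
    for (ri in r2) {
      shifted <- c(numeric(ri), counts[seq_len(total + 1L - ri)])
      counts <- counts + shifted
    }
    counts <- counts / 2^n
    w2 <- as.integer(round(2 * w_pos))
    p_ge <- sum(counts[(w2 + 1L):(total + 1L)])
    p_le <- sum(counts[seq_len(w2 + 1L)])
    p <- switch(alternative,
      two.sided = min(1, 2 * min(p_ge, p_le)),
      greater = p_ge,
      less = p_le
    )
    method <- "exact"
  } else {
    mu <- n * (n + 1) / 4
    ties <- table(r)
    sigma2 <- n * (n + 1) * (2 * n + 1) / 24 - sum(ties^3 - ties) / 48
    z_num <- w_pos - mu
    correct <- switch(alternative,
      two.sided = sign(z_num) * 0.5, greater = 0.5, less = -0.5
    )
    z <- (z_num - correct) / sqrt(sigma2)
    p <- switch(alternative,
      two.sided = min(1, 2 * stats::pnorm(-abs(z))),
      greater = stats::pnorm(z, lower.tail = FALSE),
      less = stats::pnorm(z)
    )
    method <- "normal-approximation"
  }
  structure(
    list(statistic = w_pos, p_value = p, method = method,
         alternative = alternative, n_effective = n, n_zero_dropped = n_zero),
    class = "wilcoxon_signed_rank"
  )
}

#' @export
print.wilcoxon_signed_rank <- function(x, ...) {
  cat(sprintf(
    "Wilcoxon signed-rank (%s): W+ = %g, n = %d (%d zero pairs dropped), %s p = %.4g\n",
    x$method, x$statistic, x$n_effective, x$n_zero_dropped, x$alternative,
    x$p_value
  ))
  invisible(x)
}

#' Holm step-down adjustment
#'
#' Sequential (step-down) Bonferroni correction of a family of p-values:
#' with the p-values sorted ascending, the i-th adjusted value is the
#' running maximum of `(m - i + 1) * p_(i)`, capped at 1, and results are
#' returned in the original input order. Dominates the unadjusted
#' p-values and is dominated by plain Bonferroni.
#'
#' @param p Numeric vector of p-values in \[0, 1\].
#' @return Adjusted p-values, same length and order as `p`.
#' @export
holm_adjust <- function(p) {
  if (length(p) == 0L) return(numeric(0))
  if (anyNA(p) || any(!is.finite(p)) || any(p < 0 | p > 1)) {
    stop_dcar("All p-values must lie in [0, 1].", "dcar_validation_error")
  }
  stats::p.adjust(p, method = "holm")
}

#' Median and interquartile range
#'
#' Median with first and third quartiles computed by linear interpolation
#' between order statistics (`stats::quantile()` type 7), the convention
#' used throughout the cohort summaries.
#'
#' @param values Non-empty numeric vector without missing values.
#' @return Named numeric vector `c(median, q1, q3)`.
#' @export
median_iqr <- function(values) {
  if (length(values) < 1L || anyNA(values)) {
    stop_dcar("`values` must be non-empty and free of missing values.",
              "dcar_validation_error")
  }
  q <- stats::quantile(values, probs = c(0.5, 0.25, 0.75), type = 7,
                       names = FALSE)
  c(median = q[1], q1 = q[2], q3 = q[3])
}
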