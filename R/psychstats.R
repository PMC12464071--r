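#' Learning index
#'
#' `LI = (post - pre) / pre`: the relative threshold change from the
#' pre-training to the post-training measurement. Negative values indicate
#' improvement (lower thresholds); `LI = -0.5` means the threshold halved.
#' Scale-invariant by construction. Vectorized.
#'
#' @param pre,post thresholds in degrees; `pre` must be > 0.
#' @return Numeric vector of learning indices.
#' @export
learning_index <- function(pre, post) {
  if (any(!is.finite(pre)) || any(pre <= 0))
    stop("pre-training thresholds must be positive")
  (post - pre) / pre
}

#' Apply the learner-exclusion rule to a cohort
#'
#' Subjects whose training-location learning index is weaker than the
#' criterion (i.e. `LI > criterion_li`, default -0.20: less than 20%
#' improvement) are excluded. A criterion of -0.30 reproduces the common
#' robustness check.
#'
#' @param summaries data frame with one row per subject, containing at least
#'   `subject_id`, `randomization` and `li_training` (training-location LI).
#' @param criterion_li exclusion criterion on the training-location LI.
#' @return A list: `retained` (subset of `summaries`), `excluded`, and
#'   `report` (data frame of retained/excluded counts per randomization
#'   group).
#' @export
apply_exclusions <- function(summaries, criterion_li = -0.20) {
  stopifnot(is.data.frame(summaries),
            all(c("subject_id", "li_training") %in% names(summaries)))
  drop <- !is.finite(summaries$li_training) |
    summaries$li_training > criterion_li
  grp <- if ("randomization" %in% names(summaries))
    summaries$randomization else rep("all", nrow(summaries))
  report <- as.data.frame(table(group = grp, excluded = factor(
    drop, levels = c(FALSE, TRUE), labels = c("retained", "excluded"))))
  list(retained = summaries[!drop, , drop = FALSE],
       excluded = summaries[drop, , drop = FALSE],
       report = report, criterion_li = criterion_li)
}

#' Power-law fit to a learning curve
#'
#' Least-squares fit of `T(b) = a * b^(-beta) + c` to block-ordered
#' thresholds, with `a > 0`, `beta >= 0`, `c >= 0`. The asymptote `c` can be
#' pinned to zero (`three_param = FALSE`). Fitting is by bounded
#' quasi-Newton (`optim`, L-BFGS-B) from several deterministic starting
#' points; non-convergence is flagged, not raised.
#'
#' @param block_index positive block indices (1..N).
#' @param thresholds positive thresholds, same length (>= 4 for the
#'   3-parameter model).
#' @param three_param fit the asymptote `c` (default) or pin `c = 0`.
#' @details The model is linear in `(a, c)` at fixed `beta`, so the fit
#'   profiles the decay rate: for each `beta` the amplitudes are solved by
#'   (nonnegativity-constrained) linear least squares, and `beta` is found by
#'   a coarse grid on \[0, 10\] followed by golden-section refinement.
#' @return A list `a`, `beta`, `c`, `residual` (residual norm), `fitted`,
#'   `converged`.
#' @export
power_law_fit <- function(block_index, thresholds, three_param = TRUE) {
  b <- as.numeric(block_index); y <- as.numeric(thresholds)
  stopifnot(length(b) == length(y))
  if (any(b <= 0)) stop("block_index must be positive")
  if (any(!is.finite(y)) || any(y <= 0)) stop("thresholds must be positive")
  if (length(y) < (if (three_param) 4L else 3L))
    stop("need at least 4 blocks (3 for the two-parameter model)")
  solve_amp <- function(beta) {
    x <- b^(-beta)
    if (three_param) {
      cf <- tryCatch(stats::coef(stats::lm.fit(cbind(x, 1), y)),
                     error = function(e) c(NA, NA))
      a <- cf[1]; cc <- cf[2]
      if (!is.finite(a) || !is.finite(cc)) { a <- 0; cc <- mean(y) }
      if (cc < 0) { cc <- 0; a <- max(sum(x * y) / sum(x * x), 0) }
      if (a < 0) { a <- 0; cc <- max(mean(y), 0) }
    } else {
      a <- max(sum(x * y) / sum(x * x), 0); cc <- 0
    }
    mu <- a * x + cc
    list(a = a, c = cc, rss = sum((y - mu)^2), fitted = mu)
  }
  grid <- seq(0, 10, by = 0.1)
  rss_g <- vapply(grid, function(bb) solve_amp(bb)$rss, numeric(1))
  i <- which.min(rss_g)
  lo <- grid[max(i - 1L, 1L)]; hi <- grid[min(i + 1L, length(grid))]
  opt <- stats::optimize(function(bb) solve_amp(bb)$rss, c(lo, hi),
                         tol = 1e-10)
  beta <- opt$minimum
  sol <- solve_amp(beta)
  converged <- is.finite(sol$rss)
  list(a = unname(sol$a), beta = beta, c = unname(sol$c),
       residual = sqrt(sol$rss), fitted = sol$fitted, converged = converged)
}

#' Welch two-sample t-test with Cohen's d
#'
#' Welch's unequal-variance t statistic with Welch-Satterthwaite degrees of
#' freedom (via [stats::t.test()]), sign convention `a - b`, plus Cohen's d
#' from the pooled standard deviation (the conventional effect-size default;
#' set `d_method = "welch"` for the average-variance variant).
#'
#' @param a,b numeric samples, each of length >= 2.
#' @param d_method `"pooled"` (default) or `"welch"` denominator for d.
#' @return A list: `t`, `df`, `p` (two-sided), `cohens_d`, `mean_diff`.
#' @export
welch_t <- function(a, b, d_method = c("pooled", "welch")) {
  d_method <- match.arg(d_method)
  a <- as.numeric(a); b <- as.numeric(b)
  if (length(a) < 2 || length(b) < 2) stop("each sample needs n >= 2")
  v1 <- stats::var(a); v2 <- stats::var(b)
  if (v1 == 0 && v2 == 0) stop("degenerate samples: both variances are zero")
  ht <- stats::t.test(a, b, var.equal = FALSE)
  n1 <- length(a); n2 <- length(b)
  sd_den <- if (d_method == "pooled")
    sqrt(((n1 - 1) * v1 + (n2 - 1) * v2) / (n1 + n2 - 2))
  else sqrt((v1 + v2) / 2)
  list(t = unname(ht$statistic), df = unname(ht$parameter),
       p = ht$p.value, cohens_d = (mean(a) - mean(b)) / sd_den,
       mean_diff = mean(a) - mean(b))
}

#' Pearson correlation test
#'
#' `t = r * sqrt(n - 2) / sqrt(1 - r^2)` on `df = n - 2`, with one- or
#' two-sided p-value. Perfect correlations (|r| = 1) yield `t = Inf` and
#' `p = 0` with a warning rather than an error.
#'
#' @param x,y paired numeric vectors without missing values, n >= 4.
#' @param sided `"two"` (default), `"greater"` (r > 0) or `"less"`.
#' @return A list: `r`, `t`, `df`, `p`, `n`.
#' @export
pearson_r_test <- function(x, y, sided = c("two", "greater", "less")) {
  sided <- match.arg(sided)
  x <- as.numeric(x); y <- as.numeric(y)
  if (length(x) != length(y)) stop("x and y must be paired")
  if (anyNA(x) || anyNA(y)) stop("missing values not allowed")
  n <- length(x)
  if (n < 4) stop("need n >= 4")
  if (stats::var(x) == 0 || stats::var(y) == 0)
    stop("zero-variance input: correlation undefined")
  r <- stats::cor(x, y)
  df <- n - 2
  if (abs(r) >= 1 - 1e-12) {
    warning("|r| = 1: t is infinite")
    t <- sign(r) * Inf
  } else {
    t <- r * sqrt(df) / sqrt(1 - r^2)
  }
  p <- switch(sided,
              two = 2 * stats::pt(-abs(t), df),
              greater = stats::pt(t, df, lower.tail = FALSE),
              less = stats::pt(t, df))
  list(r = r, t = t, df = df, p = p, n = n)
}

#' Compare two independent Pearson correlations (Fisher r-to-z)
#'
#' \deqn{z = \frac{\mathrm{atanh}(r_1) - \mathrm{atanh}(r_2)}
#'   {\sqrt{1/(n_1-3) + 1/(n_2-3)}}}
#' with the p-value from the standard normal; one-sided tests the
#' alternative `r1 > r2`. Cohen's q is `|atanh(r1) - atanh(r2)|`.
#'
#' @param r1,r2 sample correlations, |r| < 1.
#' @param n1,n2 sample sizes, each >= 4.
#' @param sided `"one"` (alternative r1 > r2) or `"two"`.
#' @return An object of class `correlation_comparison`: `r1`, `n1`, `r2`,
#'   `n2`, `z_stat`, `p_value`, `sidedness`, `cohens_q`.
#' @examples
#' compare_independent_correlations(0.71, 13, 0.09, 16, sided = "one")
#' @export
compare_independent_correlations <- function(r1, n1, r2, n2,
                                             sided = c("one", "two")) {
  sided <- match.arg(sided)
  if (abs(r1) >= 1 || abs(r2) >= 1) stop("|r| must be < 1")
  if (n1 <= 3 || n2 <= 3) stop("need n > 3 in each group")
  dz <- atanh(r1) - atanh(r2)
  z <- dz / sqrt(1 / (n1 - 3) + 1 / (n2 - 3))
  p <- if (sided == "one") stats::pnorm(z, lower.tail = FALSE)
  else 2 * stats::pnorm(-abs(z))
  out <- list(r1 = r1, n1 = n1, r2 = r2, n2 = n2, z_stat = z, p_value = p,
              sidedness = sided, cohens_q = abs(dz))
  class(out) <- "correlation_comparison"
  out
}

#' @export
print.correlation_comparison <- function(x, ...) {
  cat(sprintf(
    "Fisher r-to-z: r1 = %.3f (n = %d) vs r2 = %.3f (n = %d)\n  z = %.4f, %s-sided p = %.4f, Cohen's q = %.3f\n",
    x$r1, x$n1, x$r2, x$n2, x$z_stat, x$sidedness, x$p_value, x$cohens_q))
  invisible(x)
}

#' Partial eta squared from an F statistic
#'
#' `eta_p^2 = F * df1 / (F * df1 + df2)`; monotone in F and bounded in
#' \[0, 1). Vectorized.
#'
#' @param f F statistic(s), >= 0.
#' @param df1,df2 numerator and denominator degrees of freedom, > 0.
#' @return Partial eta squared value(s).
#' @export
partial_eta_sq <- function(f, df1, df2) {
  if (any(f < 0)) stop("F must be nonnegative")
  if (any(df1 <= 0) || any(df2 <= 0)) stop("degrees of freedom must be > 0")
  f * df1 / (f * df1 + df2)
}
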