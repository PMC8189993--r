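#' Welch's t-test from summary statistics
#'
#' Two-sided Welch test computed directly from group means, SDs and sizes,
#' with the Welch--Satterthwaite degrees of freedom.  Equivalent to
#' `t.test(x, y)` on raw data with matching summaries.
#'
#' @param mean1,sd1,n1 First group summary (n >= 2, sd >= 0).
#' @param mean2,sd2,n2 Second group summary.
#' @return List with `t`, `df`, `p`.
#' @export
welch_from_summary <- function(mean1, sd1, n1, mean2, sd2, n2) {
  if (n1 < 2 || n2 < 2) stop("each group needs n >= 2")
  if (sd1 < 0 || sd2 < 0 || (sd1 == 0 && sd2 == 0)) {
    stop("SDs must be non-negative and not both zero")
  }
  v1 <- sd1^2 / n1
  v2 <- sd2^2 / n2
  t <- (mean1 - mean2) / sqrt(v1 + v2)
  df <- (v1 + v2)^2 / (v1^2 / (n1 - 1) + v2^2 / (n2 - 1))
  list(t = t, df = df, p = 2 * stats::pt(-abs(t), df))
}

# Degrees to radians with an input check.
.check_angles <- function(a, min_n, name) {
  a <- a[is.finite(a)]
  if (length(a) < min_n) {
    stop(name, " needs at least ", min_n, " finite angles per sample")
  }
  a * pi / 180
}

# Watson's two-sample U^2 statistic on two angle vectors (radians).
.watson_u2 <- function(a, b) {
  n <- length(a); m <- length(b); N <- n + m
  x <- c(a, b)
  g <- c(rep(1L, n), rep(2L, m))
  o <- order(x)
  g <- g[o]
  # empirical CDF difference at each pooled ordered point
  dk <- cumsum(ifelse(g == 1L, 1 / n, 0)) - cumsum(ifelse(g == 2L, 1 / m, 0))
  (n * m / N^2) * sum((dk - mean(dk))^2)
}

# Asymptotic tail of the U^2 distribution.
.u2_pvalue <- function(u2, terms = 20) {
  k <- seq_len(terms)
  p <- 2 * sum((-1)^(k - 1) * exp(-2 * k^2 * pi^2 * u2))
  min(max(p, 0), 1)
}

#' Watson's two-sample test of homogeneity for circular data
#'
#' Computes Watson's U^2 on the pooled circular ranks of two angle samples
#' (degrees), with an asymptotic p-value from the standard U^2 tail series
#' and/or a randomization p-value obtained by permuting sample labels,
#' \eqn{p = (1 + \#\{U^2_{perm} \ge U^2_{obs}\})/(B+1)}.
#'
#' @param angles_a,angles_b Angle samples in degrees (>= 4 each).
#' @param mode `"asymptotic"`, `"randomization"`, or `"both"`.
#' @param B Number of permutations.
#' @param seed Seed for the permutations.
#' @return List with `statistic`, `p_asymptotic`, `p_randomization`, `B`,
#'   `seed`.
#' @export
watson_two_sample <- function(angles_a, angles_b,
                              mode = c("both", "asymptotic", "randomization"),
                              B = 999, seed = 1) {
  mode <- match.arg(mode)
  a <- .check_angles(angles_a, 4, "watson_two_sample")
  b <- .check_angles(angles_b, 4, "watson_two_sample")
  u2 <- .watson_u2(a, b)
  out <- list(statistic = u2, p_asymptotic = NA_real_,
              p_randomization = NA_real_, B = B, seed = seed)
  if (mode %in% c("both", "asymptotic")) out$p_asymptotic <- .u2_pvalue(u2)
  if (mode %in% c("both", "randomization")) {
    x <- c(a, b); n <- length(a)
    set.seed(seed)
    hits <- 0L
    for (r in seq_len(B)) {
      i <- sample.int(length(x), n)
      if (.watson_u2(x[i], x[-i]) >= u2 - 1e-12) hits <- hits + 1L
    }
    out$p_randomization <- (1 + hits) / (B + 1)
  }
  out
}

# Mardia-Watson-Wheeler uniform-scores W statistic (radians input).
.mww_w <- function(a, b) {
  n <- length(a); m <- length(b); N <- n + m
  r <- rank(c(a, b), ties.method = "average")
  gamma <- 2 * pi * r / N
  ga <- gamma[seq_len(n)]
  gb <- gamma[n + seq_len(m)]
  2 * ((sum(cos(ga))^2 + sum(sin(ga))^2) / n +
       (sum(cos(gb))^2 + sum(sin(gb))^2) / m)
}

#' Mardia-Watson-Wheeler test for a common circular distribution
#'
#' Large-sample uniform-scores test: the pooled angles are ranked around the
#' circle, each rank mapped to a uniform score, and the statistic
#' \eqn{W = 2\sum_j (C_j^2 + S_j^2)/n_j} is referred to a chi-square with 2
#' degrees of freedom (two samples); optionally confirmed by a randomization
#' version permuting sample labels.
#'
#' @inheritParams watson_two_sample
#' @return List with `statistic`, `p_asymptotic`, `p_randomization`, `B`,
#'   `seed`.
#' @export
mardia_watson_wheeler <- function(angles_a, angles_b,
                                  mode = c("both", "asymptotic",
                                           "randomization"),
                                  B = 999, seed = 1) {
  mode <- match.arg(mode)
  a <- .check_angles(angles_a, 4, "mardia_watson_wheeler")
  b <- .check_angles(angles_b, 4, "mardia_watson_wheeler")
  w <- .mww_w(a, b)
  out <- list(statistic = w, p_asymptotic = NA_real_,
              p_randomization = NA_real_, B = B, seed = seed)
  if (mode %in% c("both", "asymptotic")) {
    out$p_asymptotic <- stats::pchisq(w, df = 2, lower.tail = FALSE)
  }
  if (mode %in% c("both", "randomization")) {
    x <- c(a, b); n <- length(a)
    set.seed(seed)
    hits <- 0L
    for (r in seq_len(B)) {
      i <- sample.int(length(x), n)
      if (.mww_w(x[i], x[-i]) >= w - 1e-12) hits <- hits + 1L
    }
    out$p_randomization <- (1 + hits) / (B + 1)
  }
  out
}

# The four size-structure metrics on a sorted size vector.
.size_metrics <- function(sizes) {
  s <- sort(sizes)
  ratios <- s[-1] / s[-length(s)]   # larger / next larger, always >= 1
  diffs <- s[-1] - s[-length(s)]
  c(variance_ratio = stats::var(ratios),
    variance_difference = stats::var(diffs),
    minimum_ratio = min(ratios),
    minimum_difference = min(diffs))
}

#' Hutchinson size-ratio null-model battery
#'
#' Tests whether a set of coexisting species' body sizes are more regularly
#' spaced than chance.  Sizes are sorted; adjacent ratios are computed as
#' larger over next larger (hence >= 1) and adjacent absolute differences
#' likewise.  Four metrics are evaluated: the variance of the ratios, the
#' variance of the differences, the minimum ratio and the minimum
#' difference.  The null model fixes the smallest and largest size and draws
#' the interior sizes i.i.d. Uniform(min, max); each metric's p-value is the
#' lower tail \eqn{(1 + \#\{null \le obs\})/(iterations + 1)} since small
#' variances or minima indicate regular spacing.
#'
#' @param sizes Numeric vector of >= 3 positive sizes.
#' @param iterations Null-model replicates.
#' @param seed Seed.
#' @return List with `observed` (four metrics), `p` (per-metric lower-tail
#'   p), `null_mean`, `iterations`, `seed`.
#' @export
size_ratio_null_test <- function(sizes, iterations = 1000, seed = 1) {
  if (length(sizes) < 3) stop("need at least 3 sizes")
  if (any(sizes <= 0)) stop("sizes must be positive")
  obs <- .size_metrics(sizes)
  lo <- min(sizes); hi <- max(sizes)
  k <- length(sizes) - 2
  set.seed(seed)
  nulls <- matrix(NA_real_, iterations, 4)
  for (r in seq_len(iterations)) {
    nulls[r, ] <- .size_metrics(c(lo, hi, stats::runif(k, lo, hi)))
  }
  colnames(nulls) <- names(obs)
  p <- (1 + colSums(sweep(nulls, 2, obs, `<=`))) / (iterations + 1)
  list(observed = obs, p = p, null_mean = colMeans(nulls),
       iterations = iterations, seed = seed)
}
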