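#' Welch's heteroscedasticity-robust one-way ANOVA
#'
#' Tests equality of group means without assuming equal variances, the
#' appropriate omnibus test when group spreads of a measurement such as
#' PVSvf differ strongly. With weights `w_i = n_i / s_i^2`,
#' `F = [sum w_i (m_i - m_w)^2 / (k-1)] / [1 + 2(k-2)/(k^2-1) L]` where
#' `m_w` is the weighted grand mean and
#' `L = sum (1 - w_i/sum w)^2 / (n_i - 1)`; the denominator degrees of
#' freedom are `(k^2 - 1) / (3 L)` (Welch-Satterthwaite). The effect
#' size uses the classical one-way omega-squared
#' `df1 (F - 1) / (df1 (F - 1) + N)`.
#'
#' @param groups named list of numeric vectors, one per group; each
#'   needs `n >= 2` and positive variance.
#' @return An object of class `welch_anova`: `F`, `df1`, `df2`, `p`,
#'   `omega_sq`, `n_total`, `k`.
#' @export
welch_anova <- function(groups) {
  g <- check_groups(groups)
  k <- length(g)
  n <- lengths(g)
  m <- vapply(g, mean, numeric(1))
  v <- vapply(g, var, numeric(1))
  w <- n / v
  sw <- sum(w)
  mw <- sum(w * m) / sw
  lambda <- sum((1 - w / sw)^2 / (n - 1))
  Fstat <- (sum(w * (m - mw)^2) / (k - 1)) /
    (1 + 2 * (k - 2) / (k^2 - 1) * lambda)
  df1 <- k - 1
  df2 <- (k^2 - 1) / (3 * lambda)
  p <- pf(Fstat, df1, df2, lower.tail = FALSE)
  N <- sum(n)
  omega <- df1 * (Fstat - 1) / (df1 * (Fstat - 1) + N)
  structure(list(F = Fstat, df1 = df1, df2 = df2, p = p,
                 omega_sq = omega, n_total = N, k = k),
            class = "welch_anova")
}

#' @export
print.welch_anova <- function(x, ...) {
  cat(sprintf("Welch's ANOVA: F(%d, %.1f) = %.4f, p = %.4g, omega^2 = %.3f\n",
              x$df1, x$df2, x$F, x$p, x$omega_sq))
  invisible(x)
}

check_groups <- function(groups) {
  if (!is.list(groups) || length(groups) < 2)
    stop("need a list of k >= 2 groups")
  g <- lapply(groups, as.numeric)
  if (is.null(names(g)) || any(!nzchar(names(g))))
    names(g) <- paste0("group", seq_along(g))
  for (nm in names(g)) {
    x <- g[[nm]]
    if (length(x) < 2) stop("group '", nm, "' has fewer than 2 observations")
    if (anyNA(x) || any(!is.finite(x))) stop("group '", nm, "' has non-finite values")
    if (var(x) == 0) stop("group '", nm, "' has zero variance")
  }
  g
}

#' Games-Howell pairwise comparisons
#'
#' Post-hoc pairwise mean comparisons for unequal variances and sizes,
#' with the multiplicity correction built into the studentized-range
#' reference distribution. For groups i, j: estimate `m_j - m_i`,
#' `SE = sqrt(s_i^2/n_i + s_j^2/n_j)`, Welch-Satterthwaite degrees of
#' freedom, adjusted p from the studentized range with `k` groups at
#' `q = |estimate| sqrt(2) / SE`, and confidence interval
#' `estimate +/- q_crit / sqrt(2) * SE`. Cohen's d (pooled SD) is
#' reported per pair.
#'
#' @param groups named list of numeric vectors (see [welch_anova()]).
#' @param conf.level confidence level for the intervals (default 0.95).
#' @return data.frame of class `games_howell` with one row per pair:
#'   `group1`, `group2`, `estimate`, `se`, `df`, `ci_low`, `ci_high`,
#'   `p_adj`, `cohens_d`.
#' @export
games_howell <- function(groups, conf.level = 0.95) {
  g <- check_groups(groups)
  k <- length(g)
  n <- lengths(g)
  m <- vapply(g, mean, numeric(1))
  v <- vapply(g, var, numeric(1))
  pairs <- utils::combn(k, 2)
  rows <- apply(pairs, 2, function(ij) {
    i <- ij[1]; j <- ij[2]
    est <- m[j] - m[i]
    se <- sqrt(v[i] / n[i] + v[j] / n[j])
    df <- (v[i] / n[i] + v[j] / n[j])^2 /
      ((v[i] / n[i])^2 / (n[i] - 1) + (v[j] / n[j])^2 / (n[j] - 1))
    q <- abs(est) * sqrt(2) / se
    p_adj <- ptukey(q, nmeans = k, df = df, lower.tail = FALSE)
    qc <- qtukey(conf.level, nmeans = k, df = df)
    d <- cohens_d(m[i], sqrt(v[i]), n[i], m[j], sqrt(v[j]), n[j])
    data.frame(group1 = names(g)[i], group2 = names(g)[j],
               estimate = unname(est), se = unname(se), df = unname(df),
               ci_low = unname(est - qc / sqrt(2) * se),
               ci_high = unname(est + qc / sqrt(2) * se),
               p_adj = unname(p_adj), cohens_d = unname(d))
  })
  out <- do.call(rbind, rows)
  class(out) <- c("games_howell", "data.frame")
  out
}

#' Cohen's d from group summaries (pooled SD)
#'
#' `|mean_b - mean_a| / s_pooled` with
#' `s_pooled = sqrt(((n_a-1) s_a^2 + (n_b-1) s_b^2) / (n_a + n_b - 2))`.
#'
#' @param mean_a,sd_a,n_a first group summaries.
#' @param mean_b,sd_b,n_b second group summaries.
#' @return Non-negative standardized mean difference.
#' @export
cohens_d <- function(mean_a, sd_a, n_a, mean_b, sd_b, n_b) {
  if (sd_a < 0 || sd_b < 0 || n_a < 2 || n_b < 2)
    stop("need sds >= 0 and ns >= 2")
  sp <- sqrt(((n_a - 1) * sd_a^2 + (n_b - 1) * sd_b^2) / (n_a + n_b - 2))
  if (sp == 0) stop("pooled standard deviation is zero")
  abs(mean_b - mean_a) / sp
}

#' Spearman's rank correlation
#'
#' Pearson correlation of mid-ranks (average ranks for ties), with the
#' two-sided p-value from the t approximation
#' `t = rho sqrt((n-2)/(1-rho^2))` on `n - 2` degrees of freedom.
#'
#' @param x,y numeric vectors of equal length >= 3.
#' @return list with `rho` and `p`.
#' @export
spearman_rho <- function(x, y) {
  if (length(x) != length(y) || length(x) < 3)
    stop("x and y must have equal length >= 3")
  if (anyNA(x) || anyNA(y)) stop("missing values not supported")
  if (var(x) == 0 || var(y) == 0)
    stop("rank correlation undefined for a constant vector")
  rho <- stats::cor(rank(x), rank(y))
  n <- length(x)
  p <- if (abs(rho) >= 1) 0 else {
    tstat <- rho * sqrt((n - 2) / (1 - rho^2))
    2 * pt(-abs(tstat), df = n - 2)
  }
  list(rho = rho, p = p)
}

#' Intraclass correlation for intra-rater agreement
#'
#' Two-way mixed-effects, absolute-agreement, single-measurement ICC —
#' ICC(A,1) — for two ratings of the same subjects by one rater:
#' `(MS_R - MS_E) / (MS_R + (k-1) MS_E + k/n (MS_C - MS_E))` with
#' `k = 2` ratings, from the two-way ANOVA decomposition.
#'
#' @param rating1,rating2 paired measurement vectors, `n >= 3` subjects.
#' @return Scalar ICC.
#' @export
icc_intrarater <- function(rating1, rating2) {
  if (length(rating1) != length(rating2) || length(rating1) < 3)
    stop("need >= 3 paired subjects")
  x <- cbind(rating1, rating2)
  if (anyNA(x)) stop("missing values not supported")
  n <- nrow(x); k <- ncol(x)
  grand <- mean(x)
  rm_ <- rowMeans(x); cm <- colMeans(x)
  if (var(rm_) == 0) stop("zero between-subject variance: ICC undefined")
  ms_r <- k * sum((rm_ - grand)^2) / (n - 1)
  ms_c <- n * sum((cm - grand)^2) / (k - 1)
  resid <- x - outer(rm_, rep(1, k)) - outer(rep(1, n), cm) + grand
  ms_e <- sum(resid^2) / ((n - 1) * (k - 1))
  (ms_r - ms_e) / (ms_r + (k - 1) * ms_e + k / n * (ms_c - ms_e))
}

#' Bland-Altman bias and limits of agreement
#'
#' For paired ratings, the bias is the mean of the differences
#' (`rating2 - rating1`) and the limits of agreement are
#' `bias +/- 1.96 sd(differences)`.
#'
#' @param rating1,rating2 paired measurement vectors (>= 2 pairs).
#' @return list with `bias`, `loa_low`, `loa_high`.
#' @export
bland_altman <- function(rating1, rating2) {
  if (length(rating1) != length(rating2) || length(rating1) < 2)
    stop("need >= 2 pairs")
  d <- rating2 - rating1
  bias <- mean(d)
  s <- sd(d)
  list(bias = bias, loa_low = bias - 1.96 * s, loa_high = bias + 1.96 * s)
}

#' Ordinary least-squares regression summary
#'
#' Least-squares fit of `y` on the columns of `X` (with intercept),
#' reporting coefficient estimates, t-based confidence intervals,
#' p-values, and the adjusted R-squared
#' `1 - (1 - R^2)(n - 1)/(n - p - 1)`.
#'
#' @param y numeric response.
#' @param X data.frame or matrix of predictors.
#' @param conf.level confidence level for intervals (default 0.95).
#' @return list with `coefficients` (data.frame: term, estimate, ci_low,
#'   ci_high, p) and `adj_r_squared`.
#' @export
ols_regression <- function(y, X, conf.level = 0.95) {
  X <- as.data.frame(X)
  if (nrow(X) != length(y)) stop("y and X sizes differ")
  if (length(y) <= ncol(X) + 1) stop("need n > number of predictors + 1")
  dat <- cbind(data.frame(.y = y), X)
  fit <- lm(.y ~ ., data = dat)
  if (anyNA(stats::coef(fit))) stop("rank-deficient design matrix")
  sm <- summary(fit)
  ci <- confint(fit, level = conf.level)
  co <- stats::coef(sm)
  list(coefficients = data.frame(term = rownames(co),
                                 estimate = co[, "Estimate"],
                                 ci_low = ci[, 1], ci_high = ci[, 2],
                                 p = co[, "Pr(>|t|)"],
                                 row.names = NULL),
       adj_r_squared = sm$adj.r.squared,
       sigma = sm$sigma, n = length(y))
}

#' Monte-Carlo power of Welch's ANOVA
#'
#' Estimates the power of [welch_anova()] at level `alpha` for `k`
#' normal populations: draws `reps` replicate datasets with group `i`
#' sampled `N(mean_i, sd_i^2)` of size `n_i`, and reports the fraction
#' rejected. Fully reproducible given the seed; the Monte-Carlo standard
#' error is at most `sqrt(0.25/reps)`.
#'
#' @param ns,means,sds parallel group parameter vectors (k >= 2).
#' @param alpha significance level in (0, 1).
#' @param reps number of replicates (>= 1000).
#' @param seed RNG seed (mandatory; caller's RNG state is preserved).
#' @return Estimated power (scalar), with attribute `"mc_se"`.
#' @export
welch_power_mc <- function(ns, means, sds, alpha = 0.05, reps = 10000,
                           seed) {
  k <- length(ns)
  if (k < 2 || length(means) != k || length(sds) != k)
    stop("ns, means, sds must be parallel vectors with k >= 2")
  if (any(ns < 2) || any(sds <= 0)) stop("need ns >= 2 and sds > 0")
  if (!is.numeric(alpha) || alpha <= 0 || alpha >= 1)
    stop("alpha must be in (0, 1)")
  if (reps < 1000) stop("reps must be >= 1000")
  if (missing(seed)) stop("a seed is mandatory")

  p <- with_local_seed(seed, {
    # vectorized over replicates: per-rep means and variances per group
    m <- matrix(0, k, reps); v <- matrix(0, k, reps)
    for (i in seq_len(k)) {
      x <- matrix(rnorm(ns[i] * reps, means[i], sds[i]), ns[i], reps)
      m[i, ] <- colMeans(x)
      v[i, ] <- (colSums(x^2) - ns[i] * m[i, ]^2) / (ns[i] - 1)
    }
    w <- ns / v
    sw <- colSums(w)
    mw <- colSums(w * m) / sw
    lambda <- colSums((1 - sweep(w, 2, sw, "/"))^2 / (ns - 1))
    num <- colSums(w * (m - matrix(mw, k, reps, byrow = TRUE))^2) / (k - 1)
    Fstat <- num / (1 + 2 * (k - 2) / (k^2 - 1) * lambda)
    df2 <- (k^2 - 1) / (3 * lambda)
    pf(Fstat, k - 1, df2, lower.tail = FALSE)
  })
  power <- mean(p < alpha)
  attr(power, "mc_se") <- sqrt(power * (1 - power) / reps)
  power
}

#' Median and quartiles from category counts
#'
#' Expands an ordered score-to-count table (as printed in cohort
#' characteristics tables) to the full per-subject value list and
#' computes the median and quartiles by linear interpolation between
#' order statistics (position `1 + p(n - 1)`).
#'
#' @param counts named numeric vector (names = scores, values = counts)
#'   or a two-column data.frame `(score, count)`.
#' @return list with `median`, `q1`, `q3`, `n`.
#' @export
median_iqr_from_counts <- function(counts) {
  if (is.data.frame(counts)) {
    scores <- as.numeric(counts[[1]]); n <- as.numeric(counts[[2]])
  } else {
    if (is.null(names(counts))) stop("counts must carry scores as names")
    scores <- as.numeric(names(counts)); n <- as.numeric(counts)
  }
  if (anyNA(scores) || anyNA(n) || any(n < 0) || any(n != round(n)))
    stop("counts must be non-negative integers keyed by numeric scores")
  if (sum(n) < 1) stop("empty counts")
  ord <- order(scores)
  values <- rep(scores[ord], n[ord])
  q <- quantile(values, c(0.25, 0.5, 0.75), type = 7, names = FALSE)
  list(median = q[2], q1 = q[1], q3 = q[3], n = length(values))
}
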