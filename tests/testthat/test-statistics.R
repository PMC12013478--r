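test_that("Welch's ANOVA matches the hand-evaluated formula and stats::oneway.test", {
  w <- welch_anova(list(a = c(0, 1, 2), b = c(2, 3, 4), c = c(4, 5, 6)))
  expect_equal(w$F, 72 / 7, tolerance = 1e-12)
  expect_equal(w$df1, 2)
  expect_equal(w$df2, 4, tolerance = 1e-12)
  expect_equal(w$omega_sq, 2 * (72 / 7 - 1) / (2 * (72 / 7 - 1) + 9),
               tolerance = 1e-12)

  # property: agrees with the independent base-R implementation
  set.seed(17)
  for (rep in 1:20) {
    k <- sample(2:5, 1)
    g <- lapply(seq_len(k), function(i)
      rnorm(sample(3:12, 1), mean = runif(1, -2, 2), sd = runif(1, 0.5, 3)))
    names(g) <- paste0("g", seq_len(k))
    w <- welch_anova(g)
    o <- stats::oneway.test(y ~ grp,
                            data.frame(y = unlist(g),
                                       grp = factor(rep(names(g), lengths(g)))),
                            var.equal = FALSE)
    expect_equal(w$F, unname(o$statistic), tolerance = 1e-10)
    expect_equal(w$df2, unname(o$parameter[2]), tolerance = 1e-10)
    expect_equal(w$p, unname(o$p.value), tolerance = 1e-10)
  }
})

test_that("Welch's ANOVA with two groups reduces to the Welch t-test", {
  set.seed(23)
  x <- rnorm(12, 0, 1); y <- rnorm(7, 1, 3)
  w <- welch_anova(list(x = x, y = y))
  tt <- stats::t.test(x, y, var.equal = FALSE)
  expect_equal(w$F, unname(tt$statistic)^2, tolerance = 1e-10)
  expect_equal(w$p, tt$p.value, tolerance = 1e-10)
  expect_equal(w$df2, unname(tt$parameter), tolerance = 1e-10)
})

test_that("degenerate group inputs are rejected", {
  expect_error(welch_anova(list(a = 1:3)), "k >= 2")
  expect_error(welch_anova(list(a = 1:3, b = c(2, 2, 2))), "zero variance")
  expect_error(welch_anova(list(a = 1:3, b = 5)), "fewer than 2")
})

test_that("Games-Howell reproduces hand-evaluated SE and Welch-Satterthwaite df", {
  # pair with s1^2 = 1, n1 = 3 and s2^2 = 4, n2 = 3
  g <- list(a = c(-1, 0, 1), b = c(-2, 0, 2), c = c(10, 11, 12))
  gh <- games_howell(g)
  ab <- gh[gh$group1 == "a" & gh$group2 == "b", ]
  expect_equal(ab$se, sqrt(5 / 3), tolerance = 1e-12)
  expect_equal(ab$df, 50 / 17, tolerance = 1e-12)
  expect_equal(ab$estimate, 0)
  expect_equal(ab$p_adj, 1)
  # intervals always contain the estimate
  expect_true(all(gh$ci_low <= gh$estimate & gh$estimate <= gh$ci_high))
})

test_that("Games-Howell p-values are never below the unadjusted pairwise Welch p", {
  set.seed(29)
  for (rep in 1:10) {
    g <- lapply(1:4, function(i) rnorm(sample(4:10, 1), runif(1, 0, 2),
                                       runif(1, 0.5, 2)))
    names(g) <- paste0("g", 1:4)
    gh <- games_howell(g)
    for (r in seq_len(nrow(gh))) {
      praw <- stats::t.test(g[[gh$group1[r]]], g[[gh$group2[r]]],
                            var.equal = FALSE)$p.value
      expect_gte(gh$p_adj[r] + 1e-12, praw)
    }
  }
})

test_that("Cohen's d uses the pooled standard deviation", {
  expect_equal(cohens_d(0, 1, 10, 1, 1, 10), 1)
  expect_equal(cohens_d(3, 2, 5, 3, 1, 8), 0)
  expect_equal(cohens_d(0, 1, 5, 2, 2, 10),
               2 / sqrt((4 * 1 + 9 * 4) / 13), tolerance = 1e-12)
  expect_error(cohens_d(1, 0, 5, 2, 0, 5), "zero")
})

test_that("Spearman correlation uses mid-ranks with a t-approximation p", {
  expect_equal(spearman_rho(1:10, (1:10)^3)$rho, 1)
  expect_equal(spearman_rho(1:10, -(1:10))$rho, -1)
  expect_equal(spearman_rho(1:10, (1:10)^3)$p, 0)
  s <- spearman_rho(c(1, 2, 3, 4), c(1, 3, 2, 4))
  expect_equal(s$rho, 0.8, tolerance = 1e-12)
  # rho agrees with the base implementation, including ties
  set.seed(31)
  x <- sample(1:5, 30, replace = TRUE); y <- x + sample(0:2, 30, replace = TRUE)
  expect_equal(spearman_rho(x, y)$rho,
               unname(stats::cor(x, y, method = "spearman")), tolerance = 1e-12)
  expect_error(spearman_rho(rep(1, 5), 1:5), "constant")
})

test_that("ICC(A,1) is 1 for identical ratings, symmetric, and ~0.5 at equal noise", {
  set.seed(37)
  s <- rnorm(50, 10, 2)
  expect_equal(icc_intrarater(s, s), 1)
  r1 <- s + rnorm(50, 0, 0.5); r2 <- s + rnorm(50, 0, 0.5)
  expect_equal(icc_intrarater(r1, r2), icc_intrarater(r2, r1), tolerance = 1e-12)
  # rater noise with variance equal to the subject spread halves the ICC
  set.seed(38)
  s2 <- rnorm(4000, 0, 1)
  icc <- icc_intrarater(s2 + rnorm(4000), s2 + rnorm(4000))
  expect_equal(icc, 0.5, tolerance = 0.05)
  expect_error(icc_intrarater(1:2, 1:2), "3 paired")
  expect_error(icc_intrarater(c(1, 1, 1), c(2, 2, 2)), "between-subject")
})

test_that("Bland-Altman limits follow bias +/- 1.96 sd of the differences", {
  expect_equal(bland_altman(c(1, 2, 3), c(1, 2, 3)),
               list(bias = 0, loa_low = 0, loa_high = 0))
  b <- bland_altman(c(0, 0, 0, 0), c(1, 1, 1, 1))
  expect_equal(b$bias, 1); expect_equal(b$loa_low, 1); expect_equal(b$loa_high, 1)
  b2 <- bland_altman(c(0, 0, 0), c(-1, 0, 1))
  expect_equal(b2$bias, 0)
  expect_equal(b2$loa_high, 1.96, tolerance = 1e-12)
  expect_error(bland_altman(1, 2), "pairs")
})

test_that("OLS summaries match the normal-equations oracle", {
  x <- c(0, 1, 2, 3, 4, 5)
  fit <- suppressWarnings(ols_regression(2 * x + 1, data.frame(x = x)))
  expect_equal(fit$coefficients$estimate, c(1, 2), tolerance = 1e-10)
  expect_equal(fit$adj_r_squared, 1, tolerance = 1e-10)

  set.seed(41)
  X <- data.frame(a = rnorm(6), b = rnorm(6))
  y <- rnorm(6)
  fit2 <- ols_regression(y, X)
  beta <- solve(t(cbind(1, as.matrix(X))) %*% cbind(1, as.matrix(X)),
                t(cbind(1, as.matrix(X))) %*% y)
  expect_equal(fit2$coefficients$estimate, as.vector(beta), tolerance = 1e-10)

  # null model: coefficients near zero, adjusted R^2 near zero
  set.seed(42)
  xb <- rnorm(4000); yb <- rnorm(4000)
  fit3 <- ols_regression(yb, data.frame(x = xb))
  expect_lt(abs(fit3$coefficients$estimate[2]), 0.05)
  expect_lt(abs(fit3$adj_r_squared), 0.01)
  expect_error(ols_regression(1:4, data.frame(a = 1:4, b = 2 * (1:4))),
               "rank-deficient")
})

test_that("Monte-Carlo Welch power is calibrated at the null and saturates for huge effects", {
  null_pw <- welch_power_mc(c(10, 10, 10), c(0, 0, 0), c(1, 2, 3),
                            alpha = 0.05, reps = 10000, seed = 3)
  mcse <- sqrt(0.25 / 10000)
  expect_lt(abs(null_pw - 0.05), 3 * mcse + 0.005)
  expect_gt(welch_power_mc(c(20, 20), c(0, 5), c(1, 1), reps = 2000,
                           seed = 3), 0.999)
  expect_identical(
    as.numeric(welch_power_mc(c(5, 5), c(0, 1), c(1, 1), reps = 1000, seed = 9)),
    as.numeric(welch_power_mc(c(5, 5), c(0, 1), c(1, 1), reps = 1000, seed = 9)))
  expect_error(welch_power_mc(c(5, 5), c(0, 1), c(1, 1), alpha = 2,
                              reps = 1000, seed = 1), "alpha")
})

test_that("power grows with effect size and sample size", {
  p_small <- welch_power_mc(c(8, 8), c(0, 0.5), c(1, 1), reps = 2000, seed = 7)
  p_big <- welch_power_mc(c(8, 8), c(0, 1.5), c(1, 1), reps = 2000, seed = 7)
  p_bign <- welch_power_mc(c(40, 40), c(0, 0.5), c(1, 1), reps = 2000, seed = 7)
  expect_gt(p_big, p_small)
  expect_gt(p_bign, p_small)
})

test_that("median/IQR from counts agree with quantiles of the expanded list", {
  s <- median_iqr_from_counts(c(`4` = 1))
  expect_equal(c(s$median, s$q1, s$q3), c(4, 4, 4))

  set.seed(43)
  for (rep in 1:10) {
    scores <- sort(sample(0:8, 5))
    counts <- sample(0:6, 5, replace = TRUE)
    if (sum(counts) == 0) counts[1] <- 1
    s <- median_iqr_from_counts(stats::setNames(counts, scores))
    expanded <- rep(scores, counts)
    q <- unname(quantile(expanded, c(0.25, 0.5, 0.75), type = 7))
    expect_equal(c(s$q1, s$median, s$q3), q)
  }
  expect_error(median_iqr_from_counts(c(`1` = 0)), "empty")
})

test_that("cohort tables reproduce the published descriptive statistics", {
  cnt <- dcaa_csvd_score_counts()
  expected <- list(symptomatic = c(5, 3, 6), presymptomatic = c(1, 0, 3),
                   control_over50 = c(0, 0, 1), control_under50 = c(0, 0, 0))
  for (g in names(expected)) {
    s <- median_iqr_from_counts(data.frame(cnt$score, cnt[[g]]))
    expect_equal(c(s$median, s$q1, s$q3), expected[[g]], label = g)
  }
  base <- dcaa_baseline_summary()
  expect_equal(followup_availability_pct(base$n, base$n_followup),
               c(57, 87, 30, 47))
})
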