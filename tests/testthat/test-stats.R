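# Group-level inference: t tests, JZS Bayes factors, winsorization,
# repeated-measures trends, Max-T correction.

test_that("one-sample t matches the closed form", {
  tt <- one_sample_t(c(1, 2, 3), tail = "two.sided")
  expect_equal(tt$statistic, 2 / (1 / sqrt(3)), tolerance = 1e-10)
  expect_equal(tt$df, 2)
  # symmetric values: t = 0, one-tailed p = 0.5
  tt2 <- one_sample_t(c(-2, -1, 0, 1, 2), tail = "greater")
  expect_equal(tt2$statistic, 0)
  expect_equal(tt2$p_value, 0.5)
  set.seed(31)
  v <- rnorm(15, 0.4)
  tt3 <- one_sample_t(v, mu = 0.1, tail = "less")
  m <- mean(v) - 0.1
  s <- sd(v) / sqrt(15)
  expect_equal(tt3$statistic, m / s, tolerance = 1e-10)
  expect_equal(tt3$p_value, pt(m / s, 14), tolerance = 1e-10)
  expect_error(one_sample_t(rep(1, 5)), "zero variance")
})

# Independent JZS oracle: marginal likelihood by integrating over the
# effect-size variance g (inverse-gamma(1/2, r^2/2) prior), the g-form of
# the default Bayes factor.
jzs_oracle <- function(t, n, rscale = sqrt(2) / 2) {
  nu <- n - 1
  m0 <- (1 + t^2 / nu)^(-(nu + 1) / 2)
  dens_g <- function(g) {
    sqrt(rscale^2 / 2) / gamma(0.5) * g^(-1.5) * exp(-rscale^2 / (2 * g))
  }
  m1 <- integrate(function(g) {
    (1 + n * g)^(-0.5) *
      (1 + t^2 / ((1 + n * g) * nu))^(-(nu + 1) / 2) * dens_g(g)
  }, 0, Inf, rel.tol = 1e-10)$value
  m1 / m0
}

test_that("JZS Bayes factors match the g-integral oracle within 1%", {
  for (tv in c(0, 1.2, 2.5, 4)) {
    got <- jzs_bayes_factor(t = tv, n = 20, tail = "two.sided")
    expect_equal(got, jzs_oracle(tv, 20), tolerance = 0.01)
  }
  expect_lt(jzs_bayes_factor(t = 0, n = 20, tail = "two.sided"), 1)
  # monotone in |t| at fixed n
  bfs <- vapply(c(0.5, 1, 2, 3, 5),
                function(tv) jzs_bayes_factor(t = tv, n = 20,
                                              tail = "two.sided"), numeric(1))
  expect_true(all(diff(bfs) > 0))
  # one-sided splits the two-sided marginal by direction
  b2 <- jzs_bayes_factor(t = 2, n = 20, tail = "two.sided")
  bg <- jzs_bayes_factor(t = 2, n = 20, tail = "greater")
  bl <- jzs_bayes_factor(t = 2, n = 20, tail = "less")
  expect_equal((bg + bl) / 2, b2, tolerance = 1e-6)
  expect_gt(bg, b2)
})

test_that("winsorization replaces values beyond the 3-IQR fences", {
  v <- c(1, 2, 3, 4, 5)
  expect_identical(winsorize_outliers(v)$values, v)
  expect_equal(winsorize_outliers(v)$n_replaced, 0)
  v2 <- c(1, 2, 3, 4, 100)
  w <- winsorize_outliers(v2)
  q <- quantile(v2, c(0.25, 0.75), type = 7, names = FALSE)
  fence <- q[2] + 3 * (q[2] - q[1])
  expect_equal(w$values, c(1, 2, 3, 4, fence))
  expect_equal(w$n_replaced, 1)
  # idempotent
  expect_equal(winsorize_outliers(w$values)$values, w$values)
})

test_that("RM-ANOVA recovers a planted linear trend and its interaction", {
  set.seed(32)
  n <- 16
  df <- expand.grid(subject = 1:n, cue = c("a", "b"), level = 1:4)
  df$y <- ifelse(df$cue == "a", df$level, -df$level) * 0.5 + rnorm(nrow(df), 0, 0.4)
  res <- rm_anova_trends(df, dv = "y", subject = "subject",
                         within = c("cue", "level"),
                         trend_factor = "level", trend_by = "cue")
  # opposite linear profiles per cue: strong cue x level interaction,
  # strong cue x linear-trend contrast, weak overall level main effect
  an <- res$anova
  expect_lt(an$p_value[an$effect == "cue:level"], 0.001)
  li <- res$trend_interactions[res$trend_interactions$trend == "linear", ]
  expect_lt(li$p_value, 0.001)
  expect_gt(li$estimate, 0)
  qi <- res$trend_interactions[res$trend_interactions$trend == "quadratic", ]
  expect_gt(qi$p_value, 0.01)
  expect_true(all(an$pes >= 0 & an$pes <= 1))
  # pure linear main trend (single within factor)
  df2 <- expand.grid(subject = 1:n, level = 1:4)
  df2$y2 <- df2$level * 0.5 + rnorm(nrow(df2), 0, 0.3)
  res2 <- rm_anova_trends(df2, dv = "y2", subject = "subject",
                          within = "level", trend_factor = "level")
  tr <- res2$trends
  expect_lt(tr$p_value[tr$trend == "linear"], 0.001)
  expect_gt(tr$p_value[tr$trend == "quadratic"], 0.05)
  expect_equal(tr$df, rep(15 * 3, 3))
})

test_that("RM-ANOVA F matches a manual sums-of-squares oracle", {
  set.seed(33)
  df <- expand.grid(subject = 1:8, level = 1:3)
  df$y <- rnorm(nrow(df)) + df$level * 0.3
  res <- rm_anova_trends(df, dv = "y", subject = "subject", within = "level")
  y <- matrix(df$y[order(df$level, df$subject)], 8, 3)
  n <- 8; k <- 3
  ss_level <- n * sum((colMeans(y) - mean(y))^2)
  resid <- y - rowMeans(y) - matrix(colMeans(y), n, k, byrow = TRUE) + mean(y)
  ss_err <- sum(resid^2)
  F_oracle <- (ss_level / (k - 1)) / (ss_err / ((n - 1) * (k - 1)))
  expect_equal(res$anova$statistic[res$anova$effect == "level"], F_oracle,
               tolerance = 1e-10)
  expect_equal(res$anova$pes[res$anova$effect == "level"],
               ss_level / (ss_level + ss_err), tolerance = 1e-10)
})

test_that("trend contrasts are mutually orthogonal on balanced designs", {
  cp <- contr.poly(4)
  expect_equal(crossprod(cp), diag(3), tolerance = 1e-12, ignore_attr = TRUE)
  expect_error(rm_anova_trends(
    data.frame(subject = c(1, 1, 2), level = c(1, 2, 1), y = 1:3),
    dv = "y", subject = "subject", within = "level"), "unbalanced")
})

test_that("Max-T correction controls order and reduces to one test", {
  set.seed(34)
  m <- matrix(rnorm(20 * 6), 20, 6)
  m[, 2] <- m[, 2] + 1.5
  res <- maxt_correction(m, n_perm = 2000, tail = "greater", seed = 1)
  expect_true(all(res$p_corrected >= res$p_uncorrected - 1e-12))
  ord <- order(res$statistic, decreasing = TRUE)
  expect_true(all(diff(res$p_corrected[ord]) >= -1e-12))
  expect_lt(res$p_corrected[2], 0.01)
  # m = 1: corrected equals the marginal permutation p, which tracks the
  # parametric one-sample p for a null column
  r1 <- maxt_correction(m[, 3, drop = FALSE], n_perm = 5000, seed = 2)
  expect_equal(r1$p_corrected, r1$p_uncorrected)
  expect_equal(r1$p_uncorrected,
               one_sample_t(m[, 3], tail = "greater")$p_value,
               tolerance = 0.05)
})
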