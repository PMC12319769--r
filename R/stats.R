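#' One-sample t test
#'
#' Thin wrapper around [stats::t.test()] returning a tidy one-row tibble;
#' directional tests use `tail = "greater"` (the standard hypothesis for
#' information scores, which should exceed zero when coding is present).
#'
#' @param values Numeric vector (n >= 3).
#' @param mu Null value.
#' @param tail `"two.sided"`, `"greater"` or `"less"`.
#' @return Tibble with `estimate`, `statistic`, `df`, `p_value`, `tail`.
#' @export
one_sample_t <- function(values, mu = 0, tail = c("two.sided", "greater", "less")) {
  tail <- match.arg(tail)
  stopifnot(length(values) >= 3)
  if (stats::sd(values) == 0) stop("zero variance: t statistic undefined")
  tt <- stats::t.test(values, mu = mu, alternative = tail)
  tibble::tibble(estimate = unname(tt$estimate), statistic = unname(tt$statistic),
                 df = unname(tt$parameter), p_value = tt$p.value, tail = tail)
}

#' JZS (Jeffreys-Zellner-Siow) Bayes factor for a one-sample design
#'
#' Default-prior Bayes factor BF10 comparing H1 (standardized effect size
#' with a Cauchy(0, `rscale`) prior) against the point null.  The marginal
#' likelihood under H1 is obtained by integrating the noncentral-t
#' likelihood of the observed t statistic over the Cauchy prior.  For
#' directional tests the prior is the half-Cauchy truncated to the
#' hypothesized direction.
#'
#' @param values Numeric vector; alternatively supply `t` and `n` directly.
#' @param mu Null value (used with `values`).
#' @param tail `"two.sided"`, `"greater"` or `"less"`.
#' @param rscale Cauchy prior scale (default `sqrt(2)/2 = 0.707`, the field
#'   default for medium effects).
#' @param t,n Observed t statistic and sample size (override `values`).
#' @return BF10 as a single positive number.
#' @export
jzs_bayes_factor <- function(values = NULL, mu = 0,
                             tail = c("two.sided", "greater", "less"),
                             rscale = sqrt(2) / 2, t = NULL, n = NULL) {
  tail <- match.arg(tail)
  if (is.null(t)) {
    stopifnot(!is.null(values), length(values) >= 3)
    n <- length(values)
    t <- (mean(values) - mu) / (stats::sd(values) / sqrt(n))
  }
  df <- n - 1
  # the noncentral-t density warns about its last-digit precision at large
  # noncentrality; the integral is insensitive at the 1e-6 level
  like <- function(delta) {
    suppressWarnings(stats::dt(t, df, ncp = delta * sqrt(n)))
  }
  dens <- function(delta) stats::dcauchy(delta, 0, rscale)
  m1 <- switch(tail,
    two.sided = stats::integrate(function(d) like(d) * dens(d),
                                 -Inf, Inf, rel.tol = 1e-8)$value,
    greater = 2 * stats::integrate(function(d) like(d) * dens(d),
                                   0, Inf, rel.tol = 1e-8)$value,
    less = 2 * stats::integrate(function(d) like(d) * dens(d),
                                -Inf, 0, rel.tol = 1e-8)$value)
  m0 <- stats::dt(t, df)
  m1 / m0
}

#' Winsorize extreme values at interquartile-range fences
#'
#' Values beyond `[Q1 - k*IQR, Q3 + k*IQR]` (type-7 quartiles) are replaced
#' by the nearest fence.  The operation is idempotent.
#'
#' @param values Numeric vector (n >= 4).
#' @param k_iqr Fence multiplier (default 3).
#' @return List with `values` (winsorized) and `n_replaced`.
#' @export
winsorize_outliers <- function(values, k_iqr = 3) {
  stopifnot(length(values) >= 4)
  q <- stats::quantile(values, c(0.25, 0.75), type = 7, names = FALSE)
  iqr <- q[2] - q[1]
  lo <- q[1] - k_iqr * iqr
  hi <- q[2] + k_iqr * iqr
  out <- pmin(pmax(values, lo), hi)
  list(values = out, n_replaced = sum(out != values))
}

#' Repeated-measures ANOVA with polynomial trend contrasts
#'
#' Fits a balanced within-subject ANOVA (one or two within factors) via
#' [stats::aov()] with subject error strata and reports F, p and partial
#' eta squared for each effect.  For an ordered factor, polynomial trend
#' contrasts are tested against the pooled subject-by-factor error (t with
#' `(n-1)(K-1)` df); the interaction of a two-level factor with each trend
#' is additionally tested as a per-subject contrast-difference one-sample
#' t test (df `n-1`).
#'
#' @param data Long-format data frame.
#' @param dv,subject Column names (strings) of the response and subject id.
#' @param within Character vector of one or two within-subject factors.
#' @param trend_factor Optional ordered factor (one of `within`) on which
#'   polynomial trends are tested.
#' @param trend_by Optional second (two-level) factor for trend-by-factor
#'   interaction contrasts.
#' @return List with tibbles `anova` (effect, df1, df2, F, p_value, pes),
#'   `trends` and `trend_interactions` (NULL when not requested).
#' @export
rm_anova_trends <- function(data, dv, subject, within,
                            trend_factor = NULL, trend_by = NULL) {
  df <- data.frame(
    y = data[[dv]],
    subject = factor(data[[subject]])
  )
  for (w in within) df[[w]] <- factor(data[[w]])
  counts <- table(df[c("subject", within)])
  if (any(counts != 1)) stop("unbalanced design: need exactly one observation per subject x cell")

  rhs <- paste(within, collapse = " * ")
  form <- stats::as.formula(paste0(
    "y ~ ", rhs, " + Error(subject/(", rhs, "))"))
  fit <- stats::aov(form, data = df)
  sumr <- summary(fit)
  rows <- list()
  for (stratum in sumr) {
    tab <- if (is.list(stratum)) stratum[[1]] else stratum
    tab <- as.data.frame(tab)
    resid_row <- grepl("Residuals", rownames(tab))
    ss_err <- tab$`Sum Sq`[resid_row]
    df_err <- tab$Df[resid_row]
    eff <- which(!resid_row)
    for (i in eff) {
      rows[[length(rows) + 1L]] <- tibble::tibble(
        effect = trimws(rownames(tab)[i]),
        df1 = tab$Df[i], df2 = df_err,
        statistic = tab$`F value`[i], p_value = tab$`Pr(>F)`[i],
        pes = tab$`Sum Sq`[i] / (tab$`Sum Sq`[i] + ss_err))
    }
  }
  anova_tab <- dplyr::bind_rows(rows)

  trends <- NULL
  trend_int <- NULL
  if (!is.null(trend_factor)) {
    lev <- levels(df[[trend_factor]])
    K <- length(lev)
    cp <- stats::contr.poly(K)
    trend_names <- c("linear", "quadratic", "cubic", paste0("deg", 4:25))[seq_len(K - 1)]
    # subject x level means (other factors averaged out)
    cell <- stats::aggregate(y ~ subject + df_level_,
                             data = transform(df, df_level_ = df[[trend_factor]]),
                             FUN = mean)
    wide <- matrix(NA_real_, nlevels(df$subject), K)
    wide[cbind(as.integer(cell$subject), as.integer(cell$df_level_))] <- cell$y
    n <- nrow(wide)
    # pooled-error contrast t: error = subject x level interaction stratum
    resid <- wide - rowMeans(wide) -
      matrix(colMeans(wide), n, K, byrow = TRUE) + mean(wide)
    ms_err <- sum(resid^2) / ((n - 1) * (K - 1))
    trends <- purrr::map_dfr(seq_len(K - 1), function(j) {
      cvec <- cp[, j]
      est <- sum(cvec * colMeans(wide))
      se <- sqrt(ms_err * sum(cvec^2) / n)
      tt <- est / se
      ddf <- (n - 1) * (K - 1)
      tibble::tibble(trend = trend_names[j], estimate = est, statistic = tt,
                     df = ddf, p_value = 2 * stats::pt(-abs(tt), ddf))
    })
    if (!is.null(trend_by)) {
      blev <- levels(df[[trend_by]])
      if (length(blev) != 2) stop("trend_by must have exactly two levels")
      cell2 <- stats::aggregate(
        y ~ subject + df_level_ + df_by_,
        data = transform(df, df_level_ = df[[trend_factor]],
                         df_by_ = df[[trend_by]]),
        FUN = mean)
      trend_int <- purrr::map_dfr(seq_len(K - 1), function(j) {
        cvec <- cp[, j]
        per_sub <- vapply(levels(df$subject), function(s) {
          g <- cell2[cell2$subject == s, ]
          c1 <- sum(cvec * g$y[g$df_by_ == blev[1]][order(g$df_level_[g$df_by_ == blev[1]])])
          c2 <- sum(cvec * g$y[g$df_by_ == blev[2]][order(g$df_level_[g$df_by_ == blev[2]])])
          c1 - c2
        }, numeric(1))
        tt <- one_sample_t(per_sub, tail = "two.sided")
        tibble::tibble(trend = trend_names[j],
                       contrast = paste(blev[1], "-", blev[2]),
                       estimate = mean(per_sub), statistic = tt$statistic,
                       df = tt$df, p_value = tt$p_value,
                       F_value = tt$statistic^2)
      })
    }
  }
  list(anova = anova_tab, trends = trends, trend_interactions = trend_int)
}

#' Permutation Max-T familywise correction for one-sample tests
#'
#' Jointly tests m one-sample hypotheses on the same subjects by
#' sign-flipping whole subjects (preserving the across-test dependence) and
#' comparing each observed t to the step-down distribution of the maximum
#' t across the family — permutation analogue of Holm-Bonferroni.
#'
#' @param mat n_subjects x m matrix (or data frame) of per-subject values;
#'   column names identify the tests.
#' @param n_perm Number of sign-flip permutations.
#' @param tail `"greater"`, `"less"` or `"two.sided"`.
#' @param seed Optional integer seed.
#' @return Tibble with `test`, `statistic`, `p_uncorrected` (marginal
#'   sign-flip permutation p) and `p_corrected` (step-down Max-T).
#' @export
maxt_correction <- function(mat, n_perm = 10000, tail = "greater", seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  mat <- as.matrix(mat)
  n <- nrow(mat)
  m <- ncol(mat)
  if (is.null(colnames(mat))) colnames(mat) <- paste0("test", seq_len(m))
  tstat <- function(means, ssq) {
    sdv <- sqrt(pmax((ssq - n * means^2) / (n - 1), 0))
    means / (sdv / sqrt(n))
  }
  ssq <- colSums(mat^2)
  obs <- tstat(colMeans(mat), ssq)
  adj <- switch(tail, greater = identity, less = function(x) -x, abs)
  obs_a <- adj(obs)

  signs <- matrix(sample(c(-1, 1), n_perm * n, replace = TRUE), n_perm, n)
  perm_means <- signs %*% mat / n                 # n_perm x m
  perm_t <- adj(t(tstat(t(perm_means), ssq)))     # n_perm x m (sign flips keep ssq)

  p_unc <- unname((1 + colSums(perm_t >= rep(obs_a, each = n_perm))) /
                    (1 + n_perm))

  ord <- order(obs_a, decreasing = TRUE)
  p_cor <- numeric(m)
  for (k in seq_len(m)) {
    cols <- ord[k:m]
    maxstat <- if (length(cols) == 1) perm_t[, cols] else
      do.call(pmax, as.data.frame(perm_t[, cols, drop = FALSE]))
    p_cor[ord[k]] <- (1 + sum(maxstat >= obs_a[ord[k]])) / (1 + n_perm)
  }
  p_cor[ord] <- cummax(p_cor[ord])  # enforce step-down monotonicity
  tibble::tibble(test = colnames(mat), statistic = unname(obs),
                 p_uncorrected = p_unc, p_corrected = p_cor)
}
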