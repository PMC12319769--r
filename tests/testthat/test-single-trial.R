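# Trial-level similarity and unique-contribution regressions.

mk_meta <- function(loc, resp = loc, start = rep(-10, length(loc))) {
  tibble::tibble(true_location = loc, response_location = resp,
                 start_position_m = start,
                 path_length_m = loc * 4 - start,
                 onset_s = (seq_along(loc) - 1) * 12,
                 traveled_time_s = (loc * 4 - start) / 4)
}

test_that("trial similarity is 20x20 and matches a correlation oracle", {
  coh <- default_small_cohort()
  s <- trial_similarity(coh$pattern[[1]], coh$pattern[[2]])
  expect_equal(dim(s), c(20, 20))
  oracle <- matrix(NA_real_, 20, 20)
  for (i in 1:20) for (j in 1:20) {
    oracle[i, j] <- cor(coh$pattern[[1]][i, ], coh$pattern[[2]][j, ])
  }
  expect_equal(s, oracle, tolerance = 1e-12)
  expect_equal(diag(trial_similarity(coh$pattern[[1]], coh$pattern[[1]])),
               rep(1, 20))
})

test_that("trial distances implement the worked response/location example", {
  # trial A: occupies Loc1, reports Loc2; trial B: occupies Loc2, reports
  # Loc4 -> 8 m apart in response, 4 m in location
  a <- mk_meta(1L, 2L)
  b <- mk_meta(2L, 4L)
  expect_equal(trial_distances(a, b, "response")[1, 1], 8)
  expect_equal(trial_distances(a, b, "location")[1, 1], 4)
  # identical trials are 0 apart under every predictor
  for (p in c("location", "response", "path_length", "temporal",
              "traveled_time")) {
    expect_equal(trial_distances(a, a, p)[1, 1], 0)
  }
  # path length: starts -10 / -4, same location Loc2 -> |14 - 8| = 6 m
  a2 <- mk_meta(2L, start = -10)
  b2 <- mk_meta(2L, start = -4)
  expect_equal(trial_distances(a2, b2, "path_length")[1, 1], 6)
  expect_error(trial_distances(a, b, "speed"), "unknown predictor")
})

test_that("a single predictor gives the sign-reversed standardized slope", {
  set.seed(11)
  sim <- matrix(runif(400, -0.6, 0.6), 20, 20)
  dm <- list(location = matrix(sample(c(0, 4, 8, 12), 400, TRUE), 20, 20))
  uc <- unique_contributions(sim, dm)
  z <- scale(atanh(c(sim)))
  x <- scale(c(dm$location))
  expect_equal(uc$beta_unique, -cor(z, x)[1, 1], tolerance = 1e-10)
  expect_equal(uc$beta_unique, uc$beta_total, tolerance = 1e-12)
  # OLS oracle for two predictors
  dm$response <- matrix(sample(c(0, 4, 8, 12), 400, TRUE), 20, 20)
  uc2 <- unique_contributions(sim, dm)
  fit <- lm(z ~ scale(c(dm$location)) + scale(c(dm$response)))
  expect_equal(uc2$beta_unique, -unname(coef(fit)[2:3]), tolerance = 1e-10)
})

test_that("coefficients are invariant to affine predictor rescaling", {
  set.seed(12)
  sim <- matrix(runif(400, -0.6, 0.6), 20, 20)
  d1 <- matrix(rnorm(400), 20, 20)
  d2 <- matrix(rnorm(400), 20, 20)
  uc <- unique_contributions(sim, list(a = d1, b = d2))
  uc2 <- unique_contributions(sim, list(a = 5 * d1 + 2, b = d2))
  expect_equal(uc$beta_unique, uc2$beta_unique, tolerance = 1e-10)
})

test_that("near-collinear predictors are flagged degenerate", {
  set.seed(13)
  sim <- matrix(runif(400, -0.6, 0.6), 20, 20)
  d <- matrix(sample(c(0, 4, 8, 12), 400, TRUE), 20, 20)
  uc <- unique_contributions(sim, list(location = d, response = d))
  expect_true(all(uc$degenerate))
  expect_true(all(is.na(uc$beta_unique)))
  expect_false(anyNA(uc$beta_total))
})

test_that("planted response coding is recovered with location controlled", {
  # similarity driven by response distance alone; responses partially
  # decorrelated from locations by planted errors
  set.seed(14)
  betas <- replicate(40, {
    loc_a <- rep(1:4, each = 5)[sample.int(20)]
    loc_b <- rep(1:4, each = 5)[sample.int(20)]
    err <- function(l) ifelse(runif(20) < 0.25,
                              pmax(1, pmin(4, l + sample(c(-1, 1), 20, TRUE))),
                              l)
    a <- mk_meta(loc_a, err(loc_a))
    b <- mk_meta(loc_b, err(loc_b))
    rd <- trial_distances(a, b, "response")
    sim <- tanh(-0.05 * rd + matrix(rnorm(400, 0, 0.1), 20, 20))
    uc <- unique_contributions(sim, list(
      location = trial_distances(a, b, "location"), response = rd))
    uc$beta_unique
  })
  expect_gt(mean(betas[2, ]), 0.1)          # response recovered
  expect_lt(abs(mean(betas[1, ])), 0.05)    # location contributes nothing
  expect_gt(mean(betas[2, ]), mean(betas[1, ]) + 0.1)
})

test_that("cohort decomposition recovers the response-driven architecture", {
  coh <- cached_cohort("resp_only", small_cfg(
    n_subjects = 6, seed = 77,
    pop_gains = c(stimulus_lm = 0, stimulus_sm = 0, response_shared = 1.5),
    noise_sd = 2))
  dec <- decompose_cohort(coh, c("location", "response"), "within_sm")
  tests <- dec$tests
  bu <- tests[tests$coefficient == "beta_unique", ]
  expect_lt(bu$p_value[bu$predictor == "response"], 0.05)
  expect_gt(bu$p_value[bu$predictor == "location"], 0.05)
  expect_equal(unique(dec$coefficients$n_runpairs), 28)
  dec_b <- decompose_cohort(coh, c("response"), "between_cue")
  expect_equal(unique(dec_b$coefficients$n_runpairs), 64)
  dec_l <- decompose_cohort(coh, c("response"), "lumped")
  expect_equal(unique(dec_l$coefficients$n_runpairs), 120)
})

test_that("the design decorrelates response distance from temporal distance", {
  coh <- default_small_cohort()
  rs <- c()
  rows <- which(coh$subject == 1 & coh$cue == "landmark")
  for (i in rows) for (j in rows) {
    if (j <= i) next
    rd <- trial_distances(coh$meta[[i]], coh$meta[[j]], "response")
    td <- trial_distances(coh$meta[[i]], coh$meta[[j]], "temporal")
    rs <- c(rs, cor(c(rd), c(td)))
  }
  expect_lt(abs(mean(rs)), 0.1)
})
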