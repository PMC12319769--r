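# Condition-level RSA: part averaging, pairings, similarity, information score.

loc_pattern <- function(meta, V) {
  outer(meta$true_location, seq_len(V)) + meta$run[1]
}

test_that("part averaging combines the two environment runs voxel-wise", {
  coh <- toy_cohort(loc_pattern)
  parts <- part_averages(coh, "location")
  expect_equal(nrow(parts), 8)              # 4 parts per cue
  expect_true(all(table(parts$cue) == 4))
  expect_equal(parts$day, rep(c(1, 1, 2, 2), 2))
  # part 1 of a cue averages the first run of each environment
  lm <- coh[coh$cue == "landmark" & coh$day == 1, ]
  lm <- lm[order(lm$run), ]
  first_runs <- vapply(split(seq_len(4), lm$environment), `[`, integer(1), 1)
  # label means are l * (1:V) + run, so the part is the run-offset average
  expected <- outer(1:4, 1:8) + (lm$run[first_runs[1]] +
                                   lm$run[first_runs[2]]) / 2
  got <- parts$mat[[which(parts$cue == "landmark")[1]]]
  expect_equal(got, expected)
})

run_label_patterns_public <- function(meta, pattern, mode) {
  navrsa:::run_label_patterns(meta, pattern, mode)
}

test_that("labels missing from one environment run fall back to the other", {
  coh <- toy_cohort(loc_pattern)
  lm_rows <- which(coh$cue == "landmark" & coh$day == 1)
  lm_rows <- lm_rows[order(coh$run[lm_rows])]
  envs <- split(lm_rows, coh$environment[lm_rows])
  r1 <- envs[[1]][1]   # first run of the first environment
  m <- coh$meta[[r1]]
  m$response_location <- ifelse(m$true_location == 4, 3L, m$true_location)
  coh$meta[[r1]] <- m
  parts <- part_averages(coh, "response")
  p1 <- parts[parts$cue == "landmark", ]$mat[[1]]
  other <- envs[[2]][1]
  expect_equal(p1[4, ],
               run_label_patterns_public(coh$meta[[other]],
                                         coh$pattern[[other]], "response")[4, ])
  expect_false(anyNA(p1))
})

test_that("labels missing from a whole run produce NA rows", {
  coh <- toy_cohort(loc_pattern)
  m <- coh$meta[[1]]
  m$response_location <- pmin(m$true_location, 3L)
  lp <- run_label_patterns_public(m, coh$pattern[[1]], "response")
  expect_true(all(is.na(lp[4, ])))
  expect_false(anyNA(lp[1:3, ]))
})

test_that("pairings follow the cross-validation scheme", {
  coh <- toy_cohort(loc_pattern)
  parts <- part_averages(coh, "location")
  expect_equal(nrow(enumerate_pairings(parts, "within_lm")), 6)
  expect_equal(nrow(enumerate_pairings(parts, "within_sm")), 6)
  expect_equal(nrow(enumerate_pairings(parts, "between_cue")), 16)
  # two parts admit exactly one within-cue pair
  two <- parts[parts$cue == "landmark", ][1:2, ]
  expect_equal(nrow(enumerate_pairings(two, "within_lm")), 1)
  # day filters
  expect_equal(nrow(enumerate_pairings(parts, "within_lm", day_relation = 1)), 1)
  expect_equal(nrow(enumerate_pairings(parts, "within_lm",
                                       day_relation = "different")), 4)
  expect_equal(nrow(enumerate_pairings(parts, "between_cue",
                                       day_relation = "same")), 8)
  # environment filters require env-resolved parts
  expect_error(enumerate_pairings(parts, "within_lm", env_relation = "same"),
               "env_resolved")
  pe <- part_averages(coh, "location", env_resolved = TRUE)
  expect_equal(nrow(pe), 16)
  expect_equal(nrow(enumerate_pairings(pe, "within_lm",
                                       env_relation = "same")), 12)
  expect_equal(nrow(enumerate_pairings(pe, "within_lm",
                                       env_relation = "different")), 16)
})

test_that("pairing similarity matches an elementwise correlation oracle", {
  set.seed(7)
  a <- matrix(rnorm(40), 4, 10)
  b <- matrix(rnorm(40), 4, 10)
  got <- pairing_similarity(a, b)
  oracle <- matrix(NA_real_, 4, 4)
  for (i in 1:4) for (j in 1:4) oracle[i, j] <- cor(a[i, ], b[j, ])
  expect_equal(got, oracle, tolerance = 1e-12)
  expect_equal(diag(pairing_similarity(a, a)), rep(1, 4))
  x <- rbind(c(1, 2, 3), c(3, 2, 1), c(1, 1, 2), c(2, 1, 1))
  expect_equal(pairing_similarity(x, x)[1, 2], -1)
  # constant vectors give missing entries
  a[2, ] <- 5
  expect_true(all(is.na(pairing_similarity(a, b)[2, ])))
})

test_that("mean similarity averages cell-wise, ignoring isolated missing", {
  m1 <- matrix(0.1, 4, 4)
  m2 <- matrix(0.2, 4, 4)
  m3 <- matrix(0.3, 4, 4)
  expect_equal(mean_similarity(list(m1, m2, m3)), matrix(0.2, 4, 4))
  m1[2, 3] <- NA
  expect_equal(mean_similarity(list(m1, m2, m3))[2, 3], 0.25)
  m2[2, 3] <- NA
  m3[2, 3] <- NA
  expect_error(mean_similarity(list(m1, m2, m3)), "missing in every pairing")
  # brute-force oracle on random fixtures
  set.seed(8)
  ms <- replicate(5, matrix(runif(16, -0.5, 0.5), 4, 4), simplify = FALSE)
  oracle <- matrix(0, 4, 4)
  for (i in 1:4) for (j in 1:4) {
    oracle[i, j] <- mean(vapply(ms, function(m) m[i, j], numeric(1)))
  }
  expect_equal(mean_similarity(ms), oracle, tolerance = 1e-12)
})

test_that("the information score is the sign-reversed Fisher-z correlation", {
  # build a similarity matrix whose Fisher-z cells correlate with the RDM
  # at exactly -0.5
  d <- c(rdm_matrix())
  u <- (d - mean(d)) / sqrt(sum((d - mean(d))^2))
  set.seed(9)
  w <- rnorm(16)
  w <- residuals(lm(w ~ d))
  w <- w / sqrt(sum(w^2))
  z <- 0.3 * (-0.5 * u + sqrt(0.75) * w)
  expect_equal(cor(z, d), -0.5, tolerance = 1e-12)
  sc <- spatial_information_score(matrix(tanh(z), 4, 4))
  expect_equal(sc$score, atanh(0.5), tolerance = 1e-10)
  expect_equal(sc$n_cells, 16)

  # invariant to positive rescaling of the RDM
  sc2 <- spatial_information_score(matrix(tanh(z), 4, 4),
                                   rdm = rdm_matrix(spacing = 17.3))
  expect_equal(sc$score, sc2$score, tolerance = 1e-12)

  expect_error(spatial_information_score(matrix(0.2, 4, 4)), "constant")
})

test_that("scores on distance-shuffled cells are centred at zero", {
  set.seed(10)
  z <- rnorm(16, sd = 0.3)
  scores <- replicate(500, {
    spatial_information_score(matrix(tanh(sample(z)), 4, 4))$score
  })
  expect_lt(abs(mean(scores)), 0.05)
})

test_that("scores are invariant to common affine rescaling within parts", {
  coh <- default_small_cohort()
  sc1 <- score_suite(coh, "response")
  coh2 <- coh
  coh2$pattern <- lapply(coh2$pattern, function(p) 3.7 * p + 11)
  sc2 <- score_suite(coh2, "response")
  expect_equal(sc1$score, sc2$score, tolerance = 1e-10)
})

test_that("condition-level scores equal label-averaged trial-level scores", {
  # the condition-level label vectors are the label means of the trial
  # patterns; recomputing them by hand from the trial data must give the
  # same part matrices and hence the same scores
  coh <- default_small_cohort()
  parts <- part_averages(coh, "response")
  i <- which(coh$subject == 2 & coh$cue == "landmark" & coh$day == 1)
  i <- i[order(coh$run[i])]
  byenv <- split(i, coh$environment[i])
  manual <- matrix(NA_real_, 4, ncol(coh$pattern[[1]]))
  for (l in 1:4) {
    vecs <- lapply(byenv, function(ix) {
      r <- ix[1]
      rows <- which(coh$meta[[r]]$response_location == l)
      if (length(rows)) colMeans(coh$pattern[[r]][rows, , drop = FALSE])
    })
    vecs <- vecs[!vapply(vecs, is.null, logical(1))]
    if (length(vecs)) manual[l, ] <- Reduce(`+`, vecs) / length(vecs)
  }
  p <- parts[parts$subject == 2 & parts$cue == "landmark", ]$mat[[1]]
  expect_equal(p, manual)
})

test_that("environment- and day-resolved suites score every slice", {
  coh <- default_small_cohort()
  se <- score_suite(coh, "response", by = "environment")
  expect_equal(nrow(se), 4 * 3 * 3)
  expect_setequal(unique(se$env_relation), c("nature", "city", "different"))
  sd_ <- score_suite(coh, "response", by = "day")
  expect_setequal(unique(sd_$day_relation), c("day1", "day2", "different"))
  gt <- score_group_tests(se)
  expect_equal(nrow(gt), 9)
  expect_true(all(gt$p_value >= 0 & gt$p_value <= 1))
})
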