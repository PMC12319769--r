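#' Trial-level pattern-similarity matrix for a run pair
#'
#' Entry (s, t) is the Pearson correlation between trial s of run A and
#' trial t of run B; with 20 effective trials per run the matrix is 20 x 20.
#' Constant trial vectors give `NA` entries.
#'
#' @param pattern_a,pattern_b Trials x voxels activation matrices.
#' @return A 20 x 20 (trials_a x trials_b) similarity matrix.
#' @export
trial_similarity <- function(pattern_a, pattern_b) {
  stopifnot(ncol(pattern_a) == ncol(pattern_b))
  suppressWarnings(stats::cor(t(pattern_a), t(pattern_b)))
}

#' Trial-pair distance matrix under a predictor
#'
#' Entry (s, t) is `|x_s - x_t|` where `x` is the trial's value of the
#' predictor: true-location or reported-location track coordinate (so two
#' trials at `Loc1` reporting `Loc2` and at `Loc2` reporting `Loc4` are 4 m
#' apart in location and 8 m in response), path length (m), traveled time
#' (s), or within-run onset time (s, the temporal-distance control).
#'
#' @param meta_a,meta_b Effective-trial metadata tibbles of the two runs.
#' @param predictor One of `"location"`, `"response"`, `"path_length"`,
#'   `"temporal"`, `"traveled_time"`.
#' @return A length(a) x length(b) distance matrix.
#' @export
trial_distances <- function(meta_a, meta_b, predictor) {
  val <- function(m) switch(predictor,
    location = m$true_location * 4,
    response = m$response_location * 4,
    path_length = m$path_length_m,
    temporal = m$onset_s,
    traveled_time = m$traveled_time_s,
    stop("unknown predictor: ", predictor))
  abs(outer(val(meta_a), val(meta_b), `-`))
}

#' Unique contributions of competing predictors to pattern similarity
#'
#' Vectorizes the Fisher-transformed similarity matrix and the predictor
#' distance matrices, z-standardizes everything, and fits an ordinary
#' least-squares multiple regression (intercept retained).  Coefficients
#' are sign-reversed so that a positive value means nearer trials are more
#' similar.  When two predictors are nearly collinear (|r| > 0.999, e.g.
#' location and response distances under error-free behaviour) the pair is
#' flagged degenerate and coefficients are withheld.
#'
#' @param sim Trial similarity matrix ([trial_similarity()]).
#' @param predictors Named list of distance matrices ([trial_distances()]).
#' @param include_diagonal Use same-trial-index cells?  Defaults TRUE:
#'   cross-run same-index cells are ordinary cross-validated comparisons.
#' @return A tibble with one row per predictor: `beta_unique` (joint fit),
#'   `beta_total` (single-predictor fit), `n_cells`, `degenerate`.
#' @export
unique_contributions <- function(sim, predictors, include_diagonal = TRUE) {
  stopifnot(length(predictors) >= 1, !is.null(names(predictors)))
  keep <- if (include_diagonal) rep(TRUE, length(sim)) else
    c(row(sim) != col(sim))
  y <- c(sim)[keep]
  X <- vapply(predictors, function(m) c(m)[keep], numeric(sum(keep)))
  ok <- stats::complete.cases(cbind(y, X))
  y <- y[ok]
  X <- X[ok, , drop = FALSE]
  y <- pmin(pmax(y, -1 + 1e-7), 1 - 1e-7)
  zy <- as.numeric(scale(atanh(y)))
  zX <- apply(X, 2, function(v) as.numeric(scale(v)))

  degenerate <- FALSE
  if (ncol(zX) > 1) {
    pc <- suppressWarnings(stats::cor(zX))
    if (any(abs(pc[upper.tri(pc)]) > 0.999, na.rm = TRUE)) degenerate <- TRUE
  }
  beta_total <- vapply(seq_len(ncol(zX)), function(j) {
    -unname(stats::coef(stats::lm.fit(cbind(1, zX[, j]), zy))[2])
  }, numeric(1))
  beta_unique <- if (degenerate) rep(NA_real_, ncol(zX)) else {
    -unname(stats::coef(stats::lm.fit(cbind(1, zX), zy))[-1])
  }
  tibble::tibble(predictor = names(predictors), beta_unique = beta_unique,
                 beta_total = beta_total, n_cells = length(zy),
                 degenerate = degenerate)
}

# Run-pair index sets per relation, over a subject's 16 runs.
run_pairs_for_relation <- function(subj_rows, relation) {
  cue <- subj_rows$cue
  if (relation == "lumped") {
    idx <- which(upper.tri(diag(nrow(subj_rows))), arr.ind = TRUE)
    return(data.frame(i = idx[, 1], j = idx[, 2]))
  }
  if (relation == "between_cue") {
    return(expand.grid(i = which(cue == "landmark"),
                       j = which(cue == "self_motion")))
  }
  want <- if (relation == "within_lm") "landmark" else if
    (relation == "within_sm") "self_motion" else stop("unknown relation: ", relation)
  rs <- which(cue == want)
  idx <- t(utils::combn(rs, 2))
  data.frame(i = idx[, 1], j = idx[, 2])
}

#' Cohort-level unique-contribution decomposition
#'
#' For every subject, regresses trial-level pattern similarity on the
#' requested predictor distances for each run pair of the relation,
#' averages coefficients across run pairs (degenerate pairs dropped), and
#' runs directional group tests per predictor.
#'
#' @param cohort An `rsa_cohort`.
#' @param predictors Character vector of predictor names
#'   (see [trial_distances()]).
#' @param relation `"within_lm"`, `"within_sm"`, `"between_cue"`, or
#'   `"lumped"` (all runs of all cue conditions pooled).
#' @param include_diagonal Passed to [unique_contributions()].
#' @return A list of class `rsa_decomposition`: `coefficients` (tibble:
#'   subject, relation, predictor, beta_unique, beta_total, n_runpairs,
#'   n_degenerate) and `tests` (directional group tests per predictor and
#'   coefficient type).
#' @export
decompose_cohort <- function(cohort, predictors = c("location", "response"),
                             relation = c("within_lm", "within_sm",
                                          "between_cue", "lumped"),
                             include_diagonal = TRUE) {
  relation <- match.arg(relation)
  coefs <- cohort |>
    dplyr::group_by(.data$subject) |>
    dplyr::group_modify(function(df, key) {
      pairs <- run_pairs_for_relation(df, relation)
      per_pair <- purrr::map_dfr(seq_len(nrow(pairs)), function(k) {
        i <- pairs$i[k]
        j <- pairs$j[k]
        sim <- trial_similarity(df$pattern[[i]], df$pattern[[j]])
        dm <- lapply(stats::setNames(predictors, predictors), function(p) {
          trial_distances(df$meta[[i]], df$meta[[j]], p)
        })
        unique_contributions(sim, dm, include_diagonal = include_diagonal)
      })
      per_pair |>
        dplyr::group_by(.data$predictor) |>
        dplyr::summarise(
          beta_unique = mean(.data$beta_unique, na.rm = TRUE),
          beta_total = mean(.data$beta_total),
          n_runpairs = dplyr::n(),
          n_degenerate = sum(.data$degenerate), .groups = "drop")
    }) |>
    dplyr::ungroup() |>
    dplyr::mutate(relation = relation, .after = "subject")

  tests <- coefs |>
    tidyr::pivot_longer(c("beta_unique", "beta_total"),
                        names_to = "coefficient", values_to = "value") |>
    dplyr::filter(!is.nan(.data$value)) |>
    dplyr::group_by(.data$relation, .data$predictor, .data$coefficient) |>
    dplyr::group_modify(function(d, key) {
      tt <- one_sample_t(d$value, tail = "greater")
      bf <- jzs_bayes_factor(d$value, tail = "greater")
      tibble::tibble(n = nrow(d), mean = mean(d$value),
                     statistic = tt$statistic, df = tt$df,
                     p_value = tt$p_value, bf10 = bf)
    }) |>
    dplyr::ungroup()
  structure(list(coefficients = coefs, tests = tests),
            class = "rsa_decomposition")
}

#' @export
print.rsa_decomposition <- function(x, ...) {
  cat("<rsa_decomposition>\n")
  print(x$tests)
  invisible(x)
}

#' @export
tidy.rsa_decomposition <- function(x, ...) x$coefficients

#' @export
glance.rsa_decomposition <- function(x, ...) x$tests
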