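#' Model representational dissimilarity matrix for the four track locations
#'
#' Dissimilarity between labels i and j is the physical distance
#' `|i - j| * spacing`; the spatial information score is invariant to the
#' spacing because it only enters through a Pearson correlation.
#'
#' @param spacing Inter-location spacing in metres.
#' @return A 4 x 4 numeric matrix.
#' @export
rdm_matrix <- function(spacing = 4) {
  abs(outer(1:4, 1:4, `-`)) * spacing
}

# Label-average a run's trial patterns: 4 x V matrix, NA rows for labels
# absent from the run (possible in response mode).
run_label_patterns <- function(meta, pattern, label_mode) {
  lab <- switch(label_mode,
                location = meta$true_location,
                response = meta$response_location,
                stop("unknown label_mode: ", label_mode))
  out <- matrix(NA_real_, 4, ncol(pattern))
  for (l in 1:4) {
    rows <- which(lab == l)
    if (length(rows) > 0) out[l, ] <- colMeans(pattern[rows, , drop = FALSE])
  }
  out
}

#' Split a subject's runs into cross-validation parts
#'
#' For each cue and scanning day the four runs are divided chronologically
#' into two parts; each part averages, voxel-by-voxel and per label, the
#' two runs belonging to the two environments (the environment factor is
#' averaged out).  This yields four parts per cue (parts 1-2 from day 1,
#' 3-4 from day 2).  With `env_resolved = TRUE` every run is its own part
#' and keeps its environment label, enabling environment-relation scores.
#'
#' @param cohort An `rsa_cohort` (or compatible tibble with `meta` and
#'   `pattern` list-columns).
#' @param label_mode `"location"` or `"response"`: whether trials are
#'   grouped by the true or the reported location.
#' @param env_resolved Keep environments separate (one part per run)?
#' @return A tibble with columns `subject`, `cue`, `day`, `part_index`,
#'   `environment` (NA when averaged out) and `mat` (list of 4 x V
#'   label-mean matrices; NA rows mark labels missing from both runs).
#' @export
part_averages <- function(cohort, label_mode = c("response", "location"),
                          env_resolved = FALSE) {
  label_mode <- match.arg(label_mode)
  subj <- cohort$subject[0]
  cue_v <- character(0)
  day_v <- integer(0)
  env_v <- character(0)
  idx_v <- integer(0)
  mats <- list()
  for (s in unique(cohort$subject)) {
    for (cue in c("landmark", "self_motion")) {
      df <- cohort[cohort$subject == s & cohort$cue == cue, ]
      if (!setequal(df$day, 1:2) || nrow(df) != 8) {
        stop("each cue needs 2 days x 4 runs; subject ", s,
             " cue ", cue, " has ", nrow(df), " runs")
      }
      pi <- 0L
      for (d in 1:2) {
        dd <- df[df$day == d, ]
        dd <- dd[order(dd$run), ]
        if (env_resolved) {
          for (i in seq_len(nrow(dd))) {
            pi <- pi + 1L
            subj <- c(subj, s)
            cue_v <- c(cue_v, cue)
            day_v <- c(day_v, d)
            env_v <- c(env_v, dd$environment[i])
            idx_v <- c(idx_v, pi)
            mats[[length(mats) + 1L]] <-
              run_label_patterns(dd$meta[[i]], dd$pattern[[i]], label_mode)
          }
        } else {
          envs <- split(seq_len(nrow(dd)), dd$environment)
          if (length(envs) != 2 || !all(lengths(envs) == 2)) {
            stop("expected 2 runs per environment per day")
          }
          for (k in 1:2) {  # k-th chronological run of each environment
            ms <- lapply(envs, function(ix) {
              i <- ix[k]
              run_label_patterns(dd$meta[[i]], dd$pattern[[i]], label_mode)
            })
            # cell-wise mean; a label present in only one environment run
            # falls back to that run's vector
            m <- (ms[[1]] + ms[[2]]) / 2
            only1 <- is.na(ms[[1]][, 1]) & !is.na(ms[[2]][, 1])
            only2 <- !is.na(ms[[1]][, 1]) & is.na(ms[[2]][, 1])
            m[only1, ] <- ms[[2]][only1, , drop = FALSE]
            m[only2, ] <- ms[[1]][only2, , drop = FALSE]
            pi <- pi + 1L
            subj <- c(subj, s)
            cue_v <- c(cue_v, cue)
            day_v <- c(day_v, d)
            env_v <- c(env_v, NA_character_)
            idx_v <- c(idx_v, pi)
            mats[[length(mats) + 1L]] <- m
          }
        }
      }
    }
  }
  tibble::tibble(subject = subj, cue = cue_v, day = day_v,
                 environment = env_v, part_index = idx_v, mat = mats)
}

#' Enumerate cross-validation part pairings for a relation
#'
#' Within-cue relations pair all distinct parts of that cue (6 unordered
#' pairs of 4 parts; 28 in environment-resolved mode); the between-cue
#' relation takes all ordered landmark x self-motion part pairs (16, or 64
#' environment-resolved).  Optional filters restrict pairings to the same
#' or different environment or scanning day.
#'
#' @param parts Output of [part_averages()] for one subject.
#' @param relation `"within_lm"`, `"within_sm"` or `"between_cue"`.
#' @param env_relation Optional `"same"` or `"different"` (requires
#'   environment-resolved parts).
#' @param day_relation Optional `"same"`, `"different"`, or a day number
#'   (1 or 2) to keep only pairings within that day.
#' @return A tibble with list-columns `a` and `b` (4 x V part matrices).
#' @export
enumerate_pairings <- function(parts, relation,
                               env_relation = NULL, day_relation = NULL) {
  stopifnot(relation %in% c("within_lm", "within_sm", "between_cue"))
  get_cue <- function(cue) parts[parts$cue == cue, ]
  if (relation == "between_cue") {
    pa <- get_cue("landmark")
    pb <- get_cue("self_motion")
    idx <- expand.grid(i = seq_len(nrow(pa)), j = seq_len(nrow(pb)))
  } else {
    pa <- pb <- get_cue(if (relation == "within_lm") "landmark" else "self_motion")
    idx <- which(upper.tri(diag(nrow(pa))), arr.ind = TRUE)
    idx <- data.frame(i = idx[, 1], j = idx[, 2])
  }
  keep <- rep(TRUE, nrow(idx))
  if (!is.null(env_relation)) {
    ea <- pa$environment[idx$i]
    eb <- pb$environment[idx$j]
    if (anyNA(ea) || anyNA(eb)) {
      stop("environment relation requires env_resolved part averages")
    }
    keep <- keep & if (env_relation == "same") ea == eb else ea != eb
  }
  if (!is.null(day_relation)) {
    da <- pa$day[idx$i]
    db <- pb$day[idx$j]
    keep <- keep & switch(as.character(day_relation),
                          same = da == db,
                          different = da != db,
                          da == as.integer(day_relation) &
                            db == as.integer(day_relation))
  }
  idx <- idx[keep, , drop = FALSE]
  tibble::tibble(a = pa$mat[idx$i], b = pb$mat[idx$j])
}

#' Pattern-similarity matrix of one part pairing
#'
#' Entry (i, j) is the Pearson correlation between part `a`'s label-i mean
#' activation vector and part `b`'s label-j vector.  Missing labels and
#' constant vectors (undefined correlations) yield `NA` entries.
#'
#' @param a,b 4 x V label-mean matrices (rows = labels).
#' @param voxels Optional voxel (column) subset.
#' @return A 4 x 4 similarity matrix.
#' @export
pairing_similarity <- function(a, b, voxels = NULL) {
  if (!is.null(voxels)) {
    a <- a[, voxels, drop = FALSE]
    b <- b[, voxels, drop = FALSE]
  }
  suppressWarnings(stats::cor(t(a), t(b)))
}

#' Cell-wise mean of similarity matrices
#'
#' `NA` cells are ignored; a cell is an error only if it is missing in
#' every pairing.
#'
#' @param mats List of equal-size similarity matrices.
#' @return The mean matrix.
#' @export
mean_similarity <- function(mats) {
  stopifnot(length(mats) >= 1)
  arr <- array(unlist(mats), dim = c(dim(mats[[1]]), length(mats)))
  ok <- !is.na(arr)
  arr[!ok] <- 0
  out <- rowSums(arr, dims = 2) / rowSums(ok, dims = 2)
  if (any(is.nan(out))) {
    bad <- which(is.nan(out), arr.ind = TRUE)
    stop("similarity cell (", bad[1, 1], ",", bad[1, 2],
         ") is missing in every pairing")
  }
  out
}

#' Spatial information score
#'
#' The Fisher-transformed cells of the mean pattern-similarity matrix are
#' correlated with the model RDM; the correlation is Fisher transformed and
#' reversed in sign, so a positive score means that nearer locations have
#' more similar activation patterns.  By default all 16 cells of the
#' (possibly asymmetric) cross-validated matrix enter the correlation,
#' including the 0 m diagonal; set `include_diagonal = FALSE` to restrict
#' the score to distinct-location cells (pure distance coding).
#'
#' @param mean_sim 4 x 4 mean similarity matrix.
#' @param rdm Model dissimilarity matrix (default [rdm_matrix()]).
#' @param include_diagonal Use the 0 m diagonal cells?
#' @return A one-row tibble with `score`, `n_cells` and `low_confidence`
#'   (TRUE when fewer than 8 cells were available).
#' @export
spatial_information_score <- function(mean_sim, rdm = rdm_matrix(),
                                      include_diagonal = TRUE) {
  stopifnot(identical(dim(mean_sim), dim(rdm)))
  keep <- if (include_diagonal) rep(TRUE, length(rdm)) else
    c(row(rdm) != col(rdm))
  s <- c(mean_sim)[keep]
  d <- c(rdm)[keep]
  ok <- !is.na(s)
  s <- s[ok]
  d <- d[ok]
  if (length(s) < 3 || stats::sd(d) == 0) {
    stop("too few similarity cells to compute a spatial information score")
  }
  s <- pmin(pmax(s, -1 + 1e-7), 1 - 1e-7)
  z <- atanh(s)
  if (stats::sd(z) == 0) stop("constant similarity matrix: score undefined")
  r <- stats::cor(z, d)
  tibble::tibble(score = -atanh(r), n_cells = length(s),
                 low_confidence = length(s) < 8)
}

#' Per-subject spatial information scores for a cohort
#'
#' Computes, for every subject, the spatial information score of each
#' requested relation, optionally resolved by environment or day relation.
#'
#' @param cohort An `rsa_cohort` (or compatible tibble).
#' @param label_mode `"response"` or `"location"`.
#' @param relations Character vector among `"within_lm"`, `"within_sm"`,
#'   `"between_cue"`.
#' @param by `"none"` (the main analysis: environments averaged, days
#'   pooled), `"environment"` (same-nature / same-city / different), or
#'   `"day"` (day 1 / day 2 / different).
#' @param include_diagonal Passed to [spatial_information_score()].
#' @param voxels Optional voxel subset (indices into the ROI).
#' @return A tibble of class `rsa_scores`: `subject`, `label_mode`,
#'   `relation`, `env_relation`, `day_relation`, `score`, `n_pairings`.
#' @examples
#' \donttest{
#' cohort <- simulate_cohort(sim_config(n_subjects = 3, n_voxels = 40))
#' score_suite(cohort, "response")
#' }
#' @export
score_suite <- function(cohort, label_mode = c("response", "location"),
                        relations = c("within_lm", "within_sm", "between_cue"),
                        by = c("none", "environment", "day"),
                        include_diagonal = TRUE, voxels = NULL) {
  label_mode <- match.arg(label_mode)
  by <- match.arg(by)
  parts <- part_averages(cohort, label_mode,
                         env_resolved = identical(by, "environment"))
  scores_from_parts(parts, label_mode, relations, by, include_diagonal, voxels)
}

# Core scorer on precomputed part averages (reused by the adaptation-link
# partition analysis, which rescores many voxel subsets).
scores_from_parts <- function(parts, label_mode, relations, by,
                              include_diagonal = TRUE, voxels = NULL) {
  out <- list()
  add <- function(x) out[[length(out) + 1L]] <<- x
  for (sub in unique(parts$subject)) {
    ps <- parts[parts$subject == sub, ]
    for (rel in relations) {
      if (by == "none") {
        add(score_one(enumerate_pairings(ps, rel), sub, label_mode, rel,
                      NA_character_, NA_character_, include_diagonal, voxels))
      } else if (by == "environment") {
        for (env in c("nature", "city")) {
          # same-environment pairings within one environment: keep only
          # that environment's parts
          add(score_one(enumerate_pairings(ps[ps$environment == env, ], rel),
                        sub, label_mode, rel, env, NA_character_,
                        include_diagonal, voxels))
        }
        add(score_one(enumerate_pairings(ps, rel, env_relation = "different"),
                      sub, label_mode, rel, "different", NA_character_,
                      include_diagonal, voxels))
      } else {  # by day
        for (d in 1:2) {
          add(score_one(enumerate_pairings(ps, rel, day_relation = d),
                        sub, label_mode, rel, NA_character_, paste0("day", d),
                        include_diagonal, voxels))
        }
        add(score_one(enumerate_pairings(ps, rel, day_relation = "different"),
                      sub, label_mode, rel, NA_character_, "different",
                      include_diagonal, voxels))
      }
    }
  }
  res <- tibble::tibble(
    subject = unlist(lapply(out, `[[`, "subject")),
    label_mode = vapply(out, `[[`, character(1), "label_mode"),
    relation = vapply(out, `[[`, character(1), "relation"),
    env_relation = vapply(out, `[[`, character(1), "env_relation"),
    day_relation = vapply(out, `[[`, character(1), "day_relation"),
    score = vapply(out, `[[`, numeric(1), "score"),
    n_pairings = vapply(out, `[[`, integer(1), "n_pairings"),
    low_confidence = vapply(out, `[[`, logical(1), "low_confidence"))
  class(res) <- c("rsa_scores", class(res))
  res
}

score_one <- function(pairings, subject, label_mode, relation,
                      env_relation, day_relation, include_diagonal, voxels) {
  # lean path equivalent to spatial_information_score(mean_similarity(...));
  # cells missing in every pairing are dropped by pairwise deletion
  S <- matrix(0, 4, 4)
  cnt <- matrix(0L, 4, 4)
  for (k in seq_len(nrow(pairings))) {
    cm <- pairing_similarity(pairings$a[[k]], pairings$b[[k]], voxels = voxels)
    ok <- !is.na(cm)
    cm[!ok] <- 0
    S <- S + cm
    cnt <- cnt + ok
  }
  m <- S / cnt
  rdm <- rdm_matrix()
  keep <- if (include_diagonal) rep(TRUE, 16L) else c(row(rdm) != col(rdm))
  s <- c(m)[keep]
  d <- c(rdm)[keep]
  ok <- !is.na(s) & !is.nan(s)
  s <- pmin(pmax(s[ok], -1 + 1e-7), 1 - 1e-7)
  d <- d[ok]
  if (length(s) < 3) stop("too few similarity cells for a score")
  z <- atanh(s)
  if (stats::sd(z) == 0) stop("constant similarity matrix: score undefined")
  list(subject = subject, label_mode = label_mode,
       relation = relation, env_relation = env_relation,
       day_relation = day_relation, score = -atanh(stats::cor(z, d)),
       n_pairings = nrow(pairings), low_confidence = sum(ok) < 8)
}

#' Group-level tests of spatial information scores
#'
#' For each relation (and environment/day slice) the subject scores are
#' tested against zero with a directional one-sample t test and a JZS
#' Bayes factor; optional winsorization of extreme scores.
#'
#' @param scores An `rsa_scores` tibble.
#' @param tail `"greater"` (directional, the default hypothesis that
#'   nearer locations are more similar), `"less"` or `"two.sided"`.
#' @param winsorize Apply [winsorize_outliers()] before testing?
#' @return A tibble with one row per relation slice: `t`, `df`, `p_value`,
#'   `bf10`, `n`, `mean_score`, `n_winsorized`.
#' @export
score_group_tests <- function(scores, tail = "greater", winsorize = FALSE) {
  scores |>
    dplyr::group_by(.data$label_mode, .data$relation,
                    .data$env_relation, .data$day_relation) |>
    dplyr::group_modify(function(df, key) {
      v <- df$score
      nw <- 0L
      if (winsorize) {
        w <- winsorize_outliers(v)
        v <- w$values
        nw <- w$n_replaced
      }
      tt <- one_sample_t(v, mu = 0, tail = tail)
      bf <- jzs_bayes_factor(v, mu = 0, tail = tail)
      tibble::tibble(n = length(v), mean_score = mean(v), t = tt$statistic,
                     df = tt$df, p_value = tt$p_value, bf10 = bf,
                     n_winsorized = nw)
    }) |>
    dplyr::ungroup()
}

#' @export
tidy.rsa_scores <- function(x, ...) tibble::as_tibble(x)

#' @export
glance.rsa_scores <- function(x, tail = "greater", ...) {
  score_group_tests(x, tail = tail)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
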