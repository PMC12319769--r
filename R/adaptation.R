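#' Per-voxel fMRI-adaptation effect
#'
#' For each voxel, the OLS slope of trial activation on the distance to
#' the previously occupied location, with current-location fixed effects
#' partialled out (edge locations have a larger mean distance to the
#' previous location, so a raw distance regression would leak the voxel's
#' location-activation profile into the adaptation estimate).  Computed
#' across all effective trials of the cue's runs, optionally restricted to
#' one day or environment.  A positive slope is the adaptation signature:
#' activation is suppressed when the previous location was close.  The
#' slope is signed and spatially unsmoothed, matching how voxels are
#' ranked downstream.
#'
#' @param cohort An `rsa_cohort`.
#' @param subject Subject id.
#' @param cue `"landmark"` or `"self_motion"`.
#' @param day,environment Optional scope restrictions.
#' @return Numeric vector of per-voxel slopes (activation units per metre).
#' @export
voxel_fmria_effect <- function(cohort, subject,
                               cue = c("landmark", "self_motion"),
                               day = NULL, environment = NULL) {
  cue <- match.arg(cue)
  rows <- cohort[cohort$subject == subject & cohort$cue == cue, ]
  if (!is.null(day)) rows <- rows[rows$day == day, ]
  if (!is.null(environment)) rows <- rows[rows$environment == environment, ]
  if (nrow(rows) == 0) stop("no runs in scope for subject ", subject)
  d <- unlist(lapply(rows$meta, function(m) m$dist_prev_m))
  if (length(unique(d)) < 3) {
    stop("fewer than 3 distinct distance-to-previous values in scope")
  }
  loc <- unlist(lapply(rows$meta, function(m) m$true_location))
  Y <- do.call(rbind, rows$pattern)
  adaptation_slope(d, loc, Y)
}

# Partial OLS slope of Y columns on d, adjusting for location factor.
adaptation_slope <- function(d, loc, Y, weights = NULL) {
  X <- cbind(stats::model.matrix(~ factor(loc, levels = 1:4)), d = d)
  if (is.null(weights)) {
    fit <- stats::lm.fit(X, Y)
    co <- fit$coefficients
  } else {
    co <- stats::lm.wfit(X, Y, w = weights)$coefficients
  }
  if (is.matrix(co)) unname(co[nrow(co), ]) else unname(co[length(co)])
}

#' Partition voxels by ranked adaptation effect
#'
#' Voxels are sorted ascending by the signed effect (ties broken by
#' original index, so all-equal effects preserve the original order) and
#' split into `n_bins` contiguous bins; when the count does not divide
#' evenly, earlier bins absorb the extra voxel.
#'
#' @param effect Per-voxel signed effect ([voxel_fmria_effect()]), or any
#'   per-voxel ordering score.
#' @param n_bins Number of bins (e.g. 4 quarters or 10 deciles).
#' @return List of `n_bins` integer vectors of voxel indices (bin 1 =
#'   lowest effects).
#' @export
rank_partition <- function(effect, n_bins = 4) {
  n <- length(effect)
  stopifnot(n >= n_bins)
  ord <- order(effect, seq_along(effect))
  sizes <- rep(n %/% n_bins, n_bins)
  extra <- n %% n_bins
  if (extra > 0) sizes[seq_len(extra)] <- sizes[seq_len(extra)] + 1L
  out <- split(ord, rep(seq_len(n_bins), sizes))
  names(out) <- NULL
  lapply(out, unname)
}

#' Partition-wise spatial information scores
#'
#' Ranks each subject's voxels by that subject's own adaptation map for
#' `rank_cue`, splits them into equal bins, recomputes the spatial
#' information scores on each bin's voxel subset, and tests the bin and
#' score-type effects with a repeated-measures ANOVA.
#'
#' @param cohort An `rsa_cohort`.
#' @param rank_cue Cue whose adaptation map ranks the voxels.
#' @param n_bins 4 (quarters) or 10 (deciles).
#' @param label_mode Label definition for the scores (default
#'   `"response"`).
#' @param relations Score relations to compute per bin.
#' @param min_bin_voxels Warn when a bin falls below this size.
#' @param day,environment Optional adaptation-map scope.
#' @return List of class `partition_scores`: `scores` (tibble: subject,
#'   bin, relation, score), `anova`.
#' @export
partition_scores <- function(cohort, rank_cue = "landmark", n_bins = 4,
                             label_mode = "response",
                             relations = c("within_lm", "within_sm",
                                           "between_cue"),
                             min_bin_voxels = 20,
                             day = NULL, environment = NULL) {
  parts <- part_averages(cohort, label_mode)
  out <- list()
  warned <- FALSE
  for (sub in unique(cohort$subject)) {
    eff <- voxel_fmria_effect(cohort, sub, rank_cue, day, environment)
    bins <- rank_partition(eff, n_bins)
    if (!warned && any(lengths(bins) < min_bin_voxels)) {
      warning("partition bins smaller than ", min_bin_voxels, " voxels")
      warned <- TRUE
    }
    ps <- parts[parts$subject == sub, ]
    for (b in seq_along(bins)) {
      sc <- scores_from_parts(ps, label_mode, relations, by = "none",
                              voxels = bins[[b]])
      out[[length(out) + 1L]] <- dplyr::mutate(sc, bin = b,
                                               n_voxels = length(bins[[b]]))
    }
  }
  scores <- dplyr::bind_rows(out)
  anova <- NULL
  if (n_bins > 1 && length(relations) > 1 && length(unique(scores$subject)) > 1) {
    anova <- rm_anova_trends(scores, dv = "score", subject = "subject",
                             within = c("bin", "relation"))
  }
  structure(list(scores = scores, anova = anova), class = "partition_scores")
}

#' Empirical chance levels for partition scores
#'
#' Repeats the partition analysis with randomly ordered (instead of
#' adaptation-ranked) voxels; the per-bin scores averaged over
#' randomizations (per subject, then across subjects) are the chance
#' levels against which the ranked-bin scores are compared.
#'
#' @param cohort An `rsa_cohort`.
#' @param n_bins Number of bins.
#' @param n_rand Number of voxel randomizations (default 1000).
#' @param label_mode,relations As in [partition_scores()].
#' @param seed Optional integer seed.
#' @return Tibble: `subject`, `bin`, `relation`, `chance_score` (mean over
#'   randomizations).
#' @export
empirical_chance <- function(cohort, n_bins = 4, n_rand = 1000,
                             label_mode = "response",
                             relations = c("within_lm", "within_sm",
                                           "between_cue"),
                             seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  stopifnot(n_rand >= 1)
  parts <- part_averages(cohort, label_mode)
  V <- ncol(parts$mat[[1]])
  rdm <- rdm_matrix()
  out <- list()
  for (sub in unique(cohort$subject)) {
    ps <- parts[parts$subject == sub, ]
    pairs_by_rel <- lapply(stats::setNames(relations, relations),
                           function(rel) enumerate_pairings(ps, rel))
    acc <- matrix(0, n_bins, length(relations),
                  dimnames = list(NULL, relations))
    for (r in seq_len(n_rand)) {
      bins <- rank_partition(stats::runif(V), n_bins)
      for (b in seq_len(n_bins)) {
        for (rel in relations) {
          acc[b, rel] <- acc[b, rel] +
            fast_subset_score(pairs_by_rel[[rel]], bins[[b]], rdm)
        }
      }
    }
    out[[length(out) + 1L]] <- tibble::tibble(
      subject = sub,
      bin = rep(seq_len(n_bins), times = length(relations)),
      relation = rep(relations, each = n_bins),
      chance_score = c(acc / n_rand))
  }
  dplyr::bind_rows(out)
}

# Tibble-free spatial information score on a voxel subset of precomputed
# pairings (inner loop of the voxel-randomization chance levels).
fast_subset_score <- function(pairings, voxels, rdm) {
  S <- matrix(0, 4, 4)
  cnt <- matrix(0L, 4, 4)
  for (k in seq_len(nrow(pairings))) {
    cm <- suppressWarnings(stats::cor(t(pairings$a[[k]][, voxels, drop = FALSE]),
                                      t(pairings$b[[k]][, voxels, drop = FALSE])))
    ok <- !is.na(cm)
    cm[!ok] <- 0
    S <- S + cm
    cnt <- cnt + ok
  }
  m <- S / cnt
  s <- pmin(pmax(c(m), -1 + 1e-7), 1 - 1e-7)
  ok <- !is.na(s)
  -atanh(stats::cor(atanh(s[ok]), c(rdm)[ok]))
}

#' Spatial information profile along an ROI axis
#'
#' Splits voxels into deciles along a per-voxel axis coordinate (for
#' simulated cohorts, the generator's long-axis coordinate; for real data,
#' e.g. a connectopy rank), computes the spatial information scores per
#' decile, and tests the linear trend plus the planned contrast of the
#' eight posterior deciles (3-10) against the two anterior ones (1-2).
#'
#' @param cohort An `rsa_cohort`.
#' @param axis_rank Optional per-voxel coordinate; defaults to the
#'   simulator's ground-truth axis.
#' @param n_deciles Number of axis bins (default 10).
#' @param label_mode,relations As in [partition_scores()].
#' @return List of class `axis_profile`: `scores`, `trend` (pooled-error
#'   linear-trend t), `posterior_contrast` (per-subject paired t of deciles
#'   3-10 vs 1-2), `anova`.
#' @export
axis_profile <- function(cohort, axis_rank = NULL, n_deciles = 10,
                         label_mode = "response",
                         relations = c("within_lm", "within_sm",
                                       "between_cue")) {
  if (is.null(axis_rank)) {
    gt <- attr(cohort, "ground_truth")
    if (is.null(gt)) stop("no axis_rank supplied and cohort has no ground truth")
    axis_rank <- gt[[1]]$axis
  }
  if (length(axis_rank) < 4 * n_deciles) {
    stop("axis profile needs at least 4 voxels per bin (", length(axis_rank),
         " voxels for ", n_deciles, " bins); pattern correlations on 2-3 ",
         "voxel bins are degenerate")
  }
  bins <- rank_partition(axis_rank, n_deciles)
  parts <- part_averages(cohort, label_mode)
  out <- list()
  for (sub in unique(cohort$subject)) {
    ps <- parts[parts$subject == sub, ]
    for (b in seq_along(bins)) {
      sc <- scores_from_parts(ps, label_mode, relations, by = "none",
                              voxels = bins[[b]])
      out[[length(out) + 1L]] <- dplyr::mutate(sc, decile = b)
    }
  }
  scores <- dplyr::bind_rows(out)
  anova <- rm_anova_trends(scores, dv = "score", subject = "subject",
                           within = c("decile", "relation"),
                           trend_factor = "decile")
  per_sub <- scores |>
    dplyr::group_by(.data$subject) |>
    dplyr::summarise(diff = mean(.data$score[.data$decile >= 3]) -
                       mean(.data$score[.data$decile <= 2]),
                     .groups = "drop")
  contrast <- one_sample_t(per_sub$diff, tail = "two.sided")
  structure(list(scores = scores,
                 trend = anova$trends[anova$trends$trend == "linear", ],
                 posterior_contrast = contrast, anova = anova$anova),
            class = "axis_profile")
}

#' @export
tidy.partition_scores <- function(x, ...) x$scores

#' @export
glance.partition_scores <- function(x, ...) x$anova$anova

#' @export
tidy.axis_profile <- function(x, ...) x$scores
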