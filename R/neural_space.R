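#' Physical layout of the four test locations
#'
#' Collinear points at 0, 4, 8, 12 m embedded in the plane.
#' @param dim Embedding dimension (>= 1).
#' @return A 4 x `dim` coordinate matrix.
#' @export
physical_layout <- function(dim = 2) {
  cbind(location_positions(), matrix(0, 4, dim - 1))
}

#' Neural distance matrix from a pattern-similarity matrix
#'
#' Distance is 1 minus the Pearson pattern similarity; symmetric
#' off-diagonal pairs are averaged, the diagonal is set to 0 (only relative
#' distances matter for multidimensional scaling), and the off-diagonal
#' entries are min-max normalized to \[0, 1\] (the manually zeroed diagonal
#' is excluded from the minimum and maximum).
#'
#' @param sim A 4 x 4 (possibly asymmetric) similarity matrix.
#' @param normalize Apply min-max normalization?
#' @return A symmetric, zero-diagonal 4 x 4 distance matrix.
#' @export
neural_distance_matrix <- function(sim, normalize = TRUE) {
  stopifnot(is.matrix(sim), nrow(sim) == ncol(sim))
  d <- 1 - sim
  d <- (d + t(d)) / 2
  diag(d) <- 0
  if (normalize) d <- minmax_offdiag(d)
  d
}

minmax_offdiag <- function(d) {
  off <- row(d) != col(d)
  lo <- min(d[off])
  hi <- max(d[off])
  if (hi == lo) {
    warning("constant distance matrix: all normalized entries set to 0")
    d[] <- 0
  } else {
    d[off] <- (d[off] - lo) / (hi - lo)
  }
  d
}

#' Procrustes alignment of one configuration to another
#'
#' Finds the translation, uniform scaling, rotation and (optionally)
#' reflection of `x` that best matches `target`, and reports the
#' standardized Procrustes distance
#' `1 - (sum of singular values)^2 / (ss_x * ss_target)`, which is 0 iff
#' the configurations match up to the allowed transforms and is invariant
#' to rigid motions, reflections and uniform scaling of either input.
#'
#' @param x,target n x d coordinate matrices.
#' @param scale Allow uniform scaling (default TRUE).
#' @return List with `coords` (aligned `x`), `distance`, `rotation`,
#'   `scale_factor`.
#' @export
procrustes_fit <- function(x, target, scale = TRUE) {
  stopifnot(identical(dim(x), dim(target)))
  xc <- sweep(x, 2, colMeans(x))
  yc <- sweep(target, 2, colMeans(target))
  ssx <- sum(xc^2)
  ssy <- sum(yc^2)
  if (ssy == 0) stop("degenerate target configuration")
  if (ssx == 0) {
    return(list(coords = matrix(colMeans(target), nrow(x), ncol(x),
                                byrow = TRUE),
                distance = 1, rotation = diag(ncol(x)), scale_factor = 0))
  }
  sv <- svd(crossprod(xc, yc))
  rot <- sv$u %*% t(sv$v)
  trace <- sum(sv$d)
  b <- if (scale) trace / ssx else 1
  coords <- b * xc %*% rot + matrix(colMeans(target), nrow(x), ncol(x),
                                    byrow = TRUE)
  dist <- 1 - trace^2 / (ssx * ssy)
  list(coords = coords, distance = max(dist, 0), rotation = rot,
       scale_factor = b)
}

#' Reconstruct the neural space of the four locations
#'
#' Classical (metric) multidimensional scaling embeds the normalized
#' neural distance matrix in `dim` dimensions; the configuration is then
#' Procrustes-aligned (translation, uniform scaling, rotation, reflection)
#' to the physical track layout.
#'
#' @param ndm A symmetric zero-diagonal distance matrix
#'   ([neural_distance_matrix()]).
#' @param dim Embedding dimension (default 2; 1 is natural for the
#'   collinear physical layout).
#' @return List of class `neural_space`: `coords` (aligned 4 x `dim`),
#'   `mds_coords` (pre-alignment), `procrustes_distance`.
#' @export
reconstruct_space <- function(ndm, dim = 2) {
  stopifnot(is.matrix(ndm), isSymmetric(unname(ndm)))
  if (max(ndm) == 0) stop("degenerate (all-zero) neural distance matrix")
  xy <- suppressWarnings(stats::cmdscale(ndm, k = dim))
  if (ncol(xy) < dim) {  # non-positive eigenvalues: pad with zero axes
    xy <- cbind(xy, matrix(0, nrow(xy), dim - ncol(xy)))
  }
  fit <- procrustes_fit(xy, physical_layout(dim))
  structure(list(coords = fit$coords, mds_coords = xy,
                 procrustes_distance = fit$distance),
            class = "neural_space")
}

#' @export
print.neural_space <- function(x, ...) {
  cat("<neural_space> Procrustes distance:",
      format(x$procrustes_distance, digits = 4), "\n")
  print(round(x$coords, 3))
  invisible(x)
}

#' Permutation test of resemblance to the physical layout
#'
#' Shuffles the 6 unique off-diagonal distances over the off-diagonal
#' positions (preserving symmetry and the zero diagonal), reapplies MDS and
#' Procrustes alignment, and compares the actual Procrustes distance with
#' the surrogate distribution.  The p-value is the proportion of surrogate
#' distances strictly smaller than the actual one — inherently one-tailed,
#' and exactly 0 for a perfectly recovered layout.
#'
#' @param ndm Group-level neural distance matrix.
#' @param n_perm Number of permutations (default 5000).
#' @param dim Embedding dimension.
#' @param seed Optional integer seed.
#' @return List: `p_value`, `actual_distance`, `surrogate` (length
#'   `n_perm`), `n_perm`.
#' @export
permutation_resemblance_test <- function(ndm, n_perm = 5000, dim = 2,
                                         seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  actual <- reconstruct_space(ndm, dim)$procrustes_distance
  off <- ndm[upper.tri(ndm)]
  surrogate <- vapply(seq_len(n_perm), function(i) {
    m <- matrix(0, 4, 4)
    m[upper.tri(m)] <- sample(off)
    m <- m + t(m)
    reconstruct_space(m, dim)$procrustes_distance
  }, numeric(1))
  list(p_value = mean(surrogate < actual), actual_distance = actual,
       surrogate = surrogate, n_perm = n_perm)
}

# Subject- or group-level neural distance matrices per cue from the
# cross-validated mean similarity of all within-cue part pairings.
cue_similarity_matrices <- function(cohort, label_mode = "response",
                                    voxels = NULL) {
  parts <- part_averages(cohort, label_mode)
  out <- list()
  for (sub in unique(parts$subject)) {
    ps <- parts[parts$subject == sub, ]
    for (rel in c("within_lm", "within_sm")) {
      pr <- enumerate_pairings(ps, rel)
      sims <- purrr::map2(pr$a, pr$b, pairing_similarity, voxels = voxels)
      out[[length(out) + 1L]] <- tibble::tibble(
        subject = sub,
        cue = if (rel == "within_lm") "landmark" else "self_motion",
        sim = list(mean_similarity(sims)))
    }
  }
  dplyr::bind_rows(out)
}

#' Group-level neural space and permutation test per cue
#'
#' Subject-wise raw (un-normalized) neural distance matrices are averaged
#' cell-wise into the group matrix, normalized, embedded and aligned; the
#' permutation test assesses resemblance to the physical layout.
#'
#' @param cohort An `rsa_cohort`.
#' @param cue `"landmark"` or `"self_motion"`.
#' @param label_mode Label definition for the similarity matrices.
#' @param n_perm,dim,seed Passed to [permutation_resemblance_test()].
#' @return List: `space` (a `neural_space`), `test` (permutation result),
#'   `ndm` (group distance matrix).
#' @export
group_neural_space <- function(cohort, cue = c("landmark", "self_motion"),
                               label_mode = "location", n_perm = 5000,
                               dim = 2, seed = NULL) {
  cue <- match.arg(cue)
  sims <- cue_similarity_matrices(cohort, label_mode)
  sims <- sims[sims$cue == cue, ]
  raw <- lapply(sims$sim, neural_distance_matrix, normalize = FALSE)
  group <- Reduce(`+`, raw) / length(raw)
  ndm <- minmax_offdiag(group)
  list(space = reconstruct_space(ndm, dim),
       test = permutation_resemblance_test(ndm, n_perm = n_perm, dim = dim,
                                           seed = seed),
       ndm = ndm)
}

#' Adjacent-location neural distances and the cue-by-gradient test
#'
#' Each subject's per-cue neural space is reconstructed and aligned to the
#' physical layout; Euclidean distances between the three adjacent
#' location pairs are then submitted to a repeated-measures ANOVA with cue
#' and adjacent pair as within factors, testing the interaction of cue
#' with the linear trend of pair — the neural analogue of the mirrored
#' behavioural confusion gradients of the two cue conditions.
#'
#' @param cohort An `rsa_cohort`.
#' @param label_mode Label definition (default `"response"`).
#' @param dim Embedding dimension.
#' @return List of class `adjacent_profile`: `distances` (tibble: subject,
#'   cue, pair, distance) and `anova` ([rm_anova_trends()] output).
#' @export
adjacent_distance_profile <- function(cohort, label_mode = "location",
                                      dim = 2) {
  sims <- cue_similarity_matrices(cohort, label_mode)
  dist_tbl <- purrr::map_dfr(seq_len(nrow(sims)), function(k) {
    ndm <- neural_distance_matrix(sims$sim[[k]])
    sp <- reconstruct_space(ndm, dim)
    dd <- sqrt(rowSums((sp$coords[-1, , drop = FALSE] -
                          sp$coords[-4, , drop = FALSE])^2))
    tibble::tibble(subject = sims$subject[k], cue = sims$cue[k],
                   pair = c("Loc1-Loc2", "Loc2-Loc3", "Loc3-Loc4"),
                   distance = dd)
  })
  anova <- rm_anova_trends(dist_tbl, dv = "distance", subject = "subject",
                           within = c("cue", "pair"),
                           trend_factor = "pair", trend_by = "cue")
  structure(list(distances = dist_tbl, anova = anova),
            class = "adjacent_profile")
}

#' @export
tidy.adjacent_profile <- function(x, ...) x$distances

#' @export
glance.adjacent_profile <- function(x, ...) x$anova$trend_interactions
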