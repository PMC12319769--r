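#' Load a simulation / analysis configuration from YAML
#'
#' The file may contain a `simulation` block (fields of [sim_config()])
#' and an `analysis` block (`label_mode`, `include_diagonal`,
#' `n_perm_space`, `n_rand_chance`, `n_perm_maxt`, `n_bins`, `dim`).
#' Missing fields take the package defaults; unknown keys are rejected
#' with the offending name.
#'
#' @param path Path to a YAML file.
#' @return List with elements `simulation` (a `sim_config`) and `analysis`.
#' @export
load_config <- function(path) {
  stopifnot(file.exists(path))
  raw <- yaml::read_yaml(path)
  if (is.null(raw)) raw <- list()
  unknown_top <- setdiff(names(raw), c("simulation", "analysis"))
  if (length(unknown_top)) stop("unknown config section: ", unknown_top[1])

  sim_args <- raw$simulation %||% list()
  allowed <- names(formals(sim_config))
  unknown <- setdiff(names(sim_args), allowed)
  if (length(unknown)) stop("unknown simulation key: ", unknown[1])
  for (k in c("pop_gains", "error_base")) {
    if (!is.null(sim_args[[k]])) sim_args[[k]] <- unlist(sim_args[[k]])
  }
  for (k in c("stimulus_voxel_range", "response_voxel_range")) {
    if (!is.null(sim_args[[k]])) sim_args[[k]] <- as.numeric(sim_args[[k]])
  }
  cfg <- do.call(sim_config, sim_args)

  ana_defaults <- list(label_mode = "response", include_diagonal = TRUE,
                       n_perm_space = 5000, n_rand_chance = 1000,
                       n_perm_maxt = 10000, n_bins = 4, dim = 2)
  ana <- raw$analysis %||% list()
  unknown <- setdiff(names(ana), names(ana_defaults))
  if (length(unknown)) stop("unknown analysis key: ", unknown[1])
  ana <- utils::modifyList(ana_defaults, ana)
  if (!ana$label_mode %in% c("response", "location")) {
    stop("analysis key label_mode must be 'response' or 'location'")
  }
  list(simulation = cfg, analysis = ana)
}

#' Save a configuration to YAML
#'
#' Round-trips with [load_config()].
#' @param config List as returned by [load_config()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
save_config <- function(config, path) {
  sim <- unclass(config$simulation)
  sim$pop_gains <- as.list(sim$pop_gains)
  sim$error_base <- as.list(sim$error_base)
  yaml::write_yaml(list(simulation = sim, analysis = config$analysis), path)
  invisible(path)
}

#' Write a cohort to disk as plain-text tables
#'
#' Trial metadata goes to `trials.tsv`; each run's activation matrix goes
#' to `patterns/sub<S>_day<D>_run<R>.tsv`; `manifest.json` records the
#' configuration, package version and MD5 checksums of every artifact.
#'
#' @param cohort An `rsa_cohort`.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(file.path(dir, "patterns"), recursive = TRUE, showWarnings = FALSE)
  trials_path <- file.path(dir, "trials.tsv")
  readr::write_tsv(cohort_trials(cohort), trials_path)
  files <- trials_path
  for (i in seq_len(nrow(cohort))) {
    p <- file.path(dir, "patterns",
                   sprintf("sub%02d_day%d_run%d.tsv", cohort$subject[i],
                           cohort$day[i], cohort$run[i]))
    utils::write.table(cohort$pattern[[i]], p, sep = "\t",
                       row.names = FALSE, col.names = FALSE)
    files <- c(files, p)
  }
  cfg <- attr(cohort, "config")
  manifest <- list(
    package = "navrsa",
    version = as.character(utils::packageVersion("navrsa")),
    config = if (!is.null(cfg)) {
      c <- unclass(cfg)
      c$pop_gains <- as.list(c$pop_gains)
      c$error_base <- as.list(c$error_base)
      c
    },
    artifacts = lapply(files, function(f) {
      list(path = sub(paste0("^", dir, "/?"), "", f),
           md5 = unname(tools::md5sum(f)))
    }))
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(dir)
}

#' Read a dataset from trial metadata and activation matrices
#'
#' The hook for user-supplied (e.g. real first-level beta) data.  `meta`
#' is a TSV with the effective-trial schema (`subject`, `day`, `run`,
#' `cue`, `environment`, `true_location`, `response_location`,
#' `prev_location`, `onset_s`, kinematics).  Activation can be given as a
#' single trials x voxels TSV matrix (rows aligned with the metadata rows)
#' or, with the `RNifti` package, as a 4-D NIfTI volume plus a binary ROI
#' mask which is flattened to trials x voxels.
#'
#' @param betas_path Path to the activation TSV (or NIfTI file).
#' @param meta_path Path to the trial-metadata TSV.
#' @param mask_path Optional NIfTI ROI mask (required for NIfTI input).
#' @return An `rsa_cohort`-compatible tibble.
#' @export
read_real_dataset <- function(betas_path, meta_path, mask_path = NULL) {
  meta <- readr::read_tsv(meta_path, show_col_types = FALSE)
  need <- c("subject", "day", "run", "cue", "environment",
            "true_location", "response_location")
  missing_cols <- setdiff(need, names(meta))
  if (length(missing_cols)) stop("metadata lacks column: ", missing_cols[1])

  if (grepl("\\.nii(\\.gz)?$", betas_path)) {
    if (!requireNamespace("RNifti", quietly = TRUE)) {
      stop("NIfTI input requires the RNifti package")
    }
    if (is.null(mask_path)) stop("NIfTI input requires an ROI mask")
    vol <- RNifti::readNifti(betas_path)
    mask <- RNifti::readNifti(mask_path) > 0
    if (sum(mask) == 0) stop("ROI mask selects 0 voxels")
    n_trials <- dim(vol)[4]
    betas <- t(apply(vol, 4, function(v) v[mask]))
    dim(betas) <- c(n_trials, sum(mask))
  } else {
    betas <- as.matrix(utils::read.table(betas_path, sep = "\t"))
  }
  if (nrow(betas) != nrow(meta)) {
    stop("activation rows (", nrow(betas), ") != metadata rows (",
         nrow(meta), ")")
  }
  if (!"dist_prev_m" %in% names(meta) && "prev_location" %in% names(meta)) {
    meta$dist_prev_m <- abs(meta$true_location - meta$prev_location) * 4
  }
  key <- interaction(meta$subject, meta$day, meta$run, drop = TRUE)
  rows <- lapply(split(seq_len(nrow(meta)), key), function(ix) {
    m <- meta[ix, ]
    tibble::tibble(subject = m$subject[1], day = m$day[1], run = m$run[1],
                   cue = m$cue[1], environment = m$environment[1],
                   meta = list(m), pattern = list(betas[ix, , drop = FALSE]))
  })
  out <- dplyr::arrange(dplyr::bind_rows(rows), .data$subject, .data$day,
                        .data$run)
  class(out) <- c("rsa_cohort", class(out))
  out
}

#' Run the full simulation-and-analysis pipeline
#'
#' Simulates a cohort and executes the complete analysis chain: response-
#' and location-based spatial information scores with group tests and the
#' six-score Max-T familywise correction; unique-contribution
#' decompositions (location vs response) per cue; group neural-space
#' reconstruction with permutation tests and the adjacent-distance
#' profile; the adaptation-ranked partition analysis with empirical
#' chance levels; and the long-axis decile profile.  Fully reproducible
#' from the configuration seed.
#'
#' @param config A config list ([load_config()]), a `sim_config`, or NULL
#'   for defaults.
#' @param out_dir Optional directory; when given, all result tables are
#'   written as TSV plus a `manifest.json`.
#' @param stages Character subset of
#'   `c("scores", "unique", "space", "adaptation")` to run.
#' @return List of class `navrsa_results` with the per-stage outputs.
#' @export
run_pipeline <- function(config = NULL, out_dir = NULL,
                         stages = c("scores", "unique", "space", "adaptation")) {
  if (is.null(config)) config <- list(simulation = sim_config(),
                                      analysis = NULL)
  if (inherits(config, "sim_config")) {
    config <- list(simulation = config, analysis = NULL)
  }
  ana <- utils::modifyList(
    list(label_mode = "response", include_diagonal = TRUE,
         n_perm_space = 5000, n_rand_chance = 1000, n_perm_maxt = 10000,
         n_bins = 4, dim = 2),
    config$analysis %||% list())
  cfg <- config$simulation
  res <- list(config = config)
  message("simulating cohort (", cfg$n_subjects, " subjects, ",
          cfg$n_voxels, " voxels)")
  cohort <- simulate_cohort(cfg)

  if ("scores" %in% stages) {
    message("stage: spatial information scores")
    sc_resp <- score_suite(cohort, "response",
                           include_diagonal = ana$include_diagonal)
    sc_loc <- score_suite(cohort, "location",
                          include_diagonal = ana$include_diagonal)
    scores <- dplyr::bind_rows(sc_resp, sc_loc)
    wide <- scores |>
      dplyr::mutate(test = paste(.data$label_mode, .data$relation, sep = ".")) |>
      tidyr::pivot_wider(id_cols = "subject", names_from = "test",
                         values_from = "score")
    res$scores <- scores
    res$score_tests <- score_group_tests(scores)
    res$maxt <- maxt_correction(as.matrix(wide[, -1]),
                                n_perm = ana$n_perm_maxt, tail = "greater",
                                seed = cfg$seed + 1L)
  }
  if ("unique" %in% stages) {
    message("stage: unique contributions")
    res$unique <- lapply(
      stats::setNames(c("within_lm", "within_sm", "between_cue"),
                      c("within_lm", "within_sm", "between_cue")),
      function(rel) decompose_cohort(cohort, c("location", "response"), rel))
  }
  if ("space" %in% stages) {
    message("stage: neural space")
    res$space <- lapply(
      stats::setNames(c("landmark", "self_motion"),
                      c("landmark", "self_motion")),
      function(cue) group_neural_space(cohort, cue,
                                       label_mode = "location",
                                       n_perm = ana$n_perm_space,
                                       dim = ana$dim, seed = cfg$seed + 2L))
    res$adjacent <- adjacent_distance_profile(cohort,
                                              label_mode = "location",
                                              dim = ana$dim)
  }
  if ("adaptation" %in% stages) {
    message("stage: adaptation link")
    res$partition <- partition_scores(cohort, rank_cue = "landmark",
                                      n_bins = ana$n_bins,
                                      label_mode = ana$label_mode)
    res$chance <- empirical_chance(cohort, n_bins = ana$n_bins,
                                   n_rand = ana$n_rand_chance,
                                   label_mode = ana$label_mode,
                                   seed = cfg$seed + 3L)
    n_dec <- min(10L, max(2L, cfg$n_voxels %/% 4L))
    if (n_dec < 10) {
      message("reducing axis profile to ", n_dec, " bins for ",
              cfg$n_voxels, " voxels")
    }
    res$axis <- axis_profile(cohort, n_deciles = n_dec,
                             label_mode = ana$label_mode)
  }
  res$cohort <- cohort
  class(res) <- "navrsa_results"
  if (!is.null(out_dir)) write_results(res, out_dir)
  res
}

#' Write pipeline result tables to a directory
#'
#' @param res A `navrsa_results` list.
#' @param dir Output directory.
#' @return `dir`, invisibly.
#' @export
write_results <- function(res, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  files <- character()
  wr <- function(x, name) {
    p <- file.path(dir, paste0(name, ".tsv"))
    readr::write_tsv(x, p)
    files <<- c(files, p)
  }
  if (!is.null(res$scores)) {
    wr(res$scores, "scores")
    wr(res$score_tests, "score_tests")
    wr(res$maxt, "maxt")
  }
  if (!is.null(res$unique)) {
    wr(dplyr::bind_rows(lapply(res$unique, `[[`, "coefficients")),
       "unique_coefficients")
    wr(dplyr::bind_rows(lapply(res$unique, `[[`, "tests")), "unique_tests")
  }
  if (!is.null(res$space)) {
    sp <- purrr::imap_dfr(res$space, function(s, cue) {
      tibble::tibble(cue = cue, location = paste0("Loc", 1:4),
                     x = s$space$coords[, 1], y = s$space$coords[, 2],
                     procrustes_distance = s$space$procrustes_distance,
                     p_value = s$test$p_value)
    })
    wr(sp, "neural_space")
    wr(res$adjacent$distances, "adjacent_distances")
  }
  if (!is.null(res$partition)) {
    wr(res$partition$scores, "partition_scores")
    wr(res$chance, "partition_chance")
    wr(res$axis$scores, "axis_scores")
  }
  manifest <- list(
    package = "navrsa",
    version = as.character(utils::packageVersion("navrsa")),
    seed = attr(res$cohort, "config")$seed,
    artifacts = lapply(files, function(f) {
      list(path = basename(f), md5 = unname(tools::md5sum(f)))
    }))
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(dir)
}
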