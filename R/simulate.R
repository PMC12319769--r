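#' Simulator configuration
#'
#' Bundles every parameter of the synthetic cohort generator.  The simulator
#' realizes a three-subpopulation neuronal architecture for the
#' retrosplenial cortex: two cue-specific *adapting* populations driven by
#' the location actually occupied (one recruited under landmark navigation,
#' one under self-motion navigation) and one shared *non-adapting*
#' population driven by the location the subject reports.  Neurons have
#' Gaussian tuning curves over the 1-D track coordinate and are aggregated
#' into voxels through population-specific loading matrices whose
#' across-voxel concentration is controlled by `clustering_evenness`.
#'
#' @param n_subjects Number of subjects in a cohort.
#' @param n_voxels Number of voxels in the simulated ROI.
#' @param n_neurons_per_pop Neurons per subpopulation.
#' @param tuning_sigma Gaussian tuning-curve width (metres) over the track
#'   coordinate; locations are 4 m apart on a 12 m span.
#' @param clustering_evenness In \[0, 1\]: 1 spreads each population's
#'   neurons evenly over voxels, 0 concentrates each population in very few
#'   voxels.  Uneven clustering is what gives voxels differential tuning and
#'   hence multi-voxel pattern information.
#' @param pop_gains Named non-negative amplitudes for the three populations:
#'   `stimulus_lm`, `stimulus_sm`, `response_shared`.
#' @param adaptation_gain Repetition-suppression fraction in \[0, 1): each
#'   adapting neuron's activity is scaled by
#'   `1 - adaptation_gain * f(previous location)` with `f` its own tuning
#'   curve, so activation increases with the distance from the previously
#'   visited location (the fMRI-adaptation signature).
#' @param noise_sd SD of i.i.d. Gaussian voxel noise added to each trial.
#' @param error_base Named baseline response-error probabilities,
#'   `c(landmark = ..., self_motion = ...)`.  Defaults are calibrated so the
#'   cohort mean accuracy falls near 0.85 (landmark) and 0.79 (self-motion).
#' @param error_gradient Per-location increment of the error probability
#'   along the cue-specific direction (away from the landmark under
#'   landmark navigation; away from the path-integration anchor under
#'   self-motion navigation).
#' @param adjacent_error_prob Probability that an error lands on an adjacent
#'   location (rather than a location two or more steps away).
#' @param cue_disjoint If TRUE the two stimulus populations are planted in
#'   disjoint voxel sets.
#' @param stimulus_voxel_range,response_voxel_range Axis intervals
#'   (sub-ranges of \[0, 1\] along the ROI long axis) to which the stimulus
#'   populations and the shared response population are confined.
#' @param event_spacing_s Nominal onset spacing per event slot (seconds).
#' @param seed Integer master seed.
#' @return A `sim_config` list.
#' @export
sim_config <- function(n_subjects = 20,
                       n_voxels = 120,
                       n_neurons_per_pop = 400,
                       tuning_sigma = 6,
                       clustering_evenness = 0.5,
                       pop_gains = c(stimulus_lm = 1, stimulus_sm = 1,
                                     response_shared = 1),
                       adaptation_gain = 0.4,
                       noise_sd = 3.5,
                       error_base = c(landmark = 0.0815, self_motion = 0.1465),
                       error_gradient = 0.045,
                       adjacent_error_prob = 0.975,
                       cue_disjoint = FALSE,
                       stimulus_voxel_range = c(0, 1),
                       response_voxel_range = c(0, 1),
                       event_spacing_s = 12,
                       seed = 1L) {
  gains <- c(stimulus_lm = 0, stimulus_sm = 0, response_shared = 0)
  gains[names(pop_gains)] <- pop_gains
  base <- c(landmark = 0, self_motion = 0)
  if (length(error_base) == 1 && is.null(names(error_base))) {
    base[] <- error_base
  } else {
    base[names(error_base)] <- error_base
  }
  cfg <- list(n_subjects = as.integer(n_subjects),
              n_voxels = as.integer(n_voxels),
              n_neurons_per_pop = as.integer(n_neurons_per_pop),
              tuning_sigma = tuning_sigma,
              clustering_evenness = clustering_evenness,
              pop_gains = gains,
              adaptation_gain = adaptation_gain,
              noise_sd = noise_sd,
              error_base = base,
              error_gradient = error_gradient,
              adjacent_error_prob = adjacent_error_prob,
              cue_disjoint = isTRUE(cue_disjoint),
              stimulus_voxel_range = stimulus_voxel_range,
              response_voxel_range = response_voxel_range,
              event_spacing_s = event_spacing_s,
              seed = as.integer(seed))
  validate_sim_config(cfg)
  structure(cfg, class = "sim_config")
}

validate_sim_config <- function(cfg) {
  with(cfg, {
    stopifnot(n_subjects >= 1, n_voxels >= 2, n_neurons_per_pop >= 1,
              tuning_sigma > 0,
              clustering_evenness >= 0, clustering_evenness <= 1,
              all(pop_gains >= 0),
              adaptation_gain >= 0, adaptation_gain < 1,
              noise_sd >= 0,
              all(error_base >= 0), all(error_base <= 1),
              error_gradient >= 0,
              adjacent_error_prob >= 0, adjacent_error_prob <= 1)
    probs <- outer(error_base, error_gradient * 0:3, `+`)
    if (any(probs > 1)) stop("error_base + 3 * error_gradient must be <= 1")
  })
  invisible(cfg)
}

#' Simulate recognition responses for location-occupation trials
#'
#' Errors land predominantly on locations adjacent to the true one, and the
#' error probability increases with distance from the navigational anchor:
#' from the landmark (beyond `Loc4`) under landmark navigation, and from
#' the path-integration start marker (before `Loc1`) under self-motion
#' navigation.  This yields the mirrored accuracy gradients characteristic
#' of the two cue conditions.
#'
#' @param true_location Integer vector of true locations (1..4).
#' @param cue `"landmark"` or `"self_motion"` (scalar or vector).
#' @param cfg A [sim_config()].
#' @return Integer vector of reported locations (1..4).
#' @export
simulate_response <- function(true_location, cue, cfg = sim_config()) {
  stopifnot(all(true_location %in% 1:4), all(cue %in% c("landmark", "self_motion")))
  n <- length(true_location)
  cue <- rep_len(cue, n)
  steps_from_anchor <- ifelse(cue == "landmark", 4L - true_location,
                              true_location - 1L)
  p_err <- cfg$error_base[cue] + cfg$error_gradient * steps_from_anchor
  is_err <- stats::runif(n) < p_err
  out <- true_location
  if (any(is_err)) {
    idx <- which(is_err)
    adj <- stats::runif(length(idx)) < cfg$adjacent_error_prob
    for (k in seq_along(idx)) {
      i <- idx[k]
      l <- true_location[i]
      if (adj[k]) {
        nb <- intersect(c(l - 1L, l + 1L), 1:4)
        out[i] <- if (length(nb) == 1L) nb else sample(nb, 1L)
      } else {
        far <- setdiff(1:4, c(l - 1L, l, l + 1L))
        out[i] <- if (length(far) == 1L) far else sample(far, 1L)
      }
    }
  }
  out
}

#' Build population-to-voxel loading matrices
#'
#' Each population gets (i) a voxel propensity vector drawn from a
#' symmetric Dirichlet whose concentration increases with
#' `clustering_evenness` (restricted to the population's axis range), and
#' (ii) per-neuron loading rows drawn from a Dirichlet centred on that
#' propensity, so neurons of one population tend to co-locate when the
#' distribution is uneven.  Rows sum to one, so total drive is conserved
#' across evenness levels.  Voxels carry a long-axis coordinate in \[0, 1\]
#' (`axis`), used to confine populations and to profile scores by decile.
#'
#' @param cfg A [sim_config()].
#' @return A list with elements `stimulus_lm`, `stimulus_sm`,
#'   `response_shared` (each `n_neurons_per_pop` x `n_voxels`), `axis`
#'   (length-`n_voxels` coordinate), and `pref` (list of preferred track
#'   positions per population).
#' @export
build_population_loadings <- function(cfg = sim_config()) {
  V <- cfg$n_voxels
  n <- cfg$n_neurons_per_pop
  axis <- (seq_len(V) - 0.5) / V
  in_range <- function(range) axis >= range[1] & axis <= range[2]

  stim_allowed <- in_range(cfg$stimulus_voxel_range)
  resp_allowed <- in_range(cfg$response_voxel_range)
  if (cfg$cue_disjoint) {
    sv <- which(stim_allowed)
    half <- sv[seq_len(floor(length(sv) / 2))]
    lm_allowed <- sm_allowed <- rep(FALSE, V)
    lm_allowed[half] <- TRUE
    sm_allowed[setdiff(sv, half)] <- TRUE
  } else {
    lm_allowed <- sm_allowed <- stim_allowed
  }

  alpha_pop <- 0.05 + 400 * cfg$clustering_evenness^2
  neuron_conc <- 1  # per-neuron Dirichlet concentration multiplier

  rdirichlet1 <- function(alpha) {
    g <- stats::rgamma(length(alpha), shape = alpha)
    g / sum(g)
  }
  make_loading <- function(allowed) {
    Vs <- sum(allowed)
    if (Vs < 1) stop("population voxel range excludes all voxels")
    q <- rdirichlet1(rep(alpha_pop, Vs))
    L <- matrix(0, n, V)
    a <- neuron_conc * Vs * q + 1e-9
    g <- matrix(stats::rgamma(n * Vs, shape = rep(a, each = n)), n, Vs)
    L[, allowed] <- g / rowSums(g)
    L
  }
  list(stimulus_lm = make_loading(lm_allowed),
       stimulus_sm = make_loading(sm_allowed),
       response_shared = make_loading(resp_allowed),
       axis = axis,
       pref = list(stimulus_lm = stats::runif(n, -2, 14),
                   stimulus_sm = stats::runif(n, -2, 14),
                   response_shared = stats::runif(n, -2, 14)))
}

# Gaussian tuning of one population at the four test locations:
# n_neurons x 4 matrix.
tuning_matrix <- function(pref, sigma) {
  pos <- location_positions()
  exp(-outer(pref, pos, `-`)^2 / (2 * sigma^2))
}

# Noise-free voxel patterns for a block of trials.
# loc, resp, prev: integer vectors (1..4); returns length(loc) x V matrix.
expected_patterns <- function(loc, resp, prev, cue, cfg, loadings, tun) {
  stim <- if (cue == "landmark") "stimulus_lm" else "stimulus_sm"
  ga <- cfg$adaptation_gain
  out <- 0
  g <- cfg$pop_gains[[stim]]
  if (g > 0) {
    act <- tun[[stim]][, loc, drop = FALSE] *
      (1 - ga * tun[[stim]][, prev, drop = FALSE])
    out <- out + g * crossprod(act, loadings[[stim]])
  }
  g <- cfg$pop_gains[["response_shared"]]
  if (g > 0) {
    act <- tun[["response_shared"]][, resp, drop = FALSE]
    out <- out + g * crossprod(act, loadings[["response_shared"]])
  }
  if (is.matrix(out)) out else matrix(0, length(loc), cfg$n_voxels)
}

#' Simulate the multi-voxel activation pattern of one trial
#'
#' Stimulus-population neurons respond to the *true* location through their
#' Gaussian tuning curve, scaled down by repetition suppression
#' proportional to their response to the *previous* location; the shared
#' population responds to the *reported* location and does not adapt.
#' Voxel values are the loading-weighted sums plus Gaussian noise.
#'
#' @param true_location,response_location Integers 1..4.
#' @param prev_location Previous effective location (1..4); the lead-in
#'   event supplies it for the first effective trial.  Missing -> error.
#' @param cue `"landmark"` or `"self_motion"`.
#' @param cfg A [sim_config()].
#' @param loadings Output of [build_population_loadings()].
#' @return Numeric vector of length `n_voxels`.
#' @export
simulate_trial_pattern <- function(true_location, response_location,
                                   prev_location, cue,
                                   cfg = sim_config(),
                                   loadings = build_population_loadings(cfg)) {
  if (is.na(prev_location)) {
    stop("prev_location is missing: sequences must include the lead-in event")
  }
  tun <- lapply(loadings$pref, tuning_matrix, sigma = cfg$tuning_sigma)
  mu <- expected_patterns(true_location, response_location, prev_location,
                          cue, cfg, loadings, tun)
  drop(mu) + stats::rnorm(cfg$n_voxels, 0, cfg$noise_sd)
}

# Analytic per-voxel adaptation slope planted by the generator: partial OLS
# slope (location fixed effects adjusted) of the expected voxel activation
# on distance-to-previous over the balanced (l, p) design, computed from
# the noiseless model (the independent ground truth for recovery tests).
planted_adaptation_slope <- function(cue, cfg, loadings, tun) {
  pairs <- expand.grid(l = 1:4, p = 1:4)
  d <- abs(pairs$l - pairs$p) * 4
  resp <- pairs$l  # expectation over responses is d-independent; use truth
  mu <- expected_patterns(pairs$l, resp, pairs$p, cue, cfg, loadings, tun)
  adaptation_slope(d, pairs$l, mu)
}

#' Simulate a full cohort
#'
#' Generates, for each subject, a two-day schedule of 8 runs per day, the
#' trial-wise behavioural responses, and one 20 x `n_voxels` activation
#' matrix per run (20 effective trials; the lead-in and null events carry
#' no pattern but the lead-in supplies the first previous location).
#'
#' @param cfg A [sim_config()].
#' @return A tibble of class `rsa_cohort` with one row per subject x run:
#'   columns `subject`, `day`, `run`, `cue`, `environment`, `meta` (list of
#'   per-trial tibbles) and `pattern` (list of 20 x `n_voxels` matrices).
#'   Attributes: `config`, and `ground_truth` (per subject: loading
#'   matrices, voxel axis coordinates, planted per-voxel adaptation slopes
#'   per cue).
#' @export
simulate_cohort <- function(cfg = sim_config()) {
  validate_sim_config(cfg)
  set.seed(cfg$seed)
  subject_seeds <- sample.int(.Machine$integer.max - 1L, cfg$n_subjects)
  rows <- vector("list", cfg$n_subjects)
  truth <- vector("list", cfg$n_subjects)
  for (s in seq_len(cfg$n_subjects)) {
    set.seed(subject_seeds[s])
    trials <- make_trial_table(subject = s,
                               event_spacing_s = cfg$event_spacing_s)
    eff <- trials[!trials$is_null & !trials$is_lead_in, ]
    eff$response_location <- simulate_response(eff$true_location, eff$cue, cfg)
    eff$correct <- eff$response_location == eff$true_location
    eff$dist_prev_m <- abs(eff$true_location - eff$prev_location) * 4
    loadings <- build_population_loadings(cfg)
    tun <- lapply(loadings$pref, tuning_matrix, sigma = cfg$tuning_sigma)
    # all trials of one cue share the same generative populations, so the
    # noise-free patterns are computed in one block per cue
    mu <- matrix(0, nrow(eff), cfg$n_voxels)
    for (cue in c("landmark", "self_motion")) {
      ix <- which(eff$cue == cue)
      mu[ix, ] <- expected_patterns(eff$true_location[ix],
                                    eff$response_location[ix],
                                    eff$prev_location[ix], cue, cfg,
                                    loadings, tun)
    }
    pat <- mu + matrix(stats::rnorm(nrow(eff) * cfg$n_voxels, 0, cfg$noise_sd),
                       nrow(eff), cfg$n_voxels)
    # eff is ordered by day then run: 16 consecutive blocks of 20 trials
    chunks <- split(seq_len(nrow(eff)), rep(seq_len(16), each = 20))
    first <- vapply(chunks, `[`, integer(1), 1)
    rows[[s]] <- tibble::tibble(
      subject = s, day = eff$day[first], run = eff$run[first],
      cue = eff$cue[first], environment = eff$environment[first],
      meta = lapply(chunks, function(ix) eff[ix, ]),
      pattern = lapply(chunks, function(ix) pat[ix, , drop = FALSE]))
    truth[[s]] <- list(
      loadings = loadings,
      axis = loadings$axis,
      planted_slope = list(
        landmark = planted_adaptation_slope("landmark", cfg, loadings, tun),
        self_motion = planted_adaptation_slope("self_motion", cfg, loadings, tun)))
  }
  out <- dplyr::bind_rows(rows)
  attr(out, "config") <- cfg
  attr(out, "ground_truth") <- truth
  class(out) <- c("rsa_cohort", class(out))
  out
}

#' @export
print.rsa_cohort <- function(x, ...) {
  cfg <- attr(x, "config")
  cat(sprintf("<rsa_cohort> %d subjects, %d runs each, %d voxels\n",
              cfg$n_subjects, as.integer(nrow(x) / cfg$n_subjects),
              cfg$n_voxels))
  NextMethod()
}

#' Extract the pooled effective-trial metadata of a cohort
#'
#' @param cohort An `rsa_cohort`.
#' @return A tibble of all effective trials (including `response_location`).
#' @export
cohort_trials <- function(cohort) {
  dplyr::bind_rows(cohort$meta)
}
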