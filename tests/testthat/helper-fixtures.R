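# Shared fixtures: small cohorts are expensive enough to build once per run.

small_cfg <- function(...) {
  args <- utils::modifyList(
    list(n_subjects = 4, n_voxels = 50, n_neurons_per_pop = 60, seed = 421L),
    list(...))
  do.call(sim_config, args)
}

cached_cohort <- local({
  cache <- new.env(parent = emptyenv())
  function(key, cfg) {
    if (is.null(cache[[key]])) cache[[key]] <- simulate_cohort(cfg)
    cache[[key]]
  }
})

default_small_cohort <- function() cached_cohort("default", small_cfg())

# Hand-built two-run-per-cell cohort with known patterns, for arithmetic
# checks of the part-averaging and scoring chain.
toy_cohort <- function(pattern_fn, n_voxels = 8, seed = 99) {
  set.seed(seed)
  sched <- dplyr::bind_rows(make_session_schedule(day = 1),
                            make_session_schedule(day = 2))
  rows <- purrr::map_dfr(seq_len(nrow(sched)), function(r) {
    loc <- rep(1:4, each = 5)[sample.int(20)]
    meta <- tibble::tibble(
      subject = 1L, day = sched$day[r], run = sched$run[r],
      cue = sched$cue[r], environment = sched$environment[r],
      trial_index = 1:20, true_location = loc, response_location = loc,
      prev_location = c(loc[20], loc[-20]),
      dist_prev_m = abs(loc - c(loc[20], loc[-20])) * 4,
      onset_s = (1:20 - 1) * 12,
      path_length_m = loc * 4 + 10, traveled_time_s = loc + 1,
      correct = TRUE)
    pat <- pattern_fn(meta, n_voxels)
    tibble::tibble(subject = 1L, day = sched$day[r], run = sched$run[r],
                   cue = sched$cue[r], environment = sched$environment[r],
                   meta = list(meta), pattern = list(pat))
  })
  class(rows) <- c("rsa_cohort", class(rows))
  rows
}
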