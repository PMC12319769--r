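#' Generate a second-order counterbalanced (de Bruijn) event sequence
#'
#' Builds a cyclic event sequence over `n_labels` event types in which every
#' ordered pair of types (including repeats) occurs exactly once as a cyclic
#' neighbour pair.  This is the order-2 de Bruijn property that
#' counterbalances first-order carry-over effects: each event type is preceded
#' equally often by every type, so adaptation to the previous event and
#' pattern similarity can be estimated from the same runs without bias.
#'
#' The cycle is found as a random Eulerian circuit on the complete directed
#' graph (with self-loops) over the labels, so different seeds yield
#' different valid cycles.  With the default five labels (four track
#' locations plus a null/fixation event) the sequence has length 25 and
#' contains 20 location events, 5 per location.
#'
#' @param n_labels Number of event types (default 5: `Loc1`..`Loc4` + `Null`).
#' @param order Counterbalancing order; only `2` is supported.
#' @param seed Optional integer seed for reproducibility.
#' @return An object of class `event_sequence`: a character vector of event
#'   labels with attributes `n_labels`, `order` and `lead_in` (FALSE).
#' @examples
#' s <- make_debruijn_sequence(seed = 1)
#' length(s)            # 25
#' table(unclass(s))    # 5 of each label
#' @seealso [add_lead_in()], [make_session_schedule()], [simulate_cohort()]
#' @export
make_debruijn_sequence <- function(n_labels = 5, order = 2, seed = NULL) {
  if (!identical(as.integer(order), 2L)) {
    stop("only order-2 counterbalancing is supported (got order = ", order, ")")
  }
  if (n_labels < 2) stop("n_labels must be >= 2")
  if (!is.null(seed)) set.seed(seed)

  labels <- if (n_labels == 5) {
    c("Loc1", "Loc2", "Loc3", "Loc4", "Null")
  } else {
    paste0("E", seq_len(n_labels))
  }

  # Eulerian circuit on the complete digraph with loops: each node has
  # in-degree = out-degree = n_labels and the graph is strongly connected,
  # so a circuit always exists; Hierholzer's algorithm finds one.
  n <- n_labels
  # out_edges[[v]]: randomized stack of remaining target nodes from v
  out_edges <- lapply(seq_len(n), function(v) sample.int(n, n))
  n_left <- rep(n, n)
  stack <- integer(n * n + 1L)
  stack[1L] <- 1L
  top <- 1L
  circuit <- integer(n * n)
  filled <- 0L
  while (top > 0L) {
    v <- stack[top]
    if (n_left[v] > 0L) {
      w <- out_edges[[v]][n_left[v]]
      n_left[v] <- n_left[v] - 1L
      top <- top + 1L
      stack[top] <- w
    } else {
      filled <- filled + 1L
      circuit[filled] <- v
      top <- top - 1L
    }
  }
  # circuit holds n^2 + 1 visits, first == last; drop the duplicate closure
  seq_nodes <- rev(circuit[seq_len(filled)])
  seq_nodes <- seq_nodes[-length(seq_nodes)]

  structure(labels[seq_nodes],
            n_labels = n_labels, order = 2L, lead_in = FALSE,
            class = "event_sequence")
}

#' Duplicate the final event at the head of a sequence
#'
#' Prepends a copy of the last event so the haemodynamic response reaches a
#' steady state before the counterbalanced cycle starts; the duplicated
#' lead-in event is excluded from all analyses but supplies the
#' "previous location" for the first effective trial.
#'
#' @param seq An `event_sequence` without a lead-in.
#' @return The sequence with one extra leading event and `lead_in = TRUE`.
#' @export
add_lead_in <- function(seq) {
  stopifnot(inherits(seq, "event_sequence"))
  if (isTRUE(attr(seq, "lead_in"))) stop("sequence already has a lead-in event")
  out <- c(seq[length(seq)], unclass(seq))
  structure(out,
            n_labels = attr(seq, "n_labels"), order = attr(seq, "order"),
            lead_in = TRUE, class = "event_sequence")
}

#' Rotate a cyclic sequence so that it ends on a location event
#'
#' Rotation preserves the cyclic pair-coverage property, and a final
#' location event guarantees that the lead-in duplicate provides a defined
#' previous location for the first effective trial.
#' @param seq An `event_sequence` without lead-in.
#' @return The rotated `event_sequence`.
#' @keywords internal
rotate_to_location_end <- function(seq) {
  stopifnot(inherits(seq, "event_sequence"), !isTRUE(attr(seq, "lead_in")))
  n <- length(seq)
  if (seq[n] != "Null") return(seq)
  last_loc <- max(which(seq != "Null"))
  idx <- c((last_loc + 1L):n, 1L:last_loc)
  structure(unclass(seq)[idx],
            n_labels = attr(seq, "n_labels"), order = attr(seq, "order"),
            lead_in = FALSE, class = "event_sequence")
}

#' Generate one scanning day's run schedule
#'
#' Each scanning day has eight runs: the four cue-by-environment
#' combinations each occur twice, semi-randomized with the restriction that
#' two consecutive runs never share the same combination.  Orders are drawn
#' by rejection sampling of random permutations, which realizes the stated
#' constraints of the Latin-square counterbalancing.
#'
#' @param day Scanning day label (1 or 2).
#' @param seed Optional integer seed.
#' @param max_tries Bound on rejection-sampling attempts.
#' @return A tibble with columns `day`, `run` (1..8), `cue`
#'   (`"landmark"`/`"self_motion"`), `environment` (`"nature"`/`"city"`) and
#'   `sequence_id` (which of the day's de Bruijn sequences the run uses).
#' @export
make_session_schedule <- function(day = 1, seed = NULL, max_tries = 1000L) {
  stopifnot(day %in% c(1, 2))
  if (!is.null(seed)) set.seed(seed)
  combos <- tidyr::expand_grid(cue = c("landmark", "self_motion"),
                               environment = c("nature", "city"))
  combos <- dplyr::bind_rows(combos, combos)
  for (i in seq_len(max_tries)) {
    ord <- sample.int(8L, 8L)
    cand <- combos[ord, ]
    key <- paste(cand$cue, cand$environment)
    if (all(key[-1] != key[-8])) {
      return(tibble::tibble(day = as.integer(day), run = 1:8,
                            cue = cand$cue, environment = cand$environment,
                            sequence_id = sample.int(8L, 8L)))
    }
  }
  stop("failed to find a valid schedule in ", max_tries, " tries")
}

#' Sample per-trial movement kinematics
#'
#' The start position of the passive movement is uniform on \[-18, -4\] m
#' and the movement speed uniform on \[2, 5\] m/s, so that path length is
#' partially decorrelated from the target location.  Track coordinates put
#' `Loc1`..`Loc4` at 0, 4, 8 and 12 m, hence
#' `path_length = location_position - start_position`.
#'
#' @param location_position Target location coordinate in metres
#'   (one of 0, 4, 8, 12).
#' @return A one-row tibble with `start_position_m`, `speed_mps`,
#'   `path_length_m` and `traveled_time_s`.
#' @export
sample_kinematics <- function(location_position) {
  stopifnot(all(location_position %in% c(0, 4, 8, 12)))
  n <- length(location_position)
  start <- stats::runif(n, -18, -4)
  speed <- stats::runif(n, 2, 5)
  path <- location_position - start
  tibble::tibble(start_position_m = start, speed_mps = speed,
                 path_length_m = path, traveled_time_s = path / speed)
}

#' Location labels and track coordinates
#' @return Named numeric vector of location coordinates in metres.
#' @keywords internal
location_positions <- function() c(Loc1 = 0, Loc2 = 4, Loc3 = 8, Loc4 = 12)

#' Build the full trial table for one subject
#'
#' Combines the two session schedules with per-run de Bruijn sequences
#' (rotated so the lead-in duplicate is a location event) and sampled
#' kinematics.  Event onsets use a fixed nominal spacing per event slot;
#' they exist solely to support the temporal-distance control predictor.
#'
#' @param subject Subject identifier.
#' @param seed Integer seed; the whole table is reproducible from it.
#' @param event_spacing_s Nominal onset spacing between successive event
#'   slots in seconds (default 12).
#' @return A tibble with one row per event slot (26 per run: lead-in + 25),
#'   columns `subject`, `day`, `run`, `cue`, `environment`, `trial_index`,
#'   `event_label`, `is_lead_in`, `is_null`, `true_location` (1..4 or NA),
#'   `prev_location` (previous location event, lead-in included), `onset_s`,
#'   and the kinematic columns of [sample_kinematics()].
#' @export
make_trial_table <- function(subject = 1L, seed = NULL, event_spacing_s = 12) {
  if (!is.null(seed)) set.seed(seed)
  locpos <- location_positions()
  sched <- dplyr::bind_rows(make_session_schedule(day = 1),
                            make_session_schedule(day = 2))
  seqs <- lapply(1:16, function(i) rotate_to_location_end(make_debruijn_sequence()))
  n_ev <- 26L
  labels <- unlist(lapply(seq_len(16), function(r) {
    unclass(add_lead_in(seqs[[(sched$day[r] - 1L) * 8L + sched$sequence_id[r]]]))
  }), use.names = FALSE)
  run_of <- rep(seq_len(16), each = n_ev)
  is_null <- labels == "Null"
  loc <- ifelse(is_null, NA_integer_, match(labels, names(locpos)))
  # previous location event within each run (nulls skipped); defined for
  # every effective trial because the lead-in duplicate is a location event
  prev <- rep(NA_integer_, length(loc))
  last <- NA_integer_
  for (i in seq_along(loc)) {
    if (i %% n_ev == 1L) last <- NA_integer_
    prev[i] <- last
    if (!is.na(loc[i])) last <- loc[i]
  }
  start <- speed <- path <- ttime <- rep(NA_real_, length(labels))
  kin <- sample_kinematics(locpos[labels[!is_null]])
  start[!is_null] <- kin$start_position_m
  speed[!is_null] <- kin$speed_mps
  path[!is_null] <- kin$path_length_m
  ttime[!is_null] <- kin$traveled_time_s
  tibble::tibble(
    subject = subject,
    day = sched$day[run_of], run = sched$run[run_of],
    cue = sched$cue[run_of], environment = sched$environment[run_of],
    trial_index = rep(seq_len(n_ev), 16),
    event_label = labels,
    is_lead_in = rep(seq_len(n_ev), 16) == 1L,
    is_null = is_null, true_location = loc, prev_location = prev,
    onset_s = (rep(seq_len(n_ev), 16) - 1) * event_spacing_s,
    start_position_m = start, speed_mps = speed,
    path_length_m = path, traveled_time_s = ttime)
}

#' Write per-subject trial tables as TSV
#'
#' @param trials A trial table (or row-bound tables) from [make_trial_table()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_trial_table <- function(trials, path) {
  readr::write_tsv(trials, path)
  invisible(path)
}
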