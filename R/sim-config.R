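#' Muscle channels recorded in a session
#'
#' Canonical order of the five surface-EMG channels.
#' @export
reach_muscles <- c(
  "biceps brachii", "triceps brachii", "upper trapezius",
  "anterior deltoid", "posterior deltoid"
)

#' Default exercise protocol template
#'
#' One row per block, in execution order, for one ball mode: a baseline block
#' of 16 reaching segments, then alternating training (24 segments, with
#' terminal feedback) and retention (16 segments, concurrent feedback only)
#' blocks for terminal visual (TV), terminal haptic (TH) and terminal
#' multimodal (TM) feedback.
#'
#' @return A tibble with columns `block`, `phase`, `feedback`, `n_segments`.
#' @export
default_protocol <- function() {
  tibble::tibble(
    block      = 1:7,
    phase      = c("baseline", "training", "retention", "training",
                   "retention", "training", "retention"),
    feedback   = c("none", "TV", "TV", "TH", "TH", "TM", "TM"),
    n_segments = c(16L, 24L, 16L, 24L, 16L, 24L, 16L)
  )
}

# Per-(ball_mode, cell) movement parameters. `primary_duration` is the
# ballistic submovement duration; expected movement time is
# primary + E[k] * corrective_duration (0.25 s). Defaults chosen so expected
# movement times sit in the ranges reported for healthy adults in this task
# (baseline ~3.2-3.5 s, retention ~2.4-2.8 s).
default_conditions <- function() {
  tibble::tibble(
    ball_mode         = rep(c("big", "small"), each = 4L),
    cell              = rep(c("baseline", "TV", "TH", "TM"), 2L),
    primary_duration  = c(2.50, 2.10, 2.00, 1.90,
                          2.20, 2.05, 2.00, 2.00),
    n_corrective_mean = c(4, 2, 2, 2,
                          4, 3, 2, 2)
  )
}

#' Build a simulation configuration
#'
#' Collects every parameter of the synthetic-session generator: session
#' protocol, target geometry, submovement structure, participant and segment
#' variability, and the EMG synthesis model. Defaults emulate the study
#' conditions: two ball modes (small target radius 0.084 m, big twice that),
#' mean inter-target movement distances of 0.056 m (small) and 0.039 m (big),
#' seven blocks of 16/24/16/24/16/24/16 segments per ball mode, and
#' condition-dependent movement durations.
#'
#' @param n_participants Number of participants in the simulated cohort.
#' @param sample_rate_traj Trajectory sampling rate, Hz.
#' @param sample_rate_emg EMG sampling rate, Hz (nominal 1000).
#' @param ball_modes Character vector of ball modes, executed in order.
#' @param protocol Block table as produced by [default_protocol()].
#' @param conditions Per-(ball_mode, cell) parameter table with columns
#'   `ball_mode`, `cell`, `primary_duration` (s) and `n_corrective_mean`.
#'   Overrides `feedback_effect_s` when supplied.
#' @param feedback_effect_s Optional programmed feedback effect on movement
#'   time, in seconds. `NULL` (default) keeps the condition table defaults;
#'   `0` makes every cell identical to baseline (null effect, for type-I
#'   calibration); a positive value shortens every retention cell's primary
#'   duration by that amount relative to baseline while equalising corrective
#'   counts, so the programmed effect acts on movement time alone.
#' @param target_radius_small Small-ball radius in metres; the big-ball radius
#'   is twice this.
#' @param mean_distance Named numeric: mean inter-target movement distance per
#'   ball mode, metres.
#' @param corrective_amplitude Optional fixed first corrective submovement
#'   amplitude, metres. The default `NULL` scales the first corrective
#'   amplitude with the reach: `corrective_rel` times the primary reach
#'   distance. Proportional corrections mirror the overshoot of fast aimed
#'   movements and guarantee that the first corrective speed bump dominates
#'   the broad primary peak for every target distance, which keeps the
#'   programmed EMG peak latency sharply recoverable.
#' @param corrective_rel First corrective amplitude as a fraction of the
#'   primary reach distance (used when `corrective_amplitude` is `NULL`).
#' @param corrective_decay Geometric decay factor of successive corrective
#'   amplitudes, in (0, 1].
#' @param corrective_floor Lower bound on corrective amplitudes, metres;
#'   keeps every corrective speed bump above the 20 mm/s counting cutoff.
#' @param corrective_duration Duration of each corrective submovement,
#'   seconds. Must be at least 0.2 s so consecutive speed peaks are resolvable
#'   under the 150 ms peak-counting separation rule.
#' @param corrective_dispersion Negative-binomial size parameter of the
#'   per-segment corrective count; large values approach a Poisson count.
#' @param participant_sd Between-participant SD of an additive offset on
#'   primary durations, seconds.
#' @param duration_sd Segment-to-segment SD of the primary duration, seconds.
#' @param pos_noise_sd Additive Gaussian noise on recorded positions, metres.
#' @param intertrial_gap Gap between a target's disappearance and the next
#'   appearance, seconds.
#' @param block_gap,mode_gap Rest between blocks / ball modes, seconds.
#' @param muscle_latency_offset Named numeric: per-muscle EMG burst latency
#'   relative to the speed profile, seconds. Defaults are all anticipatory
#'   (negative): muscle activity leads the kinematics by the
#'   electromechanical delay, proximal stabilisers earliest. Anticipatory
#'   offsets also keep the dominant envelope peak inside the movement
#'   segment, whose last corrective submovement ends at contact.
#' @param emg_burst_gain Named numeric: per-muscle envelope gain,
#'   mV per (m/s).
#' @param mains_amplitude Amplitude of the 50 Hz mains component, mV.
#' @param mains_freq Mains frequency, Hz.
#' @param emg_noise_sd Baseline EMG noise SD, mV.
#'
#' @return A validated list of class `sim_config`.
#' @export
sim_config <- function(n_participants = 10L,
                       sample_rate_traj = 100,
                       sample_rate_emg = 1000,
                       ball_modes = c("big", "small"),
                       protocol = default_protocol(),
                       conditions = NULL,
                       feedback_effect_s = NULL,
                       target_radius_small = 0.084,
                       mean_distance = c(small = 0.056, big = 0.039),
                       corrective_amplitude = NULL,
                       corrective_rel = 0.4,
                       corrective_decay = 0.6,
                       corrective_floor = 0.005,
                       corrective_duration = 0.25,
                       corrective_dispersion = 20,
                       participant_sd = 0.30,
                       duration_sd = 0.15,
                       pos_noise_sd = 1e-4,
                       intertrial_gap = 0.2,
                       block_gap = 2,
                       mode_gap = 5,
                       muscle_latency_offset = c(
                         "upper trapezius"    = -0.26,
                         "anterior deltoid"   = -0.20,
                         "biceps brachii"     = -0.14,
                         "posterior deltoid"  = -0.08,
                         "triceps brachii"    = -0.02
                       ),
                       emg_burst_gain = stats::setNames(rep(10, 5), reach_muscles),
                       mains_amplitude = 0.05,
                       mains_freq = 50,
                       emg_noise_sd = 0.02) {
  if (is.null(conditions)) {
    conditions <- default_conditions()
    if (!is.null(feedback_effect_s)) {
      stopifnot(is.numeric(feedback_effect_s), length(feedback_effect_s) == 1L,
                is.finite(feedback_effect_s), feedback_effect_s >= 0)
      base <- dplyr::filter(conditions, .data$cell == "baseline")
      conditions <- conditions |>
        dplyr::left_join(
          dplyr::select(base, "ball_mode",
                        base_dur = "primary_duration",
                        base_k = "n_corrective_mean"),
          by = "ball_mode"
        ) |>
        dplyr::mutate(
          primary_duration = ifelse(.data$cell == "baseline", .data$base_dur,
                                    .data$base_dur - feedback_effect_s),
          n_corrective_mean = .data$base_k
        ) |>
        dplyr::select(-"base_dur", -"base_k")
    }
  }
  cfg <- structure(list(
    n_participants = as.integer(n_participants),
    sample_rate_traj = sample_rate_traj,
    sample_rate_emg = sample_rate_emg,
    ball_modes = ball_modes,
    protocol = protocol,
    conditions = conditions,
    target_radius = c(small = target_radius_small,
                      big = 2 * target_radius_small),
    mean_distance = mean_distance,
    corrective_amplitude = corrective_amplitude,
    corrective_rel = corrective_rel,
    corrective_decay = corrective_decay,
    corrective_floor = corrective_floor,
    corrective_duration = corrective_duration,
    corrective_dispersion = corrective_dispersion,
    participant_sd = participant_sd,
    duration_sd = duration_sd,
    pos_noise_sd = pos_noise_sd,
    intertrial_gap = intertrial_gap,
    block_gap = block_gap,
    mode_gap = mode_gap,
    muscle_latency_offset = muscle_latency_offset,
    emg_burst_gain = emg_burst_gain,
    mains_amplitude = mains_amplitude,
    mains_freq = mains_freq,
    emg_noise_sd = emg_noise_sd
  ), class = "sim_config")
  validate_sim_config(cfg)
  cfg
}

validate_sim_config <- function(cfg) {
  pos <- c("sample_rate_traj", "sample_rate_emg", "corrective_rel",
           "corrective_floor", "corrective_duration",
           "corrective_dispersion", "intertrial_gap")
  for (f in pos) {
    v <- cfg[[f]]
    if (!is.numeric(v) || length(v) != 1L || !is.finite(v) || v <= 0) {
      rlang::abort(paste0("`", f, "` must be a single positive finite number."))
    }
  }
  if (cfg$n_participants < 1L) {
    rlang::abort("`n_participants` must be at least 1.")
  }
  if (!all(cfg$ball_modes %in% c("big", "small"))) {
    rlang::abort("`ball_modes` must be a subset of {'big', 'small'}.")
  }
  if (cfg$corrective_decay <= 0 || cfg$corrective_decay > 1) {
    rlang::abort("`corrective_decay` must lie in (0, 1].")
  }
  proto <- cfg$protocol
  need <- c("block", "phase", "feedback", "n_segments")
  if (!all(need %in% names(proto))) {
    rlang::abort("`protocol` must have columns block, phase, feedback, n_segments.")
  }
  if (!all(proto$phase %in% c("baseline", "training", "retention"))) {
    rlang::abort("protocol phases must be baseline/training/retention.")
  }
  if (!all(proto$feedback %in% c("none", "TV", "TH", "TM"))) {
    rlang::abort("protocol feedback labels must be none/TV/TH/TM.")
  }
  if (any(proto$n_segments < 1L)) {
    rlang::abort("every protocol block needs at least one segment.")
  }
  # every (ball_mode, analysis cell) in use must be parameterised
  cells <- unique(analysis_cell(proto$phase, proto$feedback))
  cells <- cells[!is.na(cells)]
  cells <- union(cells, unique(proto$feedback[proto$phase == "training"]))
  want <- tidyr::expand_grid(ball_mode = cfg$ball_modes, cell = cells)
  have <- dplyr::semi_join(want, cfg$conditions, by = c("ball_mode", "cell"))
  if (nrow(have) < nrow(want)) {
    miss <- dplyr::anti_join(want, cfg$conditions, by = c("ball_mode", "cell"))
    rlang::abort(paste0(
      "`conditions` is missing cells: ",
      paste(miss$ball_mode, miss$cell, sep = "/", collapse = ", ")
    ))
  }
  if (any(cfg$conditions$primary_duration <= 0) ||
      any(cfg$conditions$n_corrective_mean < 0)) {
    rlang::abort("condition durations must be positive and corrective means nonnegative.")
  }
  if (!setequal(names(cfg$muscle_latency_offset), reach_muscles) ||
      !setequal(names(cfg$emg_burst_gain), reach_muscles)) {
    rlang::abort(paste0(
      "muscle parameter names must be exactly: ",
      paste(reach_muscles, collapse = ", ")
    ))
  }
  if (!all(cfg$ball_modes %in% names(cfg$mean_distance))) {
    rlang::abort("`mean_distance` must name every ball mode in use.")
  }
  invisible(cfg)
}

#' Map phase/feedback labels to analysis cells
#'
#' The statistical design compares baseline against each feedback's retention
#' block. Baseline maps to `"baseline"`, retention blocks map to their
#' feedback label (`"TV"`, `"TH"`, `"TM"`), and training blocks map to `NA`
#' (excluded from inference).
#'
#' @param phase,feedback Character vectors of equal length.
#' @return Character vector of analysis-cell labels.
#' @export
analysis_cell <- function(phase, feedback) {
  dplyr::case_when(
    phase == "baseline"  ~ "baseline",
    phase == "retention" ~ feedback,
    .default = NA_character_
  )
}

#' @export
print.sim_config <- function(x, ...) {
  cat("<sim_config>\n")
  cat("  participants:", x$n_participants,
      "| traj", x$sample_rate_traj, "Hz | emg", x$sample_rate_emg, "Hz\n")
  cat("  ball modes:", paste(x$ball_modes, collapse = ", "),
      "| blocks/mode:", nrow(x$protocol),
      "(", paste(x$protocol$n_segments, collapse = "/"), "segments )\n")
  cat("  mean distance (m):",
      paste(names(x$mean_distance), x$mean_distance, sep = "=", collapse = ", "),
      "\n")
  invisible(x)
}
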