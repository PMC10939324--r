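# Synthetic-session generator: minimum-jerk primary reaches plus decaying
# corrective submovements, envelope-modulated band-limited EMG bursts, and a
# protocol-structured event log.

# 8 target centres on a cube, scaled so the mean distance between successive
# randomly ordered targets equals the configured per-mode movement distance.
# For a cube each corner sees 3 neighbours at edge a, 3 at a*sqrt(2), 1 at
# a*sqrt(3): mean consecutive distance = a * (3 + 3*sqrt(2) + sqrt(3)) / 7.
target_grid <- function(mode, config, centre = c(0.45, 0, 0.30)) {
  d <- config$mean_distance[[mode]]
  a <- d / ((3 + 3 * sqrt(2) + sqrt(3)) / 7)
  corners <- as.matrix(expand.grid(x = c(-0.5, 0.5), y = c(-0.5, 0.5),
                                   z = c(-0.5, 0.5))) * a
  sweep(corners, 2, centre, "+")
}

start_position <- function(config, centre = c(0.45, 0, 0.30)) {
  centre + c(-0.12, 0, -0.08)
}

# First corrective amplitude for a reach: fixed when configured, otherwise
# proportional to the reach distance (never below the floor).
corrective_amp <- function(config, start, target) {
  if (!is.null(config$corrective_amplitude)) return(config$corrective_amplitude)
  max(config$corrective_rel * sqrt(sum((target - start)^2)),
      config$corrective_floor)
}

# Submovement decomposition of one segment: a primary minimum-jerk reach,
# then k corrective submovements whose amplitudes decay geometrically (with a
# floor) and whose endpoints alternate around the target along a single
# direction, the last landing on the target centre. The fast decay makes the
# first corrective speed bump the sharply dominant feature of the segment's
# speed envelope; the floor keeps every bump above the 20 mm/s counting
# cutoff. Returns a table of absolute onset times, durations, endpoints and
# path lengths.
segment_submovements <- function(start, target, t0, primary_duration, k,
                                 amplitude, decay, corrective_duration,
                                 floor_amp = 0, direction = NULL) {
  if (k > 0L) {
    if (is.null(amplitude)) amplitude <- floor_amp

    if (is.null(direction)) {
      direction <- stats::rnorm(3)
      direction <- direction / sqrt(sum(direction^2))
    }
    offs <- vapply(seq_len(k + 1L) - 1L, function(i) {
      if (i == k) c(0, 0, 0)
      else direction * (-1)^i * max(amplitude * decay^i, floor_amp)
    }, numeric(3))
    pts <- rbind(start, t(offs) + rep(target, each = k + 1L))
  } else {
    pts <- rbind(start, target)
  }
  nsub <- nrow(pts) - 1L
  durs <- c(primary_duration, rep(corrective_duration, nsub - 1L))
  onsets <- t0 + cumsum(c(0, durs[-nsub]))
  dist <- sqrt(rowSums((pts[-1L, , drop = FALSE] - pts[-nrow(pts), , drop = FALSE])^2))
  # plain list, not a tibble: this sits in the per-segment hot loop
  list(
    t0 = onsets, duration = durs,
    fx = pts[-nrow(pts), 1], fy = pts[-nrow(pts), 2], fz = pts[-nrow(pts), 3],
    tx = pts[-1L, 1], ty = pts[-1L, 2], tz = pts[-1L, 3],
    dist = dist
  )
}

n_subs <- function(subs) length(subs$t0)

bind_subs <- function(sub_list) {
  out <- list()
  for (f in c("t0", "duration", "fx", "fy", "fz", "tx", "ty", "tz", "dist")) {
    out[[f]] <- unlist(lapply(sub_list, `[[`, f), use.names = FALSE)
  }
  out
}

# Evaluate a submovement table on a uniform time grid. Samples outside any
# submovement hold the most recent endpoint. `times` must start at or before
# the first onset.
sample_submovements <- function(subs, times, origin) {
  n <- length(times)
  pos <- matrix(NA_real_, n, 3)
  rate <- 1 / (times[2] - times[1])
  for (i in seq_len(n_subs(subs))) {
    i1 <- max(1L, ceiling((subs$t0[i] - times[1]) * rate - 1e-9) + 1L)
    i2 <- min(n, floor((subs$t0[i] + subs$duration[i] - times[1]) * rate + 1e-9) + 1L)
    if (i2 < i1) next
    # inlined minimum-jerk evaluation (hot loop)
    s <- (times[i1:i2] - subs$t0[i]) / subs$duration[i]
    s[s < 0] <- 0; s[s > 1] <- 1
    shape <- (10 - (15 - 6 * s) * s) * s^3
    pos[i1:i2, 1] <- subs$fx[i] + shape * (subs$tx[i] - subs$fx[i])
    pos[i1:i2, 2] <- subs$fy[i] + shape * (subs$ty[i] - subs$fy[i])
    pos[i1:i2, 3] <- subs$fz[i] + shape * (subs$tz[i] - subs$fz[i])
  }
  # hold positions between movements
  known <- which(!is.na(pos[, 1]))
  if (length(known) == 0L) {
    pos[] <- rep(origin, each = n)
    return(pos)
  }
  if (known[1] > 1L) pos[seq_len(known[1] - 1L), ] <- rep(origin, each = known[1] - 1L)
  nas <- which(is.na(pos[, 1]))
  if (length(nas)) {
    src <- known[findInterval(nas, known)]
    pos[nas, ] <- pos[src, , drop = FALSE]
  }
  pos
}

# Analytic speed of a submovement table on a time grid (sum of the
# closed-form minimum-jerk speed shapes; submovements do not overlap in time).
submovement_speed <- function(subs, times) {
  v <- numeric(length(times))
  rate <- 1 / (times[2] - times[1])
  for (i in seq_len(n_subs(subs))) {
    i1 <- max(1L, ceiling((subs$t0[i] - times[1]) * rate - 1e-9) + 1L)
    i2 <- min(length(times), floor((subs$t0[i] + subs$duration[i] - times[1]) * rate + 1e-9) + 1L)
    if (i2 < i1) next
    v[i1:i2] <- v[i1:i2] +
      minimum_jerk_speed(times[i1:i2] - subs$t0[i], subs$dist[i], subs$duration[i])
  }
  v
}

#' Simulate a single reaching segment
#'
#' Builds one movement segment: a primary minimum-jerk reach of the stated
#' duration toward the target, followed by `n_corrective` corrective
#' submovements of geometrically decaying amplitude (largest first), each
#' lasting `corrective_duration` seconds so that consecutive speed peaks are
#' separated by more than the 150 ms peak-counting rule. Gaussian positional
#' noise is added when `pos_noise_sd > 0`. Uses the current RNG state; wrap in
#' [withr::with_seed()] or `set.seed()` for reproducibility.
#'
#' @param start,target Length-3 positions in metres.
#' @param primary_duration Ballistic submovement duration, seconds.
#' @param n_corrective Number of corrective submovements (`>= 0`).
#' @param config A [sim_config()]; supplies amplitude/decay/duration of the
#'   corrective submovements, the trajectory sample rate and the positional
#'   noise level.
#' @param t0 Segment onset time (target appearance), seconds.
#'
#' @return A list with `positions` (tibble `time`, `x`, `y`, `z`),
#'   `truth` (tibble with the programmed primary duration, corrective count
#'   and total movement duration) and `submovements` (the submovement table).
#' @export
simulate_segment <- function(start, target, primary_duration,
                             n_corrective = 0L, config = sim_config(),
                             t0 = 0) {
  if (any(!is.finite(c(start, target, primary_duration, n_corrective)))) {
    rlang::abort("simulate_segment: all parameters must be finite.")
  }
  subs <- segment_submovements(
    start, target, t0, primary_duration, as.integer(n_corrective),
    corrective_amp(config, start, target), config$corrective_decay,
    config$corrective_duration, config$corrective_floor
  )
  total <- sum(subs$duration)
  rate <- config$sample_rate_traj
  times <- t0 + seq(0, total, by = 1 / rate)
  pos <- sample_submovements(subs, times, start)
  if (config$pos_noise_sd > 0) {
    pos <- pos + stats::rnorm(length(pos), sd = config$pos_noise_sd)
  }
  list(
    positions = tibble::tibble(time = times, x = pos[, 1], y = pos[, 2],
                               z = pos[, 3]),
    truth = tibble::tibble(primary_duration = primary_duration,
                           n_corrective = as.integer(n_corrective),
                           duration = total),
    submovements = tibble::as_tibble(subs)
  )
}

# Build the full per-participant segment schedule (no sampling yet): one row
# per segment with timing, condition labels, target and submovement table.
build_schedule <- function(config, participant_offset) {
  n_seg <- sum(config$protocol$n_segments) * length(config$ball_modes)
  seg <- list(
    trial = integer(n_seg), ball_mode = character(n_seg),
    block = integer(n_seg), phase = character(n_seg),
    feedback = character(n_seg), appear = numeric(n_seg),
    disappear = numeric(n_seg), target_x = numeric(n_seg),
    target_y = numeric(n_seg), target_z = numeric(n_seg),
    primary_duration = numeric(n_seg), n_corrective = integer(n_seg),
    duration = numeric(n_seg)
  )
  sub_list <- vector("list", n_seg)
  transitions <- vector("list", nrow(config$protocol) * length(config$ball_modes))
  t <- 0.5
  i <- 0L
  it <- 0L
  origin <- start_position(config)
  for (mode in config$ball_modes) {
    grid <- target_grid(mode, config)
    hand <- origin
    for (b in seq_len(nrow(config$protocol))) {
      blk <- config$protocol[b, ]
      cell_par <- if (blk$phase == "baseline") "baseline" else blk$feedback
      par <- config$conditions[
        config$conditions$ball_mode == mode & config$conditions$cell == cell_par, ]
      idx <- 1L
      for (s in seq_len(blk$n_segments)) {
        if (s > 1L) {
          idx <- sample(setdiff(1:8, idx), 1L)
        }
        tgt <- grid[idx, ]
        dur <- max(0.4, par$primary_duration + participant_offset +
                     stats::rnorm(1, sd = config$duration_sd))
        # every reach ends with at least one terminal corrective adjustment;
        # the shifted count keeps the configured mean
        k <- 1L + stats::rnbinom(1, size = config$corrective_dispersion,
                                 mu = max(par$n_corrective_mean - 1, 1e-6))
        subs <- segment_submovements(
          hand, tgt, t, dur, k, corrective_amp(config, hand, tgt),
          config$corrective_decay, config$corrective_duration,
          config$corrective_floor
        )
        total <- sum(subs$duration)
        i <- i + 1L
        seg$trial[i] <- i - 1L
        seg$ball_mode[i] <- mode
        seg$block[i] <- blk$block
        seg$phase[i] <- blk$phase
        seg$feedback[i] <- blk$feedback
        seg$appear[i] <- t
        seg$disappear[i] <- t + total
        seg$target_x[i] <- tgt[1]; seg$target_y[i] <- tgt[2]
        seg$target_z[i] <- tgt[3]
        seg$primary_duration[i] <- dur
        seg$n_corrective[i] <- k
        seg$duration[i] <- total
        sub_list[[i]] <- subs
        t <- t + total + config$intertrial_gap
        hand <- tgt
      }
      # smooth return to the start position during the inter-block rest
      ret_dur <- min(1.5, config$block_gap * 0.75)
      it <- it + 1L
      transitions[[it]] <- list(
        t0 = t, duration = ret_dur,
        fx = hand[1], fy = hand[2], fz = hand[3],
        tx = origin[1], ty = origin[2], tz = origin[3],
        dist = sqrt(sum((hand - origin)^2))
      )
      hand <- origin
      t <- t + config$block_gap
    }
    t <- t + config$mode_gap
  }
  list(segments = tibble::as_tibble(seg), sub_list = sub_list,
       transitions = bind_subs(transitions), t_end = t)
}

#' Simulate surface EMG for a session
#'
#' Synthesises the five-channel EMG recording implied by a session speed
#' profile: per channel, baseline Gaussian noise plus a burst of band-limited
#' (20-400 Hz) noise whose amplitude envelope is the speed profile shifted by
#' the muscle's programmed latency offset and scaled by its burst gain, plus a
#' sinusoidal mains component. Uses the current RNG state.
#'
#' @param speed Tibble with columns `time`, `speed`: the session speed
#'   profile. Interpolated onto the EMG grid if sampled at another rate.
#' @param events Event log (used only to determine the time span).
#' @param config A [sim_config()].
#'
#' @return A [as_emg()] recording sampled at `config$sample_rate_emg`.
#' @export
simulate_emg <- function(speed, events, config = sim_config()) {
  t_end <- max(speed$time, events$disappear)
  fs <- config$sample_rate_emg
  times <- seq(0, t_end, by = 1 / fs)
  v <- stats::approx(speed$time, speed$speed, xout = times, method = "linear",
                     rule = 2)$y
  emg_from_envelope(v, times, config)
}

# Core EMG synthesis from a speed envelope already on the EMG grid.
emg_from_envelope <- function(v, times, config) {
  fs <- config$sample_rate_emg
  n <- length(times)
  bf <- signal::butter(4, c(20, 400) / (fs / 2), type = "pass")
  out <- list(time = times)
  for (m in reach_muscles) {
    env <- shift_series(v, round(config$muscle_latency_offset[[m]] * fs))
    sig <- stats::rnorm(n, sd = config$emg_noise_sd)
    gain <- config$emg_burst_gain[[m]]
    if (gain > 0 && any(env > 0)) {
      carrier <- as.numeric(signal::filter(bf, stats::rnorm(n)))
      carrier <- carrier / stats::sd(carrier)
      sig <- sig + gain * env * carrier
    }
    if (config$mains_amplitude > 0) {
      sig <- sig + config$mains_amplitude *
        sin(2 * pi * config$mains_freq * times)
    }
    out[[m]] <- sig
  }
  as_emg(tibble::as_tibble(out), sample_rate = fs)
}

# Shift a series by `lag` samples (positive = delay), zero-padded.
shift_series <- function(x, lag) {
  n <- length(x)
  if (lag == 0) return(x)
  out <- numeric(n)
  if (lag > 0) out[(lag + 1):n] <- x[1:(n - lag)]
  else out[1:(n + lag)] <- x[(1 - lag):n]
  out
}

#' Simulate a complete reaching session
#'
#' Generates one participant's session: trajectory, EMG, event log and the
#' ground-truth record of programmed parameters. Per ball mode the protocol
#' template is emitted in order (by default 16/24/16/24/16/24/16 segments);
#' each block's first target is the fixed first position and the remaining
#' targets are drawn in randomised order without immediate repeats. Output is
#' deterministic given `(seed, participant)`.
#'
#' @param config A [sim_config()].
#' @param participant 1-based participant index; combined with `seed` to give
#'   each participant an independent, reproducible substream.
#' @param seed Integer seed for the session.
#' @param components Which heavyweight components to generate: any of
#'   `"trajectory"`, `"emg"`. The event log and truth tables are always
#'   produced.
#'
#' @return A list of class `sim_session` with elements `trajectory`
#'   ([as_trajectory()] tibble or `NULL`), `emg` ([as_emg()] tibble or
#'   `NULL`), `events` ([as_events()] tibble), `truth` (one row per segment:
#'   programmed primary duration, corrective count, movement duration) and
#'   `truth_latency` (one row per segment x muscle: programmed EMG peak
#'   latency in seconds, present when `"emg"` is generated).
#' @export
simulate_session <- function(config = sim_config(), participant = 1L,
                             seed = 1L,
                             components = c("trajectory", "emg")) {
  validate_sim_config(config)
  components <- match.arg(components, c("trajectory", "emg"),
                          several.ok = TRUE)
  set.seed(as.integer((as.numeric(seed) + 104729 * participant) %% 2147483647))
  p_off <- stats::rnorm(1, sd = config$participant_sd)
  sched <- build_schedule(config, p_off)
  seg <- sched$segments
  events <- as_events(seg[c("trial", "appear", "disappear", "target_x",
                            "target_y", "target_z", "ball_mode", "phase",
                            "feedback")])
  truth <- dplyr::mutate(
    seg[c("trial", "ball_mode", "block", "phase", "feedback", "appear",
          "disappear", "primary_duration", "n_corrective", "duration")],
    cell = analysis_cell(.data$phase, .data$feedback)
  )
  all_subs <- bind_subs(c(sched$sub_list, list(sched$transitions)))
  ord <- order(all_subs$t0)
  all_subs <- lapply(all_subs, `[`, ord)

  trajectory <- NULL
  if ("trajectory" %in% components) {
    rate <- config$sample_rate_traj
    times <- seq(0, sched$t_end, by = 1 / rate)
    pos <- sample_submovements(all_subs, times, start_position(config))
    if (config$pos_noise_sd > 0) {
      pos <- pos + stats::rnorm(length(pos), sd = config$pos_noise_sd)
    }
    trajectory <- as_trajectory(
      tibble::tibble(time = times, x = pos[, 1], y = pos[, 2], z = pos[, 3]),
      sample_rate = rate
    )
  }

  emg <- NULL
  truth_latency <- NULL
  if ("emg" %in% components) {
    fs <- config$sample_rate_emg
    etimes <- seq(0, sched$t_end, by = 1 / fs)
    v <- submovement_speed(all_subs, etimes)
    emg <- emg_from_envelope(v, etimes, config)
    truth_latency <- programmed_latency(v, etimes, seg, config)
  }

  structure(list(trajectory = trajectory, emg = emg, events = events,
                 truth = truth, truth_latency = truth_latency,
                 participant = as.integer(participant), seed = seed),
            class = "sim_session")
}

# Programmed per-segment, per-muscle peak latency: the argmax time of the
# latency-shifted speed envelope restricted to the segment window, minus the
# appearance time.
programmed_latency <- function(v, etimes, seg, config) {
  fs <- config$sample_rate_emg
  res <- vector("list", length(reach_muscles))
  for (mi in seq_along(reach_muscles)) {
    m <- reach_muscles[mi]
    env <- shift_series(v, round(config$muscle_latency_offset[[m]] * fs))
    lat <- numeric(nrow(seg))
    for (i in seq_len(nrow(seg))) {
      i1 <- max(1L, ceiling(seg$appear[i] * fs - 1e-9) + 1L)
      i2 <- min(length(etimes), floor(seg$disappear[i] * fs + 1e-9) + 1L)
      lat[i] <- etimes[i1 + which.max(env[i1:i2]) - 1L] - seg$appear[i]
    }
    res[[mi]] <- tibble::tibble(trial = seg$trial, muscle = m, latency = lat)
  }
  dplyr::bind_rows(res)
}

#' @export
print.sim_session <- function(x, ...) {
  cat("<sim_session> participant", x$participant, "seed", x$seed, "\n")
  cat("  ", nrow(x$events), "segments;",
      if (is.null(x$trajectory)) "no trajectory;" else
        paste0(nrow(x$trajectory), " trajectory samples;"),
      if (is.null(x$emg)) "no EMG" else paste0(nrow(x$emg), " EMG samples"),
      "\n")
  invisible(x)
}
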