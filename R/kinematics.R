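# Velocity-profile kinematics: speed profiles, the five per-segment
# variables (movement time, mean velocity, peak velocity, time to peak,
# velocity peak number) and condition-level summaries.

#' Zero-phase low-pass smoothing of a trajectory
#'
#' Applies a 2nd-order Butterworth low-pass, forward-backward (zero phase),
#' to each position coordinate. Peak counting is sensitive to quantisation
#' spikes in differentiated position data, so the analysis pipeline smooths
#' positions before differentiation by default (10 Hz cutoff).
#'
#' @param traj Trajectory tibble.
#' @param cutoff Low-pass cutoff in Hz, or `NULL` to return `traj` unchanged.
#' @return The smoothed trajectory.
#' @export
smooth_trajectory <- function(traj, cutoff = 10) {
  if (is.null(cutoff)) return(traj)
  fs <- sample_rate(traj)
  if (cutoff >= fs / 2) {
    rlang::abort("smoothing cutoff must be below the Nyquist frequency.")
  }
  bf <- signal::butter(2, cutoff / (fs / 2), type = "low")
  for (col in c("x", "y", "z")) {
    traj[[col]] <- filtfilt_pad(bf, traj[[col]])
  }
  traj
}

# Central finite differences with one-sided boundary stencils, per column.
central_diff <- function(p, dt) {
  n <- length(p)
  c(p[2] - p[1], (p[3:n] - p[1:(n - 2)]) / 2, p[n] - p[n - 1]) / dt
}

#' Speed profile of a movement segment
#'
#' Differentiates the 3-D position samples (central differences in the
#' interior, one-sided at the boundaries) and takes the Euclidean norm.
#' Optionally low-pass filters the positions (zero-phase) before
#' differentiation.
#'
#' @param seg Tibble with columns `time`, `x`, `y`, `z` on a uniform grid
#'   (at least 4 samples).
#' @param smoothing_cutoff Optional low-pass cutoff (Hz) applied to positions
#'   before differentiation; `NULL` for none.
#' @return A tibble of class `reach_speed` with columns `time`, `speed`
#'   (m/s).
#' @export
speed_profile <- function(seg, smoothing_cutoff = NULL) {
  if (nrow(seg) < 4L) rlang::abort("a speed profile needs at least 4 samples.")
  dt <- diff(seg$time)
  rate <- 1 / stats::median(dt)
  check_uniform_grid(seg$time, rate, what = "segment")
  if (!is.null(smoothing_cutoff)) {
    bf <- signal::butter(2, smoothing_cutoff / (rate / 2), type = "low")
    for (col in c("x", "y", "z")) {
      seg[[col]] <- filtfilt_pad(bf, seg[[col]])
    }
  }
  d <- 1 / rate
  vx <- central_diff(seg$x, d)
  vy <- central_diff(seg$y, d)
  vz <- central_diff(seg$z, d)
  structure(tibble::tibble(time = seg$time,
                           speed = sqrt(vx^2 + vy^2 + vz^2)),
            class = c("reach_speed", class(tibble::tibble())))
}

#' Movement time of a segment
#'
#' Time required to complete one movement segment: the target's disappearance
#' time minus its appearance time.
#'
#' @param trial A one-row event tibble (or any list with `appear`,
#'   `disappear`).
#' @return Seconds.
#' @export
movement_time <- function(trial) {
  trial$disappear - trial$appear
}

#' Mean velocity of a speed profile
#'
#' Arithmetic mean of the speed samples over the segment; for a straight
#' reach this approximates path length divided by duration.
#'
#' @param sp A `reach_speed` tibble.
#' @return m/s.
#' @export
mean_velocity <- function(sp) {
  if (nrow(sp) == 0L) rlang::abort("empty speed profile.")
  mean(sp$speed)
}

#' Peak velocity and its time
#'
#' Maximum speed sample in the segment; plateau ties are broken by the
#' earliest time.
#'
#' @param sp A `reach_speed` tibble.
#' @return Named list with `v_peak` (m/s) and `t_at_peak` (seconds).
#' @export
peak_velocity <- function(sp) {
  if (nrow(sp) == 0L) rlang::abort("empty speed profile.")
  i <- which.max(sp$speed)
  list(v_peak = sp$speed[i], t_at_peak = sp$time[i])
}

#' Time to peak velocity
#'
#' Time from the appearance of the target to the moment peak velocity is
#' recorded; splits the reach into its ballistic and correction phases.
#'
#' @param trial A one-row event tibble with `appear`.
#' @param sp The segment's speed profile.
#' @return Seconds.
#' @export
time_to_peak <- function(trial, sp) {
  peak_velocity(sp)$t_at_peak - trial$appear
}

#' Count velocity peaks (movement-smoothness index)
#'
#' Scans the speed profile for alternating local minima and maxima (the
#' segment start is treated as the initial minimum). A maximum is a candidate
#' peak when it rises more than `amplitude_cutoff` above the preceding
#' minimum; candidates are then accepted greedily in time order, requiring at
#' least `min_separation` since the last accepted peak. Fewer peaks indicate
#' a smoother movement.
#'
#' @param sp A `reach_speed` tibble (columns `time`, `speed`).
#' @param amplitude_cutoff Minimum rise above the preceding minimum, m/s
#'   (default 0.020, i.e. 20 mm/s).
#' @param min_separation Minimum time between accepted peaks, seconds
#'   (default 0.150).
#' @return Integer peak count.
#' @export
count_velocity_peaks <- function(sp, amplitude_cutoff = 0.020,
                                 min_separation = 0.150) {
  if (nrow(sp) == 0L) rlang::abort("empty speed profile.")
  count_peaks_vec(sp$time, sp$speed, amplitude_cutoff, min_separation)
}

# vector core of the peak count (hot loop)
count_peaks_vec <- function(times, speed, amplitude_cutoff, min_separation) {
  ex <- alternating_extrema(speed)
  n_acc <- 0L
  last_t <- -Inf
  prev_min <- NA_real_
  for (j in seq_along(ex$value)) {
    if (ex$type[j] < 0L) {
      prev_min <- ex$value[j]
    } else if (!is.na(prev_min) &&
               ex$value[j] - prev_min > amplitude_cutoff) {
      tj <- times[ex$index[j]]
      if (tj - last_t >= min_separation - 1e-9) {
        n_acc <- n_acc + 1L
        last_t <- tj
      }
    }
  }
  n_acc
}

# Alternating minima/maxima of a sampled profile, as a plain list
# (index, value, type) with type -1 = minimum, +1 = maximum. Plateaus are
# compressed to their first sample; the profile start is forced to be the
# initial minimum; a rising final run ends in a maximum. Consecutive
# same-type extrema are merged keeping the more extreme value (earlier
# sample on ties).
alternating_extrema <- function(y) {
  keep <- c(TRUE, diff(y) != 0)
  idx <- which(keep)
  yv <- y[idx]
  m <- length(yv)
  if (m == 1L) {
    return(list(index = idx[1], value = yv[1], type = -1L))
  }
  type <- integer(m)
  type[1] <- -1L  # contract: segment start is the initial minimum
  if (m > 2L) {
    mid <- 2:(m - 1L)
    up <- yv[mid] > yv[mid - 1L] & yv[mid] > yv[mid + 1L]
    dn <- yv[mid] < yv[mid - 1L] & yv[mid] < yv[mid + 1L]
    type[mid] <- ifelse(up, 1L, ifelse(dn, -1L, 0L))
  }
  type[m] <- if (yv[m] > yv[m - 1L]) 1L else -1L
  sel <- type != 0L
  idx <- idx[sel]; yv <- yv[sel]; type <- type[sel]
  # enforce alternation (preallocated stack)
  nn <- length(yv)
  oi <- integer(nn); ov <- numeric(nn); ot <- integer(nn)
  k <- 0L
  for (j in seq_len(nn)) {
    if (k > 0L && ot[k] == type[j]) {
      better <- if (type[j] < 0L) yv[j] < ov[k] else yv[j] > ov[k]
      if (better) { ov[k] <- yv[j]; oi[k] <- idx[j] }
    } else {
      k <- k + 1L
      oi[k] <- idx[j]; ov[k] <- yv[j]; ot[k] <- type[j]
    }
  }
  list(index = oi[seq_len(k)], value = ov[seq_len(k)], type = ot[seq_len(k)])
}

#' Per-segment kinematic features
#'
#' Computes the five kinematic variables for every segment: movement time
#' (s), mean velocity (m/s), peak velocity (m/s), time to peak (s) and
#' velocity peak number.
#'
#' @param segments Output of [segment_session()].
#' @param smoothing_cutoff Position low-pass cutoff (Hz) applied per segment
#'   before differentiation, or `NULL`.
#' @param amplitude_cutoff,min_separation Peak-counting parameters, see
#'   [count_velocity_peaks()].
#' @return A tibble with one row per segment: the trial metadata plus
#'   `movement_time`, `v_avg`, `v_peak`, `time_to_peak`, `n_peak`.
#' @export
kinematic_features <- function(segments, smoothing_cutoff = 10,
                               amplitude_cutoff = 0.020,
                               min_separation = 0.150) {
  feats <- purrr::map(segments$data, function(d) {
    sp <- speed_profile(d, smoothing_cutoff = smoothing_cutoff)
    pk <- peak_velocity(sp)
    tibble::tibble(
      v_avg = mean_velocity(sp),
      v_peak = pk$v_peak,
      t_at_peak = pk$t_at_peak,
      n_peak = count_velocity_peaks(sp, amplitude_cutoff, min_separation)
    )
  })
  out <- dplyr::bind_cols(
    segments[setdiff(names(segments), "data")],
    dplyr::bind_rows(feats)
  )
  out$movement_time <- out$disappear - out$appear
  out$time_to_peak <- out$t_at_peak - out$appear
  out[c("trial", "ball_mode", "phase", "feedback", "cell",
        "movement_time", "v_avg", "v_peak", "time_to_peak", "n_peak")]
}

#' Segment features straight from a session (fast path)
#'
#' Equivalent pipeline to [segment_session()] + [kinematic_features()], but
#' the position low-pass is applied once to the continuous recording before
#' segmentation and the speed is differentiated once over the whole session.
#' Filtering the continuous signal avoids per-segment filter transients and
#' is much faster for whole-cohort simulations.
#'
#' @param traj Trajectory tibble.
#' @param events Event log.
#' @inheritParams kinematic_features
#' @return As [kinematic_features()].
#' @export
analyze_kinematics <- function(traj, events, smoothing_cutoff = 10,
                               amplitude_cutoff = 0.020,
                               min_separation = 0.150) {
  rate <- sample_rate(traj)
  traj <- smooth_trajectory(traj, smoothing_cutoff)
  d <- 1 / rate
  vx <- central_diff(traj$x, d)
  vy <- central_diff(traj$y, d)
  vz <- central_diff(traj$z, d)
  speed <- sqrt(vx^2 + vy^2 + vz^2)
  idx <- segment_indices(traj$time, events, rate)
  t0 <- traj$time[1]
  tn <- traj$time[nrow(traj)]
  n <- nrow(events)
  v_avg <- v_peak <- t_at_peak <- numeric(n)
  n_peak <- integer(n)
  for (i in seq_len(n)) {
    if (events$appear[i] < t0 - 1e-9 || events$disappear[i] > tn + 1e-9) {
      rlang::abort(paste0("trial ", events$trial[i],
                          " is not covered by the trajectory."))
    }
    ii <- idx$first[i]:idx$last[i]
    if (length(ii) < 4L) {
      rlang::abort(paste0("trial ", events$trial[i], ": degenerate segment."))
    }
    ts <- traj$time[ii]
    vs <- speed[ii]
    pk <- which.max(vs)
    v_avg[i] <- mean(vs)
    v_peak[i] <- vs[pk]
    t_at_peak[i] <- ts[pk]
    n_peak[i] <- count_peaks_vec(ts, vs, amplitude_cutoff, min_separation)
  }
  out <- events[c("trial", "ball_mode", "phase", "feedback", "cell")]
  out$movement_time <- events$disappear - events$appear
  out$v_avg <- v_avg
  out$v_peak <- v_peak
  out$time_to_peak <- t_at_peak - events$appear
  out$n_peak <- n_peak
  out
}

#' Condition-level feature summaries
#'
#' Averages each kinematic feature over the segments of every
#' (participant,) ball mode and analysis cell, mirroring the design in which
#' each block's segments are averaged to remove path-length variation.
#' Training segments (cell `NA`) are excluded.
#'
#' @param features Per-segment feature tibble ([kinematic_features()] or
#'   [analyze_kinematics()]), optionally with a `participant` column.
#' @return A tibble with one row per (participant x) ball mode x cell:
#'   per-feature means and the segment count `n_segments`.
#' @export
summarize_features <- function(features) {
  features <- dplyr::filter(features, !is.na(.data$cell))
  if (nrow(features) == 0L) {
    rlang::abort("no analysable segments (all cells are training).")
  }
  grp <- intersect(c("participant", "ball_mode", "cell"), names(features))
  out <- features |>
    dplyr::group_by(dplyr::across(dplyr::all_of(grp))) |>
    dplyr::summarise(
      dplyr::across(dplyr::all_of(c("movement_time", "v_avg", "v_peak",
                                    "time_to_peak", "n_peak")), mean),
      n_segments = dplyr::n(), .groups = "drop"
    )
  cells <- unique(features$cell)
  want <- tidyr::expand_grid(ball_mode = unique(features$ball_mode),
                             cell = cells)
  have <- dplyr::distinct(out, .data$ball_mode, .data$cell)
  miss <- dplyr::anti_join(want, have, by = c("ball_mode", "cell"))
  if (nrow(miss)) {
    rlang::abort(paste0("cells with zero segments: ",
                        paste(miss$ball_mode, miss$cell, sep = "/",
                              collapse = ", ")))
  }
  out
}
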