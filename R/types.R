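#' Construct a trajectory table
#'
#' A trajectory is a tibble with columns `time` (seconds, strictly increasing
#' uniform grid), `x`, `y`, `z` (metres) and a `sample_rate` attribute.
#'
#' @param df Data frame with columns `time`, `x`, `y`, `z`.
#' @param sample_rate Sampling rate in Hz; inferred from the time grid when
#'   `NULL`.
#' @return A tibble of class `reach_trajectory`.
#' @export
as_trajectory <- function(df, sample_rate = NULL) {
  need <- c("time", "x", "y", "z")
  if (!all(need %in% names(df))) {
    rlang::abort("a trajectory needs columns time, x, y, z.")
  }
  df <- tibble::as_tibble(df)[need]
  if (nrow(df) < 2L) rlang::abort("a trajectory needs at least 2 samples.")
  dt <- diff(df$time)
  if (any(dt <= 0)) rlang::abort("trajectory time must be strictly increasing.")
  if (is.null(sample_rate)) sample_rate <- 1 / stats::median(dt)
  check_uniform_grid(df$time, sample_rate, what = "trajectory")
  structure(df, sample_rate = sample_rate,
            class = c("reach_trajectory", class(tibble::tibble())))
}

#' Construct an EMG recording table
#'
#' An EMG recording is a tibble with a `time` column (seconds) and one column
#' per muscle channel (millivolts), plus a `sample_rate` attribute.
#'
#' @param df Data frame with `time` plus channel columns.
#' @param sample_rate Sampling rate in Hz; inferred when `NULL`.
#' @return A tibble of class `reach_emg`.
#' @export
as_emg <- function(df, sample_rate = NULL) {
  if (!"time" %in% names(df)) rlang::abort("an EMG recording needs a `time` column.")
  channels <- setdiff(names(df), "time")
  if (length(channels) < 1L) rlang::abort("an EMG recording needs at least one channel.")
  if (anyDuplicated(channels)) {
    rlang::abort("duplicate channel labels in EMG recording.")
  }
  df <- tibble::as_tibble(df)[c("time", channels)]
  dt <- diff(df$time)
  if (any(dt <= 0)) rlang::abort("EMG time must be strictly increasing.")
  if (is.null(sample_rate)) sample_rate <- 1 / stats::median(dt)
  check_uniform_grid(df$time, sample_rate, what = "EMG recording")
  structure(df, sample_rate = sample_rate, channels = channels,
            class = c("reach_emg", class(tibble::tibble())))
}

#' Sampling rate of a trajectory or EMG recording
#' @param x A `reach_trajectory` or `reach_emg` object.
#' @return Sampling rate in Hz.
#' @export
sample_rate <- function(x) {
  sr <- attr(x, "sample_rate")
  if (is.null(sr)) {
    if (!"time" %in% names(x) || nrow(x) < 2L) {
      rlang::abort("cannot infer a sample rate from this object.")
    }
    sr <- 1 / stats::median(diff(x$time))
  }
  sr
}

#' Channel labels of an EMG recording
#' @param x A `reach_emg` object (or any tibble with a `time` column).
#' @return Character vector of channel names.
#' @export
emg_channels <- function(x) {
  ch <- attr(x, "channels")
  if (is.null(ch)) ch <- setdiff(names(x), "time")
  ch
}

#' Construct and validate a trial event log
#'
#' The event log is the segmentation authority: one row per movement segment
#' with the target's appearance and disappearance times, target position and
#' condition labels. Intervals must be chronologically ordered and pairwise
#' disjoint, and `trial` indices consecutive from 0.
#'
#' @param df Data frame with columns `trial`, `appear`, `disappear`,
#'   `target_x`, `target_y`, `target_z`, `ball_mode`, `phase`, `feedback`.
#' @return A tibble of class `reach_events`, with an added `cell` column
#'   giving the analysis cell (see [analysis_cell()]).
#' @export
as_events <- function(df) {
  need <- c("trial", "appear", "disappear", "target_x", "target_y",
            "target_z", "ball_mode", "phase", "feedback")
  miss <- setdiff(need, names(df))
  if (length(miss)) {
    rlang::abort(paste0("event log is missing columns: ",
                        paste(miss, collapse = ", ")))
  }
  df <- tibble::as_tibble(df)
  bad_mode <- setdiff(unique(df$ball_mode), c("big", "small"))
  if (length(bad_mode)) {
    rlang::abort(paste0("unknown ball_mode: ", paste(bad_mode, collapse = ", "),
                        " (allowed: big, small)"))
  }
  bad_ph <- setdiff(unique(df$phase), c("baseline", "training", "retention"))
  if (length(bad_ph)) {
    rlang::abort(paste0("unknown phase: ", paste(bad_ph, collapse = ", "),
                        " (allowed: baseline, training, retention)"))
  }
  bad_fb <- setdiff(unique(df$feedback), c("none", "TV", "TH", "TM"))
  if (length(bad_fb)) {
    rlang::abort(paste0("unknown feedback: ", paste(bad_fb, collapse = ", "),
                        " (allowed: none, TV, TH, TM)"))
  }
  if (any(df$appear >= df$disappear)) {
    i <- which(df$appear >= df$disappear)[1]
    rlang::abort(paste0("trial ", df$trial[i], ": appear must precede disappear."))
  }
  if (is.unsorted(df$appear, strictly = TRUE)) {
    rlang::abort("trials must be in chronological order.")
  }
  if (nrow(df) > 1L && any(df$appear[-1] < df$disappear[-nrow(df)])) {
    i <- which(df$appear[-1] < df$disappear[-nrow(df)])[1]
    rlang::abort(paste0("trial intervals overlap between trials ",
                        df$trial[i], " and ", df$trial[i + 1], "."))
  }
  if (!identical(as.integer(df$trial), seq_len(nrow(df)) - 1L)) {
    rlang::abort("trial indices must be consecutive from 0.")
  }
  df$trial <- as.integer(df$trial)
  df$cell <- analysis_cell(df$phase, df$feedback)
  structure(df, class = c("reach_events", class(tibble::tibble())))
}

# Zero-phase filtering with odd-reflection end padding. signal::filtfilt
# zero-pads internally, which produces large edge transients whenever a
# signal does not start or end near zero; reflecting the signal about its
# endpoints (as MATLAB's filtfilt does) removes them.
filtfilt_pad <- function(flt, x) {
  n <- length(x)
  np <- min(n - 1L, 300L)
  if (np < 1L) return(as.numeric(signal::filtfilt(flt, x)))
  ext <- c(2 * x[1] - x[(np + 1L):2L], x, 2 * x[n] - x[(n - 1L):(n - np)])
  y <- as.numeric(signal::filtfilt(flt, ext))
  y[(np + 1L):(np + n)]
}

check_uniform_grid <- function(times, rate, tol = 0.01, what = "series") {
  dt <- diff(times)
  target <- 1 / rate
  dev <- abs(dt - target) / target
  if (any(dev > tol)) {
    i <- which(dev > tol)[1]
    rlang::abort(paste0(
      what, " time grid is not uniform at ", rate, " Hz: step ",
      signif(dt[i], 6), " s between samples ", i, " and ", i + 1, "."
    ))
  }
  invisible(times)
}
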