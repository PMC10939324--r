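#' Cut a session trajectory into per-trial movement segments
#'
#' A movement segment runs from a target's appearance to its disappearance
#' (hand contact); the event log is authoritative, so no velocity-threshold
#' onset detection is performed. Samples on the closed interval
#' `[appear, disappear]` (boundary samples included) belong to the segment;
#' inter-trial samples are discarded.
#'
#' @param traj A trajectory tibble ([as_trajectory()]).
#' @param events An event log ([as_events()]).
#'
#' @return A tibble with one row per trial, in event order: the trial's
#'   metadata (`trial`, `appear`, `disappear`, `ball_mode`, `phase`,
#'   `feedback`, `cell`), `n_samples`, and a `data` list-column of per-segment
#'   sample tibbles (`time`, `x`, `y`, `z`).
#' @export
segment_session <- function(traj, events) {
  rate <- sample_rate(traj)
  t0 <- traj$time[1]
  tn <- traj$time[nrow(traj)]
  idx <- segment_indices(traj$time, events, rate)
  data <- vector("list", nrow(events))
  for (i in seq_len(nrow(events))) {
    if (events$appear[i] < t0 - 1e-9 || events$disappear[i] > tn + 1e-9) {
      rlang::abort(paste0(
        "trial ", events$trial[i], " [", events$appear[i], ", ",
        events$disappear[i], "] s is not covered by the trajectory [",
        t0, ", ", tn, "] s."))
    }
    ii <- idx$first[i]:idx$last[i]
    if (length(ii) < 4L) {
      rlang::abort(paste0("trial ", events$trial[i], ": degenerate segment (",
                          length(ii), " samples, need >= 4)."))
    }
    data[[i]] <- traj[ii, c("time", "x", "y", "z")]
  }
  out <- events[c("trial", "appear", "disappear", "ball_mode", "phase",
                  "feedback", "cell")]
  out$n_samples <- idx$last - idx$first + 1L
  out$data <- data
  out
}

# First/last sample indices of each closed event interval on a uniform grid.
segment_indices <- function(times, events, rate) {
  t0 <- times[1]
  first <- pmax(1L, as.integer(ceiling((events$appear - t0) * rate - 1e-6)) + 1L)
  last <- pmin(length(times),
               as.integer(floor((events$disappear - t0) * rate + 1e-6)) + 1L)
  list(first = first, last = last)
}

#' Select the first movement segment of a condition
#'
#' Returns the chronologically first trial matching the given selectors; used
#' for the EMG peak-latency statistic, which is defined on the first segment
#' of a block because only the first target position is common across
#' conditions.
#'
#' @param events An event log.
#' @param ball_mode,phase,feedback,cell Optional selectors; `NULL` matches
#'   anything. `cell` selects on the analysis cell (see [analysis_cell()]).
#' @return A one-row tibble (the matching trial event).
#' @export
first_segment <- function(events, ball_mode = NULL, phase = NULL,
                          feedback = NULL, cell = NULL) {
  m <- rep(TRUE, nrow(events))
  if (!is.null(ball_mode)) m <- m & events$ball_mode == ball_mode
  if (!is.null(phase)) m <- m & events$phase == phase
  if (!is.null(feedback)) m <- m & events$feedback == feedback
  if (!is.null(cell)) m <- m & !is.na(events$cell) & events$cell == cell
  if (!any(m)) {
    rlang::abort(paste0(
      "no trial matches selector (ball_mode=", ball_mode %||% "*",
      ", phase=", phase %||% "*", ", feedback=", feedback %||% "*",
      ", cell=", cell %||% "*", ")."))
  }
  events[which(m)[1], ]
}
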