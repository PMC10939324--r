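# Surface-EMG preprocessing (Butterworth band-pass + mains notch, both
# zero-phase) and the peak-latency statistic.

#' EMG filter specification
#'
#' Band-pass plus mains-notch chain applied to every channel. Both filters
#' are applied forward-backward (zero phase): the statistic of interest is a
#' latency, so phase distortion must not bias peak times. The notch is a
#' 2nd-order Butterworth band-stop of width `notch_freq / notch_quality`.
#'
#' @param bandpass_low,bandpass_high Band-pass corner frequencies, Hz
#'   (defaults 20 and 400).
#' @param notch_freq Mains frequency to remove, Hz (default 50; set 60 for
#'   data recorded on 60 Hz mains).
#' @param order Butterworth design order of the band-pass (default 4).
#' @param notch_quality Quality factor Q of the notch (default 30).
#' @return A list of class `filter_spec`.
#' @export
filter_spec <- function(bandpass_low = 20, bandpass_high = 400,
                        notch_freq = 50, order = 4, notch_quality = 30) {
  if (!(bandpass_low > 0 && bandpass_low < bandpass_high)) {
    rlang::abort("need 0 < bandpass_low < bandpass_high.")
  }
  structure(list(bandpass_low = bandpass_low, bandpass_high = bandpass_high,
                 notch_freq = notch_freq, order = order,
                 notch_quality = notch_quality, family = "butterworth"),
            class = "filter_spec")
}

filter_channel <- function(x, spec, fs) {
  nyq <- fs / 2
  bp <- signal::butter(spec$order,
                       c(spec$bandpass_low, spec$bandpass_high) / nyq,
                       type = "pass")
  x <- filtfilt_pad(bp, x)
  if (!is.null(spec$notch_freq) && spec$notch_freq > 0) {
    bw <- spec$notch_freq / spec$notch_quality
    ns <- signal::butter(2, c(spec$notch_freq - bw / 2,
                              spec$notch_freq + bw / 2) / nyq, type = "stop")
    x <- filtfilt_pad(ns, x)
  }
  x
}

#' Preprocess an EMG recording
#'
#' Applies the zero-phase band-pass then zero-phase notch of `spec` to every
#' channel; the time grid and channel labels are unchanged.
#'
#' @param emg An EMG recording ([as_emg()]).
#' @param spec A [filter_spec()].
#' @return The filtered recording.
#' @export
preprocess_emg <- function(emg, spec = filter_spec()) {
  fs <- sample_rate(emg)
  if (fs <= 2 * spec$bandpass_high) {
    rlang::abort(paste0(
      "band-pass upper cutoff ", spec$bandpass_high,
      " Hz violates the Nyquist limit of a ", fs, " Hz recording."))
  }
  for (ch in emg_channels(emg)) {
    emg[[ch]] <- filter_channel(emg[[ch]], spec, fs)
  }
  emg
}

#' Moving-RMS envelope of a signal
#'
#' Root-mean-square of the signal over a centred window; windows are
#' truncated at the signal edges. This turns the band-passed interference
#' signal into a smooth nonnegative activation envelope whose argmax is a
#' stable peak-time estimate.
#'
#' @param x Numeric signal.
#' @param sample_rate Sampling rate, Hz.
#' @param window Window length in seconds (default 0.050); must span at
#'   least 2 samples and no more than the signal.
#' @return Nonnegative numeric vector, same length as `x`.
#' @export
emg_envelope <- function(x, sample_rate, window = 0.050) {
  w <- round(window * sample_rate)
  if (w < 2L) rlang::abort("envelope window must span at least 2 samples.")
  if (w > length(x)) rlang::abort("envelope window is longer than the signal.")
  half <- w %/% 2L
  cs <- cumsum(c(0, x^2))
  n <- length(x)
  lo <- pmax(0L, seq_len(n) - 1L - half)
  hi <- pmin(n, seq_len(n) + half)
  sqrt((cs[hi + 1L] - cs[lo + 1L]) / (hi - lo))
}

#' sEMG peak latency per muscle
#'
#' The peak latency is the time between the appearance of the target and the
#' peak of the muscle's processed sEMG, measured on the first movement
#' segment of the selected condition (only the first target position is
#' common across conditions). Per muscle: band-pass + notch (zero phase),
#' envelope (moving RMS by default, rectified raw signal optionally),
#' restrict to `[appear, disappear]`, then latency = argmax time - appear
#' (earliest sample on plateaus).
#'
#' Filtering is performed on a window padded by `pad` seconds around the
#' segment rather than the full recording; the zero-phase IIR chain is local,
#' so this changes nothing at the peak while keeping whole-cohort analyses
#' fast.
#'
#' @param emg An EMG recording covering the segment.
#' @param events The session event log.
#' @param spec A [filter_spec()].
#' @param ball_mode,cell Condition selectors passed to [first_segment()].
#' @param window Envelope window, seconds.
#' @param mode `"envelope"` (moving RMS, default) or `"rectified"` (absolute
#'   value of the filtered signal).
#' @param pad Seconds of context filtered on each side of the segment.
#' @return A tibble with one row per muscle: `muscle`, `latency` (s),
#'   `peak_time` (s), `trial`, `ball_mode`, `cell`.
#' @export
peak_latency <- function(emg, events, spec = filter_spec(),
                         ball_mode = NULL, cell = NULL, window = 0.050,
                         mode = c("envelope", "rectified"), pad = 1) {
  mode <- match.arg(mode)
  trial <- first_segment(events, ball_mode = ball_mode, cell = cell)
  fs <- sample_rate(emg)
  if (fs <= 2 * spec$bandpass_high) {
    rlang::abort(paste0("band-pass upper cutoff ", spec$bandpass_high,
                        " Hz violates the Nyquist limit at ", fs, " Hz."))
  }
  t1 <- emg$time[1]
  tn <- emg$time[nrow(emg)]
  if (trial$appear < t1 - 1e-9 || trial$disappear > tn + 1e-9) {
    rlang::abort(paste0("EMG does not cover trial ", trial$trial,
                        " [", trial$appear, ", ", trial$disappear, "] s."))
  }
  wi <- which(emg$time >= trial$appear - pad - 1e-9 &
                emg$time <= trial$disappear + pad + 1e-9)
  inseg <- emg$time[wi] >= trial$appear - 1e-9 &
    emg$time[wi] <= trial$disappear + 1e-9
  res <- purrr::map(emg_channels(emg), function(ch) {
    x <- filter_channel(emg[[ch]][wi], spec, fs)
    env <- if (mode == "envelope") emg_envelope(x, fs, window) else abs(x)
    env <- env[inseg]
    tt <- emg$time[wi][inseg]
    i <- which.max(env)
    tibble::tibble(muscle = ch, latency = tt[i] - trial$appear,
                   peak_time = tt[i], trial_index = trial$trial,
                   ball_mode = trial$ball_mode, cell = trial$cell) |>
      dplyr::rename(trial = "trial_index")
  })
  dplyr::bind_rows(res)
}

#' Peak latencies for every condition of a session
#'
#' Applies [peak_latency()] to the first segment of each (ball mode,
#' analysis cell) combination present in the event log.
#'
#' @inheritParams peak_latency
#' @return A tibble of per-muscle latencies across all conditions.
#' @export
session_latencies <- function(emg, events, spec = filter_spec(),
                              window = 0.050,
                              mode = c("envelope", "rectified")) {
  mode <- match.arg(mode)
  combos <- dplyr::distinct(
    dplyr::filter(events, !is.na(.data$cell)), .data$ball_mode, .data$cell)
  purrr::pmap(combos, function(ball_mode, cell) {
    peak_latency(emg, events, spec, ball_mode = ball_mode, cell = cell,
                 window = window, mode = mode)
  }) |>
    dplyr::bind_rows()
}
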