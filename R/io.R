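# Versioned plain-text session formats:
#   trajectory.csv  "# reachmetrics-trajectory v1 sample_rate_hz=<r>" + time,x,y,z
#   emg.csv         "# reachmetrics-emg v1 sample_rate_hz=<r>" + time,<channels>
#   events.jsonl    one JSON object per line; first line is a format header
# Times are seconds from session start, positions metres (robot base frame),
# EMG millivolts. Readers reject invalid files rather than repairing them.

format_header <- function(kind, rate) {
  sprintf("# reachmetrics-%s v1 sample_rate_hz=%s", kind,
          format(rate, digits = 15))
}

parse_header <- function(path, kind) {
  line <- readLines(path, n = 1L)
  pat <- paste0("^# reachmetrics-", kind, " v1 sample_rate_hz=([0-9.eE+-]+)$")
  if (!grepl(pat, line)) {
    rlang::abort(paste0(path, ":1: not a reachmetrics ", kind,
                        " v1 file (bad header)."))
  }
  as.numeric(sub(pat, "\\1", line))
}

read_delim_body <- function(path) {
  readr::read_csv(path, skip = 1L, show_col_types = FALSE,
                  name_repair = "minimal", progress = FALSE)
}

write_delim_body <- function(df, path, header) {
  writeLines(header, path)
  readr::write_csv(df, path, append = TRUE, col_names = TRUE,
                   progress = FALSE)
}

#' Read / write a trajectory file
#'
#' `trajectory.csv` holds a one-line versioned header carrying the sampling
#' rate, then comma-separated columns `time`, `x`, `y`, `z` (seconds /
#' metres). Reading validates monotone, uniform time; a round-trip
#' reproduces the trajectory to better than 1e-9.
#'
#' @param path File path.
#' @return `read_trajectory()` returns a [as_trajectory()] tibble.
#' @export
read_trajectory <- function(path) {
  rate <- parse_header(path, "trajectory")
  df <- read_delim_body(path)
  miss <- setdiff(c("time", "x", "y", "z"), names(df))
  if (length(miss)) {
    rlang::abort(paste0(path, ":2: missing columns: ",
                        paste(miss, collapse = ", ")))
  }
  bad <- which(diff(df$time) <= 0)
  if (length(bad)) {
    rlang::abort(paste0(path, ":", bad[1] + 3L,
                        ": time is not strictly increasing."))
  }
  withCallingHandlers(
    as_trajectory(df, sample_rate = rate),
    error = function(e) rlang::abort(paste0(path, ": ", conditionMessage(e)))
  )
}

#' @rdname read_trajectory
#' @param traj A trajectory tibble.
#' @export
write_trajectory <- function(traj, path) {
  rate <- sample_rate(traj)
  df <- tibble::as_tibble(as.data.frame(traj)[c("time", "x", "y", "z")])
  write_delim_body(df, path, format_header("trajectory", rate))
  invisible(path)
}

#' Read / write an EMG recording file
#'
#' `emg.csv` holds a versioned header with the sampling rate, then `time`
#' plus one column per muscle channel (millivolts); channel labels come from
#' the header row and must be unique.
#'
#' @param path File path.
#' @return `read_emg()` returns a [as_emg()] tibble.
#' @export
read_emg <- function(path) {
  rate <- parse_header(path, "emg")
  labels <- strsplit(readLines(path, n = 2L)[2], ",", fixed = TRUE)[[1]]
  if (anyDuplicated(labels)) {
    rlang::abort(paste0(path, ":2: duplicate channel label: ",
                        labels[duplicated(labels)][1]))
  }
  df <- read_delim_body(path)
  if (!"time" %in% names(df)) {
    rlang::abort(paste0(path, ":2: missing `time` column."))
  }
  bad <- which(diff(df$time) <= 0)
  if (length(bad)) {
    rlang::abort(paste0(path, ":", bad[1] + 3L,
                        ": time is not strictly increasing."))
  }
  withCallingHandlers(
    as_emg(df, sample_rate = rate),
    error = function(e) rlang::abort(paste0(path, ": ", conditionMessage(e)))
  )
}

#' @rdname read_emg
#' @param emg An EMG tibble.
#' @export
write_emg <- function(emg, path) {
  rate <- sample_rate(emg)
  df <- tibble::as_tibble(as.data.frame(emg))
  write_delim_body(df, path, format_header("emg", rate))
  invisible(path)
}

#' Read / write a trial event log
#'
#' `events.jsonl` holds one JSON object per line: a format-header record
#' first, then one record per trial with fields `trial`, `appear`,
#' `disappear`, `target` (length-3 array, metres), `ball_mode`, `phase`,
#' `feedback`. Event-log invariants (ordered, disjoint intervals; consecutive
#' indices; known labels) are enforced on read.
#'
#' @param path File path.
#' @return `read_events()` returns a [as_events()] tibble.
#' @export
read_events <- function(path) {
  lines <- readLines(path)
  if (length(lines) < 1L) rlang::abort(paste0(path, ": empty event log."))
  hdr <- tryCatch(jsonlite::fromJSON(lines[1]), error = function(e) NULL)
  if (is.null(hdr) || !identical(hdr$format, "reachmetrics-events") ||
      !identical(as.integer(hdr$version), 1L)) {
    rlang::abort(paste0(path, ":1: not a reachmetrics-events v1 file."))
  }
  body <- lines[-1]
  body <- body[nzchar(trimws(body))]
  recs <- vector("list", length(body))
  for (i in seq_along(body)) {
    rec <- tryCatch(jsonlite::fromJSON(body[i]), error = function(e) NULL)
    if (is.null(rec)) {
      rlang::abort(paste0(path, ":", i + 1L, ": malformed JSON record."))
    }
    need <- c("trial", "appear", "disappear", "target", "ball_mode",
              "phase", "feedback")
    miss <- setdiff(need, names(rec))
    if (length(miss)) {
      rlang::abort(paste0(path, ":", i + 1L, ": missing fields: ",
                          paste(miss, collapse = ", ")))
    }
    if (length(rec$target) != 3L) {
      rlang::abort(paste0(path, ":", i + 1L, ": target must be length 3."))
    }
    recs[[i]] <- tibble::tibble(
      trial = rec$trial, appear = rec$appear, disappear = rec$disappear,
      target_x = rec$target[1], target_y = rec$target[2],
      target_z = rec$target[3], ball_mode = rec$ball_mode,
      phase = rec$phase, feedback = rec$feedback
    )
  }
  withCallingHandlers(
    as_events(dplyr::bind_rows(recs)),
    error = function(e) rlang::abort(paste0(path, ": ", conditionMessage(e)))
  )
}

#' @rdname read_events
#' @param events An event-log tibble.
#' @export
write_events <- function(events, path) {
  lines <- c(
    jsonlite::toJSON(list(format = "reachmetrics-events", version = 1L),
                     auto_unbox = TRUE),
    vapply(seq_len(nrow(events)), function(i) {
      as.character(jsonlite::toJSON(list(
        trial = events$trial[i],
        appear = events$appear[i], disappear = events$disappear[i],
        target = c(events$target_x[i], events$target_y[i],
                   events$target_z[i]),
        ball_mode = events$ball_mode[i], phase = events$phase[i],
        feedback = events$feedback[i]
      ), auto_unbox = TRUE, digits = NA))
    }, character(1))
  )
  writeLines(lines, path)
  invisible(path)
}

#' Write / read a full session directory
#'
#' A session directory holds `trajectory.csv`, `emg.csv` and `events.jsonl`
#' for one participant.
#'
#' @param session A `sim_session` (or any list with `trajectory`, `emg`,
#'   `events`).
#' @param dir Directory path (created if needed).
#' @return `read_session()` returns a list with elements `trajectory`,
#'   `emg`, `events` (components whose file is absent are `NULL`).
#' @export
write_session <- function(session, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  if (!is.null(session$trajectory)) {
    write_trajectory(session$trajectory, file.path(dir, "trajectory.csv"))
  }
  if (!is.null(session$emg)) {
    write_emg(session$emg, file.path(dir, "emg.csv"))
  }
  write_events(session$events, file.path(dir, "events.jsonl"))
  invisible(dir)
}

#' @rdname write_session
#' @export
read_session <- function(dir) {
  ev <- file.path(dir, "events.jsonl")
  if (!file.exists(ev)) {
    rlang::abort(paste0("session directory ", dir, " has no events.jsonl."))
  }
  tr <- file.path(dir, "trajectory.csv")
  em <- file.path(dir, "emg.csv")
  list(
    trajectory = if (file.exists(tr)) read_trajectory(tr) else NULL,
    emg = if (file.exists(em)) read_emg(em) else NULL,
    events = read_events(ev)
  )
}
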