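# Orchestration: simulate -> read -> segment -> features/latency -> stats as
# one reproducible run with a manifest.

#' Build a pipeline run configuration
#'
#' @param mode `"simulate"` (write session files only), `"analyze"` (read
#'   session files and write result tables) or `"full"` (both).
#' @param out_dir Output directory; session files go to
#'   `out_dir/participant_<i>/`, result tables to `out_dir/`.
#' @param session_dir Directory of existing sessions (analyze mode);
#'   defaults to `out_dir`.
#' @param sim A [sim_config()].
#' @param filters A [filter_spec()].
#' @param seed Run seed; recorded in the manifest and used for every source
#'   of randomness.
#' @param smoothing_cutoff,amplitude_cutoff,min_separation Kinematic
#'   settings.
#' @param comparisons Post-hoc family, see [posthoc_bonferroni()].
#' @param sphericity Sphericity policy, see [rm_anova2()].
#' @param emg Whether to simulate/analyse EMG (default `TRUE`).
#' @return A list of class `run_config`.
#' @export
run_config <- function(mode = c("full", "simulate", "analyze"),
                       out_dir = "reachmetrics_run",
                       session_dir = NULL,
                       sim = sim_config(),
                       filters = filter_spec(),
                       seed = 1L,
                       smoothing_cutoff = 10,
                       amplitude_cutoff = 0.020,
                       min_separation = 0.150,
                       comparisons = "baseline",
                       sphericity = "auto",
                       emg = TRUE) {
  mode <- match.arg(mode)
  structure(list(mode = mode, out_dir = out_dir,
                 session_dir = session_dir %||% out_dir, sim = sim,
                 filters = filters, seed = seed,
                 smoothing_cutoff = smoothing_cutoff,
                 amplitude_cutoff = amplitude_cutoff,
                 min_separation = min_separation,
                 comparisons = comparisons, sphericity = sphericity,
                 emg = emg),
            class = "run_config")
}

participant_dir <- function(root, p) {
  file.path(root, sprintf("participant_%02d", p))
}

#' Run the reaching-analysis pipeline
#'
#' Executes the stages requested by the configuration. `simulate` writes one
#' session directory per participant (`trajectory.csv`, `emg.csv`,
#' `events.jsonl`). `analyze` reads each session, segments it, computes
#' per-segment kinematic features, per-condition summaries, per-muscle peak
#' latencies, and the two-way repeated-measures ANOVA and Bonferroni
#' post-hoc tables for every kinematic feature and muscle. All tables are
#' written as CSV under `out_dir` and a JSON manifest records the
#' configuration, seed and per-stage record counts. Identical configuration
#' and seed produce identical outputs.
#'
#' @param config A [run_config()].
#' @return The manifest, invisibly, as a list. Result tables are also
#'   returned in the `tables` element (analyze/full modes).
#' @export
run_pipeline <- function(config = run_config()) {
  stopifnot(inherits(config, "run_config"))
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  manifest <- list(
    package = "reachmetrics",
    version = as.character(utils::packageVersion("reachmetrics")),
    mode = config$mode, seed = config$seed,
    n_participants = config$sim$n_participants,
    ball_modes = config$sim$ball_modes,
    blocks_per_mode = nrow(config$sim$protocol),
    segments_per_block = config$sim$protocol$n_segments,
    emg = config$emg,
    settings = list(
      smoothing_cutoff_hz = config$smoothing_cutoff,
      amplitude_cutoff_ms = config$amplitude_cutoff * 1000,
      min_separation_s = config$min_separation,
      bandpass_hz = c(config$filters$bandpass_low,
                      config$filters$bandpass_high),
      notch_hz = config$filters$notch_freq,
      sphericity = config$sphericity,
      comparisons = config$comparisons
    ),
    stages = list()
  )
  comp <- if (config$emg) c("trajectory", "emg") else "trajectory"

  if (config$mode %in% c("simulate", "full")) {
    for (p in seq_len(config$sim$n_participants)) {
      ses <- simulate_session(config$sim, participant = p,
                              seed = config$seed, components = comp)
      write_session(ses, participant_dir(config$out_dir, p))
    }
    manifest$stages$simulate <- list(
      participants = config$sim$n_participants,
      segments_per_participant = config$sim$n_participants * 0 +
        sum(config$sim$protocol$n_segments) * length(config$sim$ball_modes)
    )
  }

  tables <- NULL
  if (config$mode %in% c("analyze", "full")) {
    root <- if (config$mode == "full") config$out_dir else config$session_dir
    dirs <- list.dirs(root, recursive = FALSE)
    dirs <- dirs[grepl("participant_\\d+$", dirs)]
    if (length(dirs) == 0L) {
      rlang::abort(paste0("no participant_* session directories under ",
                          root, "."))
    }
    feats_all <- list()
    lat_all <- list()
    for (d in sort(dirs)) {
      p <- as.integer(sub(".*participant_(\\d+)$", "\\1", d))
      ses <- tryCatch(read_session(d), error = function(e) {
        rlang::abort(paste0("stage analyze, participant ", p, ": ",
                            conditionMessage(e)))
      })
      if (is.null(ses$trajectory)) {
        rlang::abort(paste0("stage analyze, participant ", p,
                            ": missing trajectory.csv in ", d, "."))
      }
      feats <- analyze_kinematics(ses$trajectory, ses$events,
                                  smoothing_cutoff = config$smoothing_cutoff,
                                  amplitude_cutoff = config$amplitude_cutoff,
                                  min_separation = config$min_separation)
      feats$participant <- p
      feats_all[[length(feats_all) + 1L]] <- feats
      if (config$emg) {
        if (is.null(ses$emg)) {
          rlang::abort(paste0("stage analyze, participant ", p,
                              ": missing emg.csv in ", d, "."))
        }
        lat <- session_latencies(ses$emg, ses$events, config$filters)
        lat$participant <- p
        lat_all[[length(lat_all) + 1L]] <- lat
      }
    }
    feats_all <- dplyr::bind_rows(feats_all)
    summaries <- feats_all |>
      dplyr::group_split(.data$participant) |>
      purrr::map(summarize_features) |>
      dplyr::bind_rows()
    tables <- list(features = feats_all, summary = summaries)

    responses <- c("movement_time", "v_avg", "v_peak", "time_to_peak",
                   "n_peak")
    anova_rows <- list(); posthoc_rows <- list()
    n_parts <- length(unique(summaries$participant))
    if (n_parts >= 2L) {
      for (resp in responses) {
        dat <- rm_dataset(summaries, response = resp)
        fit <- rm_anova2(dat, sphericity = config$sphericity)
        tb <- tidy(fit)
        tb$response <- resp
        anova_rows[[resp]] <- tb
        ph <- posthoc_bonferroni(dat, comparisons = config$comparisons)
        ph$response <- resp
        posthoc_rows[[resp]] <- ph
      }
    }
    if (config$emg) {
      lat_all <- dplyr::bind_rows(lat_all)
      tables$latency <- lat_all
      if (n_parts >= 2L) {
        for (m in unique(lat_all$muscle)) {
          dat <- lat_all |>
            dplyr::filter(.data$muscle == m) |>
            dplyr::transmute(.data$participant, .data$ball_mode,
                             .data$cell, value = .data$latency)
          fit <- rm_anova2(dat, sphericity = config$sphericity)
          tb <- tidy(fit)
          tb$response <- paste0("latency:", m)
          anova_rows[[tb$response[1]]] <- tb
          ph <- posthoc_bonferroni(dat, comparisons = config$comparisons)
          ph$response <- paste0("latency:", m)
          posthoc_rows[[ph$response[1]]] <- ph
        }
      }
    }
    if (length(anova_rows)) {
      tables$anova <- dplyr::bind_rows(anova_rows)
      tables$anova$sig <- significance_stars(tables$anova$p)
      tables$posthoc <- dplyr::bind_rows(posthoc_rows)
      tables$posthoc$sig <- significance_stars(tables$posthoc$p_adj)
    }
    for (nm in names(tables)) {
      readr::write_csv(tables[[nm]],
                       file.path(config$out_dir, paste0(nm, ".csv")),
                       progress = FALSE)
    }
    manifest$stages$analyze <- list(
      participants = length(dirs),
      segments = nrow(feats_all),
      summary_rows = nrow(summaries),
      latency_rows = if (config$emg) nrow(tables$latency) else 0L,
      tables = names(tables)
    )
  }
  jsonlite::write_json(manifest,
                       file.path(config$out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  manifest$tables <- tables
  invisible(manifest)
}
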