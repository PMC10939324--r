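#' Assemble a repeated-measures dataset from cohort summaries
#'
#' Stacks per-participant condition summaries into the long format consumed
#' by [rm_anova2()] and [posthoc_bonferroni()]: one value per participant,
#' ball mode and analysis cell.
#'
#' @param summaries A tibble of per-participant summaries
#'   ([summarize_features()] output with a `participant` column, or any
#'   table with `participant`, `ball_mode`, `cell` and the response).
#' @param response Name of the response column to analyse.
#' @return A tibble `participant`, `ball_mode`, `cell`, `value`.
#' @export
rm_dataset <- function(summaries, response = "movement_time") {
  need <- c("participant", "ball_mode", "cell", response)
  miss <- setdiff(need, names(summaries))
  if (length(miss)) {
    rlang::abort(paste0("summaries are missing columns: ",
                        paste(miss, collapse = ", ")))
  }
  tibble::tibble(
    participant = summaries$participant,
    ball_mode = summaries$ball_mode,
    cell = summaries$cell,
    value = summaries[[response]]
  )
}

#' Bonferroni-corrected post-hoc paired comparisons
#'
#' Paired t-tests on participant-matched values for each requested pair of
#' factor levels, with Bonferroni adjustment over the comparison family. The
#' default family compares baseline against each retention cell (m = 3),
#' separately per ball mode; `comparisons = "all"` uses every pair (m = 6
#' for four cells).
#'
#' @param data Long-format tibble (see [rm_dataset()]).
#' @param factor Name of the factor column compared (default `"cell"`).
#' @param comparisons Either `"baseline"` (baseline vs each other level),
#'   `"all"` (all pairs), or a list of length-2 character vectors.
#' @param by Optional stratifying column (default `"ball_mode"`; set `NULL`
#'   to pool).
#' @param subject,response Column names.
#' @return A tibble with one row per (stratum x) comparison: `level_1`,
#'   `level_2`, `estimate` (mean of level_1 - level_2), `t`, `df`, `p_raw`,
#'   `p_adj`, `m`.
#' @export
posthoc_bonferroni <- function(data, factor = "cell",
                               comparisons = "baseline",
                               by = "ball_mode", subject = "participant",
                               response = "value") {
  levels <- unique(as.character(data[[factor]]))
  if (is.character(comparisons) && length(comparisons) == 1L) {
    comparisons <- switch(comparisons,
      baseline = {
        if (!"baseline" %in% levels) {
          rlang::abort("no 'baseline' level for the default comparison family.")
        }
        purrr::map(setdiff(levels, "baseline"), ~ c("baseline", .x))
      },
      all = utils::combn(levels, 2, simplify = FALSE),
      rlang::abort("`comparisons` must be 'baseline', 'all', or a list of pairs.")
    )
  }
  bad <- purrr::keep(comparisons, ~ !all(.x %in% levels))
  if (length(bad)) {
    rlang::abort(paste0("unknown factor levels in comparison: ",
                        paste(bad[[1]], collapse = " vs ")))
  }
  m <- length(comparisons)
  strata <- if (is.null(by)) list(data) else split(data, data[[by]])
  out <- purrr::imap(strata, function(d, stratum) {
    purrr::map(comparisons, function(cmp) {
      d1 <- d[d[[factor]] == cmp[1], c(subject, response)]
      d2 <- d[d[[factor]] == cmp[2], c(subject, response)]
      merged <- dplyr::inner_join(d1, d2, by = subject,
                                  suffix = c("_1", "_2"))
      if (nrow(merged) < 2L) {
        rlang::abort("paired comparisons need at least 2 participants.")
      }
      diffs <- merged[[paste0(response, "_1")]] -
        merged[[paste0(response, "_2")]]
      if (stats::sd(diffs) == 0) {
        tt <- list(statistic = c(t = 0), parameter = c(df = nrow(merged) - 1L),
                   p.value = 1, estimate = mean(diffs))
      } else {
        tt <- stats::t.test(diffs)
      }
      tibble::tibble(
        stratum = if (is.null(by)) NA_character_ else stratum,
        level_1 = cmp[1], level_2 = cmp[2],
        estimate = unname(tt$estimate[1]),
        t = unname(tt$statistic), df = unname(tt$parameter),
        p_raw = tt$p.value, p_adj = pmin(1, m * tt$p.value), m = m
      )
    }) |> dplyr::bind_rows()
  }) |> dplyr::bind_rows()
  if (!is.null(by)) names(out)[names(out) == "stratum"] <- by
  else out$stratum <- NULL
  out
}

#' Simulate, analyse and summarise one cohort
#'
#' Runs the kinematic pipeline (simulate, segment, features, condition means)
#' for every participant of a configuration and stacks the per-participant
#' summaries.
#'
#' @param config A [sim_config()].
#' @param seed Cohort seed.
#' @param smoothing_cutoff,amplitude_cutoff,min_separation Analysis settings,
#'   see [analyze_kinematics()].
#' @return A tibble of per-participant condition summaries with a
#'   `participant` column.
#' @export
simulate_cohort_features <- function(config = sim_config(), seed = 1L,
                                     smoothing_cutoff = 10,
                                     amplitude_cutoff = 0.020,
                                     min_separation = 0.150) {
  purrr::map(seq_len(config$n_participants), function(p) {
    ses <- simulate_session(config, participant = p, seed = seed,
                            components = "trajectory")
    feats <- analyze_kinematics(ses$trajectory, ses$events,
                                smoothing_cutoff = smoothing_cutoff,
                                amplitude_cutoff = amplitude_cutoff,
                                min_separation = min_separation)
    feats$participant <- p
    summarize_features(feats)
  }) |> dplyr::bind_rows()
}

#' Monte-Carlo calibration / power of the full pipeline
#'
#' Repeatedly simulates a cohort under `config`, runs the complete kinematic
#' pipeline (simulate, segment, features, condition means, two-way
#' repeated-measures ANOVA on the chosen response) and records how often each
#' effect is declared significant at `alpha`. With a null configuration
#' (`feedback_effect_s = 0`) this measures type-I error; with a programmed
#' effect it measures power.
#'
#' @param config A [sim_config()].
#' @param n_replicates Number of simulated experiments.
#' @param alpha Significance level (default 0.05).
#' @param seed Base seed; replicate r uses an independent substream.
#' @param response Feature analysed (default `"movement_time"`).
#' @param sphericity Sphericity policy passed to [rm_anova2()].
#' @return A tibble with one row per effect: `effect`, `detections`,
#'   `n_replicates`, `detection_rate`.
#' @export
power_check <- function(config = sim_config(), n_replicates = 100,
                        alpha = 0.05, seed = 1L,
                        response = "movement_time",
                        sphericity = "auto") {
  hits <- NULL
  for (r in seq_len(n_replicates)) {
    rep_seed <- as.integer((as.numeric(seed) + 7919 * r) %% 2147483647)
    summaries <- simulate_cohort_features(config, seed = rep_seed)
    fit <- rm_anova2(rm_dataset(summaries, response = response),
                     sphericity = sphericity)
    p <- stats::setNames(fit$table$p, fit$table$effect)
    det <- !is.na(p) & p < alpha
    hits <- if (is.null(hits)) det else hits + det
  }
  tibble::tibble(
    effect = names(hits),
    detections = as.integer(hits),
    n_replicates = n_replicates,
    detection_rate = as.numeric(hits) / n_replicates
  )
}
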