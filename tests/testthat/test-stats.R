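rm_grid <- function(n = 10, a = 2, b = 4, values = NULL, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  g <- tidyr::expand_grid(participant = seq_len(n),
                          ball_mode = paste0("A", seq_len(a)),
                          cell = paste0("B", seq_len(b)))
  g$value <- values %||% stats::rnorm(nrow(g))
  g
}

test_that("a 2-level factor is trivially spherical", {
  d <- rm_grid(n = 8, seed = 1)
  m <- mauchly_rm(d, "ball_mode")
  expect_equal(m$W, 1)
  expect_equal(m$epsilon_gg, 1)
})

test_that("Mauchly's test keeps its level under compound symmetry", {
  # compound-symmetric data satisfy sphericity: rejections should be rare
  set.seed(99)
  n <- 20; k <- 4
  rejected <- 0
  for (r in 1:200) {
    subj <- stats::rnorm(n, sd = 1)
    Y <- matrix(stats::rnorm(n * k, sd = 0.7), n, k) + subj
    d <- tibble::tibble(
      participant = rep(seq_len(n), k),
      cell = rep(paste0("B", seq_len(k)), each = n),
      value = as.numeric(Y))
    m <- mauchly_rm(d, "cell")
    if (!is.na(m$p) && m$p < 0.05) rejected <- rejected + 1
  }
  expect_lte(rejected / 200, 0.10)
})

test_that("Mauchly agrees with the multivariate reference implementation", {
  set.seed(12)
  n <- 12; k <- 4
  Y <- matrix(stats::rnorm(n * k), n, k) %*% diag(c(1, 1.8, 0.6, 1.2))
  d <- tibble::tibble(
    participant = rep(seq_len(n), k),
    cell = rep(paste0("B", seq_len(k)), each = n),
    value = as.numeric(Y))
  m <- mauchly_rm(d, "cell")
  ref <- stats::mauchly.test(stats::lm(Y ~ 1), X = ~1)
  expect_equal(m$W, unname(ref$statistic), tolerance = 1e-8)
  # the chi-square approximations differ in higher-order terms
  expect_equal(m$p, ref$p.value, tolerance = 2e-3)
  expect_lt(m$epsilon_gg, 1)
})

test_that("strongly heterogeneous covariance gives epsilon below 1", {
  set.seed(3)
  n <- 15; k <- 4
  Y <- matrix(stats::rnorm(n * k), n, k) %*% diag(c(3, 1, 0.3, 0.1))
  d <- tibble::tibble(
    participant = rep(seq_len(n), k),
    cell = rep(paste0("B", seq_len(k)), each = n),
    value = as.numeric(Y))
  expect_lt(mauchly_rm(d, "cell")$epsilon_gg, 0.8)
})

test_that("rm_anova2 matches the aov error-strata decomposition to 1e-8", {
  for (seed in 1:5) {
    d <- rm_grid(n = 10, seed = seed)
    fit <- rm_anova2(d, sphericity = "none")
    ref <- aov_reference(d)
    tb <- fit$table
    expect_equal(tb$F[tb$effect == "ball_mode"], ref$A$F, tolerance = 1e-8)
    expect_equal(tb$p[tb$effect == "ball_mode"], ref$A$p, tolerance = 1e-8)
    expect_equal(tb$F[tb$effect == "cell"], ref$B$F, tolerance = 1e-8)
    expect_equal(tb$p[tb$effect == "cell"], ref$B$p, tolerance = 1e-8)
    expect_equal(tb$F[tb$effect == "ball_mode:cell"], ref$AB$F,
                 tolerance = 1e-8)
    expect_equal(tb$p[tb$effect == "ball_mode:cell"], ref$AB$p,
                 tolerance = 1e-8)
    # SS conservation
    ss <- fit$ss
    expect_equal(ss$total,
                 ss$subject + ss$A + ss$B + ss$AB + ss$As + ss$Bs + ss$ABs,
                 tolerance = 1e-8)
  }
})

test_that("degenerate effects give F = 0 and p = 1", {
  # response identical across factor B for every participant
  set.seed(4)
  d <- rm_grid(n = 6)
  per <- tidyr::expand_grid(participant = 1:6, ball_mode = c("A1", "A2"))
  per$v <- stats::rnorm(12)
  d <- dplyr::left_join(d, per, by = c("participant", "ball_mode"))
  d$value <- d$v
  fit <- rm_anova2(d)
  tb <- fit$table
  expect_equal(tb$F[tb$effect == "cell"], 0)
  expect_equal(tb$p[tb$effect == "cell"], 1)

  # additive 2x2 data: interaction SS exactly zero
  d2 <- tibble::tibble(
    participant = rep(1:3, each = 4),
    ball_mode = rep(c("A1", "A1", "A2", "A2"), 3),
    cell = rep(c("B1", "B2"), 6),
    value = c(1, 2, 3, 4, 2, 3, 4, 5, 3, 4, 5, 6))
  fit2 <- rm_anova2(d2)
  expect_equal(fit2$ss$AB, 0, tolerance = 1e-12)
  expect_equal(fit2$table$F[fit2$table$effect == "ball_mode:cell"], 0)
})

test_that("participant order does not change any statistic", {
  d <- rm_grid(n = 9, seed = 6)
  fit1 <- rm_anova2(d)
  d2 <- d[sample(nrow(d)), ]
  d2$participant <- match(d2$participant, c(4, 1, 9, 2, 7, 5, 3, 8, 6))
  fit2 <- rm_anova2(d2[order(d2$participant), ])
  expect_equal(fit1$table$F, fit2$table$F, tolerance = 1e-10)
  expect_equal(fit1$table$p, fit2$table$p, tolerance = 1e-10)
})

test_that("for 2 levels the F statistic equals the squared paired t", {
  d <- rm_grid(n = 10, b = 4, seed = 8)
  fit <- rm_anova2(d)
  wide <- d |>
    dplyr::group_by(.data$participant, .data$ball_mode) |>
    dplyr::summarise(m = mean(.data$value), .groups = "drop") |>
    tidyr::pivot_wider(names_from = "ball_mode", values_from = "m")
  tt <- stats::t.test(wide$A1, wide$A2, paired = TRUE)
  expect_equal(fit$table$F[fit$table$effect == "ball_mode"],
               unname(tt$statistic)^2, tolerance = 1e-8)
})

test_that("unbalanced or missing designs are rejected", {
  d <- rm_grid(n = 5, seed = 2)
  expect_error(rm_anova2(d[-1, ]), "exactly one value")
  expect_error(rm_anova2(d[1:4, ]), "at least 2 subjects")
  drop_cell <- d[!(d$participant == 1 & d$cell == "B1"), ]
  expect_error(mauchly_rm(drop_cell, "cell"), "missing|unbalanced")
})

test_that("tidy and glance views expose the fitted ANOVA", {
  d <- rm_grid(n = 8, seed = 10)
  fit <- rm_anova2(d)
  td <- tidy(fit)
  expect_s3_class(td, "tbl_df")
  expect_equal(td$effect, c("ball_mode", "cell", "ball_mode:cell"))
  expect_true(all(c("F", "p", "epsilon", "mauchly_W") %in% names(td)))
  gl <- glance(fit)
  expect_equal(gl$n_subjects, 8)
  expect_equal(gl$n_levels_b, 4)
})

test_that("Bonferroni post-hoc comparisons follow their definitions", {
  # identical paired values: t = 0, p = 1
  d <- tibble::tibble(
    participant = rep(1:6, 2),
    ball_mode = "small",
    cell = rep(c("baseline", "TV"), each = 6),
    value = rep(stats::rnorm(6), 2))
  ph <- posthoc_bonferroni(d, comparisons = list(c("baseline", "TV")))
  expect_equal(ph$t, 0)
  expect_equal(ph$p_raw, 1)
  expect_equal(ph$p_adj, 1)

  # adjusted p = m * raw p, capped at 1
  set.seed(14)
  d2 <- rm_grid(n = 10, values = NULL, seed = 14)
  names(d2)[names(d2) == "cell"] <- "cell"
  d2$cell <- sub("B1", "baseline", d2$cell)
  ph2 <- posthoc_bonferroni(d2, comparisons = "baseline")
  expect_equal(ph2$m, rep(3, nrow(ph2)))
  expect_equal(ph2$p_adj, pmin(1, 3 * ph2$p_raw))

  # closed-form paired t on a constructed difference
  n <- 10
  set.seed(15)
  diffs <- stats::rnorm(n, mean = 0.4, sd = 0.5)
  base <- stats::rnorm(n)
  d3 <- tibble::tibble(
    participant = rep(1:n, 2), ball_mode = "big",
    cell = rep(c("baseline", "TH"), each = n),
    value = c(base + diffs, base))
  ph3 <- posthoc_bonferroni(d3, comparisons = list(c("baseline", "TH")))
  expect_equal(ph3$t, mean(diffs) / (stats::sd(diffs) / sqrt(n)),
               tolerance = 1e-10)

  expect_error(
    posthoc_bonferroni(d3[c(1, 11), ], comparisons = list(c("baseline", "TH"))),
    "at least 2 participants")
  expect_error(posthoc_bonferroni(d3, comparisons = list(c("baseline", "XX"))),
               "unknown factor levels")
  # all-pairs family
  ph4 <- posthoc_bonferroni(rm_grid(n = 6, seed = 16), comparisons = "all")
  expect_equal(unique(ph4$m), 6)
})

test_that("power_check is deterministic for a fixed seed", {
  cfg <- tiny_config(n_participants = 4)
  r1 <- power_check(cfg, n_replicates = 1, seed = 5)
  r2 <- power_check(cfg, n_replicates = 1, seed = 5)
  expect_identical(r1, r2)
  expect_equal(nrow(r1), 3)
  expect_true(all(r1$detection_rate %in% c(0, 1)))
})
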