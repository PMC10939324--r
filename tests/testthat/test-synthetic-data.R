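test_that("a pure primary reach yields a single speed maximum", {
  cfg <- sim_config(pos_noise_sd = 0)
  set.seed(1)
  seg <- simulate_segment(c(0, 0, 0), c(0.3, 0, 0), primary_duration = 2,
                          n_corrective = 0, config = cfg)
  sp <- speed_profile(seg$positions)
  expect_equal(count_velocity_peaks(sp), 1L)
  # time to peak at the temporal midpoint, within one sample
  expect_equal(sp$time[which.max(sp$speed)], 1,
               tolerance = 1.01 / cfg$sample_rate_traj)
})

test_that("forced corrective submovements appear as resolvable speed bumps", {
  cfg <- sim_config(pos_noise_sd = 0, corrective_amplitude = 0.02,
                    corrective_duration = 0.4)
  set.seed(2)
  seg <- simulate_segment(c(0, 0, 0), c(0.3, 0, 0), primary_duration = 2,
                          n_corrective = 2, config = cfg)
  sp <- speed_profile(seg$positions)
  expect_equal(count_velocity_peaks(sp), 3L)
  expect_equal(oracle_count_peaks(sp$time, sp$speed), 3)
  # end point lands on the target (within any positive target radius)
  endpoint <- as.numeric(seg$positions[nrow(seg$positions), c("x", "y", "z")])
  expect_lt(sqrt(sum((endpoint - c(0.3, 0, 0))^2)), cfg$target_radius[["small"]])
  expect_equal(seg$truth$n_corrective, 2L)
})

test_that("sessions follow the protocol template and are deterministic", {
  cfg <- tiny_config()
  s1 <- simulate_session(cfg, participant = 1, seed = 9)
  s2 <- simulate_session(cfg, participant = 1, seed = 9)
  expect_identical(s1$trajectory, s2$trajectory)
  expect_identical(s1$emg, s2$emg)
  expect_identical(s1$events, s2$events)
  s3 <- simulate_session(cfg, participant = 2, seed = 9)
  expect_false(identical(s1$trajectory, s3$trajectory))

  # full default protocol: 7 blocks of 16/24/16/24/16/24/16 per ball mode
  full <- sim_config(n_participants = 1)
  ses <- simulate_session(full, participant = 1, seed = 1,
                          components = "trajectory")
  counts <- ses$truth |>
    dplyr::count(.data$ball_mode, .data$block) |>
    dplyr::arrange(.data$ball_mode, .data$block)
  expect_equal(counts$n, rep(c(16, 24, 16, 24, 16, 24, 16), 2))
  expect_equal(nrow(ses$events), 2 * (16 * 4 + 24 * 3))
  expect_equal(nrow(ses$truth), nrow(ses$events))
})

test_that("event intervals are ordered, disjoint, and cover the trajectory", {
  ses <- simulate_session(tiny_config(), participant = 1, seed = 3,
                          components = "trajectory")
  ev <- ses$events
  expect_true(all(ev$appear < ev$disappear))
  expect_true(all(diff(ev$appear) > 0))
  expect_true(all(ev$appear[-1] >= ev$disappear[-nrow(ev)]))
  expect_gte(min(ev$appear), min(ses$trajectory$time))
  expect_lte(max(ev$disappear), max(ses$trajectory$time))
})

test_that("emitted inter-target distances match the configured geometry", {
  cfg <- sim_config(n_participants = 1)
  ses <- simulate_session(cfg, participant = 1, seed = 5,
                          components = "trajectory")
  for (mode in c("small", "big")) {
    ev <- dplyr::filter(ses$events, .data$ball_mode == mode)
    tg <- as.matrix(ev[, c("target_x", "target_y", "target_z")])
    d <- sqrt(rowSums((tg[-1, ] - tg[-nrow(tg), ])^2))
    d <- d[d > 1e-9]  # block boundaries can repeat the fixed first target
    expect_lt(abs(mean(d) - cfg$mean_distance[[mode]]), 2 * stats::sd(d))
    # 8 distinct target positions
    expect_equal(nrow(unique(round(tibble::as_tibble(tg), 9))), 8)
  }
})

test_that("pure-primary segments have time-to-peak at half the duration", {
  cfg <- sim_config(pos_noise_sd = 0)
  set.seed(4)
  for (dur in c(0.8, 1.6, 2.4)) {
    seg <- simulate_segment(c(0.1, 0.2, 0.3), c(0.15, 0.22, 0.35),
                            primary_duration = dur, n_corrective = 0,
                            config = cfg)
    sp <- speed_profile(seg$positions)
    expect_equal(sp$time[which.max(sp$speed)], dur / 2,
                 tolerance = 1.01 / cfg$sample_rate_traj)
  }
})

test_that("null EMG configuration produces an all-zero recording", {
  cfg <- tiny_config(emg_noise_sd = 0, mains_amplitude = 0,
                     emg_burst_gain = stats::setNames(rep(0, 5), reach_muscles))
  expect_error(sim_config(emg_burst_gain = c(bogus = 1)), "muscle")
  ses <- simulate_session(cfg, participant = 1, seed = 1)
  for (ch in reach_muscles) expect_equal(max(abs(ses$emg[[ch]])), 0)
})

test_that("a mains-only recording concentrates its power at 50 Hz", {
  cfg <- tiny_config(emg_noise_sd = 0,
                     emg_burst_gain = stats::setNames(rep(0, 5), reach_muscles),
                     mains_amplitude = 0.1)
  ses <- simulate_session(cfg, participant = 1, seed = 1)
  x <- ses$emg[["biceps brachii"]][1:8192]
  sp <- Mod(stats::fft(x))[1:4096]
  freqs <- (0:4095) * 1000 / 8192
  expect_lt(abs(freqs[which.max(sp[-1]) + 1] - 50), 1)
})

test_that("a programmed latency offset shifts the EMG envelope peak", {
  cfg <- sim_config(emg_noise_sd = 1e-4, mains_amplitude = 0)
  # single bump speed profile at 1 kHz
  times <- seq(0, 4, by = 1e-3)
  speed <- tibble::tibble(time = times,
                          speed = minimum_jerk_speed(times - 1, 0.3, 1.2))
  events <- as_events(tibble::tibble(
    trial = 0L, appear = 0.5, disappear = 3.5, target_x = 0.3, target_y = 0,
    target_z = 0, ball_mode = "small", phase = "baseline", feedback = "none"))
  off <- cfg$muscle_latency_offset
  set.seed(11)
  emg <- simulate_emg(speed, events, cfg)
  # speed peak at t = 1.6; each channel's envelope peak follows its offset
  fs <- sample_rate(emg)
  for (m in c("biceps brachii", "upper trapezius")) {
    x <- preprocess_emg(emg, filter_spec())[[m]]
    env <- emg_envelope(x, fs, 0.05)
    t_pk <- emg$time[which.max(env)]
    expect_equal(t_pk, 1.6 + off[[m]], tolerance = 0.05)
  }
})

test_that("simulation configs are validated", {
  expect_error(sim_config(n_participants = 0), "at least 1")
  expect_error(sim_config(corrective_duration = -1), "positive")
  expect_error(sim_config(ball_modes = "medium"), "subset")
  proto <- default_protocol()
  proto$feedback[2] <- "XX"
  expect_error(sim_config(protocol = proto), "feedback")
  expect_error(simulate_segment(c(0, 0, NA), c(1, 0, 0), 1, 0), "finite")
})
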