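lin_seg <- function(rate = 100, dur = 2, vel = 0.1) {
  times <- seq(0, dur, by = 1 / rate)
  tibble::tibble(time = times, x = vel * times, y = 0, z = 0)
}

test_that("speed of linear motion is exact in the interior", {
  sp <- speed_profile(lin_seg())
  expect_equal(sp$speed[2:(nrow(sp) - 1)],
               rep(0.1, nrow(sp) - 2), tolerance = 1e-12)
  # stationary segment
  still <- tibble::tibble(time = seq(0, 1, 0.01), x = 0.2, y = 0.1, z = 0)
  expect_equal(max(speed_profile(still)$speed), 0)
  # non-uniform grid is rejected
  bad <- lin_seg(); bad$time[5] <- bad$time[5] + 0.004
  expect_error(speed_profile(bad), "not uniform")
})

test_that("sampled minimum-jerk reach attains the closed-form peak speed", {
  times <- seq(0, 2, by = 0.01)
  pos <- minimum_jerk_position(times, c(0, 0, 0), c(0.3, 0, 0), 2)
  seg <- tibble::tibble(time = times, x = pos[, 1], y = pos[, 2], z = pos[, 3])
  sp <- speed_profile(seg)
  expect_equal(max(sp$speed), 0.28125, tolerance = 0.005)
  expect_equal(mean_velocity(sp), 0.3 / 2, tolerance = 0.01)
  pk <- peak_velocity(sp)
  expect_equal(pk$t_at_peak, 1, tolerance = 0.0101)
})

test_that("movement time is the event interval", {
  expect_equal(movement_time(list(appear = 1.0, disappear = 3.5)), 2.5)
  expect_equal(movement_time(list(appear = 0, disappear = 7)), 7)
  # simulated truth: programmed total duration within one sample
  ses <- simulate_session(tiny_config(), participant = 1, seed = 2,
                          components = "trajectory")
  feats <- analyze_kinematics(ses$trajectory, ses$events)
  expect_equal(feats$movement_time, ses$truth$duration, tolerance = 1e-9)
})

test_that("peak velocity breaks plateau ties by earliest time", {
  sp <- structure(tibble::tibble(time = c(0, 0.01, 0.02),
                                 speed = c(0, 0.2, 0.1)),
                  class = c("reach_speed", class(tibble::tibble())))
  expect_equal(peak_velocity(sp), list(v_peak = 0.2, t_at_peak = 0.01))
  flat <- structure(tibble::tibble(time = seq(0, 0.05, 0.01),
                                   speed = rep(0.1, 6)),
                    class = c("reach_speed", class(tibble::tibble())))
  expect_equal(peak_velocity(flat)$t_at_peak, 0)
  expect_equal(time_to_peak(list(appear = 0), sp), 0.01)
  # peak at appearance
  expect_equal(time_to_peak(list(appear = 0.01), sp), 0)
})

test_that("the two counting rules behave as specified on crafted profiles", {
  rate <- 1000
  bump <- function(center, height, times, width = 0.04) {
    height * exp(-(times - center)^2 / (2 * width^2))
  }
  times <- seq(0, 1, by = 1 / rate)
  # two 0.1 m/s bumps, dip to ~0.05, maxima 300 ms apart -> both counted
  two <- tibble::tibble(
    time = times,
    speed = bump(0.35, 0.1, times) + bump(0.65, 0.1, times))
  expect_equal(count_velocity_peaks(two), 2L)
  expect_equal(oracle_count_peaks(two$time, two$speed), 2)
  # same shapes 100 ms apart -> separation rule keeps only the first
  close <- tibble::tibble(
    time = times,
    speed = bump(0.45, 0.1, times, 0.02) + bump(0.55, 0.1, times, 0.02))
  expect_equal(count_velocity_peaks(close), 1L)
  expect_equal(oracle_count_peaks(close$time, close$speed), 1)
  # a rise of 15 mm/s above its preceding minimum is below the cutoff
  sub <- tibble::tibble(
    time = times,
    speed = 0.1 * exp(-(times - 0.3)^2 / (2 * 0.03^2)) +
      bump(0.7, 0.015, times, 0.02))
  expect_equal(count_velocity_peaks(sub), 1L)
  expect_equal(oracle_count_peaks(sub$time, sub$speed), 1)
})

test_that("peak counting matches the brute-force oracle on random profiles", {
  set.seed(42)
  for (i in 1:200) {
    sp <- random_speed_profile()
    expect_equal(count_velocity_peaks(sp),
                 oracle_count_peaks(sp$time, sp$speed),
                 info = paste("profile", i))
  }
})

test_that("adding a well-separated above-cutoff bump raises the count by 1", {
  set.seed(7)
  rate <- 100
  for (i in 1:25) {
    sp <- random_speed_profile(rate)
    n0 <- count_velocity_peaks(sp)
    # place a tall narrow bump in a quiet zone far from existing peaks
    t_new <- max(sp$time) + 1.2
    times2 <- seq(0, t_new + 1, by = 1 / rate)
    pad <- tibble::tibble(
      time = times2,
      speed = c(sp$speed, rep(0, length(times2) - nrow(sp))) +
        0.2 * exp(-(times2 - t_new)^2 / (2 * 0.05^2)))
    expect_equal(count_velocity_peaks(pad), n0 + 1L)
  }
})

test_that("features are stable under doubling of the sample rate", {
  for (rate in c(100, 200)) {
    times <- seq(0, 2, by = 1 / rate)
    pos <- minimum_jerk_position(times, c(0, 0, 0), c(0.25, 0.1, 0.05), 2)
    seg <- tibble::tibble(time = times, x = pos[, 1], y = pos[, 2],
                          z = pos[, 3])
    sp <- speed_profile(seg)
    res <- c(mean_velocity(sp), peak_velocity(sp)$v_peak,
             count_velocity_peaks(sp))
    if (rate == 100) base <- res
  }
  expect_equal(res[1], base[1], tolerance = 0.01)
  expect_equal(res[2], base[2], tolerance = 0.01)
  expect_equal(res[3], base[3])
})

test_that("v_avg never exceeds v_peak on simulated sessions", {
  ses <- simulate_session(tiny_config(), participant = 2, seed = 31,
                          components = "trajectory")
  feats <- analyze_kinematics(ses$trajectory, ses$events)
  expect_true(all(feats$v_avg <= feats$v_peak))
  expect_true(all(feats$time_to_peak <= feats$movement_time + 1e-9))
  expect_true(all(feats$time_to_peak >= 0))
  expect_true(all(feats$n_peak >= 0))
})

test_that("condition summaries are per-cell means over segments", {
  f <- tibble::tibble(
    trial = 0:3, ball_mode = "small", phase = "baseline", feedback = "none",
    cell = "baseline", movement_time = c(2, 4, 3, 3), v_avg = 0.1,
    v_peak = 0.2, time_to_peak = 1, n_peak = c(1L, 3L, 2L, 2L),
    participant = 1)
  s <- summarize_features(f)
  expect_equal(s$movement_time, 3)
  expect_equal(s$n_peak, 2)
  expect_equal(s$n_segments, 4L)
  # a missing cell is an aggregation error
  f2 <- dplyr::bind_rows(f, dplyr::mutate(f, ball_mode = "big",
                                          cell = "TV", feedback = "TV",
                                          phase = "retention"))
  expect_error(summarize_features(f2), "zero segments")
})

test_that("per-segment and whole-session feature routes agree", {
  ses <- simulate_session(tiny_config(), participant = 1, seed = 17,
                          components = "trajectory")
  seg <- segment_session(ses$trajectory, ses$events)
  slow <- kinematic_features(seg, smoothing_cutoff = NULL)
  fast <- analyze_kinematics(ses$trajectory, ses$events,
                             smoothing_cutoff = NULL)
  expect_equal(fast$movement_time, slow$movement_time)
  # interior-dominated features agree closely; the routes differ only in the
  # boundary stencils (one-sided per segment vs continuous recording)
  expect_equal(fast$v_peak, slow$v_peak, tolerance = 0.02)
  expect_lt(mean(abs(fast$n_peak - slow$n_peak)), 0.2)
  expect_equal(stats::median(fast$n_peak - slow$n_peak), 0)
})
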