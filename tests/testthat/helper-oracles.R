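# Independent oracles used by the tests. These are deliberately written as
# slow, explicit implementations that share no code with the package.

# Brute-force velocity-peak count: explicit extremum scan with plateau
# handling, explicit alternation pass, then sequential application of the
# amplitude and separation rules.
oracle_count_peaks <- function(times, speed, cutoff = 0.020, sep = 0.150) {
  n <- length(speed)
  # compress plateaus to their first sample
  rep_idx <- c()
  for (i in seq_len(n)) {
    if (i == 1 || speed[i] != speed[i - 1]) rep_idx <- c(rep_idx, i)
  }
  y <- speed[rep_idx]
  m <- length(y)
  kind <- rep(NA_character_, m)
  kind[1] <- "min"  # segment start counts as the initial minimum
  if (m >= 2) {
    for (j in 2:m) {
      left <- y[j - 1]
      right <- if (j < m) y[j + 1] else NA
      if (j < m) {
        if (y[j] > left && y[j] > right) kind[j] <- "max"
        if (y[j] < left && y[j] < right) kind[j] <- "min"
      } else {
        kind[j] <- if (y[j] > left) "max" else "min"
      }
    }
  }
  ext_i <- which(!is.na(kind))
  # alternation: merge runs of the same kind, keeping the extreme value and
  # the earliest sample on ties
  seq_i <- c(); seq_k <- c()
  for (j in ext_i) {
    if (length(seq_k) > 0 && seq_k[length(seq_k)] == kind[j]) {
      prev <- seq_i[length(seq_i)]
      if ((kind[j] == "min" && y[j] < y[prev]) ||
          (kind[j] == "max" && y[j] > y[prev])) {
        seq_i[length(seq_i)] <- j
      }
    } else {
      seq_i <- c(seq_i, j)
      seq_k <- c(seq_k, kind[j])
    }
  }
  # amplitude rule then greedy separation rule
  count <- 0
  last_accept <- -Inf
  prev_min_val <- NA
  for (q in seq_along(seq_i)) {
    j <- seq_i[q]
    if (seq_k[q] == "min") {
      prev_min_val <- y[j]
    } else {
      if (!is.na(prev_min_val) && (y[j] - prev_min_val) > cutoff) {
        t_j <- times[rep_idx[j]]
        if (t_j - last_accept >= sep - 1e-9) {
          count <- count + 1
          last_accept <- t_j
        }
      }
    }
  }
  count
}

# Closed-form quintic evaluated on a fine grid, differentiated numerically:
# an oracle for the minimum-jerk peak speed that does not reuse the package's
# speed formula.
oracle_mj_peak_speed <- function(distance, duration, dt = 1e-5) {
  t <- seq(0, duration, by = dt)
  s <- t / duration
  x <- distance * (10 * s^3 - 15 * s^4 + 6 * s^5)
  max(abs(diff(x)) / dt)
}

# Random synthetic speed profile: 0-5 bumps of random amplitude (including
# sub-cutoff) and random spacing (including sub-150 ms), on a baseline that
# may itself be nonzero. Returns a tibble(time, speed).
random_speed_profile <- function(rate = 100) {
  dur <- stats::runif(1, 2, 5)
  times <- seq(0, dur, by = 1 / rate)
  n_bump <- sample(0:5, 1)
  speed <- rep(stats::runif(1, 0, 0.01), length(times))
  if (n_bump > 0) {
    centers <- sort(stats::runif(n_bump, 0.1, dur - 0.1))
    heights <- stats::runif(n_bump, 0.005, 0.3)
    widths <- stats::runif(n_bump, 0.03, 0.25)
    for (b in seq_len(n_bump)) {
      speed <- speed + heights[b] * exp(-(times - centers[b])^2 /
                                          (2 * widths[b]^2))
    }
  }
  # occasional additive jitter makes micro-extrema
  if (stats::runif(1) < 0.5) {
    speed <- pmax(0, speed + stats::rnorm(length(times), sd = 0.002))
  }
  tibble::tibble(time = times, speed = speed)
}

# Compact session config for fast unit tests: full 7-block structure with
# fewer segments per block.
tiny_config <- function(n_participants = 2, ...) {
  proto <- default_protocol()
  proto$n_segments <- rep(4L, 7L)
  sim_config(n_participants = n_participants, protocol = proto, ...)
}

# Reference two-way within-subject ANOVA via base R aov() error strata;
# independent of the package's sums-of-squares implementation.
aov_reference <- function(data) {
  d <- data
  d$participant <- factor(d$participant)
  d$ball_mode <- factor(d$ball_mode)
  d$cell <- factor(d$cell)
  a <- summary(stats::aov(
    value ~ ball_mode * cell + Error(participant / (ball_mode * cell)),
    data = d))
  get_row <- function(stratum, term) {
    tb <- a[[stratum]][[1]]
    i <- grep(term, trimws(rownames(tb)), fixed = TRUE)[1]
    list(F = tb[i, "F value"], p = tb[i, "Pr(>F)"])
  }
  list(A = get_row("Error: participant:ball_mode", "ball_mode"),
       B = get_row("Error: participant:cell", "cell"),
       AB = get_row("Error: participant:ball_mode:cell", "ball_mode:cell"))
}

# dB ratio of output to input RMS
rms_db <- function(out, input) 20 * log10(sqrt(mean(out^2)) / sqrt(mean(input^2)))
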