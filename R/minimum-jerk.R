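#' Minimum-jerk position along a point-to-point reach
#'
#' Evaluates the quintic minimum-jerk trajectory between two points. The
#' profile `10 s^3 - 15 s^4 + 6 s^5` (with `s = t / duration`) is the unique
#' polynomial that moves from rest to rest while minimising integrated squared
#' jerk; its speed is bell-shaped with a single peak of `1.875 * D / T` at the
#' temporal midpoint, which makes it the standard model for the ballistic
#' phase of a goal-directed reach.
#'
#' @param t Time(s) since movement onset, in seconds. Vectorised.
#' @param start,end Numeric length-3 start and end positions in metres.
#' @param duration Movement duration in seconds, `> 0`.
#'
#' @return A numeric matrix with one row per element of `t` and columns
#'   `x`, `y`, `z`.
#'
#' @examples
#' minimum_jerk_position(c(0, 1, 2), c(0, 0, 0), c(0.3, 0, 0), 2)
#' @export
minimum_jerk_position <- function(t, start, end, duration) {
  stopifnot(is.numeric(t), is.numeric(start), is.numeric(end))
  if (length(start) != 3L || length(end) != 3L) {
    rlang::abort("`start` and `end` must be length-3 position vectors.")
  }
  if (!is.numeric(duration) || length(duration) != 1L ||
      !is.finite(duration) || duration <= 0) {
    rlang::abort("`duration` must be a single positive number.")
  }
  if (any(!is.finite(t)) || any(t < -1e-12) || any(t > duration + 1e-12)) {
    rlang::abort("`t` must lie within [0, duration].")
  }
  s <- pmin(pmax(t / duration, 0), 1)
  shape <- 10 * s^3 - 15 * s^4 + 6 * s^5
  out <- outer(shape, end - start) + rep(start, each = length(t))
  colnames(out) <- c("x", "y", "z")
  out
}

#' Minimum-jerk speed profile
#'
#' Closed-form speed (magnitude of velocity) of a straight minimum-jerk reach
#' of length `distance` over `duration`: `D/T * (30 s^2 - 60 s^3 + 30 s^4)`.
#' Zero outside `[0, duration]`, so sums of these shapes describe a reach made
#' of non-overlapping submovements.
#'
#' @param t Time(s) since submovement onset, seconds. Vectorised; values
#'   outside `[0, duration]` yield zero.
#' @param distance Path length of the submovement in metres.
#' @param duration Submovement duration in seconds.
#' @return Numeric vector of speeds in m/s.
#' @export
minimum_jerk_speed <- function(t, distance, duration) {
  s <- t / duration
  inside <- s >= 0 & s <= 1
  v <- numeric(length(t))
  si <- s[inside]
  v[inside] <- distance / duration * (30 * si^2 - 60 * si^3 + 30 * si^4)
  v
}
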