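# Parametric trajectories with closed-form kinematics.  These are the oracle
# surface for the analysis functions: each fixture knows its generating
# parameters, so recovered speed, heading, acceleration, turning speed and
# lead/follow delays can be checked against exact values.

#' Constant-velocity line fixture
#'
#' @param speed Speed in length units per second (>= 0).
#' @param heading Direction of travel, degrees clockwise from +y ("north").
#' @param n_frames Number of frames (>= 2).
#' @param fps Frame rate, frames/s.
#' @param origin Numeric length-2 starting position.
#' @param id,body_length Passed to [trajectory()].
#' @return A [trajectory()].  The generating parameters are attached as
#'   attribute `params`.
#' @export
make_line <- function(speed, heading = 0, n_frames = 48, fps = 24,
                      origin = c(0, 0), id = "line", body_length = 40.6) {
  if (!is.finite(n_frames) || n_frames < 2) {
    stop("invalid-argument: n_frames must be >= 2")
  }
  if (speed < 0) stop("invalid-argument: speed must be >= 0")
  t <- (seq_len(n_frames) - 1) / fps
  th <- deg2rad(heading)
  tr <- trajectory(x = origin[1L] + speed * sin(th) * t,
                   y = origin[2L] + speed * cos(th) * t,
                   id = id, fps = fps, body_length = body_length)
  attr(tr, "params") <- list(speed = speed, heading = wrap_deg(heading))
  tr
}

#' Uniform circular-motion fixture
#'
#' The position angle advances clockwise (from north) at `angular_rate`
#' rad/s, so the true speed is `radius * |angular_rate|`, the true turning
#' speed is `angular_rate` (in rad/s; positive = clockwise) and the true
#' acceleration magnitude is `radius * angular_rate^2`.
#'
#' @param radius Circle radius (> 0), length units.
#' @param angular_rate Signed angular rate in rad/s (positive = clockwise).
#' @param n_frames,fps,id,body_length As in [make_line()].
#' @param phase0 Initial position angle, degrees clockwise from north.
#' @param center Circle centre.
#' @return A [trajectory()] with attribute `params` (including the
#'   closed-form `speed`, `accel_mag` and `turn_speed_deg_s`).
#' @export
make_circle <- function(radius, angular_rate, n_frames = 240, fps = 24,
                        phase0 = 0, center = c(0, 0), id = "circle",
                        body_length = 40.6) {
  if (!is.finite(radius) || radius <= 0) {
    stop("invalid-argument: radius must be > 0")
  }
  t <- (seq_len(n_frames) - 1) / fps
  phi <- deg2rad(phase0) + angular_rate * t
  tr <- trajectory(x = center[1L] + radius * sin(phi),
                   y = center[2L] + radius * cos(phi),
                   id = id, fps = fps, body_length = body_length)
  attr(tr, "params") <- list(
    radius = radius, angular_rate = angular_rate,
    speed = radius * abs(angular_rate),
    accel_mag = radius * angular_rate^2,
    turn_speed_deg_s = rad2deg(angular_rate))
  tr
}

#' Delayed-follower fixture
#'
#' The follower repeats the leader's path `delay_frames` frames later, offset
#' in space; the first `delay_frames` frames are filled by extrapolating the
#' leader's initial velocity backwards.  The planted delay is ground truth
#' for the leadership analysis.
#'
#' @param leader A [trajectory()].
#' @param delay_frames Integer >= 0, strictly less than the leader frame
#'   count.
#' @param offset Numeric length-2 spatial offset of the follower.
#' @param id Follower id.
#' @return A [trajectory()] with attribute `params$delay_frames`.
#' @export
make_delayed_follower <- function(leader, delay_frames, offset = c(0, 0),
                                  id = "follower") {
  stopifnot(inherits(leader, "trajectory"))
  nf <- n_frames(leader)
  if (delay_frames < 0 || delay_frames >= nf) {
    stop("invalid-argument: delay_frames must be in [0, n_frames)")
  }
  d <- as.integer(delay_frames)
  idx <- seq_len(nf) - d
  x <- numeric(nf)
  y <- numeric(nf)
  inside <- idx >= 1L
  x[inside] <- leader$x[idx[inside]]
  y[inside] <- leader$y[idx[inside]]
  if (any(!inside)) {
    # extrapolate backwards with the leader's initial per-frame velocity
    vx <- leader$x[2L] - leader$x[1L]
    vy <- leader$y[2L] - leader$y[1L]
    k <- idx[!inside] - 1L  # negative frame offsets
    x[!inside] <- leader$x[1L] + k * vx
    y[!inside] <- leader$y[1L] + k * vy
  }
  tr <- trajectory(x = x + offset[1L], y = y + offset[2L], id = id,
                   fps = leader$fps, body_length = leader$body_length)
  attr(tr, "params") <- list(delay_frames = d, offset = offset)
  tr
}
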