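# Per-individual kinematics from discrete positions.  Velocity is a forward
# finite difference, acceleration a central difference, heading the angle of
# the velocity vector clockwise from +y, and turning speed the wrapped
# heading difference per unit time.  Frames where a quantity is undefined
# (edges of the differencing stencils, zero speed) are NA, never
# extrapolated; downstream statistics respect the NA mask.

#' Savitzky-Golay smoothing of a trajectory
#'
#' Polynomial least-squares smoothing of x and y independently, preserving
#' the frame count (endpoint frames are fitted with the one-sided polynomial
#' fits of the filter).  Exact on polynomial paths up to `polyorder`.
#'
#' @param traj A [trajectory()].
#' @param window Odd filter window in frames (default 15, the tracking
#'   pipeline's setting at 24 fps).
#' @param polyorder Polynomial order (default 3).
#' @return A smoothed [trajectory()].
#' @export
smooth_trajectory <- function(traj, window = 15, polyorder = 3) {
  stopifnot(inherits(traj, "trajectory"))
  if (window %% 2 != 1) stop("invalid-argument: window must be odd")
  if (window > n_frames(traj)) {
    stop("invalid-argument: window exceeds frame count")
  }
  if (polyorder >= window) {
    stop("invalid-argument: polyorder must be < window")
  }
  trajectory(x = signal::sgolayfilt(traj$x, p = polyorder, n = window),
             y = signal::sgolayfilt(traj$y, p = polyorder, n = window),
             id = traj$id, fps = traj$fps, body_length = traj$body_length)
}

#' Forward-difference velocity of a trajectory
#'
#' `v(t) = (r(t + dt) - r(t)) / dt`; the final frame has no forward
#' neighbour and is NA.
#'
#' @param traj A [trajectory()].
#' @return Data frame with columns `frame` (0-based), `u` (x-component),
#'   `w` (y-component), in length units per second.
#' @export
velocity_series <- function(traj) {
  stopifnot(inherits(traj, "trajectory"))
  nf <- n_frames(traj)
  u <- c(diff(traj$x) * traj$fps, NA_real_)
  w <- c(diff(traj$y) * traj$fps, NA_real_)
  data.frame(frame = seq_len(nf) - 1L, u = u, w = w)
}

#' Central-difference acceleration of a trajectory
#'
#' `a(t) = (r(t + dt) - 2 r(t) + r(t - dt)) / dt^2`; first and last frames
#' are NA.  Exact on quadratic paths.
#'
#' @param traj A [trajectory()].
#' @return Data frame with columns `frame`, `ax`, `ay` (length units / s^2).
#' @export
acceleration_series <- function(traj) {
  stopifnot(inherits(traj, "trajectory"))
  nf <- n_frames(traj)
  if (nf < 3L) stop("invalid-argument: acceleration needs >= 3 frames")
  ax <- ay <- rep(NA_real_, nf)
  i <- 2:(nf - 1L)
  ax[i] <- (traj$x[i + 1L] - 2 * traj$x[i] + traj$x[i - 1L]) * traj$fps^2
  ay[i] <- (traj$y[i + 1L] - 2 * traj$y[i] + traj$y[i - 1L]) * traj$fps^2
  data.frame(frame = seq_len(nf) - 1L, ax = ax, ay = ay)
}

#' Turning speed from a heading series
#'
#' Wrapped heading difference per unit time: differences beyond +-180
#' degrees are folded to the shorter arc, clockwise positive.  NA wherever
#' either heading of the pair is undefined.
#'
#' @param heading Heading series in degrees (NA where undefined).
#' @param fps Frame rate.
#' @return Turning speed in degrees/s, same length, last frame NA.
#' @export
turning_speed <- function(heading, fps) {
  gamma <- c(wrap_deg(diff(heading)) * fps, NA_real_)
  gamma
}

#' Full kinematics of a trajectory
#'
#' Computes the velocity, speed, heading, acceleration and turning-speed
#' series of one individual from its raw (or pre-smoothed) positions.
#'
#' @param traj A [trajectory()].
#' @param smooth_window Optional odd window for Savitzky-Golay pre-smoothing
#'   (`NULL` = no smoothing; the empirical pipeline uses 15).
#' @param polyorder Smoothing polynomial order.
#' @return Data frame with columns `frame` (0-based), `t` (s), `u`, `w`,
#'   `speed`, `heading` (deg, clockwise from +y, NA at zero speed),
#'   `ax`, `ay`, `accel` (magnitude), `turn_speed` (deg/s), `valid`
#'   (velocity defined).  Speeds in length units per second.
#' @export
kinematics <- function(traj, smooth_window = NULL, polyorder = 3) {
  stopifnot(inherits(traj, "trajectory"))
  if (!is.null(smooth_window)) {
    traj <- smooth_trajectory(traj, window = smooth_window,
                              polyorder = polyorder)
  }
  vel <- velocity_series(traj)
  speed <- sqrt(vel$u^2 + vel$w^2)
  heading <- ifelse(!is.na(speed) & speed > 0,
                    heading_deg(vel$u, vel$w), NA_real_)
  acc <- if (n_frames(traj) >= 3L) acceleration_series(traj) else
    data.frame(frame = vel$frame, ax = NA_real_, ay = NA_real_)
  data.frame(
    frame = vel$frame,
    t = vel$frame / traj$fps,
    u = vel$u, w = vel$w,
    speed = speed,
    heading = heading,
    ax = acc$ax, ay = acc$ay,
    accel = sqrt(acc$ax^2 + acc$ay^2),
    turn_speed = turning_speed(heading, traj$fps),
    valid = !is.na(speed)
  )
}
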