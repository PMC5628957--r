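# Angle helpers.  Headings are degrees clockwise from +y ("north"),
# wrapped to (-180, 180]; turning anti-clockwise gives negative differences.

#' Wrap angles in degrees to (-180, 180]
#'
#' Angular differences beyond +-180 degrees are folded to the shorter arc,
#' preserving the sign convention (clockwise positive).
#'
#' @param x Numeric vector of angles in degrees.
#' @return Wrapped angles in (-180, 180].
#' @export
wrap_deg <- function(x) {
  w <- (x + 180) %% 360 - 180
  w[which(w == -180)] <- 180
  w
}

# heading (deg, clockwise from +y) of velocity components (u east, w north)
heading_deg <- function(u, w) atan2(u, w) * 180 / pi

deg2rad <- function(x) x * pi / 180
rad2deg <- function(x) x * 180 / pi

# rotate 2-column matrix of vectors by `rad` radians anti-clockwise
# (standard maths convention; used internally by the simulator)
rotate_vec <- function(v, rad) {
  cs <- cos(rad)
  sn <- sin(rad)
  cbind(cs * v[, 1L] - sn * v[, 2L], sn * v[, 1L] + cs * v[, 2L])
}

# row-wise normalization; zero rows stay zero
normalize_rows <- function(v) {
  nrm <- sqrt(rowSums(v^2))
  ok <- nrm > 0
  v[ok, ] <- v[ok, , drop = FALSE] / nrm[ok]
  v
}
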