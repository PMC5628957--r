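# Group-referenced geometry and order parameters: nearest-neighbour
# distance, centroid kinematics, centre distance, the group-frame transform
# (relative bearing, forward/backward coordinates, front occupancy),
# pairwise relative headings, cohesion (mean inter-individual distance) and
# polarization.

#' Nearest-neighbour distances within one frame
#'
#' @param pos An n x 2 matrix of fish positions (n >= 2).
#' @return Numeric vector of per-fish distances to the closest group mate.
#' @export
nearest_neighbour_distance <- function(pos) {
  pos <- as.matrix(pos)
  n <- nrow(pos)
  if (n < 2L) stop("invalid-argument: need >= 2 fish")
  d <- as.matrix(stats::dist(pos))
  diag(d) <- Inf
  unname(apply(d, 1L, min))
}

#' Group cohesion: mean inter-individual distance
#'
#' Mean pairwise Euclidean distance over all unordered pairs (identical to
#' the ordered-pair mean).  Smaller = more cohesive.
#'
#' @param pos An n x 2 matrix of fish positions (n >= 2).
#' @return Scalar mean pairwise distance.
#' @export
cohesion_iid <- function(pos) {
  pos <- as.matrix(pos)
  if (nrow(pos) < 2L) stop("invalid-argument: need >= 2 fish")
  mean(stats::dist(pos))
}

#' Group polarization
#'
#' Norm of the mean heading unit vector:
#' `rho = (1/n) * ||sum_i (sin psi_i, cos psi_i)||`, ranging from 0
#' (complete non-alignment) to 1 (complete alignment).  NA headings are
#' dropped (n counts valid headings); all-NA input gives NA.
#'
#' @param headings Heading vector in degrees.
#' @return Scalar in `[0, 1]`, or NA.
#' @export
polarization <- function(headings) {
  h <- headings[!is.na(headings)]
  if (length(h) == 0L) return(NA_real_)
  r <- deg2rad(h)
  sqrt(sum(sin(r))^2 + sum(cos(r))^2) / length(h)
}

#' Pairwise relative headings
#'
#' `theta_ij = wrap(psi_i - psi_j)` in degrees; antisymmetric up to the
#' 180-degree wrap.  NA where either heading is undefined.
#'
#' @param headings Heading vector (degrees) for the n fish of one frame.
#' @return An n x n matrix of wrapped heading differences (0 diagonal).
#' @export
pairwise_relative_direction <- function(headings) {
  n <- length(headings)
  wrap_deg(matrix(headings, n, n) - matrix(headings, n, n, byrow = TRUE))
}

#' Centroid trajectory and kinematics of a group
#'
#' The group centre is the per-frame mean position of all members; its
#' velocity, speed and heading are computed with the same finite-difference
#' pipeline as for individual fish.
#'
#' @param gt A [group_trajectory()].
#' @param smooth_window Optional Savitzky-Golay window applied to the member
#'   trajectories before averaging.
#' @return List with `traj` (the centroid [trajectory()]) and `kin` (its
#'   [kinematics()] table).
#' @export
centroid_series <- function(gt, smooth_window = NULL) {
  stopifnot(inherits(gt, "group_trajectory"))
  trs <- gt$trajectories
  if (!is.null(smooth_window)) {
    trs <- lapply(trs, smooth_trajectory, window = smooth_window)
  }
  xc <- rowMeans(vapply(trs, function(tr) tr$x, numeric(n_frames(gt))))
  yc <- rowMeans(vapply(trs, function(tr) tr$y, numeric(n_frames(gt))))
  ctr <- trajectory(xc, yc, id = "centroid", fps = trs[[1L]]$fps,
                    body_length = trs[[1L]]$body_length)
  list(traj = ctr, kin = kinematics(ctr))
}

#' Group-frame transform of one frame
#'
#' Shifts the origin to the group centroid and rotates into the direction of
#' travel of the group: `delta = atan2(x_i - x_c, y_i - y_c)` is the bearing
#' of fish i from the centroid, `sigma = wrap(delta - psi_c)` its bearing
#' relative to the centroid heading, and `(x', y') = CD * (sin sigma,
#' cos sigma)` its coordinates in the group frame (positive y' = in front of
#' the group centre).  Distances are preserved: `sqrt(x'^2 + y'^2) = CD`.
#'
#' @param pos An n x 2 matrix of fish positions.
#' @param psi_c Centroid heading, degrees clockwise from +y (NA when the
#'   centroid is stationary; then sigma/x'/y'/front are NA).
#' @return Data frame with columns `cd`, `delta`, `sigma`, `xprime`,
#'   `yprime`, `front` (strictly `y' > 0`).
#' @export
group_frame_transform <- function(pos, psi_c) {
  pos <- as.matrix(pos)
  dx <- pos[, 1L] - mean(pos[, 1L])
  dy <- pos[, 2L] - mean(pos[, 2L])
  cd <- sqrt(dx^2 + dy^2)
  delta <- heading_deg(dx, dy)
  if (is.na(psi_c)) {
    sigma <- xp <- yp <- rep(NA_real_, nrow(pos))
    front <- rep(NA, nrow(pos))
  } else {
    sigma <- wrap_deg(delta - psi_c)
    xp <- cd * sin(deg2rad(sigma))
    yp <- cd * cos(deg2rad(sigma))
    front <- yp > 0
  }
  data.frame(cd = cd, delta = delta, sigma = sigma,
             xprime = xp, yprime = yp, front = front)
}

#' Frame-by-frame group metrics
#'
#' Computes, for every frame of a group trajectory, the per-fish metrics
#' (speed, heading, nearest-neighbour distance, centre distance and its
#' within-group rank, group-frame coordinates, front flag) and the per-frame
#' group metrics (centroid position/speed/heading, mean inter-individual
#' distance, polarization).
#'
#' @param gt A [group_trajectory()].
#' @param smooth_window Optional Savitzky-Golay window applied to all
#'   trajectories (including before centroid computation).
#' @return List of class `group_metrics` with `per_fish` (long data frame:
#'   `frame, id, speed, heading, nnd, cd, cd_rank, delta, sigma, xprime,
#'   yprime, front`), `per_frame` (`frame, xc, yc, vc, psi_c, iid, rho`),
#'   `fps`, `body_length`.  Centroid headings at centroid speed below
#'   1e-6 length units/s are treated as undefined.
#' @export
group_metrics <- function(gt, smooth_window = NULL) {
  stopifnot(inherits(gt, "group_trajectory"))
  trs <- gt$trajectories
  if (!is.null(smooth_window)) {
    trs <- lapply(trs, smooth_trajectory, window = smooth_window)
  }
  n <- length(trs)
  nf <- n_frames(gt)
  fps <- trs[[1L]]$fps
  ids <- names(trs)
  X <- vapply(trs, function(tr) tr$x, numeric(nf))
  Y <- vapply(trs, function(tr) tr$y, numeric(nf))

  kin <- lapply(trs, kinematics)
  speed <- vapply(kin, function(k) k$speed, numeric(nf))
  heading <- vapply(kin, function(k) k$heading, numeric(nf))

  # pairwise distances, vectorized over frames
  pairs <- utils::combn(n, 2L)
  pd <- matrix(NA_real_, nf, ncol(pairs))
  nnd <- matrix(Inf, nf, n)
  for (p in seq_len(ncol(pairs))) {
    i <- pairs[1L, p]
    j <- pairs[2L, p]
    pd[, p] <- sqrt((X[, i] - X[, j])^2 + (Y[, i] - Y[, j])^2)
    nnd[, i] <- pmin(nnd[, i], pd[, p])
    nnd[, j] <- pmin(nnd[, j], pd[, p])
  }
  iid <- rowMeans(pd)

  xc <- rowMeans(X)
  yc <- rowMeans(Y)
  ctr <- trajectory(xc, yc, id = "centroid", fps = fps,
                    body_length = trs[[1L]]$body_length)
  ckin <- kinematics(ctr)
  psi_c <- ifelse(!is.na(ckin$speed) & ckin$speed > 1e-6,
                  ckin$heading, NA_real_)

  dx <- X - xc
  dy <- Y - yc
  cd <- sqrt(dx^2 + dy^2)
  delta <- heading_deg(dx, dy)
  sigma <- wrap_deg(delta - psi_c)  # NA rows where psi_c undefined
  xp <- cd * sin(deg2rad(sigma))
  yp <- cd * cos(deg2rad(sigma))
  front <- yp > 0
  cd_rank <- t(apply(cd, 1L, rank, ties.method = "average"))

  rho <- vapply(seq_len(nf), function(f) polarization(heading[f, ]),
                numeric(1))

  per_fish <- data.frame(
    frame = rep(seq_len(nf) - 1L, n),
    id = rep(ids, each = nf),
    speed = as.vector(speed), heading = as.vector(heading),
    nnd = as.vector(nnd), cd = as.vector(cd),
    cd_rank = as.vector(cd_rank),
    delta = as.vector(delta), sigma = as.vector(sigma),
    xprime = as.vector(xp), yprime = as.vector(yp),
    front = as.vector(front))
  per_frame <- data.frame(
    frame = seq_len(nf) - 1L, xc = xc, yc = yc,
    vc = ckin$speed, psi_c = psi_c, iid = iid, rho = rho)
  structure(list(per_fish = per_fish, per_frame = per_frame,
                 fps = fps, body_length = trs[[1L]]$body_length,
                 n_fish = n, ids = ids),
            class = "group_metrics")
}

#' @export
print.group_metrics <- function(x, ...) {
  cat(sprintf("<group_metrics: %d fish x %d frames>\n",
              x$n_fish, nrow(x$per_frame)))
  invisible(x)
}

#' Per-fish front-position fraction
#'
#' Fraction of frames a fish was strictly in front of the group centre
#' (`y' > 0`), over the frames where the centroid heading is defined.
#'
#' @param gm A [group_metrics()] result.
#' @param frames Optional 0-based frame indices restricting the window
#'   (e.g. the first 5 minutes of a trial).
#' @return Named numeric vector of per-fish fractions in `[0, 1]` (NaN when
#'   no frame is classifiable).
#' @export
front_fraction <- function(gm, frames = NULL) {
  pf <- gm$per_fish
  if (!is.null(frames)) pf <- pf[pf$frame %in% frames, , drop = FALSE]
  out <- tapply(pf$front, pf$id, function(fl) mean(fl, na.rm = TRUE))
  out[gm$ids]
}

#' Per-trial summary statistics of a group
#'
#' Per-fish medians of speed, nearest-neighbour distance and centre
#' distance, plus the mean centre-distance rank and front fraction; group
#' level, the means of cohesion and polarization and the group speed under
#' both conventions: the median centroid speed and the mean of the member
#' median speeds.
#'
#' @param gm A [group_metrics()] result.
#' @return List with `per_fish` (data frame) and `group` (one-row data
#'   frame).
#' @export
group_summary <- function(gm) {
  pf <- gm$per_fish
  agg <- function(v, f) as.numeric(tapply(v, pf$id, f)[gm$ids])
  med <- function(v) stats::median(v, na.rm = TRUE)
  per_fish <- data.frame(
    id = gm$ids,
    median_speed = agg(pf$speed, med),
    median_nnd = agg(pf$nnd, med),
    median_cd = agg(pf$cd, med),
    mean_cd_rank = agg(pf$cd_rank, function(v) mean(v, na.rm = TRUE)),
    front_fraction = as.numeric(front_fraction(gm)))
  group <- data.frame(
    mean_iid = mean(gm$per_frame$iid, na.rm = TRUE),
    mean_rho = mean(gm$per_frame$rho, na.rm = TRUE),
    median_centroid_speed = med(gm$per_frame$vc),
    mean_median_speed = mean(per_fish$median_speed))
  list(per_fish = per_fish, group = group)
}
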