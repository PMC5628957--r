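#' Single-individual trajectory
#'
#' A `trajectory` holds the per-frame 2-D positions of one individual sampled
#' at a uniform frame rate, together with the metadata needed to express
#' kinematics in biologically meaningful units (frames per second and body
#' length).  Coordinates are in mm for empirical data; simulator output uses
#' model length units with `body_length = 1`.
#'
#' The coordinate convention throughout the package is x to the right and
#' y "north" (up); headings are measured clockwise from +y in (-180, 180]
#' degrees.
#'
#' @param x,y Numeric vectors of equal length (>= 2): per-frame positions.
#' @param id Individual identifier (coerced to character).
#' @param fps Frame rate, frames/s (> 0). Default 24 (the tracking rate).
#' @param body_length Body length in the same length unit as `x`/`y` (> 0).
#'   Default 40.6 mm, the study population mean.
#' @return An object of class `trajectory`: a list with elements `id`, `x`,
#'   `y`, `fps`, `body_length`.
#' @export
trajectory <- function(x, y, id = "fish1", fps = 24, body_length = 40.6) {
  x <- as.numeric(x)
  y <- as.numeric(y)
  if (length(x) != length(y)) {
    stop("invalid-argument: x and y must have equal length")
  }
  if (length(x) < 2L) {
    stop("invalid-argument: a trajectory needs at least 2 frames")
  }
  if (anyNA(x) || anyNA(y)) {
    stop("invalid-argument: positions must not contain missing values")
  }
  if (!is.finite(fps) || fps <= 0) stop("invalid-argument: fps must be > 0")
  if (!is.finite(body_length) || body_length <= 0) {
    stop("invalid-argument: body_length must be > 0")
  }
  structure(
    list(id = as.character(id)[1L], x = x, y = y,
         fps = fps, body_length = body_length),
    class = "trajectory"
  )
}

#' @export
print.trajectory <- function(x, ...) {
  cat(sprintf("<trajectory '%s': %d frames @ %g fps, BL %g>\n",
              x$id, n_frames(x), x$fps, x$body_length))
  invisible(x)
}

#' Number of frames in a trajectory or group trajectory
#' @param x A `trajectory` or `group_trajectory`.
#' @return Integer frame count.
#' @export
n_frames <- function(x) {
  if (inherits(x, "group_trajectory")) x <- x$trajectories[[1L]]
  length(x$x)
}

#' Food patch geometry
#'
#' Patches are either squares (the experimental Perspex grids, given by a
#' half-width) or discs (the simulated patches, given by a radius).
#'
#' @param center Numeric length-2, patch centre.
#' @param half_width Half side length of a square patch (mm); mutually
#'   exclusive with `radius`.
#' @param radius Radius of a disc patch (length units).
#' @param items_initial Number of food items provisioned on the patch.
#' @return An object of class `food_patch`.
#' @export
food_patch <- function(center, half_width = NULL, radius = NULL,
                       items_initial = 5L) {
  center <- as.numeric(center)
  if (length(center) != 2L || anyNA(center)) {
    stop("invalid-argument: center must be a numeric pair")
  }
  if (is.null(half_width) == is.null(radius)) {
    stop("invalid-argument: give exactly one of half_width or radius")
  }
  size <- if (is.null(radius)) half_width else radius
  if (!is.finite(size) || size <= 0) {
    stop("invalid-argument: patch size must be > 0")
  }
  structure(
    list(center = center,
         shape = if (is.null(radius)) "square" else "disc",
         half_width = half_width, radius = radius,
         items_initial = as.integer(items_initial)),
    class = "food_patch"
  )
}

#' Distance from points to the boundary/interior of a patch
#'
#' Zero for points on or over the patch, otherwise the Euclidean distance to
#' the patch region.
#'
#' @param patch A `food_patch`.
#' @param x,y Numeric vectors of point coordinates.
#' @return Numeric vector of distances (0 over the patch).
#' @export
patch_distance <- function(patch, x, y) {
  dx <- x - patch$center[1L]
  dy <- y - patch$center[2L]
  if (patch$shape == "square") {
    ex <- pmax(abs(dx) - patch$half_width, 0)
    ey <- pmax(abs(dy) - patch$half_width, 0)
    sqrt(ex^2 + ey^2)
  } else {
    pmax(sqrt(dx^2 + dy^2) - patch$radius, 0)
  }
}

#' Aligned trajectories of one group
#'
#' Bundles the member trajectories of a group (identical frame counts and
#' frame rates) with the arena geometry, an optional plant-cover disc, and an
#' optional list of food patches.
#'
#' @param trajectories List of >= 2 [trajectory()] objects with identical
#'   frame counts, frame rates and unique ids.
#' @param arena Either `NULL` (unbounded), or a list
#'   `list(type = "circular", center =, radius =)` /
#'   `list(type = "periodic", size =)`.
#' @param cover Optional disc `list(center =, radius =)` of plant cover.
#' @param patches Optional list of [food_patch()] objects.
#' @return An object of class `group_trajectory`.
#' @export
group_trajectory <- function(trajectories, arena = NULL, cover = NULL,
                             patches = NULL) {
  if (length(trajectories) < 2L) {
    stop("invalid-argument: a group needs at least 2 trajectories")
  }
  stopifnot(all(vapply(trajectories, inherits, logical(1), "trajectory")))
  nf <- vapply(trajectories, n_frames, integer(1))
  if (length(unique(nf)) != 1L) {
    stop("invalid-argument: member trajectories must share frame count")
  }
  fps <- vapply(trajectories, function(tr) tr$fps, numeric(1))
  if (length(unique(fps)) != 1L) {
    stop("invalid-argument: member trajectories must share fps")
  }
  ids <- vapply(trajectories, function(tr) tr$id, character(1))
  if (anyDuplicated(ids)) {
    stop("invalid-argument: trajectory ids must be unique")
  }
  names(trajectories) <- ids
  structure(
    list(trajectories = trajectories, arena = arena, cover = cover,
         patches = patches),
    class = "group_trajectory"
  )
}

#' @export
print.group_trajectory <- function(x, ...) {
  cat(sprintf("<group_trajectory: %d fish x %d frames @ %g fps>\n",
              length(x$trajectories), n_frames(x),
              x$trajectories[[1L]]$fps))
  invisible(x)
}

#' Per-frame position matrix of a group
#'
#' @param gt A `group_trajectory`.
#' @param frame 1-based frame index.
#' @return An n-fish x 2 matrix of (x, y), rownames the fish ids.
#' @export
positions_at <- function(gt, frame) {
  n <- length(gt$trajectories)
  out <- matrix(NA_real_, n, 2L,
                dimnames = list(names(gt$trajectories), c("x", "y")))
  for (i in seq_len(n)) {
    out[i, ] <- c(gt$trajectories[[i]]$x[frame], gt$trajectories[[i]]$y[frame])
  }
  out
}

# internal: ids of a group
group_ids <- function(gt) names(gt$trajectories)
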