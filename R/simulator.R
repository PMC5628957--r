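# Zonal self-propelled-particle model of a shoal whose members differ
# consistently in intrinsic speed and goal-orientedness (omega).  Each agent
# carries a position, a unit direction, a constant intrinsic speed and a
# constant omega.  Per time step: (1) a social desired-direction vector from
# the repulsion / orientation / attraction zones (repulsion takes priority
# and is omnidirectional; orientation and attraction are restricted to the
# field of perception); (2) the goal term omega * g, where g points along
# the current motion unless a rewarding cue is within the cue-detection
# radius; (3) wrapped-Gaussian heading noise; (4) a capped turn towards the
# noisy target; (5) displacement at the intrinsic speed.  The free-schooling
# arena is periodic; the foraging arena is circular with depletable food
# patches and a repelling edge zone.

#' Simulation configuration
#'
#' Defaults follow the standard zonal-model parameterization used for small
#' shoals: arena size 500, repulsion radius 1, orientation radius 6,
#' unbounded attraction, 270-degree field of perception, turning rate 60
#' degrees per time unit, time step 0.1, speed error 0.1, omega error 0.01,
#' cue radius 30, and for the foraging context 3 patches of radius 10 with
#' 50 items each depleted at rate 0.001.  Intrinsic speeds (explored range
#' 0.1-2.0) default to mean 1.0 and omega (explored range 0.01-0.1) to mean
#' 0.05.  One model length unit corresponds to roughly one body length, and
#' one time unit to one second.
#'
#' @param n_agents Number of agents (5 or 20 in the study design).
#' @param context `"schooling"` (periodic arena, no patches) or
#'   `"foraging"` (circular arena with patches).
#' @param arena_size Periodic box side / circular arena diameter, A.
#' @param r_r,r_o,r_a Repulsion / orientation / attraction zone radii
#'   (`0 < r_r < r_o <= r_a`).
#' @param field_of_perception Perception field alpha in degrees; the blind
#'   area behind the agent is `360 - alpha` and applies to the orientation
#'   and attraction zones only.
#' @param psi_max Maximum turning rate, degrees per time unit.
#' @param speed_mean,speed_sd Mean and s.d. of the per-agent intrinsic
#'   speed draw (Gaussian mode); non-positive draws are resampled.
#' @param omega_mean,omega_sd Mean and s.d. of the per-agent omega draw,
#'   floored at 0.
#' @param speed_distribution `"gaussian"` or `"gamma"`.
#' @param gamma_shape,gamma_scale Gamma parameters (k, theta) for the
#'   right-skewed speed mode.
#' @param dt Time step.
#' @param noise_sd Heading-noise s.d. in degrees (wrapped Gaussian).
#'   Default 2.86 deg (0.05 rad), the customary value in this model
#'   lineage.
#' @param cue_radius Detection radius of a rewarding cue, r_c.
#' @param n_patches,items_per_patch,feeding_rate,patch_radius Foraging
#'   parameters: number of food patches, items provisioned per patch,
#'   Bernoulli feeding probability per on-patch agent per step, and patch
#'   radius.
#' @param boundary_zone_frac Width of the repelling edge zone of the
#'   circular arena, as a fraction of the arena radius.
#' @param n_steps Number of time steps; `NULL` picks the context default
#'   (2000 schooling, 10000 foraging).
#' @param thin_every Snapshot storage interval in steps; `NULL` picks the
#'   context default (200 schooling, 500 foraging).
#' @param literal_signs If `TRUE`, use the literal printed signs of the
#'   orientation/attraction sums (which make those terms repulsive); kept
#'   only for auditability.
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(n_agents = 5, context = c("schooling", "foraging"),
                       arena_size = 500, r_r = 1, r_o = 6, r_a = Inf,
                       field_of_perception = 270, psi_max = 60,
                       speed_mean = 1.0, speed_sd = 0.1,
                       omega_mean = 0.05, omega_sd = 0.01,
                       speed_distribution = c("gaussian", "gamma"),
                       gamma_shape = 0.4, gamma_scale = 0.05,
                       dt = 0.1, noise_sd = 2.86, cue_radius = 30,
                       n_patches = 3, items_per_patch = 50,
                       feeding_rate = 0.001, patch_radius = 10,
                       boundary_zone_frac = 0.04,
                       n_steps = NULL, thin_every = NULL,
                       literal_signs = FALSE) {
  context <- match.arg(context)
  speed_distribution <- match.arg(speed_distribution)
  if (n_agents < 1) stop("invalid-argument: n_agents must be >= 1")
  if (!(r_r > 0 && r_r < r_o && r_o <= r_a)) {
    stop("invalid-argument: need 0 < r_r < r_o <= r_a")
  }
  if (dt <= 0) stop("invalid-argument: dt must be > 0")
  if (is.null(n_steps)) {
    n_steps <- if (context == "schooling") 2000L else 10000L
  }
  if (is.null(thin_every)) {
    thin_every <- if (context == "schooling") 200L else 500L
  }
  structure(
    list(n_agents = as.integer(n_agents), context = context,
         arena_size = arena_size, r_r = r_r, r_o = r_o, r_a = r_a,
         field_of_perception = field_of_perception, psi_max = psi_max,
         speed_mean = speed_mean, speed_sd = speed_sd,
         omega_mean = omega_mean, omega_sd = omega_sd,
         speed_distribution = speed_distribution,
         gamma_shape = gamma_shape, gamma_scale = gamma_scale,
         dt = dt, noise_sd = noise_sd, cue_radius = cue_radius,
         n_patches = as.integer(n_patches),
         items_per_patch = as.integer(items_per_patch),
         feeding_rate = feeding_rate, patch_radius = patch_radius,
         boundary_zone_frac = boundary_zone_frac,
         n_steps = as.integer(n_steps), thin_every = as.integer(thin_every),
         literal_signs = literal_signs),
    class = "sim_config")
}

# arena centre for the given context
arena_center <- function(config) {
  if (config$context == "schooling") {
    rep(config$arena_size / 2, 2L)
  } else {
    c(0, 0)
  }
}

#' Draw the initial population state
#'
#' Per-agent intrinsic speed (Gaussian, resampled at a positive floor, or
#' Gamma) and omega (Gaussian floored at 0) are drawn once and held constant
#' for the whole simulation; positions are clustered at the arena centre and
#' directions uniform on the circle.  In the foraging context the three food
#' patches are placed in a randomly rotated, roughly equilateral triangular
#' formation at intermediate distance from the centre.  Deterministic under
#' a fixed seed.
#'
#' @param config A [sim_config()].
#' @param seed Optional integer seed (`set.seed` is called when given).
#' @return A world state: list with `pos` / `upos` (wrapped and unwrapped
#'   n x 2 position matrices), `dir` (unit directions), `speed`, `omega`,
#'   `eaten`, `patches` (data frame `x, y, radius, items` or NULL), `t`,
#'   `step`, `events`, `config`.
#' @export
init_population <- function(config, seed = NULL) {
  stopifnot(inherits(config, "sim_config"))
  if (!is.null(seed)) set.seed(seed)
  n <- config$n_agents
  ctr <- arena_center(config)
  ang <- stats::runif(n, 0, 2 * pi)
  rad <- sqrt(stats::runif(n)) * config$r_o
  pos <- cbind(ctr[1L] + rad * cos(ang), ctr[2L] + rad * sin(ang))
  th <- stats::runif(n, 0, 2 * pi)
  dir <- cbind(cos(th), sin(th))
  if (config$speed_distribution == "gaussian") {
    speed <- stats::rnorm(n, config$speed_mean, config$speed_sd)
    while (any(speed <= 1e-6)) {
      bad <- speed <= 1e-6
      speed[bad] <- stats::rnorm(sum(bad), config$speed_mean,
                                 config$speed_sd)
    }
  } else {
    speed <- stats::rgamma(n, shape = config$gamma_shape,
                           scale = config$gamma_scale)
    speed <- pmax(speed, 1e-6)
  }
  omega <- pmax(stats::rnorm(n, config$omega_mean, config$omega_sd), 0)
  patches <- NULL
  if (config$context == "foraging") {
    R <- config$arena_size / 2
    rot <- stats::runif(1, 0, 2 * pi)
    prad <- stats::runif(config$n_patches, 0.375 * R, 0.875 * R)
    pang <- rot + 2 * pi * (seq_len(config$n_patches) - 1) /
      config$n_patches
    patches <- data.frame(
      x = prad * cos(pang), y = prad * sin(pang),
      radius = config$patch_radius,
      items = rep(config$items_per_patch, config$n_patches))
  }
  list(pos = pos, upos = pos, dir = dir, speed = speed, omega = omega,
       eaten = integer(n), patches = patches, t = 0, step = 0L,
       events = list(), coincident = 0L, config = config)
}

# ---- physics internals (shared by sim_step and run_experiment) ----------

# social desired-direction contributions for all agents: n x 2 matrix.
# Repulsion (omnidirectional, distance <= r_r) takes priority; otherwise
# the per-zone-normalized orientation and attraction sums (restricted to
# the perception field) are added.
social_vectors_all <- function(pos, dir, config) {
  n <- nrow(pos)
  A <- config$arena_size
  dxm <- matrix(pos[, 1L], n, n, byrow = TRUE) - pos[, 1L]
  dym <- matrix(pos[, 2L], n, n, byrow = TRUE) - pos[, 2L]
  if (config$context == "schooling") {  # minimum-image on the torus
    dxm <- dxm - A * round(dxm / A)
    dym <- dym - A * round(dym / A)
  }
  d <- sqrt(dxm^2 + dym^2)
  off <- !diag(n)
  ux <- dxm / d
  uy <- dym / d
  ux[!is.finite(ux)] <- 0
  uy[!is.finite(uy)] <- 0

  repmask <- off & d > 0 & d <= config$r_r
  coincident <- off & d == 0
  cosang <- (dxm * dir[, 1L] + dym * dir[, 2L]) / d
  visible <- off & !is.na(cosang) &
    cosang >= cos(deg2rad(config$field_of_perception / 2))
  omask <- visible & d > config$r_r & d <= config$r_o
  amask <- visible & d > config$r_o & d <= config$r_a

  sgn <- if (isTRUE(config$literal_signs)) -1 else 1
  s_r <- cbind(-rowSums(ux * repmask), -rowSums(uy * repmask))
  djx <- matrix(dir[, 1L], n, n, byrow = TRUE)
  djy <- matrix(dir[, 2L], n, n, byrow = TRUE)
  s_o <- normalize_rows(sgn * cbind(rowSums(djx * omask),
                                    rowSums(djy * omask)))
  s_a <- normalize_rows(sgn * cbind(rowSums(ux * amask),
                                    rowSums(uy * amask)))
  repelled <- rowSums(repmask) > 0
  n_coin <- 0L
  if (any(coincident)) {
    # coincident positions: maximal repulsion along a random direction
    for (i in which(rowSums(coincident) > 0)) {
      a <- stats::runif(1, 0, 2 * pi)
      s_r[i, ] <- s_r[i, ] + c(cos(a), sin(a))
      repelled[i] <- TRUE
      n_coin <- n_coin + 1L
    }
  }
  s <- s_o + s_a
  s[repelled, ] <- s_r[repelled, , drop = FALSE]
  attr(s, "repelled") <- repelled
  attr(s, "coincident") <- n_coin
  s
}

#' Social desired-direction contribution of one focal agent
#'
#' If any neighbour is within the repulsion radius, returns the (priority)
#' repulsion sum pointing away from those neighbours; otherwise the sum of
#' the normalized orientation and attraction terms, each restricted to the
#' field of perception.
#'
#' @param pos n x 2 position matrix (row `focal` is the focal agent).
#' @param dir n x 2 unit direction matrix.
#' @param config A [sim_config()].
#' @param focal Row index of the focal agent, or `NULL` for all agents.
#' @return Length-2 vector (or n x 2 matrix when `focal = NULL`).
#' @export
social_vector <- function(pos, dir, config, focal = 1L) {
  s <- social_vectors_all(as.matrix(pos), as.matrix(dir), config)
  if (is.null(focal)) s else s[focal, ]
}

# goal unit vectors: current motion, or towards the nearest still-rewarding
# cue within the cue radius
goal_vectors <- function(pos, dir, config, patches) {
  g <- dir
  if (!is.null(patches)) {
    live <- which(patches$items > 0L)
    if (length(live)) {
      px <- patches$x[live]
      py <- patches$y[live]
      for (i in seq_len(nrow(pos))) {
        dd <- sqrt((px - pos[i, 1L])^2 + (py - pos[i, 2L])^2)
        k <- which.min(dd)
        if (dd[k] <= config$cue_radius && dd[k] > 0) {
          g[i, ] <- c(px[k] - pos[i, 1L], py[k] - pos[i, 2L]) / dd[k]
        }
      }
    }
  }
  g
}

#' Desired direction from social and goal terms
#'
#' `d = s / |s| + omega * g`, normalized; `g` points along the current
#' motion unless a rewarding cue lies within the cue radius, in which case
#' it points at the nearest cue.  A zero resultant keeps the previous
#' direction.
#'
#' @param s n x 2 social vectors (from [social_vector()]).
#' @param dir n x 2 current unit directions.
#' @param pos n x 2 positions.
#' @param omega Per-agent goal-orientedness weights.
#' @param config A [sim_config()].
#' @param patches Optional patch data frame (`x, y, radius, items`).
#' @return n x 2 matrix of unit desired directions.
#' @export
desired_direction <- function(s, dir, pos, omega, config, patches = NULL) {
  s <- as.matrix(s)
  g <- goal_vectors(as.matrix(pos), as.matrix(dir), config, patches)
  d <- normalize_rows(s) + omega * g
  nrm <- sqrt(rowSums(d^2))
  zero <- nrm < 1e-12
  d <- normalize_rows(d)
  d[zero, ] <- dir[zero, , drop = FALSE]
  d
}

#' Heading noise and capped turn
#'
#' The desired direction is rotated by a wrapped-Gaussian angle of s.d.
#' `noise_sd` degrees; the agent then turns from its current direction
#' towards the noisy target along the shorter arc, by at most
#' `psi_max * dt` degrees.
#'
#' @param dir n x 2 current unit directions.
#' @param target n x 2 desired unit directions.
#' @param config A [sim_config()].
#' @return n x 2 matrix of new unit directions.
#' @export
apply_noise_and_turn <- function(dir, target, config) {
  dir <- as.matrix(dir)
  target <- as.matrix(target)
  n <- nrow(dir)
  eps <- stats::rnorm(n, 0, deg2rad(config$noise_sd))
  noisy <- rotate_vec(target, eps)
  a1 <- atan2(dir[, 2L], dir[, 1L])
  a2 <- atan2(noisy[, 2L], noisy[, 1L])
  dth <- (a2 - a1 + pi) %% (2 * pi) - pi
  dth[which(dth == -pi)] <- pi
  cap <- deg2rad(config$psi_max * config$dt)
  within <- abs(dth) <= cap
  newang <- a1 + sign(dth) * cap
  out <- cbind(cos(newang), sin(newang))
  out[within, ] <- noisy[within, , drop = FALSE]
  out
}

# one synchronous update of plain state components; returns modified pieces
advance_state <- function(pos, upos, dir, speed, omega, patches, t_new,
                          config, events, eaten) {
  s <- social_vectors_all(pos, dir, config)
  target <- desired_direction(s, dir, pos, omega, config, patches)
  if (config$context == "foraging") {
    R <- config$arena_size / 2
    rr <- sqrt(rowSums(pos^2))
    edge <- rr >= R * (1 - config$boundary_zone_frac)
    if (any(edge)) {
      b <- -pos[edge, , drop = FALSE] / rr[edge]
      target[edge, ] <- b
    }
  }
  dir <- apply_noise_and_turn(dir, target, config)
  stepv <- dir * speed * config$dt
  upos <- upos + stepv
  pos <- pos + stepv
  if (config$context == "schooling") {
    pos <- pos %% config$arena_size
  } else {
    R <- config$arena_size / 2
    rr <- sqrt(rowSums(pos^2))
    out <- rr > R
    if (any(out)) {  # clamp to the wall; direction already points inward
      pos[out, ] <- pos[out, , drop = FALSE] * (R / rr[out])
      upos[out, ] <- pos[out, , drop = FALSE]
    }
    # feeding: Bernoulli(f) per on-patch agent per step, agents in index
    # order, one item per draw while items remain
    if (!is.null(patches)) {
      for (i in seq_len(nrow(pos))) {
        dd <- sqrt((patches$x - pos[i, 1L])^2 + (patches$y - pos[i, 2L])^2)
        k <- which(dd <= patches$radius & patches$items > 0L)
        if (length(k)) {
          k <- k[which.min(dd[k])]
          if (stats::runif(1) < config$feeding_rate) {
            patches$items[k] <- patches$items[k] - 1L
            eaten[i] <- eaten[i] + 1L
            events[[length(events) + 1L]] <-
              c(time = t_new, agent = i, patch = k)
          }
        }
      }
    }
  }
  if (any(!is.finite(pos))) {
    stop(sprintf("internal-error: non-finite position at t = %g", t_new))
  }
  list(pos = pos, upos = upos, dir = dir, patches = patches,
       events = events, eaten = eaten,
       coincident = attr(s, "coincident"))
}

#' Advance a simulation world by one time step
#'
#' Synchronous update of all agents: social vector, goal reconciliation,
#' boundary handling, heading noise, capped turn, displacement, then
#' feeding (foraging context).
#'
#' @param world A world state from [init_population()].
#' @return The world at `t + dt`.
#' @export
sim_step <- function(world) {
  config <- world$config
  st <- advance_state(world$pos, world$upos, world$dir, world$speed,
                      world$omega, world$patches,
                      world$t + config$dt, config, world$events,
                      world$eaten)
  world$pos <- st$pos
  world$upos <- st$upos
  world$dir <- st$dir
  world$patches <- st$patches
  world$events <- st$events
  world$eaten <- st$eaten
  world$coincident <- world$coincident + st$coincident
  world$t <- world$t + config$dt
  world$step <- world$step + 1L
  world
}

#' Feeding update of a foraging world (no movement)
#'
#' Applies only the Bernoulli feeding draws for agents currently on a
#' still-provisioned patch.  Exposed for direct testing of the feeding
#' process; [sim_step()] applies the same rule after displacement.
#'
#' @param world A foraging world state.
#' @return The world with items, eaten counts and the event log updated.
#' @export
feeding_update <- function(world) {
  config <- world$config
  if (is.null(world$patches)) {
    stop("invalid-argument: feeding requires a foraging world")
  }
  p <- world$patches
  for (i in seq_len(nrow(world$pos))) {
    dd <- sqrt((p$x - world$pos[i, 1L])^2 + (p$y - world$pos[i, 2L])^2)
    k <- which(dd <= p$radius & p$items > 0L)
    if (length(k)) {
      k <- k[which.min(dd[k])]
      if (stats::runif(1) < config$feeding_rate) {
        p$items[k] <- p$items[k] - 1L
        world$eaten[i] <- world$eaten[i] + 1L
        world$events[[length(world$events) + 1L]] <-
          c(time = world$t, agent = i, patch = k)
      }
    }
  }
  world$patches <- p
  world
}

#' Run one simulated trial
#'
#' Runs the model for the configured number of steps (2000 for the
#' free-schooling context, 10000 for foraging, by default) and returns
#' analysis-grade full-resolution trajectories, the thinned snapshot frames
#' of the storage protocol, the feeding-event log and the per-agent traits.
#' Periodic trajectories are returned unwrapped (continuous across the
#' torus seam) so that finite-difference kinematics are exact; the wrapped
#' coordinates stay internal to the dynamics.
#'
#' @param config A [sim_config()].
#' @param seed Integer seed.
#' @return List of class `sim_result`: `gt` (a [group_trajectory()] with
#'   fps `1/dt` and body length 1 model unit), `agents` (data frame `id,
#'   speed, omega, eaten`), `events` (data frame `time, agent, patch`),
#'   `patches` (final patch state), `thin_frames` (0-based stored-snapshot
#'   frame indices), `config`, `seed`.
#' @export
run_experiment <- function(config, seed = 1L) {
  stopifnot(inherits(config, "sim_config"))
  world <- init_population(config, seed = seed)
  n <- config$n_agents
  ns <- config$n_steps
  X <- matrix(NA_real_, ns + 1L, n)
  Y <- matrix(NA_real_, ns + 1L, n)
  X[1L, ] <- world$upos[, 1L]
  Y[1L, ] <- world$upos[, 2L]
  pos <- world$pos
  upos <- world$upos
  dir <- world$dir
  patches <- world$patches
  events <- list()
  eaten <- world$eaten
  coincident <- 0L
  for (k in seq_len(ns)) {
    st <- advance_state(pos, upos, dir, world$speed, world$omega, patches,
                        k * config$dt, config, events, eaten)
    pos <- st$pos
    upos <- st$upos
    dir <- st$dir
    patches <- st$patches
    events <- st$events
    eaten <- st$eaten
    coincident <- coincident + st$coincident
    X[k + 1L, ] <- upos[, 1L]
    Y[k + 1L, ] <- upos[, 2L]
  }
  fps <- 1 / config$dt
  ids <- sprintf("a%d", seq_len(n))
  trajs <- lapply(seq_len(n), function(i) {
    trajectory(X[, i], Y[, i], id = ids[i], fps = fps, body_length = 1)
  })
  arena <- if (config$context == "schooling") {
    list(type = "periodic", size = config$arena_size)
  } else {
    list(type = "circular", center = c(0, 0),
         radius = config$arena_size / 2)
  }
  patch_objs <- NULL
  if (!is.null(patches)) {
    patch_objs <- lapply(seq_len(nrow(patches)), function(k) {
      food_patch(center = c(patches$x[k], patches$y[k]),
                 radius = patches$radius[k],
                 items_initial = config$items_per_patch)
    })
  }
  gt <- group_trajectory(trajs, arena = arena, patches = patch_objs)
  ev <- if (length(events)) {
    as.data.frame(do.call(rbind, events))
  } else {
    data.frame(time = numeric(0), agent = numeric(0), patch = numeric(0))
  }
  structure(
    list(gt = gt,
         agents = data.frame(id = ids, speed = world$speed,
                             omega = world$omega, eaten = eaten),
         events = ev, patches = patches,
         thin_frames = seq(config$thin_every, ns, by = config$thin_every),
         coincident = coincident, config = config, seed = seed),
    class = "sim_result")
}

#' @export
print.sim_result <- function(x, ...) {
  cat(sprintf(
    "<sim_result: %d agents, %d steps (%s context), %d feeding events>\n",
    x$config$n_agents, x$config$n_steps, x$config$context, nrow(x$events)))
  invisible(x)
}

#' Rescale simulator output to empirical units
#'
#' Interprets one model length unit as one body length and one time unit as
#' one second, scaling positions to mm so that the empirical analysis
#' thresholds (mm, cm/s, BL/s) apply directly.
#'
#' @param sim A `sim_result` (or its `gt`).
#' @param bl_mm Body length in mm per model unit (default 40.6).
#' @return A [group_trajectory()] in mm with `body_length = bl_mm`.
#' @export
sim_to_mm <- function(sim, bl_mm = 40.6) {
  gt <- if (inherits(sim, "sim_result")) sim$gt else sim
  stopifnot(inherits(gt, "group_trajectory"))
  trajs <- lapply(gt$trajectories, function(tr) {
    trajectory(tr$x * bl_mm, tr$y * bl_mm, id = tr$id, fps = tr$fps,
               body_length = bl_mm)
  })
  group_trajectory(trajs, arena = gt$arena, cover = gt$cover,
                   patches = gt$patches)
}
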