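# Shared in-code fixtures for the test suite.

# a two-fish group swimming north in parallel, fish 1 always `lead_bl` body
# lengths ahead of fish 2
parallel_pair <- function(n_frames = 120, speed = 60, lead_bl = 2,
                          fps = 24, bl = 40.6) {
  f1 <- make_line(speed, heading = 0, n_frames = n_frames, fps = fps,
                  origin = c(0, lead_bl * bl), id = "f1",
                  body_length = bl)
  f2 <- make_line(speed, heading = 0, n_frames = n_frames, fps = fps,
                  origin = c(0, 0), id = "f2", body_length = bl)
  group_trajectory(list(f1, f2))
}

# a group built from explicit per-fish position matrices (frames x 2)
group_from_positions <- function(..., fps = 24, bl = 40.6) {
  mats <- list(...)
  trajs <- lapply(seq_along(mats), function(i) {
    trajectory(mats[[i]][, 1L], mats[[i]][, 2L], id = sprintf("f%d", i),
               fps = fps, body_length = bl)
  })
  group_trajectory(trajs)
}

# a leader along +y with a non-periodic speed modulation (two
# incommensurate sinusoids), so the delayed-correlation profile has a
# unique maximum at the planted lag
speeding_leader <- function(n_frames = 2400, fps = 24, base = 80,
                            amp = 20, period_s = 3, bl = 40.6) {
  t <- (seq_len(n_frames) - 1) / fps
  sp <- base + amp * sin(2 * pi * t / period_s) +
    0.6 * amp * sin(2 * pi * t / (period_s * exp(1)))
  trajectory(x = rep(0, n_frames), y = cumsum(sp) / fps, id = "leader",
             fps = fps, body_length = bl)
}

# synthetic assay cohort for behaviour scores: per-fish true tendencies plus
# trial noise, two trials each
make_assay_cohort <- function(n_fish = 20, n_groups = 4, seed = 1) {
  set.seed(seed)
  ids <- sprintf("fish%02d", seq_len(n_fish))
  bold <- runif(n_fish, 0.05, 0.95)
  dist <- runif(n_fish, 50, 450)
  assays <- data.frame(
    id = rep(ids, each = 2),
    trial = rep(1:2, n_fish),
    prop_out_cover = pmin(pmax(rep(bold, each = 2) +
                                 rnorm(2 * n_fish, 0, 0.03), 0), 1),
    shoal_distance = pmax(rep(dist, each = 2) +
                            rnorm(2 * n_fish, 0, 10), 1))
  groups <- data.frame(id = ids,
                       group = rep(seq_len(n_groups),
                                   length.out = n_fish))
  list(assays = assays, groups = groups, true_bold = bold,
       true_dist = dist, ids = ids)
}

# rotate row-vectors clockwise-in-heading terms by `deg` (used to build
# turn-cap targets)
rotate_target <- function(v, deg) {
  th <- deg * pi / 180
  cbind(cos(th) * v[, 1] - sin(th) * v[, 2],
        sin(th) * v[, 1] + cos(th) * v[, 2])
}

# fast simulator config for structural tests
quick_config <- function(...) {
  sim_config(n_steps = 200L, thin_every = 50L, ...)
}
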