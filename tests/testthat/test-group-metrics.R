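test_that("nearest-neighbour distance and cohesion match brute-force enumeration", {
  collinear <- cbind(c(0, 1, 3), 0)
  expect_equal(nearest_neighbour_distance(collinear), c(1, 1, 2))
  expect_equal(nearest_neighbour_distance(rbind(c(1, 1), c(1, 1))),
               c(0, 0))
  s <- 2.5
  tri <- rbind(c(0, 0), c(s, 0), c(s / 2, s * sqrt(3) / 2))
  expect_equal(nearest_neighbour_distance(tri), rep(s, 3))

  expect_equal(cohesion_iid(rbind(c(0, 0), c(0, 7))), 7)
  expect_equal(cohesion_iid(tri), s)
  sq <- rbind(c(0, 0), c(1, 0), c(1, 1), c(0, 1))
  expect_equal(cohesion_iid(sq), (4 * 1 + 2 * sqrt(2)) / 6)
  # brute force on random configurations up to 6 fish
  set.seed(11)
  for (n in 3:6) {
    pos <- matrix(runif(2 * n, 0, 100), n, 2)
    pd <- as.matrix(dist(pos))
    expect_equal(cohesion_iid(pos), mean(pd[upper.tri(pd)]))
    expect_equal(nearest_neighbour_distance(pos),
                 unname(apply(pd + diag(Inf, n), 1, min)))
    # the smallest pair distance never exceeds the pair mean
    expect_lte(min(nearest_neighbour_distance(pos)),
               cohesion_iid(pos) + 1e-12)
  }
  expect_error(nearest_neighbour_distance(matrix(0, 1, 2)),
               "invalid-argument")
  expect_error(cohesion_iid(matrix(0, 1, 2)), "invalid-argument")
})

test_that("polarization anchors and bounds hold", {
  expect_equal(polarization(c(37, 37, 37, 37)), 1)
  expect_equal(polarization(c(90, -90)), 0)
  expect_equal(polarization(c(0, 90)), sqrt(2) / 2)
  expect_true(is.na(polarization(c(NA_real_, NA_real_))))
  set.seed(3)
  for (k in 1:25) {
    rho <- polarization(runif(sample(2:8, 1), -180, 180))
    expect_gte(rho, 0)
    expect_lte(rho, 1 + 1e-12)
  }
})

test_that("pairwise relative direction wraps and is antisymmetric", {
  th <- pairwise_relative_direction(c(170, -170))
  expect_equal(th[1, 2], -20)
  expect_equal(th[2, 1], 20)
  par <- pairwise_relative_direction(c(12, 12, 12))
  expect_true(all(par == 0))
  anti <- pairwise_relative_direction(c(0, 180))
  expect_equal(abs(anti[1, 2]), 180)
})

test_that("group-frame transform places fish relative to travel direction", {
  # fish ahead of a centroid travelling north
  pos <- rbind(c(0, 30), c(0, -30))
  tf <- group_frame_transform(pos, psi_c = 0)
  expect_equal(tf$sigma, c(0, 180))
  expect_equal(tf$yprime, c(30, -30))
  expect_equal(tf$front, c(TRUE, FALSE))

  # group travelling east, fish due north of centroid: left flank
  pos2 <- rbind(c(0, 50), c(0, -50))
  tf2 <- group_frame_transform(pos2, psi_c = 90)
  expect_equal(tf2$sigma[1], -90)
  expect_equal(tf2$xprime[1], -50)
  expect_equal(tf2$yprime[1], 0, tolerance = 1e-12)

  # isometry: group-frame radius equals centre distance
  set.seed(5)
  pos3 <- matrix(rnorm(10, sd = 40), 5, 2)
  tf3 <- group_frame_transform(pos3, psi_c = 37)
  expect_equal(sqrt(tf3$xprime^2 + tf3$yprime^2), tf3$cd)
  # stationary centroid masks the transform
  tfna <- group_frame_transform(pos3, psi_c = NA_real_)
  expect_true(all(is.na(tfna$front)))
})

test_that("group metrics are invariant under rigid motions", {
  sim <- run_experiment(quick_config(), seed = 2)
  gm <- group_metrics(sim$gt)
  th <- 0.7
  R <- matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2, 2)
  shift <- c(123, -45)
  moved <- lapply(sim$gt$trajectories, function(tr) {
    xy <- cbind(tr$x, tr$y) %*% R
    trajectory(xy[, 1] + shift[1], xy[, 2] + shift[2], id = tr$id,
               fps = tr$fps, body_length = tr$body_length)
  })
  gm2 <- group_metrics(group_trajectory(moved))
  expect_equal(gm2$per_frame$iid, gm$per_frame$iid, tolerance = 1e-9)
  expect_equal(gm2$per_frame$rho, gm$per_frame$rho, tolerance = 1e-9)
  expect_equal(gm2$per_fish$nnd, gm$per_fish$nnd, tolerance = 1e-9)
  expect_equal(gm2$per_fish$cd, gm$per_fish$cd, tolerance = 1e-9)
  # group-frame coordinates co-rotate with the travel direction
  expect_equal(gm2$per_fish$sigma, gm$per_fish$sigma, tolerance = 1e-6)
  expect_equal(gm2$per_fish$yprime, gm$per_fish$yprime, tolerance = 1e-6)
})

test_that("centroid kinematics and front occupancy behave on constructed groups", {
  # mirrored pair: centroid pinned at the origin
  t <- 0:49
  f1 <- cbind(10 + t, 5 + 2 * t)
  gt <- group_from_positions(f1, -f1)
  cs <- centroid_series(gt)
  expect_equal(cs$traj$x, rep(0, 50))
  expect_equal(cs$kin$speed[1:49], rep(0, 49))

  # common translation north at 10 mm/s
  gt2 <- parallel_pair(speed = 10)
  cs2 <- centroid_series(gt2)
  expect_equal(cs2$kin$speed[1:119], rep(10, 119))
  expect_equal(cs2$kin$heading[1:119], rep(0, 119))

  gm <- group_metrics(gt2)
  expect_equal(mean(vapply(gt2$trajectories, function(tr) tr$x[1],
                           numeric(1))), gm$per_frame$xc[1])
  ff <- front_fraction(gm)
  expect_equal(unname(ff["f1"]), 1)
  expect_equal(unname(ff["f2"]), 0)
  expect_true(all(ff >= 0 & ff <= 1))
})

test_that("trial summaries use the stated conventions", {
  f1 <- make_line(10, 0, n_frames = 60, origin = c(0, 50), id = "s1")
  f2 <- make_line(20, 0, n_frames = 60, origin = c(30, 0), id = "s2")
  gm <- group_metrics(group_trajectory(list(f1, f2)))
  gs <- group_summary(gm)
  expect_equal(gs$per_fish$median_speed, c(10, 20))
  expect_equal(gs$group$mean_median_speed, 15)
  expect_equal(gs$group$median_centroid_speed, 15)
  # determinism of a seeded simulator summary
  s1 <- group_summary(group_metrics(run_experiment(quick_config(),
                                                   seed = 9)$gt))
  s2 <- group_summary(group_metrics(run_experiment(quick_config(),
                                                   seed = 9)$gt))
  expect_identical(s1, s2)
})
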