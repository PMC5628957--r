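test_that("provisioning arithmetic matches the experimental design", {
  pr <- provisioning()
  expect_equal(pr$items_per_trial, 15)
  expect_equal(pr$max_daily_intake, 30)
  expect_equal(provisioning(n_patches = 3, items_per_patch = 50,
                            trials_per_day = 1)$items_per_trial, 150)
})

test_that("patch discovery honours the vicinity rule and tie-break", {
  bl <- 40.6
  patch <- food_patch(c(200, 0), half_width = 25)
  # fish A crosses the patch at t = 3 s; B arrives later; C never comes
  fps <- 24
  nfr <- 24 * 6
  mk <- function(x0, v, id) {
    make_line(v, heading = 90, n_frames = nfr, origin = c(x0, 0), id = id)
  }
  # A at x = 200 - 25 - 30 (vicinity edge) exactly at t = 3
  a <- mk(200 - 55 - 3 * 50, 50, "A")
  b <- mk(200 - 55 - 5 * 50, 50, "B")
  c_ <- make_line(0, 0, n_frames = nfr, origin = c(-500, -500), id = "C")
  gt <- group_trajectory(list(a, b, c_), patches = list(patch))
  pd <- patch_discovery(gt)
  expect_equal(pd$discoveries$id, "A")
  expect_equal(pd$discoveries$time_s, 3, tolerance = 1 / fps)
  expect_equal(pd$arrivals$id[pd$arrivals$order], c("A", "B"))

  # passing at 31 mm from the boundary: no discovery
  graze <- make_line(100, heading = 0, n_frames = nfr,
                     origin = c(200 - 25 - 31, -100), id = "G")
  far <- make_line(0, 0, n_frames = nfr, origin = c(-500, 0), id = "F")
  gt2 <- group_trajectory(list(graze, far), patches = list(patch))
  expect_equal(nrow(patch_discovery(gt2)$discoveries), 0L)
  # ... and at exactly 30 mm it counts
  touch <- make_line(100, heading = 0, n_frames = nfr,
                     origin = c(200 - 25 - 30, -100), id = "T")
  gt3 <- group_trajectory(list(touch, far), patches = list(patch))
  expect_equal(patch_discovery(gt3)$discoveries$id, "T")

  # simultaneous arrival: tie broken by fish order
  twin1 <- mk(200 - 55 - 2 * 50, 50, "z_first")
  twin2 <- mk(200 - 55 - 2 * 50, 50, "a_second")
  gt4 <- group_trajectory(list(twin1, twin2), patches = list(patch))
  expect_equal(patch_discovery(gt4)$discoveries$id, "z_first")
})

test_that("depletion latencies account for every provisioned item", {
  lat <- depletion_latencies(c(20, 10, 30), n_provisioned = 3,
                             trial_end = 300)
  expect_equal(lat$latency_s, c(10, 20, 30))
  expect_false(any(lat$censored))

  lat2 <- depletion_latencies(runif(12, 0, 300), n_provisioned = 15,
                              trial_end = 300)
  expect_equal(sum(lat2$censored), 3L)
  expect_equal(nrow(lat2), 15L)
  expect_true(all(lat2$latency_s[lat2$censored] == 300))
  expect_error(depletion_latencies(1:5, 3, 10), "invalid-argument")

  dt1 <- depletion_time(c(5, 9, 14), n = 2, t_max = 100)
  expect_equal(dt1$latency_s, 9)
  dt2 <- depletion_time(c(5), n = 2, t_max = 100)
  expect_true(dt2$censored)
  expect_equal(dt2$latency_s, 100)
})

test_that("cover metrics reproduce hand-computed occupancy", {
  fps <- 2
  nfr <- 240  # 120 s at 2 fps
  cover <- list(center = c(0, 0), radius = 75)
  # A: outside for the second half; others always inside
  ax <- c(rep(0, 120), rep(200, 120))
  a <- trajectory(ax, rep(0, nfr), id = "A", fps = fps)
  b <- trajectory(rep(10, nfr), rep(5, nfr), id = "B", fps = fps)
  c_ <- trajectory(rep(-10, nfr), rep(5, nfr), id = "C", fps = fps)
  gt <- group_trajectory(list(a, b, c_), cover = cover)
  cm <- cover_metrics(gt)
  expect_equal(cm$per_fish$prop_out, c(0.5, 0, 0))
  expect_equal(cm$per_fish$prop_out_alone, c(0.5, 0, 0))
  expect_equal(cm$group$mean_n_out, 0.5)
  expect_equal(cm$group$prop_all_out, 0)

  # all fish always out
  far <- lapply(1:3, function(i) {
    trajectory(rep(300 + i, 10), rep(0, 10), id = sprintf("f%d", i),
               fps = fps)
  })
  cm2 <- cover_metrics(group_trajectory(far), cover = cover)
  expect_equal(cm2$group$prop_all_out, 1)
  expect_equal(cm2$per_fish$prop_out_alone, c(0, 0, 0))

  # single excursion with a staggered exit order A, B, C
  sx <- function(t0) c(rep(0, t0), rep(200, nfr - t0))
  stag <- group_trajectory(list(
    trajectory(sx(60), rep(0, nfr), id = "A", fps = fps),
    trajectory(sx(90), rep(0, nfr), id = "B", fps = fps),
    trajectory(sx(120), rep(0, nfr), id = "C", fps = fps)),
    cover = cover)
  cm3 <- cover_metrics(stag)
  expect_equal(cm3$group$n_excursions, 1)
  expect_equal(cm3$per_fish$mean_leave_order, c(1, 2, 3))
  expect_error(cover_metrics(group_trajectory(far)), "invalid-argument")
})

test_that("behaviour scores scale, invert and relativize as specified", {
  cohort <- make_assay_cohort(n_fish = 20, n_groups = 4)
  sc <- behavior_scores(cohort$assays, cohort$groups)
  expect_true(all(sc$exploration >= 0 & sc$exploration <= 1))
  expect_true(all(sc$social_proximity >= 0 & sc$social_proximity <= 1))
  # the fish closest to the shoal gets proximity 1, the farthest 0
  expect_equal(sc$social_proximity[which.min(cohort$true_dist)], 1,
               tolerance = 0.05)
  expect_equal(sc$social_proximity[which.max(cohort$true_dist)], 0,
               tolerance = 0.05)
  # sqrt + invert + scale is strictly monotone decreasing in distance
  mean_d <- tapply(cohort$assays$shoal_distance, cohort$assays$id, mean)
  ord <- order(mean_d[sc$id])
  expect_true(all(diff(sc$social_proximity[ord]) < 0))
  # relative scores: focal minus group-mates mean
  k <- 3
  mates <- sc$group == sc$group[k] & sc$id != sc$id[k]
  expect_equal(sc$relative_exploration[k],
               sc$exploration[k] - mean(sc$exploration[mates]))
  # single-trial fish are flagged
  one <- cohort$assays[cohort$assays$trial == 1, ]
  expect_warning(s1 <- behavior_scores(one), "single-trial")
  expect_true(all(s1$single_trial))
})

test_that("simulated foraging events feed the depletion accounting", {
  sim <- run_experiment(sim_config(context = "foraging",
                                   speed_mean = 2, omega_mean = 0.1,
                                   n_steps = 4000L), seed = 5)
  provided <- sim$config$n_patches * sim$config$items_per_patch
  expect_equal(sum(sim$patches$items) + sum(sim$agents$eaten), provided)
  if (nrow(sim$events) > 0) {
    lat <- depletion_latencies(sim$events$time, provided,
                               trial_end = sim$config$n_steps *
                                 sim$config$dt)
    expect_equal(sum(!lat$censored), nrow(sim$events))
    expect_true(all(diff(lat$latency_s) >= 0))
  }
})
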