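# Foraging-context analytics: patch discovery order, depletion latencies,
# cover occupancy, and the individual behavioural scores (exploration and
# social proximity) derived from the two assay types.

#' Provisioning arithmetic of the foraging design
#'
#' Items provided per foraging trial (patches x items per patch) and the
#' theoretical per-fish daily maximum intake (trials per day x items per
#' trial).
#'
#' @param n_patches Food patches per trial (default 3).
#' @param items_per_patch Items per patch (default 5 bloodworms).
#' @param trials_per_day Foraging trials per day (default 2).
#' @return List with `items_per_trial` and `max_daily_intake`.
#' @export
provisioning <- function(n_patches = 3, items_per_patch = 5,
                         trials_per_day = 2) {
  items <- n_patches * items_per_patch
  list(items_per_trial = items,
       max_daily_intake = trials_per_day * items)
}

#' Patch discovery order
#'
#' A fish is "in the vicinity" of a patch when within `vicinity` length
#' units of the patch boundary or over the patch; the discoverer of a
#' patch is the first arrival during the trial (ties within one frame
#' broken by fish order in the group).
#'
#' @param gt A [group_trajectory()] with `patches` set (or `patches`
#'   given).
#' @param patches Optional list of [food_patch()] overriding
#'   `gt$patches`.
#' @param vicinity Vicinity margin around the patch boundary (default 30,
#'   mm in empirical units).
#' @return List with `discoveries` (data frame `patch, id, time_s,
#'   frame`: the first arrival per discovered patch) and `arrivals` (full
#'   arrival order: one row per fish per patch it ever visited).
#'   Undiscovered patches contribute no rows.
#' @export
patch_discovery <- function(gt, patches = NULL, vicinity = 30) {
  if (is.null(patches)) patches <- gt$patches
  if (is.null(patches)) stop("invalid-argument: no patches defined")
  fps <- gt$trajectories[[1L]]$fps
  ids <- group_ids(gt)
  arr <- list()
  for (p in seq_along(patches)) {
    for (i in seq_along(ids)) {
      tr <- gt$trajectories[[i]]
      near <- patch_distance(patches[[p]], tr$x, tr$y) <= vicinity
      if (any(near)) {
        f <- which(near)[1L]
        arr[[length(arr) + 1L]] <- data.frame(
          patch = p, id = ids[i], fish = i, frame = f - 1L,
          time_s = (f - 1L) / fps)
      }
    }
  }
  if (!length(arr)) {
    empty <- data.frame(patch = integer(0), id = character(0),
                        fish = integer(0), frame = integer(0),
                        time_s = numeric(0))
    return(list(discoveries = empty, arrivals = empty))
  }
  arrivals <- do.call(rbind, arr)
  arrivals <- arrivals[order(arrivals$patch, arrivals$frame,
                             arrivals$fish), , drop = FALSE]
  arrivals$order <- stats::ave(arrivals$frame, arrivals$patch,
                               FUN = seq_along)
  first <- arrivals[!duplicated(arrivals$patch), , drop = FALSE]
  rownames(arrivals) <- rownames(first) <- NULL
  list(discoveries = first, arrivals = arrivals)
}

#' Per-item depletion latencies
#'
#' Sorted latencies of item consumptions from trial start; items never
#' eaten are censored at trial end.
#'
#' @param times Consumption times in seconds (any order).
#' @param n_provisioned Items provided in the trial.
#' @param trial_end Trial length in seconds (censoring time).
#' @return Data frame `item, latency_s, censored` with one row per
#'   provisioned item.
#' @export
depletion_latencies <- function(times, n_provisioned, trial_end) {
  times <- sort(as.numeric(times))
  if (length(times) > n_provisioned) {
    stop("invalid-argument: more events than provisioned items")
  }
  n_cens <- n_provisioned - length(times)
  data.frame(
    item = seq_len(n_provisioned),
    latency_s = c(times, rep(trial_end, n_cens)),
    censored = c(rep(FALSE, length(times)), rep(TRUE, n_cens)))
}

#' Latency to the n-th consumed item
#'
#' Survival-style depletion-speed summary: the time at which the `n`-th
#' item was consumed, censored at `t_max` when fewer were eaten.
#'
#' @param times Consumption times in seconds.
#' @param n Item count of interest.
#' @param t_max Censoring time.
#' @return List with `latency_s` and `censored`.
#' @export
depletion_time <- function(times, n, t_max) {
  times <- sort(as.numeric(times))
  if (length(times) >= n) {
    list(latency_s = times[n], censored = FALSE)
  } else {
    list(latency_s = t_max, censored = TRUE)
  }
}

#' Cover-occupancy metrics
#'
#' Out-of-cover is scored from the tracked point being outside the cover
#' disc.  Per fish: proportion of time out of cover, proportion out of
#' cover alone (no group mate concurrently out), and the mean order number
#' for leaving cover over excursions (an excursion is a maximal run of
#' frames in which the group centroid is outside the disc; within an
#' excursion fish are ordered by their first out-of-cover frame, ties by
#' fish order).  Group level: mean number of fish out per frame and the
#' proportion of time all fish were out.
#'
#' @param gt A [group_trajectory()] with `cover` set (or `cover` given).
#' @param cover Optional `list(center =, radius =)` overriding
#'   `gt$cover`.
#' @param frames Optional 0-based frame indices restricting the window
#'   (e.g. while food was still available).
#' @return List with `per_fish` (`id, prop_out, prop_out_alone,
#'   mean_leave_order`), `group` (`mean_n_out, prop_all_out,
#'   n_excursions`).
#' @export
cover_metrics <- function(gt, cover = NULL, frames = NULL) {
  if (is.null(cover)) cover <- gt$cover
  if (is.null(cover)) stop("invalid-argument: no cover region defined")
  n <- length(gt$trajectories)
  nf <- n_frames(gt)
  sel <- if (is.null(frames)) seq_len(nf) else frames + 1L
  out <- vapply(gt$trajectories, function(tr) {
    sqrt((tr$x - cover$center[1L])^2 + (tr$y - cover$center[2L])^2) >
      cover$radius
  }, logical(nf))
  out <- out[sel, , drop = FALSE]
  n_out <- rowSums(out)
  prop_out <- colMeans(out)
  prop_alone <- colMeans(out & n_out == 1L)

  xc <- rowMeans(vapply(gt$trajectories, function(tr) tr$x,
                        numeric(nf)))[sel]
  yc <- rowMeans(vapply(gt$trajectories, function(tr) tr$y,
                        numeric(nf)))[sel]
  ctr_out <- sqrt((xc - cover$center[1L])^2 +
                  (yc - cover$center[2L])^2) > cover$radius
  runs <- rle(ctr_out)
  ends <- cumsum(runs$lengths)
  starts <- ends - runs$lengths + 1L
  exc <- which(runs$values)
  orders <- matrix(NA_real_, length(exc), n)
  for (k in seq_along(exc)) {
    fr <- starts[exc[k]]:ends[exc[k]]
    first <- apply(out[fr, , drop = FALSE], 2L, function(v) {
      if (any(v)) which(v)[1L] else NA_integer_
    })
    participated <- !is.na(first)
    if (any(participated)) {
      orders[k, participated] <- rank(first[participated],
                                      ties.method = "first")
    }
  }
  mean_order <- if (length(exc)) {
    apply(orders, 2L, function(v) {
      if (all(is.na(v))) NA_real_ else mean(v, na.rm = TRUE)
    })
  } else {
    rep(NA_real_, n)
  }
  list(
    per_fish = data.frame(id = group_ids(gt), prop_out = prop_out,
                          prop_out_alone = prop_alone,
                          mean_leave_order = mean_order),
    group = data.frame(mean_n_out = mean(n_out),
                       prop_all_out = mean(n_out == n),
                       n_excursions = length(exc)))
}

#' Individual behavioural scores from the two assays
#'
#' Exploration ("boldness"): the per-fish mean, across the two boldness
#' trials, of the proportion of time out of cover, min-max scaled to
#' `[0, 1]` across the cohort.  Social proximity: the per-fish mean shoal
#' distance, square-root transformed and inverted (cohort max minus
#' value) before min-max scaling, so that higher scores mean a stronger
#' proximity tendency.  Relative scores subtract the mean score of the
#' fish's group mates from the focal fish's score.
#'
#' @param assays Data frame with one row per fish per trial: columns
#'   `id`, `trial`, `prop_out_cover` (boldness assay) and
#'   `shoal_distance` (social assay, mm).
#' @param groups Optional data frame `id, group` enabling the relative
#'   scores.
#' @return Data frame `id, exploration, social_proximity` (plus
#'   `relative_exploration, relative_social_proximity` when `groups` is
#'   given) and `single_trial` (TRUE when a fish had fewer than 2
#'   trials).
#' @export
behavior_scores <- function(assays, groups = NULL) {
  need <- c("id", "prop_out_cover", "shoal_distance")
  if (!all(need %in% names(assays))) {
    stop("invalid-argument: assays needs id, prop_out_cover, shoal_distance")
  }
  ids <- unique(assays$id)
  ntrial <- as.integer(table(assays$id)[ids])
  expl_raw <- as.numeric(tapply(assays$prop_out_cover, assays$id,
                                mean)[ids])
  soc_raw <- as.numeric(tapply(assays$shoal_distance, assays$id,
                               mean)[ids])
  minmax <- function(v) {
    r <- range(v)
    if (diff(r) == 0) return(rep(0.5, length(v)))
    (v - r[1L]) / diff(r)
  }
  soc_t <- sqrt(soc_raw)
  soc_inv <- max(soc_t) - soc_t
  out <- data.frame(
    id = ids,
    exploration = minmax(expl_raw),
    social_proximity = minmax(soc_inv),
    single_trial = ntrial < 2L)
  if (any(out$single_trial)) {
    warning("single-trial scores for: ",
            paste(ids[out$single_trial], collapse = ", "))
  }
  if (!is.null(groups)) {
    out$group <- groups$group[match(out$id, groups$id)]
    rel <- function(score) {
      vapply(seq_len(nrow(out)), function(k) {
        mates <- out$group == out$group[k] & out$id != out$id[k]
        score[k] - mean(score[mates])
      }, numeric(1))
    }
    out$relative_exploration <- rel(out$exploration)
    out$relative_social_proximity <- rel(out$social_proximity)
  }
  out
}
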