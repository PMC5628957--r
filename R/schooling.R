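# Frame-wise schooling classification.  A frame counts as schooling when
# the group is cohesive (mean inter-individual distance below a ceiling),
# moves (centroid speed above a floor), is aligned (polarization above a
# floor), and has no outlier or group split; thresholds are boundary
# inclusive.  A 5 x 5 x 5 grid of alternative thresholds provides a
# robustness scan of any correlation built on the schooling proportion.

#' Schooling criteria
#'
#' Defaults: IID <= 160 mm, centroid speed >= 0.5 BL/s, polarization
#' >= 0.6, no outlier or split at the 4-BL proximity cut-off.
#'
#' @param iid_max Cohesion ceiling, mm (same length unit as the data).
#' @param vc_min_bl Centroid-speed floor in body lengths per second.
#' @param rho_min Polarization floor in (0, 1].
#' @param outlier_nnd_max_bl Connectivity cut-off for the outlier/split
#'   rule, in body lengths.
#' @return List of class `schooling_criteria`.
#' @export
schooling_criteria <- function(iid_max = 160, vc_min_bl = 0.5,
                               rho_min = 0.6, outlier_nnd_max_bl = 4) {
  if (iid_max <= 0 || vc_min_bl <= 0 || outlier_nnd_max_bl <= 0) {
    stop("invalid-argument: thresholds must be > 0")
  }
  if (rho_min <= 0 || rho_min > 1) {
    stop("invalid-argument: rho_min must be in (0, 1]")
  }
  structure(list(iid_max = iid_max, vc_min_bl = vc_min_bl,
                 rho_min = rho_min,
                 outlier_nnd_max_bl = outlier_nnd_max_bl),
            class = "schooling_criteria")
}

# connected components of an adjacency matrix (tiny n; label propagation)
components_of <- function(adj) {
  n <- nrow(adj)
  comp <- seq_len(n)
  repeat {
    new <- comp
    for (i in seq_len(n)) {
      new[i] <- min(comp[adj[i, ] | seq_len(n) == i])
    }
    if (identical(new, comp)) break
    comp <- new
  }
  match(comp, unique(comp))
}

#' Outlier / group-split detection for one frame
#'
#' Links fish whose pairwise distance is at most `max_link` body lengths
#' and inspects the connected components: a fully connected group is `ok`;
#' two or more components of two or more fish each is a `split`; otherwise
#' any isolated fish makes the frame an `outlier`.
#'
#' @param pos An n x 2 position matrix.
#' @param body_length Body length in the positions' length unit.
#' @param max_link Cut-off in body lengths (default 4).
#' @return List with `status` (`"ok"`, `"outlier"` or `"split"`),
#'   `isolated` (logical per fish) and `components` (integer labels).
#' @export
detect_outlier_split <- function(pos, body_length, max_link = 4) {
  pos <- as.matrix(pos)
  n <- nrow(pos)
  if (n < 2L) stop("invalid-argument: need >= 2 fish")
  d <- as.matrix(stats::dist(pos))
  adj <- d <= max_link * body_length
  diag(adj) <- FALSE
  comp <- components_of(adj)
  sizes <- tabulate(comp)
  status <- if (length(sizes) == 1L) {
    "ok"
  } else if (sum(sizes >= 2L) >= 2L) {
    "split"
  } else {
    "outlier"
  }
  list(status = status, isolated = sizes[comp] == 1L, components = comp)
}

#' Frame-wise schooling classification
#'
#' Boundary-inclusive: a frame is schooling iff `iid <= iid_max`,
#' `vc >= vc_min`, `rho >= rho_min` and the split status is `ok`.  Frames
#' with any masked input are NA (excluded, not non-schooling).
#'
#' @param iid Mean inter-individual distance (length units).
#' @param vc Centroid speed in body lengths per second.
#' @param rho Polarization.
#' @param status Character vector of split statuses (`"ok"` etc.).
#' @param criteria A [schooling_criteria()].
#' @return Logical vector (NA where any input is masked).
#' @export
classify_frames <- function(iid, vc, rho, status, criteria) {
  ok <- status == "ok"
  out <- iid <= criteria$iid_max & vc >= criteria$vc_min_bl &
    rho >= criteria$rho_min & ok
  out
}

#' Proportion of classified frames spent schooling
#'
#' @param flags Logical classification vector (NA = unclassified).
#' @return Fraction in `[0, 1]`; NA when no frame is classifiable.
#' @export
schooling_proportion <- function(flags) {
  if (all(is.na(flags))) return(NA_real_)
  mean(flags, na.rm = TRUE)
}

#' Per-frame schooling table of one trial
#'
#' Computes the metrics feeding the classifier (IID, centroid speed in
#' BL/s, polarization, outlier/split status) plus the classification under
#' the given criteria.
#'
#' @param gt A [group_trajectory()].
#' @param criteria A [schooling_criteria()].
#' @param smooth_window Optional Savitzky-Golay window.
#' @return Data frame `frame, iid, vc_bl, vc, rho, status, schooling`
#'   carrying attribute `body_length`.
#' @export
schooling_table <- function(gt, criteria = schooling_criteria(),
                            smooth_window = NULL) {
  gm <- group_metrics(gt, smooth_window = smooth_window)
  bl <- gm$body_length
  nf <- nrow(gm$per_frame)
  status <- character(nf)
  for (f in seq_len(nf)) {
    status[f] <- detect_outlier_split(
      positions_at(gt, f), bl,
      max_link = criteria$outlier_nnd_max_bl)$status
  }
  vc_bl <- gm$per_frame$vc / bl
  out <- data.frame(
    frame = gm$per_frame$frame,
    iid = gm$per_frame$iid,
    vc_bl = vc_bl,
    vc = gm$per_frame$vc,
    rho = gm$per_frame$rho,
    status = status,
    schooling = classify_frames(gm$per_frame$iid, vc_bl,
                                gm$per_frame$rho, status, criteria))
  attr(out, "body_length") <- bl
  out
}

#' Threshold grid of the schooling-robustness scan
#'
#' Polarization 0.4-0.8 (step 0.1), centroid speed 1.0-3.0 cm/s (step
#' 0.5) and cohesion 100-220 mm (step 30): 125 combinations, of which one
#' is the primary criterion set (polarization 0.6, 2.0 cm/s -- the grid
#' point the 0.5 BL/s primary speed threshold maps to at a 40.6 mm body
#' length -- and 160 mm).
#'
#' @return Data frame `rho_min, speed_cm_s, iid_max, primary` with
#'   attribute `n_alternatives` (combinations minus the primary).
#' @export
robustness_thresholds <- function() {
  grid <- expand.grid(rho_min = c(0.4, 0.5, 0.6, 0.7, 0.8),
                      speed_cm_s = c(1.0, 1.5, 2.0, 2.5, 3.0),
                      iid_max = c(100, 130, 160, 190, 220))
  grid$primary <- grid$rho_min == 0.6 & grid$speed_cm_s == 2.0 &
    grid$iid_max == 160
  attr(grid, "n_alternatives") <- nrow(grid) - sum(grid$primary)
  grid
}

#' Robustness scan of a schooling-proportion correlation
#'
#' Recomputes the per-trial schooling proportion under every threshold
#' combination of [robustness_thresholds()] and correlates it (Spearman)
#' with a scalar per-trial group covariate.
#'
#' @param tables List of [schooling_table()] data frames, one per trial
#'   (>= 3).  Speed thresholds are applied in cm/s on the `vc` column; the
#'   tables must therefore be in mm (for simulator output use
#'   [sim_to_mm()]).
#' @param covariate Numeric per-trial covariate (e.g. group mean intrinsic
#'   speed).
#' @param exact Use the exact Spearman permutation p-value (only for
#'   <= 12 trials); default asymptotic t approximation.
#' @return The [robustness_thresholds()] grid with columns `rho_s`, `p`
#'   and `n_trials` added; attribute `n_alternatives` preserved.
#' @export
robustness_grid <- function(tables, covariate, exact = FALSE) {
  if (length(tables) < 3L) stop("invalid-argument: need >= 3 trials")
  if (length(covariate) != length(tables)) {
    stop("invalid-argument: one covariate value per trial")
  }
  if (stats::sd(covariate) == 0) {
    stop("undefined-result: covariate has zero variance")
  }
  grid <- robustness_thresholds()
  grid$rho_s <- NA_real_
  grid$p <- NA_real_
  grid$n_trials <- length(tables)
  for (r in seq_len(nrow(grid))) {
    props <- vapply(tables, function(tab) {
      vc_cm <- tab$vc / 10  # mm/s -> cm/s
      fl <- tab$iid <= grid$iid_max[r] & vc_cm >= grid$speed_cm_s[r] &
        tab$rho >= grid$rho_min[r] & tab$status == "ok"
      schooling_proportion(fl)
    }, numeric(1))
    if (stats::sd(props, na.rm = TRUE) == 0 || all(is.na(props))) next
    ct <- suppressWarnings(
      stats::cor.test(props, covariate, method = "spearman",
                      exact = exact))
    grid$rho_s[r] <- unname(ct$estimate)
    grid$p[r] <- ct$p.value
  }
  grid
}
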