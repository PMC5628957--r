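# Propagation-of-motion analysis.  For each dyad, the speed (Pearson) or
# direction (mean heading-vector dot product) of fish i at time t is
# compared with fish j at t + tau for lags up to +-72 frames (3 s at 24
# fps); the lag maximising the correlation estimates who precedes whom.
# Positive tau means i precedes (leads) j.  Analysis frames are restricted
# to close (< 4 BL), fast-moving (> 1 BL/s each) pairs.

#' Eligible analysis frames of a dyad
#'
#' Strict inequalities: pairwise distance < `max_dist_bl` body lengths and
#' both fish faster than `min_speed_bl` body lengths per second.
#'
#' @param gt A [group_trajectory()].
#' @param i,j Fish indices.
#' @param kin Optional precomputed list of [kinematics()] tables (one per
#'   fish).
#' @param max_dist_bl Distance cut-off in body lengths (default 4).
#' @param min_speed_bl Speed floor in body lengths per second (default 1).
#' @return Logical per-frame mask (FALSE where speeds are undefined).
#' @export
eligible_frames <- function(gt, i, j, kin = NULL, max_dist_bl = 4,
                            min_speed_bl = 1) {
  bl <- gt$trajectories[[1L]]$body_length
  ti <- gt$trajectories[[i]]
  tj <- gt$trajectories[[j]]
  if (is.null(kin)) kin <- lapply(gt$trajectories, kinematics)
  d <- sqrt((ti$x - tj$x)^2 + (ti$y - tj$y)^2)
  si <- kin[[i]]$speed
  sj <- kin[[j]]$speed
  m <- d < max_dist_bl * bl & !is.na(si) & !is.na(sj) &
    si > min_speed_bl * bl & sj > min_speed_bl * bl
  m
}

# correlation profile over lags -max_lag..max_lag for one frame range
lag_profile <- function(a, b, eligible, lags, channel, min_overlap,
                        frames = seq_along(a)) {
  nf <- length(a)
  vapply(lags, function(lag) {
    ta <- frames[frames + lag >= 1L & frames + lag <= nf]
    tb <- ta + lag
    m <- eligible[ta] & eligible[tb] & !is.na(a[ta]) & !is.na(b[tb])
    if (sum(m) < min_overlap) return(NA_real_)
    x <- a[ta][m]
    y <- b[tb][m]
    if (channel == "speed") {
      if (stats::sd(x) == 0 || stats::sd(y) == 0) return(NA_real_)
      stats::cor(x, y)
    } else {
      mean(cos(deg2rad(x - y)))
    }
  }, numeric(1))
}

#' Delayed correlation of one dyad
#'
#' For every lag `tau` in `-max_lag..max_lag` frames, correlates fish i's
#' series at `t` with fish j's at `t + tau` over the eligible overlapping
#' frames: Pearson correlation for the speed channel, the mean cosine of
#' the heading difference for the direction channel.  The delay estimate
#' `tau*` is the argmax lag (ties broken towards the smaller absolute
#' lag); with sliding windows the reported `tau*` is the mean of the
#' per-window maxima.
#'
#' @param a,b Per-frame series of fish i and j: speeds (speed channel) or
#'   headings in degrees (direction channel).
#' @param eligible Logical per-frame eligibility mask (see
#'   [eligible_frames()]); `TRUE` everywhere if omitted.
#' @param fps Frame rate.
#' @param channel `"speed"` or `"direction"`.
#' @param max_lag Scan half-width in frames (default 72, i.e. 3 s at 24
#'   fps).
#' @param min_overlap Minimum eligible overlapping frames per lag (default
#'   240, i.e. 10 s at 24 fps); lags with fewer are undefined, and a dyad
#'   with no defined lag returns NA.
#' @param window_s Sliding-window length in seconds (`NULL` = single
#'   whole-series window); windows overlap 50%.
#' @return List of class `dyad_delay`: `tau_frames`, `tau_s` (positive = i
#'   precedes j), `peak`, `n_windows`, `profile` (whole-series lag
#'   profile), `lags`.
#' @export
delayed_correlation <- function(a, b, eligible = NULL, fps = 24,
                                channel = c("speed", "direction"),
                                max_lag = 72, min_overlap = 240,
                                window_s = NULL) {
  channel <- match.arg(channel)
  nf <- length(a)
  stopifnot(length(b) == nf)
  if (is.null(eligible)) eligible <- rep(TRUE, nf)
  lags <- seq.int(-max_lag, max_lag)
  tie_order <- order(abs(lags), lags)
  pick <- function(prof) {
    if (all(is.na(prof))) return(NA_integer_)
    best <- max(prof, na.rm = TRUE)
    cand <- which(prof == best)
    cand[order(match(cand, tie_order))][1L]
  }
  profile <- lag_profile(a, b, eligible, lags, channel, min_overlap)
  if (is.null(window_s)) {
    k <- pick(profile)
    tau <- if (is.na(k)) NA_real_ else lags[k]
    peak <- if (is.na(k)) NA_real_ else profile[k]
    nw <- 1L
  } else {
    w <- round(window_s * fps)
    starts <- seq(1L, max(1L, nf - w + 1L), by = max(1L, w %/% 2L))
    taus <- peaks <- numeric(0)
    for (s in starts) {
      fr <- s:min(nf, s + w - 1L)
      prof <- lag_profile(a, b, eligible, lags, channel, min_overlap,
                          frames = fr)
      k <- pick(prof)
      if (!is.na(k)) {
        taus <- c(taus, lags[k])
        peaks <- c(peaks, prof[k])
      }
    }
    nw <- length(taus)
    tau <- if (nw) mean(taus) else NA_real_
    peak <- if (nw) mean(peaks) else NA_real_
  }
  structure(list(tau_frames = tau, tau_s = tau / fps, peak = peak,
                 n_windows = nw, profile = profile, lags = lags),
            class = "dyad_delay")
}

#' Dyadic delays of all pairs in a group
#'
#' @param gt A [group_trajectory()].
#' @param channel `"speed"` or `"direction"`.
#' @param use_diff First-difference the speed series before correlating
#'   (default `FALSE`: raw speeds).
#' @param smooth_window Optional Savitzky-Golay window for the kinematics.
#' @param max_dist_bl,min_speed_bl Eligibility cut-offs, body lengths and
#'   BL/s.
#' @param max_lag,min_overlap,window_s Passed to [delayed_correlation()].
#' @return Data frame `i, j, id_i, id_j, tau_s, peak, n_windows` (one row
#'   per unordered pair; `tau_s > 0` means i precedes j).
#' @export
dyad_delays <- function(gt, channel = c("speed", "direction"),
                        use_diff = FALSE, smooth_window = NULL,
                        max_dist_bl = 4, min_speed_bl = 1,
                        max_lag = 72, min_overlap = 240,
                        window_s = NULL) {
  channel <- match.arg(channel)
  trs <- gt$trajectories
  if (!is.null(smooth_window)) {
    trs <- lapply(trs, smooth_trajectory, window = smooth_window)
    gt <- group_trajectory(trs, arena = gt$arena, cover = gt$cover,
                           patches = gt$patches)
  }
  kin <- lapply(gt$trajectories, kinematics)
  fps <- gt$trajectories[[1L]]$fps
  series <- lapply(kin, function(k) {
    if (channel == "speed") {
      if (use_diff) c(NA_real_, diff(k$speed)) else k$speed
    } else {
      k$heading
    }
  })
  n <- length(trs)
  pairs <- utils::combn(n, 2L)
  rows <- lapply(seq_len(ncol(pairs)), function(p) {
    i <- pairs[1L, p]
    j <- pairs[2L, p]
    el <- eligible_frames(gt, i, j, kin = kin, max_dist_bl = max_dist_bl,
                          min_speed_bl = min_speed_bl)
    dd <- delayed_correlation(series[[i]], series[[j]], el, fps = fps,
                              channel = channel, max_lag = max_lag,
                              min_overlap = min_overlap,
                              window_s = window_s)
    data.frame(i = i, j = j, id_i = names(trs)[i], id_j = names(trs)[j],
               tau_s = dd$tau_s, peak = dd$peak, n_windows = dd$n_windows)
  })
  do.call(rbind, rows)
}

#' Directed leadership network from dyadic delays
#'
#' For each dyad with a defined non-zero delay, adds a directed edge from
#' the earlier (leading) fish to the later one, weighted by the absolute
#' delay in seconds; zero-delay dyads contribute no edge.
#'
#' @param dyads A [dyad_delays()] data frame.
#' @param ids Optional character vector of all fish ids (so that fish with
#'   no edges still appear as nodes).
#' @return List of class `leadership_network`: `graph` (directed, weighted
#'   `igraph`), `edges` (`leader, follower, delay_s, peak`), `summary`
#'   (`id, out_degree, in_degree, net, mean_lead_delay_s`).
#' @export
leadership_network <- function(dyads, ids = NULL) {
  if (is.null(ids)) ids <- sort(unique(c(dyads$id_i, dyads$id_j)))
  keep <- !is.na(dyads$tau_s) & dyads$tau_s != 0
  d <- dyads[keep, , drop = FALSE]
  leader <- ifelse(d$tau_s > 0, d$id_i, d$id_j)
  follower <- ifelse(d$tau_s > 0, d$id_j, d$id_i)
  edges <- data.frame(leader = leader, follower = follower,
                      delay_s = abs(d$tau_s), peak = d$peak)
  g <- igraph::graph_from_data_frame(edges, directed = TRUE,
                                     vertices = data.frame(name = ids))
  igraph::E(g)$weight <- edges$delay_s
  outd <- igraph::degree(g, mode = "out")
  ind <- igraph::degree(g, mode = "in")
  mld <- vapply(ids, function(id) {
    w <- edges$delay_s[edges$leader == id]
    if (length(w)) mean(w) else NA_real_
  }, numeric(1))
  summary <- data.frame(id = ids, out_degree = as.integer(outd[ids]),
                        in_degree = as.integer(ind[ids]),
                        net = as.integer(outd[ids] - ind[ids]),
                        mean_lead_delay_s = mld)
  structure(list(graph = g, edges = edges, summary = summary),
            class = "leadership_network")
}

#' @export
print.leadership_network <- function(x, ...) {
  cat(sprintf("<leadership_network: %d fish, %d edges>\n",
              nrow(x$summary), nrow(x$edges)))
  invisible(x)
}
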