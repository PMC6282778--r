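#' Segment the position stream into shuttle trials
#'
#' A trial is one end-to-end run: it starts at the first position sample
#' beyond an endzone boundary (entry into the running ROI) and ends at the
#' first sample beyond the opposite boundary; intervals are half-open in
#' time. Excursions that return to the endzone they started from are kept
#' in the table but marked excluded with reason `"incomplete"`. Slope
#' direction is determined by the departure end: trials departing the
#' ground-level end (the end opposite the block's elevated end) are uphill.
#' For 0-degree blocks the block's recorded `elevated_end` carries the
#' running-direction convention of the session's tilted blocks, so the
#' same rule applies.
#'
#' @param positions data.frame `t`, `x`, `y` (validated).
#' @param geometry A [track_geometry()].
#' @param schedule Session schedule table (block per row).
#' @return data.frame with one row per excursion: `trial_id`, `block_id`,
#'   `tilt_deg`, `direction`, `t_start_s`, `t_end_s`, `duration_s`,
#'   `mean_speed_cms` (ROI length / duration), `included`, `reason`.
#'   Excursions in progress when a block ends are dropped. An empty
#'   data.frame (with columns) if the rat never leaves an endzone.
#' @export
segment_trials <- function(positions, geometry, schedule) {
  empty <- data.frame(trial_id = integer(0), block_id = integer(0),
                      tilt_deg = numeric(0), direction = character(0),
                      t_start_s = numeric(0), t_end_s = numeric(0),
                      duration_s = numeric(0), mean_speed_cms = numeric(0),
                      included = logical(0), reason = character(0))
  rows <- list()
  for (bi in seq_len(nrow(schedule))) {
    blk <- schedule[bi, ]
    sel <- positions$t >= blk$t_start & positions$t < blk$t_end
    t <- positions$t[sel]
    x <- positions$x[sel]
    if (length(t) < 2) next
    # zone per sample: "south", "roi", "north"
    zone <- ifelse(x < geometry$roi_min_cm, "south",
                   ifelse(x >= geometry$roi_max_cm, "north", "roi"))
    ground_end <- opposite_end(blk$elevated_end)
    i <- 1L
    n <- length(zone)
    while (i <= n) {
      if (zone[i] != "roi") { i <- i + 1L; next }
      # need a known departure end before the first ROI sample
      if (i == 1L) {
        while (i <= n && zone[i] == "roi") i <- i + 1L
        next
      }
      dep <- zone[i - 1L]
      j <- i
      while (j <= n && zone[j] == "roi") j <- j + 1L
      if (j > n) break                      # excursion truncated by block end
      arr <- zone[j]
      t0 <- t[i]
      t1 <- t[j]
      direction <- if (dep == ground_end) "uphill" else "downhill"
      if (arr == dep) {
        rows[[length(rows) + 1L]] <- data.frame(
          block_id = blk$block_id, tilt_deg = blk$tilt_deg,
          direction = direction, t_start_s = t0, t_end_s = t1,
          duration_s = t1 - t0,
          mean_speed_cms = geometry$roi_long_cm / (t1 - t0),
          included = FALSE, reason = "incomplete")
      } else {
        rows[[length(rows) + 1L]] <- data.frame(
          block_id = blk$block_id, tilt_deg = blk$tilt_deg,
          direction = direction, t_start_s = t0, t_end_s = t1,
          duration_s = t1 - t0,
          mean_speed_cms = geometry$roi_long_cm / (t1 - t0),
          included = TRUE, reason = "")
      }
      i <- j
    }
  }
  if (!length(rows)) return(empty)
  out <- do.call(rbind, rows)
  out <- cbind(trial_id = seq_len(nrow(out)), out)
  out
}

#' Apply the trial-inclusion speed filter
#'
#' Trials that took longer than 7 s to shuttle (mean speed below about
#' 15 cm/s over the 103 cm ROI) are marked excluded with reason `"slow"`;
#' previously excluded trials keep their reason. Applying the filter twice
#' equals applying it once.
#'
#' @param trials Output of [segment_trials()].
#' @param max_duration_s Exclusion threshold (s); strictly greater is
#'   excluded.
#' @return The trial table with updated `included`/`reason`.
#' @export
apply_trial_filters <- function(trials, max_duration_s = 7) {
  if (!nrow(trials)) return(trials)
  slow <- trials$included & trials$duration_s > max_duration_s
  trials$included[slow] <- FALSE
  trials$reason[slow] <- "slow"
  trials
}

#' Number of fine-grid bins occupied in a set of trials
#'
#' Builds the running-ROI occupancy map from the included trials and counts
#' bins with at least `min_dwell_s` of dwell, the measure used to quantify
#' how much of the track the animal used under a condition.
#'
#' @param positions data.frame `t`, `x`, `y`.
#' @param trials Trial table (only `included` rows contribute).
#' @param geometry A [track_geometry()].
#' @param min_dwell_s Minimum dwell for a bin to count (s).
#' @return Integer bin count (0 for an empty condition).
#' @export
occupied_extent <- function(positions, trials, geometry,
                            min_dwell_s = 0.1) {
  occ <- build_occupancy_map(positions, trials, geometry,
                             min_dwell_s = min_dwell_s)
  sum(occ$visited)
}

# Per-trial firing rates of one unit: in-ROI spikes / trial duration,
# for the included trials handed in. Trials are disjoint, so spikes are
# assigned by a single interval search.
trial_firing_rates <- function(spike_times, trials, positions, geometry) {
  n <- nrow(trials)
  if (!n) return(numeric(0))
  o <- order(trials$t_start_s)
  ts <- trials$t_start_s[o]
  te <- trials$t_end_s[o]
  counts <- integer(n)
  if (length(spike_times)) {
    idx <- findInterval(spike_times, ts)
    ok <- idx >= 1 & spike_times < te[pmax(idx, 1L)]
    if (any(ok)) {
      x <- stats::approx(positions$t, positions$x, spike_times[ok],
                         rule = 2, ties = "ordered")$y
      inr <- in_roi(x, geometry)
      counts <- tabulate(idx[ok][inr], nbins = n)
    }
  }
  out <- numeric(n)
  out[o] <- counts
  out / trials$duration_s
}
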