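#' Build an occupancy map
#'
#' Accumulates per-bin dwell time on the fine 2.5 cm grid over the running
#' ROI from the included trials of one condition. Each position sample
#' contributes its forward inter-sample interval to the bin it falls in
#' (intervals are capped at five times the median to survive tracking
#' gaps). Bins with less than `min_dwell_s` (100 ms) of dwell are marked
#' unvisited and excluded from every downstream computation; occupancy
#' probabilities `p_i` are dwell fractions over visited bins.
#'
#' @param positions data.frame `t`, `x`, `y`.
#' @param trials Trial table; only rows with `included` contribute.
#' @param geometry A [track_geometry()].
#' @param min_dwell_s Visited-bin threshold (s).
#' @return Object of class `occupancy_map`: `dwell` (short x long axis
#'   matrix, s), `visited` (logical matrix), `total_time_s` (included-trial
#'   time), `unanalyzable` flag (no included trials), and the geometry.
#' @export
build_occupancy_map <- function(positions, trials, geometry,
                                min_dwell_s = 0.1) {
  ny <- geometry$n_bins_short
  nx <- geometry$n_bins_long
  dwell <- matrix(0, ny, nx)
  inc <- trials[trials$included, , drop = FALSE]
  total <- if (nrow(inc)) sum(inc$duration_s) else 0
  if (nrow(inc)) {
    t <- positions$t
    dt <- diff(t)
    dt <- c(dt, stats::median(dt))
    dt <- pmin(dt, 5 * stats::median(dt))
    keep <- rep(FALSE, length(t))
    for (i in seq_len(nrow(inc)))
      keep <- keep | (t >= inc$t_start_s[i] & t < inc$t_end_s[i])
    bin <- fine_bin_index(positions$x[keep], positions$y[keep], geometry)
    ok <- !is.na(bin$ix)
    if (any(ok)) {
      idx <- (bin$ix[ok] - 1L) * ny + bin$iy[ok]
      acc <- tapply(dt[keep][ok], idx, sum)
      dwell[as.integer(names(acc))] <- acc
    }
  }
  structure(list(dwell = dwell, visited = dwell >= min_dwell_s,
                 total_time_s = total, min_dwell_s = min_dwell_s,
                 unanalyzable = nrow(inc) == 0, geometry = geometry),
            class = "occupancy_map")
}

# occupancy probabilities over visited bins (matrix, NA unvisited)
occupancy_prob <- function(occ) {
  p <- occ$dwell
  p[!occ$visited] <- NA
  tot <- sum(p, na.rm = TRUE)
  if (tot > 0) p <- p / tot
  p
}

#' Build a firing-rate map
#'
#' Bins the unit's spikes from the same included trials as the occupancy
#' map and divides elementwise by dwell time: `rate = spikes / dwell` on
#' visited bins. Spikes landing in removed (sub-100 ms) bins are excluded
#' from the map but still counted in `n_spikes_roi`, the count used by the
#' 100-spike place-cell criterion.
#'
#' @param spike_times Numeric vector of spike times (s).
#' @param positions data.frame `t`, `x`, `y` (for spike positions, by
#'   linear interpolation at spike times).
#' @param trials Trial table; spikes outside included trials are ignored.
#' @param occupancy The matching [build_occupancy_map()] result.
#' @return Object of class `rate_map`: `rate` (Hz; NA unvisited),
#'   `n_spikes_map`, `n_spikes_roi`, `mean_rate_hz` (occupancy-weighted
#'   mean), plus the occupancy reference.
#' @export
build_rate_map <- function(spike_times, positions, trials, occupancy) {
  g <- occupancy$geometry
  ny <- g$n_bins_short
  counts <- matrix(0, ny, g$n_bins_long)
  n_roi <- 0L
  inc <- trials[trials$included, , drop = FALSE]
  if (nrow(inc) && length(spike_times)) {
    keep <- rep(FALSE, length(spike_times))
    for (i in seq_len(nrow(inc)))
      keep <- keep | (spike_times >= inc$t_start_s[i] &
                      spike_times < inc$t_end_s[i])
    st <- spike_times[keep]
    if (length(st)) {
      sx <- stats::approx(positions$t, positions$x, st, rule = 2, ties = "ordered")$y
      sy <- stats::approx(positions$t, positions$y, st, rule = 2, ties = "ordered")$y
      bin <- fine_bin_index(sx, sy, g)
      ok <- !is.na(bin$ix)
      n_roi <- sum(ok)
      if (any(ok)) {
        idx <- (bin$ix[ok] - 1L) * ny + bin$iy[ok]
        acc <- tapply(rep(1L, sum(ok)), idx, sum)
        counts[as.integer(names(acc))] <- acc
      }
    }
  }
  rate <- counts / occupancy$dwell
  rate[!occupancy$visited] <- NA
  p <- occupancy_prob(occupancy)
  mean_rate <- sum(p * rate, na.rm = TRUE)
  structure(list(rate = rate, occupancy = occupancy,
                 n_spikes_map = sum(counts[occupancy$visited]),
                 n_spikes_roi = n_roi, mean_rate_hz = mean_rate),
            class = "rate_map")
}

# Gaussian kernel smoothing with unvisited-bin renormalisation. sigma in
# bins; kernel truncated at 3 sigma. Unvisited bins stay NA and are
# excluded from each bin's kernel mass (renormalised rather than
# zero-filled, to avoid deflating rates at ROI edges).
smooth_matrix <- function(m, visited, sigma = 1, trunc = 3) {
  r <- ceiling(trunc * sigma)
  off <- -r:r
  k <- exp(-(off^2) / (2 * sigma^2))
  k2 <- outer(k, k)
  ny <- nrow(m)
  nx <- ncol(m)
  num <- matrix(0, ny, nx)
  den <- matrix(0, ny, nx)
  mv <- m
  mv[!visited] <- 0
  w <- visited * 1
  for (dy in off) for (dx in off) {
    ks <- k2[dy + r + 1, dx + r + 1]
    ys <- max(1, 1 - dy):min(ny, ny - dy)
    xs <- max(1, 1 - dx):min(nx, nx - dx)
    num[ys, xs] <- num[ys, xs] + ks * mv[ys + dy, xs + dx]
    den[ys, xs] <- den[ys, xs] + ks * w[ys + dy, xs + dx]
  }
  out <- num / den
  out[!visited] <- NA
  out
}

#' Smooth a rate map
#'
#' Gaussian smoothing with a one-bin (2.5 cm) sigma, truncated at three
#' sigma, used only as the input to place-field detection; the metric
#' battery is computed on unsmoothed maps. Unvisited bins are excluded
#' from the kernel and the remaining mass renormalised.
#'
#' @param rm A [build_rate_map()] result.
#' @param sigma_bins Kernel sigma in bins.
#' @return A `rate_map` whose `rate` is the smoothed map (`smoothed` flag
#'   set).
#' @export
smooth_rate_map <- function(rm, sigma_bins = 1) {
  out <- rm
  out$rate <- smooth_matrix(rm$rate, rm$occupancy$visited,
                            sigma = sigma_bins)
  out$smoothed <- TRUE
  out
}

# 8-connected component labelling of a logical matrix (flood fill).
label_components <- function(mask) {
  ny <- nrow(mask)
  nx <- ncol(mask)
  lab <- matrix(0L, ny, nx)
  nxt <- 0L
  for (j in seq_len(nx)) for (i in seq_len(ny)) {
    if (!mask[i, j] || lab[i, j] != 0L) next
    nxt <- nxt + 1L
    queue <- matrix(c(i, j), ncol = 2)
    lab[i, j] <- nxt
    while (nrow(queue)) {
      cur <- queue[1, , drop = FALSE]
      queue <- queue[-1, , drop = FALSE]
      for (dy in -1:1) for (dx in -1:1) {
        if (dy == 0 && dx == 0) next
        yi <- cur[1] + dy
        xi <- cur[2] + dx
        if (yi < 1 || yi > ny || xi < 1 || xi > nx) next
        if (mask[yi, xi] && lab[yi, xi] == 0L) {
          lab[yi, xi] <- nxt
          queue <- rbind(queue, c(yi, xi))
        }
      }
    }
  }
  lab
}

# number of 8-neighbours of each cell for which `mask` is TRUE
neighbour_count <- function(mask) {
  ny <- nrow(mask)
  nx <- ncol(mask)
  m <- mask * 1
  cnt <- matrix(0, ny, nx)
  for (dy in -1:1) for (dx in -1:1) {
    if (dy == 0 && dx == 0) next
    ys <- max(1, 1 - dy):min(ny, ny - dy)
    xs <- max(1, 1 - dx):min(nx, nx - dx)
    cnt[ys, xs] <- cnt[ys, xs] + m[ys + dy, xs + dx]
  }
  cnt
}

#' Detect place fields on a smoothed rate map
#'
#' Keeps bins whose rate is at least `threshold_frac` (15%) of the map
#' peak and which have at least `min_neighbors` (7) of their eight
#' neighbours also meeting the rate criterion; all other bins are zeroed.
#' Surviving bins are grouped into 8-connected components, each reported
#' with its size (bins), bounding-box length (long axis) and width (short
#' axis), aspect ratio and peak; the largest component is the main field.
#' Note that edge bins have at most five neighbours and therefore can
#' never seed a field bin themselves, an accepted consequence of the
#' neighbour rule.
#'
#' @param rm_smooth A smoothed `rate_map` (see [smooth_rate_map()]).
#' @param threshold_frac Fraction of the map peak a field bin must reach.
#' @param min_neighbors Minimum qualifying 8-neighbours.
#' @return List of class `place_fields`: `fields` (data.frame per field:
#'   `field_id`, `size_bins`, `length_bins`, `width_bins`, `aspect`,
#'   `peak_row`, `peak_col`, `peak_rate_hz`, `is_main`), `label` (component
#'   matrix), `field_rate` (map with non-field bins zeroed). Empty field
#'   table on a zero-peak map.
#' @export
detect_fields <- function(rm_smooth, threshold_frac = 0.15,
                          min_neighbors = 7) {
  rate <- rm_smooth$rate
  visited <- rm_smooth$occupancy$visited
  empty <- list(fields = data.frame(field_id = integer(0),
                                    size_bins = integer(0),
                                    length_bins = integer(0),
                                    width_bins = integer(0),
                                    aspect = numeric(0),
                                    peak_row = integer(0),
                                    peak_col = integer(0),
                                    peak_rate_hz = numeric(0),
                                    is_main = logical(0)),
                label = matrix(0L, nrow(rate), ncol(rate)),
                field_rate = {
                  fr <- rate
                  fr[] <- 0
                  fr
                })
  class(empty) <- "place_fields"
  pk <- suppressWarnings(max(rate, na.rm = TRUE))
  if (!is.finite(pk) || pk <= 0) return(empty)
  above <- !is.na(rate) & rate >= threshold_frac * pk
  keep <- above & neighbour_count(above) >= min_neighbors
  if (!any(keep)) return(empty)
  lab <- label_components(keep)
  fr <- rate
  fr[!keep | is.na(fr)] <- 0
  ids <- sort(unique(lab[lab > 0]))
  fields <- do.call(rbind, lapply(ids, function(id) {
    sel <- which(lab == id, arr.ind = TRUE)
    pkv <- max(rate[lab == id])
    pki <- which(lab == id & rate == pkv, arr.ind = TRUE)[1, ]
    data.frame(field_id = id, size_bins = nrow(sel),
               length_bins = diff(range(sel[, 2])) + 1L,
               width_bins = diff(range(sel[, 1])) + 1L,
               aspect = (diff(range(sel[, 2])) + 1) /
                        (diff(range(sel[, 1])) + 1),
               peak_row = pki[1], peak_col = pki[2],
               peak_rate_hz = pkv, is_main = FALSE)
  }))
  main <- order(-fields$size_bins, -fields$peak_rate_hz)[1]
  fields$is_main[main] <- TRUE
  structure(list(fields = fields, label = lab, field_rate = fr),
            class = "place_fields")
}

#' Collapse a map to the long axis
#'
#' Averages each short-axis column over its visited bins, producing one
#' value per long-axis bin (41 by default). Columns with no visited bin
#' are NA. For sequence plots the vectors are additionally min-max
#' normalised per cell (see [sequence_matrix()]); uphill and downhill are
#' normalised separately there.
#'
#' @param m Matrix (short x long axis) with NA for unvisited bins, or a
#'   `rate_map`.
#' @return Numeric vector, one entry per long-axis bin.
#' @export
collapse_to_1d <- function(m) {
  if (inherits(m, "rate_map")) m <- m$rate
  v <- colMeans(m, na.rm = TRUE)
  v[is.nan(v)] <- NA
  v
}

# min-max normalisation to [0, 1]; constant vectors map to 0
normalize01 <- function(v) {
  rng <- range(v, na.rm = TRUE)
  if (!is.finite(rng[1]) || diff(rng) == 0) return(ifelse(is.na(v), NA, 0))
  (v - rng[1]) / diff(rng)
}

#' Detect the phase-precession field on the coarse grid
#'
#' For phase-precession analysis the running ROI is divided into a coarse
#' 4 x 20 grid (about 6 cm x 5.15 cm bins, reward areas excluded by
#' construction). Bins firing above the map mean (over visited coarse
#' bins) with at least two qualifying 8-neighbours are clustered; the
#' largest cluster is returned as the field.
#'
#' @param spike_times Spike times (s).
#' @param positions data.frame `t`, `x`, `y`.
#' @param trials Included trials of the analysed condition/direction.
#' @param geometry A [track_geometry()].
#' @return `NULL` when no qualifying cluster exists (the cell is skipped
#'   for precession); otherwise a list: `cols` (coarse columns in the
#'   cluster), `x_min_cm`/`x_max_cm` (ROI-local field extent), `rate`
#'   (coarse map), `n_bins`.
#' @export
detect_fields_coarse <- function(spike_times, positions, trials, geometry) {
  inc <- trials[trials$included, , drop = FALSE]
  if (!nrow(inc)) return(NULL)
  ny <- geometry$coarse_short
  nx <- geometry$coarse_long
  dwell <- matrix(0, ny, nx)
  counts <- matrix(0, ny, nx)
  t <- positions$t
  dt <- diff(t)
  dt <- c(dt, stats::median(dt))
  keep <- rep(FALSE, length(t))
  for (i in seq_len(nrow(inc)))
    keep <- keep | (t >= inc$t_start_s[i] & t < inc$t_end_s[i])
  bin <- coarse_bin_index(positions$x[keep], positions$y[keep], geometry)
  ok <- !is.na(bin$ix)
  if (any(ok)) {
    idx <- (bin$ix[ok] - 1L) * ny + bin$iy[ok]
    acc <- tapply(dt[keep][ok], idx, sum)
    dwell[as.integer(names(acc))] <- acc
  }
  if (length(spike_times)) {
    keep_s <- rep(FALSE, length(spike_times))
    for (i in seq_len(nrow(inc)))
      keep_s <- keep_s | (spike_times >= inc$t_start_s[i] &
                          spike_times < inc$t_end_s[i])
    st <- spike_times[keep_s]
    if (length(st)) {
      sx <- stats::approx(positions$t, positions$x, st, rule = 2, ties = "ordered")$y
      sy <- stats::approx(positions$t, positions$y, st, rule = 2, ties = "ordered")$y
      sb <- coarse_bin_index(sx, sy, geometry)
      ok <- !is.na(sb$ix)
      if (any(ok)) {
        idx <- (sb$ix[ok] - 1L) * ny + sb$iy[ok]
        acc <- tapply(rep(1L, sum(ok)), idx, sum)
        counts[as.integer(names(acc))] <- acc
      }
    }
  }
  visited <- dwell > 0
  if (!any(visited)) return(NULL)
  rate <- counts / dwell
  rate[!visited] <- NA
  mu <- mean(rate, na.rm = TRUE)
  above <- !is.na(rate) & rate > mu
  keep_b <- above & neighbour_count(above) >= 2
  if (!any(keep_b)) return(NULL)
  lab <- label_components(keep_b)
  sizes <- tabulate(lab[lab > 0])
  best <- which.max(sizes)
  cols <- sort(unique(which(lab == best, arr.ind = TRUE)[, 2]))
  wx <- geometry$roi_long_cm / nx
  list(cols = cols, x_min_cm = (min(cols) - 1) * wx,
       x_max_cm = max(cols) * wx, rate = rate, n_bins = sizes[best])
}
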