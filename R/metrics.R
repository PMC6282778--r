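#' Spatial information (bits per spike)
#'
#' Skaggs information of a rate map: `I = sum_i p_i (l_i / L) log2(l_i / L)`
#' with `p_i` the occupancy probability of bin i, `l_i` its firing rate and
#' `L = sum_i p_i l_i` the overall mean rate. Terms with `l_i = 0`
#' contribute zero (the `x log x` limit). Uniform maps score 0; a cell
#' firing in one of N equally occupied bins scores `log2(N)`.
#'
#' @param rate Numeric vector of per-bin rates (Hz) over visited bins, or a
#'   `rate_map` (its occupancy supplies `p`).
#' @param p Occupancy probabilities, same length as `rate`, summing to 1.
#' @return Bits per spike, or NA when the mean rate is zero (undefined).
#' @export
spatial_information <- function(rate, p = NULL) {
  if (inherits(rate, "rate_map")) {
    v <- rate$occupancy$visited
    p <- occupancy_prob(rate$occupancy)[v]
    rate <- rate$rate[v]
  }
  stopifnot(length(rate) == length(p))
  lam <- sum(p * rate)
  if (!is.finite(lam) || lam <= 0) return(NA_real_)
  r <- rate / lam
  pos <- r > 0
  sum(p[pos] * r[pos] * log2(r[pos]))
}

#' Sparsity of a rate map
#'
#' `S = (sum p_i l_i)^2 / sum p_i l_i^2`, the fraction-of-environment
#' measure of firing concentration: 1 for uniform firing (the
#' Cauchy-Schwarz equality case), `1/N` for firing confined to one of N
#' equally occupied bins.
#'
#' @inheritParams spatial_information
#' @return Sparsity in (0, 1], or NA when the mean rate is zero.
#' @export
sparsity <- function(rate, p = NULL) {
  if (inherits(rate, "rate_map")) {
    v <- rate$occupancy$visited
    p <- occupancy_prob(rate$occupancy)[v]
    rate <- rate$rate[v]
  }
  stopifnot(length(rate) == length(p))
  num <- sum(p * rate)^2
  den <- sum(p * rate^2)
  if (!is.finite(den) || den <= 0) return(NA_real_)
  num / den
}

#' Spatial coherence of a rate map
#'
#' First-order spatial autocorrelation: the Pearson correlation, across
#' visited bins, between each bin's rate and the mean rate of its visited
#' 8-neighbours, Fisher z-transformed. Computed on the unsmoothed map.
#' Bins with no visited neighbour are excluded. The place-cell criterion
#' is applied to the z value (which, unlike r, can exceed 1).
#'
#' @param rate Matrix of rates (short x long axis) with NA for unvisited
#'   bins, or a `rate_map`.
#' @return Fisher z value, or NA when either vector has zero variance
#'   (e.g. a constant map) or fewer than 8 bins qualify.
#' @export
spatial_coherence <- function(rate) {
  if (inherits(rate, "rate_map")) rate <- rate$rate
  visited <- !is.na(rate)
  m0 <- rate
  m0[!visited] <- 0
  nb_sum <- neighbour_sum(m0)
  nb_n <- neighbour_count(visited)
  sel <- visited & nb_n > 0
  if (sum(sel) < 8) return(NA_real_)
  a <- rate[sel]
  b <- nb_sum[sel] / nb_n[sel]
  if (stats::sd(a) == 0 || stats::sd(b) == 0) return(NA_real_)
  r <- stats::cor(a, b)
  r <- min(max(r, -1 + 1e-12), 1 - 1e-12)
  atanh(r)
}

# sum of the 8-neighbour values of each cell
neighbour_sum <- function(m) {
  ny <- nrow(m)
  nx <- ncol(m)
  s <- matrix(0, ny, nx)
  for (dy in -1:1) for (dx in -1:1) {
    if (dy == 0 && dx == 0) next
    ys <- max(1, 1 - dy):min(ny, ny - dy)
    xs <- max(1, 1 - dx):min(nx, nx - dx)
    s[ys, xs] <- s[ys, xs] + m[ys + dy, xs + dx]
  }
  s
}

#' Default place-cell inclusion criteria
#'
#' A unit counts as a place cell in a condition when it fired at least 100
#' spikes there (in-ROI, included trials), kept a mean rate of at least
#' 0.1 Hz (in-ROI spikes over included-trial time), conveyed at least
#' 1 bit/spike of spatial information and had spatial coherence (Fisher z)
#' above 0.5.
#'
#' @return Named list of thresholds.
#' @export
place_cell_criteria <- function() {
  list(min_spikes = 100, min_rate_hz = 0.1, min_info_bits = 1,
       min_coherence_z = 0.5)
}

#' Evaluate the metric battery for one unit in one condition
#'
#' Computes spike counts, mean and peak rate, spatial information,
#' sparsity, coherence, field counts and coverages, the main-field aspect
#' ratio and in/out-field rates, then applies the place-cell criteria.
#' Metrics are computed on the unsmoothed map; fields come from the
#' smoothed one. Coverage is field bins over occupied bins. Cells meeting
#' the criteria in a condition are the ones whose metrics contribute to
#' that condition's averages.
#'
#' @param unit_id Unit label.
#' @param tilt_deg,direction Condition labels.
#' @param rate_map Unsmoothed [build_rate_map()] result.
#' @param fields [detect_fields()] result for the smoothed map.
#' @param trial_rates Per-trial firing rates (Hz) of the unit in the
#'   condition's included trials.
#' @param total_time_s Included-trial time (s).
#' @param criteria Thresholds, see [place_cell_criteria()].
#' @return One-row data.frame of class metrics.
#' @export
evaluate_place_cell <- function(unit_id, tilt_deg, direction, rate_map,
                                fields, trial_rates, total_time_s,
                                criteria = place_cell_criteria()) {
  occ <- rate_map$occupancy
  n_occ <- sum(occ$visited)
  n_spk <- rate_map$n_spikes_roi
  mean_rate <- if (total_time_s > 0) n_spk / total_time_s else NA_real_
  peak <- suppressWarnings(max(rate_map$rate, na.rm = TRUE))
  if (!is.finite(peak)) peak <- NA_real_
  info <- spatial_information(rate_map)
  sp <- sparsity(rate_map)
  coh <- spatial_coherence(rate_map)
  ftab <- fields$fields
  n_fields <- nrow(ftab)
  tot_cov <- if (n_occ > 0) sum(ftab$size_bins) / n_occ else NA_real_
  main_cov <- if (n_occ > 0 && n_fields > 0)
    ftab$size_bins[ftab$is_main] / n_occ else NA_real_
  main_aspect <- if (n_fields > 0) ftab$aspect[ftab$is_main] else NA_real_
  infield <- outfield <- NA_real_
  if (n_fields > 0) {
    fmask <- fields$label > 0
    infield <- mean(rate_map$rate[fmask & occ$visited], na.rm = TRUE)
    out_sel <- !fmask & occ$visited
    if (any(out_sel)) outfield <- mean(rate_map$rate[out_sel], na.rm = TRUE)
  }
  is_pc <- isTRUE(n_spk >= criteria$min_spikes) &&
    isTRUE(mean_rate >= criteria$min_rate_hz) &&
    isTRUE(info >= criteria$min_info_bits) &&
    isTRUE(coh > criteria$min_coherence_z)
  data.frame(unit_id = unit_id, tilt_deg = tilt_deg, direction = direction,
             n_trials = length(trial_rates), n_spikes = n_spk,
             mean_rate_hz = mean_rate, peak_rate_hz = peak,
             info_bits_per_spike = info, sparsity = sp, coherence_z = coh,
             n_fields = n_fields, total_field_coverage = tot_cov,
             main_field_coverage = main_cov,
             main_field_aspect = main_aspect,
             infield_rate_hz = infield, outfield_rate_hz = outfield,
             is_place_cell = is_pc)
}
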