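# Evaluate every unit on one set of included trials (one condition, or one
# half of a condition in the split-half protocol): occupancy, rate maps,
# smoothed maps, fields, metric battery, per-trial rates, 1D vector and 1D
# place-field peak. Returns list(occupancy, units = NULL) when the trial
# set is empty/unanalyzable.
condition_eval <- function(s, tr, tilt_deg, direction,
                           criteria = place_cell_criteria()) {
  g <- s$geometry
  occ <- build_occupancy_map(s$positions, tr, g)
  if (occ$unanalyzable || !any(occ$visited))
    return(list(occupancy = occ, units = NULL))
  total_t <- sum(tr$duration_s)
  units <- stats::setNames(lapply(names(s$spikes), function(u) {
    rm_raw <- build_rate_map(s$spikes[[u]], s$positions, tr, occ)
    rm_sm <- smooth_rate_map(rm_raw)
    flds <- detect_fields(rm_sm)
    rates <- trial_firing_rates(s$spikes[[u]], tr, s$positions, g)
    v1 <- collapse_to_1d(rm_raw)
    pf1 <- collapse_to_1d(flds$field_rate)
    peak_src <- if (any(pf1 > 0, na.rm = TRUE)) pf1 else v1
    pk_bin <- if (any(is.finite(peak_src)))
      which.max(replace(peak_src, is.na(peak_src), -Inf)) else NA
    list(metrics = evaluate_place_cell(u, tilt_deg, direction, rm_raw,
                                       flds, rates, total_t, criteria),
         rate = rm_raw, smoothed = rm_sm, fields = flds,
         trial_rates = rates, vec1d = v1,
         peak_cm = if (is.na(pk_bin)) NA_real_
                   else fine_bin_centre(pk_bin, g))
  }), names(s$spikes))
  list(occupancy = occ, units = units)
}

#' Run the full place-cell analysis on a session
#'
#' Orchestrates the pipeline: segments and filters trials, builds
#' per-condition occupancy maps and per-unit rate maps on the 2.5 cm grid,
#' smooths and detects fields, computes the metric battery and place-cell
#' flags, classifies remapping across the ordered tilt pairs within each
#' slope direction, and computes spatial correlations over common-occupied
#' bins (with an optional shuffle null).
#'
#' @param s A `slope_session`.
#' @param shuffles Shuffle iterations per correlation (0 skips the null).
#' @param seed RNG seed for the shuffle nulls.
#' @param criteria Place-cell thresholds, see [place_cell_criteria()].
#' @return List of class `slope_results`: `trials`, `metrics`,
#'   `remap_calls`, `correlations`, `vectors` (per direction/tilt/unit 1D
#'   rate vectors), `peaks` (1D place-field peaks, ROI-local cm), `maps`
#'   (per condition: occupancy; per unit: rate, smoothed, fields),
#'   `geometry`, `elevated_end`, `seed`.
#' @export
analyze_session <- function(s, shuffles = 0, seed = 1,
                            criteria = place_cell_criteria()) {
  validate_session(s)
  g <- s$geometry
  trials <- apply_trial_filters(segment_trials(s$positions, g, s$schedule))
  tilts <- sort(unique(s$schedule$tilt_deg))
  dirs <- c("uphill", "downhill")
  units <- names(s$spikes)

  maps <- list()
  metrics <- list()
  vectors <- list()
  peaks <- list()
  trial_rates <- list()
  for (dir in dirs) {
    for (tl in tilts) {
      key <- paste0(tl, "_", dir)
      tr <- trials[trials$tilt_deg == tl & trials$direction == dir &
                     trials$included, , drop = FALSE]
      ev <- condition_eval(s, tr, tl, dir, criteria)
      maps[[key]] <- list(occupancy = ev$occupancy, units = list())
      if (is.null(ev$units)) next
      for (u in units) {
        eu <- ev$units[[u]]
        metrics[[paste(u, key)]] <- eu$metrics
        trial_rates[[paste(u, key)]] <- eu$trial_rates
        vectors[[dir]][[as.character(tl)]][[u]] <- eu$vec1d
        peaks[[paste(u, key)]] <- data.frame(
          unit_id = u, tilt_deg = tl, direction = dir,
          peak_cm = eu$peak_cm)
        maps[[key]]$units[[u]] <- list(rate = eu$rate, smoothed = eu$smoothed,
                                       fields = eu$fields)
      }
    }
  }
  metrics <- do.call(rbind, unname(metrics))
  peaks <- do.call(rbind, unname(peaks))

  is_active <- function(u, tl, dir) {
    row <- metrics[metrics$unit_id == u & metrics$tilt_deg == tl &
                     metrics$direction == dir, ]
    nrow(row) == 1 && isTRUE(row$is_place_cell)
  }
  peak_of <- function(u, tl, dir) {
    row <- peaks[peaks$unit_id == u & peaks$tilt_deg == tl &
                   peaks$direction == dir, ]
    if (nrow(row) == 1) row$peak_cm else NA_real_
  }
  pairs <- if (length(tilts) >= 2) utils::combn(tilts, 2, simplify = FALSE)
           else list()
  calls <- list()
  cors <- list()
  for (dir in dirs) {
    # common-occupied bins across all tilt conditions of the direction
    occs <- lapply(tilts, function(tl)
      maps[[paste0(tl, "_", dir)]]$occupancy)
    have <- !vapply(occs, `[[`, logical(1), "unanalyzable")
    common <- NULL
    if (all(have)) {
      common <- Reduce(`&`, lapply(occs, `[[`, "visited"))
    }
    for (p in pairs) {
      a <- p[1]
      b <- p[2]
      ka <- paste0(a, "_", dir)
      kb <- paste0(b, "_", dir)
      for (u in units) {
        act_a <- is_active(u, a, dir)
        act_b <- is_active(u, b, dir)
        cl <- classify_remapping(
          act_a, act_b, peak_of(u, a, dir), peak_of(u, b, dir),
          trial_rates[[paste(u, ka)]], trial_rates[[paste(u, kb)]])
        calls[[paste(u, dir, a, b)]] <- data.frame(
          unit_id = u, direction = dir, tilt_a = a, tilt_b = b,
          call = cl$call, peak_sep_cm = cl$peak_sep_cm,
          p_rank_sum = cl$p_rank_sum)
        if (!(act_a || act_b)) next
        ma <- maps[[ka]]$units[[u]]
        mb <- maps[[kb]]$units[[u]]
        if (is.null(ma) || is.null(mb) || is.null(common)) next
        sc <- spatial_correlation(ma$rate, mb$rate, common)
        nul <- NA_real_
        if (shuffles > 0 && !sc$skipped)
          nul <- shuffle_null(ma$rate, mb$rate, common,
                              n_shuffles = shuffles,
                              seed = seed + a + b)$mean_null_r
        cors[[paste(u, dir, a, b)]] <- data.frame(
          unit_id = u, direction = dir, tilt_a = a, tilt_b = b,
          r = sc$r, n_common = sc$n_common, n_nonzero = sc$n_nonzero,
          skipped = sc$skipped, mean_null_r = nul,
          n_shuffles = if (shuffles > 0) shuffles else NA_integer_,
          seed = seed)
      }
    }
  }
  structure(list(
    trials = trials, metrics = metrics,
    remap_calls = if (length(calls)) do.call(rbind, unname(calls)) else NULL,
    correlations = if (length(cors)) do.call(rbind, unname(cors)) else NULL,
    vectors = vectors, peaks = peaks, maps = maps, geometry = g,
    elevated_end = s$schedule$elevated_end[1], seed = seed),
    class = "slope_results")
}

#' @export
print.slope_results <- function(x, ...) {
  cat(sprintf("<slope_results> %d trials (%d included), %d unit-conditions",
              nrow(x$trials), sum(x$trials$included),
              if (is.null(x$metrics)) 0L else nrow(x$metrics)))
  cat(sprintf(", %d place-cell conditions, %d remap calls\n",
              if (is.null(x$metrics)) 0L else sum(x$metrics$is_place_cell),
              if (is.null(x$remap_calls)) 0L else nrow(x$remap_calls)))
  invisible(x)
}

#' Sequence matrices for one slope direction
#'
#' Builds the cell x position matrices of 1D rate vectors for every tilt
#' of a direction, ordered by each cell's 1D peak in the baseline tilt and
#' min-max normalised per cell (uphill and downhill handled as separate
#' ensembles). Only cells flagged as place cells in at least one tilt of
#' the direction are included.
#'
#' @param results An [analyze_session()] result.
#' @param baseline_tilt Ordering condition (deg).
#' @param direction `"uphill"` or `"downhill"`.
#' @return Named list of matrices, one per tilt, see [sequence_matrix()].
#' @export
sequence_matrices <- function(results, baseline_tilt = 0,
                              direction = "uphill") {
  v <- results$vectors[[direction]]
  if (is.null(v)) return(list())
  m <- results$metrics
  active_any <- unique(m$unit_id[m$direction == direction & m$is_place_cell])
  v <- lapply(v, function(tl) tl[names(tl) %in% active_any])
  base <- v[[as.character(baseline_tilt)]]
  stats::setNames(lapply(names(v), function(tl)
    sequence_matrix(v[[tl]], base)), names(v))
}

#' Elevation-half contingency table from analysis results
#'
#' Convenience wrapper assembling the inputs of
#' [elevation_half_analysis()] from an [analyze_session()] result: cells
#' active at 0 degrees, their 0-degree 1D place-field peaks, and the
#' session's elevated end.
#'
#' @param results An [analyze_session()] result.
#' @return Contingency matrix (remap categories x top/bottom).
#' @export
elevation_half_table <- function(results) {
  m <- results$metrics
  act0 <- m[m$tilt_deg == 0 & m$is_place_cell, c("unit_id", "direction")]
  calls <- results$remap_calls
  keep <- calls$tilt_a == 0 &
    paste(calls$unit_id, calls$direction) %in%
      paste(act0$unit_id, act0$direction)
  peaks0 <- results$peaks[results$peaks$tilt_deg == 0, ]
  elevation_half_analysis(calls[keep, , drop = FALSE], peaks0,
                          results$geometry, results$elevated_end)
}

#' Within- versus between-condition split-half remapping
#'
#' Controls for drift over time: place-cell activity is compared across
#' similar time windows within one tilt condition and between consecutive
#' tilt conditions. Within each direction, the first `n_half` and second
#' `n_half` included trials of every block after the first are classified
#' against each other ("within"); the last `n_half` trials of each block
#' are classified against the first `n_half` of the following block
#' ("between"). Calls use the same six-way classifier as the main
#' analysis, evaluated on the half-condition trial sets.
#'
#' @param s A `slope_session`.
#' @param n_half Trials per half (10).
#' @param criteria Place-cell thresholds.
#' @return data.frame: `unit_id`, `direction`, `comparison`
#'   (within/between), `block_a`, `block_b`, `call`.
#' @export
split_half_remapping <- function(s, n_half = 10,
                                 criteria = place_cell_criteria()) {
  validate_session(s)
  g <- s$geometry
  trials <- apply_trial_filters(segment_trials(s$positions, g, s$schedule))
  blocks <- s$schedule[order(s$schedule$t_start), ]
  rows <- list()
  halves <- function(bid, dir) {
    tr <- trials[trials$block_id == bid & trials$direction == dir &
                   trials$included, , drop = FALSE]
    tr <- tr[order(tr$t_start_s), ]
    if (nrow(tr) < 2 * n_half)
      return(NULL)
    list(first = tr[seq_len(n_half), ],
         last = tr[seq(nrow(tr) - n_half + 1, nrow(tr)), ])
  }
  classify_halves <- function(ha, hb, dir, tag, ba, bb) {
    ea <- condition_eval(s, ha, NA, dir, criteria)
    eb <- condition_eval(s, hb, NA, dir, criteria)
    if (is.null(ea$units) || is.null(eb$units)) return(NULL)
    do.call(rbind, lapply(names(s$spikes), function(u) {
      ma <- ea$units[[u]]
      mb <- eb$units[[u]]
      cl <- classify_remapping(
        isTRUE(ma$metrics$is_place_cell), isTRUE(mb$metrics$is_place_cell),
        ma$peak_cm, mb$peak_cm, ma$trial_rates, mb$trial_rates)
      data.frame(unit_id = u, direction = dir, comparison = tag,
                 block_a = ba, block_b = bb, call = cl$call)
    }))
  }
  for (dir in c("uphill", "downhill")) {
    hs <- lapply(blocks$block_id, halves, dir = dir)
    names(hs) <- blocks$block_id
    for (bi in seq_len(nrow(blocks))) {
      bid <- blocks$block_id[bi]
      if (bi > 1 && !is.null(hs[[bi]]))
        rows[[paste("w", dir, bid)]] <- classify_halves(
          hs[[bi]]$first, hs[[bi]]$last, dir, "within", bid, bid)
      if (bi < nrow(blocks) && !is.null(hs[[bi]]) &&
          !is.null(hs[[bi + 1]]))
        rows[[paste("b", dir, bid)]] <- classify_halves(
          hs[[bi]]$last, hs[[bi + 1]]$first, dir, "between", bid,
          blocks$block_id[bi + 1])
    }
  }
  if (!length(rows)) return(NULL)
  do.call(rbind, unname(rows))
}

#' Theta phase-precession analysis for a session
#'
#' For each unit and tilt condition, detects the precession field on the
#' coarse 4 x 20 grid from the analysed direction's included trials,
#' assigns theta phases to in-field spikes (envelope above mean), and fits
#' the circular-linear regression. Only uphill trials (and the equivalent
#' running direction on the flat) are analysed.
#'
#' @param s A `slope_session` (must carry an LFP).
#' @param direction Running direction analysed.
#' @param min_spikes Minimum qualifying in-field spikes per cell and
#'   condition.
#' @return data.frame, one row per unit x tilt that was evaluated:
#'   `unit_id`, `tilt_deg`, `n_spikes`, `slope_deg_per_field`,
#'   `offset_deg`, `rho`, `p_value`, `bounded`, `significant`, `skipped`
#'   (`""`, `"no_field"` or `"too_few_spikes"`).
#' @export
precession_analysis <- function(s, direction = "uphill", min_spikes = 50) {
  validate_session(s)
  if (is.null(s$lfp)) stop("LFP required", call. = FALSE)
  g <- s$geometry
  theta <- theta_phase_series(s$lfp)
  trials <- apply_trial_filters(segment_trials(s$positions, g, s$schedule))
  tilts <- sort(unique(s$schedule$tilt_deg))
  rows <- list()
  for (tl in tilts) {
    tr <- trials[trials$tilt_deg == tl & trials$direction == direction &
                   trials$included, , drop = FALSE]
    if (!nrow(tr)) next
    for (u in names(s$spikes)) {
      fld <- detect_fields_coarse(s$spikes[[u]], s$positions, tr, g)
      if (is.null(fld)) {
        rows[[paste(u, tl)]] <- data.frame(
          unit_id = u, tilt_deg = tl, n_spikes = 0L,
          slope_deg_per_field = NA_real_, offset_deg = NA_real_,
          rho = NA_real_, p_value = NA_real_, bounded = NA,
          significant = NA, skipped = "no_field")
        next
      }
      pairs <- assign_spike_phases(s$spikes[[u]], theta, fld, s$positions,
                                   tr, g, min_spikes = min_spikes)
      if (is.null(pairs)) {
        rows[[paste(u, tl)]] <- data.frame(
          unit_id = u, tilt_deg = tl, n_spikes = 0L,
          slope_deg_per_field = NA_real_, offset_deg = NA_real_,
          rho = NA_real_, p_value = NA_real_, bounded = NA,
          significant = NA, skipped = "too_few_spikes")
        next
      }
      fit <- circular_linear_fit(pairs)
      rows[[paste(u, tl)]] <- data.frame(
        unit_id = u, tilt_deg = tl, n_spikes = fit$n,
        slope_deg_per_field = fit$slope_deg_per_field,
        offset_deg = fit$offset_deg, rho = fit$rho,
        p_value = fit$p_value, bounded = fit$bounded,
        significant = fit$significant, skipped = "")
    }
  }
  if (!length(rows)) return(NULL)
  do.call(rbind, unname(rows))
}
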