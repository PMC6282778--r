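#' Classify remapping for one unit across an ordered tilt pair
#'
#' Six mutually exclusive, exhaustive calls for the change in a cell's
#' activity from the shallower to the steeper tilt, slope direction held
#' constant: active in neither condition is `inactive`; active only on the
#' steeper, `turn_on`; only on the shallower, `turn_off`. When active on
#' both, the peak bins of the 1D place-field maps are compared: a
#' separation of at least 20 cm (about 20% of the running area) is
#' `field_remap`; otherwise a two-sided Wilcoxon rank-sum test on the
#' per-trial firing rates decides `rate_remap` (p < 0.05) against
#' `stable`.
#'
#' @param active_a,active_b Place-cell flags for the shallower / steeper
#'   condition.
#' @param peak_cm_a,peak_cm_b ROI-local long-axis position (cm) of the 1D
#'   place-field-map peak in each condition (ignored unless both active).
#' @param trial_rates_a,trial_rates_b Per-trial firing rates (Hz).
#' @param sep_threshold_cm Peak-separation threshold (cm); the boundary
#'   value itself triggers `field_remap`.
#' @param alpha Rank-sum significance level.
#' @return List: `call`, `peak_sep_cm`, `p_rank_sum`.
#' @export
classify_remapping <- function(active_a, active_b, peak_cm_a = NA,
                               peak_cm_b = NA, trial_rates_a = NULL,
                               trial_rates_b = NULL,
                               sep_threshold_cm = 20, alpha = 0.05) {
  if (!active_a && !active_b)
    return(list(call = "inactive", peak_sep_cm = NA_real_,
                p_rank_sum = NA_real_))
  if (!active_a)
    return(list(call = "turn_on", peak_sep_cm = NA_real_,
                p_rank_sum = NA_real_))
  if (!active_b)
    return(list(call = "turn_off", peak_sep_cm = NA_real_,
                p_rank_sum = NA_real_))
  sep <- abs(peak_cm_a - peak_cm_b)
  if (is.finite(sep) && sep >= sep_threshold_cm)
    return(list(call = "field_remap", peak_sep_cm = sep,
                p_rank_sum = NA_real_))
  w <- wilcoxon_rank_sum(trial_rates_a, trial_rates_b)
  call <- if (is.finite(w$p_value) && w$p_value < alpha) "rate_remap"
          else "stable"
  list(call = call, peak_sep_cm = sep, p_rank_sum = w$p_value)
}

#' Spatial correlation between two conditions
#'
#' Pearson correlation of a unit's per-bin firing rates between two tilt
#' conditions over the bins occupied in all three tilt conditions of the
#' slope direction. The correlation is only computed when at least three
#' common-occupied bins have non-zero rate in both maps (guarding against
#' spurious values); otherwise the pair is reported skipped.
#'
#' @param rate_a,rate_b Rate matrices (or `rate_map`s) of the two
#'   conditions.
#' @param common Logical matrix of common-occupied bins (across all three
#'   tilts); when `NULL`, the intersection of the two maps' visited bins.
#' @param min_nonzero Minimum common bins with non-zero rate in both maps.
#' @return List: `r` (NA when skipped), `n_common`, `n_nonzero`,
#'   `skipped`.
#' @export
spatial_correlation <- function(rate_a, rate_b, common = NULL,
                                min_nonzero = 3) {
  if (inherits(rate_a, "rate_map")) rate_a <- rate_a$rate
  if (inherits(rate_b, "rate_map")) rate_b <- rate_b$rate
  if (is.null(common)) common <- !is.na(rate_a) & !is.na(rate_b)
  common <- common & !is.na(rate_a) & !is.na(rate_b)
  a <- rate_a[common]
  b <- rate_b[common]
  nz <- sum(a > 0 & b > 0)
  if (nz < min_nonzero || length(a) < 3 ||
      stats::sd(a) == 0 || stats::sd(b) == 0)
    return(list(r = NA_real_, n_common = length(a), n_nonzero = nz,
                skipped = TRUE))
  list(r = stats::cor(a, b), n_common = length(a), n_nonzero = nz,
       skipped = FALSE)
}

#' Shuffle null for a spatial correlation
#'
#' Permutes the bin locations of one map (the steeper condition) uniformly
#' over the common-occupied bins and recomputes the Pearson correlation
#' `n_shuffles` times (10,000 by default); the mean of the null
#' correlations is returned for comparison with the actual value. Seeded
#' and reproducible.
#'
#' @inheritParams spatial_correlation
#' @param n_shuffles Number of permutations.
#' @param seed Integer RNG seed.
#' @return List: `mean_null_r`, `null_r` (vector), `n_shuffles`, `seed`.
#' @export
shuffle_null <- function(rate_a, rate_b, common = NULL,
                         n_shuffles = 10000, seed = 1) {
  if (inherits(rate_a, "rate_map")) rate_a <- rate_a$rate
  if (inherits(rate_b, "rate_map")) rate_b <- rate_b$rate
  if (is.null(common)) common <- !is.na(rate_a) & !is.na(rate_b)
  common <- common & !is.na(rate_a) & !is.na(rate_b)
  a <- rate_a[common]
  b <- rate_b[common]
  set.seed(seed)
  n <- length(a)
  r <- vapply(seq_len(n_shuffles), function(i) {
    bs <- b[sample.int(n)]
    if (stats::sd(a) == 0 || stats::sd(bs) == 0) return(NA_real_)
    stats::cor(a, bs)
  }, numeric(1))
  list(mean_null_r = mean(r, na.rm = TRUE), null_r = r,
       n_shuffles = n_shuffles, seed = seed)
}

#' Build an ordered sequence matrix
#'
#' Stacks the 1D rate vectors of an ensemble (rows = cells) for a target
#' condition, ordering rows by each cell's 1D peak bin in a baseline
#' condition and min-max normalising each row to [0, 1]. With baseline =
#' target the peak positions form a ridge along the diagonal; ensemble
#' turnover between conditions shows up as loss of that structure. Uphill
#' and downhill ensembles are normalised separately by construction (one
#' matrix per direction).
#'
#' @param vectors_target Named list (by unit) of 1D rate vectors for the
#'   condition being displayed.
#' @param vectors_baseline Named list of 1D vectors for the ordering
#'   condition; units present in both are used.
#' @return Matrix (cells x long-axis bins) with attribute `order` (unit
#'   ids, baseline peak order) and `peaks` (baseline peak bins).
#' @export
sequence_matrix <- function(vectors_target, vectors_baseline) {
  units <- intersect(names(vectors_baseline), names(vectors_target))
  units <- units[vapply(units, function(u)
    any(is.finite(vectors_baseline[[u]])) &&
      any(is.finite(vectors_target[[u]])), logical(1))]
  if (!length(units))
    return(structure(matrix(numeric(0), 0, 0), order = character(0),
                     peaks = integer(0)))
  peaks <- vapply(units, function(u)
    which.max(replace(vectors_baseline[[u]],
                      is.na(vectors_baseline[[u]]), -Inf)), integer(1))
  ord <- units[order(peaks)]
  m <- do.call(rbind, lapply(ord, function(u)
    normalize01(vectors_target[[u]])))
  rownames(m) <- ord
  structure(m, order = ord, peaks = sort(peaks))
}

#' Elevation-half remapping contingency table
#'
#' Splits the running ROI at its midpoint into the half nearer the
#' elevated ("top") and the pivot ("bottom") end, assigns each 0-degree
#' active cell to a half by its 1D place-field-map peak (exact-midpoint
#' ties go to bottom), and tabulates the remap calls of the 0-to-15 and
#' 0-to-25 degree pairs by half.
#'
#' @param calls data.frame of remap calls with columns `unit_id`,
#'   `direction`, `tilt_a`, `tilt_b`, `call`; only rows with `tilt_a == 0`
#'   enter the table.
#' @param peaks_0 data.frame `unit_id`, `direction`, `peak_cm` (ROI-local,
#'   cm) of the 0-degree 1D peak per unit and direction.
#' @param geometry A [track_geometry()].
#' @param elevated_end `"north"` (top = far half, larger x) or `"south"`.
#' @return Contingency matrix (remap categories x top/bottom).
#' @export
elevation_half_analysis <- function(calls, peaks_0, geometry,
                                    elevated_end = "north") {
  mid <- geometry$roi_long_cm / 2
  sel <- calls$tilt_a == 0
  calls <- calls[sel, , drop = FALSE]
  key <- paste(calls$unit_id, calls$direction)
  pk <- peaks_0$peak_cm[match(key, paste(peaks_0$unit_id,
                                         peaks_0$direction))]
  # ties at the exact midpoint go to bottom
  top <- if (elevated_end == "north") pk > mid else pk < mid
  half <- ifelse(top, "top", "bottom")
  levels <- c("inactive", "turn_on", "turn_off", "field_remap",
              "rate_remap", "stable")
  keep <- !is.na(half)
  table(factor(calls$call[keep], levels = levels),
        factor(half[keep], levels = c("top", "bottom")))
}

#' Pearson chi-squared test of independence
#'
#' Pearson statistic `sum (O - E)^2 / E` with expected counts from the
#' row/column margins, no continuity correction, df = (r-1)(c-1), p from
#' the chi-squared distribution.
#'
#' @param tab Matrix of non-negative counts, at least 2 x 2.
#' @return List: `statistic`, `df`, `p_value`, `expected`.
#' @export
chi_square_independence <- function(tab) {
  tab <- as.matrix(tab)
  if (nrow(tab) < 2 || ncol(tab) < 2)
    stop("need at least 2 rows and 2 columns", call. = FALSE)
  if (any(tab < 0)) stop("counts must be non-negative", call. = FALSE)
  rs <- rowSums(tab)
  cs <- colSums(tab)
  if (any(rs == 0))
    stop("degenerate row (all-zero margin): ",
         paste(which(rs == 0), collapse = ", "), call. = FALSE)
  if (any(cs == 0))
    stop("degenerate column (all-zero margin): ",
         paste(which(cs == 0), collapse = ", "), call. = FALSE)
  ct <- suppressWarnings(stats::chisq.test(tab, correct = FALSE))
  list(statistic = unname(ct$statistic), df = unname(ct$parameter),
       p_value = ct$p.value, expected = ct$expected)
}

#' Pearson chi-squared goodness-of-fit test
#'
#' @param observed Vector of non-negative counts.
#' @param expected_prop Expected proportions (default equal split); must
#'   sum to 1 with no zero cell.
#' @return List: `statistic`, `df` (k - 1), `p_value`, `expected`.
#' @export
chi_square_gof <- function(observed,
                           expected_prop = rep(1 / length(observed),
                                               length(observed))) {
  if (sum(observed) <= 0) stop("no observations", call. = FALSE)
  if (any(expected_prop <= 0))
    stop("zero expected cell", call. = FALSE)
  if (abs(sum(expected_prop) - 1) > 1e-8)
    stop("expected proportions must sum to 1", call. = FALSE)
  ct <- suppressWarnings(stats::chisq.test(observed, p = expected_prop))
  list(statistic = unname(ct$statistic), df = unname(ct$parameter),
       p_value = ct$p.value, expected = ct$expected)
}

#' Wilcoxon rank-sum test
#'
#' Two-sided rank-sum test with midrank ties: exact when the combined
#' sample size is at most 20 and there are no ties, otherwise the normal
#' approximation with tie correction (and continuity correction).
#'
#' @param a,b Non-empty numeric samples.
#' @return List: `statistic` (Mann-Whitney W of `a`), `p_value`, `exact`.
#' @export
wilcoxon_rank_sum <- function(a, b) {
  stopifnot(length(a) > 0, length(b) > 0)
  ties <- anyDuplicated(c(a, b)) > 0
  exact <- !ties && (length(a) + length(b)) <= 20
  wt <- suppressWarnings(stats::wilcox.test(a, b, exact = exact,
                                            correct = !exact))
  list(statistic = unname(wt$statistic), p_value = wt$p.value,
       exact = exact)
}

#' Published reference contingency data
#'
#' The per-cell recordings behind the original tilted-shuttle-box study
#' are not deposited, but its contingency tables are published and serve
#' here as fixed reference inputs for validating the contingency-test
#' implementations: remap-type frequencies of 0-degree-active cells split
#' by elevation half (`elevation`), remap-type frequencies within versus
#' between tilt conditions from the split-half protocol (`stability`), and
#' counts of place cells active on downhill versus uphill conditions
#' (`activation`).
#'
#' @return List of integer tables: `elevation` (6 x 2, remap type x
#'   top/bottom), `stability` (6 x 2, remap type x within/between),
#'   `activation` (named vector, downhill/uphill).
#' @export
reference_remap_counts <- function() {
  types <- c("inactive", "turn_on", "turn_off", "field_remap",
             "rate_remap", "stable")
  elevation <- matrix(c(44, 17, 24, 3, 4, 6,
                        45, 24, 11, 2, 7, 11), ncol = 2,
                      dimnames = list(types, c("top", "bottom")))
  stability <- matrix(c(379, 36, 55, 4, 13, 107,
                        228, 60, 45, 4, 10, 49), ncol = 2,
                      dimnames = list(types, c("within", "between")))
  list(elevation = elevation, stability = stability,
       activation = c(downhill = 125, uphill = 87))
}
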