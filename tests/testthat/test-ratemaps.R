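# hand-built positions: stand still at one spot for a known time
still_positions <- function(x, y, dur, fs = 50) {
  t <- seq(0, dur, by = 1 / fs)
  data.frame(t = t, x = x, y = y)
}

one_trial <- function(dur) {
  data.frame(trial_id = 1L, block_id = 1L, tilt_deg = 0,
             direction = "uphill", t_start_s = 0, t_end_s = dur,
             duration_s = dur, mean_speed_cms = 103 / dur,
             included = TRUE, reason = "")
}

test_that("occupancy accumulates dwell and removes sub-100 ms bins", {
  g <- track_geometry()
  pos <- still_positions(30, 12, 3)
  occ <- build_occupancy_map(pos, one_trial(3), g)
  expect_equal(sum(occ$visited), 1)
  expect_equal(max(occ$dwell), 3, tolerance = 0.05)
  # a bin crossed for only 80 ms in total is removed
  pos2 <- rbind(still_positions(30, 12, 0.06),
                within(still_positions(60, 12, 3), t <- t + 0.08))
  occ2 <- build_occupancy_map(pos2, one_trial(3.1), g)
  b30 <- fine_bin_index(30, 12, g)
  expect_false(occ2$visited[b30$iy, b30$ix])
  # conservation: dwell over visited bins never exceeds included time
  gs <- mini_session()
  tr <- apply_trial_filters(segment_trials(gs$session$positions,
                                           gs$session$geometry,
                                           gs$session$schedule))
  occ3 <- build_occupancy_map(gs$session$positions, tr,
                              gs$session$geometry)
  expect_lte(sum(occ3$dwell[occ3$visited]),
             sum(tr$duration_s[tr$included]) * 1.02)
})

test_that("rate maps are spikes over dwell and conserve spike counts", {
  g <- track_geometry()
  pos <- still_positions(30, 12, 2)
  occ <- build_occupancy_map(pos, one_trial(2), g)
  st <- seq(0.1, 1.9, length.out = 6)
  rm1 <- build_rate_map(st, pos, one_trial(2), occ)
  expect_equal(max(rm1$rate, na.rm = TRUE), 6 / max(occ$dwell),
               tolerance = 1e-9)
  expect_equal(rm1$n_spikes_map, 6)
  # zero spikes -> all-zero map with zero mean rate
  rm0 <- build_rate_map(numeric(0), pos, one_trial(2), occ)
  expect_true(all(rm0$rate[occ$visited] == 0))
  expect_equal(rm0$mean_rate_hz, 0)
  # conservation identity on a full generated session
  gs <- mini_session()
  s <- gs$session
  tr <- apply_trial_filters(segment_trials(s$positions, s$geometry,
                                           s$schedule))
  tr0 <- tr[tr$tilt_deg == 0 & tr$direction == "uphill", ]
  occ2 <- build_occupancy_map(s$positions, tr0, s$geometry)
  rm2 <- build_rate_map(s$spikes$u01, s$positions, tr0, occ2)
  expect_equal(sum(rm2$rate * occ2$dwell, na.rm = TRUE),
               rm2$n_spikes_map, tolerance = 1e-9)
})

test_that("smoothing preserves mass on a delta map and fixes uniform maps", {
  g <- track_geometry()
  ny <- g$n_bins_short
  nx <- g$n_bins_long
  # kernel definition, away from edges: discretised Gaussian, unit mass
  delta21 <- matrix(0, 21, 41)
  delta21[11, 21] <- 1
  sm21 <- slopecell:::smooth_matrix(delta21, matrix(TRUE, 21, 41))
  expect_equal(sum(sm21), 1, tolerance = 1e-6)
  expect_equal(which(sm21 == max(sm21), arr.ind = TRUE)[1, ],
               c(row = 11, col = 21))
  occ <- structure(list(dwell = matrix(1, ny, nx),
                        visited = matrix(TRUE, ny, nx),
                        total_time_s = ny * nx, min_dwell_s = 0.1,
                        unanalyzable = FALSE, geometry = g),
                   class = "occupancy_map")
  unif <- structure(list(rate = matrix(2, ny, nx), occupancy = occ),
                    class = "rate_map")
  expect_equal(smooth_rate_map(unif)$rate, matrix(2, ny, nx),
               tolerance = 1e-9)
  # averaging never raises the peak
  gs <- classic_session(seed = 3)
  rmap <- analyze_session(gs$session)$maps[["0_uphill"]]$units[["u1"]]
  expect_lte(max(rmap$smoothed$rate, na.rm = TRUE),
             max(rmap$rate$rate, na.rm = TRUE))
})

test_that("field detection enforces the neighbour rule and main-field choice", {
  g <- track_geometry()
  ny <- g$n_bins_short
  nx <- g$n_bins_long
  occ <- structure(list(dwell = matrix(1, ny, nx),
                        visited = matrix(TRUE, ny, nx),
                        total_time_s = ny * nx, min_dwell_s = 0.1,
                        unanalyzable = FALSE, geometry = g),
                   class = "occupancy_map")
  # isolated supra-threshold bin: fails the 7-neighbour rule, no field
  iso <- matrix(0.01, ny, nx)
  iso[5, 20] <- 10
  f <- detect_fields(structure(list(rate = iso, occupancy = occ),
                               class = "rate_map"))
  expect_equal(nrow(f$fields), 0)
  # two Gaussian bumps 50 cm apart: two fields, larger one is main
  xs <- (seq_len(nx) - 0.5) * 2.5
  bump <- function(c0, amp, sd) amp * exp(-(xs - c0)^2 / (2 * sd^2))
  m <- matrix(rep(bump(25, 10, 8) + bump(75, 6, 4), each = ny), ny, nx)
  f2 <- detect_fields(structure(list(rate = m, occupancy = occ),
                                class = "rate_map"))
  expect_equal(nrow(f2$fields), 2)
  main <- f2$fields[f2$fields$is_main, ]
  expect_lt(abs((main$peak_col - 0.5) * 2.5 - 25), 2.6)
  expect_gt(main$size_bins, max(f2$fields$size_bins[!f2$fields$is_main]))
  # bounding-box measurements
  expect_equal(main$aspect, main$length_bins / main$width_bins)
})

test_that("1D collapse averages the short axis and commutes with scaling", {
  g <- track_geometry()
  m <- matrix(rep(seq_len(g$n_bins_long), each = g$n_bins_short),
              g$n_bins_short, g$n_bins_long)
  expect_equal(collapse_to_1d(m), as.numeric(seq_len(g$n_bins_long)))
  m[2, ] <- NA   # unvisited row is ignored
  expect_equal(collapse_to_1d(m), as.numeric(seq_len(g$n_bins_long)))
  expect_equal(collapse_to_1d(3 * m), 3 * collapse_to_1d(m))
})

test_that("coarse field detection matches the fine grid on planted bumps", {
  gs <- classic_session(seed = 4)
  s <- gs$session
  tr <- apply_trial_filters(segment_trials(s$positions, s$geometry,
                                           s$schedule))
  tru <- tr[tr$direction == "uphill" & tr$included, ]
  fld <- detect_fields_coarse(s$spikes$u1, s$positions, tru, s$geometry)
  expect_false(is.null(fld))
  expect_true(fld$x_min_cm <= 41.25 && 41.25 <= fld$x_max_cm)
  # a silent unit has no above-average cluster
  expect_null(detect_fields_coarse(numeric(0), s$positions, tru,
                                   s$geometry))
})

test_that("with two coarse fields the largest cluster is analysed", {
  cfg <- scenario_config(n_units = 2, tilt_order = 0)
  us <- list(
    unit_spec("big", center_cm = 30, sigma_cm = 9, peak_hz = 30,
              baseline_hz = 0.2, direction = "uphill"),
    unit_spec("small", center_cm = 80, sigma_cm = 4, peak_hz = 30,
              baseline_hz = 0.2, direction = "uphill"))
  gs <- generate_session(cfg, units = us, seed = 6)
  s <- gs$session
  # merge both trains into one two-field unit
  both <- sort(c(s$spikes$big, s$spikes$small))
  tr <- apply_trial_filters(segment_trials(s$positions, s$geometry,
                                           s$schedule))
  tru <- tr[tr$direction == "uphill" & tr$included, ]
  fld <- detect_fields_coarse(both, s$positions, tru, s$geometry)
  expect_false(is.null(fld))
  # the wide 30 cm field wins over the narrow 80 cm one
  expect_true(fld$x_min_cm <= 30 && 30 <= fld$x_max_cm)
  expect_false(fld$x_min_cm <= 80 && 80 <= fld$x_max_cm)
})
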