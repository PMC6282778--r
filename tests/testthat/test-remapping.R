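test_that("the six-way classifier covers every branch exhaustively", {
  # neither active
  expect_equal(classify_remapping(FALSE, FALSE)$call, "inactive")
  # active on the steeper only / the shallower only
  expect_equal(classify_remapping(FALSE, TRUE)$call, "turn_on")
  expect_equal(classify_remapping(TRUE, FALSE)$call, "turn_off")
  # both active, peaks 30 and 55 cm: field remap (and at the 20 cm
  # boundary itself)
  expect_equal(classify_remapping(TRUE, TRUE, 30, 55)$call, "field_remap")
  expect_equal(classify_remapping(TRUE, TRUE, 30, 50)$call, "field_remap")
  # peaks close, rates two-fold different: rate remap
  set.seed(1)
  ra <- stats::rpois(20, 20) / 2
  rb <- stats::rpois(20, 40) / 2
  cl <- classify_remapping(TRUE, TRUE, 40, 45, ra, rb)
  expect_equal(cl$call, "rate_remap")
  expect_lt(cl$p_rank_sum, 0.05)
  # same rates: stable
  expect_equal(classify_remapping(TRUE, TRUE, 40, 45, ra, ra)$call,
               "stable")
})

test_that("every place-cell pair receives exactly one call", {
  gs <- mini_session()
  res <- analyze_session(gs$session)
  calls <- res$remap_calls
  # 2 units x 2 directions x 3 ordered pairs
  expect_equal(nrow(calls), 12)
  expect_equal(anyDuplicated(calls[, c("unit_id", "direction", "tilt_a",
                                       "tilt_b")]), 0)
  expect_true(all(calls$call %in% c("inactive", "turn_on", "turn_off",
                                    "field_remap", "rate_remap",
                                    "stable")))
  expect_true(all(calls$tilt_a < calls$tilt_b))
})

test_that("spatial correlations behave on identity, skip and null cases", {
  m <- matrix(stats::rexp(40), 4, 10)
  expect_equal(spatial_correlation(m, m)$r, 1, tolerance = 1e-12)
  # two common non-zero bins: skipped
  a <- c(1, 2, 0, 0, 0)
  b <- c(2, 1, 0, 0, 0)
  sc <- spatial_correlation(a, b)
  expect_true(sc$skipped)
  expect_true(is.na(sc$r))
  # independent random maps decorrelate over seeds
  set.seed(10)
  rs <- replicate(100, spatial_correlation(stats::rexp(40),
                                           stats::rexp(40))$r)
  expect_lt(abs(mean(rs)), 0.05)
})

test_that("the shuffle null concentrates near zero and is reproducible", {
  set.seed(20)
  a <- stats::rexp(40)
  b <- a + stats::rnorm(40, 0, 0.3)
  n1 <- shuffle_null(a, b, n_shuffles = 2000, seed = 5)
  n2 <- shuffle_null(a, b, n_shuffles = 2000, seed = 5)
  expect_identical(n1$mean_null_r, n2$mean_null_r)
  expect_lt(abs(n1$mean_null_r), 3 / sqrt(40 * 2000) * 5)
  # the planted match beats its null by a wide margin
  actual <- spatial_correlation(a, b)$r
  expect_gt(actual, n1$mean_null_r)
  expect_gt(mean(actual > n1$null_r), 0.999)
})

test_that("sequence matrices expose ensemble order and its breakdown", {
  set.seed(30)
  nx <- 41
  mk <- function(center) {
    v <- exp(-((seq_len(nx) - center)^2) / 18)
    v + stats::rnorm(nx, 0, 0.02)
  }
  centers <- sample(5:37, 12)
  base <- stats::setNames(lapply(centers, mk), paste0("u", 1:12))
  sm <- sequence_matrix(base, base)
  # self-ordering: row peaks are non-decreasing down the matrix
  rp <- apply(sm, 1, which.max)
  expect_true(all(diff(rp) >= 0))
  expect_true(all(sm >= 0 & sm <= 1))
  # stable ensemble: target = jittered baseline, order preserved
  stab <- stats::setNames(lapply(centers + sample(-1:1, 12, TRUE), mk),
                          paste0("u", 1:12))
  sm2 <- sequence_matrix(stab, base)
  expect_gt(stats::cor(apply(sm2, 1, which.max), seq_len(12),
                       method = "spearman"), 0.9)
  # full turnover: independent centres, order destroyed
  turns <- replicate(50, {
    turn <- stats::setNames(lapply(sample(5:37, 12), mk),
                            paste0("u", 1:12))
    sm3 <- sequence_matrix(turn, base)
    stats::cor(apply(sm3, 1, which.max), seq_len(12),
               method = "spearman")
  })
  expect_lt(abs(mean(turns)), 0.15)
})

test_that("elevation halves follow the geometry and the tie rule", {
  g <- track_geometry()
  calls <- data.frame(unit_id = c("a", "b", "c"), direction = "uphill",
                      tilt_a = 0, tilt_b = 15,
                      call = c("stable", "turn_off", "rate_remap"))
  peaks <- data.frame(unit_id = c("a", "b", "c"), direction = "uphill",
                      peak_cm = c(20, 80, 51.5))
  tab <- elevation_half_analysis(calls, peaks, g, "north")
  # 20 cm (pivot side) and the exact midpoint both land in bottom
  expect_equal(tab["stable", "bottom"], 1)
  expect_equal(tab["rate_remap", "bottom"], 1)
  expect_equal(tab["turn_off", "top"], 1)
  # flipping the elevated end flips the halves
  tab2 <- elevation_half_analysis(calls, peaks, g, "south")
  expect_equal(tab2["stable", "top"], 1)
})

test_that("position-independent remapping yields a null elevation table", {
  set.seed(40)
  ok <- replicate(50, {
    n <- 60
    calls <- data.frame(unit_id = paste0("u", 1:n), direction = "uphill",
                        tilt_a = 0, tilt_b = 15,
                        call = sample(c("stable", "rate_remap", "turn_off"),
                                      n, TRUE, prob = c(0.4, 0.3, 0.3)))
    peaks <- data.frame(unit_id = paste0("u", 1:n), direction = "uphill",
                        peak_cm = stats::runif(n, 0, 103))
    tab <- elevation_half_analysis(calls, peaks, track_geometry(),
                                   "north")
    tab <- tab[rowSums(tab) > 0, , drop = FALSE]
    chi_square_independence(tab)$p_value > 0.05
  })
  expect_gte(mean(ok), 0.9)
})

test_that("chi-squared statistics match hand calculations and edge cases", {
  expect_equal(chi_square_independence(matrix(10, 2, 2))$statistic, 0)
  expect_error(chi_square_independence(matrix(c(0, 0, 3, 4), 2, 2,
                                              byrow = TRUE)),
               "row")
  expect_error(chi_square_independence(matrix(c(0, 3, 0, 4), 2, 2,
                                              byrow = TRUE)),
               "column")
  expect_error(chi_square_independence(matrix(1:3, 1)), "2 rows")
  # goodness of fit: hand value 2 * 10^2 / 50 = 4
  g1 <- chi_square_gof(c(60, 40))
  expect_equal(g1$statistic, 4, tolerance = 1e-12)
  expect_equal(g1$df, 1)
  expect_equal(chi_square_gof(c(50, 50))$statistic, 0)
  expect_error(chi_square_gof(c(10, 10), c(1, 0)), "zero expected")
})

test_that("the rank-sum test is exact for small samples and detects shifts", {
  # identical samples give p = 1 under symmetry
  expect_equal(wilcoxon_rank_sum(c(1, 2, 3), c(1, 2, 3))$p_value, 1)
  w <- wilcoxon_rank_sum(c(1, 2, 3), c(10, 11, 12))
  expect_true(w$exact)
  expect_equal(w$p_value, 0.1, tolerance = 1e-12)
  # power: 2 SD shift at n = 20 per group
  set.seed(50)
  sig <- replicate(50, {
    a <- stats::rnorm(20)
    b <- stats::rnorm(20, 2)
    wilcoxon_rank_sum(a, b)$p_value < 0.05
  })
  expect_gte(mean(sig), 0.95)
})

test_that("programmed remap types are recovered end-to-end", {
  gs <- cached("remap8", generate_session(scenario_config(n_units = 8),
                                          seed = 2))
  res <- analyze_session(gs$session)
  calls <- res$remap_calls
  tc <- gs$truth$calls
  mm <- match(paste(tc$unit_id, tc$direction, tc$tilt_a, tc$tilt_b),
              paste(calls$unit_id, calls$direction, calls$tilt_a,
                    calls$tilt_b))
  expect_gte(mean(calls$call[mm] == tc$true_call), 0.8)
})

test_that("an all-stable ensemble is called stable throughout", {
  us <- lapply(1:12, function(i)
    unit_spec(sprintf("u%02d", i), center_cm = 10 + 6.8 * i, peak_hz = 28,
              baseline_hz = 0.8,
              direction = if (i %% 2) "uphill" else "downhill"))
  # hold running speed constant across tilts so that only Poisson noise
  # can produce apparent rate changes (tilt-dependent speeds slow the
  # trials and shift trial rates even for spatially stable cells)
  eq <- list(uphill = 33, downhill = 33)
  gs <- generate_session(
    scenario_config(n_units = 12,
                    speed_cms = list(`0` = eq, `15` = eq, `25` = eq)),
    units = us, seed = 13)
  res <- analyze_session(gs$session)
  calls <- res$remap_calls
  tc <- gs$truth$calls
  mm <- match(paste(tc$unit_id, tc$direction, tc$tilt_a, tc$tilt_b),
              paste(calls$unit_id, calls$direction, calls$tilt_a,
                    calls$tilt_b))
  got <- calls$call[mm]
  # among active (both-condition) pairs the ensemble reads as stable up
  # to the rank-sum false-positive rate
  active <- got %in% c("stable", "rate_remap", "field_remap")
  expect_gt(sum(active), 10)
  expect_gte(mean(got[active] == "stable"), 0.9)
})

test_that("split halves stay stable within conditions more than between", {
  gs <- cached("remap8", generate_session(scenario_config(n_units = 8),
                                          seed = 2))
  sh <- split_half_remapping(gs$session)
  expect_true(all(c("within", "between") %in% sh$comparison))
  stable_rate <- tapply(sh$call == "stable", sh$comparison, mean)
  expect_gt(stable_rate["within"], stable_rate["between"])
})
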