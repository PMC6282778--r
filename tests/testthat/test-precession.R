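pure_tone_lfp <- function(f = 8, fs = 250, dur = 60, amp = 100,
                          noise = 0, seed = 1) {
  set.seed(seed)
  t <- seq(0, dur, by = 1 / fs)
  list(t = t, uv = -amp * cos(2 * pi * f * t) +
         stats::rnorm(length(t)) * noise, fs = fs)
}

test_that("phase is trough-referenced and advances 360 degrees per cycle", {
  th <- theta_phase_series(pure_tone_lfp())
  mins <- seq(1, 59, by = 1 / 8)          # LFP minima
  maxs <- mins + 1 / 16                   # LFP maxima
  pm <- slopecell:::interp_phase(th, mins)
  px <- slopecell:::interp_phase(th, maxs)
  expect_lt(max(circ_dist(pm, 0)), 1)
  expect_lt(max(circ_dist(px, 180)), 1)
  # consecutive troughs are exactly one cycle apart
  expect_lt(max(abs(diff(circ_dist(pm, 0)))), 0.5)
  expect_equal(mean(th$envelope[2000:10000]), 100, tolerance = 0.01)
})

test_that("out-of-band drift does not perturb the phase estimate", {
  clean <- theta_phase_series(pure_tone_lfp())
  t <- clean$t
  drift <- pure_tone_lfp()
  drift$uv <- drift$uv + 400 * sin(2 * pi * 2 * t)
  th <- theta_phase_series(drift)
  mid <- t > 5 & t < 55
  expect_lt(max(circ_dist(th$phase_deg[mid], clean$phase_deg[mid])), 2)
})

test_that("too-short or absent LFP is rejected with a clear message", {
  expect_error(theta_phase_series(NULL), "LFP required")
  expect_error(theta_phase_series(pure_tone_lfp(dur = 3)), "5 s")
})

test_that("spike-phase assignment enforces the envelope and count rules", {
  gs <- prec_session()
  s <- gs$session
  th <- theta_phase_series(s$lfp)
  tr <- apply_trial_filters(segment_trials(s$positions, s$geometry,
                                           s$schedule))
  tru <- tr[tr$direction == "uphill" & tr$included, ]
  fld <- detect_fields_coarse(s$spikes$u1, s$positions, tru, s$geometry)
  pairs <- assign_spike_phases(s$spikes$u1, th, fld, s$positions, tru,
                               s$geometry)
  expect_false(is.null(pairs))
  expect_gte(nrow(pairs), 50)
  expect_true(all(pairs$x_norm >= 0 & pairs$x_norm <= 1))
  # every retained spike rode an above-mean envelope
  env <- stats::approx(th$t, th$envelope, pairs$t)$y
  expect_true(all(env > attr(pairs, "env_mean")))
  # a 49-spike cell is skipped
  few <- sort(sample(s$spikes$u1, 49))
  expect_null(assign_spike_phases(few, th, fld, s$positions, tru,
                                  s$geometry))
})

test_that("the circular-linear fit recovers noiseless lines exactly", {
  set.seed(2)
  x <- stats::runif(300)
  phi <- (350 - 360 * x) %% 360
  f <- circular_linear_fit(data.frame(x_norm = x, phase_deg = phi))
  expect_lt(abs(f$slope_deg_per_field + 360), 1)   # within one grid step
  expect_lt(circ_dist(f$offset_deg, 350), 1)
  expect_gt(f$rho, 0.99)
  expect_false(f$bounded)
  # grid search agrees with a dense brute-force maximisation
  dense <- seq(-720, 720, by = 0.1)
  Rd <- vapply(dense, slopecell:::resultant_length, numeric(1),
               x = x, phi_rad = phi * pi / 180)
  expect_lt(abs(f$slope_deg_per_field - dense[which.max(Rd)]), 1)
})

test_that("slopes past two cycles per traverse are clipped and flagged", {
  set.seed(3)
  x <- stats::runif(300)
  phi <- (350 - 900 * x) %% 360
  f <- circular_linear_fit(data.frame(x_norm = x, phase_deg = phi))
  expect_equal(f$slope_deg_per_field, -720)
  expect_true(f$bounded)
})

test_that("uniform phases yield small correlations and calibrated errors", {
  set.seed(4)
  nulls <- t(replicate(100, {
    xi <- stats::runif(200)
    ph <- stats::runif(200, 0, 360)
    fi <- circular_linear_fit(data.frame(x_norm = xi, phase_deg = ph))
    c(fi$rho, fi$p_value)
  }))
  expect_lt(mean(abs(nulls[, 1])), 0.12)
  # slope selection makes the p-value mildly anticonservative; the
  # false-positive rate stays well below one in five
  expect_lte(mean(nulls[, 2] < 0.05), 0.2)
  # degenerate input: identical phases
  d <- circular_linear_fit(data.frame(x_norm = stats::runif(60),
                                      phase_deg = rep(123, 60)))
  expect_true(is.na(d$rho))
})

test_that("von Mises phase noise leaves the fitted slope unbiased", {
  set.seed(5)
  sl <- replicate(25, {
    x <- stats::runif(400)
    ph <- (350 - 360 * x + rvonmises(400, 0, 4)) %% 360
    circular_linear_fit(data.frame(x_norm = x,
                                   phase_deg = ph))$slope_deg_per_field
  })
  expect_lt(abs(mean(sl) + 360) / 360, 0.05)
})

test_that("the full pipeline recovers a programmed precession slope", {
  gs <- prec_session()
  pf <- precession_analysis(gs$session)
  expect_equal(nrow(pf), 1)
  expect_gt(pf$n_spikes, 50)
  expect_lt(abs(pf$slope_deg_per_field + 360) / 360, 0.25)
  expect_lt(pf$p_value, 0.05)
  expect_true(pf$slope_deg_per_field < 0)  # precession, not procession
})

test_that("Rayleigh behaves at concentration, uniformity and cancellation", {
  r1 <- rayleigh_test(rep(77, 50))
  expect_lt(r1$p_value, 1e-6)
  anti <- c(seq(0, 170, by = 10), seq(180, 350, by = 10))
  r2 <- rayleigh_test(anti)
  expect_lt(r2$R_bar, 1e-10)
  expect_gt(r2$p_value, 0.99)
  set.seed(6)
  ok <- replicate(50, rayleigh_test(stats::runif(500, 0, 360))$p_value >
                    0.05)
  expect_gte(mean(ok), 0.9)
})

test_that("Watson-Williams separates means and stays calibrated", {
  set.seed(7)
  g1 <- rvonmises(50, 0, 8)
  g2 <- rvonmises(50, 0, 8)
  same <- watson_williams_test(list(g1, g2))
  expect_gt(same$p_value, 0.05)
  diff9 <- watson_williams_test(list(rvonmises(50, 0, 8),
                                     rvonmises(50, 90, 8)))
  expect_lt(diff9$p_value, 0.001)
  # three groups from one distribution: p roughly uniform over seeds
  ps <- replicate(200, {
    gs3 <- lapply(1:3, function(i) rvonmises(30, 45, 5))
    watson_williams_test(gs3)$p_value
  })
  expect_gt(stats::ks.test(ps, "punif")$p.value, 0.01)
  # low-concentration input carries a warning
  weak <- watson_williams_test(list(stats::runif(30, 0, 360),
                                    stats::runif(30, 0, 360)))
  expect_false(is.null(weak$warning))
})

test_that("offsets fitted per condition follow a programmed phase shift", {
  # a single cell's fitted offset jitters with the detected field's entry
  # bin, so the ordering is read from the ensemble circular mean
  mk <- function(phi0, tilt) {
    us <- lapply(1:8, function(i)
      unit_spec(sprintf("u%d", i), center_cm = 18 + 9 * i, sigma_cm = 8,
                peak_hz = 28, baseline_hz = 0.2, direction = "uphill",
                phi0_deg = phi0, slope_deg = -360, kappa = 8))
    cfg <- scenario_config(n_units = 8, tilt_order = tilt,
                           lfp_noise_sd = 5)
    gs <- generate_session(cfg, units = us, seed = 17)
    pf <- precession_analysis(gs$session)
    off <- pf$offset_deg[pf$skipped == ""]
    (Arg(mean(exp(1i * off * pi / 180))) * 180 / pi) %% 360
  }
  # the generator moves firing 40 degrees earlier per tilt step; the
  # fitted ensemble offsets must reproduce that ordering
  off <- c(mk(330, 0), mk(290, 15), mk(250, 25))
  d1 <- (off[1] - off[2]) %% 360
  d2 <- (off[2] - off[3]) %% 360
  expect_true(d1 > 5 && d1 < 180)
  expect_true(d2 > 5 && d2 < 180)
})
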