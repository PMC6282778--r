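# Shared fixtures, built in code. Expensive sessions are cached per test
# run so several test files can reuse them.

.fixture_cache <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (!exists(key, envir = .fixture_cache))
    assign(key, force(expr), envir = .fixture_cache)
  get(key, envir = .fixture_cache)
}

# small two-unit session over all three tilts (fast: 4 laps/condition)
mini_session <- function(seed = 7) {
  cached(paste0("mini", seed), {
    us <- list(
      unit_spec("u01", center_cm = 35, peak_hz = 25, baseline_hz = 1,
                direction = "uphill"),
      unit_spec("u02", center_cm = 70, peak_hz = 25, baseline_hz = 1,
                direction = "downhill",
                remap = list(`15` = list(type = "turn_off"),
                             `25` = list(type = "turn_off"))))
    generate_session(scenario_config(n_units = 2, laps_per_condition = 4),
                     units = us, seed = seed)
  })
}

# single classic place cell, one flat block, full 20 laps
classic_session <- function(seed = 1, peak_hz = 25, baseline_hz = 0.5,
                            center_cm = 41.25, sigma_cm = 6, ...) {
  u <- unit_spec("u1", center_cm = center_cm, sigma_cm = sigma_cm,
                 peak_hz = peak_hz, baseline_hz = baseline_hz,
                 direction = "uphill", ...)
  generate_session(scenario_config(n_units = 1, tilt_order = 0),
                   units = list(u), seed = seed)
}

# one precessing cell with kappa = 4 phase noise, flat block only
prec_session <- function() {
  cached("prec1", {
    u <- unit_spec("u1", center_cm = 50, sigma_cm = 8, peak_hz = 25,
                   baseline_hz = 0.2, direction = "uphill",
                   phi0_deg = 350, slope_deg = -360, kappa = 4)
    generate_session(scenario_config(n_units = 1, tilt_order = 0,
                                     lfp_noise_sd = 5),
                     units = list(u), seed = 8)
  })
}

# draw from a von Mises distribution (Best & Fisher rejection sampler);
# independent of any package code, used as a test-side generator
rvonmises <- function(n, mu_deg, kappa) {
  if (kappa < 1e-8) return(stats::runif(n, 0, 360))
  a <- 1 + sqrt(1 + 4 * kappa^2)
  b <- (a - sqrt(2 * a)) / (2 * kappa)
  r <- (1 + b^2) / (2 * b)
  out <- numeric(n)
  i <- 0
  while (i < n) {
    u <- stats::runif(3)
    z <- cos(pi * u[1])
    f <- (1 + r * z) / (r + z)
    c2 <- kappa * (r - f)
    if (c2 * (2 - c2) - u[2] > 0 || log(c2 / u[2]) + 1 - c2 >= 0) {
      i <- i + 1
      out[i] <- ((sign(u[3] - 0.5) * acos(f)) * 180 / pi + mu_deg) %% 360
    }
  }
  out
}

# literal-formula Pearson chi-squared oracle (independence)
oracle_chisq <- function(tab) {
  e <- outer(rowSums(tab), colSums(tab)) / sum(tab)
  sum((tab - e)^2 / e)
}

# circular distance in degrees, in [0, 180]
circ_dist <- function(a, b) {
  d <- abs(a - b) %% 360
  pmin(d, 360 - d)
}
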