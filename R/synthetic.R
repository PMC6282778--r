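#' Scenario configuration for the synthetic session generator
#'
#' Collects everything the generator needs to emulate one recording day on
#' the tiltable shuttle track: the tilt blocks and their order, laps per
#' condition, mean running speeds per tilt and slope direction, theta
#' parameters and sampling rates. The defaults reproduce the study
#' conditions the pipeline is built for: about 20 laps in each of the three
#' tilt conditions, group-mean running speeds of roughly 33 cm/s on the
#' flat, slowing with tilt and slowest downhill, and an 8 Hz theta rhythm.
#'
#' @param n_units Number of simulated units in the default ensemble.
#' @param laps_per_condition Laps (out-and-back) per tilt block; one lap
#'   yields two end-to-end trials.
#' @param tilt_order Tilt angles of the consecutive blocks (degrees).
#' @param elevated_end End of the box that is raised in tilted blocks; the
#'   same label is recorded for 0-degree blocks as the session's
#'   running-direction convention.
#' @param speed_cms Named list `speed_cms[[tilt]][[direction]]` of mean
#'   running speeds (cm/s).
#' @param speed_cv Per-run coefficient of variation of running speed.
#' @param dwell_s Mean pause in an endzone between runs (s).
#' @param y_sd Stationary SD of the lateral (short-axis) wander (cm).
#' @param n_failed_per_block Incomplete (turn-around) excursions injected
#'   per block, for exercising the trial-inclusion filters.
#' @param pos_fs Position sampling rate (Hz).
#' @param theta_hz Theta frequency (Hz); in-band fixtures use 7-9 Hz.
#' @param theta_kappa von Mises concentration of spike phases around the
#'   preferred (precessing) phase; `Inf` means zero phase noise.
#' @param lfp_fs,lfp_amp_uv,lfp_noise_sd LFP sampling rate (Hz), theta
#'   amplitude (microvolts) and additive white-noise SD (microvolts).
#' @return An object of class `scenario_config`.
#' @export
scenario_config <- function(n_units = 30,
                            laps_per_condition = 20,
                            tilt_order = c(0, 15, 25),
                            elevated_end = c("north", "south"),
                            speed_cms = list(
                              `0`  = list(uphill = 32.7, downhill = 33.4),
                              `15` = list(uphill = 33.4, downhill = 31.5),
                              `25` = list(uphill = 30.0, downhill = 26.6)),
                            speed_cv = 0.05,
                            dwell_s = 3,
                            y_sd = 2.5,
                            n_failed_per_block = 0,
                            pos_fs = 50,
                            theta_hz = 8,
                            theta_kappa = 4,
                            lfp_fs = 250,
                            lfp_amp_uv = 100,
                            lfp_noise_sd = 10) {
  elevated_end <- match.arg(elevated_end)
  stopifnot(laps_per_condition >= 1, pos_fs > 0, lfp_fs > 0,
            theta_hz > 0, speed_cv >= 0, dwell_s > 0)
  stopifnot(all(tilt_order %in% c(0, 15, 25)))
  cfg <- list(n_units = n_units, laps_per_condition = laps_per_condition,
              tilt_order = tilt_order, elevated_end = elevated_end,
              speed_cms = speed_cms, speed_cv = speed_cv, dwell_s = dwell_s,
              y_sd = y_sd, n_failed_per_block = n_failed_per_block,
              pos_fs = pos_fs, theta_hz = theta_hz,
              theta_kappa = theta_kappa, lfp_fs = lfp_fs,
              lfp_amp_uv = lfp_amp_uv, lfp_noise_sd = lfp_noise_sd)
  class(cfg) <- "scenario_config"
  cfg
}

#' Specification of one simulated unit
#'
#' Defines a Gaussian spatial tuning curve on the running ROI, a slope
#' direction preference, programmed remapping between the 0-degree baseline
#' and each tilted condition, and programmed theta phase precession. The
#' base tuning describes the unit at 0 degrees; `remap` entries transform
#' it at 15 and/or 25 degrees.
#'
#' Remap entries are lists with a `type` and type-specific fields:
#' `list(type = "stable")`, `list(type = "rate_remap", factor = 2)`
#' (peak rate scaled), `list(type = "field_remap", shift_cm = 30)` (field
#' centre moved), `list(type = "turn_off")` (silent at that tilt) and
#' `list(type = "turn_on")` (silent at 0 degrees, active at that tilt).
#'
#' @param id Unit identifier (character).
#' @param center_cm Field centre, cm along the running ROI (0-103).
#' @param sigma_cm Tuning-curve SD (cm).
#' @param peak_hz Peak in-field rate above baseline (Hz).
#' @param baseline_hz Out-of-field rate (Hz).
#' @param direction Slope-direction preference: `"uphill"`, `"downhill"`
#'   or `"both"`.
#' @param remap Named list of remap entries keyed by tilt (`"15"`, `"25"`).
#' @param phi0_deg Theta phase at field entry (deg).
#' @param slope_deg Programmed precession slope, deg per field traverse;
#'   negative = precession. Bounded to two theta cycles.
#' @param kappa von Mises phase concentration; `NULL` uses the scenario's.
#' @return An object of class `unit_spec`.
#' @export
unit_spec <- function(id, center_cm, sigma_cm = 6, peak_hz = 15,
                      baseline_hz = 0.1,
                      direction = c("uphill", "downhill", "both"),
                      remap = list(), phi0_deg = 200, slope_deg = -360,
                      kappa = NULL) {
  direction <- match.arg(direction)
  stopifnot(sigma_cm > 0, peak_hz >= 0, baseline_hz >= 0,
            peak_hz >= baseline_hz || peak_hz == 0,
            abs(slope_deg) <= 720)
  u <- list(id = as.character(id), center_cm = center_cm,
            sigma_cm = sigma_cm, peak_hz = peak_hz,
            baseline_hz = baseline_hz, direction = direction,
            remap = remap, phi0_deg = phi0_deg, slope_deg = slope_deg,
            kappa = kappa)
  class(u) <- "unit_spec"
  u
}

# Effective tuning of a unit at one tilt angle, after applying its
# programmed remap transform. A turn_on entry silences the 0-degree base.
tuning_for_tilt <- function(unit, tilt) {
  tun <- list(center_cm = unit$center_cm, sigma_cm = unit$sigma_cm,
              peak_hz = unit$peak_hz, baseline_hz = unit$baseline_hz)
  key <- as.character(tilt)
  if (tilt == 0) {
    if (any(vapply(unit$remap, function(r) identical(r$type, "turn_on"),
                   logical(1))))
      tun$peak_hz <- 0
    return(tun)
  }
  r <- unit$remap[[key]]
  if (is.null(r) || identical(r$type, "stable")) return(tun)
  switch(r$type,
    rate_remap = { tun$peak_hz <- tun$peak_hz * r$factor },
    field_remap = { tun$center_cm <- tun$center_cm + r$shift_cm },
    turn_off = { tun$peak_hz <- 0 },
    turn_on = { },  # active here; the 0-degree base was silenced above
    stop("unknown remap type: ", r$type, call. = FALSE))
  tun
}

# Remap call implied by the programmed tuning for an ordered tilt pair
# (shallower -> steeper), matching the classifier's vocabulary.
truth_remap_call <- function(unit, tilt_a, tilt_b) {
  a <- tuning_for_tilt(unit, tilt_a)
  b <- tuning_for_tilt(unit, tilt_b)
  act_a <- a$peak_hz > 0
  act_b <- b$peak_hz > 0
  if (!act_a && !act_b) return("inactive")
  if (!act_a) return("turn_on")
  if (!act_b) return("turn_off")
  if (abs(a$center_cm - b$center_cm) >= 20) return("field_remap")
  if (abs(a$peak_hz - b$peak_hz) > 1e-9) return("rate_remap")
  "stable"
}

# Analytic theta phase of the synthetic LFP (0 deg = LFP trough)
true_theta_phase <- function(t, config) (360 * config$theta_hz * t) %% 360

#' Generate a shuttle-run trajectory
#'
#' Simulates alternating end-to-end runs through the consecutive tilt
#' blocks of the scenario, with raised-cosine acceleration inside the
#' endzones, constant cruise speed across the running ROI, pauses at the
#' reward wells and a small mean-reverting lateral wander. Per-run cruise
#' speeds are drawn around the scenario's per-tilt, per-direction means.
#'
#' @param config A [scenario_config()].
#' @param seed Optional integer; when given, the RNG is seeded so the same
#'   seed and config reproduce the series exactly.
#' @return A list of class `slope_trajectory` with elements `positions`
#'   (data.frame `t`, `x`, `y`), `schedule` (block table) and `runs`
#'   (per-run bookkeeping used by the spike generator).
#' @export
generate_trajectory <- function(config, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  g <- track_geometry()
  dwell_ez <- g$endzone_cm / 2             # endzone centre offset from wall
  x_of <- c(south = dwell_ez, north = g$long_axis_cm - dwell_ez)
  ramp_d <- g$roi_min_cm - dwell_ez        # centre -> ROI boundary, 4.25 cm

  segs <- list()   # each: t0 set later; dur, type, x0, x1, v
  runs <- list()
  blocks <- list()
  t_cum <- 0
  add_seg <- function(dur, type, x0, x1, v) {
    segs[[length(segs) + 1L]] <<- list(t0 = t_cum, dur = dur, type = type,
                                       x0 = x0, x1 = x1, v = v)
    t_cum <<- t_cum + dur
  }
  ground_end <- opposite_end(config$elevated_end)

  for (bi in seq_along(config$tilt_order)) {
    tilt <- config$tilt_order[bi]
    t_block0 <- t_cum
    cur <- "south"
    n_runs <- 2L * config$laps_per_condition
    fail_at <- integer(0)
    if (config$n_failed_per_block > 0)
      fail_at <- unique(pmax(1L, floor(seq(2, n_runs - 1,
                             length.out = config$n_failed_per_block))))
    add_seg(config$dwell_s * stats::runif(1, 0.8, 1.2), "dwell",
            x_of[[cur]], x_of[[cur]], 0)
    for (ri in seq_len(n_runs)) {
      dest <- opposite_end(cur)
      dir_label <- if (cur == ground_end) "uphill" else "downhill"
      v <- config$speed_cms[[as.character(tilt)]][[dir_label]]
      v <- max(5, v * (1 + stats::rnorm(1) * config$speed_cv))
      sgn <- if (dest == "north") 1 else -1
      if (ri %in% fail_at) {
        # incomplete excursion: out to mid-track and back, then the real run
        x_mid <- g$long_axis_cm / 2
        leg <- abs(x_mid - x_of[[cur]])
        T_leg <- leg / (v / 1.5)
        add_seg(T_leg, "fail_out", x_of[[cur]], x_mid, v)
        add_seg(T_leg, "fail_back", x_mid, x_of[[cur]], v)
        add_seg(config$dwell_s * stats::runif(1, 0.8, 1.2), "dwell",
                x_of[[cur]], x_of[[cur]], 0)
      }
      t_run0 <- t_cum
      T_ramp <- 2 * ramp_d / v
      add_seg(T_ramp, "ramp_in", x_of[[cur]],
              x_of[[cur]] + sgn * ramp_d, v)
      add_seg(g$roi_long_cm / v, "cruise",
              x_of[[cur]] + sgn * ramp_d,
              x_of[[cur]] + sgn * (ramp_d + g$roi_long_cm), v)
      add_seg(T_ramp, "ramp_out",
              x_of[[dest]] - sgn * ramp_d, x_of[[dest]], v)
      runs[[length(runs) + 1L]] <- data.frame(
        t0 = t_run0, t1 = t_cum, tilt_deg = tilt, sign = sgn,
        direction = dir_label, v_cms = v)
      add_seg(config$dwell_s * stats::runif(1, 0.8, 1.2), "dwell",
              x_of[[dest]], x_of[[dest]], 0)
      cur <- dest
    }
    blocks[[bi]] <- data.frame(block_id = bi, tilt_deg = tilt,
                               elevated_end = config$elevated_end,
                               t_start = t_block0, t_end = t_cum)
  }

  seg_t0 <- vapply(segs, `[[`, numeric(1), "t0")
  dt <- 1 / config$pos_fs
  t <- seq(0, t_cum - dt / 2, by = dt)
  si <- findInterval(t, seg_t0)
  u <- t - seg_t0[si]
  dur <- vapply(segs, `[[`, numeric(1), "dur")[si]
  x0 <- vapply(segs, `[[`, numeric(1), "x0")[si]
  x1 <- vapply(segs, `[[`, numeric(1), "x1")[si]
  v <- vapply(segs, `[[`, numeric(1), "v")[si]
  type <- vapply(segs, `[[`, character(1), "type")[si]
  sgn <- sign(x1 - x0)
  x <- x0
  r <- type == "ramp_in"
  x[r] <- x0[r] + sgn[r] * v[r] / 2 *
    (u[r] - dur[r] / pi * sin(pi * u[r] / dur[r]))
  r <- type == "cruise"
  x[r] <- x0[r] + sgn[r] * v[r] * u[r]
  r <- type == "ramp_out"
  x[r] <- x0[r] + sgn[r] * v[r] / 2 *
    (u[r] + dur[r] / pi * sin(pi * u[r] / dur[r]))
  r <- type %in% c("fail_out", "fail_back")
  x[r] <- x0[r] + (x1[r] - x0[r]) * (1 - cos(pi * u[r] / dur[r])) / 2

  # lateral wander: mean-reverting walk around the midline
  n <- length(t)
  y <- numeric(n)
  mid <- g$short_axis_cm / 2
  th <- 1.0
  y[1] <- mid
  noise <- stats::rnorm(n - 1) * config$y_sd * sqrt(2 * th * dt)
  for (i in seq_len(n - 1))
    y[i + 1] <- y[i] + th * (mid - y[i]) * dt + noise[i]
  y <- pmin(pmax(y, 0.5), g$short_axis_cm - 0.5)

  out <- list(positions = data.frame(t = t, x = x, y = y),
              schedule = do.call(rbind, blocks),
              runs = do.call(rbind, runs),
              geometry = g, config = config)
  class(out) <- "slope_trajectory"
  out
}

# besselI-normalised von Mises density factor (time-average 1 over phase)
vm_factor <- function(delta_deg, kappa) {
  exp(kappa * cos(delta_deg * pi / 180)) / besselI(kappa, 0)
}

# Instantaneous firing rate of a unit at arbitrary times, given the
# trajectory. Encodes the generative model: Gaussian spatial tuning gated
# by slope-direction preference and condition-specific (remapped) tuning,
# multiplied by a von Mises theta-phase factor concentrated on the
# programmed precession line.
unit_rate_fn <- function(times, traj, unit, config) {
  g <- traj$geometry
  lam <- rep(0, length(times))
  runs <- traj$runs
  idx <- findInterval(times, runs$t0)
  ok <- idx >= 1 & idx <= nrow(runs)
  ok[ok] <- times[ok] <= runs$t1[idx[ok]]
  base0 <- tuning_for_tilt(unit, 0)$baseline_hz
  lam[] <- base0
  if (!any(ok)) return(lam)
  ti <- times[ok]
  ri <- idx[ok]
  x <- stats::approx(traj$positions$t, traj$positions$x, ti, rule = 2, ties = "ordered")$y
  xr <- roi_x(x, g)
  tilt <- runs$tilt_deg[ri]
  tun <- lapply(c(`0` = 0, `15` = 15, `25` = 25), tuning_for_tilt,
                unit = unit)
  key <- as.character(tilt)
  cen <- vapply(tun, `[[`, numeric(1), "center_cm")[key]
  sig <- vapply(tun, `[[`, numeric(1), "sigma_cm")[key]
  pk <- vapply(tun, `[[`, numeric(1), "peak_hz")[key]
  bl <- vapply(tun, `[[`, numeric(1), "baseline_hz")[key]
  gate <- unit$direction == "both" | runs$direction[ri] == unit$direction
  f <- pk * exp(-(xr - cen)^2 / (2 * sig^2)) * gate
  kappa <- if (is.null(unit$kappa)) config$theta_kappa else unit$kappa
  if (is.finite(kappa) && kappa > 0) {
    xn <- (xr - (cen - 2 * sig)) / (4 * sig)
    xn[runs$sign[ri] < 0] <- 1 - xn[runs$sign[ri] < 0]
    xn <- pmin(pmax(xn, 0), 1)
    pref <- unit$phi0_deg + unit$slope_deg * xn
    f <- f * vm_factor(true_theta_phase(ti, config) - pref, kappa)
  }
  lam[ok] <- bl + f
  lam
}

#' Generate the spike train of one unit
#'
#' Draws an inhomogeneous Poisson spike train whose rate is the unit's
#' (condition-specific, direction-gated) Gaussian spatial tuning multiplied
#' by a von Mises theta-phase factor concentrated on the programmed
#' phase-precession line, via thinning of a homogeneous train. With
#' `kappa = Inf` (zero phase noise) spikes are instead placed exactly at
#' the times where the theta phase crosses the programmed preferred phase
#' within the field, thinned by the spatial envelope, so spike phases lie
#' exactly on the programmed line.
#'
#' @param traj A [generate_trajectory()] result.
#' @param unit A [unit_spec()].
#' @param config The [scenario_config()] used for the trajectory.
#' @param seed Optional integer RNG seed.
#' @return Sorted numeric vector of spike times (s).
#' @export
generate_unit_spikes <- function(traj, unit, config, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  t_end <- max(traj$positions$t)
  kappa <- if (is.null(unit$kappa)) config$theta_kappa else unit$kappa
  if (is.finite(kappa)) {
    tun <- lapply(c(0, 15, 25), tuning_for_tilt, unit = unit)
    pk_max <- max(vapply(tun, `[[`, numeric(1), "peak_hz"))
    bl_max <- max(vapply(tun, `[[`, numeric(1), "baseline_hz"))
    lam_max <- bl_max +
      pk_max * (if (kappa > 0) exp(kappa) / besselI(kappa, 0) else 1)
    if (lam_max <= 0) return(numeric(0))
    n_cand <- stats::rpois(1, lam_max * t_end)
    if (n_cand == 0) return(numeric(0))
    cand <- sort(stats::runif(n_cand, 0, t_end))
    lam <- unit_rate_fn(cand, traj, unit, config)
    st <- cand[stats::runif(n_cand) < lam / lam_max]
    return(unique(st))
  }
  # zero phase noise: spikes on theta-phase crossings of the programmed line
  g <- traj$geometry
  st <- numeric(0)
  for (ri in seq_len(nrow(traj$runs))) {
    run <- traj$runs[ri, ]
    tn <- tuning_for_tilt(unit, run$tilt_deg)
    if (tn$peak_hz <= 0) next
    if (!(unit$direction == "both" || run$direction == unit$direction)) next
    tg <- seq(run$t0, run$t1, by = 1 / (20 * config$theta_hz))
    x <- stats::approx(traj$positions$t, traj$positions$x, tg, rule = 2, ties = "ordered")$y
    xr <- roi_x(x, g)
    xn <- (xr - (tn$center_cm - 2 * tn$sigma_cm)) / (4 * tn$sigma_cm)
    if (run$sign < 0) xn <- 1 - xn
    infield <- xn >= 0 & xn <= 1
    pref <- unit$phi0_deg + unit$slope_deg * pmin(pmax(xn, 0), 1)
    d <- 360 * config$theta_hz * tg - pref     # continuous phase difference
    kf <- floor(d / 360)
    cross <- which(diff(kf) != 0 & infield[-length(infield)] &
                     infield[-1])
    for (ci in cross) {
      m <- 360 * max(kf[ci], kf[ci + 1])
      tc <- tg[ci] + (m - d[ci]) / (d[ci + 1] - d[ci]) * diff(tg[ci + 0:1])
      xc <- stats::approx(traj$positions$t, traj$positions$x, tc,
                          rule = 2, ties = "ordered")$y
      env <- exp(-(roi_x(xc, g) - tn$center_cm)^2 / (2 * tn$sigma_cm^2))
      if (stats::runif(1) < env) st <- c(st, tc)
    }
  }
  sort(unique(st))
}

# Default ensemble: field centres spread over the ROI, alternating slope
# preferences, programmed remap types cycled over the six-way vocabulary.
default_units <- function(config) {
  types <- list(list(type = "stable"),
                list(type = "rate_remap", factor = 2),
                list(type = "rate_remap", factor = 0.5),
                list(type = "field_remap", shift_cm = 30),
                list(type = "turn_on"),
                list(type = "turn_off"))
  n <- config$n_units
  centers <- stats::runif(n, 15, 88)
  lapply(seq_len(n), function(i) {
    rt <- types[[(i - 1L) %% length(types) + 1L]]
    if (identical(rt$type, "field_remap") && centers[i] + rt$shift_cm > 95)
      rt$shift_cm <- -rt$shift_cm
    unit_spec(id = sprintf("u%02d", i), center_cm = centers[i],
              sigma_cm = 6, peak_hz = stats::runif(1, 15, 35),
              baseline_hz = 1,
              direction = if (i %% 2) "uphill" else "downhill",
              remap = list(`15` = rt, `25` = rt),
              phi0_deg = 200, slope_deg = -360)
  })
}

#' Generate a complete ground-truthed session
#'
#' Assembles a trajectory, per-unit spike trains, a synthetic theta LFP
#' (sinusoid at the scenario's theta frequency plus Gaussian noise, trough
#' at phase zero) and the condition schedule into a [session()], paired
#' with the ground truth that produced it. Identical `seed` and `config`
#' reproduce the session exactly.
#'
#' @param config A [scenario_config()].
#' @param units Optional list of [unit_spec()]s; by default an ensemble of
#'   `config$n_units` units cycling through the six programmed remap types.
#' @param seed Integer RNG seed.
#' @return List with elements `session` (a `slope_session`) and `truth`
#'   (list: `units` the specs, `tuning` per-unit-per-tilt tuning table,
#'   `calls` programmed remap calls for the three ordered tilt pairs).
#' @export
generate_session <- function(config = scenario_config(), units = NULL,
                             seed = 1) {
  set.seed(seed)
  traj <- generate_trajectory(config)
  if (is.null(units)) units <- default_units(config)
  ids <- vapply(units, `[[`, character(1), "id")
  if (anyDuplicated(ids)) stop("duplicate unit ids", call. = FALSE)
  spikes <- stats::setNames(
    lapply(units, generate_unit_spikes, traj = traj, config = config), ids)
  t_lfp <- seq(0, max(traj$positions$t), by = 1 / config$lfp_fs)
  uv <- -config$lfp_amp_uv * cos(2 * pi * config$theta_hz * t_lfp) +
    stats::rnorm(length(t_lfp)) * config$lfp_noise_sd
  s <- session(traj$positions, spikes, traj$schedule, traj$geometry,
               lfp = list(t = t_lfp, uv = uv, fs = config$lfp_fs),
               pos_fs = config$pos_fs)
  tuning <- do.call(rbind, lapply(units, function(u) {
    do.call(rbind, lapply(c(0, 15, 25), function(tl) {
      tn <- tuning_for_tilt(u, tl)
      data.frame(unit_id = u$id, tilt_deg = tl, center_cm = tn$center_cm,
                 sigma_cm = tn$sigma_cm, peak_hz = tn$peak_hz,
                 baseline_hz = tn$baseline_hz, direction = u$direction,
                 phi0_deg = u$phi0_deg, slope_deg = u$slope_deg)
    }))
  }))
  pairs <- list(c(0, 15), c(0, 25), c(15, 25))
  calls <- do.call(rbind, lapply(units, function(u) {
    do.call(rbind, lapply(pairs, function(p) {
      data.frame(unit_id = u$id, tilt_a = p[1], tilt_b = p[2],
                 direction = u$direction,
                 true_call = truth_remap_call(u, p[1], p[2]))
    }))
  }))
  list(session = s,
       truth = list(units = units, tuning = tuning, calls = calls,
                    config = config, seed = seed))
}
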