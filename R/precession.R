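#' Theta phase series from the LFP
#'
#' Band-pass filters the LFP between 7 and 9 Hz with a 4th-order
#' Butterworth applied forward-backward (zero phase distortion in the
#' passband), takes the analytic signal, and reports instantaneous phase
#' re-referenced so that 0 degrees falls at the trough (minimum) of the
#' filtered signal, together with the amplitude envelope.
#'
#' @param lfp List `t`, `uv`, `fs` (uniform sampling).
#' @param band Passband (Hz).
#' @param order Butterworth order (per pass).
#' @return Object of class `theta_phase`: `t`, `phase_deg` (in [0, 360),
#'   0 = trough), `envelope` (microvolts), `filtered`, `fs`.
#' @export
theta_phase_series <- function(lfp, band = c(7, 9), order = 4) {
  if (is.null(lfp)) stop("LFP required", call. = FALSE)
  stopifnot(all(c("t", "uv", "fs") %in% names(lfp)))
  if (diff(range(lfp$t)) < 5)
    stop("LFP too short: need at least 5 s", call. = FALSE)
  bf <- signal::butter(order, band / (lfp$fs / 2), type = "pass")
  filt <- signal::filtfilt(bf, lfp$uv)
  an <- analytic_signal(filt)
  phase <- (Arg(an) * 180 / pi + 180) %% 360
  structure(list(t = lfp$t, phase_deg = phase, envelope = Mod(an),
                 filtered = filt, fs = lfp$fs),
            class = "theta_phase")
}

# Analytic signal via the frequency-domain Hilbert construction: zero the
# negative frequencies, double the positive ones, inverse transform.
analytic_signal <- function(x) {
  n <- length(x)
  X <- stats::fft(x)
  h <- numeric(n)
  if (n %% 2 == 0) {
    h[1] <- 1
    h[n / 2 + 1] <- 1
    h[2:(n / 2)] <- 2
  } else {
    h[1] <- 1
    h[2:((n + 1) / 2)] <- 2
  }
  stats::fft(X * h, inverse = TRUE) / n
}

# interpolate phase (deg) at arbitrary times through the unwrapped phase
interp_phase <- function(theta, times) {
  ph <- theta$phase_deg * pi / 180
  unw <- ph + c(0, cumsum(round(-diff(ph) / (2 * pi)))) * 2 * pi
  (stats::approx(theta$t, unw, times, rule = 2, ties = "ordered")$y * 180 / pi) %% 360
}

#' Assign phases and field positions to in-field spikes
#'
#' Collects spikes fired during in-field traversals of the analysed
#' direction's included trials, maps each to its normalised position in
#' the field (0 at the entry edge, 1 at the exit, per the running
#' direction) and its instantaneous theta phase, and discards spikes fired
#' while the theta amplitude envelope was at or below its mean (computed
#' over the in-ROI position samples of the analysed trials). Cells
#' providing fewer than `min_spikes` (50) qualifying spikes are skipped.
#'
#' @param spike_times Spike times (s).
#' @param theta A [theta_phase_series()] result.
#' @param field Coarse field from [detect_fields_coarse()] (`x_min_cm`,
#'   `x_max_cm`, ROI-local).
#' @param positions data.frame `t`, `x`, `y`.
#' @param trials Included trials of the analysed condition and direction.
#' @param geometry A [track_geometry()].
#' @param min_spikes Minimum qualifying spikes.
#' @return data.frame `t`, `x_norm`, `phase_deg` with attributes
#'   `env_mean` and `n_candidates`; `NULL` when fewer than `min_spikes`
#'   qualify (cell skipped).
#' @export
assign_spike_phases <- function(spike_times, theta, field, positions,
                                trials, geometry, min_spikes = 50) {
  inc <- trials[trials$included, , drop = FALSE]
  if (!nrow(inc) || is.null(field)) return(NULL)
  # envelope mean over in-ROI samples of the analysed trials
  keep <- rep(FALSE, nrow(positions))
  for (i in seq_len(nrow(inc)))
    keep <- keep | (positions$t >= inc$t_start_s[i] &
                    positions$t < inc$t_end_s[i])
  keep <- keep & in_roi(positions$x, geometry)
  env_t <- stats::approx(theta$t, theta$envelope, positions$t[keep],
                         rule = 2, ties = "ordered")$y
  env_mean <- mean(env_t)
  rows <- list()
  for (i in seq_len(nrow(inc))) {
    tr <- inc[i, ]
    sel <- spike_times >= tr$t_start_s & spike_times < tr$t_end_s
    if (!any(sel)) next
    st <- spike_times[sel]
    sx <- roi_x(stats::approx(positions$t, positions$x, st, rule = 2, ties = "ordered")$y,
                geometry)
    infield <- sx >= field$x_min_cm & sx <= field$x_max_cm
    if (!any(infield)) next
    st <- st[infield]
    sx <- sx[infield]
    # direction of travel within this trial (sign of x displacement)
    x0 <- stats::approx(positions$t, positions$x, tr$t_start_s, rule = 2, ties = "ordered")$y
    x1 <- stats::approx(positions$t, positions$x, tr$t_end_s, rule = 2, ties = "ordered")$y
    sgn <- sign(x1 - x0)
    xn <- (sx - field$x_min_cm) / (field$x_max_cm - field$x_min_cm)
    if (sgn < 0) xn <- 1 - xn
    rows[[length(rows) + 1L]] <- data.frame(t = st, x_norm = xn)
  }
  if (!length(rows)) return(NULL)
  out <- do.call(rbind, rows)
  env_s <- stats::approx(theta$t, theta$envelope, out$t, rule = 2, ties = "ordered")$y
  n_cand <- nrow(out)
  out <- out[env_s > env_mean, , drop = FALSE]
  if (nrow(out) < min_spikes) return(NULL)
  out$phase_deg <- interp_phase(theta, out$t)
  attr(out, "env_mean") <- env_mean
  attr(out, "n_candidates") <- n_cand
  out
}

# mean resultant length of phi - a * x (phi deg, a deg per traverse)
resultant_length <- function(a, x, phi_rad) {
  Mod(mean(exp(1i * (phi_rad - a * pi / 180 * x))))
}

#' Circular-linear regression of spike phase on field position
#'
#' Estimates the phase-precession slope as the value of `a` maximising the
#' mean resultant length `R(a) = |mean exp(i(phi_j - a x_j))|` over a
#' 1-degree-per-traverse grid on [-720, 720] (two theta cycles per field
#' traverse), refined locally by golden-section search. The phase offset
#' is the circular mean of `phi_j - a x_j` (the phase at field entry), and
#' the circular-linear correlation and its asymptotic normal p-value
#' follow the standard circular-linear correlation construction. Slopes at
#' the bound are reported with `bounded = TRUE`.
#'
#' @param pairs data.frame with `x_norm` (position in field, 0-1) and
#'   `phase_deg`.
#' @param slope_bound Bound on |slope| (deg per traverse).
#' @param grid_step Grid resolution (deg per traverse).
#' @return One-row data.frame of class `precession_fit`: `n`,
#'   `slope_deg_per_field`, `offset_deg`, `rho`, `p_value`, `bounded`,
#'   `significant`. `rho` is NA for degenerate inputs (all phases equal).
#' @export
circular_linear_fit <- function(pairs, slope_bound = 720, grid_step = 1) {
  x <- pairs$x_norm
  phi <- pairs$phase_deg * pi / 180
  n <- length(x)
  stopifnot(n >= 3)
  grid <- seq(-slope_bound, slope_bound, by = grid_step)
  Rg <- vapply(grid, resultant_length, numeric(1), x = x, phi_rad = phi)
  a0 <- grid[which.max(Rg)]
  lo <- max(-slope_bound, a0 - grid_step)
  hi <- min(slope_bound, a0 + grid_step)
  opt <- stats::optimize(resultant_length, c(lo, hi), x = x,
                         phi_rad = phi, maximum = TRUE)
  a <- if (opt$objective >= max(Rg)) opt$maximum else a0
  bounded <- abs(a) >= slope_bound - grid_step / 2
  if (bounded) a <- sign(a) * slope_bound
  offset <- (Arg(mean(exp(1i * (phi - a * pi / 180 * x)))) * 180 / pi) %% 360
  # circular-linear correlation between phase and fitted circular position
  psi <- (a * pi / 180 * x) %% (2 * pi)
  phi_bar <- Arg(mean(exp(1i * phi)))
  psi_bar <- Arg(mean(exp(1i * psi)))
  sp <- sin(phi - phi_bar)
  sq <- sin(psi - psi_bar)
  den <- sqrt(sum(sp^2) * sum(sq^2))
  if (den == 0) {
    fit <- data.frame(n = n, slope_deg_per_field = a, offset_deg = offset,
                      rho = NA_real_, p_value = NA_real_,
                      bounded = bounded, significant = NA)
    class(fit) <- c("precession_fit", class(fit))
    return(fit)
  }
  rho <- sum(sp * sq) / den
  l20 <- mean(sp^2)
  l02 <- mean(sq^2)
  l22 <- mean(sp^2 * sq^2)
  p <- if (l22 > 0) {
    z <- rho * sqrt(n * l20 * l02 / l22)
    2 * stats::pnorm(-abs(z))
  } else NA_real_
  fit <- data.frame(n = n, slope_deg_per_field = a, offset_deg = offset,
                    rho = rho, p_value = p, bounded = bounded,
                    significant = isTRUE(p < 0.05))
  class(fit) <- c("precession_fit", class(fit))
  fit
}

#' Rayleigh test of circular uniformity
#'
#' @param angles_deg Angles in degrees (at least 3).
#' @return List: `R_bar` (mean resultant length), `statistic`
#'   (`Z = n R_bar^2`), `p_value` (finite-sample corrected
#'   approximation).
#' @export
rayleigh_test <- function(angles_deg) {
  n <- length(angles_deg)
  stopifnot(n >= 3)
  a <- angles_deg * pi / 180
  Rbar <- Mod(mean(exp(1i * a)))
  Z <- n * Rbar^2
  p <- exp(-Z) * (1 + (2 * Z - Z^2) / (4 * n) -
                    (24 * Z - 132 * Z^2 + 76 * Z^3 - 9 * Z^4) /
                    (288 * n^2))
  list(R_bar = Rbar, statistic = Z, p_value = min(max(p, 0), 1))
}

#' Watson-Williams test for equal circular means
#'
#' High-concentration F test comparing the circular means of two or more
#' groups, with the standard concentration correction factor
#' `1 + 3 / (8 kappa)`. The test assumes reasonably concentrated samples;
#' when the pooled mean resultant length falls below 0.45 a warning is
#' attached to the result.
#'
#' @param groups List of numeric vectors of angles (deg), each of length
#'   at least 5.
#' @return List: `F`, `df1`, `df2`, `p_value`, `kappa`, `warning` (NULL or
#'   a message).
#' @export
watson_williams_test <- function(groups) {
  stopifnot(length(groups) >= 2, all(lengths(groups) >= 5))
  k <- length(groups)
  ns <- lengths(groups)
  N <- sum(ns)
  rads <- lapply(groups, function(g) g * pi / 180)
  Ri <- vapply(rads, function(a) Mod(sum(exp(1i * a))), numeric(1))
  R <- Mod(sum(vapply(rads, function(a) sum(exp(1i * a)), complex(1))))
  rw <- sum(Ri) / N
  warn <- NULL
  if (rw < 0.45)
    warn <- sprintf("pooled resultant %.2f < 0.45: assumptions doubtful",
                    rw)
  kappa <- a1inv(rw)
  K <- 1 + 3 / (8 * kappa)
  Fstat <- K * ((sum(Ri) - R) / (k - 1)) / ((N - sum(Ri)) / (N - k))
  p <- stats::pf(Fstat, k - 1, N - k, lower.tail = FALSE)
  list(F = Fstat, df1 = k - 1, df2 = N - k, p_value = p, kappa = kappa,
       warning = warn)
}

# inverse of A(kappa) = I1(kappa) / I0(kappa) (standard approximation)
a1inv <- function(r) {
  if (r >= 0 && r < 0.53) return(2 * r + r^3 + 5 * r^5 / 6)
  if (r < 0.85) return(-0.4 + 1.39 * r + 0.43 / (1 - r))
  1 / (r^3 - 4 * r^2 + 3 * r)
}
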