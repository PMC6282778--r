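#' Assemble a recording session
#'
#' A session bundles everything one recording day produced: the tracked
#' position stream, per-unit spike trains, an optional LFP channel and the
#' schedule of tilt-condition blocks, together with the track geometry.
#' All downstream stages (trial segmentation, rate maps, remapping,
#' phase precession) operate on this object.
#'
#' @param positions data.frame with columns `t` (s, strictly increasing),
#'   `x` (cm along the long axis) and `y` (cm along the short axis).
#' @param spikes Named list, one numeric vector of spike times (s, sorted)
#'   per unit. Empty vectors are allowed.
#' @param schedule data.frame with columns `block_id`, `tilt_deg`
#'   (0, 15 or 25), `elevated_end` (`"north"` or `"south"`; for 0-degree
#'   blocks this records the running-direction convention of the session's
#'   tilted blocks), `t_start` and `t_end` (s). Blocks must not overlap.
#' @param geometry A [track_geometry()].
#' @param lfp Optional list with elements `t` (s), `uv` (microvolts) and
#'   `fs` (sampling rate, Hz); the sampling must be uniform at `fs`.
#' @param pos_fs Position sampling rate (Hz), recorded for provenance.
#' @param validate Run [validate_session()] before returning?
#' @return An object of class `slope_session`.
#' @seealso [load_session()], [write_session()], [generate_session()]
#' @export
session <- function(positions, spikes, schedule, geometry = track_geometry(),
                    lfp = NULL, pos_fs = NULL, validate = TRUE) {
  s <- structure(list(positions = positions, spikes = spikes,
                      schedule = schedule, geometry = geometry,
                      lfp = lfp, pos_fs = pos_fs),
                 class = "slope_session")
  if (validate) validate_session(s)
  s
}

#' Validate a session against its invariants
#'
#' Checks that timestamps are strictly increasing within every series, that
#' positions stay inside the box, that every spike falls within the tracked
#' time span and that schedule blocks do not overlap. Violations raise an
#' error naming the offending series and row.
#'
#' @param s A `slope_session`.
#' @return `s`, invisibly, if valid.
#' @export
validate_session <- function(s) {
  stopifnot(inherits(s, "slope_session"))
  p <- s$positions
  if (!all(c("t", "x", "y") %in% names(p)))
    stop("positions must have columns t, x, y", call. = FALSE)
  if (nrow(p) < 2L)
    stop("positions: need at least two samples", call. = FALSE)
  bad <- which(diff(p$t) <= 0)
  if (length(bad))
    stop(sprintf("positions: non-increasing timestamp at row %d (t = %.6f)",
                 bad[1] + 1L, p$t[bad[1] + 1L]), call. = FALSE)
  g <- s$geometry
  out <- which(p$x < 0 | p$x > g$long_axis_cm |
               p$y < 0 | p$y > g$short_axis_cm)
  if (length(out))
    stop(sprintf("positions: coordinates outside the %g x %g cm box at row %d",
                 g$long_axis_cm, g$short_axis_cm, out[1]), call. = FALSE)
  span <- range(p$t)
  for (u in names(s$spikes)) {
    st <- s$spikes[[u]]
    if (length(st) == 0) next
    if (is.unsorted(st, strictly = TRUE))
      stop(sprintf("spikes[%s]: non-increasing timestamps", u), call. = FALSE)
    if (min(st) < span[1] || max(st) > span[2])
      stop(sprintf("spikes[%s]: spike time outside the session span [%g, %g]",
                   u, span[1], span[2]), call. = FALSE)
  }
  sch <- s$schedule
  need <- c("block_id", "tilt_deg", "elevated_end", "t_start", "t_end")
  if (!all(need %in% names(sch)))
    stop("schedule must have columns ", paste(need, collapse = ", "),
         call. = FALSE)
  if (any(sch$t_end <= sch$t_start))
    stop("schedule: block with t_end <= t_start", call. = FALSE)
  if (!all(sch$tilt_deg %in% c(0, 15, 25)))
    stop("schedule: tilt_deg must be one of 0, 15, 25", call. = FALSE)
  if (!all(sch$elevated_end %in% c("north", "south")))
    stop("schedule: elevated_end must be 'north' or 'south'", call. = FALSE)
  o <- order(sch$t_start)
  if (nrow(sch) > 1 && any(sch$t_start[o][-1] < sch$t_end[o][-nrow(sch)]))
    stop("schedule: condition blocks overlap", call. = FALSE)
  if (!is.null(s$lfp)) {
    l <- s$lfp
    if (!all(c("t", "uv", "fs") %in% names(l)))
      stop("lfp must have elements t, uv, fs", call. = FALSE)
    dt <- diff(l$t)
    if (any(dt <= 0))
      stop("lfp: non-increasing timestamps", call. = FALSE)
    if (max(abs(dt - 1 / l$fs)) > 1e-6)
      stop("lfp: sampling not uniform at the declared rate", call. = FALSE)
  }
  invisible(s)
}

#' @export
print.slope_session <- function(x, ...) {
  cat(sprintf("<slope_session> %.1f s, %d position samples, %d units",
              diff(range(x$positions$t)), nrow(x$positions),
              length(x$spikes)))
  cat(sprintf(", %d schedule blocks, LFP %s\n", nrow(x$schedule),
              if (is.null(x$lfp)) "absent" else
                sprintf("%d samples @ %g Hz", length(x$lfp$t), x$lfp$fs)))
  invisible(x)
}

num_fmt <- function(x) formatC(x, format = "g", digits = 12)

write_tsv <- function(df, path) {
  df2 <- df
  for (j in seq_along(df2))
    if (is.numeric(df2[[j]]) && !is.integer(df2[[j]]))
      df2[[j]] <- num_fmt(df2[[j]])
  utils::write.table(df2, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = TRUE)
}

#' Write a session to a directory
#'
#' The on-disk format is plain delimited text plus a YAML config, chosen so
#' sessions can be inspected and produced from any language: `positions.tsv`
#' (t_s, x_cm, y_cm), `spikes.tsv` (unit_id, t_s), optionally `lfp.tsv`
#' (t_s, uv) and `session.yaml` (geometry, sampling rates, schedule blocks
#' with elevated end). [load_session()] on the result reproduces every
#' numeric field to better than 1e-9.
#'
#' @param s A validated `slope_session`.
#' @param path Directory to create/write into.
#' @return `path`, invisibly.
#' @export
write_session <- function(s, path) {
  validate_session(s)
  dir.create(path, recursive = TRUE, showWarnings = FALSE)
  if (!dir.exists(path)) stop("cannot create directory ", path, call. = FALSE)
  p <- s$positions
  write_tsv(data.frame(t_s = p$t, x_cm = p$x, y_cm = p$y),
            file.path(path, "positions.tsv"))
  sp <- data.frame(
    unit_id = rep(names(s$spikes), lengths(s$spikes)),
    t_s = unlist(s$spikes, use.names = FALSE))
  # keep a header-only file when every train is empty
  write_tsv(sp, file.path(path, "spikes.tsv"))
  if (!is.null(s$lfp))
    write_tsv(data.frame(t_s = s$lfp$t, uv = s$lfp$uv),
              file.path(path, "lfp.tsv"))
  g <- s$geometry
  cfg <- list(
    geometry = list(long_axis_cm = g$long_axis_cm,
                    short_axis_cm = g$short_axis_cm,
                    roi_long_cm = g$roi_long_cm,
                    bin_side_cm = g$bin_side_cm,
                    pivot_end = g$pivot_end),
    pos_fs = s$pos_fs,
    lfp_fs = if (is.null(s$lfp)) NULL else s$lfp$fs,
    units = as.list(names(s$spikes)),
    schedule = lapply(seq_len(nrow(s$schedule)), function(i) {
      b <- s$schedule[i, ]
      list(block_id = as.integer(b$block_id), tilt_deg = b$tilt_deg,
           elevated_end = b$elevated_end,
           t_start = b$t_start, t_end = b$t_end)
    }))
  yaml::write_yaml(cfg, file.path(path, "session.yaml"),
                   precision = 12L)
  invisible(path)
}

#' Load a session from a directory
#'
#' Reads the delimited-text session format written by [write_session()]
#' (see there for the schemas), validates it, and reports per-file record
#' counts on `stderr`. The LFP file is optional; stages that need it
#' (phase precession) signal "LFP required" when it is absent.
#'
#' @param path Session directory.
#' @param quiet Suppress the record-count messages?
#' @return A validated `slope_session`.
#' @export
load_session <- function(path, quiet = FALSE) {
  need <- c("positions.tsv", "spikes.tsv", "session.yaml")
  missing <- need[!file.exists(file.path(path, need))]
  if (length(missing))
    stop("session directory ", path, " is missing: ",
         paste(missing, collapse = ", "), call. = FALSE)
  cfg <- yaml::read_yaml(file.path(path, "session.yaml"))
  g <- cfg$geometry
  geometry <- track_geometry(long_axis_cm = g$long_axis_cm,
                             short_axis_cm = g$short_axis_cm,
                             roi_long_cm = g$roi_long_cm,
                             bin_side_cm = g$bin_side_cm,
                             pivot_end = g$pivot_end)
  pos <- utils::read.delim(file.path(path, "positions.tsv"))
  positions <- data.frame(t = pos$t_s, x = pos$x_cm, y = pos$y_cm)
  sp <- utils::read.delim(file.path(path, "spikes.tsv"),
                          colClasses = c("character", "numeric"))
  units <- unlist(cfg$units)
  spikes <- stats::setNames(
    lapply(units, function(u) sort(sp$t_s[sp$unit_id == u])), units)
  lfp <- NULL
  if (file.exists(file.path(path, "lfp.tsv"))) {
    lf <- utils::read.delim(file.path(path, "lfp.tsv"))
    lfp <- list(t = lf$t_s, uv = lf$uv, fs = cfg$lfp_fs)
  }
  schedule <- do.call(rbind, lapply(cfg$schedule, function(b)
    data.frame(block_id = b$block_id, tilt_deg = b$tilt_deg,
               elevated_end = b$elevated_end,
               t_start = b$t_start, t_end = b$t_end)))
  if (!quiet)
    message(sprintf(
      "load_session: %d position samples, %d spikes over %d units, %s, %d blocks",
      nrow(positions), nrow(sp), length(spikes),
      if (is.null(lfp)) "no LFP" else
        sprintf("%d LFP samples", length(lfp$t)),
      nrow(schedule)))
  session(positions, spikes, schedule, geometry, lfp = lfp,
          pos_fs = cfg$pos_fs)
}

#' Write analysis reports
#'
#' Emits the delimited-text result tables produced by [analyze_session()]
#' and [precession_analysis()] plus a machine-readable YAML summary of
#' record counts. Tables present are written as `trials.tsv`, `metrics.tsv`,
#' `remap_calls.tsv`, `correlations.tsv` and `precession.tsv`; their columns
#' are the columns of the corresponding result data.frames. Reruns on the
#' same inputs and seed produce byte-identical files.
#'
#' @param results Named list of data.frames; recognised names are `trials`,
#'   `metrics`, `remap_calls` (or `remap`), `correlations`, `precession`.
#' @param path Output directory.
#' @return `path`, invisibly.
#' @export
write_report <- function(results, path) {
  dir.create(path, recursive = TRUE, showWarnings = FALSE)
  if (!dir.exists(path)) stop("cannot create directory ", path, call. = FALSE)
  tabs <- c(trials = "trials", metrics = "metrics",
            remap_calls = "remap_calls", remap = "remap_calls",
            correlations = "correlations", precession = "precession")
  summary <- list()
  for (nm in names(tabs)) {
    if (is.null(results[[nm]])) next
    df <- results[[nm]]
    write_tsv(df, file.path(path, paste0(tabs[[nm]], ".tsv")))
    summary[[paste0("n_", tabs[[nm]])]] <- nrow(df)
  }
  if (!is.null(results$metrics))
    summary$n_place_cell_conditions <-
      sum(results$metrics$is_place_cell, na.rm = TRUE)
  if (!is.null(results$seed)) summary$seed <- results$seed
  yaml::write_yaml(summary, file.path(path, "summary.yaml"))
  invisible(path)
}
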