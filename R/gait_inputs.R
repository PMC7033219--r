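# Gait loading inputs: storage-file I/O, EMG envelope processing, and the
# synthetic stance-phase generator that stands in for a measured walking
# trial (double-bump vertical load, early-stance flexion peak with a
# pre-toe-off rise, muscle envelopes consistent with the sagittal moment
# demand).

#' Time series container
#'
#' @param t Time stamps (s), strictly increasing.
#' @param v Values, same length as \code{t}.
#' @param label Name of the quantity.
#' @param units Unit string.
#' @return Object of class \code{time_series}.
#' @export
time_series <- function(t, v, label = "", units = "") {
  t <- as.numeric(t); v <- as.numeric(v)
  if (length(t) != length(v)) stop_knee("t and v must have equal length")
  if (any(!is.finite(t)) || any(!is.finite(v)))
    stop_knee("time series must be finite")
  if (length(t) > 1 && any(diff(t) <= 0))
    stop_knee("time must be strictly increasing")
  structure(list(t = t, v = v, label = label, units = units),
            class = "time_series")
}

#' @export
print.time_series <- function(x, ...) {
  cat(sprintf("<time_series %s [%s]: %d samples, t in [%g, %g]>\n",
              x$label, x$units, length(x$t), min(x$t), max(x$t)))
  invisible(x)
}

#' Read a motion/storage file
#'
#' Reads the tab-delimited storage dialect used by musculoskeletal tools
#' (a keyed header block terminated by an \code{endheader} line, then a
#' header row of column names and a numeric table whose first column is
#' time) or a plain TSV with a single header row. Repeated time stamps are
#' de-duplicated (first occurrence kept).
#'
#' @param path File path.
#' @param dialect "auto" (default), "header-keyed" or "plain-tsv".
#' @return Named list of \code{\link{time_series}}, one per non-time
#'   column, with the header metadata in attribute \code{header}.
#' @export
read_storage <- function(path, dialect = c("auto", "header-keyed", "plain-tsv")) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) stop_knee("file not found: %s", path)
  lines <- readLines(path, warn = FALSE)
  if (length(lines) < 2) stop_knee("storage file too short: %s", path)
  hdr_end <- grep("^\\s*endheader\\s*$", lines, ignore.case = TRUE)
  keyed <- length(hdr_end) > 0
  if (dialect == "header-keyed" && !keyed)
    stop_knee("parse error: no endheader line in %s", path)
  if (dialect == "plain-tsv") keyed <- FALSE
  meta <- list()
  start <- 1
  if (keyed) {
    for (ln in lines[seq_len(hdr_end[1] - 1)]) {
      kv <- strsplit(trimws(ln), "[=\t ]+")[[1]]
      if (length(kv) >= 2) meta[[kv[1]]] <- paste(kv[-1], collapse = " ")
    }
    start <- hdr_end[1] + 1
  }
  if (start > length(lines)) stop_knee("parse error: missing column header (line %d)", start)
  cols <- strsplit(lines[start], "\t")[[1]]
  cols <- trimws(cols)
  if (length(cols) < 2)
    stop_knee("parse error: header on line %d declares fewer than 2 columns", start)
  body <- lines[(start + 1):length(lines)]
  body <- body[nzchar(trimws(body))]
  rows <- strsplit(body, "\t")
  nc <- lengths(rows)
  bad <- which(nc != length(cols))
  if (length(bad) > 0)
    stop_knee("parse error: row %d has %d fields, header declares %d",
              bad[1], nc[bad[1]], length(cols))
  m <- matrix(as.numeric(unlist(rows)), ncol = length(cols), byrow = TRUE)
  if (any(!is.finite(m))) stop_knee("data error: non-numeric value in table")
  tcol <- m[, 1]
  keep <- !duplicated(tcol)
  m <- m[keep, , drop = FALSE]
  tcol <- m[, 1]
  if (length(tcol) > 1 && any(diff(tcol) <= 0))
    stop_knee("data error: time not strictly increasing after de-duplication")
  out <- lapply(2:length(cols), function(j)
    time_series(tcol, m[, j], label = cols[j]))
  names(out) <- cols[-1]
  attr(out, "header") <- meta
  attr(out, "time") <- tcol
  out
}

#' Write a motion/storage file
#'
#' Inverse of \code{\link{read_storage}}: writes a keyed header block (or
#' none for the plain-TSV dialect) followed by a tab-delimited table whose
#' first column is time. Values are written with full double precision so a
#' read/write round trip is lossless to 1e-12 relative.
#'
#' @param x Named list of \code{\link{time_series}} sharing one time grid.
#' @param path Output path.
#' @param dialect "header-keyed" (default) or "plain-tsv".
#' @param meta Named list of header key/value pairs.
#' @return \code{path}, invisibly.
#' @export
write_storage <- function(x, path, dialect = c("header-keyed", "plain-tsv"),
                          meta = list()) {
  dialect <- match.arg(dialect)
  t <- x[[1]]$t
  for (s in x) if (!isTRUE(all.equal(s$t, t, tolerance = 0)))
    stop_knee("all series must share the same time grid")
  con <- file(path, "w")
  on.exit(close(con))
  if (dialect == "header-keyed") {
    writeLines(sprintf("nRows=%d", length(t)), con)
    writeLines(sprintf("nColumns=%d", length(x) + 1), con)
    for (k in names(meta)) writeLines(sprintf("%s=%s", k, meta[[k]]), con)
    writeLines("endheader", con)
  }
  nms <- names(x)
  writeLines(paste(c("time", nms), collapse = "\t"), con)
  vals <- cbind(t, do.call(cbind, lapply(x, function(s) s$v)))
  apply_fmt <- function(r) paste(formatC(r, format = "g", digits = 17), collapse = "\t")
  writeLines(vapply(seq_len(nrow(vals)), function(i) apply_fmt(vals[i, ]), ""), con)
  invisible(path)
}

#' Raw EMG record
#'
#' @param fs Sampling rate (Hz, > 0).
#' @param raw Raw signal (length >= 2).
#' @param muscle Muscle name.
#' @return Object of class \code{emg_record}.
#' @export
emg_record <- function(fs, raw, muscle = "") {
  if (fs <= 0) stop_knee("fs must be > 0")
  if (length(raw) < 2) stop_knee("raw signal must have length >= 2")
  structure(list(fs = fs, raw = as.numeric(raw), muscle = muscle),
            class = "emg_record")
}

#' EMG linear envelope
#'
#' Standard gait-EMG processing: zero-phase band-pass, full-wave
#' rectification, zero-phase low-pass, then normalization to the trial
#' maximum (or a supplied maximum, e.g. from an MVC trial).
#'
#' @param rec An \code{\link{emg_record}}.
#' @param band Band-pass corner frequencies (Hz), inside (0, fs/2).
#' @param lp Low-pass cutoff (Hz), below the band's upper edge.
#' @param norm "trial-max" or "supplied-max".
#' @param max_value Normalization denominator for "supplied-max".
#' @param order Butterworth order per pass.
#' @return \code{\link{time_series}} with values in [0, 1].
#' @export
emg_envelope <- function(rec, band = c(20, 450), lp = 6,
                         norm = c("trial-max", "supplied-max"),
                         max_value = NULL, order = 2) {
  norm <- match.arg(norm)
  nyq <- rec$fs / 2
  if (band[1] <= 0 || band[2] >= nyq)
    stop_knee("configuration error: band (%g, %g) Hz outside (0, fs/2 = %g)",
              band[1], band[2], nyq)
  if (lp >= band[2]) stop_knee("configuration error: lp must be below the band's upper edge")
  x <- rec$raw
  bp <- signal::butter(order, band / nyq, type = "pass")
  x <- signal::filtfilt(bp, x)
  x <- abs(x)
  lpf <- signal::butter(order, lp / nyq, type = "low")
  env <- pmax(signal::filtfilt(lpf, x), 0)
  denom <- switch(norm,
                  "trial-max" = max(env),
                  "supplied-max" = {
                    if (is.null(max_value) || max_value <= 0)
                      stop_knee("supplied-max normalization needs max_value > 0")
                    max_value
                  })
  v <- if (denom > 0) env / denom else env
  time_series(seq_along(v) / rec$fs, clamp(v, 0, 1),
              label = rec$muscle, units = "normalized")
}

gauss_bump <- function(t, center, width) exp(-((t - center) / width)^2)

#' Synthetic stance-phase gait trial
#'
#' Generates loading inputs for one stance phase on a uniform 0-100% grid:
#' a knee flexion curve with an early-stance peak and a pre-toe-off rise, a
#' double-bump vertical residual force, frontal (adduction) and transverse
#' (rotation) knee moments, a sagittal flexion-extension moment demand, and
#' per-muscle normalized envelopes for the measured muscles that are
#' consistent with that demand (the unbounded static-optimization solution
#' plus optional noise).
#'
#' @param params Named list overriding any of: \code{n_grid} (101),
#'   \code{bodyweight_n} (765), \code{peak_flexion_deg} (22),
#'   \code{base_flexion_deg} (3), \code{peak_load_bw} (0.95),
#'   \code{extension_demand_nm} (40), \code{flexion_demand_nm} (30),
#'   \code{adduction_peak_nm} (18), \code{rotation_peak_nm} (5),
#'   \code{noise_sd} (0.02, envelope noise), \code{drive_mode}
#'   ("envelope" or "force"), \code{muscles}
#'   (\code{\link{default_muscles}}).
#' @param seed Integer seed; fixed seed gives a byte-identical trial.
#' @return A \code{gait_trial}: list with \code{stance_pct},
#'   \code{flexion_deg}, \code{flexion_moment_nm}, \code{muscle_drive}
#'   (matrix, NA columns for unmeasured muscles in envelope mode),
#'   \code{drive_mode}, \code{residual_force} (n x 3, N, tibia frame),
#'   \code{adduction_moment_nm}, \code{rotation_moment_nm},
#'   \code{bodyweight_n} and \code{muscles}.
#' @export
synth_gait <- function(params = list(), seed = 1) {
  p <- utils::modifyList(list(
    n_grid = 101, bodyweight_n = 765, peak_flexion_deg = 22,
    base_flexion_deg = 3, peak_load_bw = 0.95,
    extension_demand_nm = 40, flexion_demand_nm = 30,
    adduction_peak_nm = 12, rotation_peak_nm = 1.5,
    noise_sd = 0.02, drive_mode = "envelope",
    muscles = default_muscles()), params)
  if (p$bodyweight_n <= 0) stop_knee("configuration error: bodyweight must be > 0")
  if (p$peak_flexion_deg < 0 || p$peak_load_bw < 0)
    stop_knee("configuration error: amplitudes must be >= 0")
  t <- seq(0, 100, length.out = p$n_grid)
  # flexion: early-stance bump + pre-toe-off rise, scaled so the maximum
  # equals the requested peak exactly
  shape <- 0.85 * gauss_bump(t, 15, 10) + gauss_bump(t, 100, 20)
  flex <- p$base_flexion_deg +
    (p$peak_flexion_deg - p$base_flexion_deg) * shape / max(shape)
  # vertical residual load: two bumps with a midstance valley
  vshape <- 0.88 * gauss_bump(t, 25, 15) + gauss_bump(t, 72, 14) +
    0.25 * gauss_bump(t, 50, 30)
  fy <- -p$peak_load_bw * p$bodyweight_n * vshape / max(vshape)
  fx <- 0.10 * p$bodyweight_n * sin(2 * pi * t / 100) *
    gauss_bump(t, 50, 45)
  fz <- -0.03 * p$bodyweight_n * gauss_bump(t, 50, 40)
  m_flex <- -p$extension_demand_nm * gauss_bump(t, 18, 13) +
    p$flexion_demand_nm * gauss_bump(t, 75, 12)
  m_add <- p$adduction_peak_nm * (0.9 * gauss_bump(t, 25, 16) +
                                    gauss_bump(t, 72, 15))
  m_rot <- p$rotation_peak_nm * sin(pi * t / 100)
  mus <- p$muscles
  drive <- matrix(NA_real_, p$n_grid, nrow(mus),
                  dimnames = list(NULL, mus$name))
  with_seed(seed, {
    for (i in seq_len(p$n_grid)) {
      sol <- solve_activations_emg(m_flex[i], mus)
      drive[i, ] <- sol$a
    }
    if (p$noise_sd > 0)
      drive <- drive + matrix(stats::rnorm(length(drive), 0, p$noise_sd),
                              nrow(drive))
  })
  drive <- clamp(drive, 0, 1)
  if (p$drive_mode == "envelope") {
    drive[, !mus$measured] <- NA_real_
  } else {
    drive <- sweep(drive, 2, mus$f_max, "*")    # force magnitudes, N
  }
  gait_trial(stance_pct = t, flexion_deg = flex, flexion_moment_nm = m_flex,
             muscle_drive = drive, drive_mode = p$drive_mode,
             residual_force = cbind(fx, fy, fz),
             adduction_moment_nm = m_add, rotation_moment_nm = m_rot,
             bodyweight_n = p$bodyweight_n, muscles = mus)
}

#' Gait trial container
#'
#' Validates and assembles the time-indexed loading inputs for one stance
#' phase. All series share the \code{stance_pct} grid.
#'
#' @param stance_pct Stance grid (0-100, strictly increasing).
#' @param flexion_deg Knee flexion angle (deg).
#' @param flexion_moment_nm External flexion-extension moment demand (N m).
#' @param muscle_drive Matrix (frames x muscles): normalized envelopes in
#'   [0, 1] (mode "envelope", NA = no EMG) or force magnitudes in N (mode
#'   "force").
#' @param drive_mode "envelope" or "force".
#' @param residual_force n x 3 matrix (N, tibia frame).
#' @param adduction_moment_nm,rotation_moment_nm Frontal/transverse knee
#'   moments (N m).
#' @param bodyweight_n Bodyweight (N, > 0).
#' @param muscles Muscle definition data.frame.
#' @return Object of class \code{gait_trial}.
#' @export
gait_trial <- function(stance_pct, flexion_deg, flexion_moment_nm,
                       muscle_drive, drive_mode, residual_force,
                       adduction_moment_nm, rotation_moment_nm,
                       bodyweight_n, muscles) {
  n <- length(stance_pct)
  if (any(diff(stance_pct) <= 0)) stop_knee("stance grid must be strictly increasing")
  lens <- c(length(flexion_deg), length(flexion_moment_nm),
            nrow(muscle_drive), nrow(residual_force),
            length(adduction_moment_nm), length(rotation_moment_nm))
  if (any(lens != n)) stop_knee("all series must share the stance grid (length %d)", n)
  if (bodyweight_n <= 0) stop_knee("bodyweight must be > 0")
  if (drive_mode == "envelope") {
    vals <- muscle_drive[!is.na(muscle_drive)]
    if (any(vals < 0 | vals > 1)) stop_knee("EMG envelopes must be in [0, 1]")
  }
  structure(list(stance_pct = stance_pct, flexion_deg = flexion_deg,
                 flexion_moment_nm = flexion_moment_nm,
                 muscle_drive = muscle_drive, drive_mode = drive_mode,
                 residual_force = residual_force,
                 adduction_moment_nm = adduction_moment_nm,
                 rotation_moment_nm = rotation_moment_nm,
                 bodyweight_n = bodyweight_n, muscles = muscles),
            class = "gait_trial")
}

#' @export
print.gait_trial <- function(x, ...) {
  cat(sprintf(paste0("<gait_trial: %d frames, bodyweight %.0f N, ",
                     "flexion %.1f-%.1f deg, drive mode '%s' (%d muscles)>\n"),
              length(x$stance_pct), x$bodyweight_n, min(x$flexion_deg),
              max(x$flexion_deg), x$drive_mode, ncol(x$muscle_drive)))
  invisible(x)
}

#' @export
as.data.frame.gait_trial <- function(x, ...) {
  df <- data.frame(stance_pct = x$stance_pct, flexion_deg = x$flexion_deg,
                   flexion_moment_nm = x$flexion_moment_nm,
                   residual_fx_n = x$residual_force[, 1],
                   residual_fy_n = x$residual_force[, 2],
                   residual_fz_n = x$residual_force[, 3],
                   adduction_moment_nm = x$adduction_moment_nm,
                   rotation_moment_nm = x$rotation_moment_nm)
  drv <- as.data.frame(x$muscle_drive)
  names(drv) <- paste0("drive_", names(drv))
  cbind(df, drv)
}

#' Export a gait trial to CSV
#'
#' @param trial A \code{\link{gait_trial}}.
#' @param path Output path.
#' @return \code{path}, invisibly.
#' @export
write_gait_csv <- function(trial, path) {
  df <- as.data.frame(trial)
  attr(df, "bodyweight_n") <- trial$bodyweight_n
  utils::write.csv(cbind(df, bodyweight_n = trial$bodyweight_n,
                         drive_mode = trial$drive_mode),
                   path, row.names = FALSE)
  invisible(path)
}
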