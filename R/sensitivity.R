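# Ligament pre-strain sensitivity sweep: one stance run per pre-strain
# offset of one ligament, the other three held at their reference values;
# metrics extraction and tidy reporting.

#' Pre-strain sweep specification
#'
#' @param ligament One of "ACL", "PCL", "LCL", "MCL".
#' @param offsets_pct Percentage-point shifts of the reference pre-strain.
#' @param config Model configuration (see \code{\link{default_config}}).
#' @param trial A \code{\link{gait_trial}} (default: the synthetic
#'   benchmark trial at the configured seed).
#' @return Object of class \code{sweep_spec}.
#' @export
sweep_spec <- function(ligament, offsets_pct = c(-10, -5, 0, 5, 10),
                       config = default_config(), trial = NULL) {
  if (length(ligament) != 1 || !ligament %in% c("ACL", "PCL", "LCL", "MCL"))
    stop_knee("exactly one of ACL/PCL/LCL/MCL per sweep")
  if (any(!is.finite(offsets_pct))) stop_knee("offsets must be finite")
  if (is.null(trial))
    trial <- synth_gait(config$gait %||% list(), seed = config$seed %||% 1)
  structure(list(ligament = ligament, offsets_pct = offsets_pct,
                 config = config, trial = trial), class = "sweep_spec")
}

#' Run a ligament pre-strain sweep
#'
#' One full stance simulation per offset; only the pre-strain of the
#' ligament of interest is changed, the other three stay at their
#' reference values. Non-convergent runs are recorded with their status
#' and the sweep continues.
#'
#' @param spec A \code{\link{sweep_spec}}.
#' @param frames Optional frame subset passed to \code{\link{run_stance}}
#'   (scaled-down sweeps).
#' @param quiet Suppress progress output.
#' @return Object of class \code{metrics_table}: \code{$frames} has one
#'   row per (ligament, offset, frame); \code{$runs} one row per offset
#'   with peak metrics and run status.
#' @export
sweep_prestrain <- function(spec, frames = NULL, quiet = TRUE) {
  per_frame <- list()
  per_run <- list()
  for (off in spec$offsets_pct) {
    offsets <- c(ACL = 0, PCL = 0, LCL = 0, MCL = 0)
    offsets[spec$ligament] <- off
    model <- knee_model(spec$config, prestrain_offsets_pct = offsets)
    sol <- tryCatch(run_stance(spec$trial, model, frames = frames,
                               quiet = quiet),
                    kneestance_error = function(e) e)
    if (inherits(sol, "error")) {
      per_run[[length(per_run) + 1]] <-
        data.frame(ligament = spec$ligament, offset_pct = off,
                   status = conditionMessage(sol), peak_jcf_bw = NA,
                   peak_jcf_stance_pct = NA, ml_ratio_at_peak = NA,
                   peak_area_mm2 = NA, stringsAsFactors = FALSE)
      next
    }
    rows <- extract_metrics(sol)
    rows <- cbind(ligament = spec$ligament, offset_pct = off, rows)
    per_frame[[length(per_frame) + 1]] <- rows
    s <- summary(sol)
    per_run[[length(per_run) + 1]] <-
      data.frame(ligament = spec$ligament, offset_pct = off, status = "ok",
                 peak_jcf_bw = s$peak_jcf_bw,
                 peak_jcf_stance_pct = s$peak_jcf_stance_pct,
                 ml_ratio_at_peak = s$ml_ratio_at_peak,
                 peak_area_mm2 = s$peak_contact_area_mm2,
                 stringsAsFactors = FALSE)
  }
  structure(list(frames = do.call(rbind, per_frame),
                 runs = do.call(rbind, per_run)),
            class = "metrics_table")
}

#' Per-frame metric rows of a stance solution
#'
#' Per-frame joint and tissue metrics (the grouped tissue means are over
#' cartilage-to-cartilage contacting cells only; frames with no such
#' contact carry NA, not zero), ready for tidy reporting.
#'
#' @param sol A \code{\link{run_stance}} solution.
#' @return data.frame, one row per frame.
#' @export
extract_metrics <- function(sol) {
  cbind(sol$frames, as.data.frame(sol$ligaments))
}

#' Elementwise envelope across sweep runs
#'
#' Per-frame minimum and maximum of a metric over all runs of a metrics
#' table, for banded plots of sweep variation.
#'
#' @param table A \code{\link{sweep_prestrain}} result (or a row-bound
#'   combination of several).
#' @param metric Column name, e.g. "jcf_bw".
#' @return data.frame with stance_pct, min and max per frame.
#' @export
metrics_envelope <- function(table, metric = "jcf_bw") {
  f <- table$frames
  if (is.null(f) || !metric %in% names(f))
    stop_knee("metric %s not present", metric)
  sp <- sort(unique(f$stance_pct))
  data.frame(stance_pct = sp,
             min = vapply(sp, function(s) min(f[[metric]][f$stance_pct == s], na.rm = TRUE), 0),
             max = vapply(sp, function(s) max(f[[metric]][f$stance_pct == s], na.rm = TRUE), 0))
}

#' Combine metrics tables
#'
#' @param ... \code{metrics_table} objects (e.g. one per ligament).
#' @return A single \code{metrics_table}.
#' @export
combine_metrics <- function(...) {
  tabs <- list(...)
  structure(list(frames = do.call(rbind, lapply(tabs, `[[`, "frames")),
                 runs = do.call(rbind, lapply(tabs, `[[`, "runs"))),
            class = "metrics_table")
}

#' @export
print.metrics_table <- function(x, ...) {
  cat(sprintf("<metrics_table: %d runs, %d frame rows>\n",
              nrow(x$runs), if (is.null(x$frames)) 0L else nrow(x$frames)))
  if (nrow(x$runs) > 0) print(x$runs, row.names = FALSE)
  invisible(x)
}

#' Write sweep results to disk
#'
#' Writes a tidy CSV (one row per ligament/offset/frame), a JSON summary
#' of per-run peaks, and optionally per-metric plots.
#'
#' @param table A \code{\link{metrics_table}}.
#' @param outdir Output directory (created if missing).
#' @param plots If TRUE, write JCF/area PDF plots.
#' @return Named list of file paths, invisibly.
#' @export
report <- function(table, outdir, plots = FALSE) {
  if (!dir.exists(outdir)) dir.create(outdir, recursive = TRUE)
  csv <- file.path(outdir, "sweep_frames.csv")
  f <- table$frames
  if (is.null(f)) f <- data.frame(ligament = character(), offset_pct = numeric())
  utils::write.csv(f, csv, row.names = FALSE)
  jsn <- file.path(outdir, "sweep_summary.json")
  jsonlite::write_json(table$runs, jsn, auto_unbox = TRUE, digits = NA,
                       dataframe = "rows", na = "null")
  out <- list(csv = csv, json = jsn)
  if (plots && !is.null(table$frames) && nrow(table$frames) > 0) {
    pdf_path <- file.path(outdir, "sweep_jcf.pdf")
    grDevices::pdf(pdf_path, width = 7, height = 5)
    on.exit(grDevices::dev.off())
    env <- metrics_envelope(table, "jcf_bw")
    graphics::plot(env$stance_pct, env$max, type = "n",
                   xlab = "stance (%)", ylab = "JCF (BW)",
                   ylim = c(0, max(env$max) * 1.05))
    graphics::polygon(c(env$stance_pct, rev(env$stance_pct)),
                      c(env$min, rev(env$max)), col = "grey85", border = NA)
    base <- table$frames[table$frames$offset_pct == 0, ]
    if (nrow(base) > 0) {
      base <- base[base$ligament == base$ligament[1], ]
      graphics::lines(base$stance_pct, base$jcf_bw, lwd = 2)
    }
    out$pdf <- pdf_path
  }
  invisible(out)
}
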