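# Human-readable run report: deterministic text tables plus optional plots.

#' Summarize a completed pipeline run
#'
#' Reads the tables persisted by [run_pipeline()] in `run_dir` and writes a
#' deterministic plain-text report (`report.txt`) plus optional PNG figures
#' (MSD curves per condition, per-condition MSD at 66 ms). Sections whose
#' inputs are absent (e.g. no dose-response fit) are listed as absent.
#' Re-generating the report for an unchanged run reproduces the text
#' byte-for-byte.
#'
#' @param run_dir run directory of a completed pipeline run.
#' @param plots write PNG figures (default TRUE).
#' @return path of the report file, invisibly; the report text is also
#'   returned as the `text` attribute.
#' @export
pipeline_report <- function(run_dir, plots = TRUE) {
  need <- function(f) file.path(run_dir, f)
  lines <- c("Single-molecule imaging run report",
             paste0("run directory: ", basename(run_dir)), "")
  if (!file.exists(need("cells.csv"))) {
    lines <- c(lines, "cells.csv: ABSENT (run incomplete)")
  } else {
    cells <- read.csv(need("cells.csv"))
    lines <- c(lines, sprintf("cells: %d recorded, %d successful, %d excluded (no track over the minimum duration)",
                              nrow(cells), sum(cells$success),
                              sum(!cells$success)), "")
    ok <- cells[cells$success & is.finite(cells$msd_66ms), , drop = FALSE]
    if (nrow(ok)) {
      lines <- c(lines, "MSD at dt = 66 ms by condition (um^2, mean +/- SE over cells):")
      for (cond in sort(unique(ok$condition))) {
        v <- ok$msd_66ms[ok$condition == cond]
        lines <- c(lines, sprintf("  %-16s %.5f +/- %.5f  (n = %d)",
                                  cond, mean(v), sd(v) / sqrt(length(v)),
                                  length(v)))
      }
      lines <- c(lines, "")
    }
  }
  if (file.exists(need("fits.json"))) {
    fits <- jsonlite::read_json(need("fits.json"))
    if (!length(fits$dose)) fits["dose"] <- list(NULL)
    if (!length(fits$inhibition)) fits["inhibition"] <- list(NULL)
    if (!is.null(fits$dose)) {
      lines <- c(lines, "Dose-response fit:",
                 sprintf("  EC50 = %.4g nM, Hill h = %.3g, MSD %.4g -> %.4g um^2 (%s error model)",
                         fits$dose$ec50, fits$dose$h, fits$dose$msd_max,
                         fits$dose$msd_min, fits$dose$model), "")
    } else {
      lines <- c(lines, "Dose-response fit: absent", "")
    }
    if (!is.null(fits$inhibition)) {
      lines <- c(lines, "Inhibition fit:",
                 sprintf("  EC50 = %.4g nM, IC50 = %.4g nM, MSD %.4g -> %.4g um^2 (%s error model)",
                         fits$inhibition$ec50, fits$inhibition$ic50,
                         fits$inhibition$msd_max, fits$inhibition$msd_min,
                         fits$inhibition$model), "")
    } else {
      lines <- c(lines, "Inhibition fit: absent", "")
    }
  } else {
    lines <- c(lines, "fits.json: ABSENT")
  }
  if (file.exists(need("msd.csv"))) {
    m <- read.csv(need("msd.csv"))
    lines <- c(lines, sprintf("MSD curves: %d cells x up to %d lags (msd.csv)",
                              length(unique(m$cell)), max(m$lag)))
    if (plots) {
      grDevices::png(need("msd_curves.png"), width = 600, height = 450)
      on.exit(grDevices::dev.off(), add = TRUE)
      cells_u <- unique(m$cell)
      plot(NA, xlim = range(m$t), ylim = range(m$msd),
           xlab = "lag time (s)", ylab = "MSD (um^2)",
           main = "Per-cell MSD curves")
      for (cu in cells_u) {
        mm <- m[m$cell == cu, ]
        lines(mm$t, mm$msd, col = "#00000055")
      }
    }
  } else {
    lines <- c(lines, "MSD curves: absent")
  }
  path <- need("report.txt")
  writeLines(lines, path)
  out <- invisible(path)
  attr(out, "text") <- lines
  out
}
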