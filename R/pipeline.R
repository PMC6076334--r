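# Pipeline orchestration on files: per-movie tracking, per-cell statistics,
# condition-level fits, structured logs. Every stage is an exported function;
# the pipeline is their composition with persistence in a run directory.

#' Run the imaging-analysis pipeline on a set of movies
#'
#' For every movie in the manifest: detect and fit spots, link trajectories,
#' filter them, and compute per-cell statistics (MSD curve, step diffusion,
#' residence time). Cells are kept only if at least one trajectory lasts
#' longer than `min_track_s` seconds (the cell-success criterion). When the
#' manifest carries concentration columns (`L`, optionally `I`), the
#' dose-response (or inhibition) fit is run on the per-cell MSD at 66 ms.
#'
#' @param manifest data.frame (or CSV path) with columns `path` (TIFF
#'   movie), `cell` (id), `condition` (label), optional `L` and `I`
#'   (concentrations, nM); alternatively `stacks` may supply in-memory
#'   arrays.
#' @param out_dir run directory (created; intermediates persisted here).
#' @param config a [sim_config()] (pixel size, frame interval); written to
#'   the run directory as resolved configuration.
#' @param stacks optional named list of arrays keyed by `manifest$path`,
#'   bypassing file reads.
#' @param threshold,max_dist,sigma_bounds tracking thresholds (defaults
#'   0.25, 6 px, `c(1.5, 2.5)`).
#' @param min_track_s cell-success duration (s, default 1).
#' @param masks optional named list of cell masks keyed by `manifest$path`.
#' @param seed seed recorded and used for the statistical fits.
#' @return list (class `smi_run`): `status` (`"ok"` or `"failed"`),
#'   `failed_stage` (on failure), `cells` (per-cell summary), `msd`
#'   (per-cell curves), `fits` (condition-level fits), `log` (stage
#'   records), `out_dir`.
#' @export
run_pipeline <- function(manifest, out_dir, config = sim_config(),
                         stacks = NULL, threshold = 0.25, max_dist = 6,
                         sigma_bounds = c(1.5, 2.5), min_track_s = 1,
                         masks = NULL, seed = 1L) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  log_path <- file.path(out_dir, "log.jsonl")
  logs <- list()
  log_stage <- function(stage, ...) {
    rec <- c(list(stage = stage), list(...))
    logs[[length(logs) + 1L]] <<- rec
    cat(jsonlite::toJSON(rec, auto_unbox = TRUE), "\n",
        file = log_path, append = TRUE, sep = "")
  }
  fail <- function(stage, msg) {
    log_stage(stage, status = "failed", message = msg)
    structure(list(status = "failed", failed_stage = stage, message = msg,
                   log = logs, out_dir = out_dir), class = "smi_run")
  }

  if (is.character(manifest)) {
    if (!file.exists(manifest)) return(fail("manifest", "manifest not found"))
    manifest <- read.csv(manifest)
  }
  if (is.null(manifest) || nrow(manifest) == 0L)
    return(fail("manifest", "empty input: no movies listed"))
  write_config(config, file.path(out_dir, "config.txt"))
  write.csv(manifest, file.path(out_dir, "manifest.csv"), row.names = FALSE)
  log_stage("manifest", status = "ok", n_movies = nrow(manifest), seed = seed)

  px <- config$pixel_size; dt <- config$frame_interval
  min_frames <- ceiling(min_track_s / dt) + 1L
  cell_rows <- list(); msd_rows <- list(); all_traj <- list()
  for (i in seq_len(nrow(manifest))) {
    mv <- manifest[i, ]
    stack <- if (!is.null(stacks) && !is.null(stacks[[mv$path]]))
      stacks[[mv$path]]
    else if (file.exists(mv$path)) read_stack(mv$path)
    else return(fail("read", sprintf("movie not found: %s", mv$path)))

    tr <- tryCatch(track_movie(stack, threshold = threshold,
                               max_dist = max_dist),
                   error = function(e) NULL)
    if (is.null(tr)) return(fail("track", sprintf("tracking failed: %s", mv$path)))
    mask <- if (!is.null(masks)) masks[[mv$path]] else NULL
    fl <- filter_trajectories(tr$trajectories, mask = mask,
                              sigma_bounds = sigma_bounds)
    traj <- fl$kept
    log_stage("track", status = "ok", movie = mv$path,
              spots = nrow(tr$spots),
              tracks_kept = unname(fl$log["kept"]),
              tracks_removed = unname(fl$log["removed"]))

    lens <- if (nrow(traj)) table(traj$track) else integer(0)
    success <- any(lens >= min_frames)
    traj_um <- traj
    if (nrow(traj_um)) { traj_um$x <- traj_um$x * px; traj_um$y <- traj_um$y * px }
    disp <- step_displacements(traj_um, lag = 2L)
    msd66 <- if (nrow(disp)) mean(disp$dr2) else NA_real_
    sdres <- step_diffusion(traj_um, dt = dt)
    res <- if (nrow(traj_um)) residence_time(traj_um, dt)$mean else NA_real_
    row <- data.frame(cell = mv$cell, condition = mv$condition,
                      path = mv$path, n_tracks = length(lens),
                      success = success, msd_66ms = msd66,
                      D_step = sdres$mean, residence = res)
    if (!is.null(mv$L)) row$L <- mv$L
    if (!is.null(mv$I)) row$I <- mv$I
    cell_rows[[length(cell_rows) + 1L]] <- row
    if (success && nrow(traj_um)) {
      m <- msd(traj_um, dt = dt)
      msd_rows[[length(msd_rows) + 1L]] <- cbind(cell = mv$cell, m)
      traj_um$cell <- mv$cell
      all_traj[[length(all_traj) + 1L]] <- traj_um
    }
  }
  cells <- do.call(rbind, cell_rows)
  excluded <- sum(!cells$success)
  log_stage("cells", status = "ok", n_cells = nrow(cells),
            n_success = sum(cells$success), n_excluded = excluded)
  write.csv(cells, file.path(out_dir, "cells.csv"), row.names = FALSE)
  msd_tab <- if (length(msd_rows)) do.call(rbind, msd_rows) else NULL
  if (!is.null(msd_tab))
    write.csv(msd_tab, file.path(out_dir, "msd.csv"), row.names = FALSE)
  if (length(all_traj))
    write.csv(do.call(rbind, all_traj),
              file.path(out_dir, "trajectories.csv"), row.names = FALSE)

  ok <- cells[cells$success & is.finite(cells$msd_66ms), , drop = FALSE]
  fits <- list()
  fits$by_condition <- if (nrow(ok)) {
    aggregate(msd_66ms ~ condition, ok, function(v)
      c(mean = mean(v), se = sd(v) / sqrt(length(v)), n = length(v)))
  } else NULL
  if (!is.null(ok$L) && !is.null(ok$I) &&
      length(unique(ok$L)) >= 2L && length(unique(ok$I)) >= 2L) {
    fits$inhibition <- tryCatch(
      fit_inhibition(data.frame(L = ok$L, I = ok$I, msd = ok$msd_66ms),
                     seed = seed), error = function(e) NULL)
  } else if (!is.null(ok$L) && length(unique(ok$L)) >= 3L) {
    fits$dose <- tryCatch(
      fit_dose_response(data.frame(L = ok$L, msd = ok$msd_66ms), seed = seed),
      error = function(e) NULL)
  }
  log_stage("fits", status = "ok",
            dose = !is.null(fits$dose), inhibition = !is.null(fits$inhibition))
  fit_json <- list(
    by_condition = fits$by_condition,
    dose = if (!is.null(fits$dose))
      fits$dose[c("ec50", "h", "msd_max", "msd_min", "model")],
    inhibition = if (!is.null(fits$inhibition))
      fits$inhibition[c("ec50", "ic50", "msd_max", "msd_min", "model")])
  jsonlite::write_json(fit_json, file.path(out_dir, "fits.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       dataframe = "columns")
  structure(list(status = "ok", cells = cells, msd = msd_tab, fits = fits,
                 log = logs, out_dir = out_dir, seed = seed),
            class = "smi_run")
}

#' @export
print.smi_run <- function(x, ...) {
  if (x$status != "ok") {
    cat(sprintf("<smi_run> FAILED at stage '%s': %s\n", x$failed_stage, x$message))
  } else {
    cat(sprintf("<smi_run> ok: %d cells (%d successful) in %s\n",
                nrow(x$cells), sum(x$cells$success), x$out_dir))
  }
  invisible(x)
}
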