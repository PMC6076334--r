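# Time-course binning: recompute the per-interval estimators (state
# fractions, mean intensity, cluster fractions, residence time) in fixed
# time bins, flagging pre-stimulus bins as baseline.

#' Per-bin time course of single-molecule statistics
#'
#' Splits trajectories into `bin_width`-second bins by their start time and
#' recomputes the requested estimators per bin. Bins that end at or before
#' `stim_time` are flagged as baseline (pre-stimulus). Empty bins are
#' omitted and listed in the `omitted` attribute.
#'
#' @param traj trajectory data.frame `track, frame, x, y` (um) with either a
#'   `time` column (s) or times derived as `frame * dt`; an `intensity`
#'   column enables the intensity/cluster estimators.
#' @param bin_width bin width in seconds (default 40).
#' @param dt frame interval (s).
#' @param stim_time stimulation time (s); bins entirely before it are
#'   baseline. `NULL` disables the flag.
#' @param what estimators to compute: subset of `"states"`, `"intensity"`,
#'   `"clusters"`, `"residence"`, `"msd"`.
#' @param n_states state count for the mixture (fixed across bins so the
#'   fractions are comparable; default 3).
#' @param n_max_cluster maximum oligomer size.
#' @param seed RNG seed for the mixture restarts.
#' @return data.frame with one row per bin: `bin, t_start, t_end, baseline,
#'   n_tracks` plus the requested estimator columns (`frac_1..`, `D_1..`,
#'   `mean_intensity`, `monomer/dimer/oligomer` fractions, `residence`,
#'   `msd_66ms`). Attribute `omitted` lists empty bins.
#' @export
timecourse <- function(traj, bin_width = 40, dt = 0.033, stim_time = NULL,
                       what = c("states", "intensity", "residence"),
                       n_states = 3L, n_max_cluster = 10L, seed = 1L) {
  what <- match.arg(what, c("states", "intensity", "clusters", "residence",
                            "msd"), several.ok = TRUE)
  if (is.null(traj$time)) traj$time <- traj$frame * dt
  starts <- tapply(traj$time, traj$track, min)
  bin_of_track <- floor(starts / bin_width)
  traj$bin <- bin_of_track[as.character(traj$track)]
  bins <- sort(unique(traj$bin))

  rows <- list(); omitted <- integer(0)
  for (b in bins) {
    sub <- traj[traj$bin == b, , drop = FALSE]
    if (nrow(sub) == 0L) { omitted <- c(omitted, b); next }
    row <- data.frame(bin = b, t_start = b * bin_width,
                      t_end = (b + 1) * bin_width,
                      baseline = if (is.null(stim_time)) NA else
                        (b + 1) * bin_width <= stim_time,
                      n_tracks = length(unique(sub$track)))
    if ("states" %in% what) {
      disp <- step_displacements(sub, lag = 2L)
      if (nrow(disp) >= 10L * n_states) {
        sm <- suppressWarnings(fit_state_mixture(sqrt(disp$dr2), n_states,
                                                 dt = 2 * dt, seed = seed))
        for (i in seq_len(n_states)) {
          row[[paste0("frac_", i)]] <- if (i <= sm$n_states) sm$fractions[i] else NA
          row[[paste0("D_", i)]] <- if (i <= sm$n_states) sm$D[i] else NA
        }
      } else {
        for (i in seq_len(n_states)) {
          row[[paste0("frac_", i)]] <- NA; row[[paste0("D_", i)]] <- NA
        }
      }
    }
    if ("intensity" %in% what && !is.null(sub$intensity)) {
      first <- sub[!duplicated(sub$track), , drop = FALSE]
      row$mean_intensity <- mean(first$intensity)
    }
    if ("clusters" %in% what && !is.null(sub$intensity)) {
      first <- sub[!duplicated(sub$track), , drop = FALSE]
      cm <- suppressWarnings(fit_cluster_sizes(first$intensity,
                                               n_max = n_max_cluster,
                                               seed = seed))
      row$monomer <- cm$fractions[1, 1]
      row$dimer <- cm$fractions[1, 2]
      row$oligomer <- sum(cm$fractions[1, -(1:2)])
      row$mean_size <- cm$mean_size[1]
    }
    if ("residence" %in% what) row$residence <- residence_time(sub, dt)$mean
    if ("msd" %in% what) {
      disp <- step_displacements(sub, lag = 2L)
      row$msd_66ms <- if (nrow(disp)) mean(disp$dr2) else NA_real_
    }
    rows[[length(rows) + 1L]] <- row
  }
  out <- do.call(rbind, rows)
  attr(out, "omitted") <- omitted
  out
}

#' Welch test between two per-cell distributions
#'
#' Two-sided Welch t-test used to flag significant shifts of per-cell
#' summaries (e.g. MSD at 66 ms before vs after stimulation); differences
#' with `p < alpha` are flagged.
#'
#' @param before,after numeric per-cell values.
#' @param alpha significance flag threshold (default 0.005).
#' @return list `p`, `significant`, `mean_before`, `mean_after`.
#' @export
compare_cells <- function(before, after, alpha = 0.005) {
  tt <- t.test(before, after)
  list(p = tt$p.value, significant = tt$p.value < alpha,
       mean_before = mean(before), mean_after = mean(after))
}
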