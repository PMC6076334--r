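# Displacement-based mobility estimators: step diffusion coefficients,
# pooled MSD curves, residence times.

#' Two-frame step displacements of trajectories
#'
#' Overlapping displacements over `lag` frames for every track, in the
#' spatial units of the input coordinates.
#'
#' @param traj data.frame `track, frame, x, y` (consecutive frames within a
#'   track).
#' @param lag frame lag (default 2, i.e. 66 ms at 33 ms/frame).
#' @return data.frame `track, frame, dr2` (squared displacement).
#' @export
step_displacements <- function(traj, lag = 2L) {
  out <- lapply(split(traj, traj$track), function(t_) {
    t_ <- t_[order(t_$frame), , drop = FALSE]
    n <- nrow(t_)
    if (n <= lag) return(NULL)
    i <- seq_len(n - lag)
    data.frame(track = t_$track[i], frame = t_$frame[i],
               dr2 = (t_$x[i + lag] - t_$x[i])^2 + (t_$y[i + lag] - t_$y[i])^2)
  })
  out <- do.call(rbind, out[!vapply(out, is.null, TRUE)])
  if (is.null(out)) data.frame(track = integer(0), frame = integer(0),
                               dr2 = numeric(0)) else { rownames(out) <- NULL; out }
}

#' Per-molecule step diffusion coefficients
#'
#' `D = dr^2 / (4 T)` from the mean squared step displacement of each track
#' over `T = lag * dt` (default 66 ms). Tracks shorter than `lag + 1` frames
#' are excluded.
#'
#' @param traj trajectory data.frame with positions in um.
#' @param dt frame interval (s, default 0.033).
#' @param lag frame lag (default 2).
#' @return list `molecules` (data.frame `track, D, n_steps`), `mean`, `sd`,
#'   `se`, `n` over molecules.
#' @export
step_diffusion <- function(traj, dt = 0.033, lag = 2L) {
  disp <- step_displacements(traj, lag = lag)
  if (nrow(disp) == 0L)
    return(list(molecules = data.frame(track = integer(0), D = numeric(0),
                                       n_steps = integer(0)),
                mean = NA_real_, sd = NA_real_, se = NA_real_, n = 0L))
  Tlag <- lag * dt
  agg <- aggregate(dr2 ~ track, disp, function(v) c(mean(v), length(v)))
  mol <- data.frame(track = agg$track, D = agg$dr2[, 1] / (4 * Tlag),
                    n_steps = as.integer(agg$dr2[, 2]))
  list(molecules = mol, mean = mean(mol$D), sd = sd(mol$D),
       se = sd(mol$D) / sqrt(nrow(mol)), n = nrow(mol))
}

#' Pooled mean square displacement curve
#'
#' For each lag `n = 1..max_lag`, the average of
#' `[x(m+n) - x(m)]^2 + [y(m+n) - y(m)]^2` over all tracks and all
#' (overlapping) start frames `m`; every displacement counts once.
#'
#' @param traj trajectory data.frame (positions in um).
#' @param dt frame interval (s).
#' @param max_lag largest lag in frames (default 15).
#' @return data.frame `lag, t, msd, n` (`n` = number of displacements; lags
#'   with none are omitted).
#' @export
msd <- function(traj, dt = 0.033, max_lag = 15L) {
  traj <- traj[order(traj$track, traj$frame), , drop = FALSE]
  tracks <- split(traj[, c("x", "y", "frame")], traj$track)
  sums <- numeric(max_lag); counts <- integer(max_lag)
  for (t_ in tracks) {
    n <- nrow(t_)
    if (n < 2L) next
    for (lg in seq_len(min(max_lag, n - 1L))) {
      i <- seq_len(n - lg)
      d2 <- (t_$x[i + lg] - t_$x[i])^2 + (t_$y[i + lg] - t_$y[i])^2
      sums[lg] <- sums[lg] + sum(d2)
      counts[lg] <- counts[lg] + length(d2)
    }
  }
  keep <- counts > 0L
  data.frame(lag = seq_len(max_lag)[keep], t = (seq_len(max_lag) * dt)[keep],
             msd = sums[keep] / counts[keep], n = counts[keep])
}

#' Per-cell MSD curves
#'
#' @param traj trajectory data.frame with a `cell` column.
#' @inheritParams msd
#' @return data.frame `cell, lag, t, msd, n`.
#' @export
msd_by_cell <- function(traj, dt = 0.033, max_lag = 15L) {
  out <- lapply(split(traj, traj$cell), function(t_) {
    m <- msd(t_, dt = dt, max_lag = max_lag)
    if (nrow(m)) cbind(cell = t_$cell[1], m) else NULL
  })
  out <- do.call(rbind, out[!vapply(out, is.null, TRUE)])
  rownames(out) <- NULL
  out
}

#' Mean residence time of trajectories
#'
#' Average track duration `(length - 1) * dt`, e.g. the membrane residence
#' time of a recruited adaptor protein before dissociation or bleaching.
#'
#' @param traj trajectory data.frame.
#' @param dt frame interval (s).
#' @return list `mean`, `se`, `n` (tracks).
#' @export
residence_time <- function(traj, dt = 0.033) {
  len <- table(traj$track)
  dur <- (as.numeric(len) - 1) * dt
  list(mean = mean(dur),
       se = if (length(dur) > 1L) sd(dur) / sqrt(length(dur)) else NA_real_,
       n = length(dur))
}
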