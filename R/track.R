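# Frame-to-frame linking, trajectory assembly and trajectory filtering.

#' Link spots between two consecutive frames
#'
#' All candidate pairs with center-to-center distance below `max_dist` px
#' are listed; links are then chosen one-to-one. The default `"greedy"`
#' method accepts pairs in ascending distance (ties broken by previous-spot
#' then current-spot order), the shortest connection first; `"optimal"`
#' exhaustively searches the maximum-cardinality matching of minimum total
#' distance (reference method, exponential in the frame size -- use it only
#' on small frames or as an oracle).
#'
#' @param prev,cur data.frames with columns `x, y` (sub-pixel positions) for
#'   frames t-1 and t.
#' @param max_dist linking radius in px (default 6; pairs at exactly
#'   `max_dist` or beyond are not linked).
#' @param method `"greedy"` or `"optimal"`.
#' @return list `links` (data.frame `prev, cur, dist` of row indices),
#'   `unmatched_prev` (trajectory ends), `unmatched_cur` (new trajectories).
#' @export
link_frames <- function(prev, cur, max_dist = 6, method = c("greedy", "optimal")) {
  method <- match.arg(method)
  np <- nrow(prev); nc <- nrow(cur)
  empty <- data.frame(prev = integer(0), cur = integer(0), dist = numeric(0))
  if (np == 0L || nc == 0L)
    return(list(links = empty, unmatched_prev = seq_len(np),
                unmatched_cur = seq_len(nc)))
  d <- sqrt(outer(prev$x, cur$x, "-")^2 + outer(prev$y, cur$y, "-")^2)
  cand <- which(d < max_dist, arr.ind = TRUE)
  if (nrow(cand) == 0L)
    return(list(links = empty, unmatched_prev = seq_len(np),
                unmatched_cur = seq_len(nc)))
  cand <- data.frame(prev = cand[, 1], cur = cand[, 2],
                     dist = d[cand])
  links <- if (method == "greedy") greedy_match(cand) else optimal_match(cand)
  list(links = links,
       unmatched_prev = setdiff(seq_len(np), links$prev),
       unmatched_cur = setdiff(seq_len(nc), links$cur))
}

greedy_match <- function(cand) {
  cand <- cand[order(cand$dist, cand$prev, cand$cur), , drop = FALSE]
  used_p <- logical(max(cand$prev)); used_c <- logical(max(cand$cur))
  keep <- logical(nrow(cand))
  for (i in seq_len(nrow(cand))) {
    p <- cand$prev[i]; c_ <- cand$cur[i]
    if (!used_p[p] && !used_c[c_]) {
      keep[i] <- TRUE; used_p[p] <- TRUE; used_c[c_] <- TRUE
    }
  }
  out <- cand[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}

# Exhaustive maximum-cardinality minimum-total-distance matching.
optimal_match <- function(cand) {
  best <- list(n = -1L, total = Inf, rows = integer(0))
  nr <- nrow(cand)
  recurse <- function(i, used_p, used_c, rows, total) {
    if (i > nr) {
      n <- length(rows)
      if (n > best$n || (n == best$n && total < best$total))
        best <<- list(n = n, total = total, rows = rows)
      return(invisible())
    }
    p <- cand$prev[i]; c_ <- cand$cur[i]
    if (!(p %in% used_p) && !(c_ %in% used_c))
      recurse(i + 1L, c(used_p, p), c(used_c, c_), c(rows, i),
              total + cand$dist[i])
    recurse(i + 1L, used_p, used_c, rows, total)
  }
  recurse(1L, integer(0), integer(0), integer(0), 0)
  out <- cand[best$rows, , drop = FALSE]
  out <- out[order(out$prev), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Build trajectories from per-frame spot tables
#'
#' Links consecutive frames with [link_frames()]; unmatched current spots
#' start new trajectories and unmatched previous spots terminate theirs.
#' There is no gap closing: a missed frame ends the track.
#'
#' @param spots data.frame with columns `frame` (0-based, consecutive
#'   integers), `x`, `y` and any further per-spot columns (e.g. `I0`,
#'   `sigmaA`), typically assembled from [detect_frame()] results.
#' @param max_dist linking radius (px).
#' @param method linking method, see [link_frames()].
#' @return the input spots with a `track` id column, ordered by
#'   `(track, frame)`.
#' @export
build_trajectories <- function(spots, max_dist = 6, method = "greedy") {
  if (nrow(spots) == 0L) return(cbind(spots, track = integer(0)))
  spots$track <- NA_integer_
  frames <- sort(unique(spots$frame))
  next_id <- 1L
  prev_idx <- which(spots$frame == frames[1])
  spots$track[prev_idx] <- seq_along(prev_idx)
  next_id <- length(prev_idx) + 1L
  for (fi in seq_along(frames)[-1]) {
    if (frames[fi] != frames[fi - 1L] + 1L) {
      # non-consecutive recording: everything restarts
      cur_idx <- which(spots$frame == frames[fi])
      spots$track[cur_idx] <- seq.int(next_id, length.out = length(cur_idx))
      next_id <- next_id + length(cur_idx)
      prev_idx <- cur_idx
      next
    }
    cur_idx <- which(spots$frame == frames[fi])
    lk <- link_frames(spots[prev_idx, , drop = FALSE],
                      spots[cur_idx, , drop = FALSE],
                      max_dist = max_dist, method = method)
    if (nrow(lk$links))
      spots$track[cur_idx[lk$links$cur]] <- spots$track[prev_idx[lk$links$prev]]
    for (u in lk$unmatched_cur) {
      spots$track[cur_idx[u]] <- next_id
      next_id <- next_id + 1L
    }
    prev_idx <- cur_idx
  }
  spots[order(spots$track, spots$frame), , drop = FALSE]
}

#' Filter trajectories by cell mask and spot size
#'
#' Removes trajectories with any spot outside the cell mask, or whose mean
#' fitted width lies outside `sigma_bounds` (per-spot instead of
#' per-trajectory mean behind `per_spot = TRUE`).
#'
#' @param traj trajectory data.frame (`track, frame, x, y, sigmaA, ...`).
#' @param mask optional 0/1 cell mask aligned to the movie; a spot at
#'   position `(x, y)` is inside the cell if the nearest pixel is 1.
#' @param sigma_bounds allowed fitted-width interval in px (default
#'   `c(1.5, 2.5)`).
#' @param per_spot apply the width bounds to every spot instead of the
#'   per-trajectory mean.
#' @return list `kept` (filtered data.frame), `removed` (data.frame
#'   `track, reason`), `log` (named counts).
#' @export
filter_trajectories <- function(traj, mask = NULL,
                                sigma_bounds = c(1.5, 2.5),
                                per_spot = FALSE) {
  ids <- unique(traj$track)
  reasons <- character(0); removed_ids <- integer(0)
  for (id in ids) {
    t_ <- traj[traj$track == id, , drop = FALSE]
    reason <- NULL
    if (!is.null(mask)) {
      r <- round(t_$y) + 1L; c_ <- round(t_$x) + 1L
      inside <- r >= 1L & r <= nrow(mask) & c_ >= 1L & c_ <= ncol(mask)
      inside[inside] <- mask[cbind(r[inside], c_[inside])] > 0
      if (!all(inside)) reason <- "outside_cell"
    }
    if (is.null(reason) && !is.null(t_$sigmaA)) {
      bad <- if (per_spot)
        any(t_$sigmaA < sigma_bounds[1] | t_$sigmaA > sigma_bounds[2])
      else {
        m <- mean(t_$sigmaA)
        m < sigma_bounds[1] || m > sigma_bounds[2]
      }
      if (bad) reason <- "spot_size"
    }
    if (!is.null(reason)) {
      removed_ids <- c(removed_ids, id)
      reasons <- c(reasons, reason)
    }
  }
  kept <- traj[!(traj$track %in% removed_ids), , drop = FALSE]
  list(kept = kept,
       removed = data.frame(track = removed_ids, reason = reasons),
       log = c(kept = length(ids) - length(removed_ids),
               removed = length(removed_ids)))
}

#' Track a movie end to end
#'
#' Detection, sub-pixel fitting and linking over all frames of a stack.
#'
#' @param stack array `[H, W, n_frames]`.
#' @param template,threshold,half detection settings (see [detect_frame()]).
#' @param max_dist,method linking settings (see [build_trajectories()]).
#' @return list `spots` (all fitted spots with `frame`), `trajectories`
#'   (spots with `track` ids), `dropped` (summed drop counts).
#' @export
track_movie <- function(stack, template = gaussian_template(),
                        threshold = 0.25, half = 5L, max_dist = 6,
                        method = "greedy") {
  n_frames <- dim(stack)[3]
  all_spots <- list()
  dropped <- c(border = 0L, failed = 0L)
  for (f in seq_len(n_frames)) {
    det <- detect_frame(stack[, , f], template, threshold, half)
    dropped <- dropped + det$dropped
    if (nrow(det$spots)) {
      det$spots$frame <- f - 1L
      all_spots[[length(all_spots) + 1L]] <- det$spots
    }
  }
  spots <- if (length(all_spots)) do.call(rbind, all_spots) else
    data.frame(I0 = numeric(0), x = numeric(0), y = numeric(0),
               sigmaA = numeric(0), a = numeric(0), b = numeric(0),
               Iback = numeric(0), converged = logical(0), rss = numeric(0),
               frame = integer(0))
  traj <- build_trajectories(spots, max_dist = max_dist, method = method)
  list(spots = spots, trajectories = traj, dropped = dropped)
}
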