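# Trajectory simulator: 2-D Brownian motion with a static mixture of
# diffusion states and optional confinement in a reflecting square.

#' Simulate 2-D single-molecule trajectories
#'
#' Draws `n_tracks` random walks at the configured frame interval. Each track
#' is assigned one diffusive state from `states` (a static mixture: the state
#' does not change along a track unless `switch_prob > 0`). Per frame each
#' coordinate moves by a normal step of variance `2 D dt`, i.e. squared
#' displacement expectation `4 D dt` for the x/y pair. With `confinement` set,
#' positions are reflected at the walls of a square of side `confinement`
#' (um) centred on the track's starting position.
#'
#' @param n_tracks number of trajectories.
#' @param n_frames frames per trajectory.
#' @param states data.frame with columns `D` (um^2/s, >= 0) and `fraction`
#'   (summing to 1 within 1e-9).
#' @param confinement side of the reflecting square (um), or `NULL` for free
#'   diffusion.
#' @param config a [sim_config()].
#' @param switch_prob per-frame probability of redrawing the state from the
#'   mixture (Markov switching extension; default 0 = static assignment).
#' @param seed RNG seed; defaults to `config$rng_seed`.
#' @return list with
#'   \item{tracks}{data.frame `track, frame, x, y, state` (positions in um;
#'     `frame` is 0-based)}
#'   \item{truth}{list: `per_track` (track, state, D, n), `states`,
#'     `confinement`}
#' @examples
#' sim <- simulate_trajectories(5, 20, data.frame(D = 0.1, fraction = 1))
#' head(sim$tracks)
#' @export
simulate_trajectories <- function(n_tracks, n_frames,
                                  states = data.frame(D = 0.1, fraction = 1),
                                  confinement = NULL,
                                  config = sim_config(),
                                  switch_prob = 0,
                                  seed = config$rng_seed) {
  stopifnot(is.data.frame(states), all(c("D", "fraction") %in% names(states)))
  if (abs(sum(states$fraction) - 1) > 1e-9)
    stopf("state fractions must sum to 1 (got %.12f)", sum(states$fraction))
  if (any(states$D < 0)) stopf("diffusion coefficients must be >= 0")
  if (!is.null(confinement) && confinement <= 0) stopf("confinement side must be > 0")
  if (!is.null(seed)) set.seed(seed)

  field_um <- config$field_size * config$pixel_size
  dt <- config$frame_interval
  state_of <- sample.int(nrow(states), n_tracks, replace = TRUE,
                         prob = states$fraction)
  n_steps <- n_frames - 1L

  tracks <- vector("list", n_tracks)
  for (i in seq_len(n_tracks)) {
    st <- integer(n_frames)
    st[1] <- state_of[i]
    if (switch_prob > 0 && n_frames > 1L) {
      for (f in 2:n_frames) {
        st[f] <- if (runif(1) < switch_prob)
          sample.int(nrow(states), 1L, prob = states$fraction) else st[f - 1L]
      }
    } else st[] <- st[1]

    if (is.null(confinement)) {
      x0 <- runif(1, 0, field_um[2])
      y0 <- runif(1, 0, field_um[1])
    } else {
      # box placed in the field; start uniform inside it (stationary
      # occupancy, so the ensemble MSD plateaus at C^2/3)
      bx <- runif(1, 0, max(field_um[2] - confinement, 0))
      by <- runif(1, 0, max(field_um[1] - confinement, 0))
      x0 <- bx + runif(1, 0, confinement)
      y0 <- by + runif(1, 0, confinement)
    }
    if (n_steps > 0L) {
      sds <- sqrt(2 * states$D[st[-1L]] * dt)
      dx <- rnorm(n_steps, 0, sds)
      dy <- rnorm(n_steps, 0, sds)
      x <- x0 + cumsum(c(0, dx))
      y <- y0 + cumsum(c(0, dy))
    } else {
      x <- x0; y <- y0
    }
    if (!is.null(confinement)) {
      x <- reflect_fold(x - bx, confinement) + bx
      y <- reflect_fold(y - by, confinement) + by
    }
    tracks[[i]] <- data.frame(track = i, frame = seq_len(n_frames) - 1L,
                              x = x, y = y, state = st)
  }
  tracks <- do.call(rbind, tracks)
  truth <- list(
    per_track = data.frame(track = seq_len(n_tracks), state = state_of,
                           D = states$D[state_of]),
    states = states,
    confinement = confinement
  )
  list(tracks = tracks, truth = truth)
}

# Fold coordinates into [0, L] by reflection at the walls.
reflect_fold <- function(p, L) {
  m <- p %% (2 * L)
  ifelse(m > L, 2 * L - m, m)
}
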