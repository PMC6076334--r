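# Movie renderer: emitters as symmetric Gaussians on a planar background,
# optional shot + read noise, with exported per-spot ground truth.

#' Render a fluorescence movie from trajectories
#'
#' Each emitter is drawn as a symmetric 2-D Gaussian of width
#' `config$psf_sigma` whose peak amplitude is drawn once per track from a
#' normal with mean `n * monomer_mean` and variance `n * monomer_sd^2`, where
#' `n` is the track's oligomer size. A planar background
#' `a (x - cx) + b (y - cy) + offset` is added, then camera noise according to
#' `config$noise_model`. Emitters whose center leaves the field are clipped
#' from the image (with a warning) but kept in the ground truth.
#'
#' @param tracks trajectory data.frame from [simulate_trajectories()]
#'   (positions in um).
#' @param oligomer_sizes integer vector, one size (>= 1) per track id; a
#'   single value is recycled.
#' @param config a [sim_config()].
#' @param noise apply the configured camera noise (set `FALSE` for noiseless
#'   renders).
#' @param seed RNG seed (intensities + noise); defaults to `config$rng_seed`.
#' @param truth_csv optional path: write the per-spot ground truth table
#'   alongside the movie.
#' @return list with
#'   \item{stack}{array `[H, W, n_frames]` (a.u.)}
#'   \item{truth}{data.frame `track, frame, x_px, y_px, n, intensity` (true
#'     sub-pixel positions in pixels, drawn peak amplitude)}
#' @export
render_movie <- function(tracks, oligomer_sizes = 1L, config = sim_config(),
                         noise = TRUE, seed = config$rng_seed,
                         truth_csv = NULL) {
  if (!is.null(seed)) set.seed(seed)
  ids <- sort(unique(tracks$track))
  if (length(oligomer_sizes) == 1L) oligomer_sizes <- rep(oligomer_sizes, length(ids))
  if (length(oligomer_sizes) != length(ids))
    stopf("oligomer_sizes must have one entry per track (%d tracks)", length(ids))
  if (any(oligomer_sizes < 1)) stopf("oligomer sizes must be >= 1")

  H <- config$field_size[1]; W <- config$field_size[2]
  px <- config$pixel_size
  n_frames <- max(tracks$frame) + 1L

  # one amplitude per track: N(n mu, n sigma^2), truncated at a small positive
  amp <- rnorm(length(ids),
               mean = oligomer_sizes * config$monomer_mean,
               sd = sqrt(oligomer_sizes) * config$monomer_sd)
  amp <- pmax(amp, 1e-3)
  names(amp) <- as.character(ids)
  size_of <- setNames(oligomer_sizes, as.character(ids))

  # planar background over the pixel grid (0-based centers)
  xs <- matrix(rep(0:(W - 1L), each = H), H, W)
  ys <- matrix(rep(0:(H - 1L), W), H, W)
  bg <- config$background_offset +
    config$background_slope[1] * (xs - (W - 1) / 2) +
    config$background_slope[2] * (ys - (H - 1) / 2)

  stack <- array(0, c(H, W, n_frames))
  sig <- config$psf_sigma
  r <- ceiling(4 * sig)
  clipped <- 0L

  xpx <- tracks$x / px
  ypx <- tracks$y / px
  for (k in seq_len(nrow(tracks))) {
    f <- tracks$frame[k] + 1L
    xg <- xpx[k]; yg <- ypx[k]
    if (xg < 0 || xg > W - 1 || yg < 0 || yg > H - 1) { clipped <- clipped + 1L; next }
    a <- amp[[as.character(tracks$track[k])]]
    c0 <- max(0L, floor(xg) - r); c1 <- min(W - 1L, ceiling(xg) + r)
    r0 <- max(0L, floor(yg) - r); r1 <- min(H - 1L, ceiling(yg) + r)
    cc <- c0:c1; rr <- r0:r1
    gx <- exp(-(cc - xg)^2 / (2 * sig^2))
    gy <- exp(-(rr - yg)^2 / (2 * sig^2))
    stack[rr + 1L, cc + 1L, f] <- stack[rr + 1L, cc + 1L, f] + a * outer(gy, gx)
  }
  if (clipped > 0L)
    warning(sprintf("%d emitter positions outside the field were clipped", clipped))

  for (f in seq_len(n_frames)) {
    img <- stack[, , f] + bg
    if (noise && config$noise_model == "poisson-gaussian") {
      img <- rpois(length(img), pmax(img, 0)) +
        rnorm(length(img), 0, config$read_noise_sd)
    } else if (noise && config$noise_model == "gaussian") {
      img <- img + rnorm(length(img), 0, config$read_noise_sd)
    }
    stack[, , f] <- img
  }

  truth <- data.frame(
    track = tracks$track, frame = tracks$frame,
    x_px = xpx, y_px = ypx,
    n = as.integer(size_of[as.character(tracks$track)]),
    intensity = as.numeric(amp[as.character(tracks$track)])
  )
  if (!is.null(truth_csv)) write.csv(truth, truth_csv, row.names = FALSE)
  list(stack = stack, truth = truth)
}

#' Simulate a single-molecule field at a given spot density
#'
#' Convenience wrapper used by the cell-search module: stationary monomeric
#' emitters at `density` spots/um^2 rendered into one frame.
#'
#' @param density spots per um^2.
#' @param size image side in pixels.
#' @param config a [sim_config()].
#' @param seed RNG seed.
#' @param defocus optional extra blur sigma (px) emulating a slightly
#'   out-of-focus snapshot.
#' @return list `image` (matrix), `n_spots`, `density`.
#' @export
simulate_density_scene <- function(density, size = 128L, config = sim_config(),
                                   seed = config$rng_seed, defocus = 0) {
  if (!is.null(seed)) set.seed(seed)
  cfg <- config
  cfg$field_size <- c(size, size)
  area_um2 <- (size * cfg$pixel_size)^2
  n <- rpois(1, density * area_um2)
  if (n == 0L) {
    tr <- NULL
  } else {
    tr <- data.frame(track = seq_len(n), frame = 0L,
                     x = runif(n, 0, (size - 1L) * cfg$pixel_size),
                     y = runif(n, 0, (size - 1L) * cfg$pixel_size),
                     state = 1L)
  }
  img <- if (is.null(tr)) {
    base <- matrix(cfg$background_offset, size, size)
    matrix(rpois(size^2, base) + rnorm(size^2, 0, cfg$read_noise_sd), size, size)
  } else {
    render_movie(tr, 1L, cfg, noise = TRUE, seed = NULL)$stack[, , 1]
  }
  if (defocus > 0) img <- gaussian_blur(img, defocus)
  list(image = img, n_spots = n, density = density)
}
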