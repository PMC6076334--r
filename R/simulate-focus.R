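# Simulated bright-field iris scenes for autofocusing: a circular dark/bright
# edge whose blur grows with distance from the true focal plane.

#' Render one synthetic iris image at a given defocus
#'
#' The iris is a bright disk on a dark background; the edge is blurred with a
#' Gaussian of width `blur0 + blur_rate * |z - true_focus|` (px), emulating a
#' monotone defocus blur, then Gaussian camera noise is added.
#'
#' @param z stage position (um).
#' @param true_focus in-focus stage position (um).
#' @param size image side (px).
#' @param blur0 residual in-focus blur (px).
#' @param blur_rate blur growth (px per um of defocus).
#' @param inside,outside intensities of the disk and surround (a.u.).
#' @param noise_sd Gaussian noise SD (a.u.), 0 for noiseless.
#' @param seed seed; noise is a deterministic function of `(seed, z)` so a
#'   stage revisiting a position reproduces the identical image.
#' @return intensity matrix `[size, size]`.
#' @export
render_iris <- function(z, true_focus, size = 128L, blur0 = 0.5,
                        blur_rate = 0.4, inside = 3000, outside = 600,
                        noise_sd = 30, seed = 1L) {
  radius <- 0.42 * size
  ctr <- (size + 1) / 2
  d <- sqrt(outer((seq_len(size) - ctr)^2, (seq_len(size) - ctr)^2, "+"))
  img <- matrix(outside, size, size)
  # half-pixel anti-aliased step edge
  t_ <- pmin(pmax((radius - d) / 1.0 + 0.5, 0), 1)
  img <- outside + (inside - outside) * t_
  sigma <- blur0 + blur_rate * abs(z - true_focus)
  img <- gaussian_blur(img, sigma)
  if (noise_sd > 0) {
    set.seed((as.integer(seed) * 7919L + as.integer(round(z * 1000)) %% 100000L) %% 2147483600L)
    img <- img + matrix(rnorm(size^2, 0, noise_sd), size, size)
  }
  img
}

#' Simulated focus stage
#'
#' Returns a closure `f(z)` producing the iris image at stage position `z`;
#' the autofocus routines drive this closure exactly as they would a physical
#' Z axis.
#'
#' @inheritParams render_iris
#' @param ... further arguments passed to [render_iris()].
#' @return function of one argument `z` returning an image matrix.
#' @export
focus_stage <- function(true_focus, size = 128L, noise_sd = 30, seed = 1L, ...) {
  force(true_focus); force(size); force(noise_sd); force(seed)
  dots <- list(...)
  function(z) {
    do.call(render_iris, c(list(z = z, true_focus = true_focus, size = size,
                                noise_sd = noise_sd, seed = seed), dots))
  }
}

#' Simulate a labelled focus stack
#'
#' Renders `round((z_range[2]-z_range[1])/z_step)` iris images starting at
#' `z_range[1]`. Images within `label_halfwidth` um of the true focus carry
#' label 1 (in focus), all others 0 -- the training convention for the coarse
#' autofocus classifier.
#'
#' @param z_range `c(from, to)` stage range (um).
#' @param z_step step (um), > 0.
#' @param true_focus in-focus position (um).
#' @param size image side (px).
#' @param noise_sd Gaussian noise SD.
#' @param label_halfwidth half-width of the in-focus labelling slab (um,
#'   default 4).
#' @param seed RNG seed.
#' @param ... passed to [render_iris()].
#' @return list with `z` (positions), `images` (list of matrices), `labels`
#'   (0/1 integer vector), `true_focus`.
#' @export
simulate_focus_stack <- function(z_range, z_step, true_focus, size = 32L,
                                 noise_sd = 30, label_halfwidth = 4,
                                 seed = 1L, ...) {
  if (z_step <= 0) stopf("z_step must be > 0")
  n <- round((z_range[2] - z_range[1]) / z_step)
  z <- z_range[1] + (seq_len(n) - 1L) * z_step
  images <- lapply(z, render_iris, true_focus = true_focus, size = size,
                   noise_sd = noise_sd, seed = seed, ...)
  labels <- as.integer(abs(z - true_focus) <= label_halfwidth)
  list(z = z, images = images, labels = labels, true_focus = true_focus)
}
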