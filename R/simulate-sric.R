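# Synthetic surface-reflection interference contrast (SRIC) scenes: textured
# elliptical cell footprints on a structured background, with a pixel-exact
# ground-truth mask for segmentation training.

#' Simulate an SRIC cell scene with ground-truth mask
#'
#' Cells are non-overlapping ellipses with random centers, axes and
#' orientation; their interior carries an interference-like texture distinct
#' from the smoothly varying background. The returned mask is the exact
#' rasterization of the ellipses.
#'
#' @param n_cells number of cells (>= 0).
#' @param size image side (px).
#' @param axis_range semi-axis range (px).
#' @param contrast mean intensity offset of cell interiors over background
#'   (a.u.).
#' @param noise_sd pixel noise SD (a.u.).
#' @param seed RNG seed.
#' @param max_tries rejection-sampling budget for non-overlapping placement.
#' @return list with
#'   \item{image}{intensity matrix}
#'   \item{mask}{0/1 matrix, 1 inside cells}
#'   \item{cells}{data.frame `cx, cy, a, b, theta, area_px` (0-based centers;
#'     `area_px` is the rasterized pixel count of each ellipse)}
#' @export
simulate_sric_scene <- function(n_cells, size = 128L, axis_range = NULL,
                                contrast = 600, noise_sd = 40, seed = 1L,
                                max_tries = 200L) {
  if (n_cells < 0) stopf("n_cells must be >= 0")
  if (is.null(axis_range)) axis_range <- c(size / 12, size / 6)
  if (!is.null(seed)) set.seed(seed)
  H <- W <- as.integer(size)
  xs <- matrix(rep(0:(W - 1L), each = H), H, W)
  ys <- matrix(rep(0:(H - 1L), W), H, W)

  background <- 1200 + 90 * smooth_noise(H, W, size / 6) +
    50 * sin(2 * pi * xs / (size / 2.5))

  mask <- matrix(0L, H, W)
  cells <- data.frame(cx = numeric(0), cy = numeric(0), a = numeric(0),
                      b = numeric(0), theta = numeric(0), area_px = integer(0))
  tries <- 0L
  while (nrow(cells) < n_cells && tries < max_tries * max(n_cells, 1L)) {
    tries <- tries + 1L
    a <- runif(1, axis_range[1], axis_range[2])
    b <- runif(1, axis_range[1], axis_range[2])
    cx <- runif(1, max(a, b), W - 1 - max(a, b))
    cy <- runif(1, max(a, b), H - 1 - max(a, b))
    # enforce non-overlap via center distance (keeps mask area additive)
    if (nrow(cells) > 0) {
      dmin <- min(sqrt((cells$cx - cx)^2 + (cells$cy - cy)^2) -
                    (pmax(cells$a, cells$b) + max(a, b)))
      if (dmin < 2) next
    }
    th <- runif(1, 0, pi)
    u <- (xs - cx) * cos(th) + (ys - cy) * sin(th)
    v <- -(xs - cx) * sin(th) + (ys - cy) * cos(th)
    inside <- (u / a)^2 + (v / b)^2 <= 1
    mask[inside] <- 1L
    cells <- rbind(cells, data.frame(cx = cx, cy = cy, a = a, b = b,
                                     theta = th, area_px = sum(inside)))
  }
  if (nrow(cells) < n_cells)
    warning(sprintf("placed %d of %d requested cells", nrow(cells), n_cells))

  texture <- contrast + 60 * smooth_noise(H, W, 3) +
    40 * sin(2 * pi * (xs + ys) / 9)
  img <- background + mask * texture
  if (noise_sd > 0) img <- img + matrix(rnorm(H * W, 0, noise_sd), H, W)
  list(image = img, mask = mask, cells = cells)
}
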