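# Spot detection: normalized cross-correlation against a Gaussian template,
# thresholding + labelling, and sub-pixel Gaussian-plus-plane fitting.

#' Gaussian detection template
#'
#' `I[i, j] = exp(-(i^2 + j^2) / (2 sigma^2)) / (sqrt(2 pi) sigma)` on the
#' square support `i, j in [-half, half]`; symmetric with its maximum at the
#' center. Defaults cover a diffraction-limited spot (sigma 2 px, 11 x 11
#' support).
#'
#' @param sigma template width (px).
#' @param half half-width of the support (px); the ROI side is
#'   `2 * half + 1`.
#' @return `(2 half + 1)^2` matrix.
#' @export
gaussian_template <- function(sigma = 2, half = 5L) {
  g <- seq(-half, half)
  m <- exp(-outer(g^2, g^2, "+") / (2 * sigma^2)) / (sqrt(2 * pi) * sigma)
  m
}

#' Pearson-normalized cross-correlation map
#'
#' At every pixel where the template window fits inside the image, the
#' Pearson correlation between the window and the template is computed
#' (two-pass: window means first, then centered products), giving values in
#' \[-1, 1\]. Border pixels are `NA`; windows with zero variance give 0.
#'
#' @param image numeric matrix, strictly larger than the template.
#' @param template square template matrix of odd side (default
#'   [gaussian_template()]).
#' @return correlation matrix of `dim(image)`.
#' @export
correlation_map <- function(image, template = gaussian_template()) {
  th <- nrow(template)
  if (th != ncol(template) || th %% 2L == 0L) stopf("template must be square with odd side")
  if (nrow(image) <= th || ncol(image) <= th) stopf("image must be larger than the template")
  half <- (th - 1L) %/% 2L
  H <- nrow(image); W <- ncol(image)
  Ho <- H - th + 1L; Wo <- W - th + 1L
  tc <- template - mean(template)
  tden <- sqrt(sum(tc^2))

  # pass 1: window means
  s1 <- matrix(0, Ho, Wo)
  for (di in 0:(th - 1L)) for (dj in 0:(th - 1L))
    s1 <- s1 + image[(1L + di):(Ho + di), (1L + dj):(Wo + dj)]
  xave <- s1 / (th * th)

  # pass 2: centered cross products and window variance
  num <- matrix(0, Ho, Wo)
  ss <- matrix(0, Ho, Wo)
  for (di in 0:(th - 1L)) for (dj in 0:(th - 1L)) {
    xc <- image[(1L + di):(Ho + di), (1L + dj):(Wo + dj)] - xave
    num <- num + tc[di + 1L, dj + 1L] * xc
    ss <- ss + xc * xc
  }
  den <- tden * sqrt(ss)
  val <- ifelse(den > 0, num / den, 0)

  out <- matrix(NA_real_, H, W)
  out[(half + 1L):(H - half), (half + 1L):(W - half)] <- val
  out
}

#' Detect spot candidates in a correlation map
#'
#' Binarizes the map at `threshold`, labels connected components and returns
#' one candidate per component with its binary centroid. Raising the
#' threshold towards 1 rejects dim spots; lowering it towards 0 admits noise.
#'
#' @param corr_map correlation map from [correlation_map()].
#' @param threshold correlation cutoff (default 0.25).
#' @param min_px minimum component size in pixels (default 4): a true
#'   diffraction-limited spot exceeds the threshold over tens of contiguous
#'   pixels, while shot-noise exceedances are nearly always 1-3 px.
#' @return data.frame `label, x, y, n_px, peak` (0-based centroid
#'   coordinates, component size, maximal correlation); zero rows if nothing
#'   exceeds the threshold.
#' @export
detect_spots <- function(corr_map, threshold = 0.25, min_px = 4L) {
  bin <- !is.na(corr_map) & corr_map >= threshold
  if (!any(bin))
    return(data.frame(label = integer(0), x = numeric(0), y = numeric(0),
                      n_px = integer(0), peak = numeric(0)))
  labels <- EBImage::bwlabel(bin)
  tab <- component_table(labels)
  tab <- tab[tab$area >= min_px, , drop = FALSE]
  peak <- vapply(tab$label, function(l) max(corr_map[labels == l], na.rm = TRUE), 0)
  data.frame(label = tab$label, x = tab$cx, y = tab$cy, n_px = tab$area,
             peak = peak, row.names = NULL)
}

#' Sub-pixel spot fit: symmetric Gaussian plus inclined plane
#'
#' Least-squares (Levenberg--Marquardt) fit of
#' `I0 exp(-((x-xg)^2 + (y-yg)^2) / (2 sigmaA^2)) + a (x-xg) + b (y-yg) +
#' Iback` to the `(2 half + 1)^2` ROI around a candidate centroid. Candidates
#' closer than `half` px to the image border are not fitted (the ROI would
#' clip) and return `NULL`.
#'
#' @param image intensity matrix.
#' @param centroid numeric `c(x, y)` 0-based candidate position.
#' @param half ROI half-width (default 5).
#' @param psf_sigma starting value for `sigmaA`.
#' @return one-row data.frame `I0, x, y, sigmaA, a, b, Iback, converged,
#'   rss`, or `NULL` when the ROI clips the border or the fit fails.
#' @export
fit_spot <- function(image, centroid, half = 5L, psf_sigma = 2) {
  cx <- round(centroid[1]); cy <- round(centroid[2])
  H <- nrow(image); W <- ncol(image)
  if (cx - half < 0 || cx + half > W - 1L || cy - half < 0 || cy + half > H - 1L)
    return(NULL)
  xs <- (cx - half):(cx + half)
  ys <- (cy - half):(cy + half)
  roi <- image[ys + 1L, xs + 1L]
  grid <- expand.grid(x = xs, y = ys)
  z <- as.numeric(t(roi))          # row-major: y fixed per block
  df <- data.frame(x = grid$x, y = grid$y, z = z)
  iback0 <- median(z)
  resid_fn <- function(p) {
    z - (p[1] * exp(-((df$x - p[2])^2 + (df$y - p[3])^2) / (2 * p[4]^2)) +
           p[5] * (df$x - p[2]) + p[6] * (df$y - p[3]) + p[7])
  }
  p0 <- c(max(z) - iback0, centroid[1], centroid[2], psf_sigma, 0, 0, iback0)
  fit <- tryCatch(
    minpack.lm::nls.lm(p0, fn = resid_fn,
                       lower = c(-Inf, min(xs), min(ys), 0.2, -Inf, -Inf, -Inf),
                       upper = c(Inf, max(xs), max(ys), 3 * (half + 1),
                                 Inf, Inf, Inf),
                       control = minpack.lm::nls.lm.control(maxiter = 200)),
    error = function(e) NULL)
  if (is.null(fit) || !(fit$info %in% 1:4)) return(NULL)
  p <- fit$par
  data.frame(I0 = p[1], x = p[2], y = p[3], sigmaA = abs(p[4]),
             a = p[5], b = p[6], Iback = p[7],
             converged = TRUE, rss = fit$deviance)
}

#' Detect and fit all spots in one frame
#'
#' Correlation map, thresholding and sub-pixel fitting in one call; border
#' candidates and failed fits are dropped and counted.
#'
#' @param frame intensity matrix.
#' @param template detection template.
#' @param threshold correlation cutoff (default 0.25).
#' @param half fit ROI half-width.
#' @return list `spots` (data.frame as [fit_spot()] plus `frame = NA` column
#'   to be filled by the caller) and `dropped` (named counts).
#' @export
detect_frame <- function(frame, template = gaussian_template(),
                         threshold = 0.25, half = 5L) {
  cm <- correlation_map(frame, template)
  cand <- detect_spots(cm, threshold)
  fits <- list(); n_border <- 0L; n_failed <- 0L
  for (i in seq_len(nrow(cand))) {
    f <- fit_spot(frame, c(cand$x[i], cand$y[i]), half = half)
    if (is.null(f)) {
      onb <- cand$x[i] < half || cand$y[i] < half ||
        cand$x[i] > ncol(frame) - 1L - half || cand$y[i] > nrow(frame) - 1L - half
      if (onb) n_border <- n_border + 1L else n_failed <- n_failed + 1L
      next
    }
    fits[[length(fits) + 1L]] <- f
  }
  spots <- if (length(fits)) do.call(rbind, fits) else
    data.frame(I0 = numeric(0), x = numeric(0), y = numeric(0),
               sigmaA = numeric(0), a = numeric(0), b = numeric(0),
               Iback = numeric(0), converged = logical(0), rss = numeric(0))
  list(spots = spots, dropped = c(border = n_border, failed = n_failed))
}
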