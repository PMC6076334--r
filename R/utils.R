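# Shared low-level helpers: image i/o, Gaussian blur, histogram utilities.

#' Write an image stack as a multi-page TIFF
#'
#' Pixel values are rescaled by `scale` into the [0, 1] range expected by the
#' TIFF writer and stored as 16-bit; `scale` is the intensity (a.u.) mapped to
#' the maximum sample value. Use the same `scale` in [read_stack()] to recover
#' the original arbitrary units.
#'
#' @param stack numeric array `[H, W, n_frames]` (or a matrix for one frame).
#' @param path output file path.
#' @param scale intensity corresponding to full scale (default 65535 so that
#'   integer a.u. round-trip exactly through the 16-bit file).
#' @return `path`, invisibly.
#' @export
write_stack <- function(stack, path, scale = 65535) {
  if (is.matrix(stack)) stack <- array(stack, c(dim(stack), 1L))
  frames <- lapply(seq_len(dim(stack)[3]), function(k) {
    m <- stack[, , k] / scale
    m[m < 0] <- 0
    m[m > 1] <- 1
    m
  })
  tiff::writeTIFF(frames, path, bits.per.sample = 16L)
  invisible(path)
}

#' Read a multi-page TIFF into an image stack
#'
#' @param path TIFF file path.
#' @param scale intensity corresponding to full scale (see [write_stack()]).
#' @return numeric array `[H, W, n_frames]`.
#' @export
read_stack <- function(path, scale = 65535) {
  frames <- tiff::readTIFF(path, all = TRUE)
  if (is.matrix(frames)) frames <- list(frames)
  H <- nrow(frames[[1]]); W <- ncol(frames[[1]])
  out <- array(0, c(H, W, length(frames)))
  for (k in seq_along(frames)) {
    f <- frames[[k]]
    if (length(dim(f)) == 3L) f <- f[, , 1]  # grey stored with channels
    out[, , k] <- f * scale
  }
  out
}

# Separable Gaussian blur with replicated edges. Kernel support +/- 3 sigma,
# sigma capped at a quarter of the smaller image side (heavier defocus is
# visually indistinguishable and keeps the kernel bounded).
gaussian_blur <- function(img, sigma) {
  if (sigma <= 0) return(img)
  sigma <- min(sigma, min(dim(img)) / 4)
  r <- max(1L, ceiling(3 * sigma))
  k <- dnorm(seq(-r, r), sd = sigma)
  k <- k / sum(k)
  blur_1d <- function(m) {
    n <- nrow(m)
    idx <- function(i) pmin(pmax(i, 1L), n)
    out <- matrix(0, n, ncol(m))
    for (o in seq(-r, r)) out <- out + k[o + r + 1L] * m[idx(seq_len(n) + o), , drop = FALSE]
    out
  }
  t(blur_1d(t(blur_1d(img))))
}

# Smooth spatial noise field: white noise blurred to correlation length `scale`.
smooth_noise <- function(H, W, scale, amplitude = 1) {
  base <- matrix(rnorm(H * W), H, W)
  f <- gaussian_blur(base, scale)
  amplitude * f / max(sd(f), 1e-12)
}

# Moving average with windows shrunk at the ends so every point keeps a value.
moving_average <- function(x, width) {
  n <- length(x)
  if (width <= 1L || n == 0L) return(x)
  half <- width %/% 2L
  cs <- cumsum(c(0, x))
  lo <- pmax(seq_len(n) - half, 1L)
  hi <- pmin(seq_len(n) + (width - half - 1L), n)
  (cs[hi + 1L] - cs[lo]) / (hi - lo + 1L)
}

# Split a weighted histogram (counts over ordered bin centers) at the bin
# boundary maximizing between-class variance; returns the index of the last
# bin in the lower class. Exhaustive over all candidate splits.
otsu_split_index <- function(counts, mids) {
  stopifnot(length(counts) == length(mids), length(counts) >= 2L)
  w <- counts / sum(counts)
  mu <- cumsum(w * mids)
  om <- cumsum(w)
  mu_t <- mu[length(mu)]
  cand <- seq_len(length(counts) - 1L)
  om_c <- om[cand]
  bc <- (mu_t * om_c - mu[cand])^2 / (om_c * (1 - om_c))
  bc[!is.finite(bc)] <- -Inf
  cand[which.max(bc)]
}

stopf <- function(...) stop(sprintf(...), call. = FALSE)
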