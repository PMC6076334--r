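# Dual-color channel registration: least-squares similarity (translation +
# rotation + isotropic scaling) or full affine transform fitted on fiducial
# pairs, e.g. gold-particle positions imaged in both channels.

#' Fit the channel-2 to channel-1 coordinate transform
#'
#' `"similarity"` (default: translation, rotation, scaling; the closed-form
#' complex least-squares solution) or `"affine"` (6-parameter linear least
#' squares). Requires at least 3 fiducial pairs, non-collinear for the
#' affine model.
#'
#' @param ch1,ch2 data.frames with columns `x, y`: matched fiducial
#'   positions in the reference channel (1) and the channel to be mapped (2).
#' @param type `"similarity"` or `"affine"`.
#' @return object of class `channel_transform`: list `A` (2x2), `t`
#'   (length-2 translation), `scale`, `rotation` (radians, similarity only),
#'   `residual_rms`, `type`.
#' @export
fit_channel_transform <- function(ch1, ch2, type = c("similarity", "affine")) {
  type <- match.arg(type)
  n <- nrow(ch1)
  if (n < 3L || nrow(ch2) != n) stopf("need >= 3 matched fiducial pairs")
  if (type == "affine") {
    X <- cbind(ch2$x, ch2$y, 1)
    if (qr(X)$rank < 3L) stopf("fiducials are collinear; affine transform is degenerate")
    bx <- qr.solve(X, ch1$x)
    by <- qr.solve(X, ch1$y)
    A <- rbind(bx[1:2], by[1:2])
    tvec <- c(bx[3], by[3])
    scale <- sqrt(abs(det(A)))
    rot <- atan2(A[2, 1], A[1, 1])
  } else {
    z2 <- complex(real = ch2$x, imaginary = ch2$y)
    z1 <- complex(real = ch1$x, imaginary = ch1$y)
    m2 <- mean(z2); m1 <- mean(z1)
    zc2 <- z2 - m2; zc1 <- z1 - m1
    denom <- sum(Mod(zc2)^2)
    if (denom < 1e-12) stopf("fiducials are coincident")
    a <- sum(Conj(zc2) * zc1) / denom
    tvec_c <- m1 - a * m2
    A <- matrix(c(Re(a), Im(a), -Im(a), Re(a)), 2, 2)
    tvec <- c(Re(tvec_c), Im(tvec_c))
    scale <- Mod(a)
    rot <- Arg(a)
  }
  pred <- cbind(ch2$x, ch2$y) %*% t(A) + matrix(tvec, n, 2, byrow = TRUE)
  res <- sqrt(mean((pred[, 1] - ch1$x)^2 + (pred[, 2] - ch1$y)^2))
  structure(list(A = A, t = tvec, scale = scale, rotation = rot,
                 residual_rms = res, type = type),
            class = "channel_transform")
}

#' Apply a channel transform to positions
#'
#' @param transform a [fit_channel_transform()] result.
#' @param positions data.frame with columns `x, y` (channel-2 coordinates).
#' @param inverse map channel 1 back to channel 2.
#' @return data.frame with transformed `x, y` (other columns preserved).
#' @export
apply_channel_transform <- function(transform, positions, inverse = FALSE) {
  A <- transform$A; tv <- transform$t
  p <- cbind(positions$x, positions$y)
  q <- if (inverse) t(solve(A) %*% (t(p) - tv)) else
    p %*% t(A) + matrix(tv, nrow(p), 2, byrow = TRUE)
  out <- positions
  out$x <- q[, 1]; out$y <- q[, 2]
  out
}

#' @export
print.channel_transform <- function(x, ...) {
  cat(sprintf("<channel_transform> %s: scale %.6f, rotation %.4f rad, shift (%.3f, %.3f), residual RMS %.4g px\n",
              x$type, x$scale, x$rotation, x$t[1], x$t[2], x$residual_rms))
  invisible(x)
}
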