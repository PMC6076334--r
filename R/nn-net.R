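# Encoder-decoder network: three stride-2 convolution stages, then three
# 2x-upsample + convolution stages, ReLU hidden activations and a sigmoid
# output. Shared by the coarse autofocus classifier and the cell-search /
# cell-region segmentation.

#' Create an encoder--decoder segmentation network
#'
#' The architecture is three convolution stages (3x3, stride 2, ReLU) that
#' halve the resolution, mirrored by three deconvolution stages (2x
#' nearest-neighbour upsampling followed by a 3x3 convolution) that restore
#' it, ending in a sigmoid so every output pixel is a probability in (0, 1).
#' Output shape equals input shape; inputs must have sides divisible by 8.
#'
#' @param channels encoder channel widths for the three stages (the decoder
#'   mirrors them).
#' @param in_channels input image channels (1 for greyscale).
#' @param strides per-stage encoder strides (1 or 2); the decoder mirrors
#'   them in reverse, upsampling where the encoder downsampled. The default
#'   `c(2, 2, 2)` gives a stride-8 bottleneck; segmentation tasks needing
#'   sharper boundaries can use `c(2, 2, 1)`.
#' @param seed seed for the random (He) weight initialization; `NULL` leaves
#'   the RNG untouched.
#' @param init_scale multiply the initialization SD (0 gives an all-zero
#'   network whose output is identically 0.5).
#' @return object of class `encdec_net`.
#' @examples
#' net <- nn_new(seed = 1)
#' p <- nn_forward(net, matrix(0, 32, 32))
#' range(p)   # strictly inside (0, 1)
#' @export
nn_new <- function(channels = c(8L, 16L, 32L), in_channels = 1L,
                   strides = c(2L, 2L, 2L), seed = NULL, init_scale = 1) {
  stopifnot(length(channels) == 3L, length(strides) == 3L,
            all(strides %in% 1:2))
  if (!is.null(seed)) set.seed(seed)
  cin <- c(in_channels, channels[1:2])            # encoder inputs
  dec_in <- c(channels[3], channels[2], channels[1])
  dec_out <- c(channels[2], channels[1], in_channels)
  dec_strides <- rev(strides)
  mk <- function(ci, co) {
    sd <- init_scale * sqrt(2 / (9 * ci))
    list(W = array(rnorm(9 * ci * co, 0, max(sd, 0)), c(3, 3, ci, co)),
         b = numeric(co))
  }
  layers <- c(
    lapply(1:3, function(i) c(mk(cin[i], channels[i]), type = "down",
                              stride = strides[i])),
    lapply(1:3, function(i) c(mk(dec_in[i], dec_out[i]), type = "up",
                              stride = dec_strides[i]))
  )
  structure(list(layers = layers, channels = channels,
                 in_channels = in_channels, strides = strides,
                 trained = FALSE),
            class = "encdec_net")
}

as_input_array <- function(image, in_channels, down = 8L) {
  if (is.matrix(image)) image <- array(image, c(dim(image), 1L))
  d <- dim(image)
  if (d[3] != in_channels) stopf("expected %d input channel(s), got %d", in_channels, d[3])
  if (d[1] %% down != 0L || d[2] %% down != 0L)
    stopf("image sides must be divisible by %d (got %dx%d)", down, d[1], d[2])
  image
}

# Forward pass; with cache = TRUE keeps layer inputs/pre-activations for
# backprop.
nn_forward_full <- function(net, image, cache = FALSE) {
  strides <- if (is.null(net$strides)) c(2L, 2L, 2L) else net$strides
  x <- as_input_array(image, net$in_channels, down = prod(strides))
  n <- length(net$layers)
  caches <- if (cache) vector("list", n) else NULL
  for (i in seq_len(n)) {
    ly <- net$layers[[i]]
    if (ly$type == "down") {
      z <- conv_fwd(x, ly$W, ly$b, stride = ly$stride)
      a <- relu_fwd(z)
      if (cache) caches[[i]] <- list(x = x, z = z)
    } else {
      u <- if (ly$stride == 2L) up2_fwd(x) else x
      z <- conv_fwd(u, ly$W, ly$b, stride = 1L)
      a <- if (i == n) sigmoid_fwd(z) else relu_fwd(z)
      if (cache) caches[[i]] <- list(x = x, u = u, z = z)
    }
    x <- a
  }
  list(out = x, caches = caches)
}

#' Run the network on an image
#'
#' @param net an [nn_new()] network.
#' @param image numeric matrix (or `[H, W, C]` array) with sides divisible
#'   by 8. Inputs are used as-is; callers normalize intensities (the training
#'   helpers divide by the image maximum).
#' @return probability map, a matrix of values in (0, 1) with the input shape.
#' @export
nn_forward <- function(net, image) {
  out <- nn_forward_full(net, image, cache = FALSE)$out
  if (dim(out)[3] == 1L) out <- out[, , 1] else out
  out
}

# Backward pass: dL/d(output) -> gradients per layer (same shapes as weights).
nn_backward <- function(net, fwd, dout) {
  n <- length(net$layers)
  grads <- vector("list", n)
  dx <- dout
  for (i in rev(seq_len(n))) {
    ly <- net$layers[[i]]
    cc <- fwd$caches[[i]]
    if (ly$type == "down") {
      dz <- relu_bwd(cc$z, dx)
      g <- conv_bwd(cc$x, ly$W, dz, stride = ly$stride)
      grads[[i]] <- list(dW = g$dW, db = g$db)
      dx <- g$dx
    } else {
      dz <- if (i == n) dx else relu_bwd(cc$z, dx)  # sigmoid grad folded into loss
      g <- conv_bwd(cc$u, ly$W, dz, stride = 1L)
      grads[[i]] <- list(dW = g$dW, db = g$db)
      dx <- if (ly$stride == 2L) up2_bwd(g$dx) else g$dx
    }
  }
  grads
}

#' Average residual square (ARS) between a prediction and a target mask
#'
#' Root of the mean squared per-pixel residual,
#' `sqrt(mean((y - d)^2))` over the full grid. For predictions in \[0, 1\]
#' against binary targets the score lies in \[0, 1\]: 0 for an exact match, 1
#' for a maximally wrong prediction. An untrained network scored against
#' balanced binary masks sits at or above 0.5.
#'
#' @param predicted numeric matrix/array (typically a probability map).
#' @param target binary mask of the same shape.
#' @return scalar score >= 0.
#' @export
ars <- function(predicted, target) {
  if (!all(dim(predicted) == dim(target)))
    stopf("prediction and target shapes differ")
  sqrt(mean((as.numeric(predicted) - as.numeric(target))^2))
}

#' Save / load a network settings file
#'
#' The full architecture (layer types, channel widths, activations are
#' implied by the class) and all weights/biases are written to a single
#' binary settings file which can be reloaded for inference.
#'
#' @param net an `encdec_net`.
#' @param path file path.
#' @export
nn_save <- function(net, path) { saveRDS(net, path); invisible(path) }

#' @rdname nn_save
#' @return `nn_load` returns the network.
#' @export
nn_load <- function(path) {
  net <- readRDS(path)
  if (!inherits(net, "encdec_net")) stopf("not an encdec_net settings file")
  net
}

#' @export
print.encdec_net <- function(x, ...) {
  cat(sprintf("<encdec_net> 3 conv (stride 2) + 3 deconv stages, channels %s, %s\n",
              paste(x$channels, collapse = "/"),
              if (isTRUE(x$trained)) "trained" else "untrained"))
  invisible(x)
}
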