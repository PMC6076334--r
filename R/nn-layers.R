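# Minimal convolutional building blocks in base R. Images are [H, W, C]
# arrays; convolutions are 3x3 with zero padding 1, computed as a sum of nine
# offset matrix products (BLAS does the heavy lifting), which keeps both the
# forward pass and the exact gradients simple.

conv_pad <- function(x) {
  d <- dim(x)
  xp <- array(0, c(d[1] + 2L, d[2] + 2L, d[3]))
  xp[2:(d[1] + 1L), 2:(d[2] + 1L), ] <- x
  xp
}

# 3x3 convolution, stride 1 or 2, zero padding 1.
# W: array [3, 3, Cin, Cout]; b: numeric [Cout].
conv_fwd <- function(x, W, b, stride = 1L) {
  d <- dim(x); Cin <- d[3]; Cout <- dim(W)[4]
  Ho <- if (stride == 2L) d[1] %/% 2L else d[1]
  Wo <- if (stride == 2L) d[2] %/% 2L else d[2]
  xp <- conv_pad(x)
  rows <- seq.int(1L, by = stride, length.out = Ho)
  cols <- seq.int(1L, by = stride, length.out = Wo)
  y <- matrix(rep(b, each = Ho * Wo), Ho * Wo, Cout)
  for (di in 0:2) for (dj in 0:2) {
    sl <- matrix(xp[rows + di, cols + dj, ], Ho * Wo, Cin)
    y <- y + sl %*% matrix(W[di + 1L, dj + 1L, , ], Cin, Cout)
  }
  array(y, c(Ho, Wo, Cout))
}

# Gradients of conv_fwd. dy: [Ho, Wo, Cout]. Returns list(dx, dW, db).
conv_bwd <- function(x, W, dy, stride = 1L) {
  d <- dim(x); Cin <- d[3]; Cout <- dim(W)[4]
  dd <- dim(dy); Ho <- dd[1]; Wo <- dd[2]
  xp <- conv_pad(x)
  dxp <- array(0, dim(xp))
  rows <- seq.int(1L, by = stride, length.out = Ho)
  cols <- seq.int(1L, by = stride, length.out = Wo)
  dym <- matrix(dy, Ho * Wo, Cout)
  dW <- array(0, dim(W))
  for (di in 0:2) for (dj in 0:2) {
    sl <- matrix(xp[rows + di, cols + dj, ], Ho * Wo, Cin)
    dW[di + 1L, dj + 1L, , ] <- crossprod(sl, dym)
    dsl <- dym %*% t(matrix(W[di + 1L, dj + 1L, , ], Cin, Cout))
    dxp[rows + di, cols + dj, ] <- dxp[rows + di, cols + dj, , drop = FALSE] +
      array(dsl, c(Ho, Wo, Cin))
  }
  list(dx = dxp[2:(d[1] + 1L), 2:(d[2] + 1L), , drop = FALSE],
       dW = dW, db = colSums(dym))
}

# Nearest-neighbour 2x upsampling and its gradient (sum over each 2x2 block).
up2_fwd <- function(x) {
  d <- dim(x)
  x[rep(seq_len(d[1]), each = 2L), rep(seq_len(d[2]), each = 2L), , drop = FALSE]
}

up2_bwd <- function(dy) {
  d <- dim(dy)
  odd_r <- seq.int(1L, d[1], by = 2L); odd_c <- seq.int(1L, d[2], by = 2L)
  dy[odd_r, odd_c, , drop = FALSE] + dy[odd_r + 1L, odd_c, , drop = FALSE] +
    dy[odd_r, odd_c + 1L, , drop = FALSE] + dy[odd_r + 1L, odd_c + 1L, , drop = FALSE]
}

relu_fwd <- function(x) { x[x < 0] <- 0; x }
relu_bwd <- function(x, dy) { dy[x <= 0] <- 0; dy }
sigmoid_fwd <- function(x) 1 / (1 + exp(-x))
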