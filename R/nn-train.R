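# Adam trainer and training-set-size cross-validation for the
# encoder-decoder network.

#' Scale an image to the unit range for network input
#'
#' Divides by the image maximum (guarding zero images). Apply the same
#' normalization at training and inference time.
#'
#' @param image numeric matrix.
#' @return matrix with maximum 1.
#' @export
nn_normalize <- function(image) {
  m <- max(image)
  if (m <= 0) image else image / m
}

#' Train a network with Adam
#'
#' Minimizes the mean squared error between the sigmoid output map and the
#' binary target masks (the quantity whose root is the ARS); binary
#' cross-entropy is available behind `loss = "bce"`. Mini-batch gradients,
#' adaptive moment estimation updates, fixed-seed shuffling: two runs with
#' the same seed produce identical loss traces and weights.
#'
#' @param net an [nn_new()] network.
#' @param images list of input matrices (normalize with [nn_normalize()]).
#' @param targets list of target masks (same shapes, values in \[0, 1\]).
#' @param epochs training epochs.
#' @param lr learning rate.
#' @param beta1,beta2,eps Adam moment decay rates and stabilizer.
#' @param batch_size mini-batch size.
#' @param loss `"mse"` (default) or `"bce"`.
#' @param seed RNG seed for shuffling.
#' @param verbose print per-epoch loss.
#' @return list with
#'   \item{net}{trained network}
#'   \item{trace}{data.frame `epoch, loss` (mean per-sample loss)}
#'   \item{ars_before, ars_after}{mean training-set ARS before/after}
#' @export
train_adam <- function(net, images, targets, epochs = 20L, lr = 1e-3,
                       beta1 = 0.9, beta2 = 0.999, eps = 1e-8,
                       batch_size = 8L, loss = c("mse", "bce"),
                       seed = 1L, verbose = FALSE) {
  loss <- match.arg(loss)
  n <- length(images)
  if (n == 0L) stopf("empty training set")
  if (length(targets) != n) stopf("images and targets differ in length")
  if (!is.null(seed)) set.seed(seed)

  mean_ars <- function(nt) mean(vapply(seq_len(n), function(i)
    ars(nn_forward(nt, images[[i]]), targets[[i]]), 0))
  ars0 <- mean_ars(net)

  nl <- length(net$layers)
  mW <- lapply(net$layers, function(l) array(0, dim(l$W)))
  vW <- lapply(net$layers, function(l) array(0, dim(l$W)))
  mb <- lapply(net$layers, function(l) numeric(length(l$b)))
  vb <- lapply(net$layers, function(l) numeric(length(l$b)))
  t_adam <- 0L
  trace <- data.frame(epoch = integer(0), loss = numeric(0))

  for (ep in seq_len(epochs)) {
    ord <- sample.int(n)
    ep_loss <- 0
    for (start in seq(1L, n, by = batch_size)) {
      idx <- ord[start:min(start + batch_size - 1L, n)]
      gW <- lapply(net$layers, function(l) array(0, dim(l$W)))
      gb <- lapply(net$layers, function(l) numeric(length(l$b)))
      for (i in idx) {
        fwd <- nn_forward_full(net, images[[i]], cache = TRUE)
        y <- fwd$out
        d <- targets[[i]]
        if (is.matrix(d)) d <- array(d, dim(y))
        npx <- length(y)
        if (loss == "mse") {
          ep_loss <- ep_loss + mean((y - d)^2)
          dz <- 2 * (y - d) / npx * y * (1 - y)   # sigmoid grad folded in
        } else {
          yc <- pmin(pmax(y, 1e-7), 1 - 1e-7)
          ep_loss <- ep_loss - mean(d * log(yc) + (1 - d) * log(1 - yc))
          dz <- (y - d) / npx
        }
        g <- nn_backward(net, fwd, dz)
        for (k in seq_len(nl)) {
          gW[[k]] <- gW[[k]] + g[[k]]$dW
          gb[[k]] <- gb[[k]] + g[[k]]$db
        }
      }
      t_adam <- t_adam + 1L
      bc1 <- 1 - beta1^t_adam; bc2 <- 1 - beta2^t_adam
      for (k in seq_len(nl)) {
        gWk <- gW[[k]] / length(idx); gbk <- gb[[k]] / length(idx)
        mW[[k]] <- beta1 * mW[[k]] + (1 - beta1) * gWk
        vW[[k]] <- beta2 * vW[[k]] + (1 - beta2) * gWk^2
        mb[[k]] <- beta1 * mb[[k]] + (1 - beta1) * gbk
        vb[[k]] <- beta2 * vb[[k]] + (1 - beta2) * gbk^2
        net$layers[[k]]$W <- net$layers[[k]]$W -
          lr * (mW[[k]] / bc1) / (sqrt(vW[[k]] / bc2) + eps)
        net$layers[[k]]$b <- net$layers[[k]]$b -
          lr * (mb[[k]] / bc1) / (sqrt(vb[[k]] / bc2) + eps)
      }
    }
    ep_loss <- ep_loss / n
    if (!is.finite(ep_loss))
      stopf("training diverged at epoch %d (loss is not finite)", ep)
    trace <- rbind(trace, data.frame(epoch = ep, loss = ep_loss))
    if (verbose) message(sprintf("epoch %3d  loss %.6f", ep, ep_loss))
  }
  net$trained <- TRUE
  list(net = net, trace = trace, ars_before = ars0, ars_after = mean_ars(net))
}

#' Cross-validate the training-set size
#'
#' Trains fresh networks on subsets of increasing size and reports the
#' train/test ARS gap ("distance"); the size at which the distance flattens
#' indicates a sufficient amount of training data. With `size` equal to the
#' full pool and one fold, train and test sets coincide and the distance
#' is 0.
#'
#' @param images,targets the full pool of training pairs.
#' @param sizes training-set sizes to probe (each <= pool size).
#' @param folds repeats per size (different random subsets).
#' @param channels network width passed to [nn_new()].
#' @param epochs,lr,batch_size training settings per fit.
#' @param seed base RNG seed.
#' @return data.frame `size, fold, train_ars, test_ars, distance`.
#' @export
cross_validate_training_size <- function(images, targets, sizes, folds = 3L,
                                         channels = c(8L, 16L, 32L),
                                         epochs = 15L, lr = 1e-3,
                                         batch_size = 8L, seed = 1L) {
  n <- length(images)
  if (any(sizes > n)) stopf("sizes must not exceed the pool size (%d)", n)
  out <- list()
  for (s in sizes) for (f in seq_len(folds)) {
    fit_seed <- (seed * 1000L + s * 10L + f) %% 2147483600L
    set.seed(fit_seed)
    idx <- sample.int(n, s)
    test_idx <- if (s == n) idx else setdiff(seq_len(n), idx)
    net <- nn_new(channels = channels, seed = fit_seed)
    fit <- train_adam(net, images[idx], targets[idx], epochs = epochs,
                      lr = lr, batch_size = batch_size, seed = fit_seed)
    test_ars <- mean(vapply(test_idx, function(i)
      ars(nn_forward(fit$net, images[[i]]), targets[[i]]), 0))
    out[[length(out) + 1L]] <- data.frame(
      size = s, fold = f, train_ars = fit$ars_after, test_ars = test_ars,
      distance = test_ars - fit$ars_after)
  }
  do.call(rbind, out)
}
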