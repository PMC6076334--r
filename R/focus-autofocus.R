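# Two-step autofocus: coarse scan judged by the trained classifier, then a
# fine sharpness-peak scan with a Gaussian fit.

#' Train the coarse autofocus classifier
#'
#' The encoder-decoder network learns a constant map per image: 1 for iris
#' images within the in-focus slab, 0 otherwise. The scalar evaluation value
#' of an image is the spatial mean of the output probability map.
#'
#' @param stack a labelled stack from [simulate_focus_stack()] (or any list
#'   with `images` and 0/1 `labels`).
#' @param channels,epochs,lr,batch_size,seed training settings (see
#'   [train_adam()]).
#' @return list `net`, `trace`, `ars_after`.
#' @export
train_focus_classifier <- function(stack, channels = c(8L, 16L, 32L),
                                   epochs = 15L, lr = 1e-3, batch_size = 16L,
                                   seed = 1L) {
  imgs <- lapply(stack$images, nn_normalize)
  tgts <- lapply(seq_along(imgs), function(i) {
    matrix(stack$labels[i], nrow(imgs[[i]]), ncol(imgs[[i]]))
  })
  net <- nn_new(channels = channels, seed = seed)
  fit <- train_adam(net, imgs, tgts, epochs = epochs, lr = lr,
                    batch_size = batch_size, seed = seed)
  list(net = fit$net, trace = fit$trace, ars_after = fit$ars_after)
}

#' Evaluation value of an iris image under the coarse classifier
#'
#' @param net trained classifier network.
#' @param image iris image matrix (raw intensities; normalized internally).
#' @return scalar in (0, 1).
#' @export
focus_evaluation_value <- function(net, image) {
  mean(nn_forward(net, nn_normalize(image)))
}

#' Coarse autofocus scan
#'
#' Steps the axis upward from the start of the range, evaluating each iris
#' image with the classifier, and stops at the first position whose
#' evaluation value exceeds `threshold`.
#'
#' @param stage function `z -> image` (e.g. [focus_stage()]).
#' @param net trained coarse classifier.
#' @param z_range scan range (um), default `c(0, 750)`.
#' @param z_step step (um), default 2.5.
#' @param threshold stopping rule on the evaluation value (default 0.5).
#' @return list `success`, `z` (stopping position, `NA` on failure),
#'   `value`, `trace` (data.frame `z, value` of evaluated positions).
#' @export
coarse_focus <- function(stage, net, z_range = c(0, 750), z_step = 2.5,
                         threshold = 0.5) {
  if (!isTRUE(net$trained)) stopf("classifier network is untrained")
  zs <- seq(z_range[1], z_range[2], by = z_step)
  trace <- data.frame(z = numeric(0), value = numeric(0))
  for (z in zs) {
    v <- focus_evaluation_value(net, stage(z))
    trace <- rbind(trace, data.frame(z = z, value = v))
    if (v > threshold)
      return(list(success = TRUE, z = z, value = v, trace = trace))
  }
  list(success = FALSE, z = NA_real_, value = max(trace$value), trace = trace)
}

#' Fine autofocus by sharpness-peak fitting
#'
#' Scans a short range around `center_z` in fine steps (a PFS-like feedback
#' axis: the full range of `pfs_range` a.u. corresponds to `range_um` um, a
#' step of `pfs_step` a.u. to ~32 nm), computes the sharpness E at each
#' position, fits a Gaussian to the E profile and returns its center plus a
#' calibration `offset`. If the fit fails or lands outside the scanned
#' window, the argmax position is used and flagged.
#'
#' @param stage function `z -> image`.
#' @param center_z scan center (um), typically the coarse-focus result.
#' @param range_um scanned range (um), default 3.5.
#' @param pfs_range,pfs_step scan extent and step in PFS arbitrary units
#'   (2200 a.u. across `range_um`, step 20 a.u.).
#' @param offset calibration offset added to the fitted peak (um, default 0;
#'   instrument-specific).
#' @param roi,smooth passed to [sharpness_E()].
#' @param recenter when the fitted peak lands within 15% of the scanned
#'   window's edge (the true focus may lie just outside), rescan once
#'   centred on the peak (default TRUE).
#' @return list `pfs0` (fitted peak, um), `final_z = pfs0 + offset`,
#'   `profile` (data.frame `z, pfs, E`), `fallback` (TRUE if argmax used),
#'   `recentred`.
#' @export
fine_focus <- function(stage, center_z, range_um = 3.5, pfs_range = 2200,
                       pfs_step = 20, offset = 0, roi = 21L, smooth = 20L,
                       recenter = TRUE) {
  scan <- function(center) {
    um_per_au <- range_um / pfs_range
    pfs <- seq(0, pfs_range, by = pfs_step)
    zs <- center - range_um / 2 + pfs * um_per_au
    E <- vapply(zs, function(z) {
      img <- stage(z)
      half <- img[(nrow(img) %/% 2 + 1L):nrow(img), , drop = FALSE]
      tryCatch(sharpness_E(half, roi = roi, smooth = smooth)$E,
               error = function(e) NA_real_)
    }, 0)
    profile <- data.frame(z = zs, pfs = pfs, E = E)
    ok <- is.finite(E)
    z_hat <- NA_real_
    fallback <- TRUE
    if (sum(ok) >= 5L) {
      df <- profile[ok, ]
      a0 <- max(df$E); mu0 <- df$z[which.max(df$E)]
      s0 <- max(range_um / 6, 1e-3); c0 <- min(df$E)
      fit <- tryCatch(
        minpack.lm::nlsLM(E ~ a * exp(-(z - mu)^2 / (2 * s^2)) + c0_,
                          data = df,
                          start = list(a = a0 - min(df$E), mu = mu0, s = s0,
                                       c0_ = c0),
                          control = minpack.lm::nls.lm.control(maxiter = 200)),
        error = function(e) NULL)
      if (!is.null(fit)) {
        mu <- coef(fit)[["mu"]]
        if (mu >= min(zs) && mu <= max(zs)) { z_hat <- mu; fallback <- FALSE }
      }
    }
    if (fallback) z_hat <- profile$z[which.max(ifelse(ok, E, -Inf))]
    list(z_hat = z_hat, profile = profile, fallback = fallback)
  }
  s1 <- scan(center_z)
  recentred <- FALSE
  edge <- 0.15 * range_um
  if (recenter &&
      (s1$z_hat - min(s1$profile$z) < edge ||
       max(s1$profile$z) - s1$z_hat < edge)) {
    s1 <- scan(s1$z_hat)
    recentred <- TRUE
  }
  list(pfs0 = s1$z_hat, final_z = s1$z_hat + offset, profile = s1$profile,
       fallback = s1$fallback, recentred = recentred)
}

#' Two-step autofocus
#'
#' Runs [coarse_focus()] then, on success, [fine_focus()] centred on the
#' coarse position.
#'
#' Because the ascending coarse scan stops at the lower edge of the in-focus
#' slab, the fine window is centred `fine_precenter` um above the coarse
#' stop (half the 4-um labelling slab by default) so the sharpness peak
#' falls inside the scanned range.
#'
#' @inheritParams coarse_focus
#' @inheritParams fine_focus
#' @param fine_stage stage used for the fine scan (e.g. a higher-resolution
#'   view of the same optics); defaults to `stage`.
#' @param fine_precenter um added to the coarse stop to centre the fine
#'   window (default 2).
#' @param ... passed to [fine_focus()].
#' @return list `success`, `final_z`, `coarse`, `fine`.
#' @export
autofocus <- function(stage, net, z_range = c(0, 750), z_step = 2.5,
                      threshold = 0.5, fine_stage = stage,
                      fine_precenter = 2, ...) {
  cf <- coarse_focus(stage, net, z_range = z_range, z_step = z_step,
                     threshold = threshold)
  if (!cf$success)
    return(list(success = FALSE, final_z = NA_real_, coarse = cf, fine = NULL))
  ff <- fine_focus(fine_stage, center_z = cf$z + fine_precenter, ...)
  list(success = TRUE, final_z = ff$final_z, coarse = cf, fine = ff)
}
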