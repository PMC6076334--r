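# Trained networks are expensive; train each once per test run, lazily.

.net_cache <- new.env(parent = emptyenv())

cached <- function(key, builder) {
  if (is.null(.net_cache[[key]])) .net_cache[[key]] <- builder()
  .net_cache[[key]]
}

# Coarse autofocus classifier: one labelled stack around a known focus,
# 0.1 um steps (+-20 um), 32 px iris images.
get_focus_classifier <- function() {
  cached("focus", function() {
    stack <- simulate_focus_stack(c(280, 320), 0.1, true_focus = 300,
                                  size = 32, noise_sd = 30, seed = 11)
    train_focus_classifier(stack, epochs = 8, seed = 12)
  })
}

# SRIC cell-region segmentation net (held-out scenes use seeds >= 200).
get_sric_net <- function() {
  cached("sric", function() {
    scenes <- lapply(1:24, function(i)
      simulate_sric_scene(2, size = 128, axis_range = c(18, 30), seed = i))
    train_segmentation_net(lapply(scenes, `[[`, "image"),
                           lapply(scenes, `[[`, "mask"),
                           epochs = 40, lr = 2e-3, seed = 21)
  })
}

# Inhibition-grid replicates (fit + profile CIs are expensive; computed once
# and asserted from two test files).
get_inhibition_replicates <- function() {
  cached("inhibition", function() {
    grid <- expand.grid(L = c(0.3, 1, 3, 10, 30, 60),
                        I = c(0, 10, 100, 1000, 4000, 10000))
    truth <- list(msd_max = 0.065, msd_min = 0.030, ec50 = 4.7, ic50 = 2300)
    do.call(rbind, lapply(1:5, function(k) {
      tab <- simulate_response_tables(grid, truth, sigma = 0.12, n_cells = 3,
                                      seed = 5000 + k)
      fit <- fit_inhibition(tab$cells, seed = 6000 + k)
      ce <- dose_profile_ci(tab$cells, fit, "ec50", n_grid = 21L)
      ci <- dose_profile_ci(tab$cells, fit, "ic50", n_grid = 21L)
      data.frame(rep = k, ec50 = fit$ec50, ic50 = fit$ic50,
                 msd_max = fit$msd_max,
                 ec_in_ci = truth$ec50 >= ce$lower & truth$ec50 <= ce$upper,
                 ic_in_ci = truth$ic50 >= ci$lower & truth$ic50 <= ci$upper)
    }))
  })
}

# Suitable-spot-density net: uniform scenes labelled by the 1-3 um^-2 band,
# including slightly defocused examples.
get_density_net <- function() {
  cached("density", function() {
    dens <- c(0.05, 0.1, 0.3, 0.5, 1.2, 1.5, 2, 2.5, 3, 5, 8, 10)
    imgs <- list(); tgts <- list(); k <- 0
    for (rep in 1:4) for (dd in dens) {
      k <- k + 1
      sc <- simulate_density_scene(dd, size = 64, seed = 1000 + k,
                                   defocus = if (k %% 3 == 0) 1 else 0)
      imgs[[k]] <- sc$image
      tgts[[k]] <- matrix(as.numeric(dd >= 1 & dd <= 3), 64, 64)
    }
    train_segmentation_net(imgs, tgts, epochs = 30, lr = 2e-3, seed = 22)
  })
}
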