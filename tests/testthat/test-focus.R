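# Otsu threshold, iris-edge ROIs, sharpness E, two-step autofocus.

test_that("Otsu threshold separates two-level and bimodal images and matches brute force", {
  two <- matrix(c(rep(10, 50), rep(200, 50)), 10, 10)
  th <- otsu_threshold(two)
  expect_gt(th, 10); expect_lt(th, 200)
  expect_error(otsu_threshold(matrix(5, 4, 4)), "constant")

  set.seed(1)
  for (k in 1:5) {
    img <- matrix(sample(0:255, 300, TRUE), 15, 20)
    expect_equal(otsu_threshold(img), brute_force_otsu(img))
  }
  # bimodal Gaussian mixture: the threshold separates the modes
  set.seed(2)
  bi <- matrix(round(c(rnorm(500, 60, 10), rnorm(500, 190, 12))), 25, 40)
  thb <- otsu_threshold(bi)
  expect_gt(thb, 70); expect_lt(thb, 180)
})

test_that("edge ROIs straddle a horizontal step edge and skip all-white columns", {
  H <- 84; W <- 84; r_edge <- 40
  bin <- matrix(0, H, W)
  bin[1:r_edge, ] <- 1                       # white above the edge
  rois <- find_edge_rois(bin)
  expect_gt(nrow(rois), 0)
  centers <- rois$row + 10
  expect_true(all(abs(centers - r_edge) <= 10))
  expect_equal(nrow(find_edge_rois(matrix(1, 84, 84))), 0)
})

test_that("edge ROIs trace a circular boundary", {
  H <- W <- 168
  ctr <- (H + 1) / 2; rad <- 70
  d <- sqrt(outer((seq_len(H) - ctr)^2, (seq_len(W) - ctr)^2, "+"))
  bin <- ifelse(d <= rad, 1, 0)
  # use the lower half, where scanning down crosses the circle
  low <- bin[(H / 2 + 1):H, ]
  rois <- find_edge_rois(low)
  ok <- 0
  for (i in seq_len(nrow(rois))) {
    cy <- rois$row[i] + 10 + H / 2
    cx <- rois$col[i] + 10
    ok <- ok + (abs(sqrt((cy - ctr)^2 + (cx - ctr)^2) - rad) < 15)
  }
  expect_gte(ok, nrow(rois) - 1)   # allow one outlier where the edge exits
})

test_that("sharpness score reproduces hand-computed histogram cases", {
  # peaks (10, 10), valley 2 -> E = 10 * 10 / 2^2 = 25 (no smoothing)
  res <- sharpness_from_histogram(c(10, 2, 10), smooth = 1L)
  expect_equal(res$E, 25)
  # equal peaks and valley -> E = 1
  expect_equal(sharpness_from_histogram(c(7, 7, 7), smooth = 1L)$E, 1)
  # empty valley -> infinite score, documented sentinel
  expect_equal(sharpness_from_histogram(c(10, 0, 10), smooth = 1L)$E, Inf)
})

test_that("E is large in focus and invariant under affine brightness rescaling", {
  img <- render_iris(z = 100, true_focus = 100, size = 128, noise_sd = 30,
                     seed = 3)
  half <- img[65:128, ]
  E <- sharpness_E(half)$E
  expect_gt(E, 1)
  expect_equal(sharpness_E(3.7 * half + 250)$E, E, tolerance = 1e-8)
  expect_equal(sharpness_E(0.01 * half - 5)$E, E, tolerance = 1e-8)
  # defocus reduces the score
  far <- render_iris(z = 112, true_focus = 100, size = 128, noise_sd = 30,
                     seed = 3)
  expect_lt(sharpness_E(far[65:128, ])$E, E)
})

test_that("coarse focus stops inside the labelled slab; a flat classifier fails", {
  cls <- get_focus_classifier()
  truth <- 412
  stage <- focus_stage(truth, size = 32, noise_sd = 30, seed = 4)
  cf <- coarse_focus(stage, cls$net)
  expect_true(cf$success)
  expect_lte(abs(cf$z - truth), 5)
  # evaluation values make a 0 <-> 1 transition across the slab
  expect_gt(focus_evaluation_value(cls$net, stage(truth)), 0.8)
  expect_lt(focus_evaluation_value(cls$net, stage(truth - 60)), 0.2)

  flat <- nn_new(seed = 5, init_scale = 0)   # constant 0.5 output, never > 0.5
  flat$trained <- TRUE
  cf0 <- coarse_focus(focus_stage(100, 32, 30, seed = 6), flat,
                      z_range = c(0, 50))
  expect_false(cf0$success)
  expect_true(is.na(cf0$z))
})

test_that("fine focus finds a noiseless peak within one step and noisy within a few", {
  truth <- 250
  clean <- focus_stage(truth, size = 128, noise_sd = 0, seed = 7)
  ff <- fine_focus(clean, center_z = truth + 0.4)
  expect_lte(abs(ff$pfs0 - truth), 20 * 3.5 / 2200)   # one PFS step
  noisy <- focus_stage(truth, size = 128, noise_sd = 30, seed = 8)
  ffn <- fine_focus(noisy, center_z = truth + 0.4)
  expect_lte(abs(ffn$pfs0 - truth), 0.1)              # a few steps
})

test_that("the two-step procedure lands inside the in-focus slab", {
  cls <- get_focus_classifier()
  set.seed(9)
  for (k in 1:5) {
    truth <- runif(1, 100, 650)
    af <- autofocus(focus_stage(truth, 32, 30, seed = 900 + k), cls$net,
                    fine_stage = focus_stage(truth, 128, 30, seed = 950 + k))
    expect_true(af$success)
    expect_lte(abs(af$final_z - truth), 4)
  }
})
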