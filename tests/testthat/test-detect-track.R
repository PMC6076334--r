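# Spot detection, sub-pixel fitting, linking, filtering, registration.

test_that("the detection template is symmetric with a central maximum", {
  tpl <- gaussian_template()
  expect_equal(dim(tpl), c(11L, 11L))
  expect_equal(tpl, t(tpl))
  expect_equal(tpl, tpl[11:1, 11:1])
  expect_equal(which.max(tpl), 61L)   # center of the 11x11 support
})

test_that("correlation map hits +/-1 on pasted templates and matches brute force", {
  tpl <- gaussian_template()
  img <- matrix(0.5, 32, 32)
  img[10:20, 14:24] <- img[10:20, 14:24] + tpl
  cm <- correlation_map(img, tpl)
  expect_equal(cm[15, 19], 1.0)
  img_neg <- matrix(0.5, 32, 32)
  img_neg[10:20, 14:24] <- img_neg[10:20, 14:24] - tpl
  expect_equal(correlation_map(img_neg, tpl)[15, 19], -1.0)

  set.seed(1)
  for (k in 1:3) {
    rimg <- matrix(runif(32 * 32), 32, 32)
    expect_lt(max(abs(correlation_map(rimg, tpl) -
                        brute_force_correlation(rimg, tpl)), na.rm = TRUE),
              1e-10)
  }
  # constant windows are defined as zero correlation
  flat <- matrix(7, 20, 20)
  cmf <- correlation_map(flat, tpl)
  expect_true(all(cmf[6:15, 6:15] == 0))
  expect_true(all(abs(cm) <= 1 + 1e-12, na.rm = TRUE))
})

test_that("spot candidates respect the correlation threshold", {
  tpl <- gaussian_template()
  expect_equal(nrow(detect_spots(matrix(0.2, 20, 20), 0.25)), 0)

  mv <- noiseless_test_movie(n = 2, n_frames = 1, seed = 2)
  cm <- correlation_map(mv$stack[, , 1], tpl)
  expect_equal(nrow(detect_spots(cm, 0.25)), 2)

  # threshold sweep on a noisy frame: stricter keeps fewer candidates
  cfg <- sim_config(field_size = c(64, 64), monomer_mean = 300,
                    read_noise_sd = 25)
  tr <- data.frame(track = 1:4, frame = 0, x = c(1, 3, 1, 3),
                   y = c(1, 1, 3, 3), state = 1)
  noisy <- render_movie(tr, 1L, cfg, seed = 3)$stack[, , 1]
  cmn <- correlation_map(noisy, tpl)
  n_strict <- nrow(detect_spots(cmn, 0.8))
  n_ref <- nrow(detect_spots(cmn, 0.25))
  n_loose <- nrow(detect_spots(cmn, 0.02))
  expect_lte(n_strict, n_ref)
  expect_lte(n_ref, n_loose)
})

test_that("Gaussian-plus-plane fit recovers parameters and flags border spots", {
  cfg <- sim_config(field_size = c(32, 32), noise_model = "none",
                    monomer_mean = 1000, monomer_sd = 0,
                    background_offset = 100)
  tr <- data.frame(track = 1, frame = 0, x = 1.52, y = 1.41, state = 1)
  mv <- render_movie(tr, 1L, cfg, noise = FALSE, seed = 4)
  f <- fit_spot(mv$stack[, , 1], c(15, 14))
  expect_lt(abs(f$I0 - 1000) / 1000, 1e-3)
  expect_lt(abs(f$sigmaA - 2) / 2, 1e-3)
  expect_lt(abs(f$Iback - 100) / 100, 1e-3)
  expect_lt(abs(f$a), 0.5); expect_lt(abs(f$b), 0.5)
  # border candidate: ROI would clip
  expect_null(fit_spot(mv$stack[, , 1], c(2, 15)))

  # tilted background recovered in expectation at SNR 10
  cfg2 <- cfg; cfg2$background_slope <- c(20, -10)
  cfg2$noise_model <- "gaussian"; cfg2$read_noise_sd <- 100
  slopes <- t(vapply(1:20, function(k) {
    mvk <- render_movie(tr, 1L, cfg2, noise = TRUE, seed = 100 + k)
    fk <- fit_spot(mvk$stack[, , 1], c(15, 14))
    c(fk$a, fk$b)
  }, c(0, 0)))
  expect_lt(abs(mean(slopes[, 1]) - 20) / 20, 0.05)
  expect_lt(abs(mean(slopes[, 2]) + 10) / 10, 0.05)
})

test_that("frame linking respects the 6 px radius and the shortest connection", {
  one <- link_frames(data.frame(x = 0, y = 0), data.frame(x = 3, y = 0))
  expect_equal(nrow(one$links), 1)
  none <- link_frames(data.frame(x = 0, y = 0), data.frame(x = 7, y = 0))
  expect_equal(nrow(none$links), 0)
  expect_equal(none$unmatched_prev, 1L)
  expect_equal(none$unmatched_cur, 1L)
  # exactly at the radius: not linked ("below 6 pixels")
  at6 <- link_frames(data.frame(x = 0, y = 0), data.frame(x = 6, y = 0))
  expect_equal(nrow(at6$links), 0)

  # crossing 2x2 geometry: greedy picks the shortest pairs
  prev <- data.frame(x = c(0, 4), y = c(0, 0))
  cur <- data.frame(x = c(1, 3), y = c(0, 0))
  norm_links <- function(l) {
    l <- l[order(l$prev), c("prev", "cur")]
    rownames(l) <- NULL
    l
  }
  g <- link_frames(prev, cur, method = "greedy")$links
  o <- link_frames(prev, cur, method = "optimal")$links
  expect_equal(norm_links(g), norm_links(o))
})

test_that("greedy equals exhaustive matching under well-separated motion", {
  set.seed(5)
  for (k in 1:20) {
    n <- sample(2:5, 1)
    # spots at least 8 px apart, displacements below 2 px (< half separation)
    base <- data.frame(x = runif(n, 0, 60), y = runif(n, 0, 60))
    while (n > 1 && min(dist(base)) < 8) {
      base <- data.frame(x = runif(n, 0, 60), y = runif(n, 0, 60))
    }
    cur <- base
    cur$x <- cur$x + runif(n, -1.4, 1.4)
    cur$y <- cur$y + runif(n, -1.4, 1.4)
    norm_links <- function(l) {
      l <- l[order(l$prev), c("prev", "cur")]
      rownames(l) <- NULL
      l
    }
    g <- link_frames(base, cur, method = "greedy")$links
    o <- link_frames(base, cur, method = "optimal")$links
    expect_equal(norm_links(g), norm_links(o))
  }
})

test_that("trajectory filters remove off-cell tracks and bad spot sizes", {
  mk_traj <- function(id, x, y, sigmaA) {
    data.frame(track = id, frame = 0:2, x = x, y = y, sigmaA = sigmaA)
  }
  mask <- matrix(0L, 40, 40); mask[10:30, 10:30] <- 1L
  fx <- rbind(
    mk_traj(1, 20, 20, 2.0),     # kept
    mk_traj(2, 20, 20, 2.6),     # size too large
    mk_traj(3, 20, 20, 1.0),     # size too small
    mk_traj(4, 35, 35, 2.0),     # outside the cell
    mk_traj(5, c(20, 20, 35), 20, 2.0),  # leaves the cell mid-track
    mk_traj(6, 15, 25, 2.2),     # kept
    mk_traj(7, 25, 15, 1.6),     # kept
    mk_traj(8, 12, 12, 3.0),     # size too large
    mk_traj(9, 28, 28, 2.4),     # kept
    mk_traj(10, 20, 28, 1.9)     # kept (5 kept, but one more below)
  )
  # per-trajectory mean rule: a single 2.6 spot in an otherwise 2.0 track stays
  fx <- rbind(fx, data.frame(track = 11, frame = 0:2, x = 22, y = 22,
                             sigmaA = c(2.0, 2.6, 2.0)))
  out <- filter_trajectories(fx, mask = mask)
  expect_equal(sort(unique(out$kept$track)), c(1, 6, 7, 9, 10, 11))
  expect_equal(unname(out$log["removed"]), 5L)
  expect_setequal(out$removed$reason[out$removed$track %in% c(4, 5)],
                  "outside_cell")
  # per-spot variant removes track 11 as well
  out2 <- filter_trajectories(fx, mask = mask, per_spot = TRUE)
  expect_false(11 %in% out2$kept$track)
})

test_that("channel registration recovers similarity transforms", {
  set.seed(6)
  ch2 <- data.frame(x = runif(12, 0, 512), y = runif(12, 0, 512))
  ident <- fit_channel_transform(ch2, ch2)
  expect_equal(ident$residual_rms, 0, tolerance = 1e-10)
  expect_equal(ident$scale, 1, tolerance = 1e-12)
  expect_equal(ident$rotation, 0, tolerance = 1e-12)

  th <- 2 * pi / 180
  Rm <- matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2, 2)
  p1 <- as.matrix(ch2) %*% t(Rm) * 1.003
  ch1 <- data.frame(x = p1[, 1] + 3.2, y = p1[, 2] - 1.1)
  tf <- fit_channel_transform(ch1, ch2)
  expect_equal(tf$rotation, th, tolerance = 1e-9)
  expect_equal(tf$scale, 1.003, tolerance = 1e-9)
  expect_equal(tf$t, c(3.2, -1.1), tolerance = 1e-7)
  back <- apply_channel_transform(tf, ch2)
  expect_equal(back$x, ch1$x, tolerance = 1e-8)

  # 0.1 px fiducial noise shows up as a comparable residual
  noisy1 <- ch1
  noisy1$x <- noisy1$x + rnorm(12, 0, 0.1)
  noisy1$y <- noisy1$y + rnorm(12, 0, 0.1)
  tfn <- fit_channel_transform(noisy1, ch2)
  expect_gt(tfn$residual_rms, 0.03)
  expect_lt(tfn$residual_rms, 0.3)

  expect_error(fit_channel_transform(ch1[1:2, ], ch2[1:2, ]), "3 matched")
  coll <- data.frame(x = 1:5, y = 2 * (1:5) + 1)
  expect_error(fit_channel_transform(coll, coll, type = "affine"),
               "collinear")
})

test_that("a noiseless movie is recovered exactly end to end", {
  mv <- noiseless_test_movie(n = 5, n_frames = 10, seed = 7)
  res <- track_movie(mv$stack)
  lens <- table(res$trajectories$track)
  expect_equal(length(lens), 5L)
  expect_true(all(lens == 10))
  err <- vapply(seq_len(nrow(res$trajectories)), function(k) {
    tt <- mv$truth[mv$truth$frame == res$trajectories$frame[k], ]
    min(sqrt((tt$x_px - res$trajectories$x[k])^2 +
               (tt$y_px - res$trajectories$y[k])^2))
  }, 0)
  expect_lt(sqrt(mean(err^2)), 0.05)
})
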