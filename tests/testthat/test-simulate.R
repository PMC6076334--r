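# Synthetic-data generator: diffusion statistics, confinement, rendering,
# determinism.

test_that("zero-diffusion tracks are stationary and fractions must sum to 1", {
  sim <- simulate_trajectories(5, 20, data.frame(D = 0, fraction = 1), seed = 1)
  for (t_ in split(sim$tracks, sim$tracks$track)) {
    expect_equal(var(t_$x), 0)
    expect_equal(var(t_$y), 0)
  }
  expect_error(
    simulate_trajectories(2, 5, data.frame(D = c(0.1, 0.2),
                                           fraction = c(0.5, 0.4))),
    "sum to 1")
})

test_that("per-state step variance matches the assigned diffusion coefficients", {
  states <- data.frame(D = c(0.16, 0.092, 0.065), fraction = rep(1 / 3, 3))
  cfg <- sim_config(field_size = c(5000, 5000))   # generous field, no clipping
  sim <- simulate_trajectories(450, 101, states, config = cfg, seed = 2)
  dt <- cfg$frame_interval
  per_track <- sim$truth$per_track
  for (s in 1:3) {
    ids <- per_track$track[per_track$state == s]
    tr <- sim$tracks[sim$tracks$track %in% ids, ]
    disp <- step_displacements(tr, lag = 1L)
    expect_gt(nrow(disp), 1e4)
    D_hat <- mean(disp$dr2) / (4 * dt)
    expect_lt(abs(D_hat - states$D[s]) / states$D[s], 0.05)
  }
})

test_that("free-diffusion ensemble MSD matches 4Dt within 3 SE", {
  cfg <- sim_config(field_size = c(5000, 5000))
  D <- 0.1
  sim <- simulate_trajectories(1e4, 4, data.frame(D = D, fraction = 1),
                               config = cfg, seed = 3)
  for (lag in 1:3) {
    by_track <- split(sim$tracks, sim$tracks$track)
    d2 <- vapply(by_track, function(t_) {
      (t_$x[1 + lag] - t_$x[1])^2 + (t_$y[1 + lag] - t_$y[1])^2
    }, 0)
    expect_lt(abs(mean(d2) - 4 * D * lag * cfg$frame_interval),
              3 * sd(d2) / sqrt(length(d2)))
  }
})

test_that("confined tracks stay in the box and the MSD plateaus near C^2/3", {
  C <- 0.264; D <- 0.05
  cfg <- sim_config()
  sim <- simulate_trajectories(2e4, 31, data.frame(D = D, fraction = 1),
                               confinement = C, config = cfg, seed = 4)
  # every track confined to a side-C square around its start
  rng_x <- tapply(sim$tracks$x, sim$tracks$track, function(v) diff(range(v)))
  rng_y <- tapply(sim$tracks$y, sim$tracks$track, function(v) diff(range(v)))
  expect_lte(max(rng_x), C)
  expect_lte(max(rng_y), C)
  # plateau: at lag 30 frames, 12 D t / C^2 >> 1
  plateau <- ensemble_msd(sim$tracks, 30L)
  expect_lt(abs(plateau - C^2 / 3) / (C^2 / 3), 0.03)
})

test_that("renderer inverts noiselessly and is linear in the drawn amplitude", {
  cfg <- sim_config(field_size = c(32, 32), noise_model = "none",
                    monomer_sd = 0)
  tr <- data.frame(track = 1, frame = 0, x = 1.53, y = 1.47, state = 1)
  mv <- render_movie(tr, 1L, cfg, noise = FALSE, seed = 5)
  fit <- fit_spot(mv$stack[, , 1], c(15, 15))
  expect_lt(abs(fit$x - 15.3), 0.01)
  expect_lt(abs(fit$y - 14.7), 0.01)
  expect_lt(abs(fit$I0 - mv$truth$intensity[1]) / mv$truth$intensity[1], 1e-3)

  # linearity: integrated signal above background proportional to n
  tr2 <- data.frame(track = 1:2, frame = 0, x = c(0.8, 2.4), y = c(0.8, 2.4),
                    state = 1)
  mv2 <- render_movie(tr2, c(1L, 3L), cfg, noise = FALSE, seed = 6)
  img <- mv2$stack[, , 1] - cfg$background_offset
  s1 <- sum(img[1:16, 1:16]); s3 <- sum(img[17:32, 17:32])
  expect_lt(abs(s3 / s1 - 3), 0.02)
})

test_that("drawn spot intensities follow the n-mer mixture density", {
  cfg <- sim_config(field_size = c(8, 8), monomer_mean = 1000,
                    monomer_sd = 200)
  n_tracks <- 1e4
  sizes <- sample(1:3, n_tracks, TRUE, c(0.6, 0.3, 0.1))
  tr <- data.frame(track = seq_len(n_tracks), frame = 0, x = 0.4, y = 0.4,
                   state = 1)
  mv <- render_movie(tr, sizes, cfg, noise = FALSE, seed = 7)
  x <- mv$truth$intensity
  breaks <- seq(min(x) - 1, max(x) + 1, length.out = 40)
  obs <- as.numeric(table(cut(x, breaks)))
  mids <- (breaks[-1] + breaks[-length(breaks)]) / 2
  expd <- cluster_density(mids, c(0.6, 0.3, 0.1), 1000, 200) *
    diff(breaks) * n_tracks
  keep <- expd >= 5
  chi2 <- sum((obs[keep] - expd[keep])^2 / expd[keep])
  expect_lt(chi2 / sum(keep), 2)   # close to the analytic mixture
})

test_that("identical seed gives bit-identical movies and stacks", {
  cfg <- sim_config(field_size = c(32, 32))
  sim1 <- simulate_trajectories(5, 8, config = cfg, seed = 8)
  sim2 <- simulate_trajectories(5, 8, config = cfg, seed = 8)
  expect_identical(sim1, sim2)
  m1 <- suppressWarnings(render_movie(sim1$tracks, 1L, cfg, seed = 9))
  m2 <- suppressWarnings(render_movie(sim2$tracks, 1L, cfg, seed = 9))
  expect_identical(m1$stack, m2$stack)
  s1 <- simulate_focus_stack(c(0, 10), 1, 5, size = 32, seed = 10)
  s2 <- simulate_focus_stack(c(0, 10), 1, 5, size = 32, seed = 10)
  expect_identical(s1, s2)
})

test_that("focus stacks have the right image count and in-focus labels", {
  st <- simulate_focus_stack(c(0, 750), 2.5, true_focus = 400, size = 32,
                             noise_sd = 0, seed = 11)
  expect_length(st$images, 300)
  expect_identical(st$labels, as.integer(abs(st$z - 400) <= 4))
  # the sharpest image under the histogram score is the closest to focus
  st2 <- simulate_focus_stack(c(385, 415), 2.5, true_focus = 400, size = 64,
                              noise_sd = 40, seed = 11)
  E <- vapply(st2$images, function(im) {
    half <- im[33:64, , drop = FALSE]
    tryCatch(sharpness_E(half, roi = 11L, smooth = 10L)$E,
             error = function(e) -Inf)
  }, 0)
  expect_equal(st2$z[which.max(E)], st2$z[which.min(abs(st2$z - 400))])
})

test_that("SRIC scenes have exact masks and area bookkeeping", {
  empty <- simulate_sric_scene(0, size = 64, seed = 12)
  expect_equal(sum(empty$mask), 0)
  sc <- simulate_sric_scene(5, size = 160, seed = 13)
  expect_equal(sum(sc$mask), sum(sc$cells$area_px))
  analytic <- sum(pi * sc$cells$a * sc$cells$b)
  expect_lt(abs(sum(sc$mask) - analytic) / analytic, 0.05)
})

test_that("response tables hit the model curve in the noise-free limit", {
  truth <- list(msd_max = 0.06, msd_min = 0.02, ec50 = 6.6, h = 1)
  tab <- simulate_response_tables(c(0, 1, 6.6, 50), truth, sigma = 0,
                                  n_cells = 4, seed = 14)
  expect_equal(tab$cells$msd[tab$cells$L == 0], rep(0.06, 4))
  expect_equal(unique(tab$cells$msd[tab$cells$L == 6.6]),
               hill_msd(6.6, 0.06, 0.02, 6.6, 1))
  # with scatter, the L = 0 condition scatters around msd_max
  tabn <- simulate_response_tables(c(0, 50), truth, sigma = 0.2,
                                   n_cells = 500, seed = 15)
  expect_lt(abs(mean(tabn$cells$msd[tabn$cells$L == 0]) - 0.06) / 0.06, 0.05)
})
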