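# Statistics layer: diffusion estimators, confined MLE, mixtures, AIC,
# pharmacology, residence time, time-course binning.

test_that("step diffusion is zero for stationary tracks and unbiased for Brownian", {
  still <- data.frame(track = rep(1:3, each = 5), frame = rep(0:4, 3),
                      x = 1, y = 2)
  expect_equal(step_diffusion(still)$mean, 0)

  cfg <- sim_config(field_size = c(5000, 5000))
  sim <- simulate_trajectories(1000, 13, data.frame(D = 0.11, fraction = 1),
                               config = cfg, seed = 1)
  sd_res <- step_diffusion(sim$tracks, dt = cfg$frame_interval)
  expect_lt(abs(sd_res$mean - 0.11), 3 * sd_res$se)

  # bias below 1% at ~1e5 displacements
  sim2 <- simulate_trajectories(2000, 52, data.frame(D = 0.11, fraction = 1),
                                config = cfg, seed = 2)
  disp <- step_displacements(sim2$tracks, lag = 2L)
  expect_gt(nrow(disp), 1e5 - 1)
  D_hat <- mean(disp$dr2) / (4 * 2 * cfg$frame_interval)
  expect_lt(abs(D_hat - 0.11) / 0.11, 0.01)
})

test_that("MSD reproduces the stationary, ballistic and Brownian closed forms", {
  still <- data.frame(track = 1, frame = 0:9, x = 3, y = 4)
  expect_true(all(msd(still)$msd == 0))

  # straight-line motion with step s per frame: MSD(n dt) = 2 (n s)^2 in 2-D
  s <- 0.05
  ball <- data.frame(track = 1, frame = 0:20, x = s * (0:20), y = s * (0:20))
  mb <- msd(ball, max_lag = 5L)
  expect_equal(mb$msd, 2 * (mb$lag * s)^2, tolerance = 1e-12)

  cfg <- sim_config(field_size = c(5000, 5000))
  D <- 0.08
  sim <- simulate_trajectories(3000, 16, data.frame(D = D, fraction = 1),
                               config = cfg, seed = 3)
  m <- msd(sim$tracks, dt = cfg$frame_interval, max_lag = 10L)
  per_track <- split(sim$tracks, sim$tracks$track)
  for (lg in c(1L, 5L, 10L)) {
    vals <- unlist(lapply(per_track, function(t_) {
      n <- nrow(t_); i <- seq_len(n - lg)
      (t_$x[i + lg] - t_$x[i])^2 + (t_$y[i + lg] - t_$y[i])^2
    }))
    se <- sd(vals) / sqrt(length(per_track))   # tracks are the free unit
    expect_lt(abs(m$msd[m$lag == lg] - 4 * D * lg * cfg$frame_interval),
              3 * se)
  }
})

test_that("confined-diffusion MLE recovers (D, C) and prefers the log-normal model", {
  d <- simulate_confined_curves(100, D = 0.05, C = 0.264, sigma = 0.2,
                                seed = 4)
  fit <- fit_confined(d, seed = 5)
  expect_lt(abs(fit$D - 0.05) / 0.05, 0.05)
  expect_lt(abs(fit$C - 0.264) / 0.264, 0.05)
  expect_gt(fit$logL_log, fit$logL_norm)      # scatter is log-normal
  expect_identical(fit$model, "lognormal")
  expect_length(fit$sigma, 15L)
  # chosen model always carries the larger likelihood
  expect_gte(max(fit$logL_log, fit$logL_norm),
             if (fit$model == "lognormal") fit$logL_norm else fit$logL_log)
})

test_that("free-diffusion curves drive the confinement fit to the 4Dt regime", {
  tj <- (1:15) / 30
  D <- 0.06
  free <- matrix(rep(4 * D * tj, each = 40), 40, 15) *
    exp(matrix(rnorm(40 * 15, 0, 0.02), 40, 15))
  fit <- fit_confined(free, seed = 6)
  fitted_curve <- confined_msd(tj, fit$D, fit$C)
  expect_lt(max(abs(fitted_curve - 4 * D * tj) / (4 * D * tj)), 0.05)
  expect_gt(fit$C^2 / 3, 4 * D * tail(tj, 1))   # plateau beyond the window
})

test_that("AIC selects the true number of diffusion states", {
  set.seed(7)
  r1 <- sample_displacements(5000, 0.1, 1)
  sel1 <- select_states(r1, seed = 8)
  expect_equal(sel1$n_states, 1L)

  r3 <- sample_displacements(1e4, c(0.01, 0.08, 0.3), c(0.3, 0.4, 0.3))
  sel3 <- select_states(r3, seed = 9)
  expect_equal(sel3$n_states, 3L)
  expect_lt(max(abs(sel3$fractions - c(0.3, 0.4, 0.3))), 0.05)
  expect_lt(max(abs(sel3$D - c(0.01, 0.08, 0.3)) / c(0.01, 0.08, 0.3)), 0.2)
  # the AIC table is the brute-force criterion over N = 1..4
  expect_equal(sel3$aic_table$aic,
               -2 * sel3$aic_table$logL + 2 * (2 * sel3$aic_table$n_states - 1))
  expect_equal(sel3$aic, min(sel3$aic_table$aic))
})

test_that("cluster-size mixture recovers fractions and mean sizes", {
  set.seed(10)
  mono <- rnorm(5000, 1000, 200)
  cm1 <- fit_cluster_sizes(mono, seed = 11)
  expect_gt(cm1$fractions[1, 1], 0.95)
  expect_lt(abs(cm1$mean_size[1] - 1), 0.05)

  x <- sample_cluster_intensities(1e4, c(0.6, 0.3, 0.1), 1000, 200)
  cm <- fit_cluster_sizes(x, seed = 12)
  expect_lt(max(abs(cm$fractions[1, 1:3] - c(0.6, 0.3, 0.1))), 0.05)
  expect_lt(abs(cm$mu - 1000) / 1000, 0.05)

  # pre/post-stimulation mixtures with mean sizes 1.5 and 2.1, global mu/sigma
  pre <- sample_cluster_intensities(5000, c(0.6, 0.3, 0.1), 1000, 200)       # 1.5
  post <- sample_cluster_intensities(5000, c(0.35, 0.35, 0.18, 0.09, 0.03),  # 2.1
                                     1000, 200)
  cm2 <- fit_cluster_sizes(list(pre = pre, post = post), seed = 13)
  expect_lt(abs(cm2$mean_size[1] - 1.5), 0.1)
  expect_lt(abs(cm2$mean_size[2] - 2.1), 0.15)
})

test_that("all mixture fractions sum to one after every fit", {
  set.seed(14)
  for (k in 1:3) {
    r <- sample_displacements(2000, c(0.02, 0.2), c(0.5, 0.5))
    sm <- fit_state_mixture(r, 2, seed = k)
    expect_equal(sum(sm$fractions), 1, tolerance = 1e-12)
    x <- sample_cluster_intensities(2000, c(0.7, 0.3), 900, 150)
    cmk <- fit_cluster_sizes(x, seed = k)
    expect_equal(unname(rowSums(cmk$fractions)), 1, tolerance = 1e-12)
  }
})

test_that("dose-response MLE recovers the Hill parameters", {
  concs <- c(0, 0.06, 0.2, 0.6, 2, 6, 20, 60, 200, 600)
  truth <- list(msd_max = 0.065, msd_min = 0.030, ec50 = 6.6, h = 1.0)

  # noise-free data on the curve: exact recovery, L = 0 pins MSD_max
  exact <- simulate_response_tables(concs, truth, sigma = 0, n_cells = 3,
                                    seed = 15)
  f0 <- fit_dose_response(exact$cells, seed = 16)
  expect_lt(abs(f0$ec50 - 6.6) / 6.6, 0.01)
  expect_lt(abs(f0$h - 1) , 0.01)
  expect_lt(abs(f0$msd_max - 0.065) / 0.065, 0.001)

  # log-normally scattered cells: within the profile CI; log-normal preferred
  tab <- simulate_response_tables(concs, truth, sigma = 0.15, n_cells = 18,
                                  seed = 17)
  fit <- fit_dose_response(tab$cells, seed = 18)
  expect_gt(fit$logL_log, fit$logL_norm)
  ci <- dose_profile_ci(tab$cells, fit, "ec50", n_grid = 21L)
  expect_gte(6.6, ci$lower)
  expect_lte(6.6, ci$upper)
  expect_lt(abs(fit$h - 1), 0.3)

  # replicate median: EC50 within 25%, h within 0.2
  ests <- t(vapply(1:5, function(k) {
    tk <- simulate_response_tables(concs, truth, sigma = 0.15, n_cells = 18,
                                   seed = 20 + k)
    fk <- fit_dose_response(tk$cells, seed = 30 + k)
    c(fk$ec50, fk$h)
  }, c(0, 0)))
  expect_lt(abs(median(ests[, 1]) - 6.6) / 6.6, 0.25)
  expect_lt(abs(median(ests[, 2]) - 1.0), 0.2)

  expect_warning(fit_dose_response(
    data.frame(L = rep(c(0, 1, 10), each = 4),
               msd = rep(0.05, 12) * exp(rnorm(12, 0, 0.01))),
    seed = 19), "flat")
})

test_that("the inhibition surface reduces to its limits and recovers EC50/IC50", {
  # model nesting: [I] = 0 row equals the Hill curve with h = 1
  L <- c(0.5, 2, 8, 30)
  expect_equal(inhibition_msd(L, 0, 0.06, 0.02, 4.7, 2300),
               hill_msd(L, 0.06, 0.02, 4.7, 1))
  # [I] -> infinity restores MSD_max at any ligand level
  expect_equal(inhibition_msd(L, 1e12, 0.06, 0.02, 4.7, 2300),
               rep(0.06, 4), tolerance = 1e-6)

  # recovery at the experimental scale (6x6 grid, 3 cells per condition)
  # over replicate draws: majority CI coverage plus accurate median MLEs
  reps <- get_inhibition_replicates()
  expect_gte(sum(reps$ec_in_ci), 3)
  expect_gte(sum(reps$ic_in_ci), 3)
  expect_lt(abs(median(reps$ec50) - 4.7) / 4.7, 0.25)
  expect_lt(abs(median(reps$ic50) - 2300) / 2300, 0.35)
  expect_lt(abs(median(reps$msd_max) - 0.065) / 0.065, 0.1)
})

test_that("residence time averages track durations", {
  traj <- data.frame(track = rep(1:4, each = 10), frame = rep(0:9, 4),
                     x = 0, y = 0)
  rt <- residence_time(traj)
  expect_equal(rt$mean, 9 * 0.033)

  set.seed(22)
  lens <- pmax(2, rgeom(2000, 0.033 / 0.5) + 1)   # mean duration ~0.5 s
  tg <- do.call(rbind, lapply(seq_along(lens), function(i)
    data.frame(track = i, frame = seq_len(lens[i]) - 1, x = 0, y = 0)))
  rtg <- residence_time(tg)
  expect_lt(abs(rtg$mean - mean((lens - 1) * 0.033)), 1e-12)
  expect_lt(abs(rtg$mean - 0.5), 3 * rtg$se + 0.05)
})

test_that("time-course bins are stable under stationarity and localize a change", {
  cfg <- sim_config(field_size = c(5000, 5000))
  mk_seg <- function(D, t0, n, seed) {
    sim <- simulate_trajectories(n, 10, data.frame(D = D, fraction = 1),
                                 config = cfg, seed = seed)
    sim$tracks$time <- t0 + sim$tracks$frame * cfg$frame_interval
    sim$tracks$track <- paste0(seed, "_", sim$tracks$track)
    sim$tracks
  }
  # stationary: three 40-s bins of identical dynamics
  stat <- do.call(rbind, lapply(0:2, function(b)
    mk_seg(0.1, b * 40 + 1, 150, 100 + b)))
  tc <- timecourse(stat, what = "msd", stim_time = 0)
  expect_equal(nrow(tc), 3L)
  expect_lt(diff(range(tc$msd_66ms)) / mean(tc$msd_66ms), 0.2)

  # step change at t = 80 s: slower diffusion from bin 2 onwards
  step <- rbind(mk_seg(0.1, 1, 150, 200), mk_seg(0.1, 41, 150, 201),
                mk_seg(0.02, 81, 150, 202))
  tcs <- timecourse(step, what = "msd", stim_time = 80)
  expect_equal(tcs$baseline, c(TRUE, TRUE, FALSE))
  expect_lt(tcs$msd_66ms[3], 0.5 * tcs$msd_66ms[2])
  drop_bin <- which.max(-diff(tcs$msd_66ms))
  expect_equal(tcs$bin[drop_bin + 1L], 2)
})
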