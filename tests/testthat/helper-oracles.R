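# Independent oracles used across test files.

# Double-loop Pearson cross-correlation, the direct transcription of the
# normalized-correlation definition.
brute_force_correlation <- function(image, template) {
  R <- (nrow(template) - 1L) %/% 2L
  H <- nrow(image); W <- ncol(image)
  out <- matrix(NA_real_, H, W)
  tave <- mean(template)
  for (i in (R + 1L):(H - R)) for (j in (R + 1L):(W - R)) {
    win <- image[(i - R):(i + R), (j - R):(j + R)]
    xave <- mean(win)
    num <- sum((template - tave) * (win - xave))
    den <- sqrt(sum((template - tave)^2)) * sqrt(sum((win - xave)^2))
    out[i, j] <- if (den > 0) num / den else 0
  }
  out
}

# Exhaustive Otsu: scan every candidate split level of an integer image.
brute_force_otsu <- function(img) {
  vals <- as.numeric(img)
  best <- -Inf; bt <- NA
  for (t in seq(min(vals), max(vals) - 1L)) {
    lo <- vals[vals <= t]; hi <- vals[vals > t]
    if (!length(lo) || !length(hi)) next
    w0 <- length(lo) / length(vals)
    bc <- w0 * (1 - w0) * (mean(lo) - mean(hi))^2
    if (bc > best) { best <- bc; bt <- t }
  }
  bt + 0.5
}

# Ensemble MSD computed directly from the first frame of every track.
ensemble_msd <- function(tracks, lag) {
  by_track <- split(tracks, tracks$track)
  d2 <- vapply(by_track, function(t_) {
    t_ <- t_[order(t_$frame), ]
    if (nrow(t_) <= lag) return(NA_real_)
    (t_$x[1 + lag] - t_$x[1])^2 + (t_$y[1 + lag] - t_$y[1])^2
  }, 0)
  mean(d2, na.rm = TRUE)
}

# Rayleigh-mixture displacement sampler (r^2 exponential within each state).
sample_displacements <- function(n, D, fractions, dt = 0.066) {
  st <- sample(seq_along(D), n, TRUE, fractions)
  sqrt(-4 * D[st] * dt * log(runif(n)))
}

# Oligomer intensity sampler for the cluster-size mixture.
sample_cluster_intensities <- function(n, fractions, mu, sigma) {
  k <- sample(seq_along(fractions), n, TRUE, fractions)
  rnorm(n, k * mu, sqrt(k) * sigma)
}

# A small noiseless movie with well-separated slow emitters plus its truth.
noiseless_test_movie <- function(n = 5, n_frames = 10, seed = 1) {
  cfg <- sim_config(field_size = c(64, 64), noise_model = "none",
                    monomer_sd = 0)
  set.seed(seed)
  tr <- do.call(rbind, lapply(seq_len(n), function(i) {
    x0 <- (10 + (i - 1) %% 3 * 18) * 0.1
    y0 <- (10 + (i - 1) %/% 3 * 25) * 0.1
    s <- simulate_trajectories(1, n_frames, data.frame(D = 0.02, fraction = 1),
                               config = cfg, seed = 50 + seed * 100 + i)$tracks
    s$track <- i
    s$x <- s$x - s$x[1] + x0
    s$y <- s$y - s$y[1] + y0
    s
  }))
  mv <- render_movie(tr, 1L, cfg, noise = FALSE, seed = seed)
  list(stack = mv$stack, truth = mv$truth, tracks = tr, config = cfg)
}
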