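# Finite-mixture MLEs: diffusion-state mixtures on single-frame-pair
# displacements (AIC-selected state count) and oligomer-size mixtures on
# first-frame intensities.

#' Displacement density of an N-state diffusion mixture
#'
#' `P(r) = sum_n C_n r / (2 D_n dt) exp(-r^2 / (4 D_n dt))`: each state
#' contributes a Rayleigh-type displacement density at lag `dt`.
#'
#' @param r displacement (um).
#' @param fractions state fractions (sum 1).
#' @param D state diffusion coefficients (um^2/s).
#' @param dt displacement lag (s, default 0.066).
#' @return density values.
#' @export
displacement_density <- function(r, fractions, D, dt = 0.066) {
  out <- 0
  for (n in seq_along(D))
    out <- out + fractions[n] * r / (2 * D[n] * dt) * exp(-r^2 / (4 * D[n] * dt))
  out
}

#' Fit an N-state diffusion mixture to displacements
#'
#' Maximum likelihood via expectation--maximization: squared displacements
#' are exponentially distributed with mean `4 D_n dt` within each state, so
#' both EM steps are closed-form. Several seeded restarts guard against
#' local maxima; states whose diffusion coefficients collapse onto each
#' other (relative difference < 1e-6) are merged with a warning. The AIC is
#' `-2 logL + 2k` with `k = 2N - 1` free parameters.
#'
#' @param r displacements (um) at lag `dt`.
#' @param n_states number of states N.
#' @param dt displacement lag (s, default 0.066).
#' @param n_restarts EM restarts.
#' @param tol convergence tolerance on the log-likelihood.
#' @param max_iter EM iteration cap.
#' @param seed RNG seed.
#' @return object of class `state_model`: `fractions`, `D` (ascending),
#'   `n_states`, `logL`, `aic`, `k`, `n`.
#' @export
fit_state_mixture <- function(r, n_states, dt = 0.066, n_restarts = 5L,
                              tol = 1e-8, max_iter = 500L, seed = 1L) {
  r <- r[is.finite(r) & r > 0]
  if (length(r) < n_states * 2L) stopf("too few displacements for %d states", n_states)
  s <- r^2
  mean_s <- mean(s)
  if (!is.null(seed)) set.seed(seed)

  run_em <- function(mu0) {                # mu = 4 D dt per state
    K <- length(mu0)
    w <- rep(1 / K, K); mu <- mu0
    ll_old <- -Inf
    for (it in seq_len(max_iter)) {
      dens <- vapply(seq_len(K), function(k) w[k] / mu[k] * exp(-s / mu[k]),
                     numeric(length(s)))
      tot <- rowSums(dens)
      tot[tot < 1e-300] <- 1e-300
      ll <- sum(log(tot))
      resp <- dens / tot
      nk <- colSums(resp)
      w <- nk / length(s)
      mu <- pmax(colSums(resp * s) / pmax(nk, 1e-12), 1e-12)
      if (abs(ll - ll_old) < tol) break
      ll_old <- ll
    }
    list(w = w, mu = mu, ll = ll)
  }

  # quantile-spread starts plus randomized restarts
  best <- NULL
  for (rs in seq_len(n_restarts)) {
    mu0 <- if (rs == 1L) {
      quantile(s, probs = (seq_len(n_states) - 0.5) / n_states, names = FALSE)
    } else {
      mean_s * exp(runif(n_states, -2, 2))
    }
    mu0 <- pmax(sort(mu0), 1e-12)
    fit <- run_em(mu0)
    if (is.null(best) || fit$ll > best$ll) best <- fit
  }

  ord <- order(best$mu)
  D <- best$mu[ord] / (4 * dt)
  fractions <- best$w[ord]
  # merge states that collapsed onto the same D
  if (n_states > 1L) {
    rel <- diff(D) / pmax(D[-length(D)], 1e-300)
    if (any(rel < 1e-6)) {
      warning("degenerate states merged (identical diffusion coefficients)")
      keep <- c(TRUE, rel >= 1e-6)
      grp <- cumsum(keep)
      fractions <- as.numeric(tapply(fractions, grp, sum))
      D <- as.numeric(tapply(D, grp, function(v) v[1]))
    }
  }
  fractions <- fractions / sum(fractions)
  # logL in displacement space (Jacobian 2r from the squared-displacement
  # representation) -- this is the quantity entering the AIC
  ll_r <- sum(log(pmax(displacement_density(r, fractions, D, dt), 1e-300)))
  k <- 2L * length(D) - 1L
  structure(list(fractions = fractions, D = D, n_states = length(D),
                 logL = ll_r, aic = -2 * ll_r + 2 * k, k = k,
                 n = length(r), dt = dt),
            class = "state_model")
}

#' Select the number of diffusion states by AIC
#'
#' Fits the mixture for `N = 1..n_max` and adopts the model with the
#' smallest AIC.
#'
#' @inheritParams fit_state_mixture
#' @param n_max largest candidate state count (default 4).
#' @return the winning `state_model`, with an `aic_table` element
#'   (data.frame `n_states, logL, aic`).
#' @export
select_states <- function(r, dt = 0.066, n_max = 4L, n_restarts = 5L,
                          seed = 1L) {
  models <- lapply(seq_len(n_max), function(N)
    suppressWarnings(fit_state_mixture(r, N, dt = dt, n_restarts = n_restarts,
                                       seed = seed + N)))
  aic <- vapply(models, `[[`, 0, "aic")
  best <- models[[which.min(aic)]]
  best$aic_table <- data.frame(
    n_states = vapply(models, `[[`, 0L, "n_states"),
    logL = vapply(models, `[[`, 0, "logL"), aic = aic)
  best
}

#' @export
print.state_model <- function(x, ...) {
  cat(sprintf("<state_model> N = %d (AIC %.1f, n = %d)\n", x$n_states, x$aic, x$n))
  for (i in seq_along(x$D))
    cat(sprintf("  state %d: D = %.4f um^2/s, fraction %.3f\n", i, x$D[i], x$fractions[i]))
  invisible(x)
}

#' Oligomer-size (cluster) intensity mixture density
#'
#' `P(x) = sum_n C_n / (sqrt(2 pi n) sigma) exp(-(x - n mu)^2 / (2 n
#' sigma^2))`: the n-mer intensity is normal with mean `n mu` and variance
#' `n sigma^2`.
#'
#' @param x intensities (a.u.).
#' @param fractions n-mer fractions (sum 1), `fractions[n]` for size n.
#' @param mu,sigma monomer intensity mean and SD.
#' @return density values.
#' @export
cluster_density <- function(x, fractions, mu, sigma) {
  out <- 0
  for (n in seq_along(fractions))
    out <- out + fractions[n] * dnorm(x, n * mu, sqrt(n) * sigma)
  out
}

#' Fit the oligomer-size mixture to first-frame intensities
#'
#' Maximum likelihood via EM for the joint model over all conditions:
#' monomer `mu` and `sigma` are global, the size fractions `C_1..C_N` are
#' per condition, `N` capped at `n_max` (default 10). Closed-form M-steps:
#' `mu = sum(w x) / sum(w n)`, `sigma^2 = sum(w (x - n mu)^2 / n) / sum(w)`.
#'
#' @param intensities numeric vector, or a named list of vectors (one per
#'   condition).
#' @param n_max maximum cluster size (default 10).
#' @param mu0,sigma0 optional starting values (default: mode-based guess).
#' @param n_restarts randomized restarts around the start.
#' @param tol,max_iter EM controls.
#' @param seed RNG seed.
#' @return object of class `cluster_model`: `mu`, `sigma`, `fractions`
#'   (matrix, conditions x sizes), `mean_size` (per condition,
#'   `sum(n C_n)`), `logL`, `n` per condition. A warning is attached when
#'   any condition has fewer than 100 spots.
#' @export
fit_cluster_sizes <- function(intensities, n_max = 10L, mu0 = NULL,
                              sigma0 = NULL, n_restarts = 3L, tol = 1e-8,
                              max_iter = 500L, seed = 1L) {
  if (!is.list(intensities)) intensities <- list(all = intensities)
  intensities <- lapply(intensities, function(v) v[is.finite(v) & v > 0])
  ns <- vapply(intensities, length, 0L)
  if (any(ns == 0L)) stopf("empty intensity vector")
  if (any(ns < 100L))
    warning("fewer than 100 spots in some condition: expect wide confidence intervals")
  if (!is.null(seed)) set.seed(seed)
  x_all <- unlist(intensities, use.names = FALSE)
  if (is.null(mu0)) {
    dd <- density(x_all)
    mu0 <- dd$x[which.max(dd$y)]       # dominant (usually monomer) peak
    if (mu0 <= 0) mu0 <- median(x_all)
  }
  if (is.null(sigma0)) sigma0 <- max(mu0 / 4, 1e-6)
  sizes <- seq_len(n_max)

  run_em <- function(mu, sigma) {
    K <- length(intensities)
    frac <- matrix(1 / n_max, K, n_max)
    ll_old <- -Inf; ll <- -Inf
    for (it in seq_len(max_iter)) {
      ll <- 0
      sxw <- 0; snw <- 0; svw <- 0; sw <- 0
      new_frac <- frac
      for (k in seq_len(K)) {
        x <- intensities[[k]]
        dens <- vapply(sizes, function(n)
          frac[k, n] * dnorm(x, n * mu, sqrt(n) * sigma), numeric(length(x)))
        tot <- rowSums(dens)
        tot[tot < 1e-300] <- 1e-300
        ll <- ll + sum(log(tot))
        resp <- dens / tot
        rk <- colSums(resp)
        new_frac[k, ] <- rk / length(x)
        # weighted sums for the global mu / sigma updates
        sxw <- sxw + sum(resp * x)            # x recycles down columns
        snw <- snw + sum(rk * sizes)
        svw <- svw + sum(resp * sweep((outer(x, sizes * mu, "-"))^2, 2, sizes, "/"))
        sw <- sw + sum(resp)
      }
      frac <- new_frac
      mu <- max(sxw / max(snw, 1e-12), 1e-12)
      sigma <- sqrt(max(svw / max(sw, 1e-12), 1e-16))
      if (abs(ll - ll_old) < tol) break
      ll_old <- ll
    }
    list(mu = mu, sigma = sigma, frac = frac, ll = ll)
  }

  best <- NULL
  for (rs in seq_len(n_restarts)) {
    m0 <- if (rs == 1L) mu0 else mu0 * exp(runif(1, -0.2, 0.2))
    s0 <- if (rs == 1L) sigma0 else sigma0 * exp(runif(1, -0.2, 0.2))
    fit <- run_em(m0, s0)
    # the model has a near-exact mu -> mu/2 relabelling degeneracy (every
    # n-mer re-expressed as a 2n-mer); on likelihood ties keep the larger mu
    if (is.null(best) || fit$ll > best$ll + 1e-6 ||
        (fit$ll > best$ll - 1e-6 && fit$mu > best$mu)) best <- fit
  }
  frac <- best$frac
  frac <- frac / rowSums(frac)
  rownames(frac) <- names(intensities)
  colnames(frac) <- paste0("n", sizes)
  structure(list(mu = best$mu, sigma = best$sigma, fractions = frac,
                 mean_size = as.numeric(frac %*% sizes),
                 logL = best$ll, n = ns, n_max = n_max),
            class = "cluster_model")
}

#' @export
print.cluster_model <- function(x, ...) {
  cat(sprintf("<cluster_model> mu = %.1f, sigma = %.1f (N <= %d)\n",
              x$mu, x$sigma, x$n_max))
  for (k in seq_len(nrow(x$fractions)))
    cat(sprintf("  %s: mean size %.2f (monomer %.2f, dimer %.2f, >dimer %.2f)\n",
                rownames(x$fractions)[k], x$mean_size[k],
                x$fractions[k, 1], x$fractions[k, 2],
                sum(x$fractions[k, -(1:2)])))
  invisible(x)
}
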