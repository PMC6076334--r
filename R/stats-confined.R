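# Confined-diffusion MLE: MSD saturation model fitted across cells under a
# normal or log-normal cell-to-cell error model, per-lag scales profiled out.

#' Confined-diffusion MSD model
#'
#' `MSD(t) = (C^2 / 3) (1 - exp(-12 D t / C^2))`: initial slope `4 D t`,
#' plateau `C^2 / 3` for a square confinement domain of side `C`.
#'
#' @param t lag times (s).
#' @param D diffusion coefficient (um^2/s).
#' @param C confinement length (um).
#' @return model MSD values (um^2).
#' @export
confined_msd <- function(t, D, C) {
  (C^2 / 3) * (1 - exp(-12 * D * t / C^2))
}

# Profiled log-likelihood terms at fixed model curve m (length J) for the
# cell x lag matrix d [N x J]. Scales sigma_j maximized out in closed form.
confined_loglik_norm <- function(d, m) {
  N <- nrow(d)
  r2 <- colMeans((d - matrix(m, N, length(m), byrow = TRUE))^2)
  sig2 <- pmax(r2, 1e-12)
  sum(-N / 2 * log(2 * pi) - N / 2 * log(sig2) - N / 2)
}

confined_loglik_log <- function(d, m) {
  N <- nrow(d)
  e <- log(d) - matrix(log(m), N, length(m), byrow = TRUE)
  A <- colMeans(e^2)
  # stationary point of the profiled log-normal likelihood with the
  # -sigma^2/2 median shift: sigma_j^2 = 2 (sqrt(1 + mean(e^2)) - 1)
  sig2 <- pmax(2 * (sqrt(1 + A) - 1), 1e-12)
  B <- colMeans(e)
  per_lag <- -N / 2 * log(2 * pi) - N / 2 * log(sig2) -
    N * (A / (2 * sig2) + B / 2 + sig2 / 8)
  sum(per_lag) - sum(log(d))
}

confined_sigma <- function(d, m, model) {
  N <- nrow(d)
  if (model == "normal") {
    sqrt(pmax(colMeans((d - matrix(m, N, length(m), byrow = TRUE))^2), 1e-12))
  } else {
    e <- log(d) - matrix(log(m), N, length(m), byrow = TRUE)
    sqrt(pmax(2 * (sqrt(1 + colMeans(e^2)) - 1), 1e-12))
  }
}

#' Fit the confined-diffusion model across cells by maximum likelihood
#'
#' Fits `(D, C)` plus one scale per lag to the per-cell MSD curves under both
#' a normal and a log-normal error model (the log-normal uses the median
#' convention `log d ~ N(log MSD - sigma^2/2, sigma^2)` so that the mean of
#' `d` is the model MSD). Per-lag scales are profiled out in closed form;
#' `(D, C)` are optimized from several starting points. The model with the
#' larger log-likelihood is adopted.
#'
#' @param d matrix of per-cell MSD values, cells in rows, lags `1..J` in
#'   columns (um^2); or a data.frame from [msd_by_cell()] (reshaped
#'   internally, requiring a complete cell x lag grid).
#' @param dt frame interval (s); lag `j` is at time `j * dt`.
#' @param n_restarts random restarts around the moment-based start.
#' @param seed seed for the restarts.
#' @return object of class `confined_fit`: list with `D`, `C`, `sigma`,
#'   `model` (`"normal"` or `"lognormal"`), `logL_norm`, `logL_log`,
#'   `normal` and `lognormal` (each `D, C, sigma, logL`), `converged`.
#' @export
fit_confined <- function(d, dt = 1 / 30, n_restarts = 5L, seed = 1L) {
  if (is.data.frame(d)) {
    cells <- sort(unique(d$cell)); lags <- sort(unique(d$lag))
    m_ <- matrix(NA_real_, length(cells), length(lags))
    for (i in seq_len(nrow(d)))
      m_[match(d$cell[i], cells), match(d$lag[i], lags)] <- d$msd[i]
    if (anyNA(m_)) stopf("per-cell MSD table has missing cell x lag entries")
    d <- m_
  }
  if (nrow(d) < 2L) stopf("need at least 2 cells")
  J <- ncol(d)
  tj <- seq_len(J) * dt
  mean_curve <- colMeans(d)

  # moment starts: D from the first lag, C from the plateau
  D0 <- max(mean_curve[1] / (4 * tj[1]), 1e-6)
  C0 <- max(sqrt(3 * max(mean_curve)), 1e-4)
  if (!is.null(seed)) set.seed(seed)
  starts <- rbind(c(log(D0), log(C0)),
                  matrix(c(log(D0), log(C0)), n_restarts, 2, byrow = TRUE) +
                    matrix(rnorm(2 * n_restarts, 0, 0.5), n_restarts, 2))

  fit_one <- function(loglik_fn) {
    obj <- function(p) {
      m <- confined_msd(tj, exp(p[1]), exp(p[2]))
      if (any(m <= 0)) return(1e10)
      -loglik_fn(d, m)
    }
    best <- NULL
    for (s in seq_len(nrow(starts))) {
      o <- tryCatch(optim(starts[s, ], obj, method = "Nelder-Mead",
                          control = list(maxit = 2000, reltol = 1e-12)),
                    error = function(e) NULL)
      if (!is.null(o) && (is.null(best) || o$value < best$value)) best <- o
    }
    if (is.null(best)) return(NULL)
    ref <- tryCatch(optim(best$par, obj, method = "BFGS",
                          control = list(maxit = 500, reltol = 1e-10)),
                    error = function(e) NULL)
    if (!is.null(ref) && ref$value < best$value) best <- ref
    best
  }

  on <- fit_one(confined_loglik_norm)
  ol <- fit_one(confined_loglik_log)
  if (is.null(on) || is.null(ol)) stopf("confined fit did not converge")
  pn <- exp(on$par); pl <- exp(ol$par)
  mn <- confined_msd(tj, pn[1], pn[2]); ml <- confined_msd(tj, pl[1], pl[2])
  normal <- list(D = pn[1], C = pn[2],
                 sigma = confined_sigma(d, mn, "normal"), logL = -on$value)
  lognormal <- list(D = pl[1], C = pl[2],
                    sigma = confined_sigma(d, ml, "lognormal"), logL = -ol$value)
  use_log <- lognormal$logL > normal$logL
  chosen <- if (use_log) lognormal else normal
  structure(list(D = chosen$D, C = chosen$C, sigma = chosen$sigma,
                 model = if (use_log) "lognormal" else "normal",
                 logL_norm = normal$logL, logL_log = lognormal$logL,
                 normal = normal, lognormal = lognormal,
                 t = tj, n_cells = nrow(d), converged = TRUE),
            class = "confined_fit")
}

#' @export
print.confined_fit <- function(x, ...) {
  cat(sprintf("<confined_fit> D = %.4f um^2/s, C = %.4f um (%s error model; logL norm %.2f / log %.2f; %d cells)\n",
              x$D, x$C, x$model, x$logL_norm, x$logL_log, x$n_cells))
  invisible(x)
}

#' Simulate per-cell MSD curves from the confined model
#'
#' Generator counterpart of [fit_confined()]: each cell's curve is the model
#' MSD with multiplicative log-normal scatter (median convention).
#'
#' @param n_cells number of cells.
#' @param D,C model parameters.
#' @param sigma per-lag log-normal scale (recycled over lags).
#' @param dt frame interval (s).
#' @param n_lags number of lags (default 15).
#' @param seed RNG seed.
#' @return matrix `[n_cells, n_lags]` of per-cell MSD values.
#' @export
simulate_confined_curves <- function(n_cells, D, C, sigma = 0.2, dt = 1 / 30,
                                     n_lags = 15L, seed = 1L) {
  if (!is.null(seed)) set.seed(seed)
  tj <- seq_len(n_lags) * dt
  m <- confined_msd(tj, D, C)
  sigma <- rep_len(sigma, n_lags)
  d <- matrix(0, n_cells, n_lags)
  for (j in seq_len(n_lags))
    d[, j] <- exp(rnorm(n_cells, log(m[j]) - sigma[j]^2 / 2, sigma[j]))
  d
}
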