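# Dose-response pharmacology by maximum likelihood: Hill EC50 fit and
# noncompetitive-inhibition EC50/IC50 fit on per-cell MSD values, with one
# nuisance scale per condition (profiled out) under both a normal and a
# log-normal error model.

# Profiled log-likelihood of per-cell values d grouped by condition, given
# the model value m per condition. Returns the total logL.
grouped_loglik <- function(d, cond, m_by_cond, model) {
  ll <- 0
  for (k in seq_along(m_by_cond)) {
    dk <- d[cond == k]
    m <- m_by_cond[k]
    N <- length(dk)
    if (N == 0L) next
    if (m <= 0) return(-Inf)
    if (model == "normal") {
      s2 <- max(mean((dk - m)^2), 1e-12)
      ll <- ll + (-N / 2 * log(2 * pi) - N / 2 * log(s2) - N / 2)
    } else {
      e <- log(dk) - log(m)
      A <- mean(e^2); B <- mean(e)
      s2 <- max(2 * (sqrt(1 + A) - 1), 1e-12)
      ll <- ll + (-N / 2 * log(2 * pi) - N / 2 * log(s2) -
                    N * (A / (2 * s2) + B / 2 + s2 / 8)) - sum(log(dk))
    }
  }
  ll
}

grouped_sigma <- function(d, cond, m_by_cond, model) {
  vapply(seq_along(m_by_cond), function(k) {
    dk <- d[cond == k]; m <- m_by_cond[k]
    if (model == "normal") sqrt(max(mean((dk - m)^2), 1e-12))
    else sqrt(max(2 * (sqrt(1 + mean((log(dk) - log(m))^2)) - 1), 1e-12))
  }, 0)
}

dose_optimize <- function(d, cond, model_fn, theta0, model, n_restarts, seed) {
  obj <- function(theta) {
    m <- model_fn(theta)
    if (any(!is.finite(m)) || any(m <= 0)) return(1e10)
    -grouped_loglik(d, cond, m, model)
  }
  if (!is.null(seed)) set.seed(seed)
  best <- NULL
  starts <- rbind(theta0,
                  matrix(theta0, n_restarts, length(theta0), byrow = TRUE) +
                    matrix(rnorm(n_restarts * length(theta0), 0, 0.4),
                           n_restarts, length(theta0)))
  for (s in seq_len(nrow(starts))) {
    o <- tryCatch(optim(starts[s, ], obj, method = "Nelder-Mead",
                        control = list(maxit = 5000, reltol = 1e-12)),
                  error = function(e) NULL)
    if (!is.null(o) && (is.null(best) || o$value < best$value)) best <- o
  }
  if (is.null(best)) return(NULL)
  ref <- tryCatch(optim(best$par, obj, method = "BFGS",
                        control = list(maxit = 1000, reltol = 1e-10)),
                  error = function(e) NULL)
  if (!is.null(ref) && ref$value < best$value) best <- ref
  best
}

#' Fit the Hill dose-response curve to per-cell MSD values
#'
#' Maximum-likelihood fit of [hill_msd()] (parameters `MSD_max >= MSD_min`,
#' `EC50 > 0`, Hill `h > 0`) with one nuisance scale per concentration,
#' under both a normal and a log-normal error model (median convention,
#' scales profiled out); the model with the larger log-likelihood is
#' adopted.
#'
#' @param cells data.frame with columns `L` (concentration, nM) and `msd`
#'   (per-cell MSD value, um^2); one row per cell.
#' @param n_restarts randomized restarts.
#' @param seed RNG seed.
#' @return object of class `dose_fit`: `msd_max`, `msd_min`, `ec50`, `h`,
#'   `sigma` (named per condition), `model`, `logL_norm`, `logL_log`,
#'   `normal`/`lognormal` sub-fits, `flat` (TRUE with a warning when the
#'   response shows no transition and EC50 is unidentifiable).
#' @export
fit_dose_response <- function(cells, n_restarts = 5L, seed = 1L) {
  stopifnot(all(c("L", "msd") %in% names(cells)))
  if (length(unique(cells$L)) < 3L) stopf("need >= 3 concentrations")
  levs <- sort(unique(cells$L))
  cond <- match(cells$L, levs)
  d <- cells$msd
  means <- vapply(seq_along(levs), function(k) mean(d[cond == k]), 0)

  hi <- means[1]; lo <- means[length(means)]
  flat <- (hi - lo) < 0.05 * max(means)
  if (flat) warning("dose-response is flat: EC50 is unidentifiable")
  span0 <- max(hi - lo, 0.05 * max(means))
  pos <- levs[levs > 0]
  ec0 <- if (length(pos)) exp(mean(log(range(pos)))) else 1
  # theta = (log msd_min, log span, log ec50, log h)
  theta0 <- c(log(max(lo, 1e-4)), log(span0), log(ec0), 0)
  model_fn <- function(theta)
    hill_msd(levs, exp(theta[1]) + exp(theta[2]), exp(theta[1]),
             exp(theta[3]), exp(theta[4]))

  fits <- lapply(c("normal", "lognormal"), function(md) {
    o <- dose_optimize(d, cond, model_fn, theta0, md, n_restarts, seed)
    if (is.null(o)) return(NULL)
    th <- o$par
    m <- model_fn(th)
    list(msd_min = exp(th[1]), msd_max = exp(th[1]) + exp(th[2]),
         ec50 = exp(th[3]), h = exp(th[4]), logL = -o$value,
         sigma = setNames(grouped_sigma(d, cond, m, md), paste0("L", levs)))
  })
  if (any(vapply(fits, is.null, TRUE))) stopf("dose-response fit failed")
  names(fits) <- c("normal", "lognormal")
  use_log <- fits$lognormal$logL > fits$normal$logL
  ch <- if (use_log) fits$lognormal else fits$normal
  structure(c(ch[c("msd_max", "msd_min", "ec50", "h", "sigma")],
              list(model = if (use_log) "lognormal" else "normal",
                   logL_norm = fits$normal$logL,
                   logL_log = fits$lognormal$logL,
                   normal = fits$normal, lognormal = fits$lognormal,
                   concentrations = levs, flat = flat,
                   n_cells = nrow(cells))),
            class = "dose_fit")
}

#' @export
print.dose_fit <- function(x, ...) {
  cat(sprintf("<dose_fit> EC50 = %.3g nM, h = %.3g, MSD %.4g -> %.4g um^2 (%s model)\n",
              x$ec50, x$h, x$msd_max, x$msd_min, x$model))
  invisible(x)
}

#' Fit the noncompetitive-inhibition surface to per-cell MSD values
#'
#' Maximum-likelihood fit of [inhibition_msd()] over a ligand x inhibitor
#' concentration grid (parameters `MSD_max >= MSD_min`, `EC50`, `IC50`),
#' one nuisance scale per `(L, I)` condition, both error models, larger
#' log-likelihood adopted. With `[I] = 0` the model reduces to the Hill
#' curve with `h = 1`.
#'
#' @param cells data.frame with columns `L`, `I` (nM) and `msd` (um^2).
#' @inheritParams fit_dose_response
#' @return object of class `inhibition_fit` with `msd_max`, `msd_min`,
#'   `ec50`, `ic50`, `sigma`, `model`, `logL_norm`, `logL_log`, sub-fits.
#' @export
fit_inhibition <- function(cells, n_restarts = 5L, seed = 1L) {
  stopifnot(all(c("L", "I", "msd") %in% names(cells)))
  if (length(unique(cells$L)) < 2L || length(unique(cells$I)) < 2L)
    stopf("need >= 2 ligand and >= 2 inhibitor levels")
  key <- paste(cells$L, cells$I, sep = "_")
  levs <- unique(data.frame(L = cells$L, I = cells$I, key = key))
  cond <- match(key, levs$key)
  d <- cells$msd
  means <- vapply(seq_len(nrow(levs)), function(k) mean(d[cond == k]), 0)

  hi <- max(means); lo <- min(means)
  span0 <- max(hi - lo, 0.05 * hi)
  posL <- unique(cells$L[cells$L > 0]); posI <- unique(cells$I[cells$I > 0])
  ec0 <- exp(mean(log(range(posL))))
  ic0 <- if (length(posI)) exp(mean(log(range(posI)))) else 1
  theta0 <- c(log(max(lo, 1e-4)), log(span0), log(ec0), log(ic0))
  model_fn <- function(theta)
    inhibition_msd(levs$L, levs$I, exp(theta[1]) + exp(theta[2]),
                   exp(theta[1]), exp(theta[3]), exp(theta[4]))

  fits <- lapply(c("normal", "lognormal"), function(md) {
    o <- dose_optimize(d, cond, model_fn, theta0, md, n_restarts, seed)
    if (is.null(o)) return(NULL)
    th <- o$par
    m <- model_fn(th)
    list(msd_min = exp(th[1]), msd_max = exp(th[1]) + exp(th[2]),
         ec50 = exp(th[3]), ic50 = exp(th[4]), logL = -o$value,
         sigma = setNames(grouped_sigma(d, cond, m, md), levs$key))
  })
  if (any(vapply(fits, is.null, TRUE))) stopf("inhibition fit failed")
  names(fits) <- c("normal", "lognormal")
  use_log <- fits$lognormal$logL > fits$normal$logL
  ch <- if (use_log) fits$lognormal else fits$normal
  structure(c(ch[c("msd_max", "msd_min", "ec50", "ic50", "sigma")],
              list(model = if (use_log) "lognormal" else "normal",
                   logL_norm = fits$normal$logL,
                   logL_log = fits$lognormal$logL,
                   normal = fits$normal, lognormal = fits$lognormal,
                   conditions = levs[, c("L", "I")], n_cells = nrow(cells))),
            class = "inhibition_fit")
}

#' @export
print.inhibition_fit <- function(x, ...) {
  cat(sprintf("<inhibition_fit> EC50 = %.3g nM, IC50 = %.3g nM, MSD %.4g -> %.4g um^2 (%s model)\n",
              x$ec50, x$ic50, x$msd_max, x$msd_min, x$model))
  invisible(x)
}
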