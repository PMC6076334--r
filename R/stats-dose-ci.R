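# Profile-likelihood confidence intervals for the dose-response parameters.

#' Profile-likelihood confidence interval for EC50 / IC50 / Hill h
#'
#' Scans the named parameter on a log grid around its MLE, re-maximizing the
#' remaining structural parameters at each value (nuisance scales stay
#' profiled in closed form), and returns the interval where the profile
#' log-likelihood stays within `qchisq(level, 1) / 2` of its maximum.
#'
#' @param cells the per-cell table given to [fit_dose_response()] or
#'   [fit_inhibition()].
#' @param fit the corresponding fit object.
#' @param param `"ec50"`, `"ic50"` or `"h"`.
#' @param level confidence level (default 0.95).
#' @param span half-width of the scanned range in log10 units (default 2).
#' @param n_grid grid points.
#' @return list `lower`, `upper`, `estimate`, `level` (bounds may be
#'   infinite when the profile never drops below the cutoff inside the
#'   scanned range).
#' @export
dose_profile_ci <- function(cells, fit, param = c("ec50", "ic50", "h"),
                            level = 0.95, span = 2, n_grid = 41L) {
  param <- match.arg(param)
  two_drug <- inherits(fit, "inhibition_fit")
  if (param == "ic50" && !two_drug) stopf("ic50 requires an inhibition fit")
  if (param == "h" && two_drug) stopf("the inhibition model has no Hill exponent")
  model <- fit$model
  if (two_drug) {
    key <- paste(cells$L, cells$I, sep = "_")
    levs <- unique(data.frame(L = cells$L, I = cells$I, key = key))
    cond <- match(key, levs$key)
  } else {
    levs <- sort(unique(cells$L))
    cond <- match(cells$L, levs)
  }
  d <- cells$msd

  fixed_ll <- function(value) {
    # theta = structural params with `param` pinned at `value`
    model_fn <- function(th) {
      if (two_drug) {
        inhibition_msd(levs$L, levs$I, exp(th[1]) + exp(th[2]), exp(th[1]),
                       if (param == "ec50") value else exp(th[3]),
                       if (param == "ic50") value else exp(th[3]))
      } else {
        hill_msd(levs, exp(th[1]) + exp(th[2]), exp(th[1]),
                 if (param == "ec50") value else exp(th[3]),
                 if (param == "h") value else exp(th[3]))
      }
    }
    th0 <- c(log(max(fit$msd_min, 1e-6)),
             log(max(fit$msd_max - fit$msd_min, 1e-6)),
             log(switch(param,
                        ec50 = if (two_drug) fit$ic50 else fit$h,
                        ic50 = fit$ec50,
                        h = fit$ec50)))
    obj <- function(th) {
      m <- model_fn(th)
      if (any(!is.finite(m)) || any(m <= 0)) return(1e10)
      -grouped_loglik(d, cond, m, model)
    }
    o <- tryCatch(optim(th0, obj, method = "Nelder-Mead",
                        control = list(maxit = 3000, reltol = 1e-10)),
                  error = function(e) NULL)
    if (is.null(o)) -Inf else -o$value
  }

  mle <- fit[[param]]
  grid <- 10^seq(log10(mle) - span, log10(mle) + span, length.out = n_grid)
  prof <- vapply(grid, fixed_ll, 0)
  ll_max <- max(prof, if (two_drug) fit$logL_log else -Inf,
                fit[[if (model == "lognormal") "logL_log" else "logL_norm"]])
  cutoff <- ll_max - stats::qchisq(level, 1) / 2
  inside <- prof >= cutoff
  if (!any(inside)) return(list(lower = mle, upper = mle, estimate = mle,
                                level = level))
  lg <- log10(grid)
  cross <- function(i_out, i_in) {
    # log-linear interpolation of the profile crossing between two grid points
    10^(lg[i_out] + (cutoff - prof[i_out]) / (prof[i_in] - prof[i_out]) *
          (lg[i_in] - lg[i_out]))
  }
  first <- min(which(inside)); last <- max(which(inside))
  lower <- if (first == 1L) 0 else cross(first - 1L, first)
  upper <- if (last == n_grid) Inf else cross(last + 1L, last)
  list(lower = lower, upper = upper, estimate = mle, level = level)
}
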