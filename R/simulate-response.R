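# Dose-response simulator: per-cell MSD values scattered log-normally around
# the pharmacological model curves, with ground truth.

#' Hill dose-response model for MSD suppression
#'
#' `MSD([L]) = MSD_max - (MSD_max - MSD_min) / (1 + (EC50/[L])^h)`;
#' at `[L] = 0` the response equals `MSD_max`.
#'
#' @param L ligand concentration(s), nM.
#' @param msd_max,msd_min upper/lower MSD boundaries (um^2).
#' @param ec50 half-maximal effective concentration (nM).
#' @param h Hill coefficient.
#' @return model MSD values.
#' @export
hill_msd <- function(L, msd_max, msd_min, ec50, h = 1) {
  ifelse(L <= 0, msd_max,
         msd_max - (msd_max - msd_min) / (1 + (ec50 / L)^h))
}

#' Noncompetitive-inhibition dose-response model
#'
#' `MSD([L],[I]) = MSD_max - (MSD_max - MSD_min) /
#'   ((1 + EC50/[L]) (1 + [I]/IC50))`.
#'
#' @param L ligand concentration(s), nM.
#' @param I inhibitor concentration(s), nM.
#' @inheritParams hill_msd
#' @param ic50 half-maximal inhibitory concentration (nM).
#' @export
inhibition_msd <- function(L, I, msd_max, msd_min, ec50, ic50) {
  ifelse(L <= 0, msd_max,
         msd_max - (msd_max - msd_min) / ((1 + ec50 / L) * (1 + I / ic50)))
}

#' Simulate per-cell MSD response tables
#'
#' Draws `n_cells` per condition from a log-normal scatter around the model
#' curve with the median convention `log d ~ N(log MSD - sigma^2/2, sigma^2)`,
#' so the expectation of `d` equals the model MSD. With `sigma = 0` the cell
#' values equal the curve exactly.
#'
#' @param concentrations ligand concentrations (nM); for the inhibition model
#'   a data.frame with columns `L` and `I` (one row per condition).
#' @param truth named list of model parameters: `msd_max`, `msd_min`, `ec50`
#'   and either `h` (Hill model) or `ic50` (noncompetitive inhibition model).
#' @param sigma log-normal scale per condition (recycled).
#' @param n_cells cells per condition.
#' @param seed RNG seed.
#' @return list with `cells` (data.frame `L[, I], cell, msd`) and `truth`.
#' @examples
#' tab <- simulate_response_tables(c(0, 1, 10, 100),
#'   truth = list(msd_max = 0.06, msd_min = 0.02, ec50 = 6.6, h = 1),
#'   sigma = 0.2, n_cells = 18)
#' @export
simulate_response_tables <- function(concentrations, truth, sigma = 0.2,
                                     n_cells = 18L, seed = 1L) {
  if (!is.null(seed)) set.seed(seed)
  if (any(sigma < 0)) stopf("sigma must be >= 0")
  two_drug <- is.data.frame(concentrations)
  cond <- if (two_drug) concentrations else data.frame(L = concentrations)
  if (any(cond$L < 0)) stopf("concentrations must be >= 0")
  sigma <- rep_len(sigma, nrow(cond))
  m <- if (two_drug) {
    inhibition_msd(cond$L, cond$I, truth$msd_max, truth$msd_min,
                   truth$ec50, truth$ic50)
  } else {
    hill_msd(cond$L, truth$msd_max, truth$msd_min, truth$ec50,
             if (is.null(truth$h)) 1 else truth$h)
  }
  rows <- lapply(seq_len(nrow(cond)), function(i) {
    d <- if (sigma[i] == 0) rep(m[i], n_cells) else
      exp(rnorm(n_cells, log(m[i]) - sigma[i]^2 / 2, sigma[i]))
    out <- data.frame(L = cond$L[i], cell = seq_len(n_cells), msd = d)
    if (two_drug) out$I <- cond$I[i]
    out
  })
  cells <- do.call(rbind, rows)
  if (two_drug) cells <- cells[, c("L", "I", "cell", "msd")]
  list(cells = cells, truth = c(truth, list(sigma = sigma)))
}
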