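#' Benchmark error statistics
#'
#' The six statistics used to score hydrodynamic-radius predictors against
#' experiment: root-mean-square deviation (RMSD, A), root-mean-square
#' relative deviation (RMSRD, percent of the experimental value), the
#' coefficient of determination R^2 about the experimental mean (which can
#' be negative for predictors worse than the mean), R^2 adjusted for the
#' number of fitting parameters, and the third quartiles of the absolute
#' (A) and relative (percent) errors.
#'
#' @param predicted,experimental Equal-length numeric vectors, A.
#' @param n_fp Number of fitting parameters of the predictor (0 for
#'   simulation-based methods).
#' @param quartile_type Quantile convention passed to [stats::quantile()];
#'   the default 7 interpolates linearly between order statistics.
#' @return An object of class `"metrics_report"` (a one-row data frame)
#'   with columns `rmsd`, `rmsrd`, `r2`, `r2_adj`, `q3_ae`, `q3_re`,
#'   `n_fp`, `n_proteins`.
#' @examples
#' error_stats(c(12, 8), c(10, 10), n_fp = 0) # RMSD 2, RMSRD 20
#' @export
error_stats <- function(predicted, experimental, n_fp = 0L,
                        quartile_type = 7L) {
  predicted <- as.numeric(predicted)
  experimental <- as.numeric(experimental)
  n <- length(predicted)
  if (n == 0L || length(experimental) != n)
    stop("error_stats: predicted and experimental must be equal-length, non-empty")
  if (any(!is.finite(experimental)) || any(experimental <= 0))
    stop("error_stats: experimental values must be positive and finite")
  d <- predicted - experimental
  rel <- d / experimental
  rmsd <- sqrt(mean(d^2))
  rmsrd <- 100 * sqrt(mean(rel^2))
  ss_res <- sum(d^2)
  ss_tot <- sum((experimental - mean(experimental))^2)
  r2 <- 1 - ss_res / ss_tot
  if (n_fp > 0L && n <= n_fp + 1L)
    stop(sprintf("error_stats: adjusted R^2 needs n > n_fp + 1 (n = %d, n_fp = %d)",
                 n, n_fp))
  r2_adj <- if (n_fp > 0L) 1 - (1 - r2) * (n - 1) / (n - n_fp - 1) else r2
  q3_ae <- unname(stats::quantile(abs(d), 0.75, type = quartile_type))
  q3_re <- unname(stats::quantile(100 * abs(rel), 0.75, type = quartile_type))
  out <- data.frame(rmsd = rmsd, rmsrd = rmsrd, r2 = r2, r2_adj = r2_adj,
                    q3_ae = q3_ae, q3_re = q3_re, n_fp = as.integer(n_fp),
                    n_proteins = n)
  class(out) <- c("metrics_report", "data.frame")
  out
}

#' Power-law baseline for hydrodynamic radius versus chain length
#'
#' Fits `R_h = prefactor * N^gamma` by ordinary least squares in log-log
#' space. With `n_params = 2` both prefactor and exponent are free; with
#' `n_params = 1` the exponent is fixed (default: the excluded-volume
#' chain value 0.588, the "random coil" baseline) and only the prefactor
#' is fitted, which reduces to the geometric mean of `rh / N^gamma`. When
#' `loo = TRUE`, per-record predictions are computed under leave-one-out
#' cross-validation: each record is predicted from the fit that excludes
#' it.
#'
#' @param n_residues Chain lengths.
#' @param rh Experimental hydrodynamic radii, A.
#' @param n_params 1 (fixed exponent) or 2 (free exponent).
#' @param fixed_gamma Exponent used when `n_params = 1`.
#' @param loo Compute leave-one-out predictions.
#' @return An object of class `"rh_powerlaw"`: list with `prefactor`,
#'   `gamma`, `fixed_gamma` (logical), `n_params`, `loo_predictions`
#'   (or NULL), `n_residues`, `rh`.
#' @examples
#' pf <- fit_power_law(c(50, 100, 200, 400), 5 * c(50, 100, 200, 400)^0.5)
#' coef(pf)
#' @export
fit_power_law <- function(n_residues, rh, n_params = 2L, fixed_gamma = 0.588,
                          loo = TRUE) {
  n_residues <- as.numeric(n_residues)
  rh <- as.numeric(rh)
  m <- length(rh)
  if (m < 3L || length(n_residues) != m)
    stop("fit_power_law: need at least 3 (n_residues, rh) pairs of equal length")
  if (any(n_residues <= 0) || any(rh <= 0))
    stop("fit_power_law: lengths and radii must be positive")
  if (!n_params %in% c(1L, 2L)) stop("fit_power_law: n_params must be 1 or 2")
  if (n_params == 2L && length(unique(n_residues)) < 2L)
    stop("fit_power_law: degenerate design, all chain lengths identical")

  fit_once <- function(idx) {
    ln <- log(n_residues[idx]); lr <- log(rh[idx])
    if (n_params == 2L) {
      co <- stats::lm.fit(cbind(1, ln), lr)$coefficients
      c(prefactor = exp(co[[1]]), gamma = co[[2]])
    } else {
      c(prefactor = exp(mean(lr - fixed_gamma * ln)), gamma = fixed_gamma)
    }
  }
  full <- fit_once(seq_len(m))
  loo_pred <- NULL
  if (loo) {
    loo_pred <- vapply(seq_len(m), function(i) {
      co <- fit_once(setdiff(seq_len(m), i))
      co[["prefactor"]] * n_residues[i]^co[["gamma"]]
    }, numeric(1))
  }
  structure(list(prefactor = full[["prefactor"]], gamma = full[["gamma"]],
                 fixed_gamma = n_params == 1L, n_params = as.integer(n_params),
                 loo_predictions = loo_pred, n_residues = n_residues, rh = rh),
            class = "rh_powerlaw")
}

#' @export
coef.rh_powerlaw <- function(object, ...) {
  c(prefactor = object$prefactor, gamma = object$gamma)
}

#' @export
predict.rh_powerlaw <- function(object, n_residues = object$n_residues, ...) {
  object$prefactor * as.numeric(n_residues)^object$gamma
}

#' @export
print.rh_powerlaw <- function(x, ...) {
  cat(sprintf("Power-law fit: R_h = %.3f * N^%.4f (%s exponent, %d records)\n",
              x$prefactor, x$gamma,
              if (x$fixed_gamma) "fixed" else "fitted", length(x$rh)))
  invisible(x)
}
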