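# Mean squared displacement and the subdiffusion exponent alpha, used to
# caveat MSM timescales: trapping in cavities bends log MSD vs log lag below
# slope 1 at intermediate lags.

#' Mean squared displacement and power-law exponent
#'
#' Time- and ensemble-averaged MSD over all overlapping origins,
#' `MSD(lag) = <|x(t + lag) - x(t)|^2>`, evaluated on a log-spaced lag grid;
#' `alpha` is the least-squares slope of `log MSD` vs `log lag` over the fit
#' window (default: one decade centered at the geometric mean of the
#' available lags).
#'
#' @param traj a `gas_traj`.
#' @param max_lag largest lag (ps); default a quarter of the trajectory.
#' @param fit_window length-2 vector of lag bounds (ps) for the alpha fit.
#' @param n_lags number of lag grid points.
#' @return object of class `gas_msd`: `msd` data.frame (`lag_ps`,
#'   `msd_A2`, `n_samples`), `alpha`, `alpha_se`, `fit_window`,
#'   `immobile` flag.
#' @export
msd_alpha <- function(traj, max_lag = NULL, fit_window = NULL, n_lags = 30L) {
  stopifnot(inherits(traj, "gas_traj"))
  nf <- n_frames(traj)
  if (is.null(max_lag)) max_lag <- traj$stride * floor((nf - 1L) / 4)
  max_L <- floor(max_lag / traj$stride)
  if (max_L < 2L) stop("max_lag must span at least 2 frames")
  Ls <- sort(unique(round(exp(seq(log(1), log(max_L), length.out = n_lags)))))
  msd <- vapply(Ls, function(L) {
    d <- traj$rel[(1L + L):nf, , , drop = FALSE] -
      traj$rel[1:(nf - L), , , drop = FALSE]
    mean(d[, , 1L]^2 + d[, , 2L]^2 + d[, , 3L]^2)
  }, numeric(1L))
  tab <- data.frame(lag_ps = Ls * traj$stride, msd_A2 = msd,
                    n_samples = (nf - Ls) * length(traj$ids))
  immobile <- max(msd) < 1e-12
  if (is.null(fit_window)) {
    gm <- exp(mean(log(range(tab$lag_ps))))
    fit_window <- c(gm / sqrt(10), gm * sqrt(10))
  }
  sel <- tab$lag_ps >= fit_window[1L] & tab$lag_ps <= fit_window[2L] &
    tab$msd_A2 > 0
  alpha <- NA_real_; alpha_se <- NA_real_
  if (!immobile) {
    if (sum(sel) < 5L) stop("fewer than 5 MSD points in the fit window")
    fit <- stats::lm(log(msd_A2) ~ log(lag_ps), data = tab[sel, ])
    alpha <- unname(stats::coef(fit)[2L])
    alpha_se <- unname(summary(fit)$coefficients[2L, 2L])
  }
  structure(list(msd = tab, alpha = alpha, alpha_se = alpha_se,
                 fit_window = fit_window, immobile = immobile),
            class = "gas_msd")
}

#' @export
print.gas_msd <- function(x, ...) {
  if (x$immobile) {
    cat("gas_msd: immobile particle(s); MSD = 0, alpha undefined\n")
  } else {
    cat(sprintf("gas_msd: alpha = %.3f +/- %.3f over lags %.3g..%.3g ps\n",
                x$alpha, x$alpha_se, x$fit_window[1L], x$fit_window[2L]))
  }
  invisible(x)
}
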