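# Electrophysiology summaries: fold activation and Hill dose-response fits.

#' Fold activation of a current by a ligand
#'
#' `FA = I_activated / I_basal`, the current in the ligand's presence over
#' the basal current.
#'
#' @param I_basal basal current (pA, non-zero).
#' @param I_activated activated current (pA).
#' @return list of class `fold_activation` with `I_basal`, `I_activated`,
#'   `FA`.
#' @export
fold_activation <- function(I_basal, I_activated) {
  if (any(I_basal == 0)) stop("fold activation undefined for I_basal = 0")
  structure(list(I_basal = I_basal, I_activated = I_activated,
                 FA = I_activated / I_basal),
            class = "fold_activation")
}

#' @export
print.fold_activation <- function(x, ...) {
  cat(sprintf("fold activation: %.3g\n", x$FA))
  invisible(x)
}

#' Hill fit of a concentration-inhibition relationship
#'
#' Nonlinear least squares of
#' `%inhibition(x) = base + (max - base) / (1 + (x_half / x)^rate)`
#' with `base = 0` and `max = 100` fixed unless freed. Initialization:
#' `x_half` at the geometric mean of the doses, `rate = 1`; the Hill
#' coefficient is bounded to [0.3, 5]. With a `replicate` grouping, each
#' measurement is fitted independently and the replicate fits are summarised
#' alongside the pooled fit.
#'
#' @param doses concentrations in uM (> 0, at least 4 distinct).
#' @param inhibition percent inhibition (noise tolerated in [-10, 110]).
#' @param replicate optional grouping vector for per-measurement fits.
#' @param free_asymptotes estimate `base` and `max` instead of fixing 0/100.
#' @return list of class `dose_response_fit`: `x_half` (uM), `rate`, `base`,
#'   `max`, `se` (named standard errors), `residuals`, `fitted`, `model`
#'   (the nls object), and `replicates` (data.frame of per-replicate
#'   estimates, when grouped).
#' @export
hill_fit <- function(doses, inhibition, replicate = NULL,
                     free_asymptotes = FALSE) {
  if (any(doses <= 0)) stop("doses must be positive")
  if (length(unique(doses)) < 4) stop("need at least 4 distinct doses")
  if (any(inhibition < -10 | inhibition > 110)) {
    stop("inhibition values outside [-10, 110] %")
  }
  reps <- NULL
  if (!is.null(replicate)) {
    grp <- split(seq_along(doses), replicate)
    reps <- do.call(rbind, lapply(names(grp), function(g) {
      f <- hill_fit(doses[grp[[g]]], inhibition[grp[[g]]],
                    free_asymptotes = free_asymptotes)
      data.frame(replicate = g, x_half = f$x_half, rate = f$rate)
    }))
  }
  dat <- data.frame(x = doses, y = inhibition)
  start_xh <- exp(mean(log(doses)))
  fit <- if (free_asymptotes) {
    minpack.lm::nlsLM(
      y ~ base + (max - base) / (1 + (x_half / x)^rate), data = dat,
      start = list(base = 0, max = 100, x_half = start_xh, rate = 1),
      lower = c(base = -10, max = 0, x_half = 1e-9, rate = 0.3),
      upper = c(base = 50, max = 110, x_half = Inf, rate = 5),
      control = minpack.lm::nls.lm.control(maxiter = 200)
    )
  } else {
    minpack.lm::nlsLM(
      y ~ 0 + (100 - 0) / (1 + (x_half / x)^rate), data = dat,
      start = list(x_half = start_xh, rate = 1),
      lower = c(x_half = 1e-9, rate = 0.3),
      upper = c(x_half = Inf, rate = 5),
      control = minpack.lm::nls.lm.control(maxiter = 200)
    )
  }
  if (!fit$convInfo$isConv) {
    stop("Hill fit did not converge; last iterate x_half = ",
         signif(coef(fit)[["x_half"]], 4))
  }
  cf <- stats::coef(fit)
  se <- tryCatch(summary(fit)$coefficients[, "Std. Error"],
                 error = function(e) rep(NA_real_, length(cf)))
  structure(list(
    x_half = cf[["x_half"]],
    rate = cf[["rate"]],
    base = if (free_asymptotes) cf[["base"]] else 0,
    max = if (free_asymptotes) cf[["max"]] else 100,
    se = se,
    residuals = stats::residuals(fit),
    fitted = stats::fitted(fit),
    model = fit,
    replicates = reps
  ), class = "dose_response_fit")
}

#' @export
print.dose_response_fit <- function(x, ...) {
  cat(sprintf("Hill fit: IC50 = %.4g uM, rate = %.3g (base %.3g, max %.3g)\n",
              x$x_half, x$rate, x$base, x$max))
  invisible(x)
}

#' Evaluate a Hill inhibition curve
#'
#' @param x concentration(s), uM.
#' @param x_half IC50, uM.
#' @param rate Hill coefficient.
#' @param base,max inhibition floor and ceiling, %.
#' @return percent inhibition.
#' @export
hill_curve <- function(x, x_half, rate = 1, base = 0, max = 100) {
  base + (max - base) / (1 + (x_half / x)^rate)
}
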