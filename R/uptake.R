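#' Construct an uptake series
#'
#' Time-resolved drug-positivity or mean-fluorescent-intensity
#' measurements for one compound, as produced by flow cytometry at a
#' ladder of exposure times.
#'
#' @param times time of each measurement (minutes for uptake, days for
#'   washout), strictly increasing.
#' @param values fraction-positive in `[0, 1]` or MFI (AU, >= 0).
#' @param value_kind `"fraction"` or `"mfi"`.
#' @param compound compound label (e.g. `"DOXO"`).
#' @return An object of class `uptake_series`.
#' @export
uptake_series <- function(times, values, value_kind = c("fraction", "mfi"),
                          compound = NA_character_) {
  value_kind <- match.arg(value_kind)
  if (length(times) != length(values)) stop("times and values lengths differ")
  if (any(diff(times) <= 0)) stop("times must be strictly increasing")
  if (value_kind == "fraction" && any(values < 0 | values > 1)) {
    stop("fraction values must lie in [0, 1]")
  }
  if (any(values < 0)) stop("values must be >= 0")
  structure(list(times = as.numeric(times), values = as.numeric(values),
                 value_kind = value_kind, compound = compound),
            class = "uptake_series")
}

uptake_curve <- function(t, P, k, v0 = 0) v0 + (P - v0) * (1 - exp(-k * t))
washout_curve <- function(t, I0, lambda, B) B + (I0 - B) * exp(-lambda * t)

#' Fit the saturating-exponential uptake model
#'
#' Least-squares fit of `v(t) = v0 + (P - v0) (1 - exp(-k t))`: the signal
#' rises from `v0` toward the plateau `P` at rate `k` per minute, so the
#' half-saturation time is `ln(2)/k`. Parameter confidence intervals come
#' from a seeded residual bootstrap. Fraction-positive data are fitted on
#' the raw scale.
#'
#' @param series an [uptake_series()] (>= 4 points, times >= 0) or a
#'   data.frame with columns `times`/`values`.
#' @param v0 signal at time zero, held fixed (default 0).
#' @param n_boot residual-bootstrap replicates for the CIs (default 199;
#'   0 skips the bootstrap).
#' @param seed RNG seed for the bootstrap (default 1).
#' @return An object of class `uptake_fit` with components `par`
#'   (named `P`, `k`, `v0`), `rss`, `half_saturation_min`, `ci`
#'   (2.5/97.5% bootstrap percentiles), `data`, `convergence` info.
#' @export
fit_uptake <- function(series, v0 = 0, n_boot = 199, seed = 1) {
  if (is.data.frame(series)) {
    series <- uptake_series(series$times, series$values,
                            value_kind = "mfi")
  }
  stopifnot(inherits(series, "uptake_series"))
  t <- series$times; v <- series$values
  if (length(t) < 4) stop("need at least 4 points to fit")
  if (any(t < 0)) stop("times must be >= 0")
  if (stats::sd(v) == 0) {
    stop("constant series: uptake rate k is unidentifiable")
  }
  fit1 <- function(vv) {
    P0 <- max(vv)
    k0 <- max(1 / stats::median(t[t > 0]), 1e-4)
    fit <- minpack.lm::nlsLM(
      vv ~ v0 + (P - v0) * (1 - exp(-k * t)),
      start = list(P = P0, k = k0),
      lower = c(P = 0, k = 1e-8),
      control = minpack.lm::nls.lm.control(maxiter = 200)
    )
    stats::coef(fit)
  }
  co <- tryCatch(fit1(v), error = function(e) {
    stop("uptake fit failed to converge: ", conditionMessage(e),
         "\nresiduals about the mean: ",
         paste(signif(v - mean(v), 3), collapse = ", "))
  })
  pred <- uptake_curve(t, co["P"], co["k"], v0)
  res <- v - pred
  if (co["P"] > 1.5 * max(v)) {
    warning("fitted plateau far above the observed range; ",
            "the series may not have reached saturation")
  }
  ci <- NULL
  if (n_boot > 0) {
    boot <- with_seed(seed, {
      replicate(n_boot, {
        vb <- pred + sample(res, length(res), replace = TRUE)
        out <- tryCatch(fit1(vb), error = function(e) c(P = NA, k = NA))
        out
      })
    })
    ci <- apply(boot, 1, stats::quantile, probs = c(0.025, 0.975),
                na.rm = TRUE)
  }
  structure(list(par = c(P = unname(co["P"]), k = unname(co["k"]), v0 = v0),
                 rss = sum(res^2),
                 half_saturation_min = log(2) / co[["k"]],
                 ci = ci, data = series, residuals = res,
                 fitted = pred, n_boot = n_boot, seed = seed),
            class = "uptake_fit")
}

#' @export
print.uptake_fit <- function(x, ...) {
  cat("Saturating-exponential uptake fit\n")
  if (!is.na(x$data$compound)) cat("  compound:", x$data$compound, "\n")
  cat(sprintf("  plateau P        = %.4g\n", x$par["P"]))
  cat(sprintf("  rate k           = %.4g /min\n", x$par["k"]))
  cat(sprintf("  half-saturation  = %.3g min\n", x$half_saturation_min))
  cat(sprintf("  RSS              = %.3g on %d points\n",
              x$rss, length(x$data$times)))
  if (!is.null(x$ci)) {
    cat(sprintf("  bootstrap 95%% CI: P [%.4g, %.4g], k [%.4g, %.4g]\n",
                x$ci[1, "P"], x$ci[2, "P"], x$ci[1, "k"], x$ci[2, "k"]))
  }
  invisible(x)
}

#' @export
coef.uptake_fit <- function(object, ...) object$par

#' @export
residuals.uptake_fit <- function(object, ...) object$residuals

#' @export
predict.uptake_fit <- function(object, newdata = NULL, ...) {
  t <- if (is.null(newdata)) object$data$times else {
    if (is.data.frame(newdata)) newdata$times else newdata
  }
  uptake_curve(t, object$par["P"], object$par["k"], object$par["v0"])
}

#' @export
summary.uptake_fit <- function(object, ...) {
  print(object)
  invisible(object)
}

#' @export
plot.uptake_fit <- function(x, ...) {
  t <- x$data$times
  graphics::plot(t, x$data$values, xlab = "time (min)",
                 ylab = x$data$value_kind, pch = 19, ...)
  tt <- seq(0, max(t), length.out = 200)
  graphics::lines(tt, uptake_curve(tt, x$par["P"], x$par["k"], x$par["v0"]))
  invisible(x)
}

#' Simulate new series from a fitted uptake model
#'
#' Draws Gaussian noise with the fit's residual standard deviation around
#' the fitted curve.
#'
#' @param object an `uptake_fit`.
#' @param nsim number of simulated series.
#' @param seed RNG seed.
#' @param ... unused.
#' @return A matrix, one column per simulation.
#' @export
simulate.uptake_fit <- function(object, nsim = 1, seed = 1, ...) {
  s <- stats::sd(object$residuals)
  with_seed(seed, {
    matrix(object$fitted + stats::rnorm(length(object$fitted) * nsim, 0, s),
           ncol = nsim)
  })
}

#' Fit the exponential washout model
#'
#' Least-squares fit of `v(t) = B + (I0 - B) exp(-lambda t)`: the signal
#' decays from the initial level `I0` toward the background `B` at rate
#' `lambda` per day. The time to background is the first time at which
#' the remaining excess drops below 5% of the initial excess, i.e.
#' `ln(20)/lambda` in closed form.
#'
#' @param series an [uptake_series()] in days (>= 4 points, decreasing
#'   trend).
#' @return An object of class `washout_fit` with `par` (`I0`, `lambda`,
#'   `B`), `rss`, and `time_to_background_days`.
#' @export
fit_washout <- function(series) {
  if (is.data.frame(series)) {
    series <- uptake_series(series$times, series$values, value_kind = "mfi")
  }
  stopifnot(inherits(series, "uptake_series"))
  t <- series$times; v <- series$values
  if (length(t) < 4) stop("need at least 4 points to fit")
  if (max(v) == min(v)) stop("constant series: washout is degenerate")
  if (stats::cor(t, v) >= 0) {
    stop("series does not decrease over time: not a washout")
  }
  fit <- minpack.lm::nlsLM(
    v ~ B + (I0 - B) * exp(-lambda * t),
    start = list(I0 = max(v), lambda = 1 / stats::median(t[t > 0]),
                 B = min(v)),
    lower = c(I0 = 0, lambda = 1e-8, B = 0),
    control = minpack.lm::nls.lm.control(maxiter = 200)
  )
  co <- stats::coef(fit)
  pred <- washout_curve(t, co["I0"], co["lambda"], co["B"])
  structure(list(par = c(I0 = unname(co["I0"]), lambda = unname(co["lambda"]),
                         B = unname(co["B"])),
                 rss = sum((v - pred)^2),
                 time_to_background_days = log(20) / co[["lambda"]],
                 data = series, fitted = pred, residuals = v - pred),
            class = "washout_fit")
}

#' @export
print.washout_fit <- function(x, ...) {
  cat("Exponential washout fit\n")
  cat(sprintf("  initial level I0   = %.4g\n", x$par["I0"]))
  cat(sprintf("  decay rate lambda  = %.4g /day\n", x$par["lambda"]))
  cat(sprintf("  background B       = %.4g\n", x$par["B"]))
  cat(sprintf("  time to background = %.3g days (5%% criterion)\n",
              x$time_to_background_days))
  invisible(x)
}

#' @export
coef.washout_fit <- function(object, ...) object$par

#' @export
predict.washout_fit <- function(object, newdata = NULL, ...) {
  t <- if (is.null(newdata)) object$data$times else {
    if (is.data.frame(newdata)) newdata$times else newdata
  }
  washout_curve(t, object$par["I0"], object$par["lambda"], object$par["B"])
}

#' Saturation reached after a given exposure
#'
#' The fraction of the plateau reached after `exposure_min` minutes:
#' `1 - exp(-k * exposure)`. Maps an exposure regimen (e.g. a 2-h
#' incubation) to the expected degree of cell saturation.
#'
#' @param model an `uptake_fit`.
#' @param exposure_min exposure duration in minutes (>= 0).
#' @return A number in `[0, 1)`.
#' @export
saturation_at <- function(model, exposure_min) {
  stopifnot(inherits(model, "uptake_fit"), all(exposure_min >= 0))
  1 - exp(-model$par[["k"]] * exposure_min)
}
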