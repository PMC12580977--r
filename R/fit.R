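#' Fit a two-state melting model to a GP curve
#'
#' Least-squares fit of the two-state mean function (see [ideal_gp()]) to
#' an observed GP-versus-temperature curve, by Levenberg-Marquardt
#' nonlinear least squares. Initialization is deterministic and documented:
#' plateaus from the curve extremes, `t_m` from the derivative peak and
#' `width_k` from the derivative FWHM divided by `2 log(3 + 2 sqrt(2))`
#' (falling back to the GP midpoint temperature and a tenth of the
#' temperature span when the nonparametric extraction fails).
#'
#' @param curve A [gp_curve()] (or data.frame with `temperature` and `gp`)
#'   with at least 6 points spanning the transition.
#' @param start Optional starting values: a [melt_model()] or named list
#'   overriding any of `gp_gel`, `gp_fluid`, `t_m`, `width_k` (and the
#'   slopes when `include_drift = TRUE`).
#' @param include_drift Also fit linear plateau drifts `slope_gel`,
#'   `slope_fluid` (default `FALSE`).
#' @param control A [minpack.lm::nls.lm.control()] list.
#' @return An object of class `"melt_fit"`: list with the fitted `model`
#'   (a [melt_model()]), the underlying `fit` (an `nls` object), the
#'   fitting `data`, `start` values, `converged` flag and `sigma` (residual
#'   standard deviation). Supports `coef()`, `predict()`, `fitted()`,
#'   `residuals()`, `summary()`, `plot()` and `simulate()`.
#' @examples
#' m <- update(condition_model("DMPC"), noise_sd = 0)
#' cur <- gp_curve(10:40, ideal_gp(10:40, m))
#' fit <- fit_two_state(cur)
#' coef(fit)
#' @export
fit_two_state <- function(curve, start = NULL, include_drift = FALSE,
                          control = minpack.lm::nls.lm.control(maxiter = 200)) {
  curve <- as_gp_curve(curve)
  df <- data.frame(temperature = curve$temperature, gp = curve$gp)
  if (nrow(df) < 6L)
    stop_typed("laurdanGP_insufficient_data_error",
               "fit_two_state needs at least 6 points")
  if (diff(range(df$gp)) < 1e-8)
    stop_typed("laurdanGP_no_transition_error",
               "flat GP curve: nothing to fit")

  init <- list(gp_gel = max(df$gp), gp_fluid = min(df$gp),
               t_m = NA_real_, width_k = NA_real_)
  tr <- tryCatch(find_transition(curve), error = function(e) NULL)
  if (!is.null(tr)) {
    init$t_m <- tr$t_m
    init$width_k <- tr$fwhm / (2 * log(3 + 2 * sqrt(2)))
  } else {
    mid <- (max(df$gp) + min(df$gp)) / 2
    init$t_m <- df$temperature[which.min(abs(df$gp - mid))]
    init$width_k <- diff(range(df$temperature)) / 10
  }
  if (include_drift) init$slope_gel <- init$slope_fluid <- 0
  if (!is.null(start)) {
    start <- if (inherits(start, "melt_model")) unclass(start) else start
    init <- utils::modifyList(init, start[intersect(names(start), names(init))])
  }

  span <- diff(range(df$temperature))
  if (include_drift) {
    formula <- gp ~ two_state_gp(temperature, gp_gel, gp_fluid, t_m, width_k,
                                 slope_gel, slope_fluid)
    lower <- c(gp_gel = -1, gp_fluid = -1,
               t_m = min(df$temperature) - span, width_k = 1e-6,
               slope_gel = -1, slope_fluid = -1)
    upper <- c(gp_gel = 1, gp_fluid = 1,
               t_m = max(df$temperature) + span, width_k = 100 * span,
               slope_gel = 1, slope_fluid = 1)
  } else {
    formula <- gp ~ two_state_gp(temperature, gp_gel, gp_fluid, t_m, width_k)
    lower <- c(gp_gel = -1, gp_fluid = -1,
               t_m = min(df$temperature) - span, width_k = 1e-6)
    upper <- c(gp_gel = 1, gp_fluid = 1,
               t_m = max(df$temperature) + span, width_k = 100 * span)
  }

  fit <- tryCatch(
    minpack.lm::nlsLM(formula, data = df, start = init,
                      lower = lower, upper = upper, control = control),
    error = function(e)
      stop_typed("laurdanGP_fit_error",
                 paste("two-state fit failed:", conditionMessage(e)),
                 start = init))
  cf <- as.list(stats::coef(fit))
  model <- melt_model(gp_gel = cf$gp_gel, gp_fluid = cf$gp_fluid,
                      t_m = cf$t_m, width_k = cf$width_k,
                      slope_gel = cf$slope_gel %||% 0,
                      slope_fluid = cf$slope_fluid %||% 0)
  structure(list(model = model, fit = fit, data = df, start = init,
                 include_drift = include_drift,
                 converged = isTRUE(fit$convInfo$isConv),
                 sigma = stats::sigma(fit),
                 condition = attr(curve, "condition")),
            class = "melt_fit")
}

#' @export
coef.melt_fit <- function(object, ...) stats::coef(object$fit)

#' @export
fitted.melt_fit <- function(object, ...) as.numeric(stats::fitted(object$fit))

#' @export
residuals.melt_fit <- function(object, ...) as.numeric(stats::residuals(object$fit))

#' Predict GP at new temperatures from a fitted two-state model
#'
#' @param object A `melt_fit`.
#' @param newdata Optional `data.frame` with a `temperature` column (or a
#'   numeric vector of temperatures); defaults to the fitting data.
#' @param ... Unused.
#' @return Predicted GP values (unclamped mean function).
#' @export
predict.melt_fit <- function(object, newdata = NULL, ...) {
  tt <- if (is.null(newdata)) object$data$temperature
        else if (is.numeric(newdata)) newdata
        else newdata$temperature
  m <- object$model
  two_state_gp(tt, m$gp_gel, m$gp_fluid, m$t_m, m$width_k,
               m$slope_gel, m$slope_fluid)
}

#' @export
print.melt_fit <- function(x, ...) {
  cat("Two-state melting model fit\n")
  if (!is.null(x$condition)) cat("  condition:", x$condition, "\n")
  print(x$model)
  cat(sprintf("  residual sd %.3g on %d points; %s\n", x$sigma,
              nrow(x$data),
              if (x$converged) "converged" else "NOT converged"))
  invisible(x)
}

#' @export
summary.melt_fit <- function(object, ...) {
  s <- summary(object$fit)
  structure(list(coefficients = s$coefficients, sigma = s$sigma,
                 converged = object$converged, n = nrow(object$data),
                 condition = object$condition),
            class = "summary.melt_fit")
}

#' @export
print.summary.melt_fit <- function(x, ...) {
  cat("Two-state melting model fit\n")
  if (!is.null(x$condition)) cat("  condition:", x$condition, "\n")
  stats::printCoefmat(x$coefficients)
  cat(sprintf("Residual standard deviation: %.4g (n = %d)%s\n", x$sigma, x$n,
              if (x$converged) "" else "  [not converged]"))
  invisible(x)
}

#' @export
plot.melt_fit <- function(x, ..., xlab = "Temperature (°C)", ylab = "GP") {
  graphics::plot(x$data$temperature, x$data$gp, pch = 19,
                 xlab = xlab, ylab = ylab, ...)
  tt <- seq(min(x$data$temperature), max(x$data$temperature), length.out = 300)
  graphics::lines(tt, predict(x, tt))
  graphics::abline(v = x$model$t_m, lty = 2)
  invisible(x)
}

#' Simulate GP curves from a fitted two-state model
#'
#' Draws `nsim` replicate GP curves at the fitting temperatures: the
#' fitted mean function plus Gaussian noise with the fit's residual
#' standard deviation, clamped to `[-1, 1]`.
#'
#' @param object A `melt_fit`.
#' @param nsim Number of simulated curves.
#' @param seed Optional integer seed.
#' @param ... Unused.
#' @return A list of `nsim` [gp_curve()]s.
#' @export
simulate.melt_fit <- function(object, nsim = 1, seed = NULL, ...) {
  draw <- function() {
    mu <- predict(object)
    lapply(seq_len(nsim), function(i) {
      gp <- pmin(1, pmax(-1, mu + stats::rnorm(length(mu), sd = object$sigma)))
      gp_curve(object$data$temperature, gp, condition = object$condition)
    })
  }
  if (is.null(seed)) draw() else run_with_seed(seed, draw())
}
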