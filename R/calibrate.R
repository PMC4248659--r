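# Calibration: V2 against wild-type fermentation time series, the milk
# buffering quadratic against titration data, and R^2 scoring.

#' Coefficient of determination
#'
#' `R^2 = 1 - sum((obs - pred)^2) / sum((obs - mean(obs))^2)`.  At most 1;
#' unbounded below (a prediction worse than the observed mean gives a
#' negative value).
#'
#' @param observed,predicted equal-length numeric vectors (length >= 2);
#'   `observed` must have nonzero variance.
#' @return dimensionless scalar.
#' @export
r_squared <- function(observed, predicted) {
  stopifnot(length(observed) == length(predicted), length(observed) >= 2)
  if (any(!is.finite(observed)) || any(!is.finite(predicted)))
    stop("observed and predicted must be finite")
  ss_tot <- sum((observed - mean(observed))^2)
  if (ss_tot == 0) stop("observed series has zero variance")
  1 - sum((observed - predicted)^2) / ss_tot
}

# Simulate the model at the data's sampling times and return predicted
# lactose / lactic acid.  init = NULL recomputes the pre-culture equilibrium
# from the trial parameters, which keeps noiseless recovery exact.
.predict_observables <- function(params, data, init, variant, ...) {
  times <- sort(unique(c(0, data$time_h)))
  traj <- simulate_batch(params,
                         init = if (is.null(init)) default_initial_state(params)
                                else init,
                         times = times, variant = variant, ...)
  idx <- match(data$time_h, traj$times)
  data.frame(time_h = data$time_h,
             lactose_M = traj$states[idx, "LAC_out"],
             lactic_acid_M = traj$states[idx, "LA"])
}

#' Fit the basal lacSZ transcription rate V2 to fermentation data
#'
#' One-dimensional least squares over `V2` alone, all other parameters held
#' fixed: the wild-type model is simulated at each candidate `V2`, and the
#' residuals of extracellular lactose and lactic acid against the data are
#' each normalized by the observed range of that series before summing, so
#' neither observable dominates the joint objective.  Minimization uses
#' bounded golden-section search ([stats::optimize()]) on `bounds`.
#'
#' @param data data frame with columns `time_h`, `lactose_M`,
#'   `lactic_acid_M` (>= 3 time points).
#' @param params a [lacferm_params()] object supplying every fixed
#'   parameter; its `V2` entry is ignored.
#' @param bounds search interval for V2, 1/h.
#' @param init optional fixed initial state.  The default (`NULL`)
#'   recomputes [default_initial_state()] from each trial parameter set, so
#'   the assumed pre-culture equilibrium tracks the candidate V2.
#' @param ... passed to [simulate_batch()].
#'
#' @return an object of class `fit_V2` with components `V2` (the estimate),
#'   `r_squared` (named, per observable), `objective`, `at_bound`, `data`,
#'   `fitted`, `params` (updated with the estimate) and `bounds`.  Methods:
#'   `print`, `summary`, `coef`, `predict`, `residuals`, `plot`.
#'
#' @examples
#' \donttest{
#' d <- generate_fermentation_data(noise_sd = c(0, 0), seed = 1)
#' fit <- fit_V2(d$data)
#' coef(fit)
#' }
#' @export
fit_V2 <- function(data, params = lacferm_params(), bounds = c(0.1, 50),
                   init = NULL, ...) {
  stopifnot(is.data.frame(data),
            all(c("time_h", "lactose_M", "lactic_acid_M") %in% names(data)))
  if (nrow(data) < 3) stop("need at least 3 time points")
  stopifnot(length(bounds) == 2, bounds[1] > 0, bounds[1] < bounds[2])
  rng_lac <- diff(range(data$lactose_M))
  rng_la <- diff(range(data$lactic_acid_M))
  if (rng_lac == 0 && rng_la == 0)
    stop("degenerate data: both observables have zero variance")
  w_lac <- if (rng_lac > 0) 1 / rng_lac else 0
  w_la <- if (rng_la > 0) 1 / rng_la else 0

  objective <- function(V2) {
    p <- update_params(params, V2 = V2)
    pred <- .predict_observables(p, data, init, "wild_type", ...)
    sum((w_lac * (pred$lactose_M - data$lactose_M))^2) +
      sum((w_la * (pred$lactic_acid_M - data$lactic_acid_M))^2)
  }
  opt <- stats::optimize(objective, interval = bounds, tol = 1e-6)
  V2_hat <- opt$minimum
  at_bound <- min(V2_hat - bounds[1], bounds[2] - V2_hat) <
    1e-3 * diff(bounds)
  if (at_bound)
    warning("fitted V2 lies at a search bound; widen `bounds`")

  p_hat <- update_params(params, V2 = V2_hat)
  fitted <- .predict_observables(p_hat, data, init, "wild_type", ...)
  r2 <- c(
    lactose = if (rng_lac > 0)
      r_squared(data$lactose_M, fitted$lactose_M) else NA_real_,
    lactic_acid = if (rng_la > 0)
      r_squared(data$lactic_acid_M, fitted$lactic_acid_M) else NA_real_
  )
  structure(list(V2 = V2_hat, r_squared = r2, objective = opt$objective,
                 at_bound = at_bound, data = data, fitted = fitted,
                 params = p_hat, bounds = bounds, init = init),
            class = "fit_V2")
}

#' @export
print.fit_V2 <- function(x, ...) {
  cat("Wild-type calibration of the basal lacSZ transcription rate\n")
  cat(sprintf("  V2 = %.4g 1/h  (bounds %.3g-%.3g%s)\n", x$V2,
              x$bounds[1], x$bounds[2],
              if (x$at_bound) ", AT BOUND" else ""))
  cat(sprintf("  R^2 lactose = %.4f, R^2 lactic acid = %.4f\n",
              x$r_squared[["lactose"]], x$r_squared[["lactic_acid"]]))
  invisible(x)
}

#' @export
coef.fit_V2 <- function(object, ...) c(V2 = object$V2)

#' @export
summary.fit_V2 <- function(object, ...) {
  res <- residuals(object)
  out <- list(V2 = object$V2, r_squared = object$r_squared,
              objective = object$objective, at_bound = object$at_bound,
              n = nrow(object$data),
              rmse = c(lactose = sqrt(mean(res$lactose_M^2)),
                       lactic_acid = sqrt(mean(res$lactic_acid_M^2))))
  class(out) <- "summary.fit_V2"
  out
}

#' @export
print.summary.fit_V2 <- function(x, ...) {
  cat(sprintf("V2 estimate: %.4g 1/h on %d time points\n", x$V2, x$n))
  cat(sprintf("R^2: lactose %.4f, lactic acid %.4f\n",
              x$r_squared[["lactose"]], x$r_squared[["lactic_acid"]]))
  cat(sprintf("RMSE: lactose %.3g M, lactic acid %.3g M\n",
              x$rmse[["lactose"]], x$rmse[["lactic_acid"]]))
  if (x$at_bound) cat("warning: estimate at search bound\n")
  invisible(x)
}

#' Predict observables from a V2 fit
#'
#' @param object a `fit_V2` object.
#' @param newdata optional data frame with a `time_h` column (default: the
#'   calibration data's times).
#' @param ... passed to [simulate_batch()].
#' @return data frame `time_h`, `lactose_M`, `lactic_acid_M`.
#' @export
predict.fit_V2 <- function(object, newdata = NULL, ...) {
  d <- if (is.null(newdata)) object$data else newdata
  stopifnot("time_h" %in% names(d))
  .predict_observables(object$params, d, object$init, "wild_type", ...)
}

#' @export
residuals.fit_V2 <- function(object, ...) {
  data.frame(time_h = object$data$time_h,
             lactose_M = object$data$lactose_M - object$fitted$lactose_M,
             lactic_acid_M = object$data$lactic_acid_M -
               object$fitted$lactic_acid_M)
}

#' @export
plot.fit_V2 <- function(x, ...) {
  grid <- data.frame(time_h = seq(0, max(x$data$time_h), length.out = 81))
  curve <- predict(x, grid)
  ylim <- range(0, x$data$lactose_M, x$data$lactic_acid_M,
                curve$lactose_M, curve$lactic_acid_M)
  graphics::plot(x$data$time_h, x$data$lactose_M, pch = 16,
                 col = "steelblue", ylim = ylim, xlab = "time (h)",
                 ylab = "concentration (M)",
                 main = sprintf("V2 fit (V2 = %.3g 1/h)", x$V2), ...)
  graphics::points(x$data$time_h, x$data$lactic_acid_M, pch = 17,
                   col = "firebrick")
  graphics::lines(curve$time_h, curve$lactose_M, col = "steelblue")
  graphics::lines(curve$time_h, curve$lactic_acid_M, col = "firebrick")
  graphics::legend("right", c("lactose", "lactic acid"),
                   col = c("steelblue", "firebrick"), pch = c(16, 17),
                   lty = 1, bty = "n")
  invisible(x)
}

#' Fit the milk pH-buffering curve
#'
#' Ordinary least-squares fit of the quadratic `pH = c0 - c1*LA + c2*LA^2`
#' to titration measurements (pH of the medium after adding known amounts
#' of lactic acid), via [stats::lm()].  Note the sign convention: `c1` is
#' reported positive for a curve that falls with added acid.
#'
#' @param titration data frame with columns `lactic_acid_M` and `pH`
#'   (replicates welcome); at least 3 distinct lactic-acid levels.
#' @return an object of class `pH_curve_fit` with `coefficients`
#'   (`c0, c1, c2`), `r_squared`, and the underlying `lm` fit.  Methods:
#'   `print`, `coef`, `predict`, `summary`, `plot`.
#' @examples
#' titr <- data.frame(lactic_acid_M = c(0, 0.05, 0.1, 0.15),
#'                    pH = pH_from_LA(c(0, 0.05, 0.1, 0.15)))
#' coef(fit_pH_curve(titr))
#' @export
fit_pH_curve <- function(titration) {
  stopifnot(is.data.frame(titration),
            all(c("lactic_acid_M", "pH") %in% names(titration)))
  LA <- titration$lactic_acid_M
  if (any(!is.finite(LA)) || any(LA < 0))
    stop("lactic_acid_M must be finite and nonnegative")
  if (length(unique(LA)) < 3)
    stop("need at least 3 distinct lactic-acid levels (rank-deficient ",
         "design for a quadratic)")
  fit <- stats::lm(pH ~ LA + I(LA^2), data = data.frame(LA = LA,
                                                        pH = titration$pH))
  b <- stats::coef(fit)
  coefs <- c(c0 = unname(b[1]), c1 = -unname(b[2]), c2 = unname(b[3]))
  ss_tot <- sum((titration$pH - mean(titration$pH))^2)
  r2 <- if (ss_tot > 0) 1 - sum(stats::resid(fit)^2) / ss_tot else NA_real_
  structure(list(coefficients = coefs, r_squared = r2, lm = fit,
                 data = titration),
            class = "pH_curve_fit")
}

#' @export
print.pH_curve_fit <- function(x, ...) {
  cat("Milk pH-buffering curve: pH = c0 - c1*LA + c2*LA^2\n")
  print(signif(x$coefficients, 6))
  cat(sprintf("  R^2 = %.4f on %d points\n", x$r_squared, nrow(x$data)))
  invisible(x)
}

#' @export
coef.pH_curve_fit <- function(object, ...) object$coefficients

#' @export
predict.pH_curve_fit <- function(object, newdata = NULL, ...) {
  LA <- if (is.null(newdata)) object$data$lactic_acid_M
        else if (is.data.frame(newdata)) newdata$lactic_acid_M
        else as.numeric(newdata)
  b <- object$coefficients
  b[["c0"]] - b[["c1"]] * LA + b[["c2"]] * LA^2
}

#' @export
summary.pH_curve_fit <- function(object, ...) summary(object$lm, ...)

#' @export
plot.pH_curve_fit <- function(x, ...) {
  LA <- x$data$lactic_acid_M
  grid <- seq(0, max(LA), length.out = 101)
  graphics::plot(LA, x$data$pH, pch = 16, xlab = "lactic acid (M)",
                 ylab = "pH", main = "milk buffering curve", ...)
  graphics::lines(grid, predict(x, grid), col = "firebrick")
  invisible(x)
}
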