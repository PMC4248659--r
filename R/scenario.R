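# Two-level significance study of the adjustable design parameters
# (promoter basal rate V0, pH-induced rate V1, RBS strength K_LR) against a
# wild-type blank control.

# Published two-level settings and the companion values held fixed while
# one parameter is varied.
.two_level_defaults <- list(
  V1   = list(levels = c(10.5, 21),  held = list(V0 = 1,   K_LR = 564)),
  V0   = list(levels = c(0.1, 1),    held = list(V1 = 10.5, K_LR = 564)),
  K_LR = list(levels = c(564, 1128), held = list(V0 = 1,   V1 = 10.5))
)

#' Two-level scenario study of a promoter/RBS design parameter
#'
#' Simulates the engineered model at a low and a high setting of one of the
#' three adjustable design parameters -- `V1` (pH-induced promoter
#' strength), `V0` (promoter leakiness) or `K_LR` (lacR
#' ribosome-binding-site strength) -- alongside a wild-type blank control,
#' and summarizes each run by final lactic acid, final pH and the time at
#' which the medium pH crosses the promoter threshold.
#'
#' Default levels are the published two-level settings (`V1`: 10.5/21 1/h,
#' `V0`: 0.1/1 1/h, `K_LR`: 564/1128 1/h), with the respective companion
#' parameters held at their published values when `base_params` is not
#' supplied.  Reported pH values are conditional on the package's buffering
#' curve constants (`c0`, `c1`, `c2`), which are a package assumption.
#'
#' @param param_name `"V1"`, `"V0"` or `"K_LR"`.
#' @param low,high the two levels (default: published settings;
#'   `low < high` required).
#' @param base_params baseline [lacferm_params()]; when omitted, the
#'   published held-fixed companion values for the chosen scenario are
#'   applied on top of the defaults.
#' @param init initial state (default [default_initial_state()]).
#' @param t_end horizon, h.
#' @param ... passed to [simulate_batch()].
#' @return an object of class `two_level_scenario`: trajectories `low`,
#'   `high`, `wild_type` plus a `summaries` data frame (one row per run).
#' @examples
#' \donttest{
#' sc <- run_two_level("V1")
#' sc$summaries
#' }
#' @export
run_two_level <- function(param_name = c("V1", "V0", "K_LR"),
                          low = NULL, high = NULL,
                          base_params = NULL, init = NULL, t_end = 8, ...) {
  param_name <- match.arg(param_name)
  def <- .two_level_defaults[[param_name]]
  if (is.null(low)) low <- def$levels[1]
  if (is.null(high)) high <- def$levels[2]
  if (!(is.finite(low) && is.finite(high) && low < high))
    stop("need finite low < high")
  if (is.null(base_params))
    base_params <- do.call(update_params, c(list(lacferm_params()),
                                            def$held))
  if (is.null(init)) init <- default_initial_state(base_params)

  run <- function(level, value, variant) {
    p <- if (variant == "engineered")
      do.call(update_params,
              c(list(base_params), stats::setNames(list(value), param_name)))
    else base_params
    tryCatch(
      simulate_batch(p, init = init, t_end = t_end, variant = variant, ...),
      error = function(e)
        stop("simulation failed for level '", level, "': ",
             conditionMessage(e))
    )
  }
  traj <- list(low = run("low", low, "engineered"),
               high = run("high", high, "engineered"),
               wild_type = run("wild_type", NA, "wild_type"))
  summaries <- do.call(rbind, lapply(names(traj), function(nm) {
    s <- summarize_scenario(traj[[nm]])
    cbind(data.frame(level = nm,
                     value = c(low = low, high = high,
                               wild_type = NA_real_)[[nm]]),
          as.data.frame(s))
  }))
  structure(list(param_name = param_name, low = low, high = high,
                 trajectories = traj, summaries = summaries,
                 base_params = base_params),
            class = "two_level_scenario")
}

#' Summarize a fermentation run
#'
#' Final lactic acid (M), final pH, total lactose consumed (M), and the
#' time at which the medium pH first crosses the promoter threshold
#' (linear interpolation within the bracketing output interval; `NA` when
#' the threshold is never reached).
#'
#' @param traj a `lacferm_trajectory`.
#' @return a list with components `final_LA`, `final_pH`,
#'   `pH_cross_time_h`, `lactose_consumed`, `t_end`, `variant`.
#' @export
summarize_scenario <- function(traj) {
  stopifnot(inherits(traj, "lacferm_trajectory"))
  n <- length(traj$times)
  thr <- traj$params$pH_threshold
  pH <- traj$pH
  cross <- NA_real_
  if (pH[1] <= thr) {
    cross <- 0
  } else {
    i <- which(pH[-n] > thr & pH[-1] <= thr)
    if (length(i)) {
      i <- i[1]
      frac <- (pH[i] - thr) / (pH[i] - pH[i + 1])
      cross <- traj$times[i] + frac * (traj$times[i + 1] - traj$times[i])
    }
  }
  list(final_LA = unname(traj$states[n, "LA"]),
       final_pH = pH[n],
       pH_cross_time_h = cross,
       lactose_consumed = unname(traj$states[1, "LAC_out"] -
                                   traj$states[n, "LAC_out"]),
       t_end = traj$times[n],
       variant = traj$variant)
}

#' @export
print.two_level_scenario <- function(x, ...) {
  cat(sprintf("Two-level scenario: %s at %.4g vs %.4g 1/h (+ wild-type)\n",
              x$param_name, x$low, x$high))
  print(x$summaries, row.names = FALSE)
  invisible(x)
}

#' Plot a two-level scenario
#'
#' Two panels: lactic acid and medium pH against time for the low level,
#' high level and wild-type control.
#'
#' @param x a `two_level_scenario`.
#' @param ... passed to plotting primitives.
#' @export
plot.two_level_scenario <- function(x, ...) {
  op <- graphics::par(mfrow = c(1, 2), mar = c(4, 4, 2, 1))
  on.exit(graphics::par(op))
  cols <- c(low = "steelblue", high = "firebrick", wild_type = "grey30")
  t <- x$trajectories$wild_type$times
  LA <- sapply(x$trajectories, function(tr) tr$states[, "LA"])
  graphics::matplot(t, LA, type = "l", lty = 1, col = cols,
                    xlab = "time (h)", ylab = "lactic acid (M)",
                    main = paste("effect of", x$param_name), ...)
  graphics::legend("topleft", names(cols), col = cols, lty = 1, bty = "n")
  pH <- sapply(x$trajectories, function(tr) tr$pH)
  graphics::matplot(t, pH, type = "l", lty = 1, col = cols,
                    xlab = "time (h)", ylab = "pH", main = "medium pH")
  graphics::abline(h = x$base_params$pH_threshold, lty = 2, col = "grey60")
  invisible(x)
}

#' Write scenario results as CSV
#'
#' One tidy table: `time_h`, `level`, lactic acid, lactose and pH columns
#' for the three runs, plus the summary block appended as attributes-free
#' separate file when `summary_path` is given.
#'
#' @param scenario a `two_level_scenario`.
#' @param path output CSV for the trajectories.
#' @param summary_path optional CSV for the per-run summaries.
#' @return `path`, invisibly.
#' @export
write_scenario_csv <- function(scenario, path, summary_path = NULL) {
  stopifnot(inherits(scenario, "two_level_scenario"))
  rows <- do.call(rbind, lapply(names(scenario$trajectories), function(nm) {
    tr <- scenario$trajectories[[nm]]
    data.frame(time_h = tr$times, level = nm,
               lactose_M = tr$states[, "LAC_out"],
               lactic_acid_M = tr$states[, "LA"], pH = tr$pH)
  }))
  utils::write.csv(rows, path, row.names = FALSE)
  if (!is.null(summary_path))
    utils::write.csv(scenario$summaries, summary_path, row.names = FALSE)
  invisible(path)
}
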