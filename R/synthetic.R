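# Synthetic-data generators: noisy batch-fermentation time series and milk
# pH-titration tables with known ground truth, for calibration and
# parameter-recovery experiments.

#' Generate a synthetic batch-fermentation dataset
#'
#' Simulates the wild-type model at the supplied ground-truth parameters,
#' samples extracellular lactose and lactic acid at `sample_times`
#' (default: every two hours over 8 h, the usual laboratory sampling
#' schedule for milk fermented at 43 degrees C with about 8\% skim-milk
#' solids), and adds independent Gaussian measurement noise truncated at
#' zero.
#'
#' @param true_params ground-truth [lacferm_params()].
#' @param init initial state (default [default_initial_state()] at the
#'   ground-truth parameters).
#' @param sample_times sampling times, h.
#' @param noise_sd Gaussian noise standard deviation, M: a single value or
#'   `c(lactose, lactic_acid)`.  Default (`NULL`): 2\% of each observable's
#'   simulated range.
#' @param seed RNG seed; the same seed reproduces the table exactly and the
#'   caller's RNG state is restored afterwards.
#' @param variant model variant to sample from (default `"wild_type"`, the
#'   organism the calibration data come from).
#' @param ... passed to [simulate_batch()].
#' @return an object of class `synthetic_dataset`: `kind = "fermentation"`,
#'   `data` (columns `time_h`, `lactose_M`, `lactic_acid_M`), `truth`
#'   (parameters and initial state), `noise_sd` (named, per observable) and
#'   `seed`.
#' @examples
#' d <- generate_fermentation_data(seed = 42)
#' d$data
#' @export
generate_fermentation_data <- function(true_params = lacferm_params(),
                                       init = NULL,
                                       sample_times = c(0, 2, 4, 6, 8),
                                       noise_sd = NULL, seed = NULL,
                                       variant = "wild_type", ...) {
  stopifnot(length(sample_times) >= 2, all(sample_times >= 0),
            all(diff(sort(sample_times)) > 0))
  sample_times <- sort(sample_times)
  if (is.null(init)) init <- default_initial_state(true_params)
  traj <- simulate_batch(true_params, init = init,
                         times = sort(unique(c(0, sample_times))),
                         variant = variant, ...)
  idx <- match(sample_times, traj$times)
  clean <- data.frame(time_h = sample_times,
                      lactose_M = unname(traj$states[idx, "LAC_out"]),
                      lactic_acid_M = unname(traj$states[idx, "LA"]))
  if (is.null(noise_sd))
    noise_sd <- 0.02 * c(diff(range(clean$lactose_M)),
                         diff(range(clean$lactic_acid_M)))
  if (length(noise_sd) == 1) noise_sd <- rep(noise_sd, 2)
  noise_sd <- stats::setNames(as.numeric(noise_sd),
                              c("lactose", "lactic_acid"))
  if (any(!is.finite(noise_sd)) || any(noise_sd < 0))
    stop("noise_sd must be finite and nonnegative")

  add_noise <- function() {
    data.frame(
      time_h = clean$time_h,
      lactose_M = pmax(clean$lactose_M +
                         stats::rnorm(nrow(clean), 0, noise_sd[["lactose"]]),
                       0),
      lactic_acid_M = pmax(clean$lactic_acid_M +
                             stats::rnorm(nrow(clean), 0,
                                          noise_sd[["lactic_acid"]]), 0))
  }
  data <- if (is.null(seed)) add_noise()
          else withr::with_seed(seed, add_noise())
  structure(list(kind = "fermentation", data = data,
                 truth = list(params = true_params, init = init,
                              clean = clean, variant = variant),
                 noise_sd = noise_sd, seed = seed),
            class = "synthetic_dataset")
}

#' Generate a synthetic pH-titration dataset
#'
#' Emulates a milk-buffering titration: the medium pH after adding known
#' amounts of lactic acid, in replicated parallel experiments (default 3),
#' generated from the quadratic `pH = c0 - c1*LA + c2*LA^2` plus Gaussian
#' noise truncated at zero.
#'
#' @param c_true named ground-truth constants `c(c0=, c1=, c2=)`.
#' @param LA_grid lactic-acid additions, M (>= 3 distinct nonnegative
#'   values).
#' @param replicates parallel experiments per level.
#' @param noise_sd pH measurement noise (default: 2\% of the curve's range
#'   over the grid).
#' @param seed RNG seed (caller's RNG state restored).
#' @return a `synthetic_dataset` with `kind = "titration"` and `data`
#'   columns `replicate`, `lactic_acid_M`, `pH`.
#' @export
generate_buffering_data <- function(c_true = c(c0 = 6.7, c1 = 24, c2 = 30),
                                    LA_grid = seq(0, 0.2, by = 0.02),
                                    replicates = 3, noise_sd = NULL,
                                    seed = NULL) {
  stopifnot(all(c("c0", "c1", "c2") %in% names(c_true)),
            all(LA_grid >= 0), length(unique(LA_grid)) >= 3,
            replicates >= 1)
  pH_true <- c_true[["c0"]] - c_true[["c1"]] * LA_grid +
    c_true[["c2"]] * LA_grid^2
  if (is.null(noise_sd)) noise_sd <- 0.02 * diff(range(pH_true))
  if (!is.finite(noise_sd) || noise_sd < 0)
    stop("noise_sd must be finite and nonnegative")
  gen <- function() {
    data.frame(
      replicate = rep(seq_len(replicates), each = length(LA_grid)),
      lactic_acid_M = rep(LA_grid, replicates),
      pH = pmax(rep(pH_true, replicates) +
                  stats::rnorm(length(LA_grid) * replicates, 0, noise_sd),
                0))
  }
  data <- if (is.null(seed)) gen() else withr::with_seed(seed, gen())
  structure(list(kind = "titration", data = data,
                 truth = list(c_true = c_true, LA_grid = LA_grid,
                              pH_true = pH_true),
                 noise_sd = c(pH = noise_sd), seed = seed),
            class = "synthetic_dataset")
}

#' @export
print.synthetic_dataset <- function(x, ...) {
  cat(sprintf("Synthetic %s dataset: %d rows, seed = %s\n", x$kind,
              nrow(x$data), if (is.null(x$seed)) "none" else x$seed))
  cat("noise sd:", paste(names(x$noise_sd),
                         signif(x$noise_sd, 3), collapse = ", "), "\n")
  invisible(x)
}

#' Write a synthetic dataset (CSV + ground-truth sidecar JSON)
#'
#' The CSV uses the same column dialect the calibration functions read;
#' the sidecar records the generating parameters, noise model and seed.
#'
#' @param dataset a `synthetic_dataset`.
#' @param path output CSV path; the sidecar is written next to it as
#'   `<path>.truth.json`.
#' @return `path`, invisibly.
#' @export
write_dataset <- function(dataset, path) {
  stopifnot(inherits(dataset, "synthetic_dataset"))
  utils::write.csv(dataset$data, path, row.names = FALSE)
  truth <- dataset$truth
  if (!is.null(truth$params)) truth$params <- unclass(truth$params)
  truth$clean <- NULL
  jsonlite::write_json(
    list(kind = dataset$kind, truth = truth,
         noise_sd = as.list(dataset$noise_sd), seed = dataset$seed),
    paste0(path, ".truth.json"), auto_unbox = TRUE, digits = NA,
    pretty = TRUE)
  invisible(path)
}
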