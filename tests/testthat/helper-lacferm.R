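# Shared fixtures for the test suite.

# A random nonnegative model state with realistic magnitudes per pool.
random_state <- function() {
  c(LAC_out = runif(1, 0, 0.15), LAC_in = runif(1, 0, 5e-3),
    GLU = runif(1, 0, 5e-3), PYR = runif(1, 0, 5e-2),
    LA = runif(1, 0, 0.3), M = runif(1, 0, 1e-9),
    LR = runif(1, 0, 1e-6), N = runif(1, 0, 1e-9),
    LS = runif(1, 0, 1e-6), LZ = runif(1, 0, 1e-6),
    X = runif(1, 0, 2))
}

# Ishigami function (a = 7, b = 0.1) on [-pi, pi]^3 and its analytic
# first-order Sobol indices, used as the estimator oracle.
ishigami <- function(X) {
  sin(X[, 1]) + 7 * sin(X[, 2])^2 + 0.1 * X[, 3]^4 * sin(X[, 1])
}
ishigami_truth <- local({
  a <- 7; b <- 0.1
  V1 <- 0.5 * (1 + b * pi^4 / 5)^2
  V2 <- a^2 / 8
  V13 <- b^2 * pi^8 * (1 / 18 - 1 / 50)
  V <- a^2 / 8 + b * pi^4 / 5 + b^2 * pi^8 / 18 + 0.5
  list(S = c(V1, V2, 0) / V,
       ST = c((V1 + V13) / V, V2 / V, V13 / V))
})
ishigami_ranges <- rbind(c(-pi, pi), c(-pi, pi), c(-pi, pi))

# Normalized-residual V2 objective recomputed independently of fit_V2.
v2_objective <- function(V2, data, params = lacferm_params()) {
  p <- update_params(params, V2 = V2)
  traj <- simulate_batch(p, init = default_initial_state(p),
                         times = sort(unique(c(0, data$time_h))),
                         variant = "wild_type")
  idx <- match(data$time_h, traj$times)
  pred_lac <- traj$states[idx, "LAC_out"]
  pred_la <- traj$states[idx, "LA"]
  sum(((pred_lac - data$lactose_M) / diff(range(data$lactose_M)))^2) +
    sum(((pred_la - data$lactic_acid_M) /
           diff(range(data$lactic_acid_M)))^2)
}
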