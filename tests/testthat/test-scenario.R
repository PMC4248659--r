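test_that("two-level runs carry the published levels and a blank control", {
  sc <- run_two_level("V1")
  expect_equal(c(sc$low, sc$high), c(10.5, 21))
  expect_equal(sc$base_params$V0, 1)
  expect_equal(sc$base_params$K_LR, 564)
  expect_named(sc$trajectories, c("low", "high", "wild_type"))
  expect_equal(sc$summaries$level, c("low", "high", "wild_type"))
  # repression only ever lowers the titre relative to wild type
  s <- setNames(sc$summaries$final_LA, sc$summaries$level)
  expect_lt(s[["high"]], s[["low"]])
  expect_lt(s[["low"]], s[["wild_type"]])
  expect_error(run_two_level("V1", low = 21, high = 10.5), "low < high")
})

test_that("final titre is monotone in the repressor drive", {
  base <- update_params(lacferm_params(), V0 = 1, K_LR = 564)
  init <- default_initial_state(base)
  final_LA <- function(p)
    summarize_scenario(simulate_batch(p, init = init))$final_LA
  la_V1 <- vapply(c(5, 10.5, 21, 42),
                  function(v) final_LA(update_params(base, V1 = v)),
                  numeric(1))
  expect_true(all(diff(la_V1) < 0))
  la_K <- vapply(c(282, 564, 1128),
                 function(v) final_LA(update_params(base, V1 = 10.5,
                                                    K_LR = v)),
                 numeric(1))
  expect_true(all(diff(la_K) < 0))
})

test_that("an engineered strain without LacR translation is wild type", {
  p <- update_params(lacferm_params(), K_LR = 0)
  init <- default_initial_state(p)
  eng <- simulate_batch(p, init = init, variant = "engineered")
  wt <- simulate_batch(p, init = init, variant = "wild_type")
  shared <- c("LAC_out", "LAC_in", "GLU", "PYR", "LA", "N", "LS", "LZ", "X")
  expect_equal(eng$states[, shared], wt$states[, shared],
               tolerance = 1e-8)
  expect_equal(max(eng$states[, "LR"]), 0)
})

test_that("run summaries report titre, pH and threshold crossing", {
  p <- update_params(lacferm_params(), V0 = 0, V2 = 0)
  zero <- simulate_batch(p, init = setNames(numeric(11),
                                            names(default_initial_state(p))),
                         variant = "wild_type")
  s <- summarize_scenario(zero)
  expect_equal(s$final_LA, 0)
  expect_equal(s$final_pH, p$c0)
  expect_true(is.na(s$pH_cross_time_h))

  wt <- simulate_batch(lacferm_params(), variant = "wild_type")
  sw <- summarize_scenario(wt)
  expect_lt(sw$final_pH, wt$pH[1])
  expect_gt(sw$lactose_consumed, 0)
  # crossing time interpolates the first bracketing grid interval
  i <- which(wt$pH[-length(wt$pH)] > 5.5 & wt$pH[-1] <= 5.5)[1]
  by_hand <- wt$times[i] + (wt$pH[i] - 5.5) / (wt$pH[i] - wt$pH[i + 1]) *
    diff(wt$times[i + 0:1])
  expect_equal(sw$pH_cross_time_h, by_hand)
  expect_gte(sw$pH_cross_time_h, wt$times[i])
  expect_lte(sw$pH_cross_time_h, wt$times[i + 1])
})

test_that("crossing time handles synthetic edge trajectories", {
  fake <- structure(list(
    times = 0:2,
    states = matrix(0, 3, 11,
                    dimnames = list(NULL, c("LAC_out", "LAC_in", "GLU",
                                            "PYR", "LA", "M", "LR", "N",
                                            "LS", "LZ", "X"))),
    pH = c(6, 5.6, 5.2),
    params = lacferm_params(),
    variant = "engineered"), class = "lacferm_trajectory")
  expect_equal(summarize_scenario(fake)$pH_cross_time_h, 1.25)
  fake$pH <- c(5.4, 5.3, 5.2)  # already past threshold at t = 0
  expect_equal(summarize_scenario(fake)$pH_cross_time_h, 0)
})
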