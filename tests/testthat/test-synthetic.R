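test_that("noiseless fermentation samples lie on the model trajectory", {
  d <- generate_fermentation_data(noise_sd = 0)
  expect_equal(d$data, d$truth$clean)
  tr <- simulate_batch(d$truth$params, init = d$truth$init,
                       times = c(0, 2, 4, 6, 8), variant = "wild_type")
  expect_equal(d$data$lactose_M, unname(tr$states[, "LAC_out"]),
               tolerance = 1e-10)
  expect_equal(d$data$lactic_acid_M, unname(tr$states[, "LA"]),
               tolerance = 1e-10)
})

test_that("fermentation noise is reproducible and seed-dependent", {
  a <- generate_fermentation_data(seed = 42)
  b <- generate_fermentation_data(seed = 42)
  c2 <- generate_fermentation_data(seed = 43)
  expect_identical(a$data, b$data)
  expect_false(identical(a$data, c2$data))
  expect_true(all(a$data$lactose_M >= 0))
  expect_error(generate_fermentation_data(noise_sd = -1e-3), "nonnegative")
  # generation does not disturb the caller's RNG stream
  set.seed(1); x <- runif(1)
  set.seed(1); invisible(generate_fermentation_data(seed = 7))
  expect_identical(runif(1), x)
})

test_that("default fermentation noise is 2% of each observable's range", {
  d <- generate_fermentation_data(seed = 1)
  clean <- d$truth$clean
  expect_equal(unname(d$noise_sd),
               0.02 * c(diff(range(clean$lactose_M)),
                        diff(range(clean$lactic_acid_M))))
})

test_that("titration data follow the generating quadratic", {
  truth <- c(c0 = 6.55, c1 = 21, c2 = 26)
  d0 <- generate_buffering_data(truth, noise_sd = 0, seed = 3)
  expect_equal(d0$data$pH,
               rep(truth[["c0"]] - truth[["c1"]] * d0$truth$LA_grid +
                     truth[["c2"]] * d0$truth$LA_grid^2, 3))
  fit <- fit_pH_curve(d0$data)
  expect_equal(coef(fit), truth, tolerance = 1e-9)
  expect_equal(nrow(d0$data), 3 * length(d0$truth$LA_grid))
})

test_that("replicate means converge to the curve with more replicates", {
  truth <- c(c0 = 6.7, c1 = 24, c2 = 30)
  curve <- function(la)
    truth[["c0"]] - truth[["c1"]] * la + truth[["c2"]] * la^2
  dev_for <- function(reps, seed) {
    d <- generate_buffering_data(truth, replicates = reps,
                                 noise_sd = 0.1, seed = seed)$data
    agg <- aggregate(pH ~ lactic_acid_M, d, mean)
    max(abs(agg$pH - curve(agg$lactic_acid_M)))
  }
  few <- mean(vapply(1:5, function(s) dev_for(2, s), numeric(1)))
  many <- mean(vapply(1:5, function(s) dev_for(40, s), numeric(1)))
  expect_lt(many, few)
})

test_that("datasets round-trip to CSV with a ground-truth sidecar", {
  d <- generate_fermentation_data(seed = 8)
  f <- withr::local_tempfile(fileext = ".csv")
  write_dataset(d, f)
  back <- read.csv(f)
  expect_equal(back$lactic_acid_M, d$data$lactic_acid_M,
               tolerance = 1e-12)
  truth <- jsonlite::read_json(paste0(f, ".truth.json"),
                               simplifyVector = TRUE)
  expect_equal(truth$truth$params$V2, 3.5)
  expect_equal(truth$seed, 8)
})

test_that("generate-fit-simulate closes the loop without external files", {
  titr <- generate_buffering_data(seed = 11)
  cfit <- fit_pH_curve(titr$data)
  ferm <- generate_fermentation_data(seed = 12)
  vfit <- fit_V2(ferm$data)
  cc <- coef(cfit)
  p <- update_params(lacferm_params(), V2 = unname(coef(vfit)),
                     c0 = cc[["c0"]], c1 = cc[["c1"]], c2 = cc[["c2"]])
  sc <- run_two_level("V1", base_params = update_params(p, V0 = 1,
                                                        K_LR = 564))
  s <- setNames(sc$summaries$final_LA, sc$summaries$level)
  expect_lt(s[["high"]], s[["wild_type"]])
})
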