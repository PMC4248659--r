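test_that("promoter switch has the tanh step shape", {
  expect_identical(switch_F(5.5), 1)              # exactly 1 at threshold
  expect_equal(switch_F(1e6), 0)                  # alkaline asymptote
  expect_equal(switch_F(-1e6), 2)                 # acidic asymptote
  expect_equal(switch_F(4.5), 1.7615941559558, tolerance = 1e-12)
  # strictly decreasing, bounded in (0, 2)
  grid <- switch_F(seq(0, 14, by = 0.05))
  expect_true(all(diff(grid) < 0))
  expect_true(all(grid > 0 & grid < 2))
  # slope at threshold equals -n
  for (n in c(0.5, 1, 3)) {
    h <- 1e-6
    slope <- (switch_F(5.5 + h, n) - switch_F(5.5 - h, n)) / (2 * h)
    expect_equal(slope, -n, tolerance = 1e-6)
  }
  expect_error(switch_F(NA_real_), "finite")
  expect_error(switch_F(5, n = 0), "positive")
})

test_that("buffering curve evaluates, stays monotone, and warns past its vertex", {
  expect_equal(pH_from_LA(0, c0 = 6.2), 6.2)
  # default constants are monotone decreasing over the fermentation range
  pH <- pH_from_LA(seq(0, 0.3, by = 0.01))
  expect_true(all(diff(pH) < 0))
  # vertex of the default quadratic sits at c1/(2 c2) = 0.4 M, beyond range
  expect_silent(pH_from_LA(0.39))
  expect_warning(pH_from_LA(c(0, 0.5)), "non-monotone")
  expect_error(pH_from_LA(-0.1), "nonnegative")
})

test_that("growth law has Monod saturation and product-inhibition zero", {
  p <- lacferm_params()
  expect_equal(growth_rate(1e6, 0, p), 0.8, tolerance = 1e-5)
  expect_equal(growth_rate(0.05, p$K_LA, p), 0)
  expect_equal(growth_rate(p$Ks, 0, p), 0.4)
  # negative above K_LA, returned as-is
  expect_lt(growth_rate(0.05, 0.5, p), 0)
})

test_that("reaction rates vanish with their enzymes and hit printed limits", {
  p <- lacferm_params()
  s <- random_state()
  s["LS"] <- 0
  r <- reaction_rates(s, p)
  expect_equal(unname(r[c("R1", "R2")]), c(0, 0))
  s <- random_state()
  s["LR"] <- 0
  r <- reaction_rates(s, p)
  expect_equal(unname(r[c("R10", "R13")]), c(0, 0))
  # glycolysis half-saturation with published constants
  s <- random_state()
  s["GLU"] <- p$Km_GLYC
  expect_equal(unname(reaction_rates(s, p)[["R4"]]), 143.82 / 2)
  # repression saturates at T_max * G
  s["LR"] <- 1e6
  expect_equal(unname(reaction_rates(s, p)[["R13"]]), 6e4 * 2.5e-9,
               tolerance = 1e-6)
})

test_that("all reaction rates are nonnegative on nonnegative states", {
  p <- lacferm_params()
  set.seed(11)
  for (i in 1:50) {
    r <- reaction_rates(random_state(), p)
    expect_true(all(r >= 0))
  }
})

test_that("wild-type expression steady state is a fixed point of the rhs", {
  p <- lacferm_params()
  # LAC_out = 0 freezes growth at 0; closed forms at mu_bar = 0
  eq <- equilibrate_expression(p, mu_bar = 0)
  expect_equal(eq[["N"]], 3.5 * 2.5e-9 / 41.58)
  s <- c(N = eq[["N"]], LS = eq[["LS"]], LZ = eq[["LZ"]])
  d <- ode_rhs(0, s, p, variant = "wild_type")
  expect_equal(unname(d[c("N", "LS", "LZ")]), c(0, 0, 0),
               tolerance = 1e-12)
})

test_that("engineered rhs reduces to wild type when the lacR circuit is off", {
  p <- update_params(lacferm_params(), V0 = 0, V1 = 0)
  set.seed(7)
  for (i in 1:20) {
    s <- random_state()
    s[c("M", "LR")] <- 0
    expect_equal(ode_rhs(0, s, p, "engineered"),
                 ode_rhs(0, s, p, "wild_type"))
  }
})

test_that("carbon is conserved pointwise when LacR-lactose binding is off", {
  p <- update_params(lacferm_params(), Kb = 0)
  set.seed(13)
  for (i in 1:20) {
    d <- ode_rhs(0, random_state(), p, "engineered")
    combo <- d[["LAC_out"]] + d[["LAC_in"]] + d[["GLU"]] +
      (d[["PYR"]] + d[["LA"]]) / p$pyr_per_glc
    expect_equal(combo, 0, tolerance = 1e-12)
  }
})

test_that("the origin is a fixed point once constitutive transcription is off", {
  s0 <- setNames(numeric(11),
                 c("LAC_out", "LAC_in", "GLU", "PYR", "LA", "M", "LR",
                   "N", "LS", "LZ", "X"))
  p_wt <- update_params(lacferm_params(), V0 = 0, V2 = 0)
  expect_equal(max(abs(ode_rhs(0, s0, p_wt, "wild_type"))), 0)
  # the engineered variant additionally needs the pH-induced term off
  p_eng <- update_params(lacferm_params(), V0 = 0, V1 = 0, V2 = 0)
  expect_equal(max(abs(ode_rhs(0, s0, p_eng, "engineered"))), 0)
  expect_error(ode_rhs(0, replace(s0, 3, NaN), p_wt, "wild_type"),
               "non-finite")
})
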