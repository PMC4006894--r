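# Closed-form rate model and its thermodynamic constituents.

test_that("unfolding free energy reduces to a line as dCp -> 0", {
  # with vanishing heat capacity change dG = dH* - T dS*, zero at 4874/17
  T0 <- u_ref$dH_star / u_ref$dS_star
  dG <- unfolding_free_energy(T0, u_ref, dCp = 1e-9)
  expect_lt(abs(dG), 1e-4)
  expect_gt(unfolding_free_energy(T0 - 10, u_ref, dCp = 1e-9), 0)
  expect_lt(unfolding_free_energy(T0 + 10, u_ref, dCp = 1e-9), 0)
})

test_that("unfolding free energy matches high-precision evaluation", {
  # frozen from an independent term-by-term evaluation of the closed form
  expect_equal(unfolding_free_energy(310, u_ref, 59.9), -13.68002,
               tolerance = 1e-6)
  # maximizer sits at the published mesophile stability temperature
  opt <- optimize(function(T) unfolding_free_energy(T, u_ref, 59.9),
                  c(250, 350), maximum = TRUE, tol = 1e-8)
  expect_equal(opt$maximum, 294.31, tolerance = 1e-2)
  expect_lt(abs(opt$maximum - 294), 0.5)
})

test_that("free energy is strictly concave with a unique maximum", {
  set.seed(1)
  for (rep in 1:50) {
    u <- universal_params(runif(1, 4000, 6000), runif(1, 12, 22),
                          runif(1, 370, 380), runif(1, 385, 395))
    dCp <- runif(1, 20, 120)
    Tg <- seq(220, 440, by = 1)
    dG <- unfolding_free_energy(Tg, u, dCp)
    d2 <- diff(dG, differences = 2)
    expect_true(all(d2 < 0))                      # concave everywhere
    d1 <- diff(dG)
    expect_lte(sum(d1[-length(d1)] > 0 & d1[-1] < 0), 1)  # single peak
    expect_lte(sum(abs(diff(sign(dG))) > 0), 2)   # at most two zeros
  }
})

test_that("domain errors are raised for invalid inputs", {
  expect_error(unfolding_free_energy(-5, u_ref, 59.9), "positive")
  expect_error(unfolding_free_energy(300, u_ref, -1), "dCp")
  expect_error(universal_params(4874, 17, 390.9, 375.5), "T_H")
  expect_error(strain_params(-1, 75300, 59.9, 422))
})

test_that("native-state probability is a proper two-state equilibrium", {
  # logistic midpoint: P = 1/2 exactly where dG = 0
  hb <- half_denaturation_bounds(u_ref, 59.9)
  expect_equal(native_state_probability(hb[["T_L"]], u_ref, 59.9, 422), 0.5,
               tolerance = 1e-9)
  expect_equal(native_state_probability(hb[["T_U"]], u_ref, 59.9, 7), 0.5,
               tolerance = 1e-9)
  # frozen from direct high-precision evaluation at the stability optimum
  expect_equal(native_state_probability(294.3, u_ref, 59.9, 422), 0.868134,
               tolerance = 1e-5)
  # n -> 0 washes out the transition entirely
  expect_equal(native_state_probability(c(260, 300, 400), u_ref, 59.9, 1e-12),
               rep(0.5, 3), tolerance = 1e-9)
})

test_that("native-state probability saturates instead of overflowing", {
  p <- native_state_probability(c(200, 500), u_ref, 59.9, 1e5)
  expect_false(any(is.nan(p)))
  expect_equal(p, c(0, 0), tolerance = 1e-12)  # deeply denatured both sides
  p2 <- native_state_probability(294.3, u_ref, 59.9, 1e5)
  expect_equal(p2, 1, tolerance = 1e-12)
})

test_that("growth rate reduces to c*T/2 without activation or denaturation", {
  s <- strain_params(c = 2.5, dH_act = 1e-9, dCp = 59.9, n = 1e-12)
  Tv <- c(280, 300, 350)
  expect_equal(growth_rate(Tv, u_ref, s), 2.5 * Tv / 2, tolerance = 1e-9)
})

test_that("growth rate equals term-by-term evaluation on a fine grid", {
  Tv <- seq(260, 400, length.out = 1000)
  r <- growth_rate(Tv, u_ref, meso)
  R <- 8.314
  dG <- u_ref$dH_star + meso$dCp * (Tv - u_ref$T_H) -
    Tv * (u_ref$dS_star + meso$dCp * log(Tv / u_ref$T_S))
  oracle <- meso$c * Tv * exp(-meso$dH_act / (R * Tv)) /
    (1 + exp(-meso$n * dG / (R * Tv)))
  expect_equal(r, oracle, tolerance = 1e-10)
  expect_true(all(r >= 0) && !any(is.nan(r)))
})

test_that("rates are invariant under joint rescaling of units and c", {
  s2 <- meso; s2$c <- meso$c * 1e3
  expect_equal(growth_rate(300, u_ref, s2), 1e3 * growth_rate(300, u_ref, meso),
               tolerance = 1e-12)
})

test_that("activation enthalpy and residue count act as the model says", {
  # larger dH_act strictly reduces the Arrhenius numerator at fixed T
  s_hi <- meso; s_hi$dH_act <- meso$dH_act * 1.2
  expect_lt(growth_rate(300, u_ref, s_hi), growth_rate(300, u_ref, meso))
  # larger n sharpens the denominator transition at its midpoint
  hb <- half_denaturation_bounds(u_ref, 59.9)
  slope <- function(n) {
    h <- 1e-3
    (native_state_probability(hb[["T_U"]] + h, u_ref, 59.9, n) -
       native_state_probability(hb[["T_U"]] - h, u_ref, 59.9, n)) / (2 * h)
  }
  expect_gt(abs(slope(844)), 1.9 * abs(slope(422)))
})

test_that("rate curves are unimodal for prior-plausible parameters", {
  set.seed(2)
  for (rep in 1:25) {
    u <- universal_params(runif(1, 4000, 6000), runif(1, 15.5, 18.5),
                          runif(1, 370, 380), runif(1, 385, 395))
    s <- strain_params(1, runif(1, 2e4, 2e5), runif(1, 20, 120),
                       runif(1, 50, 1000))
    lr <- growth_rate(seq(250, 420, by = 0.5), u, s, log = TRUE)
    d <- diff(lr)
    expect_lte(sum(d[-length(d)] > 0 & d[-1] < 0), 1)
  }
})
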