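# Hierarchical MCMC engine: determinism, prior-only sampling, parameter
# recovery at desk scale, two-stage standardization, single-strain NLS.

test_that("identical seeds give identical chains", {
  sim <- small_sim(seed = 30)
  f1 <- thermo_fit(sim$records, iterations = 300, seed = 5)
  f2 <- thermo_fit(sim$records, iterations = 300, seed = 5)
  expect_identical(f1$chain, f2$chain)
  f3 <- thermo_fit(sim$records, iterations = 300, seed = 6)
  expect_false(identical(f1$chain, f3$chain))
})

test_that("a prior-only run reproduces the uniform prior moments", {
  sim <- small_sim(seed = 31, points = 5)
  pr <- thermo_priors()
  f <- thermo_fit(sim$records, priors = pr, iterations = 8000, seed = 7,
                  lik_power = 0)
  d <- posterior_draws(f)
  for (p in rownames(pr$universal)) {
    x <- d[, paste0("u.", p)]
    b <- pr$universal[p, ]
    ess <- max(20, nrow(d) / 100)
    se <- (b[2] - b[1]) / sqrt(12) / sqrt(ess)
    expect_lt(abs(mean(x) - mean(b)), 3 * se)
    expect_gte(min(x), b[1]); expect_lte(max(x), b[2])
  }
})

test_that("strain and group parameters are recovered on synthetic data", {
  # desk-scale run: the well-populated mesophile group and the universal
  # parameters must recover; sparsely-populated groups (2 strains) keep
  # legitimately wide, weakly-identified residue-count posteriors and are
  # checked only where the data identify them
  sim <- small_sim(seed = 32)
  f <- thermo_fit(sim$records, iterations = 40000, seed = 8, thin = 4)
  cf <- coef(f)
  gm <- groups_ref[groups_ref$group == "mesophile", ]
  expect_lt(abs(cf[["mu.mesophile.dCp"]] - gm$dCp) / gm$dCp, 0.15)
  expect_lt(abs(cf[["mu.mesophile.dH_act"]] - gm$dH_act) / gm$dH_act, 0.2)
  expect_lt(abs(cf[["mu.mesophile.n"]] - gm$n) / gm$n, 0.3)
  gt <- groups_ref[groups_ref$group == "thermophile", ]
  expect_lt(abs(cf[["mu.thermophile.dCp"]] - gt$dCp) / gt$dCp, 0.15)
  # universal parameters inside their (narrow) boxes and near truth
  expect_lt(abs(cf[["u.T_S"]] - 390.9), 4)
  expect_lt(abs(cf[["u.T_H"]] - 375.5), 4)
  expect_lt(abs(cf[["u.dH_star"]] - 4874) / 4874, 0.12)
})

test_that("posterior summaries use retained draws and behave sanely", {
  sim <- small_sim(seed = 33, points = 6)
  f <- thermo_fit(sim$records, iterations = 2000, seed = 9, burn_in = 0.5)
  expect_equal(length(f$retained_rows), 1000)
  p <- f$posterior
  expect_true(all(p$lower99 < p$upper99))
  # HPDI contains the posterior mean for these unimodal marginals
  expect_true(all(p$mean >= p$lower99 & p$mean <= p$upper99))
  # methods are consistent with the stored records
  expect_length(predict(f), nrow(sim$records))
  expect_length(residuals(f), nrow(sim$records))
  expect_equal(dim(simulate(f, nsim = 2, seed = 1)),
               c(nrow(sim$records), 2))
  expect_output(print(f), "Universal parameters")
  expect_output(print(summary(f)), "Acceptance rates")
})

test_that("two-stage standardization pins fitted maxima near one", {
  cfg <- sim_config(groups = groups_ref[2, ], strains_per_group = 4,
                    points_per_strain = 12, noise_sd = 0.01, seed = 34,
                    sd_dH_act = 1000, sd_dCp = 0.5, sd_n = 8)
  sim <- simulate_growth(cfg)
  f2 <- two_stage_fit(sim$records, iterations = 10000, seed = 10,
                      stage1_iterations = 10000)
  mx <- fitted_curve_max(f2)
  expect_true(all(abs(mx - 1) < 0.08))
  # rescaled observations still have per-strain maxima near one
  mx_obs <- tapply(f2$records$rate_std, f2$records$strain_id, max)
  expect_true(all(abs(mx_obs - 1) < 0.1))
  # thermodynamic posteriors agree between the stages within MC error
  # (the residue count is weakly identified in a single-group design and
  # is allowed a wider band)
  cf1 <- coef(f2$stage1, "group"); cf2 <- coef(f2, "group")
  for (p in names(cf1)) {
    tol <- if (grepl("\\.n$", p)) 0.5 else 0.25
    expect_lt(abs(cf1[[p]] - cf2[[p]]) / abs(cf1[[p]]), tol)
  }
})

test_that("single-strain least squares recovers a noise-free strain", {
  s_true <- strain_params(1, 75300, 59.9, 422, "mesophile")
  To <- as.numeric(optimal_temperature(u_ref, s_true))
  s_true$c <- 1 / growth_rate(To, u_ref, s_true)
  temps <- biokinetic_grid(s_true, u_ref, 16)
  rec <- data.frame(temperature_K = temps,
                    rate_obs = growth_rate(temps, u_ref, s_true))
  fit <- fit_single_strain(rec, u_ref)
  cf <- coef(fit)
  expect_lt(abs(cf[["dH_act"]] - 75300) / 75300, 0.01)
  expect_lt(abs(cf[["dCp"]] - 59.9) / 59.9, 0.01)
  expect_lt(abs(cf[["n"]] - 422) / 422, 0.01)
  expect_lt(abs(cf[["dH_star"]] - 4874) / 4874, 0.01)
})

test_that("fixing all but c reduces to the closed-form linear fit", {
  s_true <- strain_params(3.2e10, 75300, 59.9, 422)
  temps <- seq(285, 305, by = 2)
  rec <- data.frame(temperature_K = temps,
                    rate_obs = growth_rate(temps, u_ref, s_true) *
                      exp(rnorm(length(temps), 0, 0.01)))
  fixed <- c(dH_act = 75300, dCp = 59.9, n = 422, dH_star = 4874,
             dS_star = u_ref$dS_star, T_H = u_ref$T_H, T_S = u_ref$T_S)
  fit <- fit_single_strain(rec, u_ref, fixed = fixed)
  # sqrt model = exp(log_c / 2) * known curve: linear LS in a = exp(log_c/2)
  base <- growth_rate(temps, u_ref,
                      strain_params(1, 75300, 59.9, 422))
  a_hat <- sum(sqrt(rec$rate_obs) * sqrt(base)) / sum(base)
  expect_equal(coef(fit)[["log_c"]], 2 * log(a_hat), tolerance = 1e-4)
})

test_that("single-strain estimates are unit-scale equivariant except c", {
  set.seed(35)
  s_true <- strain_params(1, 75300, 59.9, 422)
  To <- as.numeric(optimal_temperature(u_ref, s_true))
  s_true$c <- 1 / growth_rate(To, u_ref, s_true)
  temps <- biokinetic_grid(s_true, u_ref, 12)
  r <- growth_rate(temps, u_ref, s_true) * exp(rnorm(12, 0, 0.02))
  f1 <- fit_single_strain(data.frame(temperature_K = temps, rate_obs = r),
                          u_ref)
  f2 <- fit_single_strain(data.frame(temperature_K = temps, rate_obs = 100 * r),
                          u_ref)
  for (p in c("dH_act", "dCp", "n", "dH_star"))
    expect_equal(coef(f1)[[p]], coef(f2)[[p]], tolerance = 1e-3)
  expect_equal(coef(f2)[["log_c"]] - coef(f1)[["log_c"]], log(100),
               tolerance = 1e-3)
})

test_that("insufficient data is rejected with a clear message", {
  rec <- data.frame(temperature_K = c(290, 295, 300),
                    rate_obs = c(0.5, 1, 0.7))
  expect_error(fit_single_strain(rec, u_ref), "at least 6")
})
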