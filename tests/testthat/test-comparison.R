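# Grouping structures, thermal-group allocation, and Bayes-factor
# estimators on conjugate toys.

test_that("thermal-group allocation follows the cut-points", {
  expect_equal(allocate_thermal_groups(294), "mesophile")
  expect_equal(allocate_thermal_groups(325), "hyperthermophile")
  expect_equal(allocate_thermal_groups(277), "psychrophile")
  expect_equal(allocate_thermal_groups(307), "thermophile")
  # boundary values go to the lower group
  expect_equal(allocate_thermal_groups(c(285, 300, 316)),
               c("psychrophile", "mesophile", "thermophile"))
  expect_identical(allocate_thermal_groups(numeric(0)), character(0))
  # idempotence: re-allocating with the same T* reproduces the labels
  Ts <- c(280, 295, 310, 330)
  expect_identical(allocate_thermal_groups(Ts),
                   allocate_thermal_groups(Ts))
  # model V routes flagged Ascomycota to their own group regardless of T*
  expect_equal(allocate_thermal_groups(c(296, 296), ascomycota = c(TRUE, FALSE),
                                       model = "V"),
               c("ascomycota", "mesophile"))
})

test_that("structure assignments honour taxonomy metadata", {
  meta <- data.frame(
    strain_id = c("a", "b", "c", "d"),
    domain = c("Bacteria", "Archaea", "Eukarya", "Eukarya"),
    cellularity = c("unicellular", "unicellular", "unicellular",
                    "multicellular"),
    ascomycota = c(FALSE, FALSE, TRUE, FALSE),
    stringsAsFactors = FALSE
  )
  expect_equal(structure_assignment(meta, thermal_structure("I"))$group,
               rep("all", 4))
  expect_equal(structure_assignment(meta, thermal_structure("II"))$group,
               meta$domain)
  expect_equal(structure_assignment(meta, thermal_structure("III"))$group,
               c("Bacteria", "Archaea", "Eukarya_unicellular",
                 "Eukarya_multicellular"))
  Ts <- c(280, 320, 296, 296)
  expect_equal(structure_assignment(meta, thermal_structure("V"), Ts)$group,
               c("psychrophile", "hyperthermophile", "ascomycota",
                 "mesophile"))
  expect_error(structure_assignment(meta, thermal_structure("IV")),
               "stability temperatures")
  expect_error(thermal_structure("IV", thresholds = c(300, 285, 316)),
               "increasing")
})

# conjugate toy: y ~ N(theta, sigma2 known), theta ~ N(m0, v0).
# closed-form log marginal likelihood by direct integration:
# p(y) = N(y; m0*1, sigma2*I + v0*J)
.toy_logml_exact <- function(y, sigma2, m0, v0) {
  n <- length(y)
  S <- diag(sigma2, n) + matrix(v0, n, n)
  -0.5 * (n * log(2 * pi) + determinant(S)$modulus +
            drop((y - m0) %*% solve(S) %*% (y - m0)))
}

test_that("stepping-stone estimator matches the conjugate closed form", {
  set.seed(40)
  y <- rnorm(25, 1.4, 1)
  sigma2 <- 1; m0 <- 0; v0 <- 4
  exact <- .toy_logml_exact(y, sigma2, m0, v0)
  # power posterior at tempering b is conjugate: sample it exactly
  K <- 10
  betas <- (0:K / K)^3
  draws <- lapply(seq_len(K), function(k) {
    b <- betas[k]
    prec <- 1 / v0 + b * length(y) / sigma2
    mu <- (m0 / v0 + b * sum(y) / sigma2) / prec
    th <- rnorm(4000, mu, sqrt(1 / prec))
    vapply(th, function(t) sum(dnorm(y, t, 1, log = TRUE)), 0)
  })
  est <- stepping_stone_logml(draws, betas)
  expect_lt(abs(est$logml - exact), 3 * est$se + 0.05)
})

test_that("product-space sampler recovers a conjugate Bayes factor", {
  set.seed(41)
  y <- rnorm(20, 0.15, 1)   # moderate evidence: both models get visited
  # model 1: theta ~ N(0, 4); model 2: point null theta = 0
  exact1 <- .toy_logml_exact(y, 1, 0, 4)
  exact2 <- sum(dnorm(y, 0, 1, log = TRUE))
  exact_logbf <- exact1 - exact2
  # posterior for model 1 is conjugate; model 2 has no free parameter
  prec <- 1 / 4 + 20; mu <- sum(y) / prec
  step1 <- function(state)
    list(state = rnorm(1, mu, sqrt(1 / prec)), log_post = 0)
  step2 <- function(state) list(state = 0, log_post = 0)
  logpost1 <- function(th) sum(dnorm(y, th, 1, log = TRUE)) +
    dnorm(th, 0, 2, log = TRUE)
  logpost2 <- function(th) sum(dnorm(y, 0, 1, log = TRUE))
  pseudo1 <- list(draw = function() rnorm(1, mu, sqrt(1 / prec)),
                  logdens = function(x) dnorm(x, mu, sqrt(1 / prec),
                                              log = TRUE))
  pseudo2 <- list(draw = function() 0, logdens = function(x) 0)
  out <- product_space_bf(step1, step2, logpost1, logpost2,
                          pseudo1, pseudo2, mu, 0, n_iter = 20000)
  expect_lt(abs(out$log_bf12 - exact_logbf), 0.25)
  # identical models give a Bayes factor of one within MC error
  out2 <- product_space_bf(step1, step1, logpost1, logpost1,
                           pseudo1, pseudo1, mu, mu, n_iter = 20000)
  expect_lt(abs(out2$log_bf12), 0.1)
})

test_that("pilot stability temperatures separate the thermal groups", {
  sim <- small_sim(seed = 42)
  Ts <- pilot_stability_temperatures(sim$records)
  truth <- sim$strains$group[match(names(Ts), sim$strains$strain_id)]
  true_Ts <- stability_temperature(sim$universal, sim$strains$dCp)
  # per-strain least-squares pilots recover the stability temperatures well
  expect_lt(max(abs(Ts - true_Ts)), 4)
  expect_lt(mean(Ts[truth == "psychrophile"]) + 5,
            mean(Ts[truth == "mesophile"]))
  expect_lt(mean(Ts[truth == "mesophile"]) + 5,
            mean(Ts[truth == "thermophile"]))
  # allocation on the true stability temperatures is exact and idempotent
  Ts_true <- stability_temperature(
    sim$universal, sim$strains$dCp)
  lab <- allocate_thermal_groups(Ts_true)
  expect_equal(lab[truth == "psychrophile"],
               rep("psychrophile", sum(truth == "psychrophile")))
  expect_equal(lab[truth == "thermophile"],
               rep("thermophile", sum(truth == "thermophile")))
})
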