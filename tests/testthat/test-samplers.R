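# Low-level samplers against known targets, and the HPDI routine against
# brute-force oracles.

test_that("hpdi matches the uniform-case closed form with low tie-break", {
  iv <- hpdi(1:100, level = 0.5)
  expect_equal(unname(iv[2] - iv[1]), 49)
  expect_equal(unname(iv[1]), 1)       # ties broken toward the lowest start
  expect_error(hpdi(1:100, level = 1.2), "level")
})

test_that("hpdi recovers normal quantiles at large n", {
  set.seed(7)
  x <- rnorm(1e5)
  iv <- hpdi(x, 0.99)
  expect_equal(unname(iv), c(-2.576, 2.576), tolerance = 0.02)
})

test_that("hpdi equals an exhaustive window-scan oracle", {
  set.seed(8)
  for (rep in 1:5) {
    x <- rgamma(1000, shape = 2)
    for (level in c(0.5, 0.9, 0.99)) {
      s <- sort(x)
      m <- ceiling(level * length(s))
      best <- Inf; lo <- NA
      for (i in seq_len(length(s) - m + 1)) {       # brute force scan
        w <- s[i + m - 1] - s[i]
        if (w < best) { best <- w; lo <- i }
      }
      expect_equal(unname(hpdi(x, level)), c(s[lo], s[lo + m - 1]))
    }
  }
})

# correlated 4-D Gaussian target used by both sampler suites
.gauss_target <- function() {
  S <- outer(1:4, 1:4, function(i, j) 0.7^abs(i - j)) * (1:4 %o% 1:4)^0.5
  P <- solve(S)
  list(S = S, lp = function(x) -0.5 * drop(x %*% P %*% x))
}

test_that("the Haario kernel samples a correlated Gaussian correctly", {
  set.seed(9)
  tg <- .gauss_target()
  k <- haario_kernel(4, sd0 = 0.5, warmup = 500)
  x <- rep(0, 4); lp <- tg$lp(x)
  n <- 2e5
  out <- matrix(NA_real_, n, 4)
  for (i in seq_len(n)) {
    st <- haario_step(k, x, lp, tg$lp)
    x <- st$x; lp <- st$lp
    out[i, ] <- x
  }
  keep <- out[(n / 2 + 1):n, ]
  emp <- cov(keep)
  expect_lt(norm(emp - tg$S, "F") / norm(tg$S, "F"), 0.1)
  acc <- k$n_acc / k$n_prop
  expect_gt(acc, 0.1); expect_lt(acc, 0.5)
  # a -Inf proposal can never be accepted
  k2 <- haario_kernel(1, sd0 = 1)
  st <- haario_step(k2, 0, 0, function(x) -Inf)
  expect_false(st$accepted)
  expect_equal(st$x, 0)
})

test_that("direction updates on parallel points recover a Gaussian target", {
  set.seed(10)
  tg <- .gauss_target()
  m <- 10
  X <- matrix(rnorm(m * 4, sd = 2), m, 4)
  lps <- apply(X, 1, tg$lp)
  n_sweep <- 12000
  sums <- matrix(0, 1, 4); cnt <- 0
  for (it in seq_len(n_sweep)) {
    for (i in seq_len(m)) {
      st <- direction_update(X, i, lps[i], tg$lp)
      X[i, ] <- st$x; lps[i] <- st$lp
    }
    if (it > n_sweep / 2) { sums <- sums + colSums(X); cnt <- cnt + m }
  }
  means <- drop(sums) / cnt
  # marginal SDs are sqrt(diag(S)) = 1..2; allow 3 SE with a conservative
  # effective sample size of cnt / 50
  se <- sqrt(diag(tg$S)) / sqrt(cnt / 50)
  expect_true(all(abs(means) < 3 * se + 0.05))
})

test_that("degenerate directions and stepping-stone limits behave", {
  tg <- .gauss_target()
  X <- matrix(1, 4, 4)      # identical points: no usable direction
  st <- direction_update(X, 1, tg$lp(X[1, ]), tg$lp)
  expect_false(st$accepted)
  expect_equal(st$x, X[1, ])
  # stepping_prob = 0 gives the identical RNG trajectory as omitting the
  # stepping-stone machinery entirely
  X <- matrix(rnorm(16), 4, 4)
  set.seed(11)
  r1 <- direction_update(X, 2, tg$lp(X[2, ]), tg$lp, stepping_prob = 0,
                         stepping_sampler = function() rnorm(4),
                         stepping_logdens = function(x) sum(dnorm(x, log = TRUE)))
  set.seed(11)
  r2 <- direction_update(X, 2, tg$lp(X[2, ]), tg$lp, stepping_prob = 0)
  expect_identical(r1, r2)
})

test_that("stepping-stone proposals obey the Hastings correction", {
  # with an independence proposal equal to the target, every move accepts
  set.seed(12)
  X <- matrix(rnorm(16), 4, 4)
  lp <- function(x) sum(dnorm(x, log = TRUE))
  accepts <- replicate(200, direction_update(
    X, 1, lp(X[1, ]), lp, stepping_prob = 1,
    stepping_sampler = function() rnorm(4),
    stepping_logdens = lp)$accepted)
  expect_true(all(accepts))
})

test_that("a conjugate Gaussian toy posterior is sampled exactly", {
  # y_i ~ N(theta, 1), theta ~ N(0, 10^2): closed-form posterior
  set.seed(13)
  y <- rnorm(20, 2, 1)
  post_prec <- 20 + 1 / 100
  post_mean <- sum(y) / post_prec
  lp <- function(th) -0.5 * 20 * (th - mean(y))^2 - 0.5 * th^2 / 100
  k <- haario_kernel(1, sd0 = 0.3, warmup = 200)
  x <- 0; lpx <- lp(x); n <- 5e4
  draws <- numeric(n)
  for (i in seq_len(n)) {
    st <- haario_step(k, x, lpx, lp)
    x <- st$x; lpx <- st$lp; draws[i] <- x
  }
  keep <- draws[(n / 2):n]
  mc_se <- sd(keep) / sqrt(length(keep) / 20)
  expect_lt(abs(mean(keep) - post_mean), 3 * mc_se + 1e-3)
  expect_equal(sd(keep), sqrt(1 / post_prec), tolerance = 0.1)
})
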