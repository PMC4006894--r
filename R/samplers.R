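#' Create an adaptive-Metropolis (Haario) block kernel
#'
#' Maintains the running mean and covariance of a parameter block's history
#' and proposes multivariate-normal steps with covariance
#' `scale * cov + jitter * I`.  During the warm-up phase (and whenever the
#' empirical covariance is not usable) a fixed diagonal proposal of SD `sd0`
#' is used.
#'
#' @param d block dimension.
#' @param sd0 per-coordinate proposal SD used before adaptation (length 1
#'   or `d`).
#' @param warmup number of accepted history updates before the empirical
#'   covariance is used.
#' @param scale covariance scaling; default `2.38^2 / d`.
#' @param jitter diagonal jitter added to the scaled covariance.
#' @return An environment of class `"haario_kernel"` holding the adaptation
#'   state; pass it to [haario_step()].
#' @export
haario_kernel <- function(d, sd0 = 1, warmup = 1000,
                          scale = 2.38^2 / d, jitter = 1e-10,
                          target_acc = 0.234) {
  k <- new.env(parent = emptyenv())
  k$d <- as.integer(d)
  k$sd0 <- rep_len(sd0, d)
  k$warmup <- warmup
  k$scale <- scale
  k$jitter <- jitter
  k$target_acc <- target_acc
  k$log_lambda <- 0            # Robbins-Monro global scale
  k$count <- 0
  k$mean <- numeric(d)
  k$M2 <- matrix(0, d, d)     # sum of squared deviations (Welford)
  k$chol <- NULL
  k$n_prop <- 0L
  k$n_acc <- 0L
  class(k) <- "haario_kernel"
  k
}

# forget accumulated moments (e.g. after an initial settling phase) while
# keeping the current proposal shape and scale
.haario_reset <- function(k) {
  k$count <- 0
  k$mean <- numeric(k$d)
  k$M2 <- matrix(0, k$d, k$d)
  invisible(k)
}

# record a state into the kernel's running moments and refresh the proposal
# Cholesky once past warm-up
.haario_learn <- function(k, x) {
  k$count <- k$count + 1
  delta <- x - k$mean
  k$mean <- k$mean + delta / k$count
  k$M2 <- k$M2 + tcrossprod(delta, x - k$mean)
  if (k$count > k$warmup && k$count %% 25 == 0) {
    S <- k$scale * (k$M2 / (k$count - 1)) + diag(k$jitter, k$d)
    ch <- tryCatch(chol(S), error = function(e) NULL)
    if (!is.null(ch)) k$chol <- ch     # singular -> keep previous / diagonal
  }
  invisible(k)
}

#' One adaptive-Metropolis step on a parameter block
#'
#' Proposes from the kernel's current Gaussian proposal, evaluates
#' `log_target` and accepts or rejects by the Metropolis rule.  Proposals
#' with `-Inf` target are always rejected.  The current (post-move) state is
#' fed into the kernel's history.
#'
#' @param k a [haario_kernel()].
#' @param x current block value.
#' @param lp_x current log-target value at `x`.
#' @param log_target function of the block returning the log target density.
#' @return List with `x`, `lp` and logical `accepted`.
#' @export
haario_step <- function(k, x, lp_x, log_target) {
  d <- k$d
  z <- stats::rnorm(d)
  lam <- exp(k$log_lambda)
  prop <- if (is.null(k$chol)) x + lam * k$sd0 * z
          else x + lam * drop(z %*% k$chol)
  lp_p <- log_target(prop)
  acc <- is.finite(lp_p) && log(stats::runif(1)) < (lp_p - lp_x)
  if (acc) { x <- prop; lp_x <- lp_p }
  k$n_prop <- k$n_prop + 1L
  if (acc) k$n_acc <- k$n_acc + 1L
  # Robbins-Monro adaptation of the global scale toward the target rate
  k$log_lambda <- k$log_lambda +
    ((if (acc) 1 else 0) - k$target_acc) / max(10, k$n_prop)^0.6
  .haario_learn(k, x)
  list(x = x, lp = lp_x, accepted = acc)
}

#' One adaptive-direction update on a set of parallel points
#'
#' Updates point `i` of a set of parallel points targeting the same log
#' density, by a direction move along the line through two other randomly
#' chosen points: `x' = x_i + gamma * (x_a - x_b)` (symmetric, plain
#' Metropolis acceptance).  With probability `stepping_prob` a
#' stepping-stone (independence) proposal drawn from `stepping_sampler` is
#' used instead, accepted with the appropriate Hastings correction from
#' `stepping_logdens`.  If the two chosen points coincide the move is
#' skipped and the state returned unchanged.
#'
#' @param X numeric matrix, one row per parallel point.
#' @param i row index of the point to update.
#' @param lp_i current log-target value of row `i`.
#' @param log_target function of a point returning the log target density.
#' @param gamma step scale; default `2.38 / sqrt(2 d)` with occasional
#'   unit-scale jumps handled by the caller.
#' @param stepping_prob probability of a stepping-stone proposal.
#' @param stepping_sampler function() returning an independent proposal.
#' @param stepping_logdens function(x) giving the log proposal density.
#' @return List with `x` (updated row `i`), `lp`, and `accepted`.
#' @export
direction_update <- function(X, i, lp_i, log_target,
                             gamma = 2.38 / sqrt(2 * ncol(X)),
                             stepping_prob = 0.05,
                             stepping_sampler = NULL,
                             stepping_logdens = NULL) {
  x <- X[i, ]
  if (stepping_prob > 0 && !is.null(stepping_sampler) &&
      stats::runif(1) < stepping_prob) {
    prop <- stepping_sampler()
    lp_p <- log_target(prop)
    lr <- (lp_p - lp_i) + (stepping_logdens(x) - stepping_logdens(prop))
    acc <- is.finite(lp_p) && log(stats::runif(1)) < lr
    if (acc) return(list(x = prop, lp = lp_p, accepted = TRUE))
    return(list(x = x, lp = lp_i, accepted = FALSE))
  }
  m <- nrow(X)
  if (m < 3) return(list(x = x, lp = lp_i, accepted = FALSE))
  ab <- sample(setdiff(seq_len(m), i), 2)
  dir <- X[ab[1], ] - X[ab[2], ]
  if (all(dir == 0)) return(list(x = x, lp = lp_i, accepted = FALSE))
  prop <- x + gamma * dir
  lp_p <- log_target(prop)
  acc <- is.finite(lp_p) && log(stats::runif(1)) < (lp_p - lp_i)
  if (acc) list(x = prop, lp = lp_p, accepted = TRUE)
  else list(x = x, lp = lp_i, accepted = FALSE)
}

#' Highest posterior density interval
#'
#' The shortest contiguous interval containing `ceiling(level * N)` of the
#' sorted sample values.  Ties in width are broken toward the lowest start.
#'
#' @param samples numeric vector (>= 100 values recommended).
#' @param level coverage probability in (0, 1).
#' @return Named numeric vector `c(lower, upper)`.
#' @examples
#' hpdi(rnorm(10000), 0.99)
#' @export
hpdi <- function(samples, level = 0.99) {
  if (level <= 0 || level >= 1) stop("level must be in (0, 1)")
  s <- sort(samples)
  N <- length(s)
  m <- ceiling(level * N)
  if (m >= N) return(c(lower = s[1], upper = s[N]))
  starts <- seq_len(N - m + 1L)
  widths <- s[starts + m - 1L] - s[starts]
  i <- which.min(widths)   # which.min returns the first (lowest-start) tie
  c(lower = s[i], upper = s[i + m - 1L])
}

# split-Rhat and a crude effective sample size from one chain
.split_rhat <- function(x) {
  if (any(!is.finite(x))) return(NA_real_)
  n <- length(x) %/% 2
  if (n < 4) return(NA_real_)
  h <- list(x[1:n], x[(n + 1):(2 * n)])
  W <- mean(vapply(h, stats::var, 0))
  B <- n * stats::var(vapply(h, mean, 0))
  if (W == 0) return(1)
  sqrt(((n - 1) / n * W + B / n) / W)
}

.ess <- function(x) {
  n <- length(x)
  if (any(!is.finite(x))) return(NA_real_)
  if (n < 10 || stats::var(x) == 0) return(n)
  ac <- stats::acf(x, lag.max = min(200, n - 1), plot = FALSE)$acf[-1]
  pos <- which(ac < 0.05)
  s <- if (length(pos)) sum(ac[seq_len(pos[1] - 1)]) else sum(ac)
  max(1, n / (1 + 2 * max(0, s)))
}
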