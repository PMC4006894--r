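# Hierarchical MCMC engine.
#
# State layout:
#   u          : numeric(4)  dH_star, dS_star, T_H, T_S
#   mu         : G x 3 matrix (dH_act, dCp, n), one row per group
#   theta      : S x 4 matrix (log_c, dH_act, dCp, n), one row per strain
#   tau_strain : numeric(3)  between-strain precisions by parameter type
#   tau_obs    : scalar observational precision (sqrt-rate scale)
#
# Per-iteration sweep: Haario block update per strain, per group-mean block
# and for the (log) strain precisions; conjugate Gibbs for tau_obs; adaptive
# direction sampling (history-based pairs + low-probability stepping-stone
# proposal) for the universal parameters.

.PAR3 <- c("dH_act", "dCp", "n")

# inverse-CDF draws on a truncated support, clamped away from degenerate
# tail probabilities
.rtrunc_norm <- function(mean, sd, lo, hi) {
  p <- stats::pnorm(c(lo, hi), mean, sd)
  if (p[2] - p[1] < 1e-12) return(min(max(mean, lo), hi))
  stats::qnorm(stats::runif(1, p[1], p[2]), mean, sd)
}

.rtrunc_gamma <- function(shape, rate, lo, hi) {
  p <- stats::pgamma(c(lo, hi), shape, rate = rate)
  if (p[2] - p[1] < 1e-12) {
    mode <- (shape - 1) / rate
    return(min(max(mode, lo), hi))
  }
  stats::qgamma(stats::runif(1, p[1], p[2]), shape, rate = rate)
}

.engine_init <- function(records, assignment, priors, lik_power = 1,
                         ads = list(), gibbs_groups = TRUE) {
  stopifnot(all(c("strain_id", "temperature_K", "rate_std") %in% names(records)))
  e <- new.env(parent = emptyenv())
  e$priors <- priors
  e$beta <- lik_power
  e$ads <- utils::modifyList(list(warmup = 1000, stepping_prob = 0.05,
                                  gamma = 2.38 / sqrt(2 * 4),
                                  jump_prob = 0.1, couple = FALSE), ads)

  sid <- unique(as.character(records$strain_id))
  assignment <- assignment[match(sid, assignment$strain_id), , drop = FALSE]
  if (anyNA(assignment$group))
    stop("every strain needs a group assignment")
  grp <- unique(assignment$group)
  e$strain_ids <- sid
  e$groups <- grp
  e$S <- length(sid)
  e$G <- length(grp)
  e$gi <- match(assignment$group, grp)          # strain -> group index

  e$ridx <- match(as.character(records$strain_id), sid)
  e$T_all <- records$temperature_K
  e$y_all <- sqrt(records$rate_std)
  e$N <- nrow(records)
  e$T_by <- split(e$T_all, e$ridx)
  e$y_by <- split(e$y_all, e$ridx)
  # temperature of each strain's observed maximum rate: the model support
  # requires a non-trivial folded fraction there (see .fold_margin)
  e$T_peak <- vapply(seq_len(e$S), function(i)
    e$T_by[[i]][which.max(e$y_by[[i]])], 0)

  # --- deterministic data-driven initialization -------------------------
  ub <- priors$universal; gb <- priors$group
  e$u <- c(mean(ub["dH_star", ]), mean(ub["dS_star", ]),
           mean(ub["T_H", ]), mean(ub["T_S", ]))
  names(e$u) <- rownames(ub)

  theta <- matrix(0, e$S, 4, dimnames = list(sid, c("log_c", .PAR3)))
  for (i in seq_len(e$S)) {
    Ti <- e$T_by[[i]]; yi <- e$y_by[[i]]
    To_hat <- Ti[which.max(yi)]
    Ts_hat <- min(To_hat - 8, e$u[["T_S"]] - 10)
    dCp_hat <- min(max(-e$u[["dS_star"]] / log(Ts_hat / e$u[["T_S"]]),
                       gb["dCp", 1]), gb["dCp", 2])
    # initial residue count from the observed hot-side crash: with the
    # numerator roughly flat between the peak and the hottest record, the
    # rate ratio there reflects the native-state ratio
    T_hot <- max(Ti)
    dG_hot <- e$u[["dH_star"]] + dCp_hat * (T_hot - e$u[["T_H"]]) -
      T_hot * (e$u[["dS_star"]] + dCp_hat * log(T_hot / e$u[["T_S"]]))
    n_hat <- 300
    if (dG_hot < -1) {
      y_ratio <- (yi[which.max(Ti)] / max(yi))^2
      p_hot <- max(1e-4, min(0.6, 0.8 * y_ratio))
      n_hat <- min(max(.R_GAS * T_hot * stats::qlogis(p_hot) / dG_hot,
                       gb["n", 1] + 10), gb["n", 2] - 10)
    }
    theta[i, ] <- c(0, 7e4, dCp_hat, n_hat)
    lr <- log(To_hat) - theta[i, 2] / (.R_GAS * To_hat) +
      stats::plogis(theta[i, 4] *
                      (e$u[["dH_star"]] + dCp_hat * (To_hat - e$u[["T_H"]]) -
                         To_hat * (e$u[["dS_star"]] +
                                     dCp_hat * log(To_hat / e$u[["T_S"]]))) /
                      (.R_GAS * To_hat), log.p = TRUE)
    theta[i, 1] <- 2 * log(max(yi, 1e-3)) - lr
  }
  e$theta <- theta
  mu <- matrix(0, e$G, 3, dimnames = list(grp, .PAR3))
  for (g in seq_len(e$G))
    for (p in 1:3)
      mu[g, p] <- min(max(mean(theta[e$gi == g, p + 1]), gb[p, 1]), gb[p, 2])
  e$mu <- mu
  e$tau_strain <- exp(rowMeans(log(priors$tau_strain)))
  names(e$tau_strain) <- .PAR3
  e$tau_obs <- 400

  # --- caches -----------------------------------------------------------
  e$sse <- vapply(seq_len(e$S), function(i)
    sum((e$y_by[[i]] - .sqrt_rate(e$T_by[[i]], .u_list(e$u), theta[i, ]))^2), 0)

  # --- kernels ----------------------------------------------------------
  e$k_strain <- lapply(seq_len(e$S), function(i)
    haario_kernel(4, sd0 = c(0.05, 500, 0.3, 0.02), warmup = 200))
  e$k_group <- lapply(seq_len(e$G), function(g)
    haario_kernel(3, sd0 = c(1000, 0.5, 10), warmup = 200))
  e$k_tau <- haario_kernel(3, sd0 = 0.3, warmup = 200)
  e$k_u <- haario_kernel(4, sd0 = (ub[, 2] - ub[, 1]) / 2000, warmup = 200)
  e$ridge_scale <- 0          # log RM scale of the stability-preserving move
  e$ridge_acc <- 0L; e$ridge_prop <- 0L
  e$scale_scale <- 0          # log RM scale of the scale-invariance move
  e$gibbs_groups <- gibbs_groups
  # the folded-fraction penalty is part of the data model's identification;
  # it is switched off together with the likelihood in prior-only runs
  e$fold_w <- if (lik_power > 0) 5 else 0
  e$u_hist <- NULL        # filled by the driver with the stored chain
  e$u_acc <- 0L; e$u_prop <- 0L
  e$iter <- 0L
  e
}

.u_list <- function(u)
  list(dH_star = u[[1]], dS_star = u[[2]], T_H = u[[3]], T_S = u[[4]])

# identifying soft restriction: at the observed peak temperature the
# catalysing enzyme should retain a folded fraction above 20%
# (n dG / (R T) > logit(0.2)).  The unrestricted likelihood admits a mirror
# regime in which growth happens with a predominantly denatured enzyme
# (tiny dCp and n, inflated dH_act); it is biologically meaningless but can
# trap samplers.  Implemented as a quadratic log-density penalty on the
# violation rather than a hard support bound — hard walls can deadlock the
# coupled universal/strain updates.
.fold_margin <- function(u, dCp, n, T_peak) {
  dG <- u[[1]] + dCp * (T_peak - u[[3]]) -
    T_peak * (u[[2]] + dCp * log(T_peak / u[[4]]))
  n * dG / (.R_GAS * T_peak) - stats::qlogis(0.2)
}

.fold_penalty <- function(u, dCp, n, T_peak, w = 5) {
  -w * sum(pmax(0, -.fold_margin(u, dCp, n, T_peak))^2)
}

# sum of squared sqrt-scale residuals for all records at universal vector u
# (optionally at a full replacement theta matrix)
.sse_all <- function(e, u, theta = e$theta) {
  th <- theta[e$ridx, , drop = FALSE]
  T <- e$T_all
  dG <- u[1] + th[, 3] * (T - u[3]) - T * (u[2] + th[, 3] * log(T / u[4]))
  lr <- th[, 1] + log(T) - th[, 2] / (.R_GAS * T) +
    stats::plogis(th[, 4] * dG / (.R_GAS * T), log.p = TRUE)
  r <- (e$y_all - exp(0.5 * lr))^2
  rowsum(r, e$ridx)[, 1]
}

.engine_sweep <- function(e) {
  pr <- e$priors
  e$iter <- e$iter + 1L
  uL <- .u_list(e$u)

  # ---- strain blocks (two passes per sweep) -----------------------------
  # sampled in (log_c, dH_act, dCp, log n) coordinates: n has a long-tailed,
  # sometimes only lower-bounded conditional (flat-topped curves), which
  # multiplicative steps traverse far better; the Gaussian prior stays on
  # the natural scale, so a +log(n) Jacobian enters the target
  for (i in seq_len(e$S)) {
    g <- e$gi[i]
    mu_g <- e$mu[g, ]
    sdv <- 1 / sqrt(e$tau_strain)
    Ti <- e$T_by[[i]]; yi <- e$y_by[[i]]
    sse_i <- NA_real_
    gb <- pr$group
    tgt <- function(b) {
      th <- c(b[1:3], exp(b[4]))
      # strain parameters share the physical bounds of their group means
      if (b[1] < pr$log_c[1] || b[1] > pr$log_c[2] ||
          any(th[2:4] < gb[, 1]) || any(th[2:4] > gb[, 2]))
        return(-Inf)
      sse_i <<- sum((yi - .sqrt_rate(Ti, uL, th))^2)
      -0.5 * e$tau_obs * e$beta * sse_i +
        sum(stats::dnorm(th[2:4], mu_g, sdv, log = TRUE)) + b[4] +
        .fold_penalty(e$u, th[3], th[4], e$T_peak[i], e$fold_w)
    }
    b_cur <- c(e$theta[i, 1:3], log(e$theta[i, 4]))
    lp0 <- -0.5 * e$tau_obs * e$beta * e$sse[i] +
      sum(stats::dnorm(e$theta[i, 2:4], mu_g, sdv, log = TRUE)) + b_cur[4] +
      .fold_penalty(e$u, e$theta[i, 3], e$theta[i, 4], e$T_peak[i], e$fold_w)
    for (pass in 1:2) {
      st <- haario_step(e$k_strain[[i]], b_cur, lp0, tgt)
      if (st$accepted) {
        b_cur <- st$x
        e$theta[i, ] <- c(st$x[1:3], exp(st$x[4]))
        e$sse[i] <- sse_i
      }
      lp0 <- st$lp
    }
    # coupled residue-count move: multiplicative step in n with dH_act and
    # log c adjusted so the modelled log-rate is preserved at two anchor
    # temperatures (coldest observation and observed peak).  In the
    # (log_c, dH_act, dCp, log n) coordinates this is a symmetric
    # deterministic involution (unit Jacobian), so plain Metropolis applies;
    # it traverses the long (n, dH_act) ridge that defeats local steps.
    T1 <- min(Ti); T2 <- e$T_peak[i]
    if (e$ads$couple && e$iter > e$ads$warmup && T1 != T2) {
      lk <- stats::rnorm(1, 0, 0.35)
      dG1 <- uL$dH_star + b_cur[3] * (T1 - uL$T_H) -
        T1 * (uL$dS_star + b_cur[3] * log(T1 / uL$T_S))
      dG2 <- uL$dH_star + b_cur[3] * (T2 - uL$T_H) -
        T2 * (uL$dS_star + b_cur[3] * log(T2 / uL$T_S))
      n0 <- exp(b_cur[4]); n1 <- exp(b_cur[4] + lk)
      dg1 <- stats::plogis(n1 * dG1 / (.R_GAS * T1), log.p = TRUE) -
        stats::plogis(n0 * dG1 / (.R_GAS * T1), log.p = TRUE)
      dg2 <- stats::plogis(n1 * dG2 / (.R_GAS * T2), log.p = TRUE) -
        stats::plogis(n0 * dG2 / (.R_GAS * T2), log.p = TRUE)
      dHa_new <- b_cur[2] + .R_GAS * (dg1 - dg2) / (1 / T1 - 1 / T2)
      bp <- c(b_cur[1] + (dHa_new - b_cur[2]) / (.R_GAS * T1) - dg1,
              dHa_new, b_cur[3], b_cur[4] + lk)
      lpp <- tgt(bp)
      if (is.finite(lpp) && log(stats::runif(1)) < (lpp - lp0)) {
        b_cur <- bp
        e$theta[i, ] <- c(bp[1:3], exp(bp[4]))
        e$sse[i] <- sse_i
      }
    }
  }

  # ---- group-mean blocks ------------------------------------------------
  if (e$gibbs_groups) {
    # exact conditional: mu_gp | theta, tau ~ N(mean theta, 1/(m tau_p)),
    # truncated to the prior box
    for (g in seq_len(e$G)) {
      members <- which(e$gi == g)
      m_g <- length(members)
      for (p in 1:3) {
        mn <- mean(e$theta[members, p + 1])
        sdv <- 1 / sqrt(m_g * e$tau_strain[[p]])
        e$mu[g, p] <- .rtrunc_norm(mn, sdv, pr$group[p, 1], pr$group[p, 2])
      }
    }
  } else {
    for (g in seq_len(e$G)) {
      members <- which(e$gi == g)
      th_g <- e$theta[members, 2:4, drop = FALSE]
      sdv <- 1 / sqrt(e$tau_strain)
      tgt <- function(mu) {
        if (any(mu < pr$group[, 1] | mu > pr$group[, 2])) return(-Inf)
        sum(stats::dnorm(th_g, matrix(mu, nrow(th_g), 3, byrow = TRUE),
                         matrix(sdv, nrow(th_g), 3, byrow = TRUE), log = TRUE))
      }
      st <- haario_step(e$k_group[[g]], e$mu[g, ], tgt(e$mu[g, ]), tgt)
      if (st$accepted) e$mu[g, ] <- st$x
    }
  }

  # ---- strain precisions ------------------------------------------------
  mu_all <- e$mu[e$gi, , drop = FALSE]
  th_all <- e$theta[, 2:4, drop = FALSE]
  if (e$gibbs_groups) {
    # exact conditional per parameter type: truncated gamma(S/2 + 1, SS/2)
    for (p in 1:3) {
      ss <- sum((th_all[, p] - mu_all[, p])^2)
      e$tau_strain[[p]] <- .rtrunc_gamma(e$S / 2 + 1, ss / 2,
                                         pr$tau_strain[p, 1],
                                         pr$tau_strain[p, 2])
    }
  } else {
    tgt_tau <- function(lt) {
      tau <- exp(lt)
      if (any(tau < pr$tau_strain[, 1] | tau > pr$tau_strain[, 2])) return(-Inf)
      sdm <- matrix(1 / sqrt(tau), e$S, 3, byrow = TRUE)
      sum(stats::dnorm(th_all, mu_all, sdm, log = TRUE)) + sum(lt)
    }
    lt <- log(e$tau_strain)
    st <- haario_step(e$k_tau, lt, tgt_tau(lt), tgt_tau)
    if (st$accepted) e$tau_strain <- stats::setNames(exp(st$x), .PAR3)
  }

  # ---- observational precision: conjugate Gibbs -------------------------
  sse_tot <- sum(e$sse)
  e$tau_obs <- max(stats::rgamma(1,
                                 shape = pr$tau_obs[["shape"]] + e$beta * e$N / 2,
                                 rate = pr$tau_obs[["rate"]] + e$beta * sse_tot / 2),
                   1e-290)   # vague-gamma draws can underflow to zero

  # ---- universal parameters: adaptive direction sampling ----------------
  # mixture kernel: low-probability stepping-stone (independence) proposal,
  # direction moves through pairs of stored past states, and an adaptive
  # Metropolis component that also drives the settling phase
  ub <- pr$universal
  sse_cache <- NULL
  lp_u <- function(u) {
    if (any(u < ub[, 1] | u > ub[, 2])) return(-Inf)
    sse_cache <<- .sse_all(e, u)
    -0.5 * e$tau_obs * e$beta * sum(sse_cache) +
      .fold_penalty(u, e$theta[, 3], e$theta[, 4], e$T_peak, e$fold_w)
  }
  lp0 <- -0.5 * e$tau_obs * e$beta * sum(e$sse) +
    .fold_penalty(e$u, e$theta[, 3], e$theta[, 4], e$T_peak, e$fold_w)
  h <- e$u_hist
  use_dir <- !is.null(h) && nrow(h) >= 50 && e$iter > e$ads$warmup
  mv <- stats::runif(1)
  dir_prop <- NULL
  if (mv < e$ads$stepping_prob) {
    dir_prop <- ub[, 1] + stats::runif(4) * (ub[, 2] - ub[, 1]) # density cancels
  } else if (use_dir && mv < e$ads$stepping_prob + 0.5) {
    ab <- sample.int(nrow(h), 2)
    gam <- if (stats::runif(1) < e$ads$jump_prob) 1 else e$ads$gamma
    d <- h[ab[1], ] - h[ab[2], ]
    if (any(d != 0)) dir_prop <- e$u + gam * d
  }
  if (!is.null(dir_prop)) {
    e$u_prop <- e$u_prop + 1L
    lp_p <- lp_u(dir_prop)
    if (is.finite(lp_p) && log(stats::runif(1)) < (lp_p - lp0)) {
      e$u <- stats::setNames(dir_prop, names(e$u))
      e$sse <- sse_cache
      e$u_acc <- e$u_acc + 1L
    }
    .haario_learn(e$k_u, e$u)
  } else {
    st <- haario_step(e$k_u, e$u, lp0, lp_u)
    e$u_prop <- e$u_prop + 1L
    if (st$accepted) {
      e$u <- stats::setNames(st$x, names(e$u))
      e$sse <- sse_cache
      e$u_acc <- e$u_acc + 1L
    }
  }
  # ---- stability-preserving joint move ----------------------------------
  # proposes a shift of the universal parameters while rescaling every
  # strain's (dCp, n) so that each strain's stability temperature T*_i and
  # total peak stability n_i * dG_i(T*_i) are preserved; this moves the
  # state along the posterior's main ridge.  Deterministic 1-1 map in
  # (dCp_i, n_i), so a Jacobian enters the acceptance ratio.
  .ridge_move(e)
  .scale_move(e)
  invisible(e)
}

# exact move along the likelihood's scale-invariance direction:
# (dH*, dS*, dCp_i, mu_dCp) -> k * (.), (n_i, mu_n) -> (.) / k, precisions
# adjusted accordingly.  The likelihood and the Gaussian strain priors are
# invariant, so acceptance depends only on the uniform prior boxes, the
# tau-bound boxes and the Jacobian.
.scale_move <- function(e) {
  pr <- e$priors
  k <- exp(stats::rnorm(1, 0, exp(e$scale_scale) * 0.02))
  u1 <- e$u
  u1[[1]] <- u1[[1]] * k; u1[[2]] <- u1[[2]] * k
  tau1 <- e$tau_strain
  tau1[["dCp"]] <- tau1[["dCp"]] / k^2
  tau1[["n"]] <- tau1[["n"]] * k^2
  ok <- all(u1 >= pr$universal[, 1] & u1 <= pr$universal[, 2]) &&
    all(tau1 >= pr$tau_strain[, 1] & tau1 <= pr$tau_strain[, 2])
  mu1 <- e$mu
  mu1[, 2] <- mu1[, 2] * k; mu1[, 3] <- mu1[, 3] / k
  ok <- ok && all(mu1[, 2] >= pr$group[2, 1] & mu1[, 2] <= pr$group[2, 2]) &&
    all(mu1[, 3] >= pr$group[3, 1] & mu1[, 3] <= pr$group[3, 2]) &&
    all(e$theta[, 3] * k >= pr$group[2, 1] & e$theta[, 3] * k <= pr$group[2, 2]) &&
    all(e$theta[, 4] / k >= pr$group[3, 1] & e$theta[, 4] / k <= pr$group[3, 2])
  # the fold-penalty term is exactly invariant under this move (n dG fixed)
  acc <- FALSE
  if (ok) {
    # log Jacobian: dH*, dS* (+2), dCp_i (+S), n_i (-S), mu (+G-G),
    # tau_dCp (-2), tau_n (+2) -> 2 log k ; gamma prior on tau_obs untouched
    log_jac <- 2 * log(k)
    if (log(stats::runif(1)) < log_jac) {
      e$u <- u1
      e$mu <- mu1
      e$theta[, 3] <- e$theta[, 3] * k
      e$theta[, 4] <- e$theta[, 4] / k
      e$tau_strain <- tau1
      acc <- TRUE       # likelihood invariant: sse unchanged
    }
  }
  e$scale_scale <- e$scale_scale +
    ((if (acc) 1 else 0) - 0.3) / max(10, e$iter)^0.6
  invisible(e)
}

.ridge_move <- function(e) {
  pr <- e$priors
  ub <- pr$universal
  lam <- exp(e$ridge_scale)
  eps <- stats::rnorm(4) * lam * c(10, 0.04, 0.1, 0.1)
  u1 <- e$u + eps
  acc <- FALSE
  if (all(u1 >= ub[, 1] & u1 <= ub[, 2])) {
    L <- log(u1[[4]] / e$u[[4]])                 # log(T_S'/T_S)
    dCp <- e$theta[, 3]; n <- e$theta[, 4]
    denom <- e$u[[2]] / dCp + L
    if (all(denom > 0)) {
      dCp1 <- u1[[2]] / denom
      Tstar <- e$u[[4]] * exp(-e$u[[2]] / dCp)   # preserved by construction
      peak0 <- e$u[[1]] + dCp * (Tstar - e$u[[3]])
      peak1 <- u1[[1]] + dCp1 * (Tstar - u1[[3]])
      gb <- pr$group
      n1 <- if (all(peak1 > 0) && all(peak0 > 0)) n * peak0 / peak1 else NULL
      if (!is.null(n1) &&
          all(dCp1 >= gb[2, 1] & dCp1 <= gb[2, 2]) &&
          all(n1 >= gb[3, 1] & n1 <= gb[3, 2])) {
        log_jac <- sum(log(e$u[[2]]) + 2 * log(dCp1) - log(u1[[2]]) -
                         2 * log(dCp)) + sum(log(peak0 / peak1))
        th1 <- e$theta
        th1[, 3] <- dCp1; th1[, 4] <- n1
        # posterior ratio: likelihood + strain-parameter priors
        sse1 <- .sse_all(e, u1, th1)
        mu_all <- e$mu[e$gi, , drop = FALSE]
        sdm <- matrix(1 / sqrt(e$tau_strain), e$S, 3, byrow = TRUE)
        lpr1 <- sum(stats::dnorm(th1[, 2:4], mu_all, sdm, log = TRUE))
        lpr0 <- sum(stats::dnorm(e$theta[, 2:4], mu_all, sdm, log = TRUE))
        lr <- -0.5 * e$tau_obs * e$beta * (sum(sse1) - sum(e$sse)) +
          lpr1 - lpr0 + log_jac +
          .fold_penalty(u1, dCp1, n1, e$T_peak, e$fold_w) -
          .fold_penalty(e$u, dCp, n, e$T_peak, e$fold_w)
        if (is.finite(lr) && log(stats::runif(1)) < lr) {
          e$u <- stats::setNames(u1, names(e$u))
          e$theta <- th1
          e$sse <- sse1
          acc <- TRUE
        }
      }
    }
  }
  e$ridge_prop <- e$ridge_prop + 1L
  if (acc) e$ridge_acc <- e$ridge_acc + 1L
  e$ridge_scale <- e$ridge_scale +
    ((if (acc) 1 else 0) - 0.234) / max(10, e$ridge_prop)^0.6
  invisible(e)
}

.engine_loglik <- function(e) {
  0.5 * e$N * (log(e$tau_obs) - log(2 * pi)) - 0.5 * e$tau_obs * sum(e$sse)
}

.engine_colnames <- function(e) {
  c(paste0("u.", names(e$u)),
    as.vector(t(outer(e$groups, .PAR3, function(g, p) paste0("mu.", g, ".", p)))),
    as.vector(t(outer(e$strain_ids, c("log_c", .PAR3),
                      function(s, p) paste0("strain.", s, ".", p)))),
    paste0("tau.", .PAR3), "tau_obs", "loglik")
}

.engine_state_vec <- function(e) {
  c(e$u, as.vector(t(e$mu)), as.vector(t(e$theta)), e$tau_strain, e$tau_obs,
    .engine_loglik(e))
}

#' Fit the hierarchical thermodynamic growth model by MCMC
#'
#' The model: for every record, `sqrt(rate_std) ~ N(sqrt(r(T)), 1/tau_obs)`
#' where `r(T)` is the thermodynamic rate model ([growth_rate()]); strain
#' parameters (enthalpy of activation, heat capacity change, residue count)
#' are Gaussian around their group means with shared per-parameter-type
#' precisions; the scaling constant is sampled on the log scale with a vague
#' prior; the four universal unfolding parameters are common to all strains.
#'
#' Sampling uses adaptive-Metropolis (Haario) block updates for each
#' strain's parameter vector, each group-mean vector and the log strain
#' precisions; conjugate Gibbs for the observational precision; and adaptive
#' direction sampling (direction moves through pairs of past states plus a
#' low-probability stepping-stone proposal) for the universal parameters.
#'
#' @param records data.frame with columns `strain_id`, `temperature_K`,
#'   `rate_std` (see [standardize_rates()]); a `group` column, if present,
#'   provides the default group assignment.
#' @param assignment optional data.frame (`strain_id`, `group`) mapping each
#'   strain to its group; defaults to `records$group`, or a single common
#'   group when absent.
#' @param priors a [thermo_priors] object.
#' @param iterations total MCMC iterations.
#' @param burn_in fraction of initial iterations discarded before
#'   summarizing.
#' @param seed integer seed; identical seeds give identical chains.
#' @param thin keep every `thin`-th iteration in the stored chain.
#' @param lik_power likelihood tempering exponent in \[0, 1\] (1 = posterior,
#'   0 = prior); used by the marginal-likelihood machinery.
#' @param ads list of adaptive-direction-sampler settings (`warmup`,
#'   `stepping_prob`, `gamma`, `jump_prob`).
#' @return An object of class `"thermo_fit"`: stored chains, posterior
#'   summaries (means, SDs, 99% HPDIs, split-Rhat, effective sample size),
#'   acceptance rates, and the inputs needed for the methods
#'   (`predict`, `plot`, `simulate`, `residuals`, ...).
#' @seealso [two_stage_fit()], [fit_single_strain()], [hpdi()]
#' @export
thermo_fit <- function(records, assignment = NULL, priors = thermo_priors(),
                       iterations = 50000, burn_in = 0.5, seed = 1,
                       thin = 1L, lik_power = 1, ads = list(),
                       group_update = c("gibbs", "haario")) {
  stopifnot(burn_in >= 0, burn_in < 1, iterations >= 10)
  group_update <- match.arg(group_update)
  if (is.null(assignment)) {
    assignment <- if ("group" %in% names(records))
      unique(records[, c("strain_id", "group")])
    else data.frame(strain_id = unique(records$strain_id), group = "all",
                    stringsAsFactors = FALSE)
  }
  set.seed(seed)
  e <- .engine_init(records, assignment, priors, lik_power, ads,
                    gibbs_groups = group_update == "gibbs")
  n_keep <- floor(iterations / thin)
  chain <- matrix(NA_real_, n_keep, length(.engine_state_vec(e)),
                  dimnames = list(NULL, .engine_colnames(e)))
  ucols <- 1:4
  k <- 0L
  t0 <- proc.time()[["elapsed"]]
  for (it in seq_len(iterations)) {
    .engine_sweep(e)
    # forget the settling transient so the adapted covariances reflect the
    # stationary conditionals, not the approach path
    if (it == e$ads$warmup)
      for (kk in e$k_strain) .haario_reset(kk)
    if (it %% thin == 0L) {
      k <- k + 1L
      chain[k, ] <- .engine_state_vec(e)
      # history for the direction sampler: post-warm-up stored states,
      # refreshed periodically (diminishing adaptation)
      if (it > e$ads$warmup && k %% 25L == 0L)
        e$u_hist <- chain[max(1L, k - 5000L):k, ucols, drop = FALSE]
    }
  }
  runtime <- proc.time()[["elapsed"]] - t0
  drop_n <- floor(burn_in * k)
  retained <- chain[(drop_n + 1L):k, , drop = FALSE]
  post <- .summarize_chain(retained)
  acc <- c(strain = mean(vapply(e$k_strain, function(x) x$n_acc / max(1, x$n_prop), 0)),
           group = if (e$gibbs_groups) NA_real_
                   else mean(vapply(e$k_group,
                                    function(x) x$n_acc / max(1, x$n_prop), 0)),
           tau = if (e$gibbs_groups) NA_real_
                 else e$k_tau$n_acc / max(1, e$k_tau$n_prop),
           universal = e$u_acc / max(1, e$u_prop),
           ridge = e$ridge_acc / max(1, e$ridge_prop))
  structure(list(chain = chain, retained_rows = (drop_n + 1L):k,
                 posterior = post, acceptance = acc,
                 records = records, assignment = assignment,
                 groups = e$groups, strain_ids = e$strain_ids,
                 priors = priors, iterations = iterations, thin = thin,
                 burn_in = burn_in, seed = seed, lik_power = lik_power,
                 runtime = runtime, call = match.call()),
            class = "thermo_fit")
}

.summarize_chain <- function(retained) {
  stats_df <- data.frame(
    parameter = colnames(retained),
    mean = colMeans(retained),
    sd = apply(retained, 2, stats::sd),
    stringsAsFactors = FALSE
  )
  hp <- t(apply(retained, 2, hpdi, level = 0.99))
  stats_df$lower99 <- hp[, 1]
  stats_df$upper99 <- hp[, 2]
  stats_df$rhat <- apply(retained, 2, .split_rhat)
  stats_df$ess <- apply(retained, 2, .ess)
  rownames(stats_df) <- NULL
  stats_df
}

#' Retained (post-burn-in) posterior draws
#'
#' @param object a [thermo_fit] object.
#' @param pars optional regular expression selecting parameter columns.
#' @return Matrix of retained draws.
#' @export
posterior_draws <- function(object, pars = NULL) {
  m <- object$chain[object$retained_rows, , drop = FALSE]
  if (!is.null(pars)) m <- m[, grepl(pars, colnames(m)), drop = FALSE]
  m
}

#' Two-stage standardization fit
#'
#' Stage 1 fits the model to max-standardized rates; each strain's rates are
#' then divided by that strain's fitted maximum rate (the maximum of the
#' posterior-mean fitted curve, [fitted_curve_max()]), removing the influence
#' of the scaling constant; stage 2 refits on the rescaled data.
#'
#' @inheritParams thermo_fit
#' @param stage1_iterations iterations for the stage-1 fit (defaults to
#'   `iterations`).
#' @return A `thermo_fit` object for stage 2, with elements `stage1` (the
#'   stage-1 fit) and `fitted_max` (per-strain stage-1 fitted maxima) added.
#' @export
two_stage_fit <- function(records, assignment = NULL, priors = thermo_priors(),
                          iterations = 20000, burn_in = 0.5, seed = 1,
                          stage1_iterations = iterations, ...) {
  records <- standardize_rates(records)
  f1 <- thermo_fit(records, assignment, priors, stage1_iterations, burn_in,
                   seed, ...)
  fitted_max <- fitted_curve_max(f1)
  rec2 <- records
  rec2$rate_std <- rec2$rate_std /
    fitted_max[match(as.character(rec2$strain_id), f1$strain_ids)]
  f2 <- thermo_fit(rec2, assignment, priors, iterations, burn_in, seed + 1, ...)
  f2$stage1 <- f1
  f2$fitted_max <- fitted_max
  f2
}

#' Maximum of each strain's posterior-mean fitted curve
#'
#' The fitted curve of a strain is the posterior mean of the modelled
#' square-root rate as a function of temperature (the parameter posterior is
#' curved, so evaluating the model at posterior-mean parameters would sit
#' off the ridge); its maximum over a fine temperature grid is the "fitted
#' maximum rate" used by the two-stage standardization.
#'
#' @param object a [thermo_fit] object.
#' @param n_draws number of (thinned) retained draws to average over.
#' @param resolution grid spacing, K.
#' @return Named numeric vector of per-strain fitted maximum rates.
#' @export
fitted_curve_max <- function(object, n_draws = 200, resolution = 0.25) {
  draws <- posterior_draws(object)
  idx <- unique(round(seq(1, nrow(draws), length.out = n_draws)))
  rec <- object$records
  out <- stats::setNames(numeric(length(object$strain_ids)),
                         object$strain_ids)
  for (id in object$strain_ids) {
    w <- rec$strain_id == id
    grid <- seq(min(rec$temperature_K[w]) - 2, max(rec$temperature_K[w]) + 2,
                by = resolution)
    acc <- numeric(length(grid))
    for (j in idx) {
      d <- draws[j, ]
      th <- c(d[[paste0("strain.", id, ".log_c")]],
              d[[paste0("strain.", id, ".dH_act")]],
              d[[paste0("strain.", id, ".dCp")]],
              d[[paste0("strain.", id, ".n")]])
      acc <- acc + .sqrt_rate(grid, .u_list(d[1:4]), th)
    }
    out[[id]] <- max(acc / length(idx))^2
  }
  out
}
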