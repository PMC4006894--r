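# Model-structure comparison: the five grouping structures, thermal-group
# allocation, and Bayes factors via product-space (Carlin-Chib) and
# power-posterior stepping-stone estimators.

#' Grouping structure for the hierarchical model
#'
#' The five alternative structures: I) all strains in one group; II) by
#' taxonomic domain (Bacteria/Archaea/Eukarya); III) as II with Eukarya
#' split into unicellular and multicellular; IV) four thermal groups
#' allocated by stability temperature; V) as IV with Ascomycota strains in
#' their own group.
#'
#' @param model one of `"I"`, `"II"`, `"III"`, `"IV"`, `"V"`.
#' @param thresholds increasing T* cut-points (K) separating
#'   psychrophiles/mesophiles, mesophiles/thermophiles and
#'   thermophiles/hyperthermophiles.
#' @return An object of class `"thermal_structure"`.
#' @export
thermal_structure <- function(model = c("I", "II", "III", "IV", "V"),
                              thresholds = c(285, 300, 316)) {
  model <- match.arg(model)
  if (is.unsorted(thresholds, strictly = TRUE) || length(thresholds) != 3)
    stop("thresholds must be three strictly increasing temperatures")
  structure(list(model = model, thresholds = thresholds),
            class = "thermal_structure")
}

#' @export
print.thermal_structure <- function(x, ...) {
  cat(sprintf("Grouping structure %s (thermal cut-points %s K)\n", x$model,
              paste(x$thresholds, collapse = ", ")))
  invisible(x)
}

#' Allocate strains to thermal groups by stability temperature
#'
#' Strains are classified by T*: at or below the first threshold
#' psychrophile, then mesophile, thermophile, and hyperthermophile above
#' the last (a T* exactly on a boundary goes to the lower group).  When
#' `ascomycota` is supplied and `model = "V"`, flagged strains are routed to
#' their own group regardless of T*.
#'
#' @param T_star numeric vector of stability temperatures, K.
#' @param thresholds increasing cut-points, K.
#' @param ascomycota optional logical vector flagging Ascomycota strains.
#' @param model `"IV"` (default) or `"V"`.
#' @return Character vector of group labels.
#' @export
allocate_thermal_groups <- function(T_star, thresholds = c(285, 300, 316),
                                    ascomycota = NULL, model = "IV") {
  if (length(T_star) == 0) return(character(0))
  lab <- c("psychrophile", "mesophile", "thermophile", "hyperthermophile")
  out <- lab[1 + findInterval(T_star, thresholds, left.open = TRUE)]
  if (identical(model, "V") && !is.null(ascomycota))
    out[ascomycota] <- "ascomycota"
  out
}

#' Strain-to-group assignment under a grouping structure
#'
#' Builds the `strain_id -> group` map a structure implies, using taxonomy
#' metadata (structures II, III, V) and stability temperatures
#' (structures IV, V).
#'
#' @param metadata data.frame with columns `strain_id`, `domain`,
#'   `cellularity`, `ascomycota`.
#' @param structure a [thermal_structure] object.
#' @param T_star per-strain stability temperatures (required for IV and V),
#'   in `metadata` row order.
#' @return data.frame with columns `strain_id`, `group`.
#' @export
structure_assignment <- function(metadata, structure, T_star = NULL) {
  m <- structure$model
  grp <- switch(
    m,
    I = rep("all", nrow(metadata)),
    II = metadata$domain,
    III = ifelse(metadata$domain == "Eukarya",
                 paste0("Eukarya_", metadata$cellularity), metadata$domain),
    IV = ,
    V = {
      if (is.null(T_star))
        stop("structures IV and V need per-strain stability temperatures")
      allocate_thermal_groups(T_star, structure$thresholds,
                              ascomycota = metadata$ascomycota, model = m)
    })
  data.frame(strain_id = metadata$strain_id, group = grp,
             stringsAsFactors = FALSE)
}

#' Stability temperatures from a pilot fit
#'
#' Estimates each strain's stability temperature from an initial model fit,
#' the quantity used to allocate strains to thermal groups.  Each strain is
#' fitted independently by nonlinear least squares
#' ([fit_single_strain()], convergence temperatures and entropy change held
#' fixed) — independent per-strain fits rank the stability temperatures far
#' more reliably than a short single-group hierarchical pilot, which can
#' linger in collective modes.  Strains whose least-squares fit fails fall
#' back to a peak-temperature heuristic.
#'
#' @param records standardized growth records.
#' @param u universal parameters used for the fixed values.
#' @param ... unused (kept for backward-compatible calls).
#' @return Named numeric vector of T* (K), one entry per strain.
#' @export
pilot_stability_temperatures <- function(records,
                                         u = default_universal_params(),
                                         ...) {
  ids <- unique(as.character(records$strain_id))
  out <- stats::setNames(numeric(length(ids)), ids)
  for (id in ids) {
    rec <- records[records$strain_id == id, ]
    dCp_hat <- tryCatch({
      # fix everything universal (including dH*): frees only c, dH_act,
      # dCp, n, which pins dCp well enough to rank stability temperatures
      fit <- fit_single_strain(rec, u,
                               fixed = c(T_H = u$T_H, T_S = u$T_S,
                                         dS_star = u$dS_star,
                                         dH_star = u$dH_star))
      unname(coef(fit)[["dCp"]])
    }, error = function(e) NA_real_)
    if (!is.finite(dCp_hat) || dCp_hat < 30 || dCp_hat > 150) {
      # heuristic fallback: stability temperature a little below the
      # observed peak temperature
      T_hat <- rec$temperature_K[which.max(rec$rate_std)]
      dCp_hat <- -u$dS_star / log(min(T_hat - 8, u$T_S - 5) / u$T_S)
    }
    out[[id]] <- stability_temperature(u, dCp_hat)
  }
  out
}

# ---------------------------------------------------------------------------
# generic estimators (also used by the unit tests on conjugate toys)

#' Stepping-stone combination of power-posterior log-likelihood draws
#'
#' Given draws of the log-likelihood under each power posterior
#' `p(theta | y)^{b_k}`-tempered target, combines them into an estimate of
#' the log marginal likelihood:
#' `log ml = sum_k log E_{b_k}[exp((b_{k+1} - b_k) loglik)]`,
#' each expectation computed stably by log-sum-exp.  A delta-method MC
#' standard error is attached.
#'
#' @param loglik_draws list of numeric vectors; element `k` holds draws of
#'   the log-likelihood under tempering `betas[k]`.
#' @param betas increasing tempering schedule from 0 to 1 (length
#'   `length(loglik_draws) + 1`; the final entry must be 1).
#' @return List with `logml` and `se`.
#' @export
stepping_stone_logml <- function(loglik_draws, betas) {
  K <- length(loglik_draws)
  stopifnot(length(betas) == K + 1, betas[1] == 0, betas[K + 1] == 1,
            !is.unsorted(betas))
  logml <- 0; v <- 0
  for (k in seq_len(K)) {
    d <- (betas[k + 1] - betas[k]) * loglik_draws[[k]]
    m <- max(d)
    w <- exp(d - m)
    logml <- logml + m + log(mean(w))
    ess <- sum(w)^2 / sum(w^2)
    v <- v + stats::var(w) / (mean(w)^2 * max(1, ess))
  }
  list(logml = logml, se = sqrt(v))
}

#' Product-space (Carlin-Chib) Bayes factor between two targets
#'
#' Runs a product-space chain over two models with pseudo-priors: the state
#' is the model indicator plus both models' parameter vectors.  At each
#' iteration the current model's parameters take one MCMC step (supplied
#' `step` functions targeting each model's own posterior), the other
#' model's parameters are refreshed from their pseudo-prior, and the
#' indicator is Gibbs-sampled from the two joint densities.  With equal
#' prior model probabilities the Bayes factor of model 1 over model 2 is
#' the ratio of visit counts.
#'
#' @param step1,step2 functions `state -> list(state, log_post)` advancing
#'   a model's parameters one MCMC step on its own (un-tempered) posterior,
#'   where `log_post` is log-likelihood + log-prior up to a constant shared
#'   between the models only if identical; supply complete normalized
#'   log posterior kernels (likelihood plus proper prior).
#' @param logpost1,logpost2 functions returning log-likelihood + log-prior
#'   of a state.
#' @param pseudo1,pseudo2 lists with `draw()` and `logdens(state)` for each
#'   model's pseudo-prior.
#' @param init1,init2 initial states.
#' @param n_iter number of product-space iterations.
#' @return List with `bf12`, `log_bf12`, `visits` (2-vector), and the
#'   indicator chain.
#' @export
product_space_bf <- function(step1, step2, logpost1, logpost2,
                             pseudo1, pseudo2, init1, init2, n_iter = 5000) {
  s1 <- init1; s2 <- init2
  k <- 1L
  ind <- integer(n_iter)
  for (it in seq_len(n_iter)) {
    if (k == 1L) {
      st <- step1(s1); s1 <- st$state
      s2 <- pseudo2$draw()
    } else {
      st <- step2(s2); s2 <- st$state
      s1 <- pseudo1$draw()
    }
    l1 <- logpost1(s1) + pseudo2$logdens(s2)
    l2 <- logpost2(s2) + pseudo1$logdens(s1)
    k <- if (stats::runif(1) < stats::plogis(l1 - l2)) 1L else 2L
    ind[it] <- k
  }
  visits <- c(sum(ind == 1L), sum(ind == 2L))
  if (min(visits) < 0.01 * n_iter)
    warning("model indicator nearly stuck (", visits[1], " vs ", visits[2],
            " visits); retune the pseudo-priors or lengthen the run")
  list(bf12 = visits[1] / max(1L, visits[2]),
       log_bf12 = log(visits[1] / max(1L, visits[2])),
       visits = visits, indicator = ind)
}

# ---------------------------------------------------------------------------
# growth-model wrappers

#' Log marginal likelihood of a grouping structure
#'
#' Power-posterior stepping-stone estimate: the hierarchical model is
#' sampled at a ladder of likelihood temperings `beta_k = (k/K)^5`, the
#' log-likelihood draws at each rung are combined by
#' [stepping_stone_logml()].
#'
#' @param records standardized growth records.
#' @param assignment data.frame (`strain_id`, `group`).
#' @param priors a [thermo_priors] object.
#' @param K number of ladder rungs.
#' @param iterations MCMC iterations per rung (half discarded).
#' @param seed integer seed.
#' @return List with `logml`, `se`, `betas`.
#' @export
marginal_likelihood <- function(records, assignment, priors = thermo_priors(),
                                K = 8, iterations = 4000, seed = 1) {
  betas <- (seq(0, K) / K)^5
  draws <- vector("list", K)
  for (k in seq_len(K)) {
    f <- thermo_fit(records, assignment, priors, iterations = iterations,
                    burn_in = 0.5, seed = seed + k, lik_power = betas[k])
    # the stored loglik column is the full (untempered) log-likelihood
    draws[[k]] <- posterior_draws(f)[, "loglik"]
  }
  est <- stepping_stone_logml(draws, betas)
  c(est, list(betas = betas))
}

# Gaussian pseudo-prior fitted to a pilot run's marginal posteriors
.fit_pseudo <- function(fit, inflate = 1.5, pars = NULL) {
  d <- posterior_draws(fit, pars = pars)
  d <- d[, colnames(d) != "loglik", drop = FALSE]
  m <- colMeans(d)
  s <- pmax(apply(d, 2, stats::sd) * inflate, 1e-8)
  list(
    draw = function() stats::setNames(stats::rnorm(length(m), m, s), names(m)),
    logdens = function(x) sum(stats::dnorm(x, m, s, log = TRUE)),
    mean = m, sd = s
  )
}

#' Bayes factor between two grouping structures
#'
#' Primary method `"product-space"`: a collapsed Carlin-Chib product-space
#' sampler.  The compared structures share the likelihood and all
#' strain-level and universal parameters — they differ only in how the
#' strain-parameter means are grouped — so the shared block is kept common
#' to both models and the model indicator is updated with the group means
#' integrated out analytically (normal-uniform marginal per group and
#' parameter type; this is product-space sampling with the ideal
#' pseudo-prior, the full conditional, collapsed in closed form).  The
#' likelihood cancels from the indicator update, which therefore compares
#' how well each grouping's hierarchical prior explains the current strain
#' parameters, the prior normalization penalizing extra groups.  Posterior
#' odds are Rao-Blackwellized (averaged conditional indicator
#' probabilities).  Cross-check method `"stepping-stone"`: difference of
#' the two power-posterior log marginal likelihoods.
#'
#' @param records standardized growth records.
#' @param assignment1,assignment2 strain-to-group assignments of the two
#'   structures.
#' @param priors a [thermo_priors] object.
#' @param method `"product-space"` or `"stepping-stone"`.
#' @param pilot_iterations pilot-run length per structure.
#' @param n_iter product-space iterations (or per-rung iterations for
#'   stepping-stone).
#' @param seed integer seed.
#' @return List with `log_bf12` (structure 1 over structure 2), `bf12`, and
#'   method detail.
#' @export
bayes_factor <- function(records, assignment1, assignment2,
                         priors = thermo_priors(),
                         method = c("product-space", "stepping-stone"),
                         pilot_iterations = 4000, n_iter = 4000, seed = 1) {
  method <- match.arg(method)
  if (method == "stepping-stone") {
    m1 <- marginal_likelihood(records, assignment1, priors,
                              iterations = n_iter, seed = seed)
    m2 <- marginal_likelihood(records, assignment2, priors,
                              iterations = n_iter, seed = seed + 100)
    return(list(log_bf12 = m1$logml - m2$logml,
                bf12 = exp(m1$logml - m2$logml),
                se = sqrt(m1$se^2 + m2$se^2),
                logml = c(m1$logml, m2$logml), method = method))
  }
  set.seed(seed)
  p1 <- thermo_fit(records, assignment1, priors, pilot_iterations, seed = seed + 1)
  p2 <- thermo_fit(records, assignment2, priors, pilot_iterations, seed = seed + 2)

  e1 <- .engine_init(records, assignment1, priors)
  e2 <- .engine_init(records, assignment2, priors)
  # start both engines from their pilots' posterior means
  for (pe in list(list(e1, p1), list(e2, p2))) {
    cf <- pe[[2]]$posterior$mean
    names(cf) <- pe[[2]]$posterior$parameter
    .engine_set_state(pe[[1]], cf[names(cf) != "loglik"])
  }
  .copy_shared(e1, e2)

  k <- 1L
  ind <- integer(n_iter)
  lodds <- numeric(n_iter)
  for (it in seq_len(n_iter)) {
    cur <- if (k == 1L) e1 else e2
    oth <- if (k == 1L) e2 else e1
    .engine_sweep(cur)
    .copy_shared(cur, oth)
    l1 <- .grouping_evidence(e1, priors)
    l2 <- .grouping_evidence(e2, priors)
    lodds[it] <- l1 - l2
    k_new <- if (stats::runif(1) < stats::plogis(l1 - l2)) 1L else 2L
    if (k_new != k) {
      # refresh the incoming structure's group means from their conditional
      tgt <- if (k_new == 1L) e1 else e2
      .gibbs_mu(tgt, priors)
      k <- k_new
    }
    ind[it] <- k
  }
  visits <- c(sum(ind == 1L), sum(ind == 2L))
  # Rao-Blackwellized posterior odds: average the conditional indicator
  # probabilities instead of counting visits
  p1_mean <- mean(stats::plogis(lodds))
  list(bf12 = p1_mean / (1 - p1_mean),
       log_bf12 = log(p1_mean) - log1p(-p1_mean),
       visits = visits, indicator = ind, log_odds = lodds,
       method = "product-space")
}

# log marginal density of the strain parameters under a grouping, with the
# group means integrated out against their (box-)uniform priors: for each
# group g and parameter type p, integral of prod_i N(theta_i; mu, 1/tau_p)
# over mu times 1/width.  The box truncation of the integral is neglected
# (group posteriors sit far from the bounds).
.grouping_evidence <- function(e, priors) {
  out <- 0
  W <- priors$group[, 2] - priors$group[, 1]
  for (g in seq_len(e$G)) {
    members <- which(e$gi == g)
    m <- length(members)
    for (p in 1:3) {
      x <- e$theta[members, p + 1]
      s2 <- 1 / e$tau_strain[[p]]
      out <- out - log(W[p]) - 0.5 * (m - 1) * log(2 * pi * s2) -
        0.5 * log(m) - 0.5 * sum((x - mean(x))^2) / s2
    }
  }
  out
}

# redraw an engine's group means from their exact truncated-normal
# conditionals (same draw as the in-sweep Gibbs update)
.gibbs_mu <- function(e, priors) {
  for (g in seq_len(e$G)) {
    members <- which(e$gi == g)
    m_g <- length(members)
    for (p in 1:3)
      e$mu[g, p] <- .rtrunc_norm(mean(e$theta[members, p + 1]),
                                 1 / sqrt(m_g * e$tau_strain[[p]]),
                                 priors$group[p, 1], priors$group[p, 2])
  }
  invisible(e)
}

# copy the parameters shared between two grouping structures (everything
# except the group means) from engine `from` into engine `to`
.copy_shared <- function(from, to) {
  to$u <- from$u
  to$theta <- from$theta
  to$tau_strain <- from$tau_strain
  to$tau_obs <- from$tau_obs
  to$sse <- from$sse
  invisible(to)
}

# named full state vector (without the loglik column)
.engine_state_named <- function(e) {
  v <- .engine_state_vec(e)
  names(v) <- .engine_colnames(e)
  v[names(v) != "loglik"]
}

.engine_set_state <- function(e, state) {
  nm <- names(state)
  e$u <- stats::setNames(state[paste0("u.", names(e$u))], names(e$u))
  for (g in seq_len(e$G))
    e$mu[g, ] <- state[paste0("mu.", e$groups[g], ".", .PAR3)]
  for (i in seq_len(e$S))
    e$theta[i, ] <- state[paste0("strain.", e$strain_ids[i], ".",
                                 c("log_c", .PAR3))]
  e$tau_strain <- stats::setNames(state[paste0("tau.", .PAR3)], .PAR3)
  e$tau_obs <- unname(state[["tau_obs"]])
  uL <- .u_list(e$u)
  e$sse <- vapply(seq_len(e$S), function(i)
    sum((e$y_by[[i]] - .sqrt_rate(e$T_by[[i]], uL, e$theta[i, ]))^2), 0)
  invisible(e)
}

# full log posterior (likelihood + complete prior) of the engine's state
.engine_logpost <- function(e) {
  pr <- e$priors
  ll <- .engine_loglik(e)
  lp <- .lunif(e$u, pr$universal)
  for (g in seq_len(e$G)) lp <- lp + .lunif(e$mu[g, ], pr$group)
  lp <- lp + .lunif(e$tau_strain, pr$tau_strain)
  if (any(e$theta[, 1] < pr$log_c[1] | e$theta[, 1] > pr$log_c[2]))
    lp <- -Inf
  if (!is.finite(lp)) return(-Inf)
  # flat log_c prior: normalized uniform density over its bounds
  lp <- lp - e$S * log(diff(pr$log_c)) -
    sum(log(pr$universal[, 2] - pr$universal[, 1])) -
    e$G * sum(log(pr$group[, 2] - pr$group[, 1])) -
    sum(log(pr$tau_strain[, 2] - pr$tau_strain[, 1]))
  mu_all <- e$mu[e$gi, , drop = FALSE]
  lp <- lp + sum(stats::dnorm(e$theta[, 2:4], mu_all,
                              matrix(1 / sqrt(e$tau_strain), e$S, 3,
                                     byrow = TRUE), log = TRUE))
  lp <- lp + .fold_penalty(e$u, e$theta[, 3], e$theta[, 4], e$T_peak, e$fold_w)
  lp + stats::dgamma(e$tau_obs, pr$tau_obs[["shape"]], rate = pr$tau_obs[["rate"]],
                     log = TRUE) + ll
}

#' Compare grouping structures by Bayes factors
#'
#' Estimates the log marginal likelihood of each structure (stepping-stone
#' ladder) and reports the Bayes factor of the best structure against each
#' of the others.
#'
#' @param records standardized growth records.
#' @param metadata strain taxonomy table (see [structure_assignment()]).
#' @param structures character vector of structure labels to compare.
#' @param priors a [thermo_priors] object.
#' @param T_star per-strain stability temperatures for structures IV/V;
#'   computed by a pilot run when `NULL` and needed.
#' @param iterations per-rung iterations for the stepping-stone estimates.
#' @param K ladder rungs.
#' @param seed integer seed.
#' @return data.frame (one row per structure) with `structure`, `logml`,
#'   `se`, `log_bf_vs_best`, ordered best first.
#' @export
compare_structures <- function(records, metadata, structures = c("I", "V"),
                               priors = thermo_priors(), T_star = NULL,
                               iterations = 3000, K = 6, seed = 1) {
  stopifnot(length(structures) >= 2)
  if (is.null(T_star) && any(structures %in% c("IV", "V")))
    T_star <- pilot_stability_temperatures(records)
  rows <- lapply(seq_along(structures), function(j) {
    st <- thermal_structure(structures[j])
    asg <- structure_assignment(metadata, st, T_star = T_star)
    ml <- marginal_likelihood(records, asg, priors, K = K,
                              iterations = iterations, seed = seed + 10 * j)
    data.frame(structure = structures[j], logml = ml$logml, se = ml$se,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out <- out[order(-out$logml), ]
  out$log_bf_vs_best <- out$logml[1] - out$logml
  rownames(out) <- NULL
  out
}
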