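#' Prior specification for the hierarchical growth model
#'
#' Uniform priors (bounds informed by the protein-biochemistry literature)
#' for the universal unfolding parameters and the group-level means; Gaussian
#' priors for the strain-level parameters around their group means with
#' per-parameter-type strain precisions `tau_strain` (themselves uniform); a
#' vague log-uniform prior for the scaling constant `c`; and a gamma prior
#' for the observational precision on the square-root rate scale.
#'
#' Note that the likelihood is exactly invariant under jointly rescaling
#' `dH_star`, `dS_star` and every strain's `dCp` by a factor `k` while
#' dividing every residue count `n` by `k` (the free energy is linear in the
#' first three and enters only as `n * dG`).  Identification of the absolute
#' per-residue scale therefore comes from the priors; the default entropy
#' change bounds are kept narrow around the well-established
#' entropy-convergence value for globular proteins (about 17 J/(K mol
#' residue)) to pin that scale.
#'
#' @param universal_bounds 2-column matrix (lower, upper) with rows
#'   `dH_star` (J/mol-residue), `dS_star` (J/K/mol-residue), `T_H`, `T_S` (K).
#' @param group_bounds 2-column matrix with rows `dH_act` (J/mol), `dCp`
#'   (J/(K mol residue)), `n` (residues).
#' @param log_c_bounds bounds for the log scaling constant.
#' @param tau_strain_bounds 2-column matrix with rows `dH_act`, `dCp`, `n`:
#'   uniform bounds on the between-strain precisions.
#' @param tau_obs_gamma shape and rate of the gamma prior on the
#'   observational precision.
#' @return An object of class `"thermo_priors"`.
#' @export
thermo_priors <- function(
    universal_bounds = rbind(dH_star = c(4000, 6000),
                             dS_star = c(15.5, 18.5),
                             T_H = c(370, 380),
                             T_S = c(385, 395)),
    group_bounds = rbind(dH_act = c(20e3, 200e3),
                         dCp = c(40, 120),
                         n = c(50, 1000)),
    log_c_bounds = c(-20, 80),
    tau_strain_bounds = rbind(dH_act = c(2.5e-9, 2.5e-5),
                              dCp = c(2.5e-3, 25),
                              n = c(2.5e-5, 0.25)),
    tau_obs_gamma = c(shape = 0.001, rate = 0.001)) {
  chk <- function(b) all(is.finite(b)) && all(b[, 2] > b[, 1])
  if (!chk(universal_bounds) || !chk(group_bounds) || !chk(tau_strain_bounds) ||
      !(log_c_bounds[2] > log_c_bounds[1]))
    stop("prior bounds must be finite with lower < upper")
  if (any(tau_obs_gamma <= 0)) stop("gamma hyperparameters must be positive")
  structure(list(universal = universal_bounds, group = group_bounds,
                 log_c = log_c_bounds, tau_strain = tau_strain_bounds,
                 tau_obs = tau_obs_gamma),
            class = "thermo_priors")
}

# uniform log density over a bounds matrix: 0 inside, -Inf outside
.lunif <- function(x, bounds) {
  if (any(x < bounds[, 1] | x > bounds[, 2])) -Inf else 0
}

#' Log-likelihood of standardized growth records
#'
#' Gaussian likelihood on the square-root rate scale: for every record,
#' `sqrt(rate_std) ~ N(sqrt(r_model(T)), 1 / tau_obs)`.
#'
#' @param records data.frame with columns `strain_id`, `temperature_K`,
#'   `rate_std`.
#' @param u a [universal_params] object.
#' @param strains data.frame of per-strain parameters with columns
#'   `strain_id`, `c`, `dH_act`, `dCp`, `n`.
#' @param tau_obs observational precision (> 0) on the sqrt scale.
#' @return Scalar log-likelihood.
#' @export
growth_loglik <- function(records, u, strains, tau_obs) {
  stopifnot(tau_obs > 0)
  idx <- match(records$strain_id, strains$strain_id)
  if (anyNA(idx)) stop("records contain strains absent from the parameter table")
  lr <- log(strains$c[idx]) + log(records$temperature_K) -
    strains$dH_act[idx] / (.R_GAS * records$temperature_K)
  dG <- u$dH_star + strains$dCp[idx] * (records$temperature_K - u$T_H) -
    records$temperature_K * (u$dS_star + strains$dCp[idx] * log(records$temperature_K / u$T_S))
  lr <- lr + stats::plogis(strains$n[idx] * dG / (.R_GAS * records$temperature_K),
                           log.p = TRUE)
  out <- sum(stats::dnorm(sqrt(records$rate_std), exp(0.5 * lr),
                          1 / sqrt(tau_obs), log = TRUE))
  if (is.nan(out)) stop("NaN log-likelihood")
  out
}

#' Log-prior of the full hierarchical parameter state
#'
#' @param u a [universal_params] object (or list with the four elements).
#' @param group_means data.frame with columns `group`, `dH_act`, `dCp`, `n`.
#' @param strains data.frame with columns `strain_id`, `group`, `c`,
#'   `dH_act`, `dCp`, `n`.
#' @param tau_strain named numeric (`dH_act`, `dCp`, `n`) strain precisions.
#' @param tau_obs observational precision.
#' @param prior a [thermo_priors] object.
#' @return Scalar log-prior density (`-Inf` outside the support).
#' @export
growth_logprior <- function(u, group_means, strains, tau_strain, tau_obs,
                            prior = thermo_priors()) {
  stopifnot(inherits(prior, "thermo_priors"))
  lp <- .lunif(c(u$dH_star, u$dS_star, u$T_H, u$T_S), prior$universal)
  for (g in seq_len(nrow(group_means)))
    lp <- lp + .lunif(c(group_means$dH_act[g], group_means$dCp[g], group_means$n[g]),
                      prior$group)
  lp <- lp + .lunif(tau_strain, prior$tau_strain)
  if (any(log(strains$c) < prior$log_c[1] | log(strains$c) > prior$log_c[2]))
    lp <- -Inf
  if (!is.finite(lp)) return(-Inf)
  gi <- match(strains$group, group_means$group)
  for (p in c("dH_act", "dCp", "n"))
    lp <- lp + sum(stats::dnorm(strains[[p]], group_means[[p]][gi],
                                1 / sqrt(tau_strain[[p]]), log = TRUE))
  lp + stats::dgamma(tau_obs, shape = prior$tau_obs[["shape"]],
                     rate = prior$tau_obs[["rate"]], log = TRUE)
}
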