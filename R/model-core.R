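#' @keywords internal
.R_GAS <- 8.314

#' Universal protein-unfolding parameters
#'
#' Container for the four unfolding parameters treated as common to all
#' strains: the per-residue enthalpy and entropy changes at their respective
#' convergence temperatures, and the two convergence temperatures themselves
#' (Murphy-Privalov parameterization of globular-protein stability).
#'
#' @param dH_star enthalpy change at the enthalpy convergence temperature,
#'   J per mol amino-acid residue.
#' @param dS_star entropy change at the entropy convergence temperature,
#'   J/(K mol residue).
#' @param T_H convergence temperature for enthalpy, K.
#' @param T_S convergence temperature for entropy, K.
#' @return An object of class `"universal_params"`.
#' @examples
#' u <- universal_params(4874, 17, 375.5, 390.9)
#' @export
universal_params <- function(dH_star, dS_star, T_H, T_S) {
  stopifnot(dH_star > 0, dS_star > 0, T_H > 0, T_S > 0)
  if (T_H >= T_S)
    stop("T_H must be below T_S")
  if (T_H <= 250 || T_S >= 450)
    stop("convergence temperatures must lie in (250, 450) K")
  structure(list(dH_star = dH_star, dS_star = dS_star, T_H = T_H, T_S = T_S),
            class = "universal_params")
}

#' Per-strain rate-limiting-enzyme parameters
#'
#' @param c scaling constant of the Arrhenius numerator (rate units per K);
#'   strictly positive.
#' @param dH_act enthalpy of activation of the rate-limiting reaction, J/mol.
#' @param dCp heat capacity change on denaturation, J/(K mol residue).
#' @param n number of amino-acid residues of the putative rate-controlling
#'   enzyme (continuous-valued in the model).
#' @param group optional thermal/taxonomic group label.
#' @return An object of class `"strain_params"`.
#' @export
strain_params <- function(c, dH_act, dCp, n, group = NA_character_) {
  stopifnot(c > 0, dH_act > 0, dCp > 0, n > 0)
  structure(list(c = c, dH_act = dH_act, dCp = dCp, n = n, group = group),
            class = "strain_params")
}

#' Default universal unfolding parameters
#'
#' Posterior-mean estimates of the four universal parameters obtained from a
#' large multi-strain growth-rate compilation; used as package defaults for
#' simulation and as reference values throughout.
#'
#' @return A `universal_params` object with dH_star = 4874 J/mol-residue,
#'   dS_star = 17.0 J/(K mol-residue), T_H = 375.5 K, T_S = 390.9 K.
#' @export
default_universal_params <- function() {
  universal_params(dH_star = 4874, dS_star = 17.0, T_H = 375.5, T_S = 390.9)
}

#' Default thermal-group parameter means
#'
#' Group-level posterior means of the strain parameters for the five thermal
#' groups (psychrophiles, mesophiles, Ascomycota, thermophiles,
#' hyperthermophiles): enthalpy of activation (J/mol), heat capacity change
#' (J/K per mol residue) and residue count.
#'
#' @return A data.frame with columns `group`, `dH_act`, `dCp`, `n`.
#' @export
default_group_params <- function() {
  data.frame(
    group  = c("psychrophile", "mesophile", "ascomycota",
               "thermophile", "hyperthermophile"),
    dH_act = c(48.6, 75.3, 39.7, 71.3, 96.0) * 1000,
    dCp    = c(49.7, 59.9, 61.7, 71.4, 96.9),
    n      = c(388, 422, 340, 180, 101),
    stringsAsFactors = FALSE
  )
}

#' Per-residue Gibbs free energy of protein unfolding
#'
#' Evaluates the convergence-temperature form of the unfolding free energy,
#' `dG(T) = dH_star + dCp (T - T_H) - T (dS_star + dCp log(T / T_S))`,
#' in J per mol amino-acid residue.  The curve is concave in `T`
#' (d2G/dT2 = -dCp / T) with a unique maximum at the stability temperature.
#'
#' @param T temperature, K (vectorized).
#' @param u a [universal_params] object.
#' @param dCp heat capacity change on denaturation, J/(K mol residue).
#' @return Free energy of unfolding, J per mol residue.
#' @examples
#' unfolding_free_energy(310, default_universal_params(), dCp = 59.9)
#' @export
unfolding_free_energy <- function(T, u, dCp) {
  if (any(T <= 0)) stop("temperature must be positive (Kelvin)")
  if (dCp <= 0) stop("dCp must be positive")
  u$dH_star + dCp * (T - u$T_H) - T * (u$dS_star + dCp * log(T / u$T_S))
}

#' Probability that the rate-controlling enzyme is in its native state
#'
#' Two-state folding equilibrium for a chain of `n` residues with per-residue
#' unfolding free energy `dG(T)`:
#' `P(T) = 1 / (1 + exp(-n dG(T) / (R T)))`.
#' Computed through `plogis()` so that extreme arguments saturate to 0 or 1
#' rather than overflowing.
#'
#' @inheritParams unfolding_free_energy
#' @param n number of amino-acid residues.
#' @return Probability of the native conformation, in (0, 1) (vectorized
#'   over `T`).
#' @export
native_state_probability <- function(T, u, dCp, n) {
  dG <- unfolding_free_energy(T, u, dCp)
  stats::plogis(n * dG / (.R_GAS * T))
}

#' Thermodynamic growth-rate model
#'
#' Modelled population growth rate as a function of temperature for a single
#' rate-limiting, enzyme-catalysed reaction: an Arrhenius-type numerator
#' attenuated by the equilibrium probability that the catalysing enzyme is
#' folded,
#' `r(T) = c T exp(-dH_act / (R T)) / (1 + exp(-n dG(T) / (R T)))`.
#'
#' @param T temperature, K (vectorized).
#' @param u a [universal_params] object.
#' @param s a [strain_params] object (or any list with elements `c`,
#'   `dH_act`, `dCp`, `n`).
#' @param log if `TRUE`, return the natural log of the rate (useful where
#'   the Arrhenius factor underflows).
#' @return Non-negative growth rate in the units implied by `s$c`.
#' @examples
#' u <- default_universal_params()
#' s <- strain_params(1, 75300, 59.9, 422)
#' growth_rate(c(290, 300, 310), u, s)
#' @export
growth_rate <- function(T, u, s, log = FALSE) {
  if (any(T <= 0)) stop("temperature must be positive (Kelvin)")
  dG <- unfolding_free_energy(T, u, s$dCp)
  lr <- base::log(s$c) + base::log(T) - s$dH_act / (.R_GAS * T) +
    stats::plogis(s$n * dG / (.R_GAS * T), log.p = TRUE)
  if (log) lr else exp(lr)
}

# growth rate with parameters given as a flat numeric vector
# (log_c, dH_act, dCp, n) -- hot path used by the samplers.
.sqrt_rate <- function(T, u, th) {
  dG <- u$dH_star + th[3L] * (T - u$T_H) - T * (u$dS_star + th[3L] * log(T / u$T_S))
  exp(0.5 * (th[1L] + log(T) - th[2L] / (.R_GAS * T) +
               stats::plogis(th[4L] * dG / (.R_GAS * T), log.p = TRUE)))
}

#' @export
print.universal_params <- function(x, ...) {
  cat("Universal protein-unfolding parameters:\n")
  cat(sprintf("  dH* = %.4g J/mol-residue   dS* = %.4g J/(K mol-residue)\n",
              x$dH_star, x$dS_star))
  cat(sprintf("  T_H = %.4g K               T_S = %.4g K\n", x$T_H, x$T_S))
  invisible(x)
}

#' @export
print.strain_params <- function(x, ...) {
  cat(sprintf(
    "Strain parameters (group: %s):\n  c = %.4g, dH_act = %.4g J/mol, dCp = %.4g J/(K mol-res), n = %.4g\n",
    x$group, x$c, x$dH_act, x$dCp, x$n))
  invisible(x)
}
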