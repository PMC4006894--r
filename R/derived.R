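#' Stability temperature (temperature of minimal denaturation)
#'
#' The unique maximizer of the per-residue unfolding free energy.  From the
#' stationarity condition of `dG(T)` this has the closed form
#' `T* = T_S exp(-dS_star / dCp)`.
#'
#' @param u a [universal_params] object.
#' @param dCp heat capacity change on denaturation, J/(K mol residue);
#'   vectorized.
#' @return Stability temperature T*, K.
#' @examples
#' stability_temperature(default_universal_params(), 59.9)  # ~294.3 K
#' @export
stability_temperature <- function(u, dCp) {
  if (any(dCp <= 0)) stop("dCp must be positive")
  u$T_S * exp(-u$dS_star / dCp)
}

#' Optimal growth temperature
#'
#' Numerically locates the temperature of maximal modelled growth rate.  A
#' coarse 1 K grid brackets the maximum (and detects multimodality, which is
#' flagged by a warning and an attribute rather than a silent answer); the
#' bracket is then refined with `optimize()`.  The result is independent of
#' the scaling constant `c`.
#'
#' @param u a [universal_params] object.
#' @param s a [strain_params] object.
#' @param interval search interval in K.
#' @param tol absolute tolerance on the location, K.
#' @return Optimal temperature T_opt, K.  Attribute `"unimodal"` is `FALSE`
#'   if the coarse grid showed more than one interior local maximum.
#' @export
optimal_temperature <- function(u, s, interval = c(200, 420), tol = 1e-3) {
  grid <- seq(interval[1], interval[2], by = 1)
  lr <- growth_rate(grid, u, s, log = TRUE)
  k <- which.max(lr)
  # count interior local maxima on the coarse grid
  d <- diff(lr)
  n_max <- sum(d[-length(d)] > 0 & d[-1] < 0)
  lo <- grid[max(1L, k - 1L)]
  hi <- grid[min(length(grid), k + 1L)]
  opt <- stats::optimize(function(T) growth_rate(T, u, s, log = TRUE),
                         lower = lo, upper = hi, maximum = TRUE, tol = tol)
  out <- opt$maximum
  unimodal <- n_max <= 1L
  if (!unimodal)
    warning("growth curve is not unimodal on the search interval; returning the global maximum")
  attr(out, "unimodal") <- unimodal
  out
}

#' Temperatures of 50% denaturation
#'
#' The two roots of `dG(T) = 0` bracketing the stability temperature: below
#' `T_L` (cold denaturation) and above `T_U` (heat denaturation) less than
#' half of the enzyme population is folded.  Because `dG` is strictly concave
#' there is at most one root on each side; each is found by bracketed
#' root-finding (`uniroot`).  The roots do not depend on the residue count.
#'
#' @param u a [universal_params] object.
#' @param dCp heat capacity change, J/(K mol residue).
#' @param tol absolute root tolerance, K.
#' @return Named numeric vector `c(T_L, T_U)`, K.  If the free energy never
#'   becomes positive (`max dG <= 0`, i.e. the enzyme is always at least 50%
#'   denatured) both entries are `NA` and attribute `"always_denatured"` is
#'   `TRUE`.
#' @export
half_denaturation_bounds <- function(u, dCp, tol = 1e-9) {
  Ts <- stability_temperature(u, dCp)
  f <- function(T) unfolding_free_energy(T, u, dCp)
  if (f(Ts) <= 0) {
    out <- c(T_L = NA_real_, T_U = NA_real_)
    attr(out, "always_denatured") <- TRUE
    return(out)
  }
  lo <- Ts - 50
  while (lo > 50 && f(lo) > 0) lo <- lo - 50
  hi <- Ts + 50
  while (hi < 600 && f(hi) > 0) hi <- hi + 50
  TL <- if (f(lo) < 0)
    stats::uniroot(f, lower = lo, upper = Ts, tol = tol)$root else NA_real_
  TU <- if (f(hi) < 0)
    stats::uniroot(f, lower = Ts, upper = hi, tol = tol)$root else NA_real_
  out <- c(T_L = TL, T_U = TU)
  attr(out, "always_denatured") <- FALSE
  out
}

#' Coefficients of the non-polar hydrogen relationship
#'
#' The average number of non-polar hydrogen atoms per residue is related to
#' the per-residue heat capacity change and chain length by
#' `Nh = a + b dCp + c / n` (equivalently, the total heat capacity change is
#' affine in the total number of non-polar hydrogens and in `n`).  The
#' default coefficients are calibrated so that the relationship reproduces
#' published group-level derived values to better than 0.03 hydrogens.
#'
#' @return Named numeric vector with elements `a`, `b`, `c`.
#' @export
graziano_coefficients <- function() {
  c(a = 1.61742185, b = 0.04851548, c = 233.33050911)
}

#' Average non-polar hydrogen atoms per amino-acid residue
#'
#' @param dCp heat capacity change, J/(K mol residue).
#' @param n number of amino-acid residues.
#' @param coef coefficients of the relationship, see
#'   [graziano_coefficients()].
#' @return Nh, dimensionless (vectorized).
#' @export
nonpolar_hydrogens <- function(dCp, n, coef = graziano_coefficients()) {
  if (any(dCp <= 0) || any(n <= 0)) stop("dCp and n must be positive")
  if (any(dCp < 20 | dCp > 150) || any(n < 50 | n > 1000))
    warning("parameters outside the calibration range of the Nh relationship")
  unname(coef["a"] + coef["b"] * dCp + coef["c"] / n)
}

#' Derived thermodynamic summary for one parameter set
#'
#' Assembles the derived temperatures and indices for a single strain or
#' group-mean parameter set: non-polar hydrogen index, stability temperature,
#' optimal growth temperature, the 50%-denaturation bounds, their pairwise
#' differences, and the total heat capacity change `n * dCp`.
#'
#' @param u a [universal_params] object.
#' @param s a [strain_params] object.
#' @return A one-row data.frame with columns `group`, `Nh`, `T_star`,
#'   `T_opt`, `T_L`, `T_U`, `d_UO` (= T_U - T_opt), `d_OL` (= T_opt - T_L),
#'   `d_OS` (= T_opt - T_star) and `total_dCp` (J/(K mol)).
#' @export
derived_summary <- function(u, s) {
  Ts <- stability_temperature(u, s$dCp)
  To <- as.numeric(optimal_temperature(u, s))
  hb <- half_denaturation_bounds(u, s$dCp)
  data.frame(
    group = s$group,
    Nh = nonpolar_hydrogens(s$dCp, s$n),
    T_star = Ts, T_opt = To, T_L = hb[["T_L"]], T_U = hb[["T_U"]],
    d_UO = hb[["T_U"]] - To, d_OL = To - hb[["T_L"]], d_OS = To - Ts,
    total_dCp = s$n * s$dCp,
    stringsAsFactors = FALSE
  )
}

#' Derived-parameter table for a set of groups
#'
#' Applies [derived_summary()] to each row of a group-parameter table,
#' yielding a table of derived thermodynamic quantities by thermal group.
#'
#' @param u a [universal_params] object.
#' @param groups data.frame with columns `group`, `dH_act`, `dCp`, `n`
#'   (see [default_group_params()]).
#' @return A data.frame with one row per group, columns as in
#'   [derived_summary()].
#' @examples
#' group_summary_table(default_universal_params(), default_group_params())
#' @export
group_summary_table <- function(u, groups = default_group_params()) {
  out <- do.call(rbind, lapply(seq_len(nrow(groups)), function(i) {
    s <- strain_params(1, groups$dH_act[i], groups$dCp[i], groups$n[i],
                       group = groups$group[i])
    derived_summary(u, s)
  }))
  rownames(out) <- NULL
  out
}

#' Native-state probability curves by group
#'
#' Evaluates the native-state probability on a temperature grid for each
#' group-mean parameter set, in long format suitable for plotting the
#' characteristic flattened-top curves of the more thermophilic groups.
#'
#' @param u a [universal_params] object.
#' @param groups group-parameter data.frame (see [default_group_params()]).
#' @param temperatures grid of temperatures, K.
#' @return A data.frame with columns `group`, `temperature_K`, `p_native`.
#' @export
native_state_curves <- function(u, groups = default_group_params(),
                                temperatures = seq(260, 400, by = 0.5)) {
  out <- do.call(rbind, lapply(seq_len(nrow(groups)), function(i) {
    data.frame(group = groups$group[i], temperature_K = temperatures,
               p_native = native_state_probability(temperatures, u,
                                                   groups$dCp[i], groups$n[i]),
               stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out
}
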