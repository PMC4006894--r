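#' Simulation configuration
#'
#' Describes a synthetic multi-strain growth-rate dataset with the
#' hierarchical structure the fitting engine assumes: strains nested in
#' thermal groups, strain-level thermodynamic parameters Gaussian around the
#' group means (truncated at zero), observations on a per-strain temperature
#' grid spanning the biokinetic range, and Gaussian noise on the square-root
#' rate scale.
#'
#' The defaults emulate a large literature compilation: five thermal groups
#' at their group-mean parameter values, 14 strains, 14 temperature points
#' per strain (about the compilation's mean records-per-strain), and a
#' square-root-scale noise SD of 0.02.
#'
#' @param universal a [universal_params] object.
#' @param groups data.frame with columns `group`, `dH_act`, `dCp`, `n`.
#' @param strains_per_group integer vector, one entry per group row.
#' @param points_per_strain number of temperature points per strain.
#' @param noise_sd SD of Gaussian noise on the square-root rate scale.
#' @param sd_dH_act,sd_dCp,sd_n between-strain SDs of the strain parameters
#'   around their group means (J/mol, J/(K mol residue), residues).
#' @param seed integer seed; the same seed yields an identical dataset.
#' @return An object of class `"sim_config"`.
#' @export
sim_config <- function(universal = default_universal_params(),
                       groups = default_group_params(),
                       strains_per_group = c(2, 6, 2, 2, 2),
                       points_per_strain = 14,
                       noise_sd = 0.02,
                       sd_dH_act = 2000, sd_dCp = 1.0, sd_n = 15,
                       seed = 1L) {
  stopifnot(length(strains_per_group) == nrow(groups),
            all(strains_per_group > 0), points_per_strain >= 3,
            noise_sd >= 0, sd_dH_act >= 0, sd_dCp >= 0, sd_n >= 0)
  structure(list(universal = universal, groups = groups,
                 strains_per_group = as.integer(strains_per_group),
                 points_per_strain = as.integer(points_per_strain),
                 noise_sd = noise_sd,
                 sd = c(dH_act = sd_dH_act, dCp = sd_dCp, n = sd_n),
                 seed = as.integer(seed)),
            class = "sim_config")
}

# truncated-at-zero Gaussian draw by rejection (SD = 0 returns the mean)
.rtruncnorm_pos <- function(mean, sd) {
  if (sd == 0) return(mean)
  repeat {
    x <- stats::rnorm(1, mean, sd)
    if (x > 0) return(x)
  }
}

#' Draw one strain's parameters from its group distribution
#'
#' Strain-level parameters are Gaussian around the group means, truncated at
#' zero (all parameters are physically positive).  With all SDs zero the
#' group means are returned exactly.
#'
#' @param group_mean list or one-row data.frame with `dH_act`, `dCp`, `n`
#'   and `group`.
#' @param sd named numeric vector of between-strain SDs
#'   (`dH_act`, `dCp`, `n`).
#' @return A [strain_params] object (with `c = 1`; the scaling constant is
#'   set separately, typically so that the peak rate is 1).
#' @export
draw_strain <- function(group_mean, sd = c(dH_act = 2000, dCp = 1.0, n = 15)) {
  strain_params(
    c = 1,
    dH_act = .rtruncnorm_pos(group_mean$dH_act, sd[["dH_act"]]),
    dCp = .rtruncnorm_pos(group_mean$dCp, sd[["dCp"]]),
    n = .rtruncnorm_pos(group_mean$n, sd[["n"]]),
    group = group_mean$group
  )
}

#' Temperature grid spanning a strain's biokinetic range
#'
#' Builds a strictly increasing grid of `k` temperatures covering the range
#' over which the strain shows appreciable growth: from the cold-side
#' temperature at which the modelled rate falls to 5% of its maximum, up to
#' just above the upper 50%-denaturation temperature, clipped to the
#' observable window (271, 396) K.  The grid always contains the optimal
#' temperature itself.
#'
#' @param s a [strain_params] object.
#' @param u a [universal_params] object.
#' @param k number of points (>= 3).
#' @param window observable temperature window, K.
#' @return Increasing numeric vector of `k` temperatures.
#' @export
biokinetic_grid <- function(s, u, k = 14, window = c(271, 396)) {
  stopifnot(k >= 3)
  To <- as.numeric(optimal_temperature(u, s))
  lr_max <- growth_rate(To, u, s, log = TRUE)
  f <- function(T) growth_rate(T, u, s, log = TRUE) - (lr_max + log(0.05))
  lo <- if (f(150) < 0)
    stats::uniroot(f, lower = 150, upper = To, tol = 1e-4)$root else 150
  hb <- half_denaturation_bounds(u, s$dCp)
  hi <- if (is.na(hb[["T_U"]])) {
    if (f(To + 100) < 0)
      stats::uniroot(f, lower = To, upper = To + 100, tol = 1e-4)$root
    else To + 100
  } else hb[["T_U"]] + 1
  lo <- max(lo, window[1] + 0.1)
  hi <- min(hi, window[2] - 0.1)
  grid <- sort(unique(c(seq(lo, hi, length.out = k - 1L), To)))
  # guard against To coinciding with a grid point
  while (length(grid) < k)
    grid <- sort(c(grid, mean(grid[1:2])))
  grid
}

#' Standardize rates to a per-strain maximum of one
#'
#' Divides each strain's observed rates by that strain's maximum observed
#' rate, so standardized rates lie in \[0, 1\] with per-strain maximum exactly
#' 1.  The operation is idempotent and preserves within-strain rate ordering.
#'
#' @param records data.frame with columns `strain_id` and `rate_obs`.
#' @return The same data.frame with a `rate_std` column added/replaced.
#' @export
standardize_rates <- function(records) {
  stopifnot(all(c("strain_id", "rate_obs") %in% names(records)))
  mx <- tapply(records$rate_obs, records$strain_id, max)
  if (any(mx <= 0)) {
    bad <- names(mx)[mx <= 0]
    stop("strain(s) with no positive rate: ", paste(bad, collapse = ", "))
  }
  records$rate_std <- records$rate_obs / as.numeric(mx[as.character(records$strain_id)])
  records
}

#' Simulate a hierarchical growth-rate dataset
#'
#' Generates strains group by group: parameters drawn from truncated
#' Gaussians around the group means, the scaling constant set so that each
#' strain's peak modelled rate is 1, observations on a biokinetic-range
#' temperature grid, and noise added on the square-root scale
#' (`rate_obs = (max(0, sqrt(r_model) + eps))^2`, `eps ~ N(0, noise_sd^2)`).
#' Rates are then standardized per strain.  The generating (ground-truth)
#' parameters are returned alongside the records for recovery experiments.
#'
#' @param cfg a [sim_config] object.
#' @return A list of class `"thermo_sim"` with elements `records` (data.frame
#'   `strain_id`, `group`, `temperature_K`, `rate_obs`, `rate_std`),
#'   `strains` (ground-truth per-strain parameters incl. `c`), `metadata`
#'   (strain taxonomy: `domain`, `cellularity`, `ascomycota`), `universal`,
#'   and `config`.
#' @examples
#' sim <- simulate_growth(sim_config(seed = 42))
#' nrow(sim$records)  # 14 strains x 14 points = 196
#' @export
simulate_growth <- function(cfg = sim_config()) {
  stopifnot(inherits(cfg, "sim_config"))
  set.seed(cfg$seed)
  u <- cfg$universal
  recs <- list(); strains <- list(); meta <- list()
  sid <- 0L
  for (g in seq_len(nrow(cfg$groups))) {
    gm <- cfg$groups[g, ]
    for (j in seq_len(cfg$strains_per_group[g])) {
      sid <- sid + 1L
      id <- sprintf("S%02d", sid)
      s <- draw_strain(gm, cfg$sd)
      # scale so the peak modelled rate is exactly 1
      To <- as.numeric(optimal_temperature(u, s))
      s$c <- 1 / growth_rate(To, u, s)
      temps <- biokinetic_grid(s, u, cfg$points_per_strain)
      r_model <- growth_rate(temps, u, s)
      sq <- pmax(0, sqrt(r_model) + stats::rnorm(length(temps), 0, cfg$noise_sd))
      recs[[sid]] <- data.frame(strain_id = id, group = gm$group,
                                temperature_K = temps, rate_obs = sq^2,
                                stringsAsFactors = FALSE)
      strains[[sid]] <- data.frame(strain_id = id, group = gm$group,
                                   c = s$c, dH_act = s$dH_act, dCp = s$dCp,
                                   n = s$n, stringsAsFactors = FALSE)
      meta[[sid]] <- data.frame(strain_id = id, group = gm$group,
                                domain = .sim_domain(gm$group, j),
                                cellularity = .sim_cellularity(gm$group, j),
                                ascomycota = identical(gm$group, "ascomycota"),
                                stringsAsFactors = FALSE)
    }
  }
  records <- standardize_rates(do.call(rbind, recs))
  structure(list(records = records,
                 strains = do.call(rbind, strains),
                 metadata = do.call(rbind, meta),
                 universal = u, config = cfg),
            class = "thermo_sim")
}

# plausible taxonomy assignments for the synthetic strains: psychrophiles and
# thermophiles bacterial, hyperthermophiles archaeal, Ascomycota unicellular
# eukaryotes, mesophiles alternating bacteria / multicellular eukaryotes.
.sim_domain <- function(group, j) {
  switch(group,
         psychrophile = "Bacteria",
         mesophile = if (j %% 2 == 0) "Eukarya" else "Bacteria",
         ascomycota = "Eukarya",
         thermophile = if (j %% 2 == 0) "Archaea" else "Bacteria",
         hyperthermophile = "Archaea",
         "Bacteria")
}

.sim_cellularity <- function(group, j) {
  if (group == "mesophile" && j %% 2 == 0) "multicellular" else "unicellular"
}

#' @export
print.thermo_sim <- function(x, ...) {
  cat(sprintf("Synthetic growth dataset: %d strains, %d records, %d groups (seed %d)\n",
              nrow(x$strains), nrow(x$records),
              length(unique(x$strains$group)), x$config$seed))
  invisible(x)
}
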