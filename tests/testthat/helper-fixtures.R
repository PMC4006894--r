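# Shared fixtures: reference parameter sets and a small cached simulation.

u_ref <- default_universal_params()
groups_ref <- default_group_params()
meso <- strain_params(c = 1, dH_act = 75300, dCp = 59.9, n = 422,
                      group = "mesophile")

# a small 3-group dataset used by several inference tests
small_sim <- function(seed = 11, noise_sd = 0.02, points = 10) {
  cfg <- sim_config(
    groups = groups_ref[c(1, 2, 4), ],
    strains_per_group = c(2, 2, 2),
    points_per_strain = points,
    noise_sd = noise_sd,
    seed = seed
  )
  simulate_growth(cfg)
}
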