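---
title: "A thermodynamic model of temperature-dependent population growth"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{A thermodynamic model of temperature-dependent population growth}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(thermogrowth)
```

## The model

`thermogrowth` describes the temperature dependence of population growth
rates — microbial specific growth rates, or intrinsic rates from life-table
analysis for small multicellular poikilotherms — by assuming a single,
rate-limiting, enzyme-catalysed reaction.  The reaction proceeds at an
Arrhenius-type rate, and the enzyme that catalyses it exists in a two-state
folding equilibrium, denaturing at both low and high temperature:

$$ r(T) \;=\; \frac{c\,T\,e^{-\Delta H^{\ddagger}/(RT)}}
   {1 + e^{-n\,\Delta G(T)/(RT)}}, $$

where the per-residue free energy of unfolding follows the
convergence-temperature (Murphy–Privalov) parameterization of globular
protein stability:

$$ \Delta G(T) \;=\; \Delta H^{*} + \Delta C_p (T - T_H)
   - T \left[ \Delta S^{*} + \Delta C_p \ln (T/T_S) \right]. $$

Four parameters are *universal* — shared by every strain, because they
describe the near-universal convergence behaviour of protein unfolding
thermodynamics:

| parameter | meaning | units | default |
|---|---|---|---|
| $\Delta H^{*}$ | enthalpy change at $T_H$ | J/(mol residue) | 4874 |
| $\Delta S^{*}$ | entropy change at $T_S$ | J/(K mol residue) | 17.0 |
| $T_H$ | enthalpy convergence temperature | K | 375.5 |
| $T_S$ | entropy convergence temperature | K | 390.9 |

Four more are strain-specific: the scaling constant $c$ (absorbing rate
units; on standardized data it is a nuisance), the activation enthalpy
$\Delta H^{\ddagger}$ (J/mol; sets the steepness of the cold flank), the
heat capacity change on denaturation $\Delta C_p$ (J/(K mol residue); sets
the curvature of $\Delta G$ and hence both cold and heat denaturation), and
the residue count $n$ (dimensionless; scales per-residue stability up to
the whole protein, sharpening the transition).  $\Delta G$ is strictly
concave in $T$ ($\partial^2 \Delta G/\partial T^2 = -\Delta C_p/T$), so it
has a unique maximum and at most two zeros.

## Derived quantities

* Stability temperature: $T^{*} = T_S\, e^{-\Delta S^{*}/\Delta C_p}$, the
  unique maximizer of $\Delta G$ — where denaturation is minimal.
* Optimal growth temperature $T_{\mathrm{opt}}$: located numerically
  (coarse 1 K bracket, then golden-section refinement via `optimize()` to
  0.001 K).  It is independent of $c$ and, with $\Delta H^\ddagger > 0$,
  always sits above $T^{*}$.
* 50%-denaturation bounds $(T_L, T_U)$: the zeros of $\Delta G$, found by
  bracketed root-finding on each side of $T^{*}$ (concavity guarantees at
  most one per side).  The native-state probability
  $P(T) = 1/(1 + e^{-n \Delta G/(RT)})$ equals exactly 1/2 there, for any
  $n$.  If $\max_T \Delta G \le 0$ the enzyme is always at least half
  denatured; the result is flagged rather than silently solved.
* Non-polar hydrogen index $N_h$: the average number of non-polar hydrogen
  atoms per residue implied by $\Delta C_p$ and $n$.  The coefficients of
  the relationship ($N_h = a + b\,\Delta C_p + c/n$) ship as a calibrated
  constant set (`graziano_coefficients()`) that reproduces published
  group-level derived values to better than 0.03 hydrogens, and can be
  overridden.

`group_summary_table()` assembles all of these per thermal group;
`native_state_curves()` exports $P(T)$ curves, which show the
characteristic pattern of taller, flatter native-state peaks in
thermophiles and hyperthermophiles and a left-shifted psychrophile curve.

```{r derived}
group_summary_table(default_universal_params())
```

## Hierarchical inference

Observations are standardized per strain (`standardize_rates()`, maximum
rate 1) and modelled on the square-root scale to stabilise the variance:
$\sqrt{y_{ij}} \sim N(\sqrt{r(T_{ij})}, 1/\tau_{\mathrm{obs}})$.  Strain
parameters $(\Delta H^\ddagger_i, \Delta C_{p,i}, n_i)$ are Gaussian around
their group means with per-parameter-type precisions; group means and the
universal parameters carry uniform priors with bounds informed by protein
biochemistry; $c_i$ is sampled on the log scale with a vague prior;
$\tau_{\mathrm{obs}}$ has a vague gamma prior.

### Identifiability and the entropy-convergence prior

The likelihood is *exactly invariant* under
$(\Delta H^{*}, \Delta S^{*}, \Delta C_{p,i}) \to k \cdot (\cdot)$ with
$n_i \to n_i / k$: $\Delta G$ is linear in the first three and enters the
model only through the product $n\,\Delta G$.  The absolute per-residue
scale is therefore a prior-identified quantity, not a data-identified one.
The package pins it the way the field does — through the well-established
entropy-convergence value for globular proteins: the default prior for
$\Delta S^{*}$ is uniform on $[15.5, 18.5]$ J/(K mol residue), bracketing
the published convergence estimates (about 4.0–4.4 cal/(K mol residue)).
With that one scale anchored, the remaining universal parameters are
data-identified through the differing curvatures of strains spanning the
five thermal groups.

### A mirror regime, and the folded-fraction penalty

Beyond the scale invariance, the per-strain likelihood admits a second,
biologically meaningless regime: with a small $\Delta C_p$ and small $n$
the denominator becomes a gradual brake rather than a sharp cutoff, and an
inflated $\Delta H^\ddagger$ can then shape a similar unimodal curve in
which the "optimum" occurs where the enzyme is predominantly *denatured*
(stability temperature far below the biokinetic range).  Samplers can be
captured by this mirror regime, which collapses interval calibration.  The
fitting engine therefore adds an identifying soft restriction: at each
strain's observed peak temperature the folded fraction of the enzyme
should exceed 20%, with violations of
$n\,\Delta G(\hat T_i)/(R \hat T_i) > \mathrm{logit}\,0.2$ incurring a
quadratic log-density penalty (weight 5 per squared logit unit) rather
than a hard support bound — hard walls can deadlock the coupled
universal/strain updates.  In the legitimate regime the folded fraction
at the optimum ranges from about 0.6 (psychrophiles) to 0.9
(hyperthermophiles), so the penalty is zero there; it merely removes the
mirror image.

### Samplers

One sweep of `thermo_fit()` updates:

1. each strain's block $(\log c_i, \Delta H^\ddagger_i, \Delta C_{p,i},
   n_i)$ by adaptive-Metropolis (Haario) proposals — empirical block
   covariance scaled by $2.38^2/d$, diagonal jitter $10^{-10}$, plus a
   Robbins–Monro global scale tuned toward 23% acceptance; the adaptation
   moments are reset once after the settling phase so the learned
   covariance reflects the stationary conditional rather than the approach
   path (two passes per sweep);
2. group means and the strain precisions by their exact truncated
   conditional draws (truncated normal and truncated gamma — both are
   conditionally conjugate given the uniform priors; Haario versions remain
   available via `group_update = "haario"`);
3. the observational precision by conjugate gamma Gibbs;
4. the universal parameters by adaptive direction sampling: direction moves
   through pairs of stored past states (with occasional unit-scale jumps),
   a low-probability (5%) stepping-stone independence proposal from the
   prior box, and an adaptive-Metropolis component that also drives the
   settling phase;
5. a stability-preserving joint move that shifts the universal parameters
   while rescaling every strain's $(\Delta C_p, n)$ to preserve its
   stability temperature and total peak stability (deterministic 1–1 map
   with the corresponding Jacobian), plus an exact scale move along the
   invariance direction above.  Without moves 5 the universal parameters
   random-walk along a long curved ridge coupled to all strains and
   converge only on runs of order $10^6$ iterations; with them, desk-scale
   runs ($10^5$) equilibrate.

`hpdi()` computes highest-posterior-density intervals as the shortest
contiguous window containing $\lceil 0.99\,N \rceil$ sorted draws (ties
broken toward the lowest start).  Summaries report means, SDs, 99% HPDIs,
split-$\hat R$ and a crude autocorrelation-based effective sample size,
computed on the retained (post burn-in) half of the chain only.

`two_stage_fit()` reproduces the two-stage standardization: after a first
fit, each strain's data are divided by its fitted maximum rate and the
model refitted, which effectively removes the influence of $c$.
`fit_single_strain()` offers the classical single-strain nonlinear
least-squares route (Levenberg–Marquardt on the square-root scale), with
the customary scheme of holding $T_H$, $T_S$ and $\Delta S^{*}$ fixed.

## Synthetic data

`simulate_growth()` emulates the structure of the multi-strain literature
compilations this model is fitted to, without reproducing any actual
measurements: five thermal groups (psychrophiles, mesophiles, Ascomycota,
thermophiles, hyperthermophiles) at their published group-mean parameters,
14 strains in groups of (2, 6, 2, 2, 2), strain parameters drawn from
zero-truncated Gaussians around the group means (default between-strain
SDs: 2 kJ/mol on $\Delta H^\ddagger$, 1 J/(K mol res) on $\Delta C_p$, 15
residues on $n$ — small relative to the between-group spread), 14
temperature points per strain (the compilation's average of about 14.3
records per strain) spanning each strain's biokinetic range (from the
cold-side 5%-of-maximum temperature to just past $T_U$, clipped to the
observed 271–396 K window, always including $T_{\mathrm{opt}}$), and
Gaussian noise with SD 0.02 on the square-root rate scale.  Negative
perturbed square roots are floored at zero before squaring, since rates
are physically non-negative.

What the generator does *not* emulate: heterogeneity of measurement
methods across literature sources, irregular temperature designs,
strain-specific record counts, non-Gaussian outliers, and any taxonomic
correlation structure beyond the group labels.  Passing recovery tests on
these data therefore demonstrates the *internal* consistency of model,
sampler and summaries — not robustness to the messiness of real
compilations.

## Model-structure comparison

Five grouping structures are supported: (I) one group; (II) the three
taxonomic domains; (III) domains with Eukarya split by cellularity; (IV)
four thermal groups allocated by stability temperature (cut-points 285,
300, 316 K on $T^{*}$, chosen as midpoints between the published group
values and overridable); (V) thermal groups with Ascomycota separated.  A
$T^{*}$ exactly on a boundary goes to the lower group.  Allocation uses
$T^{*}$ from an initial fit (`pilot_stability_temperatures()`):
independent per-strain least-squares fits with the universal parameters
held fixed, which rank the stability temperatures far more reliably than
a short hierarchical pilot.

Two marginal-likelihood routes are provided.  The power-posterior
stepping-stone estimator (`marginal_likelihood()`, tempering ladder
$\beta_k = (k/K)^5$, log-sum-exp combination with a delta-method MC
standard error) samples each structure separately and is the recommended
estimator for ranking structures (`compare_structures()`).  A collapsed
product-space (Carlin–Chib) sampler is also available in `bayes_factor()`:
the structures share all strain-level and universal parameters, and the
model indicator is updated with the group means integrated out in closed
form (the ideal pseudo-prior — the full conditional — collapsed
analytically), with Rao-Blackwellized odds.  In practice the product-space
route can still mix poorly across structures when the weakly identified
residue counts allow a richer grouping to manufacture self-consistent
clusters; the stepping-stone estimator does not depend on trans-model
mixing and is therefore the method of record here.  On data with five
well-separated groups the thermal-group structure is strongly preferred
over a single group; on single-group data an artificial split earns no
preference — the complexity penalty is visible.  The magnitudes of
published Bayes factors for real compilations are not reproducible from
synthetic data; only the direction is.

## Numerical choices

* All temperatures are Kelvin internally; Celsius is converted at the I/O
  boundary only.  Activation enthalpies are J/mol internally (tables are
  conventionally printed in kJ/mol).
* The logistic denominator is evaluated through `plogis(log.p = TRUE)`,
  so extreme arguments saturate to 0/1 instead of overflowing; rates are
  computed on the log scale and never return NaN.
* Root brackets for $(T_L, T_U)$ expand in 50 K steps (down to 50 K, up to
  600 K) before bisection at $10^{-9}$ K; the optimum search uses a 1 K
  bracket and `optimize()` at $10^{-3}$ K.  A coarse-grid multimodality
  check flags non-unimodal curves instead of failing silently.
* MCMC initialization is deterministic and data-driven: universal
  parameters at prior midpoints, each strain's $\Delta C_p$ from the
  observed peak location through the $T^{*}$ relation, $n$ and
  $\Delta H^\ddagger$ at central values, $\log c$ profiled so the initial
  curve peaks at the observed maximum.
* Example and test problem sizes are deliberately desk-scale: fits of 6–14
  strains at $10^4$–$1.5\times10^5$ iterations, which the sampler
  extensions above make sufficient for recovery to a few percent.

## Limitations

* The per-residue scale is prior-identified (see above); conclusions about
  absolute $\Delta H^{*}$, $\Delta S^{*}$, $\Delta C_p$ and $n$ inherit
  the entropy-convergence prior.
* Group-level recovery assumes at least two strains per occupied group;
  single-strain groups make the group mean follow its strain.
* The two-state, single-reaction assumption is a modelling idealization;
  the package neither models protein structures nor multi-enzyme networks.
* $N_h$ coefficients are a calibration, valid roughly for
  $\Delta C_p \in [20, 150]$ and $n \in [50, 1000]$; a warning is issued
  outside that range.
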