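---
title: "All-optical internal-field analysis of GFP-type proteins: models, assumptions and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{All-optical internal-field analysis of GFP-type proteins}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(starkfp)
```

# The physical model

## Quadratic Stark effect in one dimension

The anionic GFP-type chromophore is treated as a quasi one-dimensional
dipolar system. Its permanent dipole-moment change on excitation,
$\Delta\mu$, has a field-independent part $\Delta\mu_0$ (the vacuum value)
and a part induced by the internal protein field through the polarizability
change $\Delta\alpha$:

$$\Delta\mu = \Delta\mu_0 + \Delta\alpha\, E_{\Delta\mu},$$

where $E_{\Delta\mu}$ is the projection of the internal field on the
$\Delta\mu_0$ direction (+x runs from the imidazolinone to the phenolate
ring). Because $\Delta\mu$ is measurable optically, this inverts to a field
estimate, $E_{\Delta\mu} = (\Delta\mu - \Delta\mu_0)/\Delta\alpha$
(`field_of_delta_mu()`). With a vacuum reference the result is the **total**
effective field; substituting a hydrogen-bonded-cluster reference
$\Delta\mu_{HB}$ (and the cluster-level $\Delta\alpha$) isolates the
**long-range** field created by the protein outside the cluster.

The same field shifts the 0--0 transition through the second-order Stark
effect, giving a parabola in the measurable coordinates,
$\bar\nu = A\Delta\mu^2 + C$ with $A = -1/(2hc\Delta\alpha)$ and
$C = \bar\nu_{vac} - A\Delta\mu_0^2$ (`nu_of_delta_mu()`). Fitting this
parabola across an ensemble of mutants sharing the chromophore
(`fit_stark_parabola()`) therefore yields both electro-optic constants. The
ensemble fit constrains the extremum to $\Delta\mu = 0$ (no linear term);
the class-restricted fit for one hydrogen-bonding class
(`fit_subset_quadratic()`) leaves the linear term free, because
structural (bond-length-alternation) response adds odd terms there. The
package stops at the free coefficients $(A, B, C)$: back-solving the
resonance-model parameters behind them requires equations that are not part
of this package's scope.

## Assumptions

* $\Delta\alpha$ is field-independent (no hyperpolarizability), and both
  $\Delta\mu$ and all fields are scalars -- projections on the fixed
  molecular +x axis.
* The chromophore geometry is shared across the ensemble; mutations act
  only through the electrostatic environment.
* For long-range extraction, $\Delta\mu_{HB}$ is invariant within a class
  of proteins with the same hydrogen-bonding pattern.

## Field-fluctuation broadening

If the internal field fluctuates normally with standard deviation
$\delta E$, the linear Stark effect turns field noise into frequency noise
$\kappa\,|\Delta\mu|\,\delta E$ ($\kappa$ = 16.792 cm$^{-1}$ per D·MV/cm),
which adds in quadrature to a field-independent vibrational width $\gamma$:
$w^2 = (\kappa\,\Delta\mu\,\delta E)^2 + \gamma^2$ (`linewidth_model()`).
Regressing $w^2$ on $\Delta\mu^2$ across the ensemble
(`fit_broadening()`) returns $\delta E$ from the slope and $\gamma$ from
the intercept; a negative fitted intercept (possible in noisy small
ensembles) is floored at zero and flagged `degenerate` rather than
propagated as an imaginary width.

## Solvent reaction fields

For the chromophore in water two routes to the solvent reaction field are
implemented. The spectroscopic route divides the solvent-induced dipole
change by the polarizability change,
$E_R = \Delta\mu_{ind}/\Delta\alpha$ (`reaction_field_induced()`). The
classical route places a polarizable dipole ($\mu_g$, $\alpha_g$) at the
center of a spherical cavity of radius $a$ and internal dielectric constant
$\varepsilon_{in}$ inside a solvent of constant $\varepsilon$:

$$f = \frac{2(\varepsilon - \varepsilon_{in})}
   {\varepsilon_{in}(2\varepsilon + \varepsilon_{in})\,a^3},
 \qquad E_R = \frac{f\,\mu_g}{1 - f\,\alpha_g}.$$

Several Onsager-type variants of $f$ circulate in the literature (they
differ in how the internal dielectric screens the cavity field). The form
above -- internal-dielectric-screened in both numerator and denominator --
is adopted as a package design choice; it is the variant that is consistent
with the water/HBDI parameter set used in the tests
($\mu_g = -11$ D, $\alpha_g = 22$ Å$^3$, $a = 4.7$ Å, $\varepsilon = 79$,
$\varepsilon_{in} = 2 \Rightarrow E_R \approx -17$ MV/cm, matching the
induced-dipole route), and the test suite pins it numerically. The
constructor rejects parameter sets with $1 - f\alpha_g \le 0$ (polarization
catastrophe).

# The spectroscopic front end

## Band decomposition

One-photon excitation spectra are decomposed into 3--5 Gaussians sharing a
single width (SD); the shared width is scanned systematically -- a coarse
logarithmic grid, then golden-section refinement to 0.5 cm$^{-1}$ -- and
the decomposition with minimum $\chi^2$ wins (`fit_one_photon()`). The
two-photon spectrum is then fit with the same number of bands whose widths
are clamped, bit-exactly, to the one-photon value (`fit_two_photon()`).
The lowest-center band is the 0--0 transition; its position
$\bar\nu_{00}$, peak extinction $\varepsilon(0\!-\!0)$, width $w$ and
two-photon amplitude $\sigma_2(0\!-\!0)$ feed the Stark analysis.

Numerical choices, made once and kept:

* **Variable projection with non-negative amplitudes.** At fixed centers
  and width the amplitudes are linear; they are profiled out with a small
  Lawson--Hanson NNLS (physical band amplitudes cannot be negative, and the
  constraint prevents a spurious negative band from masquerading as the
  0--0 transition at realistic noise).
* **Center initialisation by greedy peeling.** Bands are placed one at a
  time at the residual maximum. A fixed-spacing initialisation tied to the
  shared width was tried first and discarded: with a realistic vibronic
  spacing of ~1250 cm$^{-1}$ against widths of 300--600 cm$^{-1}$ it
  routinely started too compressed and stalled in local minima. Greedy
  peeling is deterministic, data-driven and spacing-agnostic.
* **Ordered-center parametrisation.** Centers are optimised as a first
  center plus log-gaps, which enforces their ordering and removes
  label-switching minima. The width scan is warm-started from the best
  decomposition found so far.
* **0--0 identification.** Lowest-center band; bands pinned at zero
  amplitude by the NNLS are treated as artifacts and skipped.
* **Baseline.** None is subtracted; inputs are expected baseline-corrected.

## Two-level extraction of the dipole change

For a dipolar two-level system under degenerate, linearly polarised
two-photon excitation of an isotropic sample, the peak 0--0 cross section
is

$$\sigma_2(0\!-\!0) = 52.56\;\frac{f_{opt}^4}{n^2}\;
  \frac{2\cos^2\gamma + 1}{15}\;\frac{\mu^2\,\Delta\mu^2}{w}\ \mathrm{GM},$$

with $\mu$, $\Delta\mu$ in debye, $w$ (Gaussian SD) in cm$^{-1}$,
$f_{opt} = (n^2+2)/3$ the Lorentz local-field factor and $\gamma$ the
angle between $\boldsymbol{\mu}$ and $\Delta\boldsymbol{\mu}$ (default
20°). The prefactor 52.56 was derived for this package from second-order
perturbation theory in Gaussian-cgs units
($4\pi^2 \times 10^{-22}/(\sqrt{2\pi}\,\hbar^2 c^3)$, with the Gaussian
lineshape evaluated at the band peak); the local-field placement
($f_{opt}^4$ with one $n^{-2}$) follows the standard two-photon convention.
Published formulations differ in constant conventions, so the package
treats internal consistency as the enforceable contract: the synthetic
generator uses this exact forward expression, making
generator-to-pipeline round trips exact, and a magnitude check anchors it
to experiment -- for the water-solution chromophore
($\mu = 6.9$ D, $\Delta\mu = 6.5$ D, $w = 700$ cm$^{-1}$) it predicts
39 GM against the observed ~40 GM maximum. Contributions of higher
intermediate states (estimated at ~5% for this chromophore) are not
modelled. The transition dipole itself comes from the integrated 0--0
extinction, $|\mu|^2 = 9.186\times 10^{-3}
\varepsilon(0\!-\!0)\,w\sqrt{2\pi}/\bar\nu_{00}$ D$^2$, without a separate
local-field correction (the same relation is used forward and backward).

# Point-charge electrostatics

Potentials at chromophore atoms are straight Coulomb sums over all
non-excluded partial charges, $V = k_C\sum_i q_i/r_i$ with
$k_C = 14.3996$ V·Å/e -- no cutoff, no periodic images (structures are
expected centred; surface artifacts average out over snapshots). Named
exclusion sets drop either the bare chromophore (total field) or the
chromophore plus its hydrogen-bonded cluster (long-range field). The
projected field is the negative slope of the unweighted regression of the
potentials at the five phenolate-to-bridge carbons (CE2, CD2, CG2, CB2,
CA2) on their positions along the CA2→CE2 axis, converted V/Å → MV/cm.

Two conventions were fixed deliberately:

* **Axis endpoints CA2→CE2**, configurable. (A CE2--C2 variant appears in
  some figure annotations; the CA2--CE2 definition from the method's main
  description wins, and both are reachable via `axis_from`/`axis_to`.)
* **Signed projection coordinates.** `project_chain()` reports each chain
  atom's signed coordinate along the axis direction (first atom at zero)
  rather than unsigned cumulative distances. For atoms listed in axis
  order the two coincide; for the conventional chain order (CE2 first
  against a CA2→CE2 axis) the signed form keeps
  $-\mathrm{slope} = E_{+x}$ with no orientation bookkeeping, which is how
  `axis_field()` gets its sign right for free.

Snapshot series (multi-model PDB or PQR) are averaged with the population
standard deviation (denominator $n$), matching how fluctuation statistics
over trajectory frames are conventionally quoted.

# The synthetic world

The generators state a world with known truth; every green test should be
read against what that world does and does not contain.

`gen_protein_ensemble()` draws per-protein fields
$E_i \sim N(\mu_E, \sigma_E)$ and pushes them through the forward Stark,
broadening and two-level models. Defaults, chosen once:

| parameter | default | why |
|---|---|---|
| $\Delta\mu_0$, $\Delta\alpha$, $\bar\nu_{vac}$ | 4.47 D, −35 Å$^3$, 20725 cm$^{-1}$ | experimental constants, so synthetic ensembles land in observed ranges |
| $n$ | 26 | the experimental ensemble size |
| field mean, SD | +4, 10 MV/cm | reproduces the observed spread: dipole changes ~1.5--6.5 D, fields ~−18…+25 MV/cm |
| $\delta E$ | 5 MV/cm | the fitted within-protein fluctuation |
| $\gamma$ | 270 cm$^{-1}$ | the fitted vibrational floor |
| $\mu$ | 6.9 D | the experimental transition dipole |
| $\sigma_\nu$ | 70 cm$^{-1}$ | frequency measurement noise, the printed intercept uncertainty scale |
| $\sigma_w$ | 20 cm$^{-1}$ | width uncertainty of the shared-width decomposition at ~1% spectral noise |
| $\sigma_{\Delta\mu}$ | 0.1 D | ~3% of a typical 3.5 D, the demonstrated accuracy of the optical extraction |

One design point deserves a note: the protein-to-protein field spread
($\sigma_E$) and the within-protein fluctuation ($\delta E$) are **separate
parameters** here. Identifying them would be tempting (both are "field
noise") but would produce ensembles spanning only ~2 D in $\Delta\mu$,
nothing like the observed 1.5--6.5 D range -- the ensemble spread is driven
by discrete environmental differences (hydrogen-bond counts, stacking),
not by the thermal fluctuation that broadens a single protein's band.
Setting $\sigma_E = 10$ MV/cm and $\delta E = 5$ MV/cm reproduces both
observations simultaneously.

What the generator does **not** emulate: discrete hydrogen-bond classes
(every synthetic protein is tagged `5HB`), correlated measurement errors
between $\Delta\mu$ and $w$, non-Gaussian vibronic structure, baseline or
instrument response, and real MD trajectories or structures. A green
recovery test therefore establishes the estimator algebra and its noise
response, not the validity of the underlying physical model for any real
protein.

`gen_spectra()` builds paired 1PA/2PA spectra as shared-width vibronic
progressions (default four bands, 1250 cm$^{-1}$ spacing, decaying
amplitudes) with multiplicative noise. `gen_uniform_field_system()` builds
a parallel-plate capacitor of point charges around a dummy chromophore
chain; charges start from the infinite-plate relation
$E = \sigma_s/\varepsilon_0$ and are then trimmed by a two-point potential
difference across the chain span, so the imposed field is analytic to
better than 1% while the five-atom regression in `axis_field()` remains an
independent estimator of it.

# Reproducibility and numerical conventions

* All interfaces use debye, Å$^3$, MV/cm, cm$^{-1}$; conversions go through
  one constant table (`stark_constants()`) re-derived from CODATA
  $h, c, e, \varepsilon_0$. Report keys carry units in their names.
* Fits are unweighted least squares unless per-point weights are supplied
  (`fit_stark_parabola(weights = )`); measurement-error weighting of the
  published ensemble fits is unknown, so unweighted is the default.
* Standard errors of derived constants
  ($\Delta\alpha = -2517.058/A$, $\Delta\mu_0 = \sqrt{(\bar\nu_{vac}-C)/A}$)
  come from the fit covariance by the delta method; no bootstrap.
* $(\bar\nu_{vac} - C)/A < 0$ reports failure (`NA` with a warning) rather
  than a complex dipole; rank-deficient designs error out.
* Every generator takes a mandatory seed and restores the caller's RNG
  state; identical spec + seed gives byte-identical output.

# Validation strategy and known limitations

The acceptance suite checks, at published tolerances: the closed-form
field values for EGFP/citrine/mTFP0.7, the constants derived from the
published parabola coefficients, both reaction-field routes, and the
electrostatics oracles (Coulomb constant, capacitor fixture,
superposition/scaling/rigid-motion invariance). The published 26-protein
data tables and the MD trajectories behind the published potential profiles
are not redistributable at desk scale; the ensemble-fit and
potential-projection stages are therefore validated by parameter recovery
on the synthetic world above (200 seeded replicates; recovery within the
published uncertainties required in ≥90% of replicates per parameter) and
by the analytic capacitor fixtures spanning the published field magnitudes.
Those substitutions are the main limitation to keep in mind: agreement with
the synthetic world does not re-derive the experimental numbers, it
verifies that the implemented estimators would recover them from data of
the stated quality.
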