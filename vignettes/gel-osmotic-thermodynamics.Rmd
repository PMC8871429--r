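---
title: "Osmotic and scattering thermodynamics of polyelectrolyte gels"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Osmotic and scattering thermodynamics of polyelectrolyte gels}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(gelosmo)
```

## The model

A swollen polymer network in a solvent bath is described by an additive
swelling pressure

$$\Pi_{tot}(\varphi) \;=\; \Pi_{mix}(\varphi) + \Pi_{elast}(\varphi) +
\Pi_{ion}(\varphi),$$

where $\varphi$ is the polymer volume fraction. `gelosmo` implements each
term, the inverse problem (removing the elastic and ionic parts from a
measured $\Pi_{tot}$ to expose $\Pi_{mix}$ and its virial coefficients), the
forward problem (equilibrium swelling and salt-induced volume transitions of
a parameterised gel), and the scattering-side counterpart (the longitudinal
osmotic modulus and the amplitude of thermal concentration fluctuations seen
by small-angle neutron scattering).

**Mixing.** Two interchangeable forms are provided:

* the osmotic virial expansion
  $\Pi_{mix} = (RT/V_1)(A_2\varphi^2 + A_3\varphi^3)$,
  with dimensionless second and third virial coefficients measuring pairwise
  and effective three-body polymer–polymer interactions
  (`mixing_pressure_virial()`), and
* the Flory–Huggins form
  $\Pi_{mix} = -(RT/V_1)[\ln(1-\varphi) + \varphi + \chi_0\varphi^2 +
  \chi_1\varphi^3]$ (`mixing_pressure_flory_huggins()`).

Matching the series expansion $-\ln(1-\varphi)-\varphi =
\varphi^2/2 + \varphi^3/3 + O(\varphi^4)$ gives the exact mapping
$A_2 = 1/2 - \chi_0$, $A_3 = 1/3 - \chi_1$ (`chi_to_virial()`). The two
forms agree to the quartic Taylor remainder,
$|\Delta| \le (RT/V_1)\,\varphi^4/[4(1-\varphi)]$, which is below 0.5 kPa
for $\varphi \le 0.2$ in water — the reason the truncated virial form is an
adequate fitting basis over the experimentally probed range
$\varphi \approx 0.01\text{–}0.2$. Terms beyond $\varphi^3$ are never
resolved by deswelling data of this extent and are not fitted.

**Elasticity.** The classical affine-network result is
$\Pi_{elast} = -A RT\nu\varphi^{1/3} = -G_s$, i.e. the elastic pressure
equals minus the shear modulus, with the concentration scaling
$G_s(\varphi) = C(\varphi/\varphi_{ref})^{1/3}$. `gaussian_network_pressure()`
re-derives the $\varphi^{1/3}$ law by numerically differentiating the
Gaussian network free energy with respect to volume, so the scaling used in
decomposition is verified against the free energy rather than assumed. The
modulus itself is estimated from uniaxial compression by the no-intercept
regression $\sigma = G_s(\Lambda - \Lambda^{-2})$ (`fit_shear_modulus()`);
no intercept is estimated because the model is exact at zero strain. The
default deformation window $0.7 < \Lambda \le 1$ reflects the regime where
gel cylinders deform without volume change or barrel distortion; it is
overridable. The reported standard error is heteroscedasticity-robust
because stress noise typically scales with $|\sigma|$. The $1/3$ exponent is
compared against the data by `fit_elasticity_scaling()` as a *report*, not a
constraint: finite chain extensibility bends the scaling at high swelling.

**Ionic term.** The ideal Donnan model: one Donnan ratio partitions every
mobile species between gel and bath, fixed by gel electroneutrality against
the anionic fixed-charge concentration
$c_f(\varphi) = f\,\varphi/V_m$, and
$\Pi_{ion} = RT\sum_j (c_j^{gel} - c_j^{sol})$. Activity coefficients are
set to one: with added salt the ionic term is small and near-ideal, and the
interesting divalent-ion physics is *deliberately not* modelled as ion
bridging or condensation — shear moduli of polyelectrolyte gels are
experimentally insensitive to counter-ion valence, so divalent salt enters
only through the empirical dependence of $A_2$ and $A_3$ on its
concentration. The effective charge fraction $f$ is a user parameter (the
chemical degree of neutralisation is not the effective osmotic charge;
counter-ion condensation reduces it substantially — the presets use
$f = 0.02$).

**Scattering.** The two-component intensity model is

$$I(q) = \frac{I_0}{(1+qL)(1+q^2R^2)} + A\,q^{-m},$$

a rod-modified Ornstein–Zernike term for thermal concentration fluctuations
(segment length $L$, cross-section $R$; a plain OZ variant with correlation
length $\xi$ is available for solutions) plus a power law for large-scale
static structure ($m = 4$ for smooth interfaces, Porod scattering). The
dynamic forward intensity is controlled by the longitudinal osmotic modulus

$$M_{os} = \varphi\,\partial\Pi_{mix}/\partial\varphi + \tfrac{4}{3}G_s
 = (RT/V_1)(2A_2\varphi^2 + 3A_3\varphi^3) + \tfrac{4}{3}G_s,$$

and `osmotic_amplitude()` converts it into absolute intensity units,
$I_{os}(0) = \Delta\rho^2 k_B T\,\varphi^2 / M_{os}$ (contrast in
cm$^{-4}$, $k_BT/M_{os}$ a volume converted m$^3\to$cm$^3$, result in
cm$^{-1}$). Comparing that prediction with the fitted $I_0$
(`consistency_check()`, default tolerance a factor 1.5) tests whether the
interactions governing gel thermodynamics are independent of observational
length scale.

### Two conventions, stated explicitly

* **The $M_{os}$ prefactor.** A frequently printed form of the modulus,
  $\varphi^2(RT/V_1)(2A_2\varphi + 3A_3\varphi^2)$, is dimensionally one
  power of $\varphi$ high relative to
  $\varphi\,\partial\Pi_{mix}/\partial\varphi$. `longitudinal_modulus()`
  evaluates the exact analytic derivative,
  $(RT/V_1)(2A_2\varphi^2 + 3A_3\varphi^3)$, treating the printed form as a
  typographical slip; the unit test checks the implementation against a
  central finite difference of the mixing pressure.
* **Elastic derivative in $M_{os}$.** Whether
  $\varphi\,\partial\Pi_{sw}/\partial\varphi$ should include the derivative
  of the elastic term (an extra $-G_s/3$) is ambiguous next to the separate
  $(4/3)G_s$ term. The default follows the expanded mixing-derivative
  convention; `include_elastic_derivative = TRUE` selects the alternative.
  Both are tested; at every stable equilibrium the alternative (full
  derivative) form is strictly positive, as thermodynamic stability
  requires.

### Stability of swelling equilibria

`solve_equilibrium_swelling()` classifies a root $\varphi^*$ of
$\Pi_{tot} = 0$ as **stable when $d\Pi_{tot}/d\varphi > 0$**. The free
energy $F(V)$ is convex at a stable volume, so $d\Pi/dV < 0$; since
$\varphi \propto 1/V$ the sign flips in $\varphi$. Concretely: compress the
gel above $\varphi^*$ and the swelling pressure turns positive, drawing
solvent back in. (With the opposite sign convention the canonical case
$A_2, A_3 > 0$ with an elastic term would have *no* stable swelling
equilibrium, which is plainly wrong.)

## Numerical choices

* **Root finding.** $\Pi_{tot}=0$ is bracketed by a sign-change scan on a
  400-node log-spaced grid over $\varphi \in [10^{-4}, 0.99]$ (equilibria
  span decades of swelling degree) and refined by Brent's method to a
  relative tolerance of $10^{-10}$. Tests compare root counts and locations
  against $10^6$-node dense scans on randomized models.
* **Donnan ratio.** The electroneutrality equation is solved in
  $u = \log y$ (strictly monotone), polished by Newton steps, and both the
  residual equation and the pressure sum are evaluated with `expm1` — the
  naive forms lose up to five significant digits at large salt excess. The
  1:1 closed form used for cross-checks is rationalized to
  $RT c_f^2 / (\sqrt{c_f^2+4c_s^2} + 2c_s)$ for the same reason.
* **Virial fitting** is weighted *linear* least squares on the
  zero-intercept basis $(\varphi^2, \varphi^3)$ — linearity gives exact
  covariance, and $A_2$, $A_3$ are the quantities of interest, so nothing
  is gained by fitting the FH form nonlinearly. Weights come from the
  uncertainty column when present.
* **SANS fitting** is bounded Levenberg–Marquardt
  (`minpack.lm`), weights $1/\sigma_I^2$ when uncertainties exist, log
  residuals otherwise; $m$ is constrained to $[2, 5]$ and all scale
  parameters to $\ge 0$. Initial guesses are derived deterministically from
  the data (high-$q$ plateau level, low-$q$ slope, crossover $q$) and a
  small multistart grid (6 starts) guards against local minima, so repeated
  fits are bit-reproducible. The covariance is
  $\hat\sigma^2 (J^\top J)^{-1}$ with diagonal preconditioning ($A$ and
  $I_0$ differ by $\sim$9 orders of magnitude).
* **Transition detection** follows the swollen branch by continuation
  (nearest stable root in $\log\varphi$), declares a transition when the
  branch disappears or the swelling degree $1/\varphi$ drops by more than a
  factor 2 (configurable) between adjacent control values, and refines the
  critical control value by bisection on branch survival to a relative
  tolerance of $10^{-3}$. With the virial expansion truncated at a negative
  $A_3$ no collapsed *root* exists ($\Pi_{tot} < 0$ for all larger
  $\varphi$), so after the transition the collapsed state is recorded at
  the scan upper bound — a known artefact of the truncation, not of the
  detector.

## What the synthetic generator emulates — and what it does not

The generator (`scenario_config()`, `generate_salt_sweep()`,
`generate_deswelling_series()`, `generate_stress_strain()`,
`generate_sans_profile()`) reproduces the statistical structure of gel
osmometry and SANS experiments with known ground truth:

* deswelling curves on 15 log-spaced points over
  $\varphi \in [0.01, 0.2]$, with 5% relative Gaussian noise — the
  repeatability of careful swelling-pressure measurements;
* affine laws $A_i(x) = a_i + b_i x$ versus the control variable. Affine is
  the minimal family reproducing the observed patterns: near-linear
  $A_2(T)$ in neutral gels and monotone $A_3(c)$ trends in charged ones.
  Three presets encode the qualitative signatures:
  * `polyelectrolyte_salt_sweep` — $A_2(c) = 0.10 - 0.02c$ stays positive
    while $A_3(c) = 0.40 - 1.2c$ crosses zero inside the CaCl$_2$ grid
    (0–1.5 mol/m$^3$); with the elastic prefactor $C = 20$ kPa at
    $\varphi_{ref} = 0.05$ and a 40 mol/m$^3$ NaCl background this
    produces a volume transition near 1 mol/m$^3$ — the sign inversion of
    $A_3$ at positive $A_2$ followed by collapse, the signature of
    many-body interactions;
  * `neutral_temperature_sweep` — $A_2(T) = 0.002\,(T - 310\,\mathrm{K})$
    changes sign across 280–340 K while $A_3 = 0.30$ stays constant and
    positive — the simple-fluid pattern; swelling varies smoothly, no
    transition;
  * `bottlebrush_salt_sweep` — $A_3(c) = 0.40 - 0.10c$ remains positive
    over the same salt range: side-chain grafting suppresses the sign
    inversion and stabilises the gel.
* per-operation random streams split from one base seed, so adding a
  generator call never perturbs another's samples;
* SANS profiles on 60 log-spaced points over
  $q \in [0.003, 0.15]\,$Å$^{-1}$ (a typical pinhole-instrument range) with
  additive noise recorded in the uncertainty column.

It does **not** emulate instrument resolution smearing, incoherent
backgrounds, the kinetics of swelling, ion-specific effects beyond the
affine virial laws, or concentration-dependent $\chi$ parameters. Passing
round-trip tests on this generator therefore demonstrates the correctness
and statistical calibration of the estimators under the stated noise model —
not robustness to systematic errors present in real reduced data.

## Problem sizes used in the validation suite

The test and acceptance runs use 15-point deswelling curves, 500-replicate
Monte-Carlo calibrations, 50 randomized gel models against $10^6$-node
brute-force scans, a 100-point Donnan cross-check grid and 60-point SANS
profiles; the full suite completes in about two minutes on one CPU. These
sizes were chosen to match the scale of the corresponding laboratory data
sets (deswelling series of 10–20 points, a handful of salt conditions)
while keeping Monte-Carlo standard errors on coverage estimates near 1%.

## Known limitations

* The truncated virial form cannot represent a collapsed branch when
  $A_3 < 0$; volume-transition results report the collapse but not a
  coexisting dense phase.
* The Donnan model is ideal; at very low added salt and high charge density
  activity corrections and counter-ion condensation matter, and $f$ must be
  interpreted as an effective parameter.
* SANS fits assume fully reduced, absolutely calibrated, unsmeared data.
* No temperature dependence of the solvent molar volume; temperature enters
  only through $RT$ and the configured $A_i(T)$ laws.
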