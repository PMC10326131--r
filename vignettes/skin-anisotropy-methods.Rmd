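---
title: "Methods: ellipse-based skin anisotropy from elastic-wave arrival times"
author: "skinaniso"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: ellipse-based skin anisotropy}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(skinaniso)
```

## The measurement and its model

In vivo skin is under anisotropic tension: an elastic surface wave launched
between two transducers 2 mm apart travels fastest along the local Langer
line (the direction of greatest tension) and slowest perpendicular to it.
Rotating the transducer pair around a fixed site in 10 degree steps yields
36 arrival-time readings per sweep, in the device's arbitrary RRT
("Resonance Running Time") units; the protocol repeats each sweep three
times and analyses the per-angle mean. Plotting each reading at its
measurement angle with the arrival time as the distance from the origin
turns an anisotropic site into an approximately elliptical point cloud: long
axis along the slow direction, short axis along the Langer line.

`skinaniso` implements that representation end to end:

1. **Ellipse fit.** `fit_ellipse_direct()` fits the conic
   $Ax^2 + Bxy + Cy^2 + Dx + Ey + F = 0$ minimizing algebraic distance under
   the ellipse-specificity constraint $4AC - B^2 = 1$, solved as a
   generalized eigenproblem via the numerically stable block decomposition
   of the scatter matrix (quadratic and linear blocks separated), with the
   data centered and rescaled first. The stable form avoids the
   ill-conditioning of the original single-eigenproblem formulation for
   near-circular profiles. Geometric parameters come from the conic: center
   from the gradient zero, axes from
   $\sqrt{-\det M_0 / (\det M \, \lambda_i)}$ with $M_0$ the full conic
   matrix, $M$ its quadratic block and $\lambda_i$ its eigenvalues, tilt
   from the eigenvector of the semi-major axis. If extraction orders the
   axes the wrong way round they are swapped and the tilt rotated 90
   degrees, so $a \ge b$ always.
2. **Metrics.** Eccentricity $e = \sqrt{1 - b^2/a^2}$ (the package's
   anisotropy measure; 0 isotropic, $\to 1$ transversely isotropic), area
   $A = \pi a b$ (inverse average stiffness across directions), semi-minor
   axis $b$ (arrival time along the Langer line, i.e. maximal stiffness),
   Langer direction $(\text{tilt} + 90°) \bmod 180°$, and the classic
   anisotropic ratio $\mathrm{AR} = \mathrm{RRT}_{max}/\mathrm{RRT}_{min}$
   for comparison.
3. **Calibration.** For an unstressed, incompressible, isotropic linear
   elastic solid the Rayleigh-wave relation $E = \rho v^2 \times 3.284$
   links stiffness to wave speed. Three reference elastomers of known
   density and tensile-test Young modulus give the RRT-to-time conversion
   (`rrt_conversion()`), about 0.284 µs per RRT on average, and
   `stiffness_from_rrt()` inverts the chain reading → time → speed →
   modulus.
4. **Inference.** A Bayesian trivariate regression of
   $(\log e,\; A/1000,\; b)$ on age, gender and configuration
   (`fit_mvreg()`), and a projected-normal circular regression of the tilt
   on configuration (`fit_circular()`), both summarised by 0.95 highest
   posterior density intervals (HPDIs); a covariate is called significant
   when 0 is outside its interval.

The eccentricity is taken on the log scale in the regression because $e$ is
bounded in $(0,1)$; the area is divided by 1000 for numerical balance with
the other outcomes. The three outcomes are modelled jointly because $e$ and
$A$ are functions of the same fitted axes and hence correlated.

## Why eccentricity instead of the anisotropic ratio

The AR uses only the two extreme readings of a sweep, so a single outlier
propagates directly into it, and noise biases it upward (a maximum of noisy
values overestimates the true maximum, a minimum underestimates the
minimum). The ellipse eccentricity pools all 36 readings. The package's
simulation study (`run_simulation_study()`) quantifies this: ellipses with
semi-minor axis 160 RRT and eccentricities $e \in \{0.5, 0.7, 0.9\}$ are
sampled on the 36-angle grid, independent $N(0, \sigma^2)$ noise with
$\sigma \in \{1, 10, 20, 30\}$ RRT is added to each radius, and both
measures are recomputed 10,000 times per cell. The AR's mean bias is
positive in every cell and grows with $\sigma$, while the fitted
eccentricity stays centered near the truth (drifting low only in the
noisiest, most eccentric cells). `outlier_demo()` reproduces the
qualitative outlier argument: displacing two readings outward at the major
axis and two inward at the minor axis inflates the AR severalfold while
elongating the fitted ellipse only slightly.

```{r simulation, eval = FALSE}
study <- run_simulation_study(n_reps = 10000, seed = 1)
study$summary
```

Noise is applied to the polar radius at each grid angle, matching the
device's geometry (one reading per direction); the per-coordinate
alternative was not adopted. Non-positive noisy radii are redrawn — with a
minimum true radius of 160 RRT and $\sigma \le 30$ this is a $>5\sigma$
event, so the truncation is negligible.

## The Bayesian models

**Trivariate regression.** With $y_i \in \mathbb{R}^3$ the outcome vector
and $x_i = (\text{age}_i, \text{gender}_i, \text{config}_i)$,

$$y_i = \alpha + \mathbf{B} x_i + \epsilon_i, \qquad
  \epsilon_i \sim N_3(0, \Sigma).$$

Gender is coded 0 = female, 1 = male; configuration 0 = natural,
1 = stretched; age is in years, uncentered. Priors are weakly informative
and conjugate: stacking $\Gamma = [\alpha; \mathbf{B}^\top]$ (4×3),
$\Gamma \mid \Sigma \sim MN(0, \tau^2 I_4, \Sigma)$ with $\tau = 100$, and
$\Sigma \sim IW(\nu_0 = 4, I_3)$. Both full conditionals are then exact
(matrix-normal and inverse-Wishart), so `fit_mvreg()` is a plain Gibbs
sampler: 4 chains × 2000 iterations, half warm-up, by default, with split-
$\widehat{R} < 1.01$ and ESS > 400 as convergence gates (violations warn
and set a flag rather than fail). Conjugacy buys verifiability: with
$\Sigma$ fixed the posterior mean of $\Gamma$ has the closed form
$(X^\top X + I/\tau^2)^{-1} X^\top Y$, which the test suite checks to
$10^{-3}$, and the diffuse prior means posterior means track the
least-squares solution; a 10× prior-scale sensitivity check is also part of
the suite. The prior is set on the raw predictor scales — at $n = 156$ rows
and $\tau = 100$ it is numerically irrelevant, and the raw scale keeps the
closed-form check exact.

**Circular regression.** The tilt is an axis (period 180°), so angles are
doubled to the full circle before fitting and all reported directions are
halved back — an explicit modelling choice, made because circular-statistics
machinery assumes period 360°. The doubled angle $\theta_i$ is modelled by a
projected normal: a latent $z_i \sim N_2(\mu_i, I_2)$ with
$\mu_i = B^\top (1, \text{config}_i)$ is observed only through its direction
$\theta_i$. Augmenting with the latent length $r_i$ restores tractability:
given lengths, each latent coordinate is an ordinary normal regression with
a conjugate $N(0, \tau^2)$ prior; given coefficients, $r_i$ has density
$\propto r\,\varphi(r - m_i)$ on $r > 0$ ($m_i$ the projection of $\mu_i$
onto the observed unit vector) and is updated exactly by a two-step slice
move ($v \sim U(0, r)$, then $r$ from $N(m_i, 1)$ truncated to
$(v, \infty)$). Per posterior draw the circular mean direction of each
configuration is $\mathrm{atan2}$ of its latent mean; the two
configurations' 0.95 HPDIs of these circular means are compared on the
circle — overlap means no evidence that stretching rotates the Langer
direction. Circular HPDIs are computed by recentering draws around their
circular mean before taking the shortest interval; this is adequate for the
concentrated posteriors that arise here, not for posteriors spread over
most of the circle.

HPDIs are the shortest contiguous interval containing
$\lceil 0.95\,n \rceil$ sorted draws. No multiple-testing adjustment is
applied to the nine coefficient tests; the zero-in-HPDI rule is used as is.

## The synthetic cohort generator

No public cohort of this design exists, so `generate_profiles()` creates
one with the statistical structure the models assume: 78 subjects
(37 female / 41 male in expectation), ages uniform on [3, 93], both
configurations per subject, outcomes drawn from the trivariate linear model
above, tilt from the projected-normal model on the doubled circle, and
3 repeats × 36 noisy radial readings (default noise SD 10 RRT, the study's
"low noise" level) per profile. Default coefficients sit near the
magnitudes reported for forearm skin (age → log-eccentricity 0.007,
stretching → semi-minor −26.8 RRT, etc.); the intercepts (−1.2, 120, 200)
are chosen so eccentricities stay in roughly 0.3–0.7 and semi-minor axes
above 100 RRT across the covariate range, keeping the back-transform
rejection rate ($e \notin (0,1)$ or $b \le 0$) below 0.1%; rejections are
counted and reported. Because one ellipse determines all three outcomes
($A = \pi b^2 / \sqrt{1 - e^2}$), $(e, b)$ are treated as free and the
recorded area truth is recomputed from the realized ellipse, preserving the
outcome correlation the multivariate model is built to absorb.

What the generator does *not* emulate: within-subject correlation between
the natural and stretched errors (drawn independently per configuration),
asymmetric or non-elliptical raw sweeps (some real subjects violate the
axisymmetry assumption), heteroscedastic or angle-correlated device noise,
and the real per-decade age distribution (uniform instead). Passing
parameter-recovery tests on this generator therefore validates the
*procedures* — fitting, sampling, interval construction — not any claim
about real skin.

## Numerical choices and edge cases

- Eccentricity uses $e = \sqrt{1 - b^2/a^2}$ with $a$ the longer semi-axis,
  the standard form that lies in $[0,1)$.
- Angles live on $[0°, 360°)$ with $360° \equiv 0°$, giving exactly 36 grid
  points; tilt and Langer directions are axial and reported in
  $[0°, 180°)$.
- The raw-data Langer rule (`langer_direction_raw()`) breaks ties toward
  the smallest angle, and is invariant to adding a constant to all arrival
  times.
- Fits with fewer than 6 points are refused; collinear or otherwise
  non-elliptical point clouds raise a degenerate-fit error, which the
  simulation study counts and excludes rather than propagates.
- The AR-vs-grid identity $\mathrm{AR} = a/b$ on noiseless profiles is
  exact when the axes lie on the 10° grid and holds within 0.5% for
  arbitrary tilt up to $e \approx 0.7$; beyond that the grid's up-to-5°
  miss of the major axis costs $\approx \tfrac12((a/b)^2 - 1)\sin^2 5°$ in
  relative error (1.9% at $e = 0.9$), which is itself a small illustration
  of why the extreme-reading statistic is fragile. The simulation study
  fixes tilt at 0° (results are rotation-invariant, which is tested
  separately), where the identity is exact.
- `rms_residual` is the RMS of the gradient-normalized (Sampson) algebraic
  distance, a first-order approximation to the geometric point-to-ellipse
  misfit in RRT units; it is a diagnostic, not a goodness-of-fit test.

## Problem sizes

The bundled tests run the full pipeline at reduced sizes chosen to keep the
suite quick while leaving Monte-Carlo error well inside the asserted
tolerances: simulation cells at 400–2,000 replicates in property tests and
10,000 replicates for the low-noise recovery checks; regression recovery at
the full 156-row cohort with 2–4 chains; HPDI coverage over 100 replicate
fits of 2 chains × 1000 iterations; circular overlap over 40 replicate
fits. `scripts/acceptance.R` recomputes the reference quantities (noiseless
AR, low-noise mean eccentricities) at the full 10,000 replicates.

## Limitations

- The Rayleigh calibration assumes an unstressed, incompressible,
  isotropic medium; real skin is pre-stressed and anisotropic, so the
  stiffness numbers are effective values, not acoustoelastic ones.
- The ellipse model assumes axisymmetric sweeps; strongly asymmetric
  profiles fit poorly and show up only through `rms_residual`.
- The circular model fixes the latent covariance at $I_2$ (homogeneous
  concentration across configurations).
- Posterior results under genuinely diffuse priors are insensitive to the
  exact prior family, but numerical agreement with other software's
  "default priors" is not claimable to more than sampling precision.
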