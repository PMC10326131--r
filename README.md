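# skinaniso

Analysis of in vivo skin anisotropy and stiffness from angular elastic-wave
arrival-time measurements.

## The problem

Skin is under anisotropic tension: a surface wave launched between two
transducers 2 mm apart travels fastest along the local Langer line (skin
tension line) and slowest perpendicular to it. Rotating the transducer pair
around a fixed site in 10° steps gives 36 arrival-time readings (in the
device's arbitrary RRT units) per sweep. Plotted with the arrival time as
the distance from the origin at each angle, an anisotropic site traces an
approximately elliptical cloud, and the geometry of that ellipse carries the
skin's mechanics:

- **eccentricity** `e = √(1 − b²/a²)` — the degree of anisotropy
  (0 isotropic, → 1 transversely isotropic);
- **area** `A = πab` — inverse average stiffness across all directions;
- **semi-minor axis** `b` — arrival time along the Langer line, i.e.
  maximal stiffness;
- **tilt** — the slow direction; the Langer line is 90° from it.

The classic summary, the anisotropic ratio `AR = RRT_max / RRT_min`, uses
only the two extreme readings and is fragile to outliers and noise-biased
upward. This package implements the ellipse-based alternative, the
Monte-Carlo study that quantifies its advantage, the Rayleigh-wave
calibration `E = ρv²·3.284` that converts RRT to physical stiffness
(≈ 0.284 µs per RRT), and the Bayesian inference layer:

- a trivariate regression `[log e, A/1000, b] = α + B[age, gender, config] + ε`,
  `ε ~ N(0, Σ)`, fit by a conjugate matrix-normal/inverse-Wishart Gibbs
  sampler and summarised with 0.95 highest posterior density intervals
  (significant = 0 outside the interval);
- a projected-normal circular regression of the (axial) ellipse tilt on the
  skin-tension configuration, comparing posterior circular means of the
  natural vs. stretched skin by HPDI overlap.

Intended users: researchers analysing Reviscometer-style angular elastography
sweeps, and methodologists studying anisotropy statistics on angular data.

## Worked example

```r
library(skinaniso)

# one noisy sweep of an ellipse with a = 250, b = 170, tilt 25 deg
ang <- seq(0, 350, by = 10)
set.seed(1)
prof <- angular_profile(ang, ellipse_polar_radius(250, 170, 25, ang) + rnorm(36, 0, 10))

fit_ellipse_direct(polar_to_cartesian(prof))
#> Direct least-squares ellipse fit (36 points)
#>   center: (-1.625, 1.396) RRT
#>   semi-major a: 251.314  semi-minor b: 170.426 RRT
#>   tilt: 25.02 deg   eccentricity: 0.7349
#>   rms algebraic residual: 8.62

as.data.frame(round(profile_metrics(prof), 3))
#>         a       b tilt_deg eccentricity     area langer_angle_deg rms_residual    ar langer_raw_deg
#>   251.314 170.426   25.024        0.735 134555.7          115.024         8.62 1.754            130
```

Despite 10-RRT noise the fit recovers the true axes (250/170), tilt (25°)
and eccentricity (true 0.733) to within a fraction of a percent, while the
AR (1.754) already overshoots the true ratio 1.471 by 19% — the
outlier-sensitivity the eccentricity avoids. The Langer line is at
115° (tilt + 90°), and the raw-data rule (nearest reading minimum) agrees to
within its 10° grid (130°).

A full synthetic end-to-end run — generate a 78-subject cohort, average
repeats, fit 156 ellipses, run both Bayesian models, write CSVs and a JSON
manifest:

```r
res <- run_pipeline(config = cohort_config(), out_dir = "run1", seed = 42)
make_report("run1")
```

The simulation study behind the eccentricity-vs-AR comparison:

```r
study <- run_simulation_study(n_reps = 10000, seed = 1)  # 12 cells, ~3 min
subset(study$summary, measure == "ar", select = c(e_true, sigma, truth, mean, bias))
```

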