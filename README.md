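# retgrad

Retinal ganglion cell density gradients and the phylogenetic comparative
analysis of avian head and eye movement.

## The problem

In birds, retinal ganglion cell (RGC) density rises from the retinal
periphery to the fovea, and the steepness of that rise differs between
species.  A steep rise means the retinal area with relatively high visual
acuity is small, so the animal must re-aim its fovea more often — which
predicts higher head movement rates and larger eye movements in species
with more pronounced density gradients.  Testing this across species
requires a chain of non-trivial steps:

1. **Topographic maps** — interpolate stereology-style counting-frame
   samples (cells counted in small frames at sites across a flattened
   wholemount retina) into a gridded density surface with isodensity
   contours.
2. **Fovea geometry** — locate the density peak and express its position
   in normalized Cartesian coordinates relative to the retinal centre
   (negative x = temporal, positive y = dorsal), with t-based
   across-species confidence intervals.
3. **Gradient slopes** — lay transects from the retinal margin to the
   fovea along the nasal, temporal, dorsal and ventral axes, and fit the
   linear slope of density (10³ cells/mm²) on normalized distance; the
   slope is the retinal-configuration proxy.  The overall slope is the
   mean of the four axis slopes.
4. **Regional comparison** — one-way GLM of slope on retinal axis with
   Tukey HSD pairwise tests.
5. **PGLS** — phylogenetic generalized least squares under Pagel's λ:
   `y = Xβ + ε`, `ε ~ N(0, σ²V(λ))`, where `V` is the Brownian-motion
   shared-path-length matrix of the phylogeny and λ (estimated by ML or
   REML, boundary values 0 and 1 allowed) scales its off-diagonals.
   Twelve models: {log head movement rate, degree of eye movement} ×
   {overall + 4 regional slopes}, eye movement ~ log head rate, and the
   size-independence check overall slope ~ log axial length.

All of the statistical machinery (BM covariance from the tree, λ profile
likelihood, GLS, F tests, studentized-range p-values) is implemented in
the package and cross-checked in the test suite against independent
oracles (`ape::vcv`, `nlme::gls` + `ape::corPagel`, `TukeyHSD`, brute-force
normal equations).

A synthetic-data module (`retina_spec()`, `generate_density_field()`,
`sample_counting_frames()`, `simulate_traits_on_tree()`) generates
retinas with a planted off-centre fovea, per-quadrant steepness, Poisson
counting noise and λ-scaled Brownian trait errors, so the whole pipeline
can be validated against known ground truth.  See the methods vignette
(`vignettes/retinal-configuration.Rmd`) for the model details and design
decisions.

## Worked example

A noiseless synthetic retina with a linear density profile rising from
500 to 4,000 cells/mm² has, by construction, a gradient slope of 3.5 in
10³ cells/mm² per unit normalized distance:

```r
library(retgrad)
spec <- retina_spec(radius = 5, fovea_xy = c(-0.145, 0.057),
                    base_density = 500, peak_density = 4000,
                    quadrant_steepness = 1)
field <- generate_density_field(spec, grid_step = 0.05)
slopes <- transect_slopes(field)
slopes$overall
#> slope_estimate [overall]: slope = 3.4739, intercept = 0.5116, r2 = 1.000
```

(the small deficit from 3.5 is the disk-averaged sampling near the foveal
peak; it vanishes as the grid is refined).  The across-species fovea
summary applied to a 29-species sample with mean −0.145, SE 0.013 in x
and mean 0.057, SE 0.017 in y gives the t-based 95% bounds:

```r
mean_position_with_ci(pos)   # pos: one row per species
#>     mean    se ci_low ci_high  n
#> x -0.145 0.013 -0.172  -0.118 29
#> y  0.057 0.017  0.022   0.092 29
```

— both intervals exclude zero: the fovea sits dorso-temporally, not at
the retinal centre.

A full simulated study (29 species, 2–5 retinas each, counting noise,
behavioural traits generated from the true overall slope on a simulated
phylogeny) runs end to end in about a minute:

```r
report <- run_study(study_config(seed = 11))
print(report)
#> Regional slope comparison (one-way GLM + Tukey HSD)
#>   nasal: 3.04 +/- 0.11 (n=29)
#>   temporal: 3.49 +/- 0.11 (n=29)
#>   dorsal: 3.50 +/- 0.10 (n=29)
#>   ventral: 3.25 +/- 0.10 (n=29)
#>   F_3,112 = 4.19, P = 0.007492
#> ...
#> PGLS battery:
#>   head_rate~overall        F_2,27 = 12.95, P = 0.001268, adj R2 = 0.299, lambda = 1.00
#>   eye_movement~overall     F_2,27 =  9.46, P = 0.004770, adj R2 = 0.232, lambda = 0.87
#>   overall~log_axial_length F_2,27 =  0.85, P = 0.363900, adj R2 = -0.005, lambda = 0.50
```

The planted pattern is recovered: the dorsal and temporal gradients are
steepest and do not differ from each other but exceed the nasal gradient;
behaviour is significantly associated with the density slopes under the
phylogenetic model; and the slope proxy is unrelated to eye size.  A
three-species toy data set for the file-based `load` mode ships in
`inst/extdata/` (synthetic, generated by the package's own simulator).

A thin command-line front end is included at `inst/cli/retgrad`
(subcommands `run-all`, `simulate`, `maps`, `slopes`, `fovea`, `regions`,
`pgls`; configuration via a YAML file mirroring `study_config()`).

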