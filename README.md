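# capdiff

Effective diffusion coefficients of proteins through hydrogels, measured
the capillary-tube way.

## The problem

Hydrogel delivery vehicles release encapsulated proteins at a rate set
largely by how fast the protein diffuses through the polymer network, and
that diffusivity varies widely with polymer chemistry, weight content and
cross-linking. The capillary-tube assay measures it in an afternoon with
microgram protein amounts: a 600 µm capillary is filled with hydrogel, a
fluorescently labelled protein reservoir is injected against one end, and
a fluorescence microscope images the first 3 mm of gel every 4 minutes
for 2 hours as the protein front advances.

Because the gel column is far longer than it is wide and the reservoir
stays at constant concentration, the normalized fluorescence follows the
semi-infinite one-dimensional Fickian solution

    F(x, t) = erfc( x / (2 * sqrt(D_eff * t)) )

with x the distance from the protein–hydrogel interface (cm), t the time
since contact (s). A single constrained nonlinear least-squares fit over
all frames — restricted to F < 0.25 (the linear fluorescence regime) and
x > 0.5 mm (away from interface-location error) — yields `D_eff` (cm²/s).

`capdiff` implements the full chain for users of this assay: a seeded
synthetic stack generator for closed-loop validation (`render_stack()`),
profile extraction and reservoir normalization (`extract_profiles()`),
the filtered fit (`fit_deff()`, a classed model object with the usual
`coef`/`predict`/`plot`/`summary` methods), a Crank–Nicolson
finite-difference forward solver as verification oracle
(`solve_diffusion_fd()`, `validate_forward_model()`), chi-square
profile-agreement tests, replicate mean ± SEM summaries, and a
parameter-recovery benchmark. A `capdiff` command-line script
(`inst/cli/capdiff.R`) wraps the same functions
(`simulate|extract|fit|validate|benchmark`).

## Worked example

Simulate a 2-h experiment at a known coefficient, then recover it:

```r
library(capdiff)

bundle <- render_stack(tube_geometry(), imaging_config(), d_eff = 1.73e-6,
                       noise = noise_model(gaussian_sigma = 0.01, seed = 42))
pm  <- extract_profiles(bundle)
pm
#> Normalized fluorescence profile matrix
#>   31 frames x 1200 positions; x in [0.0002, 0.3000] cm; t in [240, 7440] s
#>   interface at 199.10 px (model); reservoir level 55704.6

fit <- fit_deff(pm)
summary(fit)
#> Capillary-tube diffusion fit (1D semi-infinite erfc model)
#>   D_eff = 1.778e-06 cm^2/s  (SSR = 0.3086 over 21397 filtered points)
#>   bounds [1e-09, 0.0001] cm^2/s; converged: TRUE; RMSE = 0.003797
#>   per-frame RMSE: 0.001481 (min) .. 0.006589 (max) over 31 frames
```

The generating coefficient 1.73e-6 cm²/s is recovered within 3%:
21 397 of the 37 200 (time, position) points survive the two filters, and
the fit pools them all into one objective. Replicates summarize as
mean ± SEM:

```r
summarize_replicates(c(1.78e-6, 1.69e-6, 1.81e-6))
#> D_eff = 1.76e-06 +/- 3.606e-08 cm^2/s (mean +/- SEM, n = 3)
```

and the finite-difference forward model confirms the erfc description of
the capillary geometry (high p = no detectable disagreement):

```r
validate_forward_model(d_eff = 2e-6, grid = grid_spec(dx = 20e-4, dt = 4))
#> Profile agreement: chi2 = 0.0003928 on 17012 dof, p = 1 (n = 17013, floor = 0.001)
```

Real TIFF stacks enter the same way: `read_bundle()` for stacks written
with a JSON sidecar, or `extract_raw_profiles()` +
`normalize_profiles()` with an explicit `roi_spec()` for anything else.
See the vignette (`vignettes/capillary-diffusion.Rmd`) for the model
assumptions, the interface-detection design, and the generator's scope.

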