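# seedmd

Monte Carlo quantification of internal microdamage in seed
cross-section images.

Mechanical loads from handling equipment (transport, sieving, sowing)
leave internal cracks in seeds that external inspection cannot see, yet
they depress germination, storage life and reproductive quality.  X-ray
tomography exposes the cracks as stacks of 2D cross-sections; the
remaining problem is turning those images into a damage number.
`seedmd` is for researchers in post-harvest technology and biological
materials testing who need that number, with an uncertainty, from a
slice stack — and a way to validate the whole chain on images whose
true damage is known exactly.

## The method

Each cross-section is segmented into background / solid / damage /
(optional) crack-boundary labels.  N points are thrown uniformly over
the object; background hits are rejected and regenerated.  Each
accepted point scores ξ = 0 in a crack, ξ = 0.5 on the crack boundary,
ξ = 1 in solid material, and the per-section microdamage coefficient is

    K_md,i = 1 − (Σ ξ_i) / N

with plug-in variance `D_ξ = Σξ²/N − (Σξ/N)²` and confidence half-width
`x_β · sqrt(D_ξ / N)` (x_0.95 = 1.96).  The specimen coefficient is the
arithmetic mean over its 20 sections (10 horizontal + 10 vertical):

    K_md = (K_md,1 + … + K_md,20) / 20

The exact pixel-area fraction (damage + half-weighted boundary over
object) serves as the oracle `K_fmd` that the estimator is validated
against.  A phantom generator draws seed-like elliptical sections with
random-walk cracks of exactly known pixel area, driven by a virtual
load scenario (static/dynamic load, vertical/horizontal placement, load
as a fraction of the critical force F_kr), so segmentation fidelity,
estimator bias, interval coverage and the recovered fold increase of
damage across the load range can all be checked against ground truth.

## Worked example

Generate a 20-section phantom specimen loaded statically at 0.6 F_kr,
segment every section, and estimate the specimen coefficient with
N = 3400 points per section:

```r
library(seedmd)

spec  <- phantom_spec()                       # 12.6 x 8.54 mm kernel, 0.06 mm/px
stack <- generate_stack(spec, load_scenario("static", "vertical", 0.6), seed = 42)
masks <- lapply(stack$slices, function(s)
  segment_slice(bo_slice(s$raster, slice_index = s$slice_index,
                         orientation = s$orientation)))
specimen <- estimate_specimen(masks, n_points = 3400, seed = 4242,
                              oracle = mean(stack$truth$weighted_fraction))
specimen
#> specimen K_md = 0.0493 +/- 0.0016 over 20 sections; exact K_fmd = 0.0490
specimen$slice_estimates[[1]]
#> K_md[0] = 0.0468 +/- 0.0071 (beta = 0.95, N = 3400, D_xi = 0.04458)
```

The specimen estimate 0.0493 ± 0.0016 says 4.9 % of the kernel's
cross-sectional area is crack, and it brackets the exact ground-truth
fraction 0.0490: at 0.6 F_kr the static scenario's dose-response
(baseline 2 % at 0.3 F_kr, 6-fold span to 0.9 F_kr) targets
0.02·√6 ≈ 4.9 % damage.  The per-section line shows the raw Monte Carlo
quantities for section 0 (N, the ξ-variance D_ξ, and the wider
single-section interval).

The full virtual loading study and its summaries:

```r
tab <- run_virtual_study(phantom_spec(), default_scenario_grid(), seed = 7)
fold_increase(tab, "static", "vertical")   # ~6 (configured static fold span)
fold_increase(tab, "dynamic", "vertical")  # ~3
fit_trend(tab, "static", "vertical")       # degree-2 dose-response fit
write_report(tab, list(), "study-out")     # CSVs, JSON fits, dependence plots
```

A shell entry point wrapping the same functions ships in
`inst/cli/` (`seedmd phantom|estimate|study --seed … --n-points … --out …`),
with YAML configuration via `--config`.

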