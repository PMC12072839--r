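---
title: "Quantifying internal microdamage by Monte Carlo point classification"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying internal microdamage by Monte Carlo point classification}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(seedmd)
```

## The problem

Seeds and similar loose biological particles accumulate internal cracks
under the mechanical loads of handling equipment.  The damage is
invisible from the outside but depresses germination and storage life,
so it must be quantified from X-ray tomography: each specimen is imaged
as a stack of 2D cross-sections (the protocol adopted here uses 10
evenly spaced horizontal and 10 vertical sections), cracks are
delineated on each section, and the damaged area fraction is estimated.

`seedmd` implements that estimation chain end to end, together with a
synthetic phantom generator that provides exact pixel-level ground
truth, which real tomograms lack.

## The estimator

Each section is reduced to a label mask over four classes: background,
solid material, damage (crack interior) and, optionally, crack
boundary.  Points are thrown uniformly at random over the image; points
landing on background are rejected and regenerated and do not count.
Each of the $N$ accepted points receives a random variable

$$\xi_i = \begin{cases}
  0   & \text{inside a crack},\\
  0.5 & \text{on the crack boundary},\\
  1   & \text{in solid material},
\end{cases}$$

and the per-section microdamage coefficient is

$$K_{md,i} = 1 - \frac{1}{N}\sum_{i=1}^{N}\xi_i .$$

Because accepted points are uniform over the object region, $1 - \xi$
has expectation equal to the weighted damage area fraction, so
$K_{md,i}$ is unbiased for it.  The plug-in variance

$$D_\xi = \frac{1}{N}\sum_i \xi_i^2 -
          \Bigl(\frac{1}{N}\sum_i \xi_i\Bigr)^{\!2}$$

yields the normal-approximation confidence half-width
$x_\beta\sqrt{D_\xi/N}$, where $x_\beta$ is the two-sided standard
normal quantile ($x_{0.95} = 1.96$).  The specimen-level coefficient is
the arithmetic mean over its $J$ sections (20 in the standard
protocol), with half-width $x_\beta \sqrt{\sum_j D_{\xi,j}/N_j}\,/\,J$.

The exact-area *oracle* is the pixel tally
$(\,\#\text{damage} + 0.5\,\#\text{boundary}\,)/\#\text{object}$
([exact_damage_fraction()]); it plays the role of the physically
measured actual damage coefficient and is what the Monte Carlo estimate
is validated against.

### Design choices in the estimator

* **Random points, not a lattice.**  A deterministic grid also counts
  areas, but the variance and confidence-interval treatment above
  presumes independent draws, so continuous pseudo-random uniform
  points are the default.  A jittered stratified mode
  (`sample_points(..., method = "stratified")`) is provided for
  comparison; it reduces spatial clumping but its nominal CI is then
  conservative.
* **$N$ counts accepted points only.**  Background hits are rejected
  and regenerated; they never enter the sums.
* **Boundary hits.**  With real-valued coordinates the probability of
  landing exactly on a pixel edge is zero, so $\xi = 0.5$ arises only
  through an explicit *boundary band*: [derive_boundary()] relabels
  every solid or damage pixel within `band_px` (chessboard distance) of
  the opposite class.  The default band is 0, giving a two-class
  object; the band gives "on the boundary" a concrete raster meaning
  when partial-volume pixels matter.
* **Defaults** mirror the reference protocol: $N = 3400$ points per
  section, $\beta = 0.95$, $J = 20$ sections.
* **Seeding.**  One root seed per specimen; section $i$ uses stream
  `seed + i`, and the study harness offsets the estimation stream from
  the generation stream so the two never coincide.  All generators
  restore the caller's RNG state.

## The phantom

[generate_slice()] draws an elliptical body (defaults: 12.6 × 8.54 mm
at 0.06 mm/px on a 256 × 256 raster, the mid-range of measured corn
kernel length and width) and thin elongated cracks: random-walk
polylines (unit steps, Gaussian heading increments, sd 0.2 rad) dilated
to `crack_width_px` and confined to an interior ellipse a few pixels
inside the body outline, so cracks never breach the body edge.
Intensities default to solid 200, damage 60, background 10, with
optional Gaussian noise and optional colour inversion
(`polarity = "cracks-bright"`), mirroring the inverted renderings used
to make cracks visible on tomograms.

Cracks are added one at a time until the damage pixel count reaches
`round(target × object_px)`, and the final crack is truncated along its
draw path, so the ground-truth fraction equals the requested target to
within one pixel.  This exactness is deliberate: it makes the phantom a
sharp oracle, so estimator bias and interval coverage can be tested
without a rasterisation-granularity nuisance term.

The damage target comes from the virtual load scenario.  A
[load_scenario()] carries the factor structure of the loading
experiment — static (slow compression) vs dynamic (striker impact)
load, vertical vs horizontal specimen placement, and the load expressed
as a fraction of the critical force $F_{kr}$ on the grid 0.3, 0.45,
0.6, 0.75, 0.9.  Its dose-response is anchored at two points: damage
fraction `baseline` at $0.3\,F_{kr}$ rising to
`baseline × fold_span` at $0.9\,F_{kr}$, with geometric interpolation
between (exponent `shape`, default 1).  Defaults are `baseline = 0.02`
and fold spans 6 (static) and 3 (dynamic) — the magnitudes reported for
corn seeds, where static loading raises the damage level about 5.5–6
fold and dynamic loading about 3–3.3 fold across that range.  The
default `noise_sd = 0` and `replicate_noise_sd = 0` keep the phantom an
exact oracle; both noises are opt-in.

What the phantom does **not** emulate: 3D crack fields (each section
draws an independent 2D field, which suffices because the estimator
consumes sections independently), beam hardening or ring artifacts,
calibrated crack morphology statistics (width and tortuosity are
plausible placeholders, not fitted to real tomograms), or any
per-orientation difference in crack statistics.  Passing tests
therefore demonstrate the correctness of the estimation chain, not the
accuracy of any particular real-world segmentation.

## Segmentation

The paper-level protocol identifies cracks on tomographic sections but
specifies no algorithm, so the imaging module is a reasonable standard
pipeline rather than a reconstruction of a particular one:

1. normalize polarity to cracks-dark (idempotent inversion);
2. split background from foreground with a global Otsu threshold
   (overridable via `bg_threshold`);
3. object support = largest connected foreground component with holes
   filled — internal cracks must belong to the object, not the
   background;
4. damage = support pixels below the crack threshold.  By default this
   is `min(Otsu-within-support, median − 3·MAD)` of the support
   intensities; the robust term prevents Otsu from bisecting a
   unimodal, crack-free object, and the Otsu term is dropped entirely
   when the support histogram has a single level;
5. connected damage components smaller than `min_crack_area` px
   (default 5) are reassigned to solid, suppressing noise speckles;
6. optional boundary band relabelling.

Connected components use the 4-neighbourhood (the labelling primitive
available in the underlying image library); at the default crack width
of 3 px this coincides with 8-connected labelling for every structure
the pipeline produces.  The within-support Otsu split is computed
directly on the support histogram because the library routine cannot be
restricted to a pixel subset.

On noise-free phantoms this pipeline reproduces the ground-truth labels
exactly when the speckle filter is disabled; with the default filter,
only sub-5-px crack fragments (e.g. the truncated tail of the last
crack) can be reassigned, which is why the fidelity check is stated as
≥ 99 % object-pixel agreement.

Degenerate inputs: a single-intensity slice raises a segmentation
error (there is no object to find); thresholds outside the raster's
intensity range raise parameter errors; masks without object pixels
raise empty-domain errors before any sampling happens.

## The virtual study

[run_virtual_study()] crosses load type × placement × load fraction
(20 cells by default), runs generate → segment → estimate per cell and
replicate, and tabulates $K_{md}$ with its half-width and the exact
oracle.  Two summaries follow:

* [fold_increase()] — mean $K_{md}$ at the highest load fraction over
  the mean at the lowest, per group.  The ratio is defined
  max-load/min-load (not relative to an undamaged baseline) as the
  simplest consistent reading of a "fold increase across the load
  range".
* [fit_trend()] — least-squares polynomial of $K_{md}$ on load
  fraction, degree ≤ 2 (degree 2 default, matching the smooth monotone
  dose-response curves such studies report; no published curve equation
  exists to adopt).  $R^2$ is reported, defined as 1 in the degenerate
  constant-response case.

## Problem sizes and numerical choices

The shipped tests and the acceptance script use the package's own
defaults: 256 × 256 rasters (~23,500 object pixels), $N = 3400$,
$J = 20$, 200 seed replicates for the unbiasedness check, 500 for
interval coverage, and a 20-cell single-replicate study for fold-span
recovery; unit tests use a smaller 96 × 96 phantom where geometry is
irrelevant.  Variance estimates are clamped at 0 against floating-point
dust; ties in the largest-component selection resolve to the
first-labelled component (they cannot arise on phantom input).

## Known limitations

* The segmentation defaults are tuned to bimodal, single-body
  cross-sections; multi-kernel fields of view or strong illumination
  gradients would need a different support rule.
* The boundary band conflates "partial-volume pixel" with "within
  `band_px` of an interface"; it is an operationalization, not a
  physical point-spread model.
* The stratified sampling mode reuses the random-mode CI, which is then
  conservative.
* Fold-span recovery is validated on synthetic phantoms only; the
  package makes no claim about recovering the published load-damage
  curves, whose underlying data are not available.
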