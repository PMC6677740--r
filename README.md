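# notumpattern

Lateral-inhibition modelling of sensory bristle patterning in the
*Drosophila* notum, together with the quantification pipeline for
nuclear reporter intensities around a proneural stripe.

## The problem

On the fly dorsal thorax, five regular rows of microchaetae emerge from
proneural stripes that appear in a defined sequence; within each stripe,
Notch-mediated mutual inhibition singles out regularly spaced sensory
organ precursors (SOPs), and every other cell adopts the epidermal fate.
Early, proneural-independent Notch activity provides a *negative
template* that positions the first stripes; later, proneural-dependent
Notch targets sharpen SOP spacing within stripes.  This package is for
modellers and quantitative biologists who want to (i) simulate that
patterning process on realistic disordered epithelia, (ii) map genetic
perturbations onto parameter regimes and compare the resulting
phenotypes, and (iii) quantify (real or synthetic) segmented-nuclei
imaging data as distance-binned expression profiles.

## The model

Each cell *i* of a fixed, disordered periodic lattice carries a scalar
proneural activity *u<sub>i</sub>* obeying

    tau du_i/dt = f(u_i - s_i) - u_i + eta_i(t)

where *f* is a logistic sigmoid rising from 0 to 1 (self-activation
versus inhibition), *eta<sub>i</sub>* is Gaussian white noise, and the
inhibitory signal

    s_i = s0(x_i, t) + sum_{j != i} c_ij D*(u_j)

combines a time-dependent extrinsic gradient *s0* along the
medial–distal axis with distance-weighted ligand activity
*D\*(u<sub>j</sub>)* received from surrounding cells through the
Gaussian kernel *c<sub>ij</sub>*.  At intermediate signal levels a cell
is bistable — a high-*u*/low-*s* (SOP) state and a low-*u*/high-*s*
(epidermal) state — so the tissue resolves into spaced SOPs.  The
extrinsic gradient interpolates from an early plateau with notches at
the stripe-1/3/5 positions (the negative template) to late inhibitory
halos emanating from the flank stripes 1 and 5; stripes 2 and 4
self-organize in between, reproducing the sequential emergence of
stripes 3, then 2 and 4.

Four regime presets mirror the studied perturbations: `wild_type`,
`no_template` (early notches flattened: broad proneural domain over the
stripe 2–4 region), `reduced_late_inhibition` (cell–cell inhibition
scaled by 0.6: denser bristles, intact rows), and `no_inhibition`
(coupling removed: nearly every cell becomes an SOP).

## Worked example

```r
library(notumpattern)

cfg <- default_config()              # 450 cells, 15 x 30 box, 5 stripes
res <- run_simulation(cfg, seed = 1)
res$lattice
#> cell_lattice: 450 cells in a 15 x 30 periodic box
#>   mean Delaunay degree: 6  mean area: 1
res$stats
#> pattern_stats: 41 SOPs, density 0.0911 per diameter^2, spacing CV 0.0544
res$stripes
#>      center     width n_sop narrow
#> 1  1.506709 0.5188999     8   TRUE
#> 2  4.513350 0.5213510     8   TRUE
#> 3  7.518992 0.5387026     9   TRUE
#> 4 10.509140 0.5570404     8   TRUE
#> 5 13.506667 0.5264980     8   TRUE
```

The run recovers five narrow SOP rows at the expected stripe positions
(x = 1.5, 4.5, 7.5, 10.5, 13.5 cell diameters), with a nearest-neighbour
spacing coefficient of variation of 0.05 — a regular bristle pattern.

The profiling pipeline, applied to a synthetic 5-image field of
segmented nuclei (an early-onset reporter peaking on the stripe flanks):

```r
spec   <- field_spec(seed = 1)
nuclei <- generate_nucleus_field(spec)
prof   <- compute_profile(nuclei, synthetic_centerline(spec), "m3")
subset(as.data.frame(prof), abs(bin_center) <= 9)
#>    bin_center  mean    sem n_images
#> 6          -9 7.935 0.4770        5
#> 7          -7 8.765 0.8895        5
#> ...
#> 10         -1 0.127 0.0304        5
#> 11          1 0.228 0.0413        5
#> ...
#> 14          7 9.231 0.8534        5
```

The profile (per-bin sum of normalized intensity minus the 0.2
detection threshold, mean ± SEM across images) shows the two flank
maxima near ±7 µm and the central depletion that define the early-onset
reporter's accumulation pattern.

A thin command-line wrapper ships in `inst/cli/notumpattern.R`
(`simulate | profile | compare | generate`), driven by YAML run
configurations (`write_config(default_config(), "run.yaml")`).

## Package layout

- `R/geometry.R` — disordered periodic lattices (jittered hexagonal
  packing + Lloyd relaxation; periodic Voronoi/Delaunay via deldir) and
  the Gaussian signalling kernel.
- `R/dynamics.R` — the bistable lateral-inhibition dynamics and the
  Euler–Maruyama integrator.
- `R/fate_analysis.R` — fate calls, spacing statistics, stripe
  detection, binned time courses, regime comparison.
- `R/profiles.R` — per-image normalization, detection threshold (0.2),
  signed distance to a stripe centerline, binned profiles (mean ± SEM).
- `R/synthetic.R` — seeded generators for nucleus fields and planted
  stripe patterns.
- `R/config.R`, `R/cli.R` — validated YAML run configurations, regime
  presets, and command entry points.

See `vignettes/notum-patterning.Rmd` for the full account of the model,
its calibration, and the analysis conventions.
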