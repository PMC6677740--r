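---
title: "Modelling bristle patterning in the notum: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling bristle patterning in the notum: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(notumpattern)
```

This vignette is the package's account of its science: the model and
its assumptions, the parameters that matter and why they have the
defaults they have, the analysis conventions, the synthetic-data
generator, and the numerical choices.  Nothing here states an empirical
result that the test suite or `scripts/acceptance.R` does not itself
compute.

## The model

Sensory bristles on the fly dorsal thorax develop from sensory organ
precursors (SOPs) selected out of proneural stripes by Notch-mediated
mutual inhibition.  We describe each cell of a fixed epithelium by one
scalar, its proneural activity $u_i$, evolving as

$$\tau \frac{du_i}{dt} = f(u_i - s_i) - u_i + \eta_i(t),$$

with $f$ a logistic sigmoid from 0 to 1: self-activation (the
proneural positive feedback) opposed by the inhibitory signal $s_i$,
plus white noise $\eta_i$.  The signal a cell receives,

$$s_i = s_0(x_i, t) + \sum_{j \ne i} c_{ij}\, D^*(u_j),$$

combines an extrinsic gradient along the medial–distal axis $x$ with
instantaneous cell–cell inhibition: each neighbour contributes its
active-ligand output $D^*(u_j)$ (a saturating, monotone function of its
state) weighted by a Gaussian kernel
$c_{ij} = a\, e^{-d_{ij}^2 / 2\ell^2}$ decaying with the periodic
distance $d_{ij}$ over a signalling range $\ell$.

**Assumptions.** Cell positions are fixed (no rearrangement, division
or motility); signalling is instantaneous (no delay, no explicit
receptor–ligand kinetics, no cis-inhibition); all inhibitory Notch
targets are lumped into the single signal $s$; one scalar per cell
stands in for the whole proneural/E(spl) regulatory state.

**Bistability.** For intermediate constant signals the single-cell
dynamics have two stable states — high $u$ (SOP) and low $u$
(epidermal) — separated by an unstable one.  With the default sigmoid
(threshold 0.2, steepness 0.1) the bistable window is
$s \in [0.125, 0.475]$ (computed by `bistability_window()`).  Below the
window only the high state exists: an unsignalled competent cell
*becomes* an SOP by default, which is what makes total loss of
inhibition convert essentially the whole tissue.  Above it only the
epidermal state survives.  Fate is therefore controlled by where a
cell's received signal sits relative to this window as the pattern
develops.

## Geometry

Tissues are disordered periodic lattices in boxes measured in mean cell
diameters (`build_disordered_lattice()`): a commensurate hexagonal
packing, seeded Gaussian jitter (`disorder` times half the mean
spacing), then 20 Lloyd (centroidal-Voronoi) iterations on the torus.
This reproduces what matters about an epithelium for these equations —
near-uniform areas with disordered neighbour topology — without
simulating mechanics; only static positions enter the dynamics.
Delaunay adjacency and Voronoi areas come from the `deldir`
tessellation of a periodically tiled copy of the points (a margin band
of five mean spacings, or the full 3x3 tiling for small boxes); on the
torus the triangulation always has exactly $3n$ edges (mean degree 6),
which the tests assert, and the Voronoi areas partition the box area
exactly.

## The extrinsic gradient

$s_0(x, t)$ interpolates linearly in time, between `t_start = 5` and
`t_end = 15` (units of $\tau$), from an **early profile** — a plateau
of height 1 with Gaussian notches (width 1) at the stripe-1/3/5
positions, the proneural-independent *negative template* that permits
proneural activity only at the notches — to a **late profile**
representing inhibition produced by the established flank stripes 1
and 5.

The late profile is a *source halo*: a wide Gaussian (width 1.2) around
each flank-stripe position minus a narrow core Gaussian (width 0.5),
floored at zero.  A plain bump centred on a stripe would inhibit the
stripe's own cells and extinguish exactly the rows it is supposed to
represent; subtracting the core encodes that the term stands for the
signal a stripe sends to its *surroundings*, while inhibition among the
stripe's own cells is already carried by the explicit $c_{ij}$ term.
With the halo, the flank rows persist through the transition, and in
the template-less regime they even form de novo at the halo cores —
the behaviour expected of stripes "driven" by the late gradient.

## Calibration of the defaults

The literature source for this model defers all functional forms and
constants to earlier work, so the package fixes one calibrated default
set, chosen once so that the wild-type configuration is bistable and
patterning, and exposed entirely through `model_params()`,
`gradient_params()` and `default_config()`:

| parameter | default | units | role |
|---|---|---|---|
| `tau` | 1 | time | relaxation time; all times are in $\tau$ |
| `f_threshold` | 0.2 | state | sigmoid midpoint; <0.319 makes $s=0$ monostable-high |
| `f_steepness` | 0.1 | state | switch sharpness; sets the window width 0.35 |
| `noise_sigma` | 0.02 | state/$\sqrt{t}$ | symmetry breaking during SOP selection |
| `d_mid`, `d_steepness` | 0.5, 0.1 | state | ligand output engages at mid activation |
| signalling range $\ell$ | 1 | diameters | nearest-neighbour-dominated inhibition |
| strength $a$ | 2 | signal | one SOP suffices to exclude a contacting cell |
| cutoff | $3\ell$ | diameters | sparsity; Gaussian tail beyond is <0.012 |
| stripe spacing | 3 | diameters | five rows across the width-15 box |
| `fate_threshold` | 0.5 | state | midpoint of the stable branches mid-window |

Why these numbers interlock: an SOP's nearest neighbour (distance ~1)
receives $2 e^{-1/2} \approx 1.2$, far above the window top 0.475, so
contacting cells are reliably excluded; two high cells can coexist only
beyond distance ~1.7, setting the SOP spacing within rows; a cell
midway between template rows (distance 3) receives ~0.06, below the
window bottom 0.125, so stripes 2 and 4 can escape and self-organize
once the plateau fades — the sequential emergence of stripe 3 before 2
and 4.  The fate threshold is the midpoint of the two stable branches
at the centre of the bistable window (0.0073 and 0.993 at $s = 0.3$,
midpoint ≈ 0.5); the midpoint at $s = 0$ is unavailable because the
defaults are deliberately monostable-high there.

## Regimes

`make_regime_config()` maps perturbations onto pure config
transformations: `no_template` flattens the early notches (loss of the
early, proneural-independent Notch targets); `reduced_late_inhibition`
scales the state-dependent cell–cell term by 0.6 (loss of late-onset
repressors weakens mutual inhibition: denser bristles, intact rows);
`no_inhibition` zeroes the coupling and the late profile (complete
loss: tufted, contiguous SOPs).  These are direction-level phenotype
models; the package deliberately does not fit magnitudes (such as a
percentage density increase) to the biology.

## Analysis conventions

**Stripe detection.** Two detectors serve different data.  For
continuous fields (planted stripes, template-phase activity),
`stripe_profile()` bins mean $u$ along $x$ and `count_stripes()` counts
super-threshold runs at the profile's mid-range, with periodic
wraparound.  For terminal SOP patterns — sparse points, where any
mid-range threshold on binned means is fragile — `sop_stripes()`
clusters SOP $x$ positions: gaps above 0.9 diameters split clusters
(within-row scatter stays below ~0.6; isolated defect SOPs sit farther
out), clusters need at least 2 SOPs, and a cluster is a "narrow stripe"
if its extent is at most 1.5 diameters.  The template-less regime is
quantified instead by how broadly SOPs occupy the central region
(bin-occupancy) because that regime's defining feature is the *absence*
of narrow-row structure; note the model can still self-organize
quasi-periodic rows there in a minority of runs — sequential
self-organization from the flank halos is genuine model behaviour, so
the package compares occupancy levels rather than asserting that no
stripes ever form.

**Stripe-resolution time courses.** `bin_time_courses()` averages $u$
and $s$ over cells binned by distance to a stripe centre.  Two
directional facts characterize resolution in the default
configuration: lateral cells are excluded first (the lateral bin's mean
activity falls to half its peak before that of the central bin's
non-SOP cells), and once the stripe is established — operationally, at
the first snapshot after the extrinsic transition completes — the
stripe centre carries more inhibitory signal than its flanks.  The
timing matters and is a real feature of short-range inhibition, not a
technicality: *before* the transition the template itself makes the
flanks the most-signalled cells, and *later* the rising neighbour
stripes re-inhibit the flanks, so the centre-over-flank excess is a
transient property of an established stripe in isolation.  (That the
flanks otherwise dominate is consistent with reporter data in this
system, where an early-onset Notch reporter accumulates flanking the
stripe rather than at its centre.)

## The synthetic imaging fields

`generate_nucleus_field()` emulates the *structure* of segmented
confocal data around one proneural stripe: a hard-core point process of
nuclei (default ~400 per 80x60 µm image, minimum spacing 2.5 µm); a
proneural channel peaking on the stripe midline (Gaussian, width 4 µm);
an early-onset reporter as two flank peaks at ±7 µm (width 3 µm) with a
central dip; a late-onset reporter as a broad central bump (width 5 µm)
switched off in SOP nuclei (placed every ~8 µm along the midline); a
per-image, per-channel lognormal gain (sdlog 0.3) — present precisely
so that the per-image normalization step has something real to remove —
and additive Gaussian noise (sd 0.05), clipped at zero.  Five images
per field by default.

What it does *not* emulate: optics (no point-spread function, no
segmentation errors, no cuticle autofluorescence needing manual
curation), nucleus shape or intensity heterogeneity beyond the global
noise, and channel cross-talk.  Passing tests on these fields therefore
demonstrate that the pipeline recovers planted spatial structure
through realistic gain/noise, not that it is robust to segmentation
artefacts.

**The profiling conventions** follow the quantification they model:
per-image normalization so each reporter's maximum is of order one
(default scale: 99th percentile; exact maximum also available, since
the choice of scale statistic is a judgment call), detection =
normalized level *strictly* exceeding 0.2, signed perpendicular
distance to the annotated centerline (left of the walking direction
positive), 2-µm bins over ±20 µm, and per-bin statistics across images
(mean ± SEM).  Two per-bin statistics are provided because the
source descriptions differ between summing detectable intensity minus
the threshold and averaging normalized intensities:
`sum_minus_threshold` (default) and `mean_intensity`; both are tested
against an independent naive reimplementation.

## Numerical choices

- **Integrator:** explicit Euler–Maruyama,
  $u \leftarrow u + \frac{dt}{\tau}(f - u) + \sigma\sqrt{dt}\,N(0,1)$,
  default $dt = \tau/50$, guarded at $dt \le \tau/10$.  The drift is
  bounded and non-stiff; with $\sigma = 0$ and $dt \le \tau$ the update
  preserves $u \in [0,1]$ exactly, and convergence is property-tested
  against a 10x finer step.
- **Fixed points:** sign-change scan on a 2001-point grid over
  $[-0.5, 1.5]$ refined by `uniroot` to 1e-12; stability from the sign
  of $f'(u - s) - 1$ in closed form; the tests cross-check against a
  100,000-point brute-force scan.
- **Degenerate inputs:** a one-cell lattice owns the whole box and has
  no neighbours; an all-zero channel is flagged rather than divided by
  zero; an image with no detectable nuclei contributes an all-zero
  (not missing) profile; empty time-course bins are recorded as `NA`.
- **Ties and edges:** profile bins are left-closed; with periodic
  boxes, distances use the minimum image; cocircular degeneracies in
  the tessellation are avoided by construction (jittered/relaxed
  points, near-equilateral hexagonal seeds).
- **Determinism:** every stochastic entry point takes an explicit
  integer seed and sets the RNG locally; replicate aggregation uses
  explicit seed lists; manifests record all resolved parameters and
  seeds.  Identical inputs give byte-identical outputs.

## Problem sizes

The default tissue is 450 cells (15 x 30 diameters); the acceptance
analyses use five replicate tissues of 990 cells (15 x 66) for
wild-type statistics and five 450-cell replicates per regime, sizes at
which the patterning statistics are stable while a full run takes a
couple of seconds.

## Known limitations

- The quantitative defaults are a calibration, not a fit: magnitudes
  (bristle counts, density increases) are out of scope; only phenotype
  directions are claimed.
- Short-range coupling with 1–2-cell-wide stripes places the signal
  maximum on the stripe flanks except in the transient window discussed
  above; models with wider stripes or longer-range coupling can behave
  differently.
- The vertex-model mechanics behind real epithelial disorder are
  replaced by jitter + Lloyd relaxation; topological defect statistics
  are similar but not identical.
- Row normalization of the coupling kernel (optional) sacrifices exact
  symmetry on disordered lattices; the default is the symmetric,
  unnormalized kernel.
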