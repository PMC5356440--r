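---
title: "Methods: quantifying cortical microtubule targeting and junctional redeployment"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: quantifying cortical microtubule targeting and junctional redeployment}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette is the package's own account of its measurement procedures:
the models behind each readout, the tunable parameters and why their
defaults are what they are, what the synthetic-data generator does and
does not emulate, and the numerical choices that matter at the margins.

## Coordinate and angle conventions

All geometry lives in continuous micrometre coordinates with the origin
at the field's top-left corner and y increasing downward; a raster's
pixel `(r, c)` is centred at `((c − 0.5) px, (r − 0.5) px)` µm. The
default calibration is 0.1 µm/px so that the 0.2–1.2 µm² comet area gate
corresponds to exactly 20–120 px. Orientations of undirected structures
(filaments, fibril axes, junction tangents) are taken modulo 180°, and an
*approach angle* is the acute angle in [0°, 90°] between a filament's
cortex-proximal segment and the junction tangent — so "perpendicular"
approaches occupy [45°, 90°], with both bounds inclusive (the 45°
boundary is deliberately counted in, and a dedicated test pins that
choice).

## Junction line profiles

At evenly spaced positions along a junction trace, intensity is sampled
by bilinear interpolation along the line normal to the local tangent:
`n_samples` readings spanning `span` µm, by default 21 readings over
2 µm, i.e. 0.1 µm spacing with the junction at the centre sample (index
10 of 0–20). The normal at an interior vertex averages the two adjacent
segment directions; profile positions whose samples leave the image are
skipped with a warning rather than padded.

Baselining subtracts a background estimate and clips negatives to zero
(intensities are physical). The background is either supplied explicitly
(e.g. an ROI mean) or defaults to the image's 5th percentile — a robust
statistic that respects each image's own exposure and needs no extra
input. Baselining twice with background 0 is a no-op, and multiplying an
image by k scales every peak by k while leaving ratios and percent
reductions unchanged; both invariants are tested.

The **primary statistic is the per-profile peak** (the maximum reading),
with the point-wise mean profile ± SD kept for plotting. Peaks of a
treated group are normalized against the control mean; the percent
reduction is `100 (1 − mean(treated)/mean(control))`.

A consequence worth knowing: the maximum of a noisy profile is a biased
estimator, so the measured percent reduction between two punctate scenes
slightly understates the true density ratio (a halved enrichment reads
as a ~44% rather than 50% reduction under the default generator
conditions — the max picks up positive fluctuations whose relative size
grows as density falls). The recovery tests therefore assert a ±10
percentage-point window around the true reduction and strict
monotonicity across enrichment ratios, not exact equality.

## Cortical targeting metrics

* **Perpendicular fraction.** Filaments whose cortex-proximal end lies in
  a 10 × 10 µm cortical box are scored by their approach angle; the box
  edges are half-open (left/top in, right/bottom out) so tiled boxes
  never double-count. A box containing no filament is reported undefined
  and excluded from group means. The approach direction is taken from the
  filament's final segment rather than its end-to-end direction, because
  "approaching the cortex" is a local property of the tip.
* **Contacts per 10 µm.** A filament contacts the junction when its
  proximal endpoint lies within `d_contact` of the junction polyline;
  each filament counts at most once and the count is normalized by
  junction length × 10. `d_contact` defaults to 0.25 µm (≈ 2–3 px at
  default calibration) — the field's notion of "contact" is not defined
  geometrically anywhere authoritative, so the radius is an explicit,
  configurable parameter echoed into every output.
* **Nematic orientation.** Per-pixel gradients (centred finite
  differences after a σ = 1 px Gaussian pre-smooth) are averaged into
  the 2 × 2 structure tensor over the ROI; the fibril axis is the axis
  perpendicular to the dominant gradient axis, and the anisotropy is the
  tensor's eigenvalue contrast (λ₁ − λ₂)/(λ₁ + λ₂) ∈ [0, 1]. A two-pixel
  border is trimmed before averaging so the blur's edge handling cannot
  bias the tensor. When the mean squared gradient falls below a floor
  (10⁻⁸ of the mean squared intensity) the orientation is flagged
  undefined instead of raising an error — a constant ROI is a legitimate
  input. On closed-form sinusoidal stripes the recovered axis is within
  1° for a 2 µm stripe period; shorter periods incur a small known bias
  from the finite-difference transfer function (≈ 0.5° at a 1 µm
  period), which is why the validation pattern uses the longer period.

## Comet detection

Background subtraction defaults to a median filter with a 5 µm window;
thresholding defaults to Otsu on the background-subtracted image. Both
are deliberately parameter-light, standard choices — the point the
pipeline enforces is not the specific algorithm but that **one parameter
set is applied to every image of a comparison group**, which is why every
detection table carries its parameters as metadata and the pipeline
configures them once per run. Connected components use 8-connectivity;
the area gate is inclusive at both ends (a 20-px component at 0.1 µm/px
is kept, a 19-px one rejected) with a 10⁻⁹ µm² tolerance so floating-
point pixel areas cannot flip the boundary case.

Detector validation is run at low comet density (1 per 100 µm², spot
areas 0.3–0.8 µm², SNR 50) and scored 1 µm away from the field border:
at higher densities overlapping spots merge into components that exceed
the area gate, and border-clipped spots fall below it — both real
phenomena of area-gated particle counting rather than detector defects.
Under the validation conditions precision and recall are ≥ 0.95 averaged
over three seeds (matching radius 0.3 µm).

## Track linking and dynamics

Linking is greedy mutual-nearest frame-to-frame assignment: repeatedly
link the globally closest (track head, detection) pair, allow gaps up to
`max_gap` frames with the allowed distance scaling as
`max_disp × (gap + 1)`, and never reuse a detection. This is documented
plumbing for low-density data — not a re-implementation of
multi-hypothesis tracking — and is validated against an exhaustive
optimal-matching oracle on small scenes.

**Bend splitting.** Tracks are split wherever consecutive segment
orientations differ by strictly more than 30° (differences folded into
[0°, 180°]); fragments shorter than two frames are discarded and
fragment ids derive from the parent. Note the interplay with pausing: a
truly stationary comet's residual jitter has uniformly random segment
orientations, so the 30° filter chops long pauses into short fragments.
The filter's purpose is to remove abnormally bendy trajectories before
speed analysis; the package therefore exposes splitting and event
classification as separate composable steps, and the dynamics-recovery
validation runs classification directly on unsplit tracks.

**Events.** Per-frame speeds (µm/min) are classified by a run-length
rule: maximal runs of at least `min_pause_frames` consecutive segments
slower than `pause_speed_max` are pause events; everything else is
growth. The constants default to 1.5 µm/min and 2 segments — the
classification rule itself is standard, but its constants are not fixed
by any published source, so they are configuration, echoed into output
metadata. Events tile each track contiguously; a track shorter than the
minimum run becomes a single event classified by its mean speed.

Percentages of growing vs pausing are reported under **two
denominators**: per event (primary) and per unit of track time
(secondary, `pct_time_*`). The two answer different questions — events
alternate by construction, so only the time fraction converges to the
Markov stationary occupancy `p_gp/(p_gp + p_pg)`; the recovery tests
compare the time fraction against that expectation. Cells are the unit
of replication: summaries average events per cell, then cells per
treatment.

**Speed groups.** The analysis cap is `v_max = mean + 1 SD` of the
growth-event speeds of the fastest cell across all treatments; [0, v_max]
is split into four equal-width bins (very slow / slow / fast / very
fast), the last bin right-closed, with super-v_max speeds counted into
it. Equal-width bins below a capped maximum concentrate resolution at
low-to-medium speeds, which is where treatment effects appear; the edges
are configurable.

## The statistics decision tree

Each group is first assessed with the D'Agostino–Pearson omnibus K² test
(transformed skewness + kurtosis, χ² with 2 df), implemented from the
published formulas and verified against an established implementation on
frozen fixtures. The omnibus test is invalid below n = 8, so smaller
groups route directly to the nonparametric branch — this is the precise
form of "datasets too small for normality analysis". If every group
passes at α = 0.05: two groups → Welch t-test, more → one-way ANOVA.
Otherwise: Mann–Whitney U, or Kruskal–Wallis with Dunn's post test
(tie-corrected rank z statistics, Bonferroni-adjusted over all pairs, the
conventional pairing for Dunn). All tests are two-sided, and the full
decision trace — every normality p-value and the branch it forced — is
recorded in the comparison object and the pipeline log. The routed
two-group procedure holds its nominal type-I error (0.05 ± 0.01 over
2000 null simulations at n = 20).

Bud-count tables fold per-organoid counts into categories 0/1/2/3/4+,
compute percentages per region, then average regions within
genotype × day; a two-way genotype × day ANOVA on one category's region
percentages is available as a companion.

## The synthetic-data generator

The generator produces every structure the measurement modules consume,
each with a complete ground-truth record and full determinism given
(parameters, seed):

* a Voronoi cell mosaic from uniformly seeded centres (each internal
  edge returned once, tagged with its two cells);
* junction ridges with Gaussian cross-section, plus additive Gaussian
  noise floored at zero — the simplest noise model that exercises
  thresholding;
* cortical puncta: homogeneous Poisson background plus a junctional
  Poisson line process displaced normally (SD = half the band width).
  The default junctional density of 8 µm⁻¹ puts the inter-punctum
  spacing (~0.13 µm) below the PSF width (σ = 0.15 µm), producing the
  quasi-continuous junctional band seen in real cortical stainings
  rather than resolvable beads;
* straight filaments whose approach angles follow an axial von Mises
  distribution folded into [0°, 90°] (κ = 0 is exactly uniform; κ is
  capped at 10⁶, where the spread is ≈ 0.03°);
* comet spots as filled 2:1 ellipses with true areas uniform in a range;
* comet trajectories as two-state (growth/pause) Markov chains: the
  state of frame i governs segment i's displacement — growth steps are
  `Normal(v_growth, v_sd)` µm/min along a persistent direction with 3°
  angular wobble, pause steps are 0.01 µm isotropic jitter. The frame
  interval defaults to 2 s, a standard acquisition rate for +TIP comet
  imaging: growth comets then move 0.2–0.4 µm per frame, comfortably
  above localization jitter, so apparent pause speeds (~0.5 µm/min)
  stay well below the 1.5 µm/min classification threshold.

What the generator does **not** emulate: PSF optics and photobleaching,
3D geometry, curved microtubules, comet appearance/disappearance within
a movie, spatial correlation between the puncta and filament channels,
and organoid morphology. Passing recovery tests therefore demonstrate
that the measurement code is correct and well-calibrated on data whose
structure is known — they do not certify performance on real images,
where segmentation quality, optical blur and annotation error dominate.

## Problem sizes and numerical margins

The validation experiments use: 200+ profiles per arm over three seeds
for enrichment recovery; 1000 filaments for uniform-angle scoring; three
60 × 60 µm comet fields for detection scoring; 500 tracks × 60 frames ×
three seeds for dynamics recovery; 1000 random-walk tracks for the
splitting/classification oracle equivalence; and 2000 null simulations
for the type-I error — sizes chosen so each experiment's Monte-Carlo
error is several times smaller than the tolerance it is tested against.
Bilinear interpolation against a σ = 0.3 µm Gaussian ridge is accurate
to ~1.4% of amplitude at 0.1 µm sampling (second-derivative error
`f″h²/8`), which is why peak-recovery tolerances are 2%. Determinism is
absolute: every stochastic routine scopes its RNG with `withr`, so
identical seeds give bit-identical scenes, CSVs and results.
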