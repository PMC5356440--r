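# cortexmt

Quantitative image analysis of microtubule (MT) cortical targeting and
junctional protein redeployment in epithelial monolayers.

In differentiating epithelia, MT minus-end anchoring proteins such as ninein
relocate from the centrosome to non-centrosomal sites at apical cell–cell
junctions. Measuring that redeployment, and the MT plus-end behaviour that
drives it, rests on a handful of image-derived readouts: fluorescence
intensity line profiles across junctions, the percentage of MTs approaching
the cortex at perpendicular angles, MT–junction contact counts, plus-end
comet ("+TIP") counts in fixed images, and growth/pause statistics of comet
trajectories in live imaging. `cortexmt` implements these readouts as a
tested, scriptable pipeline, together with a seeded synthetic-scene
generator so that every stage can be validated by parameter recovery
without access to raw microscopy data.

## What it computes

* **Junction line profiles** — at positions along a junction trace,
  intensity is read along the junction normal: 21 readings over 2 µm
  (0.1 µm spacing), baselined against background and clipped at zero.
  Per-profile peaks are normalized against the control arm:
  ratio `r = mean(treated) / mean(control)`, percent reduction
  `100 (1 − r)`.
* **Cortical targeting** — per 10 × 10 µm cortical box, the percentage of
  filaments whose approach angle θ to the local junction tangent lies in
  [45°, 90°]; MT–junction contacts per 10 µm of junction; and the
  gradient structure-tensor (nematic) orientation of a region's texture,
  reporting the fibril axis in [0°, 180°) and an anisotropy score in
  [0, 1].
* **Comet detection** — background subtraction (5 µm median filter),
  Otsu threshold, 8-connected components, inclusive area gate
  0.2–1.2 µm² (20–120 px at 0.1 µm/px), counts per box.
* **Track post-analysis** — greedy nearest-neighbour linking (plumbing),
  track splitting where consecutive segment orientations differ by more
  than 30°, growth/pause event classification by a speed-threshold
  run-length rule, per-cell dynamics summaries, and four equal-width
  speed groups over [0, v_max] with
  `v_max = mean + 1 SD of the fastest cell's growth speeds`.
* **Group statistics** — the normality-routed decision tree:
  D'Agostino–Pearson K² per group; all normal and n ≥ 8 → t-test /
  one-way ANOVA; otherwise Mann–Whitney U / Kruskal–Wallis with Dunn's
  multiple-comparison post test. Organoid bud-count distributions
  (categories 0/1/2/3/4+) are summarized per region and genotype × day.

## Worked example

The `analysis/` directory is a numbered workflow over one shared config
(`analysis/config.yaml`); each script runs one stage into `results/run/`
and prints what it found:

```sh
Rscript analysis/01_simulate.R
Rscript analysis/02_profiles.R
# ...
Rscript analysis/06_stats.R
```

Output of a full run at the default seed (42):

```
mosaic: 9 junction edges
filaments: 150, ground-truth approach angle mean 64.4 deg
comets: 213 spots, areas 0.30-0.99 um^2

profiles: control n=138, treated n=138
relative peak ratio treated/control: 0.564
measured junctional reduction: 43.6% (true enrichment ratio 0.50)

perpendicular approach (45-90 deg): 69.4% mean over 9 boxes
contacts: 13.24 per 10 um of junction (mean over 9 junctions)

control: growth speed 11.6 um/min, growth length 3.82 um, n = 4 cells
treated: growth speed 6.0 um/min, growth length 1.89 um, n = 4 cells
vmax (fastest cell mean + 1 SD): 12.84 um/min

selected test: Mann-Whitney U, p = 5.3e-15
junctional peak change: 43.6% reduction
```

Reading these numbers: the generator halved the junctional enrichment in
the treated arm, and the profile pipeline measures a ~44% peak reduction
(the residual gap to 50% is the max-statistic bias of per-profile peaks,
discussed in the methods vignette); the simulated growth speeds of
12 vs 6.3 µm/min are recovered as 11.6 vs 6.0; and the comparison of
peak intensities routes to Mann–Whitney because the peak distributions
are right-skewed.

The same machinery is available programmatically:

```r
library(cortexmt)
cfg <- system.file("extdata", "demo_config.yaml", package = "cortexmt")
run_pipeline(cfg, "my_run")   # simulate -> profiles -> ... -> stats
```

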