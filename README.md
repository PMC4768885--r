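# trapcam

Trap-camera image analysis and capture statistics for fruit-fly
surveillance experiments.

Attractant-baited traps — such as the Jackson trap baited with trimedlure
(TML), with or without a DDVP insecticide strip — are the backbone of
detection and eradication programs for the Mediterranean fruit fly
(*Ceratitis capitata*). Field-cage studies of trap *capture efficiency*
monitor the trap's surfaces with time-lapse cameras and count flies
automatically in hundreds of thousands of images, then relate those
sightings to the flies actually captured on the sticky panel or found dead
in a tub beneath the trap. `trapcam` implements that entire analysis chain
for R, together with a seeded synthetic trap-camera simulator so that every
stage can be verified against exact ground truth without raw field imagery.

## What it computes

**Detection pipeline** (per camera / trap surface):

1. *Background model* `B = Σ wᵗ Iᵗ / Σ wᵗ` over a window of frames
   (default 50), with linear weights `wᵗ ∝ t` favouring recent frames, or
   uniform weights; a rolling-window variant is available for drifting
   scenes.
2. *Background subtraction* `Dᵗ = |Iᵗ − B|`, then linear rescale of `Dᵗ`
   to 8-bit.
3. *Segmentation*: Otsu's threshold (exhaustive 256-level between-class
   variance maximisation) or a fixed threshold.
4. *Blobbing*: binary opening then closing with a square structuring
   element (default 3×3) so each insect forms one compact particle.
5. *Particle analysis*: 8-connected components, optionally restricted to a
   region of interest, kept when their area lies in the closed gate
   [150, 950] px.

**Validation** of automatic vs manual counts: fraction of images with
`|auto − manual| ≤ 1` and `≤ 3`, and the Pearson correlation `r` (pooled
and per date), with significance from `t = r√((n−2)/(1−r²))`.

**Capture statistics**: replicate × treatment summaries (mean ± SD, n−1
denominator), one-way ANOVA of `ln(x+1)`-transformed counts between
treatments, two-way ANOVA (bait × surface, with interaction; sequential or
Type II sums of squares), Fisher's LSD post hoc comparisons, and
Kolmogorov–Smirnov normality checks of the transformed response.

**Simulator**: flies as dark ellipses with controlled pixel area over a
smooth textured background, per-surface birth–death arrival/departure
dynamics calibrated per treatment, illumination drift and sensor noise,
plus negative-binomial capture-count tables — all bit-reproducible from a
seed.

## Worked example

Simulate a monitored trap surface, run the detection pipeline, and check it
against the simulator's ground truth:

```r
library(trapcam)

cfg <- sim_config(width = 320, height = 240, n_frames = 120,
                  arrival_rate = 0.4, departure_rate = 0.2,
                  noise_sd = 2, warmup_frames = 30, seed = 42)
sim <- simulate_image_sequence(cfg)
sim
#> trapcam_stack: 120 frames of 240 x 320 px @ 6s (surface 'surface')
#>   ground truth: 168 blob sightings, mean occupancy 1.40

cs <- count_flies(sim$stack, window = 30)
validate_counts(data.frame(auto = cs$count, manual = sim$counts))
#> validation of automatic vs manual counts (120 images)
#>   within 1 of manual: 100.0%   within 3: 100.0%
#>   Pearson r = 1.000 (p = 0)
```

With `arrival_rate = 0.4` and `departure_rate = 0.2` the surface holds
0.4/0.2 = 2 flies on average at equilibrium; here every one of the 120
frames is counted exactly (at `noise_sd = 2` the flies, ~60 intensity units
darker than background, are far above the noise floor).

The packaged capture-count table (seven replicate days, three treatments)
reproduces the published capture analysis:

```r
tab <- read_capture_table(capture_counts_file())
summarize_captures(tab)
#> capture summary (mean +/- SD, n-1 denominator):
#>   released               1400.3 ± 307.8
#>   tml_trapped            324.1 ± 134.7
#>   tml_in_tub             34.7 ± 21.5
#>   ...

one_way_anova(log1_transform(tab$tml_in_tub),
              log1_transform(tab$tml_ddvp_in_tub))
#> F(1,12) = 6.73, p = 0.023  -- more dead flies under the DDVP trap
```

Trapped counts do not differ between TML and TML-DDVP (F₁,₁₂ = 0.43), but
in-tub counts do (F₁,₁₂ = 6.73, p = 0.023): the insecticide kills flies
before they enter the trap, lowering capture efficiency rather than
attraction.

A command-line front end with `simulate`, `detect`, `validate`, `stats`
and `all` subcommands is installed at `inst/cli/trapcam.R`:

```sh
Rscript "$(Rscript -e 'cat(system.file("cli/trapcam.R", package="trapcam"))')" \
    all --out runs/demo --seed 1
```

## Limitations

The simulator renders compact convex blobs on a static scene: it exercises
the pipeline's numerics exactly but not occlusion, wing posture, shadows or
camera compression artifacts, so validation metrics on synthetic data are
upper bounds on field performance. See the methods vignette
(`vignettes/trapcam-methods.Rmd`) for the full model description and design
rationale.
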