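---
title: "Methods: trap-camera detection and capture statistics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: trap-camera detection and capture statistics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

# The problem

A trap's usefulness in pest surveillance depends on two things that are easy
to conflate: *attraction* (how many insects it brings close) and *capture
efficiency* (the probability that an insect that has arrived is actually
caught). Adding a volatile insecticide such as DDVP to a trimedlure-baited
Jackson trap might raise efficiency (flies die inside) or lower it (flies
die *before* entering, or are repelled). Separating these effects requires
counting flies **on** the trap's surfaces — from time-lapse imagery — as
well as flies **in** the trap and dead beneath it.

`trapcam` implements the full analysis chain for such an experiment:
automatic detection of flies in trap-surface image sequences, validation of
the automatic counts, and the capture statistics. Because raw field imagery
for such studies is rarely published, the package also contains a simulator
that produces image sequences with exact ground truth and capture tables
with the right statistical structure; every pipeline stage is tested
against it.

# Detection pipeline

For frames $I_t$ (8-bit grayscale, nominally 640×480 at one frame per 6 s):

1. **Background model.** $B = \sum_t w_t I_t / \sum_t w_t$ over the first
   `window` frames (default 50). The default `linear` scheme uses
   $w_t \propto t$ — "linearly weighted" is ambiguous, and we resolve it
   toward the *latest* frame so the model adapts to illumination drift; a
   `uniform` scheme (plain mean) is the config alternative. The background
   is built once from a leading window by default; whether the original
   motivating tooling recomputed it over time is unknown, so a
   rolling-window mode (`rolling = TRUE` in `count_flies()`) is offered
   rather than guessed at.
2. **Subtraction.** $D_t = |I_t - B|$. The absolute value makes
   segmentation indifferent to contrast sign; the goal is "what changed",
   not "what darkened".
3. **8-bit conversion.** $D_t$ is linearly rescaled so its observed
   min/max span 0–255, rounding half-up (`floor(x + 0.5)`, not banker's
   rounding); a constant image maps to all zeros. The conversion is applied
   to the *difference* image by default; a config toggle
   (`convert = "frames"`) instead converts the raw frames before the
   background is built, since the original macro description leaves the
   order ambiguous.
4. **Threshold.** `otsu` (default) scans all 256 candidate thresholds $t$
   and maximises the between-class variance of the split
   $\{x < t\} \mid \{x \ge t\}$; ties resolve to the smallest $t$, and the
   mask is $x \ge t$. This is deterministic and parameter-free, which is
   why it is the default where the original threshold value is unstated. A
   constant image is flagged `degenerate` and yields an all-true or
   all-false mask, never an error (the area gate then discards the single
   giant component).
5. **Blobbing.** One binary opening then one closing with a square
   $3\times3$ structuring element (radius 1) — the smallest nontrivial
   element, since only "open and close" is known. Pixels beyond the frame
   count as background (plain set-arithmetic semantics; the implementation
   pads before calling EBImage's morphology, whose native border rule is
   replication). The open-then-close composition is a morphological filter
   and hence idempotent, which the tests check empirically.
6. **Particle analysis.** 8-connected components (the convention of the
   particle-analysis tools this emulates), intersected with an optional
   region of interest, kept when their area lies in the **closed** interval
   `[min_area, max_area]` = [150, 950] px by default ("150–950" read as
   inclusive). Coordinates are 0-based, row-major, origin top-left;
   bounding boxes half-open. Labeling is a 4-connected pass
   (`EBImage::bwlabel`) plus union-find merging of diagonally touching
   labels; an independent breadth-first flood fill serves as the test
   oracle.

Counts are per frame per surface, with no identity tracking across frames:
a fly that sits still for ten frames is ten sightings, exactly as in
per-image counting. `image_set_counts()` sums simultaneous surfaces of one
trap into per-image-set totals.

# Validation metrics

`validate_counts()` reports the fraction of images with
$|\text{auto} - \text{manual}| \le 1$ ("matched or off by one", inclusive)
and $\le 3$, plus the Pearson correlation pooled over all pairs — pooled,
not averaged over dates, because a single overall $r$ alongside per-date
values is the convention being reproduced — with per-group $r$ when a group
column is present. Zero-variance groups flag `degenerate` instead of
erroring. Significance uses $t = r\sqrt{(n-2)/(1-r^2)}$ with $n-2$ df;
$|r| = 1$ returns $p = 0$ flagged `exact`.

# Capture statistics

* **Transform.** Counts are transformed as $\ln(x+1)$ before ANOVA. The
  source analyses say only "log-transformed"; we compared $\ln x$,
  $\ln(x+1)$ and $\sqrt x$ pipelines on the packaged capture table and only
  the $+1$ offset reproduces all three published one-way F statistics
  (0.43, 6.73, 1.50) simultaneously — $\ln x$ gives 6.52 for the in-tub
  column. The offset also keeps zero counts defined. F is invariant to the
  log base (tested to 1e-10), so natural log is merely a convention.
* **Summaries.** Mean and sample SD with the $n-1$ denominator (required
  to reproduce the published SD row), full precision internally, one
  decimal in printed reports.
* **One-way ANOVA.** Standard between/within decomposition,
  $F_{1,\,n_a+n_b-2}$; equals the squared pooled two-sample $t$ (identity
  tested to 1e-10). Zero residual variance flags `degenerate` with
  $F = \infty$ (or NaN when there is also no between-group variance).
* **Two-way ANOVA.** Bait (3 levels) × surface (5 levels) with
  interaction on the per-replicate mean automatic count per image set
  (7×3×5 = 105 observations in the full design). Sequential (Type I) sums
  of squares are exact on balanced data; unbalanced data (e.g. missing
  camera-days, which is why a published residual df can fall short of the
  complete-design 90) can use marginal Type II SS via `ss_type =
  "marginal"` (`car::Anova`). The achieved df are always reported rather
  than forced.
* **Fisher LSD.** $\mathrm{LSD} = t_{1-\alpha/2,\,\nu}\sqrt{MS_e(1/n_i +
  1/n_j)}$ with the ANOVA residual mean square; unadjusted for
  multiplicity by convention, and identical to an unadjusted pooled
  $t$-test for two groups (tested).
* **KS normality.** $D = \sup|\hat F - \Phi_{\hat\mu,\hat\sigma}|$ against
  a normal with the observed mean and SD, p-value from the asymptotic
  Kolmogorov distribution without small-sample correction (the stated
  procedure of the analyses being reproduced); explicit reference
  parameters may be passed instead of the sample estimates.

p-values are reported but the package's own checks are built on the F and
D statistics; $\alpha$ defaults to 0.05 (0.001 is the convention for the
validation correlations).

# The simulator

`simulate_image_sequence()` renders what the pipeline assumes and nothing
more:

* **Background**: a fixed-seed smooth random field (Gaussian-blurred white
  noise, sd ≈ 12 intensity units around level 190), so background
  subtraction is exercised by real texture rather than a flat field.
  Flies are *darker* than background (default contrast 60/255), matching
  dark insects on pale trap cardboard.
* **Flies**: filled ellipses with aspect ratio in [1, 2.5] and uniform
  orientation, target area uniform over `fly_area_range` (default the
  150–950 px detection gate), re-drawn until the painted pixel count
  itself falls in the range — so the recorded ground-truth area is exact.
  Placement rejects positions whose padded bounding box touches another
  fly's (5 px pad) or the frame border; an arrival with no admissible
  position after 60 tries is skipped. The pad guarantees the 3×3 closing
  cannot bridge two flies into one particle.
* **Dynamics**: per surface, an independent birth–death chain — each
  resident fly departs with probability $d$ per frame, one fly arrives
  with probability $a$ — giving equilibrium mean occupancy $a/d$ and
  lag-1 autocorrelation $1-d$. `default_surface_rates()` calibrates
  $a$ (with $d = 0.2$) to the qualitative treatment pattern: summed
  occupancy ≈ 8.3 (TML), 4.15 (TML-DDVP), 0.76 (control) per image set,
  71% of TML sightings on the two internal panels, outer surfaces
  unaffected by DDVP. `simulate_occupancy()` exposes the chain alone for
  studying the dynamics at large frame counts without rendering.
* **Nuisance processes**: linear-in-time illumination drift of total
  amplitude `drift_amplitude` and i.i.d. Gaussian pixel noise
  (`noise_sd`); frames clip to [0, 255]. Defaults (drift 10, noise 2) are
  mild daylight drift and sensor noise for an inexpensive IP camera.
* **Warmup**: `warmup_frames` suppresses arrivals at the start,
  representing cameras that record before insects are released; aligning
  it with the background window gives the background model a fly-free
  scene, which is what makes *exact* count recovery a meaningful test.
* **Capture tables**: negative-binomial counts per treatment (defaults:
  the observed treatment means of the packaged table; dispersion 3, in the
  range implied by its variance-to-mean ratios), `total = trapped +
  in_tub` by construction. Poisson behaviour is recovered as dispersion
  → ∞ (tested).

**What the simulator does not emulate** — occlusion and merging of nearby
flies, wings/legs/shadows, perspective, compression artifacts, moving
vegetation, rain. Perfect recovery on synthetic stacks therefore verifies
the pipeline's *numerics*, not field accuracy; real-image validation
metrics will always be worse than the synthetic ones.

# Numerical choices and edge cases

* Rounding in the 8-bit conversion is half-up, not to-even.
* Otsu ties go to the smallest threshold; the degenerate (single-valued)
  histogram yields threshold 0 and a flag.
* The area gate is inclusive at both ends. The 3×3 opening trims rendered
  ellipse areas by 0–4 px (measured on random ellipses across the area
  range), so a blob whose true area sits within ~4 px of the lower gate
  edge may be trimmed across it. Exactness tests therefore simulate areas
  at least 20 px inside the gate ("blobs inside the gate"); the boundary
  behaviour is a property of any hard area gate, not a defect.
* `read_image_stack()` rounds `255 * value` on read, so 8-bit stacks
  round-trip bit-identically through PNG and multi-page TIFF.
* ROIs: rectangles are 0-based half-open; polygons rasterize by the
  even-odd rule at pixel centers; an empty ROI is an error.
* Degenerate statistics (constant responses, zero-variance groups,
  $|r|=1$) flag rather than throw throughout.

# Problem sizes in the test suite

The suite verifies exact recovery on a 500-frame 320×240 noiseless stack
and ≥95% frame-exact agreement at `noise_sd = 4` on 150 frames; labeling is
checked against the flood-fill oracle on 200 random 32×32 masks; the
capture ANOVA's type-I error is estimated from 1,000 null simulations at
the default table parameters (7 replicates, mean 34.7, dispersion 3); the
multi-surface pipeline demo runs 2–3 replicates of the 15 treatment ×
surface cells at 160×120–240×180 and 24–80 frames. These sizes make the
properties sharp (binomial/Monte-Carlo error well below the tolerances
asserted) while keeping the suite around a minute of CPU.

# Known limitations

* No fly tracking or re-identification: occupancy, not individuals, is
  counted (deliberately — the per-image convention).
* One arrival per frame per surface caps burst arrivals; at the calibrated
  rates the equilibrium approximation is unaffected, but very high
  occupancies (> ~10 flies on a small frame) will saturate placement.
* The two-way ANOVA assumes independent cells; date is a blocking factor
  in reality, and no mixed-effects variant is provided.
* Sex of flies is not modelled anywhere (field counts could not be sexed).
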