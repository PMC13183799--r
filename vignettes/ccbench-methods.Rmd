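---
title: "Human-aligned evaluation of color constancy models: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Human-aligned evaluation of color constancy models: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ccbench)
```

## The problem this package addresses

Computational color constancy models are usually scored against physical
ground truth: how accurately they recover the scene illuminant or the
surface reflectance. Human color constancy research asks a different
question: how stable does a surface *appear* when the illumination changes,
and which scene cues that stability depends on. The two criteria can
dissociate sharply — observers with excellent constancy are often poor at
reporting the illuminant — so a model that wins an illuminant-estimation
benchmark may still behave nothing like a human when individual cues (the
local surround of an object, the brightest patch in view, the scene's
spatial mean color) are selectively silenced.

`ccbench` provides the full apparatus for scoring *any* pixel-wise color
constancy model against human-style psychophysics on synthetic scenes:

1. a **synthetic scene generator** with diagonal (von Kries) image
   formation, per-pixel ground-truth reflectance, labeled competitor
   objects, a five-illuminant design, and four cue-silencing manipulations;
2. the five classical statistics-based **illuminant estimation algorithms**
   (gray world, white patch, shades of gray, gray edge, weighted gray
   edge) with diagonal white balancing;
3. a compact pixel-wise RGB-to-CIELAB **reflectance network** trained with
   a perceptually balanced color loss;
4. the **observer-side pipeline**: selection trials, paired-comparison
   choice matrices, an adapted maximum likelihood difference scaling
   (MLDS) fit, and the Color Constancy Index (CCI);
5. the **model-side task adaptation**: masked averaging of predicted
   reflectance, projection onto the constancy axis, nearest-competitor
   interpolation, and the model CCI;
6. **agreement metrics**: accuracy, bias, normalized error, Lin's
   concordance correlation (CCC), the leave-one-out inter-human agreement
   (LOO), and their ratio ncCCC.

## Image formation and the illuminant design

Scenes are flat-patch worlds rendered under a diagonal model: each pixel's
linear RGB is the surface reflectance multiplied channel-wise by the
illuminant gain, clipped to `[0, 1]`. This is deliberately the simplest
image formation under which every construct of the evaluation (tristimulus
match, white balance, reflectance prediction) is exactly defined; it omits
shadows, inter-reflections and specularities, so conclusions about models
that exploit those cues do not transfer.

Five illuminants follow the two-axis design: blue and yellow on the
daylight axis, red and green on the orthogonal axis, plus neutral. The
chromaticity coordinates of the original stimuli are not published, so the
default chromatic step is a design choice: each chromatic gain shifts a
reference gray (reflectance 0.4) by 20 CIELAB a\*b\* units — a strong but
displayable illuminant change, comparable to the spacing used in daylight
locus experiments. Yellow and green are exact mirrors of blue and red in
gain space, so the neutral gain is the centroid of the four chromatic
gains by construction. All of this is configurable through
`make_illuminant_set()`.

The CIELAB white point of the original apparatus is likewise unpublished;
the package defaults to the D65 2° white and exposes it as an argument
everywhere (`white_d65()`).

## Competitor construction and the Color Constancy Index

For an achromatic target under a test illuminant,
`make_competitor_set()` anchors the five competitor colors in the
*reflectance* CIELAB space (reflectances lit by the neutral illuminant):

* **R** — same reflectance as the target (perfect constancy, 100%);
* **T** — the surface whose reflected light under the test illuminant
  equals the target's light under neutral (zero constancy, 0%);
* **S1, S2** — thirds of the R–T segment (S1 nearer R);
* **O** — one third-step beyond R, away from T (over-constancy).

The five Lab points are exactly collinear on the uniform grid T = 0,
S2 = 1, S1 = 2, R = 3, O = 4 (in S-steps); O's distance is a design choice
(the original description fixes equal S spacing but not O), placed one
S-step past R to keep the grid uniform. The index is
`CCI = 100 * |T - Match| / |T - R|` with Euclidean CIELAB distances, so a
match at O scores 133.33%. Under the neutral illuminant T and R coincide
and the index is undefined; the set carries a `degenerate` flag and
`compute_cci()` returns `NA` with a warning.

## Cue-silencing manipulations

`apply_manipulation()` implements the four silencing conditions:

* **local_surround** — the leaf under the target is frozen at its
  neutral-illuminant rendering, removing the target-surround edge as an
  illuminant cue. In experiment 1 the silenced condition uses the default
  rose leaf (the baseline has no leaf); in experiment 2 every condition
  has a leaf of the tested surround color.
* **maximum_flux** — the bright achromatic patch is frozen at its
  neutral rendering. The patch reflectance (0.62) is the highest surface
  reflectance in any scene, chosen so it never clips under the strongest
  chromatic gain — clipping would silently neutralize its chromaticity.
* **spatial_mean_add** — colored disks are inserted whose shared rendered
  color is *solved*, using the linearity of the spatial mean in RGB, so
  the post-manipulation scene mean lands at the mirror image (about the
  scene's neutral-illuminant mean) of its current mean — i.e., on the
  opposite side of neutral from the illuminant. Where that mirror color
  is outside the display gamut the color saturates at the gamut boundary
  and the step is as large as displayable. Reaching the opposite side
  requires substantial coverage (the default 20 disks cover roughly half
  the background, much like the original scenes filled with floating
  colored spheres).
* **spatial_mean_change** — background and texture reflectances are
  rescaled channel-wise by `(neutral gain / illuminant gain)^2`, so the
  rendered background sits mirrored about its neutral rendering.

Each manipulation touches only its designated cue: the competitor patches
and their masks are never altered, which is what makes the oracle agent's
CCI exactly 100 in every cell.

## Classical algorithms

The five statistics-based estimators share a common contract: a unit-L2
illuminant direction plus a degenerate flag, with pixels at the clip
ceiling excluded from the statistics (clipping corrupts both mean- and
max-based estimates). The original comparison used a standard toolbox
without printing parameters, so the defaults follow the methods'
literature conventions and are all configurable: shades-of-gray Minkowski
order p = 6; gray edge first-order Gaussian derivatives with sigma = 1
and p = 1; weighted gray edge with weight exponent 2 on the normalized
gradient magnitude. `white_balance()` divides by the estimate and
re-anchors the mean luminance, so a surface matching the estimate maps to
neutral. A spatially constant image has no edges; the edge-based
estimators return a flagged degenerate estimate rather than silently
falling back.

## The reflectance network and its loss

The evaluated contract is pixel-wise Lab reflectance prediction, not a
specific backbone, and full-scale pre-trained encoders are far outside a
desk-scale budget. The package therefore uses a compact encoder–decoder:
a global context encoder average-pools the image to an 8×8 grid and maps
its log values through a small MLP to a scene code (in a diagonal world
the code must carry the illuminant); the per-pixel decoder maps each
pixel's log-RGB, concatenated with the code (an input skip connection),
to Lab. Training is hand-rolled mini-batch Adam; "pre-training" is
emulated by training all parameters on synthetic baseline scenes, after
which `trainable = "decoder_only"` freezes every encoder parameter
bit-exactly for condition-specific fine-tuning.

The loss is the perceptually balanced color objective

\[
L = \lambda_1\,\overline{\Delta E_{00}}
  + \lambda_2\,\overline{\omega\,[(a^p-a^{gt})^2 + (b^p-b^{gt})^2]}
  + \lambda_3\,\overline{(L^p-L^{gt})^2},
\qquad \omega = 1 + \beta\,(C^{gt}/128)^\gamma,
\]

with defaults \(\lambda_1 = 1, \lambda_2 = 0.5, \lambda_3 = 0.2,
\beta = \gamma = 2\); each term is averaged independently over all pixels
of the mini-batch. The chroma weight counters the achromatic skew of
natural pixel statistics that lets plain MSE favor desaturated outputs.
The squared terms are differentiated analytically; the CIEDE2000 term by
forward finite differences on the predicted Lab (step 1e-3, one
vectorized evaluation per channel) — exact enough everywhere except at
the non-differentiable zero-error point, where the squared terms dominate
anyway.

Default problem sizes (all configurable): 64×64 scenes, 16 layout
variations × 2 palettes × 5 illuminants = 160 training images, 60 epochs
of Adam at learning rate 3e-3 with 256 pixels sampled per image — about
20 seconds on one CPU, reaching mean per-pixel CIEDE2000 errors several
times below the raw-image (no-constancy) baseline.

## The observer pipeline and the scaling model

A synthetic observer holds an internal match on the competitors'
perceptual axis. Trials present competitors in round-robin pairs (so
every cell of the paired-comparison matrix is directly observed), each
selection is credited as a win over every other presented competitor, and
`fit_mlds()` maximizes the comparison likelihood under the adapted
difference-scaling constraints: T fixed at 0, noise SD fixed at 0.1,
competitor order preserved with minimum gap 0.025, the match a free
parameter confined to the competitor span. Optimization is multistart
L-BFGS-B on (match fraction, gaps), 12 restarts including one empirical
start at the most-chosen competitor.

**Choice of noise model.** Two Gaussian comparison models are
implemented. The default puts the noise on each competitor's perceptual
*distance* to the match, giving the canonical difference-scaling
likelihood `P(i beats j) = pnorm((d_j - d_i) / (sd * sqrt(2)))`. The
alternative (`noise_model = "position"`) perturbs the competitor
positions themselves and picks the noisy position closest to the match;
its exact win probability has a closed form, but folding away the sign of
the position error leaves the likelihood with a near-flat ridge along
which the match trades against its neighboring gaps. We verified this
directly: under the position model the global maximum-likelihood fit
overtakes the generating truth with very different gap structures even at
20,000 trials, and the recovery error does not shrink with the trial
count. The distance model is identifiable (all pairwise distance
differences pin the gaps, and the cross-side differences pin the match)
and is therefore the default on both the simulation and fitting side.

**What recovery is possible at the study's scale.** At 150 paired trials
per fit — the original experiments' order of magnitude — the recovery
study (`mlds_recovery_study()`, 20 synthetic observers spanning CCI 0 to
130%) shows a median absolute CCI error of about 3–6 percentage points
depending on the harness seed, with occasional individual errors of
15–20 points. This is the information limit of the design, not an
optimizer failure (fitted likelihoods dominate the truth's), and it is
consistent with the intra-individual variability reported for human
observers in this paradigm. Within-package simulations that need tighter
CCIs should raise the trial count.

The synthetic observer *pool* used by the experiment runners samples each
participant's condition-level CCI directly (baseline level, mechanism
effects, noise) by default, with an optional full trials→MLDS route; the
default mechanism effects reproduce the characteristic human ordering —
spatial-mean reflectance changes most damaging, maximum flux least.

## The model-side match

For each condition cell the model sees every competitor at every
placement; predictions are pooled by `average_masked()` (pixel-weighted
mean over all masked appearances), projected onto the line through R and
T, and the two competitors whose projections land closest to R are
interpolated with inverse-distance weights (closer projection → larger
weight) between their *original* Lab values. Exact ties in projected
distance are broken by increasing designed distance from R
(R, S1, S2, T, O); a zero distance selects that competitor's color
exactly. The resulting Match always lies on the segment between the two
selected competitors; matches that would fall beyond O are flagged.
Classical algorithms are scored through the identical pipeline by
treating the white-balanced image's Lab values as the predicted
reflectance map.

## Agreement metrics

Lin's CCC uses population (1/n) moments, the concordance literature's
convention; the normalized error divides the model-human RMSE by the
sample (n−1) SD of the human mean. Both conventions are switchable. The
leave-one-out agreement averages, over participants, the CCC between a
participant's CCI vector and the mean of the others over the conditions
that participant completed — participants only score their own scene, so
the human mean per condition is taken over the participants who completed
it. ncCCC divides the model-human CCC by this LOO ceiling; values above 1
mean the model tracks the mean human better than individuals agree with
each other.

## What the synthetic generator does and does not show

The generator reproduces the *structure* of the original stimuli — five
illuminants on two symmetric chromatic axes, five collinear equally
spaced competitors, multiple target placements, colored surrounds on the
axis diagonals, and four selective cue manipulations — under an exactly
diagonal rendering model with flat matte patches. It does not reproduce
photometric complexity: no shadows, no inter-reflections, no specular
highlights, no 3-D geometry, no spectral rendering. Passing the
end-to-end checks therefore demonstrates that an evaluation pipeline or a
model behaves correctly under the idealized cue structure; it does not
certify performance on rendered or natural images, where cue conflicts
and photometric noise are the interesting part.

## Numerical choices

All color math is double precision. XYZ↔Lab round-trips to 1e-9 on the
gamut interior; CIEDE2000 implements the full formula including the
hue-rotation term and reproduces the canonical verification pairs to
1e-4. Rendered values are clipped to `[0, 1]` with a warning when
clipping touches a labeled region. Estimator degeneracies (all-zero
images, edgeless images, zero-variance vectors, single-participant
pools, neutral-illuminant competitor sets) are flagged or rejected, never
silently patched. Every stochastic component takes an explicit integer
seed and restores the caller's RNG state.
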