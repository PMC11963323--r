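---
title: "Placebo color matching: model, design choices and limitations"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Placebo color matching: model, design choices and limitations}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
library(placebocolor)
```

## The problem and the model

Granule placebos for blinded trials must visually match the active granules.
`placebocolor` inverts color to formulation: from a powder's mean RGB it
predicts the doses of caramel, lemon yellow, carmine and indigo (mg per
20.00 g lactose/dextrin excipient batch) that reproduce that color.

A single global regression struggles because granule colors form distinct
light and dark populations whose color-to-dose relationships differ. The
model is therefore a two-stage hierarchy:

1. **Standardization.** Each RGB channel is z-scored with training-set mean
   and SD (sample SD, $n-1$ denominator; the choice is recorded in the model
   metadata). Query colors always reuse the *training* statistics — refitting
   the scaler on new data would silently shift the feature space.
2. **Clustering.** k-means (Euclidean distance in standardized RGB) is fit
   for every $k$ in 2–11. Two diagnostics are recorded per $k$: the
   within-cluster sum of squares $SSE = \sum_i d(x_i, u_{c(i)})^2$ and the
   mean silhouette $S = (b-a)/\max(a,b)$. The chosen $k$ is the silhouette
   argmax (ties to the smaller $k$); the SSE elbow (largest second
   difference) is reported as advisory output only. The two criteria are
   examined jointly, but a reproducible pipeline needs a deterministic rule,
   and on both simulated libraries and the motivating application the
   silhouette peak and the elbow coincide at $k = 2$.
3. **Per-cluster regression competition.** Within each cluster, five families
   compete: ordinary least squares, ridge, RBF support-vector regression,
   random forest, gradient boosting. Features are the standardized channels
   (same scaler as clustering); targets are the four pigment doses, one
   estimator per pigment. Scores are the macro-averaged RMSE and $R^2$
   described below; the family with minimal mean RMSE wins the cluster
   (ties: higher $R^2$, then a fixed family order) and is refit on the full
   cluster.
4. **Prediction.** standardize → nearest-centroid cluster assignment (ties to
   the lowest centroid index) → per-pigment prediction → negative doses
   clamped to 0 → rounding to 0.01 mg (manufacturing precision) → excipient
   fixed at 20.00 g.

## Cross-validation and scoring choices

*Repeated k-fold.* 5 folds, 3 repeats (the repeat count is a package choice:
three redraws stabilize the fold-partition noise at modest cost), all
partitions derived from the run seed, so every competition is exactly
reproducible.

*Grid search.* Hyperparameters are selected by out-of-fold RMSE on the first
fold partition; the selected configuration is then scored on all repeats.
Nothing in the design requires nested CV here: the competition compares
families against each other on a common protocol rather than estimating
absolute generalization error, and the final arbiter of pipeline quality is
a genuinely held-out query set.

*Macro-averaged scores.* RMSE and $R^2$ are computed per repeat from the
pooled out-of-fold predictions, per pigment, then averaged over pigments and
repeats. Pooling before scoring keeps $R^2$ defined even when a near-constant
target (indigo) is constant inside a single fold. Averaging over pigments
mirrors the one-score-per-cluster-model reporting convention; the per-pigment
breakdown is always retained in the CV table because indigo's near-zero doses
make its $R^2$ fragile and that should be visible, not averaged away.

*SVR scale convention.* `e1071::svm` rescales the response by default, which
would make a grid of `cost`/`epsilon` values dimensionless. The package fits
SVR on the raw mg scale (`scale = FALSE`) so the grid (C in {1, 10, 100},
epsilon in {0.1, 1} mg) has physical meaning. A target that fits entirely
inside the epsilon tube leaves no support vectors; that degenerate fit falls
back to the training-mean predictor.

*Default grids.* RF: 100/300 trees, depth unlimited/5/10, min node 1/3;
GB: 100/300 rounds, learning rate 0.05/0.1, depth 2/3; ridge penalty 0.1/1/10.
All overridable via the `grids` argument.

## Color difference and similarity

RGB is converted to CIELAB assuming sRGB companding and the D65 2° observer —
the de facto convention for industrial camera RGB; the conversion's white
point is taken as the image of (1,1,1) so white maps to exactly
$(L, a, b) = (100, 0, 0)$. $\Delta E$ is the CIE76 Euclidean distance in Lab.
Perceptibility bands use the textile/dyeing thresholds 1, 3, 6, 9, 12,
implemented half-open $[l, u)$ so every non-negative value falls in exactly
one band; the separate count "$\Delta E \le 3$" is its own threshold and uses
$\le$ as stated. When an evaluation table supplies measured Lab values
alongside RGB, the supplied Lab is authoritative — this decouples similarity
evaluation from any conversion convention. Cosine similarity is computed on
the raw RGB vectors (not Lab), pairing an intensity-insensitive hue criterion
with the intensity-sensitive $\Delta E$.

## Channel attribution

With only three features, Shapley values are computed exactly by enumerating
all $2^3$ coalitions with the classical weights — no sampling variance. The
value of a coalition is interventional: the mean prediction over background
rows with the coalition's channels replaced by the query's. The training
cluster serves as background, capped at a seeded subsample of 200 rows for
speed. Interventional rather than conditional values were chosen because they
are reproducible without a density model and are the standard practice for
tree-model explanation. The efficiency identity
$\phi_R + \phi_G + \phi_B = f(x) - E_{bg}[f]$ holds to numerical precision on
every sample and is asserted in the tests.

## The forward simulator and what it does (not) show

`simulate_granules()` draws pigment formulas and renders them with
Beer–Lambert-style subtractive mixing,
$c = \mathrm{base}_c \exp(-\sum_j K_{cj} d_j) + \varepsilon$, clipped to
[0, 255], with Gaussian measurement noise (default SD 2 channel units).
Exponential attenuation is bounded, strictly monotone in every dose, and
curved enough to be a nontrivial inverse problem.

The dose design is two-regime: a light population (caramel 0–200 mg, modest
co-pigments) and a dark one (caramel 200–800 mg, lemon yellow up to 155 mg,
carmine up to 265 mg), indigo below 1 mg and zero for 70% of samples. The
regime split gives the library the two-population structure that makes
$k = 2$ the correct clustering answer; the marginal dose ranges span the
published formulation table.

The attenuation matrix `default_attenuation()` was calibrated once, during
design, against three requirements, then frozen: (i) generated RGB minima and
maxima land near the published simulated-granule spans (R 63–255, G 54–255,
B 32–255); (ii) the light/dark populations separate cleanly (silhouette
$\ge 0.5$ at $k = 2$); (iii) the three major pigments are structurally
identifiable from three channels. Requirement (iii) drove two choices worth
recording. Indigo's per-mg attenuation is strong but bounded (0.08 on R):
an intense dye at sub-mg doses, yet small enough that its unmodeled 0–1 mg
variation does not confound caramel and carmine — with four pigments and
three channels the system is only identifiable because indigo's contribution
is minor. And caramel's and carmine's G-channel coefficients were set to keep
their spectral signatures distinguishable (caramel R-and-B-heavy, carmine
G-dominant) at unchanged total G-span. Directionally, caramel attenuates
B > G > R (brown), lemon yellow attenuates B, carmine attenuates G, indigo
R > G — so the channel-dominance attribution (caramel ← R, lemon ← B,
carmine ← G) matches pigment optics.

What passing the simulator-based tests shows: the pipeline recovers doses it
can in principle recover (held-out $R^2 \ge 0.85$ for caramel, lemon yellow,
carmine; indigo is near-constant and exempt), and its predicted recipes
re-render to within $\Delta E < 6$ of the query color for over 90% of
held-out queries. What it does not show: performance on real powders, whose
reflectance physics (scattering, particle size, gamma), dose designs and
measurement errors are richer than the simulator. One concrete consequence:
on real granule data the random-forest family reportedly dominates the
competition, while under this smooth low-dimensional simulator the
kernel/linear families tend to win — the competition machinery is identical,
but the winner is a property of the data-generating process, and the
simulator's is smoother than reality.

## Numerical and degenerate-input conventions

- k-means: `stats::kmeans` (Hartigan–Wong) with 10 seeded restarts, 300 max
  iterations; best restart by SSE. When the number of distinct points is at
  most $k$, the exact optimum (one centroid per distinct point) is
  constructed directly instead of iterating.
- Silhouette: singleton clusters score 0; a single cluster is an error; an
  all-singleton clustering scores 0.
- $R^2$ of a constant observed vector is an error at the API surface and NA
  inside CV aggregation (reported, excluded from means).
- Fold counts reduce automatically (with a warning) when a cluster has fewer
  than $2 \times$ folds samples.
- Rounding for display is half-up at 4 decimals, matching how similarity
  tables are conventionally printed; full precision is retained internally.
- Paired sensory scores: identical vectors give $t = 0, p = 1$; a constant
  nonzero difference (zero variance) is a degenerate-test error.
- Whiteboard calibration multiplies each channel by 255 / whiteboard and
  clips to [0, 255]; it is applied before ROI averaging. Pixel membership in
  the circular ROI uses pixel centers with a $\le$ comparison.

## Problem sizes

The packaged defaults are the study conditions: a 323-sample library, k
scanned over 2–11, 5-fold CV with 3 repeats, 50 held-out queries. The unit
tests exercise the same code paths on smaller libraries (60–120 samples) with
reduced grids; the acceptance checks run the full defaults.

## Known limitations

- Three channels bound what is identifiable: a fourth independent pigment
  dimension (indigo) is recoverable only weakly, and only because its doses
  are small. Richer color spaces (HSV, CMYK, spectral) are out of scope.
- The CIE76 $\Delta E$ is used throughout; CIEDE2000 and CMC differences are
  deliberately not implemented.
- The imaging module averages a caller-supplied circular region; container
  detection is upstream of the package.
- Model archives store fitted estimators via R serialization alongside the
  JSON manifest; archives are not portable across major versions of the
  underlying learners.
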