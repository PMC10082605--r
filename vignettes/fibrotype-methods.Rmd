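---
title: "Methods: fiber morphometry, texture, MRMR ranking, and classification"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: fiber morphometry, texture, MRMR ranking, and classification}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
library(fibrotype)
```

`fibrotype` classifies skin tissue regions — normal, keloid scar, and
scar-adjacent — from paired label-free multiphoton images: a collagen
channel (second harmonic generation, SHG) and an elastin channel
(two-photon excited fluorescence, TPEF). This vignette is the package's own
account of the science: the measurement model behind each of the 28
features, the feature-selection and classification procedure, what the
synthetic cohort simulator does and does not emulate, and the numerical
choices made where the design was genuinely open.

## Pipeline overview

For each imaged region (one collagen + one elastin image) the pipeline
computes 14 features per channel; the 2–3 regions of a tissue sample are
averaged into one 28-entry feature vector. Feature vectors are ranked by
minimum-redundancy maximum-relevance (MRMR), nested subsets
S₁ ⊂ S₂ ⊂ … ⊂ S₂₈ are built from the ranking, each subset is scored by
repeated leave-one-out (LOO) cross-validation of a linear stochastic
gradient-descent (SGD) classifier, and the best subset is evaluated with
one-vs-rest ROC/AUC.

## Denoising

Photon-counting microscopy images carry shot noise; a 3×3 median filter
(edge-replicated borders) is the conventional remover and is the default
first stage. No specific denoising algorithm is canonical for this imaging
modality, so the filter is configuration, not dogma: `denoise_window` can be
widened or set to `"none"`. The filter never changes image dimensions or
bit depth, is idempotent on constant images, and keeps values inside the
input range.

## Morphological features

**Density** is the fraction of "effective" (foreground) pixels. Effective is
operationalised with Otsu's threshold on the integer gray-level histogram —
parameter-free and standard for the bimodal histograms of fluorescence
images. Zero-variance images have no foreground and report density 0.

**Alignment** quantifies how concentrated fiber orientations are. The 2-D
FFT power spectrum of the mean-subtracted image is band-passed (an inner
disk of radius 4 cycles/image removes DC and slow illumination gradients;
frequencies above 0.8 of the Nyquist radius are dropped because the corners
of the square spectrum sample directions anisotropically), summed radially
into 180 one-degree bins, rotated by 90° so spectral angle maps to
real-space fiber angle, and normalised to unit mass. A semicircular von
Mises density

f(θ; μ, k) = exp(k·cos 2(θ − μ)) / (π·I₀(k))

is then fitted by least squares on the binned distribution. Orientations
live on a half circle (θ and θ+180° are the same fiber direction), hence
the doubled angle inside the cosine. Larger k means more aligned fibers;
k = 0 is isotropy. The fit is initialised from circular moments of the
doubled angles (mean resultant direction for μ; Fisher's A⁻¹ approximation
for k) and refined with bounded L-BFGS-B, k constrained to [0, 500]. If
refinement fails or does not improve on the moment estimate, the moment
estimate is returned. Tabulating the closed-form density on the 180 bins
and re-fitting recovers (μ, k) to within (1°, 0.05) — this is asserted in
the test suite.

**Width and length** come from per-fiber tracing. The published analyses in
this field use a curvelet-transform fiber extractor (CT-FIRE), an external
MATLAB tool; `fibrotype` deliberately replaces it with a transparent,
testable stand-in that preserves the measured quantities: Otsu foreground
mask → Zhang–Suen skeletonisation → removal of branch points (skeleton
pixels with more than two neighbours) → tracing of the remaining
8-connected segments → discarding segments shorter than `min_length_px`
(default 10). Length is the geodesic path length (1 per axial step, √2 per
diagonal, plus 1 for the pixel itself). Width is derived from the Euclidean
distance transform of the mask sampled along the path: a slab of width w
has centreline distance (w+1)/2, so width = 2·(mean distance) − 1. On a
rendered bar of known geometry the tracer recovers length and width to
within a few percent. In dense fiber mats, crossings create branch points
and fragment the traced segments, so absolute lengths underestimate true
fiber lengths; the feature remains informative because fragmentation
affects all classes and the *relative* ordering (scar fibers shorter than
normal) survives — the same caveat applies to curvelet-based extraction.

## Texture features

**Histogram statistics** (first-order, position-blind) over the normalized
gray-level histogram p(zᵢ) with L = 2^bit_depth levels: mean, standard
deviation σ, smoothness R = 1 − 1/(1 + (σ/(L−1))²) (dividing σ by L−1 keeps
R in [0,1) for any bit depth), standardised skewness (0 when σ = 0),
uniformity Σp², and entropy −Σ p log₂ p in bits.

**Co-occurrence statistics** (second-order, position-sensitive): pixel
values are linearly quantized to 8 gray levels (few levels keep the
co-occurrence estimates stable and match common practice);
symmetric pair counts are accumulated for the four unit-distance directions
(0°, 45°, 90°, 135°), each with its opposite offset; matrices are *summed
over directions before normalisation* (whether to average matrices or
per-direction features is a genuinely open convention — summing first is
fixed and documented here). From the normalised table p(i,j): contrast
Σ(i−j)²p, correlation Σ(i−μᵢ)(j−μⱼ)p/(σᵢσⱼ) (defined as 1 when a marginal
is degenerate), energy Σp², homogeneity Σp/(1+|i−j|). The exact formula
sheet for the original feature set is not published in the main text; the
standard Gonzalez–Woods / Haralick definitions above are adopted and every
one is cross-checked in the tests against brute-force per-pixel or
double-sum recomputation. Entropy is permutation-invariant while contrast
is not — the two families capture complementary information, which is the
reason both are included.

## Feature table

The canonical order is all collagen features then all elastin features,
morphology → histogram → co-occurrence within a channel, names prefixed
`C_` / `E_`. Region vectors are averaged per sample (arithmetic mean,
order-invariant). Any non-finite feature aborts the run naming the sample:
silent imputation would corrupt the mutual-information ranking downstream.
Group differences for single features use the two-sided Mann–Whitney test,
exact for combined n ≤ 20 without ties, tie-corrected normal approximation
otherwise. No multiple-testing correction is applied across the 28
features; per-feature p-values are descriptive here, the inferential claim
is carried by the classifier evaluation.

## MRMR ranking

Mutual information between continuous features cannot be density-estimated
from ~34 samples, so features are discretized into at most 4
equal-frequency bins (empirical quartiles; duplicate edges merged, constant
features collapse to one bin and carry zero information) and plug-in MI in
bits is computed on the empirical joint tables. The ranking is the greedy
incremental rule: first the feature with maximal relevance I(x; c) to the
class label; thereafter the feature maximizing relevance minus mean
redundancy with the already-selected set (the difference/"MID" form; the
quotient variant is not implemented). Plug-in MI on small discrete tables
produces exact ties regularly, so objectives are rounded at 1e-10 before
the argmax and ties break toward the canonical feature order — rankings are
fully reproducible. The test suite checks the greedy ranking against an
independent brute-force re-evaluation of the objective at every step on 100
random tables, and that a single planted signal feature is ranked first in
≥95 of 100 replicates.

Because the MI estimator, bin count, and MID-vs-MIQ choice for the original
clinical analysis are unpublished, the *procedure* — not any particular
published rank order — is the reproduction target.

## Classifier and evaluation

The final model is a linear one-vs-rest SGD classifier with modified-huber
loss, elastic-net penalty (strength α = 0.001), constant learning rate
η₀ = 0.01, and fitted intercepts. This configuration is the end product of
a genetic-programming AutoML model search (TPOT); re-running such a search
is out of scope by design — its value was model selection, which is already
resolved — so `fibrotype` trains the selected model directly, and a config
hook allows swapping in any classifier implementing the train/score
contract. Three settings
the hyperparameter table leaves open or inert: the elastic-net mixing
`l1_ratio` is unstated and defaults to the conventional 0.15; `power_t`
only affects inverse-scaling learning-rate schedules and is stored but
unused under the constant schedule; the epoch count defaults to 300 passes,
ample for n ≈ 34 at this learning rate. Features are z-score standardized
per training fold — SGD with a constant learning rate is scale-sensitive,
and the fold-wise recomputation guarantees the held-out sample never
influences its own fold's statistics or weights (asserted in the tests by
perturbing a held-out sample and checking fold weights are bit-identical).

Evaluation is leave-one-out: n folds, one held-out sample each — the
deterministic, data-efficient choice for small cohorts. Held-out class
probabilities (modified-huber's clipped linear mapping to [0,1],
renormalized across classes) are retained; each subset of the incremental
sweep is evaluated `repeats = 5` times under distinct derived seeds and
averaged, and the best subset size is the smallest one attaining the
maximum mean accuracy (parsimony tie-break). One-vs-rest ROC curves are
built by threshold sweep over the observed held-out scores with AUC by
trapezoidal integration, which equals the rank-based Mann–Whitney statistic
under the standard midrank tie convention (asserted exactly in the tests).

## The synthetic cohort

The simulator exists so that every stage is testable without clinical
images, which cannot be redistributed. `cohort_design()` defaults mirror
the study design: 16 scar and 10 normal tissue sections plus adjacent
regions from 8 scar specimens (34 samples), 2–3 imaged regions per sample,
512×512 8-bit images. Fibers are anti-aliased thick polylines (3 control
points, small random bow) with orientations drawn from the semicircular von
Mises law via the doubled-angle construction (Best–Fisher rejection
sampling on the full circle, halved) — the same law the alignment fit
assumes. Intensities are Gaussian per fiber; background is a constant
offset plus Gaussian noise; everything is quantized to the integer gray
range.

No quantitative per-class fiber geometry is published for this system, so
the presets are calibrated only to the qualitative class contrasts
described for the three tissue types, chosen once as a realistic desk-scale
phantom and held fixed: fiber length normal > adjacent > scar, orientation
concentration adjacent (k≈8–9) > normal (k≈2) > scar (k≈0.5–0.6), and a
weaker, more fragmented elastin signal in scar. Each region draws its own
preferred orientation uniformly on [0,180), shared by its two channels —
classes differ in how *concentrated* orientations are, not in absolute
direction, which matches how alignment functions as a feature in real
sections. Seeds derive from the master seed through a fixed
counter scheme (sample → region → channel), so cohorts are bit-reproducible
and streams are independent.

What the simulator does not emulate: SHG/TPEF image formation physics,
optical sectioning, cells and nuclei, spatially varying background,
fiber bundling and curvature distributions of real dermis, and
inter-patient variability beyond seed-to-seed geometry noise. Consequently,
passing tests demonstrate that the *computational chain* is correct and
that the classifier recovers class structure when the assumed contrasts are
present — they do not certify clinical performance. On the default
synthetic cohort the classes separate essentially perfectly (LOO accuracy
1.0, AUCs 1.0, and a best subset size of 1); the published clinical
figures (96.15% accuracy, AUC 1.0/1.0/0.99, best subset of 23 features) sit
below or above these values precisely because real tissue is noisier and
more entangled than the phantom, and they are not reproduction targets
here.

For the end-to-end alignment validation the tests use a metrological
phantom rather than the class presets: many long, thin, non-overlapping
fibers and zero background noise, the regime where the FFT orientation
distribution is an (approximately) unbiased estimate of the angular law.
There, the median fitted k over 10 seeds recovers generating
k ∈ {1, 2, 4, 8} within a few percent (tested at a 25% tolerance,
monotone in k). Dense mats bias fitted k downward — crossings add
high-frequency power at all angles — which is another reason class presets
are compared to each other, never to their nominal k.

## Problem sizes in the tests

The unit suite runs on reduced cohorts (4+4+3 samples, 128 px images,
geometry scaled with the field of view) chosen to exercise every code path
at interactive speed; the acceptance-style checks additionally run the full
default design (34 samples at 512 px) once and share it across assertions.
`scripts/acceptance.R` always runs the full default design from scratch.

## Degenerate inputs and edge policies

* Constant images: density 0, alignment k 0, no traced fibers, entropy 0,
  uniformity/energy/homogeneity 1, skewness 0, correlation 1.
* Empty foreground after thresholding: empty fiber list, width/length 0 —
  not an error.
* Non-square images are rejected by the orientation analysis (pad or crop
  upstream) rather than silently cropped.
* Orientation distribution of an all-flat spectrum falls back to uniform.
* A training fold containing a single class aborts; a class missing from a
  fold's training data contributes probability 0 for that fold.
* Constant features standardize with unit scale and discretize into one
  bin (zero MI) instead of producing NaNs.

## Known limitations

* Traced fiber length is fragmentation-limited in dense mats (see above).
* Plug-in MI on 4 bins with 34 samples is biased upward for independent
  pairs; the bias is shared across candidates and largely cancels in the
  ranking, but relevance values should be read comparatively, not as
  calibrated information measures.
* The SGD probability mapping is a clipped linear surrogate, not a
  calibrated posterior; it is used only to order samples for ROC analysis
  and to pick the argmax class.
* With 34 samples, LOO accuracy has a standard error of roughly 0.06 near
  accuracy 0.9; differences of one or two correct samples between subset
  sizes are within noise, which is why the sweep averages repeated runs and
  ties break toward smaller subsets.
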