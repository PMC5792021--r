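---
title: "Methods: multi-view CNN ensembles for specimen identification"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: multi-view CNN ensembles for specimen identification}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem and the pipeline

Taxonomic image collections attach a genus label to a *specimen*, which is
photographed in up to three standard views: head, dorsum and profile. Two
learning tasks follow: classify a single picture from any view (type 1),
and classify a specimen given one picture per view (type 2). `triview`
implements the full pipeline for both: dataset handling and splitting,
three CNN training regimes, top-t evaluation, pairwise diversity analysis,
and score-sum fusion of the single-view classifiers into type-2 ensembles.

The package's working assumptions are those of the multi-view setting:
views share label-relevant content (consensus) while each view also carries
discriminative detail the others lack (complementarity). The training
regimes probe exactly this decomposition — the general model pools all
views, the specific models isolate one view each, and the transfer models
interpolate by fine-tuning the general weights on one view.

## Dataset model and split

A dataset holds one record per specimen: a genus in `1..L` and per-view
picture lists with cardinalities `N_h`, `N_d`, `N_p`. The split allocates
fractions (default 0.7 / 0.2 / 0.1) of the specimens per genus
(stratified, largest-remainder rounding — deterministic and exact), with
the constraint that validation and test draw only from specimens with
exactly one picture per view; everything else, including specimens with
extra or missing pictures, stays in training. Design choices made where
the procedure was genuinely open:

* *Fractions apply to specimens, not pictures* — the eligibility
  constraint is itself specimen-level, and the specimen is the type-2
  sample.
* *Stratification by genus* guarantees every retained genus can appear in
  every part; a genus with too few eligible specimens under-fills its
  validation/test quota with a warning rather than failing.
* *Specimens with several pictures in a view contribute all of them to
  training*; only validation and test are restricted.
* Labels are re-indexed to a contiguous `1..L` after support filtering,
  with the old-to-new map kept on the result (`attr(ds, "label_map")`)
  and written to the manifest sidecar.

Color inputs are converted by Rec. 601 luminance weighting, padded to a
square with zeros and bilinearly resized to the configured input side.
PNG round trips quantise intensities to 8 bits (max error 1/255 ≈ 0.004),
which is far below the generator's default noise level.

## The synthetic generator

The generator emulates the *statistical structure* the method assumes, not
the appearance of real specimens. Every genus archetype has

* shared body parameters (ellipse axes 0.25–0.70 in image-half-side units,
  orientation, intensity 0.45–0.80) visible in all three views, and
* per-view parameters (texture frequency 1.5–5 cycles per image,
  orientation, phase, amplitude 0.25–0.45, plus a marking spot with
  position and radius 0.10–0.22),

rendered as a soft-edged ellipse carrying a masked sinusoidal grating and
a Gaussian spot. The per-view content is scaled by a `view_informativeness`
factor in `[0, 1]` (default head 1.0, dorsum 0.6, profile 0.8 — head views
are the most informative in real collections, dorsal the noisiest).
Archetypes are drawn by rejection until all pairwise distances in
range-normalised parameter space reach 0.8, so genera are separable by
construction. Each picture adds uniform pose jitter (default ±0.05 rad
rotation, ±3% translation) and additive Gaussian pixel noise
(`noise_sd`, default 0.05 in intensity units), clipped to `[0, 1]`.

Defaults are chosen once to mirror a realistic collection at desk scale:
5 genera, 60 specimens per genus, 64×64 grayscale pixels, and an
extra-picture probability of 3.35/3 − 1 ≈ 0.117 per view so the expected
picture count per specimen is 3.35, the rate seen in large real
collections.

Two features matter for testing:

* **Identifiability.** `nearest_archetype_classify()` is a brute-force
  oracle: it renders each genus's canonical (jitter- and noise-free)
  template per view, block-averages templates and pictures to a 16×16
  grid (tolerating the small pose jitter without any learning), and
  assigns the nearest template's genus. At zero noise it is perfect; this
  pins the generator down independently of any CNN.
* **Controllable complementarity.**
  `make_complementary_archetypes(n_groups, per_group)` builds genus groups
  that share *all* parameters except those of one designated view (cycling
  head, dorsum, profile). A single-view classifier can then separate only
  its own group's genera — within every other group its view renders
  identical distributions — capping its top-1 accuracy at
  `(per_group + (L - per_group)/per_group) / L` in expectation (2/3 for
  three groups of two), while score fusion across views can resolve
  everything. This is the substrate on which the ensemble-gain property is
  asserted.

Determinism is end to end: every picture's seed is a 31-bit polynomial
hash of (master seed, specimen id, view, picture index), so regeneration
is independent of iteration order, and identical configs produce
byte-identical manifests and PNGs.

What the generator does **not** model: photorealistic anatomy, mounting
pins and labels, lighting and scale variation, class imbalance, label
noise, or missing views (missing-view datasets are built directly in
tests). Passing the pipeline properties on this substrate shows the
machinery is correct and that the regimes/ensembles behave as the
multi-view theory predicts *when its assumptions hold*; it does not certify
accuracy levels on real photographs.

## Architecture calculus

Layer stacks are declarative tibbles; the only geometry rule is the output
size `floor((H_in − k + 2P)/S) + 1` with width equal to height. Floor
division applies to convolution and pooling alike: the reference pooling
chain 63 → 31 → 15 → 7 divides exactly, and floor is the convention that
reproduces 256 → 63 for the first convolution. Values not printed in the
reference description are filled with the AlexNet conventions and flagged
in the layer `note` field: first-convolution padding 2 (floor division
admits 2 or 3; the descriptor records the minimal value, which is also the
AlexNet one), dimension-preserving middle convolutions with kernels
5, 3, 3, 3 and padding `(k−1)/2`, max pooling, cross-channel local
response normalization, dropout rate 0.5 (configurable).

`scaled_architecture()` keeps the layer pattern and multiplies channel
counts and fully-connected widths by a factor (ceiling, floored at 8).
The desk-scale default, 64×64 input at width factor 0.125, traces
64 → 15 → 7 → 3 → 1 with 512-wide fully-connected layers; inputs below
~63 pixels collapse the pooling chain and are rejected with the offending
layer named.

## Training engine and numerical choices

The CNN engine (RcppArmadillo) implements convolution as im2col matrix
products, max pooling with recorded argmaxes, AlexNet-default LRN
(n = 5, α = 10⁻⁴, β = 0.75, k = 1), fully-connected layers, inverted
dropout (masks only at training time, activations pre-scaled by 1/keep so
scoring needs no correction), and softmax with cross-entropy. Optimization
is plain SGD with momentum 0.9, L2 weight decay 5·10⁻⁴ and step
learning-rate decay — the classical recipe for this architecture family.
Defaults (initial rate 0.01, decay 0.5 every 800 steps, batch 24) are
desk-scale; `iterations` counts mini-batch steps, the convention of the
Caffe lineage in which such training schedules are quoted, and the
full-scale schedules (tens of thousands of steps) remain expressible but
are not defaults.

Other numerical decisions:

* **Initialization** is He-scaled Gaussian (sd √(2/fan-in)), biases zero —
  appropriate for ReLU stacks and stable at these widths.
* **Checkpoint selection** monitors validation top-1 *accuracy* every
  `validation_interval` iterations (including iteration 0, so a transfer
  model's starting point — the parent's accuracy on that view — is always
  a candidate and is recorded in the history); the checkpoint with the
  highest recorded accuracy wins, ties to the earliest iteration.
* **Determinism** is contract-level: all randomness (init, batch
  sampling, dropout) derives from one seed through a fixed-width hash;
  the same seed on the same numerical backend reproduces weights and
  histories bit for bit.
* **Warm-start equality**: transfer with zero iterations returns the
  parent's weights unchanged — asserted exactly, not approximately.
* Penultimate features are the rectified output of the second
  fully-connected layer (the vector feeding the classifier head), taken
  with dropout disabled.

## Evaluation and diversity

Top-t lists sort scores descending with ties broken by ascending label
index; this makes every top-t list a prefix of the top-(t+1) list, so
accuracy and the correctness-derived diversity measures are provably
non-decreasing in t. Per-label precision for list predictions counts label
g as predicted wherever g appears in a list — the natural extension that
reduces to standard precision at t = 1 and is computable from lists alone —
with 0/0 defined as 0 so never-predicted labels drag the minimum to zero
rather than disappearing. Average precision is the unweighted (macro) mean
over labels present in the truth set. Single models are evaluated
per picture; ensembles per specimen (the type-1 vs type-2 distinction).

The four pairwise measures are computed from correctness indicators, with
`sc` and `df` *derived* as `bc + oc` and `1 − (bc + oc)`: independent
divisions would break the identities in floating point, while the derived
forms satisfy `sc = bc + oc` and `bc + oc + df = 1` to the last bit.
Ensemble-level diversity is the unweighted mean over all member pairs.
One reported measure in the surrounding literature appears under two
names; the package implements the four distinct quantities above and
treats "complementarity" as a reading of `oc`, not a fifth measure.
Member filtering before aggregation is the identity — every trained
member enters its ensemble — since no selective rule is part of the
fusion scheme.

Fusion itself is summation, not averaging, of softmax vectors (identical
rankings, but the summed form keeps the aggregated mass equal to the
member count, a useful invariant); the general model inside `G` and `All`
is one weight set applied three times, once per view image. Evaluation
refuses specimens violating the one-picture-per-view contract instead of
silently choosing a picture.

## Problem sizes used by the tests

The behavioural test suite runs the study conditions at desk scale, chosen
once as the package's own test design: 5 genera × 60 specimens at 64×64
pixels and width factor 0.125 for the regime properties (250 general /
150 view-specific iterations, 5 seeds, medians asserted), and 3
complementary groups × 2 genera × 40 specimens at zero noise for the
ensemble-gain property. Unit tests use a 16×16 two-genus toy with a small
custom stack. The acceptance script itself recomputes the exact
shape-calculus quantities, which need no training.

## Known limitations

* The engine is single-threaded CPU code for small inputs; it is not a
  substitute for a GPU framework at 256×256 full scale, though the
  reference architecture is fully expressible and traceable.
* Grayscale inputs only; one picture per (specimen, view) is required at
  evaluation time by design.
* SGD hyperparameters beyond the classical recipe (no momentum schedules,
  no adaptive optimizers) are out of scope, as are learned or weighted
  fusion rules, test-time augmentation, and external pretrained weights.
* The synthetic substrate's easiness means regime differences often
  saturate (specific and transfer both reach perfect validation accuracy
  on the default conditions); ordering assertions are therefore made as
  medians over seeds and as inequalities, not as reproductions of
  real-data accuracy tables.
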