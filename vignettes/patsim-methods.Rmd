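---
title: "Measuring multi-disease patient similarity with patsim"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Measuring multi-disease patient similarity with patsim}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(patsim)
```

## The problem

Two patients who both carry chronic, mutually reinforcing diseases —
diabetes (ICD-10 E10–E14), cerebrovascular disease (I61–I69) and ischemic
heart disease (I20–I25) — are "similar" in a clinically meaningful sense when
they share demographic risk strata and disease burden. A good similarity
measure over longitudinal claims records supports cohort retrieval,
personalized treatment comparison and downstream prediction. The difficulty
is that visit records are irregular, variable-length and coded, so a distance
must be learned over an embedded representation rather than read off raw
fields.

`patsim` implements one complete pipeline for this: simulate (or load) a
longitudinal cohort, embed visits, derive rule-based similarity labels, and
train a weight-shared convolutional encoder under a joint objective that
combines multi-label patient classification with contrastive metric learning,
benchmarked against four classical metrics.

## Patient representation

Each visit becomes a token document: a sex token, an age-group token, the
visit's diagnosis codes and its prescription codes. Documents are embedded to
$e$ dimensions (default $e = 128$) by one of two interchangeable backends:

* **PV-DM** — a distributed-memory paragraph-vector model in which every
  visit owns a paragraph vector that, averaged with the context-window token
  vectors, predicts each token in turn through a full softmax. The full
  softmax is practical because synthetic vocabularies hold a few hundred
  tokens; window 5, 40 epochs and min-count 1 are the defaults. Training is
  stochastic but seeded, so repeated runs reproduce exactly. Inference for an
  unseen document runs the same updates with token vectors frozen.
* **hash** — a training-free signed-hashing projection (each token hashes to
  a coordinate and sign; a document is the signed count vector scaled by
  $1/\sqrt{n_\text{tokens}}$). It is exactly deterministic across platforms
  and fast, which makes it the backend of choice for test fixtures; it
  preserves bag-of-token geometry but, unlike PV-DM, learns no distributional
  similarity between codes.

A patient is the matrix $P \in \mathbb{R}^{v_\text{max} \times e}$ whose first
$v$ rows are the visit embeddings in visit order and whose remaining rows are
exactly zero (default $v_\text{max} = 200$, giving the reference
$200 \times 128$ input). Patients with more than 200 visits, or any visit
with more than 12 diagnosis codes, are excluded beforehand; both rules
disqualify the whole patient, which keeps the 200-row bound exact.
We embed one paragraph per visit (visit-level embedding); the convolution
along the visit axis is what captures cross-visit structure.

## Labels

Feature labels are 14 bits over 7 categories (Table-style binning):

| category | groups |
|---|---|
| age | 0–30, 31–60, ≥61 years |
| gender | male, female |
| blood pressure | prehypertension and below (<140/<90), stage 1 (140–159 or 90–99), stage 2 (≥160 or ≥100) |
| BMI | underweight (<18.5), normal (18.5–22.9), overweight (≥23 kg/m²) |
| disease | one bit each: diabetes, cerebrovascular, ischemic |

Readings below the 120/80 prehypertension floor fall in group 1 so the BP
partition stays total, and when SBP and DBP imply different stages the higher
stage wins (the standard clinical convention). Age is the patient's static
age at generation time.

Two patients **match** on a category when they share its positive bit: the
same one-hot group, or a disease that both carry — two absences are not a
match. The match count is therefore the inner product of the two bit
vectors. A pair is labeled similar when at least 4 of 7 categories match
(the median). The worked example in the README exercises exactly this rule.
Pairs are sampled without duplicates or self-pairs, canonicalized by id
order, and split 8:2 at the pair level (a patient-disjoint split is available
as a flag).

## The joint model

The encoder applies three CNN blocks along the visit axis. A block runs
three parallel valid 1-D convolutions (kernel widths 2/3/4, stride 1, ReLU;
`block_filters` = 128/64/32 per block at reference size), max-pools each
branch (window 2), concatenates branch channels, applies dropout (rate 0.3,
training only) and then a parameter-free single-head scaled dot-product
self-attention with a residual connection ($Y = X + \mathrm{softmax}(XX^\top
/\sqrt{C})\,X$), whose rows are nonnegative and sum to one. A valid
convolution of width $h$ over $v$ rows yields $v - h + 1$ features. Branch
outputs of unequal temporal length are aligned by truncation to the
shortest. After the third block the map is flattened and projected linearly
to the patient vector (reference size 800).

Training is Siamese: both pair members pass through the same encoder. Each
patient vector feeds a sigmoid head over the 14 feature bits scored by
summed binary cross-entropy,

$$L_\text{classify}(y, \hat y) = -\sum_i y_i \log \hat y_i + (1 - y_i)\log(1 - \hat y_i),$$

and the Euclidean distance $e$ between the two vectors feeds the contrastive
loss with margin $m$ (default 1),

$$L_\text{similarity} = Y \tfrac12 e^2 + (1 - Y) \tfrac12 \max(0, m - e)^2 .$$

The total objective is the weighted sum
$L = w_1 L_\text{classify}^{(a)} + w_2 L_\text{classify}^{(b)} + w_3
L_\text{similarity}$ with default weights (1, 1, 1); weights (0, 0, 1) give
the similarity-only ablation and (1, 1, 0) the feature-learning-only
ablation. Optimization is mini-batch Adam (batch 128, learning rate 1e-3)
with early stopping (patience 10 by default) on a 10% validation slice of
the training pairs. The whole network — convolutions, pooling, attention,
heads — is implemented directly in R matrix code with hand-derived
gradients; the test suite verifies every gradient against central finite
differences to about 1e-4 relative error, and the loss formulas against
scalar oracles at 1e-9.

Numerical choices worth knowing: sigmoid outputs are clamped to
$[10^{-7}, 1-10^{-7}]$ inside the cross-entropy; the contrastive gradient
uses $\partial e/\partial z$ only when $e > 10^{-12}$ (the pull/push force
vanishes at coincident embeddings); attention subtracts row maxima before
the softmax; ties in max-pooling resolve to the earliest position; training
aborts with a diagnostic if any batch loss becomes non-finite.

**Embedding normalization.** The distance channel L2-normalizes the two
patient vectors before the Euclidean distance
(`train_config(normalize_embeddings = TRUE)`, the default; the
classification head always sees the raw vector). Two observations force
this choice. First, the similarity rule is an *overlap* criterion, and on
unnormalized vectors $\|u - v\|^2 = \|u\|^2 + \|v\|^2 - 2\,u^\top v$
confounds overlap with per-patient norms: on norm-equalized vectors the
squared distance is an affine, strictly decreasing function of the overlap,
so a single global threshold can represent the rule far more faithfully
than on raw vectors, where the same distance corresponds to different
overlaps depending on disease burden. Second, the cross-entropy term
keeps growing embedding norms during joint training, which shrinks the
(norm-divided) contrastive gradient and stalls metric shaping. With unit
vectors, distances live in $[0, 2]$, commensurate with the default margin.

Distances convert to a bounded similarity score by
$s = 1 - \min(e, m)/m$: 1 at distance zero, 0 at or beyond the margin —
a declared design choice (the loss value itself is not confined to [0, 1],
so it cannot serve as a bounded score), monotone in the distance and exactly
1 for identical patients.

**Pair classification.** The shared-positive-bit relation is not a metric
(two pairs at equal embedding distance can differ in match count through
their disease burdens), so no single global distance cut can represent it
exactly. A trained joint model therefore owns two decision channels: the
distance (similar below a threshold) and the expected category-match count
$\sum_i \hat p^{(a)}_i \hat p^{(b)}_i$ from the sigmoid head — the learned
analogue of the labeling rule (similar above a threshold). Both thresholds
are fitted on training pairs by F1 maximization, and the channel with the
higher training F1 predicts on test pairs. A similarity-only ablation has
an untrained head, so it automatically falls back to its distance channel;
the feature-learning-only mode has no meaningful distance and uses its
head — indeed the head is the only channel through which a
feature-learning-only model can make a pair decision at all. Score summaries by disease
combination always use the distance-derived similarity score.

## Class balance: MLSMOTE

Disease labels are unbalanced multi-label data. `imbalance_report()`
computes per-label $IRLbl$ (majority count over label count) and $MeanIR$;
labels with $IRLbl > MeanIR$ are tail labels. For each tail-label instance,
`mlsmote()` interpolates a synthetic instance toward one of its $k = 5$
nearest same-label neighbors (uniform position on the segment) and assigns
labels by the ranking rule: a label is on when it appears in more than half
of the seed-plus-neighbors group. At the patient level the feature space is
the mean visit embedding; a synthetic patient's matrix is the same convex
combination of its parents' matrices row-wise, so synthetics remain valid
encoder inputs, and its demographics interpolate the parents' (sex from the
seed parent). Whether balancing happens before or after pairing is not
dictated by the method; we default to patient-level balancing before pair
construction, with the pair labels then derived by the standard rules.

## Classical baselines

All four baselines operate on the mean of a patient's real visit-embedding
rows (padding rows never contribute) — the method itself does not prescribe
the baseline representation, and this choice is deterministic and comparable
across metrics. Euclidean and cosine need no fitting. Mahalanobis uses the
ridge-regularized inverse sample covariance. LSML (localized supervised
metric learning) builds, for every patient, local scatter matrices from its
$k$ nearest similar and dissimilar neighbors (as declared by the pair
labels) and takes $M$ from the leading generalized eigenvectors of the
between-scatter against the within-scatter (whitened symmetric
eigendecomposition, eigenvalue-scaled, hence PSD by construction). The
cited literature uses "LSML" for more than one algorithm; the localized
supervised variant implemented here is the one whose description matches
the neighbor-based formulation, and the choice is recorded as an
interpretation, not a fact about the original experiments.

Covariance and scatter matrices estimated from a few hundred patients in
tens of dimensions are ill-conditioned, and their raw inverses amplify
noise directions, so both learned metrics shrink toward the scaled
identity; the shrinkage strength is a hyperparameter selected from a small
grid by training-pair F1 inside `run_baseline()` (test pairs are never
touched during selection). Distances convert to similar/dissimilar
predictions by a threshold chosen on training pairs by F1 maximization,
mirroring the joint model's protocol.

## The synthetic cohort

Real national-claims data are private, so the package ships a seeded
generator that emulates the statistical structure the method needs:

* **Demographics** per sex emulate a Korean national claims cohort of
  patients carrying these three diseases: 56%
  male; male age 57.8 (SD 23.4) years, SBP 126.4 (27.1) / DBP 78.8 (12.6)
  mmHg, BMI 22.3 (5.8) kg/m²; female 60.5 (21.5), 131.8 (24.8) / 81.8
  (14.2), 23.1 (4.2).
* **Disease flags** come from per-disease logistic models sharing one latent
  risk factor (loading `comorbidity`, default 1.0), reproducing the
  cascading-comorbidity structure qualitatively; patients with no disease
  are assigned one by prevalence weight, as in a disease-filtered claims
  extract. The marginal prevalences (0.45/0.30/0.35) are modeling choices;
  per-disease counts in real claims cohorts are not available in a usable
  numeric form.
* **Visit counts** are negative-binomial (size 2, mean 30 at reference
  scale), truncated to [1, 200]; cohort summaries record only visit totals,
  so the per-patient distribution is a modeling choice.
* **Visit content**: each visit draws 1 + Poisson(2) diagnosis codes
  (capped at 12) and Poisson(1.5) prescription codes; with probability
  `signal_strength` (default 0.85) a code comes from one of the patient's
  active-disease pools, otherwise from a background pool. Every flagged
  disease is guaranteed at least one matching code, and unflagged diseases
  never emit codes, so disease flags and codes are consistent by
  construction.
* **Coupling**: blood pressure rises with age and with vascular disease,
  and BMI with diabetes (clinically motivated effect sizes of ~9/5 mmHg per
  vascular disease and +2.5 kg/m² for diabetes).
* **Risk-marker codes**: patients outside the normal BP group emit
  stage-specific hypertension codes (I10 for stage 1, I15 for stage 2) and
  patients outside the normal BMI group emit weight-status codes (R63
  underweight, E66 overweight) with per-visit probability
  `risk_marker_rate` (default 0.6). This is how BP and BMI strata actually
  surface in claims data — the records carry no numeric vitals — and
  without the channel those two label categories are essentially
  unlearnable from visit content (only a weak echo survives through the
  age/disease coupling).

What the generator does **not** emulate: real ICD-10 hierarchies and code
co-occurrence statistics, calendar time and inter-visit gaps, measurement
drift across visits, and coding noise. Passing tests on this cohort
therefore demonstrate that the pipeline learns the structure it was built
to learn — not clinical-grade performance on real claims data.

## Desk-scale study conditions

The directional experiments (joint vs similarity-only learning; learned vs
unlearned metrics) run on a fixed fixture chosen to complete on a single
CPU: 500 patients, 2000 pairs (8:2 split), visit cap 40 with mean 12 visits,
hash embeddings at $e = 64$, encoder filters 32/16/8 with output dimension
64, batch 16, learning rate 5e-3, at most 10 epochs, repeated over 3 seeds
and compared on the median test F1 (`run_config()` builds exactly this
fixture). The fixture cohort uses the strong-signal observability profile —
`signal_strength = 0.95`, `risk_marker_rate = 0.9` — because the
directional claims are about what the learners recover *when the signal is
present*; the package-level generator defaults (0.85 / 0.6) are noisier and
meant for general experimentation. These sizes are the package's own
desk-scale choice; the reference-scale architecture (200 × 128 input,
800-dimensional output, batch 128, learning rate 1e-3) is exercised by a
shape-contract test and remains the default for real use.

## Known limitations

* PV-DM uses a full softmax; it is intended for vocabularies up to a few
  thousand tokens, not real national-claims code inventories.
* The encoder trains sample-by-sample within batches in interpreted R;
  reference-scale training (100k pairs, 100 epochs) is out of desk scope.
* The similarity relation induced by the 4-of-7 rule is not a metric (it is
  not transitive), so no embedding with a single global distance threshold
  can represent it exactly; the directional comparisons should be read as
  orderings, not absolute performance claims.
* Pair-level splitting (the protocol the method was designed around) lets
  a patient appear in
  both train and test pairs; use `patient_disjoint = TRUE` for stricter
  generalization estimates.
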