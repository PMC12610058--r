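---
title: "Methods: prototype-sharing federated learning for finger-vein verification"
author: "fedvein authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: prototype-sharing federated learning for finger-vein verification}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fedvein)
```

## The problem

Finger-vein verification authenticates a person from the near-infrared
absorption pattern of the subcutaneous veins in a finger. Deep embedding
models dominate the field, but vein data are privacy-sensitive and no
single organization holds enough of them; federated learning (FL) lets
several organizations train one encoder jointly while exchanging only
model parameters. The catch is heterogeneity: collaborating datasets
differ in class counts, samples per class, orientation, contrast and
noise, and plain parameter averaging degrades badly on the small clients.

`fedvein` is a desk-scale, fully in-process simulator of a personalized
FL algorithm for this setting. Each client keeps a private classifier
head and shares two things with the server: its encoder parameters and
one *prototype* per class — the unit-normalized mean of the class's
embedding vectors. Every client's classifier weight matrix is expanded
with the other clients' prototypes, so the margin softmax pushes local
samples away from every class in the federation, not just the local
ones.

## Model

Client $k$ owns $N_k$ classes and a trainable weight matrix
$W_k \in \mathbb{R}^{d\times N_k}$. Images are first enhanced:
$I' = I + I_g$, where $I_g$ is the magnitude of the 3×3 Sobel response
(transposed stencil for horizontally oriented fingers), with responses
above a threshold $T$ (default 100) zeroed, so $I_g \in [0, T]$
pixelwise. The per-image *edge intensity* $b = \sum I_g$ is averaged per
class, min–max normalized over the client's classes to $b' \in [0,1]$,
and mapped through a logistic to a quality score
$Q = 100/(1 + e^{-u(b' - 0.5)})$ with steepness $u = 10$. Within each
training batch the scores are standardized with the population standard
deviation and a scale $h = 0.33$, clipped to $[-1, 1]$, giving the
quality indicator $\hat{Q}$.

The classifier sees the expanded matrix
$W'_k = (P_1 \cdots P_{k-1}\; W_k\; P_{k+1} \cdots P_m)$, the other
clients' prototype blocks around the local trainable block, all columns
unit-normalized. With $\cos\theta_j$ the cosine between the normalized
embedding and column $j$, the target-class logit carries two
quality-adaptive margins,

$$g_{\text{angle}} = -m\hat{Q}, \qquad g_{\text{add}} = m\hat{Q} + m,$$

$$f(\theta_y) = s\left(\cos(\theta_y + g_{\text{angle}}) - g_{\text{add}}\right),$$

and non-target logits are $s\cos\theta_j$. At $\hat{Q} = 0$ this is the
plain additive-cosine margin $s(\cos\theta_y - m)$; at $\hat{Q} = -1$
(lowest-quality classes in the batch) the margin moves entirely into
angular space. The loss is softmax cross-entropy over all columns —
local classes and frozen prototype columns alike — averaged over the
batch. Prototype columns never receive gradient; gradients flow to the
embeddings (hence the encoder) and to $W_k$ only.

One printed form of the target logit is ambiguous between an affine
reading $s(\cos\theta + g_{\text{angle}} - g_{\text{add}})$ and the
angular reading above. We default to the angular reading — it is the
standard adaptive-margin construction, and it is the only reading in
which an "angular-space margin" actually acts on the angle — and expose
`literalEq13 = TRUE` in `marginParams()` for the affine variant.

Each communication round every client installs the aggregated encoder,
trains locally, recomputes prototypes with the updated encoder over its
full training split, and uploads both. The server aggregates encoder
parameters with sample-count-proportional weights
$\omega = \sum_k (|D_k|/\sum_j |D_j|)\,\omega_k$ and aggregates
prototypes per class as
$\bar{S}_j = \tfrac{1}{|CS_j|}\sum_{k\in CS_j} (|D_k^j|/N_j)\, S_k^j$,
replacing every owner's copy so the prototype count is conserved. For a
class owned by one client this is the identity. When several clients
share a class the literal $1/|CS_j|$ factor shrinks the aggregate's
norm; `normalizedPrototypeAggregation = TRUE` switches to weights that
sum to one. Likewise the literal model-aggregation weights $|D_k|/N$
(with $N$ the federation's class count) do not sum to one; they are kept
behind `literalAggregationWeights = TRUE` for study, and the normalized
form is the default. The weight matrix $W_k$ never leaves its client —
that is the personalization.

**Bootstrap.** Before any training there are no meaningful prototypes,
so round 1 trains with $W'_k = W_k$; prototypes first circulate in
round 2.

## Evaluation protocol

Open-set verification: classes are split 8:2 per client *by class*
(seeded shuffle, `floor(0.8 n)` training classes), so test identities
are never seen in training. All unordered pairs of test-sample
embeddings are scored by cosine similarity and partitioned into genuine
and impostor sets; a pair is accepted when its score is at least the
threshold (ties accept — fixed because it changes counts at duplicated
scores). EER is found by sweeping the sorted union of observed scores
and linearly interpolating the FAR/FRR crossing, which makes perfectly
separated sets give exactly 0 and identical sets exactly 50. TAR at
FAR = 0.01 uses the smallest observed threshold whose empirical FAR is
within budget, with no interpolated credit; this conservative rule is
what makes the degenerate all-scores-equal case evaluate to 0 rather
than a spurious interpolated value. "Pairs" are unordered; ordered
pairs would double both counts and change no rate.

## The synthetic data generator

Real multi-organization vein federations cannot be redistributed, so
the generator emulates their *structure*: per client it draws identity
templates (3–6 smooth dark curves inside a brighter finger-shaped band
on a dark background, matching near-infrared transmission contrast) and
renders samples under per-sample jitter (±2 px shift, ±4° rotation,
brightness s.d. 6) plus client-level contrast
($x \mapsto 127.5 + c(x - 127.5)$), Gaussian sensor noise and
illumination offset. Labels are globally disjoint by default
(`sharedClassFraction` exercises the multi-owner aggregation branch).
The whole federation is a pure function of the spec and the master
seed; images are 8-bit grayscale PNG in a `root/<client>/<class>/`
layout, so any user-supplied dataset in that layout loads the same way.

What the generator does *not* emulate: real vein branching topology,
sensor optics, specular artifacts, finger misplacement, or the sheer
scale of the public benchmarks (hundreds to thousands of classes).
Passing tests on synthetic federations therefore demonstrate that the
algorithmic machinery behaves as specified and that prototype sharing
helps under controlled heterogeneity — not that any particular accuracy
carries over to real sensors.

## Parameters that matter

| parameter | default | units | why |
|---|---|---|---|
| `gradientThreshold` (T) | 100 | intensity | usual Sobel-threshold value; responses above it are treated as boundary artifacts and zeroed |
| `u` | 10 | — | logistic steepness of the quality score |
| `h` | 0.33 | — | batch quality-indicator scale before clipping |
| `margin` (m) | 0.4 | cosine/radians | typical margin for normalized-softmax losses |
| `scale` (s) | 16 | — | logit scale; 16 suits the small reference encoder — at 64 the softmax saturates and desk-scale training stalls |
| `d` | 64 (training) / 512 (contract) | — | embedding and prototype dimensionality; 512 matches full-scale prototype accounting, 64 keeps CPU runs fast |
| `nRounds` × `localEpochs` | 15 × 2 | — | the loss of every synthetic client drops well below its round-1 value within 15 rounds; one epoch per round is too little optimization at this scale |
| `lr`, `momentum` | 0.05, 0.9 | — | plain SGD with momentum; no optimizer is dictated by the construction |
| `batchSize` | 32 | — | batch statistics for $\hat{Q}$ need a few classes per batch |
| split ratio | 0.8 | by class | open-set protocol |

## Numerical choices and degenerate inputs

- Convolution border: replicate padding for the Sobel stencil (output
  keeps the input shape; border pixels count toward $b$ like any other).
- Degenerate min–max (single class, or all class edge intensities
  equal): $b' = 0.5$, so $Q = 50$ and the margins reduce to the fixed
  case.
- Batch of one, or zero spread in batch quality: $\hat{Q} = 0$, again
  the fixed-margin case.
- $\theta$ is `acos` of the cosine clipped to $[-1+10^{-7}, 1-10^{-7}]$;
  $\theta + g_{\text{angle}}$ is clamped to $[0, \pi]$ so the target
  logit stays monotone in $\theta$; outside the live range the
  derivative is taken as 0.
- Embeddings are L2-normalized before prototype averaging and the mean
  is re-normalized; prototypes must live on the unit sphere to act as
  weight columns. A class whose mean embedding is (near-)zero has no
  direction and raises an error.
- Log-sum-exp with max subtraction throughout; a prototype column that
  duplicates the sample's own class label (possible only with shared
  classes) is masked out of the denominator.
- All randomness flows through one seed hierarchy (`withSeed` /
  `deriveSeeds`), so a run is a pure function of its config seed.

## Problem sizes used by the test suite

The end-to-end comparison trains a 4-client federation (12/10/8/6
classes × 6 samples, 64×128 images, heterogeneous contrast 1/1/0.85/0.7,
noise s.d. 3/5/4/7, illumination offsets 0/−10/6/0) for 15 rounds × 2
epochs with the reference encoder (conv widths 8/16/24, d = 64), on five
seeds, against a local-only baseline with the identical optimization
budget; these sizes keep a full suite run in the minutes range on one
CPU while leaving enough signal for the federated-vs-local comparison to
be stable. Unit tests use 32×32 images and d = 16.

## Known limitations

- **Orientation transfer.** The reference encoder (three conv blocks)
  cannot serve vertically- and horizontally-oriented clients with one
  set of weights at this capacity: in mixed-orientation federations the
  shared encoder collapses and local training wins. Orientation
  heterogeneity is therefore a generator feature exercised by the
  preprocessing tests, while the default training conditions keep
  orientation homogeneous. Full-scale backbones do not share this
  limit; the encoder contract accepts any drop-in replacement.
- The reference encoder is deliberately tiny; absolute EER/TAR numbers
  on synthetic data are not comparable to published full-scale results.
- The simulator is single-process and synchronous with full
  participation: no client sampling, dropout, secure aggregation or
  differential privacy.
- `fedpsfvLoss` treats prototype columns as constants within a round;
  staleness of prototypes between rounds is inherent to the scheme.

## A small worked run

```{r example, eval = FALSE}
fed <- generateFederation(federationSpec(
  nClasses = c(12, 10, 8, 6), samplesPerClass = 6,
  orientation = "horizontal",
  contrastLevel = c(1, 1, 0.85, 0.7), noiseSd = c(3, 5, 4, 7),
  illuminationOffset = c(0, -10, 6, 0), masterSeed = 1))
split <- splitOpenSet(fed, 0.8, seed = 1)
run <- runFederation(split$train, federationConfig(seed = 1))
evaluateOpenSet(run$encoder, split$test)
```
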