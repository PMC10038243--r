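---
title: "Curating crystallisation outcome image datasets"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Curating crystallisation outcome image datasets}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(xtalcurate)
```

## The problem

Automated imagers photograph every droplet of a protein-crystallisation
plate repeatedly over days to months. The resulting collections — hundreds
of thousands of images scored into four gross outcome classes (*clear*,
*crystal*, *precipitate*, *other*) — are the raw material for outcome
classifiers, but they are poor training sets as collected: consecutive
timecourse images of one droplet are near-duplicates, single-annotator
labels are unreliable for a task where even experts disagree, a classifier
trained on a multi-laboratory collection loses accuracy on any laboratory
it has never seen, and minority image types (such as lipidic-cubic-phase
boluses) hide inside the data unnoticed.

`xtalcurate` implements the curation machinery around these problems:
semantic deduplication, consensus labelling, distribution- and
hardness-based selection of local images, contaminant screening, and
decision-boundary diagnostics of domain shift. Everything runs on a
deterministic synthetic droplet generator, so the full pipeline is testable
at desk scale.

## Semantic deduplication

Two images are *semantic duplicates* when they contribute essentially the
same information to a model, whether or not they are pixel-identical. The
package identifies them by euclidean proximity in an embedding space, and
removes them with a three-step procedure:

1. **Cluster count.** To retain a fraction $f$ of $n$ images, form
   $k = \mathrm{round}(f \cdot n)$ clusters (half-away-from-zero, minimum
   1): removing 10% of 100 images means forming 90 clusters
   (`num_clusters(0.9, 100)`).
2. **Pseudo-classes.** Agglomerative clustering is quadratic, so each true
   class is first split by k-means into pseudo-classes of approximately
   10 000 members ($\lceil m / 10\,000\rceil$ for a class of $m$); the
   target is configurable (`make_pseudo_classes()`). The cluster budget is
   divided among pseudo-classes proportionally to their sizes by
   largest-remainder apportionment, minimum one each, so the global
   retained count is preserved exactly.
3. **Cluster and retain.** Within each pseudo-class, average-linkage
   agglomerative clustering on euclidean distance is cut at the allocated
   number of clusters, and the member closest to each cluster's mean vector
   is retained (`dedup_within()`).

Three choices here were genuinely open and are worth recording. The linkage
criterion is not dictated by the procedure itself; we use **average
linkage** — single linkage chains through the dense duplicate groups,
complete linkage fragments them — and expose it as the documented default
rather than an option, because the test oracle (a brute-force UPGMA
enumeration) pins its exact behaviour. Ties, both equal merge heights and
equidistant-to-centroid members, are broken by lexicographically smallest
record id so results are identical across platforms. And the redundancy
experiment (`redundancy_curve()`) re-clusters from scratch at every
retention fraction rather than removing images incrementally; the
fractions are independent subsets, which keeps replicates exchangeable.

The redundancy curve retrains a classifier at each fraction and tracks its
accuracy on fixed evaluation sets: a flat curve is direct evidence that the
removed images were redundant.

## Embeddings

Similarity lives in an embedding space, not in pixels. The package defines
a provider contract — any `n × d` matrix of finite vectors aligned to
record ids (`embedding_set()`) — so a CNN's penultimate layer can be
plugged in. The built-in `baseline_embed()` is a deterministic, GPU-free
descriptor: an 8×8 mean-pooled luminance grid (64 dims, centred per image
so it encodes spatial structure rather than global brightness), a 32-bin
intensity histogram and a 16-bin gradient-magnitude histogram. Histograms
are soft-binned (linear interpolation between adjacent bins) so small
intensity shifts move the descriptor smoothly. Each of the three blocks is
standardised by its root-mean column variance; per-column scaling would
inflate near-constant histogram bins into the dominant distance component.
The standardisation statistics are stored with the set and can be reapplied
to new images — the train/apply asymmetry of any fitted embedder, made
explicit. Whether deep features should be L2-normalised before clustering
is left to the provider; the baseline uses unnormalised standardised
blocks.

## The synthetic generator

`generate_dataset()` renders geometric caricatures of droplet images, not
photorealistic ones: the algorithms under test care about separable,
controllable structure, and caricatures make every planted property
verifiable. Each class has a distinct signature inside a circular drop with
a dark rim — nothing (*clear*), 1–5 bright elongated laths (*crystal*),
granular high-frequency texture (*precipitate*), an irregular ring
(*other*) — plus a fifth non-class type, a large bolus filling most of the
drop, standing in for lipidic-mesophase contaminants.

The generator plants three kinds of structure:

* **Timecourses.** Records are grouped into wells of
  `duplicate_group_size` images rendered from one base scene with
  per-timepoint jitter (translation up to `duplicate_jitter × image_size`
  pixels, brightness up to `±duplicate_jitter`; default 0.02). At jitter 0
  the images of a well are bit-identical. Every well additionally carries
  its own illumination fingerprint — background offset, lighting tilt, two
  smooth sinusoidal texture components and its own noise level — all shared
  across the well's timepoints, so within-well embedding distances stay far
  below between-well distances (the planted-redundancy invariant asserts a
  ratio under 0.2 at jitter ≤ 0.02). All rendered masks are anti-aliased
  with a one-pixel feather so sub-pixel jitter perturbs images smoothly.
* **Sources.** Imaging styles (`style_config()`) differ in illumination,
  vignetting, noise and drop size, emulating the laboratory-to-laboratory
  variation that can dominate class variation in real collections.
* **Class balance.** Class counts follow largest-remainder apportionment of
  the configured distribution, applied at the well level (a well images one
  droplet, hence one label); with group size 1 this is exactly the
  image-level allocation. Presets encode published collection
  distributions: `marco` (clear 33.6%, crystal 12.8%, precipitate 48%,
  other 5.6%) and `cinder` (27/11/50/12), reordered to the package's
  canonical alphabetical class order.

Determinism is strict: one global seed, with per-well and per-image streams
derived by hashing `(seed, id)`, so generation is a pure function of the
configuration and insertion order cannot change an individual image. When
`n_images` is not divisible by the group size, the final well is truncated.

What the generator does **not** emulate: focus drift, plate-edge artefacts
beyond vignetting, multi-outcome drops, annotation noise correlated with
image content, and the long-tailed heterogeneity of real imagers. Passing
tests therefore demonstrate that the *procedures* are correct on data with
known structure — not that any particular accuracy will transfer to real
collections.

Synthetic *embeddings* (`generate_embeddings()`) skip rendering entirely:
isotropic Gaussian clusters at class-centre + source-offset positions, with
expected centre separations set directly. With source separation well above
class separation, an unsupervised partition of the vectors agrees better
with source than with class — the situation self-supervised features
exhibit on multi-laboratory collections — and scaling the class separation
down (same seed, smaller separation) yields a dataset shifted toward the
decision boundaries, used to validate the domain-shift diagnostics.

## Consensus labelling and selection

`consensus_label()` implements a two-round protocol: two annotators who
agree settle a label; a disagreement requires a third opinion; any label
held by two of three wins; three distinct opinions mark the record
ambiguous, and `build_consensus_manifest()` excludes it. Of the $4^3 = 64$
ordered label triples, 40 reach a consensus — the test suite checks the
implementation against this enumeration.

`select_local()` draws images from a pool of locally collected,
singly-annotated ("weak") images for training-set augmentation, either
matching a target class distribution (largest-remainder apportionment,
realised exactly or failing loudly with the per-class shortfall), uniformly,
or by *hardness* — prediction entropy in nats. The natural-log base is a
pure rescaling and cannot change any ranking. Pure top-$k$ hardness ignores
class composition by design; a distribution-constrained variant
(`constrain_distribution = TRUE`) is provided because hardness and
distribution matching are often wanted together, and because a fair
comparison against random selection needs matched counts. The package
deliberately does not attempt label cleaning of the weak pool: the evidence
that too many weak labels eventually hurt performance is an empirical
caution for the user, not an algorithm.

Timecourse uniqueness (`one_per_timecourse()`) defaults to the *last*
inspection, which carries the most outcome information; `first` and seeded
`random` rules are available.

## Probe and diagnostics

The reference classifier is a linear probe: multinomial logistic regression
with L2 penalty, minimised by full-batch gradient descent from a zero
initialisation with a step-halving line search. The objective is convex, so
the optimiser is deterministic and the loss trace non-increasing by
construction; training stops when the improvement falls below `1e-8`.
Probabilities are floored at `1e-12` before any logarithm, so confident
mistakes score large but finite.

`boundary_distances()` computes, for each of the six class pairs $(i, j)$,
the signed distance of every sample with true label $i$ or $j$ to the
pair's linear decision boundary,

$$ d = \frac{(w_i - w_j)\cdot x + (b_i - b_j)}{\lVert w_i - w_j\rVert}, $$

positive when the pairwise score favours class $i$. For a linear head this
is exact; applied to the final affine layer of a deep network it is a
first-order surrogate, and is documented as such. The *crossing fraction* —
samples whose sign contradicts their true label — equals the pairwise
misclassification rate by construction (ties on the boundary resolve to the
earlier class, matching the argmax convention). Distances are computed in
the representation (embedding) space, which is the natural choice for the
surrogate but is stated as this package's choice, not a general fact.
Comparing two datasets under one probe (`domain_shift_summary()`), a
smaller mean absolute distance together with a larger crossing fraction is
the quantitative signature of domain shift.

`project_2d()` gives the qualitative view: UMAP when the `uwot` package is
available, otherwise (with a warning) the variance-maximising linear
projection, with a deterministic sign convention so repeated runs agree
bit-for-bit.

`screen_binary()` packages the contaminant workflow: a two-class probe
trained on ≥ 20 labelled examples per side, an honest stratified 20%
hold-out for the reported confusion matrix, and a scan of the remaining
pool flagging records at or above a probability threshold (default 0.5 —
an operating point for human review, where enrichment, not purity, is the
goal).

## Numerical conventions and degenerate inputs

* Canonical class order is alphabetical — clear, crystal, precipitate,
  other — for every vector and matrix; published tables in other orders are
  reordered on load.
* Largest-remainder ties break by class order; centroid and merge-height
  ties break by record id; argmax ties break by class order. All are
  deterministic across platforms.
* Probability rows must sum to 1 within `1e-6`; class distributions within
  `1e-9`; embedding round-trips are written with 17 significant digits
  (lossless for doubles).
* Empty classes are skipped with a message in pseudo-class construction; an
  empty manifest has no class distribution (an error, not `NaN`); a cluster
  budget smaller than the number of pseudo-classes is an error advising a
  larger retain fraction.

## Problem sizes in the test suite

The suite validates the full pipeline on synthetic datasets of 40–2000
images (the largest: 500 timecourses of 4 near-duplicates at 64×64 pixels,
deduplicated 4:1 and scored by the probe against a 400-image held-out set,
in triplicate), sizes chosen so the planted structure is unambiguous while
the whole suite runs in about a minute on one CPU. Replicates are full
re-runs with distinct seeds — the probe itself is deterministic, so the
honest replicate noise is the dataset draw, not the optimiser.

## Known limitations

* The baseline embedder is a hand-crafted descriptor: it supports the
  package's procedures and tests, but real deployments should plug in
  learned features through the provider contract.
* Boundary distances on deep models are first-order surrogates; they are
  exact only for linear heads.
* The generator's caricatures cannot certify real-data accuracy; they
  certify procedure correctness under known structure.
* No plate-geometry handling, no UV-channel support, no active-learning
  loop, and no annotator-quality modelling.
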