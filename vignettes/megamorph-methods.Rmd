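---
title: "Methods: multimodal identification and biomass estimation at desk scale"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: multimodal identification and biomass estimation at desk scale}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# What this package models

`megamorph` implements a multimodal workflow for freshwater
macroinvertebrate monitoring that combines three measurement channels on
the same individual specimens:

1. **DNA megabarcoding** — each specimen is individually amplified and
   sequenced, yielding a per-specimen table of OTUs (operational
   taxonomic units) with read counts and taxonomy. The dominant OTU
   gives the specimen's species identity; counting specimens gives
   abundance.
2. **Semi-automated imaging** — a two-camera device photographs each
   specimen sinking through an ethanol-filled cuvette, producing tens
   of silhouette frames per specimen plus per-frame morphometric
   features: area (A), maximum Feret diameter (MFD) and perimeter (P).
3. **Weighing** — per-specimen dry mass on a precision balance, the
   regression target for image-based biomass estimation.

The analysis questions are (i) how reliably the dominant-OTU rule
recovers species identity, (ii) how well convolutional networks predict
species identity from images, and (iii) whether biomass regressors
benefit from taxonomic pre-training, compared against ordinary least
squares allometric baselines on the device features.

Everything runs on synthetic data generated by the package itself, so
the full pipeline is testable on one CPU in minutes without any
downloads.

# The synthetic-data generator

`generate_taxonomy()` builds a nested species/genus/family/order
taxonomy with exact rank sizes. `generate_specimens()` draws specimens
whose true dry mass follows a species-specific allometric power law

$$ m = c_s \, L^{b_s} \, e^{\varepsilon}, \qquad
   \varepsilon \sim \mathcal{N}(0, \sigma^2), $$

with body length $L$ lognormal per species. Defaults: $c_s \in
[0.02, 0.06]$ mg/mm$^b$, $b_s \in [2.2, 2.7]$, $\sigma = 0.15$ log-mg,
lengths 6–16 mm — masses span roughly 0.5–200 mg, the range typical of
EPT (Ephemeroptera, Plecoptera, Trichoptera) larvae, with an
appreciable sub-milligram tail. $\sigma = 0.15$ was chosen once to
match the residual scatter (median relative error around 15–20%) that
image-based biomass models report on real specimens; the within-species
length CV of 12% reflects a single-cohort field sample of similar
instars.

**Silhouettes.** Each species gets a parametric silhouette: an ellipse
body with a tapered abdomen, 0–6 appendage pairs, and (for
case-building caddisfly analogues) an optional rectangular case.
The species attributes sit on a coupled lattice: mean body lengths are
evenly spaced on a log grid, and the elongation grid is visited with a
stride coprime to the species count, so species adjacent in size differ
strongly in shape (and vice versa). Case geometry is itself
species-specific — real caddisfly cases are diagnostic — because a
generic case would otherwise mask every other attribute for the cased
half of those specimens. This lattice construction is what makes the
visual classes rank-separable by design at desk scale; an independent
check (multinomial regression on global shape descriptors) confirms
the classes are separable at roughly 93–94% per-frame accuracy before
any network training.

**Two views.** Camera 1 renders the silhouette; camera 0 renders the
same body with its width compressed by a per-specimen dorsoventral
factor (0.75–0.95): perpendicular views differ in projection, not
content. Frames embed the silhouette at a random in-plane rotation and
small random offset; the rasterized major-axis extent equals
$L \cdot \text{px/mm}$ within 2 px (small circular caps pin the tips
where the taper would otherwise lose a pixel). With probability
`junk_rate` a frame is replaced by a small non-target blob (bubble or
debris analogue), flagged in the generator's truth ledger.

**Weighing.** Recorded weight = true mass + additive Normal noise,
rounded to the balance readability. Values at or below zero are
returned as-is — a real balance reports negative weights for specimens
below its detection limit — and exclusion happens downstream during
curation, never in the generator.

**OTU tables.** Each specimen's sample contains one dominant OTU
carrying its true taxonomy (lognormal reads, median $2 \times 10^5$)
plus a Poisson number (mean 11.7) of non-target contaminant OTUs
(parasite/gut-content analogues; lognormal reads, median $2 \times
10^3$). Three failure modes are injected at configurable rates
(defaults 7.2% / 3.4% / 3.1%): dominant reads below the 1,000-read
threshold; dominant taxonomy swapped to a different macroinvertebrate
order; dominant taxonomy truncated above species level. A
repeated-PCR sample is simulated with probability 0.27. The ledger
records the injected state per specimen, so assignment recovery can be
checked specimen-by-specimen, not just in aggregate.

All randomness flows from one root seed through named sub-streams
(`substream_seed()`), so each stage is reproducible in isolation.

**What the generator does not emulate:** photorealistic appearance,
texture and colour, ethanol optics, motion blur, partial specimens,
reference-database idiosyncrasies, or read-level sequencing artefacts.
Passing tests therefore demonstrate that the *pipeline logic* is
correct and that the models can learn shape- and size-borne signals;
they do not certify performance on real imagery.

# Morphometric conventions

Image libraries disagree by more than 10% on perimeter and Feret
conventions, so the package pins its own:

* **Segmentation**: automatic bimodal (Otsu) threshold with a fixed
  override; largest 8-connected component only (single-specimen
  cuvette assumption).
* **Area**: foreground pixel count / (px/mm)².
* **Maximum Feret diameter**: the largest Euclidean distance between
  the *centers* of any two boundary pixels, computed from the convex
  hull but always equal to the brute-force pairwise maximum (a test
  enforces equality to 1e-9 on random masks).
* **Perimeter**: length of the Moore-traced outer boundary polygon
  (unit steps between 4-neighbours, $\sqrt2$ for diagonals). A single
  pixel has perimeter 0 under this convention.
* Coordinates are row-major with origin top-left and pixel centers at
  integer coordinates.

Non-target frames are flagged (never deleted) by area and solidity
bounds; with the default generator the junk blobs are well separated
from the smallest real silhouettes in area, and the flagging test
requires at least 90% of injected junk to be caught.

# Dataset curation and splits

`curate()` applies exclusions in a fixed order, recording the first
rule that fires: unassigned specimens; recorded weight ≤ 0 mg (the
below-detection rule — the balance readability is kept as metadata, not
used as a threshold, since real studies retain specimens far below it);
species with fewer than 5 remaining specimens; specimens with no clean
frames. Rare-species counts are computed *after* the first two rules,
mirroring the practice of cleaning taxonomy before re-computing splits.

`make_folds()` produces stratified grouped 5-fold splits: the specimen
is the group (all of its frames travel together), and within each
species specimens are dealt round-robin into folds with a rotating
start so remainders spread evenly. Fold $i$ uses fold $i$ as test and
fold $i+1 \pmod k$ as validation; the remaining folds train. The
rotation is the package's answer to an open design question (how the
study carved validation sets out of its five folds is not recoverable);
it is configurable in the sense that the fold lists are plain data.
The same fold object is reused verbatim by the classification and
biomass tasks so their results are comparable.

`compute_global_max_dim()` records the dataset-wide maximum frame
dimension `G`. `resize_with_global_aspect()` scales *every* frame by
the same factor `T/G` (area-average box filter, which preserves the
energy of thin appendages that plain decimation would drop), centers
it on a `T x T` canvas and pads with pixels sampled from the frame
border. Because the scale factor is global, inter-specimen size ratios
— the biomass signal — survive normalization; a test checks that
equal-size disks rendered into different frame geometries stay equal
to within 1 px after resizing.

# Models

## Allometric OLS baselines

`fit_linear()` regresses the transformed mass on log-transformed
predictor subsets of {A, MFD, P}, one observation per clean frame,
with specimen-grouped train/test splits (no specimen leaks across
sets). Target transforms: identity, log, log+1. Predictions are
inverse-transformed and clipped at 0 mg. These are the baselines the
networks must beat.

## The convolutional engine

No deep-learning framework is used: the package ships a compact,
fully-tested engine built on BLAS matrix operations —

* stem average-pool, then 3×3 same-padded convolution blocks
  (im2col as one cached index gather + one matrix product), ReLU,
  average pooling; widths default to 6-12-24 at a 64×64 input;
* global pooling produces per-channel mean and root-mean-square
  statistics, concatenated with seventeen fixed global moment
  descriptors of the input silhouette: foreground fraction,
  major/minor axis lengths from the second-moment eigenvalues, edge
  density, radial fourth moment, maximum radial extent, their
  logarithms, and a small quadratic basis in the logs (squared
  log-extent and log-extent times each log-shape term). The
  descriptors are the in-network analogue of the imaging device's own
  size features: average pooling alone cannot express a
  spatial-extent statistic such as the Feret diameter, the log copies
  make power laws linear in the features, and the quadratic terms
  make smooth allometric curvature and shape-conditional slopes
  expressible by a linear readout. They receive no gradient (nothing
  upstream of the input is trainable) and are invariant to every
  augmentation in the pools below;
* a feature-standardization layer whose location and scale are fixed
  at initialization from a probe of training frames (no train-time
  statistics, so inference is batch-independent and deterministic);
  near-constant channels are floored relative to the most variable
  channel so standardization never amplifies noise;
* a two-layer MLP head plus a zero-initialized linear shortcut from
  the standardized features to the output.

**Optimization.** The backbone trains with minibatch AdamW
(cross-entropy for classification with a randomized single-transform
augmentation policy — flips, lattice rotations, brightness, contrast;
L1 loss for biomass with flips and lattice rotations only, which
preserve the silhouette scale). The head is refit every epoch on the
current (frozen) backbone features of the full training set: for
classification by full-batch Polyak-momentum gradient descent on the
cross-entropy, and for biomass by iteratively reweighted least
squares on the L1 objective (the readout is linear in the features
plus the hidden ReLU basis, so a few closed-form IRLS steps reach the
optimum that first-order L1 updates approach only slowly and
unreliably), alternated with gradient steps that adapt the hidden
basis itself. This split exists because, at desk scale (tens of
specimens, frames clustered by specimen), adaptive per-coordinate
updates measurably found worse-generalizing head solutions than plain
gradient descent on the same features, while the backbone still
benefits from AdamW's conditioning. Weights reading the
high-dimensional pooled features receive extra shrinkage (ridge terms
in the IRLS; multiplicative decay in the gradient path): with few
training specimens they memorize specimen identity far faster than
the fixed descriptors. Biases are never decayed. The learning rate
follows a half-cosine decay; one seed governs initialization, batch
order and augmentation sampling, and training is bit-reproducible on
CPU.

Validation loss is evaluated after every epoch and the
minimum-validation-loss checkpoint is returned with the full loss
curve (`checkpoint_epoch == which.min(val_loss)` is an invariant).

## Transfer learning

`fine_tune_regressor()` starts from a taxonomic classifier's backbone
(and its feature standardization), replaces the head with a
single-output regression head, and optimizes mean absolute deviation
of the transformed mass. With `frozen_base = TRUE` every backbone
parameter is bit-identical after training — a test hashes them — and
only the head learns; unfrozen fine-tuning updates everything.
Training without a base (`base = NULL`) is the no-pre-training
comparator.

# Evaluation

Per-fold holdout predictions are concatenated jackknife-style
(`combine_folds()`), so each curated specimen is predicted exactly
once and metrics describe the complete dataset. Classification reports
per-class and support-weighted precision/recall/F1 and row-normalized
confusion matrices (rows sum to 100); `group_confusion()` collapses
species-level predictions to coarser ranks through the taxonomy.
Regression reports MAE and MdAE in mg, MAPE and MdAPE as fractions,
and $R^2 = 1 - SS_{res}/SS_{tot}$ (negative values possible on
holdout data). The evaluation unit is the frame, matching per-image
prediction; per-specimen medians are emitted as a clearly-labelled
secondary bundle. A class never predicted gets precision 0 rather
than an error.

# Desk-scale study conditions

The default configuration — 8 species over 3 orders, 12 specimens per
species, 16 frames each (two cameras), 5% junk frames, failure rates
7.2%/3.4%/3.1%, 5 folds, 64×64 inputs, a 6-12-24 backbone, 20
classifier epochs, 20 scratch-regressor epochs, 10 fine-tuning epochs
— was sized so a full run (all models, all folds) completes in roughly
a quarter of an hour on one CPU core. The species classifier reaches a
combined weighted F1 a little above 0.9 under these conditions; the
biomass network without pre-training reaches frame-level
$R^2 \approx 0.86$ and roughly 30% lower median percentage error than
the all-predictor linear baseline, with the perimeter-only model far
behind — reproducing the qualitative ordering reported for real
imaging data (perimeter-only worst, all-predictor linear better,
image CNNs best).

# Numerical choices and edge cases

* Read-count ties in assignment break toward the lexicographically
  smaller OTU id; sample ties toward the smaller sample id.
* A specimen with no OTU rows at all is `insufficient_reads` with 0
  reads, not an error.
* If the dominant OTU fails the order-consistency check the specimen
  is removed, not rescued by the next-best OTU (mirroring how such
  samples are reported as removed; a rescue rule would change the
  recovery-rate semantics).
* The 1,000-read threshold applies to the winning OTU after
  macroinvertebrate filtering; 999 reads fail, 1,000 pass.
* Segmentation of an all-background frame is an error at the API
  level; the batch feature extractor converts it into an NA row with
  an immediate non-target flag.
* Average pooling (not max) keeps CNN gradients exact, which is what
  makes bit-reproducible CPU training and the numeric gradient-check
  test possible.

# Known limitations

* Synthetic silhouettes carry no texture or colour; conclusions about
  real BIODISCOVER imagery require real data.
* The engine is desk-scale by design: a 3-block backbone at 64×64,
  not an ImageNet-scale architecture at 224×224. The package treats
  the architecture as configuration and the training/transfer
  protocol as the contract.
* At 12 specimens per species the high-dimensional pooled features
  are aggressively shrunk; on larger datasets that shrinkage (and the
  balance between backbone and descriptor features) should be
  revisited.
* Fold-to-fold variance is substantial at this size; headline numbers
  are reported on the jackknife-combined prediction set for exactly
  this reason.
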