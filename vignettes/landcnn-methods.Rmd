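---
title: "Simulation-based landscape model selection with landcnn"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Simulation-based landscape model selection with landcnn}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(landcnn)
```

## The inference problem

Landscape genetics asks which features of a landscape — sheer geographic
distance, topography, rivers, historical habitat dynamics — shaped the
spatial distribution of genetic variation in a species. `landcnn`
implements a simulation-based model-selection workflow for this question:
candidate hypotheses are expressed as resistance surfaces, each surface is
converted into a deme-to-deme migration matrix, SNP data are simulated
under a structured coalescent with that migration, and a convolutional
neural network (CNN) is trained on the simulated data to assign an observed
SNP matrix to the hypothesis most likely to have generated it. Because the
classifier is trained purely on simulations, the method sidesteps
likelihood computation for spatially explicit models, at the price of
committing to the generative model's assumptions.

## Candidate landscape models

Twelve hypotheses are enumerated by `enumerate_models()`: every subset of
the static predictors {slope, rivers} crossed with at most one of the two
dynamic predictors {habitat shifts, niche suitability}. The two dynamic
predictors are built from the same environmental information and are never
combined. Model 1 carries no predictors: it is the isolation-by-distance
(IBD) null, and because IBD is the uniform-landscape special case of
isolation by resistance (IBR), geographic distance is implicit in every
other model as the composite baseline.

## From rasters to migration matrices

A model's resistance surface is composed per historical epoch as

\[ r(\text{cell}) = 1 + \sum_k w_k \, \ell_k(\text{cell}), \]

where each predictor layer \(\ell_k\) is min-max normalized to [0, 1] and
\(w_k\) is that predictor's landscape effect, drawn uniformly from [2, 5].
Normalization before weighting is a deliberate choice: slope gradients,
flow accumulation and habitat indicators live on incommensurate scales, and
normalizing makes a common effect range meaningful across predictors. The
additive baseline of 1 is the distance layer, so every IBR model degrades
continuously to the IBD null as its weights approach zero.

Resistance distance \(x_{ij}\) between demes is the least-cost path over
the 8-connected cell graph, with the cost of a move equal to the mean of
the two cell resistances times the step length (1 for rook moves,
\(\sqrt 2\) for diagonal moves, in cell units). This edge-cost convention
is the common one in raster cost-distance tools and is fixed here so
results are bit-reproducible. Distances are converted to per-generation
migration rates by a cubic decay,

\[ m_{ij} = d \cdot (1 / x_{ij})^3, \]

with the dispersal scalar \(d \sim U(0.1, 0.3)\). A weaker, squared decay
leaves migration so high that genetic structure dissolves; the cubic
exponent keeps simulated differentiation in a realistic range. Because
least-cost distances are symmetric the migration matrices are symmetric;
rates are interpreted as backward (lineage-movement) probabilities per
generation. If any row sum exceeds 0.5 the whole matrix is rescaled
uniformly so the largest row sum equals 0.5 — a per-row rescale would break
symmetry — which keeps every row a valid per-generation emigration budget.
The cap can be disabled (`cap = Inf`) or set to 0 for complete isolation.

Models with dynamic predictors get epoch-wise schedules: habitat shifts
change every 1000 years, giving 21 epochs over the last 21 kyr; niche
suitability follows the seven standard late-Quaternary climate slices
(21, 17–14.7, 14.7–12.9, 12.9–11.7, 11.7–8.326, 8.326–4.2 and 4.2–0 kyr —
the published last slice ends at 0.3 kyr and is extended here to the
present so epochs tile the full interval). Generation time defaults to
1 year, so the 21 kyr split is 21,000 generations; it is a configurable
scalar, not a hard-coded constant.

## The coalescent simulator

`simulate_genotypes()` runs a structured coalescent implemented in C++:
within each epoch, lineages coalesce within demes at rate
\(\binom{k_d}{2} / N_d\) (haploid deme sizes \(N_d \sim U(5, 100)\)) and
migrate between demes at the epoch's backward rates; at the split time all
demes merge into a single ancestral population with haploid size
\(N_A \sim U(20000, 50000)\). Sites are independent genealogies; each
receives exactly one mutation placed uniformly along the total branch
length, the fixed-S scheme that guarantees a polymorphic biallelic site
among the sampled sequences. Sites are still checked and topped up until
the requested count (4364 by default, mirroring the empirical matrix) is
reached. Only sampled demes contribute sequences; unsampled demes shape
the migration landscape, nothing else. One diploid individual contributes
two sequences.

The continuous-time approximation deliberately allows per-deme sample
counts to exceed the drawn deme size (a discrete-generation simulator
would reject such draws); within-deme coalescence is then simply very
fast, which is the intended limit.

## Image encoding

A genotype matrix becomes the classifier input by a deterministic
encoding: per column the major allele is recoded 0 and the minor 1 (an
exact 50/50 tie leaves allele 0 as major), columns are stably sorted by
descending minor-allele frequency (ties keep their original order), and
rows — haploid sequences, not diploid individuals, which avoids inventing
a heterozygote pixel value — are sorted into contiguous deme blocks in
ascending deme order. The encoding is idempotent and destroys no
information the classifier is entitled to: it only fixes the nuisance
orderings of rows and columns.

## The classifier

`build_classifier()` constructs the fixed architecture: two stages of 3×1
convolution (3 sequence rows by 1 SNP column, stride 1, no padding)
followed by 3×1 max-pooling, then flatten, dense layers of 100 and 40
units, and a softmax output with one unit per model. Hidden activations
are ReLU; training uses Adam (learning rate 0.001, β₁ = 0.9, β₂ = 0.999),
categorical cross-entropy, mini-batches of 100 and 10 epochs. Two valid
conv+pool stages require an image height of at least 17 sequences.

Filter counts are not part of the published architecture; they default to
8 and 16 here, a width matched to the package's reduced default training
budgets (hundreds of images on a single CPU), and are configurable through
`n_filters` for larger corpora. Forward and backward passes are
implemented directly as BLAS matrix products (the mini-batch gradient is
computed in fixed-size chunks, which bounds memory without changing the
result), so a seeded single-threaded run is exactly reproducible.
Evaluation reports the row-normalized confusion matrix, overall accuracy,
per-model precision TP/(TP+FP) and recall TP/(TP+FN), and a five-bin
softmax calibration table (0–20, …, 80–100% confidence versus empirical
accuracy).

## Synthetic landscapes and what they do (not) show

The synthetic generators emulate the structure, not the geography, of the
production inputs: a uniform all-ones distance layer; slope as the
gradient magnitude of a Gaussian-smoothed random field; rivers as random
channel walks whose values grow downstream, a flow-accumulation analogue;
habitat shifts as 21 thresholded AR(1) latent fields (closed habitat = 1 =
high resistance, 40% closed by default); and niche suitability as 7 AR(1)
probability fields stored as resistance (1 − suitability). Consecutive
dynamic slices are autocorrelated (AR coefficient 0.85 by default), as
climate reconstructions are.

Two scale choices matter and are set once. The default grids are 16×16
(reduced design) and 24×24 (empirical mirror) with a cell size of 0.5, so
that nearest demes (separated by at least 2 cells) sit at resistance
distance ≈ 1 and typical distances span roughly 1–15. Under the cubic
decay this puts migration in the regime where pairwise FST spans a wide
intermediate range — the same matching-to-observed-structure calibration
the production workflow performed against its empirical data (whose
pairwise FST spanned roughly 0.1–0.75). On a much coarser scale migration
collapses toward zero and every model saturates at FST ≈ 1, leaving no
signal to classify.

Passing tests on these landscapes show that the machinery — surfaces,
distances, migration, coalescent, encoding, training — is correct and that
the classifier can separate strongly distinct hypotheses at small scale.
They do not show that the twelve-model problem is solvable at any given
empirical sampling design, nor do they reproduce production-scale
accuracies, which required the real rasters and tens of thousands of
simulations.

## Reduced experiment budgets

The package's default experiments are sized for minutes on one CPU, and
those sizes are package defaults, not tuned quantities:

* Reduced design: 12 demes (6 sampled, 5 diploid individuals each),
  500 SNPs, 16×16 grid.
* Self-classification: 3 models — IBD versus a strong slope effect versus
  a strong river barrier, landscape effects pinned at 5 (the top of the
  prior, hence "strong") — 100 training and 30 test images per model.
* Sampling-design experiment: the four schemes (9 or 39 sampled demes ×
  2 or 20 sequences per deme) on one shared 39-deme landscape, the same
  three models under the standard U(2, 5) effect priors, 400 examples per
  model (300 train / 100 test), 30 SNPs, filters 4/8. Many cheap narrow
  images rather than few wide ones: the 39-deme schemes produce images
  with several times the pixels of the 9-deme schemes, and with too few
  training examples their test accuracy is limited by estimation error
  rather than by the information their sampling design carries, which is
  the quantity the experiment is about.
* Reduced-budget training uses mini-batches of 20 (the full-scale default
  is 100): with a few hundred training images, batch-100 training takes
  only two or three optimizer steps per epoch and does not converge in the
  fixed 10 epochs; a smaller batch gives proportionally more steps at
  identical per-epoch cost.
* Empirical-mirror design: 39 demes, 9 sampled, 52 individuals split
  18/9/7/6/5/3/2/1/1 (the published per-deme sizes are unavailable; only
  the total of 52, the mean of 5.7 and the 1–18 range are, and this split
  realizes them), 4364 SNPs.

## Numerical and degenerate-input choices

* Constant layers min-max normalize to 0: a featureless predictor adds no
  resistance rather than a constant offset.
* `composite_resistance` with no non-distance layers returns the uniform
  surface of 1s (the empty sum), so the IBD model needs no special case.
* Co-located demes (zero resistance distance) are a conversion error, not
  an infinite rate.
* Demes with fewer than two sequences get NA rows in FST matrices.
* Empty calibration bins report count 0 and NA accuracy.
* Max-pool ties route the gradient to the first row of the window; column
  sort ties keep their original order; both choices are stable and seeded
  runs are bit-reproducible.
* The PCA plausibility check (`pca_match`) operationalizes a visual
  inspection: the target's PC1–PC2 scores must fall inside the convex hull
  and the per-PC ranges of the simulated cloud; an all-identical cloud is
  reported as degenerate rather than an error.

## Known limitations

* No recombination, selection, linked sites or within-deme growth; sites
  are exchangeable and unlinked by construction.
* Migration is symmetric; asymmetric processes (downstream drift,
  wind-borne dispersal) are out of scope.
* Hudson's ratio-of-averages estimator stands in for the original
  workflow's FST implementation, whose exact formula is not restated in
  its source; the estimator is tagged in outputs.
* GeoTIFF input is not supported (no georeferenced-TIFF reader is
  available to the package); ESRI ASCII grids are read and written
  natively.
* Accuracies from reduced-budget experiments are qualitative: they
  demonstrate orderings (e.g. richer sampling designs dominate poorer
  ones) rather than reproducing production-scale percentages.
* In the sampling-design experiment at reduced budgets, adding sequences
  per deme helps consistently, but the advantage of denser geographic
  sampling with only one individual per deme — at production scale a
  clear win — sits at the edge of detectability: those images carry the
  most pixels per example, so at small training-set sizes estimation
  error can mask the extra information.
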