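---
title: "Predicting lysine glycation sites: feature encoding, mRMR ranking and SVM incremental feature selection"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Predicting lysine glycation sites}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(glysite)
```

## The problem

Glycation is the nonenzymatic attachment of a reducing sugar to a protein
residue — most prominently lysine — and is implicated in diabetes and
neurodegenerative disease. Unlike enzymatic glycosylation it has no
sequence-recognition machinery, so predicting which lysines become
glycated from sequence alone is a weak-signal classification problem.
`glysite` implements a classical machine-learning pipeline for this task:
fixed-width peptide windows around candidate sites are encoded into a
high-dimensional feature vector, features are ranked by a
mutual-information criterion, and an optimal feature subset and classifier
are chosen by cross-validation.

## The model

### Windows

Each candidate site is represented by a 23-residue window: the site
residue plus 11 residues on each side. Windows that extend past a protein
terminus are completed with the artificial padding letter `O`
("nonexisting residue"), giving a 21-letter alphabet — the 20 standard
amino acids in alphabetical one-letter order, then `O`. Coordinates are
1-based; the annotated residue sits at window site 12.

### Features

Every window maps to a 1900-dimensional vector laid out in three blocks:

1. **Occurrence frequencies** (indices 1–21): the count of each alphabet
   letter divided by the window length L = 23. The padding letter has its
   own frequency feature and counts toward the denominator, so the block
   always sums to 1.
2. **Atchley factors** (22–136): five multivariate physicochemical scores
   per residue — polarity (F1), secondary-structure propensity (F2),
   molecular volume (F3), codon diversity (F4), electrostatic charge (F5)
   — at each of the 23 sites, grouped site-major. Feature
   `21 + 5(s−1) + f` is factor `f` at site `s`; padded sites contribute
   zeros.
3. **CKSAAP** (137–1900): the composition of k-spaced amino-acid pairs.
   For each spacing k = 1..4 and each ordered pair (a, b) over the
   21-letter alphabet (441 pair types), the number of window positions p
   with `a` at p and `b` at p + k + 1. Blocks are ordered by increasing k,
   pairs row-major with the first letter major:
   `136 + 441(k−1) + 21(rank(a)−1) + rank(b)`.

This layout is pinned by ten published worked examples (for instance the
pair of serine and tryptophan spaced by four residues at index 1793, and
the secondary-structure factor of site 3 at index 33); the test suite
asserts all ten, and `feature_index()` / `feature_name()` expose the
bijection. The examples are consistent with exactly this layout and rule
out factor-major grouping or a k = 0..3 spacing convention; we adopt it as
canonical.

### Numerical choices in the encoder

* **CKSAAP normalization.** Raw counts are divided by the number of
  k-spaced positions in the window, 23 − k − 1, following the common
  CKSAAP convention; `normalize = FALSE` preserves raw counts. The choice
  does not affect the index mapping, and under per-feature discretization
  it does not change mRMR ranking either.
* **Atchley scores** ship as a 21 × 5 in-code table (the standard
  published five-factor solution); `O` is all zeros so padding is inert in
  the factor block.
* Non-standard residues (B, J, U, X, Z) are rejected in strict mode and
  mapped to `O` in permissive mode, `O` being the designated
  "nonexisting" letter.
* The centre residue is not forced to be lysine — the loader is generic
  across PTMs — but non-K centres warn by default and can be made an
  error (`strict_center = TRUE`).

## Feature ranking: mRMR

Features are ranked greedily by maximum-relevance minimum-redundancy. With
`c` the class label, `Ω_s` the selected set of size m, the next feature
maximizes

&nbsp;&nbsp;&nbsp;&nbsp;I(f_j, c) − (1/m) Σ_{f_i ∈ Ω_s} I(f_j, f_i)

with plain relevance I(f_j, c) at the first step. Ties break to the
smaller feature index, deterministically.

Mutual information is the empirical plug-in estimator in bits (log base
2) on discretized features: each feature is mapped to three states by the
mean ± θ·σ rule (θ = 1 by default; σ the sample standard deviation;
constant features map entirely to the middle state). The original method
description does not state its MI estimator, base, or discretization, so
an exact reproduction of the published feature ranking is not guaranteed
— this is the standard, seedless convention for mRMR on continuous
features. One consequence worth knowing: a *balanced* two-valued feature
falls entirely inside mean ± σ and discretizes to a single state,
carrying no information; CKSAAP-style features are skewed enough that
this does not arise in practice.

A subtlety of the printed difference criterion: a constant feature (zero
relevance, zero redundancy) is selected as soon as every remaining
candidate scores below zero, and from then on it enlarges m, which can
reorder later, low-signal selections. We implement the criterion exactly
as printed rather than patching it.

## Classifier and subset selection: IFS with an RBF SVM

Incremental feature selection evaluates growing prefixes of the ranked
list. For prefix size i, a soft-margin SVM with the Gaussian kernel
K(u, v) = exp(−γ‖u−v‖²) is tuned over a (C, γ) lattice — default
C ∈ {2⁻⁵, 2⁻³, …, 2¹⁵}, γ ∈ {2⁻¹⁵, 2⁻¹³, …, 2³} — by stratified 10-fold
cross-validation, and the prefix with the best cross-validated Matthews
correlation coefficient (MCC) wins (ties to the smallest prefix).

Decisions made where the original description is silent:

* **Pooled fold metrics.** Held-out predictions from the 10 folds are
  pooled into one confusion table per configuration rather than averaging
  per-fold metrics; MCC on ~20-sample folds is too unstable to average.
* **Fold splits** are stratified by class and seeded (default seed 1);
  the published fold split is unknowable, so headline numbers from the
  original study are not bit-reproducible and are not asserted anywhere.
* **Scaling.** Features are linearly scaled to [−1, 1] using
  training-fold ranges only (constant features to 0); the scaling is part
  of the persisted model.
* **Grid search is re-run per prefix size** (the conservative reading);
  a `stride` and an explicit `sizes` list allow desk-scale runs.
* **Tie-breaks** in grid search: larger accuracy, then smaller C, then
  smaller γ.
* **The SVM solver is built in.** The deployment environment provides no
  R SVM package, so `glysite` includes a compact SMO solver (LIBSVM-style
  maximal-violating-pair working sets, KKT tolerance 1e−3) behind the
  narrow contract fit(X, y, C, γ) → decision function. It is validated
  against the analytic two-point solution, separable data, and
  permutation nulls. Decision ties at exactly 0 classify as positive.

Performance is reported as sensitivity, specificity, accuracy and MCC
from the pooled confusion table; any zero factor in the MCC denominator
yields MCC = 0.

## The synthetic world

`fixture_spec()` / `simulate_glycation()` generate the test bed: proteins
of length 200 drawn i.i.d. from a uniform background over the 20 standard
residues, with lysine planted at site centres spaced 25 residues apart
(windows never overlap), 89 positive and 126 negative sites by default —
the scale of the published benchmark. Both classes are K-centred, so
*only* the planted signal separates them. Each positive window receives a
planted pair (default: S and W with spacing k = 4, placed at window sites
9 and 14, straddling the centre) with probability π = 0.9; an optional
factor-shift signal biases one window site's residue by Boltzmann weights
over an Atchley factor.

What the generator does **not** emulate: real amino-acid composition,
within-protein dependence, homology between proteins, multiple signal
motifs with variable placement, or class imbalance beyond the site
counts. A green recovery test therefore establishes that the
encode → rank → select → classify chain detects a localized pair signal
of known strength — not that the package reproduces published accuracy
on real glycation data, which would require the original benchmark
annotations (loadable through `read_fasta()`/`read_annotations()` in the
published format).

An arithmetic consequence of π = 0.9 worth stating plainly: on average
10% of positive windows carry no signal at all and are statistically
identical to negatives, so even a perfect decision rule suffers
FN ≈ Binomial(89, 0.1) and the achievable cross-validated MCC tops out
near 0.92, dipping below 0.9 whenever 11 or more positives go unplanted
(probability ≈ 0.3 per replicate). A fixed MCC ≥ 0.9 bar is therefore met
by most but not all seeds; the recovery suite measures and reports this
honestly rather than tuning the world to pass.

## Tunable parameters

| parameter | default | meaning |
|---|---|---|
| `flank` | 11 | residues each side of the site; window = 2·flank+1 = 23 |
| `kmax` | 4 | largest CKSAAP spacing; 1900 features at 4 (1459 at 3, 2341 at 5) |
| `normalize` | TRUE | divide CKSAAP counts by 23−k−1 |
| `theta` | 1 | discretization width in SDs for MI |
| `k` (folds) | 10 | stratified CV folds |
| `log2C`, `log2gamma` | −5:15:2, −15:3:2 | RBF grid lattice |
| `max_pad` | none | drop windows with more than this many `O`s |
| `seed` | 1 | fold split / generator seed, always logged |

## Degenerate inputs and edge behaviour

Single-class labels error in ranking, grid search and SVM fitting;
empty window lists error in encoding but predict returns an empty frame;
position 0 or beyond the protein errors in extraction; an annotation
referencing a missing protein names the offending ID; `k` larger than
the minority class errors in fold assignment. File round-trips (feature
matrix, ranking, model JSON) serialise doubles at 17 significant digits
and reproduce values bit-exactly.

## Known limitations

* The published headline results (Ac 85.51%, MCC 0.7063, 167 optimal
  features) depend on the original benchmark annotations and on unstated
  fold splits and MI discretization; they are aspirational context, not a
  contract, and nothing in the package asserts them.
* The mRMR ranking is O(N²·n) for a full permutation of N = 1900
  features; `top_n` ranks only the prefix IFS actually consumes.
* The SMO solver targets the benchmark scale (hundreds of samples); it
  builds the full kernel matrix and is not intended for n ≫ 10⁴.

## A minimal run

```{r pipeline, eval = FALSE}
fx <- simulate_glycation(fixture_spec(seed = 1))
win <- build_dataset(fx$proteins, fx$annotations)
fm <- encode_windows(win)
rk <- mrmr_rank(fm, top_n = 20)
res <- run_ifs(fm, rk, sizes = c(1:6, 10, 15, 20),
               grid = svm_grid(log2C = c(-1, 3, 7),
                               log2gamma = c(-7, -3, 1)),
               seed = 1)
res$curve
model <- train_final(fm, res$optimal_features, res$best_config)
predict(model, win)
```

The same pipeline is available as subcommands of the
`inst/cli/glysite` script: `simulate`, `extract`, `encode`, `rank`,
`ifs`, `train`, `predict`, `evaluate`.
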