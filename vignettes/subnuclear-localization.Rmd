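---
title: "Predicting sub-nuclear localization from evolutionary profiles"
author: "subnucleaR"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Predicting sub-nuclear localization from evolutionary profiles}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(subnucleaR)
```

## The prediction problem

Nuclear proteins distribute over thirteen membrane-less sub-structures
(`subnuclear_compartments()`), and many of them also function outside the
nucleus ("traveler" proteins). Experimental annotation of sub-nuclear
localization is sparse and strongly imbalanced: a development set of a
couple of thousand proteins typically puts a third of its annotations in
chromatin, another third in the nucleolus, and leaves the seven smallest
compartments with about a tenth of the annotations between them. A
practical predictor must therefore (i) exploit annotated homologs when
they exist, (ii) generalize from profiles when they do not, and (iii) be
honest about multi-compartment proteins and about predicting nothing.

## The model

### Homology transfer

When the query aligns to an experimentally annotated protein at an
E-value below the task threshold, the donor's complete label set is
transferred. Defaults are 10^-20 for the 13-compartment task and 10^-5
for the traveler task; both are exposed (`evalue_threshold`) because the
right stringency depends on the annotation density of the donor database.
Among eligible hits the one with the highest percent identity (PIDE)
wins; ties break by smaller E-value, then lexicographic subject id, so
the result is independent of hit-table order. Self-hits are excluded
whenever performance is estimated on annotated sets. The transfer's
reliability index is `RI = int(10 * (PIDE - 20) / 8)`: 0 at 20% identity,
100 at 100%. Two decisions were open here and are fixed as follows: `int`
is truncation toward zero, and identities below 20% (possible for
accepted distant hits) clamp to 0 rather than going negative. The donor's
*full multi-label set* is transferred, not a single label, because the
confusion accounting (below) counts each observed annotation separately.

### The profile string kernel

The de novo route represents each protein by its evolutionary profile: an
`L x 20` matrix of non-negative per-position conservation costs, one
column per residue in PSI-BLAST column order (`ARNDCQEGHILKMFPSTWYV`). A
k-mer is *conserved* at a window when the sum of its residues' costs is
strictly below a threshold sigma; the feature map counts, for each of the
20^k k-mers, the windows at which it is conserved. Enumeration is
depth-first with pruning on the partial sum — valid because costs are
non-negative, and verified exactly against exhaustive 20^k enumeration in
the test suite. Kernel values are dot products of these sparse count
vectors, cosine-normalized by default so self-similarity is 1.

Profile files in the PSI-BLAST ASCII layout carry both log-odds and
percentage columns, and nothing in the kernel definition dictates which
to use. The reader defaults to the percentage (frequency) columns with
the transform `cost = -log(max(f, 0.001))`: fully conserved residues cost
0, unobserved residues cost `-log(0.001) ~ 6.9`, and the floor keeps
costs finite. The log-odds columns are available as an option
(`columns = "logodds"`, rescaled per position to `max(s) - s` to stay
non-negative). The kernel parameters default to `k = 4`, `sigma = 6`:
k = 4 balances specificity against the 20^k feature-space size, and
sigma = 6 admits a 4-mer only when its average per-residue cost is below
1.5, i.e. its residues are each roughly among the top quarter of the
position's frequency distribution. Both are per-classifier tuning
parameters in any serious application; they are plain configuration here.

The threshold comparison is strict (`< sigma`, ties excluded), matching
"falls below" read literally; with continuous cost distributions the
choice is measure-zero, and the tests pin it so it cannot drift.

### The SVM battery

Thirteen one-vs-rest soft-margin SVMs operate on the precomputed kernel
matrix; a fourteenth separates travelers from nuclear-only proteins. A
multi-label protein is a positive for each of its compartments. Class
weights are inversely proportional to class frequencies
(`w_class = n / (2 n_class)`) for the compartment battery — the minority
classes would otherwise be swamped — and off for the traveler task, which
is roughly balanced. Every label with a positive decision value is
predicted; no positive value means the explicit outcome "None". The rule
has to allow multi-label output because multi-compartment predictions are
first-class citizens of the downstream agreement analysis.

The weighted C-SVC dual is solved with kernlab's interior-point QP
(`ipop`) rather than a working-set (SMO) method. The reason is
reproducibility: on kernel matrices with near-block structure (tight
within-class similarity), SMO working-set heuristics can stall at
visibly different near-optima depending on sample order, while the
interior-point solve converges to the dual optimum and reproduces
decision values under permutation to ~1e-12. The `tol` configuration
maps to the solver's relative-precision stopping criterion
(`sigf = ceiling(-log10(tol)) + 2`, capped to [5, 12]). The bias is
recovered from the free support vectors (mean of `y - f0`), or from the
midpoint of the KKT-feasible interval when no vector is free. Stored
classifiers carry support ids, support feature vectors, dual coefficients
and bias, so the decision function is reproducible from the serialized
archive alone.

### The combination protocol and reliability

Prediction is strictly either/or: homology transfer when an eligible hit
exists, otherwise the SVM battery. Because each protein is served by
exactly one route, the combined correct-prediction count decomposes
exactly into the homology-route count plus the de novo count — the
combination cannot be worse than its components on the subsets they
serve, and the test suite asserts this identity exactly.

The de novo reliability index rescales the raw decision value by a
reference maximum, `RI = round(raw * 100 / max_raw)`, clamped to
[0, 100] with non-positive scores at 0. Two scoping decisions were open:
the maximum is taken *per label* (matching the per-class structure of the
battery — raw scores of different classifiers are not on a common scale),
and over the *training-fold positives* with positive scores, falling back
to all positive scores for labels whose positives never cross 0. Rounding
is to the nearest integer, half away from zero; clamping handles test
scores exceeding the training maximum. For multi-label de novo
predictions the reported RI is that of the top-scoring label.

## Evaluation machinery

The confusion matrix is predicted-by-observed over the 13 classes plus an
explicit "None" row. Each observed annotation of each protein contributes
total mass exactly 1 to its column: the diagonal when the label was
predicted, the "None" row when nothing was, and otherwise the top-scoring
predicted row by default. The alternative of splitting a miss
over all predicted rows is available (`attribution = "fractional"`);
column sums are identical in both modes, equal to per-class observed
annotation counts. This "once per annotation" accounting makes the
denominator of the overall accuracy `Q(n)` the annotation count, not the
protein count — with multi-label proteins the two differ, and column-sum
bookkeeping only balances under the annotation convention.

TPR and FPR follow their standard percent definitions with `NA` (plus a
warning) on empty denominators. The AUC sweeps thresholds over the
scores, traces (FPR, TPR) and integrates by trapezoid; tied scores move
the operating point diagonally, which makes the result equal to the
rank-sum statistic — the suite checks equality against an independent
pair-counting oracle at 1e-12. Cross-validation is stratified: each
class's members spread over the k folds within one sample of parity,
multi-label proteins stratifying by their rarest label so minority
classes stay represented. Reported percentages round half away from zero.

Accuracy-vs-reliability curves (`ri_curve`) are cumulative with a default
bin width of 20 on the RI scale: at each threshold, coverage is the
retained fraction of proteins and accuracy is `Q(n)` on the retained
subset.

No "random baseline" is hard-wired into the package. Several
inequivalent conventions exist (majority class, frequency-squared
matching, uniform assignment) and they disagree by design; the test suite
instead checks the uniform-assignment limit (`~100/n` on balanced
classes) by simulation.

## Composition spectra and bias correction

The spectrum of a prediction set is the distribution of predicted label
assignments over the 13 compartments (empty predictions excluded). A
classifier with unequal per-class error rates biases these spectra; with
`M[i, j] = P(predicted outcome j | observed class i)` estimated by
column-normalizing a development-set confusion matrix ("None" is a 14th
outcome), the observed outcome distribution is `q = t(M) p`. The
correction inverts this by non-negative least squares with the simplex
constraint (a weighted all-ones row), implemented over `pracma`'s NNLS;
an ill-conditioned `M` (condition number above 1e8) triggers a warning
and a ridge-regularized solve (1e-6). In the noiseless forward-model case
the inversion recovers the planted distribution to 1e-6, and applying it
to the development set's own predicted counts returns the observed class
mix exactly — both are asserted in the tests.

Distances between spectra are Euclidean on the percent scale. No
analytical standard error is attempted; the package bootstraps proteins
within each set (default 1000 resamples) because that is the assumption-
free choice and reproduces the expected 1/sqrt(n) shrinkage.

Agreement between two multi-label predictions is the fraction of the
*larger* set found in the other: `|A n B| / max(|A|, |B|)`. It is 1 only
for identical sets and penalizes over-prediction — a seven-compartment
prediction sharing one label with a two-compartment prediction scores
1/7 ~ 0.14.

## Function and network analytics

GO enrichment of a target set against a background is the upper-tail
hypergeometric probability per term, Benjamini–Hochberg adjusted across
all tested terms; significance is declared on the *adjusted* value at
0.01. The raw-vs-adjusted ambiguity was resolved in favor of adjusted
because that is the only choice under which the 0.01 rule controls the
FDR of the reported term list.

Interaction odds per compartment pair divide observed by expected counts,
the expectation allocating the total observed interaction mass
proportionally to the number of *possible* protein pairs per cell. With
multi-compartment proteins a counting rule must be fixed: a pair (u, v)
contributes once to every unordered label pair {i in labels(u),
j in labels(v)}, in the numerator and the denominator alike, and the
total observed mass is the sum over cells. Using the same rule on both
sides keeps the fixed point at exactly 1 (observed = expected gives odds
1 everywhere) and makes the mass-conservation identity
`sum(num_exp) = num_obs_total` hold by construction; both are tested, the
latter exactly. Evidence filtering (direct physical interactions,
yeast-two-hybrid validated or supported by two publications) happens at
I/O time in `read_edges`, so the graph analytics never see sub-evidence
edges. Self-loops are flagged on reading and excluded from all
statistics.

## The synthetic-data generator

The generator emulates the statistical structure the method assumes,
not biological sequences: each class is marked by `n_motifs_per_class`
(default 3) distinct k-mers planted at `sites_per_motif` (default 3)
non-overlapping positions with per-residue cost `motif_strength`
(default 0.1, far below sigma/k); background cells cost uniformly
2.5–7 (above sigma/k per residue), except that a `noise_prob` fraction
(default 0.02) are "cheap" (0.5–2), which scatters spurious conserved
k-mers through every profile the way real profiles scatter conserved
positions. These defaults put the planted within-class kernel signal well
above the expected noise overlap (~27 vs < 1 in dot-product units) — the
strong-motif regime under which recovery is tested. A `multi_label_frac`
fraction of proteins carries a second class's motifs and label;
travelers carry a dedicated motif set; class sizes can decay
geometrically (`class_size_decay`) to emulate the minority-class regime
of real annotation sets. Motif sites are drawn from k-aligned blocks
sampled without replacement, which guarantees non-overlap at any
configuration. Homology tables cover a controlled fraction of queries
with same-class donors below threshold (plus above-threshold decoys);
interaction networks connect pairs at `within_ppi_rate` /
`between_ppi_rate`; GO tables enrich one designated term per compartment
at a configured odds ratio over a 0.2 baseline.

What the generator does *not* emulate: amino-acid substitution
statistics, alignment-derived profile correlations between neighboring
positions, realistic sequence-level homology, or the long-tailed degree
distributions of real interactomes. Passing the recovery tests therefore
shows that the machinery is correct and well-calibrated on data matching
its assumptions — it does not certify accuracy on real proteomes, where
class signal is far weaker and the published accuracies (on the order of
60–70% for the 13-class task) are the realistic reference point.

## Problem sizes and determinism

The test suite runs the full 13-class x 20-proteins-per-class five-fold
cross-validation (1040 classifier fits collapse to 65 QP solves over
cached feature vectors, about half a minute), 100-profile kernel-oracle
sweeps, 50-replicate interaction-odds calibration and a 1200-draw
permutation null for the enrichment p-values — sizes chosen so the whole
suite stays around a minute while every statistical check retains power.
All randomness flows from explicit seeds: generators are pure functions
of their configuration (seeds are taken modulo offsets per generator so
profile, homology, network and GO draws are independent), and the QP
solver has no stochastic component.

## Known limitations

* Profiles must be precomputed; the package reads PSI-BLAST ASCII PSSMs
  but does not run PSI-BLAST or build profile databases.
* Raw SVM scores are not probabilities; the reliability index is a
  monotone rescaling, not a calibrated posterior (Platt-style calibration
  is deliberately out of scope).
* Hyperparameters (k, sigma, C, tol) are exposed configuration with
  sensible defaults, not per-class tuned values; any production use
  should grid-search them per classifier under cross-validation.
* The bias correction assumes the development-set confusion is
  representative of the target set's error process; transfer across very
  different proteomes violates that silently.
* Kernel feature indices use dense base-20 encoding, so k above 7
  overflows double-precision integer range; practical k stops well below
  that anyway.
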