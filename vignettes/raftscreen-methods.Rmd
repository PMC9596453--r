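---
title: "Methods: pooled microraft screening with model-guided picking"
author: "raftscreen"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: pooled microraft screening with model-guided picking}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(raftscreen)
```

## The screening problem

Pooled optical screens connect a genetic perturbation to a complex cellular
phenotype one cell at a time. Cells carrying a mixture of perturbations —
here, wild-type and pathogenic point mutants of mitofusin 2 (MFN2), whose
pathogenic variants cause perinuclear mitochondrial aggregation — are
seeded on a microraft plate (a grid of 100 × 100 µm releasable rafts),
stained with vital dyes and imaged. Per-cell morphology features feed an
ensemble of binary classifiers trained on *labeled* wells (pure wild-type
or pure mutant populations); the selected model scores every cell in the
*unlabeled* admixture wells, confident rafts are physically isolated, and
each isolated cell is genotyped by amplicon sequencing so predictions can
be evaluated against truth. In screen mode (a CRISPR tiling library with no
labeled mutants), anomaly detectors trained on uninduced control cells
replace the supervised ensemble.

`raftscreen` implements this computational core end to end and, because the
original cells and images are not available, ships a synthetic-data
generator that emulates every input: feature tables with
genotype-conditional structure, two-channel fields, plate layouts, and
paired amplicon reads.

## The synthetic screen

`simConfig()` fixes the study conditions. The defaults mirror the
mixed-variant design: two plates of four wells, three labeled wells per
class interleaved across plates (so a well-wise training split can place
its two training wells on distinct plates), and unlabeled admixture wells
at wild-type:pathogenic ratios of 50:50 and 90:10. The genotype panel is
wild type plus the four pathogenic mutants screened in the mixed pool
(L76P, R94Q, P251A, R280H).

Features are drawn from a block-equicorrelated Gaussian model: blocks of
8 features share pairwise correlation 0.3, the leading 16 features are
*informative* (mean shifted by `effect_size` standard deviations in
pathogenic cells), and every feature receives a per-plate additive offset
with SD `batch_sd` (default 0.5) — the batch structure that makes
cross-plate, well-wise validation necessary. The distributions overlap
heavily at the default `effect_size = 1`: no single feature separates the
classes, only multi-feature models do, which is the regime the method
exists for. Two trailing features are near-exact copies of the well column
index; they are the guaranteed positive control for the leak detector.
Record-level QC variables (nuclear area ~ N(120, 15) px², log-normal
nuclear and cell intensities, Beta-shaped form factor, uniform position in
the raft) have a `debris_fraction` (default 5%) subpopulation drawn from
out-of-gate distributions. Raft occupancy is Poisson truncated to 1..10
(mean 1.5), exercising the >6-cells gate; 2% of rafts carry fiduciary
marks.

What the generator does *not* emulate: realistic optics (no PSF or
aberrations), PCR chimeras and index hopping, cell growth, or the
heavy-tailed, skewed feature distributions of real high-content data.
Passing tests therefore demonstrate the pipeline's correctness and
calibration under a known model, not its performance on real images.

## Imaging front-end

`simulateImageField()` renders nuclei as Gaussian blobs and mitochondrial
puncta at radial distances `nucleus radius + Exp(mean = dispersion)`;
pathogenic cells use a small dispersion (perinuclear aggregation), wild
type a large one. Puncta are placed with a 4 px minimum separation so each
truth punctum is a distinct image object. `segmentNuclei()` is a
deliberately parameter-light stand-in for commercial tracing: Otsu
threshold, connected components, hole filling; the form factor 4πA/P² is
clamped at 1 because discrete perimeters underestimate the true contour.
`detectMitoPuncta()` band-passes the image with a difference of Gaussians
(scales 1 and 3 px, roughly the punctum radius and 3×), thresholds at
median + 5 MAD of the filtered image (falling back to 10% of the peak
response when the MAD is numerically zero, as in noiseless synthetic
fields), takes 3 × 3 local maxima with 2.5 px non-maximum suppression, and
assigns each punctum to the nearest nucleus if within 20 µm of its
boundary — farther puncta are discarded. Raft IDs encode each grid axis as
letter + digit with a base-9 digit (index i → letter 'A' + i %/% 9, digit
(i %% 9) + 1), so grid position (0, 0) reads "A1A1"; the affine
image-to-grid transform is least-squares fitted from at least three
non-collinear fiduciary marks, and cells seen twice in overlapping field
margins are de-duplicated by nearest-centroid matching.

## Quality control

The pipeline order is fixed: interval gates → leaky-feature exclusion →
per-plate normalization. Gate variables follow the screening protocol
(nuclear area, form factor, nuclear and cell intensity, raft-edge
proximity, raft occupancy > 6, fiduciary rafts); the numeric defaults are
the 1%/99% quantiles of the generator's live-cell distributions, since no
published values exist — they are config-exposed and should be recalibrated
for any other data source. Each rejected record gets the first failing gate
in a fixed alphabetical order, making the log deterministic.
Normalization is per plate and feature: subtract the median, divide by the
σ-consistent MAD — robust to residual debris and idempotent to machine
precision; zero-MAD features are dropped and logged rather than erroring.
Leak detection flags features whose rank-based η² across wells (computed
from the Kruskal–Wallis H statistic as (H − k + 1)/(n − k)) exceeds 0.5,
features constant within wells but varying across them, and any user-listed
global features. Because labeled classes necessarily occupy distinct wells,
a sufficiently strong biological feature can exceed the cutoff too; the
cutoff is a deliberate trade-off in favor of never leaking position.

## Modeling

Training labels come only from well roles, never from ground truth.
The well-wise split assigns two labeled wells per class (on distinct plates
whenever possible) to training and the rest to testing; a randomized 80–20
split is available for screen mode. Imbalanced training sets are balanced
by synthetic-minority oversampling: each synthetic point is a uniform
convex interpolation between a minority point and one of its k = 5 nearest
minority neighbors (a size-1 minority class falls back to duplication,
logged).

The model grid crosses three linear algorithms — glmnet logistic
regression, a glmnet ridge classifier on the 0/1 response, and a linear
SVM (e1071) — with regularization strengths and feature subsets produced by
five selection methods: random subsets of 2–20 features, top-k by ANOVA F,
nonzero coefficients of an L1-penalized sparse linear fit (the package's
sparse selector), variance filtering, and greedy correlation filtering
(keeping the higher-variance member of any pair with |r| above the cap).
The default grid is a few hundred models, the scale of the original
screening runs. Every model must emit scores in [0, 1] with 0 = confident
wild type; margin classifiers are squashed through a logistic map, and the
SVM's decision-value orientation is fixed against its training AUC.
Models are scored by test AUC (rank method, ties at half credit), test MCC,
and the *meta-feature* deviation: for each unlabeled well the predicted
positive fraction — computed after excluding scores in [0.4, 0.6], the
same band excluded at pick time — is compared with the well's known
expected mutant fraction; a well whose scores are all excluded contributes
the worst-case deviation 1. Pick-model selection is a deterministic
lexicographic rule: among models within δ = 0.02 of the best test AUC,
prefer the smallest train−test AUC gap, then the smallest meta deviation,
then the fewest features, then the lexicographically smallest model id.
The original selection was semi-manual; this rule is the package's
automated, overridable stand-in. Ensembles are per-cell means of member
scores.

## Picking

Per raft, the score is the mean over member cells, with a conflict veto:
if one member scores ≤ 1 − t and another ≥ t (t = 0.8 by default) the raft
is dropped, as is any raft whose score falls in the open band (0.4, 0.6).
Survivors are ranked by |score − 0.5| (ties by raft ID), the top n per
predicted class are selected, and destinations are assigned row-major
A1..H12 across 96-well plates, with an optional quota of labeled-well
control rafts interleaved at every 8th destination. Equal inputs give
byte-identical pick lists.

## Genotyping

Read pairs are 3′ quality-trimmed (Q10), the second mate is
reverse-complemented, and the pair is merged at the *longest* overlap ≥ 20
bases with mismatch rate ≤ 0.1, resolving disagreements by the higher base
quality (an exact-20-mer seed locates the candidate overlap first; a full
descending scan is the fallback, so the result is identical to scanning
alone). Unmerged mates are searched independently. Fragment counting is
exact and strand-aware: each 20-mer search fragment found as a substring of
the read or its reverse complement increments that fragment once per read;
no mismatches are tolerated, keeping the caller auditable. Per locus, the
%mutant score is mutant reads over total reads; loci under the depth floor
(10 reads by default — the original work states no floor; this prevents
single-read calls) are excluded. The call is *no-data* with no informative
locus, *WT* if no locus exceeds 50% mutant, otherwise the mutant name of
the unique argmax locus, and *ambiguous* on a tie (within 1e-9). The
packaged locus panel carries the published wild-type/mutant 20-mer pairs
and genotyping primers for the MFN2, RFP/GFP and PRIMPOL loci; flanking
context sequences are synthetic (the real amplicon contexts are not
published) and the file is labelled accordingly. gRNA identification
extracts the spacer between fixed vector flanks, assigns the majority
spacer, and reports wells as multi-infected when two spacers each reach
20% of spacer reads.

The simulated mutant allele fraction is 0.6 + 0.4 · Beta(8, 2) (mean
≈ 0.92). A mutant cDNA is overexpressed above the endogenous wild-type
copies, so mutant-majority reads are structural; the rescaled Beta keeps
the >50% rule nontrivially exercised (observed %mutant spans ~0.55–1)
while a raw Beta(8, 2) would make some mutant cells genuinely
wild-type-majority and uncallable in principle. Capture dropout removes a
fraction (1 − 0.8) of rafts entirely, matching the ~80% observed capture.
The default depth, 30 read pairs per locus per captured cell, is a
deliberately small working scale; all depths are parameters.

## Anomaly detection (screen mode)

Detectors are robust distances on random feature subsets: each of 100
detectors draws 8 features and standardizes by control-cell median and MAD;
the raw score is the Euclidean norm. The detector family is a package
choice — the original algorithms are unreported — selected for determinism
and analyzability. Thresholds are the 95th/90th percentiles of raw scores
over *all* scored cells (not controls only), with strict inequality at the
threshold; a cell's anomaly score is the number of detectors placing it in
the top 5% (n_top5) or 10% (n_top10). By construction a control-only
population is flagged at ~5%/10% rates, which the tests verify at
n = 10,000 cells and 100 detectors.

## Evaluation

Predictions join genotype calls on the raft key; ambiguous and no-data
calls and mid-band scores ([0.4, 0.6]) are excluded. The battery includes
empirical ROC with shuffled-label noise curves, confidence-band metrics at
0.7/0.8/0.9 (restricting to scores ≥ b or ≤ 1 − b), stacked confusion
counts, Kruskal–Wallis feature ranking, feature-subset analyses (all
subsets, single-feature, leave-one-out), per-gRNA one-sample t tests
against the control-cell median score with Benjamini–Hochberg step-up at
FDR 0.2, replicate reproducibility, and the rank-sum comparison of per-gRNA
anomaly scores above vs below frameshift-probability thresholds
(0.9/0.8/0.7). Three defaults are package decisions where the original is
unreported: the t-test null value (control median, overridable), the
reproducibility criterion (sign of each replicate's mean relative to the
replicate-wide median of per-gRNA means must agree), and the choice of the
rank-sum test for the frameshift comparison.

## Numerical and design choices

- **Determinism.** One master seed; stages derive child seeds via fixed
  offsets (`childSeed`). Equal config + seed reproduces every table, image
  and FASTQ byte for byte; the pipeline manifest records MD5 digests.
- **AUC.** Rank statistic with average ranks, equal to trapezoidal ROC
  area with half credit for ties; verified against pairwise concordance to
  1e-12.
- **Degenerate inputs.** Single-class test sets flag AUC as undefined;
  zero-MAD features are excluded, not fatal; empty wells produce empty
  FASTQ files; a blank image segments to an empty table.
- **Tie-breaks.** Model selection falls back to the lexicographically
  smallest model id; pick ranking breaks ties by raft ID; threshold ties in
  anomaly scoring fall below the threshold.
- **Problem sizes.** The test and acceptance workloads use a few hundred
  to a few thousand cells per condition, 48-model grids, 200-raft
  genotyping runs, and a 10,000-cell anomaly calibration — small working
  scales chosen for quick, exact reproduction; every size is a parameter.
  The null-calibration design allocates half of its 2,000 cells to
  unlabeled wells so the null AUC is estimated with adequate precision.
  The signal-recovery conditions (effect size 1.0 at 800 cells/well) were
  calibrated once so the selected model's labeled test AUC falls in
  0.85–0.95, the regime where confidence-banded picking is informative.

## Known limitations

Feature distributions are Gaussian by construction; real high-content
features are skewed and heavy-tailed, so gate quantiles and the η² leak
cutoff need recalibration on real exports. The imaging module produces a
documented subset of features, not the full commercial catalog, and makes
no claim of equivalence with proprietary tracing. Indel-aware alignment,
demultiplexing, and edit-outcome calling at Cas9 cut sites are out of
scope: genotyping is exact 20-mer counting on per-well FASTQs.
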