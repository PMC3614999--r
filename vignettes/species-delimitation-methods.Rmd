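---
title: "Methods: integrative species delimitation with leucidelim"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: integrative species delimitation with leucidelim}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(leucidelim)
```

## The problem

Closely related freshwater fishes -- leuciscine cyprinids in particular --
combine high intraspecific morphological variability with frequent
hybridization, so single lines of evidence routinely misclassify specimens
and can even cast doubt on the validity of a species.  The package
implements a delimitation workflow for a four-species sympatric system
(two congeneric *Squalius*-like taxa plus a *Telestes*-like and a
*Rutilus*-like taxon): external shape from 21 two-dimensional landmarks,
six meristic counts, and three molecular markers (mitochondrial cyt *b*,
nuclear RAG1, and the non-coding Cyfun P region), integrated by a
two-block partial least squares (PLS) model of shape-genetics covariation.

## Shape: superimposition and shape variables

`gpa_align()` performs partial Procrustes superimposition: every
configuration is centered, scaled to unit centroid size (the square root of
summed squared landmark-to-centroid distances), and iteratively rotated
onto the running consensus by the least-squares SVD rotation.  Choices that
matter:

* **Partial, not full, fitting.** Unit centroid size is imposed once;
  no secondary scaling happens during rotation, because size removal and
  rotation are conceptually distinct steps of the registration.
* **Proper rotations only.** Reflections are disallowed (rotation
  determinant forced to +1); all specimens are digitized as left-lateral
  views, so a reflection could only ever hide a data error.
* **Convergence and orientation.** Iteration stops when the consensus
  root-mean-square change drops below 1e-10 (at most 100 iterations).
  The converged consensus is rotated onto its principal axes with a fixed
  sign convention, which makes the output invariant to input order --
  without this step the orientation would inherit from whichever specimen
  came first.

`bending_energy_basis()` builds the thin-plate-spline kernel
$U(r) = r^2 \log r^2$ over the consensus landmarks and eigen-decomposes the
bending-energy matrix.  For 2-D data exactly three eigenvalues are zero
(the affine null space); the eigenvectors with positive bending energy are
the principal warps.  The two uniform (affine) shape directions are built
by the complement method: the span of the four linear deformations of the
consensus, with the similarity directions (scaling and rotation) projected
out and the remainder orthonormalized.

`partial_warp_scores()` projects each specimen's residual from the
consensus onto the principal warps (x and y separately) plus the two
uniform directions, giving the W′ matrix with $2k-4$ columns (38 for
$k = 21$).  Two deliberate conventions:

* **Orthonormal warp basis (α = 0).**  Scores are an isometric rotation of
  Procrustes tangent space, so the CVA downstream does not depend on warp
  scaling, and the row sum of squares equals the squared tangent residual
  norm -- a property the tests exploit directly.
* **Tangent projection.**  Unit-size scaling leaves each residual with a
  small component along the consensus direction (of order residual²/2);
  it is removed by orthogonal projection before scoring, so the score
  space is exactly the $2k-4$-dimensional tangent space.
* **The uniform term is included by default.**  Full separation of four
  groups needs the complete shape space; analyses that used only
  non-uniform warps can set `include_uniform = FALSE`.

## Shape: group separation

`fit_cva()` solves the between/within generalized eigenproblem with the
pooled within-group covariance on divisor $n-g$, by Cholesky whitening.
Shape data usually have more variables than within-group degrees of
freedom, so when the within matrix is singular the features are first
projected onto principal components, keeping eigenvalues above 1e-10 (and
at most $n-g$ components) -- the same internal reduction geometric
morphometrics software applies.  Canonical scores are normalized to unit
pooled within-group variance; group separation is reported as Mahalanobis
distances between group means in the full within-group metric.

`loo_crossvalidate_cva()` refits group means and the pooled covariance
without each specimen and assigns it to the nearest group in the refitted
Mahalanobis metric, with uniform priors.  The superimposition (and the
one-time principal-component reduction) are *not* refitted per fold:
re-running the registration without one specimen of 145 perturbs the
consensus negligibly, and refitting it would couple the folds through an
essentially identical consensus anyway.  `cva_permutation_test()` permutes
labels within each pair of groups and reports
$p = (1 + \#\{d_{perm} \ge d_{obs}\})/(n_{perm}+1)$.

## Meristic counts: the identification key

`fit_crt()` grows a binary classification tree on the six ordinal counts
(NSLL, NSALL, NSULL, NRDF, NRPF, NRAF) by exhaustive Gini search over all
midpoints between consecutive observed values.  Ties in impurity decrease
are broken by predictor order then by the lower threshold, so trees are
fully deterministic.  Records at a threshold go left (the "≤" rule).
Stopping defaults are `min_parent = 10`, `min_child = 5`, `max_depth = 5`:
with 145 specimens, the classical defaults of the desktop statistics
packages (minimum parent 100) cannot produce a four-leaf key at all, so
smaller limits are the only way this design can yield one leaf per
species.  Validation is stratified 10-fold cross-validation with a fixed
seed (leave-one-out is available via `cv_folds = "loo"`).

## Molecular summaries

A column of an alignment is *variable* when it contains two or more
distinct bases among A, C, G, T: variation that exists only through N is
ignored, and a column with gaps but a single base is not variable (for the
coding markers the deposited sets have no indels, so this convention
matches the standard count).  Haplotypes are exact-match collapses with N
kept distinct.  Percent identity excludes gapped positions from both
numerator and denominator; `global_align()` (Needleman-Wunsch with match
+1, mismatch -1, gap open -5, gap extend -1, via Biostrings) serves the
indel-rich Cyfun P marker.  Diagnostic differences between two taxa are
columns fixed for different bases (classified transition/transversion)
plus maximal gap blocks fixed in one taxon and absent in the other.
Band-length attribution assigns ~310 bp to the *Telestes*-like taxon,
~440 bp to the *Rutilus*-like taxon and ~410 bp to the genus
*Squalius* (species-ambiguous), each ±15 bp.

`p_distance_matrix()` computes uncorrected p-distances with pairwise
deletion; with both phylogenetic markers supplied it averages the two
matrices per pair, unweighted.  The source analysis did not state the
metric behind its distance table, so the metric is pluggable (p,
Jukes-Cantor, Kimura 2-parameter) and recorded in `metric_tag`.
`pcoa()` embeds the matrix by Gower double-centering (Lingoes and Cailliez
corrections available; a correction requested when no negative eigenvalues
exist is a logged no-op), and exactly two axes feed the downstream PLS
block.  Axis signs are fixed so each axis's largest-magnitude loading is
positive.

## Integration: two-block PLS

`two_block_pls()` takes the SVD of the $p \times q$ between-block
covariance (divisor $n-1$) between the W′ shape block and the two PCoA
axes.  Covariance -- not correlation -- is the default, matching the
morphometric convention; a correlation mode exists because block
standardization was not stated in the source analysis.  Each latent pair
reports the Pearson correlation R of its paired scores; the linear fit of
the first pair is summarized as $R^2 = R_1^2$, and monotonicity
additionally by a Spearman rank correlation.  `pls_permutation_test()`
permutes rows of the genetic block (999 permutations by default, one-sided
upper tail); for $n \le 7$ it enumerates all $n!$ permutations exactly.
P-values are reported per pair without multiplicity correction -- the
first pair carries the integration question, and the tests confirm the
per-pair null calibration.

`integration_report()` flags specimens whose position along the first
genetic latent axis falls on the opposite half-plane from their labeled
group.  A group can only flag its minority when it is coherent (at least
90% of members on one side); without this guard a homogeneous group
straddling zero would flag arbitrary specimens.

## The synthetic study

The generator plants known structure so every stage can be tested against
ground truth.  Its defaults emulate the study system:

* **Group sizes** default to (65, 26, 27, 27) -- the sampling design of
  the real survey -- so paper-scale behaviour is the default test
  condition.
* **Mean shapes** are four deformations of one 21-landmark fish outline,
  contrasting body depth (streamlined *Squalius*-like vs deeper-bodied
  others), dorsal-fin position, eye height and caudal-peduncle height --
  the contrasts the canonical axes of the real data describe.  Closest
  pair separation is ~0.033 Procrustes units.
* **Within-group noise** defaults to sd 0.004 (centroid-size units) per
  landmark coordinate, doubled for the *S. lucumonis*-like species
  (its real counterpart shows twice the intra-group spread).  This value
  places the largest between-species Mahalanobis distance near 14-15 and
  leave-one-out accuracy in the low-to-mid 90s -- the regime the original
  analysis reports.
* **Meristic ranges** overlap realistically: NSLL separates the
  *Squalius*-like pair (43-50) from the *Rutilus*-like (36-42) and
  *Telestes*-like (50-58) taxa, with NRAF and NRPF refining the remaining
  contrasts; cross-validated key accuracy sits near 91%.
* **Sequences** evolve from one random ancestor by site-independent
  equal-rate substitution (divergence 0.06 for cyt *b*, 0.007 for RAG1,
  0.015 for Cyfun P).  The two *Squalius*-like species share a clade
  ancestor, splitting the root-to-tip divergence 40/60 on stem and tips
  for the coding markers (75/25 for Cyfun P), which reproduces the
  observed pattern: congeners most similar (~93% cyt *b* identity vs
  ~87-88% across genera) and only a few fixed Cyfun P differences.
  Within-species haplotype variants arise at divergence/20.  Cyfun P
  additionally carries the species-specific deletion blocks that give the
  310/410/440 bp band lengths, including the 17 bp terminal deletion
  diagnostic of the *S. lucumonis*-like species.
* **Integrated datasets** (`simulate_integrated()`) build each specimen's
  shape as the base outline displaced along two orthonormal tangent
  directions in proportion to its PCoA coordinates, so shape offsets are
  proportional to genetic distances by construction.  Noise is calibrated
  analytically from $R = \beta\sqrt{\lambda_1}/\sqrt{\beta^2\lambda_1 + s^2}$
  so the expected first-pair PLS correlation equals `target_R`; the
  planted value is recorded in `truth`.  An optional planted outlier swaps
  one specimen's sequences to another species *after* shapes are built --
  the genotype/phenotype mismatch scenario.  Note that these shapes live
  on a two-dimensional subspace of shape space, so CVA accuracy on
  integrated datasets is intentionally lower than on
  `simulate_landmarks()` output; each generator targets its own property.

What the generator does **not** emulate: allometry (no size-shape
covariation), semilandmarks or outline data, digitizing error structure,
coalescent genealogies and incomplete lineage sorting, indel evolution
beyond fixed species-specific blocks, transition/transversion bias
(configurable in principle but uniform by default), and ecological or
geographic structure.  Passing tests therefore demonstrate correctness of
the estimators under planted structure, not robustness to every feature of
real data.

## Numerical choices and degenerate inputs

GPA tolerance 1e-10 (consensus rms change), 100 iterations; coincident
landmarks raise a singular-kernel error in the TPS basis; all-coincident
configurations are rejected at centroid-size computation.  CVA requires
every group twice-occupied and errors on rank deficiency that survives the
principal-component reduction.  The tree refuses all-constant predictors
and `min_child >= min_parent`.  Sequence parsing rejects residues outside
A, C, G, T, N, "-" with record and position; grouped operations refuse the
defaulted "unknown" taxon label.  Permutation p-values use the
add-one convention, so the smallest attainable p is $1/(n_{perm}+1)$.

## Problem sizes used by the tests

The suite runs at the study's own scale where the property demands it
(145 specimens for parameter-recovery checks: 20 seeds for classifier
accuracy, 50 for PLS recovery, 100 for outlier flagging) and at reduced
scale (8-12 per species) for structural checks; permutation calibration
uses 500 null replicates of 99 permutations each.  These sizes keep every
statistical check at the replication its acceptance band assumes.

## Known limitations

Real landmark data carry digitizing error and allometric variation that
the generator omits; the identification key's thresholds are only
qualitatively comparable to any particular empirical key; p-distance
averaging over two markers weights them equally regardless of length or
rate; and the deposited-sequence checks require a one-time network fetch
of the GenBank accessions (`fetch_genbank()`), without which the
corresponding acceptance test reports the data as unavailable.
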