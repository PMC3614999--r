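# leucidelim

Integrative species delimitation for sympatric leuciscine fishes.

Closely related cyprinid fishes of the northern Mediterranean combine high
intraspecific morphological variability with frequent hybridization, so any
single line of evidence — body shape, countable (meristic) characters, or a
single molecular marker — routinely misassigns specimens and can cast doubt
on whether a taxon is a valid species at all.  `leucidelim` implements a
complete delimitation pipeline for a four-species sympatric system (two
congeneric *Squalius*-like taxa plus a *Telestes*-like and a *Rutilus*-like
taxon) that analyses each line of evidence on its own terms and then
integrates shape with genetic distance in one quantitative model, flagging
the specimens on which the approaches disagree.

## What it computes

* **Geometric morphometrics** — generalized Procrustes superimposition
  (translation, unit-centroid-size scaling, least-squares rotation) of
  21-landmark configurations; thin-plate-spline decomposition of the
  Procrustes residuals into the W′ matrix of partial warps plus the uniform
  component; canonical variate analysis (CVA) on W′, maximizing
  between-group relative to pooled within-group variance, with Mahalanobis
  distances between group means, pairwise permutation tests, and
  leave-one-out cross-validated classification.
* **Meristic key** — a classification tree (Gini impurity, exhaustive
  threshold search, deterministic tie-breaking) over six ordinal counts
  (NSLL, NSALL, NSULL, NRDF, NRPF, NRAF), rendered as a dichotomous
  identification key with stratified cross-validation.
* **Molecular summaries** — variable sites, haplotype collapse, percent
  identity (with Needleman–Wunsch global alignment for the indel-rich
  Cyfun P region), diagnostic substitutions (transitions/transversions) and
  fixed indel blocks, amplicon band-length attribution, uncorrected
  p-distances (JC69/K80 pluggable) averaged across markers, and principal
  coordinate analysis (PCoA).
* **Integration** — two-block partial least squares: the SVD of the
  covariance between the shape block (W′) and the genetic block (two PCoA
  axes) yields paired latent vectors; the first pair's correlation R (and
  R²) measures shape–genetics integration, a permutation test gives its
  strength, and a report flags specimens whose genotype places them on the
  wrong side of the first genetic latent axis — the signature of a
  misassigned or introgressed individual.
* **Synthetic study generator** — four-species datasets (landmarks,
  meristics, three markers) with planted, parameter-controlled structure
  and analytic ground truth, including a calibrated target for the first
  PLS correlation and an optional planted genotype/phenotype outlier.

## Worked example

```r
library(leucidelim)

# a full synthetic study at the real survey's group sizes (65, 26, 27, 27),
# with planted shape–genetics covariation R = 0.9 and one specimen whose
# sequences were swapped to another species
ds  <- simulate_integrated(seed = 42, target_R = 0.9,
                           planted_outlier = c("Sl", "Rr"))
rep <- run_pipeline(ds, n_perm = 999, seed = 42)
print(rep)
#> Integrative species-delimitation report
#>   specimens: 145, species: Rr, Sl, Ss, Tm
#>   shape LOO cross-validation: 77.9% correct
#>   meristic key cross-validation: 92.4% correct
#>   PLS first-pair R = 0.907 (R^2 = 0.82, p = 0.001)
#>   genotype/phenotype disagreement flagged: Sl01
```

The fitted first-pair correlation (0.907) recovers the planted 0.9; the
permutation p-value is the smallest attainable with 999 permutations; and
the planted outlier `Sl01` — a morphological *S. lucumonis*-like specimen
carrying *R. rubilio*-like sequences — is exactly the specimen flagged.
(CVA accuracy is lower on integrated datasets than on plain landmark
simulations because their shape variation is deliberately confined to the
two genetically driven dimensions.)

The shape and meristic stages on their own, at the same scale:

```r
cfg <- simulate_landmarks(seed = 42)
g   <- gpa_align(cfg)
pw  <- partial_warp_scores(g, bending_energy_basis(g$consensus))
round(fit_cva(pw)$mahalanobis, 2)
#>       Rr    Sl    Ss    Tm
#> Rr  0.00 14.66 16.42  8.85
#> Sl 14.66  0.00  6.00 13.88
#> Ss 16.42  6.00  0.00 13.28
#> Tm  8.85 13.88 13.28  0.00
loo_crossvalidate_cva(pw)$overall_correct_pct
#> [1] 95.17241

tree <- fit_crt(simulate_meristics(seed = 42), seed = 42)
print(tree)            # dichotomous key: NSLL splits first, NRAF/NRPF refine
#> ...
#> Cross-validated correct: 93.8%
```

Mahalanobis separations in the mid-teens with leave-one-out accuracy in the
90s, and a meristic key led by NSLL, are the regime this study system
exhibits.

A thin command-line front end wraps the same functions
(`inst/cli/leucidelim.R simulate|gpa|cva|crt|seqstats|pcoa|pls|pipeline`).

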