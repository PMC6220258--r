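---
title: "Models and methods behind rarescan"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind rarescan}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

rarescan implements a whole-genome rare-variant analysis toolkit for
quantitative traits in cohorts with cryptic relatedness, of the kind used
in deep-sequencing studies of population isolates: variant-set (burden)
association tests adjusted for kinship, a ten-condition masking and
weighting scheme spanning coding and regulatory variation, a study-wide
multiple-testing threshold built on the effective number of testing
conditions, haplotype-based selection scans (iHS) with gene-level
summaries, Hudson F_ST population differentiation, and resampling-based
comparison of rare-variant counts between cohorts of unequal size. A
synthetic cohort generator provides data with the statistical structure
every stage assumes, so the entire pipeline is testable without access to
any controlled-access dataset.

This vignette documents the models, the parameters that matter, the
numerical choices, and the design decisions taken where the methodology
left room.

## The null mixed model and the set test

The association engine works on the standard polygenic model
`y = Xb + g + e`, with `g ~ N(0, sigma2_g * A)` and
`e ~ N(0, sigma2_e * I)`, where `A` is a genetic relatedness matrix on the
"2 x kinship" scale (outbred diagonal near 1). `fit_null_lmm()` estimates
the variance components by REML: a single spectral decomposition of `A`
diagonalises the covariance, and the restricted likelihood is profiled
over the heritability ratio `h2 = sigma2_g / (sigma2_g + sigma2_e)` with
Brent search on `[0, 1)`. With `A = 0` the fit reduces exactly to ordinary
least squares (the unit tests assert agreement to 1e-8). The fitted object
behaves like any R model fit: `print`, `summary`, `coef`, `residuals`,
`fitted`, `predict`, `logLik` and `simulate` methods are provided, and the
decomposition is reusable across traits or simulation replicates via
`kinship_eigen()`.

`set_test()` computes, for a weighted variant set, the family of score
statistics `Q_rho = (1 - rho) * Q_SKAT + rho * Q_burden` on the
variance-decorrelated residuals, over the grid
`rho = {0, 0.01, 0.04, 0.09, 0.16, 0.25, 0.5, 1}`. Each `Q_rho` follows a
mixture of chi-square(1) distributions under the null, with weights given
by the eigenvalues of the projected, weighted genotype cross-product; the
combined optimal-rho p-value comes from the published minimum-p
construction, integrating the survival function of the non-burden
component against the chi-square(1) density of the shared burden
component. The combined p-value is clamped to
`[min_rho p_rho, n_grid * min_rho p_rho]`, its analytic envelope.

Chi-square-mixture tails are computed by `pchisqsum()`. The default route
is a full-range Lugannani-Rice saddlepoint approximation of the
cumulant-generating function, which is asymptotically exact in the tails
and agrees with characteristic-function inversion to better than a few
percent in the body; numerical inversion of the characteristic function
(Imhof-type integral, truncated where the oscillating envelope bounds the
remainder) is retained as a cross-check route, and Liu-style moment
matching serves as the fallback at the distribution centre where the
saddlepoint degenerates. The choice was driven by numerical behaviour:
the inversion integral carries absolute error around 1e-8 and can return
garbage in the far tail, while the saddlepoint remains stable down to the
reporting floor of 1e-300.

Single-variant tests (`single_point_score_test()`) are mixed-model score
tests with score-based effect estimates; p-values below 1e-300 are floored
and flagged. Conditional analysis (`conditional_test()`) appends
conditioning covariates — raw genotypes, carrier status (at least one
minor allele across the named variants), or the per-sample count of minor
alleles over a mask — to the fixed effects, refits the null and repeats
the test. `prioritise()` classifies suggestive burdens (p at or below
5e-5): if conditioning on the set's top single-point variant leaves a
conditional p above 5e-3 the burden is flagged single-variant-driven, and
if conditioning on a known signal in the region leaves a conditional p
above 1e-4 it is flagged as recapitulating the known association. The
published description of these rules reads, literally, as excluding
burdens whose conditional p *drops below* those bounds, which would
discard exactly the strongest independent signals; we implement the only
reading under which the procedure does what it is described as doing, and
flag it here as an interpretation.

## Masks, weights and filters

`burden_conditions()` defines the ten testing conditions: unweighted
high-confidence LoF, unweighted LoF of either confidence, unweighted
high-severity exonic variants ("more damaging than missense", using a
fixed severity ordering shipped as `consequence_levels()` and editable by
the caller), CADD-weighted exonic variants with and without a
genome-wide-median filter, CADD-weighted 50 bp-padded exons, and
Eigen-based weighting over padded exons plus regulatory features
(shifted Eigen, Phred-rank Eigen, Phred-rank EigenPC) or regulatory
features alone (Phred-rank Eigen).

Weight transforms must be strictly positive. `phred_scale()` maps a score
to `-10 log10(rank / N)` by descending mean rank (ties share their rank
range); the bottom rank, nominally zero, is floored at 1e-6, as is any
other non-positive weight. `shift_eigen()` adds one unit and floors
non-positive results at 1e-6. Ranks are computed against the cohort's own
annotated score distribution by default, with an argument for an external
reference table. The genome-wide CADD median is likewise computed from the
input annotation set and overridable.

Regulatory features attach to genes by direct overlap with the gene's
exonic hull, or through any eQTL position linked to the gene; a feature
whose eQTL is reported for several genes is assigned to all of them, and
tissue is ignored. Pre-test filters keep variants with MAF below 0.05,
missingness below 1%, and an exact Hardy-Weinberg mid-p of at least 1e-5
(`hwe_midp()` enumerates the Levene-Haldane distribution of the
heterozygote count; "mid-p" counts half the probability of outcomes
exactly as likely as the observed one). A set is tested only when at least
two variants survive.

## Relatedness

`compute_grm()` builds the centered, frequency-standardised GRM over
common (MAF at least 0.05), well-called, LD-pruned variants, with missing
dosages mean-imputed. The diagonal is replaced by `1 + F_hat`, the
method-of-moments inbreeding estimate from observed versus expected
homozygosity, because downstream kinship-aware set tests require explicit
self-kinship. This replacement can nudge small eigenvalues slightly
negative; `kinship_eigen()` clips mild dips and errors only on structural
indefiniteness. `ld_prune()` is a deterministic greedy left-to-right scan
(defaults r2 0.2, window 500 kb — unstated in the source methodology and
exposed as arguments). `estimate_pihat()` implements the method-of-moments
IBD estimator from IBS sharing counts and allele frequencies (PLINK
`--genome`-style, without the small-sample bias corrections; bit-for-bit
agreement with PLINK is not claimed), and `prune_related()` removes one
random member of each pair above pi-hat 0.2 until none remains,
deterministically under a seed.

## Multiple testing

`zscore_matrix()` converts per-gene p-values to z-scores; conditions are
compared by pairwise-complete correlation and clustered by average linkage
on the distance `1 - |r|`, cut at `|r| = 0.8` (`effective_conditions()`).
The published analysis judged the clustering visually; the fixed cut
height is this package's operationalisation and is exposed as an argument,
with an eigenvalue-based effective-tests count reported alongside for
comparison. The study-wide threshold is `alpha / (N * n_cond * M)` with
`N` the mean number of genes tested per condition; with the published
inputs (N = 13,854, 3 effective conditions, 6 traits) it reproduces
2.0e-7 at two significant figures.

## Selection scans

Sites enter the iHS scan if they are biallelic single-base SNVs with MAF
at least 0.05, a known ancestral allele, HWE mid-p at least 1e-30 and
mappability at least 0.8. `ehh()` computes extended haplotype homozygosity
as the probability that two distinct carrier haplotypes are identical from
the core outward; `unstandardized_ihs()` integrates both alleles' decay
curves against genetic distance by the trapezoid rule, truncating at
EHH < 0.05 (the segment reaching the cutoff is included; there is no
maximum-gap rule), and reports `ln(iHH_ancestral / iHH_derived)` — negative
when derived haplotypes are long, as under a recent sweep. Sites whose
integration reaches a chromosome end before the cutoff are flagged and
excluded by default, mirroring the small edge-effect exclusion in the
source analysis whose exact rule is unstated. Raw scores are standardized
to mean zero and unit variance within 82 equally spaced derived-allele-
count bins spanning `[1, 2n - 1]`; bins with fewer than two records merge
into their nearest occupied neighbour. Both the EHH walk and the full iHS
are verified against brute-force all-pairs implementations to 1e-9 in the
test suite.

Gene-level summaries use four region definitions: (1) exons, (2) exons
padded by 50 bp plus assigned regulatory features, (3) the hull spanned by
the exons, (4) the hull of definition 2. Per gene, the fraction of
contained iHS-bearing SNVs with |standardized iHS| above 2 is compared to
the empirical distribution over all genes with at least one such SNV, as a
midrank percentile; matched mode restricts the comparison to genes whose
SNV count is within 10% of the target's, which also serves as the
gene-length conditioning. F_ST uses the Hudson estimator per SNP with the
weighted-mean (ratio-of-averages) combination.

## Cohort comparison

`compare_sfs()` judges the rare-variant spectrum of a smaller cohort
against size-matched subsamples of a larger one: per minor-allele-count
class, the one-sided smoothed empirical tail probability
`(#{at least as extreme} + 1) / (n_reps + 1)`; when the observation lies
outside the replicate range, a normal distribution is fitted to the
replicate counts and its tail reported, tagged `normal-fit` — the same
mechanism the source analysis used for deviations too large for empirical
quantiles. MAC/MAF conversions follow the reporting convention of two
significant figures.

## The synthetic cohort generator

The generator is a mosaic-of-founders model, not a coalescent: each sample
haplotype is stitched from a pool of founder haplotypes with breakpoints
drawn as a Poisson process on the genetic map (`mosaic_generations`
breakpoints per Morgan in expectation). This is sufficient to create the
two features the downstream analyses rely on — reduced haplotype diversity
with extended-haplotype structure, and a rare-enriched frequency spectrum —
at desk scale. Rare variation has two layers: founder variants whose
founder allele counts follow a `k^-gamma` spectrum, and private mutations
placed directly on 1-10 haplotypes with probability proportional to 1/k.
Under the isolate preset (40 founders, gamma 1.2, 60% private) the
majority of variants have MAF below 0.01, echoing the roughly 60% rare
share reported for deep whole-genome callsets; the cosmopolitan preset
(400 founders, flatter spectrum, 30% private) has a markedly smaller rare
share. These presets are stylised: they reproduce the rare-share contrast
the tests exercise, not the finer observation that isolates carry
relatively fewer singletons than cosmopolitan cohorts.

Pedigree relatedness is injected by explicit meioses: duplicates,
parent-offspring pairs and full-sib pairs, with the grandparental origin
of every transmitted allele recorded so IBD states can be audited
directly. Crossover counts default to 35 per meiosis — a human-genome-
scale map length — treating the single simulated chromosome as a stand-in
for a whole genome, so realized IBD sharing concentrates near its pedigree
expectation the way genome-wide sharing does; with per-chromosome
crossover counts, sib-pair sharing would be wildly variable and kinship-
recovery checks meaningless. Partial sweeps copy a single donor haplotype
onto a chosen fraction of haplotypes within a window around a core allele,
which creates the extended-haplotype homozygosity a recent sweep leaves
without simulating selection dynamics.

Traits follow `y = a + sum_j beta_j dosage_j + e` with polygenic
`a ~ N(0, h2 * 2K)` against the pedigree kinship and noise variance
defaulting to `1 - h2`, so the baseline variance is 1 and causal effects
are in trait-SD units, matching the reporting convention of effect sizes
like 2.59 SD for rare burden drivers. The pipeline's simulated burden
genes receive causal variants drawn from rare exonic variants (minor
allele count 3-15 by default) which are then re-annotated as LoF-class
with severity-consistent CADD/Eigen scores: burden drivers being damaging
variants is precisely the architecture the testing conditions are designed
to capture, and leaving causal status independent of annotation would test
a different (and uninteresting) scenario. Annotation scores are gamma
(CADD) and normal (Eigen/EigenPC) draws with severity-dependent location
shifts, recorded in the annotation table's attributes so tests can check
them.

What passing tests on this generator do show: correct mathematics of the
tests and scans (oracle equivalence), correct null calibration under
cryptic relatedness, and power against the architectures simulated. What
they cannot show: robustness to sequencing artefacts, genotyping error,
population stratification beyond simple relatedness, INDEL realism, or
annotation error — none of which the generator emulates.

## Problem sizes and numerical choices

The test suite runs the calibration study at n = 500 with 2,000 null
replicates (the binomial 95% band at alpha = 0.05 is then
[0.040, 0.060]), the burden-recovery study at n = 400 over 50 seeds, the
sweep-percentile study at n = 150 with ~9,000 sites over 10 seeds, and the
F_ST and spectrum studies at 16,000 and 6,000 sites respectively; the
acceptance script uses the same designs with reduced replicate counts.
These sizes were chosen as the smallest at which the binomial/KS bands are
meaningful, and are stated here so that readers scaling the studies up
know what the defaults were.

Other fixed numerical choices: weight floor 1e-6; p-value floor 1e-300;
REML convergence tolerance 1e-9 on the profile; PSD clipping threshold 5%
of the top eigenvalue; EHH cutoff 0.05; iHS bins 82; percentile ties by
midrank; all intervals 0-based half-open internally with 1-based inclusive
coordinates at VCF boundaries; every stochastic routine takes an explicit
seed and restores the caller's RNG state.

## Known limitations

Binary traits are out of scope; the set test assumes a quantitative trait
with an approximately normal residual. The pi-hat estimator matches PLINK
only to method-of-moments level. The generator's linkage structure is
mosaic, not coalescent, so fine-scale LD decay is not realistic. The
selection scan's percentile machinery needs tens of genes with iHS-bearing
SNVs to be informative, and the effective-conditions count depends on the
fixed |r| = 0.8 cut where the source analysis used visual judgement.
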