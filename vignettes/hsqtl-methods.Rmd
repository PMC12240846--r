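---
title: "Methods: phenotype-to-QTL mapping for heterogeneous-stock cohorts"
author: "hsqtl"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: phenotype-to-QTL mapping for heterogeneous-stock cohorts}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

hsqtl re-implements, as a tested pipeline over synthetic cohorts, the
analysis chain used for behavioral genome-wide association in outbred
heterogeneous-stock (HS) rodents: SNP quality control, two-site phenotype
preparation, GREML SNP heritability, leave-one-chromosome-out (LOCO)
mixed-model association with permutation thresholds, rule-based QTL calling
with conditional mapping and LD intervals, annotation colocation, and
network-based clustering of animals into addiction-severity phenotypes.
This vignette records the models, the tunable parameters and their defaults,
the numerical choices, and what the synthetic cohorts can and cannot show.

## The synthetic cohort generator

HS animals descend from eight inbred founder strains, so each genome is a
mosaic of founder haplotypes. The generator draws binary founder haplotypes,
then builds each individual as two per-chromosome mosaics whose breakpoints
follow a Poisson process on a uniform genetic map.

Two features matter for realism and were chosen deliberately:

* **Accumulated recombination.** `recomb_rate` defaults to 0.5 crossovers
  per Mb per haplotype. An HS colony recombines over many breeding
  generations (~50 at roughly 1 cM/Mb), so the *effective* map density seen
  in a cross-sectional cohort is far above the single-meiosis rate. At a
  single-meiosis rate the simulated genomes carry whole-chromosome founder
  segments, and association scans show isolated "composite-tag" spikes —
  single SNPs that happen to correlate with several distant causal variants
  at once — which the support-SNP rule (correctly) rejects.
* **Haplotype-block founder patterns.** Founder allele patterns come in
  geometric runs (`founder_block_snps`, default mean 8 SNPs) within which
  each SNP copies its neighbor's pattern with a small per-founder flip
  probability (`founder_mutation`, default 0.01). Real variants arise on
  shared haplotype backgrounds, so dense panels contain near-duplicate tags;
  with independently drawn patterns no SNP can tag its neighbor at high
  r^2 no matter how dense the panel, and the 0.5 Mb / 2 log-unit support
  rule becomes unsatisfiable by construction rather than by evidence.

Traits are built as `y = site + sex + sum_k beta_k x_k + u + e`. Planted QTL
dosages are standardized so `beta_k = sqrt(variance fraction)`; the planted
position snaps to the nearest *polymorphic* simulated SNP and the realized
SNP is recorded as ground truth, so mapping tests have an exact causal
marker. The polygenic term `u` is a random-weight combination of the
standardized non-causal SNPs — hence exactly GRM-distributed — rescaled to
`h2_poly`; it is orthogonalized against the planted QTL dosages first,
because background SNPs in LD with a QTL would otherwise add a random
increment to its effect and the configured variance fractions would hold
only on average, not per cohort. Default effect sizes of 2.5–3% of trait
variance reflect the alleles cohorts of ~1000 HS animals are powered to
detect; site effects default to a shift of 0.5 SD and a variance scale of
1.3 at the second site, and the male–female shift to 0.2 SD, so the
preparation stage has realistic structure to remove.

The progressive-ratio schedule (`progressive_ratio_schedule()`) uses the
operant formula `5 e^{0.2 n} - 5`, rounded to the nearest integer with a
floor of one lever press; the first nine requirements are
1, 2, 4, 6, 9, 12, 15, 20, 25.

The clustered-cohort generator plants three severity groups. Each group's
trait-mean vector is a severity *level* (resilient −s, intermediate 0,
vulnerable +s, for separation `s` in within-group SD units) plus a
group-specific zero-mean *profile shape* of amplitude `s`. The split is
forced by the network construction: rat–rat similarity is the Pearson
correlation between two animals' standardized trait vectors, which centers
each animal's own profile, so a uniform severity shift is invisible to the
network; only the shape component is. Shapes are balanced ±1 orthogonal sign
patterns (where the trait count is a multiple of 4) so that per-cell trait
rescaling cannot distort one group's profile more than another's. The
default battery has 12 traits; with many fewer, pairwise correlations over
so few coordinates are too noisy for reliable recovery at any separation.

## Genotype QC

Dosages are counts of the alternate allele. Per-SNP statistics are the call
rate, the minor allele frequency among non-missing calls, and a 1-df
chi-square goodness-of-fit test against Hardy–Weinberg proportions computed
from the sample allele frequency (monomorphic SNPs get p = 1 by convention).
The three filters — missingness ≤ 10%, MAF ≥ 0.5%, HWE p ≥ 1e-10 — are
conjunctive and *inclusive* at their thresholds. The chi-square rather than
an exact HWE test is a documented, swappable choice: at the extreme 1e-10
cutoff the asymptotic/exact distinction does not change any retention
decision at usable sample sizes. Missing dosages are excluded from MAF/HWE
computation and mean-imputed only where the GRM and association tests need
complete data. Positions are 1-based; intervals are closed.

## Phenotype preparation

Per site, each candidate covariate is screened by the marginal R² of a
univariate least-squares fit on the raw trait (categorical covariates
one-hot encoded); covariates explaining **more than** 2% of variance are
regressed out jointly, the residuals are inverse-normal transformed, and the
pooled two-site vector is transformed once more. Marginal (not joint)
screening matches the "explained more than 2% of trait variance" phrasing of
the rule. The transform maps average ranks through
`qnorm((r - 3/8) / (n + 1/4))` — the Blom offset, a documented constant
(`offset` argument) since the rule itself only says "quantile normalized".
Ties receive average ranks, deterministically. After preparation the two
sites have equal variance by construction, which is the basis for using a
single permutation threshold across traits.

Difference-score traits (time point 2 − time point 1) are computed on raw
values before preparation. Binary cluster-contrast phenotypes bypass the
inverse-normal transform and enter association as 0/1 with site and sex as
covariates; whether the original analyses double-transformed them is
unknowable from the text, so the simpler convention was chosen and is
configurable.

## GRM and GREML

The GRM is the GCTA-style average over SNPs of products of standardized
dosages, `A_jk = (1/m) Σ (x_ij − 2p_i)(x_ik − 2p_i) / (2p_i(1−p_i))`, with
per-SNP mean imputation and monomorphic SNPs skipped. LOCO GRMs are computed
by subtracting each chromosome's contribution from the genome-wide sum; the
SNP-count-weighted average of the LOCO GRMs reconstructs the full GRM to
machine precision, which is asserted in tests.

`fit_greml()` maximizes the restricted likelihood of
`y = Xb + g + e`, `g ~ N(0, σ²_g A)`, in the eigenbasis of `A`, where every
iteration costs O(n p²): Average-Information updates with EM fallback steps
(the EM step is guaranteed uphill), components clamped at a small positive
floor with an active set at zero, convergence at a log-likelihood change
below 1e-6 (max 100 iterations). Because the likelihood can be nearly flat
in h² at small n, the fit finishes with a one-dimensional profile-REML
polish: the total variance has a closed-form profile, leaving a 1-D
maximization over h² that pins the optimum to ~1e-7. The reported SE of h²
comes from the delta method on the inverse AI matrix. The test against
h² = 0 is a likelihood-ratio test referred to the boundary mixture
0.5·χ²₀ + 0.5·χ²₁. Heritability is reported on the observed scale for all
traits, including the binary cluster contrasts (no liability transform),
matching the single-h²-per-trait reporting convention. An identity-like GRM
(no eigenvalue spread) makes σ²_g and σ²_e jointly unidentifiable; the fit
flags this instead of failing. REML log-likelihoods shift by a constant
under affine reparameterizations of X; estimates and LRTs do not.

## Association scan and thresholds

Variance components are estimated once per left-out chromosome under that
chromosome's LOCO GRM and held fixed across its SNPs (the MLMA-LOCO
convention; per-SNP REML would cost hundreds of times more and changes
nothing detectable at these scales). Each SNP is then tested by generalized
least squares in the whitened model, with the residual scale re-estimated
per SNP and a t reference with n − p − 1 degrees of freedom. This choice has
a useful exact property: when σ²_g = 0 the whitening is a scalar, and every
statistic reduces to ordinary least squares to machine precision — the
equivalence is asserted at 1e-8 in the tests. Conditioning SNPs enter the
fixed design; SNPs collinear with the design (including each conditioning
SNP itself) are marked untestable rather than dropped.

The genome-wide threshold is the empirical (1 − α) quantile (R type-7
linear interpolation) of per-permutation maxima of −log10 p, with the
prepared phenotype shuffled across individuals. Shuffling ignores
relatedness; the single-threshold argument rests on every prepared trait
being marginally the same inverse-normal vector. This is a documented
limitation: under strong cryptic structure a relatedness-preserving
permutation scheme would be more conservative. A second tier at α = 0.10
mirrors the two-line reporting convention (genome-wide and suggestive). The
quantile of a 100-permutation run carries sampling error of a few tenths of
a −log10 unit; family-wise-error checks therefore average over independent
threshold realizations.

## QTL rules

A chromosome's candidate peak is its most significant SNP above the
threshold (ties break to the lower bp, then lexicographic id). It is
reported only with support: at least one *other* SNP within 0.5 Mb whose
−log10 p is within 2 units of the peak, both bounds inclusive. Conditional
mapping then adds the peak's dosage as a covariate, re-scans that
chromosome only, and repeats until nothing passes (the conditioning round is
recorded; more than 10 rounds aborts with a collinearity diagnostic).
Intervals run from the leftmost to the rightmost SNP within a 10 Mb search
window whose r² with the peak is at least 0.6; contiguity is *not*
required — an isolated distal SNP in strong LD extends the interval — a
documented, configurable choice motivated by the observation that loci a
few Mb apart can be declared independent when they are not in strong LD.
Colocation reports every annotation SNP (eQTL/sQTL/coding) within 3 Mb of a
peak with its r², flagging r² ≥ 0.6 as strong LD; annotation SNPs absent
from the genotype panel are emitted with r² undefined rather than dropped.

## Severity clustering

Behavioral traits are standardized within sex × site cells; rat–rat
similarity is the Pearson correlation between standardized trait vectors
over shared non-missing traits; edges are the top quantile of similarities
(default 0.8, hence ~20% edge density). The network model is a single-layer
binary stochastic block model with Dirichlet(1) block proportions and
Beta(1,1) edge probabilities, both integrated out, sampled by collapsed
Gibbs sweeps over node assignments. The chain is initialized from spectral
k-means on the adjacency matrix's leading eigenvectors — at K fixed to 3 a
uniformly random start can stall in merged-block modes — and the point
estimate is each node's posterior-mode block after label-aligning the
post-burn-in sweeps (best of the K! permutations against a reference
sweep). K = 3 (vulnerable / intermediate / resilient) is fixed by the
phenotype design; model selection over K is out of scope. The original
construction delegates its network and SBM details to earlier publications,
so the similarity measure, edge rule and priors here are this package's
documented choices, each configurable.

Blocks are labeled by mean composite severity (mean of z-scored heroin
taking/seeking traits; ties break by block size, with a warning), contrasts
are one-vs-rest 0/1 vectors that partition the cohort exactly, and cluster
composition across a peak SNP's variants is tested with a Pearson
chi-square without continuity correction, major-allele homozygotes versus
minor-allele carriers by default (df = 1; a full three-genotype table with
df = 2 is available). The plain Pearson form matches the df = 1 statistics
reported in this literature.

## Principal components

Components come from the eigendecomposition of the trait correlation matrix
over complete cases, retained at eigenvalue ≥ 1 (Kaiser), varimax-rotated
with Kaiser normalization, and displayed at |loading| ≥ 0.3. One numerical
caveat found during development: `stats::varimax` can stall in a poor local
rotation precisely when two clean factors sit symmetrically between simple
structures, so the rotation restarts from ten deterministic orthogonal
rotations and keeps the solution with the best varimax criterion. On
mutually independent traits the number of eigenvalues above 1 is unstable
by design (they hover around 1); that instability is a property of the
Kaiser rule, not of the implementation.

## Problem sizes and what the tests show

All validation runs at desk scale, chosen so the full suite completes in a
few minutes: GREML parameter recovery uses 20 cohorts of n = 800 with
m = 2000 SNPs (true h² = 0.3) and 400 null fits; family-wise error uses
n = 200, m = 2000, five 100-permutation thresholds and 200 fresh null scans;
QTL-rule simulations use n = 500 over two 30–50 Mb chromosomes at 40
SNPs/Mb; power checks use n = 850 with a 3%-variance QTL against the
−log10 p > 5.58 threshold; SBM recovery uses 300-node planted partitions
(p_in = 0.3, p_out = 0.05) over 10 seeds. Passing these shows the machinery
is correct and calibrated under the generator's assumptions — additive
biallelic effects, Gaussian noise, uniform maps, no dominance or epistasis,
no genotyping error beyond missingness, sites differing only in location and
scale. It does not show that any particular real cohort meets those
assumptions, and absolute quantities that depend on the real genome and
panel density (the 5.58 threshold's value, post-filter SNP counts, interval
widths) are data-specific and not reproduced here.

## Known limitations

* Permutation ignores relatedness (documented above).
* The sampler is a single Gibbs chain; the log-posterior trace is returned
  for diagnostics but no formal convergence test is run.
* Observed-scale h² for binary contrasts understates liability-scale
  heritability at unbalanced prevalences.
* The generator's LD decay is not calibrated to any real HS colony's; it is
  tuned only to be qualitatively right (founder mosaics, block-structured
  panels, Mb-scale decay).
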