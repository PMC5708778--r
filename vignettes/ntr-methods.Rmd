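---
title: "NTR: a non-threshold region test for rare and common variants"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{NTR: a non-threshold region test for rare and common variants}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ntr)
```

## The problem

Single-variant association tests have essentially no power against rare
variants (MAF below 1%), and region-level burden tests recover power only by
collapsing variants below an arbitrary MAF threshold — excluding causal
common variants, or drowning rare signal in common-variant noise, depending
on where the threshold is put. Burden tests also lose power when a region
mixes risk and protective alleles, because oppositely signed effects cancel
inside the collapsed score, and most region tests ignore linkage
disequilibrium (LD) between the variants they aggregate.

The NTR (non-threshold rare) test addressed here takes a different route: it
keeps every variant, rare or common, and weights each by how informative it
is — rarer variants and larger effects get larger weights — while pairwise
terms are discounted by the amount of LD between the pair, so tightly linked
variants do not contribute the same signal twice.

## The score and the statistic

Let `X_ij` be the number of minor alleles carried by individual `j` at
variant `i` in a region of `L` variants (minor = the less frequent allele in
the pooled case-control sample). Per variant, the test estimates the pooled
minor allele frequency `MF_i` and the allelic odds ratio `OR_i` (2x2
allele-count table, Haldane-Anscombe 0.5 correction when a cell is empty),
and sets the main-effect weight

    W_i = |log2 OR_i| / MF_i .

Pairwise LD is measured by Hedrick's multiallelic D', which for two
biallelic loci reduces to Lewontin's |D'| in [0, 1]; it is estimated from
phased haplotypes when available and by two-locus EM otherwise. Pair
weights come in three schemes, differing only in how effect directions are
combined (`a_i = log2 OR_i`):

    W_im(1) = (a_i + a_m)      (1/MF_i + 1/MF_m) (1 - D'_im)
    W_im(2) = |a_i + a_m|      (1/MF_i + 1/MF_m) (1 - D'_im)
    W_im(3) = (|a_i| + |a_m|)  (1/MF_i + 1/MF_m) (1 - D'_im)

Schemes 1 and 2 share magnitudes; scheme 3 bounds both (triangle
inequality). The `(1 - D')` factor zeroes pairs in complete LD. The genetic
score of individual `j` under scheme `k` is

    S_j(k) = [ sum_i W_i X_ij + sum_{i<m} W_im(k) (X_ij + X_mj) ] * PR ,

each unordered pair counted once, where `PR` is the proportion of variants
with MAF < 0.01. `PR` is a positive scale factor, so every rank-based
quantity downstream is invariant to it unless it is exactly zero (no rare
variants at all), in which case the region is flagged degenerate and p = 1.

The test statistic is the sum of case ranks `R(k) = sum_{j in cases}
rank(S_j(k))` with midranks for ties — ties are pervasive because most
individuals carry no minor allele and score exactly 0.

## The permutation null, and why weights are re-estimated

Since the weights contain odds ratios estimated from the same sample being
tested, the statistic is adaptive: a valid permutation null must recompute
the whole pipeline — OR estimates, weights, scores, ranks — under each
permuted case/control labeling. Only the label-free pooled quantities (MAF,
D') stay fixed. Holding the scores fixed and permuting labels alone looks
equivalent but is not: the signed scheme-1 weights align scores with the
observed labels in both effect directions, and the resulting test rejects a
true null roughly six times too often. With full re-estimation each scheme
is calibrated (measured 4.5–5.5% at alpha = 0.05 with 3000 cases / 3001
controls; the acceptance suite recomputes this).

From `n` permutations (default 1000) the mean `m(k)` and standard deviation
`s(k)` (n−1 denominator) of the permuted rank sums standardise the observed
statistic, `Z(k) = (R(k) − m(k)) / s(k)`; the permuted rank sums are close
to normal even with heavy ties, so each scheme's p-value is the two-sided
normal `p(k) = 2 P(Z > |Z(k)|)`, capped at 1.

The scheme `k*` with the smallest p-value is selected. The raw minimum over
the three correlated schemes is anti-conservative (measured ~9–11% type-I
at alpha = 0.05), so the region-level p-value applies an FDR correction to
the minimum: `p = min_k BH(p(1), p(2), p(3))` (Simes). When the three
schemes agree — which is the typical case under one-direction effects,
where schemes 2 and 3 coincide exactly — the correction costs nothing.
Both values are reported (`p_min` and `p`); multi-region studies apply
Benjamini-Hochberg across regions on top (`ntr_study()`).

### Numerical and degenerate-input choices

* Midranks for ties; `s(k) = 0` (all permuted rank sums identical) gives
  p = 1 with a degeneracy flag rather than an undefined Z.
* Missing genotypes are set to 0 minor alleles once at entry, so the
  observed and permuted statistics are the identical function of the data
  (exchangeability holds exactly); MAF/OR estimates in the variant table
  follow the same convention.
* Monomorphic variants are dropped with a warning; a region needs at least
  two polymorphic variants — with one variant there is no pair structure and
  the score reduces to a single-SNP test better served by `trend_test()`,
  so such regions are flagged and skipped in `ntr_study()`.
* `D'` with `D_im = 0` is defined as 0 (independence); pairs involving a
  monomorphic variant get `D' = 0` so pair weights stay finite; EM uses
  linkage-equilibrium initialisation, tolerance 1e-10, at most 1000
  iterations.
* The permutation engine collapses individuals with identical genotype
  profiles (non-carriers form one zero-score block), draws per-profile case
  counts from the corresponding multivariate hypergeometric distribution,
  and assigns weighted midranks in a single radix sort — exactly equivalent
  to naive label permutation (the test suite checks exhaustive enumeration
  against a brute-force oracle) at a small fraction of the cost.

## What the simulator emulates

`sample_case_control()` generates the case-control datasets used throughout
the power and type-I studies. Haplotypes arise by dichotomising a latent
multivariate normal
vector with AR(1) covariance `rho^|i-j|` (`rho` in {0, 0.2, 0.4, 0.6}
spanning linkage equilibrium to strong LD): allele `i` is minor exactly
when the latent component exceeds `qnorm(1 - MAF_i)`, so each variant hits
its target MAF marginally while `rho` induces decaying cross-variant LD.
Note `rho` lives on the latent scale; it is not D'. Two independent
haplotypes per individual give HWE genotypes. A region holds 8 causal
variants plus 0–32 noise variants; target MAFs are U(0.001, 0.01) for rare
variants and U(0.01, 0.5) for common ones ("rare_plus_common" draws each
variant rare with probability 1/2, the simplest mixture spanning both
classes). Disease status follows the additive
logistic model `P(D=1|X) = logistic(logit(p0) + sum ln(OR_i) X_i)` with
one-direction OR levels 1.2 / 1.5 or two-direction pairs (2.5, 0.4) /
(1.2, 0.8) (balanced 4/4 risk/protective split by default), and sampling
continues until exactly 3000 cases and 3001 controls are collected.

Three defaults are the package's own choices where the design leaves them
open: the baseline disease probability `p0 = 0.05` (a typical complex-trait
prevalence; retrospective sampling makes the case-control allele contrast
depend on it only weakly), causal variants are placed at random positions
along the AR(1) chain (so causal-causal LD is not an artifact of a fixed
layout), and noise variants draw their MAFs from the same composition
scheme as the scenario. When every OR is 1 the status is independent of the
genotypes, so the sampler draws exactly N individuals and assigns labels by
permutation — distributionally identical to rejection sampling and much
faster, which is what makes 1000-replicate null grids cheap.

What the simulator does *not* emulate: population stratification,
relatedness, genotyping error, missingness, covariates, and sequence-level
realism (no coalescent). Passing tests on these data show the method's
operating characteristics under its own stated model, not robustness to
real-data pathologies.

## Comparators

CMC (collapse below MAF 0.01 into a carrier indicator + common variants
individually, joint logistic LRT), WSS (Madsen-Browning control-frequency
weights, case rank sum, weights re-estimated per permutation), SKAT
(Beta(1, 25) MAF-density weights, intercept-only logistic null, mixture of
chi-squares via Liu moment matching, Imhof inversion as the exact option)
and SKAT-O (11-point rho grid between SKAT and the squared burden score,
min-p combined by the one-dimensional conditional integration, permutation
fallback available) are implemented behind the same region/phenotype
interface. The CMC association engine is a logistic likelihood-ratio test
rather than Hotelling's T-squared: asymptotically comparable, and it
handles the binary trait directly. Thresholds the original reports leave
open (CMC collapsing threshold) default to 0.01, matching PR's rarity
threshold.

## Problem sizes used in the checks

The acceptance suite and `scripts/acceptance.R` use: power at the
one-direction scenario (OR 1.2, rho 0.2, rare-only, no noise) at the full
3000/3001 design with 1000 permutations, 500 replicates in the test suite
and 1000 in the script; the null grid over rho in {0, 0.4} and noise in
{0, 8, 32} at a proportionally reduced 600/601 design (type-I calibration
of a rank test is not sample-size-sensitive, and the reduced design keeps
a 6000-replicate grid tractable on one CPU), 1000 replicates per scenario.
Property checks (D' oracle sweeps, exhaustive permutation enumeration,
invariances, power orderings) run at small n with fixed seeds.

## Known limitations

* Computation grows quadratically in L (all pairs); regions of hundreds of
  variants are noticeably slower than SKAT-style tests.
* The normal approximation to the permuted rank-sum distribution can be
  slightly anti-conservative at small sample sizes (a few hundred cases);
  at the study's design size it is calibrated. Increase `n_perm` and use
  the exhaustive mode for very small samples.
* No covariate adjustment: the score has no slot for confounders, so
  stratified or pre-adjusted designs are required.
* OR estimates for extremely rare variants are noisy even with the Haldane
  correction; their weights inherit that noise. This is intrinsic to the
  weighting scheme, not an implementation artifact.
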