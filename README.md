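# ntr — non-threshold rare-variant region association testing

`ntr` tests genomic regions (genes, windows, pathways) for case-control
association using **all** variants in the region — rare and common together —
instead of collapsing below an arbitrary minor-allele-frequency threshold.
It is aimed at statistical geneticists analysing case-control SNP data
(VCF or PLINK) and at methodologists running power / type-I-error studies
against the standard comparator tests (CMC, WSS, SKAT, SKAT-O).

## The method

For minor-allele counts `X_ij` (variant `i`, individual `j`) the region
score of individual `j` under pair-weighting scheme `k` is

    S_j(k) = [ Σ_i W_i X_ij + Σ_{i<m} W_im(k) (X_ij + X_mj) ] × PR

with `W_i = |log2 OR_i| / MF_i` (rarer variants and larger effects weigh
more), pair weights

    W_im(1) = (a_i + a_m)     (1/MF_i + 1/MF_m)(1 − D′_im)
    W_im(2) = |a_i + a_m|     (1/MF_i + 1/MF_m)(1 − D′_im)
    W_im(3) = (|a_i| + |a_m|) (1/MF_i + 1/MF_m)(1 − D′_im)

(`a_i = log2 OR_i`; `D′` is Hedrick's multiallelic D′, so variants in
strong LD are discounted), and `PR` the proportion of variants with
MAF < 0.01. The statistic is the sum of case ranks `R(k)`; each scheme is
standardised against a permutation null that **re-estimates the ORs and
weights under every permuted labeling**, giving `Z(k)` and the two-sided
`p(k) = 2 P(Z > |Z(k)|)`. The best scheme `k*` is selected and the region
p-value is the FDR-corrected minimum over the three schemes; across
regions, Benjamini-Hochberg q-values are attached. The three schemes share
magnitudes but differ in sign handling, so regions mixing risk and
protective alleles are not cancelled away.

## Worked example

Simulate a region under the built-in generator (latent AR(1) haplotypes,
additive logistic disease model) and test it:

```r
library(ntr)
cfg <- scenario_config(rho = 0.2, n_causal = 8, n_noise = 0,
                       composition = "rare_only", or_model = 1.5,
                       n_cases = 500, n_controls = 501)
dat <- sample_case_control(cfg, seed = 42)
fit <- ntr_region_test(dat$region, dat$status, n_perm = 1000, seed = 1)
print(fit)
#>         NTR region association test
#>
#> region: sim   L = 8 variants   PR = 0.75   permutations = 1000
#> Z(k) = 3.125, 3.561, 3.577;  k* = 3, p(k*) = 0.00034734
#> region p-value = 0.00055337  (scheme-corrected minimum)
```

`PR = 0.75` says six of the eight variants have estimated MAF below 1%
(two drifted above the rarity line in this sample); the bracketed score is
scaled by it. All eight causal variants raise risk (OR 1.5), so the three
standardised rank sums `Z(k)` nearly coincide; the direction-blind scheme
`k = 3` wins, its two-sided p-value is 3.5e-4, and the scheme-corrected
region p-value is 5.5e-4 — strong evidence, where SKAT on the same data
gives p = 0.046. The fitted object carries the per-variant table
(`fit$stats`: MAF, OR, weight) and the D′ matrix (`fit$ld`). Comparators
run through the same interface, e.g. `skat_test(dat$region, dat$status)$p`,
and `ntr_study()` tests a list of regions with BH-FDR across regions.

Real data enter through `read_genotypes()` (VCF + phenotype sidecar TSV,
or PLINK bed/bim/fam), `qc_filter()` (call rate ≥ 0.95, control-sample HWE
p ≥ 1e-4) and `slice_regions()` (gene lists or BED intervals). A thin
command-line wrapper lives at `inst/cli/ntr.R`:

```sh
Rscript "$(Rscript -e 'cat(system.file("cli/ntr.R", package="ntr"))')" test \
    --vcf data.vcf --phenotypes phen.tsv --regions genes.tsv \
    --method ntr --permutations 1000 --seed 1 --out results.tsv
```

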