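# eggwas

Evaluation framework for **exome-guided GWAS (EG-GWAS)**: association
mapping that uses the variants discovered by whole-exome sequencing as
tagSNPs, compared head-to-head against a conventional genotyping-array
panel. The package targets the within-breed canine setting — long-range LD,
small cohorts, monogenic traits — and ships everything needed to study the
trade-off on synthetic data: a breed-structured genotype generator, LD
surveys, permutation-controlled association testing, a power-simulation
engine, high-LD genome-fraction estimation and across-breed mapping of
breed-fixed coat-type-like traits.

## What it computes

- **LD**: pairwise r² from unphased genotypes by EM over haplotype
  frequencies, `r² = D²/(p_A(1−p_A)p_B(1−p_B))` with `D = p_AB − p_A p_B`;
  adjacent-marker surveys, per-Mb density bins, SNP/sample subsampling and
  background LD from unlinked markers.
- **Association**: Cochran–Armitage trend test
  (`T = Σ w_i (S r_i − R s_i)`, score-test variance, χ² 1 df) and the
  allelic χ² on 2×2 allele counts; Bonferroni and max-T permutation
  family-wise control with the add-one estimator
  `p = (1 + #{max_π ≥ T_obs})/(1 + P)`.
- **Power**: genotype-first simulation of fully penetrant recessive traits —
  every marker whose homozygote class splits the cohort 8 vs 8 defines a
  phenotype, the causal marker is withheld, and the panel must recover the
  association through LD within a ±10-marker window — stratified by causal
  location (inside/outside capture targets, SNP-dense/sparse regions,
  lincRNAs), sample size and tag distance, each with an H0 companion run.
- **Coverage**: fraction of the genome within a flank (default 5 kb, the
  distance over which r² stays above 0.6) of variant-bearing targets.
- **Mapping**: allelic scan, Bonferroni, rank and distance of the closest
  significant marker to a known causal locus, and a breed-stratified
  minimal-sample-size search.

## Worked example

```r
library(eggwas)

cfg   <- sim_config(chrom_lengths = c(chr1 = 6e6, chr2 = 6e6), seed = 42)
study <- simulate_study(cfg)
study$sites
#> genotype_matrix: 16 samples x 12000 markers on 2 chromosome(s), 0.0% missing
nrow(study$panels$array); nrow(study$panels$exome)
#> [1] 696
#> [1] 876

arr   <- qc_filter(study$array)
pairs <- adjacent_r2(arr)
round(median(pairs$r2[pairs$defined], na.rm = TRUE), 3)
#> [1] 0.487

res <- power_experiment(study, power_config(seed = 42),
                        strata = c("inside_targets", "outside_targets"),
                        max_signals = 5)
print(res, digits = 3)
#>           stratum panel n_signals power power_se median_distance_bp h0_rate
#> 1  inside_targets exome         5   0.8    0.179              25596       0
#> 2  inside_targets array         5   0.4    0.219              17087       0
#> 3 outside_targets exome         5   0.2    0.179            1666674       0
#> 4 outside_targets array         5   0.2    0.179               9827       0
```

Reading the output: the exome panel detects 4 of 5 recessive signals planted
inside capture targets (power 0.8) against 0.4 for the 17-kb array, while
outside the targets the exome panel's nearest informative marker can sit a
megabase away (`median_distance_bp`) and its advantage disappears — the
array's even spacing wins there on larger runs. `h0_rate` is the
label-shuffled companion: no spurious windowed detections at α = 0.05 here.
Five signals per cell keeps the example quick; the bundled checks average
20 replicate genomes before asserting any ordering.

The same pipeline is scriptable from a shell via `exec/eggwas`
(`eggwas simulate | ld | assoc | power | coverage | map`); every run writes
a JSON manifest with the config snapshot, root seed, named substream seeds
and input digests.

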