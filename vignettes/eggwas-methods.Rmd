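---
title: "Exome-guided GWAS evaluation: models, procedures and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Exome-guided GWAS evaluation: models, procedures and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(eggwas)
```

## The problem

Exome-guided GWAS (EG-GWAS) uses the variants discovered during whole-exome
sequencing as tagSNPs for association mapping, instead of (or alongside) a
genotyping array. Whether that works depends entirely on linkage
disequilibrium: exome variants cluster inside capture targets, so a causal
variant is either surrounded by dense tags (exonic) or must be reached
through long-range LD (intergenic). Dog breeds are the extreme favourable
case — within-breed LD extends over hundreds of kilobases — which is why this
package's generator and default parameters emulate breed-structured canine
genomes.

`eggwas` provides the full evaluation chain: a synthetic two-panel genotype
generator, QC and r² estimation from unphased genotypes, the
Cochran–Armitage trend and allelic χ² tests with Bonferroni and max-T
permutation control, a genotype-first power-simulation engine, the high-LD
genome-fraction estimate, and across-breed mapping of breed-fixed traits.

## The synthetic genotype model

Each breed descends from $F$ founder haplotypes. Founders are themselves
two-state mosaics of a single deep ancestral haplotype pair (per-bp switch
probability $\rho$, `switch_rate`), perturbed by rare per-site allele flips
(`founder_mutation_rate`, $\mu$). Each sample gamete is a mosaic over the
breed's founders with the same $\rho$; the genotype is the sum of two
gametes.

The two levels matter. A single-level founder mosaic with independently
drawn founder alleles caps adjacent-marker r² near $1/F$, far below observed
within-breed LD. With the two-level structure, nearby markers see only the
(at most two) local ancestry classes, so short-range r² is close to 1 and
decays as founder ancestry decorrelates, at a length scale set jointly by
$\rho$ and $F$. The mutation flips create a low-MAF, low-LD marker fraction
— the part of a sequencing panel that tags poorly — and spread the allele
frequency spectrum beyond the ancestry fractions $k/F$.

Calibration (a sweep over $(F, \rho, \mu)$, 16 samples, 10 Mb) chose the
defaults $\rho = 5\times10^{-6}$, $\mu = 0.06$, with per-breed founder
counts `c(10, 6, 4)` for a Poodle-like cohort of 16 plus two retriever-like
cohorts of 6. Under these settings the median adjacent r² within 5 kb
exceeds 0.6, distance-binned medians fall to roughly 0.1–0.25 by
50–150 kb, and smaller $F$ (retriever-like breeds) gives uniformly higher
LD, reproducing the qualitative breed ordering. Two features of real panels
are *not* matched: genome-wide panel medians run higher (≈0.45–0.6) than
the 0.17–0.40 reported for real canine panels, because the high-LD ancestry
backbone dominates the pair distribution; and fixation of opposite alleles
across breeds essentially never arises by drift alone, so breed-fixed
causal variants are planted explicitly (`plant_fixed_variant()`), mirroring
traits fixed by within-breed selection.

Targets ("gene-like" intervals) follow a two-state renewal process with
geometric segment lengths; intergenic gaps are a two-component mixture
(probability 0.2 of a desert-scale gap, 4× the base mean, base mean rescaled
to preserve the nominal `target_fraction`). The mixture produces the strong
per-Mb variation in exome marker density — gene clusters versus gene deserts
— without which the high-/low-density power contrast vanishes. lincRNA-like
intervals are placed uniformly in the target complement.

Panel construction: the array-like panel thins polymorphic sites to one per
`array_spacing_bp` (17 kb default, binomial jitter); the exome-like panel
keeps all polymorphic sites inside targets plus `exome_offtarget_rate`
(2%) off-target sites. With the default `site_density` of 1000 sites/Mb and
8% target fraction, the exome panel's median adjacent spacing is ~1 kb
inside targets while the array is uniform at ~17 kb, reproducing the
"denser but clustered" versus "sparser but even" contrast that drives every
downstream comparison. Missingness: the array drops genotypes at rate
`1 - callrate_array` (0.5%); exome markers first draw a per-marker call rate
from Beta(18, 2) (mean 0.9), emulating the heavier, more variable dropout of
capture sequencing. The Beta parameters are a calibration choice: real
post-QC exome call rates are reported only as ">90%".

All stages draw named substreams (`haplotypes`, `targets`, `panels`,
`missingness_*`, `traits`) from one root seed, so any stage can be
reproduced in isolation and the whole study is byte-reproducible from
`(config, seed)`.

## QC and r² estimation

QC removes markers with MAF below 0.05 (computed among called samples;
a MAF exactly at the threshold is kept), more than 50% missing genotypes,
call rate below 50% (the complementary phrasing of the same idea, kept as
an independent knob), and — only when enabled — a Hardy–Weinberg exact-test
p below a threshold. The HWE filter is off by default (`hwe_p_min = 0`):
within-breed cohorts of related dogs legitimately deviate from
Hardy–Weinberg proportions, and filtering on HWE would discard exactly the
high-LD structure under study. The exact test itself conditions on the
observed allele counts and sums the probabilities of all heterozygote
counts no more probable than the observed one.

Pairwise r² is estimated from unphased genotypes by EM over haplotype
frequencies: all genotype pairs are phase-resolved deterministically except
double heterozygotes, whose coupling/repulsion split is iterated to
convergence (tolerance $10^{-10}$, 1000 iterations maximum). Then
$D = p_{AB} - p_A p_B$ and $r^2 = D^2 / (p_A(1-p_A)p_B(1-p_B))$. Three
numerical choices:

- **Multiple starts.** The EM map has an unstable fixed point at an equal
  split for symmetric tables and can have two local maxima; the
  implementation runs from splits 0.5, 0.05 and 0.95 and keeps the solution
  with the best observed-data likelihood.
- **Flat likelihood.** If every informative sample is a double heterozygote
  the split is unidentifiable; the pair is flagged undefined rather than
  reporting the arbitrary half-split value, and undefined pairs are excluded
  from medians (but counted).
- **What "EM equals phased" can mean.** When no double heterozygotes occur,
  the EM estimate equals direct phased-haplotype counting exactly, and the
  tests assert this. For general data the unphased maximum-likelihood
  estimate differs from the realised phased counts by $O(1/n)$ — that is a
  property of the estimand, not an implementation error — so exact
  phased-equality is asserted on two-haplotype-class pools (the perfect-|D′|
  regime of tightly linked markers, where the MLE is identifiable and
  coincides with the phased counts), and on general pools the EM is checked
  against an independent brute-force likelihood maximisation instead.

Survey procedures follow the within-breed LD workflow: r² between
subsequent markers per chromosome (co-located markers deduplicated first so
no zero-distance pairs arise), per-chromosome min/Q1/mean/median/Q3/max
summaries, 1-Mb marker-density bins with 15th/85th-percentile low/high
flags, stepwise SNP subsampling, repeated 6-sample subsets (quantifying the
small-sample upward bias of r²), and background LD from one marker per
chromosome (all pairwise combinations across 38 chromosomes by default,
703 pairs per draw).

## Association testing and multiple-testing control

The Cochran–Armitage trend test uses additive weights $(0, 1, 2)$ and the
standard score-test variance; a zero variance (fewer than two genotype
classes) leaves the statistic undefined with p = 1. The allelic test is the
2×2 χ² on allele counts without continuity correction. Both drop samples
missing at a marker from that marker's table only, so case counts can fall
below the cohort size — as real sequencing panels do at partially called
sites. Bonferroni uses the number of markers that entered testing.

Max-T permutation control: the genome-wide maximum statistic is recorded
for each of `n_perm` (default 500) case/control label permutations, and
marker $j$ receives $p_j = (1 + \#\{\max_\pi \ge T_j\})/(1 + n_\text{perm})$
— the add-one estimator, conservative and never below $1/(n_\text{perm}+1)$.
Permutation maxima are taken over the tested marker set of the run
(genome-wide), matching the family-wise framing. The scan engines are
vectorised over markers *and* permutations (one matrix product per batch),
which is what makes 500-permutation max-T affordable inside the power
experiments.

## The power simulation

The engine is genotype-first: rather than simulating genotypes to match a
phenotype model, it walks over real (here: simulated) genotypes and uses
each marker whose homozygote class splits the cohort exactly in half
(8 vs 8 at $n = 16$) to define a fully penetrant autosomal recessive
phenotype. The causal marker — and any panel marker at the identical
position — is then removed from the tested set, so the panel must recover
the association through LD; leaving it in would turn the indirect design
into a direct one and trivialise the comparison. Detection requires a
marker within ±10 panel markers of the causal position (window in marker
count, truncated at chromosome ends) with max-T adjusted p ≤ 0.05. The
distance diagnostic is measured to the genome-wide most significant marker
by raw p (ties broken towards the causal position), since informative
distances can exceed any fixed window. Each signal gets an H0 companion:
labels shuffled once (preserving totals), the same windowed detection rule
applied; the aggregated rejection rate estimates the type-I error of the
procedure.

Strata: causal candidates inside/outside targets are drawn from the union
of both panels (each genotyped panel contributes the markers it carries);
density strata use array-panel causals outside targets inside 1-Mb bins at
or above the 85th / at or below the 15th percentile of exome informative
marker density; lincRNA causals are array markers inside lincRNA intervals
with eligibility relaxed to a 4–12 case arm, because exact 8/8 splits are
too rare in small interval classes. The sample-size experiment enumerates
balanced subsets ($k/2$ from each arm) a priori and evaluates at least 20%
of all combinations, with an optional hard cap per causal marker for
tractability; eligibility is re-derived within each subset. The distance
experiment always takes the causal from the array panel and tests the
single tag (Bonferroni m = 1), isolating the r²–distance relation from
panel-density effects.

## High-LD genome fraction

Target intervals (optionally restricted to those containing at least one
observed variant — on by default) are extended by a flank on both sides,
clipped, merged, and the union expressed as a genome and per-chromosome
fraction. The 5 kb default flank comes from the LD survey (r² above 0.6
within 5 kb) but is an explicit parameter so users can couple it to their
own measured decay distance. Interval arithmetic is 0-based half-open (BED);
marker positions are 1-based (map/VCF); `pos_in_intervals()` is the single
conversion point.

## Across-breed mapping

`map_trait()` runs the allelic test with per-marker complete-case counts,
Bonferroni correction and ranks on raw p (ties broken by genomic order).
`closest_significant()` returns the significant marker nearest a known
causal position (ties: smaller p, then lower position).
`min_sample_size()` subsamples stepwise, stratified by breed so the
across-breed design survives subsetting, re-applies QC within each subset
(the Bonferroni denominator is recomputed from the subset's surviving
markers), and reports the last size, walking downward, with at least one
significant subset. Fixed-trait fixtures plant the causal variant into an
in-target exome marker with complete calls; every fully-called perfectly
separating marker attains the same maximal χ², and no such marker arises by
drift, so the planted variant is uniquely top-ranked.

## Problem sizes and reproducibility of the checks

The bundled checks run on deliberately compact instances chosen as the
smallest sizes at which every qualitative contrast is stable across seeds:
two 6-Mb chromosomes (≈12,000 candidate sites, ≈700 markers per panel) per
replicate genome, 20 replicate genomes for the directional power
comparisons with 5 signals per stratum-panel pair, 500 permutations per
max-T run, 200 null replicates for the family-wise error estimate, and
10⁴ gamete pairs for the EM–phased comparison. `scripts/acceptance.R`
recomputes all headline quantities from scratch (10 replicate genomes) and
writes them as JSON; every random draw descends from the `--seed` argument
through named substreams.

## Known limitations

- The generator reproduces LD decay shape, panel geometry and breed
  ordering, not demographic history: no mutation–drift equilibrium, no
  selection, no X chromosome, no indels, and panel medians above real
  canine values (see above).
- The trend and allelic tests are asymptotic; at cohort sizes around 28
  with low-MAF markers the 1-df χ² is mildly anticonservative, which is
  visible in Bonferroni-based null rates (the max-T path does not share
  this problem and is the basis of all power claims).
- Population stratification is deliberately out of scope: across-breed
  fixtures use breed-fixed traits where confounding and signal coincide by
  construction.
- Window size (±10 markers) spans different physical distances on the two
  panels; that asymmetry is intrinsic to marker-count windows and is why
  the distance diagnostic is reported alongside power.
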