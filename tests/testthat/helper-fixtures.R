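# Shared fixture builders. Everything is generated in code; the simulated
# study below is built once per test run and reused by several files.

# tiny genotype matrix from a samples x markers matrix of 0/1/2/NA
make_gm <- function(calls, chrom = "chr1", pos = NULL, breed = NULL,
                    a1 = "A", a2 = "B") {
  calls <- as.matrix(calls)
  m <- ncol(calls)
  pos <- pos %||% seq(1000, by = 1000, length.out = m)
  chrom <- rep_len(chrom, m)
  markers <- data.frame(chrom = chrom, pos = pos,
                        id = make.unique(sprintf("%s_%d", chrom, pos)),
                        a1 = rep_len(a1, m), a2 = rep_len(a2, m),
                        stringsAsFactors = FALSE)
  samples <- data.frame(id = sprintf("s%02d", seq_len(nrow(calls))),
                        breed = rep_len(breed %||% "breed1", nrow(calls)),
                        stringsAsFactors = FALSE)
  genotype_matrix(calls, markers, samples)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# phased gametes for a pair of loci from haplotype frequencies
# hapfreq order: (00, 01, 10, 11); returns list(h1, h2, gi, gj)
draw_phased_pair <- function(n, hapfreq) {
  g <- sample(4, 2 * n, TRUE, hapfreq)
  h1 <- as.integer(g %in% c(3, 4))
  h2 <- as.integer(g %in% c(2, 4))
  i1 <- seq(1, 2 * n, 2)
  list(h1 = h1, h2 = h2, gi = h1[i1] + h1[i1 + 1], gj = h2[i1] + h2[i1 + 1])
}

phased_r2 <- function(h1, h2) {
  pA <- mean(h1); pB <- mean(h2)
  if (pA %in% c(0, 1) || pB %in% c(0, 1)) return(NA_real_)
  D <- mean(h1 * h2) - pA * pB
  D^2 / (pA * (1 - pA) * pB * (1 - pB))
}

# small default study reused across power/mapping tests (built lazily once)
study_cache <- local({
  env <- new.env()
  function() {
    if (is.null(env$study)) {
      cfg <- sim_config(chrom_lengths = c(chr1 = 4e6, chr2 = 4e6), seed = 101)
      env$study <- simulate_study(cfg)
    }
    env$study
  }
})

# helper: three-breed study with a furnishing-like breed-fixed exonic trait.
# The causal variant is planted (fixed traits arise from within-breed
# selection, which the drift-only mosaic model does not produce) into an
# in-target exome marker with complete calls that the array panel does not
# carry; the array must recover the association through LD alone.
fixed_trait_study <- function(seed = 71) {
  cfg <- sim_config(n_breeds = 3, samples_per_breed = c(16, 6, 6),
                    founders_per_breed = c(10, 6, 4),
                    chrom_lengths = c(chr1 = 3e6, chr2 = 3e6),
                    seed = seed)
  study <- simulate_study(cfg)
  exo <- qc_filter(study$exome)
  arr <- qc_filter(study$array)
  in_target <- pos_in_intervals(study$targets, exo$markers$chrom,
                                exo$markers$pos)
  complete <- colSums(is.na(exo$calls)) == 0
  cand <- exo$markers$id[in_target & complete &
                           !exo$markers$id %in% arr$markers$id]
  causal_id <- cand[1]
  fixation <- list(breed1 = "case", breed2 = "control", breed3 = "control")
  exo <- plant_fixed_variant(exo, causal_id, fixation)
  list(study = study, exo = exo, arr = arr, causal_id = causal_id,
       fixation = fixation,
       causal = exo$markers[exo$markers$id == causal_id, , drop = FALSE])
}
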