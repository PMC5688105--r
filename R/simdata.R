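# Synthetic multi-breed genotype generator with tunable LD decay, dual marker
# panels (array-like vs exome-like), per-panel missingness and plantable
# causal traits.
#
# Model: each breed descends from F founder haplotypes; each founder is itself
# a two-state mosaic of two deep ancestral haplotypes (switch probability
# `switch_rate` per bp) with rare per-site allele flips
# (`founder_mutation_rate`), and each sample gamete is a mosaic of the breed's
# founders (same switch rate). The two-level structure gives near-complete LD
# between close markers (few local haplotype classes) that decays as founder
# ancestry decorrelates along the chromosome, while mutation-derived sites
# supply the low-LD, low-MAF fraction seen in sequencing panels.

#' Simulation configuration
#'
#' Defaults are calibrated so that a 16-sample breed with `founders_per_breed`
#' around 10 shows median adjacent-marker r2 above 0.6 within 5 kb decaying to
#' roughly 0.2 by 100 kb, with smaller founder pools (retriever-like breeds)
#' giving higher LD throughout.
#'
#' @param n_breeds number of breeds.
#' @param samples_per_breed samples per breed (scalar or per-breed vector).
#' @param chrom_lengths named or unnamed vector of chromosome lengths in bp.
#' @param founders_per_breed founder haplotypes per breed, F >= 2 (scalar or
#'   per-breed vector). Smaller F means higher within-breed LD.
#' @param switch_rate per-bp probability of switching copy source, used for
#'   both founder ancestry and sample gametes.
#' @param founder_mutation_rate per founder-site probability of an allele flip.
#' @param site_density candidate polymorphic sites per Mb.
#' @param target_fraction fraction of the genome covered by gene-like target
#'   intervals.
#' @param mean_target_bp mean length of a gene-like target interval.
#' @param lincrna_fraction fraction of the genome covered by lincRNA-like
#'   intervals (placed outside targets).
#' @param mean_lincrna_bp mean lincRNA interval length.
#' @param array_spacing_bp mean spacing of the array-like panel.
#' @param exome_offtarget_rate fraction of exome-panel markers outside targets.
#' @param callrate_array per-genotype call rate of the array panel.
#' @param callrate_exome_beta `c(alpha, beta)` of the Beta distribution from
#'   which each exome-panel marker draws its call rate (mean `a/(a+b)`).
#' @param seed root seed; together with the configuration it fully determines
#'   every simulated output (all stages draw named substreams from it).
#' @return A `sim_config` list.
#' @export
sim_config <- function(n_breeds = 1,
                       samples_per_breed = 16,
                       chrom_lengths = c(chr1 = 10e6),
                       founders_per_breed = 10,
                       switch_rate = 5e-6,
                       founder_mutation_rate = 0.06,
                       site_density = 1000,
                       target_fraction = 0.08,
                       mean_target_bp = 10000,
                       lincrna_fraction = 0.02,
                       mean_lincrna_bp = 5000,
                       array_spacing_bp = 17000,
                       exome_offtarget_rate = 0.02,
                       callrate_array = 0.995,
                       callrate_exome_beta = c(18, 2),
                       seed = 1) {
  if (is.null(names(chrom_lengths))) {
    names(chrom_lengths) <- paste0("chr", seq_along(chrom_lengths))
  }
  cfg <- list(
    n_breeds = as.integer(n_breeds),
    samples_per_breed = rep_len(as.integer(samples_per_breed), n_breeds),
    chrom_lengths = chrom_lengths,
    founders_per_breed = rep_len(as.integer(founders_per_breed), n_breeds),
    switch_rate = switch_rate,
    founder_mutation_rate = founder_mutation_rate,
    site_density = site_density,
    target_fraction = target_fraction,
    mean_target_bp = mean_target_bp,
    lincrna_fraction = lincrna_fraction,
    mean_lincrna_bp = mean_lincrna_bp,
    array_spacing_bp = array_spacing_bp,
    exome_offtarget_rate = exome_offtarget_rate,
    callrate_array = callrate_array,
    callrate_exome_beta = callrate_exome_beta,
    seed = as.integer(seed)
  )
  stopifnot(
    cfg$n_breeds >= 1,
    all(cfg$samples_per_breed >= 1),
    all(cfg$chrom_lengths > 0),
    all(cfg$founders_per_breed >= 2),
    cfg$switch_rate > 0, cfg$switch_rate < 1,
    cfg$founder_mutation_rate >= 0, cfg$founder_mutation_rate < 1,
    cfg$site_density > 0,
    cfg$target_fraction > 0, cfg$target_fraction < 1,
    cfg$lincrna_fraction >= 0, cfg$lincrna_fraction < 1,
    cfg$array_spacing_bp > 0,
    cfg$exome_offtarget_rate >= 0, cfg$exome_offtarget_rate < 1,
    cfg$callrate_array >= 0, cfg$callrate_array <= 1,
    length(cfg$callrate_exome_beta) == 2, all(cfg$callrate_exome_beta > 0)
  )
  class(cfg) <- "sim_config"
  cfg
}

# copy-source paths for n_paths mosaics over K sources at positions pos
mosaic_paths <- function(n_paths, K, pos, rho) {
  n <- length(pos)
  psw <- if (n > 1) 1 - exp(-rho * diff(pos)) else numeric(0)
  out <- matrix(0L, n_paths, n)
  for (g in seq_len(n_paths)) {
    sw <- c(TRUE, stats::runif(n - 1) < psw)
    idx <- cumsum(sw)
    out[g, ] <- sample.int(K, idx[n], replace = TRUE)[idx]
  }
  out
}

#' Simulate multi-breed genotypes under the founder-mosaic model
#'
#' All breeds share one candidate site map and one deep ancestral haplotype
#' pair, so markers are comparable across breeds; breeds differ in founder
#' pools (and thereby in allele frequencies, fixed alleles and LD strength).
#' Genotypes are the sum of two mosaic gametes per sample. Identical
#' configurations and seeds give identical matrices.
#'
#' @param cfg a [sim_config()].
#' @return A [genotype_matrix()] covering all breeds and candidate sites
#'   (monomorphic sites included; QC filtering is a downstream step).
#' @export
simulate_breed_genotypes <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  if (any(cfg$founders_per_breed < 2)) {
    stop("founders_per_breed must be >= 2: a single founder admits no LD structure")
  }
  n_sites_chrom <- round(cfg$site_density * cfg$chrom_lengths / 1e6)
  if (all(n_sites_chrom == 0)) stop("site_density too low: zero candidate sites")
  with_seed(substream_seed(cfg$seed, "haplotypes"), {
    chroms <- names(cfg$chrom_lengths)
    calls_list <- vector("list", length(chroms))
    markers_list <- vector("list", length(chroms))
    n_total <- sum(cfg$samples_per_breed)
    breed_names <- paste0("breed", seq_len(cfg$n_breeds))
    for (ci in seq_along(chroms)) {
      L <- cfg$chrom_lengths[ci]
      ns <- n_sites_chrom[ci]
      if (ns == 0) next
      pos <- sort(sample.int(L, ns))
      calls <- matrix(0L, n_total, ns)
      row0 <- 0L
      for (b in seq_len(cfg$n_breeds)) {
        F <- cfg$founders_per_breed[b]
        nb <- cfg$samples_per_breed[b]
        founders <- mosaic_paths(F, 2, pos, cfg$switch_rate) - 1L
        if (cfg$founder_mutation_rate > 0) {
          flip <- matrix(stats::runif(F * ns) < cfg$founder_mutation_rate, F, ns)
          founders <- (founders + flip) %% 2L
        }
        fpath <- mosaic_paths(2L * nb, F, pos, cfg$switch_rate)
        site_idx <- seq_len(ns)
        for (s in seq_len(nb)) {
          h1 <- founders[cbind(fpath[2 * s - 1, ], site_idx)]
          h2 <- founders[cbind(fpath[2 * s, ], site_idx)]
          calls[row0 + s, ] <- h1 + h2
        }
        row0 <- row0 + nb
      }
      calls_list[[ci]] <- calls
      markers_list[[ci]] <- data.frame(
        chrom = chroms[ci], pos = pos,
        id = sprintf("%s_%d", chroms[ci], pos),
        a1 = "A", a2 = "B", stringsAsFactors = FALSE
      )
    }
    samples <- data.frame(
      id = unlist(lapply(seq_len(cfg$n_breeds), function(b) {
        sprintf("%s_s%02d", breed_names[b], seq_len(cfg$samples_per_breed[b]))
      })),
      breed = rep(breed_names, cfg$samples_per_breed),
      stringsAsFactors = FALSE
    )
    genotype_matrix(do.call(cbind, calls_list),
                    do.call(rbind, markers_list), samples)
  })
}

# alternating genic/intergenic renewal process with geometric segment
# lengths. Intergenic gaps are a two-component mixture -- mostly short gaps
# inside gene clusters, occasionally desert-scale gaps -- which reproduces
# the strong per-Mb variation of exome marker density seen around gene-dense
# and gene-poor regions; the mixture keeps the overall genic fraction at its
# nominal value (desert_prob * desert_scale < 1 required).
renewal_intervals <- function(L, mean_on, mean_off,
                              desert_prob = 0.2, desert_scale = 4) {
  mean_short <- mean_off * (1 - desert_prob * desert_scale) / (1 - desert_prob)
  gap <- function() {
    m <- if (stats::runif(1) < desert_prob) desert_scale * mean_off else mean_short
    stats::rgeom(1, 1 / m)
  }
  starts <- ends <- numeric(0)
  # start in the intergenic state
  x <- gap()
  while (x < L) {
    len_on <- stats::rgeom(1, 1 / mean_on) + 1
    starts <- c(starts, x)
    ends <- c(ends, min(x + len_on, L))
    x <- x + len_on + gap() + 1
  }
  data.frame(start = floor(starts), end = floor(ends))
}

#' Draw gene-like target intervals
#'
#' Targets are drawn by a two-state (genic/intergenic) renewal process along
#' each chromosome with geometric segment lengths, which produces the
#' clustered exome-panel spacing (skewed inter-marker distance distribution)
#' characteristic of capture designs.
#'
#' @param cfg a [sim_config()].
#' @return An [interval_set()] labelled `"targets"`.
#' @export
make_target_intervals <- function(cfg) {
  with_seed(substream_seed(cfg$seed, "targets"), {
    f <- cfg$target_fraction
    mean_off <- cfg$mean_target_bp * (1 - f) / f
    out <- lapply(names(cfg$chrom_lengths), function(ch) {
      iv <- renewal_intervals(cfg$chrom_lengths[ch], cfg$mean_target_bp,
                              mean_off)
      if (nrow(iv)) cbind(chrom = ch, iv) else NULL
    })
    out <- do.call(rbind, out)
    out <- out[out$end > out$start, , drop = FALSE]
    merge_intervals(interval_set(out$chrom, out$start, out$end, label = "targets"))
  })
}

#' Draw lincRNA-like intervals outside the targets
#'
#' @param cfg a [sim_config()].
#' @param targets target [interval_set()]; drawn intervals never overlap it.
#' @return An [interval_set()] labelled `"lincrna"`.
#' @export
make_lincrna_intervals <- function(cfg, targets) {
  with_seed(substream_seed(cfg$seed, "lincrna"), {
    total <- sum(cfg$chrom_lengths)
    n_want <- round(total * cfg$lincrna_fraction / cfg$mean_lincrna_bp)
    chrom <- start <- end <- c()
    tries <- 0
    while (length(start) < n_want && tries < 50 * n_want) {
      tries <- tries + 1
      ch <- sample(names(cfg$chrom_lengths), 1, prob = cfg$chrom_lengths)
      len <- stats::rgeom(1, 1 / cfg$mean_lincrna_bp) + 500
      s <- sample.int(max(1, cfg$chrom_lengths[ch] - len), 1)
      cand_gr <- GenomicRanges::GRanges(ch, IRanges::IRanges(s + 1, s + len))
      if (nrow(targets) &&
          length(GenomicRanges::findOverlaps(cand_gr, as_granges(targets)))) next
      chrom <- c(chrom, ch); start <- c(start, s); end <- c(end, s + len)
    }
    merge_intervals(interval_set(chrom, start, end, label = "lincrna"))
  })
}

#' Build the array-like and exome-like marker panels
#'
#' The array panel subsamples polymorphic sites at approximately uniform
#' spacing (`array_spacing_bp` on average, with binomial jitter). The exome
#' panel keeps polymorphic sites inside the target intervals plus an
#' `exome_offtarget_rate` fraction of off-target sites. The two panels may
#' intersect.
#'
#' @param gm site-level [genotype_matrix()] from [simulate_breed_genotypes()].
#' @param targets target [interval_set()].
#' @param cfg a [sim_config()].
#' @return A list with elements `array` and `exome`, each a data.frame of
#'   marker records (`chrom`, `pos`, `id`, `a1`, `a2`, `panel`).
#' @export
make_panels <- function(gm, targets, cfg) {
  with_seed(substream_seed(cfg$seed, "panels"), {
    af <- colMeans(gm$calls, na.rm = TRUE) / 2
    poly <- !is.na(af) & af > 0 & af < 1
    mk <- gm$markers[poly, , drop = FALSE]
    if (!nrow(mk)) stop("no polymorphic sites to build panels from")
    # array: Bernoulli thinning to one marker per array_spacing_bp on average
    keep <- logical(nrow(mk))
    for (ch in unique(mk$chrom)) {
      i <- which(mk$chrom == ch)
      want <- cfg$chrom_lengths[ch] / cfg$array_spacing_bp
      keep[i] <- stats::runif(length(i)) < min(1, want / length(i))
    }
    array_panel <- mk[keep, , drop = FALSE]
    # exome: on-target sites plus a fraction of off-target ones
    on <- pos_in_intervals(targets, mk$chrom, mk$pos)
    if (!any(on) && cfg$exome_offtarget_rate == 0) {
      stop("empty targets with exome_offtarget_rate = 0: exome panel would be empty")
    }
    n_off <- round(sum(on) * cfg$exome_offtarget_rate /
                     max(1e-12, 1 - cfg$exome_offtarget_rate))
    off_idx <- which(!on)
    off_sel <- if (length(off_idx) && n_off > 0) {
      sort(sample(off_idx, min(n_off, length(off_idx))))
    } else integer(0)
    exome_panel <- mk[sort(c(which(on), off_sel)), , drop = FALSE]
    if (!nrow(exome_panel)) stop("exome panel is empty")
    array_panel$panel <- "array"
    exome_panel$panel <- "exome"
    rownames(array_panel) <- rownames(exome_panel) <- NULL
    list(array = array_panel, exome = exome_panel)
  })
}

#' Trait specification for planting phenotypes
#'
#' @param model `"recessive"` or `"dominant"`.
#' @param causal_marker marker id, or `c(chrom, pos)`.
#' @param penetrance probability that a genetically affected sample is
#'   phenotypically a case (default 1: fully penetrant).
#' @param risk_allele which allele's homozygote (recessive) or carrier state
#'   (dominant) is affected: `"B"` (default) or `"A"`.
#' @param fixation optional named list/vector mapping breed name to `"case"`
#'   or `"control"` for breed-fixed traits; when given, phenotype is assigned
#'   by breed label rather than genotype.
#' @return A `trait_spec` list.
#' @export
trait_spec <- function(model = c("recessive", "dominant"), causal_marker,
                       penetrance = 1, risk_allele = c("B", "A"),
                       fixation = NULL) {
  model <- match.arg(model)
  risk_allele <- match.arg(risk_allele)
  stopifnot(penetrance >= 0, penetrance <= 1)
  structure(list(model = model, causal_marker = causal_marker,
                 penetrance = penetrance, risk_allele = risk_allele,
                 fixation = fixation),
            class = "trait_spec")
}

#' Plant a monogenic trait and derive sample phenotypes
#'
#' Recessive: a sample is a case iff homozygous for the risk allele.
#' Dominant: a case iff carrying at least one copy. With `penetrance < 1`,
#' genetic cases are independently flipped to controls with probability
#' `1 - penetrance`. In fixation mode the phenotype is assigned by breed
#' label, emulating traits fixed within breeds. Samples with a missing causal
#' genotype get a missing phenotype.
#'
#' @param gm a [genotype_matrix()].
#' @param spec a [trait_spec()].
#' @param seed seed for the penetrance flips (default derived from nothing:
#'   deterministic full-penetrance traits need no seed).
#' @return Integer phenotype vector named by sample id: 1 = control,
#'   2 = case, `NA` = missing.
#' @export
plant_trait <- function(gm, spec, seed = 1) {
  stopifnot(inherits(spec, "trait_spec"))
  n <- nrow(gm$samples)
  if (!is.null(spec$fixation)) {
    fx <- unlist(spec$fixation)
    ph <- ifelse(gm$samples$breed %in% names(fx)[fx == "case"], 2L,
                 ifelse(gm$samples$breed %in% names(fx)[fx == "control"], 1L,
                        NA_integer_))
  } else {
    j <- if (length(spec$causal_marker) == 2 && !spec$causal_marker[1] %in% gm$markers$id) {
      which(gm$markers$chrom == spec$causal_marker[1] &
              gm$markers$pos == as.integer(spec$causal_marker[2]))
    } else {
      which(gm$markers$id == spec$causal_marker[1])
    }
    if (length(j) != 1) stop("causal marker not found (or ambiguous)")
    g <- gm$calls[, j]
    if (length(unique(stats::na.omit(g))) < 2) {
      stop("causal marker is monomorphic; use fixation mode for breed-fixed traits")
    }
    dose <- if (spec$risk_allele == "B") g else 2L - g
    affected <- if (spec$model == "recessive") dose == 2L else dose >= 1L
    ph <- ifelse(is.na(affected), NA_integer_, ifelse(affected, 2L, 1L))
  }
  if (spec$penetrance < 1) {
    ph <- with_seed(seed, {
      flip <- !is.na(ph) & ph == 2L &
        stats::runif(n) > spec$penetrance
      ph[flip] <- 1L
      ph
    })
  }
  stats::setNames(ph, gm$samples$id)
}

#' Plant a breed-fixed causal variant into an existing marker
#'
#' Overwrites the genotypes at one marker with the breed-fixed pattern of a
#' trait under strong within-breed selection: samples from `"case"` breeds
#' become homozygous for the risk allele, samples from `"control"` breeds
#' homozygous for the other, and samples from unlisted breeds missing.
#' Drift alone essentially never fixes opposite alleles across breeds in the
#' mosaic model, so across-breed mapping fixtures plant the causal variant
#' explicitly. Existing missing calls at the marker are preserved by default
#' (sequencing panels often miss part of the case arm at the causal site).
#'
#' @param gm a [genotype_matrix()].
#' @param marker marker id.
#' @param fixation named list/vector: breed -> `"case"` or `"control"`.
#' @param risk_allele `"B"` (default) or `"A"`.
#' @param preserve_missing keep the marker's existing `NA` pattern.
#' @return The modified [genotype_matrix()].
#' @export
plant_fixed_variant <- function(gm, marker, fixation, risk_allele = "B",
                                preserve_missing = TRUE) {
  j <- match(marker, gm$markers$id)
  if (is.na(j)) stop("unknown marker id: ", marker)
  fx <- unlist(fixation)
  hom_case <- if (risk_allele == "B") 2L else 0L
  g <- ifelse(gm$samples$breed %in% names(fx)[fx == "case"], hom_case,
              ifelse(gm$samples$breed %in% names(fx)[fx == "control"],
                     2L - hom_case, NA_integer_))
  if (preserve_missing) g[is.na(gm$calls[, j])] <- NA_integer_
  gm$calls[, j] <- g
  gm
}

#' Apply panel-specific missingness to genotype calls
#'
#' Array-like panels drop each genotype independently at rate
#' `1 - callrate_array`. Exome-like panels first draw a per-marker call rate
#' from `Beta(alpha, beta)` and then drop genotypes independently, emulating
#' the higher and more variable per-marker missingness of sequencing assays.
#'
#' @param gm a [genotype_matrix()] (typically the site matrix).
#' @param panel panel data.frame from [make_panels()] (needs columns `id`,
#'   `panel`).
#' @param cfg a [sim_config()].
#' @param seed seed for the dropout draws; defaults to the config's
#'   `missingness` substream offset by the panel label.
#' @return The [genotype_matrix()] restricted to the panel's markers with
#'   missingness applied.
#' @export
apply_missingness <- function(gm, panel, cfg, seed = NULL) {
  stopifnot(all(panel$id %in% gm$markers$id))
  label <- panel$panel[1]
  seed <- seed %||% substream_seed(cfg$seed, paste0("missingness_", label))
  sub <- gm_subset(gm, markers = panel$id)
  with_seed(seed, {
    n <- nrow(sub$calls); m <- ncol(sub$calls)
    if (label == "array") {
      drop <- matrix(stats::runif(n * m) > cfg$callrate_array, n, m)
    } else {
      cr <- stats::rbeta(m, cfg$callrate_exome_beta[1], cfg$callrate_exome_beta[2])
      drop <- matrix(stats::runif(n * m), n, m) > rep(cr, each = n)
    }
    sub$calls[drop] <- NA_integer_
    sub
  })
}

#' Simulate a complete two-panel study
#'
#' Convenience wrapper running the full generator: genotypes, target and
#' lincRNA intervals, both panels and panel-specific missingness.
#'
#' @param cfg a [sim_config()].
#' @return A list: `cfg`, `sites` (full site [genotype_matrix()]), `targets`,
#'   `lincrnas`, `panels` (marker tables), `array` and `exome` (panel
#'   genotype matrices with missingness applied), and `build` (chromosome
#'   length table, see [genome_build()]).
#' @export
simulate_study <- function(cfg) {
  sites <- simulate_breed_genotypes(cfg)
  targets <- make_target_intervals(cfg)
  lincrnas <- make_lincrna_intervals(cfg, targets)
  panels <- make_panels(sites, targets, cfg)
  list(
    cfg = cfg,
    sites = sites,
    targets = targets,
    lincrnas = lincrnas,
    panels = panels,
    array = apply_missingness(sites, panels$array, cfg),
    exome = apply_missingness(sites, panels$exome, cfg),
    build = genome_build(names(cfg$chrom_lengths), cfg$chrom_lengths)
  )
}
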