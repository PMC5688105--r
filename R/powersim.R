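# Genotype-first power simulation for monogenic recessive traits: a marker
# whose homozygote class splits the cohort in half defines a fully penetrant
# case/control phenotype; the causal marker is omitted and the panel is asked
# to recover the association through LD, with max-T permutation control of
# the family-wise error rate. Includes the stratified experiments (causal
# inside/outside targets, SNP density, lincRNAs, sample size, tag distance)
# and the H0 companion runs.

#' Power-simulation configuration
#'
#' @param window_snps detection window: number of panel markers on each side
#'   of the causal position within which a significant marker counts as a
#'   detection (default 10; truncated at chromosome ends).
#' @param alpha significance level on max-T adjusted p-values.
#' @param n_perm permutations for max-T.
#' @param balance required case-arm size for causal-marker eligibility;
#'   `NULL` means half the cohort.
#' @param test association test for the scans.
#' @param seed root seed for permutation and subset draws.
#' @return A `power_config` list.
#' @export
power_config <- function(window_snps = 10, alpha = 0.05, n_perm = 500,
                         balance = NULL, test = "trend", seed = 1) {
  stopifnot(window_snps >= 0, alpha > 0, alpha < 1, n_perm >= 1)
  structure(list(window_snps = as.integer(window_snps), alpha = alpha,
                 n_perm = as.integer(n_perm), balance = balance,
                 test = test, seed = as.integer(seed)),
            class = "power_config")
}

#' Markers usable as simulated causal SNPs
#'
#' Under a fully penetrant autosomal recessive model, a marker defines a
#' balanced case/control design when exactly `balance` samples are homozygous
#' for one allele and the remaining samples (all of them called) form the
#' other arm. With `balance_range`, any homozygote-class size inside the
#' range qualifies (used for sparse strata such as lincRNAs).
#'
#' @param gm a QC-filtered [genotype_matrix()].
#' @param balance required homozygote-class size (default `n/2`).
#' @param balance_range optional `c(lo, hi)` replacing the exact-balance rule.
#' @return data.frame: `marker`, `chrom`, `pos`, `case_genotype` (0 or 2),
#'   `n_cases`. Possibly zero rows.
#' @export
eligible_causal_snps <- function(gm, balance = NULL, balance_range = NULL) {
  n <- nrow(gm$calls)
  balance <- balance %||% (n %/% 2)
  rows <- list()
  for (j in seq_len(ncol(gm$calls))) {
    g <- gm$calls[, j]
    if (anyNA(g)) next
    n0 <- sum(g == 0)
    n2 <- sum(g == 2)
    ok <- function(k) {
      if (!is.null(balance_range)) {
        k >= balance_range[1] && k <= balance_range[2] && k < n
      } else {
        k == balance
      }
    }
    case_g <- if (ok(n2) && n2 > 0) 2L else if (ok(n0) && n0 > 0) 0L else next
    k <- if (case_g == 2L) n2 else n0
    rows[[length(rows) + 1]] <- data.frame(
      marker = gm$markers$id[j], chrom = gm$markers$chrom[j],
      pos = gm$markers$pos[j], case_genotype = case_g, n_cases = k,
      stringsAsFactors = FALSE
    )
  }
  if (!length(rows)) {
    return(data.frame(marker = character(), chrom = character(),
                      pos = integer(), case_genotype = integer(),
                      n_cases = integer()))
  }
  do.call(rbind, rows)
}

# phenotype (1/2) from causal genotypes under the recessive dichotomisation
causal_phenotype <- function(causal_genotypes, case_genotype) {
  ifelse(is.na(causal_genotypes), NA_integer_,
         ifelse(causal_genotypes == case_genotype, 2L, 1L))
}

# panel marker indices within +/- window_snps markers of the causal position
window_indices <- function(markers, chrom, pos, window_snps) {
  on_chrom <- which(markers$chrom == chrom)
  if (!length(on_chrom)) return(integer(0))
  below <- on_chrom[markers$pos[on_chrom] < pos]
  above <- on_chrom[markers$pos[on_chrom] > pos]
  c(utils::tail(below, window_snps), utils::head(above, window_snps))
}

#' Run one simulated causal signal against a panel
#'
#' The phenotype is the recessive dichotomisation of the causal genotypes.
#' The causal marker itself -- and any panel marker at the identical
#' position -- is removed from the tested set, so the association must be
#' recovered through LD. Detection requires a marker within `window_snps`
#' panel markers on either side of the causal position with max-T adjusted
#' p <= alpha. The distance is recorded to the overall most significant
#' marker (ties broken towards the causal position, then by position).
#'
#' @param panel_gm QC-filtered panel [genotype_matrix()].
#' @param causal list/row with `chrom`, `pos`, `case_genotype`.
#' @param causal_genotypes genotype vector at the causal marker, aligned with
#'   `panel_gm` samples.
#' @param cfg a [power_config()].
#' @param perm_seed seed for the max-T permutations.
#' @param h0 if `TRUE`, the case/control labels are shuffled once (seeded)
#'   before testing, giving a null-calibration run.
#' @return list of class `signal_result`: `detected`, `best_marker`,
#'   `distance_bp` (`NA` when the best marker sits on another chromosome),
#'   `p_best`, `n_tested`, plus the inputs' coordinates.
#' @export
run_signal <- function(panel_gm, causal, causal_genotypes, cfg,
                       perm_seed = cfg$seed, h0 = FALSE) {
  pheno <- causal_phenotype(causal_genotypes, causal$case_genotype)
  keep <- !(panel_gm$markers$chrom == causal$chrom &
              panel_gm$markers$pos == causal$pos)
  if (!any(keep & panel_gm$markers$chrom == causal$chrom)) {
    stop("no panel marker on the causal chromosome")
  }
  tested <- gm_subset(panel_gm, markers = keep)
  if (h0) {
    pheno <- with_seed(substream_seed(perm_seed, "h0_shuffle"), {
      ok <- !is.na(pheno)
      pheno[ok] <- sample(pheno[ok])
      pheno
    })
  }
  res <- maxt_adjust(tested, pheno, test = cfg$test, n_perm = cfg$n_perm,
                     seed = perm_seed)
  win <- window_indices(tested$markers, causal$chrom, causal$pos,
                        cfg$window_snps)
  detected <- length(win) > 0 && any(res$p_maxT[win] <= cfg$alpha)
  dist_all <- ifelse(res$chrom == causal$chrom, abs(res$pos - causal$pos), Inf)
  best <- order(res$p_raw, dist_all, res$pos)[1]
  out <- list(
    causal_chrom = causal$chrom, causal_pos = causal$pos,
    detected = detected, best_marker = res$marker[best],
    distance_bp = if (is.finite(dist_all[best])) dist_all[best] else NA_real_,
    p_best = res$p_raw[best], p_maxT_best = res$p_maxT[best],
    n_tested = nrow(res), h0 = h0
  )
  class(out) <- "signal_result"
  out
}

#' Null-calibration companion of [run_signal()]
#'
#' Shuffles the case/control labels once (preserving their totals) and
#' reports whether any window marker is max-T significant, estimating the
#' type-I error of the windowed detection rule.
#'
#' @inheritParams run_signal
#' @return Logical: was a (spurious) detection declared?
#' @export
run_h0 <- function(panel_gm, causal, causal_genotypes, cfg,
                   perm_seed = cfg$seed) {
  run_signal(panel_gm, causal, causal_genotypes, cfg,
             perm_seed = perm_seed, h0 = TRUE)$detected
}

# draw up to k rows from a data.frame, seeded
sample_rows <- function(df, k, seed) {
  if (nrow(df) <= k) return(df)
  with_seed(seed, df[sort(sample.int(nrow(df), k)), , drop = FALSE])
}

#' Stratified power experiment
#'
#' Evaluates the power of each panel to detect simulated recessive signals,
#' stratified by causal-variant location:
#' \describe{
#'   \item{inside_targets / outside_targets}{causal candidates from the union
#'     of both panels, partitioned by target-interval membership.}
#'   \item{high_density_bins / low_density_bins}{causal = array-panel markers
#'     outside the targets but inside 1-Mb bins at or above the 85th / at or
#'     below the 15th percentile of the exome panel's informative-marker
#'     density.}
#'   \item{lincrna}{causal = array-panel markers inside lincRNA intervals
#'     (which never overlap targets), with eligibility relaxed to a 4-12
#'     case-arm range.}
#' }
#' Every signal gets an H0 companion run (labels shuffled once).
#'
#' @param study a [simulate_study()] result, or a list with elements
#'   `array`, `exome` (panel genotype matrices), `targets`, `lincrnas`,
#'   `build`.
#' @param cfg a [power_config()].
#' @param strata subset of the stratum names above.
#' @param panels which panels to evaluate.
#' @param max_signals cap on causal signals per stratum x panel (keeps large
#'   designs tractable; signals are a seeded random draw of the eligible set).
#' @param params [qc_params()] applied to each panel before testing.
#' @return data.frame with one row per stratum x panel: `stratum`, `panel`,
#'   `n_signals`, `power`, `power_se`, `median_distance_bp`, `h0_rate`.
#'   Strata with no eligible causal SNPs give an `NA` row with a warning.
#'   Attribute `signals` holds the per-signal audit table.
#' @export
power_experiment <- function(study, cfg = power_config(),
                             strata = c("inside_targets", "outside_targets",
                                        "high_density_bins",
                                        "low_density_bins", "lincrna"),
                             panels = c("exome", "array"),
                             max_signals = 25,
                             params = qc_params()) {
  strata <- match.arg(strata, several.ok = TRUE)
  qc <- lapply(study[c("array", "exome")], qc_filter, params = params)
  # causal candidate pools
  pools <- list()
  need_union <- any(c("inside_targets", "outside_targets") %in% strata)
  if (need_union) {
    elig <- do.call(rbind, lapply(names(qc), function(p) {
      e <- eligible_causal_snps(qc[[p]], balance = cfg$balance)
      e$source_panel <- rep(p, nrow(e))
      e
    }))
    elig <- elig[!duplicated(paste(elig$chrom, elig$pos)), , drop = FALSE]
    inside <- pos_in_intervals(study$targets, elig$chrom, elig$pos)
    pools$inside_targets <- elig[inside, , drop = FALSE]
    pools$outside_targets <- elig[!inside, , drop = FALSE]
  }
  if (any(c("high_density_bins", "low_density_bins") %in% strata)) {
    bins <- bin_marker_counts(qc$exome, build = study$build)
    arr_elig <- eligible_causal_snps(qc$array, balance = cfg$balance)
    arr_elig$source_panel <- rep("array", nrow(arr_elig))
    off <- !pos_in_intervals(study$targets, arr_elig$chrom, arr_elig$pos)
    for (cls in c("high", "low")) {
      b <- bins[bins$density_class == cls, , drop = FALSE]
      iv <- interval_set(b$chrom, b$start, b$end, label = cls)
      inb <- pos_in_intervals(iv, arr_elig$chrom, arr_elig$pos)
      pools[[paste0(cls, "_density_bins")]] <-
        arr_elig[off & inb, , drop = FALSE]
    }
  }
  if ("lincrna" %in% strata) {
    arr_relaxed <- eligible_causal_snps(qc$array, balance_range = c(4, 12))
    arr_relaxed$source_panel <- rep("array", nrow(arr_relaxed))
    inl <- pos_in_intervals(study$lincrnas, arr_relaxed$chrom, arr_relaxed$pos)
    pools$lincrna <- arr_relaxed[inl, , drop = FALSE]
  }
  rows <- list()
  audit <- list()
  for (st in strata) {
    pool <- pools[[st]]
    for (pn in panels) {
      if (is.null(pool) || nrow(pool) == 0) {
        warning("stratum ", st, ": no eligible causal SNPs")
        rows[[length(rows) + 1]] <- data.frame(
          stratum = st, panel = pn, n_signals = 0L, power = NA_real_,
          power_se = NA_real_, median_distance_bp = NA_real_,
          h0_rate = NA_real_)
        next
      }
      sel <- sample_rows(pool, max_signals,
                         substream_seed(cfg$seed, paste0("signals_", st, "_", pn)))
      det <- dist <- h0 <- numeric(0)
      for (k in seq_len(nrow(sel))) {
        causal <- sel[k, ]
        src <- qc[[causal$source_panel]]
        cg <- src$calls[, causal$marker]
        ps <- substream_seed(cfg$seed, paste(st, pn, causal$marker, sep = "_"))
        sr <- run_signal(qc[[pn]], causal, cg, cfg, perm_seed = ps)
        det <- c(det, sr$detected)
        dist <- c(dist, sr$distance_bp)
        h0 <- c(h0, run_h0(qc[[pn]], causal, cg, cfg, perm_seed = ps + 1L))
        audit[[length(audit) + 1]] <- data.frame(
          stratum = st, panel = pn, causal_marker = causal$marker,
          causal_chrom = causal$chrom, causal_pos = causal$pos,
          detected = sr$detected, best_marker = sr$best_marker,
          distance_bp = sr$distance_bp, p_best = sr$p_best,
          stringsAsFactors = FALSE)
      }
      pw <- mean(det)
      rows[[length(rows) + 1]] <- data.frame(
        stratum = st, panel = pn, n_signals = length(det), power = pw,
        power_se = sqrt(pw * (1 - pw) / length(det)),
        median_distance_bp = stats::median(dist, na.rm = TRUE),
        h0_rate = mean(h0))
    }
  }
  out <- do.call(rbind, rows)
  attr(out, "signals") <- do.call(rbind, audit)
  out
}

#' Power as a function of sample size
#'
#' For each (even) target size `k`, balanced subsets -- `k/2` of the causal
#' marker's case arm and `k/2` of its control arm -- are enumerated a priori;
#' at least `min_fraction` of all such combinations (and at least one) are
#' drawn at random and each is evaluated with [run_signal()] on the panel
#' restricted to the subset (markers re-QC'd within the subset). Eligibility
#' is re-derived per subset: by construction the causal marker remains
#' balanced at `k/2`.
#'
#' @param panel_gm QC-filtered panel [genotype_matrix()].
#' @param causal_pool data.frame from [eligible_causal_snps()] on the full
#'   cohort (the causal genotypes are taken from `causal_gm`).
#' @param causal_gm [genotype_matrix()] carrying the causal genotypes
#'   (defaults to `panel_gm`).
#' @param sizes even subset sizes to evaluate.
#' @param min_fraction minimum fraction of all balanced combinations to
#'   evaluate per causal marker and size.
#' @param max_subsets hard cap on subsets per causal marker and size
#'   (tractability; `Inf` disables it).
#' @param max_signals cap on causal markers used.
#' @param cfg a [power_config()].
#' @param params [qc_params()] re-applied within each subset.
#' @return data.frame: `size`, `n_evaluated`, `n_combinations`, `power`,
#'   `power_se`; attribute `per_subset` has the per-subset detections.
#' @export
sample_size_experiment <- function(panel_gm, causal_pool, causal_gm = panel_gm,
                                   sizes = c(14, 12, 10, 8, 6),
                                   min_fraction = 0.2, max_subsets = Inf,
                                   max_signals = 10,
                                   cfg = power_config(),
                                   params = qc_params()) {
  if (any(sizes %% 2 != 0)) stop("sizes must be even (balanced designs)")
  n <- nrow(panel_gm$calls)
  if (any(sizes > n)) stop("size exceeds the cohort")
  pool <- sample_rows(causal_pool, max_signals,
                      substream_seed(cfg$seed, "size_signals"))
  rows <- list()
  per <- list()
  for (k in sizes) {
    det <- logical(0)
    n_comb_total <- 0
    for (q in seq_len(nrow(pool))) {
      causal <- pool[q, ]
      cg <- causal_gm$calls[, causal$marker]
      case_idx <- which(cg == causal$case_genotype)
      ctrl_idx <- which(cg != causal$case_genotype & !is.na(cg))
      b <- length(case_idx)
      if (k / 2 > b || k / 2 > length(ctrl_idx)) next
      n_comb <- choose(b, k / 2) * choose(length(ctrl_idx), k / 2)
      n_comb_total <- n_comb_total + n_comb
      n_eval <- min(max(1, ceiling(min_fraction * n_comb)), max_subsets)
      seeds <- substream_seed(cfg$seed, paste0("size", k, "_", causal$marker))
      subsets <- with_seed(seeds, {
        lapply(seq_len(n_eval), function(i) {
          sort(c(sample(case_idx, k / 2), sample(ctrl_idx, k / 2)))
        })
      })
      for (i in seq_along(subsets)) {
        sub <- gm_subset(panel_gm, samples = subsets[[i]])
        sub <- qc_filter(sub, params)
        if (!any(sub$markers$chrom == causal$chrom)) next
        cfg_k <- cfg
        cfg_k$balance <- k / 2
        sr <- run_signal(sub, causal, cg[subsets[[i]]], cfg_k,
                         perm_seed = seeds + i)
        det <- c(det, sr$detected)
        per[[length(per) + 1]] <- data.frame(
          size = k, causal_marker = causal$marker, subset = i,
          detected = sr$detected, distance_bp = sr$distance_bp)
      }
    }
    pw <- mean(det)
    rows[[length(rows) + 1]] <- data.frame(
      size = k, n_evaluated = length(det), n_combinations = n_comb_total,
      power = pw, power_se = sqrt(pw * (1 - pw) / max(1, length(det))))
  }
  out <- do.call(rbind, rows)
  attr(out, "per_subset") <- do.call(rbind, per)
  out
}

#' Power as a function of tag-causal distance
#'
#' Selects (tagSNP, causal SNP) pairs whose physical separation falls inside
#' each distance bin -- the causal SNP always drawn from the array panel, on
#' the same chromosome as the tag -- simulates the recessive phenotype at the
#' causal SNP and tests the association with the single tagSNP (Bonferroni
#' m = 1, i.e. raw p <= alpha).
#'
#' @param tag_gm QC-filtered panel providing the tagSNPs.
#' @param array_gm QC-filtered array panel providing the causal SNPs.
#' @param bins list of `c(lo, hi)` distance bins in bp (disjoint, ordered).
#' @param cfg a [power_config()] (`balance` governs causal eligibility).
#' @param max_pairs cap on pairs per bin.
#' @return data.frame: `bin_lo`, `bin_hi`, `n_pairs`, `power` (`NA` for bins
#'   with no pairs).
#' @export
distance_effect_experiment <- function(tag_gm, array_gm,
                                       bins = list(c(1, 2e4), c(5e4, 3e5),
                                                   c(5e5, 8e5), c(1e6, 2e6)),
                                       cfg = power_config(),
                                       max_pairs = 50) {
  lo <- vapply(bins, `[`, numeric(1), 1)
  hi <- vapply(bins, `[`, numeric(1), 2)
  if (any(lo >= hi) || any(utils::head(hi, -1) > utils::tail(lo, -1))) {
    stop("distance bins must be disjoint and ordered")
  }
  elig <- eligible_causal_snps(array_gm, balance = cfg$balance)
  rows <- list()
  for (bi in seq_along(bins)) {
    pairs <- list()
    for (q in seq_len(nrow(elig))) {
      causal <- elig[q, ]
      cand <- which(tag_gm$markers$chrom == causal$chrom &
                      abs(tag_gm$markers$pos - causal$pos) >= lo[bi] &
                      abs(tag_gm$markers$pos - causal$pos) <= hi[bi])
      if (length(cand)) {
        pairs[[length(pairs) + 1]] <- data.frame(q = q, tag = cand)
      }
    }
    if (!length(pairs)) {
      rows[[length(rows) + 1]] <- data.frame(
        bin_lo = lo[bi], bin_hi = hi[bi], n_pairs = 0L, power = NA_real_)
      next
    }
    pairs <- do.call(rbind, pairs)
    pairs <- sample_rows(pairs, max_pairs,
                         substream_seed(cfg$seed, paste0("distbin", bi)))
    det <- logical(nrow(pairs))
    for (i in seq_len(nrow(pairs))) {
      causal <- elig[pairs$q[i], ]
      cg <- array_gm$calls[, causal$marker]
      pheno <- causal_phenotype(cg, causal$case_genotype)
      g <- tag_gm$calls[, pairs$tag[i]]
      counts <- geno_counts(g, pheno)
      det[i] <- if (sum(counts$cases) == 0 || sum(counts$controls) == 0) {
        FALSE
      } else {
        res <- catt(counts)
        !is.na(res$p) && res$p <= cfg$alpha
      }
    }
    rows[[length(rows) + 1]] <- data.frame(
      bin_lo = lo[bi], bin_hi = hi[bi], n_pairs = nrow(pairs),
      power = mean(det))
  }
  do.call(rbind, rows)
}
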