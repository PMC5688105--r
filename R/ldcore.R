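# Marker QC, EM-based r2 between unphased genotypes, and the LD survey
# procedures (adjacent-marker r2, binned marker density, SNP and sample
# subsampling, background LD from unlinked SNPs).

#' QC filter parameters
#'
#' @param maf_min minimum minor allele frequency among called samples;
#'   markers with MAF strictly below it are removed (MAF exactly at the
#'   threshold is kept).
#' @param max_missing maximum fraction of missing genotypes.
#' @param min_nonzero_genotypes minimum fraction of successfully called
#'   genotypes (the complement of the missingness rule; kept as a separate
#'   knob so the two call-rate rules can be tightened independently).
#' @param hwe_p_min markers with Hardy-Weinberg exact p strictly below this
#'   are removed; the default 0 disables the filter.
#' @return A `qc_params` list.
#' @export
qc_params <- function(maf_min = 0.05, max_missing = 0.5,
                      min_nonzero_genotypes = 0.5, hwe_p_min = 0) {
  p <- list(maf_min = maf_min, max_missing = max_missing,
            min_nonzero_genotypes = min_nonzero_genotypes,
            hwe_p_min = hwe_p_min)
  stopifnot(all(unlist(p) >= 0), all(unlist(p) <= 1))
  class(p) <- "qc_params"
  p
}

#' Filter markers on MAF, call rate and (optionally) HWE
#'
#' MAF is computed among called samples only. The filter is idempotent:
#' applying it twice gives the same marker set.
#'
#' @param gm a [genotype_matrix()].
#' @param params a [qc_params()].
#' @return The filtered [genotype_matrix()] with attribute `qc_report`, a list
#'   of per-rule removal counts (a marker failing several rules is counted
#'   under each).
#' @export
qc_filter <- function(gm, params = qc_params()) {
  calls <- gm$calls
  n <- nrow(calls)
  n_called <- colSums(!is.na(calls))
  miss_frac <- 1 - n_called / n
  af <- ifelse(n_called > 0, colSums(calls, na.rm = TRUE) / (2 * n_called), NA)
  maf <- pmin(af, 1 - af)
  fail_maf <- is.na(maf) | maf < params$maf_min
  fail_miss <- miss_frac > params$max_missing
  fail_nonzero <- (n_called / n) < params$min_nonzero_genotypes
  fail_hwe <- rep(FALSE, ncol(calls))
  if (params$hwe_p_min > 0) {
    for (j in seq_len(ncol(calls))) {
      g <- calls[, j]
      cnt <- c(sum(g == 0, na.rm = TRUE), sum(g == 1, na.rm = TRUE),
               sum(g == 2, na.rm = TRUE))
      if (sum(cnt) > 0) {
        fail_hwe[j] <- hwe_exact_p(cnt[1], cnt[2], cnt[3]) < params$hwe_p_min
      }
    }
  }
  keep <- !(fail_maf | fail_miss | fail_nonzero | fail_hwe)
  out <- gm_subset(gm, markers = keep)
  attr(out, "qc_report") <- list(
    n_in = ncol(calls), n_kept = sum(keep),
    removed_maf = sum(fail_maf), removed_missing = sum(fail_miss),
    removed_nonzero = sum(fail_nonzero), removed_hwe = sum(fail_hwe)
  )
  out
}

#' Hardy-Weinberg exact test
#'
#' Two-sided exact p-value conditioning on the observed allele counts: the sum
#' of the probabilities of all heterozygote counts whose conditional
#' probability does not exceed that of the observed count.
#'
#' @param n_AA,n_AB,n_BB genotype counts.
#' @return The exact p-value in `(0, 1]`.
#' @export
hwe_exact_p <- function(n_AA, n_AB, n_BB) {
  stopifnot(n_AA >= 0, n_AB >= 0, n_BB >= 0)
  n <- n_AA + n_AB + n_BB
  if (n == 0) stop("all genotype counts are zero")
  nA <- 2 * n_AA + n_AB
  nB <- 2 * n_BB + n_AB
  # heterozygote counts compatible with the allele counts share nA's parity
  hets <- seq(nA %% 2, min(nA, nB), by = 2)
  logp <- vapply(hets, function(h) {
    aa <- (nA - h) / 2
    bb <- (nB - h) / 2
    lgamma(n + 1) - lgamma(aa + 1) - lgamma(h + 1) - lgamma(bb + 1) +
      h * log(2) + lgamma(nA + 1) + lgamma(nB + 1) - lgamma(2 * n + 1)
  }, numeric(1))
  p <- exp(logp - max(logp))
  p <- p / sum(p)
  obs <- p[match(n_AB, hets)]
  min(1, sum(p[p <= obs * (1 + 1e-12)]))
}

#' r2 and D between two markers from unphased genotypes (EM)
#'
#' Haplotype frequencies are estimated by EM: every genotype combination is
#' phase-resolved deterministically except double heterozygotes, whose
#' coupling/repulsion split is iterated to convergence (initial split 0.5,
#' stop when the largest frequency change is below `tol` or after `max_iter`
#' iterations). `D = p_AB - p_A p_B` and
#' `r2 = D^2 / (p_A (1 - p_A) p_B (1 - p_B))`, computed on pairwise-complete
#' samples. When the likelihood carries no phase information (all informative
#' samples are double heterozygotes) the pair is flagged undefined rather
#' than reporting the arbitrary half-split value.
#'
#' @param geno_i,geno_j genotype vectors (0/1/2/NA) of equal length.
#' @param tol,max_iter EM convergence controls.
#' @return A list of class `ld_pair`: `r2`, `D`, `n_used`, `defined`,
#'   `converged`, `iterations`, and the four haplotype frequencies `p00`,
#'   `p01`, `p10`, `p11` (first index = allele B at marker i).
#' @export
r2_em <- function(geno_i, geno_j, tol = 1e-10, max_iter = 1000) {
  stopifnot(length(geno_i) == length(geno_j))
  keep <- !is.na(geno_i) & !is.na(geno_j)
  gi <- geno_i[keep]
  gj <- geno_j[keep]
  n <- length(gi)
  undefined <- list(r2 = NA_real_, D = NA_real_, n_used = n, defined = FALSE,
                    converged = FALSE, iterations = 0L,
                    p00 = NA_real_, p01 = NA_real_, p10 = NA_real_, p11 = NA_real_)
  class(undefined) <- "ld_pair"
  if (n < 2) return(undefined)
  if (length(unique(gi)) < 2 || length(unique(gj)) < 2) return(undefined)
  tab <- table(factor(gi, 0:2), factor(gj, 0:2))
  # phase-determined haplotype counts (x[ab]: a = B-allele at i, b at j)
  x00 <- 2 * tab[1, 1] + tab[1, 2] + tab[2, 1]
  x01 <- 2 * tab[1, 3] + tab[1, 2] + tab[2, 3]
  x10 <- 2 * tab[3, 1] + tab[2, 1] + tab[3, 2]
  x11 <- 2 * tab[3, 3] + tab[3, 2] + tab[2, 3]
  ndh <- tab[2, 2]
  if (ndh == n) return(undefined)  # flat likelihood: no phase information
  tot <- 2 * n
  freqs <- function(w) {
    c(x00 + ndh * w, x01 + ndh * (1 - w), x10 + ndh * (1 - w),
      x11 + ndh * w) / tot
  }
  loglik <- function(p) {
    sum(c(x00, x01, x10, x11) * log(pmax(p, 1e-300))) +
      if (ndh > 0) ndh * log(pmax(p[4] * p[1] + p[3] * p[2], 1e-300)) else 0
  }
  # multiple starts guard against the unstable symmetric fixed point at
  # w = 0.5 (perfectly symmetric tables) and local maxima; the run with the
  # best observed-data likelihood wins
  best <- NULL
  it <- 0L
  converged <- FALSE
  for (w0 in if (ndh == 0) 0.5 else c(0.5, 0.05, 0.95)) {
    p <- freqs(w0)
    this_it <- 0L
    this_conv <- ndh == 0
    while (!this_conv && this_it < max_iter) {
      this_it <- this_it + 1L
      den <- p[4] * p[1] + p[3] * p[2]
      w <- if (den > 0) p[4] * p[1] / den else 0.5
      pn <- freqs(w)
      if (max(abs(pn - p)) < tol) this_conv <- TRUE
      p <- pn
    }
    if (is.null(best) || loglik(p) > loglik(best) + 1e-12) {
      best <- p
      it <- this_it
      converged <- this_conv
    }
  }
  p <- best
  pA <- p[3] + p[4]
  pB <- p[2] + p[4]
  D <- p[4] - pA * pB
  denom <- pA * (1 - pA) * pB * (1 - pB)
  if (denom <= 0) return(undefined)
  out <- list(r2 = min(1, D^2 / denom), D = D, n_used = n, defined = TRUE,
              converged = converged, iterations = it,
              p00 = p[1], p01 = p[2], p10 = p[3], p11 = p[4])
  class(out) <- "ld_pair"
  out
}

#' @export
print.ld_pair <- function(x, ...) {
  cat(sprintf("ld_pair: r2 = %s, D = %s, n = %d%s\n",
              format(x$r2, digits = 4), format(x$D, digits = 4), x$n_used,
              if (!x$defined) " (undefined)" else ""))
  invisible(x)
}

#' r2 between subsequent markers
#'
#' One pair per consecutive marker pair within each chromosome, in position
#' order. Markers co-located at the same (chrom, pos) -- as can happen when
#' panels are merged -- are deduplicated first (keeping the first by input
#' order) so that no distance-0 pairs arise.
#'
#' @param gm a QC-filtered [genotype_matrix()] (pass `params` to have the
#'   filter applied here).
#' @param params optional [qc_params()] applied before pairing.
#' @return A data.frame: `marker_i`, `marker_j`, `chrom`, `distance_bp`,
#'   `r2`, `D`, `n_used`, `defined`. Undefined pairs are retained in the
#'   table (flagged) but should be excluded from medians; the attached
#'   attribute `n_undefined` counts them.
#' @export
adjacent_r2 <- function(gm, params = NULL) {
  if (!is.null(params)) gm <- qc_filter(gm, params)
  dup <- duplicated(paste(gm$markers$chrom, gm$markers$pos))
  if (any(dup)) gm <- gm_subset(gm, markers = !dup)
  res <- list()
  for (ch in unique(gm$markers$chrom)) {
    idx <- which(gm$markers$chrom == ch)
    if (length(idx) < 2) {
      warning("chromosome ", ch, " has fewer than 2 markers; skipped")
      next
    }
    for (k in seq_len(length(idx) - 1)) {
      i <- idx[k]
      j <- idx[k + 1]
      lp <- r2_em(gm$calls[, i], gm$calls[, j])
      res[[length(res) + 1]] <- data.frame(
        marker_i = gm$markers$id[i], marker_j = gm$markers$id[j],
        chrom = ch, distance_bp = gm$markers$pos[j] - gm$markers$pos[i],
        r2 = lp$r2, D = lp$D, n_used = lp$n_used, defined = lp$defined,
        stringsAsFactors = FALSE
      )
    }
  }
  out <- if (length(res)) do.call(rbind, res) else {
    data.frame(marker_i = character(), marker_j = character(),
               chrom = character(), distance_bp = numeric(), r2 = numeric(),
               D = numeric(), n_used = integer(), defined = logical())
  }
  attr(out, "n_undefined") <- sum(!out$defined)
  out
}

#' Per-chromosome summary of adjacent-marker r2
#'
#' @param pairs output of [adjacent_r2()].
#' @return data.frame with min/Q1/mean/median/Q3/max r2 per chromosome
#'   (defined pairs only).
#' @export
adjacent_r2_summary <- function(pairs) {
  p <- pairs[pairs$defined, , drop = FALSE]
  do.call(rbind, lapply(split(p, p$chrom), function(d) {
    q <- stats::quantile(d$r2, c(0, .25, .5, .75, 1), names = FALSE)
    data.frame(chrom = d$chrom[1], n_pairs = nrow(d), min = q[1], q1 = q[2],
               mean = mean(d$r2), median = q[3], q3 = q[4], max = q[5])
  }))
}

#' Smoothed r2-versus-distance curve
#'
#' Locally weighted smoothing of pair r2 against inter-marker distance, a
#' reporting convenience with no inferential role.
#'
#' @param pairs output of [adjacent_r2()] (or any pair table with
#'   `distance_bp` and `r2`).
#' @param span lowess smoother span.
#' @return data.frame `distance_bp`, `r2_smooth`.
#' @export
ld_distance_curve <- function(pairs, span = 2 / 3) {
  p <- pairs[pairs$defined & !is.na(pairs$r2), , drop = FALSE]
  if (nrow(p) < 3) return(data.frame(distance_bp = numeric(), r2_smooth = numeric()))
  fit <- stats::lowess(p$distance_bp, p$r2, f = span)
  data.frame(distance_bp = fit$x, r2_smooth = fit$y)
}

#' Count QC-passing markers in non-overlapping genomic bins
#'
#' @param gm a [genotype_matrix()] (already QC-filtered).
#' @param binsize_bp bin width, default 1 Mb.
#' @param build optional [genome_build()]; when given, bins cover whole
#'   chromosomes (so empty bins are reported), otherwise bins run to the last
#'   marker.
#' @param probs percentiles of the per-bin count distribution used to flag
#'   low/high-density bins.
#' @return data.frame `chrom`, `start`, `end`, `count`, `density_class`
#'   (`"low"` if count <= the lower percentile, `"high"` if >= the upper,
#'   else `"mid"`), with attribute `thresholds`.
#' @export
bin_marker_counts <- function(gm, binsize_bp = 1e6, build = NULL,
                              probs = c(0.15, 0.85)) {
  chroms <- if (!is.null(build)) build$chrom else unique(gm$markers$chrom)
  rows <- lapply(chroms, function(ch) {
    len <- if (!is.null(build)) {
      build$length[build$chrom == ch]
    } else {
      max(gm$markers$pos[gm$markers$chrom == ch], 0)
    }
    n_bins <- max(1, ceiling(len / binsize_bp))
    start <- (seq_len(n_bins) - 1) * binsize_bp
    pos <- gm$markers$pos[gm$markers$chrom == ch]
    cnt <- tabulate(floor((pos - 1) / binsize_bp) + 1, nbins = n_bins)
    data.frame(chrom = ch, start = start,
               end = pmin(start + binsize_bp, max(len, start + binsize_bp)),
               count = cnt, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  thr <- stats::quantile(out$count, probs, names = FALSE)
  out$density_class <- ifelse(out$count <= thr[1], "low",
                              ifelse(out$count >= thr[2], "high", "mid"))
  attr(out, "thresholds") <- stats::setNames(thr, c("p_low", "p_high"))
  out
}

#' Effect of SNP quantity on adjacent-marker r2
#'
#' Random marker subsets of decreasing size, each re-paired and summarised by
#' the median adjacent r2, mirroring stepwise panel thinning.
#'
#' @param gm a QC-filtered [genotype_matrix()].
#' @param counts marker counts to subsample to.
#' @param reps subsets per count.
#' @param seed seed.
#' @param maf_min threshold used for the reported polymorphic-marker count.
#' @return Long-format data.frame: `count`, `rep`, `median_r2`,
#'   `n_polymorphic`, `n_pairs`.
#' @export
subsample_snps_experiment <- function(gm, counts = c(9000, 7500, 6000, 4500, 3000, 1500),
                                      reps = 10, seed = 1, maf_min = 0.05) {
  m <- ncol(gm$calls)
  bad <- counts[counts > m]
  if (length(bad)) {
    stop("requested count ", bad[1], " exceeds the ", m, " available markers")
  }
  with_seed(seed, {
    rows <- list()
    for (cnt in counts) {
      for (r in seq_len(reps)) {
        idx <- sort(sample.int(m, cnt))
        sub <- gm_subset(gm, markers = idx)
        pairs <- suppressWarnings(adjacent_r2(sub))
        af <- colMeans(sub$calls, na.rm = TRUE) / 2
        maf <- pmin(af, 1 - af)
        rows[[length(rows) + 1]] <- data.frame(
          count = cnt, rep = r,
          median_r2 = stats::median(pairs$r2[pairs$defined], na.rm = TRUE),
          n_polymorphic = sum(!is.na(maf) & maf >= maf_min),
          n_pairs = sum(pairs$defined)
        )
      }
    }
    do.call(rbind, rows)
  })
}

#' Sample-subset distribution of the median adjacent r2
#'
#' Repeatedly subsamples `k` samples, re-applies QC within the subset and
#' records the median adjacent-marker r2, quantifying the small-sample upward
#' bias of r2.
#'
#' @param gm a [genotype_matrix()].
#' @param k samples per subset (>= 2).
#' @param reps number of subsets.
#' @param seed seed.
#' @param params [qc_params()] re-applied within each subset.
#' @return data.frame `rep`, `median_r2`, `n_markers`.
#' @export
subsample_samples_r2 <- function(gm, k = 6, reps = 100, seed = 1,
                                 params = qc_params()) {
  n <- nrow(gm$calls)
  if (k < 2) stop("k must be >= 2")
  if (k > n) stop("k exceeds the number of samples")
  with_seed(seed, {
    rows <- lapply(seq_len(reps), function(r) {
      sub <- gm_subset(gm, samples = sort(sample.int(n, k)))
      sub <- qc_filter(sub, params)
      pairs <- suppressWarnings(adjacent_r2(sub))
      data.frame(rep = r,
                 median_r2 = stats::median(pairs$r2[pairs$defined], na.rm = TRUE),
                 n_markers = ncol(sub$calls))
    })
    do.call(rbind, rows)
  })
}

#' Background LD from unlinked SNPs
#'
#' Per replicate, one QC-passing marker is drawn from each of
#' `n_snps_per_draw` chromosomes and r2 is computed for all pairwise
#' combinations; the median of the per-replicate medians estimates the
#' background r2 between physically unlinked markers.
#'
#' @param gm a QC-filtered [genotype_matrix()].
#' @param n_snps_per_draw markers (= chromosomes) per draw.
#' @param reps number of draws.
#' @param seed seed.
#' @return list: `median` (median of per-rep medians), `per_rep` (vector),
#'   `pooled` (all pair r2 values), `n_pairs_per_rep`.
#' @export
background_r2 <- function(gm, n_snps_per_draw = 38, reps = 100, seed = 1) {
  chroms <- unique(gm$markers$chrom)
  if (length(chroms) < n_snps_per_draw) {
    stop(sprintf("need >= %d chromosomes with QC-passing markers, have %d",
                 n_snps_per_draw, length(chroms)))
  }
  with_seed(seed, {
    per_rep <- numeric(reps)
    pooled <- list()
    for (r in seq_len(reps)) {
      sel_chroms <- if (length(chroms) == n_snps_per_draw) chroms else {
        sample(chroms, n_snps_per_draw)
      }
      idx <- vapply(sel_chroms, function(ch) {
        cand <- which(gm$markers$chrom == ch)
        cand[sample.int(length(cand), 1)]
      }, integer(1))
      combs <- utils::combn(idx, 2)
      r2s <- vapply(seq_len(ncol(combs)), function(q) {
        r2_em(gm$calls[, combs[1, q]], gm$calls[, combs[2, q]])$r2
      }, numeric(1))
      per_rep[r] <- stats::median(r2s, na.rm = TRUE)
      pooled[[r]] <- r2s
    }
    list(median = stats::median(per_rep), per_rep = per_rep,
         pooled = unlist(pooled),
         n_pairs_per_rep = choose(n_snps_per_draw, 2))
  })
}
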