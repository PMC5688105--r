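# Across-breed mapping of breed-fixed traits: allelic association with
# Bonferroni correction, distance from the closest significant marker to a
# known causal locus, and the minimal-sample-size search.

#' Map a trait across the cohort
#'
#' Per-marker association with per-marker complete-case counts (samples
#' missing a genotype are dropped at that marker only, so case counts can
#' fall below the cohort size), Bonferroni correction over `m` tests and
#' ranks on raw p (ties broken by genomic order).
#'
#' @param gm a [genotype_matrix()] (QC-filtered as desired).
#' @param phenotypes vector: 2 = case, 1 = control, `NA` excluded.
#' @param test `"allelic"` (default) or `"trend"`.
#' @param m Bonferroni denominator; defaults to the number of markers tested.
#' @return An association table (data.frame): `marker`, `chrom`, `pos`,
#'   genotype counts of cases and controls (`cases_0/1/2`, `controls_0/1/2`),
#'   `statistic`, `p_raw`, `p_bonferroni`, `rank`.
#' @export
map_trait <- function(gm, phenotypes, test = c("allelic", "trend"), m = NULL) {
  test <- match.arg(test)
  res <- assoc_scan(gm, phenotypes, test = test)
  y <- as_case_indicator(phenotypes)
  cls <- gm$calls[!is.na(y), , drop = FALSE]
  yy <- y[!is.na(y)]
  cnt <- function(gval, grp) {
    colSums(cls == gval & !is.na(cls) & (yy == grp), na.rm = TRUE)
  }
  res$cases_0 <- cnt(0L, 1); res$cases_1 <- cnt(1L, 1); res$cases_2 <- cnt(2L, 1)
  res$controls_0 <- cnt(0L, 0); res$controls_1 <- cnt(1L, 0); res$controls_2 <- cnt(2L, 0)
  m <- m %||% nrow(res)
  res$p_bonferroni <- bonferroni(res$p_raw, m)
  res$rank <- rank_by_p(res$p_raw)
  res
}

#' Closest significant marker to a known causal locus
#'
#' Among markers with Bonferroni-corrected p <= `alpha` on the causal
#' chromosome, returns the one closest to the causal position; ties go to
#' the smaller p, then the lower position.
#'
#' @param assoc a [map_trait()] table.
#' @param causal `c(chrom, pos)`.
#' @param alpha significance level on `p_bonferroni`.
#' @return list: `marker`, `distance_bp`, `p_bonferroni`, `rank` (all `NA`
#'   when no significant marker exists on the causal chromosome).
#' @export
closest_significant <- function(assoc, causal, alpha = 0.05) {
  stopifnot(nrow(assoc) > 0)
  chrom <- as.character(causal[1])
  pos <- as.numeric(causal[2])
  sig <- assoc[assoc$chrom == chrom & assoc$p_bonferroni <= alpha, , drop = FALSE]
  if (!nrow(sig)) {
    return(list(marker = NA_character_, distance_bp = NA_real_,
                p_bonferroni = NA_real_, rank = NA_integer_))
  }
  d <- abs(sig$pos - pos)
  best <- order(d, sig$p_bonferroni, sig$pos)[1]
  list(marker = sig$marker[best], distance_bp = d[best],
       p_bonferroni = sig$p_bonferroni[best], rank = sig$rank[best])
}

#' Minimal sample size yielding a significant association
#'
#' Stepwise subsampling, sizes in descending order. Per size,
#' `combos_per_size` random subsets are drawn (stratified by breed, so the
#' across-breed design is preserved); a subset succeeds when any marker
#' survives the Bonferroni threshold after within-subset QC. The last size
#' (walking downwards) with at least one success is the reported minimum;
#' the walk stops at the first size with no successes.
#'
#' @param gm a [genotype_matrix()].
#' @param phenotypes vector (2 = case, 1 = control).
#' @param sizes total sample sizes in descending order.
#' @param combos_per_size random subsets per size.
#' @param alpha threshold on Bonferroni-corrected p.
#' @param seed seed.
#' @param test association test.
#' @param params [qc_params()] re-applied within each subset.
#' @param stratify_by_breed subsample proportionally within breeds (default)
#'   or simple random subsets.
#' @return list: `min_size` (`NA` if even the largest size never succeeds),
#'   `per_size` (data.frame `size`, `n_success`, `n_combos`).
#' @export
min_sample_size <- function(gm, phenotypes, sizes, combos_per_size = 10,
                            alpha = 0.05, seed = 1,
                            test = c("allelic", "trend"),
                            params = qc_params(),
                            stratify_by_breed = TRUE) {
  test <- match.arg(test)
  n <- nrow(gm$samples)
  sizes <- sort(sizes, decreasing = TRUE)
  if (any(sizes > n)) stop("size exceeds the cohort")
  y <- as_case_indicator(phenotypes)
  breeds <- gm$samples$breed
  rows <- list()
  min_size <- NA_integer_
  with_seed(seed, {
    for (k in sizes) {
      succ <- 0L
      for (cmb in seq_len(combos_per_size)) {
        idx <- if (stratify_by_breed) {
          tabs <- table(breeds)
          take <- round(as.numeric(tabs) / n * k)
          # fix rounding drift while respecting stratum sizes
          while (sum(take) > k) take[which.max(take)] <- take[which.max(take)] - 1L
          while (sum(take) < k) {
            room <- which(take < as.numeric(tabs))
            take[room[which.max(as.numeric(tabs)[room] - take[room])]] <-
              take[room[which.max(as.numeric(tabs)[room] - take[room])]] + 1L
          }
          unlist(lapply(seq_along(tabs), function(b) {
            pool <- which(breeds == names(tabs)[b])
            sample(pool, take[b])
          }))
        } else {
          sample.int(n, k)
        }
        idx <- sort(idx)
        yk <- y[idx]
        if (sum(yk, na.rm = TRUE) == 0 ||
            sum(1 - yk, na.rm = TRUE) == 0) next
        sub <- qc_filter(gm_subset(gm, samples = idx), params)
        if (ncol(sub$calls) == 0) next
        tab <- map_trait(sub, phenotypes[idx], test = test)
        if (any(tab$p_bonferroni <= alpha)) succ <- succ + 1L
      }
      rows[[length(rows) + 1]] <- data.frame(size = k, n_success = succ,
                                             n_combos = combos_per_size)
      if (succ > 0L) min_size <- k else break
    }
  })
  list(min_size = min_size, per_size = do.call(rbind, rows))
}
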