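# HWE oracle: enumerate all genotype configurations with the observed allele
# count and normalise -- an independent route to the conditional distribution
# used by hwe_exact_p (which works from the closed-form expression).
hwe_enum_p <- function(nAA, nAB, nBB) {
  n <- nAA + nAB + nBB
  nA <- 2 * nAA + nAB
  hets <- seq(nA %% 2, min(nA, 2 * n - nA), by = 2)
  wt <- vapply(hets, function(h) {
    aa <- (nA - h) / 2
    bb <- n - aa - h
    exp(lgamma(n + 1) - lgamma(aa + 1) - lgamma(h + 1) - lgamma(bb + 1) +
          h * log(2))
  }, numeric(1))
  p <- wt / sum(wt)
  obs <- p[match(nAB, hets)]
  sum(p[p <= obs * (1 + 1e-12)])
}

test_that("HWE exact test matches full enumeration", {
  expect_equal(hwe_exact_p(2, 4, 2), 1.0)
  expect_equal(hwe_exact_p(4, 0, 4), hwe_enum_p(4, 0, 4), tolerance = 1e-12)
  for (cnt in list(c(3, 1, 4), c(0, 8, 0), c(10, 2, 1), c(1, 1, 1),
                   c(0, 2, 6), c(5, 5, 5))) {
    expect_equal(hwe_exact_p(cnt[1], cnt[2], cnt[3]),
                 hwe_enum_p(cnt[1], cnt[2], cnt[3]), tolerance = 1e-12)
  }
  expect_true(hwe_exact_p(0, 10, 0) > 0 && hwe_exact_p(0, 10, 0) <= 1)
  expect_error(hwe_exact_p(0, 0, 0), "zero")
})

test_that("QC filter applies the MAF, missingness and call-rate rules", {
  # marker 1: MAF 0.03 among called (removed); marker 2: 60% missing
  # (removed); marker 3: monomorphic (removed); marker 4: clean
  n <- 50
  calls <- cbind(
    c(rep(1, 3), rep(0, 47)),                     # MAF 0.03
    c(rep(NA, 30), rep(c(0, 2), 10)),             # 60% missing
    rep(0, n),                                    # monomorphic
    rep(c(0, 1, 2, 1, 0), 10)                     # MAF 0.4
  )
  gm <- make_gm(calls)
  out <- qc_filter(gm, qc_params())
  rep <- attr(out, "qc_report")
  expect_identical(ncol(out$calls), 1L)
  expect_identical(out$markers$pos, gm$markers$pos[4])
  expect_gte(rep$removed_maf, 2)  # MAF 0.03 and the monomorphic marker
  expect_gte(rep$removed_missing, 1)
  # idempotence
  again <- qc_filter(out, qc_params())
  expect_identical(again$markers, out$markers)
  expect_identical(attr(again, "qc_report")$n_kept,
                   attr(again, "qc_report")$n_in)
  # boundary: MAF exactly 0.05 is kept
  gm2 <- make_gm(cbind(c(rep(1, 2), rep(0, 18)), rep(c(0, 2), 10)))
  expect_identical(ncol(qc_filter(gm2)$calls), 2L)
})

test_that("HWE filter removes extreme heterozygote deficits when enabled", {
  calls <- cbind(c(rep(0, 8), rep(2, 8)),            # no hets: HWE p tiny
                 rep(c(0, 1, 1, 2), 4))              # balanced
  gm <- make_gm(calls)
  off <- qc_filter(gm, qc_params(hwe_p_min = 0))     # disabled by default
  expect_identical(ncol(off$calls), 2L)
  on <- qc_filter(gm, qc_params(hwe_p_min = 0.01))
  expect_identical(ncol(on$calls), 1L)
})

test_that("r2_em reproduces direct haplotype counting when phase is known", {
  # perfect coupling: haplotypes AB/ab only
  lp <- r2_em(c(0, 0, 2, 2), c(0, 0, 2, 2))
  expect_equal(lp$r2, 1)
  expect_equal(lp$D, 0.25)
  # independence
  expect_equal(r2_em(c(0, 2, 0, 2), c(0, 0, 2, 2))$r2, 0)
  # monomorphic in the pairwise-complete subset -> undefined
  expect_false(r2_em(c(0, 0, 0, 0), c(0, 1, 2, 1))$defined)
  # all informative samples double-het -> flat likelihood -> undefined
  expect_false(r2_em(c(1, 1, 1, 1), c(1, 1, 1, 1))$defined)
})

test_that("EM r2 equals phased r2 exactly without double heterozygotes", {
  set.seed(42)
  n_checked <- 0
  while (n_checked < 50) {
    p <- rgamma(4, 1)
    d <- draw_phased_pair(16, p / sum(p))
    if (any(d$gi == 1 & d$gj == 1)) next
    rp <- phased_r2(d$h1, d$h2)
    if (is.na(rp)) next
    re <- r2_em(d$gi, d$gj)
    expect_equal(re$r2, rp, tolerance = 1e-12)
    n_checked <- n_checked + 1
  }
})

test_that("EM r2 equals the brute-force MLE over the double-het split", {
  # independent oracle: maximise the observed-data likelihood directly over
  # the coupling fraction w of double heterozygotes
  mle_r2 <- function(gi, gj) {
    tab <- table(factor(gi, 0:2), factor(gj, 0:2))
    x00 <- 2 * tab[1, 1] + tab[1, 2] + tab[2, 1]
    x01 <- 2 * tab[1, 3] + tab[1, 2] + tab[2, 3]
    x10 <- 2 * tab[3, 1] + tab[2, 1] + tab[3, 2]
    x11 <- 2 * tab[3, 3] + tab[3, 2] + tab[2, 3]
    ndh <- tab[2, 2]
    tot <- 2 * length(gi)
    loglik <- function(w) {
      p <- c(x00 + ndh * w, x01 + ndh * (1 - w), x10 + ndh * (1 - w),
             x11 + ndh * w) / tot
      known <- sum(c(x00, x01, x10, x11) * log(pmax(p, 1e-300)))
      dh <- if (ndh > 0) ndh * log(max(2 * (p[4] * p[1] + p[3] * p[2]), 1e-300)) else 0
      known + dh
    }
    w <- if (ndh == 0) 0.5 else {
      cand <- c(0, 1, stats::optimize(loglik, c(0, 1), maximum = TRUE,
                                      tol = 1e-12)$maximum)
      cand[which.max(vapply(cand, loglik, numeric(1)))]
    }
    p <- c(x00 + ndh * w, x01 + ndh * (1 - w), x10 + ndh * (1 - w),
           x11 + ndh * w) / tot
    pA <- p[3] + p[4]; pB <- p[2] + p[4]
    (p[4] - pA * pB)^2 / (pA * (1 - pA) * pB * (1 - pB))
  }
  set.seed(7)
  n_checked <- 0
  while (n_checked < 200) {
    p <- rgamma(4, 1)
    d <- draw_phased_pair(16, p / sum(p))
    re <- r2_em(d$gi, d$gj)
    if (!re$defined || !re$converged) next
    want <- min(1, mle_r2(d$gi, d$gj))
    if (!is.finite(want)) next  # oracle MLE degenerate at a frequency boundary
    expect_lt(abs(re$r2 - want), 1e-6)
    n_checked <- n_checked + 1
  }
})

test_that("r2 is symmetric and invariant to allele relabeling", {
  set.seed(9)
  for (k in 1:25) {
    p <- rgamma(4, 1)
    d <- draw_phased_pair(16, p / sum(p))
    a <- r2_em(d$gi, d$gj)
    if (!a$defined) next
    expect_equal(a$r2, r2_em(d$gj, d$gi)$r2, tolerance = 1e-9)
    expect_equal(a$r2, r2_em(2L - d$gi, d$gj)$r2, tolerance = 1e-9)
    expect_equal(a$r2, r2_em(d$gi, 2L - d$gj)$r2, tolerance = 1e-9)
  }
})

test_that("adjacent_r2 pairs consecutive markers within chromosomes", {
  set.seed(1)
  calls <- matrix(sample(0:2, 16 * 5, TRUE), 16, 5)
  gm <- make_gm(calls, chrom = c(rep("chr1", 3), rep("chr2", 2)),
                pos = c(100, 300, 900, 100, 5000))
  pairs <- adjacent_r2(gm)
  expect_equal(nrow(pairs), 3)  # 2 on chr1 + 1 on chr2, no cross-chromosome
  expect_equal(pairs$distance_bp, c(200, 600, 4900))
  # a single-marker chromosome is skipped with a warning
  gm1 <- make_gm(matrix(sample(0:2, 48, TRUE), 16, 3),
                 chrom = c("chr1", "chr1", "chr3"), pos = c(100, 200, 100))
  expect_warning(adjacent_r2(gm1), "fewer than 2")
  # co-located duplicates are removed before pairing: no distance-0 pairs,
  # and the medians are unchanged
  gm_dup <- make_gm(calls[, c(1, 1, 2, 3, 4, 5)],
                    chrom = c(rep("chr1", 4), rep("chr2", 2)),
                    pos = c(100, 100, 300, 900, 100, 5000))
  pairs_dup <- adjacent_r2(gm_dup)
  expect_true(all(pairs_dup$distance_bp > 0))
  expect_equal(median(pairs_dup$r2, na.rm = TRUE),
               median(pairs$r2, na.rm = TRUE))
})

test_that("bin_marker_counts tabulates per-Mb densities with percentiles", {
  gm <- make_gm(matrix(sample(0:2, 16 * 10, TRUE), 16, 10),
                pos = seq(5e5, by = 1e6, length.out = 10))
  bins <- bin_marker_counts(gm)
  expect_true(all(bins$count == 1))
  gm2 <- make_gm(matrix(sample(0:2, 16 * 10, TRUE), 16, 10),
                 pos = seq(1000, by = 100, length.out = 10))
  b2 <- bin_marker_counts(gm2, build = genome_build("chr1", 5e6))
  expect_equal(b2$count, c(10, 0, 0, 0, 0))
  expect_named(attr(b2, "thresholds"), c("p_low", "p_high"))
  expect_true(all(b2$density_class[b2$count == 0] == "low"))
})

test_that("SNP subsampling experiment is seeded and honours limits", {
  study <- study_cache()
  gm <- qc_filter(study$array)
  full <- suppressWarnings(adjacent_r2(gm))
  tab <- subsample_snps_experiment(gm, counts = ncol(gm$calls), reps = 1,
                                   seed = 5)
  expect_equal(tab$median_r2, median(full$r2[full$defined], na.rm = TRUE))
  t1 <- subsample_snps_experiment(gm, counts = c(100, 50), reps = 2, seed = 5)
  t2 <- subsample_snps_experiment(gm, counts = c(100, 50), reps = 2, seed = 5)
  expect_identical(t1, t2)
  expect_error(
    subsample_snps_experiment(gm, counts = ncol(gm$calls) + 1, seed = 5),
    "exceeds")
})

test_that("sample subsampling raises the median r2 (small-n inflation)", {
  study <- study_cache()
  gm <- qc_filter(study$array)
  sub <- subsample_samples_r2(gm, k = 6, reps = 12, seed = 3)
  full <- suppressWarnings(adjacent_r2(gm))
  expect_gte(median(sub$median_r2, na.rm = TRUE),
             median(full$r2[full$defined], na.rm = TRUE))
  # k = n reproduces the full-data median in every replicate
  all16 <- subsample_samples_r2(gm, k = nrow(gm$calls), reps = 3, seed = 3)
  expect_equal(unique(all16$median_r2),
               median(full$r2[full$defined], na.rm = TRUE))
  expect_error(subsample_samples_r2(gm, k = 1), ">= 2")
})

test_that("background LD uses one marker per chromosome and all pairs", {
  cfg <- sim_config(chrom_lengths = rep(4e5, 10), site_density = 100,
                    seed = 77)
  gm <- qc_filter(simulate_breed_genotypes(cfg))
  bg <- background_r2(gm, n_snps_per_draw = 10, reps = 5, seed = 2)
  expect_equal(bg$n_pairs_per_rep, choose(10, 2))
  expect_length(bg$pooled, 5 * choose(10, 2))
  bg2 <- background_r2(gm, n_snps_per_draw = 10, reps = 5, seed = 2)
  expect_identical(bg$per_rep, bg2$per_rep)
  expect_error(background_r2(gm, n_snps_per_draw = 11), "chromosomes")
})
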