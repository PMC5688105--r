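test_that("configuration invariants are enforced", {
  expect_error(sim_config(founders_per_breed = 1), "founders|F")
  expect_error(sim_config(switch_rate = 0))
  expect_error(sim_config(chrom_lengths = c(chr1 = 0)))
  expect_error(sim_config(callrate_array = 1.5))
  cfg <- sim_config(n_breeds = 3, founders_per_breed = c(10, 6, 4),
                    samples_per_breed = c(16, 6, 6))
  expect_equal(cfg$founders_per_breed, c(10L, 6L, 4L))
})

test_that("no recombination with two maximally different founders gives complete LD", {
  # switch_rate ~ 0: every gamete is an exact founder copy; with F = 2 the
  # population holds two haplotypes, so every polymorphic pair has r2 = 1
  # with F = 2 and no switching, half the seeds draw two identical founders
  # (fully monomorphic); walk seeds until the founders differ
  for (seed in 21:40) {
    cfg <- sim_config(chrom_lengths = c(chr1 = 1e6), site_density = 50,
                      founders_per_breed = 2, switch_rate = 1e-12,
                      founder_mutation_rate = 0, seed = seed)
    gm <- simulate_breed_genotypes(cfg)
    af <- colMeans(gm$calls) / 2
    poly <- which(af > 0 & af < 1)
    if (length(poly) > 5) break
  }
  expect_gt(length(poly), 5)
  for (k in seq_len(min(10, length(poly) - 1))) {
    lp <- r2_em(gm$calls[, poly[k]], gm$calls[, poly[k + 1]])
    expect_equal(lp$r2, 1, tolerance = 1e-9)
  }
})

test_that("the generator is deterministic in the seed, including file output", {
  cfg <- sim_config(chrom_lengths = c(chr1 = 5e5), site_density = 200,
                    seed = 33)
  s1 <- simulate_study(cfg)
  s2 <- simulate_study(cfg)
  expect_identical(s1$sites$calls, s2$sites$calls)
  expect_identical(s1$exome$calls, s2$exome$calls)
  p1 <- file.path(tempdir(), "det1"); p2 <- file.path(tempdir(), "det2")
  write_plink(s1$array, p1); write_plink(s2$array, p2)
  expect_identical(readLines(paste0(p1, ".ped")), readLines(paste0(p2, ".ped")))
  expect_identical(readLines(paste0(p1, ".map")), readLines(paste0(p2, ".map")))
  s3 <- simulate_study(sim_config(chrom_lengths = c(chr1 = 5e5),
                                  site_density = 200, seed = 34))
  expect_false(identical(s1$sites$calls, s3$sites$calls))
})

test_that("LD decays with distance (replicate-averaged binned medians)", {
  bins <- list(c(0, 5e3), c(5e3, 5e4), c(5e4, 5e5))
  meds <- matrix(NA_real_, 8, 3)
  for (r in seq_len(nrow(meds))) {
    cfg <- sim_config(chrom_lengths = c(chr1 = 2e6), site_density = 150,
                      seed = 400 + r)
    gm <- qc_filter(simulate_breed_genotypes(cfg))
    pos <- gm$markers$pos
    m <- ncol(gm$calls)
    set.seed(500 + r)
    for (b in seq_along(bins)) {
      vals <- c()
      for (i in sample.int(m, m)) {
        j <- which(pos > pos[i] + bins[[b]][1] & pos <= pos[i] + bins[[b]][2])
        if (length(j)) {
          vals <- c(vals, r2_em(gm$calls[, i], gm$calls[, sample(rep(j, 2), 1)])$r2)
        }
        if (length(vals) >= 60) break
      }
      meds[r, b] <- median(vals, na.rm = TRUE)
    }
  }
  avg <- colMeans(meds)
  expect_true(all(diff(avg) <= 0))
  expect_gt(avg[1], 0.6)   # strong LD at <= 5 kb
  expect_lt(avg[3], 0.45)  # decayed well below the short-range level
})

test_that("smaller founder pools give higher LD (breed ordering)", {
  med_for <- function(F, seed) {
    cfg <- sim_config(chrom_lengths = c(chr1 = 2e6), site_density = 100,
                      founders_per_breed = F, seed = seed)
    gm <- qc_filter(simulate_breed_genotypes(cfg))
    pr <- suppressWarnings(adjacent_r2(gm))
    median(pr$r2[pr$defined], na.rm = TRUE)
  }
  hi_f <- mean(vapply(1:5, function(s) med_for(12, 600 + s), numeric(1)))
  lo_f <- mean(vapply(1:5, function(s) med_for(4, 600 + s), numeric(1)))
  expect_gt(lo_f, hi_f)
})

test_that("panels respect targets, spacing and the off-target rate", {
  study <- study_cache()
  cfg <- study$cfg
  # array spacing: expected count = genome / spacing, within 20%
  expected <- sum(cfg$chrom_lengths) / cfg$array_spacing_bp
  expect_lt(abs(nrow(study$panels$array) - expected) / expected, 0.2)
  # whole-chromosome targets -> exome panel = all polymorphic sites
  cfg2 <- sim_config(chrom_lengths = c(chr1 = 3e5), site_density = 100,
                     seed = 5)
  gm2 <- simulate_breed_genotypes(cfg2)
  all_targets <- interval_set("chr1", 0, 3e5, label = "targets")
  p2 <- make_panels(gm2, all_targets, cfg2)
  af <- colMeans(gm2$calls) / 2
  expect_equal(nrow(p2$exome), sum(af > 0 & af < 1))
  # zero off-target rate -> every exome marker inside a target
  cfg3 <- sim_config(chrom_lengths = c(chr1 = 3e5), site_density = 100,
                     exome_offtarget_rate = 0, seed = 5)
  small_targets <- interval_set("chr1", c(0, 2e5), c(5e4, 25e4),
                                label = "targets")
  p3 <- make_panels(gm2, small_targets, cfg3)
  expect_true(all(pos_in_intervals(small_targets, p3$exome$chrom,
                                   p3$exome$pos)))
  # empty targets with no off-target sampling is an error
  expect_error(make_panels(gm2, interval_set(label = "targets"), cfg3),
               "empty")
})

test_that("plant_trait implements recessive, dominant and fixation modes", {
  gm <- make_gm(rbind(0, 1, 2, 2), pos = 1000)
  id <- gm$markers$id[1]
  rec <- plant_trait(gm, trait_spec("recessive", id))
  expect_equal(unname(rec), c(1L, 1L, 2L, 2L))
  dom <- plant_trait(gm, trait_spec("dominant", id))
  expect_equal(unname(dom), c(1L, 2L, 2L, 2L))
  # risk allele A flips the homozygote class
  recA <- plant_trait(gm, trait_spec("recessive", id, risk_allele = "A"))
  expect_equal(unname(recA), c(2L, 1L, 1L, 1L))
  # monomorphic causal marker without fixation map is an error
  gm_mono <- make_gm(rbind(2, 2, 2, 2), pos = 1000)
  expect_error(plant_trait(gm_mono, trait_spec("recessive",
                                               gm_mono$markers$id[1])),
               "monomorphic")
  # penetrance 0 turns everyone into a control
  p0 <- plant_trait(gm, trait_spec("recessive", id, penetrance = 0))
  expect_true(all(p0 == 1L))
})

test_that("fixation mode assigns phenotype by breed with perfect separation", {
  cfg <- sim_config(n_breeds = 3, samples_per_breed = c(16, 6, 6),
                    founders_per_breed = c(10, 6, 4),
                    chrom_lengths = c(chr1 = 2e5), site_density = 100,
                    seed = 9)
  gm <- simulate_breed_genotypes(cfg)
  ph <- plant_trait(gm, trait_spec("dominant", gm$markers$id[1],
                                   fixation = list(breed1 = "case",
                                                   breed2 = "control",
                                                   breed3 = "control")))
  expect_equal(sum(ph == 2L), 16)
  expect_equal(sum(ph == 1L), 12)
  expect_true(all(ph[gm$samples$breed == "breed1"] == 2L))
})

test_that("missingness matches the configured call-rate model", {
  study <- study_cache()
  cfg <- study$cfg
  # callrate 1 leaves the array untouched
  cfg1 <- cfg
  cfg1$callrate_array <- 1
  arr <- apply_missingness(study$sites, study$panels$array, cfg1)
  expect_false(anyNA(arr$calls))
  # Beta(9,1) exome call rates: mean observed call rate ~ 0.9 within 3 MC SE
  cfg2 <- sim_config(chrom_lengths = c(chr1 = 2e6), site_density = 500,
                     callrate_exome_beta = c(9, 1), target_fraction = 0.5,
                     seed = 55)
  st2 <- simulate_study(cfg2)
  m <- ncol(st2$exome$calls)
  cr <- colMeans(!is.na(st2$exome$calls))
  beta_sd <- sqrt(9 * 1 / ((9 + 1)^2 * 11))
  expect_lt(abs(mean(cr) - 0.9), 3 * beta_sd / sqrt(m) + 3 * 0.3 / sqrt(16 * m))
  # a zero call-rate marker is fully missing and then removed by QC
  gmz <- make_gm(matrix(sample(0:2, 32, TRUE), 16, 2))
  gmz$calls[, 1] <- NA_integer_
  expect_identical(ncol(qc_filter(gmz)$calls), 1L)
})
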