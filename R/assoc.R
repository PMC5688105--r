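# Association statistics and multiple-testing procedures: Cochran-Armitage
# trend test, allelic chi-squared test, Bonferroni and max-T permutation
# adjustment. The scan engines are vectorised over markers and over
# permutations (one matrix product per permutation batch), which keeps
# 500-permutation max-T runs cheap even inside large power simulations.

#' Genotype/allele contingency counts for one marker
#'
#' @param genos genotype vector (0/1/2/NA).
#' @param pheno phenotype vector: 2/`TRUE` = case, 1/`FALSE` = control, `NA`
#'   dropped. Samples missing either value are excluded (per-marker
#'   complete-case analysis, as in standard GWAS tools).
#' @return A list of class `contingency_counts`: `cases` = (r0, r1, r2),
#'   `controls` = (s0, s1, s2), and `alleles` = (a, b, c, d) = case-A,
#'   case-B, control-A, control-B allele counts.
#' @export
geno_counts <- function(genos, pheno) {
  if (is.logical(pheno)) pheno <- ifelse(pheno, 2L, 1L)
  keep <- !is.na(genos) & !is.na(pheno)
  g <- genos[keep]
  y <- pheno[keep]
  r <- c(sum(g == 0 & y == 2), sum(g == 1 & y == 2), sum(g == 2 & y == 2))
  s <- c(sum(g == 0 & y == 1), sum(g == 1 & y == 1), sum(g == 2 & y == 1))
  b <- r[2] + 2 * r[3]
  d <- s[2] + 2 * s[3]
  out <- list(cases = r, controls = s,
              alleles = c(a = 2 * sum(r) - b, b = b, c = 2 * sum(s) - d, d = d))
  class(out) <- "contingency_counts"
  out
}

#' Cochran-Armitage trend test
#'
#' Score test for a dose-response of genotype on case status. With genotype
#' weights `w` and per-class case/control counts `r_i`, `s_i`
#' (`n_i = r_i + s_i`, `R = sum r`, `S = sum s`, `N = R + S`):
#' `T = sum_i w_i (S r_i - R s_i)` and
#' `Var(T) = (R S / N) (sum_i w_i^2 n_i (N - n_i) - 2 sum_{i<j} w_i w_j n_i n_j)`;
#' the statistic `T^2 / Var(T)` is chi-squared with 1 df. A zero variance
#' (fewer than two genotype classes among called samples) leaves the
#' statistic undefined with p = 1.
#'
#' @param counts a [geno_counts()] result (or a list with `cases`,
#'   `controls`).
#' @param weights genotype weights, default `c(0, 1, 2)` (additive).
#' @return list `statistic` (chi-squared, 1 df; `NA` if undefined), `p`.
#' @export
catt <- function(counts, weights = c(0, 1, 2)) {
  r <- counts$cases
  s <- counts$controls
  R <- sum(r)
  S <- sum(s)
  if (R == 0 || S == 0) stop("empty case or control stratum")
  N <- R + S
  n <- r + s
  Tstat <- sum(weights * (S * r - R * s))
  br <- sum(weights^2 * n * (N - n)) -
    2 * (weights[1] * weights[2] * n[1] * n[2] +
           weights[1] * weights[3] * n[1] * n[3] +
           weights[2] * weights[3] * n[2] * n[3])
  v <- R * S / N * br
  if (v <= 0) return(list(statistic = NA_real_, p = 1))
  chisq <- Tstat^2 / v
  list(statistic = chisq, p = stats::pchisq(chisq, 1, lower.tail = FALSE))
}

#' Allelic chi-squared association test
#'
#' 2x2 chi-squared on allele counts without continuity correction:
#' `chi2 = n (ad - bc)^2 / ((a+b)(c+d)(a+c)(b+d))` with
#' `(a, b, c, d)` = case-A, case-B, control-A, control-B allele counts and
#' `n = a+b+c+d`. A zero margin leaves the statistic undefined with p = 1.
#'
#' @param counts a [geno_counts()] result.
#' @return list `statistic`, `p`, `defined`.
#' @export
allelic_chisq <- function(counts) {
  al <- counts$alleles
  a <- al[["a"]]; b <- al[["b"]]; cc <- al[["c"]]; d <- al[["d"]]
  n <- a + b + cc + d
  marg <- c(a + b, cc + d, a + cc, b + d)
  if (any(marg == 0)) return(list(statistic = NA_real_, p = 1, defined = FALSE))
  chisq <- n * (a * d - b * cc)^2 / prod(marg)
  list(statistic = chisq, p = stats::pchisq(chisq, 1, lower.tail = FALSE),
       defined = TRUE)
}

#' Bonferroni correction
#'
#' @param p_raw raw p-values.
#' @param m number of tests; defaults to `length(p_raw)` (the count of
#'   markers that entered testing).
#' @return `min(1, m * p_raw)` elementwise.
#' @export
bonferroni <- function(p_raw, m = length(p_raw)) {
  if (m < length(p_raw)) stop("m must be at least the number of p-values")
  pmin(1, m * p_raw)
}

# ---- vectorised scan engines ------------------------------------------------
#
# calls: n x m genotype matrix; Y: n x P matrix of 0/1 case indicators (one
# column per phenotype/permutation). Per-marker quantities that do not depend
# on the labels are precomputed once.

scan_precompute <- function(calls, weights = c(0, 1, 2)) {
  C <- !is.na(calls)
  Gw <- matrix(weights[calls + 1L], nrow(calls), ncol(calls))
  Gw[!C] <- 0
  storage.mode(C) <- "double"
  n1 <- colSums(calls == 1, na.rm = TRUE)
  n2 <- colSums(calls == 2, na.rm = TRUE)
  N <- colSums(C)
  n0 <- N - n1 - n2
  w <- weights
  br <- w[1]^2 * n0 * (N - n0) + w[2]^2 * n1 * (N - n1) + w[3]^2 * n2 * (N - n2) -
    2 * (w[1] * w[2] * n0 * n1 + w[1] * w[3] * n0 * n2 + w[2] * w[3] * n1 * n2)
  g0 <- calls
  g0[!C] <- 0L
  list(C = C, Gw = Gw, G0 = g0, N = N, br = br,
       sum_w = colSums(Gw), sum_g = colSums(g0))
}

# trend chi-squared for every marker (rows) x phenotype column (cols)
catt_scan <- function(pre, Y) {
  R <- crossprod(pre$C, Y)              # called cases per marker x pheno
  SwR <- crossprod(pre$Gw, Y)           # sum of weights over cases
  Tm <- pre$N * SwR - R * pre$sum_w     # = S*Swr - R*Sws
  V <- R * (pre$N - R) / pre$N * pre$br
  chisq <- Tm^2 / V
  chisq[!is.finite(chisq)] <- NA_real_
  chisq
}

# allelic chi-squared for every marker x phenotype column
allelic_scan <- function(pre, Y) {
  R <- crossprod(pre$C, Y)
  b <- crossprod(pre$G0, Y)             # case B-allele count
  S <- pre$N - R
  d <- pre$sum_g - b                    # control B-allele count
  a <- 2 * R - b
  cc <- 2 * S - d
  n <- 2 * pre$N
  denom <- (2 * R) * (2 * S) * (a + cc) * (b + d)
  chisq <- n * (a * d - b * cc)^2 / denom
  chisq[!is.finite(chisq)] <- NA_real_
  chisq
}

as_case_indicator <- function(pheno) {
  if (is.logical(pheno)) return(as.numeric(pheno))
  y <- as.numeric(pheno == 2)
  y[is.na(pheno)] <- NA
  y
}

#' Per-marker association scan
#'
#' @param gm a [genotype_matrix()].
#' @param pheno phenotype vector (2 = case, 1 = control, `NA` excluded for
#'   all markers; per-marker missing genotypes are excluded per marker).
#' @param test `"trend"` (Cochran-Armitage) or `"allelic"`.
#' @return data.frame: `marker`, `chrom`, `pos`, `statistic`, `p_raw`.
#' @export
assoc_scan <- function(gm, pheno, test = c("trend", "allelic")) {
  test <- match.arg(test)
  y <- as_case_indicator(pheno)
  keep <- !is.na(y)
  if (sum(y[keep]) == 0 || sum(1 - y[keep]) == 0) {
    stop("phenotype is degenerate: need at least one case and one control")
  }
  calls <- gm$calls[keep, , drop = FALSE]
  pre <- scan_precompute(calls)
  Y <- matrix(y[keep], ncol = 1)
  chisq <- if (test == "trend") catt_scan(pre, Y) else allelic_scan(pre, Y)
  stat <- chisq[, 1]
  data.frame(marker = gm$markers$id, chrom = gm$markers$chrom,
             pos = gm$markers$pos, statistic = stat,
             p_raw = ifelse(is.na(stat), 1,
                            stats::pchisq(stat, 1, lower.tail = FALSE)),
             stringsAsFactors = FALSE)
}

#' Max-T permutation adjustment of a genome-wide scan
#'
#' Computes the observed statistic per marker, then for each of `n_perm`
#' case/control label permutations records the genome-wide maximum statistic;
#' the adjusted p-value of marker j is
#' `(1 + #permutation maxima >= observed_j) / (1 + n_perm)` (the add-one
#' estimator, so adjusted p-values are never below `1/(n_perm + 1)`).
#' Permutations preserve the case/control totals.
#'
#' @param gm a [genotype_matrix()].
#' @param pheno phenotype vector (2 = case, 1 = control).
#' @param test `"trend"` or `"allelic"`.
#' @param n_perm number of permutations, default 500.
#' @param seed permutation seed.
#' @return data.frame as [assoc_scan()] plus `p_maxT` and `rank` (1 = most
#'   significant raw p; ties broken by genomic order).
#' @export
maxt_adjust <- function(gm, pheno, test = c("trend", "allelic"),
                        n_perm = 500, seed = 1) {
  test <- match.arg(test)
  y <- as_case_indicator(pheno)
  keep <- !is.na(y)
  y <- y[keep]
  if (sum(y) == 0 || sum(1 - y) == 0) {
    stop("phenotype is degenerate: need at least one case and one control")
  }
  calls <- gm$calls[keep, , drop = FALSE]
  pre <- scan_precompute(calls)
  engine <- if (test == "trend") catt_scan else allelic_scan
  obs <- engine(pre, matrix(y, ncol = 1))[, 1]
  Y <- with_seed(seed, {
    vapply(seq_len(n_perm), function(i) sample(y), numeric(length(y)))
  })
  perm <- engine(pre, Y)
  maxima <- apply(perm, 2, function(col) {
    m <- suppressWarnings(max(col, na.rm = TRUE))
    if (!is.finite(m)) 0 else m
  })
  p_maxT <- vapply(obs, function(o) {
    if (is.na(o)) return(1)
    (1 + sum(maxima >= o)) / (1 + n_perm)
  }, numeric(1))
  out <- data.frame(marker = gm$markers$id, chrom = gm$markers$chrom,
                    pos = gm$markers$pos, statistic = obs,
                    p_raw = ifelse(is.na(obs), 1,
                                   stats::pchisq(obs, 1, lower.tail = FALSE)),
                    p_maxT = p_maxT, stringsAsFactors = FALSE)
  out$rank <- rank_by_p(out$p_raw)
  out
}

# ranks 1..m on raw p, ties broken by genomic (input) order
rank_by_p <- function(p_raw) {
  o <- order(p_raw, seq_along(p_raw))
  r <- integer(length(p_raw))
  r[o] <- seq_along(p_raw)
  r
}
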