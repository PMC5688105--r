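# Genotype and interval containers plus readers/writers for the formats the
# pipeline touches: PLINK ped/map, VCF (bi-allelic SNPs only) and BED.

#' Construct a genotype matrix
#'
#' The central container: diploid genotypes for `n` samples at `m` bi-allelic
#' markers, coded as the per-entry count of the B (second/ALT) allele, 0, 1 or
#' 2, with `NA` for missing calls. All association and LD statistics computed
#' downstream are invariant to swapping the allele labels at any marker, so the
#' coding orientation is arbitrary.
#'
#' @param calls integer matrix, samples x markers, entries in `{0,1,2,NA}`.
#' @param markers data.frame with columns `chrom`, `pos` (1-based bp), `id`,
#'   `a1`, `a2`. Markers are reordered to genomic order (chromosomes in
#'   first-appearance order, then position) on construction.
#' @param samples data.frame with columns `id`, `breed` and optionally
#'   `phenotype` (1 = control, 2 = case, `NA` = missing).
#' @return An object of class `genotype_matrix`: a list with elements
#'   `calls`, `markers`, `samples`.
#' @export
genotype_matrix <- function(calls, markers, samples) {
  calls <- as.matrix(calls)
  storage.mode(calls) <- "integer"
  markers <- as.data.frame(markers)
  samples <- as.data.frame(samples)
  stopifnot(
    all(c("chrom", "pos", "id", "a1", "a2") %in% names(markers)),
    all(c("id") %in% names(samples)),
    nrow(calls) == nrow(samples),
    ncol(calls) == nrow(markers)
  )
  if (anyNA(markers$pos) || any(markers$pos < 1)) {
    stop("marker positions must be positive 1-based integers")
  }
  markers$pos <- as.integer(markers$pos)
  bad <- !is.na(markers$a1) & !is.na(markers$a2) & markers$a1 == markers$a2
  if (any(bad)) stop("markers with identical alleles: ", markers$id[bad][1])
  if (anyDuplicated(markers$id)) stop("duplicated marker ids")
  if (anyDuplicated(samples$id)) stop("duplicated sample ids")
  if (!"breed" %in% names(samples)) samples$breed <- "breed1"
  o <- genome_order(markers$chrom, markers$pos)
  markers <- markers[o, , drop = FALSE]
  calls <- calls[, o, drop = FALSE]
  rownames(markers) <- NULL
  rownames(calls) <- samples$id
  colnames(calls) <- markers$id
  rng <- range(calls, na.rm = TRUE)
  if (!all(is.finite(rng))) rng <- c(0L, 0L)
  if (rng[1] < 0 || rng[2] > 2) stop("calls must be 0, 1, 2 or NA")
  structure(list(calls = calls, markers = markers, samples = samples),
            class = "genotype_matrix")
}

#' @export
print.genotype_matrix <- function(x, ...) {
  cat(sprintf(
    "genotype_matrix: %d samples x %d markers on %d chromosome(s), %.1f%% missing\n",
    nrow(x$calls), ncol(x$calls), length(unique(x$markers$chrom)),
    100 * mean(is.na(x$calls))
  ))
  invisible(x)
}

#' @export
dim.genotype_matrix <- function(x) dim(x$calls)

#' Subset a genotype matrix by markers and/or samples
#'
#' @param gm a [genotype_matrix()].
#' @param markers marker ids or logical/integer index into `gm$markers`.
#' @param samples sample ids or logical/integer index into `gm$samples`.
#' @return The subset `genotype_matrix`.
#' @export
gm_subset <- function(gm, markers = NULL, samples = NULL) {
  mi <- seq_len(ncol(gm$calls))
  si <- seq_len(nrow(gm$calls))
  if (!is.null(markers)) {
    mi <- if (is.character(markers)) match(markers, gm$markers$id) else mi[markers]
    if (anyNA(mi)) stop("unknown marker id(s)")
  }
  if (!is.null(samples)) {
    si <- if (is.character(samples)) match(samples, gm$samples$id) else si[samples]
    if (anyNA(si)) stop("unknown sample id(s)")
  }
  genotype_matrix(gm$calls[si, mi, drop = FALSE],
                  gm$markers[mi, , drop = FALSE],
                  gm$samples[si, , drop = FALSE])
}

#' Construct an interval set
#'
#' Genomic intervals in BED convention: 0-based, half-open `[start, end)`.
#' Marker positions are 1-based (map/VCF convention); [pos_in_intervals()] is
#' the single place where the two conventions meet.
#'
#' @param chrom,start,end vectors defining the intervals.
#' @param label a single label for the set (e.g. `"targets"`).
#' @return An object of class `interval_set` (a sorted data.frame with
#'   attribute `label`).
#' @export
interval_set <- function(chrom = character(), start = integer(),
                         end = integer(), label = "intervals") {
  df <- data.frame(chrom = as.character(chrom),
                   start = as.numeric(start), end = as.numeric(end))
  if (nrow(df) && any(df$start >= df$end)) {
    stop("interval with start >= end")
  }
  if (nrow(df) && any(df$start < 0)) stop("negative interval start")
  o <- genome_order(df$chrom, df$start)
  df <- df[o, , drop = FALSE]
  rownames(df) <- NULL
  structure(df, class = c("interval_set", "data.frame"), label = label)
}

#' @export
print.interval_set <- function(x, ...) {
  cat(sprintf("interval_set '%s': %d interval(s), %.0f bp total\n",
              attr(x, "label"), nrow(x), sum(x$end - x$start)))
  invisible(x)
}

# interval_set -> GRanges (1-based closed internally)
as_granges <- function(iv, seqlengths = NULL) {
  gr <- GenomicRanges::GRanges(
    seqnames = if (nrow(iv)) iv$chrom else character(),
    ranges = IRanges::IRanges(start = iv$start + 1, end = iv$end)
  )
  if (!is.null(seqlengths)) {
    GenomeInfoDb::seqlevels(gr) <- names(seqlengths)
    GenomeInfoDb::seqlengths(gr) <- seqlengths
  }
  gr
}

#' Merge overlapping or touching intervals
#'
#' @param iv an [interval_set()].
#' @return An `interval_set` with pairwise-disjoint intervals.
#' @export
merge_intervals <- function(iv) {
  if (!nrow(iv)) return(iv)
  red <- GenomicRanges::reduce(as_granges(iv))
  interval_set(as.character(GenomeInfoDb::seqnames(red)),
               GenomicRanges::start(red) - 1, GenomicRanges::end(red),
               label = attr(iv, "label"))
}

#' Test whether 1-based positions fall inside an interval set
#'
#' @param iv an [interval_set()].
#' @param chrom,pos vectors of marker coordinates (1-based).
#' @return Logical vector.
#' @export
pos_in_intervals <- function(iv, chrom, pos) {
  if (!nrow(iv)) return(rep(FALSE, length(pos)))
  q <- GenomicRanges::GRanges(chrom, IRanges::IRanges(pos, pos))
  GenomicRanges::countOverlaps(q, as_granges(iv)) > 0
}

#' Read a BED file of intervals
#'
#' Plain 3+ column BED; extra columns are ignored. Intervals are returned
#' sorted and validated (`start < end`). An empty file yields an empty set.
#'
#' @param path BED file path.
#' @param label label for the returned set.
#' @param known_chroms optional character vector; intervals on other
#'   chromosomes trigger a warning but are kept.
#' @return An [interval_set()].
#' @export
read_bed <- function(path, label = basename(path), known_chroms = NULL) {
  if (file.size(path) == 0) return(interval_set(label = label))
  df <- utils::read.table(path, header = FALSE, stringsAsFactors = FALSE)
  if (ncol(df) < 3) stop("BED file needs at least 3 columns: ", path)
  iv <- interval_set(df[[1]], df[[2]], df[[3]], label = label)
  if (!is.null(known_chroms)) {
    unk <- setdiff(unique(iv$chrom), known_chroms)
    if (length(unk)) {
      warning("intervals on unknown chromosome(s): ",
              paste(unk, collapse = ", "), " (kept)")
    }
  }
  iv
}

#' Write an interval set as BED
#'
#' @param iv an [interval_set()].
#' @param path output path.
#' @export
write_bed <- function(iv, path) {
  utils::write.table(
    data.frame(iv$chrom, format(iv$start, scientific = FALSE, trim = TRUE),
               format(iv$end, scientific = FALSE, trim = TRUE)),
    path, sep = "\t", quote = FALSE, row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read genotypes from a VCF, retaining only bi-allelic SNPs
#'
#' Applies the variant-retention rule used throughout the pipeline: only
#' records with a single-base REF, a single-base ALT and exactly two alleles
#' are kept; indels and multi-allelic records are dropped and counted in the
#' attached report. Genotypes are coded as ALT-allele counts; half-missing
#' calls (e.g. `./1`) are treated as missing; phased separators are accepted
#' and phase is ignored.
#'
#' @param path VCF file (plain or bgzipped).
#' @return A [genotype_matrix()] with attribute `report` listing record
#'   counts: `n_records`, `n_kept`, `n_indel`, `n_multiallelic`.
#' @export
read_vcf_biallelic_snps <- function(path) {
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  if (nrow(v@gt) == 0 || !any(grepl("GT", v@gt[, "FORMAT"], fixed = TRUE))) {
    stop("VCF has no GT format field")
  }
  fix <- as.data.frame(v@fix, stringsAsFactors = FALSE)
  if (!nrow(fix)) stop("VCF contains no variant records: ", path)
  bases <- c("A", "C", "G", "T", "a", "c", "g", "t")
  is_snp <- fix$REF %in% bases & fix$ALT %in% bases
  is_multi <- grepl(",", fix$ALT, fixed = TRUE)
  is_indel <- !is_multi & !is_snp
  keep <- which(is_snp)
  if (!length(keep)) stop("no bi-allelic SNP records in ", path)
  gt <- v@gt[keep, -1, drop = FALSE]
  fmt <- v@gt[keep, 1]
  gt_idx <- vapply(strsplit(fmt, ":", fixed = TRUE),
                   function(f) match("GT", f), integer(1))
  if (anyNA(gt_idx)) stop("VCF record without GT in FORMAT")
  calls <- matrix(NA_integer_, nrow = ncol(gt), ncol = length(keep))
  for (j in seq_along(keep)) {
    raw <- vapply(strsplit(gt[j, ], ":", fixed = TRUE),
                  function(x) x[gt_idx[j]], character(1))
    al <- strsplit(raw, "[/|]")
    calls[, j] <- vapply(al, function(a) {
      if (length(a) != 2 || any(a == ".") || any(!a %in% c("0", "1"))) {
        return(NA_integer_)
      }
      sum(a == "1")
    }, integer(1))
  }
  markers <- data.frame(
    chrom = fix$CHROM[keep], pos = as.integer(fix$POS[keep]),
    id = ifelse(is.na(fix$ID[keep]) | fix$ID[keep] == ".",
                paste0(fix$CHROM[keep], "_", fix$POS[keep]), fix$ID[keep]),
    a1 = fix$REF[keep], a2 = fix$ALT[keep], stringsAsFactors = FALSE
  )
  # unique by (chrom, pos): keep first record
  o <- genome_order(markers$chrom, markers$pos)
  markers <- markers[o, , drop = FALSE]
  calls <- calls[, o, drop = FALSE]
  dup <- duplicated(paste(markers$chrom, markers$pos))
  markers <- markers[!dup, , drop = FALSE]
  calls <- calls[, !dup, drop = FALSE]
  markers$id <- make.unique(markers$id)
  samples <- data.frame(id = colnames(v@gt)[-1], breed = "unknown",
                        stringsAsFactors = FALSE)
  gm <- genotype_matrix(calls, markers, samples)
  attr(gm, "report") <- list(
    n_records = nrow(fix), n_kept = ncol(gm$calls),
    n_indel = sum(is_indel), n_multiallelic = sum(is_multi),
    n_duplicate_pos = sum(dup)
  )
  message(sprintf("VCF %s: %d records, %d bi-allelic SNPs kept, %d indel, %d multi-allelic dropped",
                  basename(path), nrow(fix), ncol(gm$calls),
                  sum(is_indel), sum(is_multi)))
  gm
}

#' Read PLINK text ped/map files
#'
#' Space- or tab-delimited ped with the 6 leading columns FID IID PAT MAT SEX
#' PHENO followed by two allele columns per marker; `0 0` codes a missing
#' genotype. At each marker the two observed alleles are oriented
#' alphabetically (`a1 < a2`) and genotypes are coded as counts of `a2`.
#'
#' @param ped_path,map_path file paths.
#' @return A [genotype_matrix()]; the ped FID column is taken as the breed and
#'   PHENO (1/2, 0 or -9 missing) as the phenotype.
#' @export
read_plink <- function(ped_path, map_path) {
  map <- utils::read.table(map_path, header = FALSE, stringsAsFactors = FALSE)
  if (ncol(map) < 4) stop("map file needs 4 columns")
  names(map)[1:4] <- c("chrom", "id", "cm", "pos")
  ped <- utils::read.table(ped_path, header = FALSE, stringsAsFactors = FALSE,
                           colClasses = "character")
  m <- nrow(map)
  if (ncol(ped) != 6 + 2 * m) {
    stop(sprintf("ped width %d does not match 6 + 2 x %d map rows",
                 ncol(ped), m))
  }
  n <- nrow(ped)
  calls <- matrix(NA_integer_, n, m)
  a1 <- a2 <- character(m)
  for (j in seq_len(m)) {
    x <- cbind(ped[[5 + 2 * j]], ped[[6 + 2 * j]])
    x[x == "0"] <- NA
    half <- xor(is.na(x[, 1]), is.na(x[, 2]))
    x[half, ] <- NA  # half-missing pair -> missing call
    alleles <- sort(unique(stats::na.omit(as.vector(x))))
    if (length(alleles) > 2) {
      stop(sprintf("marker %s has >2 distinct alleles", map$id[j]))
    }
    a1[j] <- if (length(alleles)) alleles[1] else "A"
    a2[j] <- if (length(alleles) == 2) alleles[2] else "N"
    calls[, j] <- ifelse(is.na(x[, 1]), NA_integer_,
                         (x[, 1] == a2[j]) + (x[, 2] == a2[j]))
  }
  pheno <- suppressWarnings(as.integer(ped[[6]]))
  pheno[!pheno %in% c(1L, 2L)] <- NA_integer_
  samples <- data.frame(id = ped[[2]], breed = ped[[1]], phenotype = pheno,
                        stringsAsFactors = FALSE)
  markers <- data.frame(chrom = as.character(map$chrom), pos = as.integer(map$pos),
                        id = as.character(map$id), a1 = a1, a2 = a2,
                        stringsAsFactors = FALSE)
  genotype_matrix(calls, markers, samples)
}

#' Write PLINK text ped/map files
#'
#' Inverse of [read_plink()]: `read_plink()` applied to the written files
#' reproduces the calls, marker order and sample order exactly (provided the
#' allele pairs are alphabetically oriented, as produced by the simulator).
#'
#' @param gm a [genotype_matrix()].
#' @param prefix output path prefix; writes `<prefix>.ped` and `<prefix>.map`.
#' @return The prefix, invisibly.
#' @export
write_plink <- function(gm, prefix) {
  m <- nrow(gm$markers)
  map <- data.frame(gm$markers$chrom, gm$markers$id, 0,
                    format(gm$markers$pos, scientific = FALSE, trim = TRUE))
  utils::write.table(map, paste0(prefix, ".map"), sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  pheno <- gm$samples$phenotype %||% rep(NA_integer_, nrow(gm$samples))
  pheno <- ifelse(is.na(pheno), 0L, pheno)
  geno_cols <- matrix("0", nrow(gm$calls), 2 * m)
  for (j in seq_len(m)) {
    g <- gm$calls[, j]
    a <- c(gm$markers$a1[j], gm$markers$a2[j])
    geno_cols[, 2 * j - 1] <- ifelse(is.na(g), "0", ifelse(g == 2, a[2], a[1]))
    geno_cols[, 2 * j] <- ifelse(is.na(g), "0", ifelse(g >= 1, a[2], a[1]))
  }
  ped <- cbind(gm$samples$breed, gm$samples$id, "0", "0", "0", pheno, geno_cols)
  utils::write.table(ped, paste0(prefix, ".ped"), sep = " ", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(prefix)
}
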