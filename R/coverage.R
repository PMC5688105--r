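# High-LD genome fraction: how much of the genome lies within LD reach of an
# exome design once target intervals are extended by the distance over which
# r2 stays high.

#' Chromosome length table
#'
#' @param chrom chromosome names (unique).
#' @param length lengths in bp (> 0).
#' @return A `genome_build` data.frame.
#' @export
genome_build <- function(chrom, length) {
  stopifnot(!anyDuplicated(chrom), all(length > 0))
  structure(data.frame(chrom = as.character(chrom),
                       length = as.numeric(length),
                       stringsAsFactors = FALSE),
            class = c("genome_build", "data.frame"))
}

#' Read a two-column chromosome-sizes file
#'
#' @param path TSV with columns chromosome, length.
#' @return A [genome_build()].
#' @export
read_genome_build <- function(path) {
  df <- utils::read.table(path, header = FALSE, stringsAsFactors = FALSE)
  genome_build(df[[1]], df[[2]])
}

#' Genome fraction within high-LD reach of target intervals
#'
#' Each target interval (optionally restricted to those containing at least
#' one observed variant) is extended by `flank_bp` on both sides, clipped to
#' the chromosome, and the merged union is expressed as a fraction of the
#' genome, overall and per chromosome. The flank is a parameter rather than a
#' constant so it can be coupled to the user's own measured LD-decay
#' distance (high r2 within ~5 kb motivates the default).
#'
#' @param targets an [interval_set()].
#' @param build a [genome_build()].
#' @param flank_bp flank added on both sides of each kept interval.
#' @param require_variants optional marker data.frame (`chrom`, `pos`); when
#'   given, only target intervals containing at least one marker are kept.
#' @return list: `fraction` (genome-wide), `per_chrom` (data.frame `chrom`,
#'   `covered_bp`, `length`, `fraction`), `covered_bp`, `n_intervals_used`.
#' @export
high_ld_fraction <- function(targets, build, flank_bp = 5000,
                             require_variants = NULL) {
  unknown <- setdiff(unique(targets$chrom), build$chrom)
  if (length(unknown)) {
    stop("targets on chromosome(s) absent from the build: ",
         paste(unknown, collapse = ", "))
  }
  iv <- targets
  lens <- stats::setNames(build$length, build$chrom)
  if (nrow(iv) && any(iv$end > lens[iv$chrom])) {
    warning("target interval(s) beyond chromosome length; clipped")
    iv$end <- pmin(iv$end, lens[iv$chrom])
    iv <- iv[iv$start < iv$end, , drop = FALSE]
  }
  if (!is.null(require_variants) && nrow(iv)) {
    keep <- logical(nrow(iv))
    for (ch in unique(iv$chrom)) {
      ii <- which(iv$chrom == ch)
      pos <- require_variants$pos[require_variants$chrom == ch]
      if (length(pos)) {
        # marker at 1-based pos is inside [start, end) iff start < pos <= end
        keep[ii] <- vapply(ii, function(k) {
          any(pos > iv$start[k] & pos <= iv$end[k])
        }, logical(1))
      }
    }
    iv <- iv[keep, , drop = FALSE]
  }
  n_used <- nrow(iv)
  per <- build
  per$covered_bp <- 0
  if (n_used) {
    ext <- interval_set(iv$chrom, pmax(0, iv$start - flank_bp),
                        pmin(lens[iv$chrom], iv$end + flank_bp),
                        label = "high_ld")
    ext <- merge_intervals(ext)
    cov <- tapply(ext$end - ext$start, ext$chrom, sum)
    per$covered_bp <- ifelse(per$chrom %in% names(cov),
                             as.numeric(cov[per$chrom]), 0)
  }
  per$fraction <- per$covered_bp / per$length
  list(fraction = sum(per$covered_bp) / sum(per$length),
       per_chrom = per[, c("chrom", "covered_bp", "length", "fraction")],
       covered_bp = sum(per$covered_bp), n_intervals_used = n_used)
}
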