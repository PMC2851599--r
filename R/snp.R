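# Threshold-based SNP calling from pileup columns.
#
# A SNP is called at a column when (i) depth over A/C/G/T is at least
# `min_depth` and (ii) the most frequent non-reference base reaches a
# frequency of at least `min_alt_freq` of that depth. Both boundaries are
# inclusive ("at least 8x", "a minimum of 20%"). N bases are excluded from
# both the numerator and the depth. Indels are outside the model entirely
# (the mapper is match/mismatch only). Two presets mirror common usage:
# depth >= 8 across contigs with many reads, and depth >= 10 for close
# inspection of the most deeply covered contigs.

#' Call SNPs from a pileup with depth and frequency thresholds
#'
#' @param pileup a `pileup` from [build_pileup()], or a single pileup
#'   data.frame (then `ref_id` must be given).
#' @param min_depth minimum A/C/G/T depth, inclusive (default 8).
#' @param min_alt_freq minimum alternate-allele frequency, inclusive
#'   (default 0.20).
#' @param ref_id reference name used when `pileup` is a bare data.frame.
#' @return data.frame with `ref_id`, `pos` (0-based), `ref`, `alt`, `depth`
#'   (A/C/G/T depth), `alt_count`, `alt_freq`. At multi-allelic columns the
#'   single most frequent alternate base is called (ties broken
#'   alphabetically).
#' @export
call_snps <- function(pileup, min_depth = 8L, min_alt_freq = 0.20,
                      ref_id = "ref") {
  if (inherits(pileup, "pileup")) {
    res <- lapply(names(pileup), function(id) {
      call_snps(pileup[[id]], min_depth = min_depth,
                min_alt_freq = min_alt_freq, ref_id = id)
    })
    out <- do.call(rbind, res)
    if (is.null(out)) out <- call_snps(data.frame(), ref_id = "none")
    rownames(out) <- NULL
    return(out)
  }
  empty <- data.frame(ref_id = character(), pos = integer(),
                      ref = character(), alt = character(),
                      depth = integer(), alt_count = integer(),
                      alt_freq = numeric(), stringsAsFactors = FALSE)
  if (nrow(pileup) == 0L) return(empty)
  cm <- as.matrix(pileup[, DNA_BASES])
  acgt_depth <- rowSums(cm)
  refb <- pileup$ref_base
  # zero out the reference column, then take the most frequent remaining base
  ref_col <- match(refb, DNA_BASES)
  altm <- cm
  ok_ref <- !is.na(ref_col)
  altm[cbind(which(ok_ref), ref_col[ok_ref])] <- 0L
  alt_idx <- max.col(altm, ties.method = "first")
  alt_count <- altm[cbind(seq_len(nrow(altm)), alt_idx)]
  called <- ok_ref & acgt_depth >= min_depth & alt_count > 0L &
    alt_count / acgt_depth >= min_alt_freq
  data.frame(ref_id = rep(ref_id, sum(called)), pos = pileup$pos[called],
             ref = refb[called], alt = DNA_BASES[alt_idx[called]],
             depth = as.integer(acgt_depth[called]),
             alt_count = as.integer(alt_count[called]),
             alt_freq = alt_count[called] / acgt_depth[called],
             stringsAsFactors = FALSE)
}

#' SNP occurrence rate per 100 bp
#'
#' @param n_snps SNP count (or a data.frame of calls, whose rows are counted).
#' @param total_bp total surveyed sequence length in bp.
#' @param digits decimals reported (default 1, matching conventional
#'   presentation).
#' @return SNPs per 100 bp, rounded to `digits`.
#' @export
snp_rate <- function(n_snps, total_bp, digits = 1L) {
  if (is.data.frame(n_snps)) n_snps <- nrow(n_snps)
  if (!is.numeric(total_bp) || length(total_bp) != 1L || total_bp <= 0) {
    stop("total_bp must be a single positive number")
  }
  round(100 * n_snps / total_bp, digits)
}

#' Restrict contigs by read count
#'
#' Keeps contigs whose read count is strictly greater than `min_reads`
#' ("more than 20 reads" excludes a contig with exactly 20).
#'
#' @param read_counts named integer vector (contig -> reads) or data.frame
#'   with columns `ref_id` and `n_reads`.
#' @param min_reads threshold, default 20.
#' @return character vector of eligible contig ids.
#' @export
contig_read_filter <- function(read_counts, min_reads = 20L) {
  if (is.data.frame(read_counts)) {
    read_counts <- stats::setNames(read_counts$n_reads, read_counts$ref_id)
  }
  names(read_counts)[read_counts > min_reads]
}

#' Write SNP calls as a minimal VCF 4.2 file
#'
#' Positions are converted to 1-based per the VCF standard; INFO carries DP
#' (A/C/G/T depth) and AF (alternate-allele frequency).
#'
#' @param calls data.frame from [call_snps()].
#' @param references named character vector (for contig headers).
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_snp_vcf <- function(calls, references, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    "##fileformat=VCFv4.2",
    "##source=marker454",
    "##INFO=<ID=DP,Number=1,Type=Integer,Description=\"A/C/G/T read depth\">",
    "##INFO=<ID=AF,Number=A,Type=Float,Description=\"Alternate allele frequency\">"),
    con)
  for (id in names(references)) {
    writeLines(sprintf("##contig=<ID=%s,length=%d>", id,
                       nchar(references[[id]])), con)
  }
  writeLines("#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO", con)
  if (nrow(calls)) {
    writeLines(sprintf("%s\t%d\t.\t%s\t%s\t.\tPASS\tDP=%d;AF=%.4f",
                       calls$ref_id, calls$pos + 1L, calls$ref, calls$alt,
                       calls$depth, calls$alt_freq), con)
  }
  invisible(path)
}
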