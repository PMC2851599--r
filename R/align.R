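# Minimal exact-seed read placement and pileup construction.
#
# This mapper stands in for assembly-derived read placement: a read is
# anchored by its leftmost k-mer that occurs at a unique position across the
# references, extended end-to-end with matches/mismatches only (no gaps,
# since indels are disregarded by the SNP definition), and rejected when the
# mismatch rate exceeds `max_mismatch_rate`. Both strands are tried; forward
# placement wins ties. Reads without a unique anchor are reported unmapped.

# Numeric 2-bit encoding of all k-mers of a sequence. k <= 26 keeps codes
# exactly representable in a double (4^26 < 2^53); positions containing a
# non-ACGT base yield NA.
kmer_codes <- function(seq, k) {
  ch <- strsplit(toupper(seq), "", fixed = TRUE)[[1]]
  n <- length(ch)
  if (n < k) return(numeric(0))
  b <- match(ch, DNA_BASES) - 1L          # NA for non-ACGT
  m <- n - k + 1L
  code <- numeric(m)
  for (j in 0:(k - 1L)) {
    code <- code + b[(1L:m) + j] * 4^(k - 1L - j)
  }
  code
}

#' Build a k-mer index over reference sequences
#'
#' @param references named character vector of reference sequences.
#' @param k k-mer size (default 21, maximum 26).
#' @return an object of class `kmer_index` mapping each k-mer occurring
#'   exactly once across all references to its (reference, offset); lookup
#'   is by binary search over sorted 2-bit k-mer codes.
#' @export
kmer_index <- function(references, k = 21L) {
  stopifnot(!is.null(names(references)), k >= 1L, k <= 26L)
  refs <- toupper(references)
  codes <- numeric(0); ref <- character(0); pos <- integer(0)
  for (id in names(refs)) {
    s <- refs[[id]]
    n <- nchar(s)
    if (n < k) next
    cc <- kmer_codes(s, k)
    keep <- !is.na(cc)
    codes <- c(codes, cc[keep])
    ref <- c(ref, rep(id, sum(keep)))
    pos <- c(pos, which(keep) - 1L)
  }
  dup <- codes %in% codes[duplicated(codes)]
  codes <- codes[!dup]; ref <- ref[!dup]; pos <- pos[!dup]
  o <- order(codes)
  structure(list(codes = codes[o], ref = ref[o], pos = pos[o],
                 k = as.integer(k), references = refs),
            class = "kmer_index")
}

align_at <- function(read_seq, ref_seq, ref_start) {
  # ungapped end-to-end comparison; read must lie fully inside the reference
  L <- nchar(read_seq)
  if (ref_start < 0L || ref_start + L > nchar(ref_seq)) return(NULL)
  a <- strsplit(read_seq, "", fixed = TRUE)[[1]]
  b <- strsplit(substr(ref_seq, ref_start + 1L, ref_start + L), "",
                fixed = TRUE)[[1]]
  list(n_mismatch = sum(a != b), length = L)
}

place_one <- function(seq, idx, max_mismatch_rate) {
  k <- idx$k
  L <- nchar(seq)
  if (L < k) return(NULL)
  qc <- kmer_codes(seq, k)
  slot <- findInterval(qc, idx$codes)
  hit <- ifelse(!is.na(qc) & slot > 0L & idx$codes[pmax(slot, 1L)] == qc,
                slot, NA_integer_)
  first <- which(!is.na(hit))[1]
  if (is.na(first)) return(NULL)
  h <- hit[first]
  ref_id <- idx$ref[h]
  ref_start <- idx$pos[h] - (first - 1L)
  al <- align_at(seq, idx$references[[ref_id]], ref_start)
  if (is.null(al) || al$n_mismatch / al$length > max_mismatch_rate) {
    return(NULL)
  }
  list(ref = ref_id, pos = ref_start, n_mismatch = al$n_mismatch, len = L)
}

#' Place reads on references by unique exact k-mer seeding
#'
#' @param reads a [read_set()] or named character vector of read sequences.
#' @param references named character vector of reference sequences, or a
#'   prebuilt [kmer_index()].
#' @param k seed k-mer size (default 21; ignored when an index is supplied).
#' @param max_mismatch_rate maximum mismatches per aligned base (default
#'   0.05).
#' @return data.frame of placements with columns `read_id`, `ref_id`, `pos`
#'   (0-based reference start), `strand` ("+"/"-"), `length`, `n_mismatch`
#'   and `seq` (the read on the reference strand); unplaced reads appear with
#'   `ref_id = NA` and `strand = "*"`.
#' @export
map_reads <- function(reads, references, k = 21L, max_mismatch_rate = 0.05) {
  if (inherits(reads, "read_set")) {
    seqs <- stats::setNames(reads$seq, reads$id)
  } else {
    seqs <- reads
    stopifnot(!is.null(names(seqs)))
  }
  idx <- if (inherits(references, "kmer_index")) references
    else kmer_index(references, k = k)
  rows <- vector("list", length(seqs))
  rc <- revcomp(seqs)
  for (i in seq_along(seqs)) {
    p <- place_one(seqs[[i]], idx, max_mismatch_rate)
    strand <- "+"
    oriented <- seqs[[i]]
    if (is.null(p)) {
      p <- place_one(rc[[i]], idx, max_mismatch_rate)
      strand <- "-"
      oriented <- rc[[i]]
    }
    if (is.null(p)) {
      rows[[i]] <- data.frame(read_id = names(seqs)[i], ref_id = NA_character_,
                              pos = NA_integer_, strand = "*",
                              length = nchar(seqs[[i]]),
                              n_mismatch = NA_integer_, seq = seqs[[i]],
                              stringsAsFactors = FALSE)
    } else {
      rows[[i]] <- data.frame(read_id = names(seqs)[i], ref_id = p$ref,
                              pos = p$pos, strand = strand, length = p$len,
                              n_mismatch = p$n_mismatch, seq = oriented,
                              stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Build per-position base-count pileups from placements
#'
#' @param placements data.frame from [map_reads()] (unmapped rows ignored).
#' @param references named character vector of reference sequences.
#' @return list of class `pileup`: one element per covered reference, each a
#'   data.frame with `pos` (0-based), `ref_base`, counts `A`,`C`,`G`,`T`,`N`
#'   and `depth` (sum of all five), restricted to covered positions.
#' @export
build_pileup <- function(placements, references) {
  placed <- placements[!is.na(placements$ref_id), , drop = FALSE]
  out <- list()
  for (id in unique(placed$ref_id)) {
    p <- placed[placed$ref_id == id, , drop = FALSE]
    reflen <- nchar(references[[id]])
    pos1 <- unlist(mapply(function(s, l) s + seq_len(l), p$pos, p$length,
                          SIMPLIFY = FALSE))
    base <- unlist(strsplit(p$seq, "", fixed = TRUE))
    code <- match(base, c(DNA_BASES, "N"))
    counts <- matrix(tabulate((pos1 - 1L) * 5L + code, nbins = 5L * reflen),
                     nrow = 5L)
    depth <- colSums(counts)
    covered <- which(depth > 0L)
    refb <- strsplit(toupper(references[[id]]), "", fixed = TRUE)[[1]]
    out[[id]] <- data.frame(pos = covered - 1L, ref_base = refb[covered],
                            A = counts[1L, covered], C = counts[2L, covered],
                            G = counts[3L, covered], T = counts[4L, covered],
                            N = counts[5L, covered], depth = depth[covered],
                            stringsAsFactors = FALSE)
  }
  class(out) <- "pileup"
  out
}

#' @export
`[.pileup` <- function(x, i) {
  structure(unclass(x)[i], class = "pileup")
}

#' Write placements as a minimal SAM file
#'
#' Mapped reads get FLAG 0/16, POS (1-based), full-length match CIGAR and the
#' reference-strand sequence; unmapped reads get FLAG 4. NM carries the
#' mismatch count.
#'
#' @param placements data.frame from [map_reads()].
#' @param references named character vector (for `@SQ` headers).
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_sam <- function(placements, references, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("@HD\tVN:1.6\tSO:unknown", con)
  for (id in names(references)) {
    writeLines(sprintf("@SQ\tSN:%s\tLN:%d", id, nchar(references[[id]])), con)
  }
  for (i in seq_len(nrow(placements))) {
    p <- placements[i, ]
    if (is.na(p$ref_id)) {
      writeLines(sprintf("%s\t4\t*\t0\t0\t*\t*\t0\t0\t%s\t*",
                         p$read_id, p$seq), con)
    } else {
      flag <- if (p$strand == "-") 16L else 0L
      writeLines(sprintf("%s\t%d\t%s\t%d\t60\t%dM\t*\t0\t0\t%s\t*\tNM:i:%d",
                         p$read_id, flag, p$ref_id, p$pos + 1L, p$length,
                         p$seq, p$n_mismatch), con)
    }
  }
  invisible(path)
}

#' Read a minimal SAM file back into a placements data.frame
#'
#' @param path SAM file path.
#' @return data.frame with the [map_reads()] columns.
#' @export
read_sam <- function(path) {
  lines <- readLines(path)
  lines <- lines[!startsWith(lines, "@")]
  if (length(lines) == 0L) {
    return(data.frame(read_id = character(), ref_id = character(),
                      pos = integer(), strand = character(),
                      length = integer(), n_mismatch = integer(),
                      seq = character(), stringsAsFactors = FALSE))
  }
  f <- strsplit(lines, "\t", fixed = TRUE)
  do.call(rbind, lapply(f, function(x) {
    flag <- as.integer(x[2])
    unmapped <- bitwAnd(flag, 4L) > 0L
    nm <- grep("^NM:i:", x, value = TRUE)
    data.frame(
      read_id = x[1],
      ref_id = if (unmapped) NA_character_ else x[3],
      pos = if (unmapped) NA_integer_ else as.integer(x[4]) - 1L,
      strand = if (unmapped) "*" else if (bitwAnd(flag, 16L) > 0L) "-" else "+",
      length = nchar(x[10]),
      n_mismatch = if (length(nm)) as.integer(sub("^NM:i:", "", nm[1]))
        else NA_integer_,
      seq = x[10], stringsAsFactors = FALSE)
  }))
}
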