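# Microsatellite (SSR) detection.
#
# An SSR locus is a maximal tandem run of a primitive 2-4 bp unit repeated at
# least `min_units` times. Maximality is in whole units: the run cannot be
# extended by one full unit in either direction, and the reported start is the
# leftmost in-phase start of the underlying tandem region. Motifs are reported
# as the lexicographically smallest rotation of the unit on the given strand
# (no reverse-complement folding, since EST sequence is strand-specific).

is_primitive_unit <- function(unit) {
  u <- nchar(unit)
  if (u <= 1L) return(TRUE)
  for (d in seq_len(u - 1L)) {
    if (u %% d == 0L &&
        unit == strrep(substr(unit, 1L, d), u %/% d)) return(FALSE)
  }
  TRUE
}

#' Canonical motif of a repeat unit
#'
#' The lexicographically smallest rotation of the unit, so that the reported
#' motif does not depend on the phase at which a tandem run is entered
#' (e.g. runs written as TA...TA and AT...AT both report motif "AT").
#'
#' @param unit repeat unit string.
#' @return canonical motif string.
#' @export
canonical_motif <- function(unit) {
  u <- nchar(unit)
  if (u <= 1L) return(unit)
  rots <- vapply(seq_len(u), function(k) {
    paste0(substr(unit, k, u), substr(unit, 1L, k - 1L))
  }, character(1))
  min(rots)
}

#' Detect simple sequence repeats in a nucleotide sequence
#'
#' Scans for maximal tandem runs of primitive di-, tri- and tetra-nucleotide
#' units with at least `min_units` contiguous repeats. `N` (or any non-ACGT
#' character) never participates in a run. A run whose primitive unit has size
#' u is reported only at unit size u, so e.g. (ATAT)xk appears once, as
#' (AT)x2k; homopolymer runs are never reported (their units are not
#' primitive at sizes 2-4).
#'
#' @param seq a single nucleotide string over A/C/G/T/N.
#' @param seq_id identifier recorded in the output.
#' @param unit_sizes integer repeat-unit sizes to scan (subset of 2:4 by
#'   default; any sizes >= 2 are accepted).
#' @param min_units minimum number of contiguous repeat units (default 4).
#' @param max_len_bp only report runs whose total length is <= this many bp
#'   (default `Inf`, no cap). Marker mining caps at 49 bp so that loci are
#'   strictly shorter than 50 bp; [classify_long_runs()] scans uncapped.
#' @return data.frame with columns `seq_id`, `start`, `end` (0-based
#'   half-open), `motif` (canonical), `unit_size`, `n_units`, sorted by
#'   ascending `start`.
#' @seealso [classify_long_runs()], [ssr_context()]
#' @export
find_ssrs <- function(seq, seq_id = "seq", unit_sizes = c(2L, 3L, 4L),
                      min_units = 4L, max_len_bp = Inf) {
  empty <- data.frame(seq_id = character(), start = integer(),
                      end = integer(), motif = character(),
                      unit_size = integer(), n_units = integer(),
                      stringsAsFactors = FALSE)
  stopifnot(length(seq) == 1L, min_units >= 2L, all(unit_sizes >= 2L))
  seq <- toupper(seq)
  n <- nchar(seq)
  if (n == 0L) return(empty)
  chars <- strsplit(seq, "", fixed = TRUE)[[1]]
  acgt <- chars %in% DNA_BASES
  rows <- list()
  for (u in sort(unique(as.integer(unit_sizes)))) {
    if (n < u * min_units) next
    i <- seq_len(n - u)
    eq <- (chars[i] == chars[i + u]) & acgt[i] & acgt[i + u]
    r <- rle(eq)
    run_end <- cumsum(r$lengths)
    run_start <- run_end - r$lengths + 1L
    hit <- which(r$values & r$lengths >= (min_units - 1L) * u)
    for (j in hit) {
      a <- run_start[j]                     # 1-based first in-phase position
      count <- r$lengths[j] %/% u + 1L      # whole units in the region
      unit <- paste(chars[a:(a + u - 1L)], collapse = "")
      if (!is_primitive_unit(unit)) next
      len <- count * u
      if (len > max_len_bp) next
      rows[[length(rows) + 1L]] <- data.frame(
        seq_id = seq_id, start = a - 1L, end = a - 1L + len,
        motif = canonical_motif(unit), unit_size = u, n_units = count,
        stringsAsFactors = FALSE)
    }
  }
  if (length(rows) == 0L) return(empty)
  out <- do.call(rbind, rows)
  out[order(out$start, out$unit_size), , drop = FALSE]
}

#' Detect SSRs across many sequences
#'
#' @param seqs named character vector of sequences.
#' @inheritParams find_ssrs
#' @return row-bound data.frame of [find_ssrs()] results.
#' @export
find_ssrs_all <- function(seqs, unit_sizes = c(2L, 3L, 4L), min_units = 4L,
                          max_len_bp = Inf) {
  stopifnot(!is.null(names(seqs)))
  res <- lapply(names(seqs), function(id) {
    find_ssrs(seqs[[id]], seq_id = id, unit_sizes = unit_sizes,
              min_units = min_units, max_len_bp = max_len_bp)
  })
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  out
}

#' Flag long SSR runs for read filtering
#'
#' Reuses [find_ssrs()] without a length cap and flags runs strictly longer
#' than `max_run_bp` (a run of exactly `max_run_bp` bp is not flagged).
#'
#' @inheritParams find_ssrs
#' @param max_run_bp run-length threshold in bp (default 50).
#' @return data.frame of flagged runs (same columns as [find_ssrs()]).
#' @export
classify_long_runs <- function(seq, seq_id = "seq", max_run_bp = 50L,
                               unit_sizes = c(2L, 3L, 4L), min_units = 4L) {
  loci <- find_ssrs(seq, seq_id = seq_id, unit_sizes = unit_sizes,
                    min_units = min_units, max_len_bp = Inf)
  loci[(loci$end - loci$start) > max_run_bp, , drop = FALSE]
}

#' Coding/non-coding SSR context and densities
#'
#' Classifies each SSR as coding when its interval overlaps a coding interval
#' by at least 1 bp, and reports SSR density (loci per bp) in each region
#' class. Coordinates are 0-based half-open on the same sequences.
#'
#' @param loci data.frame of SSR loci as from [find_ssrs_all()].
#' @param coding_intervals data.frame with columns `seq_id`, `start`, `end`
#'   (0-based half-open coding intervals).
#' @param seq_lengths named integer vector of total sequence lengths.
#' @return list of class `ssr_context_summary` with counts, bp totals and
#'   densities, plus a logical `in_coding` flag per input locus.
#' @export
ssr_context <- function(loci, coding_intervals, seq_lengths) {
  stopifnot(all(c("seq_id", "start", "end") %in% names(coding_intervals)))
  bad <- coding_intervals$end > seq_lengths[coding_intervals$seq_id] |
    coding_intervals$start < 0L
  if (any(is.na(bad)) || any(bad)) {
    stop("coding interval outside its sequence")
  }
  in_coding <- logical(nrow(loci))
  if (nrow(loci)) {
    for (k in seq_len(nrow(loci))) {
      ci <- coding_intervals[coding_intervals$seq_id == loci$seq_id[k], ,
                             drop = FALSE]
      in_coding[k] <- any(pmin(ci$end, loci$end[k]) -
                            pmax(ci$start, loci$start[k]) >= 1L)
    }
  }
  coding_bp <- sum(coding_intervals$end - coding_intervals$start)
  noncoding_bp <- sum(seq_lengths) - coding_bp
  out <- list(
    n_ssrs_total = nrow(loci),
    n_in_coding = sum(in_coding),
    n_in_noncoding = sum(!in_coding),
    coding_bp = coding_bp,
    noncoding_bp = noncoding_bp,
    density_coding = if (coding_bp > 0) sum(in_coding) / coding_bp else NA_real_,
    density_noncoding = if (noncoding_bp > 0) sum(!in_coding) / noncoding_bp
      else NA_real_,
    in_coding = in_coding)
  class(out) <- "ssr_context_summary"
  out
}

#' @export
print.ssr_context_summary <- function(x, ...) {
  cat(sprintf(paste0(
    "%d SSRs: %d coding / %d non-coding\n",
    "density %.4f per bp (coding, %d bp) vs %.4f per bp (non-coding, %d bp)\n"),
    x$n_ssrs_total, x$n_in_coding, x$n_in_noncoding,
    x$density_coding, x$coding_bp, x$density_noncoding, x$noncoding_bp))
  invisible(x)
}

#' Write SSR loci as GFF3 microsatellite features
#'
#' @param loci data.frame of SSR loci.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_ssr_gff3 <- function(loci, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("##gff-version 3", con)
  if (nrow(loci)) {
    lines <- sprintf("%s\tmarker454\tmicrosatellite\t%d\t%d\t.\t+\t.\tmotif=%s;units=%d",
                     loci$seq_id, loci$start + 1L, loci$end, loci$motif,
                     loci$n_units)
    writeLines(lines, con)
  }
  invisible(path)
}
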