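# Retroelement screening: sequence similarity against a retroelement library
# and keyword classification of annotation descriptions.
#
# The internal similarity screen is a seeded ungapped local-alignment proxy
# for a BLASTn search at E <= 1e-6 (an E-value threshold is database-size
# dependent and not portable): an 11-mer shared with the library anchors an
# ungapped extension, and a sequence matches when the best extended segment
# is at least 50 bp long with at least 80% identity. External-table mode
# consumes a precomputed tabular hit file for exact BLAST parity.

RETRO_KEYWORDS <- c("copia", "gag", "pol", "retroelement", "integrase",
                    "reverse transcriptase", "retrotransposon")

#' Classify an annotation description as retroelement-like or not
#'
#' Case-insensitive whole-word match against the seven classic retroelement
#' terms (copia, gag, pol, retroelement, integrase, reverse transcriptase,
#' retrotransposon). Short terms like "pol" and "gag" match only as
#' standalone words, so "DNA polymerase" is not a retro hit.
#'
#' @param description character vector of annotation descriptions.
#' @return character vector, "retro" or "non_retro".
#' @export
keyword_classify <- function(description) {
  pat <- paste0("\\b(", paste(gsub(" ", "[[:space:]]+", RETRO_KEYWORDS),
                              collapse = "|"), ")\\b")
  ifelse(grepl(pat, description, ignore.case = TRUE, perl = TRUE),
         "retro", "non_retro")
}

seed_hits <- function(seq, lib_kmers, k) {
  n <- nchar(seq)
  if (n < k) return(integer(0))
  starts <- seq_len(n - k + 1L)
  hit <- match(substring(seq, starts, starts + k - 1L), lib_kmers$kmer)
  which(!is.na(hit))
}

# best ungapped extension through an anchor diagonal; returns max segment
# length/identity over the anchored diagonal using prefix-sum extension
extend_anchor <- function(qchars, lchars, qpos, lpos, k,
                          match_score = 1, mismatch_score = -3) {
  off <- lpos - qpos
  # overlap of the diagonal: query i aligned to library i + off
  i1 <- max(1L, 1L - off)
  i2 <- min(length(qchars), length(lchars) - off)
  if (i2 < i1) return(NULL)
  m <- qchars[i1:i2] == lchars[(i1:i2) + off]
  sc <- ifelse(m, match_score, mismatch_score)
  a <- qpos - i1 + 1L                 # anchor index within the overlap
  b <- a + k - 1L
  # extend left of the anchor to the leftmost position maximizing the
  # suffix score sum, then right symmetrically (positive-score extension)
  left <- if (a > 1L) rev(cumsum(rev(sc[1:(a - 1L)]))) else numeric(0)
  if (length(left) && max(left) > 0) {
    lstart <- which(left == max(left))[1]
  } else lstart <- a
  right <- if (b < length(sc)) cumsum(sc[(b + 1L):length(sc)]) else numeric(0)
  if (length(right)) {
    bestr <- max(right)
    rend <- if (bestr > 0) b + which(right == bestr)[length(which(right == bestr))]
      else b
  } else rend <- b
  seg <- lstart:rend
  list(length = length(seg), identity = mean(m[seg]))
}

#' Screen sequences for similarity to a retroelement library
#'
#' @param seqs named character vector of sequences (reads or contigs).
#' @param library named character vector of retroelement sequences
#'   (`mode = "internal"`), or a hit-table data.frame from
#'   [read_hit_table()] (`mode = "external-table"`).
#' @param mode "internal" (seeded ungapped screen) or "external-table"
#'   (filter a similarity hit table at `max_evalue`).
#' @param k seed size for the internal screen (default 11).
#' @param min_len minimum extended segment length in bp (default 50).
#' @param min_identity minimum segment identity (default 0.80).
#' @param max_evalue E-value cutoff for external-table mode (default 1e-6).
#' @return sorted character vector of matched sequence ids.
#' @export
similarity_screen <- function(seqs, library, mode = c("internal", "external-table"),
                              k = 11L, min_len = 50L, min_identity = 0.80,
                              max_evalue = 1e-6) {
  mode <- match.arg(mode)
  if (mode == "external-table") {
    tab <- library
    stopifnot(is.data.frame(tab))
    hits <- tab[tab$evalue <= max_evalue, , drop = FALSE]
    return(sort(intersect(names(seqs), unique(hits$query_id))))
  }
  if (length(library) == 0L) stop("retroelement library is empty")
  stopifnot(!is.null(names(library)), !is.null(names(seqs)))
  lib <- toupper(library)
  # library k-mer dictionary (first occurrence retained per k-mer)
  kms <- character(0); lid <- character(0); lpos <- integer(0)
  for (id in names(lib)) {
    n <- nchar(lib[[id]])
    if (n < k) next
    st <- seq_len(n - k + 1L)
    kms <- c(kms, substring(lib[[id]], st, st + k - 1L))
    lid <- c(lid, rep(id, n - k + 1L))
    lpos <- c(lpos, st)
  }
  keep <- !duplicated(kms)
  dict <- list(kmer = kms[keep], id = lid[keep], pos = lpos[keep])
  lchars <- lapply(lib, function(s) strsplit(s, "", fixed = TRUE)[[1]])
  matched <- character(0)
  for (qid in names(seqs)) {
    found <- FALSE
    for (qseq in c(toupper(seqs[[qid]]), revcomp(seqs[[qid]]))) {
      n <- nchar(qseq)
      if (n < k) next
      st <- seq_len(n - k + 1L)
      hit <- match(substring(qseq, st, st + k - 1L), dict$kmer)
      anchors <- which(!is.na(hit))
      if (length(anchors) == 0L) next
      qchars <- strsplit(qseq, "", fixed = TRUE)[[1]]
      # try anchors left to right until one yields a passing segment
      for (ai in anchors) {
        h <- hit[ai]
        ext <- extend_anchor(qchars, lchars[[dict$id[h]]], ai, dict$pos[h], k)
        if (!is.null(ext) && ext$length >= min_len &&
            ext$identity >= min_identity) {
          found <- TRUE
          break
        }
      }
      if (found) break
    }
    if (found) matched <- c(matched, qid)
  }
  sort(matched)
}

#' Retroelement abundance per EST collection
#'
#' @param collections named list; each element a list/record with `n_ests`
#'   (collection size) and `n_matching` (count of ESTs matching the
#'   retroelement panel) or `matched_ids` (their ids).
#' @return data.frame with `collection`, `n_ests`, `n_matching`, `percent`
#'   (100 x n_matching / n_ests, rounded to 4 decimals).
#' @export
abundance_table <- function(collections) {
  rows <- lapply(names(collections), function(nm) {
    x <- collections[[nm]]
    n_match <- if (!is.null(x$n_matching)) x$n_matching
      else length(unique(x$matched_ids))
    if (is.null(x$n_ests) || x$n_ests <= 0) {
      stop(sprintf("collection '%s' has no ESTs", nm))
    }
    if (n_match < 0 || n_match > x$n_ests) {
      stop(sprintf("collection '%s': matching count out of range", nm))
    }
    data.frame(collection = nm, n_ests = x$n_ests, n_matching = n_match,
               percent = round(100 * n_match / x$n_ests, 4L),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Classify retro-matched contigs by their best protein hit
#'
#' For contigs that matched the retroelement library, takes the best protein
#' hit per contig from a similarity hit table (lowest E-value, ties by bit
#' score), extracts the unique protein accessions, and classifies each by
#' [keyword_classify()] on its description -- an automated proxy for manual
#' database inspection, and flagged as such in the output.
#'
#' @param hit_table data.frame from [read_hit_table()] with `description`
#'   populated.
#' @param max_evalue E-value cutoff (default 1e-4).
#' @return list with `n_unique_proteins`, `n_non_retro`,
#'   `percent_non_retro` (1 decimal), per-accession `classification`
#'   data.frame, and `method = "automated_keyword"`.
#' @export
classify_retro_contigs <- function(hit_table, max_evalue = 1e-4) {
  best <- best_hits(hit_table, max_evalue = max_evalue)
  acc <- !duplicated(best$subject_acc)
  prot <- best[acc, c("subject_acc", "description"), drop = FALSE]
  cls <- keyword_classify(prot$description)
  n <- nrow(prot)
  n_non <- sum(cls == "non_retro")
  list(n_unique_proteins = n,
       n_non_retro = n_non,
       percent_non_retro = if (n > 0) round(100 * n_non / n, 1L) else NA_real_,
       classification = data.frame(subject_acc = prot$subject_acc,
                                   class = cls, stringsAsFactors = FALSE),
       method = "automated_keyword")
}
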