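# Ingestion and summarization of tabular similarity-search results.
#
# Hit tables follow the standard 12-column tab-separated layout
# (query, subject, pident, length, mismatch, gapopen, qstart, qend, sstart,
# send, evalue, bitscore), optionally extended -- as similarity-search tools
# allow via custom column sets -- with subject length, taxon label and
# description as columns 13-15. Query/subject aligned intervals arrive
# 1-based inclusive and are stored 0-based half-open.

HIT_TABLE_COLS <- c("query_id", "subject_acc", "pident", "aln_length",
                    "mismatch", "gapopen", "qstart", "qend", "sstart",
                    "send", "evalue", "bitscore")
HIT_TABLE_EXT <- c("subject_len", "taxon", "description")

#' Read a tabular similarity hit file
#'
#' Accepts the 12 standard columns or the 15-column extended dialect with
#' subject length, taxon label and description.
#'
#' @param path tab-separated hit file (no header).
#' @return data.frame with named columns; intervals converted to 0-based
#'   half-open (`qstart`/`sstart` decremented). Missing extension columns are
#'   filled with NA.
#' @export
read_hit_table <- function(path) {
  raw <- utils::read.delim(path, header = FALSE, stringsAsFactors = FALSE,
                           quote = "", comment.char = "#")
  if (!ncol(raw) %in% c(12L, 15L)) {
    stop(sprintf("hit table must have 12 or 15 columns, found %d", ncol(raw)))
  }
  names(raw) <- c(HIT_TABLE_COLS, HIT_TABLE_EXT)[seq_len(ncol(raw))]
  for (cc in setdiff(HIT_TABLE_EXT, names(raw))) raw[[cc]] <- NA
  num <- c("pident", "aln_length", "mismatch", "gapopen", "qstart", "qend",
           "sstart", "send", "evalue", "bitscore", "subject_len")
  bad <- which(is.na(suppressWarnings(as.numeric(raw$evalue))))
  if (length(bad)) {
    stop(sprintf("malformed hit-table row at line %d (E-value '%s')",
                 bad[1], raw$evalue[bad[1]]))
  }
  for (cc in num) raw[[cc]] <- suppressWarnings(as.numeric(raw[[cc]]))
  raw$qstart <- raw$qstart - 1L
  raw$sstart <- raw$sstart - 1L
  raw
}

#' Write a hit table in the extended 15-column dialect
#'
#' @param tab data.frame with [read_hit_table()] columns (0-based intervals;
#'   converted back to 1-based inclusive on output).
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_hit_table <- function(tab, path) {
  out <- tab[, c(HIT_TABLE_COLS, HIT_TABLE_EXT)]
  out$qstart <- out$qstart + 1L
  out$sstart <- out$sstart + 1L
  utils::write.table(out, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Percentage at a table's printed precision
#'
#' @param count numerator.
#' @param total denominator.
#' @param digits decimals retained (0 for whole-percent tables, 1 for
#'   taxonomy/GO tables, 4 for abundance tables).
#' @return 100 * count / total rounded to `digits`.
#' @export
percent_of <- function(count, total, digits = 0L) {
  if (any(total <= 0)) stop("total must be positive")
  round(100 * count / total, digits)
}

#' Best hit per query under an E-value cutoff
#'
#' Drops records with E-value above `max_evalue`, then keeps one record per
#' query: lowest E-value, ties broken by highest bit score, then by
#' lexicographic subject accession (a final deterministic tie-break).
#'
#' @param records hit-table data.frame.
#' @param max_evalue cutoff, inclusive (default 1e-6).
#' @return data.frame, one row per retained query.
#' @export
best_hits <- function(records, max_evalue = 1e-6) {
  keep <- records[records$evalue <= max_evalue, , drop = FALSE]
  if (nrow(keep) == 0L) return(keep)
  ord <- order(keep$query_id, keep$evalue, -keep$bitscore, keep$subject_acc)
  keep <- keep[ord, , drop = FALSE]
  out <- keep[!duplicated(keep$query_id), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Number of unique subject accessions among best hits
#'
#' @param best data.frame from [best_hits()].
#' @return integer count.
#' @export
unique_accession_count <- function(best) {
  length(unique(best$subject_acc))
}

#' Taxonomic breakdown of best hits
#'
#' @param best data.frame from [best_hits()] with `taxon` populated.
#' @param taxon_category_map named character vector mapping taxon labels to
#'   reporting categories (e.g. Conifer, Other plant, Fungi, ...). Taxa
#'   absent from the map are counted as "Unclassified" with a warning.
#' @param digits decimals on percentages (default 1).
#' @return data.frame `category`, `count`, `percent`; percentages are of the
#'   categorized (non-Unclassified) total.
#' @export
taxon_breakdown <- function(best, taxon_category_map, digits = 1L) {
  cat <- unname(taxon_category_map[best$taxon])
  if (anyNA(cat)) {
    warning(sprintf("%d hits with unmapped taxon counted as Unclassified",
                    sum(is.na(cat))))
    cat[is.na(cat)] <- "Unclassified"
  }
  counts <- table(cat)
  total <- sum(counts[names(counts) != "Unclassified"])
  data.frame(category = names(counts), count = as.integer(counts),
             percent = ifelse(names(counts) == "Unclassified", NA_real_,
                              round(100 * as.integer(counts) / total, digits)),
             stringsAsFactors = FALSE)
}

#' Gene-ontology namespace proportions
#'
#' @param assignments data.frame with columns `query_id`, `go_id`,
#'   `namespace` (molecular_function / biological_process /
#'   cellular_component), or a named count vector per namespace.
#' @param digits decimals on percentages (default 1).
#' @return data.frame `namespace`, `count`, `percent` (of total term count).
#' @export
go_namespace_proportions <- function(assignments, digits = 1L) {
  ns_levels <- c("molecular_function", "biological_process",
                 "cellular_component")
  if (is.data.frame(assignments)) {
    stopifnot(all(assignments$namespace %in% ns_levels))
    if (!all(grepl("^GO:\\d{7}$", assignments$go_id))) {
      stop("malformed GO term identifier")
    }
    counts <- table(factor(assignments$namespace, levels = ns_levels))
  } else {
    counts <- assignments[ns_levels]
    names(counts) <- ns_levels
  }
  total <- sum(counts)
  data.frame(namespace = ns_levels, count = as.integer(counts),
             percent = round(100 * as.integer(counts) / total, digits),
             stringsAsFactors = FALSE)
}

#' Logistic model of similarity-hit presence against sequence length
#'
#' Fits hit ~ length by maximum-likelihood logistic regression and reports
#' the slope (per bp), intercept, standard errors and the slope's Wald
#' p-value. Complete separation or a single outcome class is detected and
#' flagged instead of silently reported.
#'
#' @param hit logical (or 0/1) vector: does the sequence have a significant
#'   similarity hit.
#' @param length numeric vector of sequence lengths (bp).
#' @return list with `slope`, `intercept`, `slope_se`, `intercept_se`,
#'   `p_value`, `separation` (logical), `n`.
#' @export
hit_length_logistic <- function(hit, length) {
  hit <- as.integer(hit)
  stopifnot(length(hit) == base::length(length))
  if (base::length(unique(hit)) < 2L) {
    return(list(slope = NA_real_, intercept = NA_real_, slope_se = NA_real_,
                intercept_se = NA_real_, p_value = NA_real_,
                separation = TRUE, n = base::length(hit)))
  }
  fit <- suppressWarnings(stats::glm(hit ~ length, family = stats::binomial()))
  mu <- stats::fitted(fit)
  sep <- !fit$converged || any(mu > 1 - 1e-10) || any(mu < 1e-10)
  sm <- summary(fit)$coefficients
  list(slope = unname(sm["length", 1]), intercept = unname(sm[1, 1]),
       slope_se = unname(sm["length", 2]), intercept_se = unname(sm[1, 2]),
       p_value = unname(sm["length", 4]), separation = sep,
       n = base::length(hit))
}

#' Ortholog coverage by query sequences
#'
#' Per query: the ratio of nucleotide query length to ortholog length. With
#' `divide_by_3 = TRUE` (default) subject residue lengths are converted to a
#' nucleotide-equivalent scale by multiplying by 3, so a 900-nt query fully
#' matching a 300-aa ortholog has ratio 1. Per subject: the fraction of the
#' subject covered by the union of aligned subject intervals across all
#' queries, capped at 1.
#'
#' @param hits hit-table data.frame (typically after [best_hits()], or all
#'   retained hits for the union coverage).
#' @param query_lengths named numeric vector of query sequence lengths (nt).
#' @param divide_by_3 convert subject residue lengths to nt-equivalents.
#' @return list with `per_query` (query_id, ratio) and `per_subject`
#'   (subject_acc, subject_len, covered, coverage).
#' @export
ortholog_coverage <- function(hits, query_lengths, divide_by_3 = TRUE) {
  if (any(is.na(hits$subject_len)) || any(hits$subject_len <= 0)) {
    stop("subject lengths must be positive")
  }
  denom <- if (divide_by_3) 3 * hits$subject_len else hits$subject_len
  per_query <- data.frame(
    query_id = hits$query_id,
    ratio = unname(query_lengths[hits$query_id]) / denom,
    stringsAsFactors = FALSE)
  per_subject <- do.call(rbind, lapply(split(hits, hits$subject_acc),
    function(h) {
      ir <- IRanges::reduce(IRanges::IRanges(start = h$sstart + 1L,
                                             end = h$send))
      cov <- min(1, sum(IRanges::width(ir)) / h$subject_len[1])
      data.frame(subject_acc = h$subject_acc[1],
                 subject_len = h$subject_len[1],
                 covered = sum(IRanges::width(ir)), coverage = cov,
                 stringsAsFactors = FALSE)
    }))
  rownames(per_subject) <- NULL
  list(per_query = per_query, per_subject = per_subject)
}

#' Back-of-envelope transcriptome coverage estimate
#'
#' Fold coverage = (reads x mean read length) / (genes x mean gene length),
#' the standard sequencing-depth estimate for an EST project given an assumed
#' gene complement.
#'
#' @param n_reads read count.
#' @param mean_read_len mean read length (bp).
#' @param n_genes assumed gene count (default 25,000).
#' @param mean_gene_len assumed mean gene length (default 2,000 bp).
#' @param digits decimals (default 1).
#' @return fold coverage.
#' @export
transcriptome_coverage_estimate <- function(n_reads, mean_read_len,
                                            n_genes = 25000,
                                            mean_gene_len = 2000,
                                            digits = 1L) {
  if (n_genes <= 0 || mean_gene_len <= 0) stop("gene space must be positive")
  if (n_reads <= 0 || mean_read_len <= 0) stop("read inputs must be positive")
  round((n_reads * mean_read_len) / (n_genes * mean_gene_len), digits)
}

#' Assembly summary statistics
#'
#' @param contig_lengths named numeric vector of contig lengths.
#' @param placements optional data.frame from [map_reads()]; adds per-contig
#'   read counts and depth (sum of aligned read bp / contig length).
#' @param long_bp count contigs strictly longer than this (default 800).
#' @return list of class `assembly_summary` with `n_contigs`, `mean_length`,
#'   `length_quantiles` (deciles), `n_over_long`, and optional `per_contig`
#'   data.frame (ref_id, length, n_reads, depth).
#' @export
assembly_summary <- function(contig_lengths, placements = NULL,
                             long_bp = 800L) {
  if (length(contig_lengths) == 0L) stop("no contigs")
  out <- list(n_contigs = length(contig_lengths),
              mean_length = mean(contig_lengths),
              length_quantiles = stats::quantile(contig_lengths,
                                                 probs = seq(0, 1, 0.1)),
              n_over_long = sum(contig_lengths > long_bp),
              long_bp = long_bp)
  if (!is.null(placements)) {
    placed <- placements[!is.na(placements$ref_id), , drop = FALSE]
    n_reads <- table(factor(placed$ref_id, levels = names(contig_lengths)))
    aligned <- tapply(placed$length,
                      factor(placed$ref_id, levels = names(contig_lengths)),
                      sum, default = 0)
    out$per_contig <- data.frame(
      ref_id = names(contig_lengths),
      length = unname(contig_lengths),
      n_reads = as.integer(n_reads),
      depth = unname(aligned) / unname(contig_lengths),
      stringsAsFactors = FALSE)
  }
  class(out) <- "assembly_summary"
  out
}

#' @export
print.assembly_summary <- function(x, ...) {
  cat(sprintf("%d contigs, mean length %.1f bp, %d longer than %d bp\n",
              x$n_contigs, x$mean_length, x$n_over_long, x$long_bp))
  invisible(x)
}
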