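# Read quality control: partition raw reads into kept/discarded sets.
#
# Filters are applied in a fixed order -- adapter trim, retroelement
# similarity, long SSR run, mean quality -- so that a read triggering several
# filters is attributed to exactly one (the first), and report counts are
# reproducible. Boundaries are strict: a mean quality of exactly the
# threshold passes ("less than 18" removes), and an SSR run of exactly
# `max_ssr_run_bp` passes ("longer than 50 bp" removes).

#' Mean phred quality of a read
#'
#' @param qual integer vector of phred qualities (one read), or a
#'   [read_set()] (then a vector of means is returned).
#' @return arithmetic mean quality.
#' @export
mean_quality <- function(qual) {
  if (inherits(qual, "read_set")) {
    return(vapply(qual$qual, mean_quality, numeric(1)))
  }
  if (length(qual) == 0L) stop("empty read has no mean quality")
  mean(as.numeric(qual))
}

trim_one <- function(seq, qual, adapters) {
  for (ad in adapters) {
    ad <- toupper(ad)
    la <- nchar(ad)
    if (nchar(seq) >= la && substr(seq, 1L, la) == ad) {
      seq <- substr(seq, la + 1L, nchar(seq))
      qual <- qual[-seq_len(la)]
    }
    if (nchar(seq) >= la &&
        substr(seq, nchar(seq) - la + 1L, nchar(seq)) == ad) {
      qual <- qual[seq_len(nchar(seq) - la)]
      seq <- substr(seq, 1L, nchar(seq) - la)
    }
  }
  list(seq = seq, qual = qual)
}

#' Filter a read set with the three-stage QC rule
#'
#' @param reads a [read_set()].
#' @param min_mean_q discard reads with mean quality strictly below this
#'   (default 18).
#' @param max_ssr_run_bp discard reads containing an SSR run strictly longer
#'   than this many bp (default 50).
#' @param retro_read_ids optional character vector (or function taking the
#'   read set and returning one) of read ids to discard as
#'   retroelement-matching; `NULL` disables the retro filter.
#' @param adapters optional character vector of adapter sequences trimmed by
#'   exact prefix/suffix match before any filter; `NULL` (default) disables
#'   trimming. A read trimmed to length zero is discarded as adapter-only.
#' @return list with `kept` (a read_set), `discarded` (a read_set),
#'   `reason` (named character vector, one of quality/long_ssr/retro/
#'   adapter_only, indexed by discarded read id) and `report` (class
#'   `qc_report`).
#' @export
qc_filter <- function(reads, min_mean_q = 18, max_ssr_run_bp = 50L,
                      retro_read_ids = NULL, adapters = NULL) {
  stopifnot(inherits(reads, "read_set"))
  n_in <- length(reads)
  seqs <- reads$seq
  quals <- reads$qual
  if (!is.null(adapters)) {
    for (k in seq_len(n_in)) {
      tr <- trim_one(seqs[k], quals[[k]], adapters)
      seqs[k] <- tr$seq
      quals[[k]] <- tr$qual
    }
  }
  if (is.function(retro_read_ids)) retro_read_ids <- retro_read_ids(reads)
  reason <- rep(NA_character_, n_in)
  reason[nchar(seqs) == 0L] <- "adapter_only"
  if (!is.null(retro_read_ids)) {
    reason[is.na(reason) & reads$id %in% retro_read_ids] <- "retro"
  }
  todo <- which(is.na(reason))
  for (k in todo) {
    if (nrow(classify_long_runs(seqs[k], max_run_bp = max_ssr_run_bp))) {
      reason[k] <- "long_ssr"
    }
  }
  todo <- which(is.na(reason))
  mq <- vapply(quals[todo], function(q) mean(as.numeric(q)), numeric(1))
  reason[todo[mq < min_mean_q]] <- "quality"

  keep <- is.na(reason)
  kept <- read_set(reads$id[keep], seqs[keep], quals[keep])
  disc <- read_set(reads$id[!keep], reads$seq[!keep], reads$qual[!keep])
  rvec <- stats::setNames(reason[!keep], reads$id[!keep])
  report <- structure(list(
    n_input = n_in,
    n_kept = sum(keep),
    n_discarded_quality = sum(rvec == "quality"),
    n_discarded_long_ssr = sum(rvec == "long_ssr"),
    n_discarded_retro = sum(rvec == "retro"),
    n_discarded_adapter_only = sum(rvec == "adapter_only")),
    class = "qc_report")
  list(kept = kept, discarded = disc, reason = rvec, report = report)
}

#' @export
print.qc_report <- function(x, ...) {
  cat(sprintf(paste0(
    "QC: %d reads in, %d kept\n",
    "  discarded: %d quality, %d long SSR, %d retroelement, %d adapter-only\n"),
    x$n_input, x$n_kept, x$n_discarded_quality, x$n_discarded_long_ssr,
    x$n_discarded_retro, x$n_discarded_adapter_only))
  invisible(x)
}

#' Write a QC report as a two-column TSV
#'
#' @param report a `qc_report`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_qc_report <- function(report, path) {
  df <- data.frame(metric = names(unclass(report)),
                   count = unlist(unclass(report), use.names = FALSE))
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
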