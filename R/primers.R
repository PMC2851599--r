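# PCR primer design around SSR loci.
#
# Candidate primers are enumerated in the flanks of a locus and retained when
# they satisfy five rules: GC >= 30% per primer, Tm in [52, 62] C, |dTm| <= 4
# C between primers, product length in [100, 450] bp, and a GC clamp (the two
# 3'-terminal bases are G or C).

# SantaLucia (1998) unified nearest-neighbor parameters.
# dH in kcal/mol, dS in cal/(mol K), per 5'->3' dinucleotide stack.
NN_DH <- c(AA = -7.9, AC = -8.4, AG = -7.8, AT = -7.2,
           CA = -8.5, CC = -8.0, CG = -10.6, CT = -7.8,
           GA = -8.2, GC = -9.8, GG = -8.0, GT = -8.4,
           TA = -7.2, TC = -8.2, TG = -8.5, TT = -7.9)
NN_DS <- c(AA = -22.2, AC = -22.4, AG = -21.0, AT = -20.4,
           CA = -22.7, CC = -19.9, CG = -27.2, CT = -21.0,
           GA = -22.2, GC = -24.4, GG = -19.9, GT = -22.4,
           TA = -21.3, TC = -22.2, TG = -22.7, TT = -22.2)

#' Oligonucleotide melting temperature
#'
#' Nearest-neighbor thermodynamics (SantaLucia 1998 unified parameters) with
#' the entropic salt correction, evaluated at 50 mM monovalent cation and
#' 50 nM primer concentration by default so results are comparable to
#' primer3-family tools. The Wallace rule (2(A+T) + 4(G+C)) is available via
#' `method = "wallace"`.
#'
#' @param primer primer sequence(s), 5'->3', over A/C/G/T.
#' @param method "nn" (default) or "wallace".
#' @param monovalent_mM monovalent cation concentration in mM (default 50).
#' @param primer_nM primer concentration in nM (default 50).
#' @return melting temperature(s) in degrees Celsius.
#' @export
oligo_tm <- function(primer, method = c("nn", "wallace"),
                     monovalent_mM = 50, primer_nM = 50) {
  method <- match.arg(method)
  vapply(toupper(primer), function(p) {
    if (nchar(p) < 2L || grepl("[^ACGT]", p)) {
      stop("primer must be >= 2 bases over A/C/G/T")
    }
    ch <- strsplit(p, "", fixed = TRUE)[[1]]
    if (method == "wallace") {
      return(2 * sum(ch %in% c("A", "T")) + 4 * sum(ch %in% c("G", "C")))
    }
    stacks <- paste0(ch[-length(ch)], ch[-1L])
    dh <- sum(NN_DH[stacks])
    ds <- sum(NN_DS[stacks])
    # terminal initiation terms
    for (endb in c(ch[1L], ch[length(ch)])) {
      if (endb %in% c("G", "C")) {
        dh <- dh + 0.1; ds <- ds - 2.8
      } else {
        dh <- dh + 2.3; ds <- ds + 4.1
      }
    }
    ds <- ds + 0.368 * (length(ch) - 1L) * log(monovalent_mM / 1000)
    r <- 1.987  # cal/(mol K)
    dh * 1000 / (ds + r * log(primer_nM * 1e-9 / 4)) - 273.15
  }, numeric(1), USE.NAMES = FALSE)
}

#' Default primer-design constraints
#'
#' @param product_length_range bp, default c(100, 450).
#' @param tm_range degrees C, default c(52, 62).
#' @param max_tm_diff degrees C, default 4.
#' @param min_gc minimum per-primer GC fraction, default 0.30 (inclusive).
#' @param gc_clamp require the last two bases of each primer to be G or C.
#' @param primer_len_range primer lengths enumerated, default c(18, 24).
#' @param min_flank_bp bases immediately adjacent to the locus that primers
#'   must not overlap (default 0; expose as an alternative reading of a
#'   minimum-flank rule).
#' @param tm_method Tm model passed to [oligo_tm()].
#' @return named list of constraints.
#' @export
primer_constraints <- function(product_length_range = c(100L, 450L),
                               tm_range = c(52, 62), max_tm_diff = 4,
                               min_gc = 0.30, gc_clamp = TRUE,
                               primer_len_range = c(18L, 24L),
                               min_flank_bp = 0L,
                               tm_method = "nn") {
  list(product_length_range = product_length_range, tm_range = tm_range,
       max_tm_diff = max_tm_diff, min_gc = min_gc, gc_clamp = gc_clamp,
       primer_len_range = primer_len_range, min_flank_bp = min_flank_bp,
       tm_method = tm_method)
}

#' Check a primer pair against the five design rules
#'
#' @param forward,reverse primer sequences, 5'->3'.
#' @param product_length expected PCR product length in bp.
#' @param constraints list from [primer_constraints()].
#' @return list with `ok` (logical) and `violations` (character vector drawn
#'   from gc_content, tm_range, tm_difference, product_length, gc_clamp),
#'   plus the computed `tm_forward`, `tm_reverse`, `gc_forward`, `gc_reverse`.
#' @export
check_primer_pair <- function(forward, reverse, product_length,
                              constraints = primer_constraints()) {
  stopifnot(nzchar(forward), nzchar(reverse))
  tmf <- oligo_tm(forward, method = constraints$tm_method)
  tmr <- oligo_tm(reverse, method = constraints$tm_method)
  gcf <- gc_content(forward)
  gcr <- gc_content(reverse)
  v <- character()
  if (gcf < constraints$min_gc || gcr < constraints$min_gc) {
    v <- c(v, "gc_content")
  }
  tr <- constraints$tm_range
  if (tmf < tr[1] || tmf > tr[2] || tmr < tr[1] || tmr > tr[2]) {
    v <- c(v, "tm_range")
  }
  if (abs(tmf - tmr) > constraints$max_tm_diff) v <- c(v, "tm_difference")
  pr <- constraints$product_length_range
  if (product_length < pr[1] || product_length > pr[2]) {
    v <- c(v, "product_length")
  }
  if (constraints$gc_clamp) {
    last2 <- function(p) strsplit(substr(p, nchar(p) - 1L, nchar(p)), "")[[1]]
    if (!all(last2(forward) %in% c("G", "C")) ||
        !all(last2(reverse) %in% c("G", "C"))) {
      v <- c(v, "gc_clamp")
    }
  }
  list(ok = length(v) == 0L, violations = v,
       tm_forward = tmf, tm_reverse = tmr,
       gc_forward = gcf, gc_reverse = gcr)
}

# All candidate single primers in a flank of the template, with per-primer
# properties precomputed and per-primer rules (GC, clamp, Tm window) already
# applied. side = "forward": windows wholly inside [search_lo, flank_bound)
# (0-based half-open), primer is the template substring. side = "reverse":
# windows wholly inside [flank_bound, search_hi), primer is the reverse
# complement of the window.
enumerate_primers <- function(template, flank_bound, side, constraints,
                              search_lo = 0L, search_hi = nchar(template)) {
  lens <- seq.int(constraints$primer_len_range[1],
                  constraints$primer_len_range[2])
  starts <- integer(0); ends <- integer(0)
  for (L in lens) {
    if (side == "forward") {
      s <- if (flank_bound - L >= search_lo) seq.int(search_lo, flank_bound - L)
        else integer(0)
    } else {
      s <- if (search_hi - L >= flank_bound) seq.int(flank_bound, search_hi - L)
        else integer(0)
    }
    starts <- c(starts, s)
    ends <- c(ends, s + L)
  }
  if (length(starts) == 0L) {
    return(data.frame(start = integer(), end = integer(),
                      primer = character(), tm = numeric(), gc = numeric(),
                      stringsAsFactors = FALSE))
  }
  win <- substring(template, starts + 1L, ends)
  ok <- !grepl("[^ACGT]", win)
  starts <- starts[ok]; ends <- ends[ok]; win <- win[ok]
  primer <- if (side == "forward") win else unname(revcomp(win))
  gc <- gc_content(primer)
  keep <- gc >= constraints$min_gc
  if (constraints$gc_clamp) {
    keep <- keep & grepl("[GC][GC]$", primer)
  }
  starts <- starts[keep]; ends <- ends[keep]
  primer <- primer[keep]; gc <- gc[keep]
  if (length(primer) == 0L) {
    return(data.frame(start = integer(), end = integer(),
                      primer = character(), tm = numeric(), gc = numeric(),
                      stringsAsFactors = FALSE))
  }
  tm <- oligo_tm(primer, method = constraints$tm_method)
  keep <- tm >= constraints$tm_range[1] & tm <= constraints$tm_range[2]
  data.frame(start = starts[keep], end = ends[keep], primer = primer[keep],
             tm = tm[keep], gc = gc[keep], stringsAsFactors = FALSE)
}

#' Design PCR primer pairs flanking an SSR locus
#'
#' Enumerates every primer window of the configured lengths in the left and
#' right flanks of the locus, keeps single primers passing the per-primer
#' rules, pairs them, and retains pairs passing [check_primer_pair()]. Pairs
#' are ranked by |mean Tm - 57| then by |product length - 250|, both
#' ascending, with template position as the final deterministic tie-break.
#'
#' @param template template sequence containing the locus.
#' @param locus one row of a [find_ssrs()] data.frame (uses `start`, `end`).
#' @param constraints list from [primer_constraints()].
#' @param max_pairs return at most this many top-ranked pairs (default Inf).
#' @param max_flank_bp search window on each side of the locus (default 450
#'   bp; primers further out could never yield a product within the allowed
#'   length).
#' @return data.frame with forward/reverse sequences, 0-based template
#'   positions, product length, per-primer Tm and GC%; zero rows when no
#'   valid pair exists.
#' @export
design_primers <- function(template, locus,
                           constraints = primer_constraints(),
                           max_pairs = Inf,
                           max_flank_bp = 450L) {
  n <- nchar(template)
  stopifnot(locus$start >= 0, locus$end <= n)
  fb <- max(0L, locus$start - constraints$min_flank_bp)
  rb <- min(n, locus$end + constraints$min_flank_bp)
  fwd <- enumerate_primers(template, fb, "forward", constraints,
                           search_lo = max(0L, fb - max_flank_bp))
  rev <- enumerate_primers(template, rb, "reverse", constraints,
                           search_hi = min(n, rb + max_flank_bp))
  empty <- data.frame(forward = character(), reverse = character(),
                      forward_start = integer(), forward_end = integer(),
                      reverse_start = integer(), reverse_end = integer(),
                      product_length = integer(),
                      tm_forward = numeric(), tm_reverse = numeric(),
                      gc_forward = numeric(), gc_reverse = numeric(),
                      stringsAsFactors = FALSE)
  if (nrow(fwd) == 0L || nrow(rev) == 0L) return(empty)
  # all pairs, vectorized: per-primer rules already hold, so only product
  # length and Tm difference remain
  fi <- rep(seq_len(nrow(fwd)), each = nrow(rev))
  ri <- rep(seq_len(nrow(rev)), times = nrow(fwd))
  prod_len <- rev$end[ri] - fwd$start[fi]
  keep <- prod_len >= constraints$product_length_range[1] &
    prod_len <= constraints$product_length_range[2] &
    abs(fwd$tm[fi] - rev$tm[ri]) <= constraints$max_tm_diff
  if (!any(keep)) return(empty)
  fi <- fi[keep]; ri <- ri[keep]
  out <- data.frame(
    forward = fwd$primer[fi], reverse = rev$primer[ri],
    forward_start = fwd$start[fi], forward_end = fwd$end[fi],
    reverse_start = rev$start[ri], reverse_end = rev$end[ri],
    product_length = prod_len[keep],
    tm_forward = fwd$tm[fi], tm_reverse = rev$tm[ri],
    gc_forward = 100 * fwd$gc[fi], gc_reverse = 100 * rev$gc[ri],
    stringsAsFactors = FALSE)
  ord <- order(abs((out$tm_forward + out$tm_reverse) / 2 - 57),
               abs(out$product_length - 250),
               out$forward_start, out$reverse_start)
  out <- out[ord, , drop = FALSE]
  rownames(out) <- NULL
  if (is.finite(max_pairs)) out <- out[seq_len(min(nrow(out), max_pairs)), ,
                                       drop = FALSE]
  out
}
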