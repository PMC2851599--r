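# Independent brute-force oracles used across the suite. These deliberately
# share no code with the implementation paths they check (beyond trivial
# base-R primitives).

# Exhaustive SSR oracle: tests every (start, unit size) pair, counts maximal
# whole-unit repetitions by direct substring comparison, and keeps only runs
# that are primitive-unit, long enough, and start at the leftmost in-phase
# position of their tandem region.
oracle_ssrs <- function(seq, unit_sizes = c(2L, 3L, 4L), min_units = 4L) {
  seq <- toupper(seq)
  n <- nchar(seq)
  ch <- strsplit(seq, "", fixed = TRUE)[[1]]
  acgt <- ch %in% c("A", "C", "G", "T")
  rows <- list()
  smallest_rotation <- function(unit) {
    u <- nchar(unit)
    min(vapply(seq_len(u), function(k) {
      paste0(substr(unit, k, u), substr(unit, 1L, k - 1L))
    }, character(1)))
  }
  for (u in unit_sizes) {
    if (n < u * min_units) next
    for (p in 0:(n - u * min_units)) {        # 0-based start
      if (!all(acgt[(p + 1L):(p + u)])) next
      unit <- substr(seq, p + 1L, p + u)
      primitive <- TRUE
      for (d in seq_len(u - 1L)) {
        if (u %% d == 0L && unit == strrep(substr(unit, 1L, d), u %/% d)) {
          primitive <- FALSE
        }
      }
      if (!primitive) next
      cnt <- 1L
      while (p + (cnt + 1L) * u <= n) {
        blk <- (p + cnt * u + 1L):(p + (cnt + 1L) * u)
        if (!all(acgt[blk]) ||
            substr(seq, blk[1], blk[u]) != unit) break
        cnt <- cnt + 1L
      }
      if (cnt < min_units) next
      # leftmost in-phase start: the base just before must break the period
      if (p > 0L && acgt[p] && acgt[p + u] && ch[p] == ch[p + u]) next
      rows[[length(rows) + 1L]] <- data.frame(
        seq_id = "seq", start = p, end = p + cnt * u,
        motif = smallest_rotation(unit), unit_size = u, n_units = cnt,
        stringsAsFactors = FALSE)
    }
  }
  if (length(rows) == 0L) {
    return(data.frame(seq_id = character(), start = integer(),
                      end = integer(), motif = character(),
                      unit_size = integer(), n_units = integer(),
                      stringsAsFactors = FALSE))
  }
  out <- do.call(rbind, rows)
  out <- out[order(out$start, out$unit_size), , drop = FALSE]
  rownames(out) <- NULL
  out
}

# Threshold oracle for SNP calling on one column of base counts.
oracle_snp_call <- function(counts, ref, min_depth, min_alt_freq) {
  bases <- c("A", "C", "G", "T")
  depth <- sum(unlist(counts[bases]))
  if (depth < min_depth) return(NULL)
  best_alt <- NA_character_
  best_n <- -1L
  for (b in bases) {
    if (b == ref) next
    if (counts[[b]] > best_n) {
      best_n <- counts[[b]]
      best_alt <- b
    }
  }
  if (best_n < 1L || best_n / depth < min_alt_freq) return(NULL)
  list(alt = best_alt, depth = depth, alt_count = best_n)
}

# Interval-stabbing depth oracle: reads covering position x (0-based).
oracle_depth_at <- function(placements, ref, x) {
  p <- placements[!is.na(placements$ref_id) & placements$ref_id == ref, ]
  sum(p$pos <= x & x < p$pos + p$length)
}

# Sweep-line union length of 0-based half-open intervals.
oracle_union_len <- function(starts, ends) {
  o <- order(starts)
  starts <- starts[o]; ends <- ends[o]
  total <- 0L
  cur_s <- NA_integer_; cur_e <- NA_integer_
  for (i in seq_along(starts)) {
    if (is.na(cur_s)) {
      cur_s <- starts[i]; cur_e <- ends[i]
    } else if (starts[i] <= cur_e) {
      cur_e <- max(cur_e, ends[i])
    } else {
      total <- total + (cur_e - cur_s)
      cur_s <- starts[i]; cur_e <- ends[i]
    }
  }
  if (!is.na(cur_s)) total <- total + (cur_e - cur_s)
  total
}

# Small default simulation shared by several tests.
tiny_sim <- function(seed = 11L, n_genes = 25L, n_reads = 1500L,
                     base_error_rate = 0, snp_rate = 0.005, ...) {
  cfg <- sim_config(n_genes = n_genes, gene_length_mean = 800,
                    gene_length_sd = 150, min_gene_length = 300,
                    n_reads = n_reads, base_error_rate = base_error_rate,
                    snp_rate = snp_rate, seed = seed, ...)
  list(cfg = cfg, data = simulate_dataset(cfg))
}

# Random ACGT string helper (independent of package internals).
rand_seq <- function(n, alphabet = c("A", "C", "G", "T")) {
  paste(sample(alphabet, n, replace = TRUE), collapse = "")
}

expect_same_loci <- function(a, b) {
  key <- function(d) {
    if (nrow(d) == 0L) return(character(0))
    sort(paste(d$start, d$end, d$motif, d$unit_size, d$n_units))
  }
  expect_identical(key(a), key(b))
}
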