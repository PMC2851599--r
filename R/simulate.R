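# Synthetic transcriptome, marker and read simulation with full ground
# truth, so every downstream stage is testable without external data.
#
# The generator emulates a normalized-cDNA 454 pyrosequencing experiment on
# a conifer: a pool of gene transcripts with CDS+UTR structure, a controlled
# fraction of retroelement-derived and contaminant transcripts, planted SSR
# loci with exact coordinates, biallelic SNPs segregating in an
# 8-chromosome pool (four diploid individuals), and reads with a truncated-
# normal length distribution, per-base phred qualities and substitution
# errors. Every stochastic choice is recorded in a truth table.
#
# Each stage reseeds from `config$seed` plus a fixed stage offset, so any
# stage is individually reproducible and the full pipeline is deterministic.

#' Simulation configuration
#'
#' Defaults describe a half-plate 454 Titanium EST run on a conifer
#' transcriptome: 586,732 reads averaging 306 bp, an assumed gene complement
#' of 25,000 genes of mean length 2,000 bp, and allele frequencies drawn
#' from an 8-chromosome pool. Tests and examples pass smaller `n_genes` /
#' `n_reads`; the distributions are what define the emulated conditions.
#'
#' @param n_genes total number of transcripts in the pool (before origin
#'   labelling), default 25000.
#' @param gene_length_mean,gene_length_sd transcript length distribution
#'   (bp), truncated below at `min_gene_length`; defaults 2000 / 600.
#' @param min_gene_length minimum transcript length (default 300 bp).
#' @param ssr_plant_rate per-transcript probability of one planted SSR
#'   (default 0.3).
#' @param ssr_unit_size_weights probabilities for unit sizes 2/3/4
#'   (default c(`2` = 0.77, `3` = 0.20, `4` = 0.03), the di >> tri > tetra
#'   pattern typical of plant ESTs).
#' @param ssr_repeat_range min/max planted repeat units (default c(4, 12)).
#' @param snp_rate per-bp probability of a planted biallelic site
#'   (default 0.01).
#' @param snp_alt_freq_choices design alternate-allele frequencies, by
#'   default k/8 for k = 1..7 (four diploid individuals).
#' @param retro_fraction proportion of transcripts of retroelement origin
#'   (default 0.05).
#' @param contaminant_fraction proportion of contaminant (e.g. endophytic
#'   fungus) transcripts (default 0.05).
#' @param n_reads number of simulated reads (default 586732).
#' @param read_length_mean,read_length_sd read-length distribution (bp),
#'   truncated to \[50, 600\]; defaults 306 / 75.
#' @param base_error_rate per-base substitution error probability
#'   (default 0.005; an assumption, not a calibration).
#' @param quality_mean,quality_sd per-base phred quality distribution
#'   (default 28 / 6, clamped to \[0, 40\]).
#' @param seed integer RNG seed.
#' @return validated list of class `sim_config`.
#' @export
sim_config <- function(n_genes = 25000L,
                       gene_length_mean = 2000, gene_length_sd = 600,
                       min_gene_length = 300L,
                       ssr_plant_rate = 0.3,
                       ssr_unit_size_weights = c(`2` = 0.77, `3` = 0.20,
                                                 `4` = 0.03),
                       ssr_repeat_range = c(4L, 12L),
                       snp_rate = 0.01,
                       snp_alt_freq_choices = (1:7) / 8,
                       retro_fraction = 0.05,
                       contaminant_fraction = 0.05,
                       n_reads = 586732L,
                       read_length_mean = 306, read_length_sd = 75,
                       base_error_rate = 0.005,
                       quality_mean = 28, quality_sd = 6,
                       seed = 1L) {
  cfg <- list(n_genes = as.integer(n_genes),
              gene_length_mean = gene_length_mean,
              gene_length_sd = gene_length_sd,
              min_gene_length = as.integer(min_gene_length),
              ssr_plant_rate = ssr_plant_rate,
              ssr_unit_size_weights = ssr_unit_size_weights,
              ssr_repeat_range = as.integer(ssr_repeat_range),
              snp_rate = snp_rate,
              snp_alt_freq_choices = snp_alt_freq_choices,
              retro_fraction = retro_fraction,
              contaminant_fraction = contaminant_fraction,
              n_reads = as.integer(n_reads),
              read_length_mean = read_length_mean,
              read_length_sd = read_length_sd,
              base_error_rate = base_error_rate,
              quality_mean = quality_mean, quality_sd = quality_sd,
              seed = as.integer(seed))
  probs <- c(cfg$ssr_plant_rate, cfg$snp_rate, cfg$base_error_rate,
             cfg$retro_fraction, cfg$contaminant_fraction)
  if (any(probs < 0 | probs > 1)) {
    stop("configuration error: probabilities must lie in [0, 1]")
  }
  if (cfg$retro_fraction + cfg$contaminant_fraction >= 1) {
    stop("configuration error: retro + contaminant fractions must be < 1")
  }
  if (any(cfg$snp_alt_freq_choices <= 0 | cfg$snp_alt_freq_choices >= 1)) {
    stop("configuration error: allele frequencies must lie in (0, 1)")
  }
  if (cfg$n_genes < 1L || cfg$n_reads < 0L ||
      cfg$gene_length_mean <= 0 || cfg$gene_length_sd <= 0 ||
      cfg$read_length_mean <= 0 || cfg$read_length_sd <= 0 ||
      cfg$quality_sd < 0) {
    stop("configuration error: distribution parameters must be positive")
  }
  if (abs(sum(cfg$ssr_unit_size_weights) - 1) > 1e-8 ||
      any(cfg$ssr_unit_size_weights < 0)) {
    stop("configuration error: unit-size weights must be a probability vector")
  }
  class(cfg) <- "sim_config"
  cfg
}

#' Read a simulation configuration from YAML
#'
#' @param path YAML file whose keys are [sim_config()] arguments.
#' @return a `sim_config`.
#' @export
read_sim_config <- function(path) {
  args <- yaml::read_yaml(path)
  do.call(sim_config, args)
}

rtrunc_norm <- function(n, mean, sd, lower, upper = Inf) {
  out <- numeric(0)
  while (length(out) < n) {
    x <- stats::rnorm(n - length(out), mean, sd)
    out <- c(out, x[x >= lower & x <= upper])
  }
  out
}

# A synthetic stand-in for a panel of complete plant retroelement sequences
# (copia/gypsy-like); random sequences are adequate because downstream
# screening only requires shared subsequence identity with derived reads.
synthetic_retro_library <- function(n_elements = 17L, element_length = 5000L) {
  nm <- sprintf("retroelement_%02d", seq_len(n_elements))
  nm[seq_len(min(3L, n_elements))] <-
    c("IFG7_like", "Gymny_like", "PpRT1_like")[seq_len(min(3L, n_elements))]
  stats::setNames(
    vapply(seq_len(n_elements), function(i) random_dna(element_length), ""),
    nm)
}

#' Generate a transcript pool with origin labels
#'
#' Origin counts are exact proportions: `round(n_genes * retro_fraction)`
#' retroelement transcripts and `round(n_genes * contaminant_fraction)`
#' contaminants; the remainder are genes. Gene transcripts carry a CDS
#' interval (central ~70% of the transcript, flanked by UTRs). Retroelement
#' transcripts are substrings of elements from a synthetic retro library so
#' that similarity screening can rediscover them.
#'
#' @param config a [sim_config()].
#' @return list of class `sim_transcriptome`: `transcripts` (data.frame
#'   id/origin/length/cds_start/cds_end), `seqs` (named character vector),
#'   `retro_library` (named character vector), and an empty `truth` skeleton.
#' @export
generate_transcriptome <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  n <- config$n_genes
  n_retro <- round(n * config$retro_fraction)
  n_contam <- round(n * config$contaminant_fraction)
  n_gene <- n - n_retro - n_contam
  origin <- c(rep("gene", n_gene), rep("retroelement", n_retro),
              rep("contaminant", n_contam))
  lens <- as.integer(round(rtrunc_norm(n, config$gene_length_mean,
                                       config$gene_length_sd,
                                       config$min_gene_length)))
  ids <- sprintf("t%05d", seq_len(n))
  lib <- synthetic_retro_library()
  seqs <- character(n)
  cds_start <- rep(NA_integer_, n)
  cds_end <- rep(NA_integer_, n)
  for (i in seq_len(n)) {
    if (origin[i] == "retroelement") {
      el <- lib[[sample.int(length(lib), 1L)]]
      L <- min(lens[i], nchar(el))
      lens[i] <- L
      s0 <- sample.int(nchar(el) - L + 1L, 1L)
      seqs[i] <- substr(el, s0, s0 + L - 1L)
    } else {
      seqs[i] <- random_dna(lens[i])
      if (origin[i] == "gene") {
        utr5 <- as.integer(round(0.15 * lens[i]))
        cds_len <- as.integer(round(0.70 * lens[i]))
        cds_start[i] <- utr5
        cds_end[i] <- min(lens[i], utr5 + cds_len)
      }
    }
  }
  out <- list(
    transcripts = data.frame(id = ids, origin = origin, length = lens,
                             cds_start = cds_start, cds_end = cds_end,
                             stringsAsFactors = FALSE),
    seqs = stats::setNames(seqs, ids),
    retro_library = lib,
    truth = list(planted_ssrs = NULL, planted_snps = NULL,
                 read_origins = NULL, retro_read_ids = character(0)))
  class(out) <- "sim_transcriptome"
  out
}

#' @export
print.sim_transcriptome <- function(x, ...) {
  cat(sprintf("sim_transcriptome: %d transcripts (%s)\n",
              nrow(x$transcripts),
              paste(sprintf("%d %s", table(x$transcripts$origin),
                            names(table(x$transcripts$origin))),
                    collapse = ", ")))
  invisible(x)
}

random_primitive_motif <- function(unit_size) {
  repeat {
    m <- random_dna(unit_size)
    if (is_primitive_unit(m)) return(m)
  }
}

# overwrite a window of the transcript with guard + run + guard; guard bases
# are chosen to differ from the in-phase motif base so the planted run can
# neither extend nor merge with flanking sequence
plant_one_ssr <- function(seq, motif, n_units) {
  u <- nchar(motif)
  run <- strrep(motif, n_units)
  need <- nchar(run) + 2L
  if (nchar(seq) < need + 2L) return(NULL)
  pos <- sample.int(nchar(seq) - need + 1L, 1L)  # 1-based guard position
  left_guard <- setdiff(DNA_BASES, substr(motif, u, u))[1]
  right_guard <- setdiff(DNA_BASES, substr(motif, 1L, 1L))[1]
  new_seq <- paste0(substr(seq, 1L, pos - 1L), left_guard, run, right_guard,
                    substr(seq, pos + need, nchar(seq)))
  list(seq = new_seq, start = pos, end = pos + nchar(run))  # 0-based run ivl
}

#' Plant SSR runs into transcripts
#'
#' Each transcript receives one planted SSR with probability
#' `ssr_plant_rate`. The run replaces a window of equal length (transcript
#' length and CDS coordinates are unchanged) and is bracketed by guard bases
#' that differ from the in-phase motif base, so truth coordinates are exact
#' and the run cannot extend. Optionally plants oversized filter-test runs.
#'
#' @param sim a `sim_transcriptome`.
#' @param config the [sim_config()].
#' @param long_run_units optional integer: additionally plant, in this many
#'   randomly chosen transcripts, a dinucleotide run of this many units
#'   (e.g. 26 units = 52 bp) flagged `long_run = TRUE`, as long-SSR
#'   filter-test cases. Default `NULL` (none).
#' @param n_long_runs number of long-run transcripts (default 0).
#' @return the `sim_transcriptome` with modified `seqs` and
#'   `truth$planted_ssrs` (seq_id, start, end, motif, unit_size, n_units,
#'   long_run).
#' @export
plant_ssrs <- function(sim, config, long_run_units = NULL, n_long_runs = 0L) {
  stopifnot(inherits(sim, "sim_transcriptome"))
  set.seed(config$seed + 1L)
  if (config$ssr_repeat_range[1] < 4L) {
    stop("planted repeat counts must be >= 4 units")
  }
  rows <- list()
  usizes <- as.integer(names(config$ssr_unit_size_weights))
  for (i in seq_len(nrow(sim$transcripts))) {
    if (stats::runif(1) > config$ssr_plant_rate) next
    id <- sim$transcripts$id[i]
    u <- sample(usizes, 1L, prob = config$ssr_unit_size_weights)
    n_units <- sample(seq.int(config$ssr_repeat_range[1],
                              config$ssr_repeat_range[2]), 1L)
    if (u * n_units >= 50L) n_units <- 49L %/% u   # detectable class < 50 bp
    motif <- random_primitive_motif(u)
    res <- plant_one_ssr(sim$seqs[[id]], motif, n_units)
    if (is.null(res)) next
    sim$seqs[[id]] <- res$seq
    rows[[length(rows) + 1L]] <- data.frame(
      seq_id = id, start = res$start, end = res$end,
      motif = canonical_motif(motif), unit_size = u, n_units = n_units,
      long_run = FALSE, stringsAsFactors = FALSE)
  }
  if (!is.null(long_run_units) && n_long_runs > 0L) {
    planted_ids <- vapply(rows, function(r) r$seq_id, "")
    cand <- setdiff(sim$transcripts$id, planted_ids)
    pick <- sample(cand, min(n_long_runs, length(cand)))
    for (id in pick) {
      motif <- random_primitive_motif(2L)
      res <- plant_one_ssr(sim$seqs[[id]], motif, long_run_units)
      if (is.null(res)) next
      sim$seqs[[id]] <- res$seq
      rows[[length(rows) + 1L]] <- data.frame(
        seq_id = id, start = res$start, end = res$end,
        motif = canonical_motif(motif), unit_size = 2L,
        n_units = as.integer(long_run_units), long_run = TRUE,
        stringsAsFactors = FALSE)
    }
  }
  sim$truth$planted_ssrs <- if (length(rows)) do.call(rbind, rows) else
    data.frame(seq_id = character(), start = integer(), end = integer(),
               motif = character(), unit_size = integer(),
               n_units = integer(), long_run = logical(),
               stringsAsFactors = FALSE)
  sim
}

#' Plant biallelic SNPs segregating in an 8-chromosome pool
#'
#' Sites are chosen per bp with probability `snp_rate`; each receives an
#' alternate allele carried by `round(8 * f)` of the 8 pooled chromosomes,
#' where the design frequency f is drawn from `snp_alt_freq_choices`. Reads
#' later drawn from a random chromosome carry the alternate allele with
#' probability equal to the design frequency.
#'
#' @param sim a `sim_transcriptome`.
#' @param config the [sim_config()].
#' @param n_chromosomes pool size (default 8 = four diploids).
#' @return the `sim_transcriptome` with `truth$planted_snps` (seq_id, pos
#'   0-based, ref, alt, design_freq, n_alt_chrom).
#' @export
plant_variants <- function(sim, config, n_chromosomes = 8L) {
  stopifnot(inherits(sim, "sim_transcriptome"))
  if (any(config$snp_alt_freq_choices <= 0 | config$snp_alt_freq_choices >= 1)) {
    stop("configuration error: design frequencies must lie in (0, 1)")
  }
  set.seed(config$seed + 2L)
  # avoid planting inside planted SSR runs (keeps both truths exact)
  ssr_iv <- sim$truth$planted_ssrs
  rows <- list()
  for (i in seq_len(nrow(sim$transcripts))) {
    id <- sim$transcripts$id[i]
    L <- nchar(sim$seqs[[id]])
    n_sites <- stats::rbinom(1L, L, config$snp_rate)
    if (n_sites == 0L) next
    pos <- sort(sample.int(L, n_sites)) - 1L   # 0-based
    if (!is.null(ssr_iv) && nrow(ssr_iv)) {
      iv <- ssr_iv[ssr_iv$seq_id == id, , drop = FALSE]
      if (nrow(iv)) {
        inside <- vapply(pos, function(p) {
          any(p >= iv$start - 1L & p <= iv$end)
        }, logical(1))
        pos <- pos[!inside]
      }
    }
    if (length(pos) == 0L) next
    ref <- substring(sim$seqs[[id]], pos + 1L, pos + 1L)
    alt <- vapply(ref, function(r) sample(setdiff(DNA_BASES, r), 1L), "",
                  USE.NAMES = FALSE)
    freq <- sample(config$snp_alt_freq_choices, length(pos), replace = TRUE)
    rows[[length(rows) + 1L]] <- data.frame(
      seq_id = id, pos = pos, ref = ref, alt = alt, design_freq = freq,
      n_alt_chrom = as.integer(round(n_chromosomes * freq)),
      stringsAsFactors = FALSE)
  }
  snps <- if (length(rows)) do.call(rbind, rows) else
    data.frame(seq_id = character(), pos = integer(), ref = character(),
               alt = character(), design_freq = numeric(),
               n_alt_chrom = integer(), stringsAsFactors = FALSE)
  rownames(snps) <- NULL
  sim$truth$planted_snps <- snps
  sim$truth$n_chromosomes <- as.integer(n_chromosomes)
  sim
}

#' Simulate 454-style reads from the transcript pool
#'
#' Reads are drawn from transcripts with probability proportional to
#' transcript length (uniform per-bp sampling; expression-level modelling is
#' out of scope), from a uniformly chosen pool chromosome, on either strand
#' with probability 1/2. Read lengths follow the truncated-normal
#' distribution, additionally truncated at the source transcript length
#' (recorded). Substitution errors occur per base at `base_error_rate`;
#' qualities are integer N(quality_mean, quality_sd) clamped to \[0, 40\].
#'
#' @param sim a `sim_transcriptome` after [plant_variants()].
#' @param config the [sim_config()].
#' @return list: `reads` (a [read_set()]) and `sim` (with
#'   `truth$read_origins` -- read_id, seq_id, offset, strand, length,
#'   chromosome, truncated -- and `truth$retro_read_ids` filled in).
#' @export
simulate_reads <- function(sim, config) {
  stopifnot(inherits(sim, "sim_transcriptome"))
  if (nrow(sim$transcripts) == 0L) stop("transcript pool is empty")
  set.seed(config$seed + 3L)
  n <- config$n_reads
  n_chrom <- if (!is.null(sim$truth$n_chromosomes)) sim$truth$n_chromosomes
    else 8L
  tl <- nchar(sim$seqs)
  t_idx <- sample.int(length(tl), n, replace = TRUE, prob = tl)
  want_len <- as.integer(round(rtrunc_norm(n, config$read_length_mean,
                                           config$read_length_sd, 50, 600)))
  chrom <- sample.int(n_chrom, n, replace = TRUE)
  strand <- ifelse(stats::runif(n) < 0.5, "+", "-")
  snps <- sim$truth$planted_snps
  snps_by_t <- if (!is.null(snps) && nrow(snps)) split(snps, snps$seq_id)
    else list()
  ids <- sprintf("read%06d", seq_len(n))
  seqs <- character(n)
  quals <- vector("list", n)
  truncated <- logical(n)
  offset <- integer(n)
  rlen <- integer(n)
  for (r in seq_len(n)) {
    ti <- t_idx[r]
    tid <- names(tl)[ti]
    L <- min(want_len[r], tl[ti])
    truncated[r] <- L < want_len[r]
    s0 <- sample.int(tl[ti] - L + 1L, 1L) - 1L     # 0-based offset
    frag <- substr(sim$seqs[[ti]], s0 + 1L, s0 + L)
    sn <- snps_by_t[[tid]]
    if (!is.null(sn)) {
      here <- sn[sn$pos >= s0 & sn$pos < s0 + L & chrom[r] <= sn$n_alt_chrom, ,
                 drop = FALSE]
      if (nrow(here)) {
        fr <- strsplit(frag, "", fixed = TRUE)[[1]]
        fr[here$pos - s0 + 1L] <- here$alt
        frag <- paste(fr, collapse = "")
      }
    }
    if (config$base_error_rate > 0) {
      err <- which(stats::runif(L) < config$base_error_rate)
      if (length(err)) {
        fr <- strsplit(frag, "", fixed = TRUE)[[1]]
        fr[err] <- vapply(fr[err],
                          function(b) sample(setdiff(DNA_BASES, b), 1L), "",
                          USE.NAMES = FALSE)
        frag <- paste(fr, collapse = "")
      }
    }
    seqs[r] <- frag
    quals[[r]] <- pmax(0L, pmin(40L, as.integer(round(
      stats::rnorm(L, config$quality_mean, config$quality_sd)))))
    offset[r] <- s0
    rlen[r] <- L
  }
  neg <- strand == "-"
  if (any(neg)) seqs[neg] <- revcomp(seqs[neg])
  origins <- data.frame(read_id = ids, seq_id = names(tl)[t_idx],
                        offset = offset, strand = strand, length = rlen,
                        chromosome = chrom, truncated = truncated,
                        stringsAsFactors = FALSE)
  sim$truth$read_origins <- origins
  retro_ids <- sim$transcripts$id[sim$transcripts$origin == "retroelement"]
  sim$truth$retro_read_ids <- origins$read_id[origins$seq_id %in% retro_ids]
  list(reads = read_set(ids, seqs, quals), sim = sim)
}

#' Fabricate a similarity-search annotation table with known truth
#'
#' Stands in for the tabular output of a protein similarity search over the
#' transcript pool. Gene-origin transcripts receive a hit with probability
#' given by a logistic function of transcript length (so hit-vs-length
#' models can be exercised); retroelement-origin transcripts receive
#' retroelement-keyword descriptions with probability `retro_desc_prob`.
#'
#' @param sim a `sim_transcriptome`.
#' @param config the [sim_config()].
#' @param hit_intercept,hit_slope logistic parameters for P(hit | length)
#'   (defaults -4 and 0.006 per bp).
#' @param retro_desc_prob probability a retro transcript's hit carries a
#'   retro keyword description (default 0.9).
#' @param taxon_weights named probability vector over taxon labels for
#'   gene-origin hits.
#' @return list: `table` (15-column hit table data.frame) and `truth`
#'   (data.frame of per-transcript hit flags and planted taxon/keyword
#'   labels).
#' @export
fabricate_annotation_table <- function(sim, config,
                                       hit_intercept = -4, hit_slope = 0.006,
                                       retro_desc_prob = 0.9,
                                       taxon_weights = c(Pinus = 0.10,
                                                         Arabidopsis = 0.53,
                                                         Drosophila = 0.09,
                                                         Fusarium = 0.10,
                                                         Homo = 0.14,
                                                         Escherichia = 0.04)) {
  stopifnot(inherits(sim, "sim_transcriptome"))
  set.seed(config$seed + 4L)
  tr <- sim$transcripts
  rows <- list()
  truth_rows <- list()
  for (i in seq_len(nrow(tr))) {
    id <- tr$id[i]
    L <- tr$length[i]
    if (tr$origin[i] == "contaminant") {
      truth_rows[[length(truth_rows) + 1L]] <- data.frame(
        seq_id = id, has_hit = FALSE, taxon = NA_character_,
        retro_desc = FALSE, stringsAsFactors = FALSE)
      next
    }
    p_hit <- stats::plogis(hit_intercept + hit_slope * L)
    has_hit <- stats::runif(1) < p_hit
    retro_desc <- FALSE
    taxon <- NA_character_
    if (has_hit) {
      acc <- sprintf("UP%05d", i)
      if (tr$origin[i] == "retroelement") {
        retro_desc <- stats::runif(1) < retro_desc_prob
        desc <- if (retro_desc) {
          sample(c("Ty1-copia retrotransposon polyprotein",
                   "putative reverse transcriptase",
                   "gag-pol polyprotein", "putative integrase",
                   "retroelement pol polyprotein"), 1L)
        } else "hypothetical protein"
        taxon <- "Pinus"
      } else {
        desc <- sprintf("hypothetical protein g%d", i)
        taxon <- sample(names(taxon_weights), 1L, prob = taxon_weights)
      }
      slen <- max(50L, as.integer(round(L * 0.7 / 3)))
      s_cov <- as.integer(round(slen * stats::runif(1, 0.4, 1.0)))
      sstart <- sample.int(slen - s_cov + 1L, 1L) - 1L
      rows[[length(rows) + 1L]] <- data.frame(
        query_id = id, subject_acc = acc,
        pident = round(stats::runif(1, 60, 99), 2), aln_length = s_cov,
        mismatch = 0L, gapopen = 0L,
        qstart = 0L, qend = min(L, 3L * s_cov),
        sstart = sstart, send = sstart + s_cov,
        evalue = 10^(-stats::runif(1, 7, 40)), bitscore = round(stats::runif(1, 60, 400), 1),
        subject_len = slen, taxon = taxon, description = desc,
        stringsAsFactors = FALSE)
    }
    truth_rows[[length(truth_rows) + 1L]] <- data.frame(
      seq_id = id, has_hit = has_hit, taxon = taxon,
      retro_desc = retro_desc, stringsAsFactors = FALSE)
  }
  table <- if (length(rows)) do.call(rbind, rows) else NULL
  truth <- do.call(rbind, truth_rows)
  rownames(truth) <- NULL
  list(table = table, truth = truth)
}

#' Fabricate gene-ontology assignments with chosen namespace proportions
#'
#' @param n_terms total number of GO term assignments.
#' @param proportions named probabilities over the three namespaces.
#' @param n_genes number of distinct gene ids to spread terms over.
#' @param seed RNG seed.
#' @return data.frame `query_id`, `go_id`, `namespace`.
#' @export
fabricate_go_assignments <- function(n_terms,
                                     proportions = c(molecular_function = 0.562,
                                                     biological_process = 0.253,
                                                     cellular_component = 0.185),
                                     n_genes = max(1L, n_terms %/% 4L),
                                     seed = 1L) {
  set.seed(seed)
  ns <- sample(names(proportions), n_terms, replace = TRUE,
               prob = proportions)
  data.frame(query_id = sprintf("g%05d", sample.int(n_genes, n_terms,
                                                    replace = TRUE)),
             go_id = sprintf("GO:%07d", sample.int(9999999L, n_terms)),
             namespace = ns, stringsAsFactors = FALSE)
}

#' Run the full simulation pipeline
#'
#' Convenience wrapper: transcriptome, SSR planting, variant planting, read
#' simulation. Deterministic given the config (stage-wise reseeding from
#' `config$seed`).
#'
#' @param config a [sim_config()].
#' @param long_run_units,n_long_runs passed to [plant_ssrs()].
#' @return list with `sim` (truth-complete `sim_transcriptome`) and `reads`
#'   (a [read_set()]).
#' @export
simulate_dataset <- function(config, long_run_units = NULL,
                             n_long_runs = 0L) {
  sim <- generate_transcriptome(config)
  sim <- plant_ssrs(sim, config, long_run_units = long_run_units,
                    n_long_runs = n_long_runs)
  sim <- plant_variants(sim, config)
  res <- simulate_reads(sim, config)
  list(sim = res$sim, reads = res$reads)
}

#' Write simulator truth tables as TSV files
#'
#' Emits `read_origins.tsv`, `planted_ssrs.tsv`, `planted_snps.tsv` and
#' `retro_read_ids.tsv` under `dir` (documented headers, 0-based
#' coordinates).
#'
#' @param sim a truth-complete `sim_transcriptome`.
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_truth_tables <- function(sim, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  w <- function(df, name) {
    utils::write.table(df, file.path(dir, name), sep = "\t", quote = FALSE,
                       row.names = FALSE)
  }
  w(sim$truth$read_origins, "read_origins.tsv")
  w(sim$truth$planted_ssrs, "planted_ssrs.tsv")
  w(sim$truth$planted_snps, "planted_snps.tsv")
  w(data.frame(read_id = sim$truth$retro_read_ids), "retro_read_ids.tsv")
  invisible(dir)
}
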