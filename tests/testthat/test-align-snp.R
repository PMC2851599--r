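# Read placement, pileups and SNP calling.

test_that("exact substrings place at their true offset with 0 mismatches", {
  set.seed(51)
  refs <- c(ref1 = rand_seq(600), ref2 = rand_seq(500))
  reads <- c(a = substr(refs[["ref1"]], 101, 300),
             b = substr(refs[["ref2"]], 51, 250),
             c = revcomp(substr(refs[["ref1"]], 201, 400)),
             junk = rand_seq(200))
  pl <- map_reads(reads, refs)
  expect_equal(pl$pos[pl$read_id == "a"], 100L)
  expect_equal(pl$n_mismatch[pl$read_id == "a"], 0L)
  expect_equal(pl$ref_id[pl$read_id == "b"], "ref2")
  expect_equal(pl$strand[pl$read_id == "c"], "-")
  expect_equal(pl$pos[pl$read_id == "c"], 200L)
  expect_equal(pl$strand[pl$read_id == "junk"], "*")
  # reads shorter than k are unmapped
  short <- map_reads(c(s = "ACGTACGT"), refs)
  expect_true(is.na(short$ref_id))
})

test_that("simulated reads place at their recorded origins", {
  ts <- tiny_sim(seed = 31, n_genes = 20, n_reads = 600)
  pl <- map_reads(ts$data$reads, ts$data$sim$seqs)
  tr <- ts$data$sim$truth$read_origins
  m <- merge(pl, tr, by = "read_id")
  placed <- !is.na(m$ref_id)
  expect_gt(mean(placed), 0.95)
  expect_true(all(m$ref_id[placed] == m$seq_id[placed]))
  expect_true(all(m$pos[placed] == m$offset[placed]))
  expect_true(all(m$strand.x[placed] == m$strand.y[placed]))
})

test_that("pileup depth equals the interval-stabbing oracle", {
  set.seed(53)
  refs <- c(r = rand_seq(400))
  # staggered synthetic placements
  pl <- data.frame(read_id = sprintf("x%d", 1:30),
                   ref_id = "r",
                   pos = sample(0:250, 30, replace = TRUE),
                   strand = "+", stringsAsFactors = FALSE)
  pl$length <- sample(50:150, 30, replace = TRUE)
  pl$n_mismatch <- 0L
  pl$seq <- substring(refs[["r"]], pl$pos + 1L, pl$pos + pl$length)
  pu <- build_pileup(pl, refs)$r
  for (x in sample(0:399, 40)) {
    want <- oracle_depth_at(pl, "r", x)
    got <- if (x %in% pu$pos) pu$depth[pu$pos == x] else 0L
    expect_equal(got, want)
  }
  # conservation: total depth equals total aligned length
  expect_equal(sum(pu$depth), sum(pl$length))
  # two identical reads -> constant depth 2
  two <- pl[c(1, 1), ]; two$read_id <- c("a", "b")
  pu2 <- build_pileup(two, refs)$r
  expect_true(all(pu2$depth == 2L))
  # no placements -> empty pileup
  expect_length(build_pileup(pl[0, ], refs), 0L)
})

test_that("SNP calls equal the threshold oracle on random columns", {
  set.seed(57)
  n <- 4000
  cm <- matrix(rpois(4 * n, 3), ncol = 4,
               dimnames = list(NULL, c("A", "C", "G", "T")))
  refb <- sample(c("A", "C", "G", "T"), n, replace = TRUE)
  pu <- data.frame(pos = seq_len(n) - 1L, ref_base = refb,
                   A = cm[, "A"], C = cm[, "C"], G = cm[, "G"],
                   T = cm[, "T"], N = 0L,
                   depth = rowSums(cm), stringsAsFactors = FALSE)
  for (preset in list(c(8, 0.20), c(10, 0.20), c(4, 0.35))) {
    calls <- call_snps(pu, min_depth = preset[1], min_alt_freq = preset[2],
                       ref_id = "r")
    want_pos <- integer(0); want_alt <- character(0)
    for (i in seq_len(n)) {
      o <- oracle_snp_call(as.list(pu[i, c("A", "C", "G", "T")]), refb[i],
                           preset[1], preset[2])
      if (!is.null(o)) {
        want_pos <- c(want_pos, i - 1L)
        want_alt <- c(want_alt, o$alt)
      }
    }
    expect_equal(calls$pos, want_pos)
    expect_equal(calls$alt, want_alt)
  }
})

test_that("frequency and depth boundaries are inclusive", {
  pu <- data.frame(pos = 0:1, ref_base = c("A", "A"),
                   A = c(8L, 6L), C = c(2L, 1L), G = 0L, T = 0L, N = 0L,
                   depth = c(10L, 7L), stringsAsFactors = FALSE)
  calls <- call_snps(pu, min_depth = 10, min_alt_freq = 0.20, ref_id = "r")
  # depth 10, alt 2/10 = exactly 20% -> called
  expect_equal(calls$pos, 0L)
  expect_equal(calls$alt_freq, 0.2)
  # depth 7 under min_depth 8 -> not called
  calls8 <- call_snps(pu, min_depth = 8, min_alt_freq = 0.20, ref_id = "r")
  expect_false(1L %in% calls8$pos)
})

test_that("planted SNPs are recovered exactly on error-free reads", {
  ts <- tiny_sim(seed = 42, n_genes = 30, n_reads = 2500)
  d <- ts$data
  pl <- map_reads(d$reads, d$sim$seqs)
  pu <- build_pileup(pl, d$sim$seqs)
  calls <- call_snps(pu, min_depth = 8, min_alt_freq = 0.20)
  truth <- d$sim$truth$planted_snps
  tkey <- paste(truth$seq_id, truth$pos)
  ckey <- paste(calls$ref_id, calls$pos)
  # no calls at non-planted sites
  expect_length(setdiff(ckey, tkey), 0L)
  # every eligible site (realized depth and alt frequency over threshold)
  # is called with the planted alleles
  n_elig <- 0L
  for (i in seq_len(nrow(truth))) {
    p <- pu[[truth$seq_id[i]]]
    row <- p[p$pos == truth$pos[i], , drop = FALSE]
    if (nrow(row) == 0L) next
    dep <- row$A + row$C + row$G + row$T
    altn <- row[[truth$alt[i]]]
    if (dep >= 8 && altn / dep >= 0.20) {
      n_elig <- n_elig + 1L
      j <- which(calls$ref_id == truth$seq_id[i] & calls$pos == truth$pos[i])
      expect_length(j, 1L)
      expect_equal(calls$ref[j], truth$ref[i])
      expect_equal(calls$alt[j], truth$alt[i])
    }
  }
  expect_gt(n_elig, 20L)
})

test_that("tightening thresholds never enlarges the call set", {
  ts <- tiny_sim(seed = 43, n_genes = 20, n_reads = 1500,
                 base_error_rate = 0.01)
  d <- ts$data
  pu <- build_pileup(map_reads(d$reads, d$sim$seqs), d$sim$seqs)
  key <- function(calls) paste(calls$ref_id, calls$pos)
  loose <- key(call_snps(pu, min_depth = 6, min_alt_freq = 0.15))
  tight_d <- key(call_snps(pu, min_depth = 10, min_alt_freq = 0.15))
  tight_f <- key(call_snps(pu, min_depth = 6, min_alt_freq = 0.30))
  expect_true(all(tight_d %in% loose))
  expect_true(all(tight_f %in% loose))
})

test_that("SNP rate and contig read filter reproduce their contracts", {
  expect_equal(snp_rate(301, 27496), 1.1)
  expect_equal(snp_rate(3707, 614125), 0.6)
  expect_equal(snp_rate(0, 1e6), 0)
  expect_error(snp_rate(10, 0), "positive")
  rc <- c(c1 = 21L, c2 = 20L, c3 = 500L)
  expect_setequal(contig_read_filter(rc, 20), c("c1", "c3"))
})

test_that("alternate-allele frequencies track the 8-chromosome design", {
  # design frequency 0.5: observed alt fraction within 3 binomial SD
  cfg <- sim_config(n_genes = 1, gene_length_mean = 500, gene_length_sd = 1,
                    min_gene_length = 400, ssr_plant_rate = 0,
                    snp_rate = 0, retro_fraction = 0,
                    contaminant_fraction = 0, n_reads = 4000,
                    base_error_rate = 0, read_length_mean = 300,
                    read_length_sd = 20, seed = 7)
  sim <- generate_transcriptome(cfg)
  sim <- plant_ssrs(sim, cfg)
  sim <- plant_variants(sim, cfg)
  # plant one site manually at known frequency 4/8
  id <- sim$transcripts$id[1]
  ref <- substr(sim$seqs[[id]], 251, 251)
  alt <- setdiff(c("A", "C", "G", "T"), ref)[1]
  sim$truth$planted_snps <- data.frame(
    seq_id = id, pos = 250L, ref = ref, alt = alt, design_freq = 0.5,
    n_alt_chrom = 4L, stringsAsFactors = FALSE)
  res <- simulate_reads(sim, cfg)
  pl <- map_reads(res$reads, sim$seqs)
  pu <- build_pileup(pl, sim$seqs)[[id]]
  row <- pu[pu$pos == 250L, ]
  dep <- row$A + row$C + row$G + row$T
  frac <- row[[alt]] / dep
  expect_gt(dep, 1000)
  expect_lt(abs(frac - 0.5), 3 * sqrt(0.25 / dep))
  # error-free: no third allele at the site
  others <- setdiff(c("A", "C", "G", "T"), c(ref, alt))
  expect_equal(sum(unlist(row[others])), 0L)
})

test_that("design frequencies outside (0,1) are rejected", {
  expect_error(sim_config(snp_alt_freq_choices = c(0, 0.5)),
               "frequencies")
  expect_error(sim_config(snp_alt_freq_choices = 1), "frequencies")
})
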