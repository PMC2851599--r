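# Synthetic-data generator: determinism, conservation, distributions.

test_that("origin fractions are applied as exact proportions", {
  cfg <- sim_config(n_genes = 10, retro_fraction = 0, contaminant_fraction = 0,
                    n_reads = 0, seed = 1)
  sim <- generate_transcriptome(cfg)
  expect_equal(nrow(sim$transcripts), 10L)
  expect_true(all(sim$transcripts$origin == "gene"))

  cfg2 <- sim_config(n_genes = 100, retro_fraction = 0.1,
                     contaminant_fraction = 0, n_reads = 0, seed = 7)
  sim2 <- generate_transcriptome(cfg2)
  expect_equal(sum(sim2$transcripts$origin == "retroelement"), 10L)
})

test_that("identical config and seed give byte-identical FASTA and FASTQ", {
  cfg <- sim_config(n_genes = 15, gene_length_mean = 600,
                    gene_length_sd = 100, n_reads = 200, seed = 13)
  d1 <- simulate_dataset(cfg)
  d2 <- simulate_dataset(cfg)
  f1 <- tempfile(fileext = ".fa"); f2 <- tempfile(fileext = ".fa")
  write_fasta(d1$sim$seqs, f1); write_fasta(d2$sim$seqs, f2)
  expect_identical(readLines(f1), readLines(f2))
  q1 <- tempfile(fileext = ".fq"); q2 <- tempfile(fileext = ".fq")
  write_fastq(d1$reads, q1); write_fastq(d2$reads, q2)
  expect_identical(readLines(q1), readLines(q2))
  unlink(c(f1, f2, q1, q2))
})

test_that("every read has exactly one origin record", {
  ts <- tiny_sim(seed = 23, n_genes = 15, n_reads = 300)
  org <- ts$data$sim$truth$read_origins
  expect_equal(nrow(org), 300L)
  expect_setequal(org$read_id, ts$data$reads$id)
  expect_false(anyDuplicated(org$read_id) > 0)
  # planted SNP positions lie inside their transcripts
  snp <- ts$data$sim$truth$planted_snps
  tl <- nchar(ts$data$sim$seqs)
  expect_true(all(snp$pos >= 0 & snp$pos < tl[snp$seq_id]))
  expect_true(all(snp$design_freq > 0 & snp$design_freq < 1))
})

test_that("read lengths track the configured truncated normal", {
  cfg <- sim_config(n_genes = 10, gene_length_mean = 3000,
                    gene_length_sd = 200, min_gene_length = 2000,
                    n_reads = 1000, read_length_mean = 306,
                    read_length_sd = 60, seed = 3, ssr_plant_rate = 0,
                    snp_rate = 0, retro_fraction = 0,
                    contaminant_fraction = 0)
  d <- simulate_dataset(cfg)
  lens <- nchar(d$reads$seq)
  expect_lt(abs(mean(lens) - 306), 3 * 60 / sqrt(1000))
  expect_true(all(lens >= 50 & lens <= 600))
})

test_that("error-free reads without variants are exact substrings of their
           source", {
  ts <- tiny_sim(seed = 29, n_genes = 10, n_reads = 150, snp_rate = 0)
  d <- ts$data
  org <- d$sim$truth$read_origins
  for (i in sample(nrow(org), 50)) {
    src <- d$sim$seqs[[org$seq_id[i]]]
    frag <- substr(src, org$offset[i] + 1L, org$offset[i] + org$length[i])
    read <- d$reads$seq[d$reads$id == org$read_id[i]]
    if (org$strand[i] == "-") read <- revcomp(read)
    expect_identical(read, frag)
  }
})

test_that("quality model drives the expected sub-threshold fraction", {
  # mean quality 17 with sd 2: the QC threshold of 18 should discard about
  # the fraction predicted by simulating the quality model itself
  cfg <- sim_config(n_genes = 10, n_reads = 600, quality_mean = 17,
                    quality_sd = 2, ssr_plant_rate = 0, snp_rate = 0,
                    retro_fraction = 0, contaminant_fraction = 0, seed = 37)
  d <- simulate_dataset(cfg)
  res <- qc_filter(d$reads)
  frac <- res$report$n_discarded_quality / res$report$n_input
  # independent expectation: mean of 300 iid clamped normals, sd ~ 2/sqrt(L)
  set.seed(99)
  sim_frac <- mean(replicate(2000, {
    L <- 306
    mean(pmax(0, pmin(40, round(rnorm(L, 17, 2))))) < 18
  }))
  se <- sqrt(sim_frac * (1 - sim_frac) / 600 + sim_frac * (1 - sim_frac) / 2000)
  expect_lt(abs(frac - sim_frac), 3 * max(se, 0.02))
})

test_that("planted long runs are discarded by QC when fully contained", {
  cfg <- sim_config(n_genes = 12, gene_length_mean = 700,
                    gene_length_sd = 100, ssr_plant_rate = 0, snp_rate = 0,
                    retro_fraction = 0, contaminant_fraction = 0,
                    base_error_rate = 0, n_reads = 600,
                    read_length_mean = 306, read_length_sd = 40, seed = 41)
  d <- simulate_dataset(cfg, long_run_units = 26, n_long_runs = 3)
  lr <- d$sim$truth$planted_ssrs
  lr <- lr[lr$long_run, ]
  expect_gt(nrow(lr), 0L)
  org <- d$sim$truth$read_origins
  res <- qc_filter(d$reads)
  # every read fully containing a planted 52 bp run is discarded as long_ssr
  for (i in seq_len(nrow(lr))) {
    inside <- org$seq_id == lr$seq_id[i] &
      org$offset <= lr$start[i] - 1L &
      org$offset + org$length >= lr$end[i] + 1L
    ids <- org$read_id[inside]
    if (length(ids)) {
      expect_true(all(res$reason[ids] == "long_ssr"))
    }
  }
})

test_that("fabricated annotation tables round-trip and carry planted truth", {
  ts <- tiny_sim(seed = 43, n_genes = 30, n_reads = 0)
  fab <- fabricate_annotation_table(ts$data$sim, ts$cfg)
  expect_equal(sort(fab$table$query_id),
               sort(fab$truth$seq_id[fab$truth$has_hit]))
  # contaminants never receive hits
  contam <- ts$data$sim$transcripts$id[
    ts$data$sim$transcripts$origin == "contaminant"]
  expect_false(any(fab$table$query_id %in% contam))
  # 15-column file round-trip preserves records
  f <- tempfile(fileext = ".tsv")
  write_hit_table(fab$table, f)
  back <- read_hit_table(f)
  expect_equal(nrow(back), nrow(fab$table))
  expect_equal(back$query_id, fab$table$query_id)
  expect_equal(back$evalue, fab$table$evalue, tolerance = 1e-6)
  expect_equal(back$description, fab$table$description)
  unlink(f)
  # keyword-bearing descriptions classify as retro
  kw <- fab$table[fab$table$query_id %in%
                    fab$truth$seq_id[fab$truth$retro_desc], ]
  if (nrow(kw)) expect_true(all(keyword_classify(kw$description) == "retro"))
})

test_that("configuration validation rejects invalid parameters", {
  expect_error(sim_config(retro_fraction = 0.6, contaminant_fraction = 0.5),
               "< 1")
  expect_error(sim_config(ssr_plant_rate = 1.5), "0, 1")
  expect_error(sim_config(gene_length_sd = -1), "positive")
  expect_error(sim_config(ssr_unit_size_weights = c(`2` = 0.5, `3` = 0.2,
                                                    `4` = 0.1)),
               "probability vector")
})

test_that("YAML configs load into validated sim_config objects", {
  f <- tempfile(fileext = ".yaml")
  writeLines(c("n_genes: 12", "n_reads: 34", "seed: 5",
               "read_length_mean: 306"), f)
  cfg <- read_sim_config(f)
  expect_s3_class(cfg, "sim_config")
  expect_equal(cfg$n_genes, 12L)
  expect_equal(cfg$n_reads, 34L)
  unlink(f)
})
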