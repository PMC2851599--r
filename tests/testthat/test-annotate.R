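# Annotation ingestion and summary statistics.

mk_hits <- function(...) {
  rows <- list(...)
  do.call(rbind, lapply(rows, function(r) {
    data.frame(query_id = r[[1]], subject_acc = r[[2]],
               pident = 90, aln_length = 100, mismatch = 0, gapopen = 0,
               qstart = 0, qend = 100,
               sstart = if (length(r) > 4) r[[5]] else 0,
               send = if (length(r) > 5) r[[6]] else 100,
               evalue = r[[3]], bitscore = r[[4]],
               subject_len = if (length(r) > 6) r[[7]] else 300,
               taxon = if (length(r) > 7) r[[8]] else "Pinus",
               description = "hypothetical protein",
               stringsAsFactors = FALSE)
  }))
}

test_that("best hits apply the E-value cutoff and deterministic tie-breaks", {
  tab <- mk_hits(
    list("q1", "P1", 1e-5, 100),            # above cutoff -> dropped
    list("q2", "P2", 1e-10, 200),
    list("q2", "P3", 1e-10, 180),           # lower bit score loses
    list("q3", "P4", 1e-8, 150),
    list("q3", "P5", 1e-12, 90),            # lower E wins despite bit score
    list("q4", "PB", 1e-9, 120),
    list("q4", "PA", 1e-9, 120))            # full tie -> lexicographic acc
  best <- best_hits(tab)
  expect_false("q1" %in% best$query_id)
  expect_equal(best$subject_acc[best$query_id == "q2"], "P2")
  expect_equal(best$subject_acc[best$query_id == "q3"], "P5")
  expect_equal(best$subject_acc[best$query_id == "q4"], "PA")
  # idempotent and order-independent
  expect_equal(best_hits(best), best)
  shuffled <- tab[sample(nrow(tab)), ]
  expect_equal(best_hits(shuffled), best)
})

test_that("unique accession counting is set cardinality", {
  tab <- mk_hits(list("q1", "P1", 1e-10, 100),
                 list("q2", "P1", 1e-10, 100),
                 list("q3", "P2", 1e-10, 100))
  expect_equal(unique_accession_count(best_hits(tab)), 2L)
  expect_equal(unique_accession_count(best_hits(tab[0, ])), 0L)
})

test_that("brute-force scan agrees with best_hits on a fabricated table", {
  set.seed(81)
  n <- 300
  tab <- data.frame(query_id = sprintf("q%02d", sample.int(40, n, TRUE)),
                    subject_acc = sprintf("P%03d", sample.int(120, n, TRUE)),
                    pident = 90, aln_length = 100, mismatch = 0, gapopen = 0,
                    qstart = 0, qend = 100, sstart = 0, send = 100,
                    evalue = 10^-sample.int(30, n, TRUE),
                    bitscore = sample(50:400, n, TRUE),
                    subject_len = 300, taxon = "Pinus",
                    description = "x", stringsAsFactors = FALSE)
  best <- best_hits(tab, max_evalue = 1e-6)
  for (q in unique(tab$query_id)) {
    rows <- tab[tab$query_id == q & tab$evalue <= 1e-6, ]
    if (nrow(rows) == 0L) {
      expect_false(q %in% best$query_id)
      next
    }
    rows <- rows[rows$evalue == min(rows$evalue), ]
    rows <- rows[rows$bitscore == max(rows$bitscore), ]
    want <- sort(rows$subject_acc)[1]
    expect_equal(best$subject_acc[best$query_id == q], want)
  }
})

test_that("taxon breakdown counts categories and warns on unmapped taxa", {
  tab <- mk_hits(list("q1", "P1", 1e-10, 100, 0, 100, 300, "Fusarium"),
                 list("q2", "P2", 1e-10, 100, 0, 100, 300, "Fusarium"),
                 list("q3", "P3", 1e-10, 100, 0, 100, 300, "Pinus"),
                 list("q4", "P4", 1e-10, 100, 0, 100, 300, "Martian"))
  map <- c(Fusarium = "Fungi", Pinus = "Conifer")
  expect_warning(bd <- taxon_breakdown(best_hits(tab), map), "Unclassified")
  expect_equal(bd$count[bd$category == "Fungi"], 2L)
  expect_equal(bd$percent[bd$category == "Fungi"], round(100 * 2 / 3, 1))
  expect_true(is.na(bd$percent[bd$category == "Unclassified"]))
  # percentages of categorized hits sum to 100 within rounding
  expect_lt(abs(sum(bd$percent, na.rm = TRUE) - 100), 0.2)
})

test_that("GO namespace proportions match a counting oracle", {
  counts <- c(molecular_function = 11997, biological_process = 5400,
              cellular_component = 3954)
  gp <- go_namespace_proportions(counts)
  expect_equal(gp$percent, c(56.2, 25.3, 18.5))
  set.seed(83)
  df <- fabricate_go_assignments(3000, seed = 83)
  gp2 <- go_namespace_proportions(df)
  want <- table(factor(df$namespace, levels = gp2$namespace))
  expect_equal(gp2$count, as.integer(want))
  expect_equal(gp2$percent, round(100 * as.integer(want) / 3000, 1))
  # single namespace
  one <- df[df$namespace == "molecular_function", ]
  expect_equal(go_namespace_proportions(one)$percent[1], 100)
  bad <- df; bad$go_id[1] <- "GO:12"
  expect_error(go_namespace_proportions(bad), "malformed")
})

test_that("logistic fit recovers generating parameters and flags
           degeneracy", {
  set.seed(85)
  n <- 5000
  len <- runif(n, 100, 1500)
  p <- plogis(-4 + 0.006 * len)
  hit <- rbinom(n, 1, p)
  fit <- hit_length_logistic(hit, len)
  expect_false(fit$separation)
  expect_lt(abs(fit$slope - 0.006), 3 * fit$slope_se)
  expect_lt(abs(fit$intercept - (-4)), 3 * fit$intercept_se)
  # null: slope CI covers zero for most seeds
  cover <- vapply(1:100, function(s) {
    set.seed(1000 + s)
    l2 <- runif(800, 100, 1500)
    h2 <- rbinom(800, 1, 0.3)
    f2 <- hit_length_logistic(h2, l2)
    abs(f2$slope) <= 1.96 * f2$slope_se
  }, logical(1))
  expect_gte(mean(cover), 0.9)
  # degenerate all-hit input
  expect_true(hit_length_logistic(rep(1, 50), runif(50))$separation)
})

test_that("ortholog coverage ratios and interval unions are exact", {
  tab <- mk_hits(list("q1", "S1", 1e-10, 100, 0, 150, 300),
                 list("q2", "S1", 1e-10, 100, 100, 300, 300),
                 list("q3", "S2", 1e-10, 100, 50, 100, 200))
  qlen <- c(q1 = 900, q2 = 600, q3 = 300)
  oc <- ortholog_coverage(tab, qlen)
  # 900 nt vs 300 aa -> ratio 1.0
  expect_equal(oc$per_query$ratio[oc$per_query$query_id == "q1"], 1.0)
  # union [0,150) + [100,300) covers all 300 residues
  s1 <- oc$per_subject[oc$per_subject$subject_acc == "S1", ]
  expect_equal(s1$coverage, 1.0)
  s2 <- oc$per_subject[oc$per_subject$subject_acc == "S2", ]
  expect_equal(s2$coverage, 50 / 200)
  # raw (no /3) convention
  oc_raw <- ortholog_coverage(tab, qlen, divide_by_3 = FALSE)
  expect_equal(oc_raw$per_query$ratio[1], 900 / 300)
})

test_that("union coverage equals a sweep-line oracle and is monotone", {
  set.seed(87)
  for (rep in 1:20) {
    k <- sample(2:8, 1)
    st <- sample(0:250, k, replace = TRUE)
    en <- st + sample(10:80, k, replace = TRUE)
    slen <- 400
    tab <- do.call(rbind, lapply(seq_len(k), function(i) {
      mk_hits(list(sprintf("q%d", i), "S", 1e-10, 100, st[i], en[i], slen))
    }))
    qlen <- stats::setNames(rep(300, k), sprintf("q%d", seq_len(k)))
    oc <- ortholog_coverage(tab, qlen)
    expect_equal(oc$per_subject$covered, oracle_union_len(st, en))
    # adding a query never decreases coverage
    oc_sub <- ortholog_coverage(tab[-1, , drop = FALSE], qlen)
    expect_lte(oc_sub$per_subject$coverage, oc$per_subject$coverage)
    expect_lte(oc$per_subject$coverage, 1)
  }
})

test_that("transcriptome coverage estimate is the stated arithmetic", {
  expect_equal(transcriptome_coverage_estimate(586732, 306), 3.6)
  expect_equal(transcriptome_coverage_estimate(25000 * 2000 / 306, 306), 1.0)
  set.seed(89)
  for (rep in 1:10) {
    nr <- sample(1e4:1e6, 1); ml <- runif(1, 100, 600)
    ng <- sample(1e4:3e4, 1); gl <- runif(1, 1000, 3000)
    expect_equal(transcriptome_coverage_estimate(nr, ml, ng, gl, digits = 6),
                 round(nr * ml / (ng * gl), 6))
  }
  expect_error(transcriptome_coverage_estimate(0, 306), "positive")
})

test_that("assembly summary matches brute-force recomputation", {
  set.seed(91)
  lens <- stats::setNames(sample(100:1200, 50, TRUE), sprintf("c%02d", 1:50))
  pl <- data.frame(read_id = sprintf("r%03d", 1:300),
                   ref_id = sample(names(lens), 300, TRUE),
                   pos = 0L, strand = "+",
                   length = sample(50:300, 300, TRUE),
                   n_mismatch = 0L, seq = "A", stringsAsFactors = FALSE)
  s <- assembly_summary(lens, pl)
  expect_equal(s$n_contigs, 50L)
  expect_equal(s$mean_length, mean(lens))
  expect_equal(s$n_over_long, sum(lens > 800))
  for (id in sample(names(lens), 5)) {
    rows <- pl[pl$ref_id == id, ]
    pc <- s$per_contig[s$per_contig$ref_id == id, ]
    expect_equal(pc$n_reads, nrow(rows))
    expect_equal(pc$depth, sum(rows$length) / lens[[id]])
  }
  # boundary: 801 bp contig counts as > 800
  expect_equal(assembly_summary(c(a = 801))$n_over_long, 1L)
  expect_equal(assembly_summary(c(a = 800))$n_over_long, 0L)
  expect_error(assembly_summary(numeric(0)), "no contigs")
})

test_that("simple contig statistics match hand arithmetic", {
  s <- assembly_summary(c(a = 100, b = 200, c = 300))
  expect_equal(s$mean_length, 200)
  expect_equal(s$n_over_long, 0L)
})
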