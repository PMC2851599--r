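#!/usr/bin/env Rscript
# Stage 3: microsatellite mining and primer design.
#
# Detects di-/tri-/tetra-nucleotide SSRs (>= 4 units, marker class < 50 bp)
# on the transcript set, assigns coding/non-coding context from the CDS
# intervals, designs primer pairs under the five PCR constraints, and
# checks detection against the planted truth.

source(file.path("analysis", "00_config.R"))

seqs <- read_fasta(file.path(RESULTS, "sim", "transcripts.fasta"))
tr <- utils::read.delim(file.path(RESULTS, "sim", "transcripts.tsv"))
truth <- utils::read.delim(file.path(RESULTS, "sim", "truth",
                                     "planted_ssrs.tsv"))

loci <- find_ssrs_all(seqs, max_len_bp = 49L)
out <- file.path(RESULTS, "ssr")
dir.create(out, showWarnings = FALSE)
utils::write.table(loci, file.path(out, "ssr_loci.tsv"), sep = "\t",
                   quote = FALSE, row.names = FALSE)
write_ssr_gff3(loci, file.path(out, "ssr_loci.gff3"))

message(sprintf("Detected %d SSR markers (<50 bp): %s",
                nrow(loci),
                paste(sprintf("%d of unit %d", table(loci$unit_size),
                              as.integer(names(table(loci$unit_size)))),
                      collapse = ", ")))

# recall of planted marker-class loci
plant <- truth[!truth$long_run, ]
key <- function(d) paste(d$seq_id, d$start, d$end, d$motif)
recall <- mean(key(plant) %in% key(loci))
message(sprintf("Planted-SSR recall: %.1f%% (%d loci)", 100 * recall,
                nrow(plant)))

# coding/non-coding context from gene CDS intervals
cds <- tr[!is.na(tr$cds_start), c("id", "cds_start", "cds_end")]
names(cds) <- c("seq_id", "start", "end")
gene_ids <- tr$id[tr$origin == "gene"]
ctx <- ssr_context(loci[loci$seq_id %in% gene_ids, ],
                   cds, stats::setNames(nchar(seqs), names(seqs))[gene_ids])
print(ctx)
utils::write.table(
  data.frame(metric = c("n_in_coding", "n_in_noncoding", "coding_bp",
                        "noncoding_bp", "density_coding",
                        "density_noncoding"),
             value = c(ctx$n_in_coding, ctx$n_in_noncoding, ctx$coding_bp,
                       ctx$noncoding_bp, ctx$density_coding,
                       ctx$density_noncoding)),
  file.path(out, "ssr_context.tsv"), sep = "\t", quote = FALSE,
  row.names = FALSE)

# primer design over a sample of loci (one best pair per locus)
set.seed(1)
pick <- loci[sample.int(nrow(loci), min(150L, nrow(loci))), ]
primers <- do.call(rbind, lapply(seq_len(nrow(pick)), function(i) {
  p <- design_primers(seqs[[pick$seq_id[i]]], pick[i, ], max_pairs = 1L)
  if (nrow(p) == 0L) return(NULL)
  cbind(pick[i, c("seq_id", "start", "end", "motif", "n_units")], p)
}))
utils::write.table(primers, file.path(out, "primer_pairs.tsv"), sep = "\t",
                   quote = FALSE, row.names = FALSE)
message(sprintf("Primer pairs passing all five constraints: %d of %d loci tried (%.0f%%)",
                nrow(primers), nrow(pick), 100 * nrow(primers) / nrow(pick)))
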