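#!/usr/bin/env Rscript
# Stage 4: read placement, pileups and SNP calling.
#
# Places QC-passed reads on the transcript references by unique 21-mer
# seeding, builds pileups, and calls SNPs under both presets: depth >= 10
# for the most deeply covered contigs, and depth >= 8 across contigs with
# more than 20 reads. Reports SNP rates per 100 bp and recovery against the
# planted truth.

source(file.path("analysis", "00_config.R"))

seqs <- read_fasta(file.path(RESULTS, "sim", "transcripts.fasta"))
reads <- read_fastq(file.path(RESULTS, "qc", "kept.fastq"))
truth <- utils::read.delim(file.path(RESULTS, "sim", "truth",
                                     "planted_snps.tsv"))

pl <- map_reads(reads, seqs, k = 21L, max_mismatch_rate = 0.05)
message(sprintf("Placed %d of %d reads (%.1f%%)",
                sum(!is.na(pl$ref_id)), nrow(pl),
                100 * mean(!is.na(pl$ref_id))))

out <- file.path(RESULTS, "snp")
dir.create(out, showWarnings = FALSE)
write_sam(pl, seqs, file.path(out, "placements.sam"))

pu <- build_pileup(pl, seqs)

# preset B: depth >= 10, the 20 references holding the most reads
placed <- pl[!is.na(pl$ref_id), ]
by_reads <- sort(table(placed$ref_id), decreasing = TRUE)
top20 <- names(by_reads)[seq_len(min(20L, length(by_reads)))]
calls10 <- call_snps(pu[names(pu) %in% top20], min_depth = 10L,
                     min_alt_freq = 0.20)
bp_top <- sum(nchar(seqs[top20]))
message(sprintf("Top-20 contigs: %d SNPs over %d bp = %.1f per 100 bp",
                nrow(calls10), bp_top, snp_rate(calls10, bp_top)))

# preset A: depth >= 8 across contigs with more than 20 reads
eligible <- contig_read_filter(
  data.frame(ref_id = names(by_reads), n_reads = as.integer(by_reads)),
  min_reads = 20L)
calls8 <- call_snps(pu[names(pu) %in% eligible], min_depth = 8L,
                    min_alt_freq = 0.20)
bp_all <- sum(nchar(seqs[eligible]))
message(sprintf(">20-read contigs (%d): %d SNPs over %d bp = %.1f per 100 bp",
                length(eligible), nrow(calls8), bp_all,
                snp_rate(calls8, bp_all)))

write_snp_vcf(calls8, seqs, file.path(out, "snps_depth8.vcf"))
write_snp_vcf(calls10, seqs, file.path(out, "snps_depth10_top20.vcf"))

# recovery against planted truth
tkey <- paste(truth$seq_id, truth$pos)
ckey <- paste(calls8$ref_id, calls8$pos)
message(sprintf("Calls at planted sites: %d/%d; calls at non-planted sites: %d",
                sum(ckey %in% tkey), nrow(calls8), sum(!(ckey %in% tkey))))
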