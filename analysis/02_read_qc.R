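#!/usr/bin/env Rscript
# Stage 2: read quality control.
#
# Applies the three-stage filter in its fixed order (retroelement
# similarity, long SSR runs, mean quality < 18) to the simulated reads and
# writes the kept set, the discards with reasons, and the QC report.

source(file.path("analysis", "00_config.R"))

reads <- read_fastq(file.path(RESULTS, "sim", "reads.fastq"))
lib <- read_fasta(file.path(RESULTS, "sim", "retro_library.fasta"))

retro_ids <- similarity_screen(stats::setNames(reads$seq, reads$id), lib)
res <- qc_filter(reads, min_mean_q = 18, max_ssr_run_bp = 50L,
                 retro_read_ids = retro_ids)

out <- file.path(RESULTS, "qc")
dir.create(out, showWarnings = FALSE)
write_fastq(res$kept, file.path(out, "kept.fastq"))
disc <- res$discarded
disc$id <- paste0(disc$id, " reason=", unname(res$reason[disc$id]))
write_fastq(disc, file.path(out, "discarded.fastq"))
write_qc_report(res$report, file.path(out, "qc_report.tsv"))

print(res$report)
truth_retro <- utils::read.delim(
  file.path(RESULTS, "sim", "truth", "retro_read_ids.tsv"))$read_id
message(sprintf("Retro screen: %d matched vs %d retro-origin reads in truth (agreement %.1f%%)",
                length(retro_ids), length(truth_retro),
                100 * length(intersect(retro_ids, truth_retro)) /
                  max(1, length(union(retro_ids, truth_retro)))))
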