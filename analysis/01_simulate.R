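#!/usr/bin/env Rscript
# Stage 1: simulate the sequencing experiment.
#
# Generates the transcript pool (gene / retroelement / contaminant origins),
# plants SSR loci -- including oversized 52 bp filter-test runs -- and
# biallelic SNPs segregating in an 8-chromosome pool, then draws reads.
# Writes FASTA/FASTQ plus the full ground truth under results/sim/.

source(file.path("analysis", "00_config.R"))

cfg <- workflow_config()
d <- simulate_dataset(cfg, long_run_units = 26L, n_long_runs = 8L)

out <- file.path(RESULTS, "sim")
dir.create(out, showWarnings = FALSE)
write_fasta(d$sim$seqs, file.path(out, "transcripts.fasta"))
write_fasta(d$sim$retro_library, file.path(out, "retro_library.fasta"))
write_fastq(d$reads, file.path(out, "reads.fastq"))
write_truth_tables(d$sim, file.path(out, "truth"))
utils::write.table(d$sim$transcripts, file.path(out, "transcripts.tsv"),
                   sep = "\t", quote = FALSE, row.names = FALSE)

org <- d$sim$truth$read_origins
message(sprintf("Simulated %d transcripts (%d retro, %d contaminant) and %d reads",
                nrow(d$sim$transcripts),
                sum(d$sim$transcripts$origin == "retroelement"),
                sum(d$sim$transcripts$origin == "contaminant"),
                length(d$reads)))
message(sprintf("Mean read length %.1f bp; %d planted SSRs (%d long-run), %d planted SNPs",
                mean(nchar(d$reads$seq)),
                nrow(d$sim$truth$planted_ssrs),
                sum(d$sim$truth$planted_ssrs$long_run),
                nrow(d$sim$truth$planted_snps)))
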