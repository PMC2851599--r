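#!/usr/bin/env Rscript
# Stage 6: annotation and coverage summaries.
#
# Consumes the fabricated similarity hit table for the simulated
# transcriptome and computes the annotation summaries: best hits, unique
# accessions, taxonomy breakdown, GO namespace proportions, the
# hit-versus-length logistic model, ortholog coverage ratios and the
# transcriptome coverage estimate, plus assembly-style contig statistics.

source(file.path("analysis", "00_config.R"))

cfg <- workflow_config()
seqs <- read_fasta(file.path(RESULTS, "sim", "transcripts.fasta"))
reads <- read_fastq(file.path(RESULTS, "sim", "reads.fastq"))

sim <- generate_transcriptome(cfg)
sim <- plant_ssrs(sim, cfg)
fab <- fabricate_annotation_table(sim, cfg)
out <- file.path(RESULTS, "annotation")
dir.create(out, showWarnings = FALSE)
write_hit_table(fab$table, file.path(out, "hits.tsv"))

best <- best_hits(read_hit_table(file.path(out, "hits.tsv")),
                  max_evalue = 1e-6)
message(sprintf("%d of %d transcripts with hits at E<=1e-6 (%d unique accessions)",
                nrow(best), length(seqs), unique_accession_count(best)))

taxon_map <- c(Pinus = "Conifer", Arabidopsis = "Other plant",
               Drosophila = "Insect", Fusarium = "Fungi",
               Homo = "Other Eukaryote", Escherichia = "Bacteria")
bd <- taxon_breakdown(best, taxon_map)
utils::write.table(bd, file.path(out, "taxonomy.tsv"), sep = "\t",
                   quote = FALSE, row.names = FALSE)
print(bd)

go <- fabricate_go_assignments(4000L, seed = cfg$seed + 5L)
gp <- go_namespace_proportions(go)
utils::write.table(gp, file.path(out, "go_namespaces.tsv"), sep = "\t",
                   quote = FALSE, row.names = FALSE)
print(gp)

# hit presence vs transcript length
hit <- names(seqs) %in% best$query_id
fit <- hit_length_logistic(hit, nchar(seqs))
message(sprintf("Logistic hit~length: slope %.4g (SE %.2g), intercept %.3g, p %.3g",
                fit$slope, fit$slope_se, fit$intercept, fit$p_value))

# ortholog coverage (nt/aa ratio, /3 convention) and union coverage
oc <- ortholog_coverage(best, stats::setNames(nchar(seqs), names(seqs)))
utils::write.table(oc$per_subject, file.path(out, "ortholog_coverage.tsv"),
                   sep = "\t", quote = FALSE, row.names = FALSE)
message(sprintf("Ortholog union coverage: median %.2f, fully covered %d/%d",
                stats::median(oc$per_subject$coverage),
                sum(oc$per_subject$coverage >= 1), nrow(oc$per_subject)))

# contig-style statistics of the transcript set
asm <- assembly_summary(stats::setNames(nchar(seqs), names(seqs)))
print(asm)

cov <- transcriptome_coverage_estimate(length(reads),
                                       mean(nchar(reads$seq)),
                                       n_genes = length(seqs),
                                       mean_gene_len = mean(nchar(seqs)))
message(sprintf("Simulated-run transcriptome coverage: %.1fx", cov))
message(sprintf("Published-scale estimate: %.1fx",
                transcriptome_coverage_estimate(586732, 306, 25000, 2000)))
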