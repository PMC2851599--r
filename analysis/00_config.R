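# Shared settings for the analysis workflow.
#
# The simulation emulates a half-plate 454 Titanium EST run (reads of mean
# 306 bp from a normalized conifer cDNA pool) at desk scale: 400 transcripts
# and 12,000 reads keep every stage under a minute while leaving planted
# markers deeply enough covered to be recoverable. Fractions, rates and
# distributions are the emulated study conditions; only the counts are
# scaled down.

library(marker454)

RESULTS <- file.path("results")
dir.create(RESULTS, showWarnings = FALSE)

workflow_config <- function(seed = 20090454) {
  sim_config(
    n_genes = 400L,
    gene_length_mean = 2000, gene_length_sd = 600, min_gene_length = 300L,
    ssr_plant_rate = 0.3,
    snp_rate = 0.01,
    retro_fraction = 0.05,
    contaminant_fraction = 0.05,
    n_reads = 12000L,
    read_length_mean = 306, read_length_sd = 75,
    base_error_rate = 0.005,
    quality_mean = 28, quality_sd = 6,
    seed = seed)
}
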