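# marker454

Marker discovery and transcriptome characterization from 454 EST reads.

Early transcriptome surveys of conifers — organisms with enormous,
repeat-rich genomes and no reference sequence — relied on 454
pyrosequencing of normalized cDNA to characterize the gene space and to
mine molecular markers. `marker454` is a tested, reusable R implementation
of the computational pipeline such studies used, for researchers who want
to reproduce, audit, or re-apply those analyses:

* **Read QC** — partition reads by three filters in a fixed order:
  retroelement similarity, simple-sequence-repeat runs longer than 50 bp,
  and mean phred quality below 18 (boundaries strict, so mean 18.0 and a
  50 bp run both pass).
* **SSR markers** — detect maximal, primitive-unit di-/tri-/tetra-nucleotide
  repeats with ≥ 4 contiguous units (marker class < 50 bp), assign
  coding/non-coding context and per-bp densities, and design PCR primers
  under five constraints: GC ≥ 30%, Tm ∈ [52, 62] °C, |ΔTm| ≤ 4 °C,
  product ∈ [100, 450] bp, GC clamp. Tm uses SantaLucia (1998)
  nearest-neighbor thermodynamics at 50 mM Na⁺ / 50 nM primer.
* **SNP calling** — place reads by unique exact 21-mer seeds (ungapped),
  build pileups, and call a SNP where depth ≥ *d* and the leading alternate
  allele reaches ≥ 20% of reads (both inclusive), with *d* = 10 for the
  most deeply covered contigs and *d* = 8 across contigs with more than 20
  reads; report SNPs per 100 bp.
* **Retrotransposon screen** — match sequences to a retroelement library
  (seeded ungapped alignment ≥ 50 bp at ≥ 80% identity, or an external
  tabular hit file at E ≤ 1e−6), classify annotation text by seven
  whole-word keywords (copia, gag, pol, retroelement, integrase, reverse
  transcriptase, retrotransposon), and tabulate per-collection abundance.
* **Annotation summaries** — best hits per query (E-value, bit score,
  accession tie-breaks), unique-accession counts, taxonomy and GO-namespace
  percentages, a logistic model of hit presence versus sequence length,
  ortholog coverage by interval union, and the transcriptome coverage
  estimate (reads × read length) / (genes × gene length).
* **Synthetic data** — a simulator with complete ground truth (transcript
  origins, planted SSR coordinates, planted SNP frequencies from an
  8-chromosome pool, read origins) drives every test; no external data are
  required.

## Worked example

```r
library(marker454)

cfg <- sim_config(n_genes = 50, gene_length_mean = 1500, gene_length_sd = 400,
                  n_reads = 3000, base_error_rate = 0, seed = 101)
d <- simulate_dataset(cfg)
res <- qc_filter(d$reads, retro_read_ids = d$sim$truth$retro_read_ids)
print(res$report)
#> QC: 3000 reads in, 2874 kept
#>   discarded: 0 quality, 0 long SSR, 126 retroelement, 0 adapter-only

loci <- find_ssrs_all(d$sim$seqs, max_len_bp = 49)
head(loci, 3)
#>   seq_id start end motif unit_size n_units
#> 1 t00001   218 226    AC         2       4
#> 2 t00005   764 772    CT         2       4
#> 3 t00018   524 532    CG         2       4

design_primers(d$sim$seqs[[loci$seq_id[1]]], loci[1, ], max_pairs = 1)[,
  c("forward", "reverse", "product_length", "tm_forward", "tm_reverse")]
#>                 forward                reverse product_length tm_forward tm_reverse
#> 1 AGTGACGTTTCTCCCTCGGCC GGCGTATTGATTGGACCTGACC            361   58.51663   55.48343

pl <- map_reads(res$kept, d$sim$seqs)
calls <- call_snps(build_pileup(pl, d$sim$seqs), min_depth = 8,
                   min_alt_freq = 0.2)
snp_rate(calls, sum(nchar(d$sim$seqs)))
#> [1] 0.6

transcriptome_coverage_estimate(586732, 306, 25000, 2000)
#> [1] 3.6
```

The 126 discarded reads are exactly the reads simulated from
retroelement-origin transcripts; the SSR table reports 0-based half-open
coordinates with canonical (smallest-rotation) motifs; the primer pair
satisfies all five constraints; and 0.6 SNPs per 100 bp is the planted
polymorphism recovered at the depth-8 / 20%-frequency preset. The final
line is the coverage arithmetic for a 586,732-read run of 306-bp reads
over an assumed 25,000-gene, 2,000-bp gene space: 3.6×.

## Analysis workflow

`analysis/` contains the pipeline as numbered drivers, each writing tables
under `results/`:

```sh
Rscript analysis/01_simulate.R            # transcripts, reads, ground truth
Rscript analysis/02_read_qc.R             # three-stage filter + QC report
Rscript analysis/03_ssr_markers.R         # SSR loci, context, primers
Rscript analysis/04_align_snp.R           # placements (SAM), SNPs (VCF), rates
Rscript analysis/05_retro_screen.R        # abundance table, protein classes
Rscript analysis/06_annotate_summarize.R  # annotation & coverage summaries
```

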