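---
title: "Methods: marker discovery from 454 EST reads"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: marker discovery from 454 EST reads}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(marker454)
```

# Scope

`marker454` re-implements, as a tested pipeline, the computations used to
mine molecular markers from a 454 pyrosequencing EST survey of a conifer
transcriptome: read quality control, microsatellite (SSR) detection with PCR
primer design, pileup-based SNP calling, retrotransposon abundance
screening, and summarization of tabular protein-similarity annotation.
Wet-lab steps (cDNA normalization, PCR validation), the proprietary
assembler, and running BLAST/GO-assignment tools themselves are out of
scope: the pipeline consumes read placements and tabular hit files, and a
synthetic-data generator fabricates equivalents with known ground truth.

# The synthetic experiment

The generator emulates a half-plate 454 Titanium run on a normalized cDNA
pool from four diploid individuals:

* **Transcript pool.** `n_genes` transcripts with truncated-normal lengths
  (default mean 2,000 bp, sd 600, minimum 300 bp — the assumed gene space
  of 25,000 genes averaging 2,000 bp anchors the coverage arithmetic). A
  central ~70% CDS is flanked by UTRs. Fixed fractions are labelled
  retroelement-derived (default 5%; substrings of a synthetic 17-element
  retro library, named for well-known conifer elements but random in
  sequence — similarity, not homology, is what downstream screening needs)
  and contaminant (default 5%, emulating endophytic fungi).
* **Planted SSRs.** With probability 0.3 per transcript, one tandem run of
  a random primitive 2/3/4-bp unit (weights 0.77/0.20/0.03, the di ≫ tri >
  tetra pattern of plant ESTs) with 4–12 units, overwriting a window of
  equal length so coordinates elsewhere are untouched. Guard bases that
  break the repeat phase bracket each run, so truth coordinates are exact
  and runs cannot merge with flanking sequence. Oversized 52-bp runs can be
  planted separately as filter-test cases.
* **Planted SNPs.** Sites arise per bp at `snp_rate` (default 0.01); each
  alternate allele is carried by `round(8f)` of 8 pooled chromosomes (four
  diploids), with design frequencies f drawn from {1/8, …, 7/8}. A read
  drawn from a random chromosome therefore carries the alternate allele
  with probability exactly f.
* **Reads.** Default 586,732 reads; lengths truncated-normal with mean 306
  bp (the published mean) and sd 75 (the histogram's spread is not
  tabulated, so sd is a free parameter), truncated to [50, 600] bp and at
  the source transcript. Transcripts are sampled proportional to length
  (uniform per-bp coverage; expression-level modelling is a non-goal).
  Strands are equiprobable; truth records transcript, offset, strand and
  chromosome per read. Substitution errors occur per base at
  `base_error_rate` (default 0.005 — stated as an assumption, since
  per-base error characteristics of the instrument run are not published;
  homopolymer-specific flowgram errors are deliberately not modelled).
  Qualities are integer N(28, 6) clamped to [0, 40], phred+33.

Each stage reseeds deterministically from `config$seed` plus a fixed
offset, so identical configurations give byte-identical FASTA/FASTQ output.

**What passing tests show.** Recovery statistics on this generator certify
the algorithms (detection, thresholding, bookkeeping), not instrument
realism: real 454 data adds homopolymer indels, quality-length coupling and
expression skew that the generator intentionally omits, so mapped-fraction
and false-positive numbers on real data will be less clean than the
synthetic ones.

# Read quality control

Three filters partition reads, applied in a fixed order — adapter trim
(optional, exact prefix/suffix match), retroelement similarity, long SSR
run, mean quality — so a read triggering several filters is counted once,
under the first. The published order is unstated; fixing one makes report
counts reproducible. Boundaries are strict on both sides: mean quality
exactly 18 passes ("less than 18" discards), and a 50-bp run passes
("longer than 50 bp" discards). `N` bases contribute their recorded quality
and never extend an SSR run.

# Microsatellite detection

An SSR locus is a maximal tandem run of a primitive unit (size 2–4)
repeated ≥ 4 times. The scan finds period-u self-match regions
(`s[i] == s[i+u]`), reports whole units only, and suppresses non-primitive
units, so a run appears exactly once, at its primitive unit size, with the
motif canonicalized to the lexicographically smallest rotation — reports are
invariant to the phase at which a run is entered. No reverse-complement
folding is applied because EST sequence is strand-specific. Compound or
interrupted repeats are reported as separate loci; no merging rule is
published, so none is invented. Marker mining caps loci at < 50 bp;
the QC long-run flag uses the same detector uncapped. For coding context,
a locus overlapping a CDS interval by ≥ 1 bp counts as coding (the
published rule is unstated; 1 bp overlap is the most inclusive
deterministic choice), and densities are loci per bp of each region class.

# Primer design

Candidate primers of 18–24 bp are enumerated in the flanks of each locus
and pairs retained under five rules: per-primer GC ≥ 30% (inclusive), Tm in
[52, 62] °C, |ΔTm| ≤ 4 °C, product length in [100, 450] bp, and a GC clamp
(both 3'-terminal bases G or C). Tm uses nearest-neighbor thermodynamics
(SantaLucia 1998 unified parameters) at 50 mM monovalent salt and 50 nM
primer — the defaults of primer3-family tools, for comparability — with the
Wallace rule available as an option. The published phrase "a minimum of 12
bp" is ambiguous between primer length and flank length; 12-bp primers are
not PCR-credible, so the default is the 18–24 bp primer range, and a
`min_flank_bp` knob exposes the other reading. Pairs are ranked by
|mean Tm − 57| then |product − 250| bp with positional tie-breaks, making
output deterministic and independent of enumeration order. The search is
bounded to 450 bp on either side of the locus, beyond which no admissible
product exists.

# Read placement and SNP calling

The built-in mapper stands in for assembly-derived placements: a read is
anchored at its leftmost 21-mer that occurs exactly once across the
references (2-bit numeric codes, binary search), extended end-to-end with
matches/mismatches only, and accepted under a 5% mismatch rate; both
strands are tried, forward first. Gaps are not modelled because indels are
excluded from the SNP definition and homopolymer realism is out of scope.
Pileups count A/C/G/T/N per position; total depth equals total aligned
bases.

A SNP is called where A/C/G/T depth ≥ `min_depth` and the most frequent
non-reference base reaches ≥ `min_alt_freq` of that depth, both inclusive
("at least", "a minimum of"); `N` is excluded from numerator and
denominator; at multi-allelic columns only the most frequent alternate is
reported (ties alphabetical). Two presets mirror the published usage: depth
≥ 10 for close inspection of the 20 read-richest contigs, and depth ≥ 8
across contigs with **more than** 20 reads (the companion text also
mentions "greater than 25"; the threshold is a parameter, defaulting to 20,
which matches the published contig count). Mean coverage depth of a contig
is Σ aligned read bp / contig length — the published formula is undefined,
so this definition is stated explicitly. Rates are reported as SNPs per
100 bp at one decimal. Coordinates are 0-based half-open internally, 1-based
in VCF output.

# Retroelement screening

Internal mode anchors an 11-mer shared with the library and extends
ungapped to the best-scoring segment (+1 match / −3 mismatch), matching a
sequence when the segment is ≥ 50 bp at ≥ 80% identity. These thresholds
are a stated, portable proxy for a BLASTn E ≤ 1e−6 search, whose E-values
depend on database size; external-table mode consumes a tabular hit file
filtered at E ≤ 1e−6 for exact parity with a real search. Keyword
classification matches seven terms (copia, gag, pol, retroelement,
integrase, reverse transcriptase, retrotransposon) case-insensitively as
whole words, so "polymerase" never matches "pol". Protein-level
classification of retro-matched contigs applies the same keywords to
best-hit descriptions — an automated proxy for manual database inspection,
flagged `automated_keyword` in its output. Abundance rows report
100·matching/total at 4 decimals.

# Annotation summaries

Hit tables are the standard 12 tab-separated similarity-search columns,
optionally extended (as such tools allow via custom column sets) with
subject length, taxon label and description. Best hits per query take
lowest E-value, then highest bit score, then lexicographic accession — the
last rule guarantees determinism. Unique-gene counts are accession-set
cardinality. Taxonomy and GO tables report percentages at the printed
precision of their respective tables (0, 1 and 4 decimals). The
hit-versus-length model is a maximum-likelihood logistic regression with
Wald standard errors; complete separation or single-class input is flagged
rather than reported as estimates. Ortholog coverage divides nucleotide
query length by 3× subject residue length by default (ratios above 1 then
reflect UTR content); the raw convention is a switch. Summed subject
coverage is the length of the union of aligned subject intervals (via
IRanges) divided by subject length, capped at 1. The transcriptome coverage
estimate is (reads × mean read length) / (genes × mean gene length).

# Numerical and testing choices

Problem sizes in the workflow scripts and tests — 400 transcripts / 12,000
reads for the workflow, 120 / 6,000 for the acceptance script, smaller
still in unit tests — were chosen so each stage completes in seconds to a
couple of minutes while planted markers remain deeply enough covered for
recovery statistics to be meaningful. Exhaustive SSR verification
enumerates every binary-alphabet string to length 13 (the enumerable
domain) plus hundreds of random and run-dense strings against a
brute-force oracle that tests every (start, unit, count) triple.

Known limitations: no gapped alignment or paralog disambiguation; no
genotype likelihoods (threshold calling reproduces the published
procedure, not a modern caller); adapter trimming is exact-match only; the
retro screen's internal thresholds are deliberately conservative proxies;
and mononucleotide and penta-/hexa-nucleotide repeats are excluded by
design.
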