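---
title: "Consensus molecules and SNV calling in droplet scRNA-seq"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Consensus molecules and SNV calling in droplet scRNA-seq}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dropsnv)
library(data.table)
```

## The problem

Droplet single-cell RNA-seq (10x-style 3' chemistry) reads carry three pieces
of information: a cell barcode (CB) shared by all reads of a droplet, a unique
molecular identifier (UMI) distinguishing mRNA molecules within the droplet,
and the cDNA "tag" that is actually aligned. Because cDNA is amplified twice —
once before fragmentation (producing *molecular duplicates*: same CB/UMI/gene,
different fragment positions) and once after (producing *PCR duplicates*:
identical mapping positions) — a single mRNA molecule is typically observed as
several reads that jointly cover more of the transcript than any one read.

Standard variant callers ignore this structure. `dropsnv` exploits it: reads
of one molecule are merged into a longer *consensus molecule*, with per-base
majority voting that suppresses independent amplification and sequencing
errors, and SNVs are then called from a strand- and barcode-aware pileup over
molecules rather than reads. Counting molecules (not reads) removes the
duplicate-driven inflation of allele counts, and the per-cell sparse
ref/alt matrices support downstream genotyping-style analyses (e.g. sample
deconvolution or RNA-editing profiling per cell).

## Pipeline overview

1. **Reference index** (`build_index`): Ensembl-dialect GTF + genome FASTA.
   Transcripts with biotypes `retained_intron`, `nonsense_mediated_decay`,
   `non_stop_decay`, or a spliced length under 100 bp, are removed before any
   derived structure is built. A gene's exon set is the union of exons over
   its retained transcripts; introns are the gaps inside the gene span. The
   union choice is ours (the per-gene/per-transcript alternative is not
   observable downstream, where only the exonic/intronic dichotomy is used).
2. **Read QA** (`qa_reads`): CB correction against a whitelist (exact match,
   else a unique highest-count Hamming-1 neighbour; count ties reject the
   read), rejection of UMIs with ambiguous bases, 3' poly(A) trimming keeping
   at least half of the read, and an optional DUST low-complexity filter.
3. **Alignment processing** (`merge_and_filter`, `trim_splice_overhang`,
   `annotate_reads`): alignment score cutoff 45, retention window
   `max score − 3`, soft-clipping of terminal blocks that overhang an
   annotated splice junction by ≤ 5 bp, and the six-type classification
   (unmapped / antisense / exonic / intronic / intergenic / ambiguous)
   reduced to one annotation per read. Only exonic and intronic ("countable")
   reads are quantified.
4. **UMI deduplication** (`build_umi_groups`): directional collapsing within
   each (barcode, gene) — an edge `a → b` exists when the UMIs differ at one
   base and `count(a) ≥ 2·count(b) − 1`; groups are grown from unabsorbed
   roots in descending count order. PCR duplicates are members at identical
   mapping positions. A UMI seen in several genes of one barcode keeps the
   gene with most reads; ties discard all (mirroring common practice in
   droplet quantification tools).
5. **Consensus collapsing** (`collapse_molecules`): per reference column, the
   modal base wins at ≥ 60% agreement with quality equal to the maximum among
   supporting reads; otherwise `N` with quality 2. Indels need ≥ 60% of
   overlapping reads to carry the identical indel. Groups that do not map
   linearly (conflicting junction structure in overlapping reads, or member
   indels) are emitted uncollapsed but flagged, preserving pileup coverage.
6. **Cell calling** (`call_cells`): the knee rule (99th percentile of the top
   `expected_cells` spliced-molecule counts, divided by 10) followed by four
   MAD filters computed over the candidates, all in percent units with the
   raw (unscaled) MAD: MT% above `median + min(5·MAD, 20)`, saturation or PCR
   duplicate rate below `median − min(3·MAD, 10)`, corrected-read percent
   above `median + max(10·MAD, 1.5)`.
7. **Pileup and SNV filters** (`pileup`, `call_snvs`): bases with quality
   ≥ 20, one count per molecule, per-strand and per-barcode tallies. A call
   requires ≥ 5 barcodes covering, ≥ 2 barcodes with the alternative allele,
   minor allele fraction ≥ 0.01 (alt bases over all bases across cells), and
   at least one supporting mismatch ≥ 5 bp from the nearest read end — where
   the ends of a collapsed molecule include the *internal* read-end positions
   of its fragments, since mis-spliced read ends are a dominant false-positive
   source. An optional stricter allele-fraction cutoff (strictly > 0.25) is
   provided for germline-focused analyses; edit discovery should not use it,
   because A>G edits are progressively lost as the cutoff rises.
8. **Annotation** (`annotate_calls`): bi-allelic refinement (ref+alt ≥ 95% of
   bases), strand inference (≥ 90% of molecules on one strand), and classes:
   germline (matched DNA), common SNP, or A>G edit — a strand-oriented A>G
   change (T>C on the reference for minus-strand calls) that is in the edit
   catalogue or inside an Alu-like repeat interval.
9. **Benchmarking and simulation** (`label_sites`, `per_cell_accuracy`,
   `simulate_homozygous_snvs`): pseudo-bulk TP/FP/FN against matched DNA
   evidence (≥ 15X DNA coverage, ≥ 2 alternative DNA reads as presence,
   FN additionally needs ≥ 5 covering barcodes), the two per-cell
   false-negative notions (FN[bulk]: no alt regardless of coverage;
   FN[cell]: covered but alt-free), and homozygous-SNV simulation by
   substituting reference positions ≥ 10 bp from any existing call with
   ≥ 5X coverage.

## Key parameters

| parameter | default | unit | role |
|---|---|---|---|
| `min_tx_length` | 100 | bp | transcript index length filter |
| `min_score` / `score_window` | 45 / 3 | aligner score | alignment retention |
| `max_overhang` | 5 | bp | splice-overhang trimming |
| `min_exon_bp` / `min_intron_bp` | 25 / 5 | bp (strict >) | exonic/intronic classification |
| `consensus_fraction` / `indel_fraction` | 0.60 | fraction | consensus voting |
| `min_base_quality` | 20 | phred | pileup base gate |
| `min_barcodes` / `min_alt_barcodes` | 5 / 2 | barcodes | site coverage gates |
| `min_maf` | 0.01 | fraction | minor allele fraction gate |
| `end_exclusion` | 5 | bp | read-end mismatch exclusion |
| `af_cutoff` | 0.25 | fraction (strict >) | optional germline AF cutoff |
| `expected_cells` | 3000 | cells | elbow estimate |

Every threshold is exposed as a function argument with the default above.

## The synthetic test bed

`generate_reference`, `plant_variants` and `generate_library` produce a fully
deterministic toy study whose expected pipeline output is known exactly. The
default configuration — 200 multi-exon genes on both strands, 500 cells at
~200 molecules each plus 200 ambient barcodes, truncated-geometric molecular
duplication over 1..8 fragments, 20% PCR duplication, 98 bp reads with
exponential 3' bias, zero sequencing/UMI/barcode error rates, 50 homozygous
SNVs, 50 heterozygous SNVs at allele fraction 0.5, and three clusters of ten
A>G edits spread wider than one read — is the condition set under which the
whole pipeline is validated, and the test suite and acceptance script run it
unchanged. Smaller configurations (20 genes, 20 cells) back the per-module
tests.

Three generator choices make exact truth possible and deserve mention:

* UMIs are drawn without replacement within a barcode and never at Hamming
  distance 1 within a (barcode, gene). Otherwise directional collapse could
  merge genuinely distinct molecules and no bookkeeping could predict the
  count matrix exactly.
* Intronic (unspliced pre-mRNA) molecules fragment wholly inside one intron,
  so each read's classification is unambiguous.
* Hyper-edited molecules receive fragment positions that tile their cluster
  window, with per-molecule jitter — random fragmentation in a real library
  never repeats the same cut positions across molecules, and shared internal
  read-ends would otherwise interact with the end-exclusion filter
  systematically.

What the generator does **not** emulate: alignment errors and multi-mapping
(gold alignments are the true placements), empirical quality-score and error
profiles, chimeric/doublet droplets, ambient RNA contamination of cell
barcodes, and strand bleed-through. Passing tests therefore demonstrate the
correctness of the post-alignment logic under its stated model, not robustness
to aligner artefacts — on real data the aligner, not this package, determines
placement quality.

## Numerical and design choices

* Coordinates are 0-based half-open internally; 1-based only in VCF/GTF/SAM
  interfaces. MAD is unscaled. Consensus ambiguity gets quality 2.
* "Distinct location" for multi-mapping: two retained alignments are the same
  location when on one contig with ≥ 50% reciprocal span overlap; redundant
  genome/transcriptome projections merge rather than triggering multi-mapped.
* "More than one gene" in the ambiguous class counts sense-strand genes only;
  a read overlapping one sense gene and one antisense gene is classified
  against the sense gene, otherwise the antisense class could never occur in
  antisense-overlapping gene pairs.
* Reads whose only retained alignment is intergenic receive an `intergenic`
  read annotation (non-countable); the read-level schema needs the class even
  though it assigns no gene.
* PCR duplicates contribute consensus columns like any other read; a pure PCR
  stack collapses to its common read with per-base maximum quality.
* UMI-gene conflict ties discard all participating groups.
* Group linearity: one contig and strand, no member indels, and no read may
  skip a reference position another member aligns to. Single-read groups are
  identity collapses by construction.
* The elbow estimate uses `expected_cells` = 3000 by default; the MAD filters
  are computed over elbow candidates only, as outlier screening is meaningful
  only within the cell-like population.
* `max_end_dist` considers mismatch-bearing molecules only, which is the
  reading that makes the filter act on the evidence for the variant.
* Per-cell FDR uses called-and-expressed non-truth sites per cell as its
  denominator.

## Problem sizes

The validation fixture holds ~100,000 molecules / ~250,000 reads and runs end
to end in roughly two minutes on one core; per-module tests use 20-gene,
20-cell configurations. The consensus and directional-collapse oracles check
1,000 and 200 random groups respectively against brute-force implementations.

## Known limitations

* Indel consensus is implemented and tested at the operation level, but
  groups whose reads carry indels are passed through uncollapsed rather than
  re-assembled around the indel; indel *calling* is out of scope.
* The external-BAM dialect expects CB/UB tags and a unique-gene annotation;
  it has not been exercised against the full output idiosyncrasies of any
  specific third-party tool.
* No ambient-RNA deconvolution or doublet detection; barcodes failing MAD
  filters are dropped, not corrected.
* HDF5 export requires the suggested `rhdf5` package; TSV/MTX output is the
  fallback.

## A worked example

```{r example, eval = FALSE}
cfg <- synth_config(n_genes = 20L, genes_per_contig = 20L, n_cells = 20L,
                    ambient_barcodes = 10L, molecules_per_cell = 30,
                    n_hom = 3L, n_het = 3L, n_edit_clusters = 1L)
ref <- generate_reference(cfg, seed = 7)
variants <- plant_variants(ref, cfg, seed = 7)
lib <- generate_library(ref, variants, cfg, seed = 7)
paths <- write_reference(ref, tempdir())
idx <- build_index(paths$gtf, paths$fasta)
run <- run_pipeline(lib$reads, idx, expected_cells = cfg$n_cells)
run$calls[, .(contig, pos, ref, alt, maf, n_barcodes, n_barcodes_alt)]
```
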