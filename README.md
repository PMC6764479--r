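# tdgf — discovery and validation of transcription-derived gene fusions

Transcriptional readthrough across two adjacent genes can yield a single
transcript carrying segments of both parents — a transcription-derived gene
fusion (TDGF), one of the routes by which genuinely new genes arise. `tdgf`
is an R package for finding such composite genes and validating them, aimed
at comparative genomicists working with protein-coding gene sets, RNA-seq
and ribosome-profiling reads, and genome interval annotations.

The method chain:

1. **Similarity network (SSN).** Pairwise local alignments (built-in
   Smith–Waterman with affine gaps, or a standard 12-column tabular hit
   file) are filtered to reciprocal-best edges (e-value ≤ 1e-5, self-hits
   removed) and thresholded at sequence-identity tiers of 70 / 80 / 90%.
2. **Composite detection.** A fused gene appears as a *non-transitive
   triplet* `a–c–b`: both parents align to disjoint regions of the
   composite but not to each other. Candidates are verified as *clique
   separators* (removing the composite disconnects its parent families) and
   filtered against distant-homology false positives.
3. **Breakpoints & probes.** Parents are re-aligned to the composite; the
   junction is the interval boundary (midpoint rule under gap/overlap), and
   junction probes take 50-nt flanks (RNA-seq) or 8-nt flanks (ribosome
   footprints).
4. **Junction expression.** After read QC (mean Phred ≥ 20, leading-base
   trim, footprint length > 25 nt), a read counts only if it spans the
   breakpoint with ≥ 8 nt on both sides at ≤ 2 mismatches, either strand.
   Expression is called at ≥ 1 / ≥ 3 / ≥ 5 spanning reads, with a pooled
   two-proportion z statistic for tissue enrichment and TPM for abundance.
5. **SD enrichment.** Overlap of fusion loci with segmental-duplication
   intervals is tested against 10,000 random same-size gene sets
   (add-one-corrected empirical p), with an exact hypergeometric tail as
   the analytic oracle.
6. **Phylogenetic origin.** Junction evidence across species gives a
   presence/absent/missing matrix; each fusion's origin is the MRCA of its
   present species (single-gain), tallied per tree node.

A synthetic-data generator (`simulation_config()`, `simulate_bundle()`,
`make_fixture()`) plants fusions, junction reads and SD placements with
known ground truth, so the entire chain is testable end to end.

## Worked example

```r
library(tdgf)

cfg <- simulation_config(seed = 1)       # 30 parent pairs, 10 fusions at 90%
bundle <- simulate_bundle(cfg)           # sequences, reads, BED, tree, truth
res <- run_fusion_pipeline(bundle, si_threshold = 80)
res
#> tdgf pipeline result (SI tier 80%)
#>   40 hits -> 20 reciprocal-best edges -> 20 SSN edges
#>   10 triplets -> 10 composites kept (0 filtered)
#>   10 breakpoints mapped; 4500 reads pass QC
#>   SD enrichment: 8/10 in SD, p = 0.0152
```

All 10 planted fusions are recovered as verified clique separators with no
false positives; breakpoints land within a few nucleotides of the planted
junctions (`res$breakpoints`), per-tissue junction counts and tiered
expression calls are in `res$counts`, and the SD permutation test
(`res$sd_test`) flags the 3x-enriched placement of fusion loci at
p ≈ 0.015 against a background where a random 10-gene set would typically
contain 3–4 SD-resident genes.

Individual stages are exposed directly — e.g.
`find_nontransitive_triplets()`, `verify_clique_separator()`,
`infer_breakpoint()`, `count_junction_reads()`, `permutation_test()`,
`assign_origin()` — and file-based workflows go through
`read_tabular_hits()`, `read_bed()`, `read_fastq()` and `parse_newick()`.

## Package layout

- `R/simulate.R` — synthetic bundles with planted truth
- `R/align.R`, `R/hits.R` — local alignment, tabular hits, SSN
- `R/composite.R` — triplets, clique separators, homology filter
- `R/breakpoint.R` — breakpoint inference and junction probes
- `R/expression.R` — read QC, junction counting, tiers, z, TPM
- `R/bed.R` — BED intervals, overlap, permutation test, hypergeometric tail
- `R/phylo.R` — Newick, presence matrix, origin assignment
- `R/pipeline.R` — end-to-end wrapper
- `vignettes/tdgf-methods.Rmd` — models, parameters and design rationale
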