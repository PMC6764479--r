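---
title: "Detecting transcription-derived gene fusions: models and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting transcription-derived gene fusions: models and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tdgf)
```

## The problem

Transcriptional readthrough across two adjacent genes can produce a single
transcript -- and potentially a single protein -- carrying segments of both
parents: a transcription-derived gene fusion (TDGF). Such composites are
interesting because they are a route to genuinely new genes, and because
their genomic context (notably segmental duplication, SD) is thought to
drive their formation. `tdgf` implements the full discovery-and-validation
chain for this question: detect composite genes from sequence similarity
alone, localize each fusion breakpoint, quantify transcription of the
junction itself from short reads, test whether fusion loci cluster in SD
regions, and place each fusion's origin on a species tree. A synthetic-data
generator with planted ground truth makes every stage testable end to end.

## Detection: similarity networks and graph decomposition

Detection operates on a sequence similarity network (SSN): nodes are genes,
and an undirected edge records a pairwise local-alignment hit above a
sequence-identity threshold. Hits come either from the built-in
Smith--Waterman engine (`local_align`, `all_vs_all_hits`; affine gaps via
`Biostrings::pairwiseAlignment`) or from a standard 12-column tabular hit
file (`read_tabular_hits`). Edges are reciprocal-best: the best hit per
ordered pair is kept under a deterministic tie rule (bit score, then
e-value, then lexicographic subject), and an edge survives only when hits
exist in both directions at e-value $\le 10^{-5}$, with self-hits removed.
Reciprocity is deliberately defined per pair rather than as a single best
target per query: a composite is the best partner of *each* of its parents
but can only have one global best itself, so a global-best rule would
disconnect every composite from one parent and make the fusion signature
(below) structurally undetectable.

Identity is thresholded at tiers of 70, 80 and 90% -- permissive tiers
admit older, more diverged fusions, stringent tiers isolate recent ones --
and the tiered edge sets are nested by construction.

A composite gene appears in the SSN as a **non-transitive triplet**
$a - c - b$: both parents align to the composite, in essentially disjoint
regions of it, while sharing no edge with each other. `tdgf` enumerates
these triplets (tolerating up to 20% overlap of the two parent intervals on
the composite, because local alignments fray at the junction), groups each
middle node's neighbors into parent families (connected components of the
neighbor-induced subgraph), and verifies the composite as a **clique
separator**: within its component, removing it must disconnect at least two
of its neighbor families. Two false-positive guards follow: a candidate is
discarded when any cross-family parent pair shares a pre-threshold hit at
$\ge$ 30% identity (the "parents" are then remote homologs of each other,
not independent genes), or when the family intervals on the composite
overlap by more than 20% of the shorter.

Multi-node clique separators are represented implicitly: several middle
nodes with identical family partitions each report the same families. Full
clique-minimal-separator decomposition by minimal triangulation is out of
scope; on desk-scale networks the triplet formulation is equivalent for
two-parent fusions, which is the case the biology targets.

## Breakpoints and junction probes

Each detected composite is re-aligned against one representative per parent
family in nucleotide space. With parent-A and parent-B intervals on the
composite, the breakpoint is: the boundary when the intervals abut; the
midpoint of the uncovered stretch when they leave a gap; the midpoint of
the doubly-covered stretch when they overlap. The midpoint is an unbiased,
deterministic tie rule for a quantity the alignments genuinely cannot pin
down more precisely. Breakpoints live on nucleotide coordinates because all
downstream evidence (probes, reads) is nucleotide-space.

A junction probe is the composite window of `flank` nt on each side of the
breakpoint: 50-nt flanks (100-nt probe) for RNA-seq, 8-nt flanks (~16-nt
probe) for ribosome footprints. Probes near a sequence end are truncated
and flagged.

## Junction expression

Reads are QC-filtered the way the original short-read data demanded: reads
with mean Phred below 20 are dropped and the leading 13 bases trimmed (RNA
mode); footprint mode keeps reads longer than 25 nt untrimmed. The Phred
floor is read as *mean* read quality -- a per-base reading would discard
essentially every read of a Q19-tailed library, which cannot be what a
threshold of 20 was meant to do.

A read supports a junction only if its best ungapped alignment to the
probe, on either strand, has at most 2 mismatches and covers at least 8 nt
on **both** sides of the breakpoint (capped at the flank for 16-nt
footprint probes); perfect one-flank matches never count. An
alignment-free mismatch-bounded scan is exact and sufficient here because
probes are at most 100 nt and only junction-spanning evidence is wanted; no
genome-wide mapper is involved. Counts yield tiered expression calls at
$\ge 1$, $\ge 3$ and $\ge 5$ reads. The primary call is $\ge 1$ -- the
junction is a ~100-nt target, so even genuine transcription yields few
spanning reads -- with the stricter tiers exposed for sensitivity analysis.

Per-tissue enrichment uses the pooled two-proportion $z$ statistic
comparing the fraction of fusions expressed in one tissue against the
remaining tissues pooled, with upper-tail one-sided and doubled two-sided
p-values; a degenerate pooled variance returns $z = 0$ (one-sided $p$ =
0.5, two-sided $p$ = 1). TPM is computed as length-normalized rates scaled
to $10^6$ so probe abundance is comparable to the background transcriptome.

## SD enrichment

Gene loci and SD blocks are 0-based half-open BED intervals; a gene
overlaps SD when at least one nucleotide intersects (binary, not
base-weighted; half-open abutment is not overlap). The test statistic is
the number $k$ of focal (fusion) genes overlapping SD. The null resamples
gene sets of the same size uniformly without replacement from all
protein-coding loci, 10,000 replicates by default, with the add-one
correction $p = (1 + \#\{\text{null} \ge k\})/(R + 1)$ so $p$ is never 0.
The focal size is always an explicit argument, never defaulted. This null
is exactly hypergeometric, and `hypergeometric_tail` (log-space direct
summation) is carried alongside as the analytic oracle the permutation
estimate must agree with.

### Null calibration and discreteness

The permutation p-value is a discrete statistic: under the null its
distribution is sub-uniform, stepping only at the achievable tail
probabilities. A raw Kolmogorov--Smirnov test against $U(0,1)$ would
therefore reject a *perfectly calibrated* test whenever the largest null
mass (the modal hypergeometric probability) is comparable to the KS
critical distance. The calibration check in the test suite instead applies
KS to the randomized probability integral transform computed from the same
permutation null counts -- the standard uniformity device for discrete
tests -- and separately verifies that the raw p-values are not
anti-conservative at $\alpha = 0.05$.

## Phylogenetic origin

Junction counts across species produce a presence matrix with three states:
present (expressed at the tier in at least one tissue), absent (data, no
expression), and missing (no read data). Missing is not absent: species
without data are simply ignored. Each fusion's origin is the most recent
common ancestor of its present tips (single-gain, Dollo-style; a
single-species fusion sits on that tip), and per-node counts tally origins
over the tree. Loss modeling is out of scope; with presence driven by
transcription evidence, "absent" conflates never-gained with
lost-or-silent, which is exactly why the conservative single-gain reading
is used.

## The synthetic generator

`simulation_config()` fixes the reference study conditions; all tests and
the acceptance script run against them:

| parameter | default | meaning |
|---|---|---|
| `n_parent_pairs` | 30 | unrelated coding gene pairs, 300--600 nt |
| `target_identity` | 0.90 | parent-composite nucleotide identity |
| `n_fusions` | 10 | readthrough fusions (prefix of A + suffix of B) |
| `fusion_fracA/B` | 0.5 | parent fraction retained on each side |
| `read_length` | 76 | single-end read length, nt |
| `read_depth` | 10 | background reads per transcript per tissue |
| `junction_reads_per_fusion` | 5 | planted spanning reads per tissue |
| `base_error_rate` | 0 | per-base substitution rate |
| `tissues` | 6 labels | brain, cerebellum, heart, kidney, liver, testis |
| `genome_length` | 1 Mb | single synthetic chromosome |
| `n_sd_intervals` x `sd_interval_len` | 30 x 10 kb | SD blocks (30% of genome) |
| `sd_enrichment` | 3 | fusion in-SD probability multiplier |

Mutation to a target identity uses point substitutions at exactly
`round((1 - t) L)` distinct positions, so realized identity equals the
target up to rounding. Planted junction reads cover the true breakpoint
with at least 8 nt on each side; background reads on fusion transcripts are
resampled away from the junction so that *exactly* the planted reads span
it -- this is what makes the junction counter exactly testable. Qualities
follow the simplest model that exercises the QC filters: constant per read
at $-10\log_{10}$(error rate) (Q40 when error-free), ASCII+33. Tissue
labels ride in the read name (`|tissue=X`), since FASTQ has no tissue
field.

The SD share of the synthetic genome (30%) is far above the genome-wide
human value; it was chosen once so that a ~70-gene universe gives the
permutation test measurable contrast at 10 fusion loci, with the enriched
condition ($\times 3$, near-saturating) producing in-SD fractions similar
to the observed biology, and it is not a tuning knob. The generator does
not attempt splicing, paralog families beyond pairs, platform error
profiles, or paired ends -- so passing tests demonstrate correctness of the
machinery under the stated model, not robustness to every artifact of real
libraries.

Two testing-specific conventions follow from the generator's design. The
end-to-end runs detect at the **80% tier** with identity planted at 0.90:
the mutated positions distribute hypergeometrically across the two parent
segments, so per-segment realized identity fluctuates around 90% by a
couple of percent, and the tier must sit below the planted identity --
mirroring how the tiers are used on real data. Tier *semantics* are tested
separately (identity 0.75 is detected at the 70% tier and invisible at
90%; identity 0.95 at all three). And QC in synthetic runs uses
`trim_leading = 0`: the leading-base trim exists to remove a base-caller
artifact that the generator intentionally does not produce.

## Numerical choices

* Coordinates are 0-based half-open everywhere internally; conversion
  happens only at format boundaries (tabular hits, BED, GRanges).
* The internal aligner reports a crude ungapped Karlin--Altschul e-value
  (for the default +2/−2 scheme, $\lambda = \log 3 / 2$ exactly) so the
  e-value cutoff applies uniformly to internal and external hits; the
  reporting floor `min_score = 50` keeps chance word matches between
  unrelated 300--600-nt sequences out of the network.
* All orderings (edges, triplets, candidates, families) are deterministic,
  and every stochastic step takes an explicit seed; fixture bundles are
  byte-identical across reruns of the same configuration.
* Problem sizes in the test suite (60 + 10 sequences end to end, 100
  random graphs of up to 15 nodes against exhaustive oracles, 20
  permutation-versus-hypergeometric configurations at 10,000 replicates,
  100-seed null calibration at 2,000 replicates) were chosen as the
  smallest scales at which the statistical assertions have power.

## Known limitations

* Breakpoint precision is limited by alignment fraying: at 10% parent
  divergence the inferred position is within ±6 nt of truth in ≥95% of
  cases, not exact. The midpoint rule is unbiased but cannot beat the
  information in the alignments.
* Composites with more than two parent families are carried structurally
  but none of the defaults are tuned for them.
* The tissue-enrichment z treats fusions as independent and tissues as
  exchangeable; it is a screening statistic, not a mixed model.
* Cross-species presence relies on junction reads only; absence of
  evidence in a poorly covered species shows up as "absent", not
  "missing", whenever any reads exist for that species.
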