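#' Run the fusion-discovery pipeline on a synthetic bundle
#'
#' Chains every analysis stage on a bundle from
#' \code{\link{simulate_bundle}} / \code{\link{read_fixture}}:
#' all-versus-all local alignment, reciprocal-best edge filtering, SSN
#' construction at the requested identity tier, non-transitive triplet
#' detection with clique-separator verification, distant-homology
#' filtering, breakpoint mapping, junction-probe construction, read QC,
#' junction-spanning read counting per tissue with tiered expression
#' calls, tissue enrichment, and the SD-overlap permutation test over the
#' fusion loci.
#'
#' @param bundle a fixture bundle (in-memory or loaded from disk).
#' @param si_threshold identity tier for the SSN (default 80).
#' @param flank junction-probe flank in nt (default 50, RNA-seq mode).
#' @param scoring nucleotide scoring scheme.
#' @param max_overlap_fraction triplet interval-overlap tolerance.
#' @param min_overhang,max_mismatches junction-counting parameters.
#' @param trim_leading leading-base trim for read QC. The default for
#'   synthetic bundles is 0: the generator's reads carry no base-caller
#'   artifact at the 5' end, which is what the trim exists to remove.
#' @param replicates permutation replicates for the SD test.
#' @param seed seed for the permutation test (defaults to the bundle's).
#' @return list of class \code{"tdgf_result"}: hits, edges, ssn,
#'   triplets, candidates (kept), removed, breakpoints, probes, reads_qc,
#'   counts, calls, enrichment, sd_test.
#' @export
run_fusion_pipeline <- function(bundle, si_threshold = 80, flank = 50L,
                                scoring = nt_scoring(),
                                max_overlap_fraction = 0.2,
                                min_overhang = 8L, max_mismatches = 2L,
                                trim_leading = 0L,
                                replicates = 10000L, seed = NULL) {
  if (is.null(seed)) seed <- bundle$config$seed
  transcripts <- rbind(bundle$parents[, c("id", "nt")],
                       bundle$fusions[, c("id", "nt")])
  hits <- all_vs_all_hits(transcripts, scoring)
  edges <- best_reciprocal_edges(hits)
  ssn <- build_ssn(edges, si_threshold, nodes = transcripts$id)
  triplets <- find_nontransitive_triplets(ssn, max_overlap_fraction)
  cands <- aggregate_composites(ssn, triplets)
  flt <- filter_distant_homology(cands, hits)
  seqs <- stats::setNames(transcripts$nt, transcripts$id)
  breakpoints <- map_breakpoints(flt$kept, seqs, scoring)
  probes <- lapply(seq_len(nrow(breakpoints)), function(i)
    make_junction_probe(seqs[[breakpoints$composite_id[i]]],
                        breakpoints[i, ], flank = flank))
  reads_qc <- qc_filter_reads(bundle$reads, trim_leading = trim_leading,
                              mode = "rna")
  counts <- if (length(probes))
    count_junction_matrix(probes, reads_qc, species = "human",
                          min_overhang = min_overhang,
                          max_mismatches = max_mismatches)
  else NULL
  calls <- enrichment <- NULL
  if (!is.null(counts) && nrow(counts)) {
    calls <- junction_calls_matrix(counts)
    if (ncol(calls) >= 2L) enrichment <- tissue_enrichment(calls)
  }
  sd_test <- NULL
  if (nrow(bundle$truth)) {
    sd_test <- permutation_test(bundle$genes, bundle$sd,
                                focal_labels = bundle$truth$fusion_id,
                                replicates = replicates, seed = seed)
  }
  structure(list(hits = hits, edges = edges, ssn = ssn,
                 triplets = triplets, candidates = flt$kept,
                 removed = flt$removed, breakpoints = breakpoints,
                 probes = probes, reads_qc = reads_qc, counts = counts,
                 calls = calls, enrichment = enrichment, sd_test = sd_test,
                 si_threshold = si_threshold),
            class = "tdgf_result")
}

# fusions x tissues logical matrix of tier-1 expression calls
junction_calls_matrix <- function(counts, tier = 1L) {
  fus <- sort(unique(counts$composite_id))
  tis <- sort(unique(counts$tissue))
  mat <- matrix(FALSE, length(fus), length(tis), dimnames = list(fus, tis))
  for (i in seq_len(nrow(counts)))
    mat[counts$composite_id[i], counts$tissue[i]] <-
      counts$count[i] >= tier
  mat
}

#' @export
print.tdgf_result <- function(x, ...) {
  cat(sprintf("tdgf pipeline result (SI tier %s%%)\n", format(x$si_threshold)))
  cat(sprintf("  %d hits -> %d reciprocal-best edges -> %d SSN edges\n",
              nrow(x$hits), nrow(x$edges), nrow(x$ssn$edges)))
  cat(sprintf("  %d triplets -> %d composites kept (%d filtered)\n",
              nrow(x$triplets), length(x$candidates), length(x$removed)))
  cat(sprintf("  %d breakpoints mapped; %d reads pass QC\n",
              nrow(x$breakpoints), nrow(x$reads_qc)))
  if (!is.null(x$sd_test))
    cat(sprintf("  SD enrichment: %d/%d in SD, p = %.4g\n",
                x$sd_test$observed_overlap, x$sd_test$focal_size,
                x$sd_test$p_empirical))
  invisible(x)
}
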