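#' Align a parent gene onto its composite
#'
#' Best local alignment interval of the parent on the composite nucleotide
#' sequence (same alignment engine as \code{\link{local_align}}); this is
#' how each parent's contributed segment is delimited before breakpoint
#' inference.
#'
#' @param composite_nt,parent_nt nucleotide sequences.
#' @param scoring a \code{\link{nt_scoring}} scheme.
#' @return integer vector \code{c(start, end)}, 0-based half-open on the
#'   composite, or \code{NULL} when no alignment reaches the minimum score.
#' @export
align_parent_to_composite <- function(composite_nt, parent_nt,
                                      scoring = nt_scoring()) {
  hit <- local_align(composite_nt, parent_nt, scoring,
                     query_id = "composite", subject_id = "parent")
  if (is.null(hit)) return(NULL)
  c(start = hit$query_start, end = hit$query_end)
}

#' Infer a fusion breakpoint from the two parent intervals
#'
#' With the parent-A interval preceding the parent-B interval on the
#' composite, three configurations arise. Abutting intervals put the
#' breakpoint exactly at the boundary. When the intervals leave a gap
#' (alignments frayed back from the junction) or overlap (alignments
#' extended past it), the breakpoint is the midpoint of the ambiguous
#' stretch -- an unbiased, deterministic tie rule. The junction lies
#' between composite positions \code{position - 1} and \code{position}
#' (0-based).
#'
#' @param intervalA,intervalB numeric \code{c(start, end)} on the composite,
#'   0-based half-open; A must start before B.
#' @param composite_id,parentA_id,parentB_id identifiers carried through.
#' @return one-row data.frame: composite_id, position, parentA_id,
#'   parentB_id, a_start, a_end, b_start, b_end, mode ("abutting", "gap" or
#'   "overlap").
#' @export
infer_breakpoint <- function(intervalA, intervalB, composite_id = "composite",
                             parentA_id = "parentA", parentB_id = "parentB") {
  sA <- intervalA[[1]]; eA <- intervalA[[2]]
  sB <- intervalB[[1]]; eB <- intervalB[[2]]
  if (sA >= sB) stopf("parent A's interval must start before parent B's")
  if (eB <= eA)
    stopf("ambiguous breakpoint: one parent interval is contained in the other")
  mode <- if (eA == sB) "abutting" else if (eA < sB) "gap" else "overlap"
  position <- if (mode == "abutting") eA else (eA + sB) %/% 2
  data.frame(composite_id = composite_id,
             position = as.integer(position),
             parentA_id = parentA_id, parentB_id = parentB_id,
             a_start = as.integer(sA), a_end = as.integer(eA),
             b_start = as.integer(sB), b_end = as.integer(eB),
             mode = mode, stringsAsFactors = FALSE)
}

#' Extract a junction probe around a breakpoint
#'
#' The probe is the composite subsequence covering \code{flank} nt on each
#' side of the breakpoint: 50-nt flanks (100-nt probe) for RNA-seq
#' junction counting, 8-nt flanks (16-nt probe) for ribosome footprints.
#' Near a sequence end the probe is truncated and flagged.
#'
#' @param composite_nt composite nucleotide sequence.
#' @param breakpoint breakpoint row (from \code{\link{infer_breakpoint}}) or
#'   a bare 0-based position.
#' @param flank requested nt per side.
#' @param composite_id identifier (defaults to the breakpoint's).
#' @return object of class \code{"tdgf_probe"}: list with composite_id,
#'   sequence, breakpoint_offset, flank, truncated.
#' @export
make_junction_probe <- function(composite_nt, breakpoint, flank = 50L,
                                composite_id = NULL) {
  p <- if (is.data.frame(breakpoint)) breakpoint$position else
    as.integer(breakpoint)
  if (is.null(composite_id))
    composite_id <- if (is.data.frame(breakpoint)) breakpoint$composite_id
      else "composite"
  L <- nchar(composite_nt)
  if (p <= 0L || p >= L)
    stopf("breakpoint at a sequence boundary (position %d of %d nt)", p, L)
  lo <- max(0L, p - flank); hi <- min(L, p + flank)
  structure(list(composite_id = composite_id,
                 sequence = substr(composite_nt, lo + 1L, hi),
                 breakpoint_offset = p - lo,
                 flank = as.integer(flank),
                 truncated = (lo > p - flank) || (hi < p + flank)),
            class = "tdgf_probe")
}

#' @export
print.tdgf_probe <- function(x, ...) {
  cat(sprintf(">%s|bp=%d|flank=%d%s\n%s\n", x$composite_id,
              x$breakpoint_offset, x$flank,
              if (x$truncated) "|truncated" else "", x$sequence))
  invisible(x)
}

#' Map breakpoints for a set of composite candidates
#'
#' For each candidate, one representative parent per family (the first
#' member in sorted order, for determinism) is re-aligned to the composite
#' nucleotide sequence; the first two families along the composite define
#' the A and B intervals handed to
#' \code{\link{infer_breakpoint}}. Candidates whose parents fail to align
#' are skipped with a warning.
#'
#' @param candidates a \code{"tdgf_candidates"} list.
#' @param sequences named character vector (or data.frame id/nt) holding the
#'   composite and parent nucleotide sequences.
#' @param scoring a \code{\link{nt_scoring}} scheme.
#' @return data.frame of breakpoints (see \code{\link{infer_breakpoint}}).
#' @export
map_breakpoints <- function(candidates, sequences, scoring = nt_scoring()) {
  if (is.data.frame(sequences))
    sequences <- stats::setNames(sequences$nt, sequences$id)
  out <- list()
  for (cand in candidates) {
    comp_nt <- sequences[[cand$composite_id]]
    if (is.null(comp_nt)) stopf("no sequence for composite '%s'",
                                cand$composite_id)
    reps <- vapply(seq_along(cand$families), function(i) {
      members <- cand$families[[i]]
      members[1L]
    }, character(1))
    ivals <- lapply(reps[1:2], function(pid) {
      pnt <- sequences[[pid]]
      if (is.null(pnt)) stopf("no sequence for parent '%s'", pid)
      align_parent_to_composite(comp_nt, pnt, scoring)
    })
    if (any(vapply(ivals, is.null, logical(1)))) {
      warning(sprintf("parents of '%s' did not align; candidate skipped",
                      cand$composite_id), call. = FALSE)
      next
    }
    # orient: the interval starting first is A
    ord <- order(vapply(ivals, `[[`, 0, 1L))
    bp <- tryCatch(
      infer_breakpoint(ivals[[ord[1]]], ivals[[ord[2]]],
                       composite_id = cand$composite_id,
                       parentA_id = reps[ord[1]], parentB_id = reps[ord[2]]),
      error = function(e) {
        warning(sprintf("composite '%s': %s", cand$composite_id,
                        conditionMessage(e)), call. = FALSE)
        NULL
      })
    if (!is.null(bp)) out[[length(out) + 1L]] <- bp
  }
  if (!length(out))
    return(data.frame(composite_id = character(0), position = integer(0),
                      parentA_id = character(0), parentB_id = character(0),
                      a_start = integer(0), a_end = integer(0),
                      b_start = integer(0), b_end = integer(0),
                      mode = character(0), stringsAsFactors = FALSE))
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Write junction probes as FASTA
#'
#' Probe identifiers carry the breakpoint offset and flank
#' (\code{>fusion7|bp=300|flank=50}).
#'
#' @param probes list of \code{"tdgf_probe"} objects.
#' @param path output path.
#' @export
write_probes_fasta <- function(probes, path) {
  x <- Biostrings::DNAStringSet(vapply(probes, `[[`, "", "sequence"))
  names(x) <- vapply(probes, function(p)
    sprintf("%s|bp=%d|flank=%d", p$composite_id, p$breakpoint_offset,
            p$flank), "")
  Biostrings::writeXStringSet(x, filepath = path)
}
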