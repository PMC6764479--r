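#' Scoring schemes for local alignment
#'
#' \code{nt_scoring} builds a match/mismatch nucleotide scheme with affine
#' gaps; \code{aa_scoring} selects a named protein substitution matrix
#' (e.g. "BLOSUM62"). \code{min_score} is the reporting floor: local
#' alignments scoring below it are treated as "no hit", which is what keeps
#' spurious short word matches between unrelated sequences out of the
#' similarity network. The Karlin-Altschul parameters \code{lambda} and
#' \code{K} give hits a crude ungapped e-value so the reciprocal-best
#' e-value cutoff is applicable to internally computed hits; for the default
#' +2/-2 nucleotide scheme with uniform base composition lambda solves
#' 0.25 e^{2L} + 0.75 e^{-2L} = 1 exactly (lambda = log(3)/2).
#'
#' @param match,mismatch nucleotide match reward / mismatch penalty.
#' @param gap_open,gap_extend affine gap penalties (positive numbers).
#' @param min_score minimum local-alignment score to report a hit.
#' @param lambda,K Karlin-Altschul parameters for the e-value.
#' @return a list of class \code{"tdgf_scoring"}.
#' @export
nt_scoring <- function(match = 2, mismatch = -2, gap_open = 10,
                       gap_extend = 4, min_score = 50,
                       lambda = NULL, K = 0.1) {
  if (is.null(lambda)) lambda <- ka_lambda(match, mismatch)
  structure(list(type = "nt", match = match, mismatch = mismatch,
                 gap_open = gap_open, gap_extend = gap_extend,
                 min_score = min_score, lambda = lambda, K = K),
            class = "tdgf_scoring")
}

#' @rdname nt_scoring
#' @param matrix name of a protein substitution matrix shipped with
#'   Biostrings.
#' @export
aa_scoring <- function(matrix = "BLOSUM62", gap_open = 10, gap_extend = 4,
                       min_score = 50, lambda = 0.267, K = 0.041) {
  structure(list(type = "aa", matrix = matrix,
                 gap_open = gap_open, gap_extend = gap_extend,
                 min_score = min_score, lambda = lambda, K = K),
            class = "tdgf_scoring")
}

# Ungapped Karlin-Altschul lambda for a match/mismatch scheme under uniform
# base composition: solves sum_ij p_i p_j exp(lambda * s_ij) = 1.
ka_lambda <- function(match, mismatch) {
  if (match <= 0 || mismatch >= 0) stopf("need match > 0 and mismatch < 0")
  f <- function(l) 0.25 * exp(l * match) + 0.75 * exp(l * mismatch) - 1
  stats::uniroot(f, c(1e-6, 10))$root
}

subst_matrix <- function(scoring) {
  if (scoring$type == "nt") {
    Biostrings::nucleotideSubstitutionMatrix(match = scoring$match,
                                             mismatch = scoring$mismatch,
                                             baseOnly = TRUE)
  } else {
    get(data(list = scoring$matrix, package = "Biostrings",
             envir = environment()))
  }
}

#' Optimal local alignment between two sequences
#'
#' Smith-Waterman local alignment with affine gap penalties (via
#' \code{Biostrings::pairwiseAlignment}). Identity is computed as matching
#' columns divided by all alignment columns, gap columns included in the
#' denominator. Returns \code{NULL} when the best score falls below
#' \code{scoring$min_score}.
#'
#' @param seqA,seqB sequences (character). Nucleotide for \code{nt_scoring},
#'   amino acid for \code{aa_scoring}.
#' @param scoring a \code{\link{nt_scoring}} / \code{\link{aa_scoring}}.
#' @param query_id,subject_id identifiers stamped on the returned hit.
#' @return one-row hit data.frame (see \code{\link{read_tabular_hits}} for
#'   the columns) or \code{NULL}.
#' @export
local_align <- function(seqA, seqB, scoring = nt_scoring(),
                        query_id = "query", subject_id = "subject") {
  if (!nzchar(seqA) || !nzchar(seqB)) stopf("cannot align empty sequences")
  xs <- if (scoring$type == "nt") Biostrings::DNAString(seqA) else
    Biostrings::AAString(seqA)
  ys <- if (scoring$type == "nt") Biostrings::DNAString(seqB) else
    Biostrings::AAString(seqB)
  aln <- Biostrings::pairwiseAlignment(
    xs, ys, type = "local", substitutionMatrix = subst_matrix(scoring),
    gapOpening = scoring$gap_open, gapExtension = scoring$gap_extend)
  s <- Biostrings::score(aln)
  if (s < scoring$min_score) return(NULL)
  cols <- nchar(as.character(Biostrings::pattern(aln)))
  matches <- Biostrings::nmatch(aln)
  mism <- Biostrings::nmismatch(aln)
  ev <- scoring$K * nchar(seqA) * nchar(seqB) * exp(-scoring$lambda * s)
  data.frame(query_id = query_id, subject_id = subject_id,
             percent_identity = 100 * matches / cols,
             alignment_length = cols,
             mismatches = mism,
             gap_opens = cols - matches - mism,
             query_start = Biostrings::start(Biostrings::pattern(aln)) - 1L,
             query_end = Biostrings::end(Biostrings::pattern(aln)),
             subject_start = Biostrings::start(Biostrings::subject(aln)) - 1L,
             subject_end = Biostrings::end(Biostrings::subject(aln)),
             e_value = ev, bit_score = s,
             subject_strand = "+",
             stringsAsFactors = FALSE)
}

#' All-versus-all similarity hits for a sequence set
#'
#' Runs \code{\link{local_align}} over every unordered pair and emits both
#' hit orientations (the local alignment problem is symmetric, so the
#' reverse hit is the same alignment with query and subject swapped).
#' Self-comparisons are not generated.
#'
#' @param seqs data.frame with columns \code{id}, \code{nt} (or \code{aa}
#'   sequences under \code{nt} for protein scoring).
#' @param scoring a scoring scheme.
#' @return hit data.frame (possibly 0 rows).
#' @export
all_vs_all_hits <- function(seqs, scoring = nt_scoring()) {
  n <- nrow(seqs)
  if (n < 2L) return(empty_hits())
  mk <- function(x) if (scoring$type == "nt") Biostrings::DNAStringSet(x)
    else Biostrings::AAStringSet(x)
  sm <- subst_matrix(scoring)
  out <- list(); k <- 0L
  # one vectorized call per subject: all earlier sequences as patterns
  for (j in seq(2L, n)) {
    pat <- mk(seqs$nt[seq_len(j - 1L)])
    aln <- Biostrings::pairwiseAlignment(
      pat, mk(seqs$nt[j])[[1]], type = "local", substitutionMatrix = sm,
      gapOpening = scoring$gap_open, gapExtension = scoring$gap_extend)
    s <- Biostrings::score(aln)
    keep <- which(s >= scoring$min_score)
    if (!length(keep)) next
    cols <- nchar(as.character(Biostrings::pattern(aln)))[keep]
    matches <- Biostrings::nmatch(aln)[keep]
    mism <- Biostrings::nmismatch(aln)[keep]
    ev <- scoring$K * nchar(seqs$nt[keep]) * nchar(seqs$nt[j]) *
      exp(-scoring$lambda * s[keep])
    h <- data.frame(
      query_id = seqs$id[keep], subject_id = seqs$id[j],
      percent_identity = 100 * matches / cols,
      alignment_length = cols,
      mismatches = mism, gap_opens = cols - matches - mism,
      query_start = Biostrings::start(Biostrings::pattern(aln))[keep] - 1L,
      query_end = Biostrings::end(Biostrings::pattern(aln))[keep],
      subject_start = Biostrings::start(Biostrings::subject(aln))[keep] - 1L,
      subject_end = Biostrings::end(Biostrings::subject(aln))[keep],
      e_value = ev, bit_score = s[keep], subject_strand = "+",
      stringsAsFactors = FALSE)
    rev <- h
    rev$query_id <- h$subject_id; rev$subject_id <- h$query_id
    rev$query_start <- h$subject_start; rev$query_end <- h$subject_end
    rev$subject_start <- h$query_start; rev$subject_end <- h$query_end
    k <- k + 1L; out[[k]] <- rbind(h, rev)
  }
  if (k == 0L) return(empty_hits())
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

empty_hits <- function() {
  data.frame(query_id = character(0), subject_id = character(0),
             percent_identity = numeric(0), alignment_length = integer(0),
             mismatches = integer(0), gap_opens = integer(0),
             query_start = integer(0), query_end = integer(0),
             subject_start = integer(0), subject_end = integer(0),
             e_value = numeric(0), bit_score = numeric(0),
             subject_strand = character(0), stringsAsFactors = FALSE)
}
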