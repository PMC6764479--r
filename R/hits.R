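#' Read pairwise similarity hits in 12-column tabular format
#'
#' Parses the standard 12-column tab-separated hit dialect (query, subject,
#' percent identity, alignment length, mismatches, gap opens, query start,
#' query end, subject start, subject end, e-value, bit score). Coordinates
#' in the file are 1-based inclusive; internally everything is 0-based
#' half-open, so starts are decremented and ends kept. Subject coordinates
#' given in reverse orientation (start > end) are normalized and flagged
#' with \code{subject_strand == "-"}.
#'
#' @param path file path.
#' @return hit data.frame (columns as in \code{\link{local_align}}).
#' @export
read_tabular_hits <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  if (!length(lines)) return(empty_hits())
  parts <- strsplit(lines, "\t", fixed = TRUE)
  bad <- which(lengths(parts) != 12L)
  if (length(bad))
    stopf("line %d: expected 12 tab-separated fields, found %d",
          bad[1], lengths(parts)[bad[1]])
  m <- do.call(rbind, parts)
  num <- function(col, name) {
    v <- suppressWarnings(as.numeric(m[, col]))
    if (anyNA(v))
      stopf("line %d: non-numeric value in field '%s'", which(is.na(v))[1], name)
    v
  }
  qs <- num(7, "query_start"); qe <- num(8, "query_end")
  ss <- num(9, "subject_start"); se <- num(10, "subject_end")
  if (any(qs > qe))
    stopf("line %d: reverse-oriented query coordinates are not supported",
          which(qs > qe)[1])
  strand <- ifelse(ss > se, "-", "+")
  s_lo <- pmin(ss, se); s_hi <- pmax(ss, se)
  data.frame(query_id = m[, 1], subject_id = m[, 2],
             percent_identity = num(3, "percent_identity"),
             alignment_length = as.integer(num(4, "alignment_length")),
             mismatches = as.integer(num(5, "mismatches")),
             gap_opens = as.integer(num(6, "gap_opens")),
             query_start = as.integer(qs) - 1L,
             query_end = as.integer(qe),
             subject_start = as.integer(s_lo) - 1L,
             subject_end = as.integer(s_hi),
             e_value = num(11, "e_value"),
             bit_score = num(12, "bit_score"),
             subject_strand = strand,
             stringsAsFactors = FALSE)
}

#' Write hits back to the 12-column tabular dialect
#'
#' Inverse of \code{\link{read_tabular_hits}}: converts the internal 0-based
#' half-open coordinates back to 1-based inclusive and restores reverse
#' subject orientation for minus-strand hits.
#'
#' @param hits hit data.frame.
#' @param path output path.
#' @export
write_tabular_hits <- function(hits, path) {
  minus <- hits$subject_strand == "-"
  ss <- ifelse(minus, hits$subject_end, hits$subject_start + 1L)
  se <- ifelse(minus, hits$subject_start + 1L, hits$subject_end)
  out <- data.frame(hits$query_id, hits$subject_id,
                    sprintf("%.2f", hits$percent_identity),
                    hits$alignment_length, hits$mismatches, hits$gap_opens,
                    hits$query_start + 1L, hits$query_end, ss, se,
                    format(hits$e_value, digits = 3),
                    format(hits$bit_score, digits = 4))
  utils::write.table(out, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
}

#' Reciprocal-best edges from a hit list
#'
#' Implements the reciprocal-best-hit criterion used to draw similarity
#' network edges: self-hits are removed, hits above the e-value cutoff are
#' removed, and for each ordered pair only the best hit is kept (highest
#' bit score, then lowest e-value, then lexicographically smallest
#' subject -- a deterministic tie rule). An undirected edge (a, b)
#' survives iff the surviving hit list supports it reciprocally, i.e. a
#' hits b and b hits a. Reciprocity is deliberately per pair rather than
#' "single best target per query": a composite gene is the best partner of
#' each of its parents, but can itself have only one single best partner,
#' so a global-best rule would disconnect every composite from one parent
#' and make fusion signatures undetectable. Each edge carries the aligned
#' interval on both endpoints and the mean percent identity of the two
#' directions.
#'
#' @param hits hit data.frame.
#' @param evalue_max e-value cutoff (default 1e-5).
#' @return edge data.frame: node_a, node_b (node_a < node_b),
#'   percent_identity, a_start, a_end (hit interval on node_a),
#'   b_start, b_end (on node_b), e_value.
#' @export
best_reciprocal_edges <- function(hits, evalue_max = 1e-5) {
  if (!nrow(hits)) return(empty_edges())
  hits <- hits[hits$query_id != hits$subject_id, , drop = FALSE]
  hits <- hits[hits$e_value <= evalue_max, , drop = FALSE]
  if (!nrow(hits)) return(empty_edges())
  # deterministic best hit per ordered pair
  ord <- order(hits$query_id, -hits$bit_score, hits$e_value, hits$subject_id)
  hits <- hits[ord, , drop = FALSE]
  best_pair <- hits[!duplicated(paste(hits$query_id, hits$subject_id,
                                      sep = "\r")), , drop = FALSE]
  key <- function(q, s) paste(q, s, sep = "\r")
  reciprocal <- key(best_pair$subject_id, best_pair$query_id) %in%
    key(best_pair$query_id, best_pair$subject_id)
  mutual <- best_pair[reciprocal & best_pair$query_id < best_pair$subject_id,
                      , drop = FALSE]
  if (!nrow(mutual)) return(empty_edges())
  # interval on node_b comes from the reverse-direction best hit
  rev_idx <- match(key(mutual$subject_id, mutual$query_id),
                   key(best_pair$query_id, best_pair$subject_id))
  revh <- best_pair[rev_idx, , drop = FALSE]
  edges <- data.frame(node_a = mutual$query_id, node_b = mutual$subject_id,
                      percent_identity =
                        (mutual$percent_identity + revh$percent_identity) / 2,
                      a_start = mutual$query_start, a_end = mutual$query_end,
                      b_start = revh$query_start, b_end = revh$query_end,
                      e_value = pmax(mutual$e_value, revh$e_value),
                      stringsAsFactors = FALSE)
  edges <- edges[order(edges$node_a, edges$node_b), , drop = FALSE]
  rownames(edges) <- NULL
  edges
}

empty_edges <- function() {
  data.frame(node_a = character(0), node_b = character(0),
             percent_identity = numeric(0),
             a_start = integer(0), a_end = integer(0),
             b_start = integer(0), b_end = integer(0),
             e_value = numeric(0), stringsAsFactors = FALSE)
}

#' Build a sequence similarity network at an identity threshold
#'
#' Retains reciprocal-best edges whose percent identity is at least
#' \code{si_threshold} and records the threshold on the network. All node
#' identifiers are kept, so genes that lose every edge at a stringent tier
#' remain as isolated nodes. Edge sets are nested across tiers:
#' \code{E(90)} is a subset of \code{E(80)} is a subset of \code{E(70)}.
#'
#' @param edges edge data.frame from \code{\link{best_reciprocal_edges}}.
#' @param si_threshold sequence-identity threshold in [0, 100]; the study
#'   tiers are 70, 80 and 90.
#' @param nodes optional character vector of node identifiers to keep even
#'   when isolated (defaults to the nodes present in \code{edges}).
#' @return an object of class \code{"tdgf_ssn"}: list with \code{nodes},
#'   \code{edges}, \code{si_threshold}.
#' @export
build_ssn <- function(edges, si_threshold, nodes = NULL) {
  if (!is.numeric(si_threshold) || si_threshold < 0 || si_threshold > 100)
    stopf("si_threshold must be in [0, 100]")
  if (is.null(nodes)) nodes <- sort(unique(c(edges$node_a, edges$node_b)))
  keep <- edges$percent_identity >= si_threshold
  structure(list(nodes = nodes,
                 edges = edges[keep, , drop = FALSE],
                 si_threshold = si_threshold),
            class = "tdgf_ssn")
}

#' @export
print.tdgf_ssn <- function(x, ...) {
  cat(sprintf("tdgf SSN: %d nodes, %d edges at SI >= %s%%\n",
              length(x$nodes), nrow(x$edges), format(x$si_threshold)))
  invisible(x)
}

# igraph view of an SSN (undirected, simple).
ssn_graph <- function(ssn) {
  igraph::graph_from_data_frame(
    ssn$edges[, c("node_a", "node_b"), drop = FALSE],
    directed = FALSE,
    vertices = data.frame(name = ssn$nodes, stringsAsFactors = FALSE))
}

# Named list: for node `v`, data.frame of neighbors with the hit interval of
# each neighbor's alignment ON `v`.
neighbor_intervals <- function(ssn, v) {
  e <- ssn$edges
  left <- e[e$node_a == v, , drop = FALSE]
  right <- e[e$node_b == v, , drop = FALSE]
  data.frame(
    neighbor = c(left$node_b, right$node_a),
    start = c(left$a_start, right$b_start),
    end = c(left$a_end, right$b_end),
    stringsAsFactors = FALSE)
}
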