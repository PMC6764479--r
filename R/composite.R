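#' Find non-transitive triplets in a similarity network
#'
#' A non-transitive triplet (a, c, b) is the elementary signature of a
#' composite gene: both parents a and b align to the composite c, a and b
#' share no edge with each other, and their alignments occupy essentially
#' different regions of c. The two parent intervals on c may overlap by at
#' most \code{max_overlap_fraction} of the shorter interval, which tolerates
#' local-alignment fraying at the junction without admitting ordinary
#' remote-homology paths.
#'
#' @param ssn a \code{\link{build_ssn}} network.
#' @param max_overlap_fraction maximum allowed overlap of the two parent
#'   intervals on the composite, as a fraction of the shorter (default 0.2).
#' @return data.frame: parent_a, composite, parent_b (parent_a < parent_b),
#'   a_start, a_end, b_start, b_end (parent intervals on the composite),
#'   overlap_fraction.
#' @export
find_nontransitive_triplets <- function(ssn, max_overlap_fraction = 0.2) {
  out <- list(); k <- 0L
  adj <- adjacency_set(ssn)
  for (v in ssn$nodes) {
    nb <- neighbor_intervals(ssn, v)
    if (nrow(nb) < 2L) next
    nb <- nb[order(nb$neighbor), , drop = FALSE]
    for (i in seq_len(nrow(nb) - 1L)) {
      for (j in seq((i + 1L), nrow(nb))) {
        a <- nb$neighbor[i]; b <- nb$neighbor[j]
        if (b %in% adj[[a]]) next
        ov <- overlap_fraction(nb$start[i], nb$end[i], nb$start[j], nb$end[j])
        if (ov > max_overlap_fraction) next
        k <- k + 1L
        out[[k]] <- data.frame(parent_a = a, composite = v, parent_b = b,
                               a_start = nb$start[i], a_end = nb$end[i],
                               b_start = nb$start[j], b_end = nb$end[j],
                               overlap_fraction = ov,
                               stringsAsFactors = FALSE)
      }
    }
  }
  if (!k)
    return(data.frame(parent_a = character(0), composite = character(0),
                      parent_b = character(0), a_start = integer(0),
                      a_end = integer(0), b_start = integer(0),
                      b_end = integer(0), overlap_fraction = numeric(0),
                      stringsAsFactors = FALSE))
  res <- do.call(rbind, out)
  res <- res[order(res$composite, res$parent_a, res$parent_b), , drop = FALSE]
  rownames(res) <- NULL
  res
}

adjacency_set <- function(ssn) {
  adj <- stats::setNames(vector("list", length(ssn$nodes)), ssn$nodes)
  for (i in seq_len(nrow(ssn$edges))) {
    a <- ssn$edges$node_a[i]; b <- ssn$edges$node_b[i]
    adj[[a]] <- c(adj[[a]], b)
    adj[[b]] <- c(adj[[b]], a)
  }
  adj
}

#' Verify a node set as a clique separator
#'
#' Returns TRUE iff (i) the node set induces a clique and (ii) within the
#' connected component containing the set, removing the set leaves at least
#' two connected components that each contain at least one former neighbor
#' of the set. In a similarity network, a fused gene is exactly such a
#' separator: it is the only path between its parent families.
#'
#' @param ssn a \code{\link{build_ssn}} network.
#' @param node_set non-empty character vector of node identifiers.
#' @return logical.
#' @export
verify_clique_separator <- function(ssn, node_set) {
  if (!length(node_set)) stopf("node_set must be non-empty")
  unknown <- setdiff(node_set, ssn$nodes)
  if (length(unknown)) stopf("unknown node '%s'", unknown[1])
  g <- ssn_graph(ssn)
  if (length(node_set) > 1L) {
    sub <- igraph::induced_subgraph(g, node_set)
    if (igraph::ecount(sub) < choose(length(node_set), 2)) return(FALSE)
  }
  nbrs <- setdiff(unique(unlist(lapply(node_set, function(v)
    igraph::neighbors(g, v)$name))), node_set)
  if (length(nbrs) < 2L) return(FALSE)
  # restrict to the component containing the set, then delete the set
  comp <- igraph::components(g)
  cid <- comp$membership[node_set[1]]
  inside <- names(comp$membership)[comp$membership == cid]
  gsub <- igraph::induced_subgraph(g, setdiff(inside, node_set))
  if (igraph::vcount(gsub) == 0L) return(FALSE)
  cc <- igraph::components(gsub)
  touched <- unique(cc$membership[intersect(nbrs, names(cc$membership))])
  length(touched) >= 2L
}

#' Aggregate triplets into composite candidates
#'
#' Every node that appears as the middle of at least one non-transitive
#' triplet becomes one candidate. Its parent families are the connected
#' components of the subgraph induced on the composite's neighbors (the
#' composite itself removed); each family's interval on the composite is
#' the union (range) of its members' hit intervals, and families are
#' reported in order of appearance along the composite.
#' \code{separator_verified} records whether the composite alone is a
#' clique separator of its component.
#'
#' @param ssn a \code{\link{build_ssn}} network.
#' @param triplets output of \code{\link{find_nontransitive_triplets}}
#'   computed on the same network.
#' @return list of candidates of class \code{"tdgf_candidates"}; each
#'   element has composite_id, families (list of character vectors),
#'   family_intervals (matrix, one start/end row per family),
#'   si_threshold, separator_verified, filtered_reason.
#' @export
aggregate_composites <- function(ssn, triplets) {
  mids <- sort(unique(triplets$composite))
  g <- ssn_graph(ssn)
  res <- lapply(mids, function(v) {
    nb <- neighbor_intervals(ssn, v)
    gnb <- igraph::induced_subgraph(g, nb$neighbor)
    cc <- igraph::components(gnb)
    fam_ids <- sort(unique(cc$membership))
    families <- lapply(fam_ids, function(f)
      sort(names(cc$membership)[cc$membership == f]))
    ivals <- t(vapply(families, function(members) {
      rows <- nb[nb$neighbor %in% members, , drop = FALSE]
      c(start = as.integer(min(rows$start)),
        end = as.integer(max(rows$end)))
    }, c(start = 0L, end = 0L)))
    ord <- order(ivals[, "start"], ivals[, "end"])
    families <- families[ord]
    ivals <- ivals[ord, , drop = FALSE]
    structure(list(composite_id = v,
                   families = families,
                   family_intervals = ivals,
                   si_threshold = ssn$si_threshold,
                   separator_verified = verify_clique_separator(ssn, v),
                   filtered_reason = NA_character_),
              class = "tdgf_candidate")
  })
  structure(res, class = "tdgf_candidates")
}

#' @export
print.tdgf_candidate <- function(x, ...) {
  cat(sprintf("composite %s (SI >= %s%%, separator %s): %d families\n",
              x$composite_id, format(x$si_threshold),
              if (isTRUE(x$separator_verified)) "verified" else "unverified",
              length(x$families)))
  for (i in seq_along(x$families))
    cat(sprintf("  [%d] %s @ [%d,%d)\n", i,
                paste(x$families[[i]], collapse = ","),
                x$family_intervals[i, "start"], x$family_intervals[i, "end"]))
  invisible(x)
}

#' @export
print.tdgf_candidates <- function(x, ...) {
  cat(sprintf("%d composite candidate(s)\n", length(x)))
  for (c in x) print(c)
  invisible(x)
}

#' Remove distant-homology false positives
#'
#' A candidate whose "parents" are in fact remote homologs of each other is
#' not a fusion. A candidate is removed when (i) any cross-family pair of
#' parents shares a pre-threshold hit at identity >=
#' \code{floor_identity} and e-value <= \code{evalue_max}
#' (reason \code{"parent_homology"}), or (ii) two family intervals on the
#' composite overlap by more than \code{max_family_overlap} of the shorter
#' (reason \code{"interval_overlap"}).
#'
#' @param candidates output of \code{\link{aggregate_composites}}.
#' @param unthresholded_hits the full hit list before identity thresholding.
#' @param floor_identity identity floor for the cross-family homology test
#'   (default 30).
#' @param max_family_overlap maximum tolerated family-interval overlap
#'   fraction (default 0.2).
#' @param evalue_max e-value cutoff, matching the reciprocal-best cutoff.
#' @return list with \code{kept} and \code{removed}, both
#'   \code{"tdgf_candidates"}; removed candidates carry
#'   \code{filtered_reason}.
#' @export
filter_distant_homology <- function(candidates, unthresholded_hits,
                                    floor_identity = 30,
                                    max_family_overlap = 0.2,
                                    evalue_max = 1e-5) {
  h <- unthresholded_hits
  h <- h[h$percent_identity >= floor_identity & h$e_value <= evalue_max, ,
         drop = FALSE]
  hit_key <- unique(paste(h$query_id, h$subject_id, sep = "\r"))
  kept <- list(); removed <- list()
  for (cand in candidates) {
    reason <- NA_character_
    fams <- cand$families
    nf <- length(fams)
    for (i in seq_len(nf - 1L)) {
      for (j in seq((i + 1L), nf)) {
        pairs <- expand.grid(fams[[i]], fams[[j]],
                             stringsAsFactors = FALSE)
        if (any(paste(pairs[, 1], pairs[, 2], sep = "\r") %in% hit_key) ||
            any(paste(pairs[, 2], pairs[, 1], sep = "\r") %in% hit_key)) {
          reason <- "parent_homology"
        }
        if (is.na(reason)) {
          ov <- overlap_fraction(cand$family_intervals[i, "start"],
                                 cand$family_intervals[i, "end"],
                                 cand$family_intervals[j, "start"],
                                 cand$family_intervals[j, "end"])
          if (ov > max_family_overlap) reason <- "interval_overlap"
        }
        if (!is.na(reason)) break
      }
      if (!is.na(reason)) break
    }
    if (is.na(reason)) {
      kept[[length(kept) + 1L]] <- cand
    } else {
      cand$filtered_reason <- reason
      removed[[length(removed) + 1L]] <- cand
    }
  }
  list(kept = structure(kept, class = "tdgf_candidates"),
       removed = structure(removed, class = "tdgf_candidates"))
}

#' Tabular view of composite candidates
#'
#' @param candidates a \code{"tdgf_candidates"} list.
#' @return data.frame with one row per candidate (families and intervals
#'   collapsed into comma/semicolon-separated strings), suitable for TSV
#'   export.
#' @export
candidates_table <- function(candidates) {
  if (!length(candidates))
    return(data.frame(composite_id = character(0), n_families = integer(0),
                      families = character(0), intervals = character(0),
                      si_threshold = numeric(0),
                      separator_verified = logical(0),
                      filtered_reason = character(0),
                      stringsAsFactors = FALSE))
  do.call(rbind, lapply(candidates, function(x) {
    data.frame(
      composite_id = x$composite_id,
      n_families = length(x$families),
      families = paste(vapply(x$families, paste, "", collapse = ","),
                       collapse = ";"),
      intervals = paste(sprintf("[%d,%d)", x$family_intervals[, "start"],
                                x$family_intervals[, "end"]), collapse = ";"),
      si_threshold = x$si_threshold,
      separator_verified = x$separator_verified,
      filtered_reason = x$filtered_reason,
      stringsAsFactors = FALSE)
  }))
}
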