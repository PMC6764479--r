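#' Parse a species tree from Newick
#'
#' Thin wrapper over \code{ape::read.tree} that enforces unique tip labels
#' and labels any unnamed internal nodes (\code{n1}, \code{n2}, ...) so
#' origin assignments are always nameable. Polytomies are allowed; the tree
#' is used rooted as written.
#'
#' @param path file path, or use \code{text=}.
#' @param text Newick string (alternative to \code{path}).
#' @return an \code{ape} \code{phylo} object.
#' @export
parse_newick <- function(path = NULL, text = NULL) {
  tr <- tryCatch(
    if (is.null(text)) ape::read.tree(path) else ape::read.tree(text = text),
    error = function(e) stopf("Newick parse error: %s", conditionMessage(e)),
    warning = function(w) stopf("Newick parse error: %s", conditionMessage(w)))
  if (is.null(tr)) stopf("Newick parse error: no tree found")
  if (anyDuplicated(tr$tip.label))
    stopf("duplicate tip label '%s'",
          tr$tip.label[duplicated(tr$tip.label)][1])
  if (is.null(tr$node.label) || !length(tr$node.label))
    tr$node.label <- rep("", tr$Nnode)
  empty <- !nzchar(tr$node.label)
  tr$node.label[empty] <- paste0("n", which(empty))
  tr
}

#' Build a fusion-by-species presence/absence matrix
#'
#' A fusion is \code{"P"} (present) in a species when its junction is
#' expressed -- count at or above the tier -- in at least one tissue of
#' that species; \code{"A"} (absent) when the species has read data but no
#' expressed tissue; \code{"M"} (missing) when the species has no read
#' data at all. Missing is deliberately distinct from absent: species
#' without data carry no phylogenetic signal and are ignored by origin
#' assignment. Fusions present nowhere are dropped with a warning, since
#' no origin can be inferred for them.
#'
#' @param counts data.frame from \code{\link{count_junction_matrix}} rows
#'   (composite_id, species, tissue, count), possibly concatenated over
#'   species.
#' @param species character vector of all species considered (columns);
#'   defaults to those present in \code{counts}.
#' @param tier expression tier (default 1: at least one spanning read).
#' @return character matrix (rows fusions, columns species) with entries
#'   "P", "A", "M".
#' @export
build_presence_matrix <- function(counts, species = NULL, tier = 1L) {
  if (is.null(species)) species <- sort(unique(counts$species))
  fusions <- sort(unique(counts$composite_id))
  mat <- matrix("M", nrow = length(fusions), ncol = length(species),
                dimnames = list(fusions, species))
  for (f in fusions) {
    for (s in species) {
      rows <- counts[counts$composite_id == f & counts$species == s, ,
                     drop = FALSE]
      if (!nrow(rows)) next
      mat[f, s] <- if (any(rows$count >= tier)) "P" else "A"
    }
  }
  none <- rowSums(mat == "P") == 0L
  if (any(none)) {
    warning(sprintf("%d fusion(s) present in no species dropped: %s",
                    sum(none), paste(fusions[none], collapse = ", ")),
            call. = FALSE)
    mat <- mat[!none, , drop = FALSE]
  }
  mat
}

#' Assign the origin node of a fusion on the species tree
#'
#' Single-gain (Dollo-style) placement: the origin is the most recent
#' common ancestor of every species in which the fusion is present;
#' species with missing data are ignored, and a fusion present in a single
#' species maps to that tip. The result is invariant to tip ordering and
#' to adding unrelated absent outgroups.
#'
#' @param tree a \code{phylo} from \code{\link{parse_newick}}.
#' @param presence_row named character vector ("P"/"A"/"M") or named
#'   logical (TRUE = present, NA = missing) over species.
#' @param fusion_id identifier carried into the result.
#' @return list: fusion_id, origin (tip or node label),
#'   n_supporting_species.
#' @export
assign_origin <- function(tree, presence_row, fusion_id = "fusion") {
  pres <- if (is.character(presence_row))
    names(presence_row)[presence_row == "P"]
  else names(presence_row)[!is.na(presence_row) & presence_row]
  if (!length(pres)) stopf("no species with a present call")
  unknown <- setdiff(pres, tree$tip.label)
  if (length(unknown))
    stopf("present species '%s' is not a tree tip", unknown[1])
  origin <- if (length(pres) == 1L) pres else {
    node <- ape::getMRCA(tree, pres)
    tree$node.label[node - length(tree$tip.label)]
  }
  list(fusion_id = fusion_id, origin = origin,
       n_supporting_species = length(pres))
}

#' Origin assignments for a whole presence matrix
#'
#' @param tree a \code{phylo}.
#' @param presence matrix from \code{\link{build_presence_matrix}}.
#' @return data.frame: fusion_id, origin, n_supporting_species.
#' @export
assign_origins <- function(tree, presence) {
  rows <- lapply(rownames(presence), function(f)
    as.data.frame(assign_origin(tree, presence[f, ], fusion_id = f),
                  stringsAsFactors = FALSE))
  res <- do.call(rbind, rows)
  rownames(res) <- NULL
  res
}

#' Count fusion origins per tree node
#'
#' Tallies how many fusions are assigned to each tip and internal node;
#' every node appears in the result (zeros included) and the counts sum to
#' the number of fusions.
#'
#' @param assignments data.frame from \code{\link{assign_origins}} (or a
#'   character vector of origins).
#' @param tree a \code{phylo}.
#' @return named integer vector over \code{c(tip.label, node.label)}.
#' @export
per_branch_counts <- function(assignments, tree) {
  origins <- if (is.data.frame(assignments)) assignments$origin else
    as.character(assignments)
  nodes <- c(tree$tip.label, tree$node.label)
  unknown <- setdiff(origins, nodes)
  if (length(unknown)) stopf("origin '%s' is not a tree node", unknown[1])
  counts <- stats::setNames(integer(length(nodes)), nodes)
  tab <- table(origins)
  counts[names(tab)] <- as.integer(tab)
  counts
}
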