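# Independent oracles and fixture builders used across the suite. These are
# deliberately naive (exhaustive enumeration, textbook dynamic programming)
# and share no code with the package implementation they check.

# ---- graph oracles -----------------------------------------------------

adj_from_edges <- function(nodes, edges) {
  adj <- stats::setNames(lapply(nodes, function(x) character(0)), nodes)
  for (i in seq_len(nrow(edges))) {
    a <- edges$node_a[i]; b <- edges$node_b[i]
    adj[[a]] <- union(adj[[a]], b)
    adj[[b]] <- union(adj[[b]], a)
  }
  adj
}

# exhaustive enumeration of non-transitive triplets over all node triples
oracle_triplets <- function(ssn, max_overlap_fraction = 0.2) {
  nodes <- ssn$nodes
  e <- ssn$edges
  adj <- adj_from_edges(nodes, e)
  # interval of the neighbor's alignment ON v, precomputed for speed
  itab <- new.env(parent = emptyenv())
  for (r in seq_len(nrow(e))) {
    assign(paste(e$node_a[r], e$node_b[r]), c(e$a_start[r], e$a_end[r]),
           envir = itab)
    assign(paste(e$node_b[r], e$node_a[r]), c(e$b_start[r], e$b_end[r]),
           envir = itab)
  }
  ival_on <- function(v, nbr) get(paste(v, nbr), envir = itab)
  out <- list()
  for (c_ in nodes) for (a in nodes) for (b in nodes) {
    if (a >= b || a == c_ || b == c_) next
    if (!(c_ %in% adj[[a]]) || !(c_ %in% adj[[b]])) next
    if (b %in% adj[[a]]) next
    ia <- ival_on(c_, a); ib <- ival_on(c_, b)
    ov <- max(0, min(ia[2], ib[2]) - max(ia[1], ib[1]))
    shorter <- min(ia[2] - ia[1], ib[2] - ib[1])
    frac <- if (shorter <= 0) 0 else ov / shorter
    if (frac > max_overlap_fraction) next
    out[[length(out) + 1L]] <- data.frame(
      parent_a = a, composite = c_, parent_b = b, stringsAsFactors = FALSE)
  }
  if (!length(out))
    return(data.frame(parent_a = character(0), composite = character(0),
                      parent_b = character(0), stringsAsFactors = FALSE))
  res <- do.call(rbind, out)
  res[order(res$composite, res$parent_a, res$parent_b), , drop = FALSE]
}

# hand-rolled BFS connected components (no igraph)
bfs_components <- function(nodes, adj) {
  comp <- stats::setNames(rep(NA_integer_, length(nodes)), nodes)
  cid <- 0L
  for (v in nodes) {
    if (!is.na(comp[[v]])) next
    cid <- cid + 1L
    queue <- v
    while (length(queue)) {
      u <- queue[1]; queue <- queue[-1]
      if (!is.na(comp[[u]])) next
      comp[[u]] <- cid
      queue <- c(queue, setdiff(intersect(adj[[u]], nodes),
                                names(comp)[!is.na(comp)]))
    }
  }
  comp
}

# brute-force clique-separator verdict by component recomputation
oracle_separator <- function(ssn, node_set) {
  nodes <- ssn$nodes
  adj <- adj_from_edges(nodes, ssn$edges)
  if (length(node_set) > 1L) {
    for (i in seq_len(length(node_set) - 1L))
      for (j in seq(i + 1L, length(node_set)))
        if (!(node_set[j] %in% adj[[node_set[i]]])) return(FALSE)
  }
  nbrs <- setdiff(unique(unlist(adj[node_set])), node_set)
  if (length(nbrs) < 2L) return(FALSE)
  full <- bfs_components(nodes, adj)
  inside <- names(full)[full == full[[node_set[1]]]]
  remaining <- setdiff(inside, node_set)
  if (!length(remaining)) return(FALSE)
  sub <- bfs_components(remaining, adj)
  length(unique(sub[intersect(nbrs, remaining)])) >= 2L
}

# random SSN with random disjoint-ish intervals, deterministic per seed
random_ssn <- function(n_nodes, p_edge, seed) {
  set.seed(seed)
  nodes <- sprintf("v%02d", seq_len(n_nodes))
  pairs <- t(combn(nodes, 2))
  keep <- runif(nrow(pairs)) < p_edge
  pairs <- pairs[keep, , drop = FALSE]
  if (!nrow(pairs)) {
    edges <- data.frame(node_a = character(0), node_b = character(0),
                        percent_identity = numeric(0),
                        a_start = integer(0), a_end = integer(0),
                        b_start = integer(0), b_end = integer(0),
                        e_value = numeric(0), stringsAsFactors = FALSE)
    return(build_ssn(edges, 0, nodes = nodes))
  }
  mk_ival <- function(k) {
    s <- sample(0:200, k, replace = TRUE)
    w <- sample(20:120, k, replace = TRUE)
    cbind(s, s + w)
  }
  ia <- mk_ival(nrow(pairs)); ib <- mk_ival(nrow(pairs))
  edges <- data.frame(node_a = pairs[, 1], node_b = pairs[, 2],
                      percent_identity = 100,
                      a_start = ia[, 1], a_end = ia[, 2],
                      b_start = ib[, 1], b_end = ib[, 2],
                      e_value = 0, stringsAsFactors = FALSE)
  build_ssn(edges, 0, nodes = nodes)
}

# ---- alignment oracle --------------------------------------------------

# textbook Gotoh local alignment, score only
oracle_sw_score <- function(a, b, match = 2, mismatch = -2,
                            gap_open = 10, gap_extend = 4) {
  a <- strsplit(a, "")[[1]]; b <- strsplit(b, "")[[1]]
  n <- length(a); m <- length(b)
  NEG <- -1e9
  M <- matrix(0, n + 1, m + 1)
  X <- matrix(NEG, n + 1, m + 1)  # gap in b (vertical)
  Y <- matrix(NEG, n + 1, m + 1)  # gap in a (horizontal)
  best <- 0
  for (i in 2:(n + 1)) {
    for (j in 2:(m + 1)) {
      s <- if (a[i - 1] == b[j - 1]) match else mismatch
      X[i, j] <- max(M[i - 1, j] - gap_open - gap_extend,
                     X[i - 1, j] - gap_extend)
      Y[i, j] <- max(M[i, j - 1] - gap_open - gap_extend,
                     Y[i, j - 1] - gap_extend)
      M[i, j] <- max(0, M[i - 1, j - 1] + s, X[i, j], Y[i, j])
      best <- max(best, M[i, j])
    }
  }
  best
}

# ---- combinatorial oracles ---------------------------------------------

# hypergeometric upper tail by exhaustive subset enumeration (tiny N only)
oracle_hyper_tail <- function(N, m, n, k) {
  subsets <- combn(N, n)
  hits <- colSums(subsets <= m)  # first m items are "successes"
  mean(hits >= k)
}

# brute-force reciprocal-best edge enumeration over all pairs
oracle_reciprocal_edges <- function(hits, evalue_max = 1e-5) {
  h <- hits[hits$query_id != hits$subject_id & hits$e_value <= evalue_max, ,
            drop = FALSE]
  ids <- sort(unique(c(h$query_id, h$subject_id)))
  out <- list()
  for (a in ids) for (b in ids) {
    if (a >= b) next
    ab <- any(h$query_id == a & h$subject_id == b)
    ba <- any(h$query_id == b & h$subject_id == a)
    if (ab && ba)
      out[[length(out) + 1L]] <- data.frame(node_a = a, node_b = b,
                                            stringsAsFactors = FALSE)
  }
  if (!length(out))
    return(data.frame(node_a = character(0), node_b = character(0)))
  do.call(rbind, out)
}

empty_hits_df <- function() {
  data.frame(query_id = character(0), subject_id = character(0),
             percent_identity = numeric(0), alignment_length = integer(0),
             mismatches = integer(0), gap_opens = integer(0),
             query_start = integer(0), query_end = integer(0),
             subject_start = integer(0), subject_end = integer(0),
             e_value = numeric(0), bit_score = numeric(0),
             subject_strand = character(0), stringsAsFactors = FALSE)
}

# ---- shared fixtures ---------------------------------------------------

# a small, quick bundle for module-level tests
small_config <- function(seed = 7, ...) {
  simulation_config(seed = seed, n_parent_pairs = 6, n_fusions = 3,
                    read_depth = 3, tissues = c("brain", "liver", "testis"),
                    ...)
}

seven_species_tree <- function() {
  parse_newick(text = paste0(
    "((((((human:6,chimp:6):2,gorilla:8):8,orangutan:16):9,",
    "macaque:25):18,marmoset:43):47,mouse:90);"))
}
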