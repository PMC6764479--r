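mk_ssn <- function(edges_list, nodes = NULL) {
  edges <- do.call(rbind, lapply(edges_list, function(e)
    data.frame(node_a = e[[1]], node_b = e[[2]],
               percent_identity = 100,
               a_start = e[[3]], a_end = e[[4]],
               b_start = e[[5]], b_end = e[[6]],
               e_value = 0, stringsAsFactors = FALSE)))
  build_ssn(edges, 0, nodes = nodes)
}

test_that("non-transitive triplets: path yes, triangle no", {
  # a-c-b path; intervals of a and b on c are disjoint
  ssn <- mk_ssn(list(list("a", "c", 0, 240, 0, 100),
                     list("b", "c", 0, 240, 120, 240)))
  tr <- find_nontransitive_triplets(ssn)
  expect_equal(nrow(tr), 1)
  expect_equal(tr$parent_a, "a")
  expect_equal(tr$composite, "c")
  expect_equal(tr$parent_b, "b")
  expect_equal(tr$overlap_fraction, 0)

  # closing the triangle removes the triplet
  tri <- mk_ssn(list(list("a", "c", 0, 240, 0, 100),
                     list("b", "c", 0, 240, 120, 240),
                     list("a", "b", 0, 100, 0, 100)))
  expect_equal(nrow(find_nontransitive_triplets(tri)), 0)

  # heavily overlapping parent intervals are rejected
  ov <- mk_ssn(list(list("a", "c", 0, 240, 0, 100),
                    list("b", "c", 0, 240, 50, 150)))
  expect_equal(nrow(find_nontransitive_triplets(ov, 0.2)), 0)
  expect_equal(nrow(find_nontransitive_triplets(ov, 0.6)), 1)
})

test_that("triplet detection matches exhaustive enumeration on random graphs", {
  for (seed in 1:15) {
    ssn <- random_ssn(sample(5:12, 1), runif(1, 0.15, 0.5), seed)
    got <- find_nontransitive_triplets(ssn)
    want <- oracle_triplets(ssn)
    expect_identical(paste(got$parent_a, got$composite, got$parent_b),
                     paste(want$parent_a, want$composite, want$parent_b),
                     label = sprintf("seed %d", seed))
  }
})

test_that("clique-separator verification agrees with component recomputation", {
  path <- mk_ssn(list(list("a", "c", 0, 100, 0, 100),
                      list("b", "c", 0, 100, 120, 240)))
  expect_true(verify_clique_separator(path, "c"))
  expect_false(verify_clique_separator(path, "a"))

  tri <- mk_ssn(list(list("a", "b", 0, 100, 0, 100),
                     list("b", "c", 0, 100, 0, 100),
                     list("a", "c", 0, 100, 0, 100)))
  for (v in c("a", "b", "c"))
    expect_false(verify_clique_separator(tri, v))

  expect_error(verify_clique_separator(path, "nope"), "unknown node")
  expect_error(verify_clique_separator(path, character(0)), "non-empty")

  for (seed in 16:25) {
    ssn <- random_ssn(sample(6:12, 1), runif(1, 0.2, 0.5), seed)
    nodes <- ssn$nodes
    for (v in nodes)
      expect_equal(verify_clique_separator(ssn, v), oracle_separator(ssn, v),
                   label = sprintf("seed %d node %s", seed, v))
    pairs <- t(combn(nodes, 2))
    pick <- pairs[sample(nrow(pairs), min(10, nrow(pairs))), , drop = FALSE]
    for (r in seq_len(nrow(pick)))
      expect_equal(verify_clique_separator(ssn, pick[r, ]),
                   oracle_separator(ssn, pick[r, ]),
                   label = sprintf("seed %d pair %s-%s", seed,
                                   pick[r, 1], pick[r, 2]))
  }
})

test_that("composite aggregation groups parents into families", {
  ssn <- mk_ssn(list(list("a", "c", 0, 240, 0, 100),
                     list("b", "c", 0, 240, 120, 240)))
  tr <- find_nontransitive_triplets(ssn)
  cands <- aggregate_composites(ssn, tr)
  expect_length(cands, 1)
  expect_equal(cands[[1]]$composite_id, "c")
  expect_equal(cands[[1]]$families, list("a", "b"))
  expect_true(cands[[1]]$separator_verified)
  expect_equal(unname(cands[[1]]$family_intervals[, "start"]), c(0, 120))

  # two 2-member parent cliques, no cross edges -> two families of size 2
  ssn2 <- mk_ssn(list(list("a1", "c", 0, 240, 0, 100),
                      list("a2", "c", 0, 240, 5, 95),
                      list("b1", "c", 0, 240, 120, 240),
                      list("b2", "c", 0, 240, 130, 230),
                      list("a1", "a2", 0, 100, 0, 100),
                      list("b1", "b2", 0, 100, 0, 100)))
  cands2 <- aggregate_composites(ssn2, find_nontransitive_triplets(ssn2))
  cand_c <- Filter(function(x) x$composite_id == "c", cands2)[[1]]
  expect_equal(cand_c$families, list(c("a1", "a2"), c("b1", "b2")))
  expect_equal(unname(cand_c$family_intervals[1, ]), c(0, 100))

  expect_length(aggregate_composites(ssn, tr[0, ]), 0)
})

test_that("distant-homology filtering removes remote-homolog artifacts", {
  ssn <- mk_ssn(list(list("a", "c", 0, 240, 0, 100),
                     list("b", "c", 0, 240, 120, 240)))
  cands <- aggregate_composites(ssn, find_nontransitive_triplets(ssn))
  no_hits <- empty_hits_df()
  keptres <- filter_distant_homology(cands, no_hits)
  expect_length(keptres$kept, 1)
  expect_length(keptres$removed, 0)

  # parents share a 45%-identity pre-threshold hit -> removed
  weak <- data.frame(query_id = "a", subject_id = "b",
                     percent_identity = 45, alignment_length = 80L,
                     mismatches = 40L, gap_opens = 0L, query_start = 0L,
                     query_end = 80L, subject_start = 0L, subject_end = 80L,
                     e_value = 1e-8, bit_score = 60,
                     subject_strand = "+", stringsAsFactors = FALSE)
  res <- filter_distant_homology(cands, weak)
  expect_length(res$kept, 0)
  expect_equal(res$removed[[1]]$filtered_reason, "parent_homology")

  # family intervals overlapping by half the shorter -> removed
  ssn_ov <- mk_ssn(list(list("a", "c", 0, 240, 0, 100),
                        list("b", "c", 0, 240, 50, 150)))
  cands_ov <- aggregate_composites(ssn_ov,
                                   find_nontransitive_triplets(ssn_ov, 0.6))
  res_ov <- filter_distant_homology(cands_ov, no_hits)
  expect_length(res_ov$kept, 0)
  expect_equal(res_ov$removed[[1]]$filtered_reason, "interval_overlap")
})
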