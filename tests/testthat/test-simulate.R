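test_that("parent simulation is seed-deterministic with unique in-frame ORFs", {
  a <- simulate_parents(1, 300, seed = 7)
  b <- simulate_parents(1, 300, seed = 7)
  expect_identical(a, b)
  expect_false(identical(a$nt, simulate_parents(1, 300, seed = 8)$nt))

  many <- simulate_parents(5, c(300, 600), seed = 3)
  expect_equal(nrow(many), 5)
  expect_false(anyDuplicated(many$id) > 0)
  expect_true(all(nchar(many$nt) %% 3 == 0))
  # scan every translation: stop symbol only as the final residue
  internal <- substr(many$aa, 1, nchar(many$aa) - 1)
  expect_false(any(grepl("*", internal, fixed = TRUE)))

  expect_error(simulate_parents(2, 100, seed = 1), "multiples of 3")
})

test_that("mutation hits the identity target and is monotone in it", {
  s <- simulate_parents(1, 300, seed = 2)$nt
  expect_identical(mutate_to_identity(s, 1.0, seed = 5), s)

  realized <- function(a, b) {
    ca <- strsplit(a, "")[[1]]; cb <- strsplit(b, "")[[1]]
    mean(ca == cb)
  }
  m90 <- mutate_to_identity(s, 0.9, seed = 5)
  expect_equal(nchar(m90), nchar(s))
  expect_gte(realized(s, m90), 0.88)
  expect_lte(realized(s, m90), 0.92)

  m70 <- mutate_to_identity(s, 0.7, seed = 5)
  expect_lte(realized(s, m70), realized(s, m90))

  expect_error(mutate_to_identity("", 0.9), "empty")
  expect_error(mutate_to_identity(s, 0), "target_identity")
})

test_that("fusion construction records the true breakpoint", {
  p <- simulate_parents(2, 300, seed = 4)
  f <- simulate_fusion(p$nt[1], p$nt[2], 0.5, 0.5,
                       parentA_id = p$id[1], parentB_id = p$id[2])
  expect_equal(nchar(f$sequence), 300)
  expect_equal(f$truth$true_breakpoint, 150)
  expect_identical(substr(f$sequence, 1, 150), substr(p$nt[1], 1, 150))
  expect_identical(substr(f$sequence, 151, 300), substr(p$nt[2], 151, 300))

  expect_error(simulate_fusion(p$nt[1], p$nt[2], 1.0, 0.5), "strictly inside")
  expect_error(simulate_fusion(p$nt[1], p$nt[2], 0.05, 0.5), "too short")

  # re-aligning the fusion against each parent recovers the planted
  # intervals; the junction-side ends may fray by a few nt where chance
  # matches extend the local alignment past the boundary
  ia <- align_parent_to_composite(f$sequence, p$nt[1])
  ib <- align_parent_to_composite(f$sequence, p$nt[2])
  expect_equal(ia[["start"]], 0)
  expect_equal(ib[["end"]], 300)
  expect_lte(abs(ia[["end"]] - 150), 6)
  expect_lte(abs(ib[["start"]] - 150), 6)
})

test_that("gene placement respects the SD enrichment model", {
  ids <- sprintf("g%03d", 1:40)
  lens <- rep(400L, 40)
  fus <- rep(c(TRUE, FALSE), each = 20)

  pl0 <- place_genes(ids, lens, fus, genome_length = 1e6, n_sd = 30,
                     sd_len = 10000, sd_enrichment = 0, seed = 3)
  in_sd <- S4Vectors::mcols(pl0$genes)$in_sd
  expect_false(any(in_sd[fus]))
  expect_identical(sort(overlap_genes(pl0$genes, pl0$sd)),
                   sort(S4Vectors::mcols(pl0$genes)$label[in_sd]))

  # half-open, mutually non-overlapping intervals (sweep over sorted starts)
  g <- sort(pl0$genes)
  expect_true(all(GenomicRanges::start(g)[-1] >
                    GenomicRanges::end(g)[-length(g)]))

  # neutral enrichment: fusion in-SD rate matches the background SD fraction
  pl1 <- place_genes(sprintf("f%03d", 1:200), rep(400L, 200),
                     rep(TRUE, 200), genome_length = 2e6, n_sd = 30,
                     sd_len = 10000, sd_enrichment = 1, seed = 11)
  p_sd <- 30 * 10000 / 2e6
  rate <- mean(S4Vectors::mcols(pl1$genes)$in_sd)
  se3 <- 3 * sqrt(p_sd * (1 - p_sd) / 200)
  expect_lt(abs(rate - p_sd), se3)
})

test_that("read simulation plants exactly the promised junction reads", {
  cfg <- small_config(seed = 9)
  b <- simulate_bundle(cfg)
  expect_equal(sum(b$reads$junction),
               cfg$n_fusions * length(cfg$tissues) *
                 cfg$junction_reads_per_fusion)

  # end-to-end oracle: the junction counter on error-free reads returns the
  # planted number per fusion per tissue
  seqs <- stats::setNames(c(b$parents$nt, b$fusions$nt),
                          c(b$parents$id, b$fusions$id))
  probes <- lapply(seq_len(nrow(b$truth)), function(i)
    make_junction_probe(seqs[[b$truth$fusion_id[i]]],
                        b$truth$true_breakpoint[i], flank = 50,
                        composite_id = b$truth$fusion_id[i]))
  counts <- count_junction_matrix(probes, b$reads)
  expect_true(all(counts$count == cfg$junction_reads_per_fusion))

  empty <- simulation_config(seed = 1, n_parent_pairs = 2, n_fusions = 0,
                             read_depth = 0, junction_reads_per_fusion = 0)
  expect_equal(nrow(simulate_reads(simulate_parents(2, 300, 1), NULL, empty)),
               0)

  tiny <- simulation_config(seed = 1, n_parent_pairs = 1, n_fusions = 0,
                            read_length = 400, parent_len_range = c(300, 300))
  expect_error(simulate_reads(simulate_parents(1, 300, 1), NULL, tiny),
               "read_length")
})

test_that("fixture bundles are byte-identical across reruns and reload cleanly", {
  cfg <- small_config(seed = 5)
  d1 <- withr::local_tempdir()
  d2 <- withr::local_tempdir()
  make_fixture(cfg, d1)
  make_fixture(cfg, d2)
  files <- list.files(d1)
  expect_setequal(files, c("parents.fa", "fusions.fa", "reads.fq",
                           "genes.bed", "sd.bed", "tree.nwk", "truth.tsv",
                           "config.yml"))
  for (f in files)
    expect_identical(readLines(file.path(d1, f)), readLines(file.path(d2, f)),
                     label = f)

  b <- read_fixture(d1)
  expect_equal(nrow(b$truth), cfg$n_fusions)
  expect_equal(nrow(b$fusions), cfg$n_fusions)
  expect_setequal(b$truth$parentA_id, b$parents$id[seq(1, 6, by = 2)])
  expect_equal(sort(b$tree$tip.label),
               sort(c("human", "chimp", "gorilla", "orangutan", "macaque",
                      "marmoset", "mouse")))

  d3 <- withr::local_tempdir()
  make_fixture(small_config(seed = 6), d3)
  expect_false(identical(readLines(file.path(d1, "parents.fa")),
                         readLines(file.path(d3, "parents.fa"))))
})
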