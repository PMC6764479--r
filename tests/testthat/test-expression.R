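q40 <- function(n) strrep("I", n)  # Phred 40 in ASCII+33

test_that("read QC trims leading bases and applies mean-quality/length floors", {
  reads <- data.frame(
    read_id = c("good", "lowq", "short"),
    sequence = c(strrep("ACGT", 19), strrep("ACGT", 19), strrep("AC", 20)),
    quality = c(q40(76), strrep("3", 76), q40(40)),  # "3" = Phred 18
    stringsAsFactors = FALSE)
  out <- qc_filter_reads(reads, mode = "rna")
  expect_equal(out$read_id, "good")
  expect_equal(nchar(out$sequence), 63)   # 76 - 13 leading bases
  expect_equal(nchar(out$quality), 63)

  # ribosome mode: no trim, >25 nt retained
  ribo <- data.frame(read_id = c("r25", "r26"),
                     sequence = c(strrep("A", 25), strrep("A", 26)),
                     quality = c(q40(25), q40(26)), stringsAsFactors = FALSE)
  out_r <- qc_filter_reads(ribo, mode = "ribo")
  expect_equal(out_r$read_id, "r26")
  expect_equal(nchar(out_r$sequence), 26)

  # mismatched quality string: skipped with a warning, others survive
  bad <- data.frame(read_id = c("ok", "bad"),
                    sequence = c(strrep("A", 76), strrep("A", 76)),
                    quality = c(q40(76), q40(10)), stringsAsFactors = FALSE)
  expect_warning(out_b <- qc_filter_reads(bad, mode = "rna"), "mismatch")
  expect_equal(out_b$read_id, "ok")
})

test_that("junction counting requires spanning both flanks", {
  s <- simulate_parents(1, 600, seed = 12)$nt
  probe <- make_junction_probe(s, 300, flank = 50)

  full <- data.frame(read_id = "full", sequence = probe$sequence,
                     quality = q40(100), stringsAsFactors = FALSE)
  expect_equal(count_junction_reads(probe, full)$count, 1)

  # read covering only the left flank, ending exactly at the junction
  left <- data.frame(read_id = "left", sequence = substr(s, 251, 300),
                     quality = q40(50), stringsAsFactors = FALSE)
  expect_equal(count_junction_reads(probe, left)$count, 0)

  # spanning with the minimum 8-nt overhang counts; 7 nt does not
  span8 <- data.frame(read_id = "s8", sequence = substr(s, 259, 308),
                      quality = q40(50), stringsAsFactors = FALSE)
  expect_equal(count_junction_reads(probe, span8)$count, 1)
  span7 <- data.frame(read_id = "s7", sequence = substr(s, 260, 307),
                      quality = q40(48), stringsAsFactors = FALSE)
  expect_equal(count_junction_reads(probe, span7)$count, 0)

  # mismatch budget: 2 tolerated, 3 not
  mm <- probe$sequence
  substr(mm, 10, 10) <- "N"; substr(mm, 20, 20) <- "N"
  two <- data.frame(read_id = "mm2", sequence = mm, quality = q40(100),
                    stringsAsFactors = FALSE)
  expect_equal(count_junction_reads(probe, two)$count, 1)
  substr(mm, 30, 30) <- "N"
  three <- data.frame(read_id = "mm3", sequence = mm, quality = q40(100),
                      stringsAsFactors = FALSE)
  expect_equal(count_junction_reads(probe, three)$count, 0)

  short_probe <- make_junction_probe(s, 300, flank = 3)
  # overhang capped at the flank for short footprint probes: no error
  expect_no_error(count_junction_reads(short_probe, full, min_overhang = 8))
  expect_error(count_junction_reads(
    structure(list(composite_id = "x", sequence = substr(s, 1, 10),
                   breakpoint_offset = 5, flank = 8, truncated = TRUE),
              class = "tdgf_probe"), full), "overhang")
})

test_that("counting is strand-symmetric", {
  b <- simulate_bundle(small_config(seed = 13))
  seqs <- stats::setNames(b$fusions$nt, b$fusions$id)
  probes <- lapply(seq_len(nrow(b$truth)), function(i)
    make_junction_probe(seqs[[b$truth$fusion_id[i]]],
                        b$truth$true_breakpoint[i], flank = 50,
                        composite_id = b$truth$fusion_id[i]))
  fwd <- count_junction_matrix(probes, b$reads)
  rc <- b$reads
  rc$sequence <- vapply(rc$sequence, function(x)
    as.character(Biostrings::reverseComplement(Biostrings::DNAString(x))),
    "", USE.NAMES = FALSE)
  rev <- count_junction_matrix(probes, rc)
  expect_equal(fwd$count, rev$count)
})

test_that("expression tiers are monotone threshold calls", {
  expect_equal(unname(call_expressed(1)), c(TRUE, FALSE, FALSE))
  expect_equal(unname(call_expressed(0)), c(FALSE, FALSE, FALSE))
  expect_equal(unname(call_expressed(5)), c(TRUE, TRUE, TRUE))
  for (n in 0:10) {
    calls <- call_expressed(n)
    expect_true(!calls[["5"]] || calls[["3"]])
    expect_true(!calls[["3"]] || calls[["1"]])
  }
  expect_error(call_expressed(-1), ">= 0")
})

test_that("tissue enrichment matches the closed-form two-proportion z", {
  # 20 fusions; in the focal tissue 15 expressed, 5 in each other tissue
  calls <- cbind(t1 = rep(c(TRUE, FALSE), c(15, 5)),
                 t2 = rep(c(TRUE, FALSE), c(5, 15)),
                 t3 = rep(c(TRUE, FALSE), c(5, 15)))
  res <- tissue_enrichment(calls)
  r1 <- res[res$tissue == "t1", ]
  p_t <- 15 / 20; p_r <- 10 / 40; pbar <- 25 / 60
  z_hand <- (p_t - p_r) / sqrt(pbar * (1 - pbar) * (1 / 20 + 1 / 40))
  expect_equal(r1$z_score, z_hand)
  expect_equal(r1$p_one_tailed, pnorm(z_hand, lower.tail = FALSE))
  expect_equal(r1$p_two_tailed,
               min(1, 2 * min(r1$p_one_tailed, 1 - r1$p_one_tailed)))

  # identical columns: no tissue signal
  same <- cbind(a = c(TRUE, FALSE, TRUE), b = c(TRUE, FALSE, TRUE))
  rs <- tissue_enrichment(same)
  expect_true(all(rs$z_score == 0) || all(abs(rs$z_score) < 1e-12))
  expect_true(all(rs$p_two_tailed == 1))

  # doubling relation holds across random matrices
  set.seed(77)
  for (i in 1:100) {
    m <- matrix(runif(24) < runif(1), 8, 3,
                dimnames = list(NULL, c("x", "y", "z")))
    r <- tissue_enrichment(m)
    expect_equal(r$p_two_tailed,
                 pmin(1, 2 * pmin(r$p_one_tailed, 1 - r$p_one_tailed)))
  }
  expect_error(tissue_enrichment(cbind(a = c(TRUE, FALSE))), "two tissues")
})

test_that("TPM normalizes to one million", {
  expect_equal(unname(compute_tpm(5, 100)), 1e6)
  expect_equal(unname(compute_tpm(c(3, 3), c(50, 50))), c(5e5, 5e5))
  set.seed(9)
  for (i in 1:20) {
    n <- sample(2:30, 1)
    tpm <- compute_tpm(rpois(n, 20) + 1, sample(200:2000, n))
    expect_equal(sum(tpm), 1e6, tolerance = 1e-6)
  }
  expect_warning(z <- compute_tpm(c(0, 0), c(100, 200)), "zero")
  expect_equal(unname(z), c(0, 0))
  expect_error(compute_tpm(1, 0), "> 0")
})

test_that("FASTQ round-trip preserves reads and the tissue dialect", {
  b <- simulate_bundle(small_config(seed = 17))
  f <- withr::local_tempfile(fileext = ".fq")
  write_fastq(b$reads, f)
  back <- read_fastq(f)
  expect_equal(back$sequence, b$reads$sequence)
  expect_equal(back$quality, b$reads$quality)
  expect_equal(back$tissue, b$reads$tissue)
})
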