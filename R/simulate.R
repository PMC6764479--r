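#' Simulation configuration for synthetic fusion bundles
#'
#' Collects every tunable of the synthetic-data generator into a validated
#' list. The defaults describe the reference study conditions used throughout
#' the test suite: 30 unrelated parent gene pairs of 300--600 nt, 10
#' readthrough fusions whose parent-derived segments retain 90\% nucleotide
#' identity, 76-nt single-end reads over six tissues with 5 planted
#' junction-spanning reads per fusion per tissue, and a 1-Mb genome in which
#' fusion loci are placed into segmental-duplication (SD) intervals at three
#' times the background rate.
#'
#' @param seed integer seed; the whole bundle is a deterministic function of
#'   the configuration, including this value.
#' @param n_parent_pairs number of unrelated parent gene pairs to simulate.
#' @param parent_len_range integer pair, nucleotide length range for parents;
#'   both bounds must be multiples of 3 (sequences are in-frame coding).
#' @param target_identity fraction in (0, 1]; nucleotide identity between each
#'   fusion and the matching regions of its parents.
#' @param n_fusions number of fusions (at most \code{n_parent_pairs}).
#' @param fusion_fracA,fusion_fracB fractions in (0, 1) of parent A retained
#'   as the fusion prefix and of parent B retained as the suffix.
#' @param linker_length optional unaligned spacer (nt) inserted at the
#'   junction; 0 gives a clean breakpoint.
#' @param read_length read length in nt (default 76, single-end).
#' @param read_depth background reads per transcript per tissue.
#' @param junction_reads_per_fusion planted breakpoint-spanning reads per
#'   fusion per tissue.
#' @param base_error_rate per-base substitution error probability.
#' @param tissues character vector of tissue labels (>= 1).
#' @param genome_length synthetic genome length in nt (single chromosome).
#' @param n_sd_intervals,sd_interval_len number and length (nt) of SD blocks.
#' @param sd_enrichment multiplier >= 0 applied to the background SD placement
#'   probability for fusion loci (capped at 1); 1 = no enrichment, 0 = fusions
#'   never placed in SD.
#'
#' @return an object of class \code{"tdgf_config"} (a named list).
#' @export
simulation_config <- function(seed = 1L,
                              n_parent_pairs = 30L,
                              parent_len_range = c(300L, 600L),
                              target_identity = 0.9,
                              n_fusions = 10L,
                              fusion_fracA = 0.5,
                              fusion_fracB = 0.5,
                              linker_length = 0L,
                              read_length = 76L,
                              read_depth = 10L,
                              junction_reads_per_fusion = 5L,
                              base_error_rate = 0,
                              tissues = c("brain", "cerebellum", "heart",
                                          "kidney", "liver", "testis"),
                              genome_length = 1000000L,
                              n_sd_intervals = 30L,
                              sd_interval_len = 10000L,
                              sd_enrichment = 3) {
  cfg <- list(seed = as.integer(seed),
              n_parent_pairs = as.integer(n_parent_pairs),
              parent_len_range = as.integer(parent_len_range),
              target_identity = target_identity,
              n_fusions = as.integer(n_fusions),
              fusion_fracA = fusion_fracA,
              fusion_fracB = fusion_fracB,
              linker_length = as.integer(linker_length),
              read_length = as.integer(read_length),
              read_depth = as.integer(read_depth),
              junction_reads_per_fusion = as.integer(junction_reads_per_fusion),
              base_error_rate = base_error_rate,
              tissues = as.character(tissues),
              genome_length = as.integer(genome_length),
              n_sd_intervals = as.integer(n_sd_intervals),
              sd_interval_len = as.integer(sd_interval_len),
              sd_enrichment = sd_enrichment)
  validate_config(cfg)
  structure(cfg, class = "tdgf_config")
}

validate_config <- function(cfg) {
  if (length(cfg$parent_len_range) == 1L)
    cfg$parent_len_range <- rep(cfg$parent_len_range, 2L)
  if (any(cfg$parent_len_range %% 3L != 0L))
    stopf("parent_len_range bounds must be multiples of 3")
  if (cfg$parent_len_range[1] > cfg$parent_len_range[2])
    stopf("parent_len_range must be non-decreasing")
  if (cfg$target_identity <= 0 || cfg$target_identity > 1)
    stopf("target_identity must be in (0, 1]")
  for (f in c("fusion_fracA", "fusion_fracB"))
    if (cfg[[f]] <= 0 || cfg[[f]] >= 1)
      stopf("%s must be strictly inside (0, 1)", f)
  if (cfg$n_fusions > cfg$n_parent_pairs)
    stopf("n_fusions cannot exceed n_parent_pairs")
  if (cfg$read_length < 2L)
    stopf("read_length must be >= 2")
  counts <- c("n_parent_pairs", "n_fusions", "read_depth",
              "junction_reads_per_fusion", "linker_length",
              "n_sd_intervals", "sd_interval_len", "genome_length")
  for (f in counts)
    if (cfg[[f]] < 0L) stopf("%s must be >= 0", f)
  if (cfg$base_error_rate < 0 || cfg$base_error_rate >= 1)
    stopf("base_error_rate must be in [0, 1)")
  if (length(cfg$tissues) < 1L) stopf("at least one tissue label is required")
  if (cfg$sd_enrichment < 0) stopf("sd_enrichment must be >= 0")
  if (cfg$n_sd_intervals * cfg$sd_interval_len >= cfg$genome_length)
    stopf("total SD span must be smaller than genome_length")
  invisible(cfg)
}

#' @export
print.tdgf_config <- function(x, ...) {
  cat("tdgf simulation config\n")
  cat(sprintf("  %d parent pairs (%d-%d nt), %d fusions at identity %.2f\n",
              x$n_parent_pairs, x$parent_len_range[1], x$parent_len_range[2],
              x$n_fusions, x$target_identity))
  cat(sprintf("  reads: %d nt, depth %d/tx/tissue, %d planted junction reads, error %.3g\n",
              x$read_length, x$read_depth, x$junction_reads_per_fusion,
              x$base_error_rate))
  cat(sprintf("  genome: %d nt, %d SD x %d nt, enrichment %.1f; %d tissues\n",
              x$genome_length, x$n_sd_intervals, x$sd_interval_len,
              x$sd_enrichment, length(x$tissues)))
  invisible(x)
}

SENSE_CODONS <- {
  b <- c("A", "C", "G", "T")
  all64 <- as.vector(outer(outer(b, b, paste0), b, paste0))
  setdiff(all64, c("TAA", "TAG", "TGA"))
}
STOP_CODONS <- c("TAA", "TAG", "TGA")

#' Simulate random coding parent sequences
#'
#' Draws \code{n} in-frame coding nucleotide sequences: uniformly sampled
#' sense codons terminated by a stop codon, so frame 0 contains no premature
#' stop. Deterministic for a fixed seed.
#'
#' @param n number of sequences (>= 1).
#' @param len_range length (nt) or length range; multiples of 3.
#' @param seed RNG seed.
#' @param prefix identifier prefix.
#' @return data.frame with columns \code{id}, \code{nt}, \code{aa}.
#' @export
simulate_parents <- function(n, len_range = c(300L, 600L), seed = 1L,
                             prefix = "seq") {
  if (n < 1L) stopf("n must be >= 1")
  len_range <- as.integer(len_range)
  if (length(len_range) == 1L) len_range <- rep(len_range, 2L)
  if (any(len_range %% 3L != 0L))
    stopf("sequence lengths must be multiples of 3")
  with_seed(seed, {
    pool <- seq(len_range[1] %/% 3L, len_range[2] %/% 3L)
    lens <- 3L * pool[sample.int(length(pool), n, replace = TRUE)]
    nt <- vapply(lens, function(L) {
      paste0(paste(sample(SENSE_CODONS, L %/% 3L - 1L, replace = TRUE),
                   collapse = ""),
             sample(STOP_CODONS, 1L))
    }, character(1))
    ids <- sprintf("%s%03d", prefix, seq_len(n))
    aa <- as.character(Biostrings::translate(Biostrings::DNAStringSet(nt)))
    data.frame(id = ids, nt = nt, aa = aa, stringsAsFactors = FALSE)
  })
}

#' Mutate a sequence to a target identity
#'
#' Applies point substitutions (never indels) at \code{round((1 - target) * L)}
#' distinct positions, each replaced by a different base, so the realized
#' identity (matching positions / length) equals the target up to rounding.
#'
#' @param seq nucleotide string.
#' @param target_identity fraction in (0, 1].
#' @param seed RNG seed.
#' @return mutated sequence (same length).
#' @export
mutate_to_identity <- function(seq, target_identity, seed = 1L) {
  if (!nzchar(seq)) stopf("cannot mutate an empty sequence")
  if (target_identity <= 0 || target_identity > 1)
    stopf("target_identity must be in (0, 1]")
  L <- nchar(seq)
  k <- round((1 - target_identity) * L)
  if (k == 0L) return(seq)
  with_seed(seed, {
    pos <- sample.int(L, k)
    chars <- strsplit(seq, "", fixed = TRUE)[[1]]
    bases <- c("A", "C", "G", "T")
    for (p in pos) {
      alt <- setdiff(bases, chars[p])
      chars[p] <- alt[sample.int(length(alt), 1L)]
    }
    paste(chars, collapse = "")
  })
}

#' Construct a readthrough fusion from two parents
#'
#' The fusion is the first \code{floor(fracA * |A|)} nt of parent A, an
#' optional unaligned linker, then the last \code{floor(fracB * |B|)} nt of
#' parent B. The true breakpoint is the 0-based offset at which parent-A
#' sequence ends.
#'
#' @param parentA_nt,parentB_nt parent nucleotide sequences.
#' @param fracA,fracB fractions in (0, 1) of each parent retained.
#' @param linker optional unaligned spacer sequence ("" for none).
#' @param fusion_id,parentA_id,parentB_id identifiers for the truth record.
#' @param min_segment minimum retained segment length (nt).
#' @return list with \code{sequence} and a one-row \code{truth} data.frame
#'   (fusion_id, parentA_id, parentB_id, true_breakpoint, in_sd,
#'   planted_junction_reads).
#' @export
simulate_fusion <- function(parentA_nt, parentB_nt, fracA = 0.5, fracB = 0.5,
                            linker = "", fusion_id = "fusion1",
                            parentA_id = "parentA", parentB_id = "parentB",
                            min_segment = 30L) {
  if (fracA <= 0 || fracA >= 1 || fracB <= 0 || fracB >= 1)
    stopf("fracA and fracB must be strictly inside (0, 1): the breakpoint must be internal to both parents")
  lenA <- nchar(parentA_nt); lenB <- nchar(parentB_nt)
  keepA <- floor(fracA * lenA); keepB <- floor(fracB * lenB)
  if (keepA < min_segment || keepB < min_segment)
    stopf("retained segment too short (%d / %d nt; need >= %d)",
          keepA, keepB, min_segment)
  fusion <- paste0(substr(parentA_nt, 1L, keepA), linker,
                   substr(parentB_nt, lenB - keepB + 1L, lenB))
  truth <- data.frame(fusion_id = fusion_id, parentA_id = parentA_id,
                      parentB_id = parentB_id, true_breakpoint = keepA,
                      in_sd = NA, planted_junction_reads = NA_integer_,
                      stringsAsFactors = FALSE)
  list(sequence = fusion, truth = truth)
}

#' Place gene and segmental-duplication intervals on a synthetic genome
#'
#' Lays out \code{n_sd} non-overlapping SD blocks on a single chromosome,
#' then places each gene either fully inside an SD block or fully outside.
#' A fusion gene lands in SD with probability \code{min(1, p_sd *
#' sd_enrichment)} and any other gene with the background probability
#' \code{p_sd} = SD fraction of the genome. Gene intervals never overlap
#' each other.
#'
#' @param gene_ids character vector of gene labels.
#' @param gene_lengths integer vector of gene lengths (nt).
#' @param is_fusion logical vector marking fusion loci.
#' @param genome_length,n_sd,sd_len,sd_enrichment see
#'   \code{\link{simulation_config}}.
#' @param seed RNG seed.
#' @return list with \code{genes} and \code{sd}: \code{GRanges} on "chr1";
#'   \code{genes} carries mcols \code{label}, \code{is_fusion}, \code{in_sd}.
#' @export
place_genes <- function(gene_ids, gene_lengths, is_fusion,
                        genome_length, n_sd, sd_len, sd_enrichment,
                        seed = 1L) {
  stopifnot(length(gene_ids) == length(gene_lengths),
            length(gene_ids) == length(is_fusion))
  if (n_sd * sd_len >= genome_length)
    stopf("total SD span must be smaller than genome_length")
  with_seed(seed, {
    sd_starts <- place_nonoverlapping(n_sd, sd_len, genome_length,
                                      what = "SD interval")
    sd_gr <- GenomicRanges::GRanges("chr1",
      IRanges::IRanges(start = sd_starts + 1L, width = sd_len))
    sd_gr <- sort(sd_gr)
    S4Vectors::mcols(sd_gr)$label <- sprintf("sd%03d", seq_along(sd_gr))
    p_sd <- n_sd * sd_len / genome_length
    p_gene <- ifelse(is_fusion, pmin(1, p_sd * sd_enrichment), p_sd)
    in_sd <- stats::runif(length(gene_ids)) < p_gene
    sd0 <- cbind(start = GenomicRanges::start(sd_gr) - 1L,
                 end = GenomicRanges::end(sd_gr))
    placed <- matrix(NA_integer_, nrow = length(gene_ids), ncol = 2L)
    for (i in seq_along(gene_ids)) {
      L <- gene_lengths[i]
      ok <- FALSE
      for (try in seq_len(2000L)) {
        if (in_sd[i]) {
          fits <- which(sd0[, "end"] - sd0[, "start"] >= L)
          if (!length(fits)) stopf("no SD interval can hold gene '%s'", gene_ids[i])
          j <- fits[sample.int(length(fits), 1L)]
          s <- sd0[j, "start"] +
            sample.int(sd0[j, "end"] - sd0[j, "start"] - L + 1L, 1L) - 1L
        } else {
          s <- sample.int(genome_length - L + 1L, 1L) - 1L
          # must be fully outside SD so the in-SD indicator is exact
          if (any(pmin(sd0[, "end"], s + L) > pmax(sd0[, "start"], s))) next
        }
        prev <- placed[seq_len(i - 1L), , drop = FALSE]
        if (nrow(prev) &&
            any(pmin(prev[, 2L], s + L) > pmax(prev[, 1L], s))) next
        placed[i, ] <- c(s, s + L)
        ok <- TRUE
        break
      }
      if (!ok) stopf("could not place gene '%s' without overlap (genome too crowded)",
                     gene_ids[i])
    }
    genes <- GenomicRanges::GRanges("chr1",
      IRanges::IRanges(start = placed[, 1L] + 1L, end = placed[, 2L]))
    S4Vectors::mcols(genes)$label <- gene_ids
    S4Vectors::mcols(genes)$is_fusion <- is_fusion
    S4Vectors::mcols(genes)$in_sd <- in_sd
    list(genes = genes, sd = sd_gr)
  })
}

# 0-based starts of n non-overlapping intervals of width w in [0, total).
place_nonoverlapping <- function(n, w, total, what = "interval") {
  starts <- integer(0)
  for (i in seq_len(n)) {
    ok <- FALSE
    for (try in seq_len(5000L)) {
      s <- sample.int(total - w + 1L, 1L) - 1L
      if (!length(starts) ||
          all(s + w <= starts | s >= starts + w)) {
        starts <- c(starts, s); ok <- TRUE; break
      }
    }
    if (!ok) stopf("could not place %s %d of %d without overlap", what, i, n)
  }
  starts
}

#' Simulate an RNA-seq read set with planted junction reads
#'
#' Background reads start uniformly along each transcript; for every fusion,
#' exactly \code{junction_reads_per_fusion} reads per tissue are forced to
#' cover the true breakpoint with at least \code{min(8, read overhang room)}
#' nt on each side. Background reads on a fusion transcript are resampled
#' away from the junction, so the set of breakpoint-spanning reads is
#' exactly the planted set. Per-base substitution errors occur at
#' \code{base_error_rate}; the Phred string is constant per read at
#' \code{-10 log10(error rate)} (capped at Q40 for an error-free run),
#' ASCII+33. Tissue is carried in the read name (\code{"|tissue=X"} suffix
#' dialect, since FASTQ has no tissue field).
#'
#' @param transcripts data.frame with columns \code{id}, \code{nt}.
#' @param truth truth table as produced by \code{\link{simulate_fusion}}
#'   (one row per fusion); may be NULL for no planted reads.
#' @param config a \code{\link{simulation_config}}.
#' @return data.frame: read_id, sequence, quality, tissue, transcript_id,
#'   junction (logical: planted breakpoint-spanning read).
#' @export
simulate_reads <- function(transcripts, truth, config) {
  rl <- config$read_length
  if (any(nchar(transcripts$nt) < rl))
    stopf("read_length (%d) exceeds the shortest transcript (%d nt)",
          rl, min(nchar(transcripts$nt)))
  q <- if (config$base_error_rate <= 0) 40L else
    as.integer(round(-10 * log10(config$base_error_rate)))
  qchar <- strrep(phred_encode(q), rl)
  with_seed(config$seed + 1L, {
    out <- list(); idx <- 0L; counter <- 0L
    emit <- function(tx_id, seq, tissue, junction) {
      counter <<- counter + 1L
      idx <<- idx + 1L
      out[[idx]] <<- data.frame(
        read_id = sprintf("r%06d|tx=%s|tissue=%s|j=%d",
                          counter, tx_id, tissue, as.integer(junction)),
        sequence = seq, quality = qchar, tissue = tissue,
        transcript_id = tx_id, junction = junction,
        stringsAsFactors = FALSE)
    }
    fusion_bp <- if (is.null(truth) || !nrow(truth)) integer(0) else
      stats::setNames(truth$true_breakpoint, truth$fusion_id)
    for (tissue in config$tissues) {
      for (r in seq_len(nrow(transcripts))) {
        tx <- transcripts$nt[r]; L <- nchar(tx)
        if (config$read_depth > 0L) {
          bp <- fusion_bp[transcripts$id[r]]
          for (d in seq_len(config$read_depth)) {
            # background reads on a fusion transcript are resampled until
            # they do NOT span the junction with counting overhang, so
            # exactly the planted reads are junction-spanning
            for (try in seq_len(1000L)) {
              s <- sample.int(L - rl + 1L, 1L) - 1L
              if (is.na(bp)) break
              o <- min(8L, bp, L - bp, rl %/% 2L)
              if (bp - s < o || s + rl - bp < o) break
            }
            emit(transcripts$id[r], substr(tx, s + 1L, s + rl), tissue, FALSE)
          }
        }
      }
      if (!is.null(truth) && nrow(truth) &&
          config$junction_reads_per_fusion > 0L) {
        for (r in seq_len(nrow(truth))) {
          tx <- transcripts$nt[match(truth$fusion_id[r], transcripts$id)]
          if (is.na(tx)) stopf("truth references unknown transcript '%s'",
                               truth$fusion_id[r])
          L <- nchar(tx); bp <- truth$true_breakpoint[r]
          o <- min(8L, bp, L - bp, rl %/% 2L)
          lo <- max(0L, bp + o - rl); hi <- min(L - rl, bp - o)
          if (hi < lo) stopf("cannot span breakpoint of '%s' with %d-nt reads",
                             truth$fusion_id[r], rl)
          starts <- lo + sample.int(hi - lo + 1L,
                                    config$junction_reads_per_fusion,
                                    replace = TRUE) - 1L
          for (s in starts)
            emit(truth$fusion_id[r], substr(tx, s + 1L, s + rl), tissue, TRUE)
        }
      }
    }
    reads <- if (idx) do.call(rbind, out) else
      data.frame(read_id = character(0), sequence = character(0),
                 quality = character(0), tissue = character(0),
                 transcript_id = character(0), junction = logical(0),
                 stringsAsFactors = FALSE)
    if (config$base_error_rate > 0 && nrow(reads)) {
      reads$sequence <- vapply(reads$sequence, function(s) {
        ch <- strsplit(s, "", fixed = TRUE)[[1]]
        hit <- which(stats::runif(length(ch)) < config$base_error_rate)
        for (p in hit) {
          alt <- setdiff(c("A", "C", "G", "T"), ch[p])
          ch[p] <- alt[sample.int(3L, 1L)]
        }
        paste(ch, collapse = "")
      }, character(1), USE.NAMES = FALSE)
    }
    rownames(reads) <- NULL
    reads
  })
}

#' Generate a complete synthetic fixture bundle on disk
#'
#' Simulates parents, fusions, genomic placement, reads and a species tree
#' from one configuration and writes a cross-referenced bundle:
#' \code{parents.fa}, \code{fusions.fa}, \code{reads.fq}, \code{genes.bed},
#' \code{sd.bed}, \code{tree.nwk}, \code{truth.tsv}, \code{config.yml}.
#' Re-running with the same configuration reproduces the bundle
#' byte-identically.
#'
#' @param config a \code{\link{simulation_config}}.
#' @param dir output directory (created if missing).
#' @return (invisibly) the in-memory bundle, as \code{\link{read_fixture}}
#'   would load it.
#' @export
make_fixture <- function(config, dir) {
  bundle <- simulate_bundle(config)
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  fa <- function(df, path) {
    x <- Biostrings::DNAStringSet(df$nt); names(x) <- df$id
    Biostrings::writeXStringSet(x, filepath = path)
  }
  fa(bundle$parents, file.path(dir, "parents.fa"))
  fa(bundle$fusions, file.path(dir, "fusions.fa"))
  write_fastq(bundle$reads, file.path(dir, "reads.fq"))
  write_bed(bundle$genes, file.path(dir, "genes.bed"))
  write_bed(bundle$sd, file.path(dir, "sd.bed"))
  ape::write.tree(bundle$tree, file.path(dir, "tree.nwk"))
  utils::write.table(bundle$truth, file.path(dir, "truth.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  yaml::write_yaml(unclass(config), file.path(dir, "config.yml"))
  invisible(bundle)
}

# Reference species tree used for fixtures: the study's seven species with
# round divergence times (My) on the branches.
fixture_tree_text <- function() {
  paste0("((((((human:6,chimp:6):2,gorilla:8):8,orangutan:16):9,",
         "macaque:25):18,marmoset:43):47,mouse:90);")
}

#' Simulate a fixture bundle in memory
#'
#' The in-memory counterpart of \code{\link{make_fixture}}; all downstream
#' modules can run from its return value without touching disk.
#'
#' @param config a \code{\link{simulation_config}}.
#' @return list: parents, fusions (data.frames id/nt), reads, truth, genes,
#'   sd (\code{GRanges}), tree (\code{phylo}), config.
#' @export
simulate_bundle <- function(config) {
  validate_config(unclass(config))
  np <- 2L * config$n_parent_pairs
  parents <- simulate_parents(np, config$parent_len_range,
                              seed = config$seed, prefix = "parent")
  fus <- vector("list", config$n_fusions)
  truth <- vector("list", config$n_fusions)
  linker <- if (config$linker_length > 0L)
    with_seed(config$seed + 2L,
              paste(sample(c("A", "C", "G", "T"), config$linker_length,
                           replace = TRUE), collapse = ""))
  else ""
  for (i in seq_len(config$n_fusions)) {
    a <- 2L * i - 1L; b <- 2L * i
    f <- simulate_fusion(parents$nt[a], parents$nt[b],
                         fracA = config$fusion_fracA,
                         fracB = config$fusion_fracB,
                         linker = linker,
                         fusion_id = sprintf("fusion%03d", i),
                         parentA_id = parents$id[a],
                         parentB_id = parents$id[b])
    # diverge the composite from its parents to the configured identity
    f$sequence <- mutate_to_identity(f$sequence, config$target_identity,
                                     seed = config$seed + 100L + i)
    fus[[i]] <- data.frame(id = f$truth$fusion_id, nt = f$sequence,
                           stringsAsFactors = FALSE)
    truth[[i]] <- f$truth
  }
  fusions <- if (config$n_fusions) do.call(rbind, fus) else
    data.frame(id = character(0), nt = character(0))
  truth <- if (config$n_fusions) do.call(rbind, truth) else
    data.frame(fusion_id = character(0), parentA_id = character(0),
               parentB_id = character(0), true_breakpoint = integer(0),
               in_sd = logical(0), planted_junction_reads = integer(0))
  all_ids <- c(parents$id, fusions$id)
  all_len <- c(nchar(parents$nt), nchar(fusions$nt))
  placement <- place_genes(all_ids, all_len,
                           is_fusion = all_ids %in% fusions$id,
                           genome_length = config$genome_length,
                           n_sd = config$n_sd_intervals,
                           sd_len = config$sd_interval_len,
                           sd_enrichment = config$sd_enrichment,
                           seed = config$seed + 3L)
  if (nrow(truth)) {
    m <- match(truth$fusion_id, S4Vectors::mcols(placement$genes)$label)
    truth$in_sd <- S4Vectors::mcols(placement$genes)$in_sd[m]
    truth$planted_junction_reads <- config$junction_reads_per_fusion
  }
  transcripts <- rbind(parents[, c("id", "nt")], fusions)
  reads <- simulate_reads(transcripts, truth, config)
  list(parents = parents[, c("id", "nt", "aa")], fusions = fusions,
       reads = reads, truth = truth,
       genes = placement$genes, sd = placement$sd,
       tree = parse_newick(text = fixture_tree_text()),
       config = config)
}

#' Load a fixture bundle from disk
#'
#' @param dir directory written by \code{\link{make_fixture}}.
#' @return list with the same shape as \code{\link{simulate_bundle}}.
#' @export
read_fixture <- function(dir) {
  rd <- function(path) {
    x <- Biostrings::readDNAStringSet(path)
    data.frame(id = names(x), nt = as.character(x), stringsAsFactors = FALSE)
  }
  cfg <- yaml::read_yaml(file.path(dir, "config.yml"))
  cfg$tissues <- as.character(cfg$tissues)
  truth <- utils::read.table(file.path(dir, "truth.tsv"), sep = "\t",
                             header = TRUE, stringsAsFactors = FALSE)
  list(parents = rd(file.path(dir, "parents.fa")),
       fusions = rd(file.path(dir, "fusions.fa")),
       reads = read_fastq(file.path(dir, "reads.fq")),
       truth = truth,
       genes = read_bed(file.path(dir, "genes.bed"), class = "gene"),
       sd = read_bed(file.path(dir, "sd.bed"), class = "sd"),
       tree = parse_newick(file.path(dir, "tree.nwk")),
       config = do.call(simulation_config, cfg))
}
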