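#' Read genomic intervals from BED (0-based half-open)
#'
#' Minimal BED3+ reader: chrom, start, end and an optional name column;
#' track and comment lines are skipped. Coordinates are validated
#' (\code{end > start}) with line-numbered errors. Intervals are returned
#' as a \code{GRanges} (1-based closed internally, converted at this
#' boundary) with \code{label} and \code{class} metadata columns.
#'
#' @param path BED file path.
#' @param class interval class tag, "gene" or "sd".
#' @return \code{GRanges}.
#' @export
read_bed <- function(path, class = c("gene", "sd")) {
  class <- match.arg(class)
  lines <- readLines(path)
  keep <- nzchar(lines) & !startsWith(lines, "#") &
    !startsWith(lines, "track") & !startsWith(lines, "browser")
  lineno <- which(keep)
  lines <- lines[keep]
  if (!length(lines))
    return(GenomicRanges::GRanges(seqnames = character(0),
                                  ranges = IRanges::IRanges(),
                                  label = character(0), class = character(0)))
  parts <- strsplit(lines, "\t", fixed = TRUE)
  short <- which(lengths(parts) < 3L)
  if (length(short))
    stopf("line %d: BED needs at least 3 columns", lineno[short[1]])
  chrom <- vapply(parts, `[[`, "", 1L)
  start0 <- suppressWarnings(as.integer(vapply(parts, `[[`, "", 2L)))
  end0 <- suppressWarnings(as.integer(vapply(parts, `[[`, "", 3L)))
  bad <- which(is.na(start0) | is.na(end0))
  if (length(bad))
    stopf("line %d: non-integer coordinates", lineno[bad[1]])
  zero <- which(end0 <= start0)
  if (length(zero))
    stopf("line %d: end (%d) must exceed start (%d) in half-open coordinates",
          lineno[zero[1]], end0[zero[1]], start0[zero[1]])
  label <- vapply(seq_along(parts), function(i)
    if (length(parts[[i]]) >= 4L) parts[[i]][[4L]] else
      sprintf("%s_%d_%d", chrom[i], start0[i], end0[i]), "")
  gr <- GenomicRanges::GRanges(chrom,
                               IRanges::IRanges(start = start0 + 1L,
                                                end = end0))
  S4Vectors::mcols(gr)$label <- label
  S4Vectors::mcols(gr)$class <- class
  gr
}

#' @rdname read_bed
#' @param gr \code{GRanges} with a \code{label} metadata column.
#' @export
write_bed <- function(gr, path) {
  df <- data.frame(chrom = as.character(GenomicRanges::seqnames(gr)),
                   start = GenomicRanges::start(gr) - 1L,
                   end = GenomicRanges::end(gr),
                   name = S4Vectors::mcols(gr)$label)
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
}

#' Genes overlapping segmental-duplication intervals
#'
#' A gene overlaps when at least 1 nt intersects an SD interval on the same
#' chromosome; half-open abutment is not overlap. Overlap is binary, not
#' base-pair weighted.
#'
#' @param genes,sd_intervals \code{GRanges}; genes need a \code{label}
#'   metadata column.
#' @return character vector of overlapping gene labels.
#' @export
overlap_genes <- function(genes, sd_intervals) {
  # disjoint seqlevels are a legitimate "no overlap", not worth a warning
  hits <- suppressWarnings(
    GenomicRanges::findOverlaps(genes, sd_intervals, minoverlap = 1L))
  sort(unique(S4Vectors::mcols(genes)$label[S4Vectors::queryHits(hits)]))
}

#' Permutation test for SD enrichment of a focal gene set
#'
#' Observed statistic: the number k of focal genes overlapping SD. Null:
#' each replicate draws \code{|focal|} genes uniformly without replacement
#' from the universe (no chromosomal restriction) and records its SD
#' overlap count. The empirical p-value uses the add-one correction
#' \code{p = (1 + #\{null >= k\}) / (replicates + 1)}, so it is never zero.
#' The null is exactly hypergeometric, which
#' \code{\link{hypergeometric_tail}} provides as an independent check.
#'
#' @param universe_genes \code{GRanges} of all candidate genes (labels
#'   unique).
#' @param sd_intervals \code{GRanges} of SD blocks.
#' @param focal_labels labels of the focal set (must all be in the
#'   universe). The focal size is deliberately an explicit input with no
#'   default.
#' @param replicates number of random sets (default 10000).
#' @param seed RNG seed.
#' @return object of class \code{"tdgf_permtest"}: observed_overlap,
#'   focal_size, universe_size, n_in_sd, replicates, null_counts (table),
#'   n_greater, n_equal, p_empirical, seed.
#' @export
permutation_test <- function(universe_genes, sd_intervals, focal_labels,
                             replicates = 10000L, seed = 1L) {
  labels <- S4Vectors::mcols(universe_genes)$label
  if (anyDuplicated(labels)) stopf("universe gene labels must be unique")
  missing <- setdiff(focal_labels, labels)
  if (length(missing))
    stopf("focal gene '%s' is not in the universe", missing[1])
  if (replicates < 1L) stopf("replicates must be >= 1")
  in_sd <- labels %in% overlap_genes(universe_genes, sd_intervals)
  n <- length(focal_labels); N <- length(labels); m <- sum(in_sd)
  k <- sum(in_sd[match(focal_labels, labels)])
  null <- with_seed(seed, {
    vapply(seq_len(replicates),
           function(i) sum(in_sd[sample.int(N, n)]), 0L)
  })
  n_greater <- sum(null > k); n_equal <- sum(null == k)
  structure(list(observed_overlap = k, focal_size = n, universe_size = N,
                 n_in_sd = m, replicates = as.integer(replicates),
                 null_counts = table(null),
                 n_greater = n_greater, n_equal = n_equal,
                 p_empirical = (1 + n_greater + n_equal) / (replicates + 1),
                 seed = as.integer(seed)),
            class = "tdgf_permtest")
}

#' @export
print.tdgf_permtest <- function(x, ...) {
  cat(sprintf("SD overlap permutation test: %d/%d focal genes in SD (universe %d, %d in SD)\n",
              x$observed_overlap, x$focal_size, x$universe_size, x$n_in_sd))
  cat(sprintf("  %d replicates, empirical p = %.4g (seed %d)\n",
              x$replicates, x$p_empirical, x$seed))
  invisible(x)
}

#' Exact hypergeometric upper tail
#'
#' P(X >= k) for X ~ Hypergeometric(N, m, n): drawing n genes without
#' replacement from a universe of N containing m SD-overlapping genes.
#' Computed by direct summation of the probability mass in log space
#' (\code{lchoose}), which is the exact limit of the permutation null and
#' serves as its oracle.
#'
#' @param N universe size.
#' @param m number of "successes" (SD-overlapping genes) in the universe.
#' @param n sample (focal set) size.
#' @param k observed overlap count.
#' @return probability.
#' @export
hypergeometric_tail <- function(N, m, n, k) {
  if (N < 0 || m < 0 || m > N || n < 0 || n > N)
    stopf("need 0 <= m <= N and 0 <= n <= N")
  if (k < 0 || k > n) stopf("need 0 <= k <= n")
  if (k <= max(0L, n + m - N)) return(1)
  i <- seq(k, min(m, n))
  if (!length(i)) return(0)
  lp <- lchoose(m, i) + lchoose(N - m, n - i) - lchoose(N, n)
  mx <- max(lp)
  exp(mx) * sum(exp(lp - mx))
}
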