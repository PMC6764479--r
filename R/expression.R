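#' Read and write FASTQ read sets
#'
#' Reads are returned as a plain data.frame with the tissue label recovered
#' from the \code{"|tissue=X"} read-name dialect written by
#' \code{\link{simulate_reads}} (NA when absent). Qualities are Phred+33
#' strings.
#'
#' @param path FASTQ path.
#' @return data.frame: read_id, sequence, quality, tissue.
#' @export
read_fastq <- function(path) {
  x <- Biostrings::readDNAStringSet(path, format = "fastq",
                                    with.qualities = TRUE)
  ids <- names(x)
  tissue <- ifelse(grepl("\\|tissue=([^|]+)", ids),
                   sub(".*\\|tissue=([^|]+).*", "\\1", ids), NA_character_)
  data.frame(read_id = ids, sequence = as.character(x),
             quality = as.character(S4Vectors::mcols(x)$qualities),
             tissue = tissue, stringsAsFactors = FALSE)
}

#' @rdname read_fastq
#' @param reads read data.frame (read_id, sequence, quality).
#' @export
write_fastq <- function(reads, path) {
  x <- Biostrings::DNAStringSet(reads$sequence)
  names(x) <- reads$read_id
  Biostrings::writeXStringSet(x, filepath = path, format = "fastq",
                              qualities = Biostrings::BStringSet(reads$quality))
}

#' Quality-control filter for sequencing reads
#'
#' RNA mode trims the leading bases (poor-quality base-caller output at the
#' 5' end), then drops reads whose mean Phred score is below
#' \code{min_mean_phred} or whose post-trim length is below
#' \code{min_length}. Ribosome-footprint mode (\code{mode = "ribo"}) trims
#' nothing and keeps reads longer than 25 nt. Reads whose quality string
#' length does not match the sequence are skipped (counted in the
#' \code{"skipped"} attribute) with a warning.
#'
#' @param reads read data.frame (read_id, sequence, quality, ...).
#' @param min_mean_phred minimum mean Phred score (default 20).
#' @param trim_leading bases removed from the read start (RNA default 13).
#' @param min_length minimum post-trim length (RNA default 36; ribo 26).
#' @param mode "rna" or "ribo"; presets \code{trim_leading}/\code{min_length}
#'   unless given explicitly.
#' @return filtered read data.frame (same columns).
#' @export
qc_filter_reads <- function(reads, min_mean_phred = 20,
                            trim_leading = NULL, min_length = NULL,
                            mode = c("rna", "ribo")) {
  mode <- match.arg(mode)
  if (is.null(trim_leading)) trim_leading <- if (mode == "rna") 13L else 0L
  if (is.null(min_length)) min_length <- if (mode == "rna") 36L else 26L
  if (!nrow(reads)) return(reads)
  ok_len <- nchar(reads$sequence) == nchar(reads$quality)
  if (any(!ok_len)) {
    warning(sprintf("%d read(s) with sequence/quality length mismatch skipped",
                    sum(!ok_len)), call. = FALSE)
    reads <- reads[ok_len, , drop = FALSE]
  }
  if (trim_leading > 0L) {
    reads$sequence <- substring(reads$sequence, trim_leading + 1L)
    reads$quality <- substring(reads$quality, trim_leading + 1L)
  }
  meanq <- vapply(reads$quality, phred_mean, 0, USE.NAMES = FALSE)
  keep <- !is.na(meanq) & meanq >= min_mean_phred &
    nchar(reads$sequence) >= min_length
  out <- reads[keep, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "skipped") <- sum(!ok_len)
  out
}

# Position-major (L x n) character stacks of equal-length reads, forward and
# reverse-complement, so per-offset mismatch counting is one vectorized
# column sum.
read_stack <- function(seqs) {
  n <- length(seqs); L <- nchar(seqs[1])
  v <- strsplit(paste(seqs, collapse = ""), "", fixed = TRUE)[[1]]
  fwd <- matrix(v, nrow = L, ncol = n)
  rc <- chartr("ACGTN", "TGCAN", v)
  rev <- matrix(rc, nrow = L, ncol = n)[L:1, , drop = FALSE]
  list(fwd = fwd, rev = rev)
}

# Spanning indicator for one probe over one read stack.
count_core <- function(pvec, bp, o, max_mismatches, stack) {
  L <- nrow(stack$fwd); n <- ncol(stack$fwd)
  hit <- rep(FALSE, n)
  Pl <- length(pvec)
  if (L < 2L * o) return(hit)
  for (s in seq(bp + o - L, bp - o)) {
    a <- max(0L, s); b <- min(Pl, s + L)
    if (bp - a < o || b - bp < o) next
    pcols <- seq(a + 1L, b)
    rcols <- pcols - s
    pseg <- pvec[pcols]
    mm_f <- colSums(stack$fwd[rcols, , drop = FALSE] != pseg)
    mm_r <- colSums(stack$rev[rcols, , drop = FALSE] != pseg)
    hit <- hit | (pmin(mm_f, mm_r) <= max_mismatches)
    if (all(hit)) break
  }
  hit
}

#' Count junction-spanning reads for a probe
#'
#' A read is counted iff its best ungapped alignment to the probe, on
#' either strand, has at most \code{max_mismatches} mismatches over the
#' read/probe overlap and covers at least \code{min_overhang} nt on both
#' sides of the breakpoint; reads matching only one flank -- however
#' perfectly -- never count. Each read counts at most once. For short
#' ribosome-footprint probes the effective overhang is capped at the probe
#' flank.
#'
#' @param probe a \code{\link{make_junction_probe}} object.
#' @param reads read data.frame (post-QC).
#' @param min_overhang required nt on each side of the junction (default 8).
#' @param max_mismatches mismatch budget over the overlap (default 2).
#' @return list: \code{count} and \code{spanning} (logical per read).
#' @export
count_junction_reads <- function(probe, reads, min_overhang = 8L,
                                 max_mismatches = 2L) {
  o <- min(min_overhang, probe$flank)
  P <- probe$sequence; Pl <- nchar(P); bp <- probe$breakpoint_offset
  if (Pl < 2L * o)
    stopf("probe shorter than twice the overhang (%d < %d)", Pl, 2L * o)
  if (!nrow(reads))
    return(list(count = 0L, spanning = logical(0)))
  pvec <- strsplit(P, "", fixed = TRUE)[[1]]
  spanning <- logical(nrow(reads))
  for (L in unique(nchar(reads$sequence))) {
    sel <- which(nchar(reads$sequence) == L)
    spanning[sel] <- count_core(pvec, bp, o, max_mismatches,
                                read_stack(reads$sequence[sel]))
  }
  list(count = sum(spanning), spanning = spanning)
}

#' Junction counts per composite and tissue
#'
#' Applies \code{\link{count_junction_reads}} per probe within each tissue
#' group and attaches the tiered expression calls.
#'
#' @param probes list of probes.
#' @param reads post-QC read data.frame with a \code{tissue} column.
#' @param species species label stamped on the result.
#' @param min_overhang,max_mismatches passed through.
#' @param thresholds expression tiers (default \code{c(1, 3, 5)}).
#' @return data.frame: composite_id, species, tissue, count,
#'   expressed_1 / expressed_3 / expressed_5.
#' @export
count_junction_matrix <- function(probes, reads, species = "human",
                                  min_overhang = 8L, max_mismatches = 2L,
                                  thresholds = c(1L, 3L, 5L)) {
  tissues <- sort(unique(reads$tissue))
  # one read stack per (tissue, read length), shared across probes
  stacks <- lapply(tissues, function(t) {
    seqs <- reads$sequence[reads$tissue == t]
    lapply(split(seqs, nchar(seqs)), read_stack)
  })
  names(stacks) <- tissues
  out <- list()
  for (pr in probes) {
    o <- min(min_overhang, pr$flank)
    pvec <- strsplit(pr$sequence, "", fixed = TRUE)[[1]]
    if (length(pvec) < 2L * o)
      stopf("probe '%s' shorter than twice the overhang", pr$composite_id)
    for (t in tissues) {
      n <- sum(vapply(stacks[[t]], function(st)
        sum(count_core(pvec, pr$breakpoint_offset, o, max_mismatches, st)),
        0))
      calls <- call_expressed(n, thresholds)
      row <- data.frame(composite_id = pr$composite_id, species = species,
                        tissue = t, count = n, stringsAsFactors = FALSE)
      for (k in thresholds)
        row[[paste0("expressed_", k)]] <- calls[[as.character(k)]]
      out[[length(out) + 1L]] <- row
    }
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Tiered expression calls from a junction read count
#'
#' A transcript is called expressed at tier k when at least k reads span
#' its junction; the working tiers are 1 (primary), 3 and 5. Calls are
#' monotone by construction: expressed at 5 implies expressed at 3 implies
#' expressed at 1.
#'
#' @param count spanning-read count (>= 0).
#' @param thresholds integer tiers.
#' @return named logical vector (one element per tier).
#' @export
call_expressed <- function(count, thresholds = c(1L, 3L, 5L)) {
  if (count < 0) stopf("count must be >= 0")
  stats::setNames(count >= thresholds, as.character(thresholds))
}

#' Tissue enrichment of expressed fusions
#'
#' For each tissue, tests whether the proportion of fusions expressed there
#' exceeds the proportion expressed in the remaining tissues pooled, with
#' the pooled-variance two-proportion z statistic:
#' \deqn{z = (p_t - p_r) / \sqrt{\bar p (1 - \bar p)(1/n_t + 1/n_r)}}
#' The one-tailed p-value is the upper tail of the standard normal; the
#' two-tailed p-value is \code{min(1, 2 min(p1, 1 - p1))}. A degenerate
#' pooled variance (all or none expressed everywhere) carries no signal and
#' yields z = 0, one-tailed p = 0.5, two-tailed p = 1.
#'
#' @param calls logical matrix, fusions x tissues (TRUE = expressed).
#' @return data.frame: tissue, n_expressed, proportion, z_score,
#'   p_one_tailed, p_two_tailed.
#' @export
tissue_enrichment <- function(calls) {
  if (is.data.frame(calls)) calls <- as.matrix(calls)
  if (ncol(calls) < 2L) stopf("at least two tissues are required")
  if (nrow(calls) < 1L) stopf("at least one fusion is required")
  res <- lapply(colnames(calls), function(t) {
    x_t <- sum(calls[, t]); n_t <- nrow(calls)
    rest <- calls[, setdiff(colnames(calls), t), drop = FALSE]
    x_r <- sum(rest); n_r <- length(rest)
    p_t <- x_t / n_t; p_r <- x_r / n_r
    pbar <- (x_t + x_r) / (n_t + n_r)
    v <- pbar * (1 - pbar) * (1 / n_t + 1 / n_r)
    if (v <= 0) {
      # degenerate null (all or nothing expressed everywhere): no signal
      z <- 0; p1 <- 0.5
    } else {
      z <- (p_t - p_r) / sqrt(v)
      p1 <- stats::pnorm(z, lower.tail = FALSE)
    }
    data.frame(tissue = t, n_expressed = x_t, proportion = p_t,
               z_score = z, p_one_tailed = p1,
               p_two_tailed = min(1, 2 * min(p1, 1 - p1)),
               stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, res)
  rownames(res) <- NULL
  res
}

#' Transcripts-per-million from counts and lengths
#'
#' \code{rate_i = count_i / length_i}; \code{TPM_i = 1e6 rate_i / sum(rate)}.
#' The probe counts and the background transcriptome counts enter the same
#' normalization, so probe TPM is directly comparable to transcript TPM.
#'
#' @param counts non-negative read counts.
#' @param lengths positive lengths (nt).
#' @return numeric TPM vector (names preserved); all zero (with a warning)
#'   when every count is zero.
#' @export
compute_tpm <- function(counts, lengths) {
  if (length(counts) != length(lengths))
    stopf("counts and lengths differ in length")
  if (any(lengths <= 0)) stopf("lengths must be > 0")
  rate <- counts / lengths
  total <- sum(rate)
  if (total == 0) {
    warning("all counts are zero; TPM undefined, returning zeros",
            call. = FALSE)
    return(stats::setNames(rep(0, length(counts)), names(counts)))
  }
  stats::setNames(1e6 * rate / total, names(counts))
}
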