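# Internal helpers shared across modules.

# Evaluate `expr` under a fixed RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, expr) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (has_old) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  expr
}

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)

assert_scalar_number <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x))
    stopf("'%s' must be a single number", name)
}

# Phred+33 encoding of a vector of integer qualities.
phred_encode <- function(q) {
  q <- pmax(0L, pmin(93L, as.integer(round(q))))
  vapply(q, function(qi) rawToChar(as.raw(qi + 33L)), character(1))
}

# Mean Phred score of a quality string (ASCII+33).
phred_mean <- function(qual) {
  if (nchar(qual) == 0L) return(NA_real_)
  mean(utf8ToInt(qual) - 33L)
}

# Reverse complement of a plain character DNA string.
revcomp <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

# 0-based half-open interval overlap length.
interval_overlap <- function(s1, e1, s2, e2) {
  max(0L, min(e1, e2) - max(s1, s2))
}

# Overlap of two intervals as a fraction of the shorter one.
overlap_fraction <- function(s1, e1, s2, e2) {
  ov <- interval_overlap(s1, e1, s2, e2)
  shorter <- min(e1 - s1, e2 - s2)
  if (shorter <= 0) return(0)
  ov / shorter
}
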