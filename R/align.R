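## Local alignment helpers built on Biostrings::pairwiseAlignment.
## Scoring is BLAST-like (match +2, mismatch -3, gap open 5, gap extend 2)
## so that spurious local alignments between unrelated sequences stay
## short, while 2%-diverged orthologous sequence aligns essentially
## full-length.  N is scored -1 against everything (it never helps).

align_submat <- local({
  mat <- NULL
  function() {
    if (is.null(mat)) {
      m <- Biostrings::nucleotideSubstitutionMatrix(match = 2,
                                                    mismatch = -3,
                                                    baseOnly = FALSE)
      m["N", ] <- -1; m[, "N"] <- -1
      mat <<- m
    }
    mat
  }
})

## Fraction of `pattern` bases matched in the best local alignment against
## `subject`.  Quality gates: the aligned pattern stretch must reach
## min(30, len/2) bp and 75% identity over aligned columns, otherwise the
## fraction is 0 (guards against short spurious local hits).
local_aligned_fraction <- function(pattern, subject,
                                   min_len = 30L, min_pid = 0.75) {
  np <- nchar(pattern)
  if (np == 0 || nchar(subject) == 0) return(0)
  aln <- Biostrings::pairwiseAlignment(
    pattern = Biostrings::DNAString(pattern),
    subject = Biostrings::DNAString(subject),
    type = "local", substitutionMatrix = align_submat(),
    gapOpening = 5, gapExtension = 2)
  nm <- Biostrings::nmatch(aln)
  aw <- Biostrings::nchar(aln)            # alignment length incl. gaps
  if (aw == 0) return(0)
  if (aw < min(min_len, ceiling(np / 2)) || nm / aw < min_pid) return(0)
  min(1, nm / np)
}

## Seed-based flank anchoring: exact k-mer matches of `pattern` in
## `subject` (sampled every `step` bp) vote for diagonals; the seeds on the
## modal diagonal band estimate the pattern's location and its aligned
## fraction (union of seed k-mers / pattern length).  At 2% divergence an
## exact 16-mer survives with probability ~0.72, so a truly orthologous
## flank is covered densely while an absent one gets no consistent band.
## Repeat-induced secondary diagonals (e.g. tandem arrays in part of the
## flank) lose the vote to the unique portion's single diagonal.
seed_anchor <- function(pattern, subject, k = 16L, step = 4L,
                        band = 40L) {
  np <- nchar(pattern)
  if (np < k || nchar(subject) < k) {
    return(list(frac = 0, s_start = NA_integer_, s_end = NA_integer_))
  }
  pstarts <- seq(1L, np - k + 1L, by = step)
  kmers <- substring(pattern, pstarts, pstarts + k - 1L)
  keep <- !grepl("N", kmers, fixed = TRUE)
  if (!any(keep)) {
    return(list(frac = 0, s_start = NA_integer_, s_end = NA_integer_))
  }
  ## hashed k-mer index of the subject
  sstarts <- seq_len(nchar(subject) - k + 1L)
  sk <- substring(subject, sstarts, sstarts + k - 1L)
  idx <- split(sstarts, sk)
  hits <- idx[kmers[keep]]
  n_hits <- lengths(hits)               # absent k-mers give NULL, length 0
  if (sum(n_hits) == 0) {
    return(list(frac = 0, s_start = NA_integer_, s_end = NA_integer_))
  }
  ppos <- rep(pstarts[keep], n_hits)
  spos <- unlist(hits, use.names = FALSE)
  diag <- spos - ppos
  bucket <- round(diag / band)
  tab <- table(bucket)
  best <- as.integer(names(tab)[which.max(tab)])
  sel0 <- abs(bucket - best) <= 1
  d0 <- median(diag[sel0])
  sel <- abs(diag - d0) <= band
  ## one seed per pattern position (multi-mapping repeats collapse)
  sel_p <- unique(ppos[sel])
  cov <- sum(IRanges::width(IRanges::reduce(
    IRanges::IRanges(sel_p, width = k))))
  list(frac = cov / np,
       s_start = min(spos[sel]) - 1L,                 # 0-based
       s_end = max(spos[sel]) + k - 1L,
       offset = as.integer(d0))
}

## Best local alignment summary: matched bases, aligned pattern range
## (0-based half-open, in pattern coordinates), aligned subject range,
## identity over aligned columns.
local_align_stats <- function(pattern, subject) {
  if (nchar(pattern) == 0 || nchar(subject) == 0) {
    return(list(nmatch = 0L, identity = 0,
                p_start = 0L, p_end = 0L, s_start = 0L, s_end = 0L))
  }
  aln <- Biostrings::pairwiseAlignment(
    pattern = Biostrings::DNAString(pattern),
    subject = Biostrings::DNAString(subject),
    type = "local", substitutionMatrix = align_submat(),
    gapOpening = 5, gapExtension = 2)
  pr <- aln@pattern@range
  sr <- aln@subject@range
  aw <- Biostrings::nchar(aln)
  list(nmatch = Biostrings::nmatch(aln),
       identity = if (aw > 0) Biostrings::nmatch(aln) / aw else 0,
       p_start = IRanges::start(pr) - 1L, p_end = IRanges::end(pr),
       s_start = IRanges::start(sr) - 1L, s_end = IRanges::end(sr))
}
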