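#' @importFrom stats rnorm runif rbinom rpois qpois median setNames p.adjust
#'   phyper
#' @importFrom utils head tail read.table write.table
NULL

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Random DNA sequence with a given GC content
#'
#' @param n Sequence length in bp.
#' @param gc Target GC fraction in (0, 1).
#' @return A single character string of length `n` over A/C/G/T.
#' @keywords internal
rand_dna <- function(n, gc = 0.44) {
  if (n <= 0) return("")
  p <- c(A = (1 - gc) / 2, C = gc / 2, G = gc / 2, T = (1 - gc) / 2)
  paste(sample(names(p), n, replace = TRUE, prob = p), collapse = "")
}

## 0-based half-open extraction/overwrite on plain character strings.
## All package-internal coordinates are 0-based half-open; conversion to
## 1-based happens only at I/O boundaries (GFF3, VCF).
subseq_str <- function(s, start, end) {
  if (end <= start) return("")
  substr(s, start + 1L, end)
}

set_subseq_str <- function(s, start, value) {
  substr(s, start + 1L, start + nchar(value)) <- value
  s
}

#' Point-mutate a DNA string
#'
#' Substitutes each position independently with probability `rate`, always to
#' a different base.  Used for diverged TE/repeat copies.
#' @keywords internal
mutate_dna <- function(s, rate) {
  if (rate <= 0 || nchar(s) == 0) return(s)
  x <- strsplit(s, "", fixed = TRUE)[[1]]
  idx <- which(runif(length(x)) < rate)
  if (length(idx)) {
    bases <- c("A", "C", "G", "T")
    for (i in idx) {
      alt <- setdiff(bases, x[i])
      x[i] <- alt[sample.int(3L, 1L)]
    }
  }
  paste(x, collapse = "")
}

revcomp <- function(s) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(s)))
}

## total length of the intersection of [start,end) with a set of intervals
## (data.frame with start/end), after unioning the set
intersect_width <- function(start, end, ivs) {
  if (nrow(ivs) == 0 || end <= start) return(0L)
  ir <- IRanges::IRanges(start = ivs$start + 1L, end = ivs$end)
  q <- IRanges::IRanges(start = start + 1L, end = end)
  sum(IRanges::width(IRanges::intersect(IRanges::reduce(ir), q)))
}

## place `widths` non-overlapping intervals on [lo, hi) keeping `min_gap`
## distance from `occupied` (data.frame start/end) and from each other.
## Returns data.frame(start, end); stops with an error when a width cannot
## be placed after `max_tries` attempts.
place_intervals <- function(widths, lo, hi, occupied = NULL, min_gap = 200L,
                            max_tries = 400L) {
  occ <- if (is.null(occupied) || nrow(occupied) == 0) {
    data.frame(start = integer(0), end = integer(0))
  } else {
    occupied[, c("start", "end")]
  }
  out <- data.frame(start = integer(0), end = integer(0))
  for (w in widths) {
    placed <- FALSE
    for (try in seq_len(max_tries)) {
      s <- lo + floor(runif(1) * (hi - lo - w))
      e <- s + w
      clash <- any(occ$start < e + min_gap & occ$end > s - min_gap)
      if (!clash) {
        occ <- rbind(occ, data.frame(start = s, end = e))
        out <- rbind(out, data.frame(start = s, end = e))
        placed <- TRUE
        break
      }
    }
    if (!placed) {
      stop("placement error: could not place interval of width ", w,
           " after placing ", nrow(out), " interval(s)")
    }
  }
  out
}

## lower median: for even n returns the smaller of the two central values
lower_median <- function(x) {
  x <- sort(x)
  x[floor((length(x) + 1) / 2)]
}

## deterministic seed derivation for pipeline stages (kept < 2^31)
derive_seed <- function(seed, k) {
  as.integer((as.numeric(seed) * 1103L + k * 12289L) %% 2147483587)
}
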