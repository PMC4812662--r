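#' Mechanism-classification parameters
#'
#' Junction-signature thresholds: NHR (end-joining) requires total junction
#' microhomology <= `mh_max` (the 1-10 bp microhomology range of
#' microhomology-mediated end joining); NAHR requires >= `nahr_min_len` bp
#' of junction-spanning homology at >= `nahr_min_identity`; MEI requires
#' the event body to be covered >= `mei_min_fraction` by annotated TEs;
#' VNTR requires an event length within `vntr_period_tolerance` periods of
#' an integer period multiple inside one annotated array.
#'
#' @param mh_max Maximum NHR microhomology (bp).
#' @param nahr_min_len Minimum NAHR homology length (bp); must exceed
#'   `mh_max`.
#' @param nahr_min_identity Minimum NAHR homology identity.
#' @param mei_min_fraction Minimum TE coverage fraction for MEI.
#' @param vntr_period_tolerance Allowed distance to an integer period
#'   multiple, as a fraction of the period.
#' @param homology_scan_window Junction scan window (bp).
#' @export
mechanism_params <- function(mh_max = 10L, nahr_min_len = 50L,
                             nahr_min_identity = 0.9,
                             mei_min_fraction = 0.8,
                             vntr_period_tolerance = 0.1,
                             homology_scan_window = 500L) {
  if (!(mh_max < nahr_min_len)) stop("mh_max must be < nahr_min_len")
  list(mh_max = as.integer(mh_max), nahr_min_len = as.integer(nahr_min_len),
       nahr_min_identity = nahr_min_identity,
       mei_min_fraction = mei_min_fraction,
       vntr_period_tolerance = vntr_period_tolerance,
       homology_scan_window = as.integer(homology_scan_window))
}

## case-insensitive per-character match vector; N never matches
match_vector <- function(x, y) {
  a <- strsplit(toupper(x), "", fixed = TRUE)[[1]]
  b <- strsplit(toupper(y), "", fixed = TRUE)[[1]]
  L <- min(length(a), length(b))
  if (L == 0) return(logical(0))
  a <- a[seq_len(L)]; b <- b[seq_len(L)]
  a == b & a != "N" & b != "N"
}

#' Junction microhomology of a deletion
#'
#' The right microhomology is the longest common prefix of the sequence
#' starting at the event start and the sequence starting at the event end
#' (what remains identical when the two junction sides are joined); the
#' left microhomology is the longest common suffix of the two prefixes
#' ending at start and at end.  Both are capped at `cap`; comparison is
#' case-insensitive and N matches nothing.
#'
#' @param seq Chromosome sequence (character scalar).
#' @param start,end 0-based half-open event interval.
#' @param cap Scan cap in bp.
#' @return List with `left`, `right`, `total` (bp).
#' @export
junction_microhomology <- function(seq, start, end, cap = 500L) {
  n <- nchar(seq)
  if (start < 0 || end > n || start >= end) {
    stop("invalid interval [", start, ",", end, ") on sequence of length ", n)
  }
  lcp <- function(m) {
    mis <- which(!m)
    if (length(mis) == 0) length(m) else mis[1] - 1L
  }
  right <- lcp(match_vector(subseq_str(seq, start, min(n, start + cap)),
                            subseq_str(seq, end, min(n, end + cap))))
  xs <- subseq_str(seq, max(0L, start - cap), start)
  ys <- subseq_str(seq, max(0L, end - cap), end)
  rev_str <- function(s) paste(rev(strsplit(s, "", fixed = TRUE)[[1]]),
                               collapse = "")
  left <- lcp(match_vector(rev_str(xs), rev_str(ys)))
  list(left = as.integer(left), right = as.integer(right),
       total = as.integer(left + right))
}

#' Junction-anchored flanking homology
#'
#' Scans for extended homology spanning the two junctions of a deletion:
#' the window beginning at the event start is compared with the window
#' beginning at the event end (and symmetrically the windows ending at
#' start and at end).  The homology length is the largest ungapped extent
#' anchored at the junction whose cumulative identity stays >=
#' `nahr_min_identity`; the reported identity is over that extent.
#'
#' @param seq Chromosome sequence.
#' @param start,end 0-based half-open event interval.
#' @param params [mechanism_params()].
#' @return List with `homology_len`, `identity`, `truncated` (TRUE when a
#'   window was cut by a contig edge).
#' @export
flanking_homology <- function(seq, start, end, params = mechanism_params()) {
  n <- nchar(seq)
  if (start < 0 || end > n || start >= end) {
    stop("invalid interval [", start, ",", end, ")")
  }
  W <- params$homology_scan_window
  best_run <- function(m) {
    if (length(m) == 0) return(c(0, 0))
    cum <- cumsum(m)
    L <- seq_along(m)
    ok <- which(cum / L >= params$nahr_min_identity & m)
    if (length(ok) == 0) return(c(0, 0))
    len <- max(ok)
    c(len, cum[len] / len)
  }
  truncated <- (start - W < 0) || (end + W > n)
  pre <- best_run(match_vector(
    subseq_str(seq, start, min(n, start + W)),
    subseq_str(seq, end, min(n, end + W))))
  rev_str <- function(s) paste(rev(strsplit(s, "", fixed = TRUE)[[1]]),
                               collapse = "")
  suf <- best_run(match_vector(
    rev_str(subseq_str(seq, max(0L, start - W), start)),
    rev_str(subseq_str(seq, max(0L, end - W), end))))
  win <- if (pre[1] >= suf[1]) pre else suf
  list(homology_len = as.integer(win[1]), identity = win[2],
       truncated = truncated)
}

#' TE coverage of an interval
#'
#' Fraction of the interval covered by the union of TE annotations, and
#' the family with the largest single-element overlap (ties:
#' lexicographically smallest family).
#'
#' @param chrom,start,end Interval (0-based half-open).
#' @param te TE annotation data frame (`chrom`, `start`, `end`, `family`).
#' @return List with `fraction` and `family` (empty string if no overlap).
#' @export
te_coverage <- function(chrom, start, end, te) {
  tc <- te[te$chrom == chrom, , drop = FALSE]
  frac <- intersect_width(start, end, tc) / (end - start)
  fam <- ""
  if (nrow(tc) > 0) {
    ov <- pmin(end, tc$end) - pmax(start, tc$start)
    if (any(ov > 0)) {
      tc <- tc[ov > 0, ]; ov <- ov[ov > 0]
      best <- which(ov == max(ov))
      fam <- min(tc$family[best])
    }
  }
  list(fraction = frac, family = fam)
}

#' Tandem-array context of an interval
#'
#' TRUE when both breakpoints fall within a single annotated tandem array
#' and the interval length is within `vntr_period_tolerance * period` of a
#' non-zero integer multiple of the array period.
#'
#' @param chrom,start,end Interval.
#' @param vntr Tandem-array annotation (`chrom`, `start`, `end`,
#'   `period`).
#' @param params [mechanism_params()].
#' @return List with `is_vntr` and `period` (NA when not a VNTR).
#' @export
vntr_context <- function(chrom, start, end, vntr,
                         params = mechanism_params()) {
  va <- vntr[vntr$chrom == chrom & vntr$start <= start & vntr$end >= end, ,
             drop = FALSE]
  if (nrow(va) == 0) return(list(is_vntr = FALSE, period = NA_integer_))
  p <- va$period[1]
  len <- end - start
  k <- round(len / p)
  ok <- k >= 1 && abs(len - k * p) <= params$vntr_period_tolerance * p
  list(is_vntr = ok, period = if (ok) as.integer(p) else NA_integer_)
}

#' Classify the formation mechanism of one CNV
#'
#' Decision order (first match wins): VNTR, MEI (TE coverage of the event
#' body), NAHR (junction-spanning extended homology), NHR (junction
#' microhomology <= `mh_max`), otherwise ambiguous (microhomology between
#' `mh_max` and `nahr_min_len` with no body signature).  Imprecise events
#' and events whose junction windows are mostly N are ambiguous with a
#' reason code.  The catalog is deletions-relative-to-reference, so the
#' affected allele is present in the reference for both polarity states
#' and all signatures are read on the reference interval.
#'
#' @param chrom,start,end Event interval (0-based half-open).
#' @param precise Whether breakpoints are single-nucleotide.
#' @param seqs Named character vector of reference chromosomes.
#' @param te,vntr Annotations (see [te_coverage()], [vntr_context()]).
#' @param params [mechanism_params()].
#' @return One-row data frame: `mechanism`, `microhomology_len`,
#'   `homology_len`, `homology_identity`, `te_fraction`, `te_family`,
#'   `vntr_period`, `reason`.
#' @export
classify_mechanism <- function(chrom, start, end, precise, seqs, te, vntr,
                               params = mechanism_params()) {
  res <- data.frame(mechanism = "ambiguous",
                    microhomology_len = NA_integer_,
                    homology_len = NA_integer_,
                    homology_identity = NA_real_,
                    te_fraction = NA_real_, te_family = "",
                    vntr_period = NA_integer_, reason = "")
  if (!precise) { res$reason <- "imprecise_breakpoints"; return(res) }
  seq <- seqs[[chrom]]
  if (is.null(seq) || start < 0 || end > nchar(seq)) {
    res$reason <- "missing_sequence"; return(res)
  }
  W <- params$homology_scan_window
  jwin <- paste0(subseq_str(seq, max(0L, start - W), min(nchar(seq), start + W)),
                 subseq_str(seq, max(0L, end - W), min(nchar(seq), end + W)))
  n_frac <- if (nchar(jwin) > 0) {
    lengths(regmatches(jwin, gregexpr("N", jwin, fixed = TRUE))) / nchar(jwin)
  } else 0
  if (n_frac > 0.5) { res$reason <- "junction_window_mostly_N"; return(res) }

  mh <- junction_microhomology(seq, start, end, cap = W)
  fh <- flanking_homology(seq, start, end, params)
  tc <- te_coverage(chrom, start, end, te)
  vc <- vntr_context(chrom, start, end, vntr, params)
  res$microhomology_len <- mh$total
  res$homology_len <- fh$homology_len
  res$homology_identity <- fh$identity
  res$te_fraction <- tc$fraction
  res$te_family <- tc$family
  res$vntr_period <- vc$period

  if (vc$is_vntr) {
    res$mechanism <- "VNTR"
  } else if (tc$fraction >= params$mei_min_fraction) {
    res$mechanism <- "MEI"
  } else if (fh$homology_len >= params$nahr_min_len &&
             fh$identity >= params$nahr_min_identity) {
    res$mechanism <- "NAHR"
  } else if (mh$total <= params$mh_max) {
    res$mechanism <- "NHR"
  } else {
    res$mechanism <- "ambiguous"
    res$reason <- "signature_between_mh_and_nahr"
  }
  res
}

#' Classify mechanisms for a table of events
#'
#' @param events Data frame with `event_id`, `chrom`, `start`, `end`,
#'   `precise`.
#' @param seqs,te,vntr,params See [classify_mechanism()].
#' @return Data frame of mechanism calls, one row per event, with an
#'   `nhr_subtype` column separating blunt NHEJ (0 bp) from
#'   microhomology-mediated MMEJ (1-10 bp) within NHR.
#' @export
classify_mechanisms <- function(events, seqs, te, vntr,
                                params = mechanism_params()) {
  if (anyDuplicated(events$event_id)) {
    stop("input error: duplicate event_id")
  }
  rows <- lapply(seq_len(nrow(events)), function(i) {
    r <- classify_mechanism(events$chrom[i], events$start[i],
                            events$end[i], events$precise[i],
                            seqs, te, vntr, params)
    cbind(data.frame(event_id = events$event_id[i]), r)
  })
  out <- if (length(rows)) do.call(rbind, rows) else data.frame(
    event_id = character(0), mechanism = character(0),
    microhomology_len = integer(0), homology_len = integer(0),
    homology_identity = numeric(0), te_fraction = numeric(0),
    te_family = character(0), vntr_period = integer(0),
    reason = character(0))
  out$nhr_subtype <- ifelse(out$mechanism != "NHR", "",
                            ifelse(out$microhomology_len == 0,
                                   "NHEJ", "MMEJ"))
  out
}

#' Summarize a mechanism classification
#'
#' Counts, percentages and cumulative genomic size per mechanism, plus
#' per-chromosome counts and per-mechanism size summaries.
#'
#' @param calls Mechanism calls from [classify_mechanisms()].
#' @param events The classified events (`event_id`, `chrom`, `start`,
#'   `end`).
#' @return List with `distribution` (mechanism, n, percent, cumulative_bp,
#'   median_bp, min_bp, max_bp) and `per_chromosome`.
#' @export
summarize_mechanisms <- function(calls, events) {
  if (anyDuplicated(calls$event_id)) stop("input error: duplicate event_id")
  if (nrow(calls) == 0) {
    return(list(distribution = data.frame(
      mechanism = character(0), n = integer(0), percent = numeric(0),
      cumulative_bp = numeric(0), median_bp = numeric(0),
      min_bp = numeric(0), max_bp = numeric(0)),
      per_chromosome = data.frame(chrom = character(0),
                                  mechanism = character(0),
                                  n = integer(0))))
  }
  m <- merge(calls[, c("event_id", "mechanism")],
             events[, c("event_id", "chrom", "start", "end")],
             by = "event_id")
  m$len <- m$end - m$start
  agg <- do.call(rbind, lapply(split(m, m$mechanism), function(g) {
    data.frame(mechanism = g$mechanism[1], n = nrow(g),
               cumulative_bp = sum(g$len), median_bp = median(g$len),
               min_bp = min(g$len), max_bp = max(g$len))
  }))
  agg$percent <- 100 * agg$n / nrow(m)
  agg <- agg[order(-agg$n), c("mechanism", "n", "percent", "cumulative_bp",
                              "median_bp", "min_bp", "max_bp")]
  rownames(agg) <- NULL
  per_chrom <- as.data.frame(table(chrom = m$chrom,
                                   mechanism = m$mechanism),
                             responseName = "n",
                             stringsAsFactors = FALSE)
  list(distribution = agg, per_chromosome = per_chrom)
}
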