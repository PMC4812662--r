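#' Merge parameters
#'
#' The integration thresholds: 50% reciprocal overlap for clustering, at
#' least two supporting callers per accession, and presence in at least
#' three accessions for a population-level event.
#'
#' @param reciprocal_overlap_min Minimum reciprocal overlap in (0, 1].
#' @param min_callers Minimum distinct callers per accession-level cluster.
#' @param min_accessions Minimum distinct accessions per population event.
#' @export
merge_params <- function(reciprocal_overlap_min = 0.5, min_callers = 2L,
                         min_accessions = 3L) {
  if (!(reciprocal_overlap_min > 0 && reciprocal_overlap_min <= 1)) {
    stop("reciprocal_overlap_min must be in (0,1]")
  }
  list(reciprocal_overlap_min = reciprocal_overlap_min,
       min_callers = as.integer(min_callers),
       min_accessions = as.integer(min_accessions))
}

#' Reciprocal overlap of two intervals
#'
#' `min(o/|a|, o/|b|)` where `o` is the overlap length; 0 for disjoint
#' intervals or different chromosomes.  Vectorized and symmetric.
#'
#' @param a_start,a_end,b_start,b_end 0-based half-open coordinates.
#' @param a_chrom,b_chrom Optional chromosome names; mismatch gives 0.
#' @return Fraction in [0, 1].
#' @export
reciprocal_overlap <- function(a_start, a_end, b_start, b_end,
                               a_chrom = NULL, b_chrom = NULL) {
  if (any(a_start >= a_end) || any(b_start >= b_end)) {
    stop("invalid interval: start must be < end")
  }
  o <- pmin(a_end, b_end) - pmax(a_start, b_start)
  ro <- pmin(o / (a_end - a_start), o / (b_end - b_start))
  ro[o <= 0] <- 0
  if (!is.null(a_chrom) && !is.null(b_chrom)) ro[a_chrom != b_chrom] <- 0
  ro
}

## Single-linkage clustering of intervals under the reciprocal-overlap
## predicate.  Candidate pairs come from an interval overlap query (a pair
## with RO >= t > 0 must overlap); the transitive closure is taken with
## union-find.  Returns an integer cluster id per row, canonicalized by
## (chrom, min start, min end) so the partition and the ids are invariant
## to input order.
cluster_reciprocal <- function(df, min_ro) {
  n <- nrow(df)
  if (n == 0) return(integer(0))
  parent <- seq_len(n)
  find <- function(i) {
    while (parent[i] != i) {
      parent[i] <<- parent[parent[i]]
      i <- parent[i]
    }
    i
  }
  for (ch in unique(df$chrom)) {
    idx <- which(df$chrom == ch)
    ir <- IRanges::IRanges(start = df$start[idx] + 1L, end = df$end[idx])
    hits <- IRanges::findOverlaps(ir, drop.self = TRUE, drop.redundant = TRUE)
    if (length(hits) == 0) next
    qi <- idx[S4Vectors::queryHits(hits)]
    si <- idx[S4Vectors::subjectHits(hits)]
    ro <- reciprocal_overlap(df$start[qi], df$end[qi],
                             df$start[si], df$end[si])
    keep <- which(ro >= min_ro)
    for (h in keep) {
      a <- find(qi[h]); b <- find(si[h])
      if (a != b) parent[max(a, b)] <- min(a, b)
    }
  }
  root <- vapply(seq_len(n), find, integer(1))
  ## canonical ids ordered by (chrom, min start, min end) of each cluster
  cs <- data.frame(root = unique(root))
  cs$chrom <- df$chrom[cs$root]
  cs$min_s <- vapply(cs$root, function(r) min(df$start[root == r]),
                     numeric(1))
  cs$min_e <- vapply(cs$root, function(r) min(df$end[root == r]),
                     numeric(1))
  cs <- cs[order(cs$chrom, cs$min_s, cs$min_e), ]
  cs$id <- seq_len(nrow(cs))
  cs$id[match(root, cs$root)]
}

#' Per-accession consensus of multi-caller calls
#'
#' Calls of one accession are clustered by single linkage under
#' `reciprocal_overlap >= reciprocal_overlap_min` on the same chromosome;
#' clusters supported by at least `min_callers` distinct callers yield one
#' consensus call with breakpoints from [refine_breakpoints()]; clusters
#' with fewer distinct callers are discarded.
#'
#' @param calls Data frame of calls of a single accession (`chrom`,
#'   `start`, `end`, `caller`, `accession`).
#' @param params [merge_params()].
#' @return Data frame of consensus calls (`chrom`, `start`, `end`,
#'   `precise`, `callers`, `accession`).
#' @export
consensus_per_accession <- function(calls, params = merge_params()) {
  if (nrow(calls) == 0) return(empty_consensus_calls())
  if (length(unique(calls$accession)) > 1) {
    stop("input error: calls from multiple accessions; split first")
  }
  cl <- cluster_reciprocal(calls, params$reciprocal_overlap_min)
  out <- lapply(sort(unique(cl)), function(k) {
    cc <- calls[cl == k, ]
    if (length(unique(cc$caller)) < params$min_callers) return(NULL)
    bp <- refine_breakpoints(cc)
    data.frame(chrom = cc$chrom[1], start = bp$start, end = bp$end,
               precise = bp$precise,
               callers = paste(sort(unique(cc$caller)), collapse = "+"),
               accession = cc$accession[1])
  })
  out <- do.call(rbind, out)
  if (is.null(out)) empty_consensus_calls() else out
}

empty_consensus_calls <- function() {
  data.frame(chrom = character(0), start = integer(0), end = integer(0),
             precise = logical(0), callers = character(0),
             accession = character(0))
}

#' Refine cluster breakpoints by evidence-class priority
#'
#' Split-read calls carry single-nucleotide breakpoints, so if the cluster
#' contains any SR call the modal SR (start, end) pair wins (ties: smallest
#' start, then smallest end) and the result is precise.  Otherwise the
#' lower-median paired-end start and end are used (precise).  A cluster
#' with only read-depth calls returns the boundaries of its widest member,
#' flagged imprecise.
#'
#' @param cluster Data frame of calls on one chromosome (`start`, `end`,
#'   `caller`).
#' @return List with `start`, `end`, `precise`.
#' @export
refine_breakpoints <- function(cluster) {
  if (nrow(cluster) == 0) stop("input error: empty cluster")
  sr <- cluster[cluster$caller == "SR", ]
  if (nrow(sr) > 0) {
    key <- paste(sr$start, sr$end)
    tab <- table(key)
    best <- names(tab)[tab == max(tab)]
    pairs <- do.call(rbind, strsplit(best, " "))
    ord <- order(as.integer(pairs[, 1]), as.integer(pairs[, 2]))
    win <- pairs[ord[1], ]
    return(list(start = as.integer(win[1]), end = as.integer(win[2]),
                precise = TRUE))
  }
  pe <- cluster[cluster$caller == "PE", ]
  if (nrow(pe) > 0) {
    return(list(start = as.integer(lower_median(pe$start)),
                end = as.integer(lower_median(pe$end)), precise = TRUE))
  }
  rd <- cluster[cluster$caller == "RD", ]
  widest <- which.max(rd$end - rd$start)
  list(start = as.integer(rd$start[widest]),
       end = as.integer(rd$end[widest]), precise = FALSE)
}

#' Merge per-accession consensus calls across the population
#'
#' Single-linkage clustering under the same reciprocal-overlap predicate;
#' clusters spanning at least `min_accessions` distinct accessions become
#' population events.  The representative breakpoints are those of the
#' precise member whose length is closest to the cluster's (lower) median
#' length, ties broken by smallest start then end; if the cluster has no
#' precise member the same rule runs over all members and the event is
#' flagged imprecise.
#'
#' @param per_acc Output rows of [consensus_per_accession()] across all
#'   accessions.
#' @param params [merge_params()].
#' @return Data frame of population events: `event_id`, `chrom`, `start`,
#'   `end`, `precise`, `n_accessions`, `carriers` (comma-joined),
#'   `support` (semicolon-joined `accession:callers`).
#' @export
merge_across_accessions <- function(per_acc, params = merge_params()) {
  if (nrow(per_acc) == 0) return(empty_consensus_cnv())
  cl <- cluster_reciprocal(per_acc, params$reciprocal_overlap_min)
  rows <- lapply(sort(unique(cl)), function(k) {
    cc <- per_acc[cl == k, ]
    accs <- sort(unique(cc$accession))
    if (length(accs) < params$min_accessions) return(NULL)
    pool <- if (any(cc$precise)) cc[cc$precise, ] else cc
    target <- lower_median(cc$end - cc$start)
    d <- abs((pool$end - pool$start) - target)
    ord <- order(d, pool$start, pool$end)
    rep <- pool[ord[1], ]
    data.frame(chrom = rep$chrom, start = rep$start, end = rep$end,
               precise = any(cc$precise),
               n_accessions = length(accs),
               carriers = paste(accs, collapse = ","),
               support = paste(paste0(cc$accession, ":", cc$callers),
                               collapse = ";"))
  })
  out <- do.call(rbind, rows)
  if (is.null(out)) return(empty_consensus_cnv())
  out <- out[order(out$chrom, out$start, out$end), ]
  out$event_id <- sprintf("cnv%05d", seq_len(nrow(out)))
  rownames(out) <- NULL
  out[, c("event_id", "chrom", "start", "end", "precise", "n_accessions",
          "carriers", "support")]
}

empty_consensus_cnv <- function() {
  data.frame(event_id = character(0), chrom = character(0),
             start = integer(0), end = integer(0), precise = logical(0),
             n_accessions = integer(0), carriers = character(0),
             support = character(0))
}

#' Full three-step call-set integration
#'
#' Splits the raw calls by accession, computes the per-accession >=2-caller
#' consensus, then merges across accessions requiring >= 3 accessions.
#'
#' @param calls Raw multi-accession call table (see [emit_callsets()]).
#' @param params [merge_params()].
#' @return Population consensus events (see [merge_across_accessions()]).
#' @export
merge_callsets <- function(calls, params = merge_params()) {
  if (nrow(calls) > 0 &&
      any(calls$end - calls$start < 50)) {
    stop("invalid interval: CNV calls must be >= 50 bp")
  }
  per_acc <- do.call(rbind, lapply(split(calls, calls$accession),
                                   consensus_per_accession,
                                   params = params))
  if (is.null(per_acc)) per_acc <- empty_consensus_calls()
  rownames(per_acc) <- NULL
  merge_across_accessions(per_acc, params)
}
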