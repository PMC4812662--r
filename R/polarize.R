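#' Polarization parameters
#'
#' Thresholds of the ancestral-state rule: a CNV whose internal sequence
#' aligns to its orthologous outgroup window over less than
#' `insertion_max_aligned` of its length is an insertion in the reference
#' lineage; over at least `deletion_min_aligned` it is a true deletion;
#' anything between is undefined.  Both 2-kb flanks must anchor (align over
#' at least `flank_min_aligned` of their length) for any non-undefined
#' verdict, and windows covered by assembly gaps over more than
#' `gap_max_fraction` are undefined.
#'
#' @param flank Flank length in bp.
#' @param insertion_max_aligned,deletion_min_aligned Aligned-fraction
#'   thresholds.
#' @param flank_min_aligned Minimum aligned fraction per flank.
#' @param gap_max_fraction Maximum tolerated assembly-gap fraction of the
#'   outgroup window.
#' @param probe_threshold Events larger than this are polarized with 10
#'   evenly spaced 1-kb internal probes instead of whole-event alignment.
#' @export
polarize_params <- function(flank = 2000L, insertion_max_aligned = 0.2,
                            deletion_min_aligned = 0.8,
                            flank_min_aligned = 0.5,
                            gap_max_fraction = 0.1,
                            probe_threshold = 100000L) {
  list(flank = as.integer(flank),
       insertion_max_aligned = insertion_max_aligned,
       deletion_min_aligned = deletion_min_aligned,
       flank_min_aligned = flank_min_aligned,
       gap_max_fraction = gap_max_fraction,
       probe_threshold = as.integer(probe_threshold))
}

#' Chain synteny anchors into co-linear blocks
#'
#' Anchors (ortholog gene pairs with coordinates in both genomes) are
#' sorted by reference position and chained while consecutive anchors
#' share the chromosome pair and strand, preserve outgroup order, and are
#' at most `max_gap` apart in both genomes.  Blocks with fewer than
#' `min_anchors` anchors are dropped.
#'
#' @param anchors Data frame (`gene_id`, `ref_chrom`, `ref_start`,
#'   `ref_end`, `out_chrom`, `out_start`, `out_end`, `strand`).
#' @param max_gap Maximum anchor-to-anchor gap in bp (both genomes).
#' @param min_anchors Minimum anchors per block.
#' @return Data frame of anchors with a `block_id` column, sorted by
#'   reference coordinate within block.
#' @export
build_blocks <- function(anchors, max_gap = 500000L, min_anchors = 2L) {
  if (anyDuplicated(anchors$gene_id)) {
    stop("input error: duplicate gene_id among anchors")
  }
  if (nrow(anchors) == 0) {
    anchors$block_id <- integer(0)
    return(anchors)
  }
  a <- anchors[order(anchors$ref_chrom, anchors$ref_start), ]
  a$ref_mid <- (a$ref_start + a$ref_end) %/% 2
  a$out_mid <- (a$out_start + a$out_end) %/% 2
  bid <- integer(nrow(a))
  cur <- 1L
  bid[1] <- cur
  for (i in seq_len(nrow(a))[-1]) {
    prev <- a[i - 1L, ]; this <- a[i, ]
    chain <- this$ref_chrom == prev$ref_chrom &&
      this$out_chrom == prev$out_chrom &&
      this$strand == prev$strand &&
      (this$ref_mid - prev$ref_mid) <= max_gap &&
      (if (this$strand == "+") {
        this$out_mid > prev$out_mid &&
          (this$out_mid - prev$out_mid) <= max_gap
      } else {
        this$out_mid < prev$out_mid &&
          (prev$out_mid - this$out_mid) <= max_gap
      })
    if (!chain) cur <- cur + 1L
    bid[i] <- cur
  }
  a$block_id <- bid
  keep <- table(bid)
  a <- a[bid %in% as.integer(names(keep)[keep >= min_anchors]), ]
  a$block_id <- match(a$block_id, unique(a$block_id))
  rownames(a) <- NULL
  a
}

#' Project a reference interval onto the outgroup through anchor blocks
#'
#' Both endpoints must fall inside the anchor-midpoint span of a single
#' block; each endpoint is mapped by linear interpolation between the
#' flanking anchor midpoints (strand-aware).  Returns a failure state when
#' the interval lies outside all blocks or spans a block boundary.
#'
#' @param chrom,start,end Reference interval.
#' @param blocks Output of [build_blocks()].
#' @return List with `ok`; on success also `out_chrom`, `out_start`,
#'   `out_end`, `strand`; on failure a `reason`.
#' @export
project_to_outgroup <- function(chrom, start, end, blocks) {
  bl <- blocks[blocks$ref_chrom == chrom, , drop = FALSE]
  if (nrow(bl) == 0) return(list(ok = FALSE, reason = "no_anchors"))
  bl <- bl[order(bl$ref_mid), ]     # invariance to anchor row order
  hit <- NULL
  for (b in unique(bl$block_id)) {
    bb <- bl[bl$block_id == b, ]
    if (min(bb$ref_mid) <= start && end <= max(bb$ref_mid)) { hit <- bb; break }
  }
  if (is.null(hit)) {
    spans <- any(vapply(unique(bl$block_id), function(b) {
      bb <- bl[bl$block_id == b, ]
      start < max(bb$ref_mid) && end > min(bb$ref_mid)
    }, logical(1)))
    return(list(ok = FALSE,
                reason = if (spans) "spans_block_boundary"
                         else "outside_blocks"))
  }
  interp <- function(p) {
    i <- findInterval(p, hit$ref_mid, rightmost.closed = TRUE)
    i <- min(max(i, 1L), nrow(hit) - 1L)
    m1 <- hit$ref_mid[i]; m2 <- hit$ref_mid[i + 1L]
    o1 <- hit$out_mid[i]; o2 <- hit$out_mid[i + 1L]
    ## interpolation can be off by as much as the length difference of the
    ## anchor gap in the two genomes (unbalanced material between anchors)
    c(o1 + (p - m1) * (o2 - o1) / (m2 - m1),
      abs((m2 - m1) - abs(o2 - o1)))
  }
  os <- interp(start); oe <- interp(end)
  list(ok = TRUE, out_chrom = hit$out_chrom[1],
       out_start = as.integer(round(min(os[1], oe[1]))),
       out_end = as.integer(round(max(os[1], oe[1]))),
       uncertainty = as.integer(ceiling(max(os[2], oe[2]))),
       strand = hit$strand[1])
}

#' Classify the ancestral state of one consensus CNV
#'
#' The event interval is projected onto the outgroup; the outgroup window
#' (projection +/- flank) is checked for assembly gaps, both reference
#' flanks are anchored into the window by local alignment, and the
#' CNV-internal reference sequence is aligned into the window.  Aligned
#' fraction below `insertion_max_aligned` means the sequence is absent
#' from the outgroup (an insertion acquired by the reference lineage); at
#' or above `deletion_min_aligned` means it is present (a true deletion in
#' the carriers); anything else, a failed projection, unanchored flanks or
#' a gapped window is undefined, with a reason code.
#'
#' @param chrom,start,end Event interval on the reference.
#' @param ref_seqs,out_seqs Named character vectors of chromosome
#'   sequences.
#' @param gaps Assembly-gap annotation on the outgroup (`chrom`, `start`,
#'   `end`).
#' @param blocks Anchor blocks from [build_blocks()].
#' @param params [polarize_params()].
#' @return One-row data frame: `ancestral_state`, `aligned_fraction`,
#'   `out_chrom`, `out_window_start`, `out_window_end`,
#'   `gap_fraction`, `reason`.
#' @export
classify_ancestral_state <- function(chrom, start, end, ref_seqs, out_seqs,
                                     gaps, blocks,
                                     params = polarize_params()) {
  res <- data.frame(ancestral_state = "undefined",
                    aligned_fraction = NA_real_,
                    out_chrom = NA_character_,
                    out_window_start = NA_integer_,
                    out_window_end = NA_integer_,
                    gap_fraction = NA_real_, reason = "")
  pr <- project_to_outgroup(chrom, start, end, blocks)
  if (!pr$ok) { res$reason <- paste0("projection_", pr$reason); return(res) }
  fl <- params$flank
  oseq <- out_seqs[[pr$out_chrom]]
  unc <- pr$uncertainty %||% 0L
  ## search window: projection +/- flank, widened by the projection
  ## uncertainty (anchor-gap length difference between the genomes)
  ws <- max(0L, pr$out_start - fl - unc)
  we <- min(nchar(oseq), pr$out_end + fl + unc)
  res$out_chrom <- pr$out_chrom
  window <- subseq_str(oseq, ws, we)
  if (pr$strand == "-") window <- revcomp(window)
  gch <- gaps[gaps$chrom == pr$out_chrom, , drop = FALSE]

  rseq <- ref_seqs[[chrom]]
  ## anchoring uses the junction-proximal kilobase of each flank: the
  ## outer flank may legitimately overlap a neighbouring variant, which
  ## must not veto the verdict for this event
  al <- min(1000L, fl)
  lf <- subseq_str(rseq, max(0L, start - al), start)
  rf <- subseq_str(rseq, end, min(nchar(rseq), end + al))
  la <- seed_anchor(lf, window)
  ra <- seed_anchor(rf, window)
  anchored <- la$frac >= params$flank_min_aligned &&
    ra$frac >= params$flank_min_aligned &&
    !is.na(la$s_end) && !is.na(ra$s_start)

  ## refined window: the anchored flank positions delimit the orthologous
  ## region of the CNV interior; gaps are assessed over flanks + core
  w_to_out <- function(o) {                      # window offset -> outgroup
    if (pr$strand == "-") we - o else ws + o
  }
  if (anchored) {
    core_s <- la$s_end; core_e <- max(ra$s_start, core_s)
    wo <- sort(c(w_to_out(max(0L, core_s - fl)),
                 w_to_out(min(nchar(window), core_e + fl))))
    res$out_window_start <- wo[1]; res$out_window_end <- wo[2]
    gap_frac <- intersect_width(wo[1], wo[2], gch) / max(1L, wo[2] - wo[1])
  } else {
    res$out_window_start <- ws; res$out_window_end <- we
    gap_frac <- intersect_width(ws, we, gch) / max(1L, we - ws)
  }
  res$gap_fraction <- gap_frac
  if (gap_frac > params$gap_max_fraction) {
    res$reason <- "sequence_gaps"; return(res)
  }
  if (!anchored) { res$reason <- "flank_not_anchored"; return(res) }

  ## align the CNV interior against the core region between the flanks
  margin <- 150L
  core <- subseq_str(window, max(0L, core_s - margin),
                     min(nchar(window), core_e + margin))
  len <- end - start
  if (nchar(core) < 30) {
    af <- 0
  } else if (len > params$probe_threshold) {
    probe_starts <- start + round(seq(0.05, 0.95, length.out = 10) *
                                    (len - 1000L))
    hits <- vapply(probe_starts, function(ps) {
      local_aligned_fraction(subseq_str(rseq, ps, ps + 1000L),
                             core) >= 0.5
    }, logical(1))
    af <- mean(hits)
  } else {
    af <- local_aligned_fraction(subseq_str(rseq, start, end), core)
  }
  res$aligned_fraction <- af
  res$ancestral_state <-
    if (af < params$insertion_max_aligned) "insertion"
    else if (af >= params$deletion_min_aligned) "deletion"
    else "undefined"
  if (res$ancestral_state == "undefined") res$reason <- "partial_alignment"
  res
}

#' Polarize a table of consensus CNVs
#'
#' @param consensus Consensus events (see [merge_callsets()]).
#' @param ref_seqs,out_seqs,gaps,blocks,params See
#'   [classify_ancestral_state()].
#' @return `consensus` with the polarization columns appended.
#' @export
polarize_cnvs <- function(consensus, ref_seqs, out_seqs, gaps, blocks,
                          params = polarize_params()) {
  rows <- lapply(seq_len(nrow(consensus)), function(i) {
    classify_ancestral_state(consensus$chrom[i], consensus$start[i],
                             consensus$end[i], ref_seqs, out_seqs, gaps,
                             blocks, params)
  })
  pol <- if (length(rows)) do.call(rbind, rows) else data.frame(
    ancestral_state = character(0), aligned_fraction = numeric(0),
    out_chrom = character(0), out_window_start = integer(0),
    out_window_end = integer(0), gap_fraction = numeric(0),
    reason = character(0))
  cbind(consensus, pol)
}
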