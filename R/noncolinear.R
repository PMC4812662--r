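#' Non-co-linear parameters
#'
#' @param min_cov Minimum exonic aligned fraction for co-linearity.
#' @param min_identity Minimum identity for an ancestral-copy hit.
#' @param origin_min_identity Minimum hit identity required before a
#'   duplication origin is inferred.
#' @param te_flank_window Window (bp) on each side of the duplicated copy
#'   searched for flanking TE annotations.
#' @param seed_k Exact k-mer seed length of the homolog search.
#' @export
noncolinear_params <- function(min_cov = 0.5, min_identity = 0.8,
                               origin_min_identity = 0.9,
                               te_flank_window = 1000L, seed_k = 16L) {
  list(min_cov = min_cov, min_identity = min_identity,
       origin_min_identity = origin_min_identity,
       te_flank_window = as.integer(te_flank_window),
       seed_k = as.integer(seed_k))
}

#' Is a gene co-linear with the outgroup?
#'
#' The gene span is projected through the anchor blocks; the gene is
#' co-linear iff the projection succeeds and the gene's exonic sequence
#' aligns to the projected window (with flanks) over at least `min_cov`
#' of its length.  Genes inside insertion-state CNVs whose projection
#' fails or collapses are non-co-linear.
#'
#' @param gene One row of the gene table.
#' @param gene_features Feature table (for the exons).
#' @param blocks Anchor blocks ([build_blocks()]).
#' @param ref_seqs,out_seqs Chromosome sequences.
#' @param params [noncolinear_params()].
#' @return Logical scalar.
#' @export
is_colinear <- function(gene, gene_features, blocks, ref_seqs, out_seqs,
                        params = noncolinear_params()) {
  pr <- project_to_outgroup(gene$chrom, gene$start, gene$end, blocks)
  if (!pr$ok) return(FALSE)
  ex <- gene_features[gene_features$gene_id == gene$gene_id &
                        gene_features$type == "exon", ]
  ex <- ex[order(ex$start), ]
  if (nrow(ex) == 0) return(FALSE)
  rseq <- ref_seqs[[gene$chrom]]
  exseq <- paste(vapply(seq_len(nrow(ex)), function(i)
    subseq_str(rseq, ex$start[i], ex$end[i]), character(1)), collapse = "")
  oseq <- out_seqs[[pr$out_chrom]]
  ws <- max(0L, pr$out_start - 2000L)
  we <- min(nchar(oseq), pr$out_end + 2000L)
  window <- subseq_str(oseq, ws, we)
  if (pr$strand == "-") window <- revcomp(window)
  ## per-exon alignment so introns of diverging length cannot break the
  ## single-local-alignment coverage
  tot <- 0
  off <- 0L
  for (i in seq_len(nrow(ex))) {
    w <- ex$end[i] - ex$start[i]
    sub <- substr(exseq, off + 1L, off + w)
    tot <- tot + local_aligned_fraction(sub, window) * w
    off <- off + w
  }
  (tot / nchar(exseq)) >= params$min_cov
}

#' Find the best non-self ancestral copy of a gene in the reference
#'
#' Seed-and-extend homolog search: exact `seed_k`-mers of the gene's
#' genomic span are matched genome-wide (Biostrings PDict), seed hits are
#' grouped by diagonal into candidate windows (self-overlapping candidates
#' excluded), and each candidate is scored by local alignment.  A hit is
#' returned iff its identity is >= `min_identity` over >= 50% of the gene
#' length; ties prefer higher identity, then longer alignment, then the
#' leftmost locus.
#'
#' @param gene One row of the gene table (span >= 200 bp, else empty).
#' @param ref_seqs Chromosome sequences.
#' @param params [noncolinear_params()].
#' @return List with `found`; on success `chrom`, `start`, `end`
#'   (subject locus), `identity`, `aligned_len`; else a `reason`.
#' @export
find_ancestral_copy <- function(gene, ref_seqs,
                                params = noncolinear_params()) {
  len <- gene$end - gene$start
  if (len < 200) return(list(found = FALSE, reason = "gene_too_short"))
  k <- params$seed_k
  query <- subseq_str(ref_seqs[[gene$chrom]], gene$start, gene$end)
  starts <- seq(1L, nchar(query) - k + 1L, by = 8L)
  kmers <- Biostrings::DNAStringSet(
    vapply(starts, function(s) substr(query, s, s + k - 1L), character(1)))
  keep <- !grepl("N", as.character(kmers), fixed = TRUE)
  if (!any(keep)) return(list(found = FALSE, reason = "no_seeds"))
  kmers <- kmers[keep]; starts <- starts[keep]
  pd <- Biostrings::PDict(kmers)

  cands <- NULL
  for (ch in names(ref_seqs)) {
    mi <- Biostrings::matchPDict(pd, Biostrings::DNAString(ref_seqs[[ch]]))
    sl <- IRanges::start(mi)                    # IntegerList per k-mer
    n_hits <- lengths(sl)
    if (sum(n_hits) == 0) next
    qpos <- rep(starts, n_hits)
    spos <- unlist(sl, use.names = FALSE)
    diag <- spos - qpos
    db <- round(diag / 200)                     # diagonal bucket
    for (b in unique(db)) {
      sel <- db == b
      if (sum(sel) < 2) next
      s0 <- min(spos[sel]) - min(qpos[sel])     # implied subject start, 1-based
      cs <- max(0L, s0 - 1L - 100L)
      ce <- min(nchar(ref_seqs[[ch]]), s0 - 1L + nchar(query) + 100L)
      cands <- rbind(cands, data.frame(chrom = ch, start = cs, end = ce,
                                       n_seeds = sum(sel)))
    }
  }
  if (is.null(cands)) return(list(found = FALSE, reason = "no_candidates"))
  ## drop self candidates, merge overlapping ones per chromosome
  self <- cands$chrom == gene$chrom & cands$start < gene$end &
    cands$end > gene$start
  cands <- cands[!self, , drop = FALSE]
  if (nrow(cands) == 0) return(list(found = FALSE, reason = "self_only"))
  merged <- NULL
  for (ch in unique(cands$chrom)) {
    cc <- cands[cands$chrom == ch, ]
    ir <- IRanges::reduce(IRanges::IRanges(cc$start + 1L, cc$end))
    merged <- rbind(merged, data.frame(
      chrom = ch, start = IRanges::start(ir) - 1L, end = IRanges::end(ir)))
  }
  hits <- lapply(seq_len(nrow(merged)), function(i) {
    sub <- subseq_str(ref_seqs[[merged$chrom[i]]], merged$start[i],
                      merged$end[i])
    st <- local_align_stats(query, sub)
    data.frame(chrom = merged$chrom[i],
               start = merged$start[i] + st$s_start,
               end = merged$start[i] + st$s_end,
               identity = st$identity,
               aligned_len = st$p_end - st$p_start,
               q_start = st$p_start, q_end = st$p_end)
  })
  hits <- do.call(rbind, hits)
  hits <- hits[hits$identity >= params$min_identity &
                 hits$aligned_len >= 0.5 * len, , drop = FALSE]
  ## enforce non-self after refinement too
  hits <- hits[!(hits$chrom == gene$chrom & hits$start < gene$end &
                   hits$end > gene$start), , drop = FALSE]
  if (nrow(hits) == 0) return(list(found = FALSE, reason = "no_hit"))
  ord <- order(-hits$identity, -hits$aligned_len, hits$chrom, hits$start)
  h <- hits[ord[1], ]
  list(found = TRUE, chrom = h$chrom, start = h$start, end = h$end,
       identity = h$identity, aligned_len = h$aligned_len,
       q_start = h$q_start, q_end = h$q_end)
}

#' Infer the origin mechanism of a gene duplication
#'
#' The duplication boundaries are fixed by extending the copy/ancestral
#' alignment outwards base-by-base (stopping when identity over the
#' trailing 20 bp falls below 70%); the decision order is then: `TE` when
#' TE annotations lie within `te_flank_window` on both sides of the new
#' copy; else `NAHR` when junction-anchored homology at the boundaries
#' reaches `nahr_min_len`; else `NHEJ` when boundary microhomology is at
#' most `mh_max`; else `unresolved`.
#'
#' @param gene One row of the gene table (the non-co-linear copy).
#' @param hit Ancestral-copy hit from [find_ancestral_copy()]
#'   (identity must be >= `origin_min_identity`).
#' @param ref_seqs Chromosome sequences.
#' @param te TE annotation.
#' @param params [noncolinear_params()].
#' @param mech_params [mechanism_params()] (for the NAHR/NHEJ thresholds).
#' @return List with `origin` and the boundaries `copy_start`,
#'   `copy_end`.
#' @export
infer_origin <- function(gene, hit, ref_seqs, te,
                         params = noncolinear_params(),
                         mech_params = mechanism_params()) {
  if (!isTRUE(hit$found) || hit$identity < params$origin_min_identity) {
    stop("origin inference requires an ancestral hit with identity >= ",
         params$origin_min_identity)
  }
  gseq <- ref_seqs[[gene$chrom]]
  aseq <- ref_seqs[[hit$chrom]]

  extend <- function(gpos, apos, dir, max_ext = 20000L) {
    win <- 20L
    buf <- logical(win); bi <- 0L; filled <- 0L
    last_good <- 0L
    for (i in seq_len(max_ext)) {
      gp <- gpos + dir * i; ap <- apos + dir * i
      if (gp < 0 || gp >= nchar(gseq) || ap < 0 || ap >= nchar(aseq)) break
      m <- subseq_str(gseq, gp, gp + 1L) == subseq_str(aseq, ap, ap + 1L)
      bi <- bi %% win + 1L; buf[bi] <- m; filled <- min(filled + 1L, win)
      if (m) last_good <- i
      if (filled == win && mean(buf) < 0.7) break
    }
    last_good
  }
  ## anchor the extension at the alignment's matched end pairs (the
  ## alignment may clip a few terminal bases; starting in register is
  ## what keeps the outward walk meaningful)
  gp_l <- gene$start + (hit$q_start %||% 0L)
  ap_l <- hit$start
  gp_r <- gene$start + (hit$q_end %||% (gene$end - gene$start)) - 1L
  ap_r <- hit$end - 1L
  lext <- extend(gp_l, ap_l, -1L)
  rext <- extend(gp_r, ap_r, +1L)
  b1 <- gp_l - lext
  b2 <- gp_r + rext + 1L
  tw <- params$te_flank_window
  tch <- te[te$chrom == gene$chrom, , drop = FALSE]
  te_left <- any(tch$start < b1 + 50L & tch$end > b1 - tw)
  te_right <- any(tch$start < b2 + tw & tch$end > b2 - 50L)
  origin <- if (te_left && te_right) {
    "TE"
  } else {
    ## aligned (gap-tolerant) junction homology: the extension boundaries
    ## can be off by a few bp, which an ungapped scan would not forgive
    fh <- junction_homology_aligned(gseq, b1, b2,
                                    mech_params$homology_scan_window,
                                    slack = 20L)
    if (fh$nmatch >= mech_params$nahr_min_len &&
        fh$identity >= mech_params$nahr_min_identity) {
      "NAHR"
    } else {
      mh <- junction_microhomology(gseq, b1, b2,
                                   cap = mech_params$homology_scan_window)
      if (mh$total <= mech_params$mh_max) "NHEJ" else "unresolved"
    }
  }
  list(origin = origin, copy_start = as.integer(b1), copy_end = as.integer(b2))
}

## Local-alignment version of the junction homology scan, used by origin
## inference where duplication boundaries are only approximate.  Compares
## the windows starting (and symmetrically ending) at the two boundaries
## and returns the better side's matched bases and identity.
junction_homology_aligned <- function(seq, b1, b2, W = 500L, slack = 20L) {
  n <- nchar(seq)
  pre <- local_align_stats(
    subseq_str(seq, max(0L, b1 - slack), min(n, b1 + W)),
    subseq_str(seq, max(0L, b2 - slack), min(n, b2 + W)))
  suf <- local_align_stats(
    subseq_str(seq, max(0L, b1 - W), min(n, b1 + slack)),
    subseq_str(seq, max(0L, b2 - W), min(n, b2 + slack)))
  win <- if (pre$nmatch >= suf$nmatch) pre else suf
  list(nmatch = win$nmatch, identity = win$identity)
}

#' Non-co-linear analysis of CNV genes
#'
#' For every CNV gene: co-linearity against the outgroup, ancestral-copy
#' search in the reference, and (for hits of sufficient identity) origin
#' inference.
#'
#' @param cnv_gene_ids Genes overlapped by CNVs.
#' @param genes,gene_features,blocks,ref_seqs,out_seqs,te Resources.
#' @param params [noncolinear_params()].
#' @param mech_params [mechanism_params()].
#' @return Data frame: `gene_id`, `is_colinear`, `ancestral_chrom`,
#'   `ancestral_start`, `ancestral_end`, `ancestral_identity`,
#'   `origin_mechanism`.
#' @export
noncolinear_genes <- function(cnv_gene_ids, genes, gene_features, blocks,
                              ref_seqs, out_seqs, te,
                              params = noncolinear_params(),
                              mech_params = mechanism_params()) {
  rows <- lapply(cnv_gene_ids, function(gid) {
    gene <- genes[genes$gene_id == gid, ]
    if (nrow(gene) == 0) return(NULL)
    gene <- gene[1, ]
    col <- is_colinear(gene, gene_features, blocks, ref_seqs, out_seqs,
                       params)
    out <- data.frame(gene_id = gid, is_colinear = col,
                      ancestral_chrom = NA_character_,
                      ancestral_start = NA_integer_,
                      ancestral_end = NA_integer_,
                      ancestral_identity = NA_real_,
                      origin_mechanism = "")
    if (!col) {
      hit <- find_ancestral_copy(gene, ref_seqs, params)
      if (isTRUE(hit$found)) {
        stopifnot(!(hit$chrom == gene$chrom && hit$start < gene$end &&
                      hit$end > gene$start))     # self-hit exclusion
        out$ancestral_chrom <- hit$chrom
        out$ancestral_start <- hit$start
        out$ancestral_end <- hit$end
        out$ancestral_identity <- hit$identity
        if (hit$identity >= params$origin_min_identity) {
          org <- infer_origin(gene, hit, ref_seqs, te, params, mech_params)
          out$origin_mechanism <- org$origin
        }
      }
    }
    out
  })
  out <- do.call(rbind, rows)
  out %||% data.frame(gene_id = character(0), is_colinear = logical(0),
                      ancestral_chrom = character(0),
                      ancestral_start = integer(0),
                      ancestral_end = integer(0),
                      ancestral_identity = numeric(0),
                      origin_mechanism = character(0))
}
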