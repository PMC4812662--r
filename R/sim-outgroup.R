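#' Derive the outgroup genome from the simulated reference
#'
#' The ancestral haplotype is materialized explicitly: every
#' insertion-state event interval is excised from the reference (the
#' deletion-state events are ancestral and stay).  The outgroup is the
#' ancestral haplotype mutated with per-site substitutions at
#' `outgroup_divergence`, small (1-5 bp) indels at `outgroup_indel_rate`,
#' and assembly gaps (runs of N) at `outgroup_gap_rate` expected gaps per
#' chromosome.  One synteny anchor is emitted per gene present in both
#' genomes (i.e. not overlapping an excised interval), with exact outgroup
#' coordinates obtained from the coordinate bookkeeping.
#'
#' Gap placement is monotone in `outgroup_gap_rate` for a fixed seed: the
#' candidate gap stream is drawn once and the rate only decides how many
#' candidates are realized, so raising the rate adds gaps without moving
#' existing ones.
#'
#' @param pack `genome_pack` after [implant_events()].
#' @param truth Truth table from [implant_events()].
#' @param config The [sim_config()].
#' @return List of class `outgroup_pack`: `seqs` (outgroup chromosomes),
#'   `ancestor` (ungapped, unmutated ancestral haplotype), `anchors`,
#'   `gaps` (outgroup coordinates), `maps` (per-chromosome coordinate
#'   tables) and `truth` with an added `gap_overlap_frac` column (fraction
#'   of the event's outgroup alignment window covered by assembly gaps,
#'   computed from true coordinates).
#' @export
mutate_outgroup <- function(pack, truth, config) {
  stopifnot(inherits(pack, "genome_pack"))
  set.seed(derive_seed(config$seed, 3L))
  d <- config$outgroup_divergence
  ind_rate <- config$outgroup_indel_rate
  flank <- 2000L

  out_seqs <- anc_seqs <- setNames(character(length(pack$seqs)),
                                   names(pack$seqs))
  maps <- list()
  gaps <- NULL
  for (ch in names(pack$seqs)) {
    refseq <- pack$seqs[[ch]]
    rem <- truth[truth$chrom == ch & truth$ancestral_state == "insertion",
                 c("ref_start", "ref_end")]
    rem <- rem[order(rem$ref_start), , drop = FALSE]
    names(rem) <- c("start", "end")

    ## ancestral haplotype: excise insertion-state intervals
    keep_s <- c(0L, rem$end)
    keep_e <- c(rem$start, nchar(refseq))
    pieces <- vapply(seq_along(keep_s), function(i)
      subseq_str(refseq, keep_s[i], keep_e[i]), character(1))
    anc <- paste(pieces, collapse = "")
    anc_seqs[[ch]] <- anc
    cumw <- c(0L, cumsum(rem$end - rem$start))

    n <- nchar(anc)
    x <- strsplit(anc, "", fixed = TRUE)[[1]]
    if (d > 0 && n > 0) {
      idx <- which(runif(n) < d)
      if (length(idx)) {
        bases <- c("A", "C", "G", "T")
        shift <- sample.int(3L, length(idx), replace = TRUE)
        x[idx] <- bases[(match(x[idx], bases) - 1L + shift) %% 4L + 1L]
      }
    }
    mutated <- paste(x, collapse = "")

    ## small indels, assembled as segments; coordinate records (A -> O)
    A <- 0L; O <- 0L
    if (ind_rate > 0 && n > 0) {
      n_ind <- rbinom(1, n, ind_rate)
      pos <- sort(sample.int(n - 10L, n_ind))
      pos <- pos[c(TRUE, diff(pos) > 10L)]      # keep indels separated
      type <- sample(c("ins", "del"), length(pos), replace = TRUE)
      len <- sample(1:5, length(pos), replace = TRUE)
      segs <- character(0)
      a <- 0L; o <- 0L
      for (i in seq_along(pos)) {
        p <- pos[i]
        segs <- c(segs, substr(mutated, a + 1L, p))
        o <- o + (p - a)
        if (type[i] == "ins") {
          insseq <- rand_dna(len[i], config$gc_content)
          segs <- c(segs, insseq)
          A <- c(A, p); O <- c(O, o + len[i])
          o <- o + len[i]; a <- p
        } else {
          A <- c(A, p); O <- c(O, o)            # before-deletion record
          a <- p + len[i]
          A <- c(A, a); O <- c(O, o)            # after-deletion record
        }
      }
      segs <- c(segs, substr(mutated, a + 1L, n))
      outseq <- paste(segs, collapse = "")
    } else {
      outseq <- mutated
    }

    ## assembly gaps: fixed candidate stream, rate decides how many
    u <- runif(1)
    n_cand <- 60L
    cand_pos <- floor(runif(n_cand) * max(1, nchar(outseq) - 6000L)) + 1000L
    cand_len <- sample(1500:4000, n_cand, replace = TRUE)
    k <- min(n_cand, qpois(min(u, 1 - 1e-9), config$outgroup_gap_rate))
    if (k > 0) {
      for (g in seq_len(k)) {
        gs <- cand_pos[g]; ge <- min(gs + cand_len[g], nchar(outseq))
        outseq <- set_subseq_str(outseq, gs, strrep("N", ge - gs))
        gaps <- rbind(gaps, data.frame(chrom = ch, start = gs, end = ge))
      }
    }
    out_seqs[[ch]] <- outseq
    maps[[ch]] <- list(rem = rem, cumw = cumw, A = A, O = O,
                       out_len = nchar(outseq))
  }
  gaps <- gaps %||% data.frame(chrom = character(0), start = integer(0),
                               end = integer(0))

  og <- list(seqs = out_seqs, ancestor = anc_seqs, gaps = gaps, maps = maps)

  ## synteny anchors: genes absent from no genome
  genes <- pack$genes
  anchors <- NULL
  if (nrow(genes) > 0) {
    keep <- vapply(seq_len(nrow(genes)), function(i) {
      rem <- maps[[genes$chrom[i]]]$rem
      !any(rem$start < genes$end[i] & rem$end > genes$start[i])
    }, logical(1))
    g <- genes[keep, ]
    if (nrow(g) > 0) {
      os <- mapply(function(ch, p) map_ref_to_outgroup(og, ch, p),
                   g$chrom, g$start)
      oe <- mapply(function(ch, p) map_ref_to_outgroup(og, ch, p),
                   g$chrom, g$end)
      anchors <- data.frame(
        gene_id = g$gene_id, ref_chrom = g$chrom, ref_start = g$start,
        ref_end = g$end, out_chrom = g$chrom, out_start = os,
        out_end = oe, strand = "+")
    }
  }
  og$anchors <- anchors %||% data.frame(
    gene_id = character(0), ref_chrom = character(0),
    ref_start = integer(0), ref_end = integer(0), out_chrom = character(0),
    out_start = integer(0), out_end = integer(0), strand = character(0))

  ## record the true gap-overlap fraction of each event's alignment window
  if (nrow(truth) > 0) {
    truth$gap_overlap_frac <- vapply(seq_len(nrow(truth)), function(i) {
      ch <- truth$chrom[i]
      ws <- max(0L, map_ref_to_outgroup(og, ch, truth$ref_start[i]) - flank)
      we <- min(maps[[ch]]$out_len,
                map_ref_to_outgroup(og, ch, truth$ref_end[i]) + flank)
      if (we <= ws) return(0)
      gch <- gaps[gaps$chrom == ch, , drop = FALSE]
      intersect_width(ws, we, gch) / (we - ws)
    }, numeric(1))
  } else {
    truth$gap_overlap_frac <- numeric(0)
  }
  og$truth <- truth
  class(og) <- "outgroup_pack"
  og
}

#' Map a reference position to its outgroup coordinate
#'
#' Exact coordinate bookkeeping through the ancestral excisions and the
#' outgroup indels.  Positions inside an excised (insertion-state) interval
#' collapse to the excision point.
#'
#' @param og An `outgroup_pack` from [mutate_outgroup()].
#' @param chrom Chromosome name.
#' @param pos 0-based reference position.
#' @return 0-based outgroup position.
#' @export
map_ref_to_outgroup <- function(og, chrom, pos) {
  m <- og$maps[[chrom]]
  rem <- m$rem
  i <- findInterval(pos, rem$start)
  anc <- if (i > 0 && pos < rem$end[i]) {
    rem$start[i] - m$cumw[i]
  } else {
    pos - m$cumw[i + 1L]
  }
  k <- findInterval(anc, m$A)
  o <- m$O[k] + (anc - m$A[k])
  if (k < length(m$A)) o <- min(o, m$O[k + 1L])
  max(0L, min(o, m$out_len))
}
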