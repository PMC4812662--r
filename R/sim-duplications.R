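#' Implant gene duplications with origin-diagnostic breakpoint signatures
#'
#' Copies the genomic span of existing genes (with ~250 bp of flank and
#' ~1.5% divergence between the copies) to new loci, so the new gene copy
#' is an insertion in the reference lineage and therefore non-co-linear
#' against the outgroup.  Three origin classes write distinct signatures
#' around the new copy:
#'
#' * `TE` — annotated Mutator-like TE copies directly flank both sides of
#'   the duplicated segment (transposon capture).
#' * `NHEJ` — 0-8 bp of engineered microhomology at the duplication
#'   boundaries, nothing else.
#' * `NAHR` — a 200 bp repeat heads the duplicated segment and a second
#'   diverged copy sits immediately after its end (the recombination
#'   substrate; the ancestor keeps the target-site copy).
#'
#' @param pack `genome_pack` after [implant_events()].
#' @param truth Truth table from [implant_events()].
#' @param config The [sim_config()]; `duplications_per_origin` copies are
#'   implanted per class.
#' @return List with updated `pack` and `truth` (duplication rows appended
#'   with `mechanism = "DUP"` and `origin` set; `ancestral_state` is always
#'   `insertion`).
#' @export
implant_duplications <- function(pack, truth, config) {
  n_per <- config$duplications_per_origin
  if (n_per == 0) return(list(pack = pack, truth = truth))
  set.seed(derive_seed(config$seed, 5L))
  origins <- rep(c("TE", "NHEJ", "NAHR"), each = n_per)
  pad <- 250L
  rlen <- 200L
  mut_te <- pack$te_library[["Mutator_like"]]
  te_len <- nchar(mut_te)

  ## candidate source genes: clear of events/TEs/arrays (with margin)
  busy <- rbind(
    data.frame(chrom = truth$chrom, start = truth$ref_start - 1000L,
               end = truth$ref_end + 1000L),
    data.frame(chrom = pack$te$chrom, start = pack$te$start - 500L,
               end = pack$te$end + 500L),
    data.frame(chrom = pack$vntr$chrom, start = pack$vntr$start - 500L,
               end = pack$vntr$end + 500L))
  g <- pack$genes
  clear <- vapply(seq_len(nrow(g)), function(i) {
    b <- busy[busy$chrom == g$chrom[i], , drop = FALSE]
    !any(b$start < g$end[i] + pad + rlen & b$end > g$start[i] - pad - rlen)
  }, logical(1))
  cand <- which(clear & (g$end - g$start) >= 400 & (g$end - g$start) <= 3000)
  if (length(cand) < length(origins)) {
    stop("placement error: only ", length(cand),
         " clear source genes for ", length(origins), " duplications")
  }
  src_idx <- sample(cand, length(origins))

  occupied <- rbind(
    data.frame(chrom = truth$chrom, start = truth$ref_start - 2500L,
               end = truth$ref_end + 2500L),
    data.frame(chrom = pack$te$chrom, start = pack$te$start - 2500L,
               end = pack$te$end + 2500L),
    data.frame(chrom = pack$vntr$chrom, start = pack$vntr$start - 2500L,
               end = pack$vntr$end + 2500L),
    data.frame(chrom = g$chrom, start = g$start - 1000L,
               end = g$end + 1000L))

  accs <- accession_ids(config$n_accessions)
  new_rows <- NULL
  dup_no <- 0L
  for (j in seq_along(origins)) {
    o <- origins[j]
    sg <- g[src_idx[j], ]
    ch <- sg$chrom

    lpad <- if (o == "NAHR") pad + rlen else pad
    if (o == "NAHR") {
      ## the recombination substrate: one repeat copy ancestrally present
      ## upstream of the source gene, a diverged copy at the target site
      r <- rand_dna(rlen, config$gc_content)
      pack$seqs[[ch]] <- set_subseq_str(pack$seqs[[ch]], sg$start - lpad,
                                        mutate_dna(r, 0.01))
    }
    seg <- subseq_str(pack$seqs[[ch]], sg$start - lpad, sg$end + pad)
    seg_copy <- mutate_dna(seg, 0.015)

    construct <- switch(o,
      TE = paste0(mutate_dna(mut_te, 0.03), seg_copy,
                  mutate_dna(mut_te, 0.03)),
      NHEJ = seg_copy,
      NAHR = seg_copy)
    extra_after <- if (o == "NAHR") rlen else 0L

    ## place the construct on any chromosome, clear of everything
    tch <- sample(names(pack$seqs), 1)
    occ <- occupied[occupied$chrom == tch, c("start", "end")]
    pl <- place_intervals(nchar(construct) + extra_after,
                          lo = 4000L, hi = nchar(pack$seqs[[tch]]) - 4000L,
                          occupied = occ, min_gap = 1500L)
    b0 <- pl$start[1]
    tseq <- set_subseq_str(pack$seqs[[tch]], b0, construct)
    c0 <- if (o == "TE") b0 + te_len else b0          # copy start
    c1 <- c0 + nchar(seg_copy)                        # copy end
    b3 <- b0 + nchar(construct)                       # construct end
    mh <- 0L
    if (o == "NAHR") {
      tseq <- set_subseq_str(tseq, c1, mutate_dna(r, 0.01))
    } else if (o == "NHEJ") {
      mh <- sample(0:8, 1)
      if (mh > 0) {
        tseq <- set_subseq_str(tseq, c1, subseq_str(tseq, c0, c0 + mh))
      }
      tseq <- force_mismatch(tseq, c1 + mh, c0 + mh)
      tseq <- force_mismatch(tseq, c0 - 1L, c1 - 1L)
    }
    pack$seqs[[tch]] <- tseq
    if (o == "TE") {
      pack$te <- rbind(pack$te,
        data.frame(chrom = tch, start = b0, end = b0 + te_len,
                   family = "Mutator_like"),
        data.frame(chrom = tch, start = c1, end = b3,
                   family = "Mutator_like"))
    }
    occupied <- rbind(occupied, data.frame(
      chrom = tch, start = b0 - 2500L, end = b3 + extra_after + 2500L))

    ## annotate the duplicated gene copy at its new position
    dup_no <- dup_no + 1L
    new_gid <- paste0(sg$gene_id, "d")
    shift <- (c0 + lpad) - sg$start
    pack$genes <- rbind(pack$genes, data.frame(
      gene_id = new_gid, chrom = tch, start = sg$start + shift,
      end = sg$end + shift, strand = sg$strand))
    gf <- pack$gene_features[pack$gene_features$gene_id == sg$gene_id, ]
    gf$gene_id <- new_gid; gf$chrom <- tch
    gf$start <- gf$start + shift; gf$end <- gf$end + shift
    pack$gene_features <- rbind(pack$gene_features, gf)

    k <- if (config$n_accessions <= 3) config$n_accessions else
      sample(3:config$n_accessions, 1, prob = 1 / (3:config$n_accessions))
    new_rows <- rbind(new_rows, data.frame(
      event_id = sprintf("dup%03d", dup_no),
      chrom = tch, ref_start = b0, ref_end = b3,
      mechanism = "DUP", ancestral_state = "insertion",
      carriers = paste(sort(sample(accs, k)), collapse = ","),
      te_family = if (o == "TE") "Mutator_like" else "",
      microhomology_len = mh,
      homology_len = if (o == "NAHR") rlen else 0L,
      vntr_period = NA_integer_, origin = o,
      dup_source_gene = sg$gene_id, dup_gene = new_gid,
      dup_copy_start = c0, dup_copy_end = c1))
  }
  truth$dup_source_gene <- truth$dup_source_gene %||% NA_character_
  truth$dup_gene <- truth$dup_gene %||% NA_character_
  truth$dup_copy_start <- truth$dup_copy_start %||% NA_integer_
  truth$dup_copy_end <- truth$dup_copy_end %||% NA_integer_
  truth <- rbind(truth, new_rows)
  truth <- truth[order(truth$chrom, truth$ref_start), ]
  rownames(truth) <- NULL
  list(pack = pack, truth = truth)
}
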