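## TE family library templates: name -> consensus length.  One family is
## Mutator-like, used for TE-capture duplication fixtures.
TE_FAMILIES <- c(Mutator_like = 1500L, Copia_like = 2200L, Gypsy_like = 3000L,
                 hAT_like = 900L, CACTA_like = 1300L, LINE_like = 2000L)

#' Simulate a reference genome with annotated features
#'
#' Generates per-chromosome random background sequence at the configured GC
#' content, then overwrites non-overlapping placements with TE copies
#' (diverged ~3% from their family consensus), tandem-repeat arrays and gene
#' models (genes keep background sequence; only their coordinates and
#' exon/CDS/UTR structure are annotated).
#'
#' @param config A [sim_config()] object.
#' @return A `genome_pack`: list with `seqs` (named character vector of
#'   chromosome sequences), `te`, `vntr`, `genes`, `gene_features` (0-based
#'   half-open data frames), `te_library` (named character vector) and
#'   `config`.
#' @export
simulate_reference <- function(config) {
  validate_sim_config(config)
  set.seed(derive_seed(config$seed, 1L))
  gc <- config$gc_content

  fams <- TE_FAMILIES[seq_len(config$te_library_size)]
  te_library <- vapply(fams, function(w) rand_dna(w, gc), character(1))

  chroms <- paste0("chr", seq_len(config$n_chromosomes))
  seqs <- setNames(vapply(chroms, function(ch)
    rand_dna(config$chrom_length, gc), character(1)), chroms)

  ## split feature budgets across chromosomes as evenly as possible
  split_count <- function(n) {
    base <- n %/% config$n_chromosomes
    extra <- n %% config$n_chromosomes
    base + as.integer(seq_len(config$n_chromosomes) <= extra)
  }
  n_te <- split_count(config$n_te_copies)
  n_vntr <- split_count(config$n_vntr_arrays)
  n_gene <- split_count(config$n_genes)

  te <- vntr <- genes <- gene_features <- NULL
  gene_no <- 0L
  for (ci in seq_along(chroms)) {
    ch <- chroms[ci]
    len <- config$chrom_length
    occ <- data.frame(start = integer(0), end = integer(0))

    ## --- TE copies ---
    if (n_te[ci] > 0) {
      fam_idx <- sample.int(length(te_library), n_te[ci], replace = TRUE)
      widths <- nchar(te_library)[fam_idx]
      pl <- place_intervals(widths, lo = 3000L, hi = len - 3000L,
                            occupied = occ, min_gap = 500L)
      occ <- rbind(occ, pl)
      for (i in seq_len(nrow(pl))) {
        body <- mutate_dna(te_library[[fam_idx[i]]], 0.03)
        seqs[[ch]] <- set_subseq_str(seqs[[ch]], pl$start[i], body)
      }
      te <- rbind(te, data.frame(chrom = ch, start = pl$start, end = pl$end,
                                 family = names(te_library)[fam_idx]))
    }

    ## --- tandem-repeat arrays ---
    if (n_vntr[ci] > 0) {
      periods <- sample(40:60, n_vntr[ci], replace = TRUE)
      copies <- sample(16:24, n_vntr[ci], replace = TRUE)
      widths <- periods * copies
      pl <- place_intervals(widths, lo = 3000L, hi = len - 3000L,
                            occupied = occ, min_gap = 500L)
      occ <- rbind(occ, pl)
      for (i in seq_len(nrow(pl))) {
        unit <- rand_dna(periods[i], gc)
        arr <- paste(rep(unit, copies[i]), collapse = "")
        seqs[[ch]] <- set_subseq_str(seqs[[ch]], pl$start[i], arr)
      }
      vntr <- rbind(vntr, data.frame(chrom = ch, start = pl$start,
                                     end = pl$end, period = periods,
                                     copies = copies))
    }

    ## --- sentinel genes near both chromosome ends ---
    ## ortholog anchor sets cover chromosome ends; without a terminal
    ## anchor no event near an end could be projected onto the outgroup
    for (sent in list(c(1000L, 1400L), c(len - 1400L, len - 1000L))) {
      gene_no <- gene_no + 1L
      gid <- sprintf("gene%04d", gene_no)
      genes <- rbind(genes, data.frame(
        gene_id = gid, chrom = ch, start = sent[1], end = sent[2],
        strand = "+"))
      gene_features <- rbind(gene_features, data.frame(
        gene_id = gid, type = c("exon", "CDS"), chrom = ch,
        start = c(sent[1], sent[1] + 50L),
        end = c(sent[2], sent[2] - 50L)))
      occ <- rbind(occ, data.frame(start = sent[1], end = sent[2]))
    }

    ## --- gene models ---
    if (n_gene[ci] > 0) {
      structs <- lapply(seq_len(n_gene[ci]), function(i) {
        n_ex <- sample(1:5, 1)
        ex_w <- sample(150:400, n_ex, replace = TRUE)
        in_w <- if (n_ex > 1) sample(100:800, n_ex - 1, replace = TRUE)
                else integer(0)
        list(ex_w = ex_w, in_w = in_w, width = sum(ex_w) + sum(in_w))
      })
      widths <- vapply(structs, `[[`, integer(1), "width")
      pl <- place_intervals(widths, lo = 3000L, hi = len - 3000L,
                            occupied = occ, min_gap = 500L)
      occ <- rbind(occ, pl)
      for (i in seq_len(nrow(pl))) {
        gene_no <- gene_no + 1L
        gid <- sprintf("gene%04d", gene_no)
        st <- structs[[i]]
        ex_starts <- pl$start[i] +
          cumsum(c(0L, head(st$ex_w, -1) + st$in_w))
        ex_ends <- ex_starts + st$ex_w
        strand <- sample(c("+", "-"), 1)
        ## UTRs occupy the outer portions of the terminal exons; for
        ## single-exon genes both live in the same exon
        n_ex_i <- length(st$ex_w)
        u5 <- max(0L, min(sample(50:150, 1), st$ex_w[1] - 50L))
        u3_cap <- st$ex_w[n_ex_i] - 50L - (if (n_ex_i == 1) u5 else 0L)
        u3 <- max(0L, min(sample(50:150, 1), u3_cap))
        feats <- data.frame(gene_id = gid, type = "exon",
                            chrom = ch, start = ex_starts, end = ex_ends)
        cds <- feats[, c("start", "end")]
        cds$start[1] <- cds$start[1] + u5
        cds$end[nrow(cds)] <- cds$end[nrow(cds)] - u3
        feats <- rbind(
          feats,
          data.frame(gene_id = gid, type = "CDS", chrom = ch,
                     start = cds$start, end = cds$end),
          if (u5 > 0) data.frame(gene_id = gid, type = "five_prime_UTR",
                                 chrom = ch, start = ex_starts[1],
                                 end = ex_starts[1] + u5),
          if (u3 > 0) data.frame(gene_id = gid, type = "three_prime_UTR",
                                 chrom = ch,
                                 start = ex_ends[length(ex_ends)] - u3,
                                 end = ex_ends[length(ex_ends)])
        )
        genes <- rbind(genes, data.frame(
          gene_id = gid, chrom = ch, start = pl$start[i], end = pl$end[i],
          strand = strand))
        gene_features <- rbind(gene_features, feats)
      }
    }
  }

  empty_iv <- function(extra) {
    df <- data.frame(chrom = character(0), start = integer(0),
                     end = integer(0))
    for (nm in names(extra)) df[[nm]] <- extra[[nm]]
    df
  }
  pack <- list(
    seqs = seqs,
    te = te %||% empty_iv(list(family = character(0))),
    vntr = vntr %||% empty_iv(list(period = integer(0),
                                   copies = integer(0))),
    genes = genes %||% data.frame(gene_id = character(0),
                                  chrom = character(0), start = integer(0),
                                  end = integer(0), strand = character(0)),
    gene_features = gene_features %||% data.frame(
      gene_id = character(0), type = character(0), chrom = character(0),
      start = integer(0), end = integer(0)),
    te_library = te_library,
    config = config
  )
  class(pack) <- "genome_pack"
  pack
}
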