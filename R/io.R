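#' Write chromosome sequences as FASTA (60-column wrap)
#' @param seqs Named character vector.
#' @param path Output file.
#' @export
write_fasta <- function(seqs, path) {
  Biostrings::writeXStringSet(Biostrings::DNAStringSet(seqs), path,
                              width = 60L)
  invisible(path)
}

#' Read a FASTA file into a named character vector
#' @param path FASTA file.
#' @export
read_fasta <- function(path) {
  x <- Biostrings::readDNAStringSet(path)
  setNames(as.character(x), sub("\\s.*$", "", names(x)))
}

#' Write an interval table as BED (0-based half-open, name column)
#' @param df Data frame with `chrom`, `start`, `end` and optionally a name
#'   column given by `name_col`.
#' @param path Output file.
#' @param name_col Column to put in the BED name field.
#' @export
write_bed <- function(df, path, name_col = NULL) {
  gr <- GenomicRanges::GRanges(df$chrom,
                               IRanges::IRanges(df$start + 1L, df$end))
  if (!is.null(name_col)) names(gr) <- as.character(df[[name_col]])
  rtracklayer::export(gr, path, format = "BED")
  invisible(path)
}

#' Read a BED file (0-based half-open)
#' @param path BED file.
#' @return Data frame `chrom`, `start`, `end`, `name`.
#' @export
read_bed <- function(path) {
  gr <- rtracklayer::import(path, format = "BED")
  data.frame(chrom = as.character(GenomicRanges::seqnames(gr)),
             start = GenomicRanges::start(gr) - 1L,
             end = GenomicRanges::end(gr),
             name = if (!is.null(gr$name)) gr$name else
               rep(NA_character_, length(gr)))
}

#' Write gene models as GFF3 (1-based closed at the boundary)
#' @param genes,gene_features Gene tables (see [simulate_reference()]).
#' @param path Output file.
#' @export
write_gff3 <- function(genes, gene_features, path) {
  mk <- function(chrom, start, end, strand, type, id, parent) {
    GenomicRanges::GRanges(
      chrom, IRanges::IRanges(start + 1L, end), strand = strand,
      type = type, ID = id,
      Parent = ifelse(is.na(parent), NA_character_, parent),
      phase = ifelse(type == "CDS", 0L, NA_integer_))
  }
  strand_of <- setNames(genes$strand, genes$gene_id)
  g <- mk(genes$chrom, genes$start, genes$end, genes$strand, "gene",
          genes$gene_id, NA_character_)
  f <- gene_features
  fr <- mk(f$chrom, f$start, f$end, strand_of[f$gene_id], f$type,
           paste0(f$gene_id, ":", f$type, ":", seq_len(nrow(f))),
           f$gene_id)
  all <- c(g, fr)
  rtracklayer::export(all, path, format = "GFF3")
  invisible(path)
}

#' Read gene models from GFF3
#' @param path GFF3 file.
#' @return List with `genes` and `gene_features` (0-based half-open).
#' @export
read_gff3 <- function(path) {
  gr <- rtracklayer::import(path, format = "GFF3")
  df <- data.frame(chrom = as.character(GenomicRanges::seqnames(gr)),
                   start = GenomicRanges::start(gr) - 1L,
                   end = GenomicRanges::end(gr),
                   strand = as.character(GenomicRanges::strand(gr)),
                   type = as.character(gr$type),
                   ID = as.character(gr$ID))
  parent <- vapply(gr$Parent, function(p)
    if (length(p)) as.character(p[1]) else NA_character_, character(1))
  genes <- df[df$type == "gene", ]
  genes <- data.frame(gene_id = genes$ID, chrom = genes$chrom,
                      start = genes$start, end = genes$end,
                      strand = genes$strand)
  feats <- df[df$type != "gene", ]
  feats <- data.frame(gene_id = parent[df$type != "gene"],
                      type = feats$type, chrom = feats$chrom,
                      start = feats$start, end = feats$end)
  list(genes = genes, gene_features = feats)
}

write_tsv <- function(df, path) {
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

read_tsv <- function(path) {
  read.table(path, sep = "\t", header = TRUE, stringsAsFactors = FALSE,
             comment.char = "")
}

#' Write consensus CNVs as a minimal SV VCF
#'
#' Symbolic `<DEL>` records with `END`, `SVTYPE=DEL`, `N_ACC`,
#' `SUPP_CALLERS` and optional `ANC_STATE`/`MECH` INFO keys and an
#' `IMPRECISE` flag; coordinates are converted to 1-based on write.
#'
#' @param consensus Consensus table (optionally with polarization and
#'   mechanism columns).
#' @param path Output file.
#' @param ref_seqs Optional named sequences for the REF base.
#' @export
write_consensus_vcf <- function(consensus, path, ref_seqs = NULL) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    "##fileformat=VCFv4.2",
    "##source=cnvpol",
    "##ALT=<ID=DEL,Description=\"Deletion relative to the reference\">",
    "##INFO=<ID=END,Number=1,Type=Integer,Description=\"End position\">",
    "##INFO=<ID=SVTYPE,Number=1,Type=String,Description=\"SV type\">",
    "##INFO=<ID=SVLEN,Number=1,Type=Integer,Description=\"SV length\">",
    "##INFO=<ID=N_ACC,Number=1,Type=Integer,Description=\"Carrier accessions\">",
    "##INFO=<ID=SUPP_CALLERS,Number=1,Type=String,Description=\"Supporting callers\">",
    "##INFO=<ID=ANC_STATE,Number=1,Type=String,Description=\"Ancestral state\">",
    "##INFO=<ID=MECH,Number=1,Type=String,Description=\"Formation mechanism\">",
    "##INFO=<ID=IMPRECISE,Number=0,Type=Flag,Description=\"Imprecise breakpoints\">",
    "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO"), con)
  for (i in seq_len(nrow(consensus))) {
    r <- consensus[i, ]
    ref <- if (!is.null(ref_seqs)) subseq_str(ref_seqs[[r$chrom]],
                                              r$start, r$start + 1L) else "N"
    supp <- r$support %||% ""
    callers <- paste(sort(unique(unlist(strsplit(
      sub("^[^:]*:", "", strsplit(supp, ";", fixed = TRUE)[[1]]),
      "+", fixed = TRUE)))), collapse = "+")
    info <- paste0("SVTYPE=DEL;END=", r$end, ";SVLEN=", -(r$end - r$start),
                   ";N_ACC=", r$n_accessions)
    if (nzchar(callers)) info <- paste0(info, ";SUPP_CALLERS=", callers)
    if (!is.null(r$ancestral_state) && !is.na(r$ancestral_state)) {
      info <- paste0(info, ";ANC_STATE=", r$ancestral_state)
    }
    if (!is.null(r$mechanism) && !is.na(r$mechanism)) {
      info <- paste0(info, ";MECH=", r$mechanism)
    }
    if (!isTRUE(r$precise)) info <- paste0(info, ";IMPRECISE")
    writeLines(paste(r$chrom, r$start + 1L, r$event_id, ref, "<DEL>",
                     ".", "PASS", info, sep = "\t"), con)
  }
  invisible(path)
}

#' Read deletion calls from a VCF into the internal call table
#'
#' Accepts any VCF whose records carry `SVTYPE=DEL` and an `END` INFO key
#' (parsed with VariantAnnotation); 1-based coordinates are converted to
#' the internal 0-based half-open convention.
#'
#' @param path VCF file.
#' @return Data frame with `chrom`, `start`, `end`, `id`, `precise`.
#' @export
read_cnv_vcf <- function(path) {
  if (!requireNamespace("VariantAnnotation", quietly = TRUE)) {
    stop("read_cnv_vcf requires the VariantAnnotation package")
  }
  v <- VariantAnnotation::readVcf(path)
  info <- VariantAnnotation::info(v)
  rr <- SummarizedExperiment::rowRanges(v)
  keep <- info$SVTYPE == "DEL"
  data.frame(
    chrom = as.character(GenomicRanges::seqnames(rr))[keep],
    start = GenomicRanges::start(rr)[keep] - 1L,
    end = as.integer(info$END[keep]),
    id = names(rr)[keep],
    precise = if ("IMPRECISE" %in% colnames(info)) !info$IMPRECISE[keep]
              else TRUE)
}

#' Read simulator call-set BED files
#'
#' `calls/<accession>.<caller>.bed` files: BED3 plus caller and accession
#' columns.
#'
#' @param dir Directory containing the call files.
#' @return Combined call table.
#' @export
read_callsets <- function(dir) {
  files <- list.files(dir, pattern = "\\.bed$", full.names = TRUE)
  out <- lapply(files, function(f) {
    df <- read.table(f, sep = "\t", header = FALSE,
                     stringsAsFactors = FALSE)
    names(df) <- c("chrom", "start", "end", "caller", "accession")
    df$precise <- df$caller == "SR"
    df
  })
  do.call(rbind, out)
}

#' Write all study files to a directory
#'
#' Materializes the synthetic study in the interchange formats:
#' `reference.fa`, `outgroup.fa`, `genes.gff3`, `te.bed`, `vntr.bed`,
#' `gaps.bed`, `anchors.tsv`, `truth.tsv`, `groups.tsv`, `terms.tsv` and
#' per-accession, per-caller call files under `calls/`.
#'
#' @param study A `cnv_study` from [simulate_cnv_study()].
#' @param dir Output directory (created).
#' @export
write_study <- function(study, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  dir.create(file.path(dir, "calls"), showWarnings = FALSE)
  write_fasta(study$pack$seqs, file.path(dir, "reference.fa"))
  write_fasta(study$outgroup$seqs, file.path(dir, "outgroup.fa"))
  write_gff3(study$pack$genes, study$pack$gene_features,
             file.path(dir, "genes.gff3"))
  write_bed(study$pack$te, file.path(dir, "te.bed"), name_col = "family")
  write_bed(study$pack$vntr, file.path(dir, "vntr.bed"),
            name_col = "period")
  if (nrow(study$outgroup$gaps) > 0) {
    g <- study$outgroup$gaps; g$name <- "gap"
    write_bed(g, file.path(dir, "gaps.bed"), name_col = "name")
  } else {
    file.create(file.path(dir, "gaps.bed"))
  }
  write_tsv(study$outgroup$anchors, file.path(dir, "anchors.tsv"))
  write_tsv(study$truth, file.path(dir, "truth.tsv"))
  write_tsv(study$groups, file.path(dir, "groups.tsv"))
  write_tsv(simulate_terms(study), file.path(dir, "terms.tsv"))
  calls <- study$calls
  for (acc in unique(calls$accession)) {
    for (cl in unique(calls$caller)) {
      cc <- calls[calls$accession == acc & calls$caller == cl,
                  c("chrom", "start", "end", "caller", "accession")]
      if (nrow(cc) == 0) next
      write.table(cc, file.path(dir, "calls",
                                paste0(acc, ".", cl, ".bed")),
                  sep = "\t", quote = FALSE, row.names = FALSE,
                  col.names = FALSE)
    }
  }
  invisible(dir)
}

#' Random gene-to-term annotation for enrichment runs
#'
#' Assigns each gene 0-3 terms from a pool of 20, deterministically in the
#' study seed.  Stands in for an externally provided functional
#' annotation.
#'
#' @param study A `cnv_study`.
#' @return Data frame `gene_id`, `term_id`.
#' @export
simulate_terms <- function(study) {
  set.seed(derive_seed(study$config$seed, 6L))
  terms <- sprintf("TERM:%04d", 1:20)
  rows <- lapply(study$pack$genes$gene_id, function(g) {
    k <- sample(0:3, 1)
    if (k == 0) return(NULL)
    data.frame(gene_id = g, term_id = sample(terms, k))
  })
  out <- do.call(rbind, rows)
  out %||% data.frame(gene_id = character(0), term_id = character(0))
}
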