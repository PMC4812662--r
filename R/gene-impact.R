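#' Classify the impact of CNVs on gene models
#'
#' For every overlapping (gene, event) pair the category is decided by
#' precedence: `full` when the event contains the whole annotated gene
#' span; else `partial_cds` when it intersects any CDS interval; else
#' `utr_only` when it intersects a UTR; else `intron_only`.  The summary
#' counts distinct genes per category, each gene counted once at its
#' highest-precedence category across events.
#'
#' @param events Data frame with `event_id`, `chrom`, `start`, `end`.
#' @param genes Gene table (`gene_id`, `chrom`, `start`, `end`).
#' @param gene_features Feature table (`gene_id`, `type` in
#'   exon/CDS/five_prime_UTR/three_prime_UTR, `start`, `end`).
#' @return List with `impacts` (gene_id, event_id, category) and `summary`
#'   (distinct genes per category, genes and CNVs affected, CDS-disrupted
#'   gene count).
#' @export
classify_gene_impact <- function(events, genes, gene_features) {
  ## gene-model sanity: CDS must lie within exons
  for (gid in unique(gene_features$gene_id)) {
    gf <- gene_features[gene_features$gene_id == gid, ]
    ex <- gf[gf$type == "exon", ]
    cds <- gf[gf$type == "CDS", ]
    if (nrow(cds) > 0 && nrow(ex) > 0) {
      exr <- IRanges::reduce(IRanges::IRanges(ex$start + 1L, ex$end))
      cdr <- IRanges::IRanges(cds$start + 1L, cds$end)
      if (sum(IRanges::width(IRanges::setdiff(cdr, exr))) > 0) {
        stop("input error: CDS outside exons for gene ", gid)
      }
    }
  }
  impacts <- NULL
  if (nrow(events) > 0 && nrow(genes) > 0) {
    gr <- GenomicRanges::GRanges(genes$chrom,
                                 IRanges::IRanges(genes$start + 1L,
                                                  genes$end))
    er <- GenomicRanges::GRanges(events$chrom,
                                 IRanges::IRanges(events$start + 1L,
                                                  events$end))
    hits <- GenomicRanges::findOverlaps(gr, er)
    if (length(hits) > 0) {
      rows <- lapply(seq_along(hits), function(h) {
        gi <- S4Vectors::queryHits(hits)[h]
        ei <- S4Vectors::subjectHits(hits)[h]
        g <- genes[gi, ]; e <- events[ei, ]
        gf <- gene_features[gene_features$gene_id == g$gene_id, ]
        ovl <- function(ty) {
          f <- gf[gf$type %in% ty, ]
          nrow(f) > 0 && any(f$start < e$end & f$end > e$start)
        }
        cat <- if (e$start <= g$start && e$end >= g$end) "full"
          else if (ovl("CDS")) "partial_cds"
          else if (ovl(c("five_prime_UTR", "three_prime_UTR"))) "utr_only"
          else "intron_only"
        data.frame(gene_id = g$gene_id, event_id = e$event_id,
                   category = cat)
      })
      impacts <- do.call(rbind, rows)
    }
  }
  impacts <- impacts %||% data.frame(gene_id = character(0),
                                     event_id = character(0),
                                     category = character(0))
  prec <- c(full = 1, partial_cds = 2, utr_only = 3, intron_only = 4)
  best <- vapply(split(impacts$category, impacts$gene_id),
                 function(cs) names(prec)[min(prec[cs])], character(1))
  summary <- list(
    genes_per_category = table(factor(best, levels = names(prec))),
    n_genes = length(best),
    n_cnvs = length(unique(impacts$event_id)),
    n_cds_disrupted = sum(best %in% c("full", "partial_cds")))
  list(impacts = impacts, summary = summary)
}

#' Population sharing of CNVs across accession groups
#'
#' Each event is labelled `shared`, `cultivated_only` or `wild_only` from
#' its carrier accessions; the analogous labels for the indica/japonica
#' partition are computed over the carriers belonging to those subgroups
#' (events with no indica or japonica carrier are reported as `neither`
#' and excluded from the subgroup fractions).
#'
#' @param events Data frame with `event_id`, `carriers` (comma-joined
#'   accession ids).
#' @param groups Data frame (`accession`, `group`, `subgroup`), see
#'   [accession_groups()].
#' @return List with `events` (per-event labels), `group_fractions` and
#'   `subgroup_fractions` (each summing to 1 over its event set).
#' @export
population_sharing <- function(events, groups) {
  glab <- setNames(groups$group, groups$accession)
  slab <- setNames(groups$subgroup, groups$accession)
  lab <- lapply(strsplit(events$carriers, ",", fixed = TRUE), function(cs) {
    missing <- setdiff(cs, groups$accession)
    if (length(missing)) {
      stop("input error: unlabeled accession(s): ",
           paste(missing, collapse = ", "))
    }
    g <- unique(unname(glab[cs]))
    gl <- if (all(c("cultivated", "wild") %in% g)) "shared"
      else if (identical(g, "cultivated")) "cultivated_only"
      else "wild_only"
    s <- unname(slab[cs])
    s <- unique(s[s %in% c("indica", "japonica")])
    sl <- if (length(s) == 2) "shared"
      else if (identical(s, "indica")) "indica_only"
      else if (identical(s, "japonica")) "japonica_only"
      else "neither"
    c(gl, sl)
  })
  ev <- data.frame(event_id = events$event_id,
                   group_sharing = vapply(lab, `[`, character(1), 1),
                   subgroup_sharing = vapply(lab, `[`, character(1), 2))
  gf <- prop.table(table(factor(ev$group_sharing,
                                levels = c("shared", "cultivated_only",
                                           "wild_only"))))
  sub <- ev$subgroup_sharing[ev$subgroup_sharing != "neither"]
  sf <- if (length(sub)) {
    prop.table(table(factor(sub, levels = c("shared", "indica_only",
                                            "japonica_only"))))
  } else {
    table(factor(character(0), levels = c("shared", "indica_only",
                                          "japonica_only")))
  }
  list(events = ev, group_fractions = gf, subgroup_fractions = sf)
}

#' Hypergeometric term enrichment with BH-FDR correction
#'
#' For each term with at least one annotated gene in the universe, the
#' upper-tail hypergeometric probability of observing `k` or more study
#' hits is computed (`phyper`), then adjusted across tested terms with
#' Benjamini-Hochberg.
#'
#' @param study_genes Character vector (must be a subset of `universe`).
#' @param term_map Data frame (`gene_id`, `term_id`).
#' @param universe Character vector of all genes.
#' @param alpha Significance threshold recorded in the output.
#' @return Data frame: `term_id`, `k`, `n`, `K`, `N`, `p_value`, `fdr`,
#'   `significant`, sorted by p-value.
#' @export
hypergeom_enrichment <- function(study_genes, term_map, universe,
                                 alpha = 0.05) {
  bad <- setdiff(study_genes, universe)
  if (length(bad)) {
    stop("input error: study genes not in universe: ",
         paste(bad, collapse = ", "))
  }
  term_map <- term_map[term_map$gene_id %in% universe, , drop = FALSE]
  N <- length(unique(universe))
  n <- length(unique(study_genes))
  terms <- unique(term_map$term_id)
  rows <- lapply(terms, function(tm) {
    tg <- unique(term_map$gene_id[term_map$term_id == tm])
    K <- length(tg)
    if (K == 0) return(NULL)
    k <- length(intersect(tg, study_genes))
    p <- phyper(k - 1, K, N - K, n, lower.tail = FALSE)
    data.frame(term_id = tm, k = k, n = n, K = K, N = N, p_value = p)
  })
  out <- do.call(rbind, rows)
  if (is.null(out)) {
    return(data.frame(term_id = character(0), k = integer(0),
                      n = integer(0), K = integer(0), N = integer(0),
                      p_value = numeric(0), fdr = numeric(0),
                      significant = logical(0)))
  }
  out$fdr <- p.adjust(out$p_value, method = "BH")
  out$significant <- out$fdr < alpha
  out <- out[order(out$p_value, out$term_id), ]
  rownames(out) <- NULL
  out
}
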