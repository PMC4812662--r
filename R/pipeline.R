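#' Run the full CNV analysis pipeline on a synthetic study
#'
#' Stages, in fixed order: simulate (generator + caller emulation), merge
#' (three-step integration), polarize (outgroup projection + alignment),
#' mechanism (junction signatures), impact (gene categories, population
#' sharing, enrichment), noncolinear (CNV-gene origin), report.  Every
#' stage writes its table under `out_dir` before the next starts, and the
#' whole run is deterministic in `config$seed`.
#'
#' @param config A [sim_config()].
#' @param out_dir Output directory; stage outputs and the report are
#'   written there.
#' @param merge_p,pol_p,mech_p,nc_p Stage parameter lists.
#' @param run_noncolinear Whether to run the (alignment-heavy)
#'   non-co-linear stage.
#' @return List with all stage outputs and the `report`.
#' @export
run_pipeline <- function(config, out_dir,
                         merge_p = merge_params(),
                         pol_p = polarize_params(),
                         mech_p = mechanism_params(),
                         nc_p = noncolinear_params(),
                         run_noncolinear = TRUE) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  marker <- file.path(out_dir, "INCOMPLETE")
  file.create(marker)

  stage <- function(name, expr) {
    t0 <- Sys.time()
    res <- tryCatch(force(expr), error = function(e) {
      stop("stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE)
    })
    message(sprintf("[cnvpol] %-12s %6.1fs", name,
                    as.numeric(difftime(Sys.time(), t0, units = "secs"))))
    res
  }

  study <- stage("simulate", {
    s <- simulate_cnv_study(config)
    write_study(s, out_dir)
    s
  })
  consensus <- stage("merge", {
    cs <- merge_callsets(study$calls, merge_p)
    stopifnot(all(cs$n_accessions >= merge_p$min_accessions))
    write_tsv(cs, file.path(out_dir, "consensus.tsv"))
    write_consensus_vcf(cs, file.path(out_dir, "consensus.vcf"),
                        study$pack$seqs)
    cs
  })
  blocks <- build_blocks(study$outgroup$anchors)
  polarized <- stage("polarize", {
    p <- polarize_cnvs(consensus, study$pack$seqs, study$outgroup$seqs,
                       study$outgroup$gaps, blocks, pol_p)
    write_tsv(p, file.path(out_dir, "polarized.tsv"))
    p
  })
  mech <- stage("mechanism", {
    m <- classify_mechanisms(
      polarized[, c("event_id", "chrom", "start", "end", "precise")],
      study$pack$seqs, study$pack$te, study$pack$vntr, mech_p)
    write_tsv(m, file.path(out_dir, "mechanisms.tsv"))
    ms <- summarize_mechanisms(m, polarized)
    write_tsv(ms$distribution,
              file.path(out_dir, "mechanism_distribution.tsv"))
    m
  })
  impact <- stage("impact", {
    im <- classify_gene_impact(polarized, study$pack$genes,
                               study$pack$gene_features)
    write_tsv(im$impacts, file.path(out_dir, "gene_impact.tsv"))
    sh <- population_sharing(polarized, study$groups)
    write_tsv(sh$events, file.path(out_dir, "sharing.tsv"))
    terms <- read_tsv(file.path(out_dir, "terms.tsv"))
    enr <- if (nrow(terms) > 0 && length(unique(im$impacts$gene_id)) > 0) {
      hypergeom_enrichment(unique(im$impacts$gene_id), terms,
                           study$pack$genes$gene_id)
    } else NULL
    if (!is.null(enr)) write_tsv(enr, file.path(out_dir, "enrichment.tsv"))
    list(impact = im, sharing = sh, enrichment = enr)
  })
  nc <- if (run_noncolinear) stage("noncolinear", {
    ids <- unique(impact$impact$impacts$gene_id)
    n <- noncolinear_genes(ids, study$pack$genes, study$pack$gene_features,
                           blocks, study$pack$seqs, study$outgroup$seqs,
                           study$pack$te, nc_p, mech_p)
    write_tsv(n, file.path(out_dir, "noncolinear.tsv"))
    n
  }) else NULL
  report <- stage("report", write_report(out_dir))

  file.remove(marker)
  list(study = study, consensus = consensus, polarized = polarized,
       mechanisms = mech, impact = impact$impact,
       sharing = impact$sharing, enrichment = impact$enrichment,
       noncolinear = nc, report = report, out_dir = out_dir)
}

#' Re-derive the summary report from the stage files
#'
#' Every reported number is recomputed from the stage TSVs at report
#' time; nothing is cached.  Writes `report.json` and a human-readable
#' `report.txt` under `dir` and returns the report list.
#'
#' @param dir Pipeline output directory.
#' @export
write_report <- function(dir) {
  for (f in c("consensus.tsv", "polarized.tsv", "mechanisms.tsv")) {
    if (!file.exists(file.path(dir, f))) {
      stop("integrity error: missing stage file ", file.path(dir, f))
    }
  }
  consensus <- read_tsv(file.path(dir, "consensus.tsv"))
  polarized <- read_tsv(file.path(dir, "polarized.tsv"))
  mech <- read_tsv(file.path(dir, "mechanisms.tsv"))
  if (nrow(consensus) != nrow(polarized) ||
      (nrow(mech) > 0 && !setequal(mech$event_id, consensus$event_id))) {
    orphans <- union(setdiff(mech$event_id, consensus$event_id),
                     setdiff(consensus$event_id, polarized$event_id))
    stop("integrity error: stage files disagree on events: ",
         paste(head(orphans, 5), collapse = ", "))
  }
  sizes <- consensus$end - consensus$start
  pol_tab <- table(factor(polarized$ancestral_state,
                          levels = c("insertion", "deletion", "undefined")))
  mech_split <- if (nrow(mech) > 0) {
    m2 <- merge(mech[, c("event_id", "mechanism")],
                consensus[, c("event_id", "chrom", "start", "end")],
                by = "event_id")
    split(m2, m2$mechanism)
  } else list()
  mech_tab <- lapply(mech_split, function(g)
    list(n = nrow(g), cumulative_bp = sum(g$end - g$start)))

  impact_path <- file.path(dir, "gene_impact.tsv")
  impacts <- if (file.exists(impact_path)) read_tsv(impact_path) else NULL
  sharing_path <- file.path(dir, "sharing.tsv")
  sharing <- if (file.exists(sharing_path)) read_tsv(sharing_path) else NULL

  report <- list(
    n_events = nrow(consensus),
    size = if (nrow(consensus) > 0) list(
      mean = mean(sizes), median = median(sizes),
      min = min(sizes), max = max(sizes)) else
        list(mean = 0, median = 0, min = 0, max = 0),
    precise_fraction = if (nrow(consensus) > 0) mean(consensus$precise)
                       else 0,
    polarity = list(counts = as.list(pol_tab),
                    fractions = as.list(
                      if (sum(pol_tab) > 0) pol_tab / sum(pol_tab)
                      else pol_tab)),
    mechanisms = mech_tab,
    gene_impact = if (!is.null(impacts) && nrow(impacts) > 0) {
      prec <- c(full = 1, partial_cds = 2, utr_only = 3, intron_only = 4)
      best <- vapply(split(impacts$category, impacts$gene_id),
                     function(cs) names(prec)[min(prec[cs])], character(1))
      c(as.list(table(factor(best, levels = names(prec)))),
        list(n_genes = length(best),
             n_cnvs_overlapping_genes = length(unique(impacts$event_id))))
    } else list(n_genes = 0, n_cnvs_overlapping_genes = 0),
    sharing = if (!is.null(sharing) && nrow(sharing) > 0) {
      as.list(prop.table(table(sharing$group_sharing)))
    } else list()
  )
  jsonlite::write_json(report, file.path(dir, "report.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)

  txt <- c(
    sprintf("CNV catalog: %d events", report$n_events),
    sprintf("  size mean %.1f / median %.1f / min %d / max %d bp",
            report$size$mean, report$size$median, report$size$min,
            report$size$max),
    sprintf("  single-nucleotide breakpoints: %.1f%% (%d/%d)",
            100 * report$precise_fraction,
            sum(consensus$precise), nrow(consensus)),
    "Polarity (vs. outgroup):",
    sprintf("  %-10s %5d (%.1f%%, %d/%d)", names(pol_tab), as.integer(pol_tab),
            100 * as.integer(pol_tab) / max(1, sum(pol_tab)),
            as.integer(pol_tab), sum(pol_tab)),
    "Mechanisms:",
    if (length(mech_tab)) sprintf("  %-10s %5d events, %d bp cumulative",
                                  names(mech_tab),
                                  vapply(mech_tab, `[[`, numeric(1), "n"),
                                  vapply(mech_tab, `[[`, numeric(1),
                                         "cumulative_bp"))
    else "  (none)",
    sprintf("Genes affected: %d (CNVs overlapping genes: %d)",
            report$gene_impact$n_genes,
            report$gene_impact$n_cnvs_overlapping_genes))
  writeLines(txt, file.path(dir, "report.txt"))
  report
}
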