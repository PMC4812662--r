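mk_gene <- function(gid, chrom, start, exons, u5 = 50L, u3 = 50L) {
  ## exons: list of c(start, end) relative offsets
  ex <- do.call(rbind, exons)
  ex <- data.frame(start = start + ex[, 1], end = start + ex[, 2])
  feats <- data.frame(gene_id = gid, type = "exon", chrom = chrom,
                      start = ex$start, end = ex$end)
  cds <- ex
  cds$start[1] <- cds$start[1] + u5
  cds$end[nrow(cds)] <- cds$end[nrow(cds)] - u3
  feats <- rbind(
    feats,
    data.frame(gene_id = gid, type = "CDS", chrom = chrom,
               start = cds$start, end = cds$end),
    data.frame(gene_id = gid, type = "five_prime_UTR", chrom = chrom,
               start = ex$start[1], end = ex$start[1] + u5),
    data.frame(gene_id = gid, type = "three_prime_UTR", chrom = chrom,
               start = ex$end[nrow(ex)] - u3, end = ex$end[nrow(ex)]))
  list(gene = data.frame(gene_id = gid, chrom = chrom, start = ex$start[1],
                         end = ex$end[nrow(ex)], strand = "+"),
       feats = feats)
}

test_that("gene-impact categories follow the precedence rule", {
  g <- mk_gene("gA", "chr1", 1000L,
               list(c(0L, 300L), c(500L, 800L), c(1500L, 1800L)))
  events <- data.frame(
    event_id = c("full", "cds", "utr", "intron"),
    chrom = "chr1",
    start = c(0L, 1550L, 1010L, 2350L),
    end = c(5000L, 1650L, 1040L, 2450L))
  res <- classify_gene_impact(events, g$gene, g$feats)
  got <- setNames(res$impacts$category, res$impacts$event_id)
  expect_equal(got[["full"]], "full")
  expect_equal(got[["cds"]], "partial_cds")
  expect_equal(got[["utr"]], "utr_only")
  expect_equal(got[["intron"]], "intron_only")
  ## the gene counts once, at its best category
  expect_equal(res$summary$n_genes, 1L)
  expect_equal(unname(res$summary$genes_per_category["full"]), 1L,
               ignore_attr = TRUE)

  bad_feats <- g$feats
  bad_feats$start[bad_feats$type == "CDS"][1] <- 100L  # CDS outside exons
  expect_error(classify_gene_impact(events, g$gene, bad_feats), "gA")
})

test_that("interval gene-impact logic equals the per-base oracle", {
  run <- noise_free_run()
  study <- run$study
  genes <- study$pack$genes
  feats <- study$pack$gene_features
  events <- run$pol[, c("event_id", "chrom", "start", "end")]
  res <- classify_gene_impact(events, genes, feats)
  expect_gt(nrow(res$impacts), 0)

  oracle_category <- function(gene, ev) {
    gf <- feats[feats$gene_id == gene$gene_id, ]
    span <- (gene$start + 1):gene$end
    in_ev <- function(p) p > ev$start & p <= ev$end
    covers_gene <- all(in_ev(span))
    base_in <- function(ty) {
      f <- gf[gf$type %in% ty, ]
      if (nrow(f) == 0) return(FALSE)
      pos <- unlist(lapply(seq_len(nrow(f)),
                           function(i) (f$start[i] + 1):f$end[i]))
      any(in_ev(pos))
    }
    if (covers_gene) "full"
    else if (base_in("CDS")) "partial_cds"
    else if (base_in(c("five_prime_UTR", "three_prime_UTR"))) "utr_only"
    else "intron_only"
  }
  for (i in seq_len(nrow(res$impacts))) {
    rec <- res$impacts[i, ]
    gene <- genes[genes$gene_id == rec$gene_id, ]
    ev <- events[events$event_id == rec$event_id, ]
    expect_equal(rec$category, oracle_category(gene, ev))
  }
  ## CDS-disruption identity: full + partial equals genes with CDS hit
  expect_equal(res$summary$n_cds_disrupted,
               sum(res$summary$genes_per_category[c("full", "partial_cds")]),
               ignore_attr = TRUE)
})

test_that("population sharing labels and fractions behave", {
  groups <- data.frame(
    accession = c("a1", "a2", "a3", "w1", "w2"),
    group = c("cultivated", "cultivated", "cultivated", "wild", "wild"),
    subgroup = c("indica", "japonica", "other", "other", "other"))
  events <- data.frame(event_id = c("e1", "e2", "e3"),
                       carriers = c("a1,a2,w1", "a1,a3", "w1,w2"))
  sh <- population_sharing(events, groups)
  expect_equal(sh$events$group_sharing,
               c("shared", "cultivated_only", "wild_only"))
  expect_equal(sum(sh$group_fractions), 1)
  expect_equal(sh$events$subgroup_sharing, c("shared", "indica_only",
                                             "neither"))
  expect_equal(sum(sh$subgroup_fractions), 1)
  expect_error(population_sharing(
    data.frame(event_id = "x", carriers = "zz"), groups), "zz")
})

test_that("wild-only events are rare when wild accessions are few", {
  ## 40 cultivated + 10 wild, 5 carriers drawn uniformly: the chance all
  ## five are wild is (10/50)^5 = 3.2e-4, so < 1% wild-only events
  groups <- data.frame(
    accession = sprintf("s%02d", 1:50),
    group = rep(c("cultivated", "wild"), c(40, 10)),
    subgroup = "other")
  set.seed(17)
  carriers <- replicate(500, paste(sample(groups$accession, 5),
                                   collapse = ","))
  sh <- population_sharing(data.frame(event_id = sprintf("e%03d", 1:500),
                                      carriers = carriers), groups)
  expect_lt(unname(sh$group_fractions["wild_only"]), 0.01)
  expect_equal((1 - 40 / 50)^5, 3.2e-4)
})

test_that("hypergeometric enrichment matches exhaustive enumeration", {
  ## N=10, K=4, n=5, k=4: enumerate all C(10,5) draws
  universe <- sprintf("g%02d", 1:10)
  annotated <- universe[1:4]
  study <- universe[1:5]          # contains all 4 annotated genes
  draws <- combn(10, 5)
  tail_prob <- mean(apply(draws, 2, function(d) sum(d <= 4) >= 4))
  expect_equal(tail_prob, 6 / 252)

  tm <- data.frame(gene_id = annotated, term_id = "T1")
  res <- hypergeom_enrichment(study, tm, universe)
  expect_equal(res$p_value, 6 / 252)

  ## k = 0 gives the whole sample space
  tm2 <- data.frame(gene_id = universe[6:9], term_id = "T2")
  res2 <- hypergeom_enrichment(universe[1:5], tm2, universe)
  expect_equal(res2$p_value, 1)

  expect_error(hypergeom_enrichment(c("nope"), tm, universe),
               "input error")
})

test_that("null calibration and BH monotonicity hold", {
  ## design chosen so the discrete tail crossing sits near 0.05:
  ## N=200, K=20, n=100 gives P(p < 0.05) = 0.0485 exactly
  set.seed(31)
  universe <- sprintf("g%03d", 1:200)
  tm <- do.call(rbind, lapply(1:10, function(i)
    data.frame(gene_id = sample(universe, 20),
               term_id = sprintf("T%02d", i))))
  ps <- replicate(1000, {
    study <- sample(universe, 100)
    r <- hypergeom_enrichment(study, tm, universe)
    sample(r$p_value, 1)
  })
  expect_lt(abs(mean(ps < 0.05) - 0.05), 0.02)

  r <- hypergeom_enrichment(sample(universe, 100), tm, universe)
  expect_true(all(diff(r$fdr[order(r$p_value)]) >= -1e-12))
  expect_true(all(r$fdr >= r$p_value - 1e-12))
})
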