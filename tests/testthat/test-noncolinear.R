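test_that("anchored genes are co-linear, duplicated copies are not", {
  run <- dup_run()
  study <- run$study
  ## genes that anchor the blocks project onto themselves; block-edge
  ## anchors are excluded (nothing flanks them to interpolate from)
  a <- study$outgroup$anchors
  interior <- unlist(lapply(split(a, a$ref_chrom), function(ac) {
    ac <- ac[order(ac$ref_start), ]
    ac$gene_id[3:(nrow(ac) - 2)]
  }))
  set.seed(12)
  for (g in sample(interior, 6)) {
    gene <- study$pack$genes[study$pack$genes$gene_id == g, ]
    expect_true(is_colinear(gene, study$pack$gene_features, run$blocks,
                            study$pack$seqs, study$outgroup$seqs))
  }
  ## every duplicated copy sits inside an insertion-state region
  dupg <- study$truth$dup_gene[study$truth$mechanism == "DUP"]
  for (g in sample(dupg, 6)) {
    gene <- study$pack$genes[study$pack$genes$gene_id == g, ]
    expect_false(is_colinear(gene, study$pack$gene_features, run$blocks,
                             study$pack$seqs, study$outgroup$seqs))
  }
})

test_that("is_colinear does not depend on block row order", {
  run <- dup_run()
  study <- run$study
  gene <- study$pack$genes[study$pack$genes$gene_id ==
                             study$outgroup$anchors$gene_id[10], ]
  set.seed(4)
  shuffled <- run$blocks[sample.int(nrow(run$blocks)), ]
  expect_identical(
    is_colinear(gene, study$pack$gene_features, run$blocks,
                study$pack$seqs, study$outgroup$seqs),
    is_colinear(gene, study$pack$gene_features, shuffled,
                study$pack$seqs, study$outgroup$seqs))
})

test_that("ancestral-copy search finds implanted duplicates and only them", {
  run <- dup_run()
  study <- run$study
  dup <- study$truth[study$truth$mechanism == "DUP", ]
  set.seed(8)
  for (i in sample(nrow(dup), 8)) {
    d <- dup[i, ]
    gene <- study$pack$genes[study$pack$genes$gene_id == d$dup_gene, ]
    hit <- find_ancestral_copy(gene, study$pack$seqs)
    expect_true(hit$found)
    ## ~1.5% divergence between the copies
    expect_gte(hit$identity, 0.9)
    src <- study$pack$genes[study$pack$genes$gene_id ==
                              d$dup_source_gene, ]
    expect_equal(hit$chrom, src$chrom)
    expect_lt(abs(hit$start - src$start), 200)
    ## self-hit exclusion
    expect_false(hit$chrom == gene$chrom && hit$start < gene$end &&
                   hit$end > gene$start)
  }

  ## a unique gene has no non-self hit
  uniq <- setdiff(study$pack$genes$gene_id,
                  c(dup$dup_gene, dup$dup_source_gene))
  gene <- study$pack$genes[study$pack$genes$gene_id == uniq[3], ]
  expect_false(find_ancestral_copy(gene, study$pack$seqs)$found)

  ## short genes are refused with a reason
  tiny <- gene; tiny$end <- tiny$start + 150L
  expect_equal(find_ancestral_copy(tiny, study$pack$seqs)$reason,
               "gene_too_short")
})

test_that("an exact tandem duplicate is found at identity 1", {
  set.seed(44)
  gene_seq <- random_seq(600)
  chr <- paste0(random_seq(2000), gene_seq, random_seq(1500), gene_seq,
                random_seq(2000))
  seqs <- list(chr1 = chr)
  gene <- data.frame(gene_id = "gX", chrom = "chr1", start = 2000L,
                     end = 2600L, strand = "+")
  hit <- find_ancestral_copy(gene, seqs)
  expect_true(hit$found)
  expect_equal(hit$identity, 1.0)
  expect_equal(hit$start, 2000L + 600L + 1500L)
})

test_that("duplication origins are recovered per class", {
  run <- dup_run()
  study <- run$study
  dupg <- study$truth$dup_gene[study$truth$mechanism == "DUP"]
  nc <- noncolinear_genes(dupg, study$pack$genes,
                          study$pack$gene_features, run$blocks,
                          study$pack$seqs, study$outgroup$seqs,
                          study$pack$te)
  eo <- evaluate_origins(nc, study$truth)
  expect_setequal(names(eo$per_class), c("TE", "NHEJ", "NAHR"))
  expect_true(all(eo$per_class >= 0.9))
  expect_equal(eo$noncolinear_rate, 1.0)
})
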