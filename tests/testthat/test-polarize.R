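mk_anchor <- function(gene_id, ref_chrom, ref_mid, out_chrom, out_mid,
                      strand = "+") {
  data.frame(gene_id = gene_id, ref_chrom = ref_chrom,
             ref_start = ref_mid - 1L, ref_end = ref_mid + 1L,
             out_chrom = out_chrom, out_start = out_mid - 1L,
             out_end = out_mid + 1L, strand = strand)
}

test_that("anchor chaining builds and splits blocks correctly", {
  a <- do.call(rbind, lapply(1:10, function(i)
    mk_anchor(paste0("g", i), "chr1", i * 10000L, "chr1", i * 11000L)))
  b <- build_blocks(a)
  expect_equal(length(unique(b$block_id)), 1L)
  expect_equal(nrow(b), 10L)

  ## the 6th anchor maps to another outgroup chromosome: 5 + 1 + 4, the
  ## singleton dropped at min_anchors = 2
  a2 <- a
  a2$out_chrom[6] <- "chr9"
  b2 <- build_blocks(a2)
  expect_equal(as.vector(table(b2$block_id)), c(5L, 4L))
  expect_false("g6" %in% b2$gene_id)

  expect_equal(nrow(build_blocks(a[0, ])), 0L)
  expect_error(build_blocks(rbind(a, a[1, ])), "duplicate gene_id")
})

test_that("projection interpolates linearly between anchor midpoints", {
  a <- rbind(mk_anchor("g1", "chr1", 10000L, "chr1", 12000L),
             mk_anchor("g2", "chr1", 20000L, "chr1", 23000L))
  b <- build_blocks(a)
  pr <- project_to_outgroup("chr1", 14000L, 16000L, b)
  expect_true(pr$ok)
  expect_equal(pr$out_start, 16400L)  # 12000 + 4000 * 1.1
  expect_equal(pr$out_end, 18600L)

  ## outside all blocks / unknown chromosome
  expect_false(project_to_outgroup("chr1", 100L, 200L, b)$ok)
  expect_false(project_to_outgroup("chr7", 14000L, 16000L, b)$ok)

  ## spanning a block boundary
  a3 <- rbind(a, mk_anchor("g3", "chr1", 30000L, "chr5", 1000L),
              mk_anchor("g4", "chr1", 40000L, "chr5", 11000L))
  b3 <- build_blocks(a3)
  pr3 <- project_to_outgroup("chr1", 19000L, 31000L, b3)
  expect_false(pr3$ok)
  expect_equal(pr3$reason, "spans_block_boundary")
})

test_that("strand-negative blocks project with reversed orientation", {
  a <- rbind(mk_anchor("g1", "chr1", 10000L, "chr1", 50000L, "-"),
             mk_anchor("g2", "chr1", 20000L, "chr1", 40000L, "-"))
  b <- build_blocks(a)
  pr <- project_to_outgroup("chr1", 14000L, 16000L, b)
  expect_true(pr$ok)
  expect_equal(pr$strand, "-")
  expect_equal(pr$out_start, 44000L)
  expect_equal(pr$out_end, 46000L)
})

test_that("projected windows contain the orthologous sequence", {
  run <- noise_free_run()
  study <- run$study
  set.seed(21)
  idx <- sample(nrow(run$cons), 50)
  for (i in idx) {
    cv <- run$cons[i, ]
    pr <- project_to_outgroup(cv$chrom, cv$start, cv$end, run$blocks)
    if (!pr$ok) next
    true_s <- map_ref_to_outgroup(study$outgroup, cv$chrom, cv$start)
    true_e <- map_ref_to_outgroup(study$outgroup, cv$chrom, cv$end)
    slack <- (if (is.null(pr$uncertainty)) 0 else pr$uncertainty) + 5
    expect_lte(abs(pr$out_start - true_s), slack)
    expect_lte(abs(pr$out_end - true_e), slack)
  }
})

test_that("polarity recovery is exact in the noise-free regime", {
  run <- noise_free_run()
  pe <- evaluate_polarity(run$pol, run$study$truth, run$ev$matches)
  expect_equal(pe$accuracy_gap_free, 1.0)
  ## trichotomy
  expect_true(all(run$pol$ancestral_state %in%
                    c("insertion", "deletion", "undefined")))
})

test_that("gap placement is superset-monotone in the gap rate", {
  base <- list(seed = 55L, n_chromosomes = 1L, chrom_length = 120000L,
               n_genes = 10L, n_te_copies = 4L, n_vntr_arrays = 4L,
               events_per_mechanism = c(NHR = 4L),
               outgroup_divergence = 0.01)
  gaps_at <- function(rate) {
    cfg <- do.call(sim_config, c(base, list(outgroup_gap_rate = rate)))
    pack <- simulate_reference(cfg)
    imp <- implant_events(pack, cfg)
    mutate_outgroup(imp$pack, imp$truth, cfg)
  }
  o1 <- gaps_at(0.5); o2 <- gaps_at(2); o3 <- gaps_at(5)
  key <- function(og) paste(og$gaps$chrom, og$gaps$start, og$gaps$end)
  expect_true(all(key(o1) %in% key(o2)))
  expect_true(all(key(o2) %in% key(o3)))
  ## recorded per-event gap overlap is monotone, hence so is the
  ## undefined count under the >10% rule
  expect_true(all(o2$truth$gap_overlap_frac >=
                    o1$truth$gap_overlap_frac - 1e-12))
  expect_true(all(o3$truth$gap_overlap_frac >=
                    o2$truth$gap_overlap_frac - 1e-12))
})

test_that("estimated insertion share tracks the simulated fraction", {
  ## light-weight check at one non-default fraction; the full sweep over
  ## 0.2/0.5/0.8 runs in the acceptance suite
  cfg <- sim_config_noise_free(seed = 404L, insertion_fraction = 0.5)
  study <- simulate_cnv_study(cfg)
  cons <- merge_callsets(study$calls)
  ev <- evaluate_merge(cons, study$truth)
  blocks <- build_blocks(study$outgroup$anchors)
  pol <- polarize_cnvs(cons, study$pack$seqs, study$outgroup$seqs,
                       study$outgroup$gaps, blocks)
  pe <- evaluate_polarity(pol, study$truth, ev$matches)
  se <- sqrt(0.5 * 0.5 / pe$n_defined)
  expect_lte(abs(pe$insertion_share - 0.5), 3 * se)
})
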