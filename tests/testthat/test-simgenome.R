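test_that("reference simulation respects lengths, determinism and GC", {
  cfg <- sim_config(seed = 42L, n_chromosomes = 2L, chrom_length = 100000L,
                    n_genes = 10L, n_te_copies = 6L, n_vntr_arrays = 6L,
                    events_per_mechanism = c(NHR = 4L))
  p1 <- simulate_reference(cfg)
  expect_identical(unname(nchar(p1$seqs)), c(100000L, 100000L))
  p2 <- simulate_reference(cfg)
  expect_identical(p1$seqs, p2$seqs)
  expect_identical(p1$te, p2$te)
  expect_identical(p1$genes, p2$genes)

  ## GC of non-feature background
  feats <- rbind(p1$te[, c("chrom", "start", "end")],
                 p1$vntr[, c("chrom", "start", "end")])
  s <- p1$seqs[["chr1"]]
  mask <- rep(TRUE, nchar(s))
  f1 <- feats[feats$chrom == "chr1", ]
  for (i in seq_len(nrow(f1))) mask[(f1$start[i] + 1):f1$end[i]] <- FALSE
  x <- strsplit(s, "", fixed = TRUE)[[1]][mask]
  gc <- mean(x %in% c("G", "C"))
  expect_lt(abs(gc - cfg$gc_content), 0.01)
})

test_that("annotated features have the promised structure", {
  run <- noise_free_run()
  pack <- run$study$pack
  ## TE copies at least 80% identical to their family consensus
  idx <- sample(seq_len(nrow(pack$te)), 10)
  for (i in idx) {
    tei <- pack$te[i, ]
    body <- substr(pack$seqs[[tei$chrom]], tei$start + 1, tei$end)
    cons <- pack$te_library[[tei$family]]
    L <- min(nchar(body), nchar(cons))
    a <- strsplit(body, "")[[1]][1:L]
    b <- strsplit(cons, "")[[1]][1:L]
    expect_gte(mean(a == b), 0.8)
  }
  ## tandem arrays: period in range, >= 3 copies
  expect_true(all(pack$vntr$period >= 2 & pack$vntr$period <= 100))
  expect_true(all(pack$vntr$copies >= 3))
  ## gene models: exons non-overlapping within a gene, CDS within exons
  for (gid in sample(pack$genes$gene_id, 10)) {
    gf <- pack$gene_features[pack$gene_features$gene_id == gid, ]
    ex <- gf[gf$type == "exon", ]
    ex <- ex[order(ex$start), ]
    if (nrow(ex) > 1) expect_true(all(diff(ex$start) > 0) &&
                                    all(ex$end[-nrow(ex)] <= ex$start[-1]))
    cds <- gf[gf$type == "CDS", ]
    expect_true(all(cds$start < cds$end))
    exr <- IRanges::reduce(IRanges::IRanges(ex$start + 1L, ex$end))
    cdr <- IRanges::IRanges(cds$start + 1L, cds$end)
    expect_equal(sum(IRanges::width(IRanges::setdiff(cdr, exr))), 0L)
  }
})

test_that("invalid configuration is rejected naming the field", {
  expect_error(sim_config(chrom_length = 10000L), "chrom_length")
  expect_error(sim_config(gc_content = 1.5), "gc_content")
  expect_error(sim_config(outgroup_divergence = 0.5), "outgroup_divergence")
  expect_error(sim_config(events_per_mechanism = c(FOO = 3L)),
               "events_per_mechanism")
})

test_that("implanted events carry recoverable mechanism signatures", {
  run <- noise_free_run()
  truth <- run$study$truth
  pack <- run$study$pack
  cfg <- run$study$config
  expect_equal(nrow(truth), sum(cfg$events_per_mechanism))
  expect_equal(unname(table(truth$mechanism)[names(cfg$events_per_mechanism)]),
               unname(cfg$events_per_mechanism),
               ignore_attr = TRUE)
  expect_true(all(truth$ref_end - truth$ref_start >= 50))
  expect_true(all(nchar(truth$carriers) > 0))

  mei <- truth[truth$mechanism == "MEI", ]
  for (i in sample(seq_len(nrow(mei)), 10)) {
    tc <- te_coverage(mei$chrom[i], mei$ref_start[i], mei$ref_end[i],
                      pack$te)
    expect_gte(tc$fraction, 0.9)
    expect_equal(tc$family, mei$te_family[i])
  }
  nhr <- truth[truth$mechanism == "NHR", ]
  for (i in sample(seq_len(nrow(nhr)), 10)) {
    mh <- junction_microhomology(pack$seqs[[nhr$chrom[i]]],
                                 nhr$ref_start[i], nhr$ref_end[i])
    expect_lte(mh$total, 10)
    expect_equal(mh$total, nhr$microhomology_len[i])
  }
  nahr <- truth[truth$mechanism == "NAHR", ]
  for (i in sample(seq_len(nrow(nahr)), 10)) {
    fh <- flanking_homology(pack$seqs[[nahr$chrom[i]]],
                            nahr$ref_start[i], nahr$ref_end[i])
    expect_gte(fh$homology_len, 95)
    expect_gte(fh$identity, 0.9)
  }
  vntr <- truth[truth$mechanism == "VNTR", ]
  expect_true(all((vntr$ref_end - vntr$ref_start) %% vntr$vntr_period == 0))
})

test_that("events do not overlap and keep 1 kb separation", {
  truth <- noise_free_run()$study$truth
  for (ch in unique(truth$chrom)) {
    tt <- truth[truth$chrom == ch, ]
    tt <- tt[order(tt$ref_start), ]
    if (nrow(tt) > 1) {
      expect_true(all(tt$ref_start[-1] - tt$ref_end[-nrow(tt)] >= 1000))
    }
  }
})

test_that("outgroup equals the ancestral haplotype at zero divergence", {
  run <- noise_free_run()
  og <- run$study$outgroup
  expect_identical(og$seqs, og$ancestor)
  truth <- run$study$truth
  out <- og$seqs
  idx <- sample(seq_len(nrow(truth)), 30)
  for (i in idx) {
    ev <- truth[i, ]
    evseq <- substr(run$study$pack$seqs[[ev$chrom]], ev$ref_start + 1,
                    ev$ref_end)
    present <- grepl(evseq, out[[ev$chrom]], fixed = TRUE)
    if (ev$ancestral_state == "deletion") {
      expect_true(present)
    } else if (ev$mechanism != "VNTR") {
      ## a VNTR insertion's periodic sequence partially persists in the
      ## ancestor's residual copies; full-length containment must fail
      expect_false(present)
    }
  }
})

test_that("outgroup divergence produces the expected identity", {
  cfg <- sim_config(seed = 77L, n_chromosomes = 1L, chrom_length = 120000L,
                    n_genes = 10L, n_te_copies = 4L, n_vntr_arrays = 4L,
                    events_per_mechanism = c(NHR = 3L),
                    outgroup_divergence = 0.02, outgroup_indel_rate = 0,
                    outgroup_gap_rate = 0)
  pack <- simulate_reference(cfg)
  imp <- implant_events(pack, cfg)
  og <- mutate_outgroup(imp$pack, imp$truth, cfg)
  ids <- numeric(0)
  set.seed(9)
  for (rep in 1:10) {
    p <- sample(5000:100000, 1)
    ## skip windows touching an excised interval
    rem <- og$maps[["chr1"]]$rem
    if (any(rem$start < p + 1000 & rem$end > p)) next
    o <- map_ref_to_outgroup(og, "chr1", p)
    a <- substr(imp$pack$seqs[["chr1"]], p + 1, p + 1000)
    b <- substr(og$seqs[["chr1"]], o + 1, o + 1000)
    ids <- c(ids, mean(strsplit(a, "")[[1]] == strsplit(b, "")[[1]]))
  }
  expect_gte(length(ids), 5)
  expect_lt(abs(mean(ids) - 0.98), 0.005)
})

test_that("caller emulation hits the configured sensitivity", {
  run <- noise_free_run()
  truth <- run$study$truth
  cfg <- run$study$config
  calls <- run$study$calls
  ## noise-free limit: truth x carriers x 3 callers, SR/PE breakpoints exact
  n_carriers <- sum(lengths(strsplit(truth$carriers, ",")))
  expect_equal(nrow(calls), 3L * n_carriers)
  sr <- calls[calls$caller %in% c("SR", "PE"), ]
  key <- paste(truth$chrom, truth$ref_start, truth$ref_end)
  expect_true(all(paste(sr$chrom, sr$start, sr$end) %in% key))

  ## zero sensitivity gives empty call sets
  cfg0 <- sim_config(seed = 5L,
                     caller_sensitivity = caller_sensitivity_matrix(0,
                                                        biased = FALSE),
                     false_call_rate = 0)
  calls0 <- emit_callsets(truth, cfg0, c(chr1 = 1000000L, chr2 = 1000000L))
  expect_equal(nrow(calls0), 0L)

  ## binomial emission count at sensitivity 0.9
  t30 <- truth[1:30, ]
  t30$carriers <- paste(sprintf("acc%02d", 1:10), collapse = ",")
  cfg9 <- sim_config(seed = 31L,
                     caller_sensitivity = caller_sensitivity_matrix(0.9,
                                                        biased = FALSE),
                     breakpoint_jitter_sd = c(PE = 0, SR = 0, RD = 0),
                     false_call_rate = 0)
  calls9 <- emit_callsets(t30, cfg9, c(chr1 = 1000000L, chr2 = 1000000L))
  ## 30 events x 10 carriers x 3 callers = 900 trials at p = 0.9
  expect_lt(abs(nrow(calls9) - 810), 3 * sqrt(900 * 0.9 * 0.1))
})

test_that("the whole study generator is deterministic in the seed", {
  cfg <- sim_config(seed = 88L, n_chromosomes = 1L, chrom_length = 100000L,
                    n_genes = 12L, n_te_copies = 5L, n_vntr_arrays = 5L,
                    events_per_mechanism = c(MEI = 2L, NHR = 2L, VNTR = 2L),
                    n_accessions = 5L)
  s1 <- simulate_cnv_study(cfg)
  s2 <- simulate_cnv_study(cfg)
  expect_identical(s1$pack$seqs, s2$pack$seqs)
  expect_identical(s1$outgroup$seqs, s2$outgroup$seqs)
  expect_identical(s1$truth, s2$truth)
  expect_identical(s1$calls, s2$calls)
})
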