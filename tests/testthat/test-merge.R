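test_that("reciprocal overlap follows its definition", {
  expect_equal(reciprocal_overlap(100, 200, 100, 200), 1.0)
  expect_equal(reciprocal_overlap(0, 100, 50, 250), 0.25)
  expect_equal(reciprocal_overlap(0, 100, 200, 300), 0.0)
  ## symmetric
  expect_equal(reciprocal_overlap(0, 100, 50, 250),
               reciprocal_overlap(50, 250, 0, 100))
  ## different chromosomes never overlap
  expect_equal(reciprocal_overlap(0, 100, 0, 100, "chr1", "chr2"), 0.0)
  expect_error(reciprocal_overlap(100, 100, 0, 50), "invalid interval")
})

test_that("per-accession consensus applies the >=2-caller gate", {
  params <- merge_params()
  calls <- data.frame(chrom = "chr1",
                      start = c(1000L, 1005L, 900L),
                      end = c(2000L, 1998L, 2100L),
                      caller = c("PE", "SR", "RD"),
                      accession = "accA")
  cons <- consensus_per_accession(calls, params)
  expect_equal(nrow(cons), 1L)
  expect_equal(cons$callers, "PE+RD+SR")
  expect_true(cons$precise)
  expect_equal(cons$start, 1005L)   # modal SR breakpoints win
  expect_equal(cons$end, 1998L)

  ## a single-method call never survives
  single <- calls[1, ]
  expect_equal(nrow(consensus_per_accession(single, params)), 0L)

  ## two disjoint single-caller calls form two clusters, both discarded
  two <- data.frame(chrom = "chr1", start = c(0L, 1000L),
                    end = c(100L, 1100L), caller = c("PE", "SR"),
                    accession = "accA")
  expect_equal(nrow(consensus_per_accession(two, params)), 0L)

  mixed <- calls; mixed$accession <- c("accA", "accA", "accB")
  expect_error(consensus_per_accession(mixed, params), "input error")
})

test_that("breakpoint refinement follows the SR > PE > RD priority", {
  cl <- data.frame(chrom = "chr1",
                   start = c(1005L, 1005L, 990L),
                   end = c(1998L, 1998L, 2010L),
                   caller = c("SR", "SR", "PE"))
  bp <- refine_breakpoints(cl)
  expect_equal(bp[c("start", "end", "precise")],
               list(start = 1005L, end = 1998L, precise = TRUE))

  ## modal SR ties break to smallest start, then end
  tie <- data.frame(chrom = "chr1", start = c(10L, 20L), end = c(99L, 88L),
                    caller = "SR")
  expect_equal(refine_breakpoints(tie)$start, 10L)

  ## PE-only: lower medians per endpoint
  pe <- data.frame(chrom = "chr1", start = c(100L, 104L, 108L, 120L),
                   end = c(200L, 210L, 220L, 230L), caller = "PE")
  bp <- refine_breakpoints(pe)
  expect_equal(bp$start, 104L)
  expect_equal(bp$end, 210L)
  expect_true(bp$precise)

  rd <- data.frame(chrom = "chr1", start = 900L, end = 2100L,
                   caller = "RD")
  bp <- refine_breakpoints(rd)
  expect_false(bp$precise)
  expect_equal(bp$start, 900L)

  expect_error(refine_breakpoints(rd[0, ]), "input error")
})

test_that("population merge applies the >=3-accession gate", {
  params <- merge_params()
  mk <- function(accs) data.frame(
    chrom = "chr1", start = 5000L, end = 7000L, precise = TRUE,
    callers = "PE+SR", accession = accs)
  out3 <- merge_across_accessions(mk(c("A", "B", "C")), params)
  expect_equal(nrow(out3), 1L)
  expect_equal(out3$n_accessions, 3L)
  expect_equal(out3$carriers, "A,B,C")

  out2 <- merge_across_accessions(mk(c("A", "B")), params)
  expect_equal(nrow(out2), 0L)
})

test_that("single-linkage clustering equals the transitive-closure oracle", {
  for (seed in 1:5) {
    df <- random_calls(120, seed = seed)
    got <- cnvpol:::cluster_reciprocal(df, 0.5)
    want <- oracle_cluster(df, 0.5)
    ## same partition: cluster labels must be a bijection
    expect_equal(length(unique(got)), length(unique(want)))
    expect_true(all(tapply(want, got, function(x) length(unique(x))) == 1))
  }
})

test_that("clustering and merging are invariant to input order", {
  df <- random_calls(150, seed = 9)
  params <- merge_params()
  r1 <- merge_callsets(df, params)
  set.seed(1)
  df2 <- df[sample.int(nrow(df)), ]
  r2 <- merge_callsets(df2, params)
  rownames(r1) <- rownames(r2) <- NULL
  expect_identical(r1[, c("chrom", "start", "end", "carriers")],
                   r2[, c("chrom", "start", "end", "carriers")])
})

test_that("undersized calls are rejected", {
  bad <- data.frame(chrom = "chr1", start = 10L, end = 40L, caller = "PE",
                    accession = "accA")
  expect_error(merge_callsets(bad), "50 bp")
})
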