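test_that("junction microhomology matches hand-computed examples", {
  ## deleting [2,8) from TTACGTAAACGTCC: LCP("ACGTAAACGTCC","ACGTCC") = 4,
  ## left common suffix of "TT" and "TTACGTAA" is 0
  mh <- junction_microhomology("TTACGTAAACGTCC", 2, 8)
  expect_equal(mh, list(left = 0L, right = 4L, total = 4L))

  ## a deletion inside a homopolymer runs to the run boundary
  seq <- paste0("GG", strrep("A", 30), "CC")
  mh <- junction_microhomology(seq, 5, 15)
  expect_equal(mh$right, 17L)     # remaining A-run after the junction

  ## no shared bases at all
  expect_equal(junction_microhomology("ATGGCCTA", 2, 6)$total, 0L)

  expect_error(junction_microhomology("ACGT", 2, 10), "invalid interval")
})

test_that("junction microhomology equals the brute-force scan", {
  set.seed(123)
  for (i in 1:1000) {
    n <- sample(100:300, 1)
    seq <- random_seq(n)
    start <- sample(5:(n - 60), 1)
    end <- start + sample(50:(n - start - 5), 1)
    got <- junction_microhomology(seq, start, end)
    want <- oracle_microhomology(seq, start, end)
    expect_identical(got$left, as.integer(want$left))
    expect_identical(got$right, as.integer(want$right))
  }
})

test_that("flanking homology finds implanted repeats and not noise", {
  ## constructed NAHR junction: identical 120-bp repeat at start and end
  set.seed(7)
  r <- random_seq(120)
  seq <- paste0(random_seq(300), r, random_seq(500), r, random_seq(300))
  start <- 300L; end <- 300L + 120L + 500L
  fh <- flanking_homology(seq, start, end)
  expect_gte(fh$homology_len, 120L)
  expect_gte(fh$identity, 0.9)

  ## Monte-Carlo null: random junctions almost never reach 10 bp
  set.seed(99)
  hits <- replicate(1000, {
    s <- random_seq(1200)
    a <- sample(300:500, 1); b <- a + sample(100:500, 1)
    flanking_homology(s, a, b)$homology_len
  })
  expect_gte(mean(hits <= 10), 0.99)
})

test_that("TE coverage matches the per-base bitmap oracle", {
  te <- data.frame(chrom = "chr1",
                   start = c(100L, 400L, 450L, 900L),
                   end = c(300L, 500L, 600L, 1200L),
                   family = c("Copia_like", "Mutator_like", "hAT_like",
                              "Copia_like"))
  expect_equal(te_coverage("chr1", 100, 300, te),
               list(fraction = 1.0, family = "Copia_like"))
  expect_equal(te_coverage("chr1", 300, 500, te)$fraction, 0.5)

  set.seed(11)
  bitmap <- rep(FALSE, 2000)
  for (i in seq_len(nrow(te))) bitmap[(te$start[i] + 1):te$end[i]] <- TRUE
  for (rep in 1:100) {
    s <- sample(0:1500, 1); e <- s + sample(50:400, 1)
    got <- te_coverage("chr1", s, e, te)$fraction
    expect_equal(got, mean(bitmap[(s + 1):e]))
  }
})

test_that("VNTR context requires in-array breakpoints and period multiples", {
  vntr <- data.frame(chrom = "chr1", start = c(1000L, 3000L),
                     end = c(1300L, 3400L), period = c(15L, 20L))
  expect_equal(vntr_context("chr1", 1030, 1075, vntr),
               list(is_vntr = TRUE, period = 15L))
  ## 40 bp in a period-15 array: nearest multiple 45, distance 5 > 1.5
  expect_false(vntr_context("chr1", 1030, 1070, vntr)$is_vntr)
  ## breakpoints in two different arrays
  expect_false(vntr_context("chr1", 1100, 3100, vntr)$is_vntr)
})

test_that("mechanism precedence and the ambiguous gap are honoured", {
  ## an interval that satisfies both the VNTR and the MEI signature
  set.seed(3)
  unit <- random_seq(20)
  seq <- paste0(random_seq(500), strrep(unit, 10), random_seq(500))
  seqs <- list(chr1 = seq)
  vntr <- data.frame(chrom = "chr1", start = 500L, end = 700L,
                     period = 20L)
  te <- data.frame(chrom = "chr1", start = 520L, end = 620L,
                   family = "Copia_like")
  r <- classify_mechanism("chr1", 520, 620, TRUE, seqs, te, vntr)
  expect_equal(r$mechanism, "VNTR")

  ## microhomology of 25 bp, no TE, no array: the ambiguous gap
  core <- random_seq(2000)
  mh25 <- substr(core, 501, 525)   # the deleted segment begins with the
  seq2 <- paste0(substr(core, 1, 500), mh25, random_seq(800),
                 substr(core, 501, 2000))   # same 25 bp that follow it
  seqs2 <- list(chr1 = seq2)
  start <- 500L; end <- 500L + 25L + 800L
  got <- junction_microhomology(seq2, start, end)$total
  expect_gte(got, 25L)
  r2 <- classify_mechanism("chr1", start, end, TRUE, seqs2,
                           te[0, ], vntr[0, ])
  expect_equal(r2$mechanism, "ambiguous")
  expect_match(r2$reason, "between")

  ## imprecise events are never classified
  r3 <- classify_mechanism("chr1", 500, 900, FALSE, seqs2, te[0, ],
                           vntr[0, ])
  expect_equal(r3$mechanism, "ambiguous")
  expect_equal(r3$reason, "imprecise_breakpoints")
})

test_that("raising the MEI threshold never increases the MEI count", {
  run <- noise_free_run()
  ev <- run$pol[, c("event_id", "chrom", "start", "end", "precise")]
  m1 <- classify_mechanisms(ev, run$study$pack$seqs, run$study$pack$te,
                            run$study$pack$vntr,
                            mechanism_params(mei_min_fraction = 0.8))
  m2 <- classify_mechanisms(ev, run$study$pack$seqs, run$study$pack$te,
                            run$study$pack$vntr,
                            mechanism_params(mei_min_fraction = 0.95))
  expect_lte(sum(m2$mechanism == "MEI"), sum(m1$mechanism == "MEI"))
})

test_that("mechanism summaries recount their inputs exactly", {
  ev <- data.frame(event_id = sprintf("e%02d", 1:10), chrom = "chr1",
                   start = seq(0, 9000, by = 1000),
                   end = seq(0, 9000, by = 1000) + 100L)
  calls <- data.frame(event_id = ev$event_id, mechanism = "NHR",
                      microhomology_len = 0L)
  s <- summarize_mechanisms(calls, ev)
  expect_equal(s$distribution$n, 10L)
  expect_equal(s$distribution$percent, 100)
  expect_equal(s$distribution$cumulative_bp, 1000)

  run <- noise_free_run()
  s2 <- summarize_mechanisms(run$mech, run$pol)
  recount <- table(run$mech$mechanism)
  expect_equal(sum(s2$distribution$n), nrow(run$mech))
  for (i in seq_len(nrow(s2$distribution))) {
    expect_equal(s2$distribution$n[i],
                 unname(recount[s2$distribution$mechanism[i]]),
                 ignore_attr = TRUE)
  }
  expect_equal(sum(s2$distribution$percent), 100, tolerance = 1e-9)

  empty <- summarize_mechanisms(calls[0, ], ev[0, ])
  expect_equal(nrow(empty$distribution), 0L)
  expect_error(summarize_mechanisms(rbind(calls, calls[1, ]), ev),
               "duplicate")
})

test_that("every precise event gets exactly one mechanism label", {
  run <- noise_free_run()
  expect_true(all(run$mech$mechanism %in%
                    c("MEI", "VNTR", "NAHR", "NHR", "ambiguous")))
  expect_equal(anyDuplicated(run$mech$event_id), 0L)
})
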