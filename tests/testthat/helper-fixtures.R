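# Shared fixtures.  Heavy simulations are built once per test run and
# cached in an environment so multiple test files can reuse them.

.fixtures <- new.env(parent = emptyenv())

fixture <- function(name, builder) {
  if (!exists(name, envir = .fixtures)) {
    assign(name, builder(), envir = .fixtures)
  }
  get(name, envir = .fixtures)
}

# default-sized noise-free study + merge + polarize (exact-recovery regime)
noise_free_run <- function() {
  fixture("noise_free_run", function() {
    t0 <- Sys.time()
    cfg <- sim_config_noise_free(seed = 101L)
    study <- simulate_cnv_study(cfg)
    cons <- merge_callsets(study$calls)
    ev <- evaluate_merge(cons, study$truth)
    blocks <- build_blocks(study$outgroup$anchors)
    pol <- polarize_cnvs(cons, study$pack$seqs, study$outgroup$seqs,
                         study$outgroup$gaps, blocks)
    mech <- classify_mechanisms(
      pol[, c("event_id", "chrom", "start", "end", "precise")],
      study$pack$seqs, study$pack$te, study$pack$vntr)
    elapsed <- as.numeric(difftime(Sys.time(), t0, units = "secs"))
    list(study = study, cons = cons, ev = ev, blocks = blocks, pol = pol,
         mech = mech, elapsed = elapsed)
  })
}

# default noisy study (realistic operating point)
noisy_run <- function() {
  fixture("noisy_run", function() {
    cfg <- sim_config(seed = 202L)
    study <- simulate_cnv_study(cfg)
    cons <- merge_callsets(study$calls)
    ev <- evaluate_merge(cons, study$truth)
    blocks <- build_blocks(study$outgroup$anchors)
    pol <- polarize_cnvs(cons, study$pack$seqs, study$outgroup$seqs,
                         study$outgroup$gaps, blocks)
    list(study = study, cons = cons, ev = ev, blocks = blocks, pol = pol)
  })
}

# small noise-free study with implanted gene duplications
dup_run <- function() {
  fixture("dup_run", function() {
    cfg <- sim_config_noise_free(
      seed = 303L,
      events_per_mechanism = c(MEI = 10L, VNTR = 10L, NAHR = 10L,
                               NHR = 10L),
      duplications_per_origin = 10L)
    study <- simulate_cnv_study(cfg)
    blocks <- build_blocks(study$outgroup$anchors)
    list(study = study, blocks = blocks)
  })
}

# random call table for clustering oracles
random_calls <- function(n, seed, chrom_len = 100000L, n_chrom = 2L) {
  set.seed(seed)
  w <- round(exp(runif(n, log(60), log(5000))))
  chrom <- paste0("chr", sample.int(n_chrom, n, replace = TRUE))
  s <- floor(runif(n) * (chrom_len - w))
  data.frame(chrom = chrom, start = as.integer(s), end = as.integer(s + w),
             caller = sample(c("PE", "SR", "RD"), n, replace = TRUE),
             accession = sample(sprintf("acc%02d", 1:5), n, replace = TRUE))
}

# O(n^2) transitive-closure clustering oracle: explicit all-pairs
# reciprocal-overlap graph + connected components by BFS
oracle_cluster <- function(df, min_ro = 0.5) {
  n <- nrow(df)
  s <- df$start; e <- df$end; len <- e - s
  O <- outer(e, e, pmin) - outer(s, s, pmax)
  RO <- pmin(O / matrix(len, n, n), O / matrix(len, n, n, byrow = TRUE))
  adj <- O > 0 & RO >= min_ro & outer(df$chrom, df$chrom, "==")
  diag(adj) <- FALSE
  ## connected components by BFS
  comp <- rep(NA_integer_, n)
  cid <- 0L
  for (i in seq_len(n)) {
    if (!is.na(comp[i])) next
    cid <- cid + 1L
    queue <- i
    while (length(queue)) {
      v <- queue[1]; queue <- queue[-1]
      if (!is.na(comp[v])) next
      comp[v] <- cid
      queue <- c(queue, which(adj[v, ] & is.na(comp)))
    }
  }
  comp
}

# brute-force microhomology scan on a character-vector sequence
oracle_microhomology <- function(seq, start, end, cap = 500L) {
  x <- strsplit(toupper(seq), "", fixed = TRUE)[[1]]
  n <- length(x)
  right <- 0L
  while (right < cap && start + right < n && end + right < n) {
    a <- x[start + right + 1L]; b <- x[end + right + 1L]
    if (a != b || a == "N") break
    right <- right + 1L
  }
  left <- 0L
  while (left < cap && start - left > 0 && end - left > 0) {
    a <- x[start - left]; b <- x[end - left]
    if (a != b || a == "N") break
    left <- left + 1L
  }
  list(left = left, right = right, total = left + right)
}

random_seq <- function(n, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}
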