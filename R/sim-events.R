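#' Implant mechanism-labelled CNV events into a simulated reference
#'
#' Each event is an interval of the reference that is absent from some
#' accessions (a deletion relative to the reference).  The diagnostic
#' breakpoint signature of its formation mechanism is written into the
#' reference sequence:
#'
#' * `MEI` — a TE family copy covering >= 90% of the event plus a 5-20 bp
#'   target-site duplication copied from the left flank to the event's 3'
#'   end, so that removing the event restores a single TSD copy.
#' * `NAHR` — a 100-200 bp repeat written (with ~1% divergence per copy) at
#'   the event start and immediately after the event end, leaving extended
#'   junction homology.
#' * `NHR` — 0-10 bp of engineered junction microhomology (sequence just
#'   after the event end equals the event start) with forced mismatches at
#'   both microhomology borders.
#' * `VNTR` — an integer number of periods of an annotated tandem array;
#'   both breakpoints inside the array.  Insertion-state VNTR events expand
#'   almost the whole array (the ancestor keeps two periods), the regime in
#'   which alignment-based polarization is informative.
#'
#' A fraction `insertion_fraction` of events (exact count, sampled across
#' mechanisms) is labelled `insertion` (present in the reference lineage,
#' absent from the ancestor/outgroup); the rest are `deletion` (ancestral,
#' lost by the carrier accessions).  Carrier accessions (those lacking the
#' reference allele) are drawn per event with a 1/k-weighted count between 3
#' and `n_accessions`.
#'
#' @param pack A `genome_pack` from [simulate_reference()].
#' @param config The same [sim_config()].
#' @return List with the updated `pack` (edited sequences, extended TE
#'   annotation) and `truth`, a data frame with one row per implanted event
#'   (`event_id`, `chrom`, `ref_start`, `ref_end`, `mechanism`,
#'   `ancestral_state`, `carriers`, `te_family`, `microhomology_len`,
#'   `homology_len`, `vntr_period`, `origin`).
#' @export
implant_events <- function(pack, config) {
  stopifnot(inherits(pack, "genome_pack"))
  set.seed(derive_seed(config$seed, 2L))
  counts <- config$events_per_mechanism
  mechs <- rep(names(counts), times = counts)
  n_ev <- length(mechs)
  if (n_ev == 0) {
    return(list(pack = pack, truth = empty_truth()))
  }
  chroms <- names(pack$seqs)
  chrom_len <- nchar(pack$seqs[[1]])

  ## exclusion zones for free placement: TEs and tandem arrays with a wide
  ## buffer so polarization windows stay free of confounding repeat copies
  buffer_iv <- function(df, b) {
    if (nrow(df) == 0) return(df[, c("chrom", "start", "end")])
    data.frame(chrom = df$chrom, start = pmax(0L, df$start - b),
               end = df$end + b)
  }
  excl <- rbind(buffer_iv(pack$te, 2500L), buffer_iv(pack$vntr, 2500L))

  ## --- VNTR events use existing arrays ---
  n_vntr_ev <- sum(mechs == "VNTR")
  vntr_rows <- NULL
  if (n_vntr_ev > 0) {
    cand <- which(pack$vntr$copies >= 16)
    if (length(cand) < n_vntr_ev) {
      stop("placement error: only ", length(cand),
           " tandem arrays available for ", n_vntr_ev, " VNTR events")
    }
    picks <- sample(cand, n_vntr_ev)
    arr <- pack$vntr[picks, ]
    k <- arr$copies - 2L                      # ancestor keeps two periods
    vntr_rows <- data.frame(
      chrom = arr$chrom,
      start = arr$start + arr$period,         # one period kept on the left
      end = arr$start + arr$period + k * arr$period,
      period = arr$period, k = k)
  }

  ## --- free placement for MEI / NAHR / NHR ---
  free_mechs <- mechs[mechs != "VNTR"]
  spec <- lapply(free_mechs, function(m) {
    if (m == "MEI") {
      fam <- sample(names(pack$te_library), 1)
      tsd <- sample(5:20, 1)
      len <- nchar(pack$te_library[[fam]]) + tsd
      list(mech = m, len = len, extra = 0L, fam = fam, tsd = tsd)
    } else if (m == "NAHR") {
      len <- round(exp(runif(1, log(1500), log(6000))))
      rlen <- sample(100:200, 1)
      list(mech = m, len = len, extra = rlen, rlen = rlen)
    } else {
      len <- round(exp(runif(1, log(600), log(4000))))
      mh <- sample(0:10, 1)
      list(mech = m, len = len, extra = 0L, mh = mh)
    }
  })
  ev_chrom <- sample(chroms, length(spec), replace = TRUE)

  placed <- vector("list", length(spec))
  for (ch in chroms) {
    idx <- which(ev_chrom == ch)
    if (!length(idx)) next
    widths <- vapply(idx, function(i) spec[[i]]$len + spec[[i]]$extra,
                     numeric(1))
    occ <- excl[excl$chrom == ch, c("start", "end")]
    pl <- place_intervals(widths, lo = 3000L, hi = chrom_len - 3500L,
                          occupied = occ, min_gap = 1000L)
    for (j in seq_along(idx)) {
      placed[[idx[j]]] <- c(start = pl$start[j],
                            end = pl$start[j] + spec[[idx[j]]]$len)
    }
  }

  ## --- write signatures into the reference ---
  gc <- config$gc_content
  new_te <- NULL
  free_rows <- NULL
  for (i in seq_along(spec)) {
    sp <- spec[[i]]
    ch <- ev_chrom[i]
    s <- placed[[i]][["start"]]; e <- placed[[i]][["end"]]
    seq <- pack$seqs[[ch]]
    mh_len <- 0L; hom_len <- 0L; fam <- ""
    if (sp$mech == "MEI") {
      body <- mutate_dna(pack$te_library[[sp$fam]], 0.03)
      seq <- set_subseq_str(seq, s, body)
      tsd_seq <- subseq_str(seq, s - sp$tsd, s)
      seq <- set_subseq_str(seq, e - sp$tsd, tsd_seq)
      new_te <- rbind(new_te, data.frame(chrom = ch, start = s,
                                         end = e - sp$tsd, family = sp$fam))
      fam <- sp$fam
      mh_len <- sp$tsd
    } else if (sp$mech == "NAHR") {
      r <- rand_dna(sp$rlen, gc)
      seq <- set_subseq_str(seq, s, mutate_dna(r, 0.01))
      seq <- set_subseq_str(seq, e, mutate_dna(r, 0.01))
      hom_len <- sp$rlen
    } else {                                  # NHR
      if (sp$mh > 0) {
        seq <- set_subseq_str(seq, e, subseq_str(seq, s, s + sp$mh))
      }
      seq <- force_mismatch(seq, e + sp$mh, s + sp$mh)
      seq <- force_mismatch(seq, e - 1L, s - 1L)
      mh_len <- sp$mh
    }
    pack$seqs[[ch]] <- seq
    free_rows <- rbind(free_rows, data.frame(
      chrom = ch, start = s, end = e, mechanism = sp$mech,
      te_family = fam, microhomology_len = mh_len, homology_len = hom_len,
      vntr_period = NA_integer_))
  }
  if (!is.null(new_te)) pack$te <- rbind(pack$te, new_te)
  pack$te <- pack$te[order(pack$te$chrom, pack$te$start), ]
  rownames(pack$te) <- NULL

  truth <- rbind(
    free_rows,
    if (!is.null(vntr_rows)) data.frame(
      chrom = vntr_rows$chrom, start = vntr_rows$start,
      end = vntr_rows$end, mechanism = "VNTR", te_family = "",
      microhomology_len = NA_integer_, homology_len = NA_integer_,
      vntr_period = vntr_rows$period)
  )
  truth <- truth[order(truth$chrom, truth$start), ]
  rownames(truth) <- NULL
  n <- nrow(truth)

  ## exact-count polarity assignment
  n_ins <- round(config$insertion_fraction * n)
  state <- rep("deletion", n)
  state[sample.int(n, n_ins)] <- "insertion"

  accs <- accession_ids(config$n_accessions)
  carriers <- vapply(seq_len(n), function(i) {
    kmax <- config$n_accessions
    ks <- 3:kmax
    k <- if (kmax <= 3) kmax else sample(ks, 1, prob = 1 / ks)
    paste(sort(sample(accs, k)), collapse = ",")
  }, character(1))

  truth <- data.frame(
    event_id = sprintf("ev%04d", seq_len(n)),
    chrom = truth$chrom, ref_start = truth$start, ref_end = truth$end,
    mechanism = truth$mechanism, ancestral_state = state,
    carriers = carriers, te_family = truth$te_family,
    microhomology_len = truth$microhomology_len,
    homology_len = truth$homology_len, vntr_period = truth$vntr_period,
    origin = NA_character_)
  list(pack = pack, truth = truth)
}

empty_truth <- function() {
  data.frame(event_id = character(0), chrom = character(0),
             ref_start = integer(0), ref_end = integer(0),
             mechanism = character(0), ancestral_state = character(0),
             carriers = character(0), te_family = character(0),
             microhomology_len = integer(0), homology_len = integer(0),
             vntr_period = integer(0), origin = character(0))
}

accession_ids <- function(n) sprintf("acc%02d", seq_len(n))

## force the base at 0-based position `pos` to differ from the base at
## 0-based position `ref_pos` (no-op when out of range)
force_mismatch <- function(seq, pos, ref_pos) {
  if (pos < 0 || pos >= nchar(seq) || ref_pos < 0) return(seq)
  a <- subseq_str(seq, pos, pos + 1L)
  b <- subseq_str(seq, ref_pos, ref_pos + 1L)
  if (a == b) {
    alt <- setdiff(c("A", "C", "G", "T"), b)
    seq <- set_subseq_str(seq, pos, alt[sample.int(3L, 1L)])
  }
  seq
}

#' Group labels for the simulated accessions
#'
#' Mirrors the composition of a cultivated/wild resequencing panel: ~80%
#' cultivated (split into indica and japonica subgroups plus a remainder)
#' and ~20% wild.
#'
#' @param n_accessions Number of accessions.
#' @return Data frame with `accession`, `group` (cultivated/wild) and
#'   `subgroup` (indica/japonica/other).
#' @export
accession_groups <- function(n_accessions) {
  accs <- accession_ids(n_accessions)
  n_cult <- max(1L, round(0.8 * n_accessions))
  n_jap <- max(1L, round(0.6 * n_cult))
  n_ind <- max(1L, round(0.3 * n_cult))
  group <- c(rep("cultivated", n_cult),
             rep("wild", n_accessions - n_cult))
  subgroup <- rep("other", n_accessions)
  subgroup[seq_len(n_jap)] <- "japonica"
  subgroup[n_jap + seq_len(min(n_ind, n_cult - n_jap))] <- "indica"
  data.frame(accession = accs, group = group, subgroup = subgroup)
}
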