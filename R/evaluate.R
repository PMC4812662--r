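#' Match consensus events against the implanted truth
#'
#' A consensus event matches a truth event when they share a chromosome
#' and have reciprocal overlap >= `min_ro`; each truth event takes its
#' best-overlapping consensus event.
#'
#' @param consensus Consensus table ([merge_callsets()]).
#' @param truth Truth table.
#' @param min_ro Matching threshold.
#' @return List with `recall`, `precision`, `exact_fraction` (matched
#'   truth events whose breakpoints are exact), and the per-truth-event
#'   `matches` table (`event_id`, `truth_id`, `exact`).
#' @export
evaluate_merge <- function(consensus, truth, min_ro = 0.5) {
  if (nrow(truth) == 0) {
    return(list(recall = NA_real_, precision = NA_real_,
                exact_fraction = NA_real_,
                matches = data.frame(event_id = character(0),
                                     truth_id = character(0),
                                     exact = logical(0))))
  }
  matches <- NULL
  matched_consensus <- character(0)
  for (i in seq_len(nrow(truth))) {
    tv <- truth[i, ]
    cc <- consensus[consensus$chrom == tv$chrom, , drop = FALSE]
    if (nrow(cc) > 0) {
      ro <- reciprocal_overlap(cc$start, cc$end,
                               rep(tv$ref_start, nrow(cc)),
                               rep(tv$ref_end, nrow(cc)))
      j <- which.max(ro)
      if (ro[j] >= min_ro) {
        matches <- rbind(matches, data.frame(
          event_id = cc$event_id[j], truth_id = tv$event_id,
          exact = cc$start[j] == tv$ref_start & cc$end[j] == tv$ref_end))
        matched_consensus <- c(matched_consensus, cc$event_id[j])
      }
    }
  }
  matches <- matches %||% data.frame(event_id = character(0),
                                     truth_id = character(0),
                                     exact = logical(0))
  ## precision: consensus events matching any truth event
  cons_ok <- if (nrow(consensus) > 0) {
    vapply(seq_len(nrow(consensus)), function(i) {
      cv <- consensus[i, ]
      tt <- truth[truth$chrom == cv$chrom, , drop = FALSE]
      nrow(tt) > 0 && any(reciprocal_overlap(
        tt$ref_start, tt$ref_end, rep(cv$start, nrow(tt)),
        rep(cv$end, nrow(tt))) >= min_ro)
    }, logical(1))
  } else logical(0)
  list(recall = nrow(matches) / nrow(truth),
       precision = if (nrow(consensus) > 0) mean(cons_ok) else NA_real_,
       exact_fraction = if (nrow(matches) > 0) mean(matches$exact)
                        else NA_real_,
       matches = matches)
}

#' Score polarization against the truth
#'
#' @param polarized Polarized consensus table.
#' @param truth Truth table (with `gap_overlap_frac` when available).
#' @param matches Match table from [evaluate_merge()].
#' @return List with `accuracy_gap_free` (state agreement on matched
#'   events whose true outgroup window is gap-free), `undefined_on_gaps`
#'   (fraction of matched events with true gap fraction > 0.1 that are
#'   undefined), `insertion_share` (among matched defined events) and the
#'   joined table.
#' @export
evaluate_polarity <- function(polarized, truth, matches) {
  j <- merge(matches, truth, by.x = "truth_id", by.y = "event_id")
  names(j)[names(j) == "ancestral_state"] <- "state_truth"
  pc <- polarized[, c("event_id", "ancestral_state")]
  names(pc) <- c("event_id", "state_call")
  j <- merge(j, pc, by = "event_id")
  gf <- j$gap_overlap_frac %||% rep(0, nrow(j))
  gap_free <- j[gf == 0, , drop = FALSE]
  gapped <- j[gf > 0.1, , drop = FALSE]
  defined <- j[j$state_call %in% c("insertion", "deletion"), , drop = FALSE]
  list(
    accuracy_gap_free = if (nrow(gap_free) > 0)
      mean(gap_free$state_call == gap_free$state_truth) else NA_real_,
    undefined_on_gaps = if (nrow(gapped) > 0)
      mean(gapped$state_call == "undefined") else NA_real_,
    insertion_share = if (nrow(defined) > 0)
      mean(defined$state_call == "insertion") else NA_real_,
    n_defined = nrow(defined),
    table = j)
}

#' Score mechanism classification against the truth
#'
#' @param mechanisms Mechanism calls ([classify_mechanisms()]).
#' @param truth Truth table (rows with mechanisms MEI/VNTR/NAHR/NHR).
#' @param matches Match table from [evaluate_merge()].
#' @return List with `accuracy`, `per_class` (named accuracy vector) and
#'   the `confusions` table.
#' @export
evaluate_mechanism <- function(mechanisms, truth, matches) {
  tt <- truth[truth$mechanism %in% c("MEI", "VNTR", "NAHR", "NHR"), ]
  j <- merge(matches, tt, by.x = "truth_id", by.y = "event_id")
  j <- merge(j, mechanisms[, c("event_id", "mechanism")],
             by = "event_id", suffixes = c(".truth", ".call"))
  if (nrow(j) == 0) {
    return(list(accuracy = NA_real_, per_class = numeric(0),
                confusions = j))
  }
  ok <- j$mechanism.call == j$mechanism.truth
  per_class <- vapply(split(ok, j$mechanism.truth), mean, numeric(1))
  list(accuracy = mean(ok), per_class = per_class,
       confusions = j[!ok, c("event_id", "truth_id", "mechanism.truth",
                             "mechanism.call")])
}

#' Score duplication-origin inference against the truth
#'
#' @param noncolinear Output of [noncolinear_genes()].
#' @param truth Truth table with duplication rows (`mechanism == "DUP"`).
#' @return List with `per_class` accuracy (TE/NHEJ/NAHR),
#'   `noncolinear_rate` for the duplicated genes, and the joined table.
#' @export
evaluate_origins <- function(noncolinear, truth) {
  dup <- truth[truth$mechanism == "DUP", ]
  j <- merge(dup, noncolinear, by.x = "dup_gene", by.y = "gene_id")
  if (nrow(j) == 0) {
    return(list(per_class = numeric(0), noncolinear_rate = NA_real_,
                table = j))
  }
  ok <- j$origin_mechanism == ifelse(j$origin == "NHEJ", "NHEJ",
                                     j$origin)
  list(per_class = vapply(split(ok, j$origin), mean, numeric(1)),
       noncolinear_rate = mean(!j$is_colinear),
       table = j)
}
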