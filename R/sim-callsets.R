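#' Emit noisy per-accession, per-caller CNV call sets
#'
#' For every truth event, carrier accession and caller (PE, SR, RD) a call
#' is emitted with the configured per-size-class sensitivity.  Split-read
#' calls have exact breakpoints; paired-end calls are jittered with a
#' rounded Gaussian of the configured sd; read-depth calls are snapped
#' outward to 100-bp bins.  False calls are placed uniformly per caller and
#' accession at `false_call_rate` per Mb, with sizes resampled from the
#' truth size distribution.
#'
#' @param truth Truth table (from [implant_events()] /
#'   [mutate_outgroup()]).
#' @param config The [sim_config()].
#' @param chrom_lengths Named vector of chromosome lengths (for false-call
#'   placement).
#' @return Data frame of calls: `chrom`, `start`, `end`, `caller`,
#'   `accession`, `precise`, `truth_id` (`""` for false calls).
#' @export
emit_callsets <- function(truth, config, chrom_lengths) {
  set.seed(derive_seed(config$seed, 4L))
  callers <- c("PE", "SR", "RD")
  out <- list()

  if (nrow(truth) > 0) {
    for (i in seq_len(nrow(truth))) {
      ev <- truth[i, ]
      len <- ev$ref_end - ev$ref_start
      cls <- size_class(len)
      carriers <- strsplit(ev$carriers, ",", fixed = TRUE)[[1]]
      for (acc in carriers) {
        for (cl in callers) {
          p <- config$caller_sensitivity[cl, cls]
          if (runif(1) >= p) next
          s <- ev$ref_start; e <- ev$ref_end
          if (cl == "PE") {
            sd <- config$breakpoint_jitter_sd[["PE"]]
            if (sd > 0) {
              s <- s + round(rnorm(1, 0, sd))
              e <- e + round(rnorm(1, 0, sd))
              if (e - s < 50) { mid <- (s + e) %/% 2; s <- mid - 25; e <- mid + 25 }
            }
          } else if (cl == "RD") {
            s <- (s %/% 100L) * 100L
            e <- ((e + 99L) %/% 100L) * 100L
          }
          out[[length(out) + 1L]] <- data.frame(
            chrom = ev$chrom, start = as.integer(max(0, s)),
            end = as.integer(e), caller = cl, accession = acc,
            precise = (cl == "SR"), truth_id = ev$event_id)
        }
      }
    }
  }

  ## false calls
  if (config$false_call_rate > 0 && nrow(truth) > 0) {
    genome_mb <- sum(chrom_lengths) / 1e6
    sizes <- truth$ref_end - truth$ref_start
    accs <- accession_ids(config$n_accessions)
    for (acc in accs) {
      for (cl in callers) {
        nf <- rpois(1, config$false_call_rate * genome_mb)
        if (nf == 0) next
        ch <- sample(names(chrom_lengths), nf, replace = TRUE,
                     prob = chrom_lengths)
        w <- sample(sizes, nf, replace = TRUE)
        s <- floor(runif(nf) * (chrom_lengths[ch] - w))
        e <- s + w
        if (cl == "RD") {
          s <- (s %/% 100L) * 100L
          e <- ((e + 99L) %/% 100L) * 100L
        }
        out[[length(out) + 1L]] <- data.frame(
          chrom = ch, start = as.integer(s), end = as.integer(e),
          caller = cl, accession = acc, precise = (cl == "SR"),
          truth_id = "")
      }
    }
  }

  calls <- if (length(out)) do.call(rbind, out) else data.frame(
    chrom = character(0), start = integer(0), end = integer(0),
    caller = character(0), accession = character(0), precise = logical(0),
    truth_id = character(0))
  calls <- calls[order(calls$accession, calls$chrom, calls$start,
                       calls$end, calls$caller), ]
  rownames(calls) <- NULL
  calls
}

#' Run the full synthetic study generator
#'
#' Convenience wrapper chaining [simulate_reference()], [implant_events()],
#' optional gene-duplication implantation, [mutate_outgroup()],
#' [emit_callsets()] and [accession_groups()].
#'
#' @param config A [sim_config()].
#' @return List of class `cnv_study`: `pack`, `truth`, `outgroup`,
#'   `calls`, `groups`, `config`.
#' @export
simulate_cnv_study <- function(config) {
  pack <- simulate_reference(config)
  imp <- implant_events(pack, config)
  pack <- imp$pack; truth <- imp$truth
  if (config$duplications_per_origin > 0) {
    dup <- implant_duplications(pack, truth, config)
    pack <- dup$pack; truth <- dup$truth
  }
  og <- mutate_outgroup(pack, truth, config)
  truth <- og$truth
  chrom_lengths <- setNames(nchar(pack$seqs), names(pack$seqs))
  calls <- emit_callsets(truth, config, chrom_lengths)
  study <- list(pack = pack, truth = truth, outgroup = og, calls = calls,
                groups = accession_groups(config$n_accessions),
                config = config)
  class(study) <- "cnv_study"
  study
}
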