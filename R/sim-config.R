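#' Simulation configuration
#'
#' Builds and validates the configuration for the synthetic CNV study:
#' a multi-chromosome reference, a diverged outgroup with assembly gaps,
#' TE copies with target-site duplications, tandem-repeat arrays, gene
#' models, mechanism-labelled CNVs polarized as insertions-in-reference vs.
#' true deletions, and noisy caller-like call sets for three evidence
#' classes (paired-end, split-read, read-depth).
#'
#' Default values define the study conditions used throughout the package:
#' 2 chromosomes of 1 Mb, 12 accessions, 50 implanted events per mechanism,
#' 80% of events being insertions in the reference lineage, 2% outgroup
#' divergence, per-caller sensitivity 0.9 with the known method biases
#' (read-depth blind below 500 bp, split-read blind above 10 kb), 50 bp
#' paired-end breakpoint jitter and 5 false calls per Mb per caller.
#'
#' @param n_chromosomes Number of chromosomes.
#' @param chrom_length Length of each chromosome in bp (>= 50000).
#' @param gc_content Background GC fraction in (0, 1).
#' @param n_genes Number of gene models genome-wide.
#' @param n_te_copies Number of transposable-element copies genome-wide.
#' @param te_library_size Number of TE families in the library (<= 6 named
#'   families are provided; one is Mutator-like).
#' @param n_vntr_arrays Number of tandem-repeat arrays genome-wide.
#' @param outgroup_divergence Per-site substitution probability in [0, 0.2].
#' @param outgroup_indel_rate Per-site small-indel probability (default
#'   `outgroup_divergence / 10`).
#' @param outgroup_gap_rate Expected assembly-gap count per chromosome.
#' @param events_per_mechanism Named integer vector with counts for
#'   mechanisms `MEI`, `VNTR`, `NAHR`, `NHR`.
#' @param insertion_fraction Fraction of events that are insertions in the
#'   reference lineage (the rest are true deletions).
#' @param n_accessions Number of accessions in the population.
#' @param caller_sensitivity 3x3 numeric matrix, rows `PE`,`SR`,`RD`,
#'   columns size classes `small` (50-500), `mid` (500-10k), `large` (>10k):
#'   emission probability per truth event x carrier. See
#'   [caller_sensitivity_matrix()].
#' @param breakpoint_jitter_sd Named numeric vector of per-caller breakpoint
#'   jitter standard deviations in bp (only `PE` is jittered by default;
#'   `RD` calls are always snapped to 100-bp bins).
#' @param false_call_rate Expected false calls per Mb per caller per
#'   accession.
#' @param duplications_per_origin Gene duplications implanted per origin
#'   class (`TE`, `NHEJ`, `NAHR`); 0 disables them.
#' @param seed Integer seed; the whole simulation is deterministic in it.
#' @return A validated list of class `sim_config`.
#' @export
sim_config <- function(n_chromosomes = 2L,
                       chrom_length = 1000000L,
                       gc_content = 0.44,
                       n_genes = 100L,
                       n_te_copies = 50L,
                       te_library_size = 6L,
                       n_vntr_arrays = 70L,
                       outgroup_divergence = 0.02,
                       outgroup_indel_rate = NULL,
                       outgroup_gap_rate = 1,
                       events_per_mechanism = c(MEI = 50L, VNTR = 50L,
                                                NAHR = 50L, NHR = 50L),
                       insertion_fraction = 0.8,
                       n_accessions = 12L,
                       caller_sensitivity = caller_sensitivity_matrix(0.9),
                       breakpoint_jitter_sd = c(PE = 50, SR = 0, RD = 0),
                       false_call_rate = 5,
                       duplications_per_origin = 0L,
                       seed = 1L) {
  cfg <- list(
    n_chromosomes = as.integer(n_chromosomes),
    chrom_length = as.integer(chrom_length),
    gc_content = gc_content,
    n_genes = as.integer(n_genes),
    n_te_copies = as.integer(n_te_copies),
    te_library_size = as.integer(te_library_size),
    n_vntr_arrays = as.integer(n_vntr_arrays),
    outgroup_divergence = outgroup_divergence,
    outgroup_indel_rate = outgroup_indel_rate %||% (outgroup_divergence / 10),
    outgroup_gap_rate = outgroup_gap_rate,
    events_per_mechanism = events_per_mechanism,
    insertion_fraction = insertion_fraction,
    n_accessions = as.integer(n_accessions),
    caller_sensitivity = caller_sensitivity,
    breakpoint_jitter_sd = breakpoint_jitter_sd,
    false_call_rate = false_call_rate,
    duplications_per_origin = as.integer(duplications_per_origin),
    seed = as.integer(seed)
  )
  validate_sim_config(cfg)
  class(cfg) <- "sim_config"
  cfg
}

#' Per-caller, per-size-class sensitivity matrix
#'
#' Rows are callers (`PE`, `SR`, `RD`); columns are event size classes
#' `small` (50-500 bp), `mid` (500 bp - 10 kb) and `large` (> 10 kb).  The
#' default encodes the classical method biases: read-depth cannot resolve
#' sub-bin events (< 500 bp) and split reads cannot span very large events
#' (> 10 kb).
#'
#' @param p Base sensitivity applied to informative cells.
#' @param biased If `FALSE`, all cells get `p` (e.g. for noise-free runs).
#' @return A 3x3 numeric matrix.
#' @export
caller_sensitivity_matrix <- function(p = 0.9, biased = TRUE) {
  m <- matrix(p, nrow = 3, ncol = 3,
              dimnames = list(c("PE", "SR", "RD"),
                              c("small", "mid", "large")))
  if (biased) {
    m["RD", "small"] <- 0
    m["SR", "large"] <- 0
  }
  m
}

#' Noise-free configuration
#'
#' All sensitivities 1, no jitter, no false calls, no outgroup divergence,
#' no indels and no assembly gaps: the regime in which the pipeline must
#' achieve an exact round trip against the implanted truth.
#'
#' @param ... Overrides passed on to [sim_config()].
#' @export
sim_config_noise_free <- function(...) {
  args <- list(
    caller_sensitivity = caller_sensitivity_matrix(1, biased = FALSE),
    breakpoint_jitter_sd = c(PE = 0, SR = 0, RD = 0),
    false_call_rate = 0,
    outgroup_divergence = 0,
    outgroup_indel_rate = 0,
    outgroup_gap_rate = 0
  )
  override <- list(...)
  args[names(override)] <- override
  do.call(sim_config, args)
}

validate_sim_config <- function(cfg) {
  chk <- function(ok, field, msg) {
    if (!ok) stop("invalid configuration field '", field, "': ", msg)
  }
  chk(cfg$n_chromosomes >= 1, "n_chromosomes", "must be a positive integer")
  chk(cfg$chrom_length >= 50000, "chrom_length", "must be >= 50000 bp")
  chk(cfg$gc_content > 0 && cfg$gc_content < 1, "gc_content",
      "must be in (0,1)")
  chk(cfg$n_genes >= 0, "n_genes", "must be non-negative")
  chk(cfg$n_te_copies >= 0, "n_te_copies", "must be non-negative")
  chk(cfg$te_library_size >= 1 && cfg$te_library_size <= 6,
      "te_library_size", "must be in 1..6")
  chk(cfg$n_vntr_arrays >= 0, "n_vntr_arrays", "must be non-negative")
  chk(cfg$outgroup_divergence >= 0 && cfg$outgroup_divergence <= 0.2,
      "outgroup_divergence", "must be in [0,0.2]")
  chk(cfg$outgroup_indel_rate >= 0 && cfg$outgroup_indel_rate <= 0.1,
      "outgroup_indel_rate", "must be in [0,0.1]")
  chk(cfg$outgroup_gap_rate >= 0, "outgroup_gap_rate",
      "must be non-negative")
  chk(length(cfg$events_per_mechanism) > 0 &&
        all(names(cfg$events_per_mechanism) %in%
              c("MEI", "VNTR", "NAHR", "NHR")),
      "events_per_mechanism", "names must be among MEI/VNTR/NAHR/NHR")
  chk(all(cfg$events_per_mechanism >= 0), "events_per_mechanism",
      "counts must be non-negative")
  chk(cfg$insertion_fraction >= 0 && cfg$insertion_fraction <= 1,
      "insertion_fraction", "must be in [0,1]")
  chk(cfg$n_accessions >= 1, "n_accessions", "must be positive")
  cs <- cfg$caller_sensitivity
  chk(is.matrix(cs) && all(rownames(cs) == c("PE", "SR", "RD")) &&
        all(colnames(cs) == c("small", "mid", "large")),
      "caller_sensitivity", "must be a PE/SR/RD x small/mid/large matrix")
  chk(all(cs >= 0 & cs <= 1), "caller_sensitivity",
      "probabilities must be in [0,1]")
  chk(all(cfg$breakpoint_jitter_sd >= 0), "breakpoint_jitter_sd",
      "must be non-negative")
  chk(cfg$false_call_rate >= 0, "false_call_rate", "must be non-negative")
  chk(cfg$duplications_per_origin >= 0, "duplications_per_origin",
      "must be non-negative")
  invisible(cfg)
}

## size class used by the caller-sensitivity model
size_class <- function(len) {
  ifelse(len < 500, "small", ifelse(len <= 10000, "mid", "large"))
}
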