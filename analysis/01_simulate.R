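#!/usr/bin/env Rscript
# Step 1 — generate the synthetic study.
#
# Builds the default study: 2 x 1 Mb chromosomes, 12 accessions, 200
# mechanism-labelled CNVs (50 each of MEI / VNTR / NAHR / NHR, 80%
# insertions in the reference lineage), a 2%-diverged outgroup with
# assembly gaps, and noisy PE/SR/RD call sets (sensitivity 0.9 with the
# usual method biases, 50 bp paired-end jitter, 5 false calls per Mb per
# caller).  All downstream steps work from the plain-text files written
# here.

library(cnvpol)

out <- "results/study"
cfg <- sim_config(seed = 20260921L)
study <- simulate_cnv_study(cfg)
write_study(study, out)

truth <- study$truth
cat(sprintf("wrote %s: %d truth events (%s), %d raw calls, %d accessions\n",
            out, nrow(truth),
            paste(names(table(truth$mechanism)),
                  table(truth$mechanism), sep = "=", collapse = ", "),
            nrow(study$calls), cfg$n_accessions))
cat(sprintf("insertion-state events: %d/%d (%.0f%%)\n",
            sum(truth$ancestral_state == "insertion"), nrow(truth),
            100 * mean(truth$ancestral_state == "insertion")))
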