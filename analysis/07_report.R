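#!/usr/bin/env Rscript
# Step 7 — final catalog report, re-derived from the stage files.

library(cnvpol)

## write_report() expects the stage files in one directory
for (f in c("consensus.tsv", "polarized.tsv", "mechanisms.tsv",
            "gene_impact.tsv", "sharing.tsv")) {
  stopifnot(file.exists(file.path("results", f)))
}
rep <- write_report("results")
cat(readLines("results/report.txt"), sep = "\n")
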