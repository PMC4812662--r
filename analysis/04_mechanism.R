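#!/usr/bin/env Rscript
# Step 4 — formation-mechanism classification from junction signatures.
#
# Decision order VNTR > MEI > NAHR > NHR > ambiguous, using tandem-array
# context, TE coverage of the event body, junction-anchored extended
# homology and junction microhomology.

library(cnvpol)

pol <- read.table("results/polarized.tsv", sep = "\t", header = TRUE)
truth <- read.table("results/study/truth.tsv", sep = "\t", header = TRUE)
matches <- read.table("results/merge_matches.tsv", sep = "\t",
                      header = TRUE)
ref <- read_fasta("results/study/reference.fa")
te <- read_bed("results/study/te.bed")
names(te)[names(te) == "name"] <- "family"
vn <- read_bed("results/study/vntr.bed")
vn$period <- as.integer(vn$name)

mech <- classify_mechanisms(
  pol[, c("event_id", "chrom", "start", "end", "precise")],
  ref, te, vn, mechanism_params())
write.table(mech, "results/mechanisms.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE)
s <- summarize_mechanisms(mech, pol)
write.table(s$distribution, "results/mechanism_distribution.tsv",
            sep = "\t", quote = FALSE, row.names = FALSE)

print(s$distribution, row.names = FALSE)
em <- evaluate_mechanism(mech, truth, matches)
cat(sprintf("mechanism accuracy vs truth: %.3f\n", em$accuracy))
print(round(em$per_class, 3))
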