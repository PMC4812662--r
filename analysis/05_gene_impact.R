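#!/usr/bin/env Rscript
# Step 5 — gene impact, population sharing and term enrichment.

library(cnvpol)

pol <- read.table("results/polarized.tsv", sep = "\t", header = TRUE)
gff <- read_gff3("results/study/genes.gff3")
groups <- read.table("results/study/groups.tsv", sep = "\t", header = TRUE)
terms <- read.table("results/study/terms.tsv", sep = "\t", header = TRUE)

im <- classify_gene_impact(pol, gff$genes, gff$gene_features)
write.table(im$impacts, "results/gene_impact.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)
cat(sprintf("genes affected: %d (by %d CNVs); CDS disrupted in %d genes\n",
            im$summary$n_genes, im$summary$n_cnvs,
            im$summary$n_cds_disrupted))
print(im$summary$genes_per_category)

sh <- population_sharing(pol, groups)
write.table(sh$events, "results/sharing.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE)
cat("cultivated/wild sharing:\n"); print(round(sh$group_fractions, 3))
cat("indica/japonica sharing:\n"); print(round(sh$subgroup_fractions, 3))

if (nrow(im$impacts) > 0) {
  enr <- hypergeom_enrichment(unique(im$impacts$gene_id), terms,
                              gff$genes$gene_id)
  write.table(enr, "results/enrichment.tsv", sep = "\t", quote = FALSE,
              row.names = FALSE)
  cat(sprintf("terms tested: %d; significant at FDR<0.05: %d\n",
              nrow(enr), sum(enr$significant)))
}
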