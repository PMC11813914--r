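#!/usr/bin/env Rscript
# Stage 1: generate the synthetic study inputs.
#
# Emulates the study design downstream stages expect: two breed groups of
# 10 lactating goats, a 1,000-marker panel (a desk-scale stand-in for the
# ~60K array) with first-order LD, three planted 5-SNP QTL windows on the
# focal trait, phenotype records drawn around the published group means,
# and a 100-taxon rumen ASV table with two genuinely shifted taxa.

suppressPackageStartupMessages(library(goatfe))

out <- "results/simdata"
dir.create(out, recursive = TRUE, showWarnings = FALSE)

cfg <- sim_config(seed = 20260921,
                  asv_effect_taxa = list(c(5, 2), c(12, -1)))
geno <- simulate_genotypes(cfg)
ph <- simulate_phenotypes(geno, cfg)
asv <- simulate_asv_table(cfg)

write_ped(geno, file.path(out, "goats"))
write.table(ph$records, file.path(out, "phenotypes.tsv"), sep = "\t",
            quote = FALSE, row.names = FALSE)
tax_str <- apply(asv$taxonomy, 1, function(x)
  paste(ifelse(is.na(x), "", x), collapse = ";"))
write.table(data.frame(taxon_id = colnames(asv$counts), t(asv$counts),
                       taxonomy = tax_str, check.names = FALSE),
            file.path(out, "asv_counts.tsv"), sep = "\t", quote = FALSE,
            row.names = FALSE)
saveRDS(list(cfg = cfg, truth = ph$truth), "results/simdata/truth.rds")

cat("Simulated", nrow(geno$calls), "animals x", ncol(geno$calls),
    "SNPs;", nrow(ph$truth$qtl_windows), "QTL windows planted at:\n")
print(ph$truth$qtl_windows)
cat("Realized h2 of the focal trait:",
    round(ph$truth$true_h2, 3), "\n")

genes <- simulate_gene_annotation(geno$map, seed = 20260921)
genes$name <- genes$gene_id
rtracklayer::export(genes, file.path(out, "genes.bed"))
cat("Wrote", length(genes), "synthetic gene intervals to genes.bed\n")
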