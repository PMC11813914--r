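#!/usr/bin/env Rscript
# Stage 5: back-solve SNP effects from the GEBVs, partition genetic
# variance into sliding 5-SNP windows, flag windows explaining > 0.1%
# of the total genetic variance, and annotate them with genes.

suppressPackageStartupMessages(library(goatfe))

geno <- read_ped("results/simdata/goats")
qc <- apply_qc(geno)
grm <- build_grm(qc$geno)
Z <- sweep(qc$geno$calls, 2, 2 * grm$allele_freqs)
vc <- read.table("results/gblup/variance_components.tsv", header = TRUE,
                 sep = "\t")
truth <- readRDS("results/simdata/truth.rds")$truth

dir.create("results/winscan", showWarnings = FALSE)
for (tr in vc$trait) {
  gebv <- read.table(sprintf("results/gblup/gebv_%s.tsv", tr),
                     header = TRUE, sep = "\t")
  eff <- suppressWarnings(
    backsolve_snp_effects(Z, gebv$gebv, p = grm$allele_freqs))
  eff <- per_snp_variance(eff)
  wt <- window_scan(Z, eff, qc$geno$map,
                    sigma2_a = vc$sigma2_a[vc$trait == tr])
  wt <- annotate_windows(wt, "results/simdata/genes.bed")
  out <- as.data.frame(wt); out$trait <- tr
  write.table(out, sprintf("results/winscan/windows_%s.tsv", tr),
              sep = "\t", quote = FALSE, row.names = FALSE)
  write.table(manhattan_table(wt),
              sprintf("results/winscan/manhattan_%s.tsv", tr),
              sep = "\t", quote = FALSE, row.names = FALSE)
  sig <- out[out$significant, ]
  cat(sprintf("%-14s %d/%d windows > 0.1%% of genetic variance\n",
              tr, nrow(sig), nrow(out)))
}
cat("\nPlanted QTL windows (chrom: SNP index span):\n")
print(truth$qtl_windows)
cat("At 20 animals the back-solved effects spread thinly over ~1,000\n")
cat("markers, so individual windows hold small shares and only a few\n")
cat("cross the 0.1% line -- the expected picture for a herd this size.\n")
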