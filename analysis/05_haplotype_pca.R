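#!/usr/bin/env Rscript
# Do the same haplotypes underlie parallel differentiation? Global PCA per
# side (outlier regions excluded, 1 site / 10 kb), then a local PCA over
# each SHDR's outlier windows; altitude as a predictor of local PC1 while
# controlling for global PC1 (LMG partial R^2). Also karyotype-clusters the
# planted inversion block and contrasts isolation by distance vs by
# environment from the pairwise Fst matrix.

suppressPackageStartupMessages(library(repadapt))

inp <- read_genotype_vcf("results/data/genotypes.vcf")
popmap <- read_popmap("results/data/popmap.tsv")
cfg <- read_sim_config("results/data/sim_config.yaml")
counts <- allele_counts(inp$genotypes, popmap, inp$sites)
dt <- default_trios(popmap)
focal <- popmap[popmap$species == "focal", ]

rows <- list()
for (sd_ in unique(dt$layout$side)) {
  side_tr <- dt$layout$transect[dt$layout$side == sd_]
  smp <- focal$sample[focal$side == sd_]
  excl <- do.call(rbind, lapply(side_tr, function(t)
    read_bed(sprintf("results/hdr_%s.bed", t))))
  gp <- global_pca(inp$genotypes[, smp], inp$sites, exclude = excl)
  cat(sprintf("%s global PCA: PC1 %.1f%%, PC2 %.1f%%\n", sd_,
              100 * gp$var_share[1], 100 * gp$var_share[2]))
  alt <- focal$altitude_m[match(smp, focal$sample)]
  for (t in side_tr) {
    win <- read.delim(sprintf("results/windows_%s.tsv", t))
    out_w <- call_outliers(win)
    shdr <- read_bed(sprintf("results/hdr_%s.bed", t))
    shdr <- shdr[shdr$name != "private", , drop = FALSE]
    for (i in seq_len(nrow(shdr))) {
      inwin <- out_w[out_w$chrom == shdr$chrom[i] &
                       out_w$centre >= shdr$start[i] &
                       out_w$centre < shdr$end[i],
                     c("chrom", "start", "end")]
      if (nrow(inwin) == 0) next
      lp <- tryCatch(local_pca(inp$genotypes[, smp], inp$sites,
                               merge_intervals(inwin)),
                     error = function(e) NULL)
      if (is.null(lp)) next
      aa <- altitude_association(lp$scores[, 1], alt, gp$scores[smp, 1])
      rows[[length(rows) + 1]] <- data.frame(
        side = sd_, transect = t, chrom = shdr$chrom[i],
        start = shdr$start[i], end = shdr$end[i],
        pc1_var = lp$var_share[1], p_altitude = aa$p_altitude,
        partial_r2_altitude = aa$partial_r2_altitude)
    }
  }
}
assoc <- do.call(rbind, rows)
write.table(assoc, "results/altitude_association.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)
cat(sprintf(
  "\n%d/%d SHDR local PCAs: altitude significant (p < 0.05); mean local PC1 share %.0f%%; mean altitude partial R2 %.2f\n",
  sum(assoc$p_altitude < 0.05, na.rm = TRUE), nrow(assoc),
  100 * mean(assoc$pc1_var), mean(assoc$partial_r2_altitude, na.rm = TRUE)))

# inversion karyotypes: local PCA over the planted block on chr2 (east)
truth <- read_bed("results/data/truth.bed")
inv <- truth[grepl("^inversion_block", truth$name), , drop = FALSE]
if (nrow(inv)) {
  east <- focal$sample[focal$side == "east"]
  lp <- local_pca(inp$genotypes[, east], inp$sites, inv)
  kc <- suppressWarnings(karyotype_cluster(lp$scores[, 1]))
  cat("\nInversion-block karyotype clusters (eastern samples):\n")
  print(table(kc$assignment))
  cat(sprintf("cluster separation (mean silhouette): %.2f\n", kc$separation))
}

# IBD vs IBE over the focal populations; straight-line stand-in distances on
# a transect layout (real analyses would supply least-cost path distances)
pops <- unique(focal$population)
cnt_f <- counts
fst <- pairwise_fst_matrix(counts, thin_gap = 2000)[pops, pops]
coord <- cbind(
  x = as.numeric(factor(focal$transect[match(pops, focal$population)])) * 50,
  y = focal$altitude_m[match(pops, focal$population)] / 20
)
dmat <- as.matrix(dist(coord)); dimnames(dmat) <- list(pops, pops)
cls <- setNames(focal$altitude_class[match(pops, focal$population)], pops)
ibe <- ibd_ibe_contrast(fst, dmat, cls)
cat(sprintf("\nIBE contrast (high-low vs low-low residuals): p = %.3g\n",
            ibe$p))
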