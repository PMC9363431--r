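#!/usr/bin/env Rscript
# Corroborating selection signatures inside shared HDRs: minimum Tajima's D
# and delta-pi and maximum Dxy per SHDR, compared against extrema of 10,000
# randomly placed interval sets (10th/90th percentile rule), tallying how
# many statistics support each region beyond the defining zPBS/zFst.

suppressPackageStartupMessages(library(repadapt))

cfg <- read_sim_config("results/data/sim_config.yaml")
cl <- chrom_lengths(cfg)
popmap <- read_popmap("results/data/popmap.tsv")
dt <- default_trios(popmap)

for (t in names(dt$trios)) {
  tab <- read.delim(sprintf("results/windows_%s.tsv", t))
  hdr_bed <- read_bed(sprintf("results/hdr_%s.bed", t))
  if (nrow(hdr_bed) == 0) { cat(t, ": no HDRs\n"); next }
  shdr <- hdr_bed[hdr_bed$name != "private", , drop = FALSE]
  if (nrow(shdr) == 0) { cat(t, ": no shared HDRs\n"); next }
  ex <- shdr_extrema(shdr, tab)
  nulls <- permuted_extrema_null(tab, shdr$end - shdr$start, cl,
                                 n_perm = 10000, seed = 4)
  cls <- classify_outliers(ex, nulls)
  write.table(cls, sprintf("results/enrichment_%s.tsv", t), sep = "\t",
              quote = FALSE, row.names = FALSE)
  el <- cls[cls$eligible, , drop = FALSE]
  cat(sprintf(
    "%s: %d/%d SHDRs carry >= 1 extra outlier statistic (TajD %d, dpi %d, Dxy %d)\n",
    t, sum(el$n_outlier_stats >= 1), nrow(el), sum(el$out_tajd),
    sum(el$out_delta_pi), sum(el$out_dxy)))
}
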