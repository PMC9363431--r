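# Independent oracles: brute-force / closed-form reimplementations used to
# check the package's statistics. They deliberately share no code with the
# implementation paths they verify.

# Mean pairwise Hamming difference among haplotype columns, per window
# length (nucleotide diversity oracle).
oracle_pi_haplotypes <- function(haps, window_length) {
  n <- ncol(haps)
  tot <- 0
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      tot <- tot + sum(haps[, i] != haps[, j])
    }
  }
  tot / choose(n, 2) / window_length
}

# Mean pairwise difference between haplotypes of two populations (Dxy
# oracle), per window length.
oracle_dxy_haplotypes <- function(hapsA, hapsB, window_length) {
  tot <- 0
  for (i in seq_len(ncol(hapsA))) {
    for (j in seq_len(ncol(hapsB))) {
      tot <- tot + sum(hapsA[, i] != hapsB[, j])
    }
  }
  tot / (ncol(hapsA) * ncol(hapsB)) / window_length
}

# Straight-from-formula Tajima's D for one window: S segregating sites,
# theta_pi the summed mean pairwise differences, n haplotypes.
oracle_tajimas_d <- function(theta_pi, s, n) {
  a1 <- sum(1 / seq_len(n - 1))
  a2 <- sum(1 / seq_len(n - 1)^2)
  b1 <- (n + 1) / (3 * (n - 1))
  b2 <- (2 * (n^2 + n + 3)) / (9 * n * (n - 1))
  c1 <- b1 - 1 / a1
  c2 <- b2 - (n + 2) / (a1 * n) + a2 / a1^2
  e1 <- c1 / a1
  e2 <- c2 / (a1^2 + a2)
  (theta_pi - s / a1) / sqrt(e1 * s + e2 * s * (s - 1))
}

# Direct PBS evaluation from three pairwise Fst values.
oracle_pbs_high <- function(f_hl, f_hd, f_ld) {
  tt <- function(f) -log(1 - min(max(f, 0), 1 - 1e-9))
  (tt(f_hl) + tt(f_hd) - tt(f_ld)) / 2
}

# Brute-force LMG partial R^2 for two predictors: average incremental
# R^2 over the two orderings.
oracle_lmg <- function(y, x1, x2) {
  r2 <- function(f) summary(f)$r.squared
  full <- r2(lm(y ~ x1 + x2))
  only1 <- r2(lm(y ~ x1))
  only2 <- r2(lm(y ~ x2))
  c(x1 = mean(c(only1, full - only2)), x2 = mean(c(only2, full - only1)))
}

# Build an allele_counts object directly from per-population haplotype
# matrices (sites x haplotypes, 0/1); diploids are formed by pairing
# consecutive haplotypes.
counts_from_haplotypes <- function(hap_list, positions, chrom = "chr1") {
  genos <- list()
  popmap <- list()
  for (pop in names(hap_list)) {
    h <- hap_list[[pop]]
    stopifnot(ncol(h) %% 2 == 0)
    g <- h[, seq(1, ncol(h), by = 2), drop = FALSE] +
      h[, seq(2, ncol(h), by = 2), drop = FALSE]
    colnames(g) <- sprintf("%s_%d", pop, seq_len(ncol(g)))
    genos[[pop]] <- g
    popmap[[pop]] <- data.frame(
      sample = colnames(g), population = pop, transect = pop,
      side = "west", altitude_class = "high", altitude_m = 1000,
      species = "focal", stringsAsFactors = FALSE
    )
  }
  geno <- do.call(cbind, genos)
  sites <- data.frame(chrom = chrom, pos = positions)
  allele_counts(geno, do.call(rbind, popmap), sites)
}

# Random 0/1 haplotype matrix with allele frequencies drawn uniformly.
random_haplotypes <- function(n_sites, n_haps) {
  p <- runif(n_sites, 0.05, 0.95)
  matrix(rbinom(n_sites * n_haps, 1, rep(p, n_haps)), nrow = n_sites)
}
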