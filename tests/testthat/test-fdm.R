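# Build an allele_counts object straight from a frequency table, treating
# frequencies as exact (large-n haplotype counts), for analytic f_dM checks.
counts_from_freqs <- function(p1, p2, p3, pO, positions = NULL, n = 1000) {
  m <- cbind(P1 = p1, P2 = p2, P3 = p3, O = pO)
  if (is.null(positions)) positions <- seq(100, by = 100, length.out = nrow(m))
  structure(
    list(sites = data.frame(chrom = "chr1", pos = positions),
         count = m * n, n = matrix(n, nrow(m), 4, dimnames = dimnames(m)),
         freq = m),
    class = "allele_counts"
  )
}

q_std <- quartet_config("P1", "P2", "P3", "O")
grid1 <- window_grid(c(chr1 = 50000), 50000, 50000)

test_that("f_dM hits its analytic corner values", {
  k <- 30
  # complete sharing between P3 and the highland P2
  cnt <- counts_from_freqs(rep(0, k), rep(0.5, k), rep(0.5, k), rep(0, k))
  expect_equal(fdm_track(cnt, q_std, grid1, min_sites = 1)$fdm, 1)

  # mirror case: sharing with the lowland P1
  cnt2 <- counts_from_freqs(rep(0.5, k), rep(0, k), rep(0.5, k), rep(0, k))
  expect_equal(fdm_track(cnt2, q_std, grid1, min_sites = 1)$fdm, -1)

  # p1 = p2 everywhere: ABBA and BABA cancel identically
  set.seed(2)
  p <- runif(k)
  cnt3 <- counts_from_freqs(p, p, runif(k), rep(0, k))
  expect_equal(fdm_track(cnt3, q_std, grid1, min_sites = 1)$fdm, 0)
})

test_that("f_dM is antisymmetric under P1/P2 exchange and bounded by 1", {
  set.seed(7)
  for (i in 1:20) {
    k <- 40
    p1 <- runif(k); p2 <- runif(k); p3 <- runif(k)
    pO <- rbinom(k, 1, 0.1) * runif(k, 0, 0.15)
    cnt <- counts_from_freqs(p1, p2, p3, pO)
    swapped <- counts_from_freqs(p2, p1, p3, pO)
    f <- fdm_track(cnt, q_std, grid1, min_sites = 1)$fdm
    g <- fdm_track(swapped, q_std, grid1, min_sites = 1)$fdm
    expect_equal(f, -g, tolerance = 1e-10)
    expect_lte(abs(f), 1)
  }
})

test_that("outgroup polarization flips and filters sites", {
  # a site where the outgroup is fixed for the alternate allele must be
  # repolarized, making P1 the derived-allele carrier
  cnt <- counts_from_freqs(c(0.5, 0.5), c(1, 0), c(0.5, 0.5), c(1, 0))
  # site1 polarized: derived p1 = 0.5, p2 = 0, p3 = 0.5, pO = 0 -> negative
  f <- fdm_track(cnt, q_std, grid1, min_sites = 1)$fdm
  expect_lt(f, 0)

  # outgroup polymorphic beyond tolerance: site dropped
  cnt2 <- counts_from_freqs(c(0, 0), c(0.5, 0.5), c(0.5, 0.5), c(0.4, 0))
  f2 <- fdm_track(cnt2, q_std, grid1, min_sites = 1)
  expect_equal(f2$n_informative, 1)

  # Patterson's D agrees in sign with f_dM on a directional table
  cnt3 <- counts_from_freqs(rep(0.1, 30), rep(0.6, 30), rep(0.7, 30),
                            rep(0, 30))
  expect_gt(patterson_d(cnt3, q_std)$d, 0)
})

test_that("windows below the informative-site minimum are null", {
  cnt <- counts_from_freqs(rep(0, 10), rep(0.5, 10), rep(0.5, 10), rep(0, 10))
  tr <- fdm_track(cnt, q_std, grid1, min_sites = 20)
  expect_true(is.na(tr$fdm))
  expect_equal(tr$n_informative, 10)
})

test_that("featureless simulations have near-zero genome-wide f_dM", {
  means <- vapply(1:6, function(s) {
    cfg <- two_transect_config(seed = 100 + s, n_sites = 6000,
                               n_chromosomes = 2, with_donor = TRUE)
    ds <- simulate_dataset(cfg)
    cnt <- allele_counts(ds$genotypes, ds$popmap, ds$sites)
    tr <- fdm_track(cnt, quartet_config("t1_low", "t1_high", "donor", "outgroup"),
                    chrom_lens = chrom_lengths(cfg))
    expect_true(all(abs(tr$fdm) <= 1, na.rm = TRUE))
    mean(tr$fdm, na.rm = TRUE)
  }, numeric(1))
  mc_se <- sd(means) / sqrt(length(means))
  expect_lt(abs(mean(means)), 3 * mc_se + 0.02)
})

test_that("planted introgression raises f_dM inside the tract", {
  ft <- planted_feature("introgression", "chr2", 200000, 500000,
                        c("t1_high", "t2_high"), donor_population = "donor",
                        intensity = 0.85)
  cfg <- two_transect_config(seed = 55, n_sites = 12000, n_chromosomes = 3,
                             planted_features = list(ft), with_donor = TRUE)
  ds <- simulate_dataset(cfg)
  cnt <- allele_counts(ds$genotypes, ds$popmap, ds$sites)
  tr <- fdm_track(cnt, quartet_config("t1_low", "t1_high", "donor", "outgroup"),
                  chrom_lens = chrom_lengths(cfg))
  inside <- tr$chrom == "chr2" & tr$start >= 200000 & tr$end <= 500000
  expect_gt(mean(tr$fdm[inside], na.rm = TRUE),
            mean(tr$fdm[!inside], na.rm = TRUE))
  wt <- wilcox.test(tr$fdm[inside], tr$fdm[!inside], alternative = "greater")
  expect_lt(wt$p.value, 0.01)
})

test_that("SHDR f_dM outlier calling follows the 90th-percentile-of-|min| rule", {
  g <- window_grid(c(chr1 = 1e6), 50000, 50000)
  g$fdm <- 0
  g$n_informative <- 50
  shdrs <- data.frame(chrom = "chr1", start = seq(0, 9e5, 1e5),
                      end = seq(0, 9e5, 1e5) + 5e4)
  zero <- shdr_fdm_outliers(g, shdrs)
  expect_equal(zero$threshold, 0)
  expect_equal(zero$pct_outlier, 0)

  g2 <- g
  set.seed(3)
  g2$fdm <- runif(nrow(g2), -0.1, 0.1)
  g2$fdm[3] <- 0.8  # window [100k, 150k) sits inside the second region
  out <- shdr_fdm_outliers(g2, shdrs)
  expect_true(out$per_shdr$outlier[2])
  expect_equal(out$per_shdr$max_fdm[2], 0.8)

  expect_warning(shdr_fdm_outliers(g2, shdrs[1:3, ]), "low power")
})

test_that("the KS enrichment test is one-sided in the highland direction", {
  same <- rep(seq(0.05, 0.5, length.out = 20), 1)
  expect_gt(fdm_enrichment_test(same, same)$p, 0.9)
  shifted <- fdm_enrichment_test(same + 0.5, same)
  expect_lt(shifted$p, 0.05)
  # shift in the other direction must NOT look enriched
  expect_gt(fdm_enrichment_test(same - 0.3, same)$p, 0.5)
  expect_error(fdm_enrichment_test(same[1:3], same), "insufficient")
})

test_that("background permutations honour their count and collapse when constant", {
  g <- window_grid(c(chr1 = 1e6, chr2 = 1e6), 50000, 50000)
  g$fdm <- 0.07
  bg <- background_fdm(g, widths = c(1e5, 2e5), chrom_lens = c(chr1 = 1e6, chr2 = 1e6),
                       n_perm = 1000, seed = 2, observed_mean_max = 0.07)
  expect_length(bg$null, 1000)
  expect_true(all(bg$null == 0.07))
  b2 <- background_fdm(g, c(1e5), c(chr1 = 1e6, chr2 = 1e6), n_perm = 100,
                       seed = 5, observed_mean_max = 0.2)
  expect_equal(b2$p, 1 / 101)
})
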