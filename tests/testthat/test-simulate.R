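test_that("zero-drift limit copies the ancestral frequency everywhere", {
  cfg <- two_transect_config(seed = 4, f = 0, n_sites = 2000,
                             n_chromosomes = 1)
  cfg$drift_tree$f[] <- 0
  fr <- simulate_frequencies(cfg)
  expect_true(all(abs(fr$freqs - fr$freqs[, 1]) == 0))

  # with finite samples the Fst estimator is unbiased around 0, so the
  # genome-wide ratio-of-sums estimate must not be positive on average
  geno <- sample_genotypes(fr)
  cnt <- allele_counts(geno, sim_popmap(cfg), fr$sites)
  ab <- suppressWarnings(hudson_fst_site(cnt$freq[, "t1_high"], cnt$n[, "t1_high"],
                                         cnt$freq[, "t1_low"], cnt$n[, "t1_low"]))
  fst <- sum(ab$alpha, na.rm = TRUE) / sum(ab$beta, na.rm = TRUE)
  expect_lt(fst, 0.005)
})

test_that("a full-intensity sweep fixes the target population", {
  ft <- planted_feature("sweep", "chr1", 100000, 150000, "t1_high",
                        intensity = 1)
  cfg <- two_transect_config(seed = 2, n_sites = 3000, n_chromosomes = 1,
                             planted_features = list(ft))
  cfg$sweep_sfs_thin <- 0
  fr <- simulate_frequencies(cfg)
  idx <- fr$sites$pos >= 100000 & fr$sites$pos < 150000
  expect_true(all(fr$freqs[idx, "t1_high"] == 1))
  expect_false(all(fr$freqs[idx, "t1_low"] == 1))
})

test_that("genome-wide Fst between sister populations matches the frequency-moment oracle", {
  cfg <- two_transect_config(seed = 9, f = 0.05, n_sites = 20000,
                             n_chromosomes = 2, n_diploids = 8)
  fr <- simulate_frequencies(cfg)
  geno <- sample_genotypes(fr)
  cnt <- allele_counts(geno, sim_popmap(cfg), fr$sites)

  p1 <- fr$freqs[, "t1_high"]; p2 <- fr$freqs[, "t1_low"]
  oracle <- sum((p1 - p2)^2) / sum(p1 * (1 - p2) + p2 * (1 - p1))

  ab <- suppressWarnings(hudson_fst_site(cnt$freq[, "t1_high"], cnt$n[, "t1_high"],
                                         cnt$freq[, "t1_low"], cnt$n[, "t1_low"]))
  est <- sum(ab$alpha, na.rm = TRUE) / sum(ab$beta, na.rm = TRUE)

  # Monte-Carlo SE of the genotype-sampling step by site-block jackknife
  blocks <- cut(seq_along(p1), 20, labels = FALSE)
  theta <- vapply(1:20, function(b) {
    k <- blocks != b
    sum(ab$alpha[k], na.rm = TRUE) / sum(ab$beta[k], na.rm = TRUE)
  }, numeric(1))
  se <- sqrt(19 / 20 * sum((theta - mean(theta))^2))
  expect_lt(abs(est - oracle), 3 * se + 1e-4)
})

test_that("genotype sampling is exact at fixed sites and binomial at p = 0.5", {
  pops <- list(population_spec("a", "t", "west", "high", 1000, 1000))
  cfg <- sim_config(pops, star_tree("a", 0), n_chromosomes = 1,
                    chrom_length = 3000, n_sites = 3, seed = 5)
  fr <- simulate_frequencies(cfg)
  fr$freqs[1, "a"] <- 0
  fr$freqs[2, "a"] <- 1
  fr$freqs[3, "a"] <- 0.5
  g <- sample_genotypes(fr)
  expect_true(all(g[1, ] == 0))
  expect_true(all(g[2, ] == 2))
  p_hat <- sum(g[3, ]) / (2 * 1000)
  expect_lt(abs(p_hat - 0.5), 3 * sqrt(0.25 / 2000))
  fr_bad <- fr
  fr_bad$freqs[1, 1] <- 1.5
  expect_error(sample_genotypes(fr_bad), "frequencies")
})

test_that("identical configurations reproduce byte-identical datasets", {
  cfg <- two_transect_config(seed = 31, n_sites = 1000, n_chromosomes = 1,
                             with_donor = TRUE)
  d1 <- simulate_dataset(cfg)
  d2 <- simulate_dataset(two_transect_config(seed = 31, n_sites = 1000,
                                             n_chromosomes = 1,
                                             with_donor = TRUE))
  expect_identical(d1$freqs, d2$freqs)
  expect_identical(d1$genotypes, d2$genotypes)
  d3 <- simulate_dataset(two_transect_config(seed = 32, n_sites = 1000,
                                             n_chromosomes = 1,
                                             with_donor = TRUE))
  expect_false(identical(d1$genotypes, d3$genotypes))
})

test_that("feature validation rejects inconsistent configurations", {
  expect_error(planted_feature("introgression", "chr1", 0, 10, "a"),
               "donor")
  expect_error(planted_feature("sweep", "chr1", 10, 10, "a"), "interval")
  expect_error(planted_feature("sweep", "chr1", 0, 10, "a", intensity = 1.2),
               "intensity")
  ft <- planted_feature("sweep", "chr1", 0, 2e6, "t1_high")
  expect_error(two_transect_config(planted_features = list(ft)),
               "exceeds chromosome length")
  ft2 <- planted_feature("sweep", "chr1", 1000, 2000, "nobody")
  expect_error(two_transect_config(planted_features = list(ft2)),
               "unknown population")
  f_a <- planted_feature("sweep", "chr1", 1000, 5000, "t1_high")
  f_b <- planted_feature("sweep", "chr1", 4000, 9000, "t2_high")
  expect_error(two_transect_config(planted_features = list(f_a, f_b)),
               "overlap")
  # different kinds may overlap
  f_c <- planted_feature("shared_standing", "chr1", 4000, 9000, "t2_high")
  expect_s3_class(two_transect_config(planted_features = list(f_a, f_c)),
                  "sim_config")
})

test_that("planted features move frequencies as specified", {
  fts <- list(
    planted_feature("shared_standing", "chr1", 100000, 150000,
                    c("t1_high", "t2_high"), intensity = 0.7),
    planted_feature("introgression", "chr1", 300000, 350000, "t1_high",
                    donor_population = "donor", intensity = 0.8)
  )
  cfg <- two_transect_config(seed = 8, n_sites = 5000, n_chromosomes = 1,
                             planted_features = fts, with_donor = TRUE)
  fr <- simulate_frequencies(cfg)
  st <- fr$sites$pos >= 100000 & fr$sites$pos < 150000
  expect_true(all(fr$freqs[st, "t1_high"] == 0.7))
  expect_true(all(fr$freqs[st, "t2_high"] == 0.7))

  # introgressed frequencies equal the stated donor mixture exactly
  cfg0 <- cfg
  cfg0$planted_features <- fts[1]
  fr0 <- simulate_frequencies(cfg0)
  ig <- fr$sites$pos >= 300000 & fr$sites$pos < 350000
  expect_equal(fr$freqs[ig, "t1_high"],
               0.2 * fr0$freqs[ig, "t1_high"] + 0.8 * fr0$freqs[ig, "donor"],
               tolerance = 1e-12)
})

test_that("outgroup populations carry the ancestral state almost everywhere", {
  cfg <- two_transect_config(seed = 12, n_sites = 5000, n_chromosomes = 1,
                             with_donor = TRUE)
  fr <- simulate_frequencies(cfg)
  expect_gt(mean(fr$freqs[, "outgroup"] == 0), 0.95)
  expect_true(all(fr$freqs[, "outgroup"] < 0.5))
})
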