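test_that("ld thinning keeps the greedy left-to-right subset", {
  s <- data.frame(chrom = "chr1", pos = c(1, 5000, 9999, 10001))
  expect_equal(ld_thin(s, 10000), c(1, 4))

  s2 <- data.frame(chrom = c("chr1", "chr2", "chr3"), pos = c(5, 5, 5))
  expect_equal(ld_thin(s2, 10000), 1:3)

  expect_equal(ld_thin(data.frame(chrom = character(), pos = numeric())),
               integer(0))

  set.seed(2)
  s3 <- data.frame(chrom = rep(c("chr1", "chr2"), each = 500),
                   pos = c(sort(sample(1e6, 500)), sort(sample(1e6, 500))))
  kept <- s3[ld_thin(s3, 10000), ]
  for (ch in c("chr1", "chr2")) {
    expect_true(all(diff(kept$pos[kept$chrom == ch]) >= 10000))
  }
})

make_cluster_geno <- function(n_per = 6, n_sites = 60) {
  g <- matrix(0L, n_sites, 2 * n_per)
  g[, seq_len(n_per)] <- 2L
  set.seed(1)
  noise <- matrix(rbinom(length(g), 1, 0.05), nrow(g))
  g <- pmin(pmax(g + noise - rbinom(length(g), 1, 0.05), 0), 2)
  colnames(g) <- sprintf("s%02d", seq_len(ncol(g)))
  storage.mode(g) <- "integer"
  g
}

test_that("global PCA separates constructed clusters and is duplication-invariant", {
  g <- make_cluster_geno()
  sites <- data.frame(chrom = "chr1", pos = seq(0, by = 20000, length.out = nrow(g)))
  pca <- global_pca(g, sites, thin_gap = 1)
  grp <- rep(c(1, 2), each = 6)
  expect_true(abs(cor(pca$scores[, 1], grp)) > 0.99)
  expect_gt(pca$var_share[1], max(pca$var_share[-1]))
  expect_true(all(diff(pca$var_share) <= 1e-12))
  expect_lte(sum(pca$var_share), 1 + 1e-12)

  # duplicated samples land on identical scores; sample order is irrelevant
  g2 <- cbind(g, g[, 1, drop = FALSE])
  colnames(g2)[13] <- "dup"
  pca2 <- global_pca(g2, sites, thin_gap = 1)
  expect_equal(pca2$scores["dup", ], pca2$scores["s01", ], tolerance = 1e-9)
  perm <- sample(ncol(g))
  pca3 <- global_pca(g[, perm], sites, thin_gap = 1)
  expect_equal(pca3$scores[colnames(g), 1], pca$scores[, 1], tolerance = 1e-8)

  expect_error(global_pca(matrix(1L, 10, 4,
                                 dimnames = list(NULL, paste0("s", 1:4))),
                          data.frame(chrom = "chr1", pos = 1:10 * 100),
                          thin_gap = 1),
               "zero variance")
})

test_that("global PCA honours exclusions", {
  g <- make_cluster_geno()
  sites <- data.frame(chrom = rep(c("chr1", "chr2"), each = 30),
                      pos = rep(seq(0, by = 20000, length.out = 30), 2))
  excl <- data.frame(chrom = "chr1", start = 0, end = 1e6)
  pca <- global_pca(g, sites, exclude = excl, thin_gap = 1)
  expect_true(all(pca$site_index <= 30))  # only chr2 sites survive
  pca2 <- global_pca(g, sites, exclude_chroms = "chr2", thin_gap = 1)
  expect_true(all(pca2$site_index <= 30))
})

test_that("local PCA on an SHDR separates altitude classes", {
  g <- make_cluster_geno()
  sites <- data.frame(chrom = "chr1", pos = seq(1000, by = 1000, length.out = nrow(g)))
  region <- data.frame(chrom = "chr1", start = 0, end = 30000)
  lp <- local_pca(g, sites, region)
  expect_equal(nrow(lp$scores), 12)
  expect_gte(lp$var_share[1], lp$var_share[2])
})

test_that("altitude association recovers constructed signals with exact LMG", {
  set.seed(4)
  n <- 40
  alt <- rep(c(1200, 300), each = n / 2)
  glob <- rnorm(n)
  # local PC1 proportional to altitude, global orthogonal noise
  pc1 <- scale(alt)[, 1] + rnorm(n, 0, 0.05)
  aa <- altitude_association(pc1, alt, glob)
  expect_gt(aa$partial_r2_altitude, 0.9)
  expect_lt(aa$p_altitude, 1e-6)

  # local PC1 tracking global structure only
  pc2 <- glob + rnorm(n, 0, 0.05)
  aa2 <- altitude_association(pc2, alt, glob)
  expect_lt(aa2$partial_r2_altitude, 0.1)
  expect_gt(aa2$partial_r2_global, 0.8)

  # LMG equals the brute-force ordering average and sums to model R^2
  for (i in 1:10) {
    y <- rnorm(30); x1 <- rnorm(30); x2 <- 0.5 * x1 + rnorm(30)
    aa3 <- altitude_association(y, x1, x2)
    bf <- oracle_lmg(y, x1, x2)
    expect_equal(aa3$partial_r2_altitude, unname(bf["x1"]), tolerance = 1e-12)
    expect_equal(aa3$partial_r2_global, unname(bf["x2"]), tolerance = 1e-12)
    expect_equal(aa3$partial_r2_altitude + aa3$partial_r2_global,
                 aa3$r_squared, tolerance = 1e-10)
  }

  # collinear predictors are flagged, not fitted
  aa4 <- altitude_association(rnorm(10), 1:10, (1:10) * 2)
  expect_true(aa4$collinear)
  expect_true(is.na(aa4$p_altitude))
  expect_error(altitude_association(1:3, 1:3, 1:3), ">= 4 samples")
})

test_that("karyotype clustering labels the three PC1 groups", {
  k <- karyotype_cluster(c(-1, -1, 0, 0, 1, 1))
  expect_equal(as.character(k$assignment),
               c("wt/wt", "wt/wt", "inv/wt", "inv/wt", "inv/inv", "inv/inv"))
  expect_equal(k$centers, c(-1, 0, 1))

  # flipping the sign flips homozygote labels only
  k2 <- karyotype_cluster(-c(-1, -1, 0, 0, 1, 1))
  expect_equal(as.character(k2$assignment),
               c("inv/inv", "inv/inv", "inv/wt", "inv/wt", "wt/wt", "wt/wt"))
  k3 <- karyotype_cluster(-c(-1, -1, 0, 0, 1, 1), wt = "high")
  expect_equal(as.character(k3$assignment), as.character(k$assignment))

  set.seed(5)
  expect_warning(karyotype_cluster(rnorm(30)), "separation")
  deg <- karyotype_cluster(rep(c(0, 1), 5))
  expect_true(deg$degenerate)
  expect_error(karyotype_cluster(1:5), ">= 6")
})

test_that("the pairwise Fst matrix is consistent with the window machinery", {
  cfg <- two_transect_config(seed = 15, n_sites = 4000, n_chromosomes = 1)
  ds <- simulate_dataset(cfg)
  cnt <- allele_counts(ds$genotypes, ds$popmap, ds$sites)
  m <- pairwise_fst_matrix(cnt, thin_gap = 0)
  expect_true(isSymmetric(m))
  expect_equal(diag(m), setNames(rep(0, ncol(m)), colnames(m)))

  # whole genome as one window reproduces each pair (no thinning)
  poly <- apply(cnt$freq, 1, max, na.rm = TRUE) > 0 &
    apply(cnt$freq, 1, min, na.rm = TRUE) < 1
  cnt_poly <- cnt
  cnt_poly$freq <- cnt$freq[poly, ]; cnt_poly$n <- cnt$n[poly, ]
  cnt_poly$count <- cnt$count[poly, ]; cnt_poly$sites <- cnt$sites[poly, ]
  grid1 <- window_grid(c(chr1 = 1e6), 1e6, 1e6)
  w <- window_fst(cnt_poly, "t1_high", "t2_low", grid1, min_sites = 1)
  expect_equal(m["t1_high", "t2_low"], w$fst, tolerance = 1e-12)

  # analytic edges
  haps <- list(a = matrix(c(1, 0), 2, 4), b = matrix(c(0, 1), 2, 4))
  cnt2 <- counts_from_haplotypes(haps, positions = c(100, 5000))
  m2 <- pairwise_fst_matrix(cnt2, thin_gap = 0)
  expect_equal(m2["a", "b"], 1)
  haps3 <- list(a = matrix(c(1, 0, 1, 0), 1), b = matrix(c(0, 1, 0, 1), 1))
  cnt3 <- counts_from_haplotypes(haps3, positions = 100)
  expect_lte(pairwise_fst_matrix(cnt3, thin_gap = 0)["a", "b"], 0)
})

test_that("the IBD/IBE contrast detects planted highland differentiation", {
  pops <- paste0("p", 1:8)
  cls <- setNames(rep(c("high", "low"), each = 4), pops)
  set.seed(6)
  coords <- matrix(runif(16, 0, 100), ncol = 2)
  dmat <- as.matrix(dist(coords))
  dimnames(dmat) <- list(pops, pops)

  # equal Fst everywhere: no class difference
  flat <- matrix(0.05, 8, 8, dimnames = list(pops, pops)); diag(flat) <- 0
  r0 <- ibd_ibe_contrast(flat, dmat, cls)
  expect_gt(r0$p, 0.4)

  # extra differentiation whenever a highland population is involved
  fst <- 0.001 * dmat
  for (i in 1:8) for (j in 1:8) {
    if (i != j && xor(cls[i] == "high", cls[j] == "high")) {
      fst[i, j] <- fst[i, j] + 0.05
    }
  }
  r1 <- ibd_ibe_contrast(fst, dmat, cls)
  expect_lt(r1$p, 0.01)
  expect_true(all(c("high-high", "high-low", "low-low") %in% r1$pairs$class))

  bad <- dmat; bad[1, 2] <- bad[1, 2] + 5
  expect_error(ibd_ibe_contrast(fst, bad, cls), "symmetric")
})
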