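lens <- c(chr1 = 2e6, chr2 = 2e6)
four_layout <- data.frame(transect = c("a", "b", "c", "d"),
                          side = c("west", "west", "east", "east"))

set_of <- function(iv, transect = "x") hdr_set(iv, lens, transect)
iv1 <- data.frame(chrom = "chr1", start = c(0, 500000), end = c(100000, 700000))

test_that("sharing classes follow the overlap rules", {
  sets <- list(a = set_of(iv1, "a"), b = set_of(iv1, "b"),
               c = set_of(iv1, "c"), d = set_of(iv1, "d"))
  cl <- classify_sharing(sets, four_layout)
  expect_true(all(cl$sets$a$intervals$sharing_class == "shdr_allopatric"))
  expect_equal(cl$summary$prop_shared, rep(1, 4))
  expect_equal(cl$summary$prop_allopatric, rep(1, 4))

  far <- data.frame(chrom = "chr2", start = 1.5e6, end = 1.6e6)
  sets2 <- list(a = set_of(iv1, "a"), b = set_of(far, "b"),
                c = set_of(far, "c"), d = set_of(iv1, "d"))
  cl2 <- classify_sharing(sets2, four_layout)
  expect_true(all(cl2$sets$a$intervals$sharing_class == "private"))

  # replicate overlap without opposite-side support: within-side only
  sets3 <- list(
    a = set_of(data.frame(chrom = "chr1", start = 0, end = 100000), "a"),
    b = set_of(data.frame(chrom = "chr1", start = 90000, end = 200000), "b"),
    c = set_of(iv1[0, ], "c"), d = set_of(iv1[0, ], "d"))
  cl3 <- classify_sharing(sets3, four_layout)
  expect_equal(cl3$sets$a$intervals$sharing_class, "shdr_within_side")

  # counts are nested: allopatric <= within-side <= total
  s <- cl$summary
  expect_true(all(s$n_allopatric <= s$n_shared & s$n_shared <= s$n_hdr))
})

test_that("random interval placement respects widths and bounds", {
  set.seed(5)
  for (i in 1:20) {
    w <- sample(1e4:5e5, 5)
    placed <- random_intervals(w, lens)
    expect_equal(placed$end - placed$start, w)
    expect_true(all(placed$start >= 0))
    expect_true(all(placed$end <= lens[placed$chrom]))
  }
  expect_error(random_intervals(3e6, lens), "fits on no chromosome")
})

test_that("the sharing permutation null behaves at its edges", {
  whole <- data.frame(chrom = names(lens), start = 0, end = lens)
  sets <- list(a = set_of(whole, "a"), b = set_of(whole, "b"))
  layout <- one_side_layout
  names(sets) <- layout$transect <- c("t1", "t2")
  pn <- overlap_permutation_null(sets, layout, n_perm = 50, seed = 1,
                                 focal = "t1")
  expect_equal(pn$t1$observed[["within"]], 1)
  expect_true(all(pn$t1$null_within == 1))
  expect_equal(pn$t1$p_within, 1)

  tiny <- data.frame(chrom = "chr1", start = 1e6, end = 1.005e6)
  sets2 <- list(t1 = set_of(tiny, "t1"), t2 = set_of(tiny, "t2"))
  pn2 <- overlap_permutation_null(sets2, layout, n_perm = 2000, seed = 3,
                                  focal = "t1")
  expect_lte(pn2$t1$p_within, 0.01)

  expect_error(overlap_permutation_null(sets2, layout, n_perm = 0), "positive")
})

test_that("permutation p-values are calibrated when the focal set is itself random", {
  # The sharing proportion over a handful of intervals is discrete, so ties
  # against the null make the empirical p stepped and conservative; the
  # meaningful property is calibration: rejection at alpha stays at or below
  # alpha (within binomial error), and the p-values are not degenerate.
  set.seed(101)
  partner <- set_of(random_interval_set(8, lens), "t2")
  layout <- one_side_layout
  n_rep <- 200
  pvals <- vapply(seq_len(n_rep), function(r) {
    widths <- sample(2e4:2e5, 6)
    focal <- hdr_set(random_intervals(widths, lens), lens, "t1")
    sets <- list(t1 = focal, t2 = partner)
    overlap_permutation_null(sets, layout, n_perm = 99, seed = r,
                             focal = "t1")$t1$p_within
  }, numeric(1))
  expect_lte(mean(pvals <= 0.05), 0.07)
  expect_lte(mean(pvals <= 0.25), 0.25 + 3 * sqrt(0.25 * 0.75 / n_rep))
  expect_gt(mean(pvals <= 0.5), 0.2)
})

test_that("the block jackknife matches a brute-force delete-one recomputation", {
  set.seed(21)
  focal_iv <- random_interval_set(50, lens)
  focal_iv$end <- pmin(focal_iv$start + 50000, lens[focal_iv$chrom])
  focal <- hdr_set(focal_iv, lens, "t1", merge = FALSE)
  partner <- set_of(random_interval_set(10, lens), "t2")
  sets <- list(t1 = focal, t2 = partner)
  jk <- jackknife_ci(sets, one_side_layout, "t1", block_size = 2e5)
  expect_equal(jk$n_blocks, 20)
  expect_true(jk$lower <= jk$estimate && jk$estimate <= jk$upper)

  # brute force: recompute the proportion over all 20 deletions
  blocks <- window_grid(lens, 2e5, 2e5)
  mid <- (focal$intervals$start + focal$intervals$end) / 2
  hit <- repadapt:::overlaps_any(focal$intervals, partner$intervals)
  theta <- vapply(seq_len(nrow(blocks)), function(k) {
    keep <- !(focal$intervals$chrom == blocks$chrom[k] &
                mid >= blocks$start[k] & mid < blocks$end[k])
    if (!any(keep)) jk$estimate else mean(hit[keep])
  }, numeric(1))
  se_bf <- sqrt(19 / 20 * sum((theta - mean(theta))^2))
  expect_equal(jk$se, se_bf, tolerance = 1e-12)

  # identical leave-one-out replicates -> zero-width CI
  allhit <- set_of(data.frame(chrom = names(lens), start = 0, end = lens), "t2")
  sets2 <- list(t1 = focal, t2 = allhit)
  jk2 <- jackknife_ci(sets2, one_side_layout, "t1", block_size = 2e5)
  expect_equal(jk2$se, 0)
  expect_equal(jk2$lower, jk2$upper)
})

test_that("recombination comparison separates constructed distributions", {
  rho <- data.frame(chrom = "chr1", centre = seq(25000, 2e6, 50000))
  rho$rho <- 2
  hdrs <- set_of(data.frame(chrom = "chr1", start = 0, end = 3e5), "t1")
  flat <- recomb_comparison(hdrs, rho)
  expect_equal(flat$ks_d, 0)

  rho2 <- rho
  rho2$rho <- ifelse(rho2$centre < 3e5, 0.1, 2 + rnorm(nrow(rho2), 0, 0.1))
  sep <- recomb_comparison(hdrs, rho2)
  expect_lt(sep$p, 0.05)

  empty <- hdr_set(iv1[0, ], lens, "t1")
  expect_error(recomb_comparison(empty, rho), "no rho windows fall inside")
})

test_that("candidate overlap testing counts and permutes correctly", {
  hdrs <- set_of(iv1, "t1")
  same <- candidate_overlap_test(hdrs, iv1, n_perm = 50, seed = 2)
  expect_equal(same$observed, nrow(iv1))

  off <- data.frame(chrom = "chr2", start = c(0, 1e6), end = c(1e4, 1.01e6))
  expect_equal(candidate_overlap_test(hdrs, off, 10, 2)$observed, 0)

  set.seed(33)
  cand <- rbind(iv1, random_interval_set(10, lens))
  r1 <- candidate_overlap_test(hdrs, cand, n_perm = 500, seed = 9)
  r2 <- candidate_overlap_test(hdrs, cand, n_perm = 500, seed = 9)
  expect_identical(r1$null, r2$null)
  expect_true(r1$p > 0 && r1$p <= 1)
})
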