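# Population structure: LD thinning, global and local PCA of genotype
# dosages, altitude-association models with LMG partial R-squared, inversion
# karyotype clustering, pairwise Fst matrices and isolation-by-distance /
# isolation-by-environment contrasts.

#' Greedy distance-based site thinning
#'
#' Left-to-right per chromosome: a site is kept iff it lies at least
#' `min_gap` bp from the last kept site.
#'
#' @param sites Data frame `chrom`, `pos` (0-based), sorted by position
#'   within chromosome.
#' @param min_gap Minimum spacing in bp.
#' @return Integer indices of retained sites.
#' @export
ld_thin <- function(sites, min_gap = 10000) {
  if (nrow(sites) == 0) return(integer(0))
  keep <- logical(nrow(sites))
  for (ch in unique(sites$chrom)) {
    idx <- which(sites$chrom == ch)
    if (is.unsorted(sites$pos[idx])) stop("sites must be sorted within chromosome")
    last <- -Inf
    for (i in idx) {
      if (sites$pos[i] - last >= min_gap) {
        keep[i] <- TRUE
        last <- sites$pos[i]
      }
    }
  }
  which(keep)
}

# Core dosage PCA: samples x sites, mean imputation, column centring, SVD.
# Sign fixed per component: the largest-|loading| site gets a positive
# loading, so output is deterministic under sample reordering.
dosage_pca <- function(geno) {
  x <- t(geno)
  for (j in seq_len(ncol(x))) {
    nas <- is.na(x[, j])
    if (any(nas)) x[nas, j] <- mean(x[, j], na.rm = TRUE)
  }
  x <- scale(x, center = TRUE, scale = FALSE)
  keep <- apply(x, 2, function(v) any(v != 0))
  if (!any(keep)) stop("genotype matrix has zero variance")
  x <- x[, keep, drop = FALSE]
  sv <- svd(x)
  flip <- vapply(seq_len(ncol(sv$v)), function(k) {
    sign(sv$v[which.max(abs(sv$v[, k])), k])
  }, numeric(1))
  flip[flip == 0] <- 1
  scores <- sweep(sv$u %*% diag(sv$d, nrow = length(sv$d)), 2, flip, `*`)
  loadings <- sweep(sv$v, 2, flip, `*`)
  rownames(scores) <- rownames(x)
  colnames(scores) <- paste0("PC", seq_len(ncol(scores)))
  structure(
    list(scores = scores,
         var_share = sv$d^2 / sum(sv$d^2),
         loadings = loadings,
         site_index = which(keep)),
    class = "pca_result"
  )
}

#' @export
print.pca_result <- function(x, ...) {
  cat(sprintf("pca_result: %d samples; PC1 %.1f%%, PC2 %.1f%% of variance\n",
              nrow(x$scores), 100 * x$var_share[1],
              100 * (x$var_share[2] %||% NA)))
  invisible(x)
}

#' Genome-wide (global) PCA of genotype dosages
#'
#' Restricts sites to those outside excluded (outlier/HDR) windows and
#' excluded chromosomes, thins to one site per `thin_gap`, mean-imputes
#' missing dosages, column-centres and decomposes by SVD.
#'
#' @param genotypes Sites x samples dosage matrix.
#' @param sites Data frame `chrom`, `pos` aligned with rows.
#' @param exclude Optional interval data frame (or `hdr_set`) of regions
#'   whose sites are dropped.
#' @param exclude_chroms Optional chromosome names to drop entirely (e.g. a
#'   chromosome carrying a large inversion).
#' @param thin_gap Thinning distance in bp.
#' @return A `pca_result`: sample `scores`, `var_share` per component,
#'   site `loadings`.
#' @export
global_pca <- function(genotypes, sites, exclude = NULL, exclude_chroms = NULL,
                       thin_gap = 10000) {
  keep <- rep(TRUE, nrow(sites))
  if (!is.null(exclude_chroms)) keep <- keep & !(sites$chrom %in% exclude_chroms)
  if (!is.null(exclude)) {
    iv <- intervals_of(exclude)
    if (nrow(iv)) {
      inside <- overlaps_any(
        data.frame(chrom = sites$chrom, start = sites$pos, end = sites$pos + 1), iv)
      keep <- keep & !inside
    }
  }
  idx <- which(keep)
  thin <- idx[ld_thin(sites[idx, , drop = FALSE], thin_gap)]
  if (length(thin) < 2) stop("fewer than 2 sites left after filtering")
  dosage_pca(genotypes[thin, , drop = FALSE])
}

#' Local PCA over one region's outlier windows
#'
#' As [global_pca()] but restricted to the sites inside the supplied
#' intervals (typically one SHDR's outlier windows) with no thinning or
#' window exclusion.
#'
#' @param genotypes Sites x samples dosage matrix.
#' @param sites Data frame `chrom`, `pos`.
#' @param intervals Interval data frame (or `hdr_set`) delimiting the region.
#' @return A `pca_result`.
#' @export
local_pca <- function(genotypes, sites, intervals) {
  iv <- intervals_of(intervals)
  inside <- overlaps_any(
    data.frame(chrom = sites$chrom, start = sites$pos, end = sites$pos + 1), iv)
  if (sum(inside) < 2) stop("fewer than 2 sites inside the region")
  dosage_pca(genotypes[inside, , drop = FALSE])
}

#' Altitude-association model for a local PCA
#'
#' Ordinary least squares `local_PC1 ~ altitude_m + global_PC1`, with the
#' altitude t-test p-value and LMG partial R-squared (average of sequential
#' R-squared contributions over both predictor orderings, exact for two
#' predictors; the two partial values sum to the model R-squared).
#'
#' @param local_pc1 Local PC1 score per sample.
#' @param altitude_m Altitude (metres) per sample.
#' @param global_pc1 Global PC1 score per sample.
#' @param collinearity_tol Flag the model as collinear when the
#'   altitude/global-PC1 correlation exceeds this in absolute value.
#' @return List `coef_altitude`, `p_altitude`, `r_squared`,
#'   `partial_r2_altitude`, `partial_r2_global`, `collinear`, `model`.
#' @export
altitude_association <- function(local_pc1, altitude_m, global_pc1,
                                 collinearity_tol = 0.999) {
  n <- length(local_pc1)
  if (n < 4 || length(altitude_m) != n || length(global_pc1) != n) {
    stop("need >= 4 samples with aligned predictor vectors")
  }
  if (stats::sd(altitude_m) == 0 || stats::sd(global_pc1) == 0 ||
      abs(stats::cor(altitude_m, global_pc1)) > collinearity_tol) {
    return(list(coef_altitude = NA_real_, p_altitude = NA_real_,
                r_squared = NA_real_, partial_r2_altitude = NA_real_,
                partial_r2_global = NA_real_, collinear = TRUE, model = NULL))
  }
  df <- data.frame(y = local_pc1, alt = altitude_m, glob = global_pc1)
  fit <- stats::lm(y ~ alt + glob, data = df)
  r2 <- function(f) summary(f)$r.squared
  r2_full <- r2(fit)
  r2_alt <- r2(stats::lm(y ~ alt, data = df))
  r2_glob <- r2(stats::lm(y ~ glob, data = df))
  # LMG for two predictors: average first-in and last-in contributions
  part_alt <- mean(c(r2_alt, r2_full - r2_glob))
  part_glob <- mean(c(r2_glob, r2_full - r2_alt))
  cf <- summary(fit)$coefficients
  list(coef_altitude = cf["alt", "Estimate"],
       p_altitude = cf["alt", "Pr(>|t|)"],
       r_squared = r2_full,
       partial_r2_altitude = part_alt,
       partial_r2_global = part_glob,
       collinear = FALSE, model = fit)
}

#' Karyotype clustering of local PC1 scores
#'
#' One-dimensional k-means with k = 3, deterministically initialised at the
#' minimum, median and maximum score; clusters are labelled by PC1 order as
#' the two homozygote classes with the heterozygote in the middle. Which
#' homozygote is the non-inverted ("wt") arrangement is caller-supplied
#' metadata; the default orientation labels the low-PC1 cluster `wt/wt`.
#'
#' @param pc1 Local PC1 scores (>= 6 samples).
#' @param wt `"low"` or `"high"`: which PC1 extreme is the wild-type
#'   homozygote.
#' @return List `assignment` (factor `wt/wt`, `inv/wt`, `inv/inv` per
#'   sample), `centers` (ordered cluster means), `separation` (silhouette-
#'   style diagnostic in [0, 1]; low values mean no real 3-cluster
#'   structure), `degenerate`.
#' @export
karyotype_cluster <- function(pc1, wt = c("low", "high")) {
  wt <- match.arg(wt)
  if (length(pc1) < 6) stop("karyotype clustering requires >= 6 samples")
  if (length(unique(pc1)) < 3) {
    return(list(assignment = factor(rep(NA, length(pc1)),
                                    levels = c("wt/wt", "inv/wt", "inv/inv")),
                centers = rep(NA_real_, 3), separation = NA_real_,
                degenerate = TRUE))
  }
  init <- matrix(c(min(pc1), stats::median(pc1), max(pc1)), ncol = 1)
  if (anyDuplicated(init)) init <- matrix(stats::quantile(pc1, c(0, 0.5, 1), type = 1) +
                                            c(0, 1e-9, 2e-9), ncol = 1)
  km <- stats::kmeans(matrix(pc1, ncol = 1), centers = init)
  ord <- order(km$centers)
  rank_of <- match(km$cluster, ord)
  labels <- if (wt == "low") c("wt/wt", "inv/wt", "inv/inv") else
    c("inv/inv", "inv/wt", "wt/wt")
  centers <- as.numeric(km$centers[ord])
  # mean silhouette over the 1-D clustering; ~1 for clean trimodal scores,
  # ~0.5 for unimodal data carved into thirds
  sil <- vapply(seq_along(pc1), function(i) {
    own <- rank_of[i]
    a <- mean(abs(pc1[i] - pc1[rank_of == own & seq_along(pc1) != i]))
    if (is.nan(a)) a <- 0
    b <- min(vapply(setdiff(1:3, own), function(k) {
      mean(abs(pc1[i] - pc1[rank_of == k]))
    }, numeric(1)))
    if (max(a, b) == 0) 0 else (b - a) / max(a, b)
  }, numeric(1))
  separation <- mean(sil)
  if (is.na(separation) || separation < 0.65) {
    warning("weak cluster separation; PC1 may be unimodal")
  }
  list(assignment = factor(labels[rank_of],
                           levels = c("wt/wt", "inv/wt", "inv/inv")),
       centers = centers, separation = separation, degenerate = FALSE)
}

#' Pairwise Hudson Fst matrix across populations
#'
#' Ratio-of-sums Hudson Fst per population pair over LD-thinned polymorphic
#' sites. Values are reported as computed (small negative estimates are not
#' clamped).
#'
#' @param counts An [allele_counts()] object.
#' @param thin_gap Minimum spacing between retained sites (bp).
#' @return Symmetric population x population matrix with zero diagonal.
#' @export
pairwise_fst_matrix <- function(counts, thin_gap = 2000) {
  idx <- ld_thin(counts$sites, thin_gap)
  freq <- counts$freq[idx, , drop = FALSE]
  nh <- counts$n[idx, , drop = FALSE]
  # polymorphic across the dataset (fixed differences between populations
  # count), not merely within single populations
  hi <- apply(freq, 1, max, na.rm = TRUE)
  lo <- apply(freq, 1, min, na.rm = TRUE)
  poly <- is.finite(hi) & is.finite(lo) & hi > 0 & lo < 1
  freq <- freq[poly, , drop = FALSE]
  nh <- nh[poly, , drop = FALSE]
  pops <- colnames(freq)
  m <- matrix(0, length(pops), length(pops), dimnames = list(pops, pops))
  for (i in seq_along(pops)) {
    for (j in seq_len(i - 1)) {
      ab <- suppressWarnings(hudson_fst_site(freq[, i], nh[, i], freq[, j], nh[, j]))
      m[i, j] <- m[j, i] <- sum(ab$alpha, na.rm = TRUE) / sum(ab$beta, na.rm = TRUE)
    }
  }
  m
}

#' Isolation-by-distance / isolation-by-environment contrast
#'
#' Labels every population pair `high-high`, `high-low` or `low-low`
#' (distant lowland counts as lowland), fits per-class linear Fst ~ distance
#' models, and rank-tests whether high-low pairs sit above low-low pairs
#' after removing the common distance trend.
#'
#' @param fst_matrix Symmetric pairwise Fst matrix.
#' @param dist_matrix Symmetric pairwise distance matrix (same populations,
#'   same order; e.g. least-cost-path distances supplied externally).
#' @param altitude_class Named vector mapping population to
#'   `high`/`low`/`low_distant`.
#' @return List `pairs` (per-pair table with class and residuals),
#'   `fits` (per-class lm or `NULL`), `test` (one-sided Wilcoxon rank test of
#'   high-low vs low-low residuals), `p`.
#' @export
ibd_ibe_contrast <- function(fst_matrix, dist_matrix, altitude_class) {
  if (!isSymmetric(unname(as.matrix(dist_matrix)), tol = 1e-8)) {
    stop("distance matrix must be symmetric")
  }
  pops <- rownames(fst_matrix)
  if (is.null(pops) || !identical(dim(fst_matrix), dim(as.matrix(dist_matrix)))) {
    stop("fst and distance matrices must match")
  }
  cls <- ifelse(altitude_class[pops] == "high", "high", "low")
  pr <- t(utils::combn(seq_along(pops), 2))
  pairs <- data.frame(
    pop1 = pops[pr[, 1]], pop2 = pops[pr[, 2]],
    fst = fst_matrix[pr], dist = as.matrix(dist_matrix)[pr],
    class = paste(pmin(cls[pr[, 1]], cls[pr[, 2]]),
                  pmax(cls[pr[, 1]], cls[pr[, 2]]), sep = "-"),
    stringsAsFactors = FALSE
  )
  pooled <- stats::lm(fst ~ dist, data = pairs)
  pairs$residual <- round(stats::resid(pooled), 12)
  fits <- lapply(split(pairs, pairs$class), function(d) {
    if (nrow(d) >= 3 && stats::sd(d$dist) > 0) stats::lm(fst ~ dist, data = d) else NULL
  })
  hl <- pairs$residual[pairs$class == "high-low"]
  ll <- pairs$residual[pairs$class == "low-low"]
  test <- if (length(hl) && length(ll)) {
    suppressWarnings(stats::wilcox.test(hl, ll, alternative = "greater"))
  } else NULL
  list(pairs = pairs, fits = fits, test = test,
       p = if (is.null(test)) NA_real_ else test$p.value)
}
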