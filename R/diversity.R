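# Windowed diversity and neutrality statistics: nucleotide diversity (pi),
# Tajima's D, absolute divergence (Dxy) and the elevation diversity
# difference (delta-pi), all on the same fixed window grid as the
# differentiation scan.

#' Windowed nucleotide diversity
#'
#' Per variant site the unbiased mean pairwise difference
#' `2 p (1 - p) n / (n - 1)` (with `n` the called haplotypes) is summed over
#' the window and divided by the window's effective length: the full window
#' size by default, or the number of accessible bases if a mask of
#' accessible intervals is supplied.
#'
#' @param counts An [allele_counts()] object.
#' @param pop Population id.
#' @param grid Window grid from [window_grid()].
#' @param mask Optional data frame `chrom`, `start`, `end` (0-based
#'   half-open) of accessible regions used as the denominator.
#' @param hits Optional precomputed site/window map.
#' @return Numeric vector of per-window pi (`NA` where the effective length
#'   is zero).
#' @export
pi_window <- function(counts, pop, grid, mask = NULL, hits = NULL) {
  p <- counts$freq[, pop]
  n <- counts$n[, pop]
  contrib <- ifelse(n >= 2, 2 * p * (1 - p) * n / (n - 1), NA_real_)
  if (is.null(hits)) hits <- site_window_hits(counts$sites, grid)
  tot <- window_sum(contrib, hits, nrow(grid))
  len <- effective_window_length(grid, mask)
  out <- tot / len
  out[len == 0] <- NA_real_
  out
}

effective_window_length <- function(grid, mask = NULL) {
  if (is.null(mask)) return(grid$end - grid$start)
  gw <- gr_from_bed(grid$chrom, grid$start, grid$end)
  gm <- GenomicRanges::reduce(gr_from_bed(mask$chrom, mask$start, mask$end))
  ov <- GenomicRanges::findOverlaps(gw, gm)
  w <- rep(0, nrow(grid))
  if (length(ov)) {
    inter <- IRanges::pintersect(gw[S4Vectors::queryHits(ov)],
                                 gm[S4Vectors::subjectHits(ov)])
    s <- rowsum(GenomicRanges::width(inter), S4Vectors::queryHits(ov))
    w[as.integer(rownames(s))] <- s[, 1]
  }
  w
}

# Tajima's D normalising constants for n haplotypes.
tajima_constants <- function(n) {
  stopifnot(n >= 3)
  i <- seq_len(n - 1)
  a1 <- sum(1 / i)
  a2 <- sum(1 / i^2)
  b1 <- (n + 1) / (3 * (n - 1))
  b2 <- 2 * (n^2 + n + 3) / (9 * n * (n - 1))
  c1 <- b1 - 1 / a1
  c2 <- b2 - (n + 2) / (a1 * n) + a2 / a1^2
  e1 <- c1 / a1
  e2 <- c2 / (a1^2 + a2)
  list(a1 = a1, a2 = a2, b1 = b1, b2 = b2, c1 = c1, c2 = c2, e1 = e1, e2 = e2)
}

#' Windowed Tajima's D
#'
#' Standard Tajima's D contrasting the mean pairwise diversity with
#' Watterson's estimator from the segregating-site count. Constants use the
#' population's total haplotype count; windows with no segregating sites are
#' `NA`.
#'
#' @inheritParams pi_window
#' @return Numeric vector of per-window D.
#' @export
tajimas_d_window <- function(counts, pop, grid, hits = NULL) {
  n_hap <- max(counts$n[, pop])
  if (n_hap < 3) stop("Tajima's D requires at least 3 haplotypes")
  konst <- tajima_constants(n_hap)
  p <- counts$freq[, pop]
  n <- counts$n[, pop]
  seg <- is.finite(p) & p > 0 & p < 1 & n >= 2
  contrib <- ifelse(seg, 2 * p * (1 - p) * n / (n - 1), NA_real_)
  if (is.null(hits)) hits <- site_window_hits(counts$sites, grid)
  nw <- nrow(grid)
  theta_pi <- window_sum(contrib, hits, nw)
  s <- window_count(seg, hits, nw)
  d <- rep(NA_real_, nw)
  ok <- s > 0
  v <- sqrt(konst$e1 * s[ok] + konst$e2 * s[ok] * (s[ok] - 1))
  d[ok] <- (theta_pi[ok] - s[ok] / konst$a1) / v
  d
}

#' Windowed absolute divergence (Dxy)
#'
#' Per site, Dxy is recovered from within-group and pooled mean pairwise
#' diversities as
#' `[theta_AB C(nAB,2) - theta_A C(nA,2) - theta_B C(nB,2)] / (nA nB)`,
#' with all group sizes counted in haplotypes; this reduces exactly to the
#' mean pairwise difference between sequences drawn from the two
#' populations. The window value is the site sum over the window's
#' effective length (full window size by default).
#'
#' @param counts An [allele_counts()] object.
#' @param popA,popB Population ids.
#' @param grid Window grid.
#' @param mask Optional accessibility mask (see [pi_window()]).
#' @param hits Optional precomputed site/window map.
#' @return Numeric vector of per-window Dxy.
#' @export
dxy_window <- function(counts, popA, popB, grid, mask = NULL, hits = NULL) {
  nA <- counts$n[, popA]; nB <- counts$n[, popB]
  cA <- counts$count[, popA]; cB <- counts$count[, popB]
  nAB <- nA + nB
  pA <- cA / nA; pB <- cB / nB; pAB <- (cA + cB) / nAB
  # theta_X * C(nX, 2) = pX (1 - pX) nX^2
  num <- pAB * (1 - pAB) * nAB^2 - pA * (1 - pA) * nA^2 - pB * (1 - pB) * nB^2
  dxy_site <- num / (nA * nB)
  dxy_site[nA < 2 | nB < 2] <- NA_real_
  if (is.null(hits)) hits <- site_window_hits(counts$sites, grid)
  tot <- window_sum(dxy_site, hits, nrow(grid))
  len <- effective_window_length(grid, mask)
  out <- tot / len
  out[len == 0] <- NA_real_
  out
}

#' Elevation difference in nucleotide diversity
#'
#' `delta_pi = pi_high - pi_reference`, where the reference is the distant
#' lowland population when available and the nearby lowland otherwise.
#' Strongly negative values are the footprint a highland sweep leaves.
#'
#' @param pi_high,pi_ref Per-window pi tracks on the same grid.
#' @return Elementwise difference (`NA` propagates).
#' @export
delta_pi <- function(pi_high, pi_ref) {
  if (length(pi_high) != length(pi_ref)) {
    stop("pi tracks must share one window grid")
  }
  pi_high - pi_ref
}

#' Selection-signature tracks for one transect
#'
#' Bundles, on the differentiation grid, the statistics used to corroborate
#' selection inside shared high-differentiation regions: Tajima's D of the
#' highland population, delta-pi (highland minus distant-lowland, or lowland
#' when no distant population exists) and Dxy between the same pair.
#'
#' @param counts An [allele_counts()] object.
#' @param trio Named list with `high`, `low`, optional `low_distant`.
#' @param grid Window grid.
#' @param mask Optional accessibility mask.
#' @return `grid` plus columns `tajd_high`, `pi_high`, `pi_ref`, `delta_pi`,
#'   `dxy`.
#' @export
selection_tracks <- function(counts, trio, grid, mask = NULL) {
  trio <- as.list(trio)
  ref <- if (!is.null(trio$low_distant) && !is.na(trio$low_distant)) {
    trio$low_distant
  } else {
    trio$low
  }
  hits <- site_window_hits(counts$sites, grid)
  out <- grid
  out$tajd_high <- tajimas_d_window(counts, trio$high, grid, hits = hits)
  out$pi_high <- pi_window(counts, trio$high, grid, mask, hits = hits)
  out$pi_ref <- pi_window(counts, ref, grid, mask, hits = hits)
  out$delta_pi <- delta_pi(out$pi_high, out$pi_ref)
  out$dxy <- dxy_window(counts, trio$high, ref, grid, mask, hits = hits)
  out
}
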