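# Per-site and windowed differentiation statistics: Hudson Fst components,
# ratio-of-sums windowed Fst, PBS, and genome-wide z-normalisation on a
# fixed sliding-window grid (default 5 kb windows, 1 kb steps).

#' Per-population allele counts from a genotype matrix
#'
#' @param genotypes Integer sites x samples dosage matrix (0/1/2, `NA`
#'   missing), columns named by sample.
#' @param popmap Population map data frame (see [read_popmap()]).
#' @param sites Data frame `chrom`, `pos` (0-based) aligned with the rows.
#' @return An `allele_counts` list: `sites`, `count` (derived-allele count,
#'   sites x populations), `n` (called haplotypes, 2 x called diploids) and
#'   `freq` (`count / n`, `NaN` where no calls).
#' @export
allele_counts <- function(genotypes, popmap, sites) {
  popmap <- validate_popmap(popmap)
  miss <- setdiff(popmap$sample, colnames(genotypes))
  if (length(miss)) stop("samples in popmap absent from genotypes: ",
                         paste(utils::head(miss, 5), collapse = ", "))
  pops <- unique(popmap$population)
  cnt <- matrix(0, nrow = nrow(genotypes), ncol = length(pops),
                dimnames = list(NULL, pops))
  nh <- cnt
  for (p in pops) {
    g <- genotypes[, popmap$sample[popmap$population == p], drop = FALSE]
    cnt[, p] <- rowSums(g, na.rm = TRUE)
    nh[, p] <- 2 * rowSums(!is.na(g))
  }
  structure(list(sites = sites, count = cnt, n = nh, freq = cnt / nh),
            class = "allele_counts")
}

#' Sliding-window grid over a genome
#'
#' @param chrom_lens Named vector of chromosome lengths.
#' @param size Window size in bp.
#' @param step Step in bp (`step = size` gives non-overlapping windows).
#' @return Data frame `chrom`, `start`, `end` (0-based half-open), `centre`
#'   (`start + size / 2`).
#' @export
window_grid <- function(chrom_lens, size = 5000, step = 1000) {
  stopifnot(size > 0, step > 0)
  out <- lapply(names(chrom_lens), function(ch) {
    len <- chrom_lens[[ch]]
    if (len < size) return(NULL)
    starts <- seq(0, len - size, by = step)
    data.frame(chrom = ch, start = starts, end = starts + size,
               centre = starts + size / 2, stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

# index map: for each site, the window rows containing it
site_window_hits <- function(sites, grid) {
  gr_sites <- gr_from_bed(sites$chrom, sites$pos, sites$pos + 1)
  gr_win <- gr_from_bed(grid$chrom, grid$start, grid$end)
  hits <- GenomicRanges::findOverlaps(gr_sites, gr_win)
  list(site = S4Vectors::queryHits(hits), window = S4Vectors::subjectHits(hits))
}

window_sum <- function(values, hits, n_windows) {
  out <- rep(0, n_windows)
  ok <- !is.na(values[hits$site])
  s <- rowsum(values[hits$site][ok], hits$window[ok])
  out[as.integer(rownames(s))] <- s[, 1]
  out
}

window_count <- function(keep, hits, n_windows) {
  out <- rep(0L, n_windows)
  ok <- keep[hits$site]
  if (any(ok)) {
    tb <- table(hits$window[ok])
    out[as.integer(names(tb))] <- as.integer(tb)
  }
  out
}

#' Per-site Hudson Fst components
#'
#' Bhatia's estimator: `alpha = (p1 - p2)^2 - p1(1-p1)/(n1-1) - p2(1-p2)/(n2-1)`
#' and `beta = p1(1-p2) + p2(1-p1)`, with `n` counted in haplotypes. Sites
#' with fewer than 2 haplotypes in either population are returned as `NA`
#' and tallied in the `n_skipped` attribute.
#'
#' @param p1,p2 Allele frequencies in the two populations.
#' @param n1,n2 Called haplotype counts.
#' @return List with numeric vectors `alpha` and `beta` (attribute
#'   `n_skipped` on `alpha`).
#' @export
hudson_fst_site <- function(p1, n1, p2, n2) {
  bad <- !is.finite(p1) | !is.finite(p2) | n1 <= 1 | n2 <= 1
  alpha <- (p1 - p2)^2 - p1 * (1 - p1) / (n1 - 1) - p2 * (1 - p2) / (n2 - 1)
  beta <- p1 * (1 - p2) + p2 * (1 - p1)
  alpha[bad] <- NA_real_
  beta[bad] <- NA_real_
  if (any(bad)) {
    warning(sum(bad), " site(s) skipped: fewer than 2 called haplotypes")
  }
  attr(alpha, "n_skipped") <- sum(bad)
  list(alpha = alpha, beta = beta)
}

#' Windowed weighted (ratio-of-sums) Hudson Fst
#'
#' @param counts An [allele_counts()] object.
#' @param pop1,pop2 Population ids.
#' @param grid Window grid from [window_grid()].
#' @param min_sites Minimum usable sites per window; windows below are `NA`.
#' @param hits Optional precomputed [site_window_hits()] map (internal reuse).
#' @return `grid` with columns `fst` and `n_sites` appended.
#' @export
window_fst <- function(counts, pop1, pop2, grid, min_sites = 10, hits = NULL) {
  ab <- suppressWarnings(hudson_fst_site(
    counts$freq[, pop1], counts$n[, pop1],
    counts$freq[, pop2], counts$n[, pop2]
  ))
  if (is.null(hits)) hits <- site_window_hits(counts$sites, grid)
  nw <- nrow(grid)
  num <- window_sum(ab$alpha, hits, nw)
  den <- window_sum(ab$beta, hits, nw)
  ns <- window_count(!is.na(ab$beta), hits, nw)
  fst <- num / den
  fst[den == 0 | ns < min_sites] <- NA_real_
  out <- grid
  out$fst <- fst
  out$n_sites <- ns
  out
}

#' Population branch statistics from pairwise Fst
#'
#' Pairwise Fst is clamped to `[0, 1 - 1e-9]` and transformed to a relative
#' divergence time `T = -log(1 - Fst)`; the branch lengths are then
#' `PBS_high = (T_hl + T_hd - T_ld) / 2` and its symmetric permutations for
#' the low and distant-low branches. `NA` in any input yields `NA` in all
#' three outputs for that window.
#'
#' @param fst_high_low,fst_high_dist,fst_low_dist Pairwise windowed Fst
#'   vectors for the high-low, high-distant and low-distant pairs.
#' @return Data frame `pbs_high`, `pbs_low`, `pbs_dist`.
#' @export
pbs_from_fst <- function(fst_high_low, fst_high_dist, fst_low_dist) {
  tt <- function(f) -log(1 - pmin(pmax(f, 0), 1 - 1e-9))
  t_hl <- tt(fst_high_low); t_hd <- tt(fst_high_dist); t_ld <- tt(fst_low_dist)
  any_na <- is.na(t_hl) | is.na(t_hd) | is.na(t_ld)
  out <- data.frame(
    pbs_high = (t_hl + t_hd - t_ld) / 2,
    pbs_low = (t_hl + t_ld - t_hd) / 2,
    pbs_dist = (t_hd + t_ld - t_hl) / 2
  )
  out[any_na, ] <- NA_real_
  out
}

#' Genome-wide z-normalisation of a window statistic
#'
#' `z = (x - mean) / sd` over all non-`NA` windows of one transect, with the
#' population (ddof = 0) standard deviation; a zero sd maps every window
#' to `z = 0`.
#'
#' @param x Numeric vector of window values.
#' @return Numeric vector of z-scores (`NA` preserved).
#' @export
zscore <- function(x) {
  ok <- !is.na(x)
  if (sum(ok) < 2) stop("zscore requires at least 2 non-missing windows")
  s <- sd_pop(x[ok])
  z <- rep(NA_real_, length(x))
  z[ok] <- if (s == 0) 0 else (x[ok] - mean(x[ok])) / s
  z
}

#' Windowed differentiation scan for one transect
#'
#' Computes the three pairwise windowed Fst tracks of a high / low /
#' distant-low trio, PBS per branch, and the z-normalised selection statistic
#' (`zPBS_high`, or `zFst` of the high-low pair when the trio is degenerate).
#'
#' @param counts An [allele_counts()] object.
#' @param trio Named list or vector with `high`, `low` and optionally
#'   `low_distant` population ids; a missing/`NA` `low_distant` triggers
#'   Fst-only mode.
#' @param grid Window grid (default built per `chrom_lens`).
#' @param chrom_lens Chromosome lengths, required if `grid` is `NULL`.
#' @param size,step Window geometry used when building the default grid.
#' @param min_sites Minimum sites per window.
#' @return A window-statistics data frame (one row per window): grid columns
#'   plus `n_sites`, `fst_high_low`, `fst_high_dist`, `fst_low_dist`,
#'   `pbs_high`, `pbs_low`, `pbs_dist`, `stat` (the scanned statistic name)
#'   and `z`.
#' @export
transect_scan <- function(counts, trio, grid = NULL, chrom_lens = NULL,
                          size = 5000, step = 1000, min_sites = 10) {
  trio <- as.list(trio)
  if (is.null(grid)) {
    if (is.null(chrom_lens)) stop("supply either `grid` or `chrom_lens`")
    grid <- window_grid(chrom_lens, size = size, step = step)
  }
  has_dist <- !is.null(trio$low_distant) && !is.na(trio$low_distant)
  hits <- site_window_hits(counts$sites, grid)
  hl <- window_fst(counts, trio$high, trio$low, grid, min_sites, hits)
  out <- grid
  out$fst_high_low <- hl$fst
  if (has_dist) {
    hd <- window_fst(counts, trio$high, trio$low_distant, grid, min_sites, hits)
    ld <- window_fst(counts, trio$low, trio$low_distant, grid, min_sites, hits)
    out$fst_high_dist <- hd$fst
    out$fst_low_dist <- ld$fst
    out$n_sites <- pmin(hl$n_sites, hd$n_sites, ld$n_sites)
    pbs <- pbs_from_fst(hl$fst, hd$fst, ld$fst)
    out <- cbind(out, pbs)
    out$stat <- "pbs_high"
    out$z <- zscore(out$pbs_high)
  } else {
    out$fst_high_dist <- NA_real_
    out$fst_low_dist <- NA_real_
    out$n_sites <- hl$n_sites
    out$pbs_high <- NA_real_
    out$pbs_low <- NA_real_
    out$pbs_dist <- NA_real_
    out$stat <- "fst"
    out$z <- zscore(out$fst_high_low)
  }
  out
}
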