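# Windowed excess-allele-sharing (f_dM) scans on ((P1, P2), P3), O quartets,
# SHDR-level outlier calling, KS enrichment tests and background block
# permutations. P1 is the lowland population, P2 the highland recipient,
# P3 the putative donor (allopatric conspecific highlands or a sympatric
# highland-specialist species), O the polarization outgroup.

#' Define a four-population quartet
#'
#' @param p1 Lowland population id.
#' @param p2 Highland (putative recipient) population id.
#' @param p3 Putative donor population id.
#' @param outgroup Outgroup population id (ancestral = its major allele).
#' @param label Optional display label.
#' @return A `quartet_config` list.
#' @export
quartet_config <- function(p1, p2, p3, outgroup, label = NULL) {
  ids <- c(p1, p2, p3, outgroup)
  if (anyDuplicated(ids)) stop("quartet populations must be distinct")
  structure(list(p1 = p1, p2 = p2, p3 = p3, outgroup = outgroup,
                 label = label %||% paste(p2, "<-", p3)),
            class = "quartet_config")
}

#' Read quartets from a YAML list
#' @param path YAML file: a list of records with `p1`, `p2`, `p3`,
#'   `outgroup` and optional `label`.
#' @return List of `quartet_config` objects.
#' @export
read_quartets <- function(path) {
  lapply(yaml::read_yaml(path), function(q) do.call(quartet_config, q))
}

# Polarize derived-allele frequencies against the outgroup major allele.
# Sites where the outgroup minor-allele frequency exceeds max_outgroup_maf,
# or where the outgroup has no calls, are dropped.
polarize_frequencies <- function(counts, quartet, max_outgroup_maf = 0.2) {
  pO <- counts$freq[, quartet$outgroup]
  maf <- pmin(pO, 1 - pO)
  keep <- is.finite(maf) & maf <= max_outgroup_maf &
    is.finite(counts$freq[, quartet$p1]) &
    is.finite(counts$freq[, quartet$p2]) &
    is.finite(counts$freq[, quartet$p3])
  flip <- !is.na(pO) & pO > 0.5
  pol <- function(pop) {
    p <- counts$freq[, pop]
    ifelse(flip, 1 - p, p)[keep]
  }
  list(sites = counts$sites[keep, , drop = FALSE],
       p1 = pol(quartet$p1), p2 = pol(quartet$p2), p3 = pol(quartet$p3),
       pO = pol(quartet$outgroup))
}

# Per-site ABBA-BABA numerator and f_dM denominator (Malinsky's symmetric
# dynamic-donor form): at sites with p2 >= p1 the higher of (p2, p3) stands
# in for both P2 and P3; at sites with p2 < p1 the higher of (p1, p3) stands
# in for both P1 and P3, with the term negated.
fdm_site_terms <- function(p1, p2, p3, pO) {
  num <- (1 - p1) * p2 * p3 * (1 - pO) - p1 * (1 - p2) * p3 * (1 - pO)
  hi2 <- p2 >= p1
  pd <- ifelse(hi2, pmax(p2, p3), pmax(p1, p3))
  den <- ifelse(
    hi2,
    (1 - p1) * pd * pd * (1 - pO) - p1 * (1 - pd) * pd * (1 - pO),
    -((1 - pd) * p2 * pd * (1 - pO) - pd * (1 - p2) * pd * (1 - pO))
  )
  list(num = num, den = den)
}

#' Windowed f_dM excess-allele-sharing track
#'
#' Computes f_dM = sum(num) / sum(den) per window of a fixed grid (default
#' 50 kb non-overlapping) after outgroup polarization. Positive values
#' indicate excess derived-allele sharing between P3 and the highland P2;
#' negative between P3 and the lowland P1. Windows with fewer informative
#' sites than `min_sites`, or zero denominator, are `NA`.
#'
#' @param counts An [allele_counts()] object.
#' @param quartet A [quartet_config()].
#' @param grid Window grid (default: non-overlapping windows of `size` over
#'   `chrom_lens`).
#' @param chrom_lens Chromosome lengths (used when `grid` is `NULL`).
#' @param size Window size in bp.
#' @param min_sites Minimum informative sites per window.
#' @param max_outgroup_maf Outgroup polymorphism tolerance for polarization.
#' @return `grid` with columns `fdm` and `n_informative`.
#' @export
fdm_track <- function(counts, quartet, grid = NULL, chrom_lens = NULL,
                      size = 50000, min_sites = 20, max_outgroup_maf = 0.2) {
  if (is.null(grid)) {
    if (is.null(chrom_lens)) stop("supply either `grid` or `chrom_lens`")
    grid <- window_grid(chrom_lens, size = size, step = size)
  }
  pol <- polarize_frequencies(counts, quartet, max_outgroup_maf)
  terms <- fdm_site_terms(pol$p1, pol$p2, pol$p3, pol$pO)
  informative <- terms$num != 0 | terms$den != 0
  hits <- site_window_hits(pol$sites, grid)
  nw <- nrow(grid)
  num <- window_sum(ifelse(informative, terms$num, NA_real_), hits, nw)
  den <- window_sum(ifelse(informative, terms$den, NA_real_), hits, nw)
  ni <- window_count(informative, hits, nw)
  fdm <- num / den
  fdm[den == 0 | ni < min_sites] <- NA_real_
  out <- grid
  out$fdm <- fdm
  out$n_informative <- ni
  out
}

#' Genome-wide Patterson's D
#'
#' Same ABBA-BABA numerator as f_dM over the classical denominator
#' `sum[(1-p1) p2 p3 (1-pO) + p1 (1-p2) p3 (1-pO)]`; a single genome-wide
#' summary of excess allele sharing.
#'
#' @inheritParams fdm_track
#' @return List `d`, `n_sites`.
#' @export
patterson_d <- function(counts, quartet, max_outgroup_maf = 0.2) {
  pol <- polarize_frequencies(counts, quartet, max_outgroup_maf)
  abba <- (1 - pol$p1) * pol$p2 * pol$p3 * (1 - pol$pO)
  baba <- pol$p1 * (1 - pol$p2) * pol$p3 * (1 - pol$pO)
  list(d = sum(abba - baba) / sum(abba + baba),
       n_sites = sum(abba + baba > 0))
}

#' Per-SHDR f_dM extremes and outlier flags
#'
#' Records each region's maximum and minimum f_dM over overlapping windows;
#' the outlier threshold is the 90th percentile of |minimum| across all
#' regions (regions with positive minima contribute their |min| too), and a
#' region is flagged when its maximum exceeds that threshold (strict).
#'
#' @param track An [fdm_track()] result.
#' @param shdrs An `hdr_set` or interval data frame.
#' @return List `per_shdr` (region table with `max_fdm`, `min_fdm`,
#'   `outlier`), `threshold`, `pct_outlier`, `low_power` (TRUE when fewer
#'   than 10 regions have a non-missing f_dM window).
#' @export
shdr_fdm_outliers <- function(track, shdrs) {
  iv <- intervals_of(shdrs)
  if (nrow(iv) == 0) stop("no regions supplied")
  gr_w <- gr_from_bed(track$chrom, track$start, track$end)
  gr_r <- gr_from_bed(iv$chrom, iv$start, iv$end)
  ov <- GenomicRanges::findOverlaps(gr_w, gr_r)
  mx <- rep(NA_real_, nrow(iv))
  mn <- rep(NA_real_, nrow(iv))
  sp <- split(track$fdm[S4Vectors::queryHits(ov)], S4Vectors::subjectHits(ov))
  for (nm in names(sp)) {
    v <- sp[[nm]]
    if (!all(is.na(v))) {
      i <- as.integer(nm)
      mx[i] <- max(v, na.rm = TRUE)
      mn[i] <- min(v, na.rm = TRUE)
    }
  }
  usable <- !is.na(mx)
  low_power <- sum(usable) < 10
  if (low_power) warning("fewer than 10 regions have f_dM windows; low power")
  threshold <- if (any(usable)) {
    stats::quantile(abs(mn[usable]), 0.9, names = FALSE)
  } else NA_real_
  outlier <- !is.na(mx) & !is.na(threshold) & mx > threshold
  per <- cbind(iv[, c("chrom", "start", "end"), drop = FALSE],
               data.frame(max_fdm = mx, min_fdm = mn, outlier = outlier))
  list(per_shdr = per, threshold = threshold,
       pct_outlier = 100 * mean(outlier[usable]),
       low_power = low_power)
}

#' KS enrichment test of highland-directed allele sharing
#'
#' One-sided two-sample Kolmogorov-Smirnov test of whether the distribution
#' of per-region maximum f_dM (sharing with the highlands) is stochastically
#' larger than the distribution of per-region |minimum| f_dM (sharing with
#' the lowlands).
#'
#' @param max_fdm Per-region maximum f_dM values.
#' @param abs_min_fdm Per-region absolute minimum f_dM values.
#' @return List `ks_d`, `p`.
#' @export
fdm_enrichment_test <- function(max_fdm, abs_min_fdm) {
  max_fdm <- max_fdm[!is.na(max_fdm)]
  abs_min_fdm <- abs_min_fdm[!is.na(abs_min_fdm)]
  if (length(max_fdm) < 5 || length(abs_min_fdm) < 5) {
    stop("insufficient SHDRs (need >= 5 in each distribution)")
  }
  # alternative = "less": the CDF of x lies below that of y, i.e. x
  # stochastically larger
  ks <- suppressWarnings(stats::ks.test(max_fdm, abs_min_fdm, alternative = "less"))
  list(ks_d = unname(ks$statistic), p = ks$p.value)
}

#' Background distribution of mean maximum f_dM
#'
#' Each permutation places region-sized intervals at random across the
#' genome, takes the maximum f_dM within each placed interval and records
#' the mean of those maxima, yielding the background against which the
#' observed per-region mean maximum is compared.
#'
#' @param track An [fdm_track()] result.
#' @param widths Observed region widths in bp.
#' @param chrom_lens Named chromosome lengths.
#' @param n_perm Number of permutations.
#' @param seed Integer seed.
#' @param observed_mean_max Optional observed mean maximum to compare.
#' @return List `null` (length `n_perm`), `observed`, `p` (one-sided; `NA`
#'   without an observed value), `quantiles`.
#' @export
background_fdm <- function(track, widths, chrom_lens, n_perm = 1000, seed = 1,
                           observed_mean_max = NULL) {
  if (!is.numeric(n_perm) || n_perm < 1) stop("n_perm must be a positive integer")
  null <- numeric(n_perm)
  gr_w <- gr_from_bed(track$chrom, track$start, track$end)
  with_seed(seed, {
    for (k in seq_len(n_perm)) {
      placed <- random_intervals(widths, chrom_lens)
      gr_p <- gr_from_bed(placed$chrom, placed$start, placed$end)
      ov <- GenomicRanges::findOverlaps(gr_w, gr_p)
      sp <- split(track$fdm[S4Vectors::queryHits(ov)], S4Vectors::subjectHits(ov))
      mx <- vapply(sp, function(v) if (all(is.na(v))) NA_real_ else max(v, na.rm = TRUE),
                   numeric(1))
      null[k] <- mean(mx, na.rm = TRUE)
    }
  })
  p <- if (is.null(observed_mean_max)) NA_real_ else
    (1 + sum(null >= observed_mean_max, na.rm = TRUE)) / (n_perm + 1)
  list(null = null, observed = observed_mean_max, p = p,
       quantiles = stats::quantile(null, c(0.025, 0.5, 0.975), na.rm = TRUE))
}
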