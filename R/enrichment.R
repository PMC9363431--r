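# Selection-signature enrichment inside shared high-differentiation regions:
# observed extrema per region vs extrema of randomly placed interval sets.

track_in_interval <- function(track, iv_row) {
  sel <- track$chrom == iv_row$chrom & track$centre >= iv_row$start &
    track$centre < iv_row$end
  track[sel, , drop = FALSE]
}

extrema_row <- function(sub) {
  ex <- function(x, f) if (all(is.na(x))) NA_real_ else f(x, na.rm = TRUE)
  data.frame(
    min_tajd = ex(sub$tajd_high, min), max_tajd = ex(sub$tajd_high, max),
    min_delta_pi = ex(sub$delta_pi, min), max_delta_pi = ex(sub$delta_pi, max),
    min_dxy = ex(sub$dxy, min), max_dxy = ex(sub$dxy, max),
    n_windows = sum(!is.na(sub$tajd_high) | !is.na(sub$delta_pi) | !is.na(sub$dxy))
  )
}

#' Observed selection-statistic extrema per region
#'
#' For each region, the minimum/maximum of Tajima's D (highland population),
#' delta-pi and Dxy over the non-missing windows whose centre lies in the
#' region. Regions with no eligible windows are flagged and excluded from
#' outlier classification.
#'
#' @param shdrs An `hdr_set` (or plain interval data frame).
#' @param tracks Selection tracks from [selection_tracks()] (columns
#'   `chrom`, `centre`, `tajd_high`, `delta_pi`, `dxy`).
#' @return Data frame: region coordinates, per-statistic extrema, `n_windows`
#'   and `eligible`.
#' @export
shdr_extrema <- function(shdrs, tracks) {
  iv <- intervals_of(shdrs)
  if (nrow(iv) == 0) stop("no regions supplied")
  stopifnot_cols(tracks, c("chrom", "centre", "tajd_high", "delta_pi", "dxy"),
                 "selection tracks")
  rows <- lapply(seq_len(nrow(iv)), function(i) {
    cbind(iv[i, c("chrom", "start", "end"), drop = FALSE],
          extrema_row(track_in_interval(tracks, iv[i, ])))
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out$eligible <- out$n_windows > 0
  out
}

#' Null extrema from randomly placed interval sets
#'
#' Each permutation places the same number of intervals of the same sizes as
#' the observed regions uniformly across the genome and records each placed
#' interval's extrema; extrema are pooled per statistic across permutations
#' and intervals (a size-stratified variant returns them grouped by interval
#' width).
#'
#' @param tracks Selection tracks (see [shdr_extrema()]).
#' @param widths Observed interval widths in bp.
#' @param chrom_lens Named chromosome lengths.
#' @param n_perm Number of permutations.
#' @param seed Integer seed.
#' @param stratify_size If `TRUE`, also return per-width null lists.
#' @return List of numeric vectors `min_tajd`, `max_tajd`, `min_delta_pi`,
#'   `max_delta_pi`, `min_dxy`, `max_dxy` (empty-placements dropped), plus
#'   `by_width` when stratified.
#' @export
permuted_extrema_null <- function(tracks, widths, chrom_lens, n_perm = 10000,
                                  seed = 1, stratify_size = FALSE) {
  if (!is.numeric(n_perm) || n_perm < 1) stop("n_perm must be a positive integer")
  nvals <- n_perm * length(widths)
  cols <- c("min_tajd", "max_tajd", "min_delta_pi", "max_delta_pi",
            "min_dxy", "max_dxy")
  acc <- matrix(NA_real_, nrow = nvals, ncol = length(cols),
                dimnames = list(NULL, cols))
  wacc <- rep(widths, n_perm)
  with_seed(seed, {
    row <- 0L
    for (k in seq_len(n_perm)) {
      placed <- random_intervals(widths, chrom_lens)
      for (i in seq_len(nrow(placed))) {
        row <- row + 1L
        ex <- extrema_row(track_in_interval(tracks, placed[i, ]))
        acc[row, ] <- as.numeric(ex[1, cols])
      }
    }
  })
  out <- lapply(cols, function(cn) acc[!is.na(acc[, cn]), cn])
  names(out) <- cols
  if (stratify_size) {
    out$by_width <- lapply(split(seq_len(nvals), wacc), function(idx) {
      lapply(cols, function(cn) { v <- acc[idx, cn]; v[!is.na(v)] })
    })
  }
  out
}

#' Classify regions as selection-statistic outliers
#'
#' Default (`tails = "sweep"`) direction, matching the footprint of a
#' highland sweep: a region is a Tajima's-D outlier if its observed minimum
#' falls below the 10th percentile of the null minima, a delta-pi outlier on
#' the same rule, and a Dxy outlier if its observed maximum exceeds the 90th
#' percentile of the null maxima. `tails = "literal"` applies the
#' alternative pairing (Tajima's D maximum above the 90th percentile,
#' delta-pi and Dxy minima below the 10th).
#'
#' @param extrema Observed extrema from [shdr_extrema()].
#' @param nulls Null distributions from [permuted_extrema_null()].
#' @param pctl Percentile of the one-sided rule (default 10).
#' @param tails `"sweep"` or `"literal"`.
#' @return `extrema` with logical columns `out_tajd`, `out_delta_pi`,
#'   `out_dxy`, the tally `n_outlier_stats` (0-3) and `n_stats_total`
#'   (including the defining differentiation statistic, 1-4). Ineligible
#'   regions get `NA` flags.
#' @export
classify_outliers <- function(extrema, nulls, pctl = 10,
                              tails = c("sweep", "literal")) {
  tails <- match.arg(tails)
  lo <- pctl / 100
  hi <- 1 - lo
  q <- function(v, p) {
    if (length(v) == 0) stop("null distribution is empty")
    stats::quantile(v, p, names = FALSE, na.rm = TRUE)
  }
  out <- extrema
  if (tails == "sweep") {
    out$out_tajd <- extrema$min_tajd < q(nulls$min_tajd, lo)
    out$out_delta_pi <- extrema$min_delta_pi < q(nulls$min_delta_pi, lo)
    out$out_dxy <- extrema$max_dxy > q(nulls$max_dxy, hi)
  } else {
    out$out_tajd <- extrema$max_tajd > q(nulls$max_tajd, hi)
    out$out_delta_pi <- extrema$min_delta_pi < q(nulls$min_delta_pi, lo)
    out$out_dxy <- extrema$min_dxy < q(nulls$min_dxy, lo)
  }
  flags <- c("out_tajd", "out_delta_pi", "out_dxy")
  for (f in flags) out[[f]][!out$eligible] <- NA
  out$n_outlier_stats <- rowSums(out[, flags], na.rm = TRUE)
  out$n_outlier_stats[!out$eligible] <- NA_integer_
  out$n_stats_total <- out$n_outlier_stats + 1L
  out
}
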