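# Cross-transect HDR sharing: classification, random-interval permutation
# nulls, block-jackknife confidence intervals, recombination comparison and
# candidate-locus overlap tests.

intervals_of <- function(x) {
  if (inherits(x, "hdr_set")) x$intervals else x
}

# Half-open overlap test; plain vector comparisons because this sits inside
# the permutation loops (equivalent to a countOverlaps > 0 on the same sets,
# asserted in the test suite).
overlaps_any <- function(a, b) {
  a <- intervals_of(a); b <- intervals_of(b)
  if (nrow(a) == 0) return(logical(0))
  if (nrow(b) == 0) return(rep(FALSE, nrow(a)))
  vapply(seq_len(nrow(a)), function(i) {
    any(b$chrom == a$chrom[i] & b$start < a$end[i] & b$end > a$start[i])
  }, logical(1))
}

# Merge already-validated intervals without S4 overhead (hot loops only);
# merge_intervals() is the public, clipped version.
merge_bed_fast <- function(df) {
  n <- nrow(df)
  if (n <= 1) return(df)
  o <- order(df$chrom, df$start, df$end)
  ch <- df$chrom[o]; s <- df$start[o]; e <- df$end[o]
  new <- logical(n); new[1] <- TRUE
  run_end <- e[1]
  ends <- numeric(0)
  for (i in seq_len(n)[-1]) {
    if (ch[i] != ch[i - 1] || s[i] > run_end) {
      ends <- c(ends, run_end)
      new[i] <- TRUE
      run_end <- e[i]
    } else {
      run_end <- max(run_end, e[i])
    }
  }
  ends <- c(ends, run_end)
  data.frame(chrom = ch[new], start = s[new], end = ends,
             stringsAsFactors = FALSE)
}

sharing_flags <- function(focal_iv, replicate_set, opposite_sets) {
  n <- nrow(focal_iv)
  with_rep <- if (is.null(replicate_set)) rep(FALSE, n) else
    overlaps_any(focal_iv, replicate_set)
  allo <- if (length(opposite_sets) == 0) rep(NA, n) else {
    hits <- lapply(opposite_sets, function(s) overlaps_any(focal_iv, s))
    with_rep & Reduce(`&`, hits)
  }
  list(within = with_rep, allopatric = allo)
}

#' Classify HDR sharing across transects
#'
#' An HDR is a within-side SHDR if it overlaps (at any position) an HDR of
#' the replicate transect on the same side of the barrier, and an allopatric
#' SHDR if it additionally overlaps at least one HDR in each transect on the
#' opposite side.
#'
#' @param hdr_sets Named list of `hdr_set` objects, one per transect.
#' @param layout Data frame `transect`, `side` describing which transects
#'   share a side; must cover the names of `hdr_sets`.
#' @return List with `sets` (the input sets, each with a `sharing_class`
#'   column: `private`, `shdr_within_side` or `shdr_allopatric`) and
#'   `summary` (per-transect counts and proportions).
#' @export
classify_sharing <- function(hdr_sets, layout) {
  layout <- as.data.frame(layout, stringsAsFactors = FALSE)
  stopifnot_cols(layout, c("transect", "side"), "layout")
  if (length(hdr_sets) < 2) stop("sharing requires at least 2 transects")
  miss <- setdiff(names(hdr_sets), layout$transect)
  if (length(miss)) stop("transect(s) missing from layout: ",
                         paste(miss, collapse = ", "))
  out_sets <- hdr_sets
  rows <- list()
  for (t in names(hdr_sets)) {
    side <- layout$side[layout$transect == t]
    partners <- partner_transects(t, layout, names(hdr_sets))
    fl <- sharing_flags(hdr_sets[[t]]$intervals,
                        if (is.na(partners$replicate)) NULL else hdr_sets[[partners$replicate]],
                        hdr_sets[partners$opposite])
    cls <- ifelse(fl$within,
                  ifelse(!is.na(fl$allopatric) & fl$allopatric,
                         "shdr_allopatric", "shdr_within_side"),
                  "private")
    out_sets[[t]]$intervals$sharing_class <- cls
    n <- length(cls)
    rows[[t]] <- data.frame(
      transect = t, side = side, n_hdr = n,
      n_shared = sum(fl$within),
      n_allopatric = if (all(is.na(fl$allopatric))) NA_integer_ else sum(fl$allopatric),
      prop_shared = if (n) mean(fl$within) else NA_real_,
      prop_allopatric = if (all(is.na(fl$allopatric)) || n == 0) NA_real_ else mean(fl$allopatric),
      stringsAsFactors = FALSE
    )
  }
  list(sets = out_sets, summary = do.call(rbind, rows))
}

partner_transects <- function(focal, layout, available) {
  side <- layout$side[layout$transect == focal]
  if (length(side) != 1) stop("transect '", focal, "' not in layout exactly once")
  same <- setdiff(layout$transect[layout$side == side], focal)
  same <- intersect(same, available)
  if (length(same) > 1) stop("more than one replicate transect on side '", side, "'")
  opp <- intersect(setdiff(layout$transect[layout$side != side], focal), available)
  list(replicate = if (length(same)) same else NA_character_, opposite = opp)
}

#' Place random intervals of given sizes on a genome
#'
#' Each interval keeps its width; the chromosome is chosen with probability
#' proportional to its length among chromosomes long enough to hold the
#' interval, and the start is uniform over valid positions. Placed intervals
#' may overlap.
#'
#' @param widths Interval widths in bp.
#' @param chrom_lens Named chromosome lengths.
#' @return Data frame `chrom`, `start`, `end`.
#' @export
random_intervals <- function(widths, chrom_lens) {
  if (length(widths) == 0) {
    return(data.frame(chrom = character(), start = numeric(), end = numeric(),
                      stringsAsFactors = FALSE))
  }
  chroms <- names(chrom_lens)
  out_chrom <- character(length(widths))
  out_start <- numeric(length(widths))
  for (i in seq_along(widths)) {
    w <- widths[i]
    ok <- chrom_lens >= w
    if (!any(ok)) stop("an interval of width ", w, " fits on no chromosome")
    ch <- sample(chroms[ok], 1, prob = chrom_lens[ok])
    out_chrom[i] <- ch
    out_start[i] <- floor(stats::runif(1, 0, chrom_lens[[ch]] - w + 1))
  }
  data.frame(chrom = out_chrom, start = out_start, end = out_start + widths,
             stringsAsFactors = FALSE)
}

#' Permutation null for HDR sharing proportions
#'
#' For each focal transect, every permutation re-places the same number of
#' intervals of the same sizes uniformly across the genome (merging any that
#' collide) and recomputes the sharing proportion against the *observed*
#' partner sets, giving a one-sided null for the observed proportion.
#' Empirical p = (1 + #\{null >= observed\}) / (n_perm + 1).
#'
#' @param hdr_sets Named list of `hdr_set` objects.
#' @param layout Transect/side layout (see [classify_sharing()]).
#' @param n_perm Number of permutations (> 0).
#' @param seed Integer seed.
#' @param focal Transects to randomise (default: all).
#' @return Named list per focal transect: `observed` (within-side and, when
#'   defined, allopatric proportions), `null_within`, `null_allopatric`,
#'   `p_within`, `p_allopatric`.
#' @export
overlap_permutation_null <- function(hdr_sets, layout, n_perm = 10000, seed = 1,
                                     focal = names(hdr_sets)) {
  if (!is.numeric(n_perm) || n_perm < 1) stop("n_perm must be a positive integer")
  res <- list()
  for (t in focal) {
    partners <- partner_transects(t, layout, names(hdr_sets))
    rep_set <- if (is.na(partners$replicate)) NULL else hdr_sets[[partners$replicate]]
    opp_sets <- hdr_sets[partners$opposite]
    iv <- hdr_sets[[t]]$intervals
    obs <- sharing_flags(iv, rep_set, opp_sets)
    obs_within <- if (nrow(iv)) mean(obs$within) else NA_real_
    has_allo <- length(opp_sets) > 0
    obs_allo <- if (has_allo && nrow(iv)) mean(obs$allopatric) else NA_real_
    widths <- iv$end - iv$start
    null_w <- numeric(n_perm)
    null_a <- if (has_allo) numeric(n_perm) else NULL
    cl <- hdr_sets[[t]]$chrom_lens
    with_seed(derive_seed(seed, match(t, names(hdr_sets))), {
      for (k in seq_len(n_perm)) {
        placed <- merge_bed_fast(random_intervals(widths, cl))
        fl <- sharing_flags(placed, rep_set, opp_sets)
        null_w[k] <- if (nrow(placed)) mean(fl$within) else NA_real_
        if (has_allo) null_a[k] <- if (nrow(placed)) mean(fl$allopatric) else NA_real_
      }
    })
    p_w <- if (is.na(obs_within)) NA_real_ else
      (1 + sum(null_w >= obs_within, na.rm = TRUE)) / (n_perm + 1)
    p_a <- if (!has_allo || is.na(obs_allo)) NA_real_ else
      (1 + sum(null_a >= obs_allo, na.rm = TRUE)) / (n_perm + 1)
    res[[t]] <- list(observed = c(within = obs_within, allopatric = obs_allo),
                     null_within = null_w, null_allopatric = null_a,
                     p_within = p_w, p_allopatric = p_a)
  }
  res
}

#' Block-jackknife confidence interval for a sharing proportion
#'
#' Delete-one-block jackknife over contiguous genome blocks: each replicate
#' removes the focal transect's HDRs whose midpoint falls in the deleted
#' block and recomputes the sharing proportion against the unchanged partner
#' sets. Blocks containing no focal HDR midpoints reproduce the full
#' estimate.
#'
#' @param hdr_sets Named list of `hdr_set` objects.
#' @param layout Transect/side layout.
#' @param focal Focal transect name.
#' @param block_size Block size in bp (default 1 Mb).
#' @param conf Confidence level.
#' @param statistic `"within"` (within-side sharing) or `"allopatric"`.
#' @return List `estimate`, `se`, `lower`, `upper`, `n_blocks`,
#'   `degenerate` (TRUE when every HDR midpoint sits in one block).
#' @export
jackknife_ci <- function(hdr_sets, layout, focal, block_size = 1e6,
                         conf = 0.95, statistic = c("within", "allopatric")) {
  statistic <- match.arg(statistic)
  partners <- partner_transects(focal, layout, names(hdr_sets))
  rep_set <- if (is.na(partners$replicate)) NULL else hdr_sets[[partners$replicate]]
  opp_sets <- hdr_sets[partners$opposite]
  if (statistic == "allopatric" && length(opp_sets) == 0) {
    stop("allopatric sharing undefined without opposite-side transects")
  }
  iv <- hdr_sets[[focal]]$intervals
  if (nrow(iv) == 0) stop("focal transect has no HDRs")
  cl <- hdr_sets[[focal]]$chrom_lens
  blocks <- window_grid(cl, size = block_size, step = block_size)
  # tail blocks shorter than block_size still count
  tails <- lapply(names(cl), function(ch) {
    covered <- if (any(blocks$chrom == ch)) max(blocks$end[blocks$chrom == ch]) else 0
    if (covered < cl[[ch]]) {
      data.frame(chrom = ch, start = covered, end = cl[[ch]],
                 centre = (covered + cl[[ch]]) / 2)
    }
  })
  blocks <- rbind(blocks, do.call(rbind, tails))
  if (nrow(blocks) < 10) stop("jackknife requires at least 10 genome blocks")

  prop <- function(sub) {
    fl <- sharing_flags(sub, rep_set, opp_sets)
    v <- if (statistic == "within") fl$within else fl$allopatric
    if (nrow(sub) == 0) NA_real_ else mean(v)
  }
  est <- prop(iv)
  mid <- (iv$start + iv$end) / 2
  block_of <- integer(nrow(iv))
  for (i in seq_len(nrow(iv))) {
    block_of[i] <- which(blocks$chrom == iv$chrom[i] & blocks$start <= mid[i] &
                           mid[i] < blocks$end)[1]
  }
  degenerate <- length(unique(block_of)) == 1
  if (degenerate) warning("all HDR midpoints fall in one block; jackknife SE is degenerate")
  b <- nrow(blocks)
  theta <- vapply(seq_len(b), function(k) {
    sub <- iv[block_of != k, , drop = FALSE]
    v <- prop(sub)
    if (is.na(v)) est else v
  }, numeric(1))
  se <- sqrt((b - 1) / b * sum((theta - mean(theta))^2))
  zq <- stats::qnorm(1 - (1 - conf) / 2)
  list(estimate = est, se = se, lower = est - zq * se, upper = est + zq * se,
       n_blocks = b, degenerate = degenerate)
}

#' Compare recombination rate inside vs outside HDRs
#'
#' @param hdrs An `hdr_set`.
#' @param rho_track Data frame `chrom`, `centre`, `rho` (any fixed grid).
#' @return List `inside`, `outside` (rho values split by whether the window
#'   centre falls in an HDR), `ks_d`, `p`.
#' @export
recomb_comparison <- function(hdrs, rho_track) {
  stopifnot_cols(rho_track, c("chrom", "centre", "rho"), "rho track")
  rho_track <- rho_track[!is.na(rho_track$rho), , drop = FALSE]
  centres <- data.frame(chrom = rho_track$chrom, start = rho_track$centre,
                        end = rho_track$centre + 1)
  inside <- overlaps_any(centres, hdrs)
  if (!any(inside)) stop("no rho windows fall inside HDRs")
  if (all(inside)) stop("no rho windows fall outside HDRs")
  ks <- suppressWarnings(stats::ks.test(rho_track$rho[inside], rho_track$rho[!inside]))
  list(inside = rho_track$rho[inside], outside = rho_track$rho[!inside],
       ks_d = unname(ks$statistic), p = ks$p.value)
}

#' Permutation test of candidate-locus overlap with HDRs
#'
#' Counts candidate intervals overlapping at least one HDR and compares the
#' count to a null obtained by re-placing the HDR-sized interval set at
#' random (as in [overlap_permutation_null()]).
#'
#' @param hdrs An `hdr_set`.
#' @param candidates Data frame `chrom`, `start`, `end` of candidate loci.
#' @param n_perm Number of permutations.
#' @param seed Integer seed.
#' @return List `observed`, `null` (counts per permutation), `quantiles`
#'   (10/50/90/95th), `p` (empirical, one-sided).
#' @export
candidate_overlap_test <- function(hdrs, candidates, n_perm = 10000, seed = 1) {
  if (!is.numeric(n_perm) || n_perm < 1) stop("n_perm must be a positive integer")
  iv <- hdrs$intervals
  cl <- hdrs$chrom_lens
  obs <- sum(overlaps_any(candidates, iv))
  widths <- iv$end - iv$start
  null <- integer(n_perm)
  with_seed(seed, {
    for (k in seq_len(n_perm)) {
      placed <- merge_bed_fast(random_intervals(widths, cl))
      null[k] <- sum(overlaps_any(candidates, placed))
    }
  })
  list(observed = obs, null = null,
       quantiles = stats::quantile(null, c(0.1, 0.5, 0.9, 0.95)),
       p = (1 + sum(null >= obs)) / (n_perm + 1))
}
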