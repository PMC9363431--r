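# High Differentiation Regions: outlier-window calling, buffered interval
# construction and merging.

#' Call outlier windows from a z-normalised scan
#'
#' @param track Window-statistics data frame with a `z` column (from
#'   [transect_scan()]).
#' @param threshold Outlier threshold in z units; windows with `z > threshold`
#'   (strict) are outliers, `NA` windows never are.
#' @return The outlier rows of `track`.
#' @export
call_outliers <- function(track, threshold = 4) {
  stopifnot_cols(track, c("chrom", "centre", "z"), "window track")
  track[!is.na(track$z) & track$z > threshold, , drop = FALSE]
}

#' Merge a set of genomic intervals
#'
#' Overlapping and book-ended (end == start, half-open convention) intervals
#' are merged; the result is sorted and non-overlapping. Idempotent.
#'
#' @param intervals Data frame `chrom`, `start`, `end` (0-based half-open).
#' @param chrom_lens Optional named lengths; intervals are clipped to
#'   `[0, length)` first.
#' @return Merged data frame `chrom`, `start`, `end`.
#' @export
merge_intervals <- function(intervals, chrom_lens = NULL) {
  if (nrow(intervals) == 0) {
    return(data.frame(chrom = character(), start = numeric(), end = numeric(),
                      stringsAsFactors = FALSE))
  }
  start <- pmax(intervals$start, 0)
  end <- intervals$end
  if (!is.null(chrom_lens)) {
    end <- pmin(end, chrom_lens[as.character(intervals$chrom)])
  }
  keep <- end > start
  gr <- GenomicRanges::reduce(gr_from_bed(intervals$chrom[keep], start[keep], end[keep]))
  out <- bed_from_gr(gr)
  out <- out[order(out$chrom, out$start), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Build buffered high-differentiation regions from outlier windows
#'
#' Each outlier window contributes the interval
#' `[centre - buffer, centre + buffer)` clipped to its chromosome;
#' overlapping or book-ended intervals are merged into discrete regions.
#' Each region keeps its member window count and maximum z as provenance.
#'
#' @param outliers Outlier windows from [call_outliers()].
#' @param buffer Buffer in bp on each side of the window centre.
#' @param chrom_lens Named chromosome lengths.
#' @param transect Source transect label stored with the regions.
#' @return An `hdr_set`: list with `intervals` (data frame `chrom`, `start`,
#'   `end`, `source_transect`, `n_windows`, `max_z`), `chrom_lens` and
#'   `genome_fraction`.
#' @export
build_hdrs <- function(outliers, buffer = 50000, chrom_lens, transect = "transect") {
  if (nrow(outliers) == 0) {
    iv <- data.frame(chrom = character(), start = numeric(), end = numeric(),
                     source_transect = character(), n_windows = integer(),
                     max_z = numeric(), stringsAsFactors = FALSE)
    return(structure(list(intervals = iv, chrom_lens = chrom_lens,
                          genome_fraction = 0), class = "hdr_set"))
  }
  raw <- data.frame(chrom = outliers$chrom,
                    start = outliers$centre - buffer,
                    end = outliers$centre + buffer)
  merged <- merge_intervals(raw, chrom_lens)
  gr_m <- gr_from_bed(merged$chrom, merged$start, merged$end)
  gr_w <- gr_from_bed(outliers$chrom, outliers$centre, outliers$centre + 1)
  ov <- GenomicRanges::findOverlaps(gr_w, gr_m)
  idx <- S4Vectors::subjectHits(ov)
  merged$source_transect <- transect
  merged$n_windows <- as.integer(table(factor(idx, levels = seq_len(nrow(merged)))))
  mz <- tapply(outliers$z[S4Vectors::queryHits(ov)], idx, max)
  merged$max_z <- NA_real_
  merged$max_z[as.integer(names(mz))] <- as.numeric(mz)
  structure(
    list(intervals = merged, chrom_lens = chrom_lens,
         genome_fraction = sum(merged$end - merged$start) / sum(chrom_lens)),
    class = "hdr_set"
  )
}

#' Construct an hdr_set from ready-made intervals
#'
#' For regions produced outside the scan (e.g. read from BED, already on the
#' right coordinate system).
#'
#' @param intervals Data frame `chrom`, `start`, `end`.
#' @param chrom_lens Named chromosome lengths.
#' @param transect Source label.
#' @param merge Merge the intervals first (default `TRUE`).
#' @return An `hdr_set`.
#' @export
hdr_set <- function(intervals, chrom_lens, transect = "transect", merge = TRUE) {
  iv <- if (merge) merge_intervals(intervals, chrom_lens) else
    intervals[, c("chrom", "start", "end"), drop = FALSE]
  iv$source_transect <- rep_len(transect, nrow(iv))
  iv$n_windows <- rep_len(NA_integer_, nrow(iv))
  iv$max_z <- rep_len(NA_real_, nrow(iv))
  structure(
    list(intervals = iv, chrom_lens = chrom_lens,
         genome_fraction = sum(iv$end - iv$start) / sum(chrom_lens)),
    class = "hdr_set"
  )
}

#' @export
print.hdr_set <- function(x, ...) {
  cat(sprintf("hdr_set: %d region(s), %.2f%% of the genome\n",
              nrow(x$intervals), 100 * x$genome_fraction))
  invisible(x)
}

#' Write an hdr_set (with sharing classes if present) as BED6
#' @param hdrs An `hdr_set`.
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_hdr_bed <- function(hdrs, path) {
  iv <- hdrs$intervals
  if (nrow(iv) == 0) {
    writeLines(character(0), path)
    return(invisible(path))
  }
  name <- iv$sharing_class %||% iv$source_transect
  score <- ifelse(is.na(iv$max_z), 0, round(iv$max_z, 3))
  writeLines(sprintf("%s\t%d\t%d\t%s\t%s\t.", iv$chrom, as.integer(iv$start),
                     as.integer(iv$end), name, score), path)
  invisible(path)
}
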