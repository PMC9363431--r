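# End-to-end orchestration: one configuration object, deterministic
# per-stage seeds derived from a master seed, TSV/BED outputs and a JSON
# manifest, plus a plain-markdown report of the headline tables.

#' Build a pipeline run configuration
#'
#' Either `sim` (a [sim_config()]) or both `vcf` and `popmap` paths must be
#' supplied. Trios and the transect layout default to everything derivable
#' from the population map (every transect with a `high` and `low`
#' population).
#'
#' @param sim Optional `sim_config` to simulate the input dataset.
#' @param vcf,popmap Input file paths (used when `sim` is `NULL`).
#' @param chrom_lens Named chromosome lengths (required with `vcf` input;
#'   derived from `sim` otherwise).
#' @param trios Named list (per transect) of lists `high`, `low`,
#'   `low_distant` population ids.
#' @param layout Data frame `transect`, `side`.
#' @param quartets List of [quartet_config()] objects (may be empty).
#' @param window_size,window_step Differentiation grid geometry (bp).
#' @param fdm_window_size f_dM grid size (bp, non-overlapping).
#' @param z_threshold Outlier threshold in z units.
#' @param buffer HDR buffer around outlier window centres (bp).
#' @param min_sites,fdm_min_sites Minimum sites per window.
#' @param n_perm_share,n_perm_extrema,n_perm_background Permutation counts.
#' @param jackknife_block Jackknife block size (bp).
#' @param exclude_chroms Chromosomes excluded from the global PCA.
#' @param rho_track Optional data frame `chrom`, `centre`, `rho`.
#' @param candidates Optional candidate-locus data frame `chrom`, `start`,
#'   `end`.
#' @param seed Master seed; per-stage seeds are derived from it.
#' @return A `run_config` list.
#' @export
run_config <- function(sim = NULL, vcf = NULL, popmap = NULL, chrom_lens = NULL,
                       trios = NULL, layout = NULL, quartets = list(),
                       window_size = 5000, window_step = 1000,
                       fdm_window_size = 50000, z_threshold = 4,
                       buffer = 50000, min_sites = 10, fdm_min_sites = 20,
                       n_perm_share = 10000, n_perm_extrema = 10000,
                       n_perm_background = 1000, jackknife_block = 1e6,
                       exclude_chroms = NULL, rho_track = NULL,
                       candidates = NULL, seed = 1) {
  if (is.null(sim)) {
    if (is.null(vcf) || is.null(popmap)) {
      stop("supply either `sim` or both `vcf` and `popmap`")
    }
    if (!file.exists(popmap)) stop("population map not found: ", popmap)
    if (!file.exists(vcf)) stop("VCF not found: ", vcf)
    if (is.null(chrom_lens)) stop("chrom_lens is required with VCF input")
  } else {
    stopifnot(inherits(sim, "sim_config"))
    chrom_lens <- chrom_lengths(sim)
  }
  structure(
    list(sim = sim, vcf = vcf, popmap = popmap, chrom_lens = chrom_lens,
         trios = trios, layout = layout, quartets = quartets,
         window_size = window_size, window_step = window_step,
         fdm_window_size = fdm_window_size, z_threshold = z_threshold,
         buffer = buffer, min_sites = min_sites,
         fdm_min_sites = fdm_min_sites, n_perm_share = n_perm_share,
         n_perm_extrema = n_perm_extrema,
         n_perm_background = n_perm_background,
         jackknife_block = jackknife_block, exclude_chroms = exclude_chroms,
         rho_track = rho_track, candidates = candidates,
         seed = as.integer(seed)),
    class = "run_config"
  )
}

#' Derive trios and layout from a population map
#' @param popmap Population map data frame.
#' @return List `trios` (named per transect) and `layout`.
#' @export
default_trios <- function(popmap) {
  popmap <- validate_popmap(popmap)
  trios <- list()
  layout <- list()
  for (t in unique(popmap$transect)) {
    sub <- unique(popmap[popmap$transect == t,
                         c("population", "altitude_class", "side")])
    pick <- function(cls) {
      p <- sub$population[sub$altitude_class == cls]
      if (length(p)) p[1] else NA_character_
    }
    high <- pick("high"); low <- pick("low")
    if (is.na(high) || is.na(low)) next
    trios[[t]] <- list(high = high, low = low, low_distant = pick("low_distant"))
    layout[[t]] <- data.frame(transect = t, side = sub$side[1],
                              stringsAsFactors = FALSE)
  }
  if (length(trios) == 0) stop("no transect with both a high and a low population")
  list(trios = trios, layout = do.call(rbind, layout))
}

log_stage <- function(stage, msg) {
  message(sprintf("[%s] %s: %s", format(Sys.time(), "%H:%M:%S"), stage, msg))
}

run_stage <- function(stage, expr) {
  tryCatch(expr, error = function(e) {
    stop(sprintf("stage '%s' failed: %s", stage, conditionMessage(e)),
         call. = FALSE)
  })
}

#' Run the full scan pipeline
#'
#' Stages, in order: simulate (optional), windows, hdr, share, enrich, pca,
#' fdm, report. Every stochastic stage draws its seed deterministically from
#' the master seed, all tables are written under `out_dir`, and
#' `manifest.json` records inputs, seeds, the configuration hash and the
#' files each stage produced.
#'
#' @param config A [run_config()].
#' @param out_dir Output directory.
#' @return Invisibly, the in-memory results list (`tracks`, `hdrs`,
#'   `sharing`, `perm`, `jackknife`, `enrichment`, `pca`, `fdm`, `files`).
#' @export
run_all <- function(config, out_dir) {
  stopifnot(inherits(config, "run_config"))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  hash <- config_hash(unclass(config))
  files <- list()
  tsv <- function(df, name) {
    path <- file.path(out_dir, name)
    utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
    files[[name]] <<- path
    path
  }

  # -- simulate / load ------------------------------------------------------
  if (!is.null(config$sim)) {
    log_stage("simulate", "generating synthetic dataset")
    dataset <- run_stage("simulate", simulate_dataset(config$sim))
    run_stage("simulate", write_dataset(dataset, file.path(out_dir, "data")))
    genotypes <- dataset$genotypes
    sites <- dataset$sites
    popmap <- dataset$popmap
  } else {
    log_stage("load", paste("reading", config$vcf))
    inp <- run_stage("load", read_genotype_vcf(config$vcf))
    genotypes <- inp$genotypes
    sites <- inp$sites
    popmap <- run_stage("load", read_popmap(config$popmap))
  }
  dt <- default_trios(popmap)
  trios <- config$trios %||% dt$trios
  layout <- config$layout %||% dt$layout
  cl <- config$chrom_lens

  # -- windows --------------------------------------------------------------
  log_stage("windows", sprintf("scanning %d transect(s)", length(trios)))
  counts <- run_stage("windows", allele_counts(genotypes, popmap, sites))
  grid <- window_grid(cl, config$window_size, config$window_step)
  tracks <- list()
  sel_tracks <- list()
  for (t in names(trios)) {
    tracks[[t]] <- run_stage("windows", transect_scan(
      counts, trios[[t]], grid = grid, min_sites = config$min_sites))
    sel_tracks[[t]] <- run_stage("windows", selection_tracks(
      counts, trios[[t]], grid))
    tsv(cbind(tracks[[t]], sel_tracks[[t]][, c("tajd_high", "pi_high",
                                               "pi_ref", "delta_pi", "dxy")]),
        sprintf("windows_%s.tsv", t))
  }

  # -- hdr ------------------------------------------------------------------
  log_stage("hdr", "calling high-differentiation regions")
  hdrs <- list()
  for (t in names(trios)) {
    out <- run_stage("hdr", build_hdrs(
      call_outliers(tracks[[t]], config$z_threshold),
      buffer = config$buffer, chrom_lens = cl, transect = t))
    hdrs[[t]] <- out
  }

  # -- share ----------------------------------------------------------------
  log_stage("share", sprintf("classifying sharing, %d permutations",
                             config$n_perm_share))
  sharing <- run_stage("share", classify_sharing(hdrs, layout))
  hdrs <- sharing$sets
  for (t in names(hdrs)) {
    path <- file.path(out_dir, sprintf("hdr_%s.bed", t))
    write_hdr_bed(hdrs[[t]], path)
    files[[basename(path)]] <- path
  }
  perm <- run_stage("share", overlap_permutation_null(
    hdrs, layout, n_perm = config$n_perm_share,
    seed = derive_seed(config$seed, 2)))
  jack <- list()
  for (t in names(hdrs)) {
    jack[[t]] <- tryCatch(
      jackknife_ci(hdrs, layout, t, block_size = config$jackknife_block),
      error = function(e) list(estimate = NA_real_, se = NA_real_,
                               lower = NA_real_, upper = NA_real_,
                               n_blocks = NA_integer_, degenerate = NA,
                               note = conditionMessage(e))
    )
  }
  share_tab <- sharing$summary
  share_tab$perm_p_within <- vapply(share_tab$transect,
                                    function(t) perm[[t]]$p_within, numeric(1))
  share_tab$perm_p_allopatric <- vapply(share_tab$transect,
                                        function(t) perm[[t]]$p_allopatric, numeric(1))
  share_tab$jack_lower <- vapply(share_tab$transect,
                                 function(t) jack[[t]]$lower, numeric(1))
  share_tab$jack_upper <- vapply(share_tab$transect,
                                 function(t) jack[[t]]$upper, numeric(1))
  tsv(share_tab, "sharing.tsv")

  # -- enrich ---------------------------------------------------------------
  log_stage("enrich", "testing selection signatures in SHDRs")
  enrichment <- list()
  for (t in names(hdrs)) {
    iv <- hdrs[[t]]$intervals
    shared <- iv[iv$sharing_class != "private", , drop = FALSE]
    if (nrow(shared) == 0) { enrichment[[t]] <- NULL; next }
    ex <- run_stage("enrich", shdr_extrema(shared, sel_tracks[[t]]))
    nulls <- run_stage("enrich", permuted_extrema_null(
      sel_tracks[[t]], shared$end - shared$start, cl,
      n_perm = config$n_perm_extrema, seed = derive_seed(config$seed, 3)))
    cls <- run_stage("enrich", classify_outliers(ex, nulls))
    cls$sharing_class <- shared$sharing_class
    enrichment[[t]] <- cls
    tsv(cls, sprintf("enrichment_%s.tsv", t))
  }

  # -- pca ------------------------------------------------------------------
  log_stage("pca", "global and local PCAs with altitude models")
  focal_species <- popmap$species[popmap$population == trios[[1]]$high][1]
  pca_res <- list()
  assoc_rows <- list()
  for (sd in unique(layout$side)) {
    side_tr <- layout$transect[layout$side == sd]
    smp <- popmap$sample[popmap$side == sd & popmap$species == focal_species &
                           popmap$transect %in% side_tr]
    if (length(smp) < 4) next
    excl <- do.call(rbind, lapply(hdrs[side_tr], function(h)
      h$intervals[, c("chrom", "start", "end")]))
    gp <- tryCatch(
      global_pca(genotypes[, smp, drop = FALSE], sites, exclude = excl,
                 exclude_chroms = config$exclude_chroms),
      error = function(e) NULL)
    if (is.null(gp)) next
    pca_res[[sd]] <- list(global = gp)
    alt <- popmap$altitude_m[match(smp, popmap$sample)]
    for (t in side_tr) {
      iv <- hdrs[[t]]$intervals
      shared <- iv[iv$sharing_class != "private", , drop = FALSE]
      for (i in seq_len(nrow(shared))) {
        win <- outlier_windows_in(tracks[side_tr], shared[i, ],
                                  config$z_threshold)
        if (nrow(win) == 0) next
        lp <- tryCatch(local_pca(genotypes[, smp, drop = FALSE], sites, win),
                       error = function(e) NULL)
        if (is.null(lp)) next
        aa <- altitude_association(lp$scores[, 1], alt, gp$scores[smp, 1])
        assoc_rows[[length(assoc_rows) + 1]] <- data.frame(
          side = sd, transect = t, chrom = shared$chrom[i],
          start = shared$start[i], end = shared$end[i],
          pc1_var = lp$var_share[1], p_altitude = aa$p_altitude,
          partial_r2_altitude = aa$partial_r2_altitude,
          partial_r2_global = aa$partial_r2_global,
          r_squared = aa$r_squared, stringsAsFactors = FALSE)
      }
    }
  }
  assoc <- if (length(assoc_rows)) do.call(rbind, assoc_rows) else
    data.frame()
  if (nrow(assoc)) tsv(assoc, "altitude_association.tsv")

  # -- fdm ------------------------------------------------------------------
  fdm_res <- list()
  if (length(config$quartets)) {
    log_stage("fdm", sprintf("%d quartet(s)", length(config$quartets)))
    fdm_grid <- window_grid(cl, config$fdm_window_size, config$fdm_window_size)
    for (qi in seq_along(config$quartets)) {
      q <- config$quartets[[qi]]
      tr <- run_stage("fdm", fdm_track(counts, q, grid = fdm_grid,
                                       min_sites = config$fdm_min_sites))
      rec_tr <- popmap$transect[popmap$population == q$p2][1]
      iv <- hdrs[[rec_tr]]$intervals
      shared <- iv[iv$sharing_class != "private", , drop = FALSE]
      entry <- list(quartet = q, track = tr)
      if (nrow(shared) > 0) {
        out <- tryCatch(shdr_fdm_outliers(tr, shared), error = function(e) NULL)
        entry$outliers <- out
        if (!is.null(out)) {
          usable <- !is.na(out$per_shdr$max_fdm)
          entry$enrichment <- tryCatch(
            fdm_enrichment_test(out$per_shdr$max_fdm[usable],
                                abs(out$per_shdr$min_fdm[usable])),
            error = function(e) NULL)
          entry$background <- run_stage("fdm", background_fdm(
            tr, shared$end - shared$start, cl,
            n_perm = config$n_perm_background,
            seed = derive_seed(config$seed, 5 + qi),
            observed_mean_max = mean(out$per_shdr$max_fdm[usable])))
        }
      }
      fdm_res[[q$label]] <- entry
      tsv(tr, sprintf("fdm_%02d.tsv", qi))
    }
  }

  # -- manifest + report ----------------------------------------------------
  manifest <- list(
    package = "repadapt",
    version = as.character(utils::packageVersion("repadapt")),
    config_hash = hash,
    master_seed = config$seed,
    stage_seeds = list(share = derive_seed(config$seed, 2),
                       enrich = derive_seed(config$seed, 3),
                       background_fdm = derive_seed(config$seed, 6)),
    inputs = list(simulated = !is.null(config$sim), vcf = config$vcf,
                  popmap = config$popmap),
    stages = c("simulate", "windows", "hdr", "share", "enrich", "pca", "fdm",
               "report"),
    files = names(files)
  )
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  res <- list(tracks = tracks, sel_tracks = sel_tracks, hdrs = hdrs,
              sharing = sharing, perm = perm, jackknife = jack,
              enrichment = enrichment, pca = pca_res, assoc = assoc,
              fdm = fdm_res, files = files, popmap = popmap,
              config = config)
  report(res, file.path(out_dir, "report.md"))
  log_stage("report", paste("written to", out_dir))
  invisible(res)
}

# outlier 5 kb windows (as intervals) of the same-side transects inside one
# shared region
outlier_windows_in <- function(side_tracks, region, z_threshold) {
  win <- do.call(rbind, lapply(side_tracks, function(tr) {
    o <- call_outliers(tr, z_threshold)
    o[o$chrom == region$chrom & o$centre >= region$start &
        o$centre < region$end, c("chrom", "start", "end"), drop = FALSE]
  }))
  if (is.null(win) || nrow(win) == 0) {
    return(data.frame(chrom = character(), start = numeric(), end = numeric()))
  }
  merge_intervals(win)
}

#' Write a human-readable pipeline summary
#'
#' @param res Results list from [run_all()].
#' @param path Output markdown path.
#' @return Invisibly, `path`.
#' @export
report <- function(res, path) {
  lines <- c("# Repeated-adaptation scan report", "")
  sm <- res$sharing$summary
  lines <- c(lines, "## High-differentiation regions and sharing", "")
  if (sum(sm$n_hdr) == 0) {
    lines <- c(lines, "No high-differentiation regions were called.", "")
  } else {
    lines <- c(lines,
               "| transect | side | HDRs | shared | allopatric | % shared | perm p |",
               "|---|---|---|---|---|---|---|")
    for (i in seq_len(nrow(sm))) {
      pp <- res$perm[[sm$transect[i]]]$p_within
      lines <- c(lines, sprintf(
        "| %s | %s | %d | %d | %s | %.1f%% | %s |",
        sm$transect[i], sm$side[i], sm$n_hdr[i], sm$n_shared[i],
        ifelse(is.na(sm$n_allopatric[i]), "-", sm$n_allopatric[i]),
        100 * sm$prop_shared[i],
        ifelse(is.na(pp), "-", format(pp, digits = 3))))
    }
    lines <- c(lines, "")
  }
  if (length(res$enrichment)) {
    lines <- c(lines, "## Selection-signature support in SHDRs", "")
    for (t in names(res$enrichment)) {
      e <- res$enrichment[[t]]
      if (is.null(e)) next
      el <- e[e$eligible, , drop = FALSE]
      lines <- c(lines, sprintf(
        "- %s: %d/%d SHDRs carry >= 1 additional outlier statistic",
        t, sum(el$n_outlier_stats >= 1), nrow(el)))
    }
    lines <- c(lines, "")
  }
  if (is.data.frame(res$assoc) && nrow(res$assoc)) {
    sig <- sum(res$assoc$p_altitude < 0.05, na.rm = TRUE)
    lines <- c(lines, "## Altitude association of local PCAs", "",
               sprintf("- %d/%d SHDR local PCAs have altitude as a significant predictor (p < 0.05); mean altitude partial R^2 = %.2f",
                       sig, nrow(res$assoc),
                       mean(res$assoc$partial_r2_altitude, na.rm = TRUE)), "")
  }
  if (length(res$fdm)) {
    lines <- c(lines, "## Excess allele sharing (f_dM)", "")
    for (lbl in names(res$fdm)) {
      f <- res$fdm[[lbl]]
      if (!is.null(f$outliers)) {
        lines <- c(lines, sprintf(
          "- %s: %.0f%% of SHDRs are f_dM outliers%s%s", lbl,
          f$outliers$pct_outlier,
          if (!is.null(f$enrichment))
            sprintf("; KS enrichment p = %s", format(f$enrichment$p, digits = 3))
          else "",
          if (!is.null(f$background) && !is.na(f$background$p))
            sprintf("; background permutation p = %s",
                    format(f$background$p, digits = 3))
          else ""))
      } else {
        lines <- c(lines, sprintf("- %s: no SHDRs to test", lbl))
      }
    }
    lines <- c(lines, "")
  }
  writeLines(lines, path)
  invisible(path)
}
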