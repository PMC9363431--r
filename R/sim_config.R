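#' Describe one population of a simulated sampling design
#'
#' @param id Population identifier (unique).
#' @param transect Transect identifier the population belongs to.
#' @param side Side of the dispersal barrier, `"west"` or `"east"`.
#' @param altitude_class One of `"high"`, `"low"`, `"low_distant"` for focal
#'   transect populations; `"specialist"` or `"outgroup"` for non-focal
#'   lineages used as introgression donors / polarization outgroups.
#' @param altitude_m Altitude in metres.
#' @param n_diploids Number of diploid individuals sampled (>= 2).
#' @param species Species label.
#' @param outgroup Logical; if `TRUE` the population is simulated as a
#'   long-branch outgroup carrying (almost only) the ancestral allele.
#' @return A `population_spec` list.
#' @export
population_spec <- function(id, transect, side, altitude_class, altitude_m,
                            n_diploids, species = "focal", outgroup = FALSE) {
  stopifnot(is.character(id), length(id) == 1L, nchar(id) > 0)
  if (!side %in% c("west", "east")) stop("side must be 'west' or 'east'")
  if (!is.numeric(n_diploids) || n_diploids < 2) {
    stop("n_diploids must be >= 2 (population '", id, "')")
  }
  structure(
    list(
      id = id, transect = transect, side = side,
      altitude_class = altitude_class, altitude_m = as.numeric(altitude_m),
      n_diploids = as.integer(n_diploids), species = species,
      outgroup = isTRUE(outgroup)
    ),
    class = "population_spec"
  )
}

#' Describe a planted genomic feature
#'
#' Features are applied to simulated allele frequencies after drift:
#' `sweep` shifts target-population frequencies towards fixation,
#' `shared_standing` sets one identical elevated derived frequency in all
#' targets, `introgression` mixes in donor-population frequencies, and
#' `inversion_block` makes targets segregate for a diverged haplotype whose
#' per-individual dosage produces the three-cluster local-PCA signature.
#'
#' @param kind One of `"sweep"`, `"shared_standing"`, `"introgression"`,
#'   `"inversion_block"`.
#' @param chrom Chromosome name (e.g. `"chr1"`).
#' @param start,end 0-based half-open interval in base pairs.
#' @param target_populations Character vector of target population ids.
#' @param donor_population Donor population id (required for introgression).
#' @param intensity Frequency shift / admixture proportion / haplotype
#'   frequency in `[0, 1]`.
#' @return A `planted_feature` list.
#' @export
planted_feature <- function(kind, chrom, start, end, target_populations,
                            donor_population = NULL, intensity = 1) {
  kind <- match.arg(kind, c("sweep", "shared_standing", "introgression",
                            "inversion_block"))
  if (!is.numeric(start) || !is.numeric(end) || start < 0 || end <= start) {
    stop("feature interval must satisfy 0 <= start < end")
  }
  if (!is.numeric(intensity) || intensity < 0 || intensity > 1) {
    stop("intensity must lie in [0, 1]")
  }
  if (kind == "introgression" && is.null(donor_population)) {
    stop("introgression features require a donor_population")
  }
  structure(
    list(
      kind = kind, chrom = as.character(chrom),
      start = as.numeric(start), end = as.numeric(end),
      target_populations = as.character(target_populations),
      donor_population = if (is.null(donor_population)) NULL else as.character(donor_population),
      intensity = as.numeric(intensity)
    ),
    class = "planted_feature"
  )
}

#' Full parameterisation of a synthetic genotype dataset
#'
#' The drift model is hierarchical Balding-Nichols: an ancestral derived-allele
#' frequency is drawn per site from `Beta(ancestral_beta[1], ancestral_beta[2])`
#' and each branch of `drift_tree` perturbs its parent's frequency `p` with a
#' `Beta(p (1 - F) / F, (1 - p)(1 - F) / F)` draw, where `F` in `[0, 1)` is the
#' branch drift coefficient (`F = 0` copies the parent exactly).
#'
#' @param populations List of [population_spec()] objects; leaf names of the
#'   drift tree.
#' @param drift_tree Data frame with columns `node`, `parent`, `f`: a rooted
#'   topology whose root has `parent = NA` and whose leaves are population ids.
#' @param n_chromosomes Number of chromosomes.
#' @param chrom_length Chromosome length in base pairs (all chromosomes).
#' @param n_sites Total number of polymorphic sites, split evenly across
#'   chromosomes and (by default) uniformly spaced.
#' @param ancestral_beta Length-2 Beta parameters for the ancestral
#'   derived-allele frequency.
#' @param planted_features List of [planted_feature()] objects.
#' @param seed Integer seed; fully determines all simulator output.
#' @param jitter_positions If `TRUE`, site positions are uniformly jittered
#'   within their spacing interval instead of evenly spaced.
#' @param sweep_sfs_thin Fraction of sites inside sweep features whose
#'   post-sweep target-population frequency is intermediate (in `[0.25, 0.75]`)
#'   that are removed from the dataset, inducing the rare-allele excess
#'   (negative Tajima's D) a genealogical sweep would leave.
#' @param outgroup_noise Fraction of sites at which an outgroup population
#'   carries a small non-zero derived frequency (recurrent mutation stand-in).
#' @return A `sim_config` list.
#' @export
sim_config <- function(populations, drift_tree,
                       n_chromosomes = 3, chrom_length = 1e6, n_sites = 12000,
                       ancestral_beta = c(0.8, 2.0),
                       planted_features = list(), seed = 1,
                       jitter_positions = FALSE, sweep_sfs_thin = 0.5,
                       outgroup_noise = 0.01) {
  if (inherits(populations, "population_spec")) populations <- list(populations)
  pop_ids <- vapply(populations, function(p) p$id, character(1))
  if (anyDuplicated(pop_ids)) stop("duplicate population ids")
  drift_tree <- as.data.frame(drift_tree, stringsAsFactors = FALSE)
  stopifnot_cols(drift_tree, c("node", "parent", "f"), "drift_tree")
  if (any(!is.finite(drift_tree$f)) || any(drift_tree$f < 0) || any(drift_tree$f >= 1)) {
    stop("all drift coefficients F must be finite and lie in [0, 1)")
  }
  roots <- which(is.na(drift_tree$parent))
  if (length(roots) != 1L) stop("drift_tree must have exactly one root (parent = NA)")
  known <- drift_tree$node
  if (!all(drift_tree$parent[-roots] %in% known)) {
    stop("drift_tree parent refers to an unknown node")
  }
  if (!all(pop_ids %in% known)) {
    stop("every population id must appear as a drift_tree node")
  }
  chrom_names <- paste0("chr", seq_len(n_chromosomes))
  for (ft in planted_features) {
    if (!inherits(ft, "planted_feature")) stop("planted_features must be planted_feature objects")
    if (!ft$chrom %in% chrom_names) stop("feature chromosome '", ft$chrom, "' not in the genome")
    if (ft$end > chrom_length) stop("feature interval exceeds chromosome length")
    bad <- setdiff(c(ft$target_populations, ft$donor_population), pop_ids)
    if (length(bad)) stop("unknown population id(s) in a feature: ", paste(bad, collapse = ", "))
  }
  # same-kind features may not overlap
  if (length(planted_features) > 1) {
    kinds <- vapply(planted_features, `[[`, character(1), "kind")
    for (k in unique(kinds)) {
      fs <- planted_features[kinds == k]
      if (length(fs) > 1) {
        df <- data.frame(
          chrom = vapply(fs, `[[`, character(1), "chrom"),
          start = vapply(fs, `[[`, numeric(1), "start"),
          end = vapply(fs, `[[`, numeric(1), "end")
        )
        gr <- gr_from_bed(df$chrom, df$start, df$end)
        if (any(IRanges::countOverlaps(gr, gr) > 1)) {
          stop("planted features of kind '", k, "' overlap")
        }
      }
    }
  }
  structure(
    list(
      populations = populations, drift_tree = drift_tree,
      n_chromosomes = as.integer(n_chromosomes),
      chrom_length = as.numeric(chrom_length),
      chrom_names = chrom_names,
      n_sites = as.integer(n_sites),
      ancestral_beta = as.numeric(ancestral_beta),
      planted_features = planted_features,
      seed = as.integer(seed),
      jitter_positions = isTRUE(jitter_positions),
      sweep_sfs_thin = as.numeric(sweep_sfs_thin),
      outgroup_noise = as.numeric(outgroup_noise)
    ),
    class = "sim_config"
  )
}

#' @export
print.sim_config <- function(x, ...) {
  cat(sprintf(
    "sim_config: %d populations, %d chromosomes x %g bp, %d sites, %d planted feature(s), seed %d\n",
    length(x$populations), x$n_chromosomes, x$chrom_length, x$n_sites,
    length(x$planted_features), x$seed
  ))
  invisible(x)
}

#' Named vector of chromosome lengths of a simulated genome
#' @param config A `sim_config`.
#' @return Named numeric vector.
#' @export
chrom_lengths <- function(config) {
  stats::setNames(rep(config$chrom_length, config$n_chromosomes), config$chrom_names)
}

#' Population map of a simulation design
#'
#' @param config A `sim_config`.
#' @return Data frame with one row per sample and the standard columns
#'   `sample`, `population`, `transect`, `side`, `altitude_class`,
#'   `altitude_m`, `species`.
#' @export
sim_popmap <- function(config) {
  do.call(rbind, lapply(config$populations, function(p) {
    data.frame(
      sample = sprintf("%s_%02d", p$id, seq_len(p$n_diploids)),
      population = p$id, transect = p$transect, side = p$side,
      altitude_class = p$altitude_class, altitude_m = p$altitude_m,
      species = p$species, stringsAsFactors = FALSE
    )
  }))
}

#' Default study-design simulation scenario
#'
#' Emulates the sampling design the scan is built for: two sides of a
#' dispersal barrier, each with two replicate three-population transects
#' (highland ~1235 m, lowland ~364 m, distant lowland ~95 m), one sympatric
#' highland-specialist donor species and one outgroup species, and a set of
#' planted signals (a sweep shared by all four transects, a side-restricted
#' sweep, a private sweep, a shared standing variant, an introgression tract
#' into the eastern highlands, and an inversion-like haplotype block in the
#' eastern distant lowlands).
#'
#' @param seed Integer seed.
#' @param n_diploids Diploids per focal population.
#' @param with_features If `FALSE`, the same design with no planted features
#'   (pure drift), for null calibration.
#' @return A `sim_config`.
#' @export
sim_config_default <- function(seed = 1, n_diploids = 8, with_features = TRUE) {
  pops <- list()
  alt <- c(high = 1235, low = 364, low_distant = 95)
  for (side in c("west", "east")) {
    for (tn in 1:2) {
      tid <- sprintf("t%d%s", tn, substr(side, 1, 1))
      for (cls in names(alt)) {
        pops[[length(pops) + 1]] <- population_spec(
          id = paste0(tid, "_", cls), transect = tid, side = side,
          altitude_class = cls, altitude_m = alt[[cls]],
          n_diploids = n_diploids
        )
      }
    }
  }
  pops[[length(pops) + 1]] <- population_spec(
    id = "donor_high", transect = "donor", side = "east",
    altitude_class = "specialist", altitude_m = 1400, n_diploids = n_diploids,
    species = "specialist"
  )
  pops[[length(pops) + 1]] <- population_spec(
    id = "outgroup", transect = "outgroup", side = "east",
    altitude_class = "outgroup", altitude_m = 300, n_diploids = 4,
    species = "outgroup", outgroup = TRUE
  )

  edges <- list(c("anc_w", "root", 0.04), c("anc_e", "root", 0.04),
                c("donor_high", "anc_e", 0.12), c("outgroup", "root", 0.3))
  for (side in c("west", "east")) {
    s1 <- substr(side, 1, 1)
    for (tn in 1:2) {
      tid <- sprintf("t%d%s", tn, s1)
      edges[[length(edges) + 1]] <- c(paste0("anc_", tid), paste0("anc_", s1), 0.015)
      edges[[length(edges) + 1]] <- c(paste0(tid, "_high"), paste0("anc_", tid), 0.02)
      edges[[length(edges) + 1]] <- c(paste0(tid, "_low"), paste0("anc_", tid), 0.015)
      edges[[length(edges) + 1]] <- c(paste0(tid, "_low_distant"), paste0("anc_", tid), 0.03)
    }
  }
  tree <- data.frame(
    node = c("root", vapply(edges, `[[`, character(1), 1)),
    parent = c(NA, vapply(edges, `[[`, character(1), 2)),
    f = c(0, as.numeric(vapply(edges, `[[`, character(1), 3))),
    stringsAsFactors = FALSE
  )

  highs <- c("t1w_high", "t2w_high", "t1e_high", "t2e_high")
  features <- list()
  if (with_features) {
    features <- list(
      planted_feature("sweep", "chr1", 200000, 320000, highs, intensity = 0.9),
      planted_feature("sweep", "chr1", 600000, 700000,
                      c("t1e_high", "t2e_high"), intensity = 0.85),
      planted_feature("sweep", "chr3", 100000, 180000, "t1w_high", intensity = 0.9),
      planted_feature("shared_standing", "chr2", 100000, 160000, highs,
                      intensity = 0.7),
      planted_feature("introgression", "chr3", 500000, 600000,
                      c("t1e_high", "t2e_high"),
                      donor_population = "donor_high", intensity = 0.85),
      planted_feature("inversion_block", "chr2", 400000, 800000,
                      c("t1e_low_distant", "t2e_low_distant"), intensity = 0.6)
    )
  }
  sim_config(
    populations = pops, drift_tree = tree,
    n_chromosomes = 3, chrom_length = 1e6, n_sites = 12000,
    planted_features = features, seed = seed
  )
}
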