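# Dataset serialization: GT-only VCF 4.2, population-map TSV, truth BED and
# YAML sim_config, plus the matching readers. Coordinates are 0-based
# half-open internally; VCF POS is 1-based, BED is 0-based half-open.

GT_CODES <- c("0/0", "0/1", "1/1")

#' Write a simulated dataset to disk
#'
#' Emits `genotypes.vcf` (biallelic SNPs, REF = ancestral allele, GT only),
#' `popmap.tsv`, `truth.bed` (planted features, 0-based half-open) and
#' `sim_config.yaml` into `out_dir`. The files round-trip losslessly through
#' [read_genotype_vcf()], [read_popmap()] and [read_sim_config()].
#'
#' @param dataset A `sim_dataset` from [simulate_dataset()].
#' @param out_dir Output directory (created if missing).
#' @return Invisibly, a named character vector of file paths.
#' @export
write_dataset <- function(dataset, out_dir) {
  stopifnot(inherits(dataset, "sim_dataset"))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  if (!dir.exists(out_dir)) stop("cannot create output directory: ", out_dir)
  paths <- c(
    vcf = file.path(out_dir, "genotypes.vcf"),
    popmap = file.path(out_dir, "popmap.tsv"),
    truth = file.path(out_dir, "truth.bed"),
    config = file.path(out_dir, "sim_config.yaml")
  )
  write_genotype_vcf(dataset$genotypes, dataset$sites, chrom_lengths(dataset$config),
                     paths[["vcf"]])
  utils::write.table(dataset$popmap, paths[["popmap"]], sep = "\t",
                     quote = FALSE, row.names = FALSE)
  write_truth_bed(dataset$truth, paths[["truth"]])
  write_sim_config(dataset$config, paths[["config"]])
  invisible(paths)
}

#' Write a genotype matrix as a GT-only VCF 4.2 file
#'
#' @param genotypes Integer matrix (sites x samples, dosages 0/1/2, `NA`
#'   for missing) with sample names as column names.
#' @param sites Data frame with `chrom`, `pos` (0-based).
#' @param chrom_lens Named vector of chromosome lengths for the contig header.
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_genotype_vcf <- function(genotypes, sites, chrom_lens, path) {
  stopifnot(nrow(genotypes) == nrow(sites))
  header <- c(
    "##fileformat=VCFv4.2",
    "##source=repadapt",
    sprintf("##contig=<ID=%s,length=%d>", names(chrom_lens), as.integer(chrom_lens)),
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", colnames(genotypes)), collapse = "\t")
  )
  gt <- matrix(GT_CODES[genotypes + 1L], nrow = nrow(genotypes))
  gt[is.na(gt)] <- "./."
  body <- paste(
    sites$chrom, sites$pos + 1,
    sprintf("%s_%d", sites$chrom, sites$pos + 1),
    "A", "T", ".", "PASS", ".", "GT",
    apply(gt, 1, paste, collapse = "\t"),
    sep = "\t"
  )
  writeLines(c(header, body), path)
  invisible(path)
}

#' Read a biallelic GT VCF into a dosage matrix
#'
#' @param path VCF path (plain or bgzipped; anything `vcfR` reads).
#' @return List with `sites` (data frame `chrom`, `pos` 0-based) and
#'   `genotypes` (integer sites x samples dosage matrix of the ALT allele,
#'   `NA` for missing).
#' @export
read_genotype_vcf <- function(path) {
  if (!file.exists(path)) stop("VCF not found: ", path)
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  gt <- vcfR::extract.gt(v, element = "GT")
  # tolerate phased separators
  gt <- gsub("|", "/", gt, fixed = TRUE)
  dos <- matrix(NA_integer_, nrow = nrow(gt), ncol = ncol(gt),
                dimnames = dimnames(gt))
  dos[gt == "0/0"] <- 0L
  dos[gt == "0/1" | gt == "1/0"] <- 1L
  dos[gt == "1/1"] <- 2L
  bad <- !is.na(gt) & is.na(dos)
  if (any(bad)) stop("non-biallelic or malformed GT values in ", path)
  fix <- vcfR::getFIX(v)
  sites <- data.frame(chrom = fix[, "CHROM"],
                      pos = as.numeric(fix[, "POS"]) - 1,
                      stringsAsFactors = FALSE)
  rownames(dos) <- NULL
  list(sites = sites, genotypes = dos)
}

#' Read a population map TSV
#'
#' Expects the header
#' `sample  population  transect  side  altitude_class  altitude_m  species`.
#'
#' @param path TSV path.
#' @return Data frame; validated for unique samples and a consistent
#'   population -> transect/side/class mapping.
#' @export
read_popmap <- function(path) {
  pm <- utils::read.delim(path, stringsAsFactors = FALSE)
  validate_popmap(pm)
}

#' Validate a population map data frame
#' @param pm Data frame.
#' @return The validated data frame (invisibly usable).
#' @export
validate_popmap <- function(pm) {
  stopifnot_cols(pm, c("sample", "population", "transect", "side",
                       "altitude_class", "altitude_m", "species"),
                 "population map")
  if (anyDuplicated(pm$sample)) stop("population map has duplicate sample ids")
  per_pop <- unique(pm[, c("population", "transect", "side", "altitude_class")])
  if (anyDuplicated(per_pop$population)) {
    stop("a population maps to more than one transect/side/altitude class")
  }
  pm
}

write_truth_bed <- function(truth, path) {
  if (nrow(truth) == 0) {
    writeLines(character(0), path)
    return(invisible(path))
  }
  lines <- sprintf("%s\t%d\t%d\t%s", truth$chrom, as.integer(truth$start),
                   as.integer(truth$end), paste0(truth$kind, ":", truth$targets))
  writeLines(lines, path)
  invisible(path)
}

#' Read a BED file of intervals
#' @param path BED path (>= 3 columns, 0-based half-open).
#' @return Data frame `chrom`, `start`, `end` and `name` if present.
#' @export
read_bed <- function(path) {
  if (file.size(path) == 0) {
    return(data.frame(chrom = character(), start = numeric(), end = numeric(),
                      stringsAsFactors = FALSE))
  }
  bed <- utils::read.delim(path, header = FALSE, stringsAsFactors = FALSE)
  names(bed)[1:3] <- c("chrom", "start", "end")
  if (ncol(bed) >= 4) names(bed)[4] <- "name"
  bed
}

# Fractional numerics are serialized as %.17g strings so the YAML
# round-trip is bit-exact (yaml's own float precision is lossy).
num17 <- function(x) sprintf("%.17g", x)

write_sim_config <- function(config, path) {
  obj <- list(
    n_chromosomes = config$n_chromosomes,
    chrom_length = config$chrom_length,
    n_sites = config$n_sites,
    ancestral_beta = num17(config$ancestral_beta),
    seed = config$seed,
    jitter_positions = config$jitter_positions,
    sweep_sfs_thin = num17(config$sweep_sfs_thin),
    outgroup_noise = num17(config$outgroup_noise),
    populations = lapply(config$populations, unclass),
    drift_tree = lapply(seq_len(nrow(config$drift_tree)), function(i) {
      r <- config$drift_tree[i, ]
      list(node = r$node,
           parent = if (is.na(r$parent)) NULL else r$parent,
           f = num17(r$f))
    }),
    planted_features = lapply(config$planted_features, function(ft) {
      ft <- unclass(ft)
      ft$intensity <- num17(ft$intensity)
      ft
    })
  )
  yaml::write_yaml(obj, path)
  invisible(path)
}

#' Read a simulation configuration from YAML
#' @param path YAML path written by [write_dataset()] (or hand-authored with
#'   the same fields).
#' @return A `sim_config`.
#' @export
read_sim_config <- function(path) {
  obj <- yaml::read_yaml(path)
  pops <- lapply(obj$populations, function(p) do.call(population_spec, p))
  tree <- data.frame(
    node = vapply(obj$drift_tree, `[[`, character(1), "node"),
    parent = vapply(obj$drift_tree, function(x) x$parent %||% NA_character_,
                    character(1)),
    f = as.numeric(vapply(obj$drift_tree, function(x) as.character(x$f),
                          character(1))),
    stringsAsFactors = FALSE
  )
  feats <- lapply(obj$planted_features, function(ft) {
    ft$intensity <- as.numeric(ft$intensity)
    do.call(planted_feature, ft)
  })
  sim_config(
    populations = pops, drift_tree = tree,
    n_chromosomes = obj$n_chromosomes, chrom_length = obj$chrom_length,
    n_sites = obj$n_sites,
    ancestral_beta = as.numeric(unlist(obj$ancestral_beta)),
    planted_features = feats, seed = obj$seed,
    jitter_positions = isTRUE(obj$jitter_positions),
    sweep_sfs_thin = as.numeric(obj$sweep_sfs_thin %||% 0.5),
    outgroup_noise = as.numeric(obj$outgroup_noise %||% 0.01)
  )
}
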