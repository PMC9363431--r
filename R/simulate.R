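# Hierarchical Balding-Nichols allele-frequency simulator with planted
# features. Site positions, drift draws, feature overrides and SFS thinning
# all consume the RNG in a fixed order, so a sim_config (incl. seed) fully
# determines the output.

bn_draw <- function(p, f) {
  if (f == 0) return(p)
  q <- p
  poly <- p > 0 & p < 1
  if (any(poly)) {
    q[poly] <- stats::rbeta(sum(poly), p[poly] * (1 - f) / f,
                            (1 - p[poly]) * (1 - f) / f)
  }
  q
}

sim_site_positions <- function(config) {
  m_per <- rep(config$n_sites %/% config$n_chromosomes, config$n_chromosomes)
  extra <- config$n_sites %% config$n_chromosomes
  if (extra > 0) m_per[seq_len(extra)] <- m_per[seq_len(extra)] + 1L
  out <- lapply(seq_len(config$n_chromosomes), function(i) {
    m <- m_per[i]
    spacing <- config$chrom_length / m
    offset <- if (config$jitter_positions) stats::runif(m) else 0.5
    pos <- floor((seq_len(m) - 1 + offset) * spacing)
    data.frame(chrom = config$chrom_names[i], pos = pos,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

feature_site_idx <- function(sites, ft) {
  which(sites$chrom == ft$chrom & sites$pos >= ft$start & sites$pos < ft$end)
}

#' Simulate per-population allele frequencies
#'
#' Draws an ancestral derived-allele frequency per site, propagates it down
#' the drift tree with Balding-Nichols branch draws, overrides outgroup
#' populations with near-zero derived frequencies, applies planted features,
#' and finally thins intermediate-frequency sites inside sweep features to
#' induce the rare-allele excess of a real sweep.
#'
#' @param config A [sim_config()].
#' @return A `sim_freqs` list with elements `sites` (data frame `chrom`,
#'   `pos`; 0-based), `freqs` (sites x populations matrix), `inversions`
#'   (per-feature haplotype bookkeeping used by [sample_genotypes()]) and
#'   `config`.
#' @export
simulate_frequencies <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  with_seed(config$seed, {
    sites <- sim_site_positions(config)
    n <- nrow(sites)
    p0 <- stats::rbeta(n, config$ancestral_beta[1], config$ancestral_beta[2])

    tree <- config$drift_tree
    root <- tree$node[is.na(tree$parent)]
    node_freq <- list()
    node_freq[[root]] <- p0
    todo <- tree[!is.na(tree$parent), , drop = FALSE]
    while (nrow(todo) > 0) {
      ready <- todo$parent %in% names(node_freq)
      if (!any(ready)) stop("drift_tree is not a connected rooted tree")
      for (i in which(ready)) {
        node_freq[[todo$node[i]]] <- bn_draw(node_freq[[todo$parent[i]]], todo$f[i])
      }
      todo <- todo[!ready, , drop = FALSE]
    }

    pop_ids <- vapply(config$populations, `[[`, character(1), "id")
    freqs <- do.call(cbind, node_freq[pop_ids])
    colnames(freqs) <- pop_ids

    for (p in config$populations) {
      if (p$outgroup) {
        q <- rep(0, n)
        noisy <- stats::runif(n) < config$outgroup_noise
        if (any(noisy)) q[noisy] <- stats::rbeta(sum(noisy), 0.5, 10)
        freqs[, p$id] <- q
      }
    }

    inversions <- list()
    for (k in seq_along(config$planted_features)) {
      ft <- config$planted_features[[k]]
      idx <- feature_site_idx(sites, ft)
      if (length(idx) == 0) next
      if (ft$kind == "sweep") {
        for (t in ft$target_populations) {
          freqs[idx, t] <- freqs[idx, t] + ft$intensity * (1 - freqs[idx, t])
        }
      } else if (ft$kind == "shared_standing") {
        freqs[idx, ft$target_populations] <- ft$intensity
      } else if (ft$kind == "introgression") {
        donor <- freqs[idx, ft$donor_population]
        for (t in ft$target_populations) {
          freqs[idx, t] <- (1 - ft$intensity) * freqs[idx, t] + ft$intensity * donor
        }
      } else if (ft$kind == "inversion_block") {
        hap <- stats::rbinom(length(idx), 1, 0.5)
        wt <- freqs[idx, ft$target_populations, drop = FALSE]
        for (t in ft$target_populations) {
          freqs[idx, t] <- (1 - ft$intensity) * freqs[idx, t] + ft$intensity * hap
        }
        inversions[[length(inversions) + 1]] <- list(
          feature = k, site_idx = idx, hap = hap, wt_freqs = wt,
          targets = ft$target_populations, intensity = ft$intensity
        )
      }
    }

    drop <- logical(n)
    for (ft in config$planted_features) {
      if (ft$kind != "sweep" || config$sweep_sfs_thin <= 0) next
      idx <- feature_site_idx(sites, ft)
      if (length(idx) == 0) next
      mean_t <- rowMeans(freqs[idx, ft$target_populations, drop = FALSE])
      mid <- idx[mean_t >= 0.25 & mean_t <= 0.75]
      if (length(mid)) {
        drop[mid] <- drop[mid] | stats::runif(length(mid)) < config$sweep_sfs_thin
      }
    }
    if (any(drop)) {
      keep <- which(!drop)
      remap <- match(seq_len(n), keep)  # old index -> new row (NA if dropped)
      sites <- sites[keep, , drop = FALSE]
      rownames(sites) <- NULL
      freqs <- freqs[keep, , drop = FALSE]
      inversions <- lapply(inversions, function(inv) {
        ok <- !is.na(remap[inv$site_idx])
        inv$wt_freqs <- inv$wt_freqs[ok, , drop = FALSE]
        inv$hap <- inv$hap[ok]
        inv$site_idx <- remap[inv$site_idx][ok]
        inv
      })
    }

    structure(
      list(sites = sites, freqs = freqs, inversions = inversions,
           config = config),
      class = "sim_freqs"
    )
  })
}

#' Sample diploid genotypes from simulated frequencies
#'
#' Each genotype is an independent `Binomial(2, p)` draw on the derived
#' allele. Samples from inversion-block target populations additionally carry
#' a per-individual inversion karyotype (0/1/2 copies drawn with the block's
#' haplotype frequency); at block sites their genotype combines the inverted
#' haplotype's allele with wild-type draws, which is what produces the
#' three-cluster local-PCA pattern of a real segregating inversion.
#'
#' @param sim A `sim_freqs` object from [simulate_frequencies()].
#' @return Integer matrix (sites x samples, values 0/1/2) with attribute
#'   `"inversion_karyotypes"` (list per inversion feature: named 0/1/2 vector
#'   of inverted-haplotype copies per carrier-population sample).
#' @export
sample_genotypes <- function(sim) {
  stopifnot(inherits(sim, "sim_freqs"))
  config <- sim$config
  freqs <- sim$freqs
  if (any(freqs < 0 | freqs > 1)) stop("frequencies must lie in [0, 1]")
  n <- nrow(freqs)
  popmap <- sim_popmap(config)
  with_seed(derive_seed(config$seed, 7), {
    cols <- lapply(config$populations, function(p) {
      matrix(stats::rbinom(n * p$n_diploids, 2, rep(freqs[, p$id], p$n_diploids)),
             nrow = n, ncol = p$n_diploids)
    })
    geno <- do.call(cbind, cols)
    colnames(geno) <- popmap$sample

    karyos <- list()
    for (inv in sim$inversions) {
      kf <- list()
      for (t in inv$targets) {
        smp <- popmap$sample[popmap$population == t]
        wt <- inv$wt_freqs[, t]
        m <- length(inv$site_idx)
        for (s in smp) {
          k <- stats::rbinom(1, 2, inv$intensity)
          g <- k * inv$hap
          if (k < 2) g <- g + stats::rbinom(m, 2 - k, wt)
          geno[inv$site_idx, s] <- g
          kf[[s]] <- k
        }
      }
      karyos[[length(karyos) + 1]] <- unlist(kf)
    }
    attr(geno, "inversion_karyotypes") <- karyos
    storage.mode(geno) <- "integer"
    geno
  })
}

#' Table of planted features (the simulation truth)
#' @param config A `sim_config`.
#' @return Data frame `chrom`, `start`, `end`, `kind`, `targets` (0-based
#'   half-open coordinates), or a zero-row frame if nothing was planted.
#' @export
truth_features <- function(config) {
  if (length(config$planted_features) == 0) {
    return(data.frame(chrom = character(), start = numeric(), end = numeric(),
                      kind = character(), targets = character(),
                      stringsAsFactors = FALSE))
  }
  do.call(rbind, lapply(config$planted_features, function(ft) {
    data.frame(chrom = ft$chrom, start = ft$start, end = ft$end,
               kind = ft$kind,
               targets = paste(ft$target_populations, collapse = ","),
               stringsAsFactors = FALSE)
  }))
}

#' Simulate a complete genotype dataset
#'
#' Convenience wrapper running [simulate_frequencies()] and
#' [sample_genotypes()] and bundling sites, frequencies, genotypes, the
#' population map and the planted-feature truth table.
#'
#' @param config A [sim_config()].
#' @return A `sim_dataset` list with elements `config`, `sites`, `freqs`,
#'   `genotypes`, `popmap`, `truth`.
#' @export
simulate_dataset <- function(config) {
  fr <- simulate_frequencies(config)
  geno <- sample_genotypes(fr)
  structure(
    list(config = config, sites = fr$sites, freqs = fr$freqs,
         genotypes = geno, popmap = sim_popmap(config),
         truth = truth_features(config)),
    class = "sim_dataset"
  )
}

#' @export
print.sim_dataset <- function(x, ...) {
  cat(sprintf("sim_dataset: %d sites x %d samples, %d populations\n",
              nrow(x$genotypes), ncol(x$genotypes), ncol(x$freqs)))
  invisible(x)
}
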