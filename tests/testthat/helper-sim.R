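# Small simulation designs shared across tests.

# A flat star tree: every population drifts independently from the root
# with the same F.
star_tree <- function(pop_ids, f) {
  data.frame(node = c("root", pop_ids),
             parent = c(NA, rep("root", length(pop_ids))),
             f = c(0, rep(f, length(pop_ids))),
             stringsAsFactors = FALSE)
}

# One side with two replicate transects (t1, t2), optional donor and
# outgroup lineages; used for null calibration and planted-signal runs.
two_transect_config <- function(seed = 1, f = 0.05, n_diploids = 6,
                                n_chromosomes = 3, chrom_length = 1e6,
                                n_sites = 12000, planted_features = list(),
                                with_donor = FALSE) {
  pops <- list()
  alt <- c(high = 1235, low = 364, low_distant = 95)
  for (tid in c("t1", "t2")) {
    for (cls in names(alt)) {
      pops[[length(pops) + 1]] <- population_spec(
        id = paste0(tid, "_", cls), transect = tid, side = "east",
        altitude_class = cls, altitude_m = alt[[cls]],
        n_diploids = n_diploids
      )
    }
  }
  edges <- data.frame(
    node = c("anc_s", "anc_t1", "anc_t2",
             paste0("t1_", names(alt)), paste0("t2_", names(alt))),
    parent = c("root", "anc_s", "anc_s", rep("anc_t1", 3), rep("anc_t2", 3)),
    f = c(f / 2, f / 3, f / 3, rep(f, 6)),
    stringsAsFactors = FALSE
  )
  if (with_donor) {
    pops[[length(pops) + 1]] <- population_spec(
      id = "donor", transect = "donor", side = "east",
      altitude_class = "specialist", altitude_m = 1400,
      n_diploids = n_diploids, species = "specialist")
    pops[[length(pops) + 1]] <- population_spec(
      id = "outgroup", transect = "outgroup", side = "east",
      altitude_class = "outgroup", altitude_m = 300, n_diploids = 4,
      species = "outgroup", outgroup = TRUE)
    edges <- rbind(edges,
                   data.frame(node = c("donor", "outgroup"),
                              parent = c("root", "root"), f = c(0.12, 0.3)))
  }
  tree <- rbind(data.frame(node = "root", parent = NA, f = 0), edges)
  sim_config(populations = pops, drift_tree = tree,
             n_chromosomes = n_chromosomes, chrom_length = chrom_length,
             n_sites = n_sites, planted_features = planted_features,
             seed = seed)
}

trio_of <- function(tid) {
  list(high = paste0(tid, "_high"), low = paste0(tid, "_low"),
       low_distant = paste0(tid, "_low_distant"))
}

one_side_layout <- data.frame(transect = c("t1", "t2"),
                              side = c("east", "east"),
                              stringsAsFactors = FALSE)

# Random interval sets on a small genome, for merge/overlap properties.
random_interval_set <- function(n, chrom_lens) {
  chroms <- sample(names(chrom_lens), n, replace = TRUE)
  start <- floor(runif(n, 0, chrom_lens[chroms] * 0.9))
  width <- pmax(1, floor(runif(n, 1, chrom_lens[chroms] * 0.2)))
  data.frame(chrom = chroms, start = start,
             end = pmin(start + width, chrom_lens[chroms]),
             stringsAsFactors = FALSE)
}
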