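# Shared fixtures: tiny MAG tables, random ANI matrices, and an
# independent transitive-closure oracle for the clustering.

make_mags <- function(ids, depth = 5, completeness = 90, contamination = 1,
                      abundance = 10) {
  tibble::tibble(
    mag_id = ids,
    depth_cm = rep_len(depth, length(ids)),
    completeness_pct = rep_len(completeness, length(ids)),
    contamination_pct = rep_len(contamination, length(ids)),
    read_fraction_pct = rep_len(abundance, length(ids))
  )
}

# symmetric ANI matrix from a named pair list, background `base`
make_ani <- function(ids, pairs = list(), base = 80) {
  n <- length(ids)
  m <- matrix(base, n, n, dimnames = list(ids, ids))
  for (p in pairs) {
    m[p[[1]], p[[2]]] <- p[[3]]
    m[p[[2]], p[[1]]] <- p[[3]]
  }
  diag(m) <- 100
  m
}

# random directed ANI matrix on n MAGs, values spanning the threshold
random_ani <- function(n, threshold = 95) {
  ids <- sprintf("G%02d", seq_len(n))
  m <- matrix(stats::runif(n * n, threshold - 4, threshold + 4), n, n,
              dimnames = list(ids, ids))
  diag(m) <- 100
  m
}

# brute-force single-linkage oracle: boolean transitive closure of the
# symmetrized >threshold adjacency (repeated boolean matrix product),
# independent of the graph library used by the implementation
oracle_partition <- function(ani, threshold = 95) {
  sym <- (ani + t(ani)) / 2
  adj <- sym > threshold
  diag(adj) <- TRUE
  reach <- adj
  repeat {
    nxt <- (reach %*% reach) > 0
    if (identical(nxt, reach > 0)) break
    reach <- nxt
  }
  groups <- unique(lapply(seq_len(nrow(reach)),
                          function(i) sort(rownames(ani)[reach[i, ]])))
  canonical_partition(groups)
}

canonical_partition <- function(groups) {
  groups <- lapply(unname(groups), function(g) sort(unname(g)))
  groups[order(vapply(groups, `[`, "", 1))]
}

otus_partition <- function(otus) canonical_partition(otus$members)

# strip the markers list column so MAG tables look like file input
plain_mags <- function(mags) {
  mags[, c("mag_id", "depth_cm", "completeness_pct", "contamination_pct",
           "read_fraction_pct", "taxonomy")]
}

# fraction of one profile category across ordered depths
profile_series <- function(profile, oxygen = NULL, carbon = NULL) {
  p <- profile
  if (!is.null(oxygen)) p <- p[p$oxygen_class %in% oxygen, ]
  if (!is.null(carbon)) p <- p[p$carbon_class %in% carbon, ]
  agg <- stats::aggregate(fraction_pct ~ depth_cm, p, sum)
  agg$fraction_pct[order(agg$depth_cm)]
}

pathway_series <- function(pprof, pathway) {
  p <- pprof[pprof$pathway_id == pathway, ]
  p$fraction_pct[order(p$depth_cm)]
}

# run cluster -> classify -> profile on a generated community
profile_from_community <- function(com, catalog = load_catalog()) {
  mags <- qc_filter(plain_mags(com$mags))$retained
  otus <- cluster_otus(com$ani, mags)
  mags <- attach_markers(mags, com$marker_table)
  calls <- classify_otus(otus, mags, catalog)
  abund <- otu_abundance(otus, mags)
  list(otus = otus, calls = calls, abund = abund,
       guild = guild_profile(abund, calls),
       pathway = pathway_profile(abund, calls))
}
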