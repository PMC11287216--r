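#' Quality-filter MAGs on completeness and contamination
#'
#' Retains MAGs with estimated completeness strictly above
#' `min_completeness` and contamination strictly below `max_contamination`
#' (defaults: >50% complete, <10% contaminated, the usual
#' moderate-to-high-quality cutoff).
#'
#' @param mags Tibble of MAG records with columns `mag_id`,
#'   `completeness_pct`, `contamination_pct` (other columns carried along).
#' @param min_completeness,max_contamination Thresholds in \[0, 100\].
#' @return List with `retained` and `rejected` tibbles.
#' @export
qc_filter <- function(mags, min_completeness = 50, max_contamination = 10) {
  if (min_completeness < 0 || min_completeness > 100 ||
      max_contamination < 0 || max_contamination > 100) {
    abort("QC thresholds must lie in [0, 100]")
  }
  mags <- as_tibble(mags)
  keep <- mags$completeness_pct > min_completeness &
    mags$contamination_pct < max_contamination
  list(retained = mags[keep, , drop = FALSE],
       rejected = mags[!keep, , drop = FALSE])
}

#' Symmetrize a (possibly asymmetric) pairwise ANI matrix
#'
#' fastANI-style estimates are directed; the two directions are combined
#' (arithmetic mean by default; `max` or `min` optionally). Where only one
#' direction was computed, the present value is used. The diagonal is set
#' to 100.
#'
#' @param ani Square numeric matrix with matching row/column names; `NA`
#'   marks missing pairs.
#' @param method One of `"mean"`, `"max"`, `"min"`.
#' @return Symmetric matrix of the same shape.
#' @export
symmetrize_ani <- function(ani, method = c("mean", "max", "min")) {
  method <- match.arg(method)
  if (nrow(ani) != ncol(ani) || !identical(rownames(ani), colnames(ani))) {
    abort("`ani` must be square with identical row and column names")
  }
  rev <- t(ani)
  out <- switch(method,
                mean = (ani + rev) / 2,
                max = pmax(ani, rev),
                min = pmin(ani, rev))
  only_fwd <- !is.na(ani) & is.na(rev)
  only_rev <- is.na(ani) & !is.na(rev)
  out[only_fwd] <- ani[only_fwd]
  out[only_rev] <- rev[only_rev]
  diag(out) <- 100
  out
}

#' Collapse MAGs into OTUs at an ANI threshold
#'
#' Two MAGs fall in the same OTU when they are connected by a chain of
#' pairs whose symmetrized ANI strictly exceeds `threshold_pct`
#' (single-linkage, i.e. connected components of the >threshold graph; a
#' pair at exactly the threshold does not link). OTU ids are assigned
#' deterministically by sorting clusters on their smallest member id.
#' MAGs from different depths may share an OTU.
#'
#' @param ani Square ANI matrix (%, possibly asymmetric) whose dimnames
#'   cover all MAG ids.
#' @param mags MAG tibble (typically the QC-retained set).
#' @param threshold_pct ANI threshold (default 95: the usual species-level
#'   boundary).
#' @param symmetrize How to combine the two ANI directions
#'   (see [symmetrize_ani()]).
#' @return Tibble with one row per OTU: `otu_id`, `representative_mag_id`,
#'   `n_members`, `members` (list column of mag ids).
#' @export
cluster_otus <- function(ani, mags, threshold_pct = 95,
                         symmetrize = c("mean", "max", "min")) {
  symmetrize <- match.arg(symmetrize)
  mags <- as_tibble(mags)
  absent <- setdiff(mags$mag_id, rownames(ani))
  if (length(absent)) {
    abort(paste0("MAG(s) absent from ANI matrix: ",
                 paste(absent, collapse = ", ")))
  }
  ids <- sort(mags$mag_id)
  sym <- symmetrize_ani(ani[ids, ids, drop = FALSE], method = symmetrize)
  adj <- !is.na(sym) & sym > threshold_pct
  diag(adj) <- FALSE
  g <- igraph::graph_from_adjacency_matrix(adj, mode = "undirected")
  comp <- igraph::components(g)$membership
  clusters <- split(ids, comp)
  clusters <- clusters[order(purrr::map_chr(clusters, min))]
  width <- max(2, nchar(length(clusters)))
  tibble(
    otu_id = sprintf(paste0("OTU_%0", width, "d"), seq_along(clusters)),
    representative_mag_id = purrr::map_chr(clusters, select_representative,
                                           mags = mags),
    n_members = lengths(clusters),
    members = unname(purrr::map(clusters, unname))
  )
}

#' Select the representative MAG of an OTU
#'
#' Hierarchical criteria: maximize estimated completeness, then minimize
#' estimated contamination, then maximize relative abundance (% of mapped
#' reads at the MAG's source depth); any remaining tie goes to the
#' lexicographically smallest mag id.
#'
#' @param member_ids Character vector of member mag ids (non-empty).
#' @param mags MAG tibble resolving those ids.
#' @return The representative mag id.
#' @export
select_representative <- function(member_ids, mags) {
  if (!length(member_ids)) abort("OTU has no members")
  sub <- mags[match(member_ids, mags$mag_id), , drop = FALSE]
  if (anyNA(sub$mag_id)) {
    abort("member mag id(s) missing from `mags`")
  }
  ord <- order(-sub$completeness_pct, sub$contamination_pct,
               -sub$read_fraction_pct, sub$mag_id)
  sub$mag_id[ord[1]]
}

#' Per-depth OTU relative abundance
#'
#' The abundance of an OTU at a depth is the sum of its members' read
#' fractions at that depth; depths where an OTU has no member map to 0.
#'
#' @param otus OTU tibble from [cluster_otus()].
#' @param mags MAG tibble with `mag_id`, `depth_cm`, `read_fraction_pct`.
#' @param depths Optional depths to report (defaults to all depths present
#'   in `mags`).
#' @return Long tibble: `otu_id`, `depth_cm`, `abundance_pct`.
#' @export
otu_abundance <- function(otus, mags, depths = NULL) {
  depths <- sort(unique(c(depths, mags$depth_cm)))
  membership <- tidyr::unnest(otus[, c("otu_id", "members")],
                              cols = "members")
  names(membership)[names(membership) == "members"] <- "mag_id"
  long <- membership |>
    left_join(mags[, c("mag_id", "depth_cm", "read_fraction_pct")],
              by = "mag_id") |>
    group_by(.data$otu_id, .data$depth_cm) |>
    summarise(abundance_pct = sum(.data$read_fraction_pct), .groups = "drop")
  tidyr::crossing(otu_id = otus$otu_id, depth_cm = depths) |>
    left_join(long, by = c("otu_id", "depth_cm")) |>
    mutate(abundance_pct = tidyr::replace_na(.data$abundance_pct, 0)) |>
    arrange(.data$otu_id, .data$depth_cm)
}
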