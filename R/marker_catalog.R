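#' Load a marker catalog and guild rulebook
#'
#' The catalog is the configurable rulebook of the package: marker
#' definitions (ids, display names, EC numbers, roles, hydrogenase groups)
#' together with the decision rules that map marker presence to
#' carbon-fixation pathways, electron donors/acceptors, terminal-oxidase
#' classes and fermentative hydrogenase groups. With no argument the
#' built-in default catalog is returned; it encodes the six recognized
#' autotrophic pathways (CBB, rTCA, WL, 3HP, 3HP/4HB, DC/4HB) with their
#' diagnostic marker sets and approximate ATP cost per pyruvate fixed from
#' CO2.
#'
#' @param path Path to a YAML catalog file, or `NULL` for the built-in
#'   default.
#' @return A `marker_catalog` object: list with elements `markers` (tibble),
#'   `pathway_rules`, `donor_rules`, `acceptor_rules`, `oxidase_classes`,
#'   `hydrogenase_groups`, and `allow_missing_central`.
#' @examples
#' cat <- load_catalog()
#' length(cat$pathway_rules)   # 6
#' default_atp_costs(cat)["WL"]
#' @export
load_catalog <- function(path = NULL) {
  if (is.null(path)) {
    path <- system.file("extdata", "default_catalog.yaml",
                        package = "sedguilds", mustWork = TRUE)
  }
  raw <- yaml::read_yaml(path)
  validate_catalog(new_marker_catalog(raw))
}

# Build the catalog object from a parsed config list, normalizing optional
# fields so that write + reload round-trips to an identical rulebook.
new_marker_catalog <- function(raw) {
  if (is.null(raw$markers)) abort("catalog config has no `markers` section")
  markers <- purrr::map(raw$markers, function(m) {
    tibble(
      marker_id = as.character(m$marker_id),
      display_name = as.character(m$display_name %||% m$marker_id),
      ec_number = as.character(m$ec_number %||% ""),
      role = as.character(m$role),
      hydrogenase_group = as.character(m$hydrogenase_group %||% NA_character_)
    )
  })
  markers <- dplyr::bind_rows(markers)

  rules <- purrr::map(raw$pathway_rules %||% list(), function(r) {
    list(
      pathway_id = as.character(r$pathway_id),
      required_all = as.character(unlist(r$required_all %||% character())),
      required_any = purrr::map(r$required_any %||% list(), as.character),
      unless_complete = if (is.null(r$unless_complete)) NULL else as.character(r$unless_complete),
      low_confidence = isTRUE(r$low_confidence),
      atp_cost_per_pyruvate = as.numeric(r$atp_cost_per_pyruvate %||% NA_real_)
    )
  })
  names(rules) <- purrr::map_chr(rules, "pathway_id")

  # each alternative is either a marker id or a '+'-joined co-required set
  norm_rules <- function(x) {
    purrr::map(x %||% list(), function(alts) {
      purrr::map(as.character(unlist(alts)),
                 ~ strsplit(.x, "+", fixed = TRUE)[[1]])
    })
  }

  structure(
    list(
      catalog_name = as.character(raw$catalog_name %||% "unnamed"),
      allow_missing_central = as.integer(raw$allow_missing_central %||% 0L),
      markers = markers,
      pathway_rules = rules,
      donor_rules = norm_rules(raw$donor_rules),
      acceptor_rules = norm_rules(raw$acceptor_rules),
      oxidase_classes = purrr::map(raw$oxidase_classes %||% list(), as.character),
      hydrogenase_groups = purrr::map(raw$hydrogenase_groups %||% list(), as.character)
    ),
    class = "marker_catalog"
  )
}

#' Validate a marker catalog
#'
#' Checks marker-id uniqueness, the hydrogenase-group/role pairing, and that
#' every marker referenced by any rule is declared. Called by
#' [load_catalog()]; exported so hand-built catalogs can be checked too.
#'
#' @param catalog A `marker_catalog`.
#' @return The catalog, invisibly unchanged, or an error naming the
#'   offending rule.
#' @export
validate_catalog <- function(catalog) {
  ids <- catalog$markers$marker_id
  if (anyDuplicated(ids)) {
    abort(paste0("duplicate marker_id in catalog: ",
                 paste(unique(ids[duplicated(ids)]), collapse = ", ")))
  }
  hyd <- catalog$markers$role == "hydrogenase"
  grp <- !is.na(catalog$markers$hydrogenase_group) &
    nzchar(catalog$markers$hydrogenase_group)
  if (any(hyd != grp)) {
    abort(paste0("hydrogenase_group must be set exactly for hydrogenase-role ",
                 "markers; offending: ",
                 paste(ids[hyd != grp], collapse = ", ")))
  }
  roles <- c("autotrophy", "glycolysis", "tca", "ppp", "donor", "acceptor",
             "oxidase", "hydrogenase")
  bad_role <- setdiff(unique(catalog$markers$role), roles)
  if (length(bad_role)) {
    abort(paste0("unknown marker role(s): ", paste(bad_role, collapse = ", ")))
  }

  check_refs <- function(refs, where) {
    missing <- setdiff(refs, ids)
    if (length(missing)) {
      abort(paste0("rule '", where, "' references unknown marker(s): ",
                   paste(missing, collapse = ", ")))
    }
  }
  for (r in catalog$pathway_rules) {
    check_refs(c(r$required_all, unlist(r$required_any)),
               paste0("pathway:", r$pathway_id))
    if (!is.null(r$unless_complete) &&
        !r$unless_complete %in% names(catalog$pathway_rules)) {
      abort(paste0("rule 'pathway:", r$pathway_id,
                   "' unless_complete references unknown pathway '",
                   r$unless_complete, "'"))
    }
  }
  for (nm in names(catalog$donor_rules)) {
    check_refs(unlist(catalog$donor_rules[[nm]]), paste0("donor:", nm))
  }
  for (nm in names(catalog$acceptor_rules)) {
    check_refs(unlist(catalog$acceptor_rules[[nm]]), paste0("acceptor:", nm))
  }
  check_refs(unlist(catalog$oxidase_classes), "oxidase_classes")
  groups <- catalog$markers$hydrogenase_group[hyd]
  bad_grp <- setdiff(unlist(catalog$hydrogenase_groups), groups)
  if (length(bad_grp)) {
    abort(paste0("rule 'hydrogenase_groups' references unknown group(s): ",
                 paste(bad_grp, collapse = ", ")))
  }
  invisible(catalog)
}

#' Write a catalog back to a YAML config file
#'
#' The written file reloads (via [load_catalog()]) to an identical rulebook.
#'
#' @param catalog A `marker_catalog`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_catalog <- function(catalog, path) {
  markers <- purrr::pmap(catalog$markers, function(marker_id, display_name,
                                                   ec_number, role,
                                                   hydrogenase_group) {
    m <- list(marker_id = marker_id, display_name = display_name,
              ec_number = ec_number, role = role)
    if (!is.na(hydrogenase_group)) m$hydrogenase_group <- hydrogenase_group
    m
  })
  rules <- purrr::map(unname(catalog$pathway_rules), function(r) {
    out <- list(pathway_id = r$pathway_id)
    if (length(r$required_all)) out$required_all <- as.list(r$required_all)
    if (length(r$required_any)) out$required_any <- purrr::map(r$required_any, as.list)
    if (!is.null(r$unless_complete)) out$unless_complete <- r$unless_complete
    if (r$low_confidence) out$low_confidence <- TRUE
    out$atp_cost_per_pyruvate <- r$atp_cost_per_pyruvate
    out
  })
  as_sets <- function(x) {
    purrr::map(x, function(alts) {
      purrr::map(alts, ~ paste(.x, collapse = "+"))
    })
  }
  out <- list(
    catalog_name = catalog$catalog_name,
    allow_missing_central = catalog$allow_missing_central,
    markers = markers,
    pathway_rules = rules,
    donor_rules = as_sets(catalog$donor_rules),
    acceptor_rules = as_sets(catalog$acceptor_rules),
    oxidase_classes = purrr::map(catalog$oxidase_classes, as.list),
    hydrogenase_groups = purrr::map(catalog$hydrogenase_groups, as.list)
  )
  yaml::write_yaml(out, path)
  invisible(path)
}

#' ATP cost per pyruvate for each carbon-fixation pathway
#'
#' Approximate ATP demand to synthesize one pyruvate from CO2: WL ~1 (the
#' cheapest known route, exclusive to anaerobes), rTCA 2.5 (midpoint of the
#' commonly cited 2-3), DC/4HB 5, CBB 7, 3HP/4HB 9. No accepted figure is
#' stored for the 3HP bicycle (`NA`, printed as "n/a" in reports).
#'
#' @param catalog A `marker_catalog`; default catalog if omitted.
#' @return Named numeric vector keyed by pathway id.
#' @export
default_atp_costs <- function(catalog = load_catalog()) {
  vapply(catalog$pathway_rules, function(r) r$atp_cost_per_pyruvate,
         numeric(1))
}

# marker ids of a central-metabolism set (glycolysis / tca / ppp)
central_sets <- function(catalog) {
  split(catalog$markers$marker_id, catalog$markers$role)[c("glycolysis", "tca", "ppp")]
}

#' @export
print.marker_catalog <- function(x, ...) {
  cat("<marker_catalog> '", x$catalog_name, "'\n", sep = "")
  cat("  markers:       ", nrow(x$markers), "\n", sep = "")
  cat("  pathway rules: ", length(x$pathway_rules), " (",
      paste(names(x$pathway_rules), collapse = ", "), ")\n", sep = "")
  cat("  donors:        ", paste(names(x$donor_rules), collapse = ", "), "\n", sep = "")
  cat("  acceptors:     ", paste(names(x$acceptor_rules), collapse = ", "), "\n", sep = "")
  costs <- default_atp_costs(x)
  cat("  ATP/pyruvate:  ",
      paste(names(costs), ifelse(is.na(costs), "n/a", costs),
            sep = "=", collapse = ", "), "\n", sep = "")
  invisible(x)
}
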