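# The rule engine: marker presence -> pathways, oxygen class, carbon class,
# electron donor/acceptor repertoire. All rules are positive-evidence rules
# (a capability is called when its markers are present) with one deliberate
# exception, the DC/4HB differential (see detect_pathways).

# does one alternative-set rule fire on this marker set?
sets_fire <- function(markers, alternatives) {
  any(purrr::map_lgl(alternatives, ~ all(.x %in% markers)))
}

#' Detect carbon-fixation pathways from a marker set
#'
#' A pathway is called when all of its `required_all` markers are present
#' and, if the rule lists `required_any` alternatives, at least one
#' alternative set is fully present. The DC/4HB rule is a differential
#' diagnosis: it fires on 4-BUDH plus pyruvate synthase only while the 3HP
#' marker set is incomplete, and carries a low-confidence flag (see
#' [low_confidence_pathways()]). Markers not in the catalog vocabulary are
#' ignored.
#'
#' @param markers Character vector of marker ids present in a genome.
#' @param catalog A `marker_catalog`.
#' @return Character vector of pathway ids (possibly empty).
#' @examples
#' cat <- load_catalog()
#' detect_pathways(c("RuBisCO", "PRK"), cat)   # "CBB"
#' detect_pathways("CODH_ACS", cat)            # character(0)
#' @export
detect_pathways <- function(markers, catalog) {
  fired <- character()
  for (r in catalog$pathway_rules) {
    ok <- all(r$required_all %in% markers) &&
      (length(r$required_any) == 0 || sets_fire(markers, r$required_any))
    if (ok && !is.null(r$unless_complete)) {
      ref <- catalog$pathway_rules[[r$unless_complete]]
      ok <- !all(ref$required_all %in% markers)
    }
    if (ok) fired <- c(fired, r$pathway_id)
  }
  fired
}

#' Pathway ids flagged low-confidence in a catalog
#' @param catalog A `marker_catalog`.
#' @return Character vector (in the default catalog: `"DC4HB"`).
#' @export
low_confidence_pathways <- function(catalog) {
  names(catalog$pathway_rules)[purrr::map_lgl(catalog$pathway_rules,
                                              "low_confidence")]
}

#' Classify the oxygen relationship of a genome
#'
#' A respiratory terminal oxidase (cytochrome c oxidase) makes an aerobe;
#' otherwise a detoxifying oxidase (cytochrome bd) makes an aerotolerant
#' anaerobe; a genome encoding neither is deemed an anaerobe.
#'
#' @inheritParams detect_pathways
#' @return One of `"aerobe"`, `"aerotolerant_anaerobe"`, `"anaerobe"`.
#' @export
classify_oxygen <- function(markers, catalog) {
  if (any(catalog$oxidase_classes$respiratory %in% markers)) return("aerobe")
  if (any(catalog$oxidase_classes$detox %in% markers)) {
    return("aerotolerant_anaerobe")
  }
  "anaerobe"
}

# is a central-metabolism marker set complete, allowing `allow_missing`
# absent members (MAG incompleteness motivates the knob)?
set_complete <- function(markers, set, allow_missing = 0) {
  sum(!set %in% markers) <= allow_missing
}

# marker ids of hydrogenases in the given functional group list
hydrogenases_in_groups <- function(catalog, groups) {
  m <- catalog$markers
  m$marker_id[m$role == "hydrogenase" & m$hydrogenase_group %in% groups]
}

#' Classify the carbon metabolism of a genome
#'
#' A genome with at least one detected fixation pathway is an autotroph; if
#' it additionally encodes complete glycolytic, TCA and pentose-phosphate
#' marker sets it is a facultative autotroph. A genome with no fixation
#' pathway, no terminal oxidase, a complete glycolytic set and an
#' H2-evolving hydrogenase is a fermenter; anything else is a heterotroph.
#'
#' @inheritParams detect_pathways
#' @param pathways Result of [detect_pathways()] on the same marker set.
#' @param allow_missing How many members a central set may lack and still
#'   count as complete (default from the catalog, normally 0; 1 accommodates
#'   "nearly complete" pathways in partial genomes).
#' @return One of `"autotroph"`, `"facultative_autotroph"`,
#'   `"heterotroph"`, `"fermenter"`.
#' @export
classify_carbon <- function(markers, pathways, catalog,
                            allow_missing = catalog$allow_missing_central) {
  sets <- central_sets(catalog)
  complete <- function(role) set_complete(markers, sets[[role]], allow_missing)
  if (length(pathways)) {
    if (complete("glycolysis") && complete("tca") && complete("ppp")) {
      return("facultative_autotroph")
    }
    return("autotroph")
  }
  no_oxidase <- !any(unlist(catalog$oxidase_classes) %in% markers)
  evolving <- hydrogenases_in_groups(catalog,
                                     catalog$hydrogenase_groups$evolving)
  if (no_oxidase && complete("glycolysis") && any(evolving %in% markers)) {
    return("fermenter")
  }
  "heterotroph"
}

#' Electron donor and acceptor repertoire of a genome
#'
#' Each donor/acceptor is called when any one of its alternative marker
#' sets is fully present (e.g. thiosulfate oxidation from Sox; sulfate
#' reduction from Sat + AprAB + DsrAB; H2 as donor from any uptake-capable
#' hydrogenase group).
#'
#' @inheritParams detect_pathways
#' @return List with character vectors `donors` and `acceptors`.
#' @export
donor_acceptor_profile <- function(markers, catalog) {
  fire <- function(rules) {
    names(rules)[purrr::map_lgl(rules, sets_fire, markers = markers)]
  }
  list(donors = fire(catalog$donor_rules),
       acceptors = fire(catalog$acceptor_rules))
}

#' Full guild call for one marker set
#'
#' Runs all classifiers on one genome's markers and bundles the result.
#'
#' @inheritParams detect_pathways
#' @param allow_missing See [classify_carbon()].
#' @return List with elements `pathways`, `low_confidence_pathways`,
#'   `oxygen_class`, `carbon_class`, `donors`, `acceptors`.
#' @export
call_guild <- function(markers, catalog,
                       allow_missing = catalog$allow_missing_central) {
  markers <- unique(as.character(markers))
  pathways <- detect_pathways(markers, catalog)
  da <- donor_acceptor_profile(markers, catalog)
  list(
    pathways = pathways,
    low_confidence_pathways = intersect(pathways,
                                        low_confidence_pathways(catalog)),
    oxygen_class = classify_oxygen(markers, catalog),
    carbon_class = classify_carbon(markers, pathways, catalog, allow_missing),
    donors = da$donors,
    acceptors = da$acceptors
  )
}

#' Guild call for an OTU from its members' marker sets
#'
#' The OTU-level marker set is the union of the member MAGs' markers
#' (presence in any member counts: MAG incompleteness makes absence weak
#' evidence, so evidence from sibling MAGs cross-checks the
#' representative). All classifiers are re-run on the union and an
#' evidence map records which members contributed each marker.
#'
#' @param member_markers Named list: mag id -> character vector of markers
#'   (at least one member).
#' @inheritParams detect_pathways
#' @param allow_missing See [classify_carbon()].
#' @return As [call_guild()], plus `evidence` (named list: marker ->
#'   contributing mag ids).
#' @export
call_otu_guild <- function(member_markers, catalog,
                           allow_missing = catalog$allow_missing_central) {
  if (!length(member_markers)) abort("OTU has no member marker sets")
  union_markers <- sort(unique(unlist(member_markers)))
  evidence <- purrr::map(setNames(union_markers, union_markers),
                         function(m) {
                           names(member_markers)[purrr::map_lgl(member_markers,
                                                                ~ m %in% .x)]
                         })
  out <- call_guild(union_markers, catalog, allow_missing)
  out$evidence <- evidence
  out
}

#' Classify every OTU of a clustering
#'
#' Convenience wrapper: gathers each OTU's member marker sets from the MAG
#' table and applies [call_otu_guild()].
#'
#' @param otus OTU tibble from [cluster_otus()].
#' @param mags MAG tibble carrying a `markers` list column (see
#'   [attach_markers()]).
#' @inheritParams detect_pathways
#' @param allow_missing See [classify_carbon()].
#' @return Tibble with one row per OTU: `otu_id`, `oxygen_class`,
#'   `carbon_class`, and list columns `pathways`,
#'   `low_confidence_pathways`, `donors`, `acceptors`, `evidence`.
#' @export
classify_otus <- function(otus, mags, catalog = load_catalog(),
                          allow_missing = catalog$allow_missing_central) {
  if (!"markers" %in% names(mags)) {
    abort("`mags` lacks a `markers` list column; see attach_markers()")
  }
  marker_sets <- setNames(mags$markers, mags$mag_id)
  calls <- purrr::map(otus$members, function(member_ids) {
    call_otu_guild(marker_sets[member_ids], catalog, allow_missing)
  })
  tibble(
    otu_id = otus$otu_id,
    oxygen_class = purrr::map_chr(calls, "oxygen_class"),
    carbon_class = purrr::map_chr(calls, "carbon_class"),
    pathways = purrr::map(calls, "pathways"),
    low_confidence_pathways = purrr::map(calls, "low_confidence_pathways"),
    donors = purrr::map(calls, "donors"),
    acceptors = purrr::map(calls, "acceptors"),
    evidence = purrr::map(calls, "evidence")
  )
}

#' Attach marker presence calls to a MAG table
#'
#' @param mags MAG tibble with `mag_id`.
#' @param marker_table Long tibble with columns `mag_id`, `marker_id`.
#' @return `mags` with a `markers` list column (character vector per MAG;
#'   MAGs with no annotation get an empty set).
#' @export
attach_markers <- function(mags, marker_table) {
  sets <- split(as.character(marker_table$marker_id),
                factor(marker_table$mag_id, levels = mags$mag_id))
  mags$markers <- purrr::map(unname(sets), ~ sort(unique(.x)))
  mags
}
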