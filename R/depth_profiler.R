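#' Filter OTUs on relative abundance
#'
#' Keeps OTUs whose abundance strictly exceeds `min_pct`; the rest are
#' pooled into an `"other"` category per depth. With `scope =
#' "any_depth"` an OTU is kept wherever it exceeds the threshold in at
#' least one depth (the usual display rule: over 2% for composition
#' figures, over 5% for per-OTU analysis); `"per_depth"` applies the rule
#' row-wise.
#'
#' @param abund Long abundance tibble (`otu_id`, `depth_cm`,
#'   `abundance_pct`), e.g. from [otu_abundance()].
#' @param min_pct Threshold in \[0, 100\]; strict inequality.
#' @param scope `"any_depth"` or `"per_depth"`.
#' @return List with `kept` (rows of retained OTUs) and `other`
#'   (per-depth pooled abundance of the rest, `otu_id = "other"`).
#' @export
abundance_filter <- function(abund, min_pct = 2,
                             scope = c("any_depth", "per_depth")) {
  scope <- match.arg(scope)
  if (min_pct < 0 || min_pct > 100) abort("`min_pct` must lie in [0, 100]")
  abund <- as_tibble(abund)
  if (scope == "any_depth") {
    keep_ids <- abund |>
      group_by(.data$otu_id) |>
      summarise(mx = max(.data$abundance_pct), .groups = "drop") |>
      filter(.data$mx > min_pct) |>
      pull(.data$otu_id)
    keep <- abund$otu_id %in% keep_ids
  } else {
    keep <- abund$abundance_pct > min_pct
  }
  other <- abund[!keep, , drop = FALSE] |>
    group_by(.data$depth_cm) |>
    summarise(abundance_pct = sum(.data$abundance_pct), .groups = "drop") |>
    mutate(otu_id = "other") |>
    select("otu_id", "depth_cm", "abundance_pct")
  list(kept = abund[keep, , drop = FALSE], other = other)
}

# join abundances with calls; unclassified OTUs get NA classes + a warning
join_calls <- function(abund, calls) {
  missing <- setdiff(unique(abund$otu_id), calls$otu_id)
  if (length(missing)) {
    warn(paste0("no guild call for OTU(s): ",
                paste(missing, collapse = ", "),
                "; counted as unclassified"))
  }
  left_join(abund, calls, by = "otu_id")
}

#' Depth-resolved guild composition profile
#'
#' For each depth, sums OTU abundances within each (oxygen class x carbon
#' class) guild. By default fractions are renormalized over classified
#' OTUs so they sum to 100 at every depth with at least one classified
#' OTU; with `renormalize = FALSE` raw percentages of all mapped reads are
#' kept and the unclassified remainder is reported as its own category.
#'
#' @param abund Long abundance tibble (`otu_id`, `depth_cm`,
#'   `abundance_pct`).
#' @param calls Guild-call tibble from [classify_otus()].
#' @param renormalize Renormalize over classified OTUs (default `TRUE`).
#' @return Tibble: `depth_cm`, `oxygen_class`, `carbon_class`,
#'   `fraction_pct`.
#' @export
guild_profile <- function(abund, calls, renormalize = TRUE) {
  joined <- join_calls(abund, calls) |>
    mutate(
      oxygen_class = ifelse(is.na(.data$oxygen_class), "unclassified",
                            .data$oxygen_class),
      carbon_class = ifelse(is.na(.data$carbon_class), "unclassified",
                            .data$carbon_class)
    )
  prof <- joined |>
    group_by(.data$depth_cm, .data$oxygen_class, .data$carbon_class) |>
    summarise(fraction_pct = sum(.data$abundance_pct), .groups = "drop")
  if (renormalize) {
    prof <- prof |>
      filter(.data$oxygen_class != "unclassified") |>
      group_by(.data$depth_cm) |>
      mutate(fraction_pct = 100 * .data$fraction_pct /
               sum(.data$fraction_pct)) |>
      ungroup()
  }
  arrange(prof, .data$depth_cm, .data$oxygen_class, .data$carbon_class)
}

#' Depth-resolved carbon-fixation pathway profile
#'
#' Fraction of the community (same normalization basis as
#' [guild_profile()]) carried by OTUs whose call includes each pathway.
#' Only autotroph-containing OTUs carry pathways; an OTU encoding several
#' pathways contributes its full abundance to each (overlap allowed), so
#' pathway fractions need not sum to the total autotroph fraction.
#'
#' @inheritParams guild_profile
#' @param pathways Pathway ids to report (default the three observed in
#'   depth-stratified sediment communities: WL, rTCA, CBB).
#' @return Tibble: `depth_cm`, `pathway_id`, `fraction_pct`.
#' @export
pathway_profile <- function(abund, calls,
                            pathways = c("WL", "rTCA", "CBB"),
                            renormalize = TRUE) {
  joined <- join_calls(abund, calls)
  classified <- !is.na(joined$oxygen_class)
  denom <- joined[classified, , drop = FALSE] |>
    group_by(.data$depth_cm) |>
    summarise(total = sum(.data$abundance_pct), .groups = "drop")
  if (!renormalize) denom$total <- 100
  purrr::map(pathways, function(p) {
    joined |>
      mutate(hit = purrr::map_lgl(.data$pathways, ~ p %in% .x)) |>
      filter(.data$hit) |>
      group_by(.data$depth_cm) |>
      summarise(fraction_pct = sum(.data$abundance_pct), .groups = "drop") |>
      mutate(pathway_id = p)
  }) |>
    dplyr::bind_rows() |>
    tidyr::complete(pathway_id = pathways,
                    depth_cm = sort(unique(abund$depth_cm)),
                    fill = list(fraction_pct = 0)) |>
    left_join(denom, by = "depth_cm") |>
    mutate(fraction_pct = 100 * .data$fraction_pct / .data$total) |>
    select("depth_cm", "pathway_id", "fraction_pct") |>
    arrange(.data$depth_cm, .data$pathway_id)
}

#' Stacked-bar plot of a guild profile
#'
#' @param profile Output of [guild_profile()].
#' @return A ggplot object (depth on x, guild fractions stacked).
#' @export
plot_guild_profile <- function(profile) {
  profile$guild <- paste(profile$oxygen_class, profile$carbon_class,
                         sep = " / ")
  ggplot2::ggplot(profile,
                  ggplot2::aes(x = factor(.data$depth_cm),
                               y = .data$fraction_pct,
                               fill = .data$guild)) +
    ggplot2::geom_col(width = 0.7) +
    ggplot2::labs(x = "depth (cm)", y = "community fraction (%)",
                  fill = "guild") +
    ggplot2::theme_minimal()
}

#' Stacked-bar plot of a pathway profile
#'
#' @param profile Output of [pathway_profile()].
#' @return A ggplot object.
#' @export
plot_pathway_profile <- function(profile) {
  ggplot2::ggplot(profile,
                  ggplot2::aes(x = factor(.data$depth_cm),
                               y = .data$fraction_pct,
                               fill = .data$pathway_id)) +
    ggplot2::geom_col(width = 0.7, position = "dodge") +
    ggplot2::labs(x = "depth (cm)", y = "community fraction (%)",
                  fill = "pathway") +
    ggplot2::theme_minimal()
}
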