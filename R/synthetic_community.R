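# Synthetic community generator with planted ground truth. Emulates the
# statistical structure of annotation-level inputs from a depth-stratified
# hypersaline sediment survey: a depth-structured guild composition, MAG
# incompleteness-driven marker dropout, contamination-driven foreign
# markers, within-OTU ANI block structure, and porewater chemistry
# gradients. It emits no sequences; everything is at the presence-call
# level, which is exactly what the downstream pipeline consumes.

# draws from N(mean, sd) truncated to (lo, hi] via inverse-CDF sampling
rtruncnorm_ <- function(n, mean, sd, lo, hi) {
  if (sd <= 0) return(rep(min(max(mean, lo), hi), n))
  p_lo <- pnorm(lo, mean, sd)
  p_hi <- pnorm(hi, mean, sd)
  qnorm(runif(n, p_lo, p_hi), mean, sd)
}

# one Dirichlet draw via gamma variates
rdirichlet_ <- function(alpha) {
  x <- rgamma(length(alpha), shape = alpha, rate = 1)
  x / sum(x)
}

#' Canonical marker templates for the guild archetypes
#'
#' One marker template per archetype, modeled on the kinds of populations
#' described from hypersaline sediment columns: obligately aerobic
#' halophilic heterotrophs, sulfur-oxidizing CBB facultative autotrophs,
#' WL-pathway hydrogenotrophic acetogens, aerotolerant WL sulfate reducers,
#' anaerobic rTCA autotrophs, fermentative hydrogen-evolving heterotrophs,
#' and plain anaerobic heterotrophs. Each template exercises a distinct
#' path through the rule engine.
#'
#' @param catalog A `marker_catalog`.
#' @return Named list of character marker sets.
#' @export
guild_templates <- function(catalog = load_catalog()) {
  sets <- central_sets(catalog)
  glyc <- sets$glycolysis; tca <- sets$tca; ppp <- sets$ppp
  list(
    aerobic_heterotroph = c(glyc, tca, ppp, "Cox"),
    sulfur_cbb_facultative = c("RuBisCO", "PRK", "Sox", "Sqo", "SreABC",
                               "NiFe-1a", "Cox", glyc, tca, ppp),
    wl_acetogen = c("CODH_ACS", "FHS", "NiFe-1a", "NiFe-3b", "NiFe-3c",
                    "NiFe-4g", glyc, tca, ppp),
    wl_sulfate_reducer = c("CODH_ACS", "FHS", "NiFe-1c", "Sat", "AprAB",
                           "DsrAB", "Cyd", glyc, tca, ppp),
    rtca_autotroph = c("ACLY", "ccs", "cit", "NiFe-3b", "NiFe-3c",
                       "NiFe-4d", glyc, ppp),
    fermentative_heterotroph = c(glyc, "NiFe-3c", "NiFe-4d", "FeFe"),
    anaerobic_heterotroph = c(glyc, tca)
  )
}

# default depth-structured guild mixture: aerobes and CBB autotrophs
# dominate the surface; WL autotrophs, fermenters and anaerobes take over
# with depth; rTCA appears only at the deepest interval.
default_guild_mixture <- function(depths_cm = c(0, 5, 30)) {
  m <- rbind(
    aerobic_heterotroph      = c(0.45, 0.30, 0.08),
    sulfur_cbb_facultative   = c(0.15, 0.10, 0.00),
    wl_acetogen              = c(0.10, 0.20, 0.30),
    wl_sulfate_reducer       = c(0.05, 0.10, 0.15),
    rtca_autotroph           = c(0.00, 0.00, 0.10),
    fermentative_heterotroph = c(0.05, 0.10, 0.15),
    anaerobic_heterotroph    = c(0.20, 0.20, 0.22)
  )
  colnames(m) <- as.character(depths_cm)
  m
}

#' Scenario configuration for the synthetic community generator
#'
#' Defaults define the package's reference scenario: 14 OTUs across three
#' depth intervals (0, 5, 30 cm) with a guild mixture that shifts from
#' aerobic-heterotrophic at the surface to anaerobic-autotrophic
#' (WL-dominated) at depth; MAG completeness ~N(85, 10) truncated to
#' (50, 100] and contamination ~N(2, 2) truncated to [0, 10) so every MAG
#' passes the QC gate while still exercising marker dropout; within-OTU
#' ANI ~N(98, 0.5) vs between-OTU ~N(85, 3), well separated around the 95%
#' threshold; and Dirichlet-distributed per-depth abundances.
#'
#' @param n_otus Number of OTUs (at least one per guild archetype).
#' @param depths_cm Depth intervals (cm).
#' @param guild_mixture_by_depth Matrix (guild x depth) of expected
#'   community fractions; columns must each sum to 1.
#' @param mags_per_otu Integer range for the total number of MAGs per OTU;
#'   at least one MAG is placed at every depth where the OTU's guild is
#'   planted (effective floor), extras are spread across those depths.
#' @param completeness_distribution,contamination_distribution `(mean, sd)`
#'   of the truncated-normal quality distributions.
#' @param ani_within,ani_between `(mean, sd)` of the directed ANI draws for
#'   within- and between-OTU pairs; the defaults satisfy
#'   `mean_within - 2 sd > threshold > mean_between + 2 sd`.
#' @param contaminant_marker_rate Expected foreign markers per MAG per
#'   contamination percent (Poisson).
#' @param dirichlet_concentration Total Dirichlet concentration per depth;
#'   larger values give abundances closer to the planted mixture.
#' @param ani_threshold_pct Clustering threshold the ANI separation is
#'   validated against.
#' @return A validated `scenario_config` list.
#' @export
scenario_config <- function(n_otus = 14,
                            depths_cm = c(0, 5, 30),
                            guild_mixture_by_depth = default_guild_mixture(depths_cm),
                            mags_per_otu = c(3, 5),
                            completeness_distribution = c(mean = 85, sd = 10),
                            contamination_distribution = c(mean = 2, sd = 2),
                            ani_within = c(mean = 98, sd = 0.5),
                            ani_between = c(mean = 85, sd = 3),
                            contaminant_marker_rate = 0.1,
                            dirichlet_concentration = 500,
                            ani_threshold_pct = 95) {
  config <- structure(
    list(n_otus = as.integer(n_otus), depths_cm = depths_cm,
         guild_mixture_by_depth = guild_mixture_by_depth,
         mags_per_otu = as.integer(mags_per_otu),
         completeness_distribution = completeness_distribution,
         contamination_distribution = contamination_distribution,
         ani_within = ani_within, ani_between = ani_between,
         contaminant_marker_rate = contaminant_marker_rate,
         dirichlet_concentration = dirichlet_concentration,
         ani_threshold_pct = ani_threshold_pct),
    class = "scenario_config"
  )
  validate_scenario_config(config)
}

validate_scenario_config <- function(config) {
  m <- config$guild_mixture_by_depth
  if (!is.matrix(m) || ncol(m) != length(config$depths_cm)) {
    abort("guild_mixture_by_depth must be a guild x depth matrix")
  }
  sums <- colSums(m)
  if (any(abs(sums - 1) > 1e-8)) {
    abort("guild mixtures must sum to 1 at every depth")
  }
  if (any(m < 0)) abort("guild mixtures must be non-negative")
  n_guilds <- sum(rowSums(m) > 0)
  if (config$n_otus < n_guilds) {
    abort(paste0("n_otus must be at least the number of planted guilds (",
                 n_guilds, ")"))
  }
  w <- config$ani_within; b <- config$ani_between; thr <- config$ani_threshold_pct
  if (!(w[["mean"]] - 2 * w[["sd"]] > thr && thr > b[["mean"]] + 2 * b[["sd"]])) {
    abort("ANI distributions must be separated: mean_within - 2 sd > threshold > mean_between + 2 sd")
  }
  invisible(config)
}

# deterministic largest-remainder allocation of n_otus over guilds,
# guaranteeing one OTU per planted guild
allocate_otus <- function(mixture, n_otus) {
  weight <- rowMeans(mixture)
  planted <- names(weight)[weight > 0]
  weight <- weight[planted] / sum(weight[planted])
  counts <- pmax(1L, floor(weight * n_otus))
  while (sum(counts) > n_otus) {          # trim largest surplus guilds
    i <- which.max(counts - weight * n_otus)
    counts[i] <- counts[i] - 1L
  }
  while (sum(counts) < n_otus) {          # largest remainder tops up
    i <- which.max(weight * n_otus - counts)
    counts[i] <- counts[i] + 1L
  }
  rep(planted, counts)
}

#' Generate a synthetic community with planted ground truth
#'
#' Emits every input table the pipeline consumes, plus the planted truth:
#' MAG metadata, a directed pairwise ANI matrix with within-OTU block
#' structure, a long marker table with completeness-driven dropout
#' (per-marker Bernoulli retention with probability completeness/100) and
#' contamination-driven foreign markers, and a porewater table.
#' Reproducible: the same seed yields identical output.
#'
#' @param config A [scenario_config()].
#' @param seed Integer seed for all stochastic draws.
#' @param catalog Marker catalog the templates are built from.
#' @return List with `mags` (tibble, includes a `markers` list column),
#'   `marker_table` (long tibble), `ani` (matrix), `porewater` (tibble) and
#'   `truth` (list: `otus` planted calls, `membership`,
#'   `guild_fractions` realized per depth, `config`, `seed`).
#' @export
generate_community <- function(config = scenario_config(), seed = 1,
                               catalog = load_catalog()) {
  validate_scenario_config(config)
  set.seed(as.integer(seed))
  templates <- guild_templates(catalog)
  mixture <- config$guild_mixture_by_depth
  unknown <- setdiff(rownames(mixture), names(templates))
  if (length(unknown)) {
    abort(paste0("no template for guild(s): ", paste(unknown, collapse = ", ")))
  }
  depths <- config$depths_cm
  depth_key <- as.character(depths)

  otu_guild <- allocate_otus(mixture, config$n_otus)
  width <- max(2, nchar(length(otu_guild)))
  otu_ids <- sprintf(paste0("sOTU_%0", width, "d"), seq_along(otu_guild))
  names(otu_guild) <- otu_ids

  # MAG placement: one per planted depth, extras spread over those depths
  mag_rows <- list()
  for (i in seq_along(otu_ids)) {
    g <- otu_guild[i]
    present <- depth_key[mixture[g, ] > 0]
    k <- sample(seq(config$mags_per_otu[1], config$mags_per_otu[2]), 1)
    k <- max(k, length(present))
    mag_depths <- c(present, sample(present, k - length(present),
                                    replace = TRUE))
    mag_rows[[i]] <- tibble(otu_id = otu_ids[i], guild = g,
                            depth_key = mag_depths)
  }
  depth_lookup <- setNames(depths, depth_key)
  mags <- dplyr::bind_rows(mag_rows) |>
    arrange(.data$otu_id, .data$depth_key) |>
    mutate(
      mag_id = sprintf("MAG_%03d", dplyr::row_number()),
      depth_cm = unname(depth_lookup[.data$depth_key])
    )

  # planted per-depth abundances: Dirichlet over present OTUs, alpha
  # proportional to guild fraction split evenly over that guild's OTUs
  guild_counts <- table(otu_guild)
  abund <- matrix(0, nrow = length(otu_ids), ncol = length(depths),
                  dimnames = list(otu_ids, depth_key))
  for (d in depth_key) {
    frac <- mixture[otu_guild, d]
    present <- frac > 0
    alpha <- frac[present] / as.numeric(guild_counts[otu_guild[present]]) *
      config$dirichlet_concentration
    abund[present, d] <- rdirichlet_(alpha) * 100
  }

  # member read fractions: OTU's depth share split evenly over co-located MAGs
  mags <- mags |>
    group_by(.data$otu_id, .data$depth_key) |>
    mutate(read_fraction_pct = abund[cbind(.data$otu_id, .data$depth_key)] /
             dplyr::n()) |>
    ungroup()

  n_mags <- nrow(mags)
  cd <- config$completeness_distribution
  ct <- config$contamination_distribution
  mags$completeness_pct <- rtruncnorm_(n_mags, cd[["mean"]], cd[["sd"]], 50, 100)
  mags$contamination_pct <- pmin(rtruncnorm_(n_mags, ct[["mean"]], ct[["sd"]],
                                             0, 10), 10 - 1e-9)
  # truncation interval is (50, 100] x [0, 10): nudge off the open bounds
  mags$completeness_pct <- pmax(mags$completeness_pct, 50 + 1e-9)
  mags$taxonomy <- paste0("synthetic;guild=", mags$guild)

  # markers: Bernoulli retention at completeness/100, plus Poisson
  # contaminant draws from outside the template
  all_markers <- catalog$markers$marker_id
  mags$markers <- purrr::map(seq_len(n_mags), function(i) {
    template <- templates[[mags$guild[i]]]
    retained <- template[runif(length(template)) <= mags$completeness_pct[i] / 100]
    n_cont <- rpois(1, mags$contamination_pct[i] * config$contaminant_marker_rate)
    foreign <- setdiff(all_markers, template)
    contaminants <- sample(foreign, min(n_cont, length(foreign)))
    sort(unique(c(retained, contaminants)))
  })

  marker_table <- tibble(
    mag_id = rep(mags$mag_id, lengths(mags$markers)),
    marker_id = unlist(mags$markers)
  )

  # directed ANI with within-OTU block structure
  w <- config$ani_within; b <- config$ani_between
  ani <- matrix(NA_real_, n_mags, n_mags,
                dimnames = list(mags$mag_id, mags$mag_id))
  same_otu <- outer(mags$otu_id, mags$otu_id, "==")
  off <- !diag(n_mags)
  ani[off & same_otu] <- rnorm(sum(off & same_otu), w[["mean"]], w[["sd"]])
  ani[off & !same_otu] <- rnorm(sum(off & !same_otu), b[["mean"]], b[["sd"]])
  ani <- pmin(pmax(ani, 0), 100)
  diag(ani) <- 100

  porewater <- make_porewater(depths)

  truth_calls <- purrr::map(templates, call_guild, catalog = catalog)
  truth_otus <- tibble(
    otu_id = otu_ids,
    guild = unname(otu_guild),
    oxygen_class = unname(purrr::map_chr(truth_calls[otu_guild],
                                         "oxygen_class")),
    carbon_class = unname(purrr::map_chr(truth_calls[otu_guild],
                                         "carbon_class")),
    pathways = unname(purrr::map(truth_calls[otu_guild], "pathways")),
    donors = unname(purrr::map(truth_calls[otu_guild], "donors")),
    acceptors = unname(purrr::map(truth_calls[otu_guild], "acceptors"))
  )
  guild_fractions <- tibble(
    depth_cm = rep(depths, each = length(otu_ids)),
    otu_id = rep(otu_ids, length(depths)),
    guild = rep(unname(otu_guild), length(depths)),
    abundance_pct = as.vector(abund)
  ) |>
    group_by(.data$depth_cm, .data$guild) |>
    summarise(fraction_pct = sum(.data$abundance_pct), .groups = "drop")

  mag_cols <- c("mag_id", "otu_id", "guild", "depth_cm", "completeness_pct",
                "contamination_pct", "read_fraction_pct", "taxonomy",
                "markers")
  list(
    mags = mags[, mag_cols],
    marker_table = marker_table,
    ani = ani,
    porewater = porewater,
    truth = list(
      otus = truth_otus,
      membership = mags[, c("mag_id", "otu_id", "depth_cm")],
      guild_fractions = guild_fractions,
      expected_mixture = mixture,
      config = config,
      seed = as.integer(seed)
    )
  )
}

#' Deterministic synthetic porewater chemistry table
#'
#' Linear depth gradients: pH and dissolved CO2 decline with depth (as in
#' reducing, carbonate-buffered sediment columns) and the 14C uptake signal
#' is flat by default (dark DIC assimilation with no depth trend). No
#' randomness: identical parameters give identical rows.
#'
#' @param depths_cm Depths (cm).
#' @param ph0,ph_slope pH at the surface and per-cm slope.
#' @param co2_0,co2_slope Dissolved CO2 (µM) at the surface and per-cm
#'   slope.
#' @param dpm0,dpm_slope Uptake signal (DPM gdws^-1 h^-1) at the surface
#'   and per-cm slope.
#' @return Tibble: `depth_cm`, `ph`, `co2_uM`, `dpm_rate`.
#' @export
make_porewater <- function(depths_cm = c(0, 5, 30),
                           ph0 = 7.4, ph_slope = -0.01,
                           co2_0 = 300, co2_slope = -4,
                           dpm0 = 60000, dpm_slope = 0) {
  pw <- tibble(
    depth_cm = depths_cm,
    ph = ph0 + ph_slope * depths_cm,
    co2_uM = co2_0 + co2_slope * depths_cm,
    dpm_rate = dpm0 + dpm_slope * depths_cm
  )
  if (any(pw$co2_uM < 0) || any(pw$dpm_rate < 0)) {
    abort("porewater gradients produce negative concentrations or rates")
  }
  pw
}
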