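# End-to-end orchestration: QC -> OTU clustering -> classification ->
# depth profiles -> rate normalization, with a run manifest recording every
# parameter and input digest so a run is reproducible from its output
# directory alone.

with_stage <- function(stage, out_dir, expr) {
  tryCatch(expr, error = function(e) {
    if (!is.null(out_dir)) {
      file.create(file.path(out_dir, ".partial"))
    }
    abort(paste0("stage '", stage, "' failed: ", conditionMessage(e)))
  })
}

md5_of <- function(x) {
  if (is.character(x) && length(x) == 1 && file.exists(x)) {
    return(unname(tools::md5sum(x)))
  }
  tmp <- tempfile()
  on.exit(unlink(tmp))
  saveRDS(x, tmp, version = 2)
  unname(tools::md5sum(tmp))
}

#' Run the full guild-profiling pipeline
#'
#' Executes QC filtering, OTU clustering, representative selection, guild
#' classification, depth profiling and rate normalization. Inputs may be
#' in-memory tables/matrices or file paths (tab-separated; see the
#' `read_*` readers). If `out_dir` is given, all result tables plus a
#' `manifest.json` are written there; on a stage failure a `.partial`
#' marker is left in the directory.
#'
#' @param mags MAG metadata table or path.
#' @param ani Pairwise ANI matrix or path.
#' @param markers Long marker table or path.
#' @param porewater Porewater table or path (optional: `NULL` skips the
#'   rate stage).
#' @param out_dir Output directory, or `NULL` to only return results.
#' @param catalog Marker catalog, path to a catalog YAML, or `NULL` for
#'   the default.
#' @param min_completeness,max_contamination QC thresholds (see
#'   [qc_filter()]).
#' @param ani_threshold,symmetrize Clustering parameters (see
#'   [cluster_otus()]).
#' @param min_pct,filter_scope Abundance display filter (see
#'   [abundance_filter()]).
#' @param renormalize Profile normalization (see [guild_profile()]).
#' @param allow_missing_central Central-set completeness slack (see
#'   [classify_carbon()]).
#' @param pka,specific_activity_uCi_per_umol,label_added_umol,porewater_volume_mL,dpm_per_uci
#'   Rate-normalization parameters (see [normalize_rates()]).
#' @param verbose Print stage progress.
#' @return List: `qc`, `otus`, `abundance`, `abundance_filtered`, `calls`,
#'   `guild_profile`, `pathway_profile`, `rates`, `manifest` (invisibly if
#'   `out_dir` is set).
#' @export
run_pipeline <- function(mags, ani, markers, porewater = NULL,
                         out_dir = NULL, catalog = NULL,
                         min_completeness = 50, max_contamination = 10,
                         ani_threshold = 95, symmetrize = "mean",
                         min_pct = 2, filter_scope = "any_depth",
                         renormalize = TRUE, allow_missing_central = NULL,
                         pka = 6.3, specific_activity_uCi_per_umol = 52,
                         label_added_umol = 1, porewater_volume_mL = 10,
                         dpm_per_uci = 2.22e6, verbose = TRUE) {
  say <- function(...) if (verbose) message("[sedguilds] ", ...)
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    unlink(file.path(out_dir, ".partial"))
  }
  digests <- list()

  catalog <- with_stage("catalog", out_dir, {
    if (is.null(catalog)) {
      load_catalog()
    } else if (is.character(catalog)) {
      load_catalog(catalog)
    } else {
      validate_catalog(catalog)
    }
  })
  if (is.null(allow_missing_central)) {
    allow_missing_central <- catalog$allow_missing_central
  }

  say("QC filtering MAGs")
  qc <- with_stage("qc_filter", out_dir, {
    if (is.character(mags)) {
      digests$mags <- md5_of(mags)
      mags <- read_mag_table(mags)
    } else {
      digests$mags <- md5_of(mags)
    }
    qc_filter(mags, min_completeness, max_contamination)
  })

  say("clustering ", nrow(qc$retained), " MAGs into OTUs")
  otus <- with_stage("cluster_otus", out_dir, {
    if (is.character(ani)) {
      digests$ani <- md5_of(ani)
      ani <- read_ani(ani)
    } else {
      digests$ani <- md5_of(ani)
    }
    cluster_otus(ani, qc$retained, ani_threshold, symmetrize)
  })

  abund <- with_stage("otu_abundance", out_dir,
                      otu_abundance(otus, qc$retained))
  filt <- with_stage("abundance_filter", out_dir,
                     abundance_filter(abund, min_pct, filter_scope))

  say("classifying ", nrow(otus), " OTUs")
  calls <- with_stage("classify", out_dir, {
    if (is.character(markers)) {
      digests$markers <- md5_of(markers)
      markers <- read_marker_table(markers)
    } else {
      digests$markers <- md5_of(markers)
    }
    mags_m <- attach_markers(qc$retained, markers)
    classify_otus(otus, mags_m, catalog, allow_missing_central)
  })

  say("building depth profiles")
  gprof <- with_stage("profile", out_dir,
                      guild_profile(abund, calls, renormalize))
  pprof <- with_stage("profile", out_dir,
                      pathway_profile(abund, calls, renormalize = renormalize))

  rates <- NULL
  if (!is.null(porewater)) {
    say("normalizing DIC assimilation rates")
    rates <- with_stage("rates", out_dir, {
      if (is.character(porewater)) {
        digests$porewater <- md5_of(porewater)
        porewater <- read_porewater(porewater)
      } else {
        digests$porewater <- md5_of(porewater)
      }
      normalize_rates(porewater, pka, specific_activity_uCi_per_umol,
                      label_added_umol, porewater_volume_mL, dpm_per_uci)
    })
  }

  manifest <- list(
    tool = "sedguilds",
    version = as.character(packageVersion("sedguilds")),
    timestamp = format(Sys.time(), tz = "UTC", usetz = TRUE),
    parameters = list(
      min_completeness = min_completeness,
      max_contamination = max_contamination,
      ani_threshold = ani_threshold, symmetrize = symmetrize,
      min_pct = min_pct, filter_scope = filter_scope,
      renormalize = renormalize,
      allow_missing_central = allow_missing_central,
      pka = pka,
      specific_activity_uCi_per_umol = specific_activity_uCi_per_umol,
      label_added_umol = label_added_umol,
      porewater_volume_mL = porewater_volume_mL,
      dpm_per_uci = dpm_per_uci
    ),
    catalog_name = catalog$catalog_name,
    catalog_digest = md5_of(catalog),
    input_digests = digests
  )

  result <- list(qc = qc, otus = otus, abundance = abund,
                 abundance_filtered = filt, calls = calls,
                 guild_profile = gprof, pathway_profile = pprof,
                 rates = rates, manifest = manifest)

  if (!is.null(out_dir)) {
    with_stage("write_outputs", out_dir, {
      wt <- function(df, f) readr::write_tsv(flatten_list_cols(df),
                                             file.path(out_dir, f),
                                             progress = FALSE)
      wt(qc$rejected, "qc_rejected.tsv")
      wt(otus, "otus.tsv")
      wt(abund, "otu_abundance.tsv")
      wt(filt$kept, "otu_abundance_filtered.tsv")
      wt(filt$other, "otu_abundance_other.tsv")
      calls_flat <- calls
      calls_flat$evidence <- NULL
      wt(calls_flat, "guild_calls.tsv")
      jsonlite::write_json(setNames(calls$evidence, calls$otu_id),
                           file.path(out_dir, "guild_evidence.json"),
                           auto_unbox = FALSE, pretty = TRUE)
      wt(gprof, "guild_profile.tsv")
      wt(pprof, "pathway_profile.tsv")
      if (!is.null(rates)) wt(rates, "rates.tsv")
      jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                           auto_unbox = TRUE, digits = NA, pretty = TRUE)
    })
    say("outputs written to ", out_dir)
    return(invisible(result))
  }
  result
}
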