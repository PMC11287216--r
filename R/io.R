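# Delimited-text readers and writers. All tables are tab-separated UTF-8
# with a header row; '#' lines are comments.

read_table_ <- function(path, what) {
  if (!file.exists(path)) {
    abort(paste0(what, " file not found: ", path))
  }
  readr::read_tsv(path, comment = "#", show_col_types = FALSE,
                  progress = FALSE)
}

require_cols <- function(df, cols, what) {
  missing <- setdiff(cols, names(df))
  if (length(missing)) {
    abort(paste0(what, " table lacks column(s): ",
                 paste(missing, collapse = ", ")))
  }
  df
}

#' Read a MAG metadata table
#'
#' Tab-separated with header; columns `mag_id`, `depth_cm`,
#' `completeness_pct`, `contamination_pct`, `read_fraction_pct` (optional
#' `taxonomy` and others carried along).
#'
#' @param path File path.
#' @return Tibble of MAG records.
#' @export
read_mag_table <- function(path) {
  read_table_(path, "MAG metadata") |>
    require_cols(c("mag_id", "depth_cm", "completeness_pct",
                   "contamination_pct", "read_fraction_pct"),
                 "MAG metadata")
}

#' Read a marker presence table
#'
#' Accepts either the long format (`mag_id`, `marker_id`) or a wide
#' presence/absence matrix (first column `mag_id`, one 0/1 column per
#' marker).
#'
#' @param path File path.
#' @return Long tibble (`mag_id`, `marker_id`).
#' @export
read_marker_table <- function(path) {
  df <- read_table_(path, "marker")
  if (all(c("mag_id", "marker_id") %in% names(df))) {
    return(df[, c("mag_id", "marker_id")])
  }
  if (names(df)[1] != "mag_id") {
    abort("marker table must be long (mag_id, marker_id) or wide with a leading mag_id column")
  }
  df |>
    tidyr::pivot_longer(-"mag_id", names_to = "marker_id",
                        values_to = "present") |>
    filter(.data$present > 0) |>
    select("mag_id", "marker_id")
}

#' Read a pairwise ANI table
#'
#' Accepts either a square matrix (first column holds MAG ids, header row
#' names the columns) or the fastANI-style long format with columns
#' `query`, `reference`, `ani` (extra columns ignored); missing pairs stay
#' `NA`.
#'
#' @param path File path.
#' @return Square numeric matrix with MAG-id dimnames.
#' @export
read_ani <- function(path) {
  df <- read_table_(path, "ANI")
  lng <- c("query", "reference", "ani")
  if (all(lng %in% names(df))) {
    ids <- sort(unique(c(df$query, df$reference)))
    m <- matrix(NA_real_, length(ids), length(ids),
                dimnames = list(ids, ids))
    m[cbind(df$query, df$reference)] <- df$ani
    diag(m) <- 100
    return(m)
  }
  ids <- as.character(df[[1]])
  m <- as.matrix(df[, -1])
  mode(m) <- "numeric"
  rownames(m) <- ids
  if (!identical(sort(ids), sort(colnames(m)))) {
    abort("square ANI table must have matching row ids and column names")
  }
  m[ids, ids, drop = FALSE]
}

#' Read a porewater measurement table
#'
#' Columns `depth_cm`, `ph`, `co2_uM`, `dpm_rate` (optional per-row
#' `specific_activity_uCi_per_umol`, `label_added_umol`).
#'
#' @param path File path.
#' @return Tibble.
#' @export
read_porewater <- function(path) {
  read_table_(path, "porewater") |>
    require_cols(c("depth_cm", "ph", "co2_uM", "dpm_rate"), "porewater")
}

#' Write a square ANI matrix as tab-separated text
#' @param ani Square matrix with dimnames.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_ani <- function(ani, path) {
  df <- as_tibble(ani, rownames = "mag_id")
  readr::write_tsv(df, path, progress = FALSE)
  invisible(path)
}

# flatten list columns to comma-joined strings for delimited output
flatten_list_cols <- function(df) {
  for (nm in names(df)) {
    if (is.list(df[[nm]])) {
      df[[nm]] <- purrr::map_chr(df[[nm]], ~ paste(unlist(.x), collapse = ","))
    }
  }
  df
}

#' Write the synthetic-community input tables to a directory
#'
#' Writes `mags.tsv`, `markers.tsv`, `ani.tsv`, `porewater.tsv` and
#' `ground_truth.json`.
#'
#' @param community Output of [generate_community()].
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_community <- function(community, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  mags <- community$mags
  mags$markers <- NULL
  readr::write_tsv(mags, file.path(dir, "mags.tsv"), progress = FALSE)
  readr::write_tsv(community$marker_table, file.path(dir, "markers.tsv"),
                   progress = FALSE)
  write_ani(community$ani, file.path(dir, "ani.tsv"))
  readr::write_tsv(community$porewater, file.path(dir, "porewater.tsv"),
                   progress = FALSE)
  truth <- community$truth
  truth$otus <- flatten_list_cols(truth$otus)
  truth$config <- unclass(truth$config)
  jsonlite::write_json(truth, file.path(dir, "ground_truth.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(dir)
}
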