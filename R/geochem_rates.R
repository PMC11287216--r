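#' Bicarbonate concentration from dissolved CO2 and pH
#'
#' Two-species carbonate speciation via the Henderson-Hasselbalch relation:
#' `[HCO3-] = [CO2] * 10^(pH - pKa)`. At `pH == pka` the two species are
#' equal. This deliberately ignores carbonate ion and activity corrections;
#' porewater DIC is treated as the CO2 + bicarbonate couple only.
#'
#' @param co2_uM Dissolved CO2 concentration (µM), non-negative.
#' @param ph Porewater pH (0-14).
#' @param pka First apparent dissociation constant of carbonic acid
#'   (default 6.3).
#' @return Bicarbonate concentration (µM). Vectorized.
#' @examples
#' bicarbonate_from_co2(10, 6.3)   # 10: species equal at pH = pKa
#' bicarbonate_from_co2(100, 7.3)  # 1000: one unit above pKa => 10x
#' @export
bicarbonate_from_co2 <- function(co2_uM, ph, pka = 6.3) {
  if (any(co2_uM < 0)) abort("`co2_uM` must be non-negative")
  if (any(ph < 0 | ph > 14)) abort("`ph` must lie in [0, 14]")
  co2_uM * 10^(ph - pka)
}

#' Total dissolved inorganic carbon
#'
#' DIC here is the exact sum of dissolved CO2 and bicarbonate.
#'
#' @param co2_uM,hco3_uM Concentrations (µM), non-negative.
#' @return DIC (µM). Vectorized.
#' @export
total_dic <- function(co2_uM, hco3_uM) {
  if (any(co2_uM < 0) || any(hco3_uM < 0)) {
    abort("concentrations must be non-negative")
  }
  co2_uM + hco3_uM
}

#' Isotope dilution factor from the DIC pool
#'
#' Dimensionless ratio of the total DIC amount in the incubation to the
#' amount of labeled bicarbonate added. Converts a DIC concentration (µM)
#' to an amount via the incubation porewater volume.
#'
#' @param dic_uM Total DIC concentration (µM).
#' @param porewater_volume_mL Porewater volume of the incubation (mL).
#' @param label_added_umol Amount of 14C-labeled DIC added (µmol, default 1).
#' @return Dilution factor (total DIC amount / label amount).
#' @export
dic_dilution_factor <- function(dic_uM, porewater_volume_mL,
                                label_added_umol = 1) {
  if (any(porewater_volume_mL <= 0) || any(label_added_umol <= 0)) {
    abort("`porewater_volume_mL` and `label_added_umol` must be positive")
  }
  (dic_uM * porewater_volume_mL / 1000) / label_added_umol
}

#' Convert a 14C uptake rate to a total DIC assimilation rate
#'
#' DPM are converted to µmol of label via the definitional 2.22e6 DPM/µCi
#' and the specific activity of the tracer, multiplied by the isotope
#' dilution factor (total DIC / label added) to account for assimilation of
#' the unlabeled pool, and rescaled to nmol.
#'
#' @param dpm_rate Measured uptake (DPM gdws^-1 h^-1), non-negative.
#' @param specific_activity_uCi_per_umol Specific activity of the labeled
#'   bicarbonate (µCi µmol^-1, default 52).
#' @param dilution_factor Dimensionless isotope dilution factor, see
#'   [dic_dilution_factor()].
#' @param dpm_per_uci DPM per µCi (definitional constant, 2.22e6).
#' @return Rate in nmol C gdws^-1 h^-1. Linear separately in `dpm_rate`
#'   and `dilution_factor`.
#' @examples
#' radiotracer_rate(115440, 52, 10)  # 10 nmol C gdws^-1 h^-1
#' @export
radiotracer_rate <- function(dpm_rate, specific_activity_uCi_per_umol = 52,
                             dilution_factor, dpm_per_uci = 2.22e6) {
  if (any(dpm_rate < 0)) abort("`dpm_rate` must be non-negative")
  if (any(specific_activity_uCi_per_umol <= 0)) {
    abort("`specific_activity_uCi_per_umol` must be positive")
  }
  if (any(dilution_factor <= 0)) abort("`dilution_factor` must be positive")
  if (any(dpm_per_uci <= 0)) abort("`dpm_per_uci` must be positive")
  dpm_rate / (dpm_per_uci * specific_activity_uCi_per_umol) *
    dilution_factor * 1000
}

#' Convert volumetric daily rates to gravimetric hourly rates
#'
#' Published sediment DIC-assimilation rates in µmol C cm^-3 day^-1 are
#' converted to nmol C gdws^-1 h^-1 assuming a sediment density (default
#' 2.0 g cm^-3, typical of sand-rich sediment):
#' `rate * 1000 / (density * 24)`.
#'
#' @param rate_umol_per_cm3_day Volumetric rate (µmol C cm^-3 day^-1).
#' @param density_g_per_cm3 Sediment density (g cm^-3), positive.
#' @return Rate in nmol C gdws^-1 h^-1.
#' @examples
#' volumetric_to_gravimetric(0.18)  # 3.75 -> reported as 3.8 (2 s.f.)
#' @export
volumetric_to_gravimetric <- function(rate_umol_per_cm3_day,
                                      density_g_per_cm3 = 2.0) {
  if (any(density_g_per_cm3 <= 0)) abort("`density_g_per_cm3` must be positive")
  rate_umol_per_cm3_day * 1000 / (density_g_per_cm3 * 24)
}

#' @rdname volumetric_to_gravimetric
#' @param rate_nmol_per_gdws_h Gravimetric rate (nmol C gdws^-1 h^-1).
#' @export
gravimetric_to_volumetric <- function(rate_nmol_per_gdws_h,
                                      density_g_per_cm3 = 2.0) {
  if (any(density_g_per_cm3 <= 0)) abort("`density_g_per_cm3` must be positive")
  rate_nmol_per_gdws_h * density_g_per_cm3 * 24 / 1000
}

#' Normalize a porewater table of 14C uptake to DIC assimilation rates
#'
#' For each row computes bicarbonate from CO2 and pH, total DIC, the isotope
#' dilution factor, and the normalized rate in nmol C gdws^-1 h^-1.
#'
#' @param porewater Tibble/data frame with columns `depth_cm`, `ph`,
#'   `co2_uM`, `dpm_rate`; optional per-row `specific_activity_uCi_per_umol`
#'   and `label_added_umol` override the defaults.
#' @param pka Apparent pKa of the CO2/bicarbonate couple (default 6.3).
#' @param specific_activity_uCi_per_umol Tracer specific activity
#'   (µCi µmol^-1, default 52).
#' @param label_added_umol Label added (µmol, default 1).
#' @param porewater_volume_mL Incubation porewater volume (mL, default 10).
#' @param dpm_per_uci DPM per µCi (default 2.22e6).
#' @return Input tibble with added columns `hco3_uM`, `dic_uM`,
#'   `dilution_factor`, `rate_nmol_per_gdws_h`.
#' @export
normalize_rates <- function(porewater, pka = 6.3,
                            specific_activity_uCi_per_umol = 52,
                            label_added_umol = 1,
                            porewater_volume_mL = 10,
                            dpm_per_uci = 2.22e6) {
  porewater <- as_tibble(porewater)
  need <- c("depth_cm", "ph", "co2_uM", "dpm_rate")
  missing <- setdiff(need, names(porewater))
  if (length(missing)) {
    abort(paste0("porewater table lacks column(s): ",
                 paste(missing, collapse = ", ")))
  }
  sa <- porewater[["specific_activity_uCi_per_umol"]] %||%
    specific_activity_uCi_per_umol
  label <- porewater[["label_added_umol"]] %||% label_added_umol
  porewater |>
    mutate(
      hco3_uM = bicarbonate_from_co2(.data$co2_uM, .data$ph, pka),
      dic_uM = total_dic(.data$co2_uM, .data$hco3_uM),
      dilution_factor = dic_dilution_factor(.data$dic_uM,
                                            porewater_volume_mL, label),
      rate_nmol_per_gdws_h = radiotracer_rate(.data$dpm_rate, sa,
                                              .data$dilution_factor,
                                              dpm_per_uci)
    )
}
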