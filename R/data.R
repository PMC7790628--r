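#' Published survey totals from the Manang 2019 blue sheep counts
#'
#' Season-level totals of a two-season total-count transect survey in the
#' Manang valley (Annapurna Conservation Area, Nepal): transect numbers and
#' lengths, individuals counted within the 1,000-m and 1,500-m buffers, and
#' the corrected visible survey areas. The autumn 1,000-m visible area was
#' not published and is `NA`; its density bound is therefore not
#' recomputable from these totals.
#'
#' @return data.frame with one row per season: `season`, `n_transects`,
#'   `total_length_km`, `individuals_1000m`, `individuals_1500m`,
#'   `visible_area_1000m_km2`, `visible_area_1500m_km2`.
#' @examples
#' sv <- manang_survey_summary()
#' with(sv[sv$season == "spring", ],
#'      density_estimate(individuals_1000m, visible_area_1000m_km2))
#' @export
manang_survey_summary <- function() {
  utils::read.csv(system.file("extdata", "manang_survey_2019.csv",
                              package = "bharal"))
}
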