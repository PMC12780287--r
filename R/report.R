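#' Write a segmentation report as JSON
#'
#' The report records the method, the thresholds used, infarct volume (mL),
#' mass (g) and fraction of LV mass (%), plus the resolved configuration and
#' seed so a run can be reproduced bit-identically.
#'
#' @param seg an [infarct_seg].
#' @param path output path.
#' @param config optional named list of configuration values to echo.
#' @param seed optional RNG seed to echo.
#' @return `path`, invisibly.
#' @export
write_report <- function(seg, path, config = NULL, seed = NULL) {
  rep <- list(
    method = seg$method,
    convention = seg$convention,
    thresholds = seg$thresholds,
    infarct_volume_ml = seg$volume_ml,
    infarct_mass_g = seg$mass_g,
    fraction_of_lv_pct = seg$fraction_pct,
    lv_mass_g = seg$lv_mass_g,
    density_g_per_ml = seg$density
  )
  if (!is.null(config)) rep$config <- config
  if (!is.null(seed)) rep$seed <- seed
  jsonlite::write_json(rep, path, auto_unbox = TRUE, digits = NA, null = "null")
  invisible(path)
}

#' Read a segmentation report
#' @param path JSON report path.
#' @return named list.
#' @export
read_report <- function(path) {
  if (!file.exists(path)) stop("report not found: ", path)
  jsonlite::read_json(path, simplifyVector = TRUE)
}
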