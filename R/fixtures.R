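# Bundled synthetic fixtures.

#' Synthetic cross-tracer regional-mean table
#'
#' A synthetic stand-in for a per-ROI mean-SUVR comparison between a PIB
#' and a Florbetapir cohort: 12 bilateral ROIs with plausible group-mean
#' magnitudes (wide PIB range, compressed Florbetapir range) for an AD and
#' an amyloid-positive MCI group. The values are constructed, not measured;
#' their rank structure is calibrated so the Spearman correlation between
#' the tracers' regional means reproduces the published values (0.853 in
#' AD, 0.902 in amyloid-positive MCI) exactly at 3 decimals.
#'
#' @return Tibble with columns `roi`, `pib_ad`, `florbetapir_ad`,
#'   `pib_mciplus`, `florbetapir_mciplus`.
#' @export
synthetic_roi_means <- function() {
  path <- system.file("extdata", "synthetic_roi_means.csv",
                      package = "amypet", mustWork = TRUE)
  tibble::as_tibble(read.csv(path, stringsAsFactors = FALSE))
}
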