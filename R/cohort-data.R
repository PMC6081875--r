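#' Published ten-patient Lu-177 therapy cohort tables
#'
#' Per-patient values transcribed from a published clinical cohort of five
#' Lu-177-Octreotate (NET) and five Lu-177-PSMA-617 (mCRPC) patients imaged
#' at 24/48/72 h post-injection: patient context (sex, injected activity,
#' haematocrit), reference-protocol total marrow doses with percentage
#' contributions, reference and hybrid (HP24/HP48/HP72) total doses, and
#' planar whole-body vs SPECT abdominal effective half-lives. These drive
#' the cohort-level validation of the comparison machinery; the underlying
#' images and blood counts are not public, so the dose engine itself is
#' validated on synthetic patients instead.
#'
#' @return Named list of data frames: `context`, `reference_doses`,
#'   `protocol_doses`, `half_lives`.
#' @export
lu177_cohort_tables <- function() {
  dir <- system.file("extdata", "cohort", package = "marrowdose")
  read <- function(f) utils::read.csv(file.path(dir, f), stringsAsFactors = FALSE)
  list(context = read("cohort_context.csv"),
       reference_doses = read("reference_doses.csv"),
       protocol_doses = read("protocol_doses.csv"),
       half_lives = read("half_lives.csv"))
}
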