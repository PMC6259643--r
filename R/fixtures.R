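# Loaders for the packaged CXCR2 activity fixtures (transcribed printed
# tables; see inst/extdata/cxcr2_fixtures_NOTES.md for provenance and known
# transcription caveats).

.fixture_path <- function(file) {
  p <- system.file("extdata", file, package = "qsarpipe")
  if (p == "") stop("fixture not found: ", file)
  p
}

#' CXCR2 antagonist activity fixture
#'
#' The transcribed compound id / IC50 / printed pIC50 table (126 compounds).
#' Adds `pic50_computed` (exact conversion via [ic50_to_pic50()]) and
#' `self_consistent` (TRUE when the computed value rounds to the printed one
#' at 2 decimals). An integrity checksum over the packaged file guards
#' against silent fixture corruption.
#'
#' @return data frame with columns `compound_id`, `source_table`, `ic50`,
#'   `unit`, `pic50_printed`, `pic50_computed`, `self_consistent`.
#' @export
cxcr2_activities <- function() {
  df <- utils::read.csv(.fixture_path("cxcr2_activity.csv"),
                        stringsAsFactors = FALSE,
                        colClasses = c(compound_id = "character"))
  if (nrow(df) != 126 || abs(sum(df$pic50_printed) - 879.66) > 0.01)
    stop("cxcr2_activity.csv failed its integrity check")
  df$pic50_computed <- ic50_to_pic50(df$ic50, df$unit)
  df$self_consistent <- round(df$pic50_computed, 2) == df$pic50_printed
  df
}

#' CXCR2 prediction-set fixture
#'
#' The 16 transcribed prediction-set rows: experimental pIC50 and the
#' predicted/residual pairs of the PLS, GA-PLS and stepwise-MLR models.
#' Residuals are printed as predicted minus experimental.
#'
#' @return data frame with columns `compound_id`, `pic50_exp`, and
#'   `<method>_pred` / `<method>_resid` for methods pls, gapls, smlr.
#' @export
cxcr2_test_predictions <- function() {
  df <- utils::read.csv(.fixture_path("cxcr2_test_predictions.csv"),
                        stringsAsFactors = FALSE,
                        colClasses = c(compound_id = "character"))
  if (nrow(df) != 16 || abs(sum(df$pic50_exp) - 109.47) > 0.01)
    stop("cxcr2_test_predictions.csv failed its integrity check")
  df
}
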