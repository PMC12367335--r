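#' Published benchmark MSE table for ten ICU admission cohorts
#'
#' Test-set mean squared errors (squared days) of length-of-stay models on
#' the ten most frequent ICU admission-diagnosis cohorts of a large
#' multi-center ICU database (credentialed access; not redistributed here):
#' linear regression, BiLSTM, LSTM and the wavelet-denoised LSTM on
#' 24-hour vitals, the APACHE IV clinical scoring system (treated as
#' printed constants), and the wavelet model under 3/6/12-hour real-time
#' windows. These values are inputs to the improvement-percentage
#' arithmetic, e.g. `improvement_pct(mse_lstm, mse_wtlstm)`.
#'
#' @return A data.frame with one row per cohort abbreviation (`HF`, `CVA`,
#'   `MI`, `SP`, `SR`, `RD`, `DK`, `CA`, `CABG`, `EB`) and the MSE columns
#'   described above.
#' @examples
#' b <- benchmark_mse()
#' round(improvement_pct(b$mse_lstm, b$mse_wtlstm), 2)
#' @export
benchmark_mse <- function() {
  path <- system.file("extdata", "cohort_benchmark_mse.csv", package = "wtlstm",
                      mustWork = TRUE)
  utils::read.csv(path, stringsAsFactors = FALSE)
}
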