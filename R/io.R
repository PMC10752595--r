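# Plain-text interchange formats: documents as JSONL, episodes and tabular
# outputs as CSV, manifests as JSON.

#' Write a document table as JSON lines
#'
#' One JSON object per line with fields `doc_id`, `patient_id`, `date`
#' (ISO-8601) and any further columns (e.g. `text`, `period`).
#'
#' @param documents Data frame with at least `doc_id`, `patient_id`, `date`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_documents_jsonl <- function(documents, path) {
  df <- as.data.frame(documents)
  df$date <- format(as.Date(df$date))
  con <- file(path, "w")
  on.exit(close(con))
  jsonlite::stream_out(df, con, verbose = FALSE)
  invisible(path)
}

#' Read a JSONL document table
#'
#' @param path File written by [write_documents_jsonl()] (or any JSONL with
#'   compatible fields).
#' @return Tibble with `date` parsed as Date.
#' @export
read_documents_jsonl <- function(path) {
  con <- file(path, "r")
  on.exit(close(con))
  df <- tibble::as_tibble(jsonlite::stream_in(con, verbose = FALSE))
  if (!is.null(df$date)) df$date <- as.Date(df$date)
  df
}

#' Write an episode table as CSV
#'
#' @param episodes Data frame with `patient_id`, `epi_start`, `epi_end`,
#'   `icd10_code`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_episodes_csv <- function(episodes, path) {
  readr::write_csv(episodes, path)
  invisible(path)
}

#' Read an episode CSV
#'
#' @param path CSV with columns `patient_id`, `epi_start`, `epi_end`,
#'   `icd10_code`.
#' @return Tibble with date columns parsed as Dates.
#' @export
read_episodes_csv <- function(path) {
  readr::read_csv(path, col_types = readr::cols(
    patient_id = readr::col_character(),
    epi_start = readr::col_date(),
    epi_end = readr::col_date(),
    icd10_code = readr::col_character()
  ))
}
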