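# Per-patient documentation-rate statistics and attempt-aligned trajectories.
#
# MonitoringLevel_W for a reference date is the number of documents recorded
# in the closed window [reference - W, reference - 1], divided by W. The
# reference day itself is excluded ("the preceding W days"), and a patient is
# "under monitoring" at a date only if at least one document exists strictly
# before it.

#' Documentation rate (MonitoringLevel_W) for one patient
#'
#' Counts documents dated within the closed interval
#' `[reference_date - window, reference_date - 1]` and divides by the window
#' size, giving an average documents-per-day rate. With 30 documents in the
#' preceding 30 days the level is exactly 1.
#'
#' @param doc_dates Dates of one patient's documents.
#' @param reference_date Date at which the level is evaluated.
#' @param window Window size W in days (default 30).
#' @return A one-row tibble: `reference_date`, `window`, `n_docs`, `level`.
#' @export
monitoring_level <- function(doc_dates, reference_date, window = 30) {
  if (window < 1) stop("window must be at least 1 day", call. = FALSE)
  doc_dates <- as.Date(doc_dates)
  reference_date <- as.Date(reference_date)
  n <- sum(doc_dates >= reference_date - window &
             doc_dates <= reference_date - 1)
  tibble::tibble(reference_date = reference_date, window = as.integer(window),
                 n_docs = as.integer(n), level = n / window)
}

#' Is a patient under monitoring at a given date?
#'
#' `TRUE` iff at least one document is dated strictly before the reference
#' date. A first document dated on the reference date itself does not count.
#'
#' @inheritParams monitoring_level
#' @return Logical flag.
#' @export
under_monitoring <- function(doc_dates, reference_date) {
  any(as.Date(doc_dates) < as.Date(reference_date))
}

#' Attempt-aligned documentation-coverage trajectory
#'
#' Aligns all patients at their first suicide-related admission and, for each
#' (negative) day offset, reports the fraction of monitored patients with at
#' least `min_docs` documents in the `window` days preceding that day. The
#' denominator at offset d is the number of patients under monitoring at
#' `attempt_date + d` (at least one document strictly before it); the
#' numerator is the subset with `>= min_docs` documents dated in
#' `[attempt_date + d - window, attempt_date + d - 1]`. Patients with no
#' document at all before their attempt are excluded outright.
#'
#' @param documents Data frame with `patient_id` and `date` columns (one row
#'   per document).
#' @param attempts Data frame with `patient_id` and `attempt_date`; patients
#'   absent from it are ignored.
#' @param offsets Integer day offsets, all negative (default `-365:-1`).
#' @param window Window size W in days (default 30).
#' @param min_docs Numerator threshold: minimum documents in the window for a
#'   patient to count as covered (default 1).
#' @return Tibble with `offset`, `numerator`, `denominator`, `fraction`
#'   (`NA` where the denominator is 0).
#' @export
aligned_trajectory <- function(documents, attempts, offsets = -365:-1,
                               window = 30, min_docs = 1) {
  if (any(offsets >= 0)) stop("offsets must be negative days", call. = FALSE)
  if (window < 1) stop("window must be at least 1 day", call. = FALSE)
  offsets <- sort(as.integer(offsets))
  docs <- dplyr::inner_join(
    documents[, c("patient_id", "date")],
    attempts[, c("patient_id", "attempt_date")],
    by = "patient_id"
  )
  if (nrow(docs) == 0) stop("no documents for any patient with an attempt date",
                            call. = FALSE)
  rel <- as.integer(as.Date(docs$date) - as.Date(docs$attempt_date))
  by_patient <- split(rel, docs$patient_id)
  # drop patients with no pre-attempt documentation at all
  by_patient <- by_patient[vapply(by_patient, function(r) any(r < 0), logical(1))]
  num <- den <- integer(length(offsets))
  for (r in by_patient) {
    r <- sort(r)
    monitored <- r[1] < offsets
    in_window <- findInterval(offsets - 1, r) - findInterval(offsets - window - 1, r)
    den <- den + monitored
    num <- num + (monitored & in_window >= min_docs)
  }
  tibble::tibble(offset = offsets, numerator = as.integer(num),
                 denominator = as.integer(den),
                 fraction = ifelse(den > 0, num / den, NA_real_))
}
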