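# Proximal / distal corpus selection.
#
# Proximal: documents dated between 31 and 1 days before any suicide-related
# admission. Distal: documents dated between 365 and 300 days before a
# suicide-related admission, and (for admissions after the first) at least
# 300 clear days after the previous suicide-related admission's discharge.
# All intervals are closed and at day resolution.

match_window_documents <- function(documents, admissions, lo, hi) {
  # documents within [admit - lo, admit - hi] of any listed admission,
  # deduplicated to the earliest qualifying admission
  hits <- dplyr::inner_join(
    documents, admissions,
    by = "patient_id", relationship = "many-to-many"
  )
  hits <- hits[hits$date >= hits$admit_date - lo &
                 hits$date <= hits$admit_date - hi, , drop = FALSE]
  hits |>
    dplyr::group_by(.data$doc_id) |>
    dplyr::slice_min(.data$admit_date, n = 1, with_ties = FALSE) |>
    dplyr::ungroup()
}

#' Select documents proximal to a suicide-related admission
#'
#' A document qualifies if dated within `[admit_date - window[1],
#' admit_date - window[2]]` of any suicide-related admission (default 31 to 1
#' days before). A document qualifying against several admissions appears
#' once, anchored to the earliest.
#'
#' @param documents Data frame with `doc_id`, `patient_id`, `date`, `text`.
#' @param admissions Consolidated admissions (from [build_admissions()]).
#' @param window Length-2 integer, days before admission: `c(start, end)`
#'   with `start >= end >= 0`.
#' @param anchor `"all"` (default) anchors windows to every suicide-related
#'   admission, `"first"` to each patient's first only.
#' @return Tibble of qualifying documents with `period = "proximal"` and
#'   `anchor_admission_id`.
#' @export
proximal_documents <- function(documents, admissions, window = c(31, 1),
                               anchor = c("all", "first")) {
  anchor <- match.arg(anchor)
  sui <- admissions[admissions$suicide_related, , drop = FALSE]
  if (anchor == "first") {
    sui <- sui |>
      dplyr::group_by(.data$patient_id) |>
      dplyr::slice_min(.data$admit_date, n = 1, with_ties = FALSE) |>
      dplyr::ungroup()
  }
  hits <- match_window_documents(
    documents, sui[, c("patient_id", "admission_id", "admit_date")],
    window[1], window[2]
  )
  tibble::tibble(doc_id = hits$doc_id, patient_id = hits$patient_id,
                 date = hits$date, text = hits$text, period = "proximal",
                 anchor_admission_id = hits$admission_id)
}

#' Select documents distal to a suicide-related admission
#'
#' For each patient's first suicide-related admission, documents dated within
#' `[admit - window[1], admit - window[2]]` (default 365 to 300 days before)
#' qualify. For each later suicide-related admission the same window applies,
#' but only documents dated at least `clearance` days after the previous
#' suicide-related admission's discharge qualify, so that "distal" documents
#' are never close to an earlier attempt.
#'
#' @inheritParams proximal_documents
#' @param window Length-2 integer, days before admission (default
#'   `c(365, 300)`).
#' @param clearance Minimum days from the previous suicide-related
#'   admission's discharge to the document date (default 300).
#' @return Tibble of qualifying documents with `period = "distal"`.
#' @export
distal_documents <- function(documents, admissions, window = c(365, 300),
                             clearance = 300) {
  sui <- admissions[admissions$suicide_related, , drop = FALSE]
  sui <- sui |>
    dplyr::arrange(.data$patient_id, .data$admit_date) |>
    dplyr::group_by(.data$patient_id) |>
    dplyr::mutate(prev_discharge = dplyr::lag(.data$discharge_date)) |>
    dplyr::ungroup()
  hits <- dplyr::inner_join(
    documents,
    sui[, c("patient_id", "admission_id", "admit_date", "prev_discharge")],
    by = "patient_id", relationship = "many-to-many"
  )
  keep <- hits$date >= hits$admit_date - window[1] &
    hits$date <= hits$admit_date - window[2] &
    (is.na(hits$prev_discharge) | hits$date >= hits$prev_discharge + clearance)
  hits <- hits[keep, , drop = FALSE]
  hits <- hits |>
    dplyr::group_by(.data$doc_id) |>
    dplyr::slice_min(.data$admit_date, n = 1, with_ties = FALSE) |>
    dplyr::ungroup()
  tibble::tibble(doc_id = hits$doc_id, patient_id = hits$patient_id,
                 date = hits$date, text = hits$text, period = "distal",
                 anchor_admission_id = hits$admission_id)
}

#' Build the labelled proximal/distal corpus
#'
#' Takes the union of the proximal and distal selections, drops documents of
#' `min_chars` characters or fewer (strictly more than `min_chars` survive;
#' raw length including whitespace), and resolves documents qualifying for
#' both periods in favour of proximal (the label driving the risk-detection
#' use case), recording the conflicts.
#'
#' @inheritParams proximal_documents
#' @param min_chars Length filter: documents must contain more than this many
#'   characters (default 100).
#' @param proximal_window,distal_window,clearance Window parameters passed to
#'   [proximal_documents()] and [distal_documents()].
#' @param proximal_anchor Passed to [proximal_documents()] as `anchor`.
#' @return A `labeled_corpus` object: list with `documents` (tibble of
#'   labelled documents), `summary` (per-period document/patient counts and
#'   the both-period patient overlap), and `dual_period_doc_ids`.
#' @export
build_labeled_corpus <- function(documents, admissions, min_chars = 100,
                                 proximal_window = c(31, 1),
                                 distal_window = c(365, 300), clearance = 300,
                                 proximal_anchor = "all") {
  if (anyDuplicated(documents$doc_id)) {
    stop("duplicate doc_id in document table", call. = FALSE)
  }
  prox <- proximal_documents(documents, admissions, proximal_window,
                             proximal_anchor)
  dist <- distal_documents(documents, admissions, distal_window, clearance)
  dual <- intersect(prox$doc_id, dist$doc_id)
  dist <- dist[!dist$doc_id %in% dual, , drop = FALSE]
  corpus <- dplyr::bind_rows(prox, dist)
  corpus <- corpus[nchar(corpus$text) > min_chars, , drop = FALSE]
  corpus <- dplyr::arrange(corpus, .data$doc_id)
  summ <- corpus |>
    dplyr::group_by(period = .data$period) |>
    dplyr::summarise(n_docs = dplyr::n(),
                     n_patients = dplyr::n_distinct(.data$patient_id),
                     .groups = "drop")
  overlap <- length(intersect(corpus$patient_id[corpus$period == "proximal"],
                              corpus$patient_id[corpus$period == "distal"]))
  structure(
    list(documents = corpus,
         summary = list(per_period = summ, patients_in_both = overlap,
                        n_docs = nrow(corpus),
                        n_patients = dplyr::n_distinct(corpus$patient_id)),
         dual_period_doc_ids = dual,
         min_chars = min_chars),
    class = "labeled_corpus"
  )
}

#' @export
print.labeled_corpus <- function(x, ...) {
  s <- x$summary
  cat("Labelled proximal/distal corpus\n")
  cat(sprintf("  %d documents from %d patients (> %d characters)\n",
              s$n_docs, s$n_patients, x$min_chars))
  for (i in seq_len(nrow(s$per_period))) {
    cat(sprintf("  %-8s %6d documents, %5d patients\n",
                s$per_period$period[i], s$per_period$n_docs[i],
                s$per_period$n_patients[i]))
  }
  cat(sprintf("  patients contributing to both periods: %d\n",
              s$patients_in_both))
  if (length(x$dual_period_doc_ids)) {
    cat(sprintf("  %d documents qualified for both periods (kept proximal)\n",
                length(x$dual_period_doc_ids)))
  }
  invisible(x)
}
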