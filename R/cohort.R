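# Episode -> admission (spell) consolidation and suicide-attempt identification.

#' Is an ICD-10 code suicide-related?
#'
#' Codes counted as suicide-related are intentional self-harm (X60--X84),
#' events of undetermined intent (Y10--Y34), and the sequelae codes Y87.0 and
#' Y87.2. Four-character children of an in-range three-character stem (e.g.
#' `"X60.1"`) match; `"Y87.1"` (sequelae of accidents) does not.
#'
#' @param code Character vector of ICD-10 codes: a letter, two digits, and an
#'   optional `.d` fourth character, e.g. `"X61"` or `"Y87.0"`.
#' @return Logical vector, `TRUE` where the code is suicide-related.
#' @examples
#' is_suicide_code(c("X60", "X84", "Y10", "Y34", "Y87.0"))
#' is_suicide_code(c("X59", "Y35", "Y87.1", "F32.9"))
#' @export
is_suicide_code <- function(code) {
  ok <- grepl("^[A-Za-z][0-9]{2}(\\.[0-9])?$", code)
  if (any(!ok)) {
    stop("malformed ICD-10 code(s): ",
         paste(unique(code[!ok]), collapse = ", "), call. = FALSE)
  }
  code <- toupper(code)
  letter <- substr(code, 1, 1)
  num <- as.integer(substr(code, 2, 3))
  (letter == "X" & num >= 60 & num <= 84) |
    (letter == "Y" & num >= 10 & num <= 34) |
    code %in% c("Y87.0", "Y87.2")
}

#' Consolidate one patient's consultant episodes into admissions
#'
#' Episodes whose date ranges overlap or abut (the next episode starts on or
#' before the day the current one ends) merge into a single admission spell
#' spanning the earliest start to the latest end. An admission is
#' suicide-related if any constituent episode carries a suicide-related
#' ICD-10 code.
#'
#' @param episodes Data frame with columns `patient_id`, `epi_start`,
#'   `epi_end` (Dates) and `icd10_code`, all for a single patient.
#' @return A tibble of admissions with columns `patient_id`, `admission_id`,
#'   `admit_date`, `discharge_date`, `suicide_related`, `n_episodes`.
#' @export
consolidate_episodes <- function(episodes) {
  stopifnot(all(c("patient_id", "epi_start", "epi_end", "icd10_code") %in%
                  names(episodes)))
  if (nrow(episodes) == 0) {
    return(tibble::tibble(patient_id = character(), admission_id = character(),
                          admit_date = as.Date(character()),
                          discharge_date = as.Date(character()),
                          suicide_related = logical(), n_episodes = integer()))
  }
  if (length(unique(episodes$patient_id)) > 1L) {
    stop("consolidate_episodes() expects episodes from a single patient; ",
         "use build_admissions() for a multi-patient table", call. = FALSE)
  }
  if (any(episodes$epi_end < episodes$epi_start)) {
    stop("episode with epi_end before epi_start", call. = FALSE)
  }
  ep <- episodes[order(episodes$epi_start, episodes$epi_end), ]
  suicide <- is_suicide_code(ep$icd10_code)
  start_i <- as.integer(as.Date(ep$epi_start))
  end_i <- as.integer(as.Date(ep$epi_end))
  # a new spell begins where the episode starts strictly after every earlier
  # episode has ended
  run_max_end <- cummax(end_i)
  new_spell <- c(TRUE, start_i[-1] > run_max_end[-length(run_max_end)])
  grp <- cumsum(new_spell)
  tibble::tibble(
    patient_id = ep$patient_id[1],
    admission_id = paste0(ep$patient_id[1], "_A", unique(grp)),
    admit_date = as.Date(as.vector(tapply(start_i, grp, min)),
                         origin = "1970-01-01"),
    discharge_date = as.Date(as.vector(tapply(end_i, grp, max)),
                             origin = "1970-01-01"),
    suicide_related = as.vector(tapply(suicide, grp, any)),
    n_episodes = as.integer(as.vector(tapply(grp, grp, length)))
  )
}

#' Consolidate a multi-patient episode table into admissions
#'
#' @param episodes Data frame of episodes for any number of patients
#'   (columns as in [consolidate_episodes()]).
#' @return Tibble of admissions for all patients.
#' @export
build_admissions <- function(episodes) {
  episodes |>
    dplyr::group_by(.data$patient_id) |>
    dplyr::group_split() |>
    purrr::map(consolidate_episodes) |>
    purrr::list_rbind()
}

#' Date of a patient's first suicide-related admission
#'
#' Anchored to the admission date (hospital arrival), since pre-attempt
#' windows count backwards from arrival. Admissions outside an optional
#' closed study window are ignored.
#'
#' @param admissions Consolidated admissions for one patient
#'   (from [consolidate_episodes()]).
#' @param window_start,window_end Optional Dates bounding the study window
#'   (closed interval).
#' @return A Date, or `NA` (as Date) if the patient has no suicide-related
#'   admission in the window.
#' @export
first_attempt_date <- function(admissions, window_start = NULL,
                               window_end = NULL) {
  x <- admissions[admissions$suicide_related, , drop = FALSE]
  if (!is.null(window_start)) x <- x[x$admit_date >= window_start, , drop = FALSE]
  if (!is.null(window_end)) x <- x[x$admit_date <= window_end, , drop = FALSE]
  if (nrow(x) == 0) return(as.Date(NA))
  min(x$admit_date)
}

#' First suicide-related admission date for every patient
#'
#' @param admissions Consolidated admissions table (any number of patients).
#' @inheritParams first_attempt_date
#' @return Tibble with `patient_id` and `attempt_date`; patients with no
#'   suicide-related admission in the window are dropped.
#' @export
first_attempts <- function(admissions, window_start = NULL, window_end = NULL) {
  x <- admissions[admissions$suicide_related, , drop = FALSE]
  if (!is.null(window_start)) x <- x[x$admit_date >= window_start, , drop = FALSE]
  if (!is.null(window_end)) x <- x[x$admit_date <= window_end, , drop = FALSE]
  if (nrow(x) == 0) {
    return(tibble::tibble(patient_id = character(),
                          attempt_date = as.Date(character())))
  }
  x |>
    dplyr::group_by(.data$patient_id) |>
    dplyr::summarise(attempt_date = min(.data$admit_date), .groups = "drop")
}
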