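# Synthetic EHR cohort generator with known ground truth.
#
# Emulates the data shapes the real analyses consume -- a timestamped
# free-text document table and a HES-style episode table -- with planted
# structure every downstream stage can be tested against:
#   * per-patient document arrival is an inhomogeneous Poisson point process
#     at day resolution: baseline rate lambda0 times a patient-specific
#     gamma frailty (documentation counts in real EHRs are strongly
#     overdispersed), rising linearly to lambda0 * ramp_multiplier over the
#     final ramp_length_days before a planted attempt date;
#   * planted suicide admissions are emitted as 1-3 contiguous consultant
#     episodes (exercising spell consolidation) carrying suicide-range
#     ICD-10 codes; distractor admissions carry non-suicide codes;
#   * document text is drawn from a vocabulary whose per-word proximal/
#     distal probability ratio rho is known, including multi-token phrase
#     entries (planted enriched bigrams) and inflected surface forms
#     (exercising lemmatisation); document length straddles the
#     100-character filter.
#
# One global seed; each patient's draws come from a substream keyed by a
# stable hash of the patient id, so enlarging the cohort does not perturb
# existing patients.

#' Default synthetic vocabulary with planted enrichment
#'
#' A clinical-note-flavoured vocabulary of function words, pronouns, and
#' content words. The `rho` column is the planted proximal/distal
#' probability ratio (1 = no enrichment); multi-token entries (e.g.
#' `"want to"`) emit token sequences and so plant enriched bigrams; the
#' `category` column assigns content words to ground-truth categories used
#' by the category/agreement tests.
#'
#' @return Tibble with `word`, `pos`, `base_prob`, `rho`, `category`.
#' @export
default_vocabulary <- function() {
  w <- function(word, pos, base_prob, rho = 1, category = NA_character_) {
    tibble::tibble(word = word, pos = pos, base_prob = base_prob, rho = rho,
                   category = category)
  }
  # Enrichment mass is balanced by design: sum(base_prob * rho) stays close
  # to sum(base_prob), so after renormalisation a word with rho = 1 really
  # does appear at (almost) the same rate in both periods.
  dplyr::bind_rows(
    # function words (no planted enrichment unless noted)
    w("the", "DET", 0.090), w("be", "AUX", 0.070), w("to", "PART", 0.050),
    w("of", "ADP", 0.040), w("and", "CCONJ", 0.040), w("a", "DET", 0.035),
    w("in", "ADP", 0.030), w("have", "AUX", 0.025), w("that", "SCONJ", 0.025),
    w("on", "ADP", 0.020), w("do", "AUX", 0.015), w("with", "ADP", 0.015),
    w("not", "PART", 0.030, 1.3), w("no", "DET", 0.020, 1.4),
    w("there", "PRON", 0.015, 1.2),
    # pronoun-frequency shift: female pronouns proximal, male distal
    w("she", "PRON", 0.050, 1.6), w("her", "PRON", 0.030, 1.5),
    w("he", "PRON", 0.060, 0.35), w("his", "PRON", 0.035, 0.35),
    w("it", "PRON", 0.015, 1),
    # proximal-enriched content words
    w("overdose", "NOUN", 0.048, 4, "MED"),
    w("tablet", "NOUN", 0.045, 4, "MED"),
    w("medication", "NOUN", 0.025, 2, "MED"),
    w("risk", "NOUN", 0.025, 2, "RISK"),
    w("self-harm", "NOUN", 0.045, 4, "RISK"),
    w("state", "VERB", 0.015, 2, "REPORT"),
    w("report", "VERB", 0.015, 2, "REPORT"),
    # planted enriched phrases (bigrams after lemmatisation)
    w("want to", "VERB", 0.020, 4),
    w("state that", "VERB", 0.015, 4),
    w("report that", "VERB", 0.015, 4),
    w("take overdose", "VERB", 0.012, 5),
    w("no plan", "NOUN", 0.014, 0.2),
    # distal-enriched ("protective") content words
    w("plan", "NOUN", 0.060, 0.2, "CARE"),
    w("review", "NOUN", 0.060, 0.25, "CARE"),
    w("consultant", "NOUN", 0.025, 0.3, "CARE"),
    w("clinic", "NOUN", 0.030, 0.3, "CARE"),
    w("depot", "NOUN", 0.020, 0.25, "CARE"),
    w("meal", "NOUN", 0.045, 0.35, "MILIEU"),
    w("activity", "NOUN", 0.050, 0.3, "MILIEU"),
    w("settle", "VERB", 0.030, 0.3, "MILIEU"),
    w("garden", "NOUN", 0.015, 0.3, "MILIEU"),
    w("cook", "VERB", 0.015, 0.3, "MILIEU"),
    # distal-leaning modifiers (POS placeholders in word mode)
    w("stable", "ADJ", 0.120, 0.2), w("calm", "ADJ", 0.090, 0.25),
    w("well", "ADV", 0.090, 0.3), w("good", "ADJ", 0.080, 0.3),
    w("home", "NOUN", 0.018, 0.5), w("attend", "VERB", 0.018, 0.5),
    w("appointment", "NOUN", 0.015, 0.4),
    # unenriched content words (null words for false-positive rates)
    w("patient", "NOUN", 0.050), w("ward", "NOUN", 0.020),
    w("nurse", "NOUN", 0.020, 1, "PEOPLE"),
    w("staff", "NOUN", 0.015, 1, "PEOPLE"),
    w("family", "NOUN", 0.015, 1, "PEOPLE"),
    w("say", "VERB", 0.030), w("sleep", "VERB", 0.020),
    w("see", "VERB", 0.020), w("meet", "VERB", 0.012),
    w("feel", "VERB", 0.020, 1.3),
    w("week", "NOUN", 0.015), w("mood", "NOUN", 0.020),
    w("thought", "NOUN", 0.020)
  )
}

#' Vocabulary with planted phrase (bigram) enrichment only
#'
#' A variant of [default_vocabulary()] for bigram-recovery studies: all
#' word-level enrichment is switched off (`rho = 1`) and five multi-token
#' phrases are planted as the only enriched features, at low probability
#' mass. Keeping the phrases rare and their tokens shared with neutral
#' base words ensures the planted bigrams -- rather than chance adjacencies
#' of enriched tokens, whose probability ratio would otherwise be the
#' product of two marginal ratios -- dominate the class likelihood ratios.
#'
#' @param rho Phrase enrichment ratio (default 16).
#' @param base Unnormalised phrase base probability (default 0.002).
#' @return Tibble as for [default_vocabulary()]; the planted bigrams (after
#'   lemmatisation) are in `attr(, "planted_bigrams")`.
#' @export
phrase_planted_vocabulary <- function(rho = 16, base = 0.002) {
  v <- default_vocabulary()
  v$rho <- 1
  # dilute phrase-token marginals with neutral unigram mass, so no phrase
  # token is on its own a strong class marker
  v <- dplyr::bind_rows(v, tibble::tibble(
    word = c("want", "take", "harm", "self"),
    pos = c("VERB", "VERB", "NOUN", "NOUN"),
    base_prob = c(0.02, 0.02, 0.02, 0.015), rho = 1,
    category = NA_character_))
  phrases <- c("want to", "state that", "report that", "take overdose",
               "self-harm")
  i <- match(phrases, v$word)
  v$rho[i] <- rho
  v$base_prob[i] <- base
  attr(v, "planted_bigrams") <- c("want to", "state that", "report that",
                                  "take overdose", "self harm")
  v
}

#' Simulation configuration for the synthetic EHR generator
#'
#' @param n_patients Number of patients (> 0).
#' @param study_start,study_end Calendar dates bounding the study window.
#' @param baseline_doc_rate Baseline expected documents/day per patient
#'   (lambda0, before the frailty multiplier).
#' @param ramp_multiplier Terminal rate multiplier reached on the attempt
#'   date (lambda1/lambda0); 1 means no ramp.
#' @param ramp_length_days Days before the attempt over which the rate rises
#'   linearly (default 60).
#' @param attempt_probability Fraction of patients with a planted suicide
#'   admission, in `[0, 1]`. Default 1: the emulated cohort is, by
#'   construction, a cohort of attempters.
#' @param rate_dispersion Shape of the mean-1 gamma frailty multiplying each
#'   patient's document rate; smaller = more overdispersed. The default 0.1
#'   calibrates baseline 30-day documentation coverage to roughly a third of
#'   patients. `Inf` gives a homogeneous (frailty-free) process.
#' @param vocabulary Tibble with `word`, `pos`, `base_prob` and optionally
#'   `rho`, `category` columns (default [default_vocabulary()]). Base
#'   probabilities are renormalised to sum to 1.
#' @param enrichment Optional named numeric vector overriding the
#'   vocabulary's `rho` for the named words.
#' @param doc_length_distribution List with `mean_tokens` and `min_tokens`;
#'   token counts are `max(min_tokens, Poisson(mean_tokens))` draws. The
#'   default (20, 3) yields lengths straddling the 100-character filter.
#' @param attempt_min_offset_days Planted attempt dates fall at least this
#'   many days after `study_start` (default 430, leaving room for the full
#'   distal window plus ramp).
#' @param seed Integer random seed.
#' @return A validated `sim_config` object.
#' @export
simulation_config <- function(n_patients = 500,
                              study_start = as.Date("2011-01-01"),
                              study_end = as.Date("2013-03-31"),
                              baseline_doc_rate = 0.2,
                              ramp_multiplier = 3,
                              ramp_length_days = 60,
                              attempt_probability = 1,
                              rate_dispersion = 0.1,
                              vocabulary = default_vocabulary(),
                              enrichment = NULL,
                              doc_length_distribution = list(mean_tokens = 20,
                                                             min_tokens = 3),
                              attempt_min_offset_days = 430,
                              seed = 1L) {
  study_start <- as.Date(study_start)
  study_end <- as.Date(study_end)
  if (n_patients < 1) stop("n_patients must be positive", call. = FALSE)
  if (study_end <= study_start) stop("study_end must be after study_start",
                                     call. = FALSE)
  if (baseline_doc_rate < 0 || ramp_multiplier < 0 || ramp_length_days < 1) {
    stop("rates and ramp length must be nonnegative", call. = FALSE)
  }
  if (attempt_probability < 0 || attempt_probability > 1) {
    stop("attempt_probability must be in [0, 1]", call. = FALSE)
  }
  if (rate_dispersion <= 0) stop("rate_dispersion must be positive",
                                 call. = FALSE)
  voc <- tibble::as_tibble(vocabulary)
  stopifnot(all(c("word", "pos", "base_prob") %in% names(voc)),
            nrow(voc) > 0, all(voc$base_prob > 0))
  if (!"rho" %in% names(voc)) voc$rho <- 1
  if (!"category" %in% names(voc)) voc$category <- NA_character_
  if (!is.null(enrichment)) {
    i <- match(names(enrichment), voc$word)
    if (anyNA(i)) stop("enrichment names absent from vocabulary: ",
                       paste(names(enrichment)[is.na(i)], collapse = ", "),
                       call. = FALSE)
    voc$rho[i] <- unname(enrichment)
  }
  if (any(voc$rho < 0)) stop("enrichment ratios must be nonnegative",
                             call. = FALSE)
  voc$base_prob <- voc$base_prob / sum(voc$base_prob)
  voc$prob_distal <- voc$base_prob
  voc$prob_proximal <- voc$base_prob * voc$rho /
    sum(voc$base_prob * voc$rho)
  if (as.integer(study_end - study_start) <= attempt_min_offset_days) {
    stop("study window too short for attempt_min_offset_days", call. = FALSE)
  }
  structure(
    list(n_patients = as.integer(n_patients), study_start = study_start,
         study_end = study_end, baseline_doc_rate = baseline_doc_rate,
         ramp_multiplier = ramp_multiplier,
         ramp_length_days = as.integer(ramp_length_days),
         attempt_probability = attempt_probability,
         rate_dispersion = rate_dispersion, vocabulary = voc,
         doc_length_distribution = doc_length_distribution,
         attempt_min_offset_days = as.integer(attempt_min_offset_days),
         seed = as.integer(seed)),
    class = "sim_config"
  )
}

# stable 32-bit hash of (seed, patient id): patients keep their substream
# when the cohort grows
patient_seed <- function(seed, patient_id) {
  m <- 2147483647
  h <- as.double(seed %% m)
  for (code in utf8ToInt(patient_id)) {
    h <- (h * 31 + code) %% m
  }
  as.integer(h)
}

suicide_code_pool <- function() {
  stems <- c(sprintf("X%02d", 60:84), sprintf("Y%02d", 10:34))
  c(stems, paste0(sample(stems, 10), ".", sample(0:9, 10, TRUE)),
    "Y87.0", "Y87.2")
}

nonsuicide_code_pool <- function() {
  c("F20.0", "F32.9", "F10.2", "J18.9", "S52.5", "K35.8", "I10", "Z50.1")
}

# surface-form sampler derived from the fallback tagger's lexicon: lemma ->
# one of its inflected forms, uniformly (exercises lemmatisation)
surface_form_env <- function() {
  lex <- fallback_lexicon()
  forms <- split(lex$token, lex$lemma)
  forms <- forms[lengths(forms) > 1]
  list(lemma = names(forms), flat = unlist(forms, use.names = FALSE),
       offset = cumsum(c(0, lengths(forms)))[seq_along(forms)],
       len = lengths(forms))
}

apply_surface_forms <- function(tokens, sf) {
  m <- match(tokens, sf$lemma)
  has <- !is.na(m)
  if (any(has)) {
    pick <- sf$offset[m[has]] +
      1L + as.integer(floor(stats::runif(sum(has)) * sf$len[m[has]]))
    tokens[has] <- sf$flat[pick]
  }
  tokens
}

# vectorised text generation for n documents of one period, using the
# ambient RNG state
generate_texts <- function(n, period, config, sf = surface_form_env()) {
  if (n == 0) return(character(0))
  voc <- config$vocabulary
  prob <- if (period == "proximal") voc$prob_proximal else voc$prob_distal
  dl <- config$doc_length_distribution
  n_entries <- pmax(dl$min_tokens, stats::rpois(n, dl$mean_tokens))
  entries <- sample(voc$word, sum(n_entries), replace = TRUE, prob = prob)
  toks <- strsplit(entries, " ", fixed = TRUE)
  doc_of <- rep.int(rep.int(seq_len(n), n_entries), lengths(toks))
  flat <- apply_surface_forms(unlist(toks, use.names = FALSE), sf)
  texts <- vapply(split(flat, factor(doc_of, levels = seq_len(n))),
                  paste, character(1), collapse = " ")
  unname(paste0(texts, "."))
}

#' Generate one synthetic document text
#'
#' Draws words from the period-specific multinomial (base probabilities
#' times `rho`, renormalised, for the proximal period), expands phrase
#' entries, samples inflected surface forms, and joins with spaces. Uses the
#' ambient RNG state (call `set.seed()` for reproducibility).
#'
#' @param period `"proximal"` or `"distal"`.
#' @param config A `sim_config`.
#' @return A single character string.
#' @export
generate_document_text <- function(period = c("proximal", "distal"), config) {
  period <- match.arg(period)
  generate_texts(1L, period, config)
}

#' Generate a labelled batch of synthetic documents
#'
#' Convenience generator for corpus-level tests: `n_proximal` +
#' `n_distal` documents with known period labels, no episode structure.
#' Uses the ambient RNG state.
#'
#' @param n_proximal,n_distal Documents per period.
#' @param config A `sim_config`.
#' @return Tibble with `doc_id`, `period`, `text`.
#' @export
generate_period_documents <- function(n_proximal, n_distal, config) {
  sf <- surface_form_env()
  tibble::tibble(
    doc_id = sprintf("D%05d", seq_len(n_proximal + n_distal)),
    period = rep(c("proximal", "distal"), c(n_proximal, n_distal)),
    text = c(generate_texts(n_proximal, "proximal", config, sf),
             generate_texts(n_distal, "distal", config, sf))
  )
}

simulate_patient <- function(pid, config, text, sf) {
  set.seed(patient_seed(config$seed, pid))
  frailty <- if (is.finite(config$rate_dispersion)) {
    stats::rgamma(1, shape = config$rate_dispersion,
                  rate = config$rate_dispersion)
  } else 1
  has_attempt <- stats::runif(1) < config$attempt_probability
  days <- seq(config$study_start, config$study_end, by = "1 day")
  lam <- rep(config$baseline_doc_rate * frailty, length(days))

  attempt <- as.Date(NA)
  episodes <- NULL
  if (has_attempt) {
    lo <- as.integer(config$study_start) + config$attempt_min_offset_days
    hi <- as.integer(config$study_end)
    attempt <- as.Date(if (lo >= hi) hi else sample(lo:hi, 1),
                       origin = "1970-01-01")
    # linear rate ramp over the final ramp_length_days before the attempt
    rel <- as.integer(days - attempt)
    on_ramp <- rel >= -config$ramp_length_days & rel <= 0
    frac <- (rel[on_ramp] + config$ramp_length_days) / config$ramp_length_days
    lam[on_ramp] <- lam[on_ramp] * (1 + (config$ramp_multiplier - 1) * frac)
    # suicide admission split into 1-3 contiguous episodes
    los <- sample(0:10, 1)
    discharge <- min(attempt + los, config$study_end)
    los <- as.integer(discharge - attempt)
    n_epi <- if (los == 0) 1L else sample(seq_len(min(3L, los + 1L)), 1)
    bounds <- as.integer(attempt) +
      sort(c(0L, if (n_epi > 1) sample(seq_len(los), n_epi - 1), los))
    sui_pool <- suicide_code_pool()
    codes <- c(sample(sui_pool, 1),
               if (n_epi > 1) sample(c(sui_pool, nonsuicide_code_pool()),
                                     n_epi - 1, replace = TRUE))
    episodes <- tibble::tibble(
      patient_id = pid,
      epi_start = as.Date(bounds[-length(bounds)], origin = "1970-01-01"),
      epi_end = as.Date(bounds[-1], origin = "1970-01-01"),
      icd10_code = codes
    )
  }
  # distractor (non-suicide) admissions
  n_dis <- stats::rpois(1, 0.7)
  if (n_dis > 0) {
    starts <- as.Date(sample(as.integer(config$study_start):
                               as.integer(config$study_end), n_dis),
                      origin = "1970-01-01")
    ends <- pmin(starts + sample(0:7, n_dis, replace = TRUE),
                 config$study_end)
    episodes <- dplyr::bind_rows(episodes, tibble::tibble(
      patient_id = pid, epi_start = starts, epi_end = ends,
      icd10_code = sample(nonsuicide_code_pool(), n_dis, replace = TRUE)
    ))
  }

  ndocs <- stats::rpois(length(days), lam)
  doc_dates <- rep(days, ndocs)
  documents <- tibble::tibble(
    doc_id = if (length(doc_dates)) sprintf("%s_D%04d", pid,
                                            seq_along(doc_dates)) else character(0),
    patient_id = pid, date = doc_dates
  )
  proximal <- !is.na(attempt) & doc_dates >= attempt - 31 &
    doc_dates <= attempt - 1
  documents$true_period <- ifelse(proximal, "proximal", "distal")
  documents$true_period <- as.character(documents$true_period)
  if (text && nrow(documents)) {
    documents$text <- NA_character_
    documents$text[proximal] <- generate_texts(sum(proximal), "proximal",
                                               config, sf)
    documents$text[!proximal] <- generate_texts(sum(!proximal), "distal",
                                                config, sf)
  }
  list(documents = documents, episodes = episodes,
       patient = tibble::tibble(patient_id = pid, frailty = frailty,
                                attempt_date = attempt))
}

#' Generate a synthetic EHR cohort
#'
#' Produces an episode table, a document table and a ground-truth manifest
#' under a `sim_config`. Identical config and seed give identical output;
#' each patient is simulated from a substream keyed by a stable hash of the
#' patient id.
#'
#' @param config A `sim_config` from [simulation_config()].
#' @param text Generate document text? (`FALSE` skips text generation for
#'   rate-only analyses.)
#' @return List with `documents` (tibble: `doc_id`, `patient_id`, `date`,
#'   `text` if requested), `episodes` (tibble: `patient_id`, `epi_start`,
#'   `epi_end`, `icd10_code`), and `manifest` (ground truth: `patients`
#'   with planted attempt dates and frailties, `enrichment` with true rho
#'   and category per word, `documents` with true period labels, and the
#'   generator declaration).
#' @export
generate_cohort <- function(config, text = TRUE) {
  stopifnot(inherits(config, "sim_config"))
  pids <- sprintf("P%05d", seq_len(config$n_patients))
  sf <- surface_form_env()
  sims <- lapply(pids, simulate_patient, config = config, text = text,
                 sf = sf)
  documents <- purrr::list_rbind(lapply(sims, `[[`, "documents"))
  episodes <- purrr::list_rbind(
    lapply(sims, `[[`, "episodes")[!vapply(sims, function(s)
      is.null(s$episodes), logical(1))]
  )
  if (!"patient_id" %in% names(episodes)) {
    episodes <- tibble::tibble(patient_id = character(),
                               epi_start = as.Date(character()),
                               epi_end = as.Date(character()),
                               icd10_code = character())
  }
  patients <- purrr::list_rbind(lapply(sims, `[[`, "patient"))
  manifest <- list(
    patients = patients,
    enrichment = config$vocabulary[, c("word", "pos", "base_prob", "rho",
                                       "category", "prob_proximal",
                                       "prob_distal")],
    documents = documents[, c("doc_id", "patient_id", "date", "true_period")],
    generator = list(
      point_process = "piecewise-constant-rate Poisson, day resolution, linear ramp",
      seed = config$seed, n_patients = config$n_patients,
      baseline_doc_rate = config$baseline_doc_rate,
      ramp_multiplier = config$ramp_multiplier,
      ramp_length_days = config$ramp_length_days,
      rate_dispersion = config$rate_dispersion,
      attempt_probability = config$attempt_probability
    )
  )
  cols <- c("doc_id", "patient_id", "date", if (text) "text")
  list(documents = documents[, cols], episodes = episodes,
       manifest = manifest)
}
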