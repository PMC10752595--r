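test_that("config validation rejects impossible settings", {
  expect_error(simulation_config(n_patients = 0), "positive")
  expect_error(simulation_config(study_start = "2012-01-01",
                                 study_end = "2011-01-01"), "after")
  expect_error(simulation_config(attempt_probability = 1.2), "\\[0, 1\\]")
  expect_error(simulation_config(enrichment = c(notaword = 2)), "absent")
  expect_error(simulation_config(study_end = as.Date("2011-06-01")),
               "too short")
})

test_that("vocabulary probabilities renormalise to 1 in both periods", {
  cfg <- small_config()
  expect_equal(sum(cfg$vocabulary$prob_distal), 1)
  expect_equal(sum(cfg$vocabulary$prob_proximal), 1)
  # rho = 1 everywhere makes the periods identical
  flat <- simulation_config(
    vocabulary = tibble::tibble(word = c("a", "b"), pos = "NOUN",
                                base_prob = c(0.3, 0.7)))
  expect_equal(flat$vocabulary$prob_proximal, flat$vocabulary$prob_distal)
})

test_that("identical seed and config give identical output", {
  cfg <- small_config(seed = 42, n_patients = 10)
  s1 <- generate_cohort(cfg)
  s2 <- generate_cohort(cfg)
  expect_identical(s1$documents, s2$documents)
  expect_identical(s1$episodes, s2$episodes)
  expect_identical(s1$manifest$patients, s2$manifest$patients)
})

test_that("existing patients are unperturbed when the cohort grows", {
  small <- generate_cohort(small_config(seed = 5, n_patients = 8))
  big <- generate_cohort(small_config(seed = 5, n_patients = 16))
  ids <- unique(small$documents$patient_id)
  expect_identical(small$documents,
                   big$documents[big$documents$patient_id %in% ids, ])
})

test_that("attempt_probability = 0 yields no suicide-coded episodes", {
  sim <- generate_cohort(small_config(seed = 2, attempt_probability = 0),
                         text = FALSE)
  if (nrow(sim$episodes) > 0) {
    expect_false(any(is_suicide_code(sim$episodes$icd10_code)))
  }
  expect_true(all(is.na(sim$manifest$patients$attempt_date)))
})

test_that("every planted attempt has a matching suicide-coded episode on that date", {
  sim <- generate_cohort(small_config(seed = 12), text = FALSE)
  att <- sim$manifest$patients
  att <- att[!is.na(att$attempt_date), ]
  expect_gt(nrow(att), 0)
  for (i in seq_len(nrow(att))) {
    eps <- sim$episodes[sim$episodes$patient_id == att$patient_id[i], ]
    expect_true(any(eps$epi_start == att$attempt_date[i] &
                      is_suicide_code(eps$icd10_code)))
  }
  # and consolidation recovers the attempt date as a suicide admission
  adm <- build_admissions(sim$episodes)
  fa <- first_attempts(adm)
  merged <- dplyr::inner_join(fa, att, by = "patient_id")
  expect_true(all(merged$attempt_date.x <= merged$attempt_date.y))
})

test_that("documents stay inside the study window and dates are day-resolution", {
  sim <- generate_cohort(small_config(seed = 3), text = FALSE)
  expect_true(all(sim$documents$date >= as.Date("2011-01-01")))
  expect_true(all(sim$documents$date <= as.Date("2012-06-30")))
  expect_s3_class(sim$documents$date, "Date")
})

test_that("ramp_multiplier = 1 gives a flat document rate in attempt-relative time", {
  # homogeneous process (no frailty) with no ramp: mean docs/day in the last
  # 30 days matches days [-120, -91] within sampling error
  cfg <- small_config(seed = 8, n_patients = 150, ramp_multiplier = 1,
                      rate_dispersion = Inf)
  sim <- generate_cohort(cfg, text = FALSE)
  att <- sim$manifest$patients
  docs <- dplyr::inner_join(sim$documents, att, by = "patient_id")
  rel <- as.integer(docs$date - docs$attempt_date)
  late <- sum(rel >= -30 & rel <= -1)
  early <- sum(rel >= -120 & rel <= -91)
  # both windows have expectation 0.2 * 30 * 150 = 900; allow 5 sigma
  expect_lt(abs(late - early), 5 * sqrt(late + early))
})

test_that("the planted ramp raises the document rate before the attempt", {
  cfg <- small_config(seed = 9, n_patients = 100, ramp_multiplier = 3)
  sim <- generate_cohort(cfg, text = FALSE)
  att <- sim$manifest$patients
  docs <- dplyr::inner_join(sim$documents, att, by = "patient_id")
  rel <- as.integer(docs$date - docs$attempt_date)
  rate_late <- sum(rel >= -30 & rel <= -1) / 30
  rate_early <- sum(rel >= -365 & rel <= -300) / 66
  expect_gt(rate_late, rate_early)
})

test_that("proximal word shares match the closed-form renormalisation", {
  # fixture vocabulary: w1 p=0.05 rho=4, w2 p=0.45, w3 p=0.50
  # proximal share of w1 = 0.05*4 / (0.05*4 + 0.45 + 0.50) = 0.2/1.15
  cfg <- simulation_config(
    vocabulary = tibble::tibble(word = c("w1", "w2", "w3"), pos = "NOUN",
                                base_prob = c(0.05, 0.45, 0.50),
                                rho = c(4, 1, 1)),
    doc_length_distribution = list(mean_tokens = 20, min_tokens = 3))
  expect_equal(cfg$vocabulary$prob_proximal[1], 0.2 / 1.15)
  set.seed(77)
  docs <- generate_period_documents(400, 0, cfg)
  toks <- unlist(lapply(docs$text, function(t) tokenize(t)))
  toks <- toks[toks != "."]
  expect_lt(abs(mean(toks == "w1") - 0.2 / 1.15), 0.02)
  # distal shares are the base probabilities
  set.seed(78)
  docs_d <- generate_period_documents(0, 400, cfg)
  toks_d <- unlist(lapply(docs_d$text, function(t) tokenize(t)))
  toks_d <- toks_d[toks_d != "."]
  expect_lt(abs(mean(toks_d == "w1") - 0.05), 0.01)
})

test_that("a degenerate length distribution puts every document under the filter", {
  cfg <- simulation_config(
    vocabulary = tibble::tibble(word = c("ab", "cde"), pos = "NOUN",
                                base_prob = c(0.5, 0.5)),
    doc_length_distribution = list(mean_tokens = 0, min_tokens = 3))
  set.seed(1)
  docs <- generate_period_documents(20, 20, cfg)
  expect_true(all(nchar(docs$text) <= 100))
  # default lengths straddle the filter
  set.seed(2)
  docs2 <- generate_period_documents(100, 100, small_config())
  expect_gt(sum(nchar(docs2$text) > 100), 0)
  expect_gt(sum(nchar(docs2$text) <= 100), 0)
})

test_that("generated surface forms all lemmatise back into the vocabulary", {
  set.seed(15)
  cfg <- small_config()
  docs <- generate_period_documents(30, 30, cfg)
  lemmas <- unique(unlist(lapply(docs$text, prepare_for_ngram_analysis)))
  lemmas <- setdiff(lemmas, ".")
  voc_tokens <- unique(unlist(strsplit(
    sub("self-harm", "self harm", cfg$vocabulary$word), " ", fixed = TRUE)))
  expect_true(all(lemmas %in% voc_tokens))
})
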