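worked_tokens <- c("the", "patient", "is", "not", "suicidal", ".")

test_that("n-gram extraction reproduces the worked uni/bi/tri-gram lists", {
  expect_equal(extract_ngrams(worked_tokens, 1), worked_tokens)
  expect_equal(extract_ngrams(worked_tokens, 2),
               c("the patient", "patient is", "is not", "not suicidal",
                 "suicidal ."))
  expect_equal(extract_ngrams(worked_tokens, 3),
               c("the patient is", "patient is not", "is not suicidal",
                 "not suicidal ."))
  expect_equal(extract_ngrams("alone", 2), character(0))
  expect_error(extract_ngrams(worked_tokens, 0), "at least 1")
})

test_that("n-gram counts conserve: tokens - n + 1 per document", {
  set.seed(14)
  for (i in 1:10) {
    toks <- sample(letters[1:5], sample(1:12, 1), replace = TRUE)
    for (n in 1:3) {
      expect_length(extract_ngrams(toks, n), max(0, length(toks) - n + 1))
    }
  }
})

toy_streams <- function() {
  make_streams(
    list(c("overdose", "risk", "overdose"), c("risk", "ward"),
         c("plan", "ward"), c("ward", "plan", "plan")),
    c("proximal", "proximal", "distal", "distal")
  )
}

test_that("fitted likelihoods equal hand-computed smoothed ratios on the toy corpus", {
  m <- fit_nb(toy_streams(), n = 1, alpha = 1)
  # vocabulary: overdose, plan, risk, ward (sorted); proximal grams:
  # overdose x2, risk x2, ward x1 (total 5); distal: plan x3, ward x2 (5)
  expect_equal(m$features$feature, c("overdose", "plan", "risk", "ward"))
  expect_equal(m$features$loglik_proximal,
               log((c(2, 0, 2, 1) + 1) / (5 + 4)))
  expect_equal(m$features$loglik_distal,
               log((c(0, 3, 0, 2) + 1) / (5 + 4)))
  expect_equal(unname(m$log_prior), log(c(0.5, 0.5)))
  # count conservation
  expect_equal(sum(m$features$count_proximal), 5L)
  expect_equal(sum(m$features$count_distal), 5L)
  # likelihoods sum to 1 per class
  expect_equal(sum(exp(m$features$loglik_proximal)), 1)
  expect_equal(sum(exp(m$features$loglik_distal)), 1)
})

test_that("a class-exclusive feature leans to its class for any alpha > 0", {
  for (alpha in c(0.1, 1, 5)) {
    m <- fit_nb(toy_streams(), 1, alpha)
    ov <- m$features[m$features$feature == "overdose", ]
    expect_gt(ov$loglik_proximal, ov$loglik_distal)
  }
  expect_error(fit_nb(make_streams(list("x"), "proximal"), 1), "both classes")
})

test_that("classification matches brute-force posterior enumeration on a 10-doc fixture", {
  set.seed(17)
  streams <- make_streams(
    lapply(1:10, function(i) sample(c("overdose", "plan", "ward", "risk"),
                                    sample(2:6, 1), replace = TRUE)),
    rep(c("proximal", "distal"), 5)
  )
  for (n in 1:2) {
    m <- fit_nb(streams, n, alpha = 1)
    for (i in 1:10) {
      got <- classify_nb(m, streams$tokens[[i]])
      oracle <- brute_force_nb_scores(streams, n, 1, streams$tokens[[i]])
      expect_equal(got$log_odds, unname(oracle["proximal"] - oracle["distal"]),
                   tolerance = 1e-10)
      expect_equal(got$label,
                   if (oracle["proximal"] > oracle["distal"]) "proximal" else "distal")
    }
  }
})

test_that("empty streams and ties resolve to distal; OOV n-grams are ignored", {
  m <- fit_nb(toy_streams(), 1, 1)
  empty <- classify_nb(m, character(0))
  expect_equal(empty$label, "distal")
  expect_equal(empty$log_odds, 0)
  oov <- classify_nb(m, c("zzz", "qqq"))
  expect_equal(oov$log_odds, 0)
  prox_only <- classify_nb(m, c("overdose", "risk"))
  expect_equal(prox_only$label, "proximal")
})

test_that("label swap negates log-odds and preserves the informativeness ranking", {
  streams <- toy_streams()
  swapped <- streams
  swapped$period <- ifelse(streams$period == "proximal", "distal", "proximal")
  m1 <- fit_nb(streams, 1, 1)
  m2 <- fit_nb(swapped, 1, 1)
  for (i in seq_len(nrow(streams))) {
    expect_equal(classify_nb(m1, streams$tokens[[i]])$log_odds,
                 -classify_nb(m2, streams$tokens[[i]])$log_odds,
                 tolerance = 1e-12)
  }
  expect_equal(top_informative(m1, 4)$feature, top_informative(m2, 4)$feature)
})

test_that("as alpha -> 0 likelihoods approach maximum-likelihood ratios on a zero-free vocabulary", {
  streams <- make_streams(
    list(c("a", "b", "a"), c("a", "b"), c("b", "a"), c("b", "b", "a")),
    c("proximal", "proximal", "distal", "distal")
  )
  m <- fit_nb(streams, 1, alpha = 1e-8)
  # proximal: a x3, b x2 of 5; distal: a x2, b x3 of 5
  expect_equal(exp(m$features$loglik_proximal), c(3, 2) / 5, tolerance = 1e-6)
  expect_equal(exp(m$features$loglik_distal), c(2, 3) / 5, tolerance = 1e-6)
})

test_that("informativeness ranking: zero-difference features rank last, k caps, ties break by frequency", {
  streams <- make_streams(
    list(c("x", "x", "p"), c("x", "p"), c("x", "q"), c("x", "x", "q")),
    c("proximal", "proximal", "distal", "distal")
  )
  m <- fit_nb(streams, 1, 1)
  top <- top_informative(m, 3)
  # x occurs equally (3/3): informativeness ~0, ranked last
  expect_equal(top$feature[3], "x")
  expect_equal(top$informativeness[3], 0, tolerance = 1e-12)
  expect_message(all_feats <- top_informative(m, 99), "vocabulary size")
  expect_equal(nrow(all_feats), 3)
})

test_that("feature report fills in OR, mean frequency and t*", {
  streams <- toy_streams()
  m <- fit_nb(streams, 1, 1)
  top <- top_informative(m, 4, streams)
  ov <- top[top$feature == "overdose", ]
  # mean frequency: 2 occurrences over 4 documents
  expect_equal(ov$mean_freq_per_doc, 0.5)
  expect_equal(ov$enriched_period, "proximal")
  expect_true(all(is.na(top$t_star) | top$t_star >= 1))
})

test_that("distinctiveness threshold equals a brute-force scan and handles degenerate cases", {
  # feature in every proximal doc and no distal doc -> t* = 1
  n_half <- 12
  streams <- make_streams(
    c(lapply(1:n_half, function(i) c("flag", "pad")),
      lapply(1:n_half, function(i) c("pad", "pad"))),
    rep(c("proximal", "distal"), each = n_half)
  )
  expect_equal(distinctiveness_threshold("flag", streams), 1L)
  # identical count distributions -> absent
  sym <- make_streams(
    c(lapply(1:n_half, function(i) c("pad", "pad")),
      lapply(1:n_half, function(i) c("pad", "pad"))),
    rep(c("proximal", "distal"), each = n_half)
  )
  expect_true(is.na(distinctiveness_threshold("pad", sym)))
  expect_error(distinctiveness_threshold("ghost", sym), "does not occur")

  # function word separating classes only at high counts: oracle scan
  set.seed(23)
  streams2 <- make_streams(
    c(lapply(1:20, function(i) rep("to", 5 + rpois(1, 4))),
      lapply(1:20, function(i) rep("to", 1 + rpois(1, 1)))),
    rep(c("proximal", "distal"), each = 20)
  )
  t_star <- distinctiveness_threshold("to", streams2)
  counts <- vapply(streams2$tokens, function(t) sum(t == "to"), integer(1))
  oracle <- NA_integer_
  for (t in 1:max(counts)) {
    a <- sum(counts >= t & streams2$period == "proximal")
    cc <- sum(counts >= t & streams2$period == "distal")
    or <- as.numeric(odds_ratio(a, 20 - a, cc, 20 - cc))
    p <- fisher_exact_p(a, 20 - a, cc, 20 - cc)
    if (p <= 0.05 && (or < 0.66 || or > 1.50)) { oracle <- t; break }
  }
  expect_equal(t_star, oracle)
  expect_gt(t_star, 1)
})
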