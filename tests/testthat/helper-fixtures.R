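# Shared fixture builders. Everything is generated in code; no files.

# small, fast simulation config for smoke-level tests
small_config <- function(seed = 1, n_patients = 30, ...) {
  simulation_config(
    n_patients = n_patients,
    study_start = as.Date("2011-01-01"),
    study_end = as.Date("2012-06-30"),
    attempt_min_offset_days = 430,
    seed = seed,
    ...
  )
}

# wrap ready-made token vectors as a stream tibble
make_streams <- function(tokens, periods, doc_ids = NULL) {
  tibble::tibble(
    doc_id = doc_ids %||% sprintf("d%02d", seq_along(tokens)),
    period = periods,
    tokens = tokens
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# independent Fisher oracle: enumerate all tables with the observed margins
# via binomial coefficients (no dhyper)
enum_fisher_p <- function(a, b, c, d) {
  m <- a + b
  n <- c + d
  k <- a + c
  tot <- choose(m + n, k)
  xs <- max(0, k - n):min(k, m)
  probs <- vapply(xs, function(x) choose(m, x) * choose(n, k - x) / tot,
                  numeric(1))
  p_obs <- choose(m, a) * choose(n, k - a) / tot
  min(1, sum(probs[probs <= p_obs * (1 + 1e-07)]))
}

# independent NB posterior: explicit product over the vocabulary
brute_force_nb_scores <- function(streams, n, alpha, tokens) {
  grams_by_doc <- lapply(streams$tokens, extract_ngrams, n = n)
  vocab <- sort(unique(unlist(grams_by_doc)))
  counts <- function(cls) {
    g <- unlist(grams_by_doc[streams$period == cls])
    vapply(vocab, function(v) sum(g == v), numeric(1))
  }
  cp <- counts("proximal")
  cd <- counts("distal")
  lik <- function(cnt) (cnt + alpha) / (sum(cnt) + alpha * length(vocab))
  doc_grams <- extract_ngrams(tokens, n)
  doc_grams <- doc_grams[doc_grams %in% vocab]
  score <- function(cls_counts, prior) {
    log(prior) + sum(log(lik(cls_counts)[match(doc_grams, vocab)]))
  }
  c(proximal = score(cp, mean(streams$period == "proximal")),
    distal = score(cd, mean(streams$period == "distal")))
}
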