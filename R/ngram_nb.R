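# Uni/bi/tri-gram multinomial Naive Bayes feature analysis.
#
# Each gram order (n = 1, 2, 3) is fitted as an independent two-class
# multinomial model on n-gram-mode token streams. "Informativeness" of a
# feature is the absolute difference of its per-class log-likelihoods -- the
# standard quantity inspected when reading an NB model's most discriminative
# features. The multinomial (count) variant is used rather than Bernoulli
# because downstream reporting analyses mean per-document feature
# frequencies.

#' Extract n-grams from a token stream
#'
#' All contiguous length-n windows, in order, duplicates included; tokens of
#' an n-gram are joined by single spaces. A document with fewer than n
#' tokens yields no n-grams.
#'
#' @param tokens Character vector of tokens.
#' @param n Gram order (>= 1).
#' @return Character vector of n-grams.
#' @examples
#' extract_ngrams(tokenize("The patient is not suicidal."), 2)
#' @export
extract_ngrams <- function(tokens, n) {
  if (n < 1) stop("n must be at least 1", call. = FALSE)
  len <- length(tokens)
  if (len < n) return(character(0))
  if (n == 1) return(tokens)
  parts <- lapply(seq_len(n), function(k) tokens[k:(len - n + k)])
  do.call(paste, parts)
}

#' Fit a two-class multinomial Naive Bayes model on n-gram features
#'
#' Class priors are the proximal/distal document shares; feature likelihoods
#' use additive (Lidstone) smoothing:
#' `(class count + alpha) / (class total + alpha * |V|)`.
#'
#' @param streams n-gram-mode token streams: tibble with `doc_id`, `period`
#'   and `tokens` list-column.
#' @param n Gram order.
#' @param alpha Additive smoothing parameter (default 1, Laplace).
#' @return An `nb_model`: list with `n`, `alpha`, `log_prior` (named,
#'   proximal/distal), `features` tibble (`feature`, per-class counts and
#'   log-likelihoods), `class_totals`, `vocab_size`.
#' @export
fit_nb <- function(streams, n, alpha = 1) {
  if (alpha < 0) stop("alpha must be nonnegative", call. = FALSE)
  classes <- c("proximal", "distal")
  if (!all(classes %in% streams$period)) {
    stop("both classes must be represented to fit the model", call. = FALSE)
  }
  grams <- lapply(streams$tokens, extract_ngrams, n = n)
  flat <- unlist(grams, use.names = FALSE)
  cls <- rep(streams$period, lengths(grams))
  vocab <- sort(unique(flat))
  cnt_p <- table(factor(flat[cls == "proximal"], levels = vocab))
  cnt_d <- table(factor(flat[cls == "distal"], levels = vocab))
  tot_p <- sum(cnt_p)
  tot_d <- sum(cnt_d)
  v <- length(vocab)
  features <- tibble::tibble(
    feature = vocab,
    count_proximal = as.integer(cnt_p),
    count_distal = as.integer(cnt_d),
    loglik_proximal = log(as.integer(cnt_p) + alpha) - log(tot_p + alpha * v),
    loglik_distal = log(as.integer(cnt_d) + alpha) - log(tot_d + alpha * v)
  )
  structure(
    list(n = as.integer(n), alpha = alpha,
         log_prior = c(proximal = log(mean(streams$period == "proximal")),
                       distal = log(mean(streams$period == "distal"))),
         features = features,
         class_totals = c(proximal = tot_p, distal = tot_d),
         vocab_size = v),
    class = "nb_model"
  )
}

#' @export
print.nb_model <- function(x, ...) {
  cat(sprintf("Multinomial Naive Bayes, %d-grams: %d features, alpha = %g\n",
              x$n, x$vocab_size, x$alpha))
  cat(sprintf("  class totals: proximal %d, distal %d n-grams\n",
              x$class_totals["proximal"], x$class_totals["distal"]))
  invisible(x)
}

#' Classify one token stream
#'
#' Scores each class as log-prior plus the count-weighted sum of feature
#' log-likelihoods; out-of-vocabulary n-grams are ignored. Ties (including
#' an empty stream under equal priors) resolve to `"distal"`, the reference
#' class.
#'
#' @param model A fitted `nb_model`.
#' @param tokens Character vector of tokens (n-gram-mode preparation).
#' @return List with `label` and `log_odds` (proximal minus distal score).
#' @export
classify_nb <- function(model, tokens) {
  grams <- extract_ngrams(tokens, model$n)
  i <- match(grams, model$features$feature)
  i <- i[!is.na(i)]
  cnt <- tabulate(i, nbins = model$vocab_size)
  used <- which(cnt > 0)
  score_p <- model$log_prior["proximal"] +
    sum(cnt[used] * model$features$loglik_proximal[used])
  score_d <- model$log_prior["distal"] +
    sum(cnt[used] * model$features$loglik_distal[used])
  log_odds <- unname(score_p - score_d)
  list(label = if (log_odds > 0) "proximal" else "distal",
       log_odds = log_odds)
}

#' Classify every document in a corpus
#'
#' @param model A fitted `nb_model`.
#' @param streams n-gram-mode token streams.
#' @return Tibble with `doc_id`, `period` (true label), `label` (predicted)
#'   and `log_odds`.
#' @export
classify_corpus <- function(model, streams) {
  res <- lapply(streams$tokens, classify_nb, model = model)
  tibble::tibble(doc_id = streams$doc_id, period = streams$period,
                 label = vapply(res, `[[`, character(1), "label"),
                 log_odds = vapply(res, `[[`, numeric(1), "log_odds"))
}

#' Most informative Naive Bayes features
#'
#' Ranks features by the absolute difference of per-class log-likelihoods,
#' descending; ties break by total corpus count descending, then
#' lexicographically. When `streams` are supplied, each reported feature
#' also carries its document-presence odds ratio, its mean frequency per
#' document over the whole corpus, its distinctiveness threshold `t_star`
#' (see [distinctiveness_threshold()]) and the period it leans towards.
#'
#' @param model A fitted `nb_model`.
#' @param k Number of features to return (default 30); `k` larger than the
#'   vocabulary returns everything, with a message.
#' @param streams Optional n-gram-mode token streams used to fill in the
#'   odds ratio, mean frequency and `t_star` columns.
#' @return Tibble (a feature report), ranked.
#' @export
top_informative <- function(model, k = 30, streams = NULL) {
  f <- model$features
  f$informativeness <- abs(f$loglik_proximal - f$loglik_distal)
  f$total_count <- f$count_proximal + f$count_distal
  f$enriched_period <- ifelse(f$loglik_proximal >= f$loglik_distal,
                              "proximal", "distal")
  ord <- order(-f$informativeness, -f$total_count, f$feature)
  f <- f[ord, , drop = FALSE]
  if (k > nrow(f)) {
    message("k = ", k, " exceeds vocabulary size ", nrow(f),
            "; returning all features")
    k <- nrow(f)
  }
  top <- f[seq_len(k), c("feature", "informativeness", "count_proximal",
                         "count_distal", "total_count", "enriched_period")]
  if (!is.null(streams)) {
    counts <- feature_doc_counts(top$feature, streams, model$n)
    n_prox <- sum(streams$period == "proximal")
    n_dist <- sum(streams$period == "distal")
    a <- colSums(counts[streams$period == "proximal", , drop = FALSE] >= 1)
    cc <- colSums(counts[streams$period == "distal", , drop = FALSE] >= 1)
    top$odds_ratio <- unname(as.numeric(odds_ratio(a, n_prox - a, cc,
                                                   n_dist - cc)))
    top$mean_freq_per_doc <- unname(colMeans(counts))
    top$t_star <- vapply(seq_along(top$feature), function(j) {
      threshold_scan(counts[, j], streams$period)
    }, integer(1))
  }
  top
}

# per-document occurrence counts of each feature: docs x features matrix
feature_doc_counts <- function(features, streams, n) {
  grams <- lapply(streams$tokens, extract_ngrams, n = n)
  flat <- unlist(grams, use.names = FALSE)
  doc <- rep(seq_along(grams), lengths(grams))
  j <- match(flat, features)
  keep <- !is.na(j)
  if (!any(keep)) {
    return(matrix(0L, nrow = length(grams), ncol = length(features),
                  dimnames = list(NULL, features)))
  }
  tab <- table(factor(doc[keep], levels = seq_along(grams)),
               factor(j[keep], levels = seq_along(features)))
  matrix(as.integer(tab), nrow = length(grams),
         dimnames = list(NULL, features))
}

threshold_scan <- function(doc_counts, period, p_max = 0.05, or_low = 0.66,
                           or_high = 1.50) {
  n_prox <- sum(period == "proximal")
  n_dist <- sum(period == "distal")
  max_t <- max(doc_counts)
  if (max_t < 1) return(NA_integer_)
  for (t in seq_len(max_t)) {
    a <- sum(doc_counts[period == "proximal"] >= t)
    cc <- sum(doc_counts[period == "distal"] >= t)
    or <- as.numeric(odds_ratio(a, n_prox - a, cc, n_dist - cc))
    p <- fisher_exact_p(a, n_prox - a, cc, n_dist - cc)
    if (p <= p_max && (or < or_low || or > or_high)) return(t)
  }
  NA_integer_
}

#' Distinctiveness threshold of a feature
#'
#' The smallest per-document count t such that the document-level indicator
#' "contains the feature at least t times" passes the word-retention
#' criteria (p <= `p_max` and OR outside (`or_low`, `or_high`)). Frequent
#' function words may separate the classes only at high counts; a feature
#' whose count distribution is identical in both classes has no threshold
#' (`NA`).
#'
#' @param feature A single n-gram string (tokens joined by spaces; the gram
#'   order is inferred from it).
#' @param streams n-gram-mode token streams.
#' @param p_max,or_low,or_high Retention thresholds as in [word_stats()].
#' @return Integer threshold `t_star`, or `NA` if no qualifying threshold
#'   exists up to the maximum per-document count.
#' @export
distinctiveness_threshold <- function(feature, streams, p_max = 0.05,
                                      or_low = 0.66, or_high = 1.50) {
  n <- length(strsplit(feature, " ", fixed = TRUE)[[1]])
  counts <- feature_doc_counts(feature, streams, n)
  if (sum(counts) == 0) stop("feature does not occur in the corpus",
                             call. = FALSE)
  threshold_scan(counts[, 1], streams$period, p_max, or_low, or_high)
}
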