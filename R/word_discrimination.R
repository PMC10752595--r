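# Document-level word discrimination between proximal and distal periods.
#
# Each word gets a 2x2 incidence table: (a) proximal documents containing it
# at least once, (b) proximal documents without it, (c, d) likewise for
# distal. The odds ratio (a*d)/(b*c) measures discriminability, with the
# Haldane-Anscombe +0.5 correction when any cell is zero; significance is a
# two-sided Fisher exact test. Words are retained when p <= p_max and the OR
# falls outside (or_low, or_high).

#' Document-level incidence tables for every word
#'
#' Presence is binary per document (one occurrence is enough). POS
#' placeholder labels (the uppercase Universal tags inserted by word-mode
#' preparation) are excluded from the word inventory.
#'
#' @param streams Token streams in word-analysis mode: tibble with `doc_id`,
#'   `period` (`"proximal"`/`"distal"`) and `tokens` list-column, as from
#'   [prepare_corpus()].
#' @return Tibble with `word`, `a`, `b`, `c`, `d`.
#' @export
doc_term_incidence <- function(streams) {
  n_prox <- sum(streams$period == "proximal")
  n_dist <- sum(streams$period == "distal")
  if (n_prox == 0 || n_dist == 0) {
    stop("both periods must be represented in the corpus", call. = FALSE)
  }
  present <- tibble::tibble(
    word = unlist(lapply(streams$tokens, unique), use.names = FALSE),
    period = rep(streams$period, vapply(streams$tokens,
                                        function(t) length(unique(t)),
                                        integer(1)))
  )
  present <- present[!present$word %in% upos_tags(), , drop = FALSE]
  counts <- present |>
    dplyr::count(.data$word, .data$period) |>
    tidyr::pivot_wider(names_from = "period", values_from = "n",
                       values_fill = 0L)
  if (!"proximal" %in% names(counts)) counts$proximal <- 0L
  if (!"distal" %in% names(counts)) counts$distal <- 0L
  tibble::tibble(word = counts$word,
                 a = counts$proximal, b = n_prox - counts$proximal,
                 c = counts$distal, d = n_dist - counts$distal) |>
    dplyr::arrange(.data$word)
}

#' Odds ratio of a 2x2 table
#'
#' Cross-product ratio `(a*d)/(b*c)`. If any cell is zero, 0.5 is added to
#' all four cells first (Haldane-Anscombe correction), so the result is
#' always finite and positive.
#'
#' @param a,b,c,d Nonnegative cell counts (vectorised).
#' @return Numeric odds ratio(s); the `corrected` attribute flags rows where
#'   the zero-cell correction was applied.
#' @export
odds_ratio <- function(a, b, c, d) {
  corrected <- a == 0 | b == 0 | c == 0 | d == 0
  h <- ifelse(corrected, 0.5, 0)
  out <- ((a + h) * (d + h)) / ((b + h) * (c + h))
  attr(out, "corrected") <- corrected
  out
}

#' Two-sided Fisher exact p-value of a 2x2 table
#'
#' Computed by hypergeometric enumeration: over all tables with the observed
#' margins, the probabilities of tables no more probable than the observed
#' one are summed. Log-space hypergeometric densities keep the computation
#' overflow-safe for large counts. No zero-cell correction is applied (the
#' exact test handles zeros natively).
#'
#' @param a,b,c,d Nonnegative cell counts (vectorised).
#' @return Numeric p-value(s) in `[0, 1]`.
#' @export
fisher_exact_p <- function(a, b, c, d) {
  mapply(function(a, b, c, d) {
    m <- a + b
    n <- c + d
    if (m == 0 && n == 0) stop("empty table", call. = FALSE)
    k <- a + c
    support <- max(0L, k - n):min(k, m)
    dens <- stats::dhyper(support, m, n, k)
    p_obs <- stats::dhyper(a, m, n, k)
    min(1, sum(dens[dens <= p_obs * (1 + 1e-07)]))
  }, a, b, c, d)
}

chisq_p <- function(a, b, c, d) {
  mapply(function(a, b, c, d) {
    suppressWarnings(
      stats::chisq.test(matrix(c(a, b, c, d), 2), correct = TRUE)$p.value
    )
  }, a, b, c, d)
}

#' Word-level discrimination statistics
#'
#' Builds the per-word incidence tables and computes the odds ratio, p-value
#' and retention flag for every word. Retention follows the proximal/distal
#' discrimination rule: `p <= p_max` and OR strictly below `or_low` or
#' strictly above `or_high`.
#'
#' @inheritParams doc_term_incidence
#' @param p_max Significance threshold, inclusive (default 0.05).
#' @param or_low,or_high OR retention bounds, exclusive (defaults 0.66 and
#'   1.50).
#' @param exclude Optional character vector of words to drop before testing
#'   (the curation exclusion list: abbreviations, dates, locations, ...).
#' @param test `"fisher"` (exact, default) or `"chisq"` (with continuity
#'   correction).
#' @param adjust `"none"` (default, the raw p-value filter) or `"BH"`
#'   (Benjamini-Hochberg).
#' @return Tibble with `word`, the four cell counts, `odds_ratio`,
#'   `zero_corrected`, `p_value`, `retained`, ordered by `|log OR|`
#'   descending (curation-export order).
#' @export
word_stats <- function(streams, p_max = 0.05, or_low = 0.66, or_high = 1.50,
                       exclude = NULL, test = c("fisher", "chisq"),
                       adjust = c("none", "BH")) {
  test <- match.arg(test)
  adjust <- match.arg(adjust)
  inc <- doc_term_incidence(streams)
  if (!is.null(exclude)) inc <- inc[!inc$word %in% exclude, , drop = FALSE]
  or <- odds_ratio(inc$a, inc$b, inc$c, inc$d)
  p <- if (test == "fisher") fisher_exact_p(inc$a, inc$b, inc$c, inc$d) else
    chisq_p(inc$a, inc$b, inc$c, inc$d)
  if (adjust == "BH") p <- stats::p.adjust(p, method = "BH")
  out <- inc
  out$odds_ratio <- as.numeric(or)
  out$zero_corrected <- attr(or, "corrected")
  out$p_value <- p
  out$retained <- p <= p_max & (out$odds_ratio < or_low |
                                  out$odds_ratio > or_high)
  attr(out, "test") <- test
  dplyr::arrange(out, dplyr::desc(abs(log(.data$odds_ratio))))
}

#' Apply the retention filter to a word-statistics table
#'
#' @param stats Tibble from [word_stats()] (or any table with `odds_ratio`
#'   and `p_value` columns).
#' @inheritParams word_stats
#' @return The retained rows, sorted by `|log OR|` descending.
#' @export
retain_words <- function(stats, p_max = 0.05, or_low = 0.66, or_high = 1.50) {
  keep <- stats$p_value <= p_max &
    (stats$odds_ratio < or_low | stats$odds_ratio > or_high)
  out <- stats[keep, , drop = FALSE]
  out$retained <- TRUE
  dplyr::arrange(out, dplyr::desc(abs(log(.data$odds_ratio))))
}
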