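# Category-level exposure odds ratios and inter-annotator agreement.
#
# Clinician-defined word categories are scored like single words: a document
# is "exposed" to a category if it contains at least one member lemma, and
# the category's proximal/distal odds ratio comes from the resulting 2x2
# table. Agreement between two annotators assigning the same word list to
# the same category inventory is summarised by a confusion matrix,
# per-category precision/recall/F1, and Cohen's kappa.

as_category_table <- function(categories) {
  if (is.data.frame(categories)) {
    stopifnot(all(c("word", "category") %in% names(categories)))
    return(tibble::as_tibble(categories[, c("word", "category")]))
  }
  # named list of character vectors
  tibble::tibble(word = unlist(categories, use.names = FALSE),
                 category = rep(names(categories), lengths(categories)))
}

#' Category-level exposure statistics
#'
#' For each category, counts the documents in each period containing at
#' least one member word and computes the exposure odds ratio and Fisher
#' exact p-value from the 2x2 table (zero cells handled as for single
#' words). Categories none of whose members occur anywhere are flagged.
#'
#' @param streams Word-mode token streams (tibble with `doc_id`, `period`,
#'   `tokens`), as from [prepare_corpus()].
#' @param categories Either a tibble with `word` and `category` columns or a
#'   named list of member-word vectors.
#' @return Tibble with `category`, `n_words`, `a`, `b`, `c`, `d`,
#'   `odds_ratio`, `zero_corrected`, `p_value`.
#' @export
category_exposure <- function(streams, categories) {
  cats <- as_category_table(categories)
  if (nrow(cats) == 0) stop("no categories supplied", call. = FALSE)
  n_prox <- sum(streams$period == "proximal")
  n_dist <- sum(streams$period == "distal")
  if (n_prox == 0 || n_dist == 0) {
    stop("both periods must be represented in the corpus", call. = FALSE)
  }
  doc_words <- tibble::tibble(
    doc = rep(seq_len(nrow(streams)),
              vapply(streams$tokens, function(t) length(unique(t)), integer(1))),
    period = rep(streams$period,
                 vapply(streams$tokens, function(t) length(unique(t)), integer(1))),
    word = unlist(lapply(streams$tokens, unique), use.names = FALSE)
  )
  hits <- dplyr::inner_join(doc_words, cats, by = "word",
                            relationship = "many-to-many")
  exposed <- hits |>
    dplyr::distinct(.data$category, .data$doc, .data$period) |>
    dplyr::count(.data$category, .data$period) |>
    tidyr::pivot_wider(names_from = "period", values_from = "n",
                       values_fill = 0L)
  if (!"proximal" %in% names(exposed)) exposed$proximal <- 0L
  if (!"distal" %in% names(exposed)) exposed$distal <- 0L
  all_cats <- tibble::tibble(category = sort(unique(cats$category)))
  out <- dplyr::left_join(all_cats, exposed, by = "category")
  out$proximal[is.na(out$proximal)] <- 0L
  out$distal[is.na(out$distal)] <- 0L
  n_words <- cats |> dplyr::count(.data$category, name = "n_words")
  out <- dplyr::left_join(out, n_words, by = "category")
  a <- out$proximal; b <- n_prox - a; c <- out$distal; d <- n_dist - c
  or <- odds_ratio(a, b, c, d)
  if (any(a + c == 0)) {
    warning("category with no exposed documents anywhere: ",
            paste(out$category[a + c == 0], collapse = ", "),
            " (OR computed with zero-cell correction)", call. = FALSE)
  }
  tibble::tibble(category = out$category, n_words = out$n_words,
                 a = a, b = b, c = c, d = d,
                 odds_ratio = as.numeric(or),
                 zero_corrected = attr(or, "corrected"),
                 p_value = fisher_exact_p(a, b, c, d))
}

check_same_words <- function(reference, comparison) {
  ref <- as_category_table(reference)
  cmp <- as_category_table(comparison)
  if (anyDuplicated(ref$word) || anyDuplicated(cmp$word)) {
    stop("each word must belong to exactly one category per annotator",
         call. = FALSE)
  }
  if (!setequal(ref$word, cmp$word)) {
    stop("annotators must assign the same word list", call. = FALSE)
  }
  cmp <- cmp[match(ref$word, cmp$word), , drop = FALSE]
  list(ref = ref, cmp = cmp)
}

#' F1 score from precision and recall
#'
#' Harmonic mean of precision and recall; 0 where both are 0.
#'
#' @param precision,recall Numeric vectors in `[0, 1]`.
#' @return Numeric F1 vector.
#' @export
f1_score <- function(precision, recall) {
  ifelse(precision + recall == 0, 0,
         2 * precision * recall / (precision + recall))
}

#' Per-category precision, recall and F1 between two annotators
#'
#' Treats the first annotator as the reference: for category c,
#' `recall = |both assign c| / |reference assigns c|` and
#' `precision = |both assign c| / |comparison assigns c|`. Direction matters
#' and reports should name the reference annotator.
#'
#' @param reference,comparison Word-to-category assignments (tibble with
#'   `word`, `category`, or named list of word vectors) over the same word
#'   list and category inventory.
#' @return Tibble with `category`, `n_reference`, `n_comparison`, `n_agree`,
#'   `precision`, `recall`, `f1` (precision/recall are `NaN`-free: 0 when
#'   the annotator assigned no word to the category).
#' @export
per_category_prf <- function(reference, comparison) {
  x <- check_same_words(reference, comparison)
  cats <- sort(union(x$ref$category, x$cmp$category))
  n_ref <- vapply(cats, function(c) sum(x$ref$category == c), integer(1))
  n_cmp <- vapply(cats, function(c) sum(x$cmp$category == c), integer(1))
  n_agree <- vapply(cats, function(c) {
    sum(x$ref$category == c & x$cmp$category == c)
  }, integer(1))
  precision <- unname(ifelse(n_cmp > 0, n_agree / n_cmp, 0))
  recall <- unname(ifelse(n_ref > 0, n_agree / n_ref, 0))
  tibble::tibble(category = cats, n_reference = unname(n_ref),
                 n_comparison = unname(n_cmp), n_agree = unname(n_agree),
                 precision = precision, recall = recall,
                 f1 = f1_score(precision, recall))
}

#' Cohen's kappa between two annotators
#'
#' Chance-corrected agreement: `kappa = (p_o - p_e) / (1 - p_e)` with
#' observed agreement `p_o` the fraction of words identically categorised
#' and expected agreement `p_e` the sum over categories of the product of
#' the two annotators' marginal proportions. In the degenerate case
#' `p_e = 1` (a single used category), kappa is defined as 1 if agreement is
#' perfect and 0 otherwise, with a warning.
#'
#' @inheritParams per_category_prf
#' @return A single numeric kappa in `[-1, 1]`.
#' @export
cohens_kappa <- function(reference, comparison) {
  x <- check_same_words(reference, comparison)
  n <- nrow(x$ref)
  p_o <- mean(x$ref$category == x$cmp$category)
  cats <- union(x$ref$category, x$cmp$category)
  p_a <- vapply(cats, function(c) mean(x$ref$category == c), numeric(1))
  p_b <- vapply(cats, function(c) mean(x$cmp$category == c), numeric(1))
  p_e <- sum(p_a * p_b)
  if (1 - p_e < .Machine$double.eps) {
    warning("degenerate single-category agreement; kappa defined as ",
            if (p_o == 1) 1 else 0, call. = FALSE)
    return(if (p_o == 1) 1 else 0)
  }
  (p_o - p_e) / (1 - p_e)
}

#' Full inter-annotator agreement summary
#'
#' @inheritParams per_category_prf
#' @return An `annotation_agreement` object: list with `kappa`, `prf`
#'   (from [per_category_prf()]) and `confusion` (reference in rows,
#'   comparison in columns).
#' @export
annotation_agreement <- function(reference, comparison) {
  x <- check_same_words(reference, comparison)
  cats <- sort(union(x$ref$category, x$cmp$category))
  confusion <- table(factor(x$ref$category, levels = cats),
                     factor(x$cmp$category, levels = cats),
                     dnn = c("reference", "comparison"))
  structure(list(kappa = cohens_kappa(reference, comparison),
                 prf = per_category_prf(reference, comparison),
                 confusion = confusion),
            class = "annotation_agreement")
}

#' @export
print.annotation_agreement <- function(x, ...) {
  cat(sprintf("Inter-annotator agreement over %d words, %d categories\n",
              sum(x$confusion), nrow(x$confusion)))
  cat(sprintf("  Cohen's kappa: %.3f\n", x$kappa))
  cat(sprintf("  mean F1 across categories: %.3f\n", mean(x$prf$f1)))
  invisible(x)
}
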