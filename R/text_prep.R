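# Tokenisation, POS tagging and lemmatisation.
#
# Two preparation modes feed the downstream analyses:
#   * "word" mode keeps nouns, pronouns and verbs as lemmas and replaces
#     every other word with its POS label (punctuation dropped) -- the stream
#     used for word- and category-level odds ratios;
#   * "ngram" mode lemmatises every word and keeps punctuation -- the stream
#     used for n-gram Naive Bayes features, where function words carry
#     signal and must survive.
#
# Tagging is pluggable; the bundled fallback tagger is a closed lexicon that
# covers the synthetic vocabulary and common English inflections, so the
# whole pipeline is deterministic with no model download.

#' The Universal POS tag inventory
#'
#' The 17-tag Universal Dependencies POS inventory used as placeholder
#' labels for non-content words in word-analysis mode.
#'
#' @return Character vector of 17 uppercase tags.
#' @export
upos_tags <- function() {
  c("ADJ", "ADP", "ADV", "AUX", "CCONJ", "DET", "INTJ", "NOUN", "NUM",
    "PART", "PRON", "PROPN", "PUNCT", "SCONJ", "SYM", "VERB", "X")
}

content_pos <- function() c("NOUN", "PROPN", "PRON", "VERB")

#' Tokenise free text
#'
#' Lowercases, splits on whitespace, and separates terminal punctuation
#' (`. , ; : ! ?`) into its own token. Hyphenated compounds such as
#' `"self-harm"` are kept whole.
#'
#' @param text A single character string.
#' @return Character vector of tokens (empty for whitespace-only input).
#' @examples
#' tokenize("The patient is not suicidal.")
#' @export
tokenize <- function(text) {
  stopifnot(length(text) == 1L)
  split_tokens(tolower(text))[[1]]
}

# vectorised core: character vector -> list of token vectors
split_tokens <- function(text) {
  text <- gsub("([^[:space:]])([.,;:!?])", "\\1 \\2", text)
  text <- gsub("([.,;:!?])([^[:space:]])", "\\1 \\2", text)
  lapply(strsplit(trimws(text), "[[:space:]]+"), function(v) v[nzchar(v)])
}

#' Deterministic lexicon-based POS tagger
#'
#' A closed-lexicon tagger covering the synthetic vocabulary, its inflected
#' surface forms, and common English function words. Tokens made entirely of
#' punctuation are tagged `PUNCT`; unknown word tokens fall back to `NOUN`
#' with an identity lemma. The lexicon records a separate n-gram-mode lemma
#' where it differs: `"self-harm"` lemmatises to the two-token sequence
#' `"self harm"` in n-gram mode.
#'
#' @param extra Optional tibble of additional lexicon rows
#'   (`token`, `pos`, `lemma`, optionally `ngram_lemma`) which override the
#'   bundled entries.
#' @return A `pos_tagger` object usable with [tag_tokens()] and
#'   [prepare_corpus()].
#' @export
fallback_tagger <- function(extra = NULL) {
  lex <- fallback_lexicon()
  if (!is.null(extra)) {
    extra <- tibble::as_tibble(extra)
    if (!"ngram_lemma" %in% names(extra)) extra$ngram_lemma <- extra$lemma
    lex <- dplyr::bind_rows(extra, lex)
    lex <- lex[!duplicated(lex$token), , drop = FALSE]
  }
  stopifnot(all(lex$pos %in% upos_tags()))
  structure(list(lexicon = lex, default_pos = "NOUN"), class = "pos_tagger")
}

fallback_lexicon <- function() {
  entry <- function(lemma, pos, forms = lemma, ngram_lemma = lemma) {
    tibble::tibble(token = forms, pos = pos, lemma = lemma,
                   ngram_lemma = ngram_lemma)
  }
  dplyr::bind_rows(
    # pronouns (possessives kept PRON so "his"/"her" survive as content)
    entry("she", "PRON"), entry("he", "PRON"), entry("her", "PRON"),
    entry("his", "PRON"), entry("him", "PRON"), entry("it", "PRON"),
    entry("they", "PRON", c("they", "them")), entry("i", "PRON"),
    entry("you", "PRON"), entry("we", "PRON", c("we", "us")),
    entry("there", "PRON"), entry("herself", "PRON"), entry("himself", "PRON"),
    # auxiliaries
    entry("be", "AUX", c("be", "is", "was", "are", "were", "been", "being", "am")),
    entry("have", "AUX", c("have", "has", "had", "having")),
    entry("do", "AUX", c("do", "does", "did", "done", "doing")),
    entry("will", "AUX"), entry("would", "AUX"), entry("can", "AUX"),
    entry("could", "AUX"), entry("may", "AUX"), entry("might", "AUX"),
    entry("shall", "AUX"), entry("should", "AUX"), entry("must", "AUX"),
    # verbs with inflected forms
    entry("say", "VERB", c("say", "says", "said", "saying")),
    entry("state", "VERB", c("state", "states", "stated", "stating")),
    entry("report", "VERB", c("report", "reports", "reported", "reporting")),
    entry("want", "VERB", c("want", "wants", "wanted", "wanting")),
    entry("feel", "VERB", c("feel", "feels", "felt", "feeling")),
    entry("deny", "VERB", c("deny", "denies", "denied", "denying")),
    entry("take", "VERB", c("take", "takes", "took", "taken", "taking")),
    entry("attend", "VERB", c("attend", "attends", "attended", "attending")),
    entry("sleep", "VERB", c("sleep", "sleeps", "slept", "sleeping")),
    entry("see", "VERB", c("see", "sees", "saw", "seen", "seeing")),
    entry("settle", "VERB", c("settle", "settles", "settled", "settling")),
    entry("meet", "VERB", c("meet", "meets", "met", "meeting")),
    entry("admit", "VERB", c("admit", "admits", "admitted", "admitting")),
    entry("present", "VERB", c("present", "presents", "presented")),
    entry("discuss", "VERB", c("discuss", "discusses", "discussed")),
    entry("eat", "VERB", c("eat", "eats", "ate", "eaten", "eating")),
    # nouns with plural forms
    entry("patient", "NOUN", c("patient", "patients")),
    entry("overdose", "NOUN", c("overdose", "overdoses")),
    entry("medication", "NOUN", c("medication", "medications")),
    entry("tablet", "NOUN", c("tablet", "tablets")),
    entry("risk", "NOUN", c("risk", "risks")),
    entry("plan", "NOUN", c("plan", "plans")),
    entry("review", "NOUN", c("review", "reviews")),
    entry("consultant", "NOUN", c("consultant", "consultants")),
    entry("meal", "NOUN", c("meal", "meals")),
    entry("activity", "NOUN", c("activity", "activities")),
    entry("ward", "NOUN", c("ward", "wards")),
    entry("nurse", "NOUN", c("nurse", "nurses")),
    entry("week", "NOUN", c("week", "weeks")),
    entry("home", "NOUN"), entry("family", "NOUN", c("family", "families")),
    entry("mood", "NOUN", c("mood", "moods")), entry("staff", "NOUN"),
    entry("thought", "NOUN", c("thought", "thoughts")),
    entry("appointment", "NOUN", c("appointment", "appointments")),
    entry("self-harm", "NOUN", "self-harm", ngram_lemma = "self harm"),
    entry("harm", "NOUN", c("harm", "harms")),
    entry("self", "NOUN"),
    entry("clinic", "NOUN", c("clinic", "clinics")),
    entry("depot", "NOUN", c("depot", "depots")),
    entry("garden", "NOUN", c("garden", "gardens")),
    entry("cook", "VERB", c("cook", "cooks", "cooked", "cooking")),
    # function words and modifiers
    entry("the", "DET"), entry("a", "DET", c("a", "an")), entry("no", "DET"),
    entry("this", "DET"), entry("some", "DET"), entry("any", "DET"),
    entry("to", "PART"), entry("not", "PART"),
    entry("of", "ADP"), entry("in", "ADP"), entry("on", "ADP"),
    entry("at", "ADP"), entry("by", "ADP"), entry("with", "ADP"),
    entry("for", "ADP"), entry("from", "ADP"), entry("about", "ADP"),
    entry("and", "CCONJ"), entry("or", "CCONJ"), entry("but", "CCONJ"),
    entry("that", "SCONJ"), entry("if", "SCONJ"), entry("because", "SCONJ"),
    entry("very", "ADV"), entry("also", "ADV"), entry("again", "ADV"),
    entry("today", "ADV"), entry("currently", "ADV"), entry("well", "ADV"),
    entry("suicidal", "ADJ"), entry("low", "ADJ"), entry("good", "ADJ"),
    entry("stable", "ADJ"), entry("unwell", "ADJ"), entry("calm", "ADJ")
  )
}

#' Tag a token vector
#'
#' Looks each token up in the tagger's lexicon. Punctuation-only tokens are
#' tagged `PUNCT`; unknown word tokens fall back to the tagger's default POS
#' (`NOUN`) with an identity lemma.
#'
#' @param tokens Character vector of tokens (already lowercased).
#' @param tagger A `pos_tagger` (default the bundled [fallback_tagger()]).
#' @return Tibble with `token`, `pos`, `lemma`, `ngram_lemma`.
#' @export
tag_tokens <- function(tokens, tagger = fallback_tagger()) {
  stopifnot(inherits(tagger, "pos_tagger"))
  lex <- tagger$lexicon
  i <- match(tokens, lex$token)
  pos <- ifelse(is.na(i), tagger$default_pos, lex$pos[i])
  lemma <- ifelse(is.na(i), tokens, lex$lemma[i])
  ngram_lemma <- ifelse(is.na(i), tokens, lex$ngram_lemma[i])
  punct <- grepl("^[[:punct:]]+$", tokens) & !grepl("[[:alnum:]]", tokens)
  pos[punct] <- "PUNCT"
  lemma[punct] <- tokens[punct]
  ngram_lemma[punct] <- tokens[punct]
  tibble::tibble(token = tokens, pos = pos, lemma = lemma,
                 ngram_lemma = ngram_lemma)
}

#' Prepare one document for word-level analysis
#'
#' Nouns, pronouns and verbs are replaced by their lemma; every other word
#' is replaced by its (uppercase) POS label; punctuation is dropped.
#'
#' @param text A single character string.
#' @param tagger A `pos_tagger`.
#' @return Character vector: the prepared token stream.
#' @examples
#' prepare_for_word_analysis("She reported overdoses")
#' @export
prepare_for_word_analysis <- function(text, tagger = fallback_tagger()) {
  tags <- tag_tokens(tokenize(text), tagger)
  tags <- tags[tags$pos != "PUNCT", , drop = FALSE]
  ifelse(tags$pos %in% content_pos(), tags$lemma, tags$pos)
}

#' Prepare one document for n-gram analysis
#'
#' Every word token is replaced by its lemma (function words survive);
#' punctuation is retained as tokens. Lexicon entries whose n-gram lemma is a
#' multi-token sequence (e.g. `"self-harm"` -> `"self harm"`) are expanded.
#'
#' @inheritParams prepare_for_word_analysis
#' @return Character vector: the prepared token stream.
#' @examples
#' prepare_for_ngram_analysis("There were no thoughts of self-harm.")
#' @export
prepare_for_ngram_analysis <- function(text, tagger = fallback_tagger()) {
  tags <- tag_tokens(tokenize(text), tagger)
  unlist(strsplit(tags$ngram_lemma, " ", fixed = TRUE), use.names = FALSE)
}

#' Prepare a labelled corpus into token streams
#'
#' Vectorised preparation of every document in a labelled corpus (or a plain
#' tibble with `doc_id`, `period`, `text`) in either analysis mode.
#'
#' @param corpus A `labeled_corpus` from [build_labeled_corpus()], or a data
#'   frame with at least `doc_id`, `period` and `text` columns.
#' @param mode `"word"` or `"ngram"` (see package docs for the difference).
#' @param tagger A `pos_tagger`.
#' @return Tibble with `doc_id`, `period` and a `tokens` list-column.
#' @export
prepare_corpus <- function(corpus, mode = c("word", "ngram"),
                           tagger = fallback_tagger()) {
  mode <- match.arg(mode)
  docs <- if (inherits(corpus, "labeled_corpus")) corpus$documents else
    tibble::as_tibble(corpus)
  stopifnot(all(c("doc_id", "period", "text") %in% names(docs)))
  tok_list <- split_tokens(tolower(docs$text))
  lens <- lengths(tok_list)
  flat <- unlist(tok_list, use.names = FALSE)
  idx <- rep.int(seq_along(tok_list), lens)
  tags <- tag_tokens(flat, tagger)
  if (mode == "word") {
    keep <- tags$pos != "PUNCT"
    out <- ifelse(tags$pos %in% content_pos(), tags$lemma, tags$pos)
    streams <- split(out[keep], factor(idx[keep], levels = seq_along(tok_list)))
  } else {
    streams <- split(tags$ngram_lemma,
                     factor(idx, levels = seq_along(tok_list)))
    streams <- lapply(streams, function(v) {
      unlist(strsplit(v, " ", fixed = TRUE), use.names = FALSE)
    })
  }
  tibble::tibble(doc_id = docs$doc_id, period = docs$period,
                 tokens = unname(streams))
}
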