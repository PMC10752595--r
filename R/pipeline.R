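# End-to-end orchestration: simulate (or load) -> cohort -> monitoring ->
# corpus windows -> text prep -> word discrimination -> categories ->
# n-gram NB, with every intermediate persisted when an output directory is
# given (the derivation counts at each filter are part of the result, not
# just a log).

#' Run the full proximal/distal analysis pipeline
#'
#' Either simulates a cohort from `config` or consumes supplied `documents`
#' and `episodes` tables, then runs every analysis stage. When the cohort
#' contains no suicide-related admission the pipeline stops after the cohort
#' stage and returns a partial bundle saying so.
#'
#' Category-level agreement statistics are computed against the generator's
#' planted category assignments; a second annotator is emulated by
#' reassigning each word with probability `annotation_noise` (0 gives
#' perfect agreement, exercising the kappa = 1 path).
#'
#' @param config A `sim_config` (used to simulate when `documents` is
#'   `NULL`, and for the seed).
#' @param documents,episodes Optional externally supplied tables (schemas as
#'   in [generate_cohort()]); categories/agreement are then skipped unless
#'   `categories` is given.
#' @param categories Optional word-category table (tibble `word`,
#'   `category`) overriding the manifest's planted categories.
#' @param out_dir Optional directory; when given, every stage's output is
#'   written (episodes/documents, trajectory, corpus summary, word stats,
#'   category stats, feature reports, run manifest).
#' @param window Monitoring window W in days (default 30).
#' @param offsets Trajectory day offsets (default `-365:-1`).
#' @param min_docs Trajectory numerator threshold (default 1).
#' @param min_chars Corpus length filter (default 100).
#' @param ngram_orders Gram orders to fit (default `1:3`).
#' @param k Informative features per order (default 30).
#' @param alpha NB smoothing (default 1).
#' @param annotation_noise Per-word reassignment probability for the
#'   emulated second annotator (default 0).
#' @return A `report_bundle` list: `counts`, `trajectory`, `corpus_summary`,
#'   `word_stats`, `category_stats`, `agreement`, `feature_reports`,
#'   `run_manifest`.
#' @export
run_pipeline <- function(config, documents = NULL, episodes = NULL,
                         categories = NULL, out_dir = NULL, window = 30,
                         offsets = -365:-1, min_docs = 1, min_chars = 100,
                         ngram_orders = 1:3, k = 30, alpha = 1,
                         annotation_noise = 0) {
  manifest <- NULL
  if (is.null(documents)) {
    sim <- generate_cohort(config)
    documents <- sim$documents
    episodes <- sim$episodes
    manifest <- sim$manifest
  }
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    write_documents_jsonl(documents, file.path(out_dir, "documents.jsonl"))
    write_episodes_csv(episodes, file.path(out_dir, "episodes.csv"))
  }

  admissions <- build_admissions(episodes)
  attempts <- first_attempts(admissions)
  counts <- list(n_patients = length(unique(documents$patient_id)),
                 n_documents = nrow(documents),
                 n_episodes = nrow(episodes),
                 n_admissions = nrow(admissions),
                 n_suicide_admissions = sum(admissions$suicide_related),
                 n_patients_with_attempt = nrow(attempts))
  if (nrow(attempts) == 0) {
    bundle <- structure(list(
      counts = counts, status = "no suicide-related admissions",
      admissions = admissions, run_manifest = run_manifest(config)),
      class = "report_bundle")
    if (!is.null(out_dir)) {
      jsonlite::write_json(counts, file.path(out_dir, "counts.json"),
                           auto_unbox = TRUE)
    }
    return(bundle)
  }

  trajectory <- aligned_trajectory(documents, attempts, offsets, window,
                                   min_docs)
  corpus <- build_labeled_corpus(documents, admissions, min_chars)
  word_streams <- prepare_corpus(corpus, "word")
  ngram_streams <- prepare_corpus(corpus, "ngram")
  wstats <- word_stats(word_streams)

  category_stats <- agreement <- NULL
  if (is.null(categories) && !is.null(manifest)) {
    categories <- manifest$enrichment[!is.na(manifest$enrichment$category),
                                      c("word", "category")]
  }
  if (!is.null(categories) && nrow(categories) > 0) {
    category_stats <- category_exposure(word_streams, categories)
    annot_b <- categories
    if (annotation_noise > 0) {
      set.seed(config$seed + 1L)
      flip <- stats::runif(nrow(annot_b)) < annotation_noise
      pool <- unique(categories$category)
      annot_b$category[flip] <- sample(pool, sum(flip), replace = TRUE)
    }
    agreement <- annotation_agreement(categories, annot_b)
  }

  feature_reports <- lapply(ngram_orders, function(n) {
    model <- fit_nb(ngram_streams, n, alpha)
    top_informative(model, k, ngram_streams)
  })
  names(feature_reports) <- paste0("n", ngram_orders)

  bundle <- structure(list(
    counts = counts, trajectory = trajectory,
    corpus_summary = corpus$summary, word_stats = wstats,
    category_stats = category_stats, agreement = agreement,
    feature_reports = feature_reports,
    run_manifest = run_manifest(config, window = window,
                                min_chars = min_chars, alpha = alpha, k = k)),
    class = "report_bundle")

  if (!is.null(out_dir)) {
    readr::write_csv(trajectory, file.path(out_dir, "trajectory.csv"))
    readr::write_csv(wstats, file.path(out_dir, "word_stats.csv"))
    if (!is.null(category_stats)) {
      readr::write_csv(category_stats, file.path(out_dir, "category_stats.csv"))
    }
    for (nm in names(feature_reports)) {
      readr::write_csv(feature_reports[[nm]],
                       file.path(out_dir, paste0("features_", nm, ".csv")))
    }
    jsonlite::write_json(
      c(counts, list(corpus = list(
        per_period = corpus$summary$per_period,
        patients_in_both = corpus$summary$patients_in_both))),
      file.path(out_dir, "counts.json"), auto_unbox = TRUE)
    jsonlite::write_json(bundle$run_manifest,
                         file.path(out_dir, "run_manifest.json"),
                         auto_unbox = TRUE)
  }
  bundle
}

run_manifest <- function(config, ...) {
  params <- list(...)
  c(list(seed = config$seed, n_patients = config$n_patients,
         baseline_doc_rate = config$baseline_doc_rate,
         ramp_multiplier = config$ramp_multiplier,
         ramp_length_days = config$ramp_length_days,
         attempt_probability = config$attempt_probability,
         rate_dispersion = config$rate_dispersion,
         package_version = as.character(utils::packageVersion("ehrwindows"))),
    params)
}

#' @export
print.report_bundle <- function(x, ...) {
  cat("ehrwindows report bundle\n")
  cat(sprintf("  %d patients with documents, %d documents, %d episodes -> %d admissions (%d suicide-related)\n",
              x$counts$n_patients, x$counts$n_documents, x$counts$n_episodes,
              x$counts$n_admissions, x$counts$n_suicide_admissions))
  if (!is.null(x$status)) {
    cat("  status:", x$status, "\n")
    return(invisible(x))
  }
  s <- x$corpus_summary
  cat(sprintf("  corpus: %d labelled documents from %d patients\n",
              s$n_docs, s$n_patients))
  cat(sprintf("  words retained by OR/p filter: %d of %d\n",
              sum(x$word_stats$retained), nrow(x$word_stats)))
  if (!is.null(x$agreement)) {
    cat(sprintf("  annotator agreement kappa: %.3f\n", x$agreement$kappa))
  }
  invisible(x)
}
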