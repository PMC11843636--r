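#' Exclusion lists for novel-signal filtering
#'
#' Positive preferred terms are not all informative: terms reflecting the
#' underlying disease's own progression, terms with erroneous or ambiguous
#' usage, and adverse events already described in the drug insert or in the
#' pivotal phase III trial are set aside, leaving the novel signals. Lists
#' are matched case-insensitively and may overlap.
#'
#' @param disease_related PTs tied to disease progression.
#' @param ambiguous PTs with erroneous/ambiguous usage.
#' @param known_insert PTs listed as adverse reactions in the drug insert.
#' @param known_trial PTs reported in the pivotal phase III trial.
#' @return an `exclusion_lists` object.
#' @export
exclusion_lists <- function(disease_related = character(),
                            ambiguous = character(),
                            known_insert = character(),
                            known_trial = character()) {
  structure(list(disease_related = as.character(disease_related),
                 ambiguous = as.character(ambiguous),
                 known_insert = as.character(known_insert),
                 known_trial = as.character(known_trial)),
            class = "exclusion_lists")
}

#' Default exclusion lists shipped with the package
#'
#' The insert and trial lists are reconstructions from the published per-term
#' annotations of the sparsentan/IgAN screen (the original supplementary
#' lists are not reproduced in the main text); the disease-related and
#' ambiguous lists are empty by default and should be supplied by the
#' analyst.
#'
#' @return an [exclusion_lists()] object.
#' @export
default_exclusion_lists <- function() {
  exclusion_lists(
    known_insert = read_term_file(pvscreen_extdata("known_insert_terms.txt")),
    known_trial = read_term_file(pvscreen_extdata("known_trial_terms.txt")))
}

#' Classify positive signals as novel or excluded
#'
#' Each positive PT receives exactly one status, decided by the first
#' matching rule in `order`: disease-related exclusion, ambiguous-usage
#' exclusion, known from the drug insert, known from the phase III trial,
#' and otherwise novel.
#'
#' @param positive_pts character vector of PT names, or a data.frame with a
#'   `term` column (e.g. a [run_screen()] result filtered to positives).
#' @param ex an [exclusion_lists()] object.
#' @param order precedence of the exclusion rules.
#' @return data.frame with columns `term` and `status` (one of
#'   `excluded_disease`, `excluded_ambiguous`, `known_insert`, `known_trial`,
#'   `novel`), with attribute `status_counts`. If a data.frame was supplied,
#'   the `status` column is appended to it instead.
#' @export
classify_signals <- function(positive_pts, ex = exclusion_lists(),
                             order = c("disease", "ambiguous", "insert",
                                       "trial")) {
  df <- NULL
  if (is.data.frame(positive_pts)) {
    df <- positive_pts
    terms <- df$term
  } else {
    terms <- as.character(positive_pts)
  }
  sets <- list(disease = ex$disease_related, ambiguous = ex$ambiguous,
               insert = ex$known_insert, trial = ex$known_trial)
  labels <- c(disease = "excluded_disease", ambiguous = "excluded_ambiguous",
              insert = "known_insert", trial = "known_trial")
  status <- rep("novel", length(terms))
  tn <- norm_name(terms)
  for (rule in rev(order)) {
    hit <- tn %in% norm_name(sets[[rule]])
    status[hit] <- labels[[rule]]
  }
  if (is.null(df)) df <- data.frame(term = terms, stringsAsFactors = FALSE)
  df$status <- status
  attr(df, "status_counts") <- table(factor(status, levels = c(
    "excluded_disease", "excluded_ambiguous", "known_insert", "known_trial",
    "novel")))
  df
}
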