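#' @title Clinical-priority rubric for positive signals
#' @name priority
#' @description
#' Each positive preferred term is scored 0/1/2 on five dimensions -- number
#' of target events, lower 95\% confidence limit of the ROR, mortality
#' proportion, membership of the EMA Important/Designated Medical Event
#' lists, and biological plausibility (documented in the drug insert, in the
#' pivotal trial, or nowhere) -- and the total (0-10) is banded as weak
#' (0-4), moderate (5-7) or strong (8-10) clinical priority. The published
#' rubric prints overlapping band edges; the implementation fixes them as
#' closed middle bands: events [10, 50] -> 1; ROR lower limit [2, 5] -> 1;
#' mortality [25\%, 50\%] -> 1, with the 2-point band strictly above in each
#' case.
NULL

#' Score the number of target events
#' @param a target report count(s) for the term (>= 0).
#' @return integer score(s): `a > 50` -> 2, `10 <= a <= 50` -> 1, else 0.
#' @export
score_events <- function(a) {
  stopifnot(all(a >= 0))
  ifelse(a > 50, 2L, ifelse(a >= 10, 1L, 0L))
}

#' Score the lower 95\% confidence limit of the ROR
#' @param ci_low lower ROR confidence bound(s); must exceed 1 (a term with
#'   `ci_low <= 1` is not a positive signal and cannot be scored).
#' @return integer score(s): `> 5` -> 2, `[2, 5]` -> 1, `(1, 2)` -> 0.
#' @export
score_ror_lower <- function(ci_low) {
  if (any(is.na(ci_low) | ci_low <= 1))
    stop("ROR lower limit must exceed 1 for a positive signal")
  ifelse(ci_low > 5, 2L, ifelse(ci_low >= 2, 1L, 0L))
}

#' Score the mortality proportion
#' @param p fraction(s) in [0, 1] of the term's target reports with a death
#'   outcome.
#' @return integer score(s): `> 0.5` -> 2, `[0.25, 0.5]` -> 1, else 0.
#' @export
score_mortality <- function(p) {
  stopifnot(all(p >= 0 & p <= 1))
  ifelse(p > 0.5, 2L, ifelse(p >= 0.25, 1L, 0L))
}

#' Severity lists (EMA IME / DME membership)
#'
#' @param ime_terms PTs on the Important Medical Events list.
#' @param dme_terms PTs on the Designated Medical Events list.
#' @return an `event_severity_lists` object.
#' @export
event_severity_lists <- function(ime_terms = character(),
                                 dme_terms = character()) {
  structure(list(ime_terms = as.character(ime_terms),
                 dme_terms = as.character(dme_terms)),
            class = "event_severity_lists")
}

#' Score IME/DME membership
#'
#' A term on both lists takes the higher score (maximal attribution).
#'
#' @param term PT name(s); matched case-insensitively.
#' @param lists an [event_severity_lists()].
#' @return integer score(s): DME -> 2, IME -> 1, neither -> 0.
#' @export
score_ime_dme <- function(term, lists) {
  tn <- norm_name(term)
  ifelse(tn %in% norm_name(lists$dme_terms), 2L,
         ifelse(tn %in% norm_name(lists$ime_terms), 1L, 0L))
}

#' Score biological plausibility from the novel-signal status
#' @param status status value(s) from [classify_signals()]: `known_insert`
#'   -> 2 (documented in the drug insert), `known_trial` -> 1 (reported in
#'   the pivotal trial), `novel` -> 0 (no clear prior documentation).
#' @return integer score(s).
#' @export
score_plausibility <- function(status) {
  map <- c(known_insert = 2L, known_trial = 1L, novel = 0L)
  out <- map[as.character(status)]
  if (anyNA(out))
    stop("plausibility is only scored for statuses novel/known_insert/known_trial")
  unname(out)
}

# total -> priority band
.priority_band <- function(total) {
  ifelse(total >= 8, "strong", ifelse(total >= 5, "moderate", "weak"))
}

#' Assess clinical priority of positive preferred terms
#'
#' Applies the five-dimension rubric to each positive signal and assigns the
#' weak/moderate/strong band from the total score.
#'
#' @param stats data.frame with columns `term`, `a`, `ror_ci_low` (e.g. the
#'   positive rows of a [run_screen()] PT-level result).
#' @param mortality numeric vector (recycled) of per-term mortality
#'   proportions, or `NULL` to compute them from `target_reports`.
#' @param lists an [event_severity_lists()].
#' @param status per-term plausibility status from [classify_signals()]
#'   (character vector aligned with `stats`, or a data.frame with `term`,
#'   `status`).
#' @param target_reports optional report data.frame used to compute the
#'   mortality proportion as (death-outcome target reports carrying the term)
#'   / (target reports carrying the term).
#' @return data.frame with columns `term`, `s_events`, `s_ror`,
#'   `s_mortality`, `s_ime_dme`, `s_plausibility`, `total`, `band`,
#'   `mortality_proportion`.
#' @export
assess_priority <- function(stats, mortality = NULL,
                            lists = event_severity_lists(), status,
                            target_reports = NULL) {
  if (is.data.frame(status))
    status <- status$status[match(norm_name(stats$term),
                                  norm_name(status$term))]
  if (is.null(mortality)) {
    if (is.null(target_reports))
      stop("supply either mortality proportions or target_reports")
    mortality <- vapply(stats$term, function(tm) {
      has <- vapply(target_reports$events,
                    function(e) norm_name(tm) %in% norm_name(e), logical(1))
      if (!any(has)) return(0)
      mean(target_reports$outcome[has] == "death")
    }, numeric(1))
  }
  mortality <- rep_len(mortality, nrow(stats))
  out <- data.frame(
    term = stats$term,
    s_events = score_events(stats$a),
    s_ror = score_ror_lower(stats$ror_ci_low),
    s_mortality = score_mortality(mortality),
    s_ime_dme = score_ime_dme(stats$term, lists),
    s_plausibility = score_plausibility(status),
    stringsAsFactors = FALSE)
  out$total <- out$s_events + out$s_ror + out$s_mortality + out$s_ime_dme +
    out$s_plausibility
  out$band <- .priority_band(out$total)
  out$mortality_proportion <- mortality
  out
}
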