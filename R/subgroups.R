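#' Subgroup specification for stratified screening
#'
#' Sex strata are female/male; age strata split at 45 years (ages in
#' [18, 45] form the younger stratum, strictly greater than 45 the older;
#' minors and unknown ages are excluded from both).
#'
#' @param dimension `"sex"` or `"age"`.
#' @return a `subgroup_spec` with named `strata` predicates.
#' @export
subgroup_spec <- function(dimension = c("sex", "age")) {
  dimension <- match.arg(dimension)
  strata <- switch(dimension,
    sex = list(female = function(r) r$sex == "female",
               male = function(r) r$sex == "male"),
    age = list(`18-45` = function(r) !is.na(r$age_years) &
                 r$age_years >= 18 & r$age_years <= 45,
               `>45` = function(r) !is.na(r$age_years) & r$age_years > 45))
  structure(list(dimension = dimension, strata = strata),
            class = "subgroup_spec")
}

#' Run the screen independently within each stratum
#'
#' Both the target and the comparator arm are restricted to the stratum, so
#' each stratum has its own margins and background. Reports falling in no
#' stratum (unknown sex, unknown age, minors) are excluded and counted.
#'
#' @param cohort list with `target` and `comparator` report data.frames
#'   (from [select_cohort()]).
#' @param spec a [subgroup_spec()].
#' @param pt_to_soc data.frame mapping `pt` to `soc`.
#' @param th a [threshold_config()].
#' @param levels screen levels (default PT only, matching how subgroup
#'   results are usually read).
#' @return list with per-stratum [run_screen()] data.frames (empty
#'   data.frame with a warning when a stratum has no target reports) and an
#'   `excluded` count of out-of-stratum reports.
#' @export
stratify_and_screen <- function(cohort, spec, pt_to_soc,
                                th = threshold_config(), levels = "PT") {
  in_any_t <- rep(FALSE, nrow(cohort$target))
  in_any_c <- rep(FALSE, nrow(cohort$comparator))
  out <- list()
  for (s in names(spec$strata)) {
    pred <- spec$strata[[s]]
    sel_t <- pred(cohort$target)
    sel_c <- pred(cohort$comparator)
    in_any_t <- in_any_t | sel_t
    in_any_c <- in_any_c | sel_c
    if (!any(sel_t)) {
      warning("stratum '", s, "' has no target reports; empty result")
      out[[s]] <- data.frame()
    } else {
      out[[s]] <- run_screen(cohort$target[sel_t, , drop = FALSE],
                             cohort$comparator[sel_c, , drop = FALSE],
                             pt_to_soc, th, levels = levels)
    }
  }
  out$excluded <- sum(!in_any_t) + sum(!in_any_c)
  out
}

#' Compare a shared positive term across two strata
#'
#' For terms flagged positive by both algorithms in both strata, the
#' cross-stratum contrast is the ratio of the stratum RORs; its confidence
#' interval combines the two Woolf log-variances,
#' `exp(log(ror_A/ror_B) +/- z sqrt(V_A + V_B))`. Swapping the strata
#' inverts the ratio.
#'
#' @param stats_a,stats_b [run_screen()] data.frames for the two strata.
#' @param labels length-2 character labels for the strata.
#' @param z normal quantile (default 1.959964).
#' @param require_positive restrict to terms flagged `positive_both` in both
#'   strata (default; the contrast is only interpreted for shared positive
#'   signals).
#' @return data.frame with one row per shared positive term: `term`,
#'   `ror_a`, `ror_b`, `ratio`, `ratio_ci_low`, `ratio_ci_high`,
#'   `higher_stratum`.
#' @export
compare_shared <- function(stats_a, stats_b, labels = c("A", "B"),
                           z = 1.959964, require_positive = TRUE) {
  pos_a <- if (require_positive)
    stats_a[stats_a$positive_both, , drop = FALSE] else stats_a
  pos_b <- if (require_positive)
    stats_b[stats_b$positive_both, , drop = FALSE] else stats_b
  shared <- intersect(norm_name(pos_a$term), norm_name(pos_b$term))
  ia <- match(shared, norm_name(pos_a$term))
  ib <- match(shared, norm_name(pos_b$term))
  a_ <- pos_a[ia, ]; b_ <- pos_b[ib, ]
  if (any(is.na(a_$ror) | is.na(b_$ror)))
    stop("undefined ROR in one stratum for a shared term")
  v <- function(s) 1 / s$a + 1 / s$b + 1 / s$c + 1 / s$d
  ratio <- a_$ror / b_$ror
  se <- sqrt(v(a_) + v(b_))
  out <- data.frame(term = a_$term,
                    ror_a = a_$ror, ror_b = b_$ror,
                    ratio = ratio,
                    ratio_ci_low = exp(log(ratio) - z * se),
                    ratio_ci_high = exp(log(ratio) + z * se),
                    higher_stratum = ifelse(ratio >= 1, labels[1], labels[2]),
                    stringsAsFactors = FALSE)
  names(out)[names(out) == "ror_a"] <- paste0("ror_", labels[1])
  names(out)[names(out) == "ror_b"] <- paste0("ror_", labels[2])
  rownames(out) <- NULL
  out
}
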