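#' Summarize cohort demographics
#'
#' Counts and percentages (count / total x 100, rounded half away from zero
#' to 2 decimals) by sex, age band (<18, 18-45, >45, unknown) and worst
#' outcome, with explicit Unknown categories.
#'
#' @param reports cohort report data.frame.
#' @return data.frame with columns `dimension`, `category`, `n`, `pct`
#'   (empty when the cohort is empty).
#' @export
summarize_demographics <- function(reports) {
  n <- nrow(reports)
  if (n == 0)
    return(data.frame(dimension = character(), category = character(),
                      n = integer(), pct = numeric()))
  age_band <- ifelse(is.na(reports$age_years), "unknown",
                     ifelse(reports$age_years < 18, "<18",
                            ifelse(reports$age_years <= 45, "18-45", ">45")))
  one <- function(dim, values, levels) {
    tab <- table(factor(values, levels = levels))
    tab <- tab[tab > 0 | names(tab) == "unknown"]
    data.frame(dimension = dim, category = names(tab), n = as.integer(tab),
               pct = round_half_away(100 * as.integer(tab) / n, 2),
               stringsAsFactors = FALSE)
  }
  out <- rbind(
    one("sex", reports$sex, c("female", "male", "unknown")),
    one("age", age_band, c("<18", "18-45", ">45", "unknown")),
    one("outcome", reports$outcome, rev(outcome_levels())))
  rownames(out) <- NULL
  out
}

# run one pipeline stage; on failure abort naming the stage and the
# record counts accumulated so far (the processing-funnel log)
.stage <- function(name, log, expr) {
  tryCatch(expr, error = function(e) {
    stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
         "\ncounts so far: ",
         paste(names(log), unlist(log), sep = "=", collapse = ", "),
         call. = FALSE)
  })
}

#' Run the end-to-end screening pipeline
#'
#' Parse quarters -> assemble -> optional date window -> deduplicate ->
#' select cohort -> disproportionality screen (SOC + PT) -> novel-signal
#' classification of the positive PTs -> clinical-priority rubric ->
#' subgroup screens -> demographic summary. All outputs are written as CSV
#' plus a JSON run manifest of the processing-funnel counts; identical
#' inputs give byte-identical outputs.
#'
#' @param config list with elements: `quarter_dirs` (character vector of
#'   quarter directories), `drug_synonyms` (character vector or file of the
#'   target-drug names), `indication_terms` (character vector or file;
#'   `NULL` keeps all reports), `pt_to_soc` (data.frame or CSV path with
#'   columns `pt`, `soc`), optional `thresholds` ([threshold_config()]),
#'   `exclusions` ([exclusion_lists()]), `severity`
#'   ([event_severity_lists()]), `date_window` (list with `from`/`to`
#'   YYYYMMDD integers), `subgroups` (character vector among `"sex"`,
#'   `"age"`), and `output_dir`.
#' @return invisibly, a list with the in-memory results (`cohort_summary`,
#'   `screen`, `novel`, `priority`, `subgroups`, `manifest`).
#' @export
run_pipeline <- function(config) {
  for (f in c("quarter_dirs", "drug_synonyms", "pt_to_soc", "output_dir"))
    if (is.null(config[[f]])) stop("pipeline config is missing '", f, "'")
  pt_to_soc <- config$pt_to_soc
  if (is.character(pt_to_soc))
    pt_to_soc <- utils::read.csv(pt_to_soc, stringsAsFactors = FALSE)
  syn <- config$drug_synonyms
  if (length(syn) == 1 && file.exists(syn)) syn <- read_term_file(syn)
  ind <- config$indication_terms
  if (!is.null(ind) && length(ind) == 1 && file.exists(ind))
    ind <- read_term_file(ind)
  th <- config$thresholds %||% threshold_config()
  ex <- config$exclusions %||% exclusion_lists()
  sev <- config$severity %||% event_severity_lists()
  log <- list()

  raw <- .stage("parse", log, {
    quarters <- lapply(config$quarter_dirs, parse_quarter)
    list(demo = do.call(rbind, lapply(quarters, `[[`, "demo")),
         drug = do.call(rbind, lapply(quarters, `[[`, "drug")),
         reac = do.call(rbind, lapply(quarters, `[[`, "reac")),
         outc = do.call(rbind, lapply(quarters, `[[`, "outc")),
         malformed = Reduce(`+`, lapply(quarters, `[[`, "malformed")))
  })
  log$rows_in <- nrow(raw$demo)
  log$malformed <- sum(raw$malformed)

  reports <- .stage("assemble", log, assemble_reports(raw))
  if (!is.null(config$date_window))
    reports <- .stage("date_window", log,
                      filter_date_window(reports, config$date_window$from,
                                         config$date_window$to))
  log$in_window <- nrow(reports)

  reports <- .stage("deduplicate", log, deduplicate(reports))
  log$deduplicated <- nrow(reports)

  cohort <- .stage("select_cohort", log,
                   select_cohort(reports, drug_query(syn), ind))
  log$cohort <- nrow(cohort$cohort)
  log$target_ps <- nrow(cohort$target)
  log$comparator <- nrow(cohort$comparator)

  screen <- .stage("screen", log,
                   run_screen(cohort$target, cohort$comparator, pt_to_soc, th))
  pos_pt <- screen[screen$level == "PT" & screen$positive_both, , drop = FALSE]
  log$positive_pt <- nrow(pos_pt)

  novel <- .stage("classify", log, classify_signals(pos_pt, ex))
  log$novel <- sum(novel$status == "novel")

  priority <- .stage("priority", log, {
    if (nrow(pos_pt) == 0) data.frame() else
      assess_priority(pos_pt, lists = sev, status = novel,
                      target_reports = cohort$target)
  })

  subgroups <- list()
  for (dim in config$subgroups %||% character()) {
    subgroups[[dim]] <- .stage(paste0("subgroup_", dim), log, {
      strata <- stratify_and_screen(cohort, subgroup_spec(dim), pt_to_soc, th)
      labs <- setdiff(names(strata), "excluded")
      cmp <- if (nrow(strata[[labs[1]]]) && nrow(strata[[labs[2]]]))
        compare_shared(strata[[labs[1]]], strata[[labs[2]]], labels = labs)
      else data.frame()
      c(strata, list(comparison = cmp))
    })
  }

  cohort_summary <- .stage("demographics", log,
                           summarize_demographics(cohort$target))

  dir.create(config$output_dir, recursive = TRUE, showWarnings = FALSE)
  w <- function(df, file)
    utils::write.csv(df, file.path(config$output_dir, file), row.names = FALSE)
  w(cohort_summary, "cohort_summary.csv")
  w(screen[screen$level == "SOC", ], "soc_signals.csv")
  w(screen[screen$level == "PT", ], "pt_signals.csv")
  w(novel, "novel_signals.csv")
  w(priority, "priority.csv")
  for (dim in names(subgroups)) {
    for (s in setdiff(names(subgroups[[dim]]), c("excluded", "comparison")))
      if (is.data.frame(subgroups[[dim]][[s]]) && nrow(subgroups[[dim]][[s]]))
        w(subgroups[[dim]][[s]], paste0("subgroup_", dim, "_",
                                        gsub("[^A-Za-z0-9-]", "", s), ".csv"))
    w(subgroups[[dim]]$comparison, paste0("subgroup_", dim, "_comparison.csv"))
  }
  manifest <- log
  jsonlite::write_json(manifest,
                       file.path(config$output_dir, "run_manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)

  invisible(list(cohort_summary = cohort_summary, screen = screen,
                 novel = novel, priority = priority, subgroups = subgroups,
                 manifest = manifest))
}

`%||%` <- function(x, y) if (is.null(x)) y else x
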