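#' @title Parsing, deduplication and cohort selection for FAERS-style data
#' @name faers_ingest
#' @description
#' Raw quarterly extracts arrive as four dollar-delimited ASCII tables:
#' DEMO (demographics and administrative keys), DRUG (drug mentions with
#' role codes and indication), REAC (adverse-event preferred terms) and OUTC
#' (outcome codes). `parse_quarter()` reads them, `assemble_reports()` joins
#' them into one row per report version, `deduplicate()` applies the
#' FDA-recommended versioning rules, and `select_cohort()` splits the
#' indication cohort into target and comparator reports.
NULL

# outcome severity, least to most severe; "unknown" is the floor
.outcome_levels <- c("unknown", "other_ime", "hospitalization",
                     "disability", "life_threatening", "death")
.outcome_codes <- c(DE = "death", LT = "life_threatening", DS = "disability",
                    HO = "hospitalization", OT = "other_ime")

#' Outcome severity levels, least to most severe
#' @return character vector of the ordered outcome classes.
#' @export
outcome_levels <- function() .outcome_levels

#' Most severe outcome of a report
#'
#' Reduces the outcome codes attached to one report to the single most severe
#' class under the precedence death > life-threatening > disability >
#' hospitalization > other important medical event > unknown. An empty code
#' list yields `"unknown"`.
#'
#' @param outcome_codes character vector of FAERS outcome codes (`DE`, `LT`,
#'   `DS`, `HO`, `OT`) or spelled-out class names; case-insensitive.
#' @return length-1 ordered factor over [outcome_levels()].
#' @examples
#' worst_outcome(c("HO", "DE"))  # death
#' @export
worst_outcome <- function(outcome_codes) {
  codes <- toupper(trimws(as.character(outcome_codes)))
  codes <- codes[nzchar(codes)]
  cls <- .outcome_codes[codes]
  named <- is.na(cls) & tolower(codes) %in% .outcome_levels
  cls[named] <- tolower(codes[named])
  if (anyNA(cls))
    stop("unrecognized outcome code(s): ",
         paste(unique(codes[is.na(cls)]), collapse = ", "))
  if (length(cls) == 0) cls <- "unknown"
  max(factor(cls, levels = .outcome_levels, ordered = TRUE))
}

#' Drug query by name synonyms
#'
#' Matching is case-insensitive exact match after whitespace normalization,
#' so a query for a generic name also catches brand and code names when they
#' are listed among `synonyms`.
#'
#' @param synonyms non-empty character vector of generic/brand/alternate names.
#' @return a `drug_query` object.
#' @export
drug_query <- function(synonyms) {
  synonyms <- unique(trimws(as.character(synonyms)))
  synonyms <- synonyms[nzchar(synonyms)]
  if (length(synonyms) == 0) stop("drug_query requires at least one synonym")
  structure(list(synonyms = synonyms, norm = norm_name(synonyms)),
            class = "drug_query")
}

# FAERS age units -> years
.age_unit_years <- c(YR = 1, DEC = 10, MON = 1 / 12, WK = 7 / 365.25,
                     DY = 1 / 365.25, HR = 1 / 8766)

# normalize an age value + unit code to years; unknown or implausible -> NA
normalize_age <- function(age, age_cod) {
  v <- suppressWarnings(as.numeric(age))
  mult <- .age_unit_years[toupper(trimws(age_cod))]
  mult[is.na(mult) & (is.na(age_cod) | !nzchar(trimws(age_cod)))] <- 1  # bare ages are years
  yrs <- v * mult
  yrs[!is.finite(yrs) | yrs < 0 | yrs > 120] <- NA_real_
  yrs
}

#' Parse a quarter directory of FAERS-style raw tables
#'
#' Locates the DEMO, DRUG, REAC and OUTC files (prefix match on the file
#' name, case-insensitive) and reads each through [read_faers_table()].
#' Malformed lines are counted per table, reported via warnings, and exposed
#' in the `malformed` element, never silently dropped.
#'
#' @param dir directory containing the four tables, or a named list/vector
#'   with elements `demo`, `drug`, `reac`, `outc` giving explicit paths.
#' @return list with data.frames `demo`, `drug`, `reac`, `outc` and an
#'   integer vector `malformed` of per-table malformed-line counts.
#' @export
parse_quarter <- function(dir) {
  req <- list(
    demo = c("primaryid", "caseid", "fda_dt", "sex", "age", "age_cod"),
    drug = c("primaryid", "caseid", "role_cod", "drugname", "indi_pt"),
    reac = c("primaryid", "caseid", "pt"),
    outc = c("primaryid", "caseid", "outc_cod"))
  paths <- if (is.character(dir) && length(dir) == 1 && dir.exists(dir)) {
    found <- lapply(names(req), function(tb) {
      hits <- list.files(dir, pattern = paste0("^", tb), ignore.case = TRUE,
                         full.names = TRUE)
      if (length(hits) == 0) stop("no ", toupper(tb), " table found in ", dir)
      hits[1]
    })
    names(found) <- names(req)
    found
  } else {
    as.list(dir)[names(req)]
  }
  tables <- lapply(names(req), function(tb)
    read_faers_table(paths[[tb]], required_cols = req[[tb]]))
  names(tables) <- names(req)
  tables$malformed <- vapply(tables[names(req)],
                             function(t) attr(t, "n_malformed"), integer(1))
  tables
}

#' Assemble parsed raw tables into one row per report version
#'
#' Joins DEMO, DRUG, REAC and OUTC on `primaryid`: demographics are taken
#' from DEMO, the distinct preferred terms from REAC become the `events`
#' list-column, drug mentions (name, role, indication) become the `drugs`
#' list-column, and the OUTC codes are reduced with [worst_outcome()]. Ages
#' are normalized to years ([0, 120]; anything else is unknown).
#'
#' @param raw list from [parse_quarter()].
#' @return report data.frame with columns `primaryid`, `caseid`, `fda_dt`
#'   (integer YYYYMMDD), `sex` (`female`/`male`/`unknown`), `age_years`
#'   (numeric, `NA` = unknown), `outcome`, and list-columns `drugs`, `events`.
#' @export
assemble_reports <- function(raw) {
  demo <- raw$demo
  ids <- demo$primaryid
  sex <- c(F = "female", M = "male")[toupper(trimws(demo$sex))]
  sex[is.na(sex)] <- "unknown"
  events <- split(raw$reac$pt, factor(raw$reac$primaryid, levels = ids))
  events <- lapply(events, function(e) unique(trimws(e)))
  drug_rows <- split(seq_len(nrow(raw$drug)),
                     factor(raw$drug$primaryid, levels = ids))
  drugs <- lapply(drug_rows, function(i)
    data.frame(name_as_reported = trimws(raw$drug$drugname[i]),
               role = toupper(trimws(raw$drug$role_cod[i])),
               indication = trimws(raw$drug$indi_pt[i]),
               stringsAsFactors = FALSE))
  outc <- split(raw$outc$outc_cod, factor(raw$outc$primaryid, levels = ids))
  outcome <- vapply(outc, function(o) as.character(worst_outcome(o)),
                    character(1))
  out <- data.frame(primaryid = ids, caseid = demo$caseid,
                    fda_dt = suppressWarnings(as.integer(demo$fda_dt)),
                    sex = unname(sex),
                    age_years = normalize_age(demo$age, demo$age_cod),
                    outcome = unname(outcome),
                    stringsAsFactors = FALSE)
  out$drugs <- unname(drugs)
  out$events <- unname(events)
  out
}

#' Restrict reports to a receipt-date window
#'
#' @param reports report data.frame.
#' @param from,to inclusive YYYYMMDD integer bounds (`NULL` = open).
#' @return filtered report data.frame.
#' @export
filter_date_window <- function(reports, from = NULL, to = NULL) {
  keep <- rep(TRUE, nrow(reports))
  if (!is.null(from)) keep <- keep & !is.na(reports$fda_dt) & reports$fda_dt >= from
  if (!is.null(to)) keep <- keep & !is.na(reports$fda_dt) & reports$fda_dt <= to
  reports[keep, , drop = FALSE]
}

#' Deduplicate report versions by case
#'
#' FAERS cases are re-submitted as new versions; the FDA-recommended rules
#' keep, per `caseid`, (i) the record with the most recent `fda_dt`, and
#' (ii) on ties, the record with the higher `primaryid`. The survivor is thus
#' the lexicographic maximum of `(fda_dt, primaryid)` and the result does not
#' depend on input order.
#'
#' @param reports report data.frame (one row per report version).
#' @return report data.frame with exactly one row per `caseid`, in `caseid`
#'   order.
#' @export
deduplicate <- function(reports) {
  if (nrow(reports) == 0) return(reports)
  pid <- suppressWarnings(as.numeric(reports$primaryid))
  if (anyNA(pid)) pid <- xtfrm(reports$primaryid)  # non-numeric ids: lexicographic
  o <- order(reports$caseid, reports$fda_dt, pid, na.last = FALSE)
  sorted <- reports[o, , drop = FALSE]
  out <- sorted[!duplicated(sorted$caseid, fromLast = TRUE), , drop = FALSE]
  rownames(out) <- NULL
  out
}

# does a report match the query among drug mentions with the given roles?
.matches_drug <- function(drugs, query, roles) {
  any(drugs$role %in% roles & norm_name(drugs$name_as_reported) %in% query$norm)
}

# does any drug mention carry an indication matching one of the terms?
.matches_indication <- function(drugs, terms_norm) {
  ind <- norm_name(drugs$indication)
  any(vapply(terms_norm, function(t) any(grepl(t, ind, fixed = TRUE)),
             logical(1)))
}

#' Select the analysis cohort and split it by target drug
#'
#' The cohort is every deduplicated report with at least one drug mention
#' whose indication matches one of `indication_terms` (case-insensitive
#' substring). Within the cohort, target reports carry the queried drug with
#' the primary-suspect role; all other cohort reports form the comparator.
#' Target and comparator partition the cohort. Reports listing several
#' primary-suspect drugs count as target if any of them matches (logged via
#' the `n_multi_ps` attribute).
#'
#' @param reports deduplicated report data.frame.
#' @param query a [drug_query()].
#' @param indication_terms character vector of indication search terms;
#'   `NULL` keeps every report in the cohort.
#' @param role_filter drug roles that qualify a report as target (default
#'   `"PS"`, primary suspect).
#' @return list with report data.frames `target`, `comparator`, `cohort`, and
#'   counts `n_noncohort`, `n_multi_ps`.
#' @export
select_cohort <- function(reports, query, indication_terms = NULL,
                          role_filter = "PS") {
  if (!inherits(query, "drug_query")) query <- drug_query(query)
  in_cohort <- if (is.null(indication_terms)) {
    rep(TRUE, nrow(reports))
  } else {
    tn <- norm_name(indication_terms)
    vapply(reports$drugs, .matches_indication, logical(1), terms_norm = tn)
  }
  cohort <- reports[in_cohort, , drop = FALSE]
  is_target <- vapply(cohort$drugs, .matches_drug, logical(1),
                      query = query, roles = role_filter)
  n_multi_ps <- sum(vapply(cohort$drugs, function(d)
    sum(d$role %in% role_filter & norm_name(d$name_as_reported) %in% query$norm) > 1,
    logical(1)))
  out <- list(target = cohort[is_target, , drop = FALSE],
              comparator = cohort[!is_target, , drop = FALSE],
              cohort = cohort,
              n_noncohort = sum(!in_cohort),
              n_multi_ps = n_multi_ps)
  out
}
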