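#' @title Synthetic FAERS-style report database with injected signals
#' @name synthetic_faers
#' @description
#' A seeded generator of DEMO/DRUG/REAC/OUTC raw tables shaped like FAERS
#' quarterly extracts, for one indication cohort. Each simulated case carries
#' a primary-suspect drug (target drug with probability `target_drug_share`,
#' otherwise a comparator drug), a zero-truncated-Poisson number of distinct
#' preferred terms, demographics with explicit "unknown" categories, and a
#' worst-outcome code. A configurable signal table inflates the reporting
#' rate of chosen drug-event pairs by a relative reporting ratio, giving a
#' known ground truth against which signal recovery can be measured.
NULL

# mean of a zero-truncated Poisson with rate lambda
.ztp_mean <- function(lambda) lambda / (1 - exp(-lambda))

# rate lambda such that the zero-truncated Poisson has the requested mean
.ztp_lambda <- function(mean) {
  if (mean < 1) stop("events_per_report mean must be >= 1")
  if (mean == 1) return(1e-8)
  stats::uniroot(function(l) .ztp_mean(l) - mean,
                 lower = 1e-8, upper = mean * 2 + 10, tol = 1e-10)$root
}

# n draws from a zero-truncated Poisson, capped at `cap` (dictionary size)
.rztpois <- function(n, lambda, cap) {
  out <- stats::qpois(stats::runif(n, stats::dpois(0, lambda), 1), lambda)
  pmin(pmax(out, 1L), cap)
}

#' Configuration for the synthetic report generator
#'
#' @param n_reports number of cases to simulate (> 0).
#' @param target_drug_share probability that a case's primary-suspect drug is
#'   the target drug.
#' @param pt_dictionary data.frame with columns `pt`, `soc`: the event
#'   vocabulary and its organ-class mapping.
#' @param baseline_pt_probs probability vector over the dictionary PTs (must
#'   sum to 1 within 1e-12) used for comparator reports.
#' @param signal_table data.frame with columns `pt`, `ratio`: drug-event
#'   pairs whose reporting rate under the target drug is multiplied by
#'   `ratio` (>= 0) before renormalization. Every listed PT must appear in
#'   the dictionary; unlisted PTs have ratio 1.
#' @param events_per_report mean of the zero-truncated Poisson number of
#'   distinct PTs per report (>= 1; default 3).
#' @param sex_probs named probabilities for `female`, `male`, `unknown`.
#' @param age_bands data.frame with columns `min`, `max`, `prob`; a case
#'   draws a band then a uniform age within it; a row with `NA` bounds is the
#'   explicit unknown-age category.
#' @param outcome_probs named probabilities over FAERS outcome codes `DE`,
#'   `LT`, `DS`, `HO`, `OT` plus `unknown` (no OUTC row emitted).
#' @param duplicate_rate probability that a case is emitted twice, as two
#'   versions sharing `caseid` but differing in `primaryid` and `fda_dt`.
#' @param target_synonyms names under which the target drug is reported
#'   (sampled uniformly per report).
#' @param comparator_drugs pool of comparator primary-suspect drug names.
#' @param indication indication text attached to the primary-suspect drug.
#' @param seed integer seed; the generator is fully deterministic given the
#'   configuration.
#' @return a validated `generator_config` list.
#' @export
generator_config <- function(n_reports = 2196,
                             target_drug_share = 504 / 2196,
                             pt_dictionary = default_pt_dictionary(),
                             baseline_pt_probs = NULL,
                             signal_table = NULL,
                             events_per_report = 3,
                             sex_probs = c(female = 0.435, male = 0.549,
                                           unknown = 0.016),
                             age_bands = default_age_bands(),
                             outcome_probs = c(HO = 0.026, OT = 0.062,
                                               unknown = 0.912),
                             duplicate_rate = 0.05,
                             target_synonyms = c("SPARSENTAN", "FILSPARI",
                                                 "RE-021"),
                             comparator_drugs = paste0("COMPDRUG",
                                                       sprintf("%02d", 1:20)),
                             indication = "IgA nephropathy",
                             seed = 20230101) {
  if (!is.numeric(n_reports) || n_reports < 1 || n_reports != round(n_reports))
    stop("n_reports must be a positive integer")
  stopifnot(target_drug_share >= 0, target_drug_share <= 1,
            duplicate_rate >= 0, duplicate_rate <= 1)
  if (is.null(baseline_pt_probs))
    baseline_pt_probs <- rep(1 / nrow(pt_dictionary), nrow(pt_dictionary))
  if (length(baseline_pt_probs) != nrow(pt_dictionary))
    stop("baseline_pt_probs must have one entry per dictionary PT")
  if (abs(sum(baseline_pt_probs) - 1) > 1e-12)
    stop("baseline_pt_probs must sum to 1 (within 1e-12)")
  if (is.null(signal_table))
    signal_table <- data.frame(pt = character(0), ratio = numeric(0))
  if (nrow(signal_table) > 0) {
    if (any(signal_table$ratio < 0)) stop("signal ratios must be >= 0")
    missing <- setdiff(norm_name(signal_table$pt), norm_name(pt_dictionary$pt))
    if (length(missing))
      stop("signal PT(s) not in pt_dictionary: ",
           paste(missing, collapse = ", "))
  }
  cfg <- list(n_reports = as.integer(n_reports),
              target_drug_share = target_drug_share,
              pt_dictionary = pt_dictionary,
              baseline_pt_probs = baseline_pt_probs,
              signal_table = signal_table,
              events_per_report = events_per_report,
              sex_probs = sex_probs / sum(sex_probs),
              age_bands = age_bands,
              outcome_probs = outcome_probs / sum(outcome_probs),
              duplicate_rate = duplicate_rate,
              target_synonyms = target_synonyms,
              comparator_drugs = comparator_drugs,
              indication = indication,
              seed = as.integer(seed))
  structure(cfg, class = "generator_config")
}

#' Default synthetic event vocabulary
#'
#' 250 generic preferred terms spread uniformly over 10 organ classes. With
#' uniform baseline probabilities (0.004 per PT) and ~3 events per report, a
#' cohort sized like a one-drug indication slice (~2,200 reports, ~23\%
#' target share) gives roughly 30 target reports per signal PT at a relative
#' reporting ratio of 5 -- the regime the screen is meant to detect.
#'
#' @return data.frame with columns `pt`, `soc`.
#' @export
default_pt_dictionary <- function() {
  n <- 250
  data.frame(pt = sprintf("Synthetic event %03d", seq_len(n)),
             soc = sprintf("Synthetic organ class %02d",
                           rep(seq_len(10), each = n / 10)),
             stringsAsFactors = FALSE)
}

#' Default age-band distribution
#'
#' Mirrors the demographic mix typical of an adult nephropathy cohort:
#' mostly 18-45 and >45, a sliver of minors, and a large explicit
#' unknown-age mass.
#'
#' @return data.frame with columns `min`, `max`, `prob`.
#' @export
default_age_bands <- function() {
  data.frame(min = c(2, 18, 46, NA),
             max = c(17, 45, 90, NA),
             prob = c(0.004, 0.333, 0.407, 0.256))
}

#' Generate raw FAERS-style tables with known signal structure
#'
#' Simulates `n_reports` cases. Comparator reports draw their distinct PTs
#' (without replacement within a report) proportionally to
#' `baseline_pt_probs`; target reports use `baseline_pt_probs * ratio`,
#' renormalized, where `ratio` comes from the signal table (1 for unlisted
#' PTs). A `duplicate_rate` fraction of cases is emitted twice with the same
#' `caseid` but a higher `primaryid` and a later-or-equal `fda_dt`, so that
#' deduplication keeps the intended final version.
#'
#' @param config a [generator_config()].
#' @return list with elements `tables` (data.frames `demo`, `drug`, `reac`,
#'   `outc`) and `truth` (list: data.frame `signals` with `pt`, `soc`,
#'   `ratio` for every dictionary PT, and data.frame `cases` with `caseid`,
#'   `is_target`, `duplicated`).
#' @export
generate_raw_tables <- function(config) {
  stopifnot(inherits(config, "generator_config"))
  set.seed(config$seed)
  n <- config$n_reports
  pts <- config$pt_dictionary$pt
  base <- config$baseline_pt_probs
  ratio <- rep(1, length(pts))
  if (nrow(config$signal_table) > 0) {
    idx <- match(norm_name(config$signal_table$pt), norm_name(pts))
    ratio[idx] <- config$signal_table$ratio
  }
  target_w <- base * ratio
  if (sum(target_w) <= 0) stop("signal ratios annihilate every PT probability")

  caseid <- sprintf("9%07d", seq_len(n))
  is_target <- stats::runif(n) < config$target_drug_share
  lambda <- .ztp_lambda(config$events_per_report)
  n_events <- .rztpois(n, lambda, cap = length(pts))
  events <- lapply(seq_len(n), function(i)
    pts[sample.int(length(pts), n_events[i],
                   prob = if (is_target[i]) target_w else base)])
  sex <- sample(c("F", "M", ""), n, replace = TRUE, prob = config$sex_probs)
  band <- sample.int(nrow(config$age_bands), n, replace = TRUE,
                     prob = config$age_bands$prob)
  age <- rep(NA_real_, n)
  known <- !is.na(config$age_bands$min[band])
  age[known] <- round(stats::runif(sum(known),
                                   config$age_bands$min[band][known],
                                   config$age_bands$max[band][known]))
  outc_cod <- sample(names(config$outcome_probs), n, replace = TRUE,
                     prob = config$outcome_probs)
  days_2023 <- seq(as.Date("2023-01-01"), as.Date("2023-11-30"), by = "day")
  recv_date <- sample(days_2023, n, replace = TRUE)
  drugname <- ifelse(is_target,
                     sample(config$target_synonyms, n, replace = TRUE),
                     sample(config$comparator_drugs, n, replace = TRUE))

  dup <- stats::runif(n) < config$duplicate_rate
  # emit the superseded version first: same caseid, lower primaryid and
  # earlier-or-equal fda_dt, so the second (intended) version must survive
  version <- c(rep(1L, n), rep(2L, sum(dup)))
  ridx <- c(seq_len(n), which(dup))
  primaryid <- paste0(caseid[ridx], version)
  date <- recv_date[ridx]
  date[version == 2L] <- date[version == 2L] +
    sample(0:30, sum(version == 2L), replace = TRUE)
  fda <- as.integer(format(date, "%Y%m%d"))

  demo <- data.frame(primaryid = primaryid, caseid = caseid[ridx],
                     fda_dt = fda, sex = sex[ridx],
                     age = ifelse(is.na(age[ridx]), "", age[ridx]),
                     age_cod = ifelse(is.na(age[ridx]), "", "YR"),
                     stringsAsFactors = FALSE)
  drug <- data.frame(primaryid = primaryid, caseid = caseid[ridx],
                     drug_seq = 1L, role_cod = "PS",
                     drugname = drugname[ridx],
                     indi_pt = config$indication, stringsAsFactors = FALSE)
  nev <- n_events[ridx]
  reac <- data.frame(primaryid = rep(primaryid, nev),
                     caseid = rep(caseid[ridx], nev),
                     pt = unlist(events[ridx], use.names = FALSE),
                     stringsAsFactors = FALSE)
  has_outc <- outc_cod[ridx] != "unknown"
  outc <- data.frame(primaryid = primaryid[has_outc],
                     caseid = caseid[ridx][has_outc],
                     outc_cod = outc_cod[ridx][has_outc],
                     stringsAsFactors = FALSE)

  truth <- list(
    signals = data.frame(pt = pts, soc = config$pt_dictionary$soc,
                         ratio = ratio, stringsAsFactors = FALSE),
    cases = data.frame(caseid = caseid, is_target = is_target,
                       duplicated = dup, stringsAsFactors = FALSE))
  list(tables = list(demo = demo, drug = drug, reac = reac, outc = outc),
       truth = truth)
}

#' Write generated tables as a FAERS-style quarter directory
#'
#' Serializes the four tables in the dollar-delimited dialect (fields
#' containing `$` are rejected, the dialect has no escape) plus the ground
#' truth as `truth_signals.csv`. The files round-trip through
#' [parse_quarter()].
#'
#' @param generated list from [generate_raw_tables()].
#' @param dir output directory (created if needed).
#' @return named character vector of the written file paths, invisibly.
#' @export
write_quarter <- function(generated, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  if (!dir.exists(dir)) stop("unwritable output directory: ", dir)
  paths <- c(demo = file.path(dir, "demo.txt"),
             drug = file.path(dir, "drug.txt"),
             reac = file.path(dir, "reac.txt"),
             outc = file.path(dir, "outc.txt"))
  for (tb in names(paths)) write_faers_table(generated$tables[[tb]], paths[tb])
  truth_path <- file.path(dir, "truth_signals.csv")
  utils::write.csv(generated$truth$signals, truth_path, row.names = FALSE)
  invisible(c(paths, truth = truth_path))
}
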