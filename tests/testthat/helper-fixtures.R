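# Shared fixtures: published reference tables and hand-built report sets.

ref_path <- function(file) system.file("extdata", file, package = "pvscreen")

# reference tables keep the printed statistics as strings so tests can
# compare at each cell's printed precision
read_reference <- function(file) {
  read.csv(ref_path(file), colClasses = "character", check.names = FALSE)
}

soc_reference <- function() {
  ref <- read_reference("soc_signal_reference.csv")
  for (col in c("a", "b", "c", "d")) ref[[col]] <- as.integer(ref[[col]])
  ref
}

pt_reference <- function() {
  ref <- read_reference("pt_signal_reference.csv")
  for (col in c("a", "b", "c", "d")) ref[[col]] <- as.integer(ref[[col]])
  ref
}

# number of printed decimal places of each value string
printed_decimals <- function(x) {
  ifelse(grepl(".", x, fixed = TRUE), nchar(sub(".*\\.", "", x)), 0L)
}

# TRUE where `computed`, rounded to the printed precision, agrees with the
# printed value to within `ulp` units in the last printed digit
matches_printed <- function(computed, printed, ulp = 0) {
  nd <- printed_decimals(printed)
  got <- mapply(round_half_away, computed, nd)
  abs(got - as.numeric(printed)) <= ulp * 10^(-nd) + 1e-9
}

# one report-version row in the internal representation
make_report <- function(caseid, primaryid = paste0(caseid, "1"),
                        fda_dt = 20230601L, sex = "female", age_years = 40,
                        outcome = "unknown", events = "Headache",
                        drug = "SPARSENTAN", role = "PS",
                        indication = "IgA nephropathy") {
  df <- data.frame(primaryid = as.character(primaryid),
                   caseid = as.character(caseid), fda_dt = as.integer(fda_dt),
                   sex = sex, age_years = age_years, outcome = outcome,
                   stringsAsFactors = FALSE)
  df$drugs <- list(data.frame(name_as_reported = drug, role = role,
                              indication = indication,
                              stringsAsFactors = FALSE))
  df$events <- list(unique(events))
  df
}

bind_reports <- function(...) do.call(rbind, list(...))

# a deterministic cohort of n reports: k of them target (PS drug matches),
# the rest comparator, all sharing the indication
make_cohort_reports <- function(n, k, target_events = list("Dizziness"),
                                comparator_events = list("Headache")) {
  rows <- lapply(seq_len(n), function(i) {
    tgt <- i <= k
    make_report(caseid = sprintf("C%05d", i),
                drug = if (tgt) "SPARSENTAN" else "OTHERDRUG",
                events = if (tgt)
                  target_events[[(i - 1) %% length(target_events) + 1]]
                else comparator_events[[(i - 1) %% length(comparator_events) + 1]])
  })
  do.call(rbind, rows)
}

toy_pt_soc <- function() {
  data.frame(pt = c("Dizziness", "Somnolence", "Headache", "Nausea"),
             soc = c("Nervous system disorders", "Nervous system disorders",
                     "Nervous system disorders", "Gastrointestinal disorders"),
             stringsAsFactors = FALSE)
}

# a small generator config sized for fast unit tests
small_config <- function(seed = 7, ...) {
  generator_config(n_reports = 400, seed = seed, ...)
}
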