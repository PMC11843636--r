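write_dialect <- function(lines, file = tempfile(fileext = ".txt")) {
  writeLines(lines, file)
  file
}

test_that("header-only files parse to zero records", {
  f <- write_dialect("primaryid$caseid$pt")
  tab <- read_faers_table(f, required_cols = c("primaryid", "caseid", "pt"))
  expect_equal(nrow(tab), 0)
  expect_equal(attr(tab, "n_malformed"), 0)
})

test_that("malformed lines are counted and warned about, not silently dropped", {
  lines <- c("primaryid$caseid$pt",
             sprintf("%d$C%d$Headache", 1:99, 1:99),
             "100$C100")  # one field short
  f <- write_dialect(lines)
  expect_warning(tab <- read_faers_table(f, c("primaryid", "caseid", "pt")),
                 "malformed")
  expect_equal(nrow(tab), 99)
  expect_equal(attr(tab, "n_malformed"), 1)
})

test_that("a missing mandatory column is an error naming the column", {
  f <- write_dialect("primaryid$caseid")
  expect_error(read_faers_table(f, c("primaryid", "caseid", "pt")), "pt")
})

test_that("the dialect rejects fields containing the delimiter at write time", {
  df <- data.frame(primaryid = "1", drugname = "BAD$NAME")
  expect_error(write_faers_table(df, tempfile()), "\\$")
})

test_that("generated quarters round-trip through parse and re-serialization", {
  gen <- generate_raw_tables(small_config())
  dir <- file.path(tempdir(), "rt-quarter")
  paths <- write_quarter(gen, dir)
  raw <- parse_quarter(dir)
  for (tb in c("demo", "drug", "reac", "outc")) {
    expect_equal(nrow(raw[[tb]]), nrow(gen$tables[[tb]]))
    # re-serializing the parsed fields reproduces the files byte for byte
    f2 <- tempfile()
    write_faers_table(raw[[tb]], f2)
    expect_identical(readBin(f2, "raw", file.size(f2)),
                     readBin(paths[[tb]], "raw", file.size(paths[[tb]])))
  }
})

test_that("worst_outcome follows the severity precedence", {
  expect_equal(as.character(worst_outcome(c("HO", "DE"))), "death")
  expect_equal(as.character(worst_outcome(c("OT", "HO"))), "hospitalization")
  expect_equal(as.character(worst_outcome(c("LT", "DS"))), "life_threatening")
  expect_equal(as.character(worst_outcome(character())), "unknown")
  expect_equal(as.character(worst_outcome(c("disability", "OT"))), "disability")
  expect_error(worst_outcome("XX"), "XX")
})

test_that("deduplication keeps the most recent date, then the higher version id", {
  r <- bind_reports(
    make_report("C1", primaryid = "11", fda_dt = 20230105),
    make_report("C1", primaryid = "10", fda_dt = 20230301),
    make_report("C2", primaryid = "10", fda_dt = 20230601),
    make_report("C2", primaryid = "12", fda_dt = 20230601))
  dd <- deduplicate(r)
  expect_equal(nrow(dd), 2)
  expect_equal(dd$primaryid[dd$caseid == "C1"], "10")  # rule (i): later date
  expect_equal(dd$primaryid[dd$caseid == "C2"], "12")  # rule (ii): higher id
})

test_that("deduplication is order-invariant and idempotent", {
  set.seed(5)
  rows <- lapply(1:60, function(i)
    make_report(caseid = sprintf("C%02d", (i - 1) %% 20 + 1),
                primaryid = sprintf("%03d", i),
                fda_dt = 20230100 + sample(1:28, 1)))
  r <- do.call(rbind, rows)
  base <- deduplicate(r)
  for (k in 1:5) {
    perm <- r[sample(nrow(r)), , drop = FALSE]
    expect_equal(deduplicate(perm), base)
  }
  expect_equal(deduplicate(base), base)
})

test_that("cohort selection filters on primary-suspect role and partitions the cohort", {
  r <- bind_reports(
    make_report("C1", drug = "SPARSENTAN", role = "SS"),   # SS only: not target
    make_report("C2", drug = "FILSPARI", role = "PS"),     # case-variant brand
    make_report("C3", drug = "OTHERDRUG", role = "PS"),
    make_report("C4", drug = "sparsentan ", role = "PS"),  # whitespace
    make_report("C5", drug = "SPARSENTAN", role = "PS",
                indication = "hypertension"))              # other indication
  q <- drug_query(c("sparsentan", "Filspari", "RE-021"))
  sel <- select_cohort(r, q, indication_terms = c("IgA nephropathy",
                                                  "immunoglobulin A nephropathy"))
  expect_setequal(sel$target$caseid, c("C2", "C4"))
  expect_setequal(sel$comparator$caseid, c("C1", "C3"))
  expect_equal(sel$n_noncohort, 1)
  expect_equal(nrow(sel$target) + nrow(sel$comparator), nrow(sel$cohort))
})

test_that("a fixture built to the study's funnel yields 504 target of 2196 cohort reports", {
  r <- make_cohort_reports(2196, 504)
  sel <- select_cohort(r, drug_query("sparsentan"), "IgA nephropathy")
  expect_equal(nrow(sel$target), 504)
  expect_equal(nrow(sel$comparator), 2196 - 504)
})

test_that("ages are normalized to years and implausible values become unknown", {
  raw <- list(
    demo = data.frame(primaryid = as.character(1:5), caseid = as.character(1:5),
                      fda_dt = "20230601", sex = c("F", "M", "", "F", "M"),
                      age = c("40", "480", "200", "30", "6"),
                      age_cod = c("YR", "MON", "YR", "", "DEC"),
                      stringsAsFactors = FALSE),
    drug = data.frame(primaryid = "1", caseid = "1", role_cod = "PS",
                      drugname = "X", indi_pt = "Y", stringsAsFactors = FALSE),
    reac = data.frame(primaryid = "1", caseid = "1", pt = "Headache",
                      stringsAsFactors = FALSE),
    outc = data.frame(primaryid = "1", caseid = "1", outc_cod = "HO",
                      stringsAsFactors = FALSE))
  rep <- assemble_reports(raw)
  expect_equal(rep$age_years, c(40, 40, NA, 30, 60))
  expect_equal(rep$sex, c("female", "male", "unknown", "female", "male"))
  expect_equal(rep$outcome[1], "hospitalization")
  expect_equal(rep$outcome[2], "unknown")     # no OUTC row
  expect_equal(rep$events[[2]], character(0)) # no REAC row
})

test_that("date-window filtering keeps inclusive bounds", {
  r <- bind_reports(make_report("C1", fda_dt = 20221231),
                    make_report("C2", fda_dt = 20230101),
                    make_report("C3", fda_dt = 20231231),
                    make_report("C4", fda_dt = 20240101))
  w <- filter_date_window(r, 20230101, 20231231)
  expect_setequal(w$caseid, c("C2", "C3"))
})
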