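test_that("ROR and PRR reproduce the published reference rows at printed precision", {
  for (ref in list(soc_reference(), pt_reference())) {
    est <- cbind(ror_with_ci(ref$a, ref$b, ref$c, ref$d),
                 prr_with_chi2(ref$a, ref$b, ref$c, ref$d))
    for (col in c("ror", "ror_ci_low", "prr", "chi2"))
      expect_true(all(matches_printed(est[[col]], ref[[col]])),
                  label = paste("exact printed-precision match for", col))
    # upper CI bounds carry one-unit last-digit jitter from the source's own
    # display rounding (z = 1.96 vs the exact normal quantile)
    expect_true(all(matches_printed(est$ror_ci_high, ref$ror_ci_high, ulp = 1)))
  }
})

test_that("a balanced table is the null: ROR 1 with log-symmetric CI, PRR 1, chi2 0", {
  est <- ror_with_ci(10, 10, 10, 10)
  expect_equal(est$ror, 1)
  expect_equal(log(est$ror_ci_low), -log(est$ror_ci_high))
  pc <- prr_with_chi2(10, 10, 10, 10)
  expect_equal(pc$prr, 1)
  expect_equal(pc$chi2, 0)
})

test_that("zero cells give explicit NA, never NaN/Inf, and are never flagged", {
  est <- cbind(ror_with_ci(c(0, 5, 5), c(5, 0, 5), c(5, 5, 0), 5),
               prr_with_chi2(c(0, 5, 5), c(5, 0, 5), c(5, 5, 0), 5))
  expect_false(any(is.nan(unlist(est))))
  expect_false(any(is.infinite(unlist(est))))
  expect_true(is.na(est$ror[2]))      # b = 0
  expect_true(is.na(est$ror[3]))      # c = 0
  expect_true(all(is.na(est$ror_ci_low)))
  flagged <- flag_signal(cbind(a = c(0, 5, 5), est))
  expect_false(any(flagged$positive_both))
})

test_that("chi-squared agrees with independent oracles", {
  # brute-force Pearson sum over the four cells
  brute_chi2 <- function(a, b, c, d) {
    o <- c(a, b, c, d); n <- sum(o)
    e <- c((a + b) * (a + c), (a + b) * (b + d),
           (c + d) * (a + c), (c + d) * (b + d)) / n
    sum((o - e)^2 / e)
  }
  set.seed(11)
  tabs <- matrix(sample(1:500, 4 * 500, replace = TRUE), ncol = 4)
  got <- prr_with_chi2(tabs[, 1], tabs[, 2], tabs[, 3], tabs[, 4])$chi2
  want <- apply(tabs, 1, function(r) brute_chi2(r[1], r[2], r[3], r[4]))
  expect_equal(got, want, tolerance = 1e-12)
  # stats::chisq.test without continuity correction on a few tables
  for (i in 1:5) {
    m <- matrix(tabs[i, ], 2, byrow = TRUE)
    expect_equal(got[i],
                 unname(chisq.test(m, correct = FALSE)$statistic),
                 tolerance = 1e-9)
  }
})

test_that("ROR and PRR increase strictly in a with b, c, d held fixed", {
  a <- 1:50
  r <- ror_with_ci(a, 1000, 20, 5000)$ror
  p <- prr_with_chi2(a, 1000, 20, 5000)$prr
  expect_true(all(diff(r) > 0))
  expect_true(all(diff(p) > 0))
})

test_that("ROR and PRR nearly coincide for rare events in the reference rows", {
  ref <- rbind(pt_reference()[c("a", "b", "c", "d")],
               soc_reference()[c("a", "b", "c", "d")])
  rare <- ref$a / (ref$a + ref$b) < 0.05
  est <- cbind(ror_with_ci(ref$a, ref$b, ref$c, ref$d),
               prr_with_chi2(ref$a, ref$b, ref$c, ref$d))
  expect_true(all(abs(est$ror[rare] - est$prr[rare]) / est$prr[rare] < 0.05))
})

test_that("term_pairs uses distinct-count semantics at PT and SOC level", {
  r <- make_report("C1", events = c("Dizziness", "Somnolence"))
  pt <- term_pairs(r, level = "PT")
  expect_equal(sum(pt$n), 2)
  soc <- term_pairs(r, toy_pt_soc(), level = "SOC")
  expect_equal(soc$term, "Nervous system disorders")
  expect_equal(soc$n, 1)           # two PTs in one SOC collapse to one pair
  expect_equal(attr(soc, "margin"), 1)
})

test_that("unmapped PTs fall under the sentinel term and are counted", {
  r <- make_report("C1", events = c("Dizziness", "Mystery event"))
  soc <- term_pairs(r, toy_pt_soc(), level = "SOC")
  expect_true("Unmapped SOC" %in% soc$term)
  expect_equal(attr(soc, "n_unmapped"), 1)
})

test_that("margins are constant across terms and invariant to report order", {
  set.seed(3)
  gen <- generate_raw_tables(small_config())
  reports <- deduplicate(assemble_reports(gen$tables))
  cohort <- select_cohort(reports, drug_query("sparsentan"), NULL)
  map <- gen$truth$signals[, c("pt", "soc")]
  scr <- run_screen(cohort$target, cohort$comparator, map)
  for (lv in c("PT", "SOC")) {
    sub <- scr[scr$level == lv, ]
    expect_length(unique(sub$a + sub$b), 1)
    expect_length(unique(sub$c + sub$d), 1)
  }
  perm <- sample(nrow(cohort$target))
  scr2 <- run_screen(cohort$target[perm, ], cohort$comparator, map)
  expect_equal(scr2, scr)
})

test_that("published SOC flag pattern is reproduced: 2 dual-positive, 3 ROR-only", {
  ref <- soc_reference()
  est <- cbind(ref[c("soc", "a", "b", "c", "d")],
               ror_with_ci(ref$a, ref$b, ref$c, ref$d),
               prr_with_chi2(ref$a, ref$b, ref$c, ref$d))
  est <- flag_signal(est)
  expect_equal(est$soc[est$positive_both],
               c("Nervous system disorders", "Ear and labyrinth disorders"))
  expect_equal(est$soc[est$ror_positive & !est$prr_positive],
               c("General disorders and administration site conditions",
                 "Gastrointestinal disorders",
                 "Respiratory, thoracic and mediastinal disorders"))
  expect_equal(est$positive_both, ref$flag == "both")
  expect_equal(est$ror_positive & !est$prr_positive, ref$flag == "ror_only")
  expect_false(any((est$ror_positive | est$prr_positive)[ref$flag == "none"]))
})

test_that("the minimum-count rule suppresses huge but tiny-count RORs", {
  st <- cbind(data.frame(a = 2), ror_with_ci(2, 100, 1, 10000),
              prr_with_chi2(2, 100, 1, 10000))
  flagged <- flag_signal(st)
  expect_gt(flagged$ror, 50)
  expect_false(flagged$ror_positive)
  expect_false(flagged$prr_positive)
})

test_that("run_screen output is ordered by level then descending a, ties alphabetical", {
  r1 <- make_report("C1", events = c("Dizziness", "Nausea"))
  r2 <- make_report("C2", events = "Dizziness")
  r3 <- make_report("C3", drug = "OTHERDRUG", events = "Headache")
  scr <- run_screen(bind_reports(r1, r2), r3, toy_pt_soc())
  pt <- scr[scr$level == "PT", ]
  expect_equal(pt$term, c("Dizziness", "Nausea"))
  expect_true(all(diff(pt$a) <= 0))
  soc <- scr[scr$level == "SOC", ]
  expect_equal(soc$term, c("Nervous system disorders",
                           "Gastrointestinal disorders"))
})
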