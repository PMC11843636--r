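# pvscreen

Disproportionality signal detection for spontaneous adverse-event (AE)
report databases, for pharmacovigilance analysts and methodologists. The
package takes FAERS-style quarterly raw tables (DEMO / DRUG / REAC / OUTC,
dollar-delimited ASCII), deduplicates case versions the way the FDA
recommends, selects a primary-suspect cohort for one target drug within one
indication, and screens every reported MedDRA preferred term (PT) and
system organ class (SOC) for disproportionate reporting. Positive signals
are then filtered to *novel* signals against exclusion lists, scored on a
five-dimension clinical-priority rubric, and re-screened within sex and age
subgroups. A seeded synthetic report-database generator with injected
drug-event signals makes the whole chain testable without downloading
FAERS.

## The statistics

For each term, reports are counted as (report, distinct term) pairs into a
2×2 table — `a` target pairs with the term, `b` without, `c`/`d` the same
for the comparator (all other drugs in the indication cohort):

- **ROR** (reporting odds ratio) = `ad / bc`, with Woolf 95% CI
  `exp(ln ROR ± 1.959964 · sqrt(1/a + 1/b + 1/c + 1/d))`
- **PRR** (proportional reporting ratio) = `[a/(a+b)] / [c/(c+d)]`, with
  Pearson χ² (no continuity correction)

A term is a positive signal when `a ≥ 3`, the ROR CI lower bound exceeds 1,
`PRR ≥ 2`, and `χ² ≥ 4` (all thresholds configurable). Positive PTs are
scored 0/1/2 on event count, ROR lower bound, mortality proportion,
EMA IME/DME membership, and biological plausibility; totals of 0–4 / 5–7 /
8–10 map to weak / moderate / strong clinical priority.

## Worked example

One positive signal from the packaged reference tables — hypotension under
sparsentan in the IgA-nephropathy cohort, table `a=30, b=1493, c=8, d=5180`:

```r
library(pvscreen)
round_half_away(as.matrix(cbind(ror_with_ci(30, 1493, 8, 5180),
                                prr_with_chi2(30, 1493, 8, 5180))), 2)
#>        ror ror_ci_low ror_ci_high   prr  chi2
#> [1,] 13.01       5.95       28.44 12.77 68.93
```

Hypotension is reported 13 times more often (as odds) with the target drug
than with other drugs in the same cohort; the CI excludes 1 and the Evans
criteria are met, so both algorithms flag it. With 30 target events (score
1), CI lower bound 5.95 (> 5, score 2), no deaths (0), no IME/DME (0) and
drug-insert plausibility (2), its priority total is 5 — moderate.

End to end on synthetic data with one injected signal (relative reporting
ratio 5 on one PT):

```r
cfg <- generator_config(seed = 11,
                        signal_table = data.frame(pt = "Synthetic event 042",
                                                  ratio = 5))
qd <- tempfile()
write_quarter(generate_raw_tables(cfg), qd)
res <- run_pipeline(list(quarter_dirs = qd,
                         drug_synonyms = c("sparsentan", "Filspari", "RE-021"),
                         indication_terms = "IgA nephropathy",
                         pt_to_soc = cfg$pt_dictionary,
                         subgroups = "sex", output_dir = tempfile()))
unlist(res$manifest)
#>      rows_in    malformed    in_window deduplicated       cohort    target_ps
#>         2302            0         2302         2196         2196          506
#>   comparator  positive_pt        novel
#>         1690            8            8

head(res$screen[res$screen$level == "PT" & res$screen$positive_both,
                c("term", "a", "c", "ror", "prr", "chi2")], 3)
#>                  term  a  c  ror  prr  chi2
#>   Synthetic event 042 22 21 3.60 3.56 19.96
#>   Synthetic event 101 12 16 2.56 2.55  6.50
#>   Synthetic event 179 12 16 2.56 2.55  6.50
```

The funnel shows 2,302 raw report versions collapsing to 2,196 unique cases
(106 intended duplicates removed), 506 of them target reports. The injected
PT tops the positive list; the other positives are the multiplicity
background a 250-term screen produces at these thresholds — the screen
applies no multiple-testing correction, by design, and the companion
exclusion lists are how real analyses prune such terms.

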