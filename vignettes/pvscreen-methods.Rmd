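---
title: "Disproportionality screening of spontaneous adverse-event reports"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Disproportionality screening of spontaneous adverse-event reports}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pvscreen)
```

## The problem

Spontaneous adverse-event (AE) reporting systems such as FAERS collect
voluntary reports linking drugs to medical events coded as MedDRA preferred
terms (PTs). Because there is no denominator of exposed patients, risk cannot
be estimated directly; instead, *disproportionality analysis* asks whether a
drug-event pair is reported more often than the database background would
predict. pvscreen implements this screen end to end for a single target drug
within one indication cohort — the worked case shipped with the package is
sparsentan, a dual endothelin/angiotensin-II receptor antagonist used in IgA
nephropathy (IgAN) — together with the report-level preprocessing that the
raw quarterly extracts require and a synthetic report-database generator
used to validate the whole chain.

## Report preprocessing

FAERS quarters arrive as dollar-delimited ASCII tables. The dialect has no
quoting or escape mechanism, so the writer rejects any field containing `$`
rather than emit a file that cannot be parsed back; the reader counts lines
with a wrong field count as malformed and reports them instead of silently
dropping them.

Cases are re-submitted as new versions, so the same `caseid` can appear
several times. Deduplication keeps, per case, the version with the most
recent receipt date (`fda_dt`) and, on ties, the larger `primaryid` — i.e.
the lexicographic maximum of `(fda_dt, primaryid)`. This rule makes the
result independent of input order and idempotent, both of which are tested
by permutation.

Cohort selection is two-staged: the *indication cohort* is every report with
at least one drug mention whose indication text matches a configurable term
list (default `"IgA nephropathy"`, `"immunoglobulin A nephropathy"`;
case-insensitive substring, because indication fields are free-ish text);
*target* reports are cohort members naming the target drug — matched
case-insensitively against a synonym list covering generic, brand and code
names — with the primary-suspect (PS) role. The remaining cohort reports
form the comparator. Restricting the comparator to the same indication
cohort (rather than the whole database) is deliberate: it controls for
disease-related events, and it is the configuration under which the packaged
reference tables (fixed margins 1,523 / 5,188 across every term) are
internally consistent. Reports with several matching PS entries (data
errors) count once as target and are tallied separately.

Each report's outcome codes are reduced to the single most severe class
under death > life-threatening > disability > hospitalization > other
important medical event > unknown. Ages are normalized to years from the
FAERS unit codes (YR/DEC/MON/WK/DY/HR); values outside [0, 120] become
unknown.

## The screen

The counting unit is the (report, distinct term) pair. At PT level a report
contributes one pair per distinct PT; at SOC level, one pair per distinct
organ class after mapping (two PTs of one report within a SOC collapse to
one pair). For each term the 2x2 table is

|              | term | other terms |
|--------------|------|-------------|
| target       | a    | b           |
| comparator   | c    | d           |

with `a + b` and `c + d` the level margins, identical across terms. The two
estimators are

$$\mathrm{ROR} = \frac{ad}{bc},\qquad
\mathrm{CI}_{95} = \exp\!\left(\ln \mathrm{ROR} \pm z\sqrt{\tfrac1a+\tfrac1b+\tfrac1c+\tfrac1d}\right)$$

with $z = 1.959964$, and

$$\mathrm{PRR} = \frac{a/(a+b)}{c/(c+d)},\qquad
\chi^2 = \frac{N(ad-bc)^2}{(a+b)(c+d)(a+c)(b+d)},\; N = a+b+c+d.$$

No continuity correction and no zero-cell (Haldane 0.5) correction is
applied: the packaged reference rows reproduce at printed precision only
without them, which settles the choice. Zero cells yield an explicit `NA`
("undefined"), never `NaN`, and an undefined statistic never satisfies a
threshold. In the rare-event limit ($a \ll a+b$, $c \ll c+d$) ROR and PRR
nearly coincide; the test suite checks this on all reference rows with
target reporting fraction below 5%.

A term is **ROR-positive** when $a \ge 3$ and the CI lower bound exceeds 1,
**PRR-positive** (Evans criteria) when $a \ge 3$, $\mathrm{PRR} \ge 2$ and
$\chi^2 \ge 4$, and a **positive signal** when both hold. These defaults are
configurable (`threshold_config()`); they reproduce the published flag
pattern of the reference SOC table exactly (2 dual-positive rows, 3
ROR-only rows).

One display note: the reference tables' ROR CI *upper* bounds carry a
one-unit jitter in the last printed digit (consistent with having been
printed from a mix of $z = 1.96$ and the exact quantile); the regression
tests therefore compare upper bounds to within one unit in the last printed
digit and everything else exactly at printed precision.

## Novel signals and clinical priority

Positive PTs are classified by the first matching rule in the order
disease-related exclusion, ambiguous-usage exclusion, known from the drug
insert, known from the pivotal phase III trial, otherwise novel. The order
is configurable; the default puts the clinical-irrelevance exclusions first
so that a term tied to disease progression is never presented as a "known
insert AE". Lists are user-supplied plain-text files; the shipped insert
(8 PTs) and trial (8 PTs) lists are reconstructions from the published
per-term annotations of the sparsentan screen and reproduce its 14 novel
PTs. The exact disease-related and ambiguous lists of that analysis are not
recoverable from the published material, so the shipped defaults leave them
empty rather than guess.

Each positive PT is then scored 0/1/2 on five dimensions — target-event
count, ROR CI lower bound, mortality proportion, IME/DME membership, and
biological plausibility (insert = 2, trial = 1, undocumented = 0) — and the
total (0-10) is banded weak (0-4), moderate (5-7), strong (8-10). The
published rubric prints overlapping band edges ("10-50" vs "<10", "2-5" vs
"1-2", "25-50%" vs "<25%"); the implementation fixes closed middle bands —
$[10,50] \to 1$, $[2,5] \to 1$, $[25\%,50\%] \to 1$, the 2-point band
strictly above — which is consistent with every published per-term score. A
CI lower bound at or below 1 cannot occur for a positive signal and is an
error, not a 0. The mortality denominator is the target reports in the
analysis cohort that mention the PT (cohort-scoped; configurable via the
`mortality` argument if a different denominator is wanted). A term on both
the IME and DME lists takes the higher score.

## Subgroups

`stratify_and_screen()` re-runs the screen independently inside sex
(female/male) and age strata ([18, 45] and (45, inf); age exactly 45 falls
in the younger band, minors and unknown ages are excluded and counted). Both
arms are restricted to the stratum, so each stratum has its own margins and
background — the stratum's own comparator, not the whole cohort's, defines
"expected". For terms positive in both strata the cross-stratum contrast is
the ratio of stratum RORs with the Woolf-combined interval
$\exp(\ln(\mathrm{ROR}_A/\mathrm{ROR}_B) \pm z\sqrt{V_A+V_B})$; swapping
strata inverts the ratio. A ratio of reporting fractions would be an equally
defensible estimator; the ratio of RORs was chosen because it reuses the
screen's own statistic and variance, and the choice is isolated in
`compare_shared()`.

## The synthetic generator

`generator_config()` describes a one-indication cohort: `n_reports` cases,
a Bernoulli(`target_drug_share`) target/comparator split, a zero-truncated
Poisson number of distinct PTs per report (sampled without replacement
within a report, so the (report, PT) counting unit is well defined),
categorical sex/age/outcome with explicit unknown masses, and a
`duplicate_rate` fraction of cases emitted twice with differing version
keys (the later version is the intended survivor). Target reports draw PT
$k$ with probability proportional to $p_k r_k$ (baseline times the injected
relative reporting ratio, renormalized); the truth table records $r_k$
exactly, with 1 for uninjected PTs.

Defaults mirror the worked sparsentan cohort: 2,196 reports with a 504/2,196
target share; 3.0 mean events per report (the reference margins imply
1,523 pairs from 504 reports, about 3 per report); sex 43.5% / 54.9% / 1.6%
female/male/unknown and the age-band and outcome masses of the published
demographic table; a 250-PT vocabulary over 10 organ classes with uniform
baseline probability 0.004. In that regime an injected ratio of 5 yields
roughly 30 target reports for the signal PT — the same order as the
moderate-priority signals the screen is meant to catch. The duplicate rate
(5%) is not published anywhere; it is a realistic order for FAERS-style
versioning and only exercises deduplication. The generator is a structural
stand-in, not a model of FAERS: it has no reporting-delay dynamics, drug
interactions, co-reporting correlation between PTs, country effects, or
notoriety biases, so passing recovery tests demonstrates that the pipeline
computes what it claims on data of this shape — not that the screen is
well calibrated on real spontaneous-report data.

## Numerical and validation choices

* Determinism: the generator seeds R's RNG from `config$seed`; identical
  configs give byte-identical files, and the pipeline's outputs are
  byte-identical across reruns (the run manifest contains only counts).
* Display rounding is half-away-from-zero (`round_half_away()`), matching
  how the reference tables are typeset; internal computation is never
  rounded.
* Ordering: screen output is sorted by level, then descending `a`, ties
  alphabetically, so outputs are stable.
* Validation problem sizes: the chi-squared implementation is checked
  against a brute-force $\sum (O-E)^2/E$ oracle on 10,000 random tables
  (agreement within 1e-9) and against `chisq.test(correct = FALSE)`;
  generator calibration is checked at 50,000 reports (3-standard-error
  binomial envelope under the null, empirical ratio in [4, 6] for an
  injected ratio of 5); signal recovery is measured over 200 seeded
  replicates of a 2,196-report cohort with an injected ratio-5 PT
  (recovery required in at least 95%), and the per-PT dual-positive rate
  under the global null is required to stay below 0.05, the bound recorded
  from development runs (observed values were below 0.01).
* Degenerate inputs: empty report sets deduplicate and summarize to empty
  outputs; empty strata warn and return empty results; an empty target
  cohort is an error (there is nothing to screen).

## Limitations

The screen inherits every caveat of disproportionality analysis: no
incidence, no causality, reporting biases, and no multiplicity control
(none is applied, matching standard practice for hypothesis-generating
screens). The shipped exclusion and IME/DME lists are miniature
reconstructions for testing; real analyses must supply the EMA lists and
their own exclusion terms. MedDRA itself is licensed, so PT-to-SOC mapping
is always a user-supplied file.
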