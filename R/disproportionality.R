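#' Threshold configuration for dual-algorithm signal detection
#'
#' The classical dual criteria used in spontaneous-report screening: a signal
#' is ROR-positive when the number of target reports carrying the term is at
#' least `min_a` and the lower 95\% confidence bound of the ROR exceeds
#' `ror_ci_low_gt`; it is PRR-positive (the Evans criteria) when `a >= min_a`,
#' `PRR >= prr_min` and the Pearson chi-squared statistic is at least
#' `chi2_min`. A term is a positive signal when both algorithms agree.
#'
#' @param min_a minimum target report count (default 3).
#' @param ror_ci_low_gt ROR CI lower bound must exceed this (default 1).
#' @param prr_min minimum PRR (default 2).
#' @param chi2_min minimum chi-squared (default 4).
#' @return a `threshold_config` list.
#' @export
threshold_config <- function(min_a = 3, ror_ci_low_gt = 1, prr_min = 2,
                             chi2_min = 4) {
  stopifnot(min_a >= 0, ror_ci_low_gt >= 0, prr_min >= 0, chi2_min >= 0)
  structure(list(min_a = min_a, ror_ci_low_gt = ror_ci_low_gt,
                 prr_min = prr_min, chi2_min = chi2_min),
            class = "threshold_config")
}

#' Reporting odds ratio with Woolf 95\% confidence interval
#'
#' For a 2x2 contingency table with `a` target (report, term) pairs carrying
#' the term, `b` target pairs without it, and `c`, `d` the comparator
#' counterparts: ROR = (a d)/(b c), with the confidence interval computed on
#' the log scale, `exp(log ROR +/- z sqrt(1/a + 1/b + 1/c + 1/d))`.
#'
#' Zero cells make the estimate (b or c zero) or the interval (any cell zero)
#' undefined; undefined results are returned as `NA` (explicitly missing),
#' never as `NaN` or `Inf`. No continuity or zero-cell correction is applied.
#'
#' @param a,b,c,d integer vectors of cell counts (recycled to common length).
#' @param z normal quantile for the interval (default 1.959964, two-sided 95\%).
#' @return data.frame with columns `ror`, `ror_ci_low`, `ror_ci_high`.
#' @examples
#' ror_with_ci(9, 1514, 5, 5183)   # ~6.16 (2.06-18.41)
#' @export
ror_with_ci <- function(a, b, c, d, z = 1.959964) {
  n <- max(length(a), length(b), length(c), length(d))
  a <- rep_len(as.numeric(a), n); b <- rep_len(as.numeric(b), n)
  c <- rep_len(as.numeric(c), n); d <- rep_len(as.numeric(d), n)
  if (any(c(a, b, c, d) < 0, na.rm = TRUE)) stop("cell counts must be >= 0")
  ror <- ifelse(b > 0 & c > 0, (a * d) / (b * c), NA_real_)
  ok_ci <- a > 0 & b > 0 & c > 0 & d > 0
  se <- ifelse(ok_ci, sqrt(1 / a + 1 / b + 1 / c + 1 / d), NA_real_)
  lo <- ifelse(ok_ci, exp(log(ror) - z * se), NA_real_)
  hi <- ifelse(ok_ci, exp(log(ror) + z * se), NA_real_)
  data.frame(ror = ror, ror_ci_low = lo, ror_ci_high = hi)
}

#' Proportional reporting ratio with Pearson chi-squared
#'
#' PRR = [a/(a+b)] / [c/(c+d)]; the accompanying statistic is the Pearson
#' chi-squared on the 2x2 table without continuity correction,
#' `N (ad - bc)^2 / [(a+b)(c+d)(a+c)(b+d)]` with `N = a+b+c+d`.
#'
#' The PRR is undefined when a margin or `c` is zero, the chi-squared when any
#' margin is zero; undefined values are `NA`.
#'
#' @param a,b,c,d integer vectors of cell counts (recycled to common length).
#' @return data.frame with columns `prr`, `chi2`.
#' @examples
#' prr_with_chi2(9, 1514, 5, 5183)  # ~6.13 (13.83)
#' @export
prr_with_chi2 <- function(a, b, c, d) {
  n <- max(length(a), length(b), length(c), length(d))
  a <- rep_len(as.numeric(a), n); b <- rep_len(as.numeric(b), n)
  c <- rep_len(as.numeric(c), n); d <- rep_len(as.numeric(d), n)
  if (any(c(a, b, c, d) < 0, na.rm = TRUE)) stop("cell counts must be >= 0")
  prr <- ifelse(a + b > 0 & c + d > 0 & c > 0,
                (a / (a + b)) / (c / (c + d)), NA_real_)
  N <- a + b + c + d
  ok <- (a + b) > 0 & (c + d) > 0 & (a + c) > 0 & (b + d) > 0
  chi2 <- ifelse(ok,
                 N * (a * d - b * c)^2 /
                   ((a + b) * (c + d) * (a + c) * (b + d)),
                 NA_real_)
  data.frame(prr = prr, chi2 = chi2)
}

#' Count (report, term) pairs at PT or SOC level
#'
#' The counting unit of the screen is the (report, distinct term) pair. At PT
#' level a report contributes one pair per distinct preferred term it carries;
#' at SOC level one pair per distinct system organ class after mapping its PTs
#' through `pt_to_soc` (two PTs of one report in the same SOC collapse to a
#' single pair). PTs missing from the map are counted under the sentinel term
#' `"Unmapped SOC"` and reported via the `n_unmapped` attribute.
#'
#' @param reports a report data.frame (see [assemble_reports()]) with a
#'   list-column `events` of PT character vectors.
#' @param pt_to_soc data.frame with columns `pt`, `soc` (case-insensitive on
#'   `pt`). Only needed at SOC level.
#' @param level `"PT"` or `"SOC"`.
#' @return data.frame with columns `term`, `n` (pair counts, descending),
#'   with attributes `margin` (total pairs) and `n_unmapped`.
#' @export
term_pairs <- function(reports, pt_to_soc = NULL, level = c("PT", "SOC")) {
  level <- match.arg(level)
  events <- reports$events
  if (is.null(events)) stop("reports must carry an 'events' list-column")
  pts <- unlist(lapply(events, unique), use.names = FALSE)
  rep_id <- rep(seq_along(events), vapply(events, function(e) length(unique(e)),
                                          integer(1)))
  n_unmapped <- 0L
  if (level == "SOC") {
    if (is.null(pt_to_soc)) stop("pt_to_soc mapping required at SOC level")
    soc <- pt_to_soc$soc[match(norm_name(pts), norm_name(pt_to_soc$pt))]
    n_unmapped <- sum(is.na(soc))
    soc[is.na(soc)] <- "Unmapped SOC"
    key <- !duplicated(paste0(rep_id, "\r", soc))
    terms <- soc[key]
  } else {
    terms <- pts
  }
  tab <- table(terms)
  out <- data.frame(term = names(tab), n = as.integer(tab),
                    stringsAsFactors = FALSE)
  out <- out[order(-out$n, out$term), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "margin") <- length(terms)
  attr(out, "n_unmapped") <- n_unmapped
  out
}

#' Apply dual-algorithm positivity flags
#'
#' @param stats data.frame with columns `a`, `ror_ci_low`, `prr`, `chi2`.
#' @param th a [threshold_config()].
#' @return `stats` with logical columns `ror_positive`, `prr_positive`,
#'   `positive_both` set. Undefined statistics never satisfy a criterion.
#' @export
flag_signal <- function(stats, th = threshold_config()) {
  ge <- function(x, cut) !is.na(x) & x >= cut
  gt <- function(x, cut) !is.na(x) & x > cut
  stats$ror_positive <- stats$a >= th$min_a & gt(stats$ror_ci_low, th$ror_ci_low_gt)
  stats$prr_positive <- stats$a >= th$min_a & ge(stats$prr, th$prr_min) &
    ge(stats$chi2, th$chi2_min)
  stats$positive_both <- stats$ror_positive & stats$prr_positive
  stats
}

#' Run the disproportionality screen at PT and SOC level
#'
#' Builds per-term 2x2 tables over the target/comparator split of the cohort
#' (margins are the total (report, term) pair counts at each level, identical
#' across terms of that level), computes ROR with 95\% CI and PRR with
#' chi-squared, and applies the dual-algorithm thresholds. One row is emitted
#' per term observed in the target set.
#'
#' @param target report data.frame for target-drug reports.
#' @param comparator report data.frame for the comparator reports.
#' @param pt_to_soc data.frame mapping `pt` to `soc`.
#' @param th a [threshold_config()].
#' @param levels which levels to screen (default both).
#' @return data.frame with columns `term`, `level`, `a`, `b`, `c`, `d`,
#'   `ror`, `ror_ci_low`, `ror_ci_high`, `prr`, `chi2`, `ror_positive`,
#'   `prr_positive`, `positive_both`, sorted by level then descending `a`,
#'   ties broken alphabetically by term.
#' @export
run_screen <- function(target, comparator, pt_to_soc,
                       th = threshold_config(), levels = c("SOC", "PT")) {
  if (nrow(target) == 0) stop("empty target cohort: nothing to screen")
  one_level <- function(level) {
    tp <- term_pairs(target, pt_to_soc, level)
    cp <- term_pairs(comparator, pt_to_soc, level)
    m_t <- attr(tp, "margin")
    m_c <- attr(cp, "margin")
    a <- tp$n
    c_ <- cp$n[match(norm_name(tp$term), norm_name(cp$term))]
    c_[is.na(c_)] <- 0L
    out <- data.frame(term = tp$term, level = level,
                      a = a, b = m_t - a, c = c_, d = m_c - c_,
                      stringsAsFactors = FALSE)
    out <- cbind(out, ror_with_ci(out$a, out$b, out$c, out$d),
                 prr_with_chi2(out$a, out$b, out$c, out$d))
    flag_signal(out, th)
  }
  res <- do.call(rbind, lapply(levels, one_level))
  res <- res[order(match(res$level, levels), -res$a, res$term), , drop = FALSE]
  rownames(res) <- NULL
  res
}
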