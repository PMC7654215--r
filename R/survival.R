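# Median-split Kaplan-Meier screening of candidate genes: per-gene high/low
# dichotomization at the cohort median, logrank comparison and an
# observed/expected hazard ratio with a 95% confidence interval.

#' Split patients at the cohort median of a gene's expression
#'
#' @param table A `survival_table` data.frame.
#' @param gene Gene column to split on.
#' @return Factor with levels `"high"`, `"low"`; ties at the median go to
#'   `"high"`.
#' @export
median_split <- function(table, gene) {
  if (!gene %in% names(table))
    stop_hb("hb_bad_argument", "gene '%s' not in survival table", gene)
  x <- table[[gene]]
  if (length(unique(x)) == 1L)
    stop_hb("hb_degenerate_split", "degenerate split: constant expression for '%s'", gene)
  factor(ifelse(x >= stats::median(x), "high", "low"),
         levels = c("high", "low"))
}

#' Kaplan-Meier survival curve
#'
#' Product-limit estimator of the survival function; censored subjects
#' leave the risk set without an event step.
#'
#' @param times Positive follow-up times.
#' @param events Event flags (1 = event observed, 0 = censored).
#' @return Data.frame with columns `time`, `n_risk`, `n_event`, `n_censor`,
#'   `surv` at each distinct observed time.
#' @export
km_curve <- function(times, events) {
  if (length(times) < 1L)
    stop_hb("hb_bad_argument", "km_curve needs >= 1 subject")
  fit <- survival::survfit(survival::Surv(times, events) ~ 1)
  data.frame(time = fit$time, n_risk = fit$n.risk, n_event = fit$n.event,
             n_censor = fit$n.censor, surv = fit$surv)
}

#' Two-group logrank test
#'
#' At each distinct event time the observed-minus-expected events in the
#' first group under hypergeometric sampling accumulate into the score
#' statistic; `chi2 = U^2 / Var(U)` is referred to a chi-square with one
#' degree of freedom.  Tie-corrected hypergeometric variance.
#'
#' @param times Positive follow-up times.
#' @param events Event flags (1 = event, 0 = censored).
#' @param group Two-level grouping (factor or coercible).
#' @return List with `chi2`, `p_value`, `observed` and `expected` (per
#'   group, in level order).  No events in either group gives `p = 1` with
#'   a warning.
#' @export
logrank_test <- function(times, events, group) {
  group <- droplevels(as.factor(group))
  if (nlevels(group) != 2L)
    stop_hb("hb_bad_argument", "logrank needs exactly two nonempty groups")
  if (sum(events) == 0L) {
    warning("no events: logrank variance is zero, p = 1", call. = FALSE)
    return(list(chi2 = 0, p_value = 1,
                observed = c(0, 0), expected = c(0, 0)))
  }
  sd <- survival::survdiff(survival::Surv(times, events) ~ group)
  chi2 <- unname(sd$chisq)
  list(chi2 = chi2,
       p_value = stats::pchisq(chi2, df = 1L, lower.tail = FALSE),
       observed = unname(sd$obs), expected = unname(sd$exp))
}

#' Hazard ratio from logrank observed/expected totals
#'
#' `hr = (O_A/E_A) / (O_B/E_B)` with the 95% confidence interval
#' `exp(log hr +- 1.96 * sqrt(1/E_A + 1/E_B))`.
#'
#' @param times Positive follow-up times.
#' @param events Event flags.
#' @param group Two-level grouping; the ratio is first level over second.
#' @return List with `hr` and `ci` (length-2 numeric).
#' @export
hazard_ratio <- function(times, events, group) {
  lr <- logrank_test(times, events, group)
  O <- lr$observed; E <- lr$expected
  if (any(E == 0))
    stop_hb("hb_zero_expected", "zero expected events in a group")
  if (any(O == 0))
    stop_hb("hb_zero_events", "need >= 1 observed event in each group")
  hr <- (O[1] / E[1]) / (O[2] / E[2])
  se <- sqrt(1 / E[1] + 1 / E[2])
  list(hr = hr, ci = c(exp(log(hr) - 1.96 * se), exp(log(hr) + 1.96 * se)))
}

#' Median-split Kaplan-Meier screen over candidate genes
#'
#' For each gene: median split, logrank test and hazard ratio
#' (high relative to low).  Genes are screened individually with no
#' multiplicity correction by default (an optional Benjamini-Hochberg
#' switch adjusts the significance call).  A gene whose split or test
#' fails is reported with `NA` statistics rather than aborting the screen.
#'
#' @param table A `survival_table` data.frame.
#' @param genes Gene columns to screen.
#' @param alpha Per-gene significance level on the logrank p (default 0.05).
#' @param adjust Apply Benjamini-Hochberg across the screened genes before
#'   calling significance (default FALSE).
#' @return Data.frame of class `km_screen`: `gene`, `n_high`, `n_low`,
#'   `logrank_chi2`, `p_value`, `hazard_ratio`, `hr_low`, `hr_high`,
#'   `significant`, `note`.
#' @export
km_screen <- function(table, genes, alpha = 0.05, adjust = FALSE) {
  rows <- lapply(genes, function(g) {
    res <- tryCatch({
      grp <- median_split(table, g)
      lr <- logrank_test(table$time_months, table$event, grp)
      hr <- hazard_ratio(table$time_months, table$event, grp)
      data.frame(gene = g, n_high = sum(grp == "high"),
                 n_low = sum(grp == "low"),
                 logrank_chi2 = lr$chi2, p_value = lr$p_value,
                 hazard_ratio = hr$hr, hr_low = hr$ci[1], hr_high = hr$ci[2],
                 note = "", stringsAsFactors = FALSE)
    }, error = function(e) {
      data.frame(gene = g, n_high = NA_integer_, n_low = NA_integer_,
                 logrank_chi2 = NA_real_, p_value = NA_real_,
                 hazard_ratio = NA_real_, hr_low = NA_real_,
                 hr_high = NA_real_, note = conditionMessage(e),
                 stringsAsFactors = FALSE)
    })
    res
  })
  out <- do.call(rbind, rows) %||%
    data.frame(gene = character(0), n_high = integer(0), n_low = integer(0),
               logrank_chi2 = numeric(0), p_value = numeric(0),
               hazard_ratio = numeric(0), hr_low = numeric(0),
               hr_high = numeric(0), note = character(0),
               stringsAsFactors = FALSE)
  pv <- if (adjust) stats::p.adjust(out$p_value, method = "BH") else out$p_value
  out$significant <- !is.na(pv) & pv < alpha
  attr(out, "alpha") <- alpha
  attr(out, "adjust") <- adjust
  class(out) <- c("km_screen", "data.frame")
  out
}

#' @export
print.km_screen <- function(x, ...) {
  cat(sprintf(
    "Kaplan-Meier median-split screen: %d/%d genes significant (logrank p < %g%s)\n",
    sum(x$significant, na.rm = TRUE), nrow(x), attr(x, "alpha"),
    if (isTRUE(attr(x, "adjust"))) ", BH-adjusted" else ""))
  print.data.frame(x, ...)
  invisible(x)
}
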