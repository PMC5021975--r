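# The season-wide association scan: per-condition birth-month tests,
# monthly relative-risk curves with Katz confidence intervals, inclusion
# filtering and phenome-wide FDR control.

#' A 2 x 12 birth-month contingency summary for one condition
#'
#' @param cases_by_month Integer 12-vector: patients carrying the condition,
#'   by birth month (January..December).
#' @param population_by_month Integer 12-vector: all cohort patients by
#'   birth month.
#' @return An object of class `monthly_contingency` with elements
#'   `cases_by_month`, `population_by_month`, `total_cases`,
#'   `total_population`.
#' @export
monthly_contingency <- function(cases_by_month, population_by_month) {
  c_m <- as.numeric(cases_by_month)
  n_m <- as.numeric(population_by_month)
  if (length(c_m) != 12L || length(n_m) != 12L) {
    stopf("cases_by_month and population_by_month must have length 12")
  }
  if (any(c_m < 0) || any(n_m < 0) || any(c_m > n_m)) {
    stopf("need 0 <= cases <= population in every month")
  }
  structure(list(cases_by_month = c_m, population_by_month = n_m,
                 total_cases = sum(c_m), total_population = sum(n_m)),
            class = "monthly_contingency")
}

#' Birth-month relative-risk curve with Katz confidence intervals
#'
#' For each month m, the relative risk compares the disease risk of
#' patients born in m against patients born in any other month:
#' `RR_m = (c_m / n_m) / ((C - c_m) / (N - n_m))`. Confidence intervals use
#' the Katz log method,
#' `exp(log RR +/- z * sqrt(1/a - 1/(a+b) + 1/c - 1/(c+d)))` on the month's
#' 2 x 2 collapse. If a month's case cell or complement case cell is zero,
#' 0.5 is added to all four cells of that month's 2 x 2 table
#' (Haldane-Anscombe) so the curve stays finite for permutation use.
#'
#' @param t A [monthly_contingency()] with `N > 0`, `C > 0` and every month
#'   populated.
#' @param ci_level Two-sided confidence level (default 0.95).
#' @return List with numeric 12-vectors `rr`, `ci_low`, `ci_high`.
#' @export
monthly_relative_risk <- function(t, ci_level = 0.95) {
  stopifnot(inherits(t, "monthly_contingency"))
  if (!is_prob(ci_level) || ci_level <= 0 || ci_level >= 1) {
    stopf("ci_level must be in (0, 1)")
  }
  empty <- which(t$population_by_month == 0)
  if (length(empty)) {
    stopf("no patients born in month(s) %s: relative risk undefined",
          paste(month.abb[empty], collapse = ", "))
  }
  if (t$total_cases == 0) stopf("no cases: relative risk undefined")
  a <- t$cases_by_month                               # cases, born month m
  b <- t$population_by_month - a                      # non-cases, month m
  cc <- t$total_cases - a                             # cases, other months
  d <- (t$total_population - t$population_by_month) - cc
  adjust <- a == 0 | cc == 0
  a[adjust] <- a[adjust] + 0.5
  b[adjust] <- b[adjust] + 0.5
  cc[adjust] <- cc[adjust] + 0.5
  d[adjust] <- d[adjust] + 0.5
  risk_in <- a / (a + b)
  risk_out <- cc / (cc + d)
  rr <- risk_in / risk_out
  se <- sqrt(1 / a - 1 / (a + b) + 1 / cc - 1 / (cc + d))
  z <- stats::qnorm(1 - (1 - ci_level) / 2)
  list(rr = rr, ci_low = rr * exp(-z * se), ci_high = rr * exp(z * se))
}

#' Chi-squared test of birth month versus case status
#'
#' Pearson's chi-squared on the 2 x 12 (case / non-case by birth month)
#' table; months with no births are dropped and the degrees of freedom
#' reduced accordingly (df = number of populated months - 1).
#'
#' @param t A [monthly_contingency()].
#' @return List with `chi2`, `df` and `p_raw`.
#' @export
birth_month_association_test <- function(t) {
  stopifnot(inherits(t, "monthly_contingency"))
  keep <- t$population_by_month > 0
  if (sum(keep) < 2L) {
    stopf("all patients born in a single month: association test undefined")
  }
  if (t$total_cases == 0 || t$total_cases == t$total_population) {
    stopf("case and non-case rows must both be non-empty")
  }
  tab <- rbind(cases = t$cases_by_month[keep],
               noncases = t$population_by_month[keep] - t$cases_by_month[keep])
  res <- suppressWarnings(stats::chisq.test(tab, correct = FALSE))
  list(chi2 = unname(res$statistic), df = unname(res$parameter),
       p_raw = unname(res$p.value))
}

#' Benjamini-Hochberg adjusted p-values
#'
#' Standard step-up adjustment, `q_(i) = min_{j >= i} (m * p_(j) / j)`
#' clipped at 1, returned in the input order.
#'
#' @param p_values Numeric vector of raw p-values in `[0, 1]`.
#' @return Adjusted p-values, same length and order.
#' @export
benjamini_hochberg <- function(p_values) {
  bad <- which(!is.finite(p_values) | p_values < 0 | p_values > 1)
  if (length(bad)) {
    stopf("p-values outside [0, 1] at index %s",
          paste(bad, collapse = ", "))
  }
  stats::p.adjust(p_values, method = "BH")
}

#' Scan configuration
#'
#' @param min_patients_per_condition Minimum number of cases for a condition
#'   to enter the scan (inclusive; default 1000, the usual phenome-wide
#'   inclusion threshold).
#' @param fdr_alpha FDR significance threshold (default 0.05).
#' @param ci_level Confidence level for the relative-risk intervals.
#' @return An object of class `scan_config`.
#' @export
scan_config <- function(min_patients_per_condition = 1000L,
                        fdr_alpha = 0.05, ci_level = 0.95) {
  if (!is_count(min_patients_per_condition) ||
      min_patients_per_condition < 1) {
    stopf("min_patients_per_condition must be a positive integer")
  }
  if (!is_prob(fdr_alpha) || fdr_alpha <= 0 || fdr_alpha >= 1) {
    stopf("fdr_alpha must be in (0, 1)")
  }
  structure(list(min_patients_per_condition =
                   as.integer(min_patients_per_condition),
                 fdr_alpha = fdr_alpha, ci_level = ci_level),
            class = "scan_config")
}

scan_column_names <- function() {
  c("condition_code", "label", "n_cases", "chi2", "df", "p_raw", "p_fdr",
    "max_rr", "max_rr_month", "min_rr_month",
    paste0("rr_", MONTHS), paste0("ci_low_", MONTHS),
    paste0("ci_high_", MONTHS))
}

empty_scan <- function() {
  cols <- scan_column_names()
  out <- as.data.frame(stats::setNames(
    c(list(character(0), character(0), integer(0)),
      rep(list(numeric(0)), 4L), list(numeric(0)),
      list(integer(0), integer(0)), rep(list(numeric(0)), 36L)),
    cols))
  class(out) <- c("seawas_scan", "data.frame")
  out
}

#' Run the season-wide association scan
#'
#' Tests every condition whose case count meets the inclusion threshold:
#' chi-squared birth-month association, monthly relative-risk curve with
#' confidence intervals, and Benjamini-Hochberg adjustment computed across
#' exactly the set of tested conditions (the phenome-wide family for this
#' institution). Extremum months use the earliest calendar month on ties.
#'
#' @param cohort A `seawas_cohort` (or anything [as_cohort()] accepts),
#'   already cohort-filtered.
#' @param config A [scan_config()].
#' @param labels Optional named character vector mapping condition codes to
#'   human-readable labels.
#' @return A data frame of class `seawas_scan`, one row per tested
#'   condition, with the relative-risk curve spread over columns
#'   `rr_1..rr_12` (and matching `ci_low_*`, `ci_high_*`).
#' @export
run_scan <- function(cohort, config = scan_config(), labels = NULL) {
  cohort <- as_cohort(cohort)
  stopifnot(inherits(config, "scan_config"))
  counts <- condition_case_counts(cohort)
  totals <- rowSums(counts$cases)
  keep <- names(totals)[totals >= config$min_patients_per_condition]
  if (length(keep) == 0L) {
    warnf("no condition meets the %d-case inclusion threshold",
          config$min_patients_per_condition)
    return(empty_scan())
  }
  keep <- sort(keep)
  rows <- lapply(keep, function(code) {
    t <- monthly_contingency(counts$cases[code, ], counts$n_month)
    test <- birth_month_association_test(t)
    rr <- monthly_relative_risk(t, ci_level = config$ci_level)
    data.frame(
      condition_code = code,
      label = unname(if (!is.null(labels) && code %in% names(labels))
        labels[[code]] else code),
      n_cases = as.integer(t$total_cases),
      chi2 = test$chi2, df = test$df, p_raw = test$p_raw,
      p_fdr = NA_real_,
      max_rr = max(rr$rr),
      max_rr_month = which.max(rr$rr),   # earliest month wins ties
      min_rr_month = which.min(rr$rr),
      stats::setNames(as.data.frame(as.list(rr$rr)), paste0("rr_", MONTHS)),
      stats::setNames(as.data.frame(as.list(rr$ci_low)),
                      paste0("ci_low_", MONTHS)),
      stats::setNames(as.data.frame(as.list(rr$ci_high)),
                      paste0("ci_high_", MONTHS)),
      stringsAsFactors = FALSE
    )
  })
  out <- do.call(rbind, rows)
  out$p_fdr <- benjamini_hochberg(out$p_raw)
  rownames(out) <- NULL
  class(out) <- c("seawas_scan", "data.frame")
  out
}

#' Conditions meeting the case threshold at both institutions
#'
#' @param scan_a,scan_b `seawas_scan` results for the two institutions.
#' @param threshold Minimum case count required at each institution
#'   (inclusive; default 1000).
#' @return Sorted character vector of condition codes.
#' @export
shared_condition_set <- function(scan_a, scan_b, threshold = 1000L) {
  a <- scan_a$condition_code[scan_a$n_cases >= threshold]
  b <- scan_b$condition_code[scan_b$n_cases >= threshold]
  sort(intersect(a, b))
}

#' Extract one condition's risk curve from a scan
#'
#' @param scan A `seawas_scan`.
#' @param condition_code Condition code present in the scan.
#' @param institution_label Label attached to the returned curve.
#' @return A [risk_curve()].
#' @export
scan_risk_curve <- function(scan, condition_code, institution_label = "") {
  i <- match(condition_code, scan$condition_code)
  if (is.na(i)) stopf("condition '%s' not present in scan", condition_code)
  risk_curve(condition_code, institution_label,
             as.numeric(scan[i, paste0("rr_", MONTHS)]))
}

#' Write / read scan results as tab-delimited text
#'
#' @param scan A `seawas_scan`.
#' @param path Output path for `write_scan_results()`, input path for
#'   `read_scan_results()`.
#' @return `write_scan_results()` returns the path invisibly;
#'   `read_scan_results()` returns a `seawas_scan`.
#' @export
write_scan_results <- function(scan, path) {
  stopifnot(inherits(scan, "seawas_scan"))
  out <- scan
  num <- vapply(out, is.double, logical(1))
  out[num] <- lapply(out[num], function(x) sprintf("%.17g", x))
  utils::write.table(out, path, sep = "\t", row.names = FALSE,
                     quote = FALSE)
  invisible(path)
}

#' @rdname write_scan_results
#' @export
read_scan_results <- function(path) {
  out <- utils::read.delim(path, stringsAsFactors = FALSE,
                           colClasses = c(condition_code = "character",
                                          label = "character"))
  class(out) <- c("seawas_scan", "data.frame")
  out
}
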