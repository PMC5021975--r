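# Publication-style outputs: replication summary tables, Manhattan-plot
# data, risk-curve overlays with external monthly covariates, and
# demographics comparisons between institutions.

#' A monthly covariate series (January..December)
#'
#' External 12-point series used for descriptive overlays against risk
#' curves - for example, the number of seasons in which each month was the
#' peak flu month, or mean serum vitamin D by month.
#'
#' @param name Column name used in overlay tables.
#' @param values Numeric 12-vector, months January..December.
#' @param units Free-text units.
#' @return An object of class `monthly_covariate`.
#' @export
monthly_covariate <- function(name, values, units = "") {
  values <- as.numeric(values)
  if (length(values) != 12L) {
    stopf("covariate '%s' must have exactly 12 monthly values", name)
  }
  structure(list(name = as.character(name), values = values,
                 units = as.character(units)),
            class = "monthly_covariate")
}

#' Build the two-institution replication summary table
#'
#' One row per replicated condition, carrying each institution's low- and
#' high-risk months (arg-min / arg-max of the relative-risk curve), maximum
#' relative risks, FDR-adjusted p-values, and the permutation p display
#' string. Rows are ordered by replication p ascending (condition code
#' breaks ties).
#'
#' @param scan_a,scan_b `seawas_scan` results for the two institutions.
#' @param replication A `seawas_replication` over conditions present in
#'   both scans.
#' @return A data frame with one row per replication result.
#' @export
build_summary_table <- function(scan_a, scan_b, replication) {
  codes <- replication$condition_code
  missing_a <- setdiff(codes, scan_a$condition_code)
  missing_b <- setdiff(codes, scan_b$condition_code)
  if (length(missing_a) || length(missing_b)) {
    stopf("condition sets do not match; missing from scan A: [%s], from scan B: [%s]",
          paste(missing_a, collapse = ", "),
          paste(missing_b, collapse = ", "))
  }
  ia <- match(codes, scan_a$condition_code)
  ib <- match(codes, scan_b$condition_code)
  out <- data.frame(
    condition_code = codes,
    condition_label = scan_a$label[ia],
    low_month_a = scan_a$min_rr_month[ia],
    high_month_a = scan_a$max_rr_month[ia],
    low_month_b = scan_b$min_rr_month[ib],
    high_month_b = scan_b$max_rr_month[ib],
    max_rr_a = scan_a$max_rr[ia],
    max_rr_b = scan_b$max_rr[ib],
    p_fdr_a = scan_a$p_fdr[ia],
    p_fdr_b = scan_b$p_fdr[ib],
    p_replication = replication$p_empirical,
    p_replication_display = replication$display_p,
    stringsAsFactors = FALSE
  )
  out <- out[order(out$p_replication, out$condition_code), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Manhattan-plot data for a scan
#'
#' @param scan A non-empty `seawas_scan`.
#' @param grouping Optional named character vector mapping condition codes
#'   to chapter/group labels (unmatched codes become `"unassigned"`).
#' @param alpha Significance threshold on the FDR-adjusted p-value; the flag
#'   uses strict `p_fdr < alpha`, so a condition sitting exactly at the
#'   threshold is not flagged.
#' @return Data frame with `condition_code`, `chapter`, `neg_log10_p_fdr`
#'   and logical `significant`. Zero p-values are clipped to the smallest
#'   positive double so the y-values stay finite.
#' @export
manhattan_data <- function(scan, grouping = NULL, alpha = 0.05) {
  if (nrow(scan) == 0L) stopf("scan is empty")
  chapter <- rep("all", nrow(scan))
  if (!is.null(grouping)) {
    chapter <- unname(grouping[scan$condition_code])
    chapter[is.na(chapter)] <- "unassigned"
  }
  p <- scan$p_fdr
  if (any(p == 0)) {
    message(sum(p == 0), " zero adjusted p-value(s) clipped for plotting")
    p[p == 0] <- .Machine$double.xmin
  }
  data.frame(condition_code = scan$condition_code,
             chapter = chapter,
             neg_log10_p_fdr = -log10(p),
             significant = scan$p_fdr < alpha,
             stringsAsFactors = FALSE)
}

#' Overlay a risk curve with external monthly covariates
#'
#' Purely descriptive month-by-month alignment; no statistic is computed.
#'
#' @param curve A [risk_curve()].
#' @param covariates List of [monthly_covariate()] objects (may be empty).
#' @return A 12-row data frame: `month`, `rr`, one column per covariate.
#' @export
overlay_table <- function(curve, covariates = list()) {
  stopifnot(inherits(curve, "risk_curve"))
  out <- data.frame(month = MONTHS, rr = curve$rr)
  for (cov in covariates) {
    stopifnot(inherits(cov, "monthly_covariate"))
    out[[cov$name]] <- cov$values
  }
  out
}

# Labels pooled into the "unknown" bucket before comparing demographics:
# the two institutions encode missing/declined race and ethnicity
# differently, so these are not comparable categories.
UNKNOWN_DEMOGRAPHIC_LABELS <- c("unknown", "unidentified", "declined",
                                "unidentified/unknown", "other/unidentified",
                                "na", "")

pool_demographic <- function(counts, unknown_labels) {
  nm <- tolower(trimws(names(counts)))
  nm[nm %in% unknown_labels] <- "unknown"
  tapply(as.numeric(counts), nm, sum)
}

#' Compare demographic distributions between two institutions
#'
#' For each attribute, category labels are matched case-insensitively;
#' labels meaning missing/declined, and categories present at only one
#' institution, are pooled into a single `"unknown"` bucket. A Pearson
#' chi-squared test (no continuity correction) is then run on the aligned
#' 2 x k count table. Attributes with fewer than two usable categories are
#' skipped with a message and listed in the `"skipped"` attribute.
#'
#' @param table_a,table_b Named lists: attribute name -> named vector of
#'   category counts.
#' @param unknown_labels Lower-case labels pooled into the unknown bucket.
#' @return Data frame with `attribute`, `chi2`, `df`, `p`.
#' @export
compare_demographics <- function(table_a, table_b,
                                 unknown_labels = UNKNOWN_DEMOGRAPHIC_LABELS) {
  attrs <- intersect(names(table_a), names(table_b))
  skipped <- character(0)
  rows <- list()
  for (attr in attrs) {
    a <- pool_demographic(table_a[[attr]], unknown_labels)
    b <- pool_demographic(table_b[[attr]], unknown_labels)
    shared <- setdiff(intersect(names(a), names(b)), "unknown")
    a2 <- c(a[shared],
            unknown = sum(a[!(names(a) %in% shared)]))
    b2 <- c(b[shared],
            unknown = sum(b[!(names(b) %in% shared)]))
    use <- (a2 + b2) > 0
    a2 <- a2[use]; b2 <- b2[use]
    if (length(a2) < 2L) {
      message("skipping demographic '", attr,
              "': fewer than 2 shared categories after alignment")
      skipped <- c(skipped, attr)
      next
    }
    res <- suppressWarnings(stats::chisq.test(rbind(a2, b2), correct = FALSE))
    rows[[attr]] <- data.frame(attribute = attr,
                               chi2 = unname(res$statistic),
                               df = unname(res$parameter),
                               p = unname(res$p.value),
                               stringsAsFactors = FALSE)
  }
  out <- if (length(rows)) do.call(rbind, rows) else
    data.frame(attribute = character(0), chi2 = numeric(0),
               df = numeric(0), p = numeric(0), stringsAsFactors = FALSE)
  rownames(out) <- NULL
  attr(out, "skipped") <- skipped
  out
}

#' Tabulate a cohort's demographic attributes
#'
#' @param cohort A `seawas_cohort`.
#' @param attributes Which patient columns to tabulate; defaults to every
#'   column other than `patient_id`, `birth_year`, `birth_month` and
#'   `service_year`.
#' @return Named list of category-count vectors, suitable for
#'   [compare_demographics()].
#' @export
demographic_counts <- function(cohort, attributes = NULL) {
  cohort <- as_cohort(cohort)
  if (is.null(attributes)) {
    attributes <- setdiff(names(cohort$patients),
                          c("patient_id", "birth_year", "birth_month",
                            "service_year"))
  }
  out <- lapply(attributes, function(a) {
    tab <- table(cohort$patients[[a]])
    stats::setNames(as.numeric(tab), names(tab))
  })
  stats::setNames(out, attributes)
}
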