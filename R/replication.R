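# Cross-institution replication of birth-month risk-curve patterns:
# Pearson correlation between two 12-point curves against an empirical
# permutation null.

#' A labelled birth-month risk curve
#'
#' @param condition_code Condition code.
#' @param institution_label Institution the curve was estimated at.
#' @param rr Numeric 12-vector of monthly relative risks (January..December),
#'   all finite and positive.
#' @return An object of class `risk_curve`.
#' @export
risk_curve <- function(condition_code, institution_label, rr) {
  rr <- as.numeric(rr)
  if (length(rr) != 12L || !all(is.finite(rr)) || any(rr <= 0)) {
    stopf("rr must be 12 finite positive relative risks")
  }
  structure(list(condition_code = as.character(condition_code),
                 institution_label = as.character(institution_label),
                 rr = rr),
            class = "risk_curve")
}

curve_values <- function(x) {
  if (inherits(x, "risk_curve")) x$rr else as.numeric(x)
}

curve_code <- function(x) {
  if (inherits(x, "risk_curve")) x$condition_code else NA_character_
}

#' Pearson product-moment correlation with strict validation
#'
#' @param x,y Numeric vectors of equal length (at least 3). Either vector
#'   having zero variance is an error: the correlation is undefined there
#'   and the affected condition should be excluded upstream.
#' @return The correlation coefficient.
#' @export
pearson_correlation <- function(x, y) {
  x <- curve_values(x)
  y <- curve_values(y)
  if (length(x) != length(y)) stopf("curves differ in length")
  if (length(x) < 3L) stopf("need at least 3 points")
  if (!all(is.finite(x)) || !all(is.finite(y))) stopf("non-finite values")
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    stopf("zero variance: correlation undefined")
  }
  stats::cor(x, y)
}

format_empirical_p <- function(n_exceeding, B, p, add_one) {
  if (!add_one && n_exceeding == 0L && B == 1000L) "p < 0.001"
  else format(p, digits = 6)
}

#' Permutation test for similarity of two risk curves
#'
#' Computes the observed Pearson correlation between the fixed and the
#' shuffled curve, then builds an empirical null by drawing `B` uniformly
#' random permutations of the shuffled curve's entries (the whole 12-vector
#' permuted as a block, without replacement) and correlating each against
#' the fixed curve. The empirical p-value is the proportion of null
#' correlations strictly greater than the observed one (a one-sided test of
#' pattern similarity). With the default convention, zero exceedances at
#' `B = 1000` are displayed as `"p < 0.001"`.
#'
#' @param curve_fixed,curve_shuffled [risk_curve()] objects or plain numeric
#'   vectors of equal length; `curve_shuffled` is the one randomized.
#' @param B Number of permutations (default 1000).
#' @param seed Integer seed; results are deterministic given it.
#' @param add_one Use the `(b + 1) / (B + 1)` convention instead of `b / B`.
#'   Off by default, which allows exact zeros (reported as `"p < 0.001"`).
#' @return An object of class `replication_result`: list with
#'   `condition_code`, `r_observed`, `B`, `n_exceeding`, `p_empirical`,
#'   `display_p`, `seed`.
#' @export
permutation_null <- function(curve_fixed, curve_shuffled, B = 1000L,
                             seed = 1L, add_one = FALSE) {
  if (!is_count(B) || B < 1) stopf("B must be a positive integer")
  x <- curve_values(curve_fixed)
  y <- curve_values(curve_shuffled)
  r_obs <- pearson_correlation(x, y)
  k <- length(x)
  perms <- with_seed(seed, {
    vapply(seq_len(B), function(b) sample(y), numeric(k))
  })
  # permutations preserve the multiset, so every column of `perms` shares
  # y's mean and sd; the correlations reduce to one cross-product each.
  # y itself rides along as column 1 so that the observed correlation is
  # computed by the identical arithmetic: a permutation that reproduces y
  # is then an exact tie and, under the strict ">" rule, not an exceedance.
  xc <- x - mean(x)
  r_all <- as.numeric(crossprod(cbind(y, perms) - mean(y), xc)) /
    ((k - 1) * stats::sd(x) * stats::sd(y))
  n_exceeding <- sum(r_all[-1] > r_all[1])
  p <- if (add_one) (n_exceeding + 1) / (B + 1) else n_exceeding / B
  code <- curve_code(curve_shuffled)
  if (is.na(code)) code <- curve_code(curve_fixed)
  structure(
    list(condition_code = code,
         r_observed = r_obs,
         B = as.integer(B),
         n_exceeding = as.integer(n_exceeding),
         p_empirical = p,
         display_p = format_empirical_p(n_exceeding, as.integer(B), p, add_one),
         seed = as.integer(seed)),
    class = "replication_result"
  )
}

#' @export
print.replication_result <- function(x, ...) {
  cat(sprintf("<replication_result %s: r = %.3f, %d/%d exceedances, %s>\n",
              x$condition_code, x$r_observed, x$n_exceeding, x$B,
              x$display_p))
  invisible(x)
}

#' Run the replication test over a shared condition set
#'
#' Institution A's curve is held fixed and institution B's curve is
#' randomized, for every condition in `shared`. Each condition gets its own
#' sub-seed derived from the master seed and the condition code, so results
#' do not depend on the order of `shared`.
#'
#' @param scan_a Scan whose curves are held fixed (the reference
#'   institution).
#' @param scan_b Scan whose curves are permuted (the replicating
#'   institution).
#' @param shared Character vector of condition codes present in both scans;
#'   defaults to [shared_condition_set()] at the 1000-case threshold.
#' @param B Permutations per condition.
#' @param seed Master integer seed.
#' @param add_one See [permutation_null()].
#' @return A data frame of class `seawas_replication` with one row per
#'   condition: `condition_code`, `r_observed`, `B`, `n_exceeding`,
#'   `p_empirical`, `display_p`, `seed`.
#' @export
replicate_all <- function(scan_a, scan_b,
                          shared = shared_condition_set(scan_a, scan_b),
                          B = 1000L, seed = 1L, add_one = FALSE) {
  missing_a <- setdiff(shared, scan_a$condition_code)
  missing_b <- setdiff(shared, scan_b$condition_code)
  if (length(missing_a) || length(missing_b)) {
    stopf("conditions missing from scan(s): %s",
          paste(unique(c(missing_a, missing_b)), collapse = ", "))
  }
  rows <- lapply(shared, function(code) {
    res <- permutation_null(
      scan_risk_curve(scan_a, code, "fixed"),
      scan_risk_curve(scan_b, code, "shuffled"),
      B = B, seed = derive_seed(seed, code), add_one = add_one
    )
    data.frame(condition_code = code, r_observed = res$r_observed,
               B = res$B, n_exceeding = res$n_exceeding,
               p_empirical = res$p_empirical, display_p = res$display_p,
               seed = res$seed, stringsAsFactors = FALSE)
  })
  out <- if (length(rows)) do.call(rbind, rows) else
    data.frame(condition_code = character(0), r_observed = numeric(0),
               B = integer(0), n_exceeding = integer(0),
               p_empirical = numeric(0), display_p = character(0),
               seed = integer(0), stringsAsFactors = FALSE)
  rownames(out) <- NULL
  class(out) <- c("seawas_replication", "data.frame")
  out
}

#' Write / read replication results as tab-delimited text
#'
#' @param replication A `seawas_replication` data frame.
#' @param path File path.
#' @return The path (write) or a `seawas_replication` (read).
#' @export
write_replication_results <- function(replication, path) {
  stopifnot(inherits(replication, "seawas_replication"))
  out <- replication
  out$r_observed <- sprintf("%.17g", out$r_observed)
  out$p_empirical <- sprintf("%.17g", out$p_empirical)
  utils::write.table(out, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_replication_results
#' @export
read_replication_results <- function(path) {
  out <- utils::read.delim(path, stringsAsFactors = FALSE,
                           colClasses = c(condition_code = "character",
                                          display_p = "character"))
  class(out) <- c("seawas_replication", "data.frame")
  out
}
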