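# Shared fixture builders: everything is constructed in code at test time.

# The 12-month toy contingency used for relative-risk hand arithmetic:
# 100 births per month, 20 cases in January, 10 in every other month.
toy_contingency <- function() {
  monthly_contingency(cases_by_month = c(20, rep(10, 11)),
                      population_by_month = rep(100, 12))
}

# Brute-force chi-squared: cell-by-cell sum((O - E)^2 / E) on the 2 x k
# table, written from the textbook definition, independent of chisq.test.
bruteforce_chi2 <- function(cases, population) {
  keep <- population > 0
  O <- rbind(cases[keep], population[keep] - cases[keep])
  E <- outer(rowSums(O), colSums(O)) / sum(O)
  stat <- 0
  for (i in seq_len(nrow(O))) {
    for (j in seq_len(ncol(O))) {
      stat <- stat + (O[i, j] - E[i, j])^2 / E[i, j]
    }
  }
  stat
}

# Brute-force BH step-up from the definition: q_(i) = min_{j>=i} m p_(j)/j,
# mapped back to input order.
bruteforce_bh <- function(p) {
  m <- length(p)
  ord <- order(p)
  q_sorted <- numeric(m)
  for (i in seq_len(m)) {
    cand <- sapply(i:m, function(j) m * p[ord[j]] / j)
    q_sorted[i] <- min(1, min(cand))
  }
  q <- numeric(m)
  q[ord] <- q_sorted
  q
}

# Pearson correlation straight from the sum-based definition.
bruteforce_cor <- function(x, y) {
  n <- length(x)
  sx <- sum(x); sy <- sum(y)
  num <- n * sum(x * y) - sx * sy
  den <- sqrt(n * sum(x^2) - sx^2) * sqrt(n * sum(y^2) - sy^2)
  num / den
}

# Exact permutation p for short curves: enumerate every permutation of y,
# count correlations strictly exceeding the observed one.
all_permutations <- function(v) {
  if (length(v) == 1L) return(list(v))
  out <- list()
  for (i in seq_along(v)) {
    for (rest in all_permutations(v[-i])) {
      out[[length(out) + 1L]] <- c(v[i], rest)
    }
  }
  out
}

exact_permutation_p <- function(x, y) {
  r_obs <- bruteforce_cor(x, y)
  perms <- all_permutations(y)
  mean(sapply(perms, function(p) bruteforce_cor(x, p) > r_obs))
}

# A tiny deterministic cohort built by hand (no files): 20 patients,
# 3 condition codes with known month placements.
tiny_cohort <- function() {
  patients <- data.frame(
    patient_id = sprintf("T%02d", 1:20),
    birth_year = rep(c(1950, 1980), 10),
    birth_month = rep(1:10, 2),
    sex = rep(c("F", "M"), 10),
    stringsAsFactors = FALSE
  )
  diagnoses <- data.frame(
    patient_id = c("T01", "T02", "T03", "T11", "T12", "T01", "T05"),
    code = c("A", "A", "B", "A", "B", "C", "C"),
    stringsAsFactors = FALSE
  )
  dir <- withr::local_tempdir(.local_envir = parent.frame())
  pp <- file.path(dir, "patients.csv")
  dp <- file.path(dir, "diagnoses.csv")
  write.csv(patients, pp, row.names = FALSE)
  write.csv(cbind(diagnoses, vocabulary = "SNOMED"), dp, row.names = FALSE)
  read_patients(pp, dp)
}

# A hand-built scan with fully controlled curves, for reporting fixtures.
scan_from_curves <- function(curves, n_cases = NULL, p_fdr = NULL) {
  codes <- names(curves)
  n <- length(codes)
  if (is.null(n_cases)) n_cases <- rep(2000L, n)
  if (is.null(p_fdr)) p_fdr <- rep(0.5, n)
  rr <- do.call(rbind, curves)
  out <- data.frame(
    condition_code = codes, label = codes, n_cases = n_cases,
    chi2 = rep(1, n), df = rep(11L, n), p_raw = p_fdr, p_fdr = p_fdr,
    max_rr = apply(rr, 1, max),
    max_rr_month = apply(rr, 1, which.max),
    min_rr_month = apply(rr, 1, which.min),
    stringsAsFactors = FALSE
  )
  out[paste0("rr_", 1:12)] <- rr
  out[paste0("ci_low_", 1:12)] <- rr * 0.9
  out[paste0("ci_high_", 1:12)] <- rr * 1.1
  class(out) <- c("seawas_scan", "data.frame")
  out
}
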