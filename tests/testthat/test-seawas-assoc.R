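test_that("relative risks reproduce hand arithmetic on the toy table", {
  rr <- monthly_relative_risk(toy_contingency())
  # RR_1 = (20/100) / (110/1100) = 2; RR_2 = (10/100) / (120/1100) = 11/12
  expect_equal(rr$rr[1], 2.0)
  expect_equal(rr$rr[2], 11 / 12)
  expect_true(all(rr$ci_low <= rr$rr & rr$rr <= rr$ci_high))
  # Katz CI by hand for January: a=20, b=80, c=110, d=990
  se <- sqrt(1 / 20 - 1 / 100 + 1 / 110 - 1 / 1100)
  z <- qnorm(0.975)
  expect_equal(rr$ci_low[1], 2 * exp(-z * se))
  expect_equal(rr$ci_high[1], 2 * exp(z * se))
})

test_that("uniform risk gives a flat RR curve of ones", {
  t <- monthly_contingency(rep(10, 12), rep(100, 12))
  expect_equal(monthly_relative_risk(t)$rr, rep(1, 12))
})

test_that("zero-case months stay finite via the continuity correction", {
  t <- monthly_contingency(c(0, rep(10, 11)), rep(100, 12))
  rr <- monthly_relative_risk(t)
  expect_true(all(is.finite(rr$rr)) && all(rr$rr > 0))
  expect_true(all(is.finite(rr$ci_low)) && all(is.finite(rr$ci_high)))
  # untouched months use the exact cells
  expect_equal(rr$rr[2], (10 / 100) / (100 / 1100))
})

test_that("empty birth months are an error naming the month", {
  t <- monthly_contingency(c(rep(5, 11), 0), c(rep(50, 11), 0))
  expect_error(monthly_relative_risk(t), "Dec")
})

test_that("population-weighted monthly rates reconstruct the overall prevalence", {
  set.seed(31)
  for (i in 1:20) {
    n_m <- sample(50:500, 12, replace = TRUE)
    c_m <- rbinom(12, n_m, runif(1, 0.05, 0.3))
    t <- monthly_contingency(c_m, n_m)
    expect_equal(sum((t$population_by_month / t$total_population) *
                       (t$cases_by_month / t$population_by_month)),
                 t$total_cases / t$total_population)
  }
})

test_that("chi-squared matches brute-force summation on random tables", {
  set.seed(11)
  for (i in 1:100) {
    n_m <- sample(20:200, 12, replace = TRUE)
    c_m <- rbinom(12, n_m, runif(1, 0.1, 0.5))
    if (sum(c_m) == 0 || sum(c_m) == sum(n_m)) next
    t <- monthly_contingency(c_m, n_m)
    got <- birth_month_association_test(t)
    expect_equal(got$chi2, bruteforce_chi2(c_m, n_m), tolerance = 1e-9)
    expect_equal(got$df, 11)
    expect_equal(got$p_raw, pchisq(got$chi2, 11, lower.tail = FALSE))
  }
})

test_that("a perfectly homogeneous table gives chi2 = 0, p = 1", {
  t <- monthly_contingency(rep(25, 12), rep(100, 12))
  got <- birth_month_association_test(t)
  expect_equal(got$chi2, 0)
  expect_equal(got$p_raw, 1)
})

test_that("a two-month table reproduces the closed-form 2x2 chi-squared", {
  # all patients concentrated in Jan and Feb; months without births are
  # dropped and df reduces to 1
  c_m <- c(30, 10, rep(0, 10))
  n_m <- c(100, 80, rep(0, 10))
  t <- monthly_contingency(c_m, n_m)
  got <- birth_month_association_test(t)
  a <- 30; b <- 70; cc <- 10; d <- 70
  n <- a + b + cc + d
  closed <- n * (a * d - b * cc)^2 / ((a + b) * (cc + d) * (a + cc) * (b + d))
  expect_equal(got$chi2, closed)
  expect_equal(got$df, 1)
})

test_that("single-month populations are rejected", {
  t <- monthly_contingency(c(10, rep(0, 11)), c(100, rep(0, 11)))
  expect_error(birth_month_association_test(t), "single month")
})

test_that("Benjamini-Hochberg matches hand and brute-force step-up values", {
  expect_equal(benjamini_hochberg(c(0.01, 0.02, 0.03, 0.04)),
               rep(0.04, 4))
  expect_equal(benjamini_hochberg(0.42), 0.42)
  expect_equal(benjamini_hochberg(rep(1, 5)), rep(1, 5))
  expect_error(benjamini_hochberg(c(0.1, 1.2)), "index 2")

  set.seed(7)
  for (i in 1:200) {
    p <- runif(sample(1:40, 1))
    q <- benjamini_hochberg(p)
    expect_equal(q, bruteforce_bh(p), tolerance = 1e-12)
    expect_true(all(q >= p))
    # step-up output is monotone in the raw-p ordering
    expect_true(all(diff(q[order(p)]) >= -1e-15))
  }
})

test_that("scan applies the inclusive 1000-case threshold", {
  # build a cohort by hand: one condition with exactly 999 cases, one with
  # exactly 1000, in a 24000-patient cohort spread evenly over months
  patients <- data.frame(
    patient_id = sprintf("P%05d", 1:24000),
    birth_year = 1970L,
    birth_month = rep(1:12, each = 2000),
    stringsAsFactors = FALSE
  )
  diagnoses <- rbind(
    data.frame(patient_id = patients$patient_id[1:999], code = "JUST_UNDER"),
    data.frame(patient_id = patients$patient_id[seq(1, 24000, length.out = 1000)],
               code = "AT_THRESHOLD")
  )
  dir <- withr::local_tempdir()
  write.csv(patients, file.path(dir, "p.csv"), row.names = FALSE)
  write.csv(diagnoses, file.path(dir, "d.csv"), row.names = FALSE)
  cohort <- read_patients(file.path(dir, "p.csv"), file.path(dir, "d.csv"))
  scan <- run_scan(cohort, scan_config(min_patients_per_condition = 1000))
  expect_equal(scan$condition_code, "AT_THRESHOLD")
  expect_equal(scan$n_cases, 1000L)
  # a single tested condition keeps its raw p unchanged by FDR
  expect_equal(scan$p_fdr, scan$p_raw)
})

test_that("scan output carries coherent curves, extrema and FDR family", {
  pop <- population_spec(30000)
  effects <- list(effect_spec("EFF", 0.08, 0.3, peak_month_phi = 4))
  ds <- generate_cohort(pop, effects, null_conditions = 5, seed = 21)
  scan <- run_scan(ds, scan_config(min_patients_per_condition = 100))
  expect_s3_class(scan, "seawas_scan")
  expect_true(all(scan$p_fdr >= scan$p_raw))
  rr <- as.matrix(scan[paste0("rr_", 1:12)])
  expect_equal(scan$max_rr, apply(rr, 1, max))
  expect_equal(scan$max_rr_month, unname(apply(rr, 1, which.max)))
  expect_equal(scan$min_rr_month, unname(apply(rr, 1, which.min)))
  lo <- as.matrix(scan[paste0("ci_low_", 1:12)])
  hi <- as.matrix(scan[paste0("ci_high_", 1:12)])
  expect_true(all(lo <= rr & rr <= hi))
  # the injected effect dominates the scan
  expect_equal(scan$condition_code[which.min(scan$p_raw)], "EFF")
  expect_equal(scan$max_rr_month[scan$condition_code == "EFF"], 4)
})

test_that("an empty scan is returned with a warning when nothing passes", {
  cohort <- tiny_cohort()
  expect_warning(scan <- run_scan(cohort, scan_config(1000)), "threshold")
  expect_equal(nrow(scan), 0)
  expect_named(scan, names(scan))  # stable column layout
})

test_that("shared condition sets follow the at-both-institutions rule", {
  curves <- list(A = rep(1, 12), B = rep(1, 12), C = rep(1, 12))
  scan_a <- scan_from_curves(curves, n_cases = c(1500L, 1200L, 2000L))
  scan_b <- scan_from_curves(curves, n_cases = c(900L, 1300L, 1000L))
  expect_equal(shared_condition_set(scan_a, scan_b, 1000), c("B", "C"))
  expect_equal(shared_condition_set(scan_a, scan_a, 1000), c("A", "B", "C"))
  scan_d <- scan_from_curves(list(Z = rep(1, 12)), n_cases = 5000L)
  expect_equal(shared_condition_set(scan_a, scan_d, 1000), character(0))
})

test_that("scan results round-trip through the TSV writer", {
  pop <- population_spec(5000)
  ds <- generate_cohort(pop, list(effect_spec("E", 0.2, 0.2, 9)),
                        null_conditions = 2, seed = 3)
  scan <- run_scan(ds, scan_config(min_patients_per_condition = 50))
  path <- withr::local_tempfile(fileext = ".tsv")
  write_scan_results(scan, path)
  back <- read_scan_results(path)
  expect_equal(back$condition_code, scan$condition_code)
  expect_equal(back$p_raw, scan$p_raw, tolerance = 1e-15)
  expect_equal(as.matrix(back[paste0("rr_", 1:12)]),
               as.matrix(scan[paste0("rr_", 1:12)]), tolerance = 1e-15)
})
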