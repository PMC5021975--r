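# Synthetic two-institution EHR cohorts with known birth-month effects.
#
# The generator exists so that every downstream stage (ingest, scan,
# replication, reporting) can be exercised and calibrated against known
# ground truth: real season-wide association inputs are proprietary hospital
# extracts that cannot be redistributed.

# Month-independent prevalences assigned to null conditions, cycled in order.
# The grid straddles the usual >=1000-case inclusion threshold at cohort
# sizes of 10^4..10^6, which is what power / type-I studies need.
NULL_PREVALENCE_GRID <- c(0.001, 0.005, 0.01, 0.05, 0.1)

# Prior for independently re-drawn effects at a second institution:
# peak month uniform on 1..12, amplitude uniform on this range. The range
# corresponds to max relative risks of roughly 1.02-1.17, bracketing what
# birth-month studies report for cardiovascular conditions.
INDEPENDENT_AMPLITUDE_RANGE <- c(0.02, 0.15)

#' Specify a simulated patient population
#'
#' @param n_patients Number of patients to draw (positive integer).
#' @param birth_month_probs Probabilities of being born in January..December;
#'   must be non-negative and sum to 1. Default: uniform.
#' @param birth_year_range Inclusive `c(min, max)` birth-year window.
#'   Default `c(1926, 2000)`, the window used by season-wide association
#'   studies of lifetime disease risk.
#' @param demographic_specs Optional list of demographic attributes, each a
#'   list with elements `name` (column name), `labels` (category labels) and
#'   `probs` (category probabilities summing to 1).
#' @param seed Default integer seed used when [generate_cohort()] is called
#'   without one.
#' @return An object of class `population_spec`.
#' @export
population_spec <- function(n_patients,
                            birth_month_probs = rep(1 / 12, 12),
                            birth_year_range = c(1926L, 2000L),
                            demographic_specs = list(),
                            seed = 1L) {
  if (!is_count(n_patients) || n_patients < 1) {
    stopf("n_patients must be a positive integer, got %s",
          format(n_patients))
  }
  birth_month_probs <- as.numeric(birth_month_probs)
  if (length(birth_month_probs) != 12L || any(birth_month_probs < 0)) {
    stopf("birth_month_probs must be 12 non-negative probabilities")
  }
  if (abs(sum(birth_month_probs) - 1) > 1e-12) {
    stopf("birth_month_probs must sum to 1 (got %.15f)",
          sum(birth_month_probs))
  }
  birth_year_range <- as.integer(birth_year_range)
  if (length(birth_year_range) != 2L ||
      birth_year_range[1] > birth_year_range[2]) {
    stopf("birth_year_range must be an inclusive c(min, max) pair")
  }
  for (d in demographic_specs) {
    if (!all(c("name", "labels", "probs") %in% names(d))) {
      stopf("each demographic spec needs 'name', 'labels' and 'probs'")
    }
    if (length(d$labels) != length(d$probs)) {
      stopf("demographic '%s': labels and probs differ in length", d$name)
    }
    if (abs(sum(d$probs) - 1) > 1e-12) {
      stopf("demographic '%s': probabilities must sum to 1", d$name)
    }
  }
  structure(
    list(n_patients = as.integer(n_patients),
         birth_month_probs = birth_month_probs,
         birth_year_range = birth_year_range,
         demographic_specs = demographic_specs,
         seed = as.integer(seed)),
    class = "population_spec"
  )
}

#' Specify a ground-truth birth-month effect for one condition
#'
#' Under `shape = "cosine"` the per-month disease probability is the
#' multiplicative curve `p0 * (1 + A * cos(2 * pi * (m - phi) / 12))`, so the
#' month of peak risk is `phi` and the marginal prevalence under uniform
#' births is `p0`. `amplitude_A = 0` gives a null (month-independent)
#' condition. A `custom_curve` of 12 non-negative multipliers with mean 1
#' can replace the cosine.
#'
#' @param condition_code Condition code string.
#' @param prevalence_p0 Marginal prevalence under uniform births, in (0, 1).
#' @param amplitude_A Relative amplitude of the seasonal effect, in `[0, 1)`.
#' @param peak_month_phi Month of peak risk, 1 (January) .. 12 (December).
#' @param shape `"cosine"` or `"custom"`.
#' @param custom_curve 12 non-negative multipliers with mean 1 (required for
#'   `shape = "custom"`).
#' @return An object of class `effect_spec`.
#' @export
effect_spec <- function(condition_code, prevalence_p0, amplitude_A = 0,
                        peak_month_phi = 1L,
                        shape = c("cosine", "custom"),
                        custom_curve = NULL) {
  shape <- match.arg(shape)
  if (!is_prob(prevalence_p0) || prevalence_p0 <= 0) {
    stopf("prevalence_p0 must be in (0, 1]")
  }
  if (shape == "cosine") {
    if (!is.numeric(amplitude_A) || amplitude_A < 0 || amplitude_A >= 1) {
      stopf("amplitude_A must lie in [0, 1)")
    }
    if (!(peak_month_phi %in% MONTHS)) {
      stopf("peak_month_phi must be an integer month 1..12")
    }
    if (prevalence_p0 * (1 + amplitude_A) > 1) {
      stopf("effect '%s': peak-month probability %.4f exceeds 1",
            condition_code, prevalence_p0 * (1 + amplitude_A))
    }
  } else {
    custom_curve <- as.numeric(custom_curve)
    if (length(custom_curve) != 12L || any(custom_curve < 0)) {
      stopf("custom_curve must be 12 non-negative multipliers")
    }
    if (abs(mean(custom_curve) - 1) > 1e-9) {
      stopf("custom_curve must have mean 1 so p0 is the marginal prevalence")
    }
    if (prevalence_p0 * max(custom_curve) > 1) {
      stopf("effect '%s': some monthly probability exceeds 1", condition_code)
    }
  }
  structure(
    list(condition_code = as.character(condition_code),
         prevalence_p0 = prevalence_p0,
         amplitude_A = amplitude_A,
         peak_month_phi = as.integer(peak_month_phi),
         shape = shape,
         custom_curve = custom_curve),
    class = "effect_spec"
  )
}

#' Monthly disease probabilities implied by an effect spec
#'
#' @param spec An [effect_spec()].
#' @return Numeric vector of 12 per-birth-month disease probabilities.
#' @export
effect_curve <- function(spec) {
  stopifnot(inherits(spec, "effect_spec"))
  if (spec$shape == "cosine") {
    spec$prevalence_p0 *
      (1 + spec$amplitude_A * cos(2 * pi * (MONTHS - spec$peak_month_phi) / 12))
  } else {
    spec$prevalence_p0 * spec$custom_curve
  }
}

null_effect_specs <- function(n, prefix = "NULLCOND") {
  if (n == 0) return(list())
  lapply(seq_len(n), function(i) {
    effect_spec(
      condition_code = sprintf("%s%03d", prefix, i),
      prevalence_p0 = NULL_PREVALENCE_GRID[(i - 1L) %% length(NULL_PREVALENCE_GRID) + 1L],
      amplitude_A = 0,
      peak_month_phi = 1L
    )
  })
}

#' Generate one synthetic institution cohort
#'
#' Draws birth months from the population's birth-month distribution, birth
#' years uniformly in the configured window, and demographics independently.
#' For each effect condition, disease status is Bernoulli with the monthly
#' probability given by the effect curve at the patient's birth month. Null
#' conditions are month-independent with prevalences cycled through
#' `c(0.001, 0.005, 0.01, 0.05, 0.1)`. Identical inputs and seed reproduce
#' identical output.
#'
#' @param pop A [population_spec()].
#' @param effects List of [effect_spec()] objects (may be empty).
#' @param null_conditions Number of additional null conditions to simulate.
#' @param seed Integer seed (defaults to `pop$seed`).
#' @param institution_label Label stored with the dataset.
#' @return An object of class `institution_dataset`: a list with elements
#'   `institution_label`, `patients` (data frame: `patient_id`, `birth_year`,
#'   `birth_month`, one column per demographic), `diagnoses` (data frame:
#'   `patient_id`, `code`, `vocabulary`), `truth` (data frame of the
#'   generating effect parameters) and `zero_prevalence_codes` (truth codes
#'   that ended up with no cases).
#' @export
generate_cohort <- function(pop, effects = list(), null_conditions = 0L,
                            seed = pop$seed, institution_label = "synthetic") {
  stopifnot(inherits(pop, "population_spec"))
  if (!is_count(null_conditions)) stopf("null_conditions must be >= 0")
  for (e in effects) stopifnot(inherits(e, "effect_spec"))
  specs <- c(effects, null_effect_specs(null_conditions))
  codes <- vapply(specs, `[[`, character(1), "condition_code")
  if (anyDuplicated(codes)) {
    stopf("duplicate condition codes in effects: %s",
          paste(unique(codes[duplicated(codes)]), collapse = ", "))
  }
  n <- pop$n_patients
  with_seed(seed, {
    patients <- data.frame(
      patient_id = sprintf("P%07d", seq_len(n)),
      birth_year = sample(seq(pop$birth_year_range[1], pop$birth_year_range[2]),
                          n, replace = TRUE),
      birth_month = sample.int(12L, n, replace = TRUE,
                               prob = pop$birth_month_probs),
      stringsAsFactors = FALSE
    )
    for (d in pop$demographic_specs) {
      patients[[d$name]] <- sample(as.character(d$labels), n, replace = TRUE,
                                   prob = d$probs)
    }
    diag_pid <- vector("list", length(specs))
    diag_code <- vector("list", length(specs))
    for (i in seq_along(specs)) {
      p_month <- effect_curve(specs[[i]])
      is_case <- stats::runif(n) < p_month[patients$birth_month]
      diag_pid[[i]] <- patients$patient_id[is_case]
      diag_code[[i]] <- rep(codes[i], sum(is_case))
    }
  })
  diagnoses <- data.frame(
    patient_id = as.character(unlist(diag_pid) %||% character(0)),
    code = as.character(unlist(diag_code) %||% character(0)),
    stringsAsFactors = FALSE
  )
  diagnoses$vocabulary <- rep("SNOMED", nrow(diagnoses))
  truth <- data.frame(
    condition_code = codes,
    prevalence_p0 = vapply(specs, `[[`, numeric(1), "prevalence_p0"),
    amplitude_A = vapply(specs, `[[`, numeric(1), "amplitude_A"),
    peak_month_phi = vapply(specs, `[[`, integer(1), "peak_month_phi"),
    shape = vapply(specs, `[[`, character(1), "shape"),
    stringsAsFactors = FALSE
  )
  structure(
    list(institution_label = institution_label,
         patients = patients,
         diagnoses = diagnoses,
         truth = truth,
         zero_prevalence_codes = setdiff(codes, unique(diagnoses$code))),
    class = "institution_dataset"
  )
}

#' @export
print.institution_dataset <- function(x, ...) {
  cat(sprintf("<institution_dataset '%s': %d patients, %d diagnoses, %d conditions>\n",
              x$institution_label, nrow(x$patients), nrow(x$diagnoses),
              nrow(x$truth)))
  invisible(x)
}

#' Generate a matched pair of institution cohorts
#'
#' Emulates a two-site replication design. Under `mode = "shared"` both
#' institutions use identical effect specs (patients still drawn
#' independently); under `"independent"` the second institution re-draws
#' each condition's peak month uniformly on 1..12 and its amplitude
#' uniformly on `[0.02, 0.15]`; under `"null"` all amplitudes are forced to
#' zero at both sites.
#'
#' @param shared List of [effect_spec()] objects defining the first
#'   institution's (and, in shared mode, both institutions') effects.
#' @param mode `"shared"`, `"independent"` or `"null"`.
#' @param pops List of two [population_spec()] objects.
#' @param seed Master integer seed; per-site and effect-redraw seeds are
#'   derived from it.
#' @param null_conditions Null conditions added at both sites.
#' @param labels Institution labels, length 2.
#' @return List of two `institution_dataset` objects.
#' @export
generate_pair <- function(shared, mode = c("shared", "independent", "null"),
                          pops, seed = 1L, null_conditions = 0L,
                          labels = c("site_a", "site_b")) {
  mode <- match.arg(mode)
  stopifnot(length(pops) == 2L, length(labels) == 2L)
  if (mode == "shared" && length(shared) == 0L) {
    stopf("mode 'shared' requires a non-empty list of shared effects")
  }
  zero_amplitude <- function(e) {
    effect_spec(e$condition_code, e$prevalence_p0, amplitude_A = 0,
                peak_month_phi = e$peak_month_phi)
  }
  effects_a <- shared
  effects_b <- switch(
    mode,
    shared = shared,
    null = lapply(shared, zero_amplitude),
    independent = with_seed(derive_seed(seed, "independent-effects"), {
      lapply(shared, function(e) {
        effect_spec(e$condition_code, e$prevalence_p0,
                    amplitude_A = stats::runif(1, INDEPENDENT_AMPLITUDE_RANGE[1],
                                               INDEPENDENT_AMPLITUDE_RANGE[2]),
                    peak_month_phi = sample.int(12L, 1L))
      })
    })
  )
  if (mode == "null") effects_a <- lapply(shared, zero_amplitude)
  ds_a <- generate_cohort(pops[[1]], effects_a, null_conditions,
                          seed = derive_seed(seed, paste0("cohort-", labels[1])),
                          institution_label = labels[1])
  ds_b <- generate_cohort(pops[[2]], effects_b, null_conditions,
                          seed = derive_seed(seed, paste0("cohort-", labels[2])),
                          institution_label = labels[2])
  if (!identical(ds_a$truth$condition_code, ds_b$truth$condition_code)) {
    stopf("condition code lists differ between the two truth sets")
  }
  list(ds_a, ds_b)
}

#' Write a synthetic dataset to delimited files
#'
#' Emits `patients.csv`, `diagnoses.csv` and `truth.csv` in the formats the
#' ingest readers expect; the round trip through [read_patients()] is
#' lossless.
#'
#' @param ds An `institution_dataset`.
#' @param directory Output directory (created if needed).
#' @return Invisibly, the paths written.
#' @export
write_dataset <- function(ds, directory) {
  stopifnot(inherits(ds, "institution_dataset"))
  dir.create(directory, recursive = TRUE, showWarnings = FALSE)
  paths <- file.path(directory, c("patients.csv", "diagnoses.csv", "truth.csv"))
  tables <- list(ds$patients, ds$diagnoses, ds$truth)
  for (i in seq_along(paths)) {
    tryCatch(
      utils::write.csv(tables[[i]], paths[i], row.names = FALSE),
      error = function(e) stopf("failed to write '%s': %s", paths[i],
                                conditionMessage(e))
    )
  }
  invisible(paths)
}
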