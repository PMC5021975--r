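# Reading patient/diagnosis tables, vocabulary mapping, cohort filters and
# per-condition case counting.

#' Read an ICD-9 to SNOMED-CT (or other) code mapping table
#'
#' Expects a comma-delimited file with header
#' `source_code,source_vocabulary,target_code,target_vocabulary`. A source
#' code may map to several targets (many-to-many is permitted); exactly
#' duplicated entries are dropped with a warning.
#'
#' @param path Path to the mapping file.
#' @return A data frame of class `code_mapping`.
#' @export
read_code_mapping <- function(path) {
  m <- utils::read.csv(path, stringsAsFactors = FALSE,
                       colClasses = "character")
  required <- c("source_code", "source_vocabulary", "target_code",
                "target_vocabulary")
  if (!all(required %in% names(m))) {
    stopf("mapping file '%s' must have columns %s", path,
          paste(required, collapse = ", "))
  }
  code_mapping(m[required])
}

#' Construct a code mapping from a data frame
#'
#' @param entries Data frame with columns `source_code`, `source_vocabulary`,
#'   `target_code`, `target_vocabulary`.
#' @return The validated, de-duplicated data frame of class `code_mapping`.
#' @export
code_mapping <- function(entries) {
  entries <- as.data.frame(entries, stringsAsFactors = FALSE)
  dup <- duplicated(entries)
  if (any(dup)) {
    warnf("dropping %d exactly duplicated mapping entries", sum(dup))
    entries <- entries[!dup, , drop = FALSE]
  }
  rownames(entries) <- NULL
  class(entries) <- c("code_mapping", "data.frame")
  entries
}

#' Map a set of source codes to target-vocabulary codes
#'
#' Returns the union of all target codes for the source codes present in the
#' mapping. Source codes without any mapping are dropped, not passed
#' through: the downstream analysis is defined on the target vocabulary.
#' The dropped codes are reported via the `"unmapped"` attribute and, as a
#' count, `"n_unmapped"`.
#'
#' @param codes Character vector of source codes (treated as a set).
#' @param mapping A [code_mapping()].
#' @param source_vocabulary Restrict to mapping rows with this source
#'   vocabulary; `NULL` uses all rows.
#' @return Sorted character vector of distinct target codes, with the
#'   mapping-loss report attached as attributes.
#' @export
apply_mapping <- function(codes, mapping, source_vocabulary = NULL) {
  stopifnot(inherits(mapping, "code_mapping"))
  codes <- unique(as.character(codes))
  m <- mapping
  if (!is.null(source_vocabulary)) {
    m <- m[m$source_vocabulary %in% source_vocabulary, , drop = FALSE]
  }
  hit <- m$source_code %in% codes
  targets <- sort(unique(m$target_code[hit]))
  unmapped <- sort(setdiff(codes, m$source_code))
  structure(targets, unmapped = unmapped, n_unmapped = length(unmapped))
}

#' Cohort inclusion filter
#'
#' @param birth_year_min,birth_year_max Inclusive birth-year window
#'   (defaults 1926-2000).
#' @param treatment_year_min,treatment_year_max Optional inclusive
#'   service-era window; applied by [filter_cohort()] only when the patient
#'   table carries a `service_year` column.
#' @return An object of class `cohort_filter`.
#' @export
cohort_filter <- function(birth_year_min = 1926L, birth_year_max = 2000L,
                          treatment_year_min = NULL,
                          treatment_year_max = NULL) {
  if (birth_year_min > birth_year_max) {
    stopf("birth_year_min must not exceed birth_year_max")
  }
  if (!is.null(treatment_year_min) && !is.null(treatment_year_max) &&
      treatment_year_min > treatment_year_max) {
    stopf("treatment_year_min must not exceed treatment_year_max")
  }
  structure(list(birth_year_min = as.integer(birth_year_min),
                 birth_year_max = as.integer(birth_year_max),
                 treatment_year_min = treatment_year_min,
                 treatment_year_max = treatment_year_max),
            class = "cohort_filter")
}

new_cohort <- function(patients, diagnoses, mapping_loss = NULL) {
  diagnoses <- unique(diagnoses[c("patient_id", "code")])
  rownames(diagnoses) <- NULL
  rownames(patients) <- NULL
  structure(list(patients = patients, diagnoses = diagnoses,
                 mapping_loss = mapping_loss),
            class = "seawas_cohort")
}

#' @export
print.seawas_cohort <- function(x, ...) {
  cat(sprintf("<seawas_cohort: %d patients, %d distinct (patient, condition) pairs>\n",
              nrow(x$patients), nrow(x$diagnoses)))
  if (!is.null(x$mapping_loss) && x$mapping_loss$n_unmapped_codes > 0) {
    cat(sprintf("  mapping loss: %d source codes without a mapping (%d rows dropped)\n",
                x$mapping_loss$n_unmapped_codes, x$mapping_loss$n_dropped_rows))
  }
  invisible(x)
}

#' Read patient and diagnosis tables into an analysis cohort
#'
#' The patient file needs columns `patient_id`, `birth_year`, `birth_month`
#' (1-12); any further columns are kept as demographics. The diagnosis file
#' needs `patient_id`, `code` and optionally `vocabulary`. Diagnoses are
#' reduced to distinct (patient, code) pairs - the analysis is
#' presence/absence per patient. Patients with no diagnoses are retained
#' with an empty code set. When a mapping is supplied, each diagnosis code
#' is replaced by all of its target codes; source codes without a mapping
#' are dropped and counted in the cohort's `mapping_loss` report.
#'
#' @param path_patients Path to the patients CSV.
#' @param path_diagnoses Path to the diagnoses CSV.
#' @param mapping Optional [code_mapping()] applied to diagnosis codes.
#' @return An object of class `seawas_cohort`: a list with `patients` and
#'   `diagnoses` data frames plus a `mapping_loss` report.
#' @export
read_patients <- function(path_patients, path_diagnoses, mapping = NULL) {
  pat <- utils::read.csv(path_patients, stringsAsFactors = FALSE,
                         colClasses = c(patient_id = "character"))
  required <- c("patient_id", "birth_year", "birth_month")
  if (!all(required %in% names(pat))) {
    stopf("patients file '%s' must have columns %s", path_patients,
          paste(required, collapse = ", "))
  }
  bad <- which(!(pat$birth_month %in% MONTHS))
  if (length(bad)) {
    stopf("malformed birth_month outside 1..12 in '%s' at line(s) %s",
          path_patients, paste(bad + 1L, collapse = ", "))
  }
  if (anyDuplicated(pat$patient_id)) {
    dup_ids <- unique(pat$patient_id[duplicated(pat$patient_id)])
    for (id in dup_ids) {
      rows <- pat[pat$patient_id == id, c("birth_year", "birth_month")]
      if (nrow(unique(rows)) > 1L) {
        stopf("duplicate patient_id '%s' with conflicting birth fields", id)
      }
    }
    pat <- pat[!duplicated(pat$patient_id), , drop = FALSE]
  }

  diag <- utils::read.csv(path_diagnoses, stringsAsFactors = FALSE,
                          colClasses = c(patient_id = "character",
                                         code = "character"))
  if (!all(c("patient_id", "code") %in% names(diag))) {
    stopf("diagnoses file '%s' must have columns patient_id, code",
          path_diagnoses)
  }
  unknown <- !(diag$patient_id %in% pat$patient_id)
  if (any(unknown)) {
    warnf("dropping %d diagnosis rows for patient ids absent from the patient table",
          sum(unknown))
    diag <- diag[!unknown, , drop = FALSE]
  }

  mapping_loss <- list(n_unmapped_codes = 0L, unmapped_codes = character(0),
                       n_dropped_rows = 0L)
  if (!is.null(mapping)) {
    stopifnot(inherits(mapping, "code_mapping"))
    if (!"vocabulary" %in% names(diag)) diag$vocabulary <- NA_character_
    key_diag <- paste(diag$vocabulary, diag$code, sep = "\r")
    key_map <- paste(mapping$source_vocabulary, mapping$source_code,
                     sep = "\r")
    hit <- key_diag %in% key_map
    mapping_loss <- list(
      n_unmapped_codes = length(unique(diag$code[!hit])),
      unmapped_codes = sort(unique(diag$code[!hit])),
      n_dropped_rows = sum(!hit)
    )
    mapped <- merge(
      data.frame(patient_id = diag$patient_id[hit], key = key_diag[hit],
                 stringsAsFactors = FALSE),
      data.frame(key = key_map, code = mapping$target_code,
                 stringsAsFactors = FALSE),
      by = "key"
    )
    diag <- mapped[c("patient_id", "code")]
  }
  new_cohort(pat, diag[c("patient_id", "code")], mapping_loss)
}

#' Apply a cohort filter
#'
#' Retains exactly the patients whose `birth_year` falls in the inclusive
#' window (and, if the filter carries a treatment-era window and the patient
#' table has a `service_year` column, whose service year falls in that
#' window). Patient order is preserved; diagnoses of removed patients are
#' dropped. Applying the same filter twice is a no-op.
#'
#' @param cohort A `seawas_cohort`.
#' @param f A [cohort_filter()].
#' @return The filtered `seawas_cohort`.
#' @export
filter_cohort <- function(cohort, f = cohort_filter()) {
  stopifnot(inherits(cohort, "seawas_cohort"), inherits(f, "cohort_filter"))
  keep <- cohort$patients$birth_year >= f$birth_year_min &
    cohort$patients$birth_year <= f$birth_year_max
  if ("service_year" %in% names(cohort$patients)) {
    if (!is.null(f$treatment_year_min)) {
      keep <- keep & cohort$patients$service_year >= f$treatment_year_min
    }
    if (!is.null(f$treatment_year_max)) {
      keep <- keep & cohort$patients$service_year <= f$treatment_year_max
    }
  }
  patients <- cohort$patients[keep, , drop = FALSE]
  diagnoses <- cohort$diagnoses[cohort$diagnoses$patient_id %in%
                                  patients$patient_id, , drop = FALSE]
  new_cohort(patients, diagnoses, cohort$mapping_loss)
}

#' Convert objects to an analysis cohort
#'
#' @param x Object to convert.
#' @param ... Passed to methods.
#' @return A `seawas_cohort`.
#' @export
as_cohort <- function(x, ...) UseMethod("as_cohort")

#' @describeIn as_cohort Convert a synthetic `institution_dataset` directly,
#'   without a round trip through files.
#' @export
as_cohort.institution_dataset <- function(x, ...) {
  new_cohort(x$patients, x$diagnoses[c("patient_id", "code")])
}

#' @export
as_cohort.seawas_cohort <- function(x, ...) x

#' Per-condition, per-birth-month case counts
#'
#' For every condition code, counts the patients carrying the code by birth
#' month, together with the population's per-month totals. These counts are
#' the sufficient statistics for the association scan.
#'
#' @param cohort A `seawas_cohort` (already cohort-filtered).
#' @return An object of class `case_counts`: list with `cases` (matrix,
#'   conditions x 12 months), `n_month` (population per birth month) and
#'   `n_total`.
#' @export
condition_case_counts <- function(cohort) {
  stopifnot(inherits(cohort, "seawas_cohort"))
  n_month <- tabulate(cohort$patients$birth_month, nbins = 12L)
  d <- cohort$diagnoses
  if (nrow(d) == 0L) {
    cases <- matrix(integer(0), nrow = 0, ncol = 12,
                    dimnames = list(character(0), as.character(MONTHS)))
  } else {
    bm <- cohort$patients$birth_month[match(d$patient_id,
                                            cohort$patients$patient_id)]
    tab <- table(code = d$code, month = factor(bm, levels = MONTHS))
    cases <- matrix(as.integer(tab), nrow = nrow(tab),
                    dimnames = list(rownames(tab), as.character(MONTHS)))
  }
  structure(list(cases = cases, n_month = n_month,
                 n_total = nrow(cohort$patients)),
            class = "case_counts")
}
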