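# Enumerations shared across the cohort schema
.sexes <- c("male", "female")
.pupil_levels <- c("normal", "unilateral_dilated", "bilateral_dilated")
.marshall_levels <- c("no_ct", "1", "2", "3", "4", "5", "6")
.sequences <- c("FLAIR", "DWI", "T2GRE_SWI")
.sides <- c("left", "right", "midline")

#' Packaged anatomical location ontology
#'
#' Returns the 58-entry location ontology used to register traumatic axonal
#' injury (TAI): laterality-resolved anatomical sites, each mapped to one of
#' ten region groups (hemispheric white matter, cerebellum, corpus callosum,
#' basal ganglia, thalamus, posterior limb of the internal capsule,
#' mesencephalon, pons, medulla, cerebellar peduncles). The ontology ships as
#' a plain CSV resource so that an alternative location list can be
#' substituted without code change.
#'
#' @param path Optional path to a replacement ontology CSV with columns
#'   `code`, `region_group`, `side`.
#' @return A data frame with columns `code`, `region_group`, `side`; exactly
#'   one row per sided location entry.
#' @export
tai_ontology <- function(path = NULL) {
  if (is.null(path)) {
    path <- system.file("extdata", "ontology.csv", package = "taigrade")
  }
  ont <- utils::read.csv(path, stringsAsFactors = FALSE)
  required <- c("code", "region_group", "side")
  if (!all(required %in% names(ont))) {
    stop("ontology file must have columns code, region_group, side")
  }
  key <- paste(ont$code, ont$side)
  if (anyDuplicated(key)) {
    stop("ontology contains duplicated (code, side) entries: ",
         paste(key[duplicated(key)], collapse = ", "))
  }
  grp <- tapply(ont$region_group, ont$code, function(g) length(unique(g)))
  if (any(grp > 1)) {
    stop("ontology codes mapped to multiple region groups: ",
         paste(names(grp)[grp > 1], collapse = ", "))
  }
  ont
}

#' Classify TBI severity from the admission GCS score
#'
#' Severity strata follow the usual clinical convention with GCS 13 assigned
#' to the moderate group: severe for GCS 3-8, moderate for 9-13, mild for
#' 14-15.
#'
#' @param gcs Integer vector of admission Glasgow Coma Scale scores (3-15).
#'   Missing values propagate as `NA`.
#' @return Character vector with values `"severe"`, `"moderate"`, `"mild"`.
#' @examples
#' classify_severity(c(8, 13, 15))
#' @export
classify_severity <- function(gcs) {
  bad <- !is.na(gcs) & (gcs < 3 | gcs > 15 | gcs != round(gcs))
  if (any(bad)) {
    stop("GCS score out of range [3, 15]: ",
         paste(unique(gcs[bad]), collapse = ", "))
  }
  out <- rep(NA_character_, length(gcs))
  out[!is.na(gcs) & gcs <= 8] <- "severe"
  out[!is.na(gcs) & gcs >= 9 & gcs <= 13] <- "moderate"
  out[!is.na(gcs) & gcs >= 14] <- "mild"
  out
}

.stop_schema <- function(file, rows, column, msg) {
  stop(sprintf("%s: %s (column '%s', row(s) %s)", file, msg, column,
               paste(utils::head(rows, 5), collapse = ", ")),
       call. = FALSE)
}

.check <- function(ok, file, column, msg) {
  if (any(!ok, na.rm = TRUE)) .stop_schema(file, which(!ok), column, msg)
}

#' Assemble and validate a cohort aggregate
#'
#' Joins the four cohort tables into a validated aggregate, enforcing all
#' schema invariants: enumerated fields, GCS in 3-15, non-negative days to
#' MRI, lesion rows consistent (`present = FALSE` implies zero count and
#' volume, no volumes on T2*GRE/SWI), location codes restricted to the
#' ontology, and no duplicated (patient, location, side, sequence) rows.
#'
#' @param patients,lesions,contusions,outcomes Data frames following the
#'   documented CSV schemas.
#' @param ontology Location ontology, default [tai_ontology()].
#' @return An object of class `tai_cohort`: a list with elements `patients`,
#'   `lesions`, `contusions`, `outcomes`, `ontology`.
#' @export
as_cohort <- function(patients, lesions, contusions, outcomes,
                      ontology = tai_ontology()) {
  # patients
  .check(!is.na(patients$patient_id) & patients$patient_id != "",
         "patients", "patient_id", "missing patient id")
  if (anyDuplicated(patients$patient_id)) {
    .stop_schema("patients", which(duplicated(patients$patient_id)),
                 "patient_id", "duplicated patient id")
  }
  .check(is.na(patients$gcs) |
           (patients$gcs >= 3 & patients$gcs <= 15 &
              patients$gcs == round(patients$gcs)),
         "patients", "gcs", "GCS score outside [3, 15]")
  .check(patients$sex %in% .sexes, "patients", "sex", "unknown sex code")
  .check(patients$pupils %in% .pupil_levels, "patients", "pupils",
         "unknown pupil code")
  .check(as.character(patients$marshall) %in% .marshall_levels,
         "patients", "marshall", "Marshall score outside enumerated set")
  .check(patients$days_to_mri >= 0 &
           patients$days_to_mri == round(patients$days_to_mri),
         "patients", "days_to_mri", "negative or non-integer days to MRI")
  .check(patients$contusion_on_ct %in% c(TRUE, FALSE),
         "patients", "contusion_on_ct", "non-boolean value")
  patients$marshall <- as.character(patients$marshall)

  ids <- patients$patient_id

  # lesions
  if (nrow(lesions)) {
    .check(lesions$patient_id %in% ids, "lesions", "patient_id",
           "patient id not in patients table")
    okloc <- paste(lesions$location_code, lesions$side) %in%
      paste(ontology$code, ontology$side)
    if (any(!okloc)) {
      bad <- unique(paste(lesions$location_code, lesions$side)[!okloc])
      .stop_schema("lesions", which(!okloc), "location_code",
                   paste0("location not in ontology: ",
                          paste(utils::head(bad, 3), collapse = "; ")))
    }
    .check(lesions$sequence %in% .sequences, "lesions", "sequence",
           "unknown MRI sequence")
    key <- paste(lesions$patient_id, lesions$location_code, lesions$side,
                 lesions$sequence)
    if (anyDuplicated(key)) {
      .stop_schema("lesions", which(duplicated(key)), "patient_id",
                   "duplicated (patient, location, side, sequence) row")
    }
    .check(lesions$present %in% c(TRUE, FALSE), "lesions", "present",
           "non-boolean value")
    .check(lesions$count >= 0 & lesions$count == round(lesions$count),
           "lesions", "count", "negative or non-integer lesion count")
    .check(lesions$volume_cm3 >= 0, "lesions", "volume_cm3",
           "negative lesion volume")
    .check(lesions$present | (lesions$count == 0 & lesions$volume_cm3 == 0),
           "lesions", "present", "present = FALSE with nonzero count/volume")
    .check(!lesions$present | lesions$count >= 1, "lesions", "count",
           "present = TRUE requires count >= 1")
    .check(lesions$sequence != "T2GRE_SWI" | lesions$volume_cm3 == 0,
           "lesions", "volume_cm3",
           "volumes are segmented on FLAIR/DWI only; T2GRE_SWI must be 0")
  }

  # contusions
  if (nrow(contusions)) {
    .check(contusions$patient_id %in% ids, "contusions", "patient_id",
           "patient id not in patients table")
    .check(contusions$present_mri %in% c(TRUE, FALSE), "contusions",
           "present_mri", "non-boolean value")
    .check(contusions$volume_cm3_flair >= 0, "contusions",
           "volume_cm3_flair", "negative contusion volume")
    .check(contusions$present_mri | contusions$volume_cm3_flair == 0,
           "contusions", "present_mri",
           "present_mri = FALSE with nonzero volume")
    if (anyDuplicated(contusions$patient_id)) {
      .stop_schema("contusions", which(duplicated(contusions$patient_id)),
                   "patient_id", "duplicated patient id")
    }
  }

  # outcomes
  if (nrow(outcomes)) {
    .check(outcomes$patient_id %in% ids, "outcomes", "patient_id",
           "patient id not in patients table")
    for (col in c("gose3", "gose6", "gose12")) {
      v <- outcomes[[col]]
      .check(is.na(v) | (v >= 1 & v <= 8 & v == round(v)),
             "outcomes", col, "GOSE score outside [1, 8]")
    }
    if (anyDuplicated(outcomes$patient_id)) {
      .stop_schema("outcomes", which(duplicated(outcomes$patient_id)),
                   "patient_id", "duplicated patient id")
    }
  }

  structure(list(patients = patients, lesions = lesions,
                 contusions = contusions, outcomes = outcomes,
                 ontology = ontology),
            class = "tai_cohort")
}

#' Read a cohort from its CSV tables
#'
#' Reads `patients.csv`, `lesions.csv`, `contusions.csv`, and `outcomes.csv`
#' from a directory (UTF-8, comma separator, `.` decimal, empty cell =
#' missing) and validates all invariants via [as_cohort()].
#'
#' @param dir Directory holding the four cohort CSV files.
#' @param ontology Location ontology, default [tai_ontology()].
#' @return A validated `tai_cohort` object.
#' @export
read_cohort <- function(dir, ontology = tai_ontology()) {
  rd <- function(name, cols) {
    path <- file.path(dir, name)
    if (!file.exists(path)) stop("missing cohort file: ", path)
    x <- utils::read.csv(path, stringsAsFactors = FALSE,
                         colClasses = cols, na.strings = "")
    x
  }
  patients <- rd("patients.csv", c(
    patient_id = "character", age = "numeric", sex = "character",
    gcs = "integer", pupils = "character", marshall = "character",
    days_to_mri = "integer", contusion_on_ct = "logical"))
  lesions <- rd("lesions.csv", c(
    patient_id = "character", location_code = "character",
    side = "character", sequence = "character", present = "logical",
    count = "integer", volume_cm3 = "numeric"))
  contusions <- rd("contusions.csv", c(
    patient_id = "character", present_mri = "logical",
    volume_cm3_flair = "numeric"))
  outcomes <- rd("outcomes.csv", c(
    patient_id = "character", gose3 = "integer", gose6 = "integer",
    gose12 = "integer"))
  as_cohort(patients, lesions, contusions, outcomes, ontology)
}

#' Write a cohort to CSV tables
#'
#' Inverse of [read_cohort()]: writes the four cohort tables so that reading
#' them back reproduces the cohort exactly at value level. Missing cells are
#' written as empty fields.
#'
#' @param cohort A `tai_cohort` object.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  stopifnot(inherits(cohort, "tai_cohort"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  wr <- function(x, name) {
    utils::write.csv(x, file.path(dir, name), row.names = FALSE, na = "",
                     quote = FALSE)
  }
  wr(cohort$patients, "patients.csv")
  wr(cohort$lesions, "lesions.csv")
  wr(cohort$contusions, "contusions.csv")
  wr(cohort$outcomes, "outcomes.csv")
  invisible(dir)
}

#' @export
print.tai_cohort <- function(x, ...) {
  cat("TAI cohort:", nrow(x$patients), "patients,",
      sum(x$lesions$present), "lesion annotations,",
      sum(x$contusions$present_mri), "patients with MRI contusions\n")
  sev <- classify_severity(x$patients$gcs)
  print(table(severity = factor(sev, c("mild", "moderate", "severe")),
              useNA = "ifany"))
  invisible(x)
}
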