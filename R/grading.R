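# Declarative rule engine for the anatomical TAI grading systems.

#' Load a grading rule set
#'
#' Rule sets are YAML data files mapping grades to predicate expressions over
#' the named region-feature flags (see [feature_flags()]). The final grade of
#' a patient is the highest grade whose predicate holds; patients without TAI
#' receive the rule set's `no_tai_grade` (0 for the Trondheim, standard, and
#' GCS-based systems; 1 for the Stockholm-style system, which does not
#' distinguish no-TAI patients from hemispheric TAI).
#'
#' Four rule sets ship with the package: `"trondheim"`, `"standard"`,
#' `"stockholm"`, and `"gcs_based"`. The Stockholm-style and GCS-based files
#' are approximate reconstructions (their original tier definitions are not
#' restated in full by this study) and are marked as such in the files.
#'
#' @param name One of the packaged rule set names, or a path to a custom
#'   YAML rule file.
#' @return An object of class `tai_ruleset`.
#' @export
grading_ruleset <- function(name) {
  path <- if (file.exists(name)) name else
    system.file("extdata", "rulesets", paste0(name, ".yaml"),
                package = "taigrade")
  if (!nzchar(path) || !file.exists(path)) {
    stop("unknown grading rule set: ", name)
  }
  rs <- yaml::read_yaml(path)
  if (is.null(rs$name) || is.null(rs$rules) || is.null(rs$no_tai_grade)) {
    stop("rule set file must define name, no_tai_grade, rules")
  }
  grades <- vapply(rs$rules, function(r) as.integer(r$grade), integer(1))
  if (any(diff(grades) <= 0)) {
    stop("rule grades must be strictly increasing")
  }
  exprs <- lapply(rs$rules, function(r) {
    # predicates are written scalar-style; evaluate vectorised
    txt <- gsub("\\|\\|", "|", gsub("&&", "&", r$when))
    e <- parse(text = txt)[[1]]
    unknown <- setdiff(all.vars(e), feature_flags())
    if (length(unknown)) {
      stop("rule set '", rs$name, "' references unknown feature(s): ",
           paste(unknown, collapse = ", "))
    }
    e
  })
  structure(list(name = rs$name, no_tai_grade = as.integer(rs$no_tai_grade),
                 grades = grades, predicates = exprs),
            class = "tai_ruleset")
}

#' @export
print.tai_ruleset <- function(x, ...) {
  cat("TAI grading rule set '", x$name, "' (no-TAI grade ",
      x$no_tai_grade, ")\n", sep = "")
  for (i in seq_along(x$grades)) {
    cat("  grade", x$grades[i], ":", deparse(x$predicates[[i]]), "\n")
  }
  invisible(x)
}

#' Apply a grading rule set to region features
#'
#' Evaluates every rule predicate on the feature table and returns, per
#' patient, the maximum grade whose predicate holds; patients without any TAI
#' receive the rule set's no-TAI grade.
#'
#' @param features Data frame of region features from [extract_features()]
#'   (one or more rows).
#' @param ruleset A `tai_ruleset` or the name of a packaged rule set.
#' @return Integer vector of grades, one per feature row.
#' @examples
#' \dontrun{
#' fx <- extract_features(cohort)
#' apply_grading(fx, "trondheim")
#' }
#' @export
apply_grading <- function(features, ruleset) {
  if (is.character(ruleset)) ruleset <- grading_ruleset(ruleset)
  stopifnot(inherits(ruleset, "tai_ruleset"))
  n <- nrow(features)
  grade <- rep(ruleset$no_tai_grade, n)
  for (i in seq_along(ruleset$grades)) {
    hit <- eval(ruleset$predicates[[i]], features, baseenv())
    if (length(hit) == 1) hit <- rep(hit, n)
    grade <- ifelse(features$any_tai & hit, pmax(grade, ruleset$grades[i]),
                    grade)
  }
  as.integer(grade)
}

#' Grade a cohort and summarise outcome by grade
#'
#' Applies a rule set to every patient and, when an outcome vector is
#' supplied, summarises it per grade (n, mean, SD), mirroring the
#' per-grade mean GOSE presentation used when comparing grading systems.
#'
#' @param cohort A validated `tai_cohort`.
#' @param ruleset A `tai_ruleset` or packaged rule set name.
#' @param outcome Optional numeric vector aligned with `cohort$patients`
#'   (e.g. the 6-month GOSE score).
#' @return A list with `grades` (patient_id, grade) and `summary` (grade, n,
#'   mean, sd of the outcome; only grades with n >= 1, ordered by grade).
#' @export
grade_cohort <- function(cohort, ruleset, outcome = NULL) {
  fx <- extract_features(cohort)
  g <- apply_grading(fx, ruleset)
  grades <- data.frame(patient_id = cohort$patients$patient_id, grade = g,
                       stringsAsFactors = FALSE)
  summary <- data.frame(grade = sort(unique(g)))
  summary$n <- as.integer(table(g)[as.character(summary$grade)])
  if (!is.null(outcome)) {
    stopifnot(length(outcome) == nrow(grades))
    summary$mean <- as.numeric(tapply(outcome, g, mean, na.rm = TRUE))
    summary$sd <- as.numeric(tapply(outcome, g, stats::sd, na.rm = TRUE))
    summary$sd[summary$n == 1] <- 0
  }
  list(grades = grades, summary = summary)
}
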