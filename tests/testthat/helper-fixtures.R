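# Fixture builders: small hand-constructed cohorts and feature rows.

blank_patients <- function(ids, gcs = 6) {
  data.frame(patient_id = ids, age = 30, sex = "male", gcs = gcs,
             pupils = "normal", marshall = "2", days_to_mri = 5L,
             contusion_on_ct = FALSE, stringsAsFactors = FALSE)
}

empty_lesions <- function() {
  data.frame(patient_id = character(0), location_code = character(0),
             side = character(0), sequence = character(0),
             present = logical(0), count = integer(0),
             volume_cm3 = numeric(0), stringsAsFactors = FALSE)
}

# lesion rows: list of c(patient, code, side, sequence) (+ optional count,
# volume)
lesion_rows <- function(...) {
  specs <- list(...)
  do.call(rbind, lapply(specs, function(s) {
    data.frame(patient_id = s[[1]], location_code = s[[2]], side = s[[3]],
               sequence = s[[4]], present = TRUE,
               count = if (length(s) >= 5) as.integer(s[[5]]) else 1L,
               volume_cm3 = if (length(s) >= 6) as.numeric(s[[6]]) else
                 if (s[[4]] == "T2GRE_SWI") 0 else 0.5,
               stringsAsFactors = FALSE)
  }))
}

make_cohort <- function(lesions = empty_lesions(), ids = NULL, gcs = 6,
                        gose6 = NA_integer_, gose3 = NA_integer_,
                        gose12 = NA_integer_, contusions = NULL) {
  if (is.null(ids)) {
    ids <- unique(lesions$patient_id)
    if (!length(ids)) ids <- "p1"
  }
  patients <- blank_patients(ids, gcs = gcs)
  if (is.null(contusions)) {
    contusions <- data.frame(patient_id = ids, present_mri = FALSE,
                             volume_cm3_flair = 0, stringsAsFactors = FALSE)
  }
  outcomes <- data.frame(patient_id = ids,
                         gose3 = rep_len(gose3, length(ids)),
                         gose6 = rep_len(gose6, length(ids)),
                         gose12 = rep_len(gose12, length(ids)),
                         stringsAsFactors = FALSE)
  as_cohort(patients, lesions, contusions, outcomes)
}

# one-row feature table with every flag FALSE and totals 0, overridable
feature_row <- function(...) {
  fx <- as.data.frame(setNames(as.list(rep(FALSE, length(feature_flags()))),
                               feature_flags()))
  fx$vol_tai_flair_cm3 <- 0
  fx$vol_tai_dwi_cm3 <- 0
  fx$n_tai_t2gre_swi <- 0
  fx$n_tai_brainstem_t2gre_swi <- 0
  fx$vol_contusion_flair_cm3 <- 0
  over <- list(...)
  for (nm in names(over)) fx[[nm]] <- over[[nm]]
  # keep derived flags consistent
  fx$tai_brainstem_bil <- fx$tai_mesencephalon_bil | fx$tai_pons_bil |
    fx$tai_medulla_bil
  bs_any <- fx$tai_mesencephalon_uni | fx$tai_mesencephalon_bil |
    fx$tai_pons_uni | fx$tai_pons_bil | fx$tai_medulla_uni |
    fx$tai_medulla_bil
  fx$tai_brainstem_any <- bs_any
  fx$tai_brainstem_uni <- bs_any & !fx$tai_brainstem_bil
  flags <- setdiff(feature_flags(), c("any_tai", "contusion_on_mri"))
  fx$any_tai <- Reduce(`|`, fx[flags])
  fx
}

# small synthetic config for fast generator tests
small_config <- function(n_severe = 120, n_mild = 0) {
  cfg <- preset_paper()
  cfg$strata$severe$n <- n_severe
  cfg$strata$moderate_9_12$n <- 0
  cfg$strata$moderate_13$n <- 0
  cfg$strata$mild$n <- n_mild
  cfg
}
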