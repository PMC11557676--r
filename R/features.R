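# Per-patient region features derived from lesion annotations.
#
# A region group is "present" on a side if any of its locations carries a
# lesion on ANY of the three sequences; bilaterality requires left and right
# presence of the same region group (the sequences may differ between sides).

.paired_groups <- c("internal_capsule_pl", "basal_ganglia", "thalamus",
                    "mesencephalon", "pons", "medulla", "cerebellar_peduncle")
.brainstem_groups <- c("mesencephalon", "pons", "medulla")

#' Feature flag names used by the grading rule sets
#' @return Character vector of all boolean region-feature names.
#' @export
feature_flags <- function() {
  c("tai_hemispheric", "tai_cerebellum", "tai_corpus_callosum",
    paste0("tai_", rep(.paired_groups, each = 2), c("_uni", "_bil")),
    "tai_brainstem_any", "tai_brainstem_uni", "tai_brainstem_bil",
    "any_tai", "contusion_on_mri")
}

.agg_sum <- function(values, ids, all_ids) {
  out <- rep(0, length(all_ids))
  if (length(values)) {
    s <- tapply(values, factor(ids, levels = all_ids), sum)
    out[!is.na(s)] <- s[!is.na(s)]
  }
  out
}

#' Derive per-patient region features from lesion annotations
#'
#' Computes, for every patient, the boolean location flags consumed by the
#' grading rule sets (hemispheric, cerebellar, callosal, and
#' unilateral/bilateral flags for the deep and brainstem region groups)
#' together with the quantitative totals: total TAI volume on FLAIR and on
#' DWI (cm^3), total TAI lesion count on T2*GRE/SWI, brainstem TAI count on
#' T2*GRE/SWI, and contusion presence/volume on FLAIR.
#'
#' A region group is present on a side if any of its locations has
#' `present = TRUE` on any sequence; `*_bil` requires left and right
#' presence, `*_uni` presence on exactly one side. `tai_brainstem_bil` is
#' true iff some single brainstem segment (mesencephalon, pons, or medulla)
#' is bilateral; cerebellar peduncles are tracked separately.
#'
#' @param cohort A validated `tai_cohort`.
#' @return A data frame with one row per patient (same order as
#'   `cohort$patients`).
#' @export
extract_features <- function(cohort) {
  stopifnot(inherits(cohort, "tai_cohort"))
  ids <- cohort$patients$patient_id
  les <- cohort$lesions
  ont <- cohort$ontology
  pres <- les[les$present, , drop = FALSE]
  pres$group <- ont$region_group[match(pres$location_code, ont$code)]

  fx <- data.frame(patient_id = ids, stringsAsFactors = FALSE)
  has <- function(sel_group, sel_side = NULL) {
    sel <- pres$group %in% sel_group
    if (!is.null(sel_side)) sel <- sel & pres$side %in% sel_side
    ids %in% pres$patient_id[sel]
  }
  fx$tai_hemispheric <- has("hemispheric_wm")
  fx$tai_cerebellum <- has("cerebellum")
  fx$tai_corpus_callosum <- has("corpus_callosum")
  for (g in .paired_groups) {
    left <- has(g, "left")
    right <- has(g, "right")
    fx[[paste0("tai_", g, "_uni")]] <- xor(left, right)
    fx[[paste0("tai_", g, "_bil")]] <- left & right
  }
  bs_pres <- has(.brainstem_groups)
  bs_bil <- fx$tai_mesencephalon_bil | fx$tai_pons_bil | fx$tai_medulla_bil
  fx$tai_brainstem_any <- bs_pres
  fx$tai_brainstem_uni <- bs_pres & !bs_bil
  fx$tai_brainstem_bil <- bs_bil
  fx$any_tai <- ids %in% pres$patient_id

  fx$vol_tai_flair_cm3 <- .agg_sum(
    pres$volume_cm3[pres$sequence == "FLAIR"],
    pres$patient_id[pres$sequence == "FLAIR"], ids)
  fx$vol_tai_dwi_cm3 <- .agg_sum(
    pres$volume_cm3[pres$sequence == "DWI"],
    pres$patient_id[pres$sequence == "DWI"], ids)
  fx$n_tai_t2gre_swi <- .agg_sum(
    pres$count[pres$sequence == "T2GRE_SWI"],
    pres$patient_id[pres$sequence == "T2GRE_SWI"], ids)
  bs_t2 <- pres$sequence == "T2GRE_SWI" & pres$group %in% .brainstem_groups
  fx$n_tai_brainstem_t2gre_swi <- .agg_sum(
    pres$count[bs_t2], pres$patient_id[bs_t2], ids)

  cont <- cohort$contusions
  m <- match(ids, cont$patient_id)
  fx$contusion_on_mri <- !is.na(m) & cont$present_mri[m]
  fx$vol_contusion_flair_cm3 <- ifelse(is.na(m), 0, cont$volume_cm3_flair[m])
  fx$vol_contusion_flair_cm3[is.na(fx$vol_contusion_flair_cm3)] <- 0
  fx
}
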