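test_that("packaged ontology has 58 sided entries mapped to unique groups", {
  ont <- tai_ontology()
  expect_equal(nrow(ont), 58)
  expect_equal(anyDuplicated(paste(ont$code, ont$side)), 0)
  per_code <- tapply(ont$region_group, ont$code, function(g) length(unique(g)))
  expect_true(all(per_code == 1))
  expect_setequal(unique(ont$region_group),
                  c("hemispheric_wm", "cerebellum", "corpus_callosum",
                    "basal_ganglia", "thalamus", "internal_capsule_pl",
                    "mesencephalon", "pons", "medulla",
                    "cerebellar_peduncle"))
})

test_that("severity classification partitions the GCS range", {
  expect_equal(classify_severity(8), "severe")
  expect_equal(classify_severity(13), "moderate")
  expect_equal(classify_severity(15), "mild")
  all_gcs <- 3:15
  sev <- classify_severity(all_gcs)
  expect_equal(sev, c(rep("severe", 6), rep("moderate", 5), rep("mild", 2)))
  expect_error(classify_severity(2), "out of range.*2")
  expect_error(classify_severity(16), "out of range.*16")
  expect_true(is.na(classify_severity(NA)))
})

test_that("cohort round-trips through CSV exactly", {
  les <- lesion_rows(c("p1", "pons_tegmental", "left", "DWI"),
                     c("p2", "cc_truncus", "midline", "FLAIR", 2, 1.25),
                     c("p2", "thalamus", "right", "T2GRE_SWI", 3, 0))
  coh <- make_cohort(les, ids = c("p1", "p2", "p3"),
                     gose6 = c(5L, 7L, NA))
  dir <- withr::local_tempdir()
  write_cohort(coh, dir)
  back <- read_cohort(dir)
  for (tb in c("patients", "lesions", "contusions", "outcomes")) {
    expect_equal(back[[tb]], coh[[tb]], ignore_attr = TRUE)
  }
})

test_that("empty cohort writes header-only files and reads back", {
  coh <- make_cohort(empty_lesions(), ids = "p1")
  dir <- withr::local_tempdir()
  write_cohort(coh, dir)
  expect_equal(nrow(read_cohort(dir)$lesions), 0)
  expect_equal(readLines(file.path(dir, "lesions.csv"))[1],
               "patient_id,location_code,side,sequence,present,count,volume_cm3")
})

test_that("schema violations are rejected with file/row/column context", {
  les <- lesion_rows(c("p1", "pons_tegmental", "left", "DWI"))
  les$present <- FALSE # count stays 1: invariant breach
  expect_error(make_cohort(les), "lesions.*present = FALSE")

  les2 <- lesion_rows(c("p1", "not_a_place", "left", "DWI"))
  expect_error(make_cohort(les2), "not in ontology.*not_a_place")

  les3 <- lesion_rows(c("p1", "thalamus", "right", "T2GRE_SWI"))
  les3$volume_cm3 <- 1.2
  expect_error(make_cohort(les3), "T2GRE_SWI")

  dup <- rbind(lesion_rows(c("p1", "thalamus", "right", "FLAIR")),
               lesion_rows(c("p1", "thalamus", "right", "FLAIR")))
  expect_error(make_cohort(dup), "duplicated")

  pats <- blank_patients("p1", gcs = 17)
  expect_error(as_cohort(pats, empty_lesions(),
                         data.frame(patient_id = character(0),
                                    present_mri = logical(0),
                                    volume_cm3_flair = numeric(0)),
                         data.frame(patient_id = character(0),
                                    gose3 = integer(0), gose6 = integer(0),
                                    gose12 = integer(0))),
               "GCS")
})

test_that("missing GOSE cells round-trip as empty cells", {
  coh <- make_cohort(ids = c("p1", "p2"), gose6 = c(NA, 6L))
  dir <- withr::local_tempdir()
  write_cohort(coh, dir)
  raw <- readLines(file.path(dir, "outcomes.csv"))
  expect_match(raw[2], "^p1,,,$")
  expect_identical(read_cohort(dir)$outcomes$gose6, c(NA, 6L))
})
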