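# the five exemplar lesion profiles, one per Trondheim grade
exemplar_lesions <- function() {
  list(
    g1 = lesion_rows(c("p", "frontal_wm", "right", "FLAIR")),
    g2 = lesion_rows(c("p", "cc_truncus", "midline", "FLAIR")),
    g3 = lesion_rows(c("p", "thalamus", "left", "FLAIR")),
    g4 = lesion_rows(c("p", "mesencephalon_tectum", "left", "FLAIR"),
                     c("p", "mesencephalon_tectum", "right", "DWI")),
    g5 = lesion_rows(c("p", "pons_tegmental", "left", "FLAIR"),
                     c("p", "pons_tegmental", "right", "FLAIR"),
                     c("p", "cerebellar_peduncle_middle", "left", "T2GRE_SWI"),
                     c("p", "cerebellar_peduncle_middle", "right", "T2GRE_SWI")))
}

test_that("exemplar lesion profiles receive Trondheim grades 1 through 5", {
  ex <- exemplar_lesions()
  grades <- vapply(ex, function(les) {
    apply_grading(extract_features(make_cohort(les)), "trondheim")
  }, integer(1))
  expect_equal(unname(grades), 1:5)
})

test_that("standard grading: brainstem involvement is grade 3", {
  les <- lesion_rows(c("p", "frontal_wm", "left", "FLAIR"),
                     c("p", "pons_ventral", "left", "DWI"))
  fx <- extract_features(make_cohort(les))
  expect_equal(apply_grading(fx, "standard"), 3L)
  # brainstem-only profile is also grade 3
  bs <- lesion_rows(c("p", "mesencephalon_crus_cerebri", "left", "DWI"))
  expect_equal(apply_grading(extract_features(make_cohort(bs)), "standard"),
               3L)
  # corpus callosum only: grade 2
  cc <- lesion_rows(c("p", "cc_truncus", "midline", "FLAIR"))
  expect_equal(apply_grading(extract_features(make_cohort(cc)), "standard"),
               2L)
})

test_that("no-TAI patients receive grade 0 except Stockholm's grade 1", {
  fx <- extract_features(make_cohort(empty_lesions(), ids = "p1"))
  expect_equal(apply_grading(fx, "trondheim"), 0L)
  expect_equal(apply_grading(fx, "standard"), 0L)
  expect_equal(apply_grading(fx, "gcs_based"), 0L)
  expect_equal(apply_grading(fx, "stockholm"), 1L)
})

test_that("cerebellar peduncles reach Trondheim grade 3 but never 4-5", {
  ped_bil <- feature_row(tai_cerebellar_peduncle_bil = TRUE)
  expect_equal(apply_grading(ped_bil, "trondheim"), 3L)
  expect_equal(apply_grading(ped_bil, "standard"), 3L)
})

test_that("bilateral medulla maps to the bilateral non-pons tier (grade 4)", {
  fx <- feature_row(tai_medulla_bil = TRUE)
  expect_equal(apply_grading(fx, "trondheim"), 4L)
})

test_that("unknown rule set name errors", {
  expect_error(grading_ruleset("oslo"), "unknown grading rule set")
})

# flags over which the packaged rule sets are defined
rule_flags <- c("tai_hemispheric", "tai_cerebellum", "tai_corpus_callosum",
                "tai_thalamus_uni", "tai_thalamus_bil",
                "tai_basal_ganglia_uni", "tai_basal_ganglia_bil",
                "tai_mesencephalon_uni", "tai_mesencephalon_bil",
                "tai_pons_uni", "tai_pons_bil", "tai_medulla_uni",
                "tai_medulla_bil", "tai_cerebellar_peduncle_uni",
                "tai_cerebellar_peduncle_bil", "tai_internal_capsule_pl_uni",
                "tai_internal_capsule_pl_bil")

# random feature rows under a fixed seed
random_features <- function(n, seed) {
  set.seed(seed)
  do.call(rbind, lapply(seq_len(n), function(i) {
    on <- sample(rule_flags, sample(0:5, 1))
    do.call(feature_row, setNames(as.list(rep(TRUE, length(on))), on))
  }))
}

test_that("rule engine agrees with an independent max-of-satisfied oracle", {
  # oracle: evaluate every predicate on its own and take the max grade
  oracle <- function(fx, rsname) {
    rs <- grading_ruleset(rsname)
    vapply(seq_len(nrow(fx)), function(i) {
      if (!fx$any_tai[i]) return(rs$no_tai_grade)
      sat <- rs$grades[vapply(rs$predicates, function(p) {
        isTRUE(eval(p, fx[i, , drop = FALSE], baseenv()))
      }, logical(1))]
      if (length(sat)) max(sat) else rs$no_tai_grade
    }, integer(1))
  }
  fx <- random_features(400, seed = 991)
  for (rs in c("trondheim", "standard", "stockholm", "gcs_based")) {
    expect_equal(apply_grading(fx, rs), oracle(fx, rs), label = rs)
  }
})

test_that("every feature vector receives exactly one finite grade", {
  fx <- random_features(300, seed = 7)
  for (rs in c("trondheim", "standard", "stockholm", "gcs_based")) {
    g <- apply_grading(fx, rs)
    expect_length(g, nrow(fx))
    expect_false(anyNA(g))
  }
})

test_that("adding a lesion flag never decreases any grading's grade", {
  fx <- random_features(150, seed = 13)
  set.seed(14)
  for (rs in c("trondheim", "standard", "stockholm", "gcs_based")) {
    g0 <- apply_grading(fx, rs)
    fx2 <- fx
    for (i in seq_len(nrow(fx2))) {
      add <- sample(rule_flags, 1)
      flags_on <- unlist(fx[i, rule_flags]) | rule_flags == add
      fx2[i, ] <- do.call(feature_row, setNames(as.list(flags_on),
                                                rule_flags))
    }
    expect_true(all(apply_grading(fx2, rs) >= g0), label = rs)
  }
})

test_that("Trondheim dominates the standard grading through the tier map", {
  fx <- random_features(300, seed = 29)
  tr <- apply_grading(fx, "trondheim")
  st <- apply_grading(fx, "standard")
  # standard grades 1 and 2 coincide; standard 3 (brainstem) maps to >= 3
  expect_true(all(tr[st == 1] >= 1))
  expect_true(all(tr[st == 2] >= 2))
  expect_true(all(tr[st == 3] >= 3))
})

test_that("grade_cohort summarises outcome by grade deterministically", {
  ex <- exemplar_lesions()
  les <- do.call(rbind, Map(function(l, i) {
    l$patient_id <- paste0("p", i)
    l
  }, ex, seq_along(ex)))
  coh <- make_cohort(les, ids = paste0("p", 1:5))
  res <- grade_cohort(coh, "trondheim", outcome = c(8, 8, 6, 4, 3))
  expect_equal(res$summary$grade, 1:5)
  expect_equal(res$summary$n, rep(1L, 5))
  # two identical outcomes in one grade: mean exact, SD 0
  coh2 <- make_cohort(lesion_rows(c("a", "frontal_wm", "left", "FLAIR"),
                                  c("b", "frontal_wm", "right", "DWI")),
                      ids = c("a", "b"))
  res2 <- grade_cohort(coh2, "trondheim", outcome = c(8, 8))
  expect_equal(res2$summary$mean, 8)
  expect_equal(res2$summary$sd, 0)
})
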