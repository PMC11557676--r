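test_that("rank AUC equals the brute-force all-pairs proportion", {
  brute <- function(p, l) {
    mean(outer(p[l == 1], p[l == 0], ">") +
           0.5 * outer(p[l == 1], p[l == 0], "=="))
  }
  set.seed(55)
  for (i in 1:50) {
    n <- sample(10:60, 1)
    p <- sample(round(runif(n), 2))  # rounded: plenty of ties
    l <- rbinom(n, 1, 0.4)
    if (sum(l) == 0 || sum(l) == n) next
    expect_equal(auc_rank(p, l), brute(p, l))
  }
  expect_equal(auc_rank(c(.1, .4, .6, .9), c(0, 0, 1, 1)), 1)
  expect_equal(auc_rank(c(0, 1, 0, 1), c(0, 1, 0, 1)), 1)
})

test_that("AUC is invariant to strictly monotone prediction transforms", {
  set.seed(66)
  p <- runif(100)
  l <- rbinom(100, 1, 0.5)
  expect_equal(auc_rank(p, l), auc_rank(qlogis(p), l))
  expect_equal(auc_rank(p, l), auc_rank(p^3, l))
})

test_that("rank AUC agrees with pROC", {
  skip_if_not_installed("pROC")
  set.seed(8)
  p <- rnorm(200)
  l <- rbinom(200, 1, 0.45)
  roc <- suppressMessages(pROC::roc(l, p, direction = "<",
                                    levels = c(0, 1)))
  expect_equal(auc_rank(p, l), as.numeric(pROC::auc(roc)),
               tolerance = 1e-12)
})

test_that("cross-validated AUC discriminates on a generated severe cohort", {
  cfg <- small_config(250)
  coh <- generate_cohort(cfg, seed = 37)
  fr <- filter_stratum(analysis_frame(coh, impute = FALSE), "severe")
  cv <- cv_auc(fr, covariate_preset("severe"),
               list(list(feature = "grade_trondheim")),
               scheme = "poor_vs_favourable", folds = 10, seed = 4,
               n_boot = 300)
  expect_true(cv$mean_auc > 0.5 && cv$mean_auc <= 1)
  expect_true(cv$ci[1] <= cv$mean_auc && cv$mean_auc <= cv$ci[2])
  expect_true(cv$ci[1] >= 0 && cv$ci[2] <= 1)
})

test_that("cv_auc refuses strata with too few events", {
  cfg <- small_config(0, n_mild = 120)
  coh <- generate_cohort(cfg, seed = 41)
  fr <- filter_stratum(analysis_frame(coh, impute = FALSE), "mild")
  expect_error(cv_auc(fr, covariate_preset("mild"), list(),
                      scheme = "disability_vs_good", response = "binary",
                      folds = 10, seed = 4),
               "at least 10")
})

test_that("comparison table rows are consistent with the fit table", {
  cfg <- small_config(220)
  coh <- generate_cohort(cfg, seed = 43)
  fr <- analysis_frame(coh, impute = FALSE)
  tab <- comparison_table(fr, "severe", folds = 5, seed = 6, n_boot = 200)
  expect_equal(tab$name[1], "baseline")
  base <- model_fit_table(
    list(list(name = "baseline", covariates = covariate_preset("severe"))),
    filter_stratum(fr, "severe"), "severe")
  expect_equal(tab$pseudo_r2[1], base$pseudo_r2[1], tolerance = 1e-8)
  expect_true(all(is.finite(tab$mean_auc)))
  expect_equal(nrow(tab), 8)
})

test_that("Jonckheere-Terpstra matches the exact permutation oracle", {
  # perfect increasing trend attains the minimum attainable p
  v <- c(1, 2, 3, 4, 5, 6)
  g <- rep(1:3, each = 2)
  jt <- jonckheere_terpstra(v, g)
  n_assign <- choose(6, 2) * choose(4, 2)
  expect_equal(jt$p_value, 1 / n_assign)
  expect_equal(jt$statistic, 2 * 2 * 3) # all pairs concordant

  # identical values: statistic at the null mean, p = 1
  jt0 <- jonckheere_terpstra(rep(2, 9), rep(1:3, each = 3))
  expect_equal(jt0$p_value, 1)

  # reversing the alternative flips the tail
  set.seed(5)
  v2 <- rnorm(10)
  g2 <- rep(1:2, each = 5)
  up <- jonckheere_terpstra(v2, g2, "increasing")
  dn <- jonckheere_terpstra(v2, g2, "decreasing")
  expect_gt(up$p_value + dn$p_value, 1)  # overlap only on ties

  expect_error(jonckheere_terpstra(1:5, rep(1, 5)), "at least 2")
})

test_that("normal approximation tracks the exact permutation p for n <= 12", {
  set.seed(123)
  for (i in 1:12) {
    sizes <- sample(2:4, 3, TRUE)
    sizes <- sizes[cumsum(sizes) <= 12]
    if (length(sizes) < 2) next
    v <- round(rnorm(sum(sizes)), 1)
    g <- rep(seq_along(sizes), sizes)
    pe <- jonckheere_terpstra(v, g)$p_value
    pn <- jonckheere_terpstra(v, g, exact_max = 0)$p_value
    expect_lt(abs(pe - pn), 0.06)
  }
})
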