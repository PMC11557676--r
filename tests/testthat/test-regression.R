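test_that("volume transform produces the presence / log pair", {
  tv <- transform_volume(c(0, 1, exp(1), 5.36))
  expect_equal(tv[, "presence"], c(0, 1, 1, 1))
  expect_equal(tv[, "log_volume"], c(0, 0, 1, log(5.36)))
  expect_error(transform_volume(-0.1), "negative volume")
})

# small simulated ordinal data set shared across fit tests
sim_ordinal <- function(n = 150, seed = 42, K = 4) {
  set.seed(seed)
  x <- cbind(a = rnorm(n), b = rbinom(n, 1, 0.4))
  eta <- 0.9 * x[, 1] - 0.6 * x[, 2]
  th <- c(-1, 0.3, 1.4)[seq_len(K - 1)]
  u <- runif(n)
  cum <- plogis(outer(eta, th, function(e, t) t - e))
  y <- 1L + rowSums(u > cum)
  list(x = x, y = y)
}

test_that("two-category proportional odds equals binary logistic", {
  d <- sim_ordinal(K = 2)
  fo <- fit_proportional_odds(d$x, d$y)
  fb <- fit_binary_logistic(d$x, as.integer(d$y == 2))
  expect_lt(max(abs(fo$beta - fb$beta)), 1e-6)
  expect_lt(abs(fo$theta - fb$theta), 1e-6)
  expect_lt(abs(fo$loglik - fb$loglik), 1e-6)
})

test_that("intercept-only thresholds are the cumulative-frequency logits", {
  d <- sim_ordinal()
  fit <- fit_proportional_odds(matrix(numeric(0), length(d$y), 0), d$y)
  cf <- cumsum(prop.table(table(d$y)))[1:3]
  expect_equal(fit$theta, unname(qlogis(cf)), tolerance = 1e-6)
  expect_equal(fit$loglik, fit$loglik_null, tolerance = 1e-8)
})

test_that("proportional-odds fit matches a generic-optimiser oracle", {
  # brute-force oracle: generic Nelder-Mead on the raw likelihood
  d <- sim_ordinal(n = 30, seed = 9, K = 3)
  nll <- function(par) {
    th <- c(par[1], par[1] + exp(par[2]))
    eta <- d$x %*% par[3:4]
    th_aug <- c(-Inf, th, Inf)
    -sum(log(pmax(plogis(th_aug[d$y + 1] - eta) -
                    plogis(th_aug[d$y] - eta), 1e-300)))
  }
  oracle <- optim(c(-1, 0, 0, 0), nll, method = "Nelder-Mead",
                  control = list(maxit = 5000, reltol = 1e-12))
  fit <- fit_proportional_odds(d$x, d$y)
  expect_lt(abs(fit$loglik - (-oracle$value)), 1e-4)
})

test_that("proportional-odds fit agrees with MASS::polr", {
  skip_if_not_installed("MASS")
  d <- sim_ordinal(n = 250, seed = 21)
  fit <- fit_proportional_odds(d$x, d$y)
  pol <- MASS::polr(factor(y) ~ a + b,
                    data = data.frame(y = d$y, d$x), method = "logistic",
                    Hess = TRUE)
  expect_equal(unname(fit$beta), unname(coef(pol)), tolerance = 1e-4)
  expect_equal(fit$loglik, as.numeric(logLik(pol)), tolerance = 1e-6)
  expect_equal(unname(fit$se), unname(sqrt(diag(vcov(pol)))[1:2]),
               tolerance = 1e-3)
})

test_that("fit metrics follow their definitions", {
  d <- sim_ordinal()
  fit <- fit_proportional_odds(d$x, d$y)
  expect_equal(fit$aic, -2 * fit$loglik + 2 * fit$k)
  expect_equal(fit$bic, -2 * fit$loglik + fit$k * log(fit$n))
  expect_equal(fit$pseudo_r2, 1 - fit$loglik / fit$loglik_null)
  expect_gte(fit$loglik, fit$loglik_null)  # nesting
  expect_true(all(diff(fit$theta) > 0))
  expect_equal(fit$or_table$or, exp(unname(fit$beta)))
})

test_that("balanced intercept-only binary fit gives loglik -n log 2", {
  y <- rep(c(0, 1), 50)
  fit <- fit_binary_logistic(matrix(numeric(0), 100, 0), y)
  expect_equal(fit$loglik, -100 * log(2), tolerance = 1e-8)
})

test_that("separation and rank deficiency raise informative errors", {
  x <- cbind(z = c(rep(0, 20), rep(1, 20)))
  y <- c(rep(0, 20), rep(1, 20))
  expect_error(fit_binary_logistic(x, y), "separation")
  d <- sim_ordinal()
  xx <- cbind(d$x, dup = d$x[, 1])
  expect_error(fit_proportional_odds(xx, d$y), "collinear.*dup")
})

test_that("simulated binary data recover the generating coefficient", {
  set.seed(11)
  n <- 800
  x <- cbind(z = rnorm(n))
  y <- rbinom(n, 1, plogis(-0.3 + 0.7 * x[, 1]))
  fit <- fit_binary_logistic(x, y)
  expect_lt(abs(fit$beta[["z"]] - 0.7), 2 * fit$se[["z"]])
})

test_that("log-scale equivariance: rescaling volume leaves its slope alone", {
  cfg <- small_config(250)
  coh <- generate_cohort(cfg, seed = 17)
  fr <- analysis_frame(coh, impute = FALSE)
  fr <- fr[!is.na(fr$gose6), ]
  ex1 <- list(feature = "vol_tai_flair_cm3", transform = "log_volume_pair",
              label = "v")
  x1 <- taigrade:::.build_design(fr, c("age", "gcs"), list(ex1))
  fr2 <- fr
  fr2$vol_tai_flair_cm3 <- fr$vol_tai_flair_cm3 * 10
  x2 <- taigrade:::.build_design(fr2, c("age", "gcs"), list(ex1))
  f1 <- fit_proportional_odds(x1, fr$response_ordinal)
  f2 <- fit_proportional_odds(x2, fr2$response_ordinal)
  expect_equal(f1$beta[["v_logvol"]], f2$beta[["v_logvol"]],
               tolerance = 1e-5)
  expect_equal(f1$loglik, f2$loglik, tolerance = 1e-6)
})

test_that("association table suppresses exposures below n = 10", {
  cfg <- small_config(160)
  coh <- generate_cohort(cfg, seed = 23)
  fr <- analysis_frame(coh, impute = FALSE)
  tab <- report_table2(fr, "severe",
                       list(list(feature = "tai_pons_bil"),
                            list(feature = "tai_corpus_callosum")))
  pons <- tab[tab$exposure == "tai_pons_bil", ]
  if (pons$n < 10) {
    expect_true(pons$suppressed)
    expect_true(is.na(pons$or))
  }
  cc <- tab[tab$exposure == "tai_corpus_callosum", ]
  expect_false(cc$suppressed)
  expect_true(is.finite(cc$or))
  expect_identical(cc$significant, cc$p < 0.01)
})

test_that("zero-variance exposures are dropped with a warning", {
  cfg <- small_config(120)
  coh <- generate_cohort(cfg, seed = 29)
  fr <- analysis_frame(coh, impute = FALSE)
  fr$null_flag <- rep(c(TRUE, FALSE), length.out = nrow(fr))
  fr$null_flag[] <- TRUE  # constant exposure with n >= 10 carriers
  expect_warning(
    tab <- report_table2(fr, "severe", list(list(feature = "null_flag"))),
    "without variance")
  expect_true(is.na(tab$or))
})

test_that("null-effect exposures are flagged significant at ~1% rate", {
  # type-I error at the p < 0.01 rule, 60 replicates of n = 500
  set.seed(101)
  hits <- vapply(1:60, function(r) {
    n <- 500
    x <- cbind(age = rnorm(n, 35, 12), noise = rbinom(n, 1, 0.3))
    y <- 1L + rowSums(runif(n) > plogis(outer(0.01 * x[, "age"],
                                              c(0, 1, 2), function(e, t) t - e)))
    fit <- fit_proportional_odds(x, y)
    fit$or_table$p[fit$or_table$term == "noise"] < 0.01
  }, logical(1))
  expect_lte(mean(hits), 0.05)
})

test_that("model fit table is consistent under nesting and duplication", {
  cfg <- small_config(220)
  coh <- generate_cohort(cfg, seed = 31)
  fr <- filter_stratum(analysis_frame(coh, impute = FALSE), "severe")
  specs <- list(
    list(name = "core", covariates = c("age", "gcs")),
    list(name = "core2", covariates = c("age", "gcs")),
    list(name = "core_plus", covariates = c("age", "gcs"),
         exposures = list(list(feature = "tai_corpus_callosum"))))
  tab <- model_fit_table(specs, fr, "severe")
  expect_equal(tab$loglik[1], tab$loglik[2])
  expect_gte(tab$loglik[3], tab$loglik[1])
  expect_equal(length(unique(tab$n)), 1)
})
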