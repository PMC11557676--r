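sim_enet <- function(n = 200, seed = 3, K = 4) {
  set.seed(seed)
  x <- cbind(u1 = rnorm(n), u2 = rnorm(n), p1 = rbinom(n, 1, .3),
             p2 = rnorm(n), p3 = rbinom(n, 1, .2))
  eta <- 0.5 * x[, 1] + 1.2 * x[, 3] - 0.8 * x[, 4]
  th <- c(-1, 0.2, 1.3)[seq_len(K - 1)]
  y <- 1L + rowSums(runif(n) > plogis(outer(eta, th, function(e, t) t - e)))
  list(x = x, y = y, penalized = c(FALSE, FALSE, TRUE, TRUE, TRUE))
}

test_that("penalised objective reduces to its parts", {
  d <- sim_enet()
  f <- fit_proportional_odds(d$x, d$y)
  # lambda = 0: mean negative log-likelihood
  obj0 <- penalized_objective(f$beta, f$theta, d$x, d$y, 0, 0.5, d$penalized)
  expect_equal(obj0, -f$loglik / length(d$y), tolerance = 1e-10)
  # zero penalised coefficients: no penalty contribution
  b0 <- f$beta
  b0[d$penalized] <- 0
  expect_equal(
    penalized_objective(b0, f$theta, d$x, d$y, 3, 1, d$penalized),
    penalized_objective(b0, f$theta, d$x, d$y, 0, 1, d$penalized))
  # ridge limit: (1/2) * beta^2 per unit lambda
  b1 <- rep(0, 5)
  b1[3] <- 2
  expect_equal(
    penalized_objective(b1, f$theta, d$x, d$y, 1, 0, d$penalized) -
      penalized_objective(b1, f$theta, d$x, d$y, 0, 0, d$penalized), 2)
})

test_that("lambda = 0 penalised fit equals the unpenalised fit", {
  d <- sim_enet()
  f0 <- fit_penalized(d$x, d$y, lambda = 0, alpha = 1,
                      penalized = d$penalized)
  f1 <- fit_proportional_odds(d$x, d$y)
  expect_lt(abs(f0$loglik - f1$loglik), 1e-4)
  expect_equal(unname(f0$beta), unname(f1$beta), tolerance = 1e-3)
})

test_that("large lambda with alpha = 1 zeroes all penalised coefficients", {
  d <- sim_enet()
  f <- fit_penalized(d$x, d$y, lambda = 50, alpha = 1,
                     penalized = d$penalized)
  expect_true(all(f$beta_std[d$penalized] == 0))
  expect_true(any(f$beta_std[!d$penalized] != 0))
})

test_that("solutions satisfy the KKT subgradient conditions", {
  d <- sim_enet()
  for (lam in c(0.005, 0.02, 0.08)) {
    for (al in c(0.5, 1)) {
      f <- fit_penalized(d$x, d$y, lam, al, d$penalized)
      expect_true(kkt_check(f, tol = 1e-3), label = paste(lam, al))
    }
  }
})

test_that("objective trace is non-increasing", {
  d <- sim_enet()
  f <- fit_penalized(d$x, d$y, 0.03, 0.75, d$penalized)
  expect_true(all(diff(f$obj_trace) <= 1e-10))
})

test_that("active set shrinks along the regularisation path", {
  d <- sim_enet(n = 300, seed = 8)
  lams <- exp(seq(log(0.5), log(1e-4), length.out = 12))
  nz <- integer(0)
  init <- NULL
  for (l in rev(lams)) { # ascending lambda with warm starts
    f <- fit_penalized(d$x, d$y, l, 1, d$penalized, init = init)
    init <- list(zeta = f$zeta, beta_std = f$beta_std)
    nz <- c(nz, sum(f$beta_std[d$penalized] != 0))
  }
  expect_true(all(diff(nz) <= 0)) # non-increasing in lambda
})

test_that("lasso and ridge limits agree with glmnet in the binary case", {
  skip_if_not_installed("glmnet")
  set.seed(12)
  n <- 400
  x <- cbind(a = rnorm(n), b = rnorm(n), c = rbinom(n, 1, .4))
  y <- rbinom(n, 1, plogis(0.8 * x[, 1] - 0.5 * x[, 3]))
  pen <- rep(TRUE, 3)
  for (al in c(1, 0)) {
    lam <- 0.05
    f <- fit_penalized(x, y + 1L, lambda = lam, alpha = al, penalized = pen)
    g <- glmnet::glmnet(x, y, family = "binomial", alpha = al,
                        lambda = lam, standardize = TRUE, thresh = 1e-12)
    bg <- as.numeric(g$beta)
    # P(Y = 2) = plogis(x beta - theta), so the slopes match directly
    expect_equal(unname(f$beta), bg, tolerance = 0.02,
                 label = paste("alpha", al))
  }
})

test_that("single-point tuning grid returns that point", {
  d <- sim_enet()
  sel <- select_tuning(d$x, d$y, d$penalized, lambdas = 0.05, alphas = 0.5,
                       seed = 2)
  expect_equal(sel$lambda, 0.05)
  expect_equal(sel$alpha, 0.5)
})

test_that("tuning prefers informative models to the all-zero corner", {
  d <- sim_enet(n = 300, seed = 5)
  sel <- select_tuning(d$x, d$y, d$penalized,
                       lambdas = c(5, 0.05), alphas = 1, seed = 2)
  cvtab <- sel$cv_loglik
  expect_gte(cvtab$loglik[cvtab$lambda == 0.05],
             cvtab$loglik[cvtab$lambda == 5])
})

test_that("pure-noise predictors are mostly zeroed at the selected tuning", {
  set.seed(61)
  picks <- vapply(1:5, function(r) {
    n <- 150
    x <- cbind(u = rnorm(n), p1 = rnorm(n), p2 = rnorm(n), p3 = rnorm(n))
    y <- 1L + rowSums(runif(n) > plogis(outer(0.5 * x[, 1], c(-1, 0, 1),
                                              function(e, t) t - e)))
    sel <- select_tuning(x, y, c(FALSE, TRUE, TRUE, TRUE),
                         alphas = 1, n_lambda = 20, seed = r)
    sum(sel$fit$beta_std[-1] != 0)
  }, numeric(1))
  expect_lte(median(picks), 1)
})

test_that("bootstrap inclusion is reproducible and reports unpenalised at 100", {
  d <- sim_enet(n = 250, seed = 19)
  st1 <- bootstrap_inclusion(d$x, d$y, d$penalized, lambda = 0.02,
                             alpha = 1, n_bootstrap = 40, seed = 99)
  st2 <- bootstrap_inclusion(d$x, d$y, d$penalized, lambda = 0.02,
                             alpha = 1, n_bootstrap = 40, seed = 99)
  expect_identical(st1$inclusion, st2$inclusion)
  expect_true(all(st1$inclusion$inclusion_pct[!d$penalized] == 100))
  expect_true(all(st1$inclusion$inclusion_pct >= 0 &
                    st1$inclusion$inclusion_pct <= 100))
  # the strong generating effect (p1, log-OR 1.2) dominates the noise column
  inc <- st1$inclusion
  expect_gt(inc$inclusion_pct[inc$variable == "p1"],
            inc$inclusion_pct[inc$variable == "p3"])
})
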