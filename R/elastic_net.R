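# Proportional-odds ordinal regression with elastic-net penalty:
# monotone accelerated proximal-gradient solver, 5-fold cross-validated
# tuning, and bootstrap stability selection. The core variables and the
# Marshall CT score are never penalised.

#' Elastic-net penalised ordinal objective
#'
#' Negative mean cumulative-logit log-likelihood plus the elastic-net
#' penalty lambda * (alpha * sum |beta_j| + (1 - alpha)/2 * sum beta_j^2)
#' over the penalised columns only.
#'
#' @param beta Slope vector (same order as columns of `x`).
#' @param theta Increasing threshold vector (K - 1 values).
#' @param x Design matrix.
#' @param y Integer ordinal response.
#' @param lambda Penalty strength (>= 0).
#' @param alpha Mixing parameter in [0, 1] (1 = lasso, 0 = ridge).
#' @param penalized Logical vector marking the penalised columns.
#' @return Scalar objective value.
#' @export
penalized_objective <- function(beta, theta, x, y, lambda, alpha, penalized) {
  cats <- sort(unique(y))
  yidx <- match(y, cats)
  nll <- -.po_parts(theta, beta, as.matrix(x), yidx, length(cats))$loglik /
    length(y)
  bp <- beta[penalized]
  nll + lambda * (alpha * sum(abs(bp)) + (1 - alpha) / 2 * sum(bp^2))
}

# smooth part (mean nll + ridge) and its gradient in (zeta, beta_std) space
.pen_smooth <- function(par, x, yidx, K, lambda, alpha, penalized) {
  zeta <- par[1:(K - 1)]
  beta <- par[-(1:(K - 1))]
  parts <- .po_parts(.zeta_to_theta(zeta), beta, x, yidx, K)
  n <- length(yidx)
  ridge <- lambda * (1 - alpha) / 2 * sum(beta[penalized]^2)
  gb <- -parts$grad_beta / n
  gb[penalized] <- gb[penalized] + lambda * (1 - alpha) * beta[penalized]
  list(value = -parts$loglik / n + ridge,
       grad = c(-.grad_theta_to_zeta(parts$grad_theta, zeta) / n, gb),
       loglik = parts$loglik)
}

#' Fit a penalised proportional-odds model at fixed tuning
#'
#' Minimises [penalized_objective()] by a monotone accelerated
#' proximal-gradient method (FISTA with restart and backtracking line
#' search); the l1 part is handled by soft-thresholding, so penalised
#' coefficients can be exactly zero. Columns are standardised internally to
#' full-sample mean 0 / SD 1 (standardisation can be supplied, e.g. to reuse
#' full-sample scales in bootstrap refits); coefficients are reported on the
#' original scale alongside the standardised solution.
#'
#' @param x Design matrix.
#' @param y Integer ordinal response.
#' @param lambda,alpha Elastic-net tuning parameters.
#' @param penalized Logical vector (or column names) marking penalised
#'   columns; the rest (core variables, Marshall CT score) are unpenalised.
#' @param categories Response category set defining the thresholds (defaults
#'   to the observed categories; supply the full-data set in resampling).
#' @param center,scale Optional standardisation vectors.
#' @param init Optional warm start `list(zeta, beta_std)`.
#' @param tol Relative objective-change tolerance.
#' @param max_iter Iteration cap; non-convergence is an error carrying the
#'   objective trace.
#' @return Object of class `tai_enet_fit` with original-scale `beta` and
#'   `theta`, standardised `beta_std`, the objective trace, the smooth-part
#'   gradient at the solution (for KKT checks), and the unpenalised
#'   log-likelihood of the solution.
#' @export
fit_penalized <- function(x, y, lambda, alpha, penalized,
                          categories = NULL, center = NULL, scale = NULL,
                          init = NULL, tol = 1e-8, max_iter = 5000) {
  x <- as.matrix(x)
  if (is.character(penalized)) penalized <- colnames(x) %in% penalized
  stopifnot(length(penalized) == ncol(x), alpha >= 0, alpha <= 1,
            lambda >= 0)
  if (is.null(categories)) categories <- sort(unique(y))
  K <- length(categories)
  if (K < 2) stop("need at least 2 response categories")
  yidx <- match(y, categories)
  if (anyNA(yidx)) stop("response values outside the supplied categories")
  n <- nrow(x)
  p <- ncol(x)

  if (is.null(center)) center <- colMeans(x)
  if (is.null(scale)) {
    scale <- apply(x, 2, stats::sd) * sqrt((n - 1) / n)
    scale[scale < 1e-12] <- 1
  }
  xs <- sweep(sweep(x, 2, center), 2, scale, "/")

  if (is.null(init)) {
    zeta <- .theta_to_zeta(.null_thresholds(yidx, K))
    beta <- rep(0, p)
  } else {
    zeta <- init$zeta
    beta <- init$beta_std
  }
  par <- c(zeta, beta)
  idx_beta <- K:(K - 1 + p)
  pen_idx <- idx_beta[penalized]

  prox <- function(par, t) {
    if (lambda * alpha > 0) {
      b <- par[pen_idx]
      par[pen_idx] <- sign(b) * pmax(abs(b) - t * lambda * alpha, 0)
    }
    par
  }
  obj <- function(par) {
    .pen_smooth(par, xs, yidx, K, lambda, alpha, penalized)$value +
      lambda * alpha * sum(abs(par[pen_idx]))
  }

  sm <- .pen_smooth(par, xs, yidx, K, lambda, alpha, penalized)
  Fx <- sm$value + lambda * alpha * sum(abs(par[pen_idx]))
  t_step <- 1
  mom <- 1
  par_prev <- par
  trace <- Fx
  converged <- FALSE
  for (it in seq_len(max_iter)) {
    # extrapolated point
    mom_new <- (1 + sqrt(1 + 4 * mom^2)) / 2
    v <- par + (mom - 1) / mom_new * (par - par_prev)
    smv <- .pen_smooth(v, xs, yidx, K, lambda, alpha, penalized)
    # backtracking from the extrapolated point
    t_step <- min(t_step * 2, 1e4)
    repeat {
      z <- prox(v - t_step * smv$grad, t_step)
      smz_val <- .pen_smooth(z, xs, yidx, K, lambda, alpha, penalized)$value
      dd <- z - v
      if (smz_val <= smv$value + sum(smv$grad * dd) +
          sum(dd^2) / (2 * t_step) + 1e-12) break
      t_step <- t_step / 2
      if (t_step < 1e-12) break
    }
    Fz <- smz_val + lambda * alpha * sum(abs(z[pen_idx]))
    if (Fz <= Fx) {
      par_prev <- par
      par <- z
      mom <- mom_new
      F_new <- Fz
    } else {
      # monotone fallback: plain proximal step from the current iterate
      smx <- .pen_smooth(par, xs, yidx, K, lambda, alpha, penalized)
      ts <- t_step
      repeat {
        z2 <- prox(par - ts * smx$grad, ts)
        v2 <- .pen_smooth(z2, xs, yidx, K, lambda, alpha, penalized)$value
        dd <- z2 - par
        if (v2 <= smx$value + sum(smx$grad * dd) + sum(dd^2) / (2 * ts) +
            1e-12 || ts < 1e-12) break
        ts <- ts / 2
      }
      F2 <- v2 + lambda * alpha * sum(abs(z2[pen_idx]))
      if (F2 > Fx + 1e-12) { # cannot decrease further
        converged <- TRUE
        trace <- c(trace, Fx)
        break
      }
      par_prev <- par
      par <- z2
      mom <- 1
      F_new <- F2
    }
    trace <- c(trace, F_new)
    if (abs(Fx - F_new) < tol * (abs(Fx) + 1e-10) &&
        max(abs(par - par_prev)) < 1e-6) {
      Fx <- F_new
      converged <- TRUE
      break
    }
    Fx <- F_new
  }
  if (!converged) {
    stop("penalised fit did not converge in ", max_iter,
         " iterations; objective trace tail: ",
         paste(signif(utils::tail(trace, 5), 8), collapse = ", "))
  }

  zeta <- par[1:(K - 1)]
  beta_std <- par[idx_beta]
  names(beta_std) <- colnames(x)
  beta <- beta_std / scale
  theta_std <- .zeta_to_theta(zeta)
  theta <- theta_std + sum(beta_std * center / scale)
  sm_final <- .pen_smooth(par, xs, yidx, K, lambda, alpha, penalized)
  grad_beta_smooth <- sm_final$grad[idx_beta]
  structure(list(
    beta = beta, theta = theta, beta_std = beta_std, theta_std = theta_std,
    zeta = zeta, lambda = lambda, alpha = alpha, penalized = penalized,
    categories = categories, center = center, scale = scale,
    objective = Fx, obj_trace = trace, iterations = length(trace) - 1,
    loglik = sm_final$loglik, n = n,
    grad_beta_smooth = grad_beta_smooth),
    class = "tai_enet_fit")
}

#' @export
print.tai_enet_fit <- function(x, ...) {
  nz <- sum(x$beta_std[x$penalized] != 0)
  cat(sprintf(
    "Penalised proportional-odds fit: lambda = %.4g, alpha = %.2f\n",
    x$lambda, x$alpha))
  cat(sprintf("  %d of %d penalised coefficients nonzero; loglik = %.2f\n",
              nz, sum(x$penalized), x$loglik))
  invisible(x)
}

#' KKT (subgradient) conditions of a penalised fit
#'
#' For zeroed penalised coefficients the smooth-part gradient must satisfy
#' |g_j| <= lambda * alpha; for nonzero ones g_j + lambda * alpha * sign(b_j)
#' must vanish.
#'
#' @param fit A `tai_enet_fit`.
#' @param tol Slack tolerance.
#' @return Logical: all conditions satisfied within `tol`; with attribute
#'   `slack` giving the per-column violation.
#' @export
kkt_check <- function(fit, tol = 1e-4) {
  g <- fit$grad_beta_smooth
  b <- fit$beta_std
  la <- fit$lambda * fit$alpha
  slack <- numeric(length(b))
  pen <- fit$penalized
  zero <- pen & b == 0
  slack[zero] <- pmax(abs(g[zero]) - la, 0)
  slack[pen & !zero] <- abs(g[pen & !zero] + la * sign(b[pen & !zero]))
  slack[!pen] <- abs(g[!pen])
  structure(all(slack <= tol), slack = slack)
}

# lambda just above the smallest value that zeroes all penalised columns
.lambda_max <- function(x, y, penalized, alpha_min, categories, center,
                        scale) {
  f0 <- fit_penalized(x, y, lambda = 1e9, alpha = 1, penalized = penalized,
                      categories = categories, center = center,
                      scale = scale)
  max(abs(f0$grad_beta_smooth[penalized])) / max(alpha_min, 1e-3)
}

#' Select elastic-net tuning by stratified cross-validation
#'
#' Evaluates a (lambda, alpha) grid by k-fold cross-validation with folds
#' stratified by response category, maximising the mean out-of-fold
#' log-likelihood; ties are broken towards the larger lambda (sparser
#' model). The default lambda path is 50 log-spaced values from lambda_max
#' (the smallest value zeroing every penalised coefficient) down to
#' 1e-3 * lambda_max, and the default alpha grid is
#' {0.1, 0.25, 0.5, 0.75, 1}.
#'
#' @param x,y Design matrix and integer ordinal response.
#' @param penalized Logical vector (or column names) of penalised columns.
#' @param lambdas,alphas Optional grids.
#' @param nfolds Number of folds (default 5).
#' @param seed Seed for the fold assignment (required).
#' @param n_lambda Path length when `lambdas` is NULL.
#' @return List: `lambda`, `alpha`, `cv_loglik` (grid results), `fit`
#'   (full-data fit at the selected tuning), `folds`.
#' @export
select_tuning <- function(x, y, penalized, lambdas = NULL,
                          alphas = c(0.1, 0.25, 0.5, 0.75, 1),
                          nfolds = 5, seed, n_lambda = 50) {
  x <- as.matrix(x)
  if (is.character(penalized)) penalized <- colnames(x) %in% penalized
  categories <- sort(unique(y))
  K <- length(categories)
  n <- nrow(x)
  center <- colMeans(x)
  scale <- apply(x, 2, stats::sd) * sqrt((n - 1) / n)
  scale[scale < 1e-12] <- 1
  if (is.null(lambdas)) {
    lmax <- .lambda_max(x, y, penalized, min(alphas), categories, center,
                        scale)
    lambdas <- exp(seq(log(lmax), log(1e-3 * lmax), length.out = n_lambda))
  }
  lambdas <- sort(lambdas, decreasing = TRUE)
  folds <- .stratified_folds(y, nfolds, seed)

  yidx_all <- match(y, categories)
  cv <- expand.grid(lambda = lambdas, alpha = alphas)
  cv$loglik <- NA_real_
  for (a in alphas) {
    oof <- matrix(NA_real_, n, length(lambdas))
    for (f in seq_len(nfolds)) {
      tr <- folds != f
      init <- NULL
      for (li in seq_along(lambdas)) {
        fit <- fit_penalized(x[tr, , drop = FALSE], y[tr], lambdas[li], a,
                             penalized, categories = categories,
                             center = center, scale = scale, init = init)
        init <- list(zeta = fit$zeta, beta_std = fit$beta_std)
        xs_te <- sweep(sweep(x[!tr, , drop = FALSE], 2, center), 2, scale,
                       "/")
        parts <- .po_parts(fit$theta_std, fit$beta_std, xs_te,
                           yidx_all[!tr], K)
        # per-observation log-likelihood on the held-out fold
        th_aug <- c(-Inf, fit$theta_std, Inf)
        eta <- as.numeric(xs_te %*% fit$beta_std)
        L <- stats::plogis(th_aug[yidx_all[!tr] + 1L] - eta) -
          stats::plogis(th_aug[yidx_all[!tr]] - eta)
        oof[!tr, li] <- log(pmax(L, 1e-300))
      }
    }
    cv$loglik[cv$alpha == a] <- colMeans(oof)[match(
      cv$lambda[cv$alpha == a], lambdas)]
  }
  # maximise; ties towards larger lambda (sparser)
  best <- which(cv$loglik > max(cv$loglik) - 1e-12)
  best <- best[which.max(cv$lambda[best])]
  sel_lambda <- cv$lambda[best]
  sel_alpha <- cv$alpha[best]
  full <- fit_penalized(x, y, sel_lambda, sel_alpha, penalized,
                        categories = categories, center = center,
                        scale = scale)
  list(lambda = sel_lambda, alpha = sel_alpha, cv_loglik = cv, fit = full,
       folds = folds)
}

.stratified_folds <- function(y, nfolds, seed) {
  if (missing(seed) || is.null(seed)) stop("a fold-assignment seed is required")
  set.seed(seed)
  folds <- integer(length(y))
  for (cat in unique(y)) {
    idx <- which(y == cat)
    folds[idx] <- sample(rep_len(seq_len(nfolds), length(idx)))
  }
  folds
}

#' Bootstrap stability selection for the penalised model
#'
#' Refits the penalised model on case resamples (with replacement) at fixed
#' tuning and reports, per penalised variable, the percentage of resamples in
#' which its coefficient was not shrunk to zero. Unpenalised variables are
#' reported at 100%. Resamples with fewer than 2 response categories are
#' redrawn (counted). Tuning is selected once on the full data and held
#' fixed across refits; full-sample standardisation is reused.
#'
#' @param x,y Design matrix and integer ordinal response.
#' @param penalized Logical vector (or column names) of penalised columns.
#' @param lambda,alpha Tuning (e.g. from [select_tuning()]).
#' @param n_bootstrap Number of resamples (default 500).
#' @param seed Resampling seed (required).
#' @return Object of class `tai_stability`: data frame `inclusion` with
#'   per-variable inclusion percentage and majority coefficient sign, the
#'   tuning used, and the redraw count.
#' @export
bootstrap_inclusion <- function(x, y, penalized, lambda, alpha,
                                n_bootstrap = 500, seed) {
  x <- as.matrix(x)
  if (is.character(penalized)) penalized <- colnames(x) %in% penalized
  if (missing(seed) || is.null(seed)) stop("a resampling seed is required")
  categories <- sort(unique(y))
  n <- nrow(x)
  center <- colMeans(x)
  scale <- apply(x, 2, stats::sd) * sqrt((n - 1) / n)
  scale[scale < 1e-12] <- 1
  full <- fit_penalized(x, y, lambda, alpha, penalized,
                        categories = categories, center = center,
                        scale = scale)
  warm <- list(zeta = full$zeta, beta_std = full$beta_std)
  set.seed(seed)
  nonzero <- matrix(FALSE, n_bootstrap, ncol(x))
  signs <- matrix(0, n_bootstrap, ncol(x))
  redraws <- 0L
  for (b in seq_len(n_bootstrap)) {
    repeat {
      idx <- sample.int(n, n, replace = TRUE)
      if (length(unique(y[idx])) >= 2) break
      redraws <- redraws + 1L
    }
    fit <- fit_penalized(x[idx, , drop = FALSE], y[idx], lambda, alpha,
                         penalized, categories = categories,
                         center = center, scale = scale, init = warm,
                         tol = 1e-7)
    nonzero[b, ] <- fit$beta_std != 0
    signs[b, ] <- sign(fit$beta_std)
  }
  pct <- 100 * colMeans(nonzero)
  pct[!penalized] <- 100
  maj_sign <- apply(signs, 2, function(s) {
    s <- s[s != 0]
    if (!length(s)) 0 else sign(sum(sign(s)))
  })
  structure(list(
    inclusion = data.frame(variable = colnames(x), penalized = penalized,
                           inclusion_pct = pct, sign = maj_sign,
                           stringsAsFactors = FALSE),
    lambda = lambda, alpha = alpha, n_bootstrap = n_bootstrap,
    redraws = redraws, full_fit = full),
    class = "tai_stability")
}

#' @export
print.tai_stability <- function(x, ...) {
  cat(sprintf(
    "Bootstrap stability selection: %d resamples at lambda = %.4g, alpha = %.2f\n",
    x$n_bootstrap, x$lambda, x$alpha))
  inc <- x$inclusion[order(-x$inclusion$inclusion_pct), ]
  print(inc, digits = 3, row.names = FALSE)
  invisible(x)
}

#' Penalised-model variable lists
#'
#' The clinical model penalises only the TAI presence/laterality flags (plus
#' MRI contusion presence); the quantitative model adds the TAI number and
#' volume variables (volumes as log-volume pairs). Core variables (age, GCS,
#' pupils) and the Marshall CT score are always unpenalised.
#'
#' @param frame An [analysis_frame()].
#' @param model `"clinical"` or `"quantitative"`.
#' @return List with `x` (design matrix), `penalized` (logical), and `y`
#'   (inverted GOSE response).
#' @export
elastic_net_design <- function(frame, model = c("clinical", "quantitative")) {
  model <- match.arg(model)
  frame <- frame[!is.na(frame$gose6), , drop = FALSE]
  unpen <- .build_design(frame, c("age", "gcs", "pupils", "marshall_cat"))
  flags <- c("tai_hemispheric", "tai_cerebellum", "tai_corpus_callosum",
             paste0("tai_", rep(.paired_groups, each = 2),
                    c("_uni", "_bil")),
             "contusion_on_mri")
  pen <- sapply(frame[flags], as.numeric)
  if (model == "quantitative") {
    vols <- cbind(transform_volume(frame$vol_tai_flair_cm3),
                  transform_volume(frame$vol_tai_dwi_cm3),
                  transform_volume(frame$vol_contusion_flair_cm3))
    colnames(vols) <- c("vol_tai_flair_pres", "vol_tai_flair_logvol",
                        "vol_tai_dwi_pres", "vol_tai_dwi_logvol",
                        "vol_contusion_pres", "vol_contusion_logvol")
    pen <- cbind(pen, vols,
                 n_tai_t2gre_swi = frame$n_tai_t2gre_swi,
                 n_tai_brainstem_t2gre_swi = frame$n_tai_brainstem_t2gre_swi)
  }
  keep <- apply(pen, 2, stats::sd) > 0
  if (any(!keep)) pen <- pen[, keep, drop = FALSE]
  x <- cbind(unpen, pen)
  list(x = x,
       penalized = c(rep(FALSE, ncol(unpen)), rep(TRUE, ncol(pen))),
       y = frame$response_ordinal)
}
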