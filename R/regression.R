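# Proportional-odds (cumulative logit) and binary logistic outcome models
# with the covariate conventions of the TAI analyses: log-volume pairs,
# per-stratum adjustment sets, n < 10 suppression, significance at p < 0.01.

#' Log-volume transform with paired presence indicator
#'
#' Volume covariates enter the models as their natural logarithm together
#' with a presence indicator, since ln(0) does not exist: volume 0 maps to
#' (presence 0, log-volume 0), volume v > 0 to (1, ln v).
#'
#' @param v_cm3 Non-negative volumes in cm^3.
#' @return A two-column matrix: `presence` (0/1) and `log_volume`.
#' @examples
#' transform_volume(c(0, 1, exp(1)))
#' @export
transform_volume <- function(v_cm3) {
  if (any(v_cm3 < 0, na.rm = TRUE)) {
    stop("negative volume: ", paste(utils::head(v_cm3[v_cm3 < 0]), collapse = ", "))
  }
  pres <- as.numeric(v_cm3 > 0)
  cbind(presence = pres, log_volume = ifelse(pres > 0, log(pmax(v_cm3, 1e-300)), 0))
}

# --- cumulative-logit likelihood ------------------------------------------

# Negative log-likelihood and gradient of the proportional-odds model.
# theta: K-1 increasing thresholds; beta: p slopes; yidx: response mapped to
# 1..K; returns sum convention.
.po_parts <- function(theta, beta, x, yidx, K) {
  eta <- if (length(beta)) as.numeric(x %*% beta) else numeric(nrow(x))
  th_aug <- c(-Inf, theta, Inf)
  hi <- th_aug[yidx + 1L] - eta
  lo <- th_aug[yidx] - eta
  F_hi <- stats::plogis(hi)
  F_lo <- stats::plogis(lo)
  L <- pmax(F_hi - F_lo, 1e-300)
  f_hi <- F_hi * (1 - F_hi)
  f_lo <- F_lo * (1 - F_lo)
  # d loglik_i / d theta_j
  gt <- numeric(K - 1)
  w_hi <- f_hi / L
  w_lo <- f_lo / L
  sel_hi <- yidx <= K - 1
  if (any(sel_hi)) {
    s <- rowsum(w_hi[sel_hi], yidx[sel_hi])
    gt[as.integer(rownames(s))] <- gt[as.integer(rownames(s))] + s[, 1]
  }
  sel_lo <- yidx >= 2
  if (any(sel_lo)) {
    s <- rowsum(w_lo[sel_lo], yidx[sel_lo] - 1L)
    gt[as.integer(rownames(s))] <- gt[as.integer(rownames(s))] - s[, 1]
  }
  # d loglik_i / d eta_i = -(f_hi - f_lo)/L
  ge <- -(f_hi - f_lo) / L
  gb <- if (length(beta)) as.numeric(crossprod(x, ge)) else numeric(0)
  list(loglik = sum(log(L)), grad_theta = gt, grad_beta = gb)
}

# zeta (unconstrained) <-> theta (increasing)
.zeta_to_theta <- function(zeta) cumsum(c(zeta[1], exp(zeta[-1])))
.theta_to_zeta <- function(theta) c(theta[1], log(diff(theta)))
.grad_theta_to_zeta <- function(gt, zeta) {
  cs <- rev(cumsum(rev(gt)))
  c(cs[1], if (length(gt) > 1) cs[-1] * exp(zeta[-1]))
}

.null_thresholds <- function(yidx, K) {
  cf <- cumsum(tabulate(yidx, K))[1:(K - 1)] / length(yidx)
  stats::qlogis(pmin(pmax(cf, 1e-10), 1 - 1e-10))
}

#' Fit a proportional-odds ordinal logistic regression
#'
#' Maximises the cumulative-logit likelihood P(Y <= j | x) =
#' logistic(theta_j - x beta) by quasi-Newton (BFGS) optimisation on the
#' unconstrained reparameterisation (theta_1, log-increments), with analytic
#' gradients, starting from the intercepts-only solution. Standard errors are
#' taken from the observed information at the optimum. Empty response
#' categories are dropped before fitting.
#'
#' @param x Numeric design matrix (no intercept column).
#' @param y Integer ordinal response; at least 2 observed categories.
#' @param tol Gradient-norm convergence tolerance.
#' @return Object of class `tai_po_fit` with elements `beta`, `theta`,
#'   `categories`, `loglik`, `loglik_null`, `k`, `n`, `pseudo_r2`, `aic`,
#'   `bic`, `se`, `vcov`, and `or_table` (OR, 95% CI, p, significance at
#'   p < 0.01).
#' @export
fit_proportional_odds <- function(x, y, tol = 1e-8) {
  x <- as.matrix(x)
  if (is.null(colnames(x)) && ncol(x)) colnames(x) <- paste0("x", seq_len(ncol(x)))
  keep <- stats::complete.cases(x) & !is.na(y)
  x <- x[keep, , drop = FALSE]
  y <- y[keep]
  cats <- sort(unique(y))
  K <- length(cats)
  if (K < 2) stop("need at least 2 observed response categories")
  yidx <- match(y, cats)
  n <- nrow(x)
  p <- ncol(x)
  if (p) {
    qrx <- qr(cbind(1, x))
    if (qrx$rank < p + 1) {
      drop_cols <- colnames(x)[qrx$pivot[seq(qrx$rank + 1, p + 1)] - 1]
      stop("design matrix is rank deficient; collinear column(s): ",
           paste(drop_cols, collapse = ", "))
    }
  }

  th0 <- .null_thresholds(yidx, K)
  ll_null <- sum(log(tabulate(yidx, K)[yidx] / n))
  par0 <- c(.theta_to_zeta(th0), rep(0, p))

  fn <- function(par) {
    theta <- .zeta_to_theta(par[1:(K - 1)])
    -.po_parts(theta, par[-(1:(K - 1))], x, yidx, K)$loglik
  }
  gr <- function(par) {
    zeta <- par[1:(K - 1)]
    parts <- .po_parts(.zeta_to_theta(zeta), par[-(1:(K - 1))], x, yidx, K)
    -c(.grad_theta_to_zeta(parts$grad_theta, zeta), parts$grad_beta)
  }
  opt <- stats::optim(par0, fn, gr, method = "BFGS",
                      control = list(maxit = 500, reltol = 1e-14))
  gnorm <- sqrt(sum(gr(opt$par)^2))
  if (opt$convergence != 0 && gnorm > max(tol, 1e-4) * max(1, n / 100)) {
    stop("proportional-odds fit did not converge (code ", opt$convergence,
         ", |grad| = ", signif(gnorm, 3), ")")
  }
  theta <- .zeta_to_theta(opt$par[1:(K - 1)])
  beta <- opt$par[-(1:(K - 1))]
  names(beta) <- colnames(x)
  if (length(beta) && max(abs(beta)) > 25) {
    stop("apparent separation: coefficient magnitude ",
         signif(max(abs(beta)), 3), " for ",
         names(beta)[which.max(abs(beta))])
  }
  ll <- -opt$value
  k <- (K - 1) + p

  # observed information in the (theta, beta) parameterisation
  fn_tb <- function(par) {
    -.po_parts(par[1:(K - 1)], par[-(1:(K - 1))], x, yidx, K)$loglik
  }
  H <- stats::optimHess(c(theta, beta), fn_tb)
  vc <- tryCatch(solve(H), error = function(e) matrix(NA_real_, k, k))
  se_all <- suppressWarnings(sqrt(diag(vc)))
  se <- se_all[seq(K, k)]
  names(se) <- colnames(x)

  fit <- structure(list(
    beta = beta, theta = theta, categories = cats, loglik = ll,
    loglik_null = ll_null, k = k, n = n,
    pseudo_r2 = 1 - ll / ll_null,
    aic = -2 * ll + 2 * k, bic = -2 * ll + k * log(n),
    se = se, vcov = vc, kind = "ordinal"),
    class = "tai_po_fit")
  fit$or_table <- .or_table(beta, se)
  fit
}

.or_table <- function(beta, se) {
  if (!length(beta)) return(NULL)
  z <- beta / se
  p <- 2 * stats::pnorm(-abs(z))
  data.frame(term = names(beta), beta = unname(beta), se = unname(se),
             or = exp(unname(beta)),
             ci_lo = exp(unname(beta - 1.96 * se)),
             ci_hi = exp(unname(beta + 1.96 * se)),
             p = unname(p), significant = unname(p < 0.01),
             stringsAsFactors = FALSE)
}

#' @export
print.tai_po_fit <- function(x, ...) {
  cat(sprintf("%s logistic fit: n = %d, k = %d, loglik = %.2f\n",
              if (x$kind == "ordinal") "Proportional-odds" else "Binary",
              x$n, x$k, x$loglik))
  cat(sprintf("pseudo-R2 = %.3f, AIC = %.1f, BIC = %.1f\n",
              x$pseudo_r2, x$aic, x$bic))
  if (!is.null(x$or_table)) print(x$or_table, digits = 3)
  invisible(x)
}

#' Fit a binary logistic regression with the same fit metrics
#'
#' Wraps a maximum-likelihood binomial GLM and reports the same metric fields
#' as [fit_proportional_odds()] (log-likelihood, McFadden pseudo-R2, AIC,
#' BIC, Wald ORs with 95% CI, significance at p < 0.01). Complete separation
#' is detected and raised as an error.
#'
#' @param x Numeric design matrix (no intercept column).
#' @param y Logical or 0/1 event response.
#' @return Object of class `tai_po_fit` with `kind = "binary"`; the single
#'   intercept is stored in `theta` on the cumulative-logit convention
#'   (P(no event) = logistic(theta - x beta)).
#' @export
fit_binary_logistic <- function(x, y) {
  x <- as.matrix(x)
  if (is.null(colnames(x)) && ncol(x)) colnames(x) <- paste0("x", seq_len(ncol(x)))
  keep <- stats::complete.cases(x) & !is.na(y)
  x <- x[keep, , drop = FALSE]
  y <- as.numeric(y[keep])
  if (length(unique(y)) < 2) stop("need both event and non-event responses")
  fit <- suppressWarnings(stats::glm.fit(cbind(`(Intercept)` = 1, x), y,
                                         family = stats::binomial()))
  cf <- fit$coefficients
  if (anyNA(cf)) {
    stop("design matrix is rank deficient; collinear column(s): ",
         paste(names(cf)[is.na(cf)], collapse = ", "))
  }
  if (length(cf) > 1 && max(abs(cf[-1])) > 25) {
    stop("apparent separation: coefficient magnitude ",
         signif(max(abs(cf[-1])), 3))
  }
  n <- length(y)
  ll <- -0.5 * fit$aic + length(cf)
  p1 <- mean(y)
  ll_null <- n * (p1 * log(p1) + (1 - p1) * log(1 - p1))
  k <- length(cf)
  vc <- tryCatch(chol2inv(fit$qr$qr[1:k, 1:k, drop = FALSE]),
                 error = function(e) matrix(NA_real_, k, k))
  se_all <- sqrt(diag(vc))
  beta <- cf[-1]
  se <- se_all[-1]
  names(se) <- names(beta)
  out <- structure(list(
    beta = beta, theta = -cf[1], categories = c(0, 1), loglik = ll,
    loglik_null = ll_null, k = k, n = n,
    pseudo_r2 = 1 - ll / ll_null,
    aic = -2 * ll + 2 * k, bic = -2 * ll + k * log(n),
    se = se, vcov = vc, kind = "binary"),
    class = "tai_po_fit")
  out$or_table <- .or_table(beta, se)
  out
}

#' Predicted event probability from a fitted outcome model
#'
#' For an ordinal fit, the event probability is the model-implied cumulative
#' probability P(response >= cut); for a binary fit, the fitted event
#' probability (cut ignored).
#'
#' @param fit A `tai_po_fit`.
#' @param newx Design matrix with the columns used at fit time.
#' @param cut Event cut on the response scale (ordinal response >= cut is an
#'   event); e.g. inverted GOSE >= 5 for poor outcome.
#' @return Numeric event probabilities.
#' @export
predict_event_prob <- function(fit, newx, cut = NULL) {
  newx <- as.matrix(newx)[, names(fit$beta), drop = FALSE]
  eta <- as.numeric(newx %*% fit$beta)
  if (fit$kind == "binary") return(stats::plogis(eta - fit$theta))
  if (is.null(cut)) stop("ordinal prediction requires an event cut")
  idx <- sum(fit$categories < cut)
  if (idx == 0) return(rep(1, length(eta)))
  if (idx >= length(fit$categories)) return(rep(0, length(eta)))
  1 - stats::plogis(fit$theta[idx] - eta)
}

# --- analysis frame and design construction -------------------------------

#' Per-patient analysis frame
#'
#' Joins patients, derived region features, grades under all four rule sets,
#' and constructed outcomes into the flat per-patient table used by the
#' modelling functions. The Marshall CT score is collapsed to the ordered
#' categories {1, 2, 3-4, 5-6} (plus no-CT), and pupils to dummies via
#' factors.
#'
#' @param cohort A validated `tai_cohort`.
#' @param impute Passed to [construct_outcomes()].
#' @return Data frame with one row per patient.
#' @export
analysis_frame <- function(cohort, impute = TRUE) {
  pt <- cohort$patients
  fx <- extract_features(cohort)
  oc <- construct_outcomes(cohort, impute = impute)
  fr <- cbind(pt, fx[, setdiff(names(fx), "patient_id"), drop = FALSE])
  fr$severity <- classify_severity(fr$gcs)
  fr$marshall_cat <- factor(
    c(no_ct = "no_ct", `1` = "1", `2` = "2", `3` = "3_4", `4` = "3_4",
      `5` = "5_6", `6` = "5_6")[as.character(fr$marshall)],
    levels = c("1", "2", "3_4", "5_6", "no_ct"))
  fr$pupils <- factor(fr$pupils, levels = .pupil_levels)
  fr$sex <- factor(fr$sex, levels = .sexes)
  for (rs in c("trondheim", "standard", "stockholm", "gcs_based")) {
    fr[[paste0("grade_", rs)]] <- apply_grading(fx, rs)
  }
  fr$gose6 <- oc$gose6
  fr$gose6_source <- oc$gose6_source
  fr$response_ordinal <- oc$response_ordinal
  # composite exposure rows used in the association tables
  fr$tai_brainstem_thalami_bil <- fr$tai_brainstem_bil | fr$tai_thalamus_bil
  fr$tai_mesencephalon_thalami_bil <-
    fr$tai_mesencephalon_bil | fr$tai_thalamus_bil
  fr$tai_deep_any <- fr$tai_brainstem_any | fr$tai_thalamus_uni |
    fr$tai_thalamus_bil | fr$tai_basal_ganglia_uni | fr$tai_basal_ganglia_bil
  fr
}

#' Packaged exposure list for the adjusted association table
#'
#' The MRI exposures examined one at a time in the adjusted analyses:
#' location presence/laterality variables (bilateral brainstem or thalami,
#' bilateral pons, bilateral mesencephalon or thalami, any deep TAI,
#' bilateral/unilateral brainstem, thalamus, basal ganglia, corpus callosum,
#' hemispheres), the TAI volume and count variables (volumes as log-volume
#' pairs), and the contusion variables.
#'
#' @return List of exposure specs for [report_table2()].
#' @export
table2_exposures <- function() {
  flag <- function(f, l = f) list(feature = f, label = l)
  vol <- function(f, l) list(feature = f, transform = "log_volume_pair",
                             label = l)
  list(flag("tai_brainstem_thalami_bil"),
       flag("tai_pons_bil"),
       flag("tai_mesencephalon_thalami_bil"),
       flag("tai_deep_any"),
       flag("tai_brainstem_bil"),
       flag("tai_brainstem_uni"),
       flag("tai_thalamus_bil"),
       flag("tai_thalamus_uni"),
       flag("tai_basal_ganglia_bil"),
       flag("tai_basal_ganglia_uni"),
       flag("tai_corpus_callosum"),
       flag("tai_hemispheric"),
       vol("vol_tai_flair_cm3", "vol_tai_flair"),
       vol("vol_tai_dwi_cm3", "vol_tai_dwi"),
       list(feature = "n_tai_t2gre_swi", transform = "count",
            label = "n_tai_t2gre_swi"),
       flag("contusion_on_ct"),
       flag("contusion_on_mri"),
       vol("vol_contusion_flair_cm3", "vol_contusion"))
}

#' Adjustment covariate presets per severity stratum
#'
#' Named presets for the adjusted analyses: severe and all-TBI models use the
#' core variables (age, GCS, pupils) plus the Marshall CT score; moderate TBI
#' with GCS 9-12 uses age, GCS, and Marshall; moderate TBI with GCS 13 uses
#' age and Marshall; mild TBI uses age and sex.
#'
#' @param stratum One of `"all"`, `"severe"`, `"moderate_9_12"`,
#'   `"moderate_13"`, `"mild"`, `"ms"`.
#' @return Character vector of covariate names in the analysis frame.
#' @export
covariate_preset <- function(stratum) {
  switch(stratum,
         all = c("age", "gcs", "pupils", "marshall_cat"),
         ms = c("age", "gcs", "pupils", "marshall_cat"),
         severe = c("age", "gcs", "pupils", "marshall_cat"),
         moderate_9_12 = c("age", "gcs", "marshall_cat"),
         moderate_13 = c("age", "marshall_cat"),
         mild = c("age", "sex"),
         stop("unknown stratum: ", stratum))
}

#' Select the rows of an analysis frame belonging to a stratum
#' @param frame An [analysis_frame()].
#' @param stratum Stratum name (see [covariate_preset()]).
#' @return The subset of `frame`.
#' @export
filter_stratum <- function(frame, stratum) {
  sel <- switch(stratum,
                all = rep(TRUE, nrow(frame)),
                ms = frame$severity %in% c("severe", "moderate"),
                severe = frame$severity %in% "severe",
                moderate = frame$severity %in% "moderate",
                moderate_9_12 = !is.na(frame$gcs) & frame$gcs >= 9 & frame$gcs <= 12,
                moderate_13 = !is.na(frame$gcs) & frame$gcs == 13,
                mild = frame$severity %in% "mild",
                stop("unknown stratum: ", stratum))
  sel[is.na(sel)] <- FALSE
  frame[sel, , drop = FALSE]
}

# Expand covariates and exposure terms into a numeric design matrix.
# exposures: list of list(feature=, transform = "identity"|"log_volume_pair"|
# "count", label=); interactions: list of c(colA, colB) design column pairs.
.build_design <- function(frame, covariates, exposures = list(),
                          interactions = list()) {
  cols <- list()
  for (v in covariates) {
    x <- frame[[v]]
    if (is.null(x)) stop("unknown covariate: ", v)
    if (is.factor(x)) {
      x <- droplevels(x)
      if (nlevels(x) > 1) {
        mm <- stats::model.matrix(~x)[, -1, drop = FALSE]
        colnames(mm) <- paste0(v, "_", levels(x)[-1])
        cols[[v]] <- mm
      }
    } else {
      cols[[v]] <- matrix(as.numeric(x), ncol = 1,
                          dimnames = list(NULL, v))
    }
  }
  exposure_cols <- character(0)
  report_cols <- character(0)
  n_exposed <- integer(0)
  for (ex in exposures) {
    feat <- ex$feature
    label <- if (!is.null(ex$label)) ex$label else feat
    v <- frame[[feat]]
    if (is.null(v)) stop("unknown exposure feature: ", feat)
    tr <- if (!is.null(ex$transform)) ex$transform else "identity"
    if (tr == "log_volume_pair") {
      tv <- transform_volume(v)
      colnames(tv) <- paste0(label, c("_pres", "_logvol"))
      cols[[label]] <- tv
      exposure_cols <- c(exposure_cols, colnames(tv))
      report_cols <- c(report_cols, paste0(label, "_logvol"))
      n_exposed <- c(n_exposed, sum(v > 0, na.rm = TRUE))
    } else {
      cols[[label]] <- matrix(as.numeric(v), ncol = 1,
                              dimnames = list(NULL, label))
      exposure_cols <- c(exposure_cols, label)
      report_cols <- c(report_cols, label)
      n_exposed <- c(n_exposed, sum(v > 0, na.rm = TRUE))
    }
  }
  x <- do.call(cbind, cols)
  if (is.null(x)) x <- matrix(numeric(0), nrow = nrow(frame), ncol = 0)
  for (ia in interactions) {
    if (!all(ia %in% colnames(x))) stop("interaction names unknown: ",
                                        paste(ia, collapse = ":"))
    x <- cbind(x, matrix(x[, ia[1]] * x[, ia[2]], ncol = 1,
                         dimnames = list(NULL, paste(ia, collapse = ":"))))
  }
  attr(x, "exposure_cols") <- exposure_cols
  attr(x, "report_cols") <- report_cols
  attr(x, "n_exposed") <- n_exposed
  x
}

.fit_for_stratum <- function(x, frame, stratum) {
  if (stratum %in% c("moderate_13", "mild")) {
    fit_binary_logistic(x, dichotomize_gose(frame$gose6,
                                            "disability_vs_good"))
  } else {
    fit_proportional_odds(x, frame$response_ordinal)
  }
}

#' Adjusted single-exposure association table
#'
#' For each MRI exposure, fits one adjusted model on the stratum (ordinal
#' inverted-GOSE response for all/severe/moderate 9-12; binary disability for
#' GCS 13 and mild TBI) with the stratum's covariate preset, and reports
#' n (%), OR (95% CI), and p for the exposure. Exposures carried by fewer
#' than 10 patients are suppressed (reported as NA), and significance is
#' flagged at p < 0.01. For log-volume pairs the reported OR is the
#' log-volume term. Exposure columns without variance are dropped with a
#' warning.
#'
#' @param frame An [analysis_frame()].
#' @param stratum Stratum name (see [covariate_preset()]).
#' @param exposures List of exposure specs: `list(feature =, transform =,
#'   label =)`.
#' @param min_n Suppression threshold (default 10).
#' @return Data frame with one row per exposure.
#' @export
report_table2 <- function(frame, stratum, exposures, min_n = 10) {
  fr <- filter_stratum(frame, stratum)
  fr <- fr[!is.na(fr$gose6), , drop = FALSE]
  if (!nrow(fr)) stop("empty stratum: ", stratum)
  covs <- covariate_preset(stratum)
  rows <- lapply(exposures, function(ex) {
    label <- if (!is.null(ex$label)) ex$label else ex$feature
    x <- .build_design(fr, covs, list(ex))
    n_exp <- attr(x, "n_exposed")
    out <- data.frame(exposure = label, n = n_exp,
                      pct = round(100 * n_exp / nrow(fr)),
                      or = NA_real_, ci_lo = NA_real_, ci_hi = NA_real_,
                      p = NA_real_, significant = NA, suppressed = TRUE,
                      stringsAsFactors = FALSE)
    if (n_exp < min_n) return(out)
    rep_col <- attr(x, "report_cols")
    if (stats::sd(x[, rep_col]) == 0) {
      warning("exposure without variance dropped: ", label)
      return(out)
    }
    cc <- stats::complete.cases(x)
    fit <- .fit_for_stratum(x[cc, , drop = FALSE], fr[cc, , drop = FALSE],
                            stratum)
    tt <- fit$or_table[fit$or_table$term == rep_col, ]
    out$or <- tt$or; out$ci_lo <- tt$ci_lo; out$ci_hi <- tt$ci_hi
    out$p <- tt$p; out$significant <- tt$p < 0.01; out$suppressed <- FALSE
    out
  })
  do.call(rbind, rows)
}

#' Model-fit comparison table
#'
#' Fits a list of model specifications on the identical complete-case
#' observation set and tabulates the number of estimated parameters,
#' log-likelihood, McFadden pseudo-R2, AIC, and BIC, flagging the best AIC
#' and BIC.
#'
#' @param specs List of model specs: `list(name =, covariates =, exposures =,
#'   interactions =)`.
#' @param frame Analysis-frame rows to fit on (pre-filtered to the stratum).
#' @param stratum Stratum name controlling the response type.
#' @return Data frame with one row per model.
#' @export
model_fit_table <- function(specs, frame, stratum = "ms") {
  frame <- frame[!is.na(frame$gose6), , drop = FALSE]
  designs <- lapply(specs, function(sp) {
    .build_design(frame, sp$covariates, sp$exposures %||% list(),
                  sp$interactions %||% list())
  })
  cc <- Reduce(`&`, lapply(designs, stats::complete.cases))
  ns <- unique(vapply(designs, nrow, integer(1)))
  if (length(ns) != 1) stop("models must share the observation set")
  rows <- Map(function(sp, x) {
    fit <- .fit_for_stratum(x[cc, , drop = FALSE],
                            frame[cc, , drop = FALSE], stratum)
    data.frame(name = sp$name, n = fit$n, k = fit$k, loglik = fit$loglik,
               pseudo_r2 = fit$pseudo_r2, aic = fit$aic, bic = fit$bic,
               stringsAsFactors = FALSE)
  }, specs, designs)
  out <- do.call(rbind, rows)
  out$best_aic <- out$aic == min(out$aic)
  out$best_bic <- out$bic == min(out$bic)
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a
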