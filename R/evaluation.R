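# Model comparison: cross-validated AUC with bootstrap CIs and the
# Jonckheere-Terpstra trend test.

#' Area under the ROC curve by midrank statistic
#'
#' Rank-based AUC with tie correction: equals the proportion of
#' (event, non-event) pairs in which the event carries the larger prediction,
#' ties counted 1/2 (the Mann-Whitney statistic scaled to [0, 1]).
#'
#' @param pred Numeric predictions.
#' @param label Logical or 0/1 event labels.
#' @return Scalar AUC.
#' @export
auc_rank <- function(pred, label) {
  label <- as.logical(label)
  n1 <- sum(label)
  n0 <- sum(!label)
  if (n1 == 0 || n0 == 0) stop("AUC requires both classes")
  r <- rank(pred, ties.method = "average")
  (sum(r[label]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Cross-validated AUC with bootstrap confidence interval
#'
#' Stratified k-fold split on the event label; the model is fitted on the
#' training folds and the event probability predicted on the held-out fold
#' (ordinal models: model-implied cumulative probability of the event cut;
#' binary models: fitted probability). The AUC is computed on the pooled
#' out-of-fold (prediction, label) pairs by [auc_rank()], with a percentile
#' CI from case bootstrap resamples of those pairs (no refitting, default;
#' set `refit_boot` for the slower full-refit bootstrap).
#'
#' @param frame Analysis-frame rows for the stratum.
#' @param covariates Covariate names (see [covariate_preset()]).
#' @param exposures Exposure spec list (as in [report_table2()]).
#' @param scheme Event definition: `"poor_vs_favourable"` (GOSE <= 4) or
#'   `"disability_vs_good"` (GOSE <= 6).
#' @param response `"ordinal"` or `"binary"` model for fitting.
#' @param folds Number of folds (default 10).
#' @param seed Seed for fold assignment and bootstrap (required).
#' @param n_boot Bootstrap resamples for the CI (default 2000).
#' @param min_class Minimum events and non-events required (default 10).
#' @param refit_boot Refit the model inside each bootstrap resample.
#' @return List of class `tai_cv_auc`: `mean_auc`, `ci` (2.5/97.5
#'   percentiles), `n`, `folds`, `scheme`, `predictions`.
#' @export
cv_auc <- function(frame, covariates, exposures = list(),
                   scheme = c("poor_vs_favourable", "disability_vs_good"),
                   response = c("ordinal", "binary"), folds = 10, seed,
                   n_boot = 2000, min_class = 10, refit_boot = FALSE) {
  scheme <- match.arg(scheme)
  response <- match.arg(response)
  if (missing(seed) || is.null(seed)) stop("a seed is required")
  frame <- frame[!is.na(frame$gose6), , drop = FALSE]
  event <- dichotomize_gose(frame$gose6, scheme)
  if (sum(event) < min_class || sum(!event) < min_class) {
    stop("need at least ", min_class, " events and non-events (have ",
         sum(event), "/", sum(!event), ")")
  }
  x <- .build_design(frame, covariates, exposures)
  cc <- stats::complete.cases(x)
  x <- x[cc, , drop = FALSE]
  frame <- frame[cc, , drop = FALSE]
  event <- event[cc]
  # inverted-GOSE cut implied by the event definition: GOSE <= 4 <=> 9-GOSE
  # >= 5; GOSE <= 6 <=> 9-GOSE >= 3
  cut <- if (scheme == "poor_vs_favourable") 5 else 3
  n <- nrow(x)

  fold_of <- .stratified_folds(event, folds, seed)
  pred <- rep(NA_real_, n)
  for (f in seq_len(folds)) {
    tr <- fold_of != f
    if (length(unique(event[tr])) < 2) stop("degenerate fold ", f)
    fit <- if (response == "ordinal") {
      fit_proportional_odds(x[tr, , drop = FALSE],
                            frame$response_ordinal[tr])
    } else {
      fit_binary_logistic(x[tr, , drop = FALSE], event[tr])
    }
    pred[!tr] <- predict_event_prob(fit, x[!tr, , drop = FALSE], cut)
  }
  mean_auc <- auc_rank(pred, event)
  boot <- numeric(n_boot)
  for (b in seq_len(n_boot)) {
    repeat {
      idx <- sample.int(n, n, replace = TRUE)
      if (any(event[idx]) && any(!event[idx])) break
    }
    boot[b] <- if (refit_boot) {
      fit <- if (response == "ordinal") {
        fit_proportional_odds(x[idx, , drop = FALSE],
                              frame$response_ordinal[idx])
      } else {
        fit_binary_logistic(x[idx, , drop = FALSE], event[idx])
      }
      auc_rank(predict_event_prob(fit, x[idx, , drop = FALSE], cut),
               event[idx])
    } else {
      auc_rank(pred[idx], event[idx])
    }
  }
  ci <- unname(stats::quantile(boot, c(0.025, 0.975)))
  structure(list(mean_auc = mean_auc, ci = ci, n = n, folds = folds,
                 scheme = scheme, seed = seed, predictions = pred,
                 event = event),
            class = "tai_cv_auc")
}

#' @export
print.tai_cv_auc <- function(x, ...) {
  cat(sprintf("Cross-validated AUC (%s, %d folds, n = %d): %.3f (95%% CI %.3f; %.3f)\n",
              x$scheme, x$folds, x$n, x$mean_auc, x$ci[1], x$ci[2]))
  invisible(x)
}

#' Grading and volumetric model comparison table
#'
#' Compares, within a stratum, the baseline adjustment model, the four
#' grading systems entered as single integer-scored covariates added to the
#' baseline, and the volumetric models (TAI FLAIR volume; TAI + contusion
#' FLAIR volume; contusion volume only, each as log-volume pairs), reporting
#' pseudo-R2 / AIC / BIC and the cross-validated AUC with bootstrap CI. The
#' AUC event is poor outcome (GOSE <= 4) in severe TBI and disability
#' (GOSE <= 6) otherwise; the AUC block is skipped (NA) when a class has
#' fewer than `min_class` members.
#'
#' @param frame An [analysis_frame()].
#' @param stratum Stratum name.
#' @param folds,seed,n_boot Passed to [cv_auc()].
#' @param min_class Minimum class size for the AUC block.
#' @return Data frame with one row per model.
#' @export
comparison_table <- function(frame, stratum, folds = 10, seed,
                             n_boot = 2000, min_class = 10) {
  fr <- filter_stratum(frame, stratum)
  fr <- fr[!is.na(fr$gose6), , drop = FALSE]
  if (!nrow(fr)) stop("empty stratum: ", stratum)
  covs <- covariate_preset(stratum)
  response <- if (stratum %in% c("moderate_13", "mild")) "binary" else "ordinal"
  scheme <- if (stratum == "severe") "poor_vs_favourable" else "disability_vs_good"

  specs <- list(
    list(name = "baseline", exposures = list()),
    list(name = "standard_grading",
         exposures = list(list(feature = "grade_standard"))),
    list(name = "stockholm_grading",
         exposures = list(list(feature = "grade_stockholm"))),
    list(name = "gcs_based_grading",
         exposures = list(list(feature = "grade_gcs_based"))),
    list(name = "trondheim_grading",
         exposures = list(list(feature = "grade_trondheim"))),
    list(name = "tai_flair_volume",
         exposures = list(list(feature = "vol_tai_flair_cm3",
                               transform = "log_volume_pair",
                               label = "vol_tai_flair"))),
    list(name = "tbi_flair_volume",
         exposures = list(list(feature = "vol_tai_flair_cm3",
                               transform = "log_volume_pair",
                               label = "vol_tai_flair"),
                          list(feature = "vol_contusion_flair_cm3",
                               transform = "log_volume_pair",
                               label = "vol_contusion"))),
    list(name = "contusion_volume",
         exposures = list(list(feature = "vol_contusion_flair_cm3",
                               transform = "log_volume_pair",
                               label = "vol_contusion"))))
  for (i in seq_along(specs)) specs[[i]]$covariates <- covs
  tab <- model_fit_table(specs, fr, stratum)

  event <- dichotomize_gose(fr$gose6, scheme)
  auc_possible <- sum(event) >= min_class && sum(!event) >= min_class
  tab$mean_auc <- NA_real_
  tab$auc_lo <- NA_real_
  tab$auc_hi <- NA_real_
  if (auc_possible) {
    for (i in seq_along(specs)) {
      cv <- cv_auc(fr, covs, specs[[i]]$exposures, scheme, response,
                   folds = folds, seed = seed, n_boot = n_boot,
                   min_class = min_class)
      tab$mean_auc[i] <- cv$mean_auc
      tab$auc_lo[i] <- cv$ci[1]
      tab$auc_hi[i] <- cv$ci[2]
    }
  } else {
    message("AUC block skipped for stratum '", stratum,
            "': fewer than ", min_class, " events or non-events")
  }
  tab
}

#' Jonckheere-Terpstra trend test
#'
#' Tests for a monotone trend in a numeric variable across ordered groups:
#' the statistic is the sum of pairwise Mann-Whitney counts over all ordered
#' group pairs (ties counted 1/2). The p-value uses the normal approximation
#' with tie correction, or the exact permutation distribution (full
#' enumeration) when the total n is at most `exact_max`.
#'
#' @param values Numeric observations (e.g. TAI volumes or counts).
#' @param groups Ordered factor or integer group labels (ordered by, e.g.,
#'   GOSE category); at least 2 non-empty groups.
#' @param alternative `"increasing"` (values rise with group order) or
#'   `"decreasing"`.
#' @param exact_max Use exact enumeration when `length(values) <= exact_max`.
#' @return List of class `tai_jt`: `statistic`, `p_value`, `method`,
#'   `alternative`.
#' @export
jonckheere_terpstra <- function(values, groups,
                                alternative = c("increasing", "decreasing"),
                                exact_max = 12) {
  alternative <- match.arg(alternative)
  ok <- !is.na(values) & !is.na(groups)
  values <- values[ok]
  g <- as.integer(factor(groups, levels = sort(unique(groups))))
  k <- max(g)
  if (k < 2) stop("need at least 2 non-empty ordered groups")
  if (alternative == "decreasing") g <- k + 1L - g

  jt_stat <- function(values, g) {
    s <- 0
    for (i in seq_len(max(g) - 1)) {
      for (j in seq(i + 1, max(g))) {
        xi <- values[g == i]
        xj <- values[g == j]
        if (length(xi) && length(xj)) {
          cmp <- outer(xi, xj, "<")
          tie <- outer(xi, xj, "==")
          s <- s + sum(cmp) + 0.5 * sum(tie)
        }
      }
    }
    s
  }
  J <- jt_stat(values, g)
  n <- length(values)
  if (n <= exact_max) {
    perms <- .all_group_assignments(tabulate(g))
    stats_perm <- vapply(perms, function(gg) jt_stat(values, gg), numeric(1))
    p <- mean(stats_perm >= J - 1e-12)
    method <- "exact permutation"
  } else {
    ni <- tabulate(g)
    mean_J <- (n^2 - sum(ni^2)) / 4
    # tie-corrected null variance
    tj <- table(values)
    v1 <- n * (n - 1) * (2 * n + 5) - sum(ni * (ni - 1) * (2 * ni + 5)) -
      sum(tj * (tj - 1) * (2 * tj + 5))
    v2 <- sum(ni * (ni - 1) * (ni - 2)) * sum(tj * (tj - 1) * (tj - 2))
    v3 <- sum(ni * (ni - 1)) * sum(tj * (tj - 1))
    var_J <- v1 / 72 + v2 / (36 * n * (n - 1) * (n - 2)) +
      v3 / (8 * n * (n - 1))
    if (var_J <= 0) stop("degenerate data: zero null variance")
    # continuity-corrected upper tail
    z <- (J - mean_J - 0.5) / sqrt(var_J)
    p <- stats::pnorm(z, lower.tail = FALSE)
    method <- "normal approximation with tie correction"
  }
  structure(list(statistic = J, p_value = p, method = method,
                 alternative = alternative, n = n, groups = k),
            class = "tai_jt")
}

#' @export
print.tai_jt <- function(x, ...) {
  cat(sprintf(
    "Jonckheere-Terpstra: J = %.1f, one-sided p = %.4g (%s trend, %s)\n",
    x$statistic, x$p_value, x$alternative, x$method))
  invisible(x)
}

# enumerate all assignments of n labelled positions into groups of sizes ni
.all_group_assignments <- function(ni) {
  n <- sum(ni)
  res <- list(integer(n))
  positions <- list(seq_len(n))
  for (grp in seq_along(ni)[-length(ni)]) {
    new_res <- list()
    new_pos <- list()
    for (s in seq_along(res)) {
      rem <- positions[[s]]
      cmb <- utils::combn(rem, ni[grp], simplify = FALSE)
      for (cc in cmb) {
        gg <- res[[s]]
        gg[cc] <- grp
        new_res[[length(new_res) + 1]] <- gg
        new_pos[[length(new_pos) + 1]] <- setdiff(rem, cc)
      }
    }
    res <- new_res
    positions <- new_pos
  }
  lapply(seq_along(res), function(s) {
    gg <- res[[s]]
    gg[positions[[s]]] <- length(ni)
    gg
  })
}
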