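# Construction of the 6-month GOSE endpoint: time-weighted interpolation,
# EM imputation under a joint-normal model, and the two dichotomisations.

.round_half_up <- function(x) floor(x + 0.5)

#' Interpolated 6-month GOSE from 3- and 12-month assessments
#'
#' When GOSE was assessed at 3 and 12 months, the 6-month score is taken as
#' the weighted mean corresponding to linear interpolation in time at 6
#' months: (2 * gose3 + gose12) / 3, rounded half-up and clipped to [1, 8].
#' The 2/3-1/3 weighting is configurable via `w3`.
#'
#' @param gose3,gose12 Integer GOSE scores in [1, 8]; vectors recycle.
#' @param w3 Weight on the 3-month score (default 2/3).
#' @return Integer 6-month GOSE scores.
#' @examples
#' weighted_gose6(5, 8)  # 6
#' @export
weighted_gose6 <- function(gose3, gose12, w3 = 2 / 3) {
  chk <- function(v, nm) {
    bad <- !is.na(v) & (v < 1 | v > 8 | v != round(v))
    if (any(bad)) stop(nm, " outside [1, 8]: ",
                       paste(unique(v[bad]), collapse = ", "))
  }
  chk(gose3, "gose3"); chk(gose12, "gose12")
  if (any(is.na(gose3) | is.na(gose12))) {
    stop("weighted 6-month GOSE requires both the 3- and 12-month scores")
  }
  g <- w3 * gose3 + (1 - w3) * gose12
  as.integer(pmin(8, pmax(1, .round_half_up(g))))
}

#' Dichotomise a GOSE score
#'
#' Two schemes are used depending on injury severity: `poor_vs_favourable`
#' (event = poor outcome, GOSE <= 4) and `disability_vs_good` (event =
#' disability, GOSE <= 6).
#'
#' @param gose Integer GOSE scores in [1, 8].
#' @param scheme `"poor_vs_favourable"` or `"disability_vs_good"`.
#' @return Logical event indicator.
#' @export
dichotomize_gose <- function(gose,
                             scheme = c("poor_vs_favourable",
                                        "disability_vs_good")) {
  scheme <- match.arg(scheme)
  bad <- !is.na(gose) & (gose < 1 | gose > 8 | gose != round(gose))
  if (any(bad)) stop("GOSE outside [1, 8]: ",
                     paste(unique(gose[bad]), collapse = ", "))
  cut <- if (scheme == "poor_vs_favourable") 4 else 6
  gose <= cut
}

#' EM imputation of missing 6-month GOSE under a joint-normal model
#'
#' Single deterministic imputation: the columns of `x` (first column the
#' outcome with missing entries, remaining columns complete covariates) are
#' modelled as jointly multivariate normal. The E-step replaces missing
#' outcome entries by their conditional expectations (and accumulates the
#' conditional variance into the second moments); the M-step updates the mean
#' vector and covariance matrix; iteration continues until the observed-data
#' log-likelihood changes by less than `tol`. The log-likelihood is asserted
#' to be non-decreasing. Imputed outcome values are rounded half-up and
#' clipped to `range`.
#'
#' @param x Numeric matrix or data frame; missingness confined to column 1.
#'   Covariate columns with missing entries are mean-filled first.
#' @param tol Convergence tolerance on the observed-data log-likelihood.
#' @param max_iter Maximum EM iterations.
#' @param range Clipping range for the imputed outcome (GOSE: c(1, 8)).
#' @return A list: `completed` (numeric vector, column 1 with imputations),
#'   `imputed` (logical flag per row), `n_imputed`, `iterations`, `loglik`.
#' @export
em_impute_gose <- function(x, tol = 1e-6, max_iter = 500, range = c(1, 8)) {
  x <- as.matrix(x)
  storage.mode(x) <- "double"
  p <- ncol(x)
  n <- nrow(x)
  if (p < 2) stop("need the outcome plus at least one covariate column")
  # mean-fill covariates
  for (j in 2:p) {
    if (all(is.na(x[, j]))) stop("covariate column ", j, " is all missing")
    x[is.na(x[, j]), j] <- mean(x[, j], na.rm = TRUE)
  }
  if (all(is.na(x[, 1]))) stop("outcome column is all missing")
  miss <- is.na(x[, 1])
  out <- x[, 1]
  if (!any(miss)) {
    return(list(completed = out, imputed = miss, n_imputed = 0L,
                iterations = 0L, loglik = NA_real_))
  }

  obs_loglik <- function(mu, sigma) {
    # complete rows: full density; incomplete rows: marginal over covariates
    s_oo <- sigma[-1, -1, drop = FALSE]
    ll <- sum(.dmvnorm_log(x[!miss, , drop = FALSE], mu, sigma))
    ll + sum(.dmvnorm_log(x[miss, -1, drop = FALSE], mu[-1], s_oo))
  }

  xw <- x
  xw[miss, 1] <- mean(x[!miss, 1])
  mu <- colMeans(xw)
  sigma <- stats::cov(xw) * (n - 1) / n
  # small relative ridge keeps the model proper under collinear columns
  ridge <- function(s) s + diag(1e-8 * mean(diag(s)), ncol(s))
  sigma <- ridge(sigma)
  ll_old <- -Inf
  it <- 0L
  repeat {
    it <- it + 1L
    # E-step: conditional mean/variance of x1 | covariates for missing rows
    s11 <- sigma[1, 1]
    s1o <- sigma[1, -1, drop = FALSE]
    s_oo <- sigma[-1, -1, drop = FALSE]
    w <- solve(s_oo, t(s1o))                       # p-1 x 1
    cond_var <- max(s11 - as.numeric(s1o %*% w), 0)
    dev <- sweep(x[miss, -1, drop = FALSE], 2, mu[-1])
    cond_mean <- mu[1] + as.numeric(dev %*% w)
    xw[miss, 1] <- cond_mean
    # M-step with the conditional-variance correction on the (1,1) moment
    mu <- colMeans(xw)
    centered <- sweep(xw, 2, mu)
    ss <- crossprod(centered) / n
    ss[1, 1] <- ss[1, 1] + sum(rep(cond_var, sum(miss))) / n
    sigma <- ridge(ss)
    ll <- obs_loglik(mu, sigma)
    if (ll < ll_old - 1e-6 * (1 + abs(ll_old))) {
      stop("EM log-likelihood decreased at iteration ", it)
    }
    if (abs(ll - ll_old) < tol) break
    if (it >= max_iter) {
      stop("EM did not converge in ", max_iter,
           " iterations (last increments: ", signif(ll - ll_old, 3), ")")
    }
    ll_old <- ll
  }
  imputed_vals <- pmin(range[2], pmax(range[1], .round_half_up(xw[miss, 1])))
  out[miss] <- imputed_vals
  list(completed = out, imputed = miss, n_imputed = sum(miss),
       iterations = it, loglik = ll)
}

.dmvnorm_log <- function(x, mu, sigma) {
  if (!nrow(x)) return(numeric(0))
  p <- length(mu)
  ch <- chol(sigma + diag(1e-10, p))
  z <- forwardsolve(t(ch), t(sweep(x, 2, mu)))
  -0.5 * p * log(2 * pi) - sum(log(diag(ch))) - 0.5 * colSums(z^2)
}

#' Construct the analysis outcome for a cohort
#'
#' Builds the 6-month GOSE endpoint per patient: observed `gose6` when
#' available; else the time-weighted interpolation of `gose3` and `gose12`
#' when both exist; else the 3-month score (the convention for the mild-TBI
#' cohort, assessed at 3 months only); remaining missing values are imputed
#' with [em_impute_gose()] over (gose6, age, GCS, Marshall-as-integer,
#' Trondheim grade, log1p total FLAIR TAI volume). The model response is the
#' inverted score, 9 - GOSE, which increases with worse outcome.
#'
#' @param cohort A validated `tai_cohort`.
#' @param impute Use EM imputation for remaining missing values (default
#'   TRUE).
#' @return Data frame: patient_id, gose6, gose6_source (observed / weighted /
#'   gose3 / imputed / missing), response_ordinal, plus an `em` attribute
#'   with the imputation report.
#' @export
construct_outcomes <- function(cohort, impute = TRUE) {
  oc <- cohort$outcomes
  ids <- cohort$patients$patient_id
  m <- match(ids, oc$patient_id)
  g3 <- oc$gose3[m]; g6 <- oc$gose6[m]; g12 <- oc$gose12[m]
  out <- g6
  source <- ifelse(!is.na(g6), "observed", NA_character_)
  w <- is.na(out) & !is.na(g3) & !is.na(g12)
  if (any(w)) {
    out[w] <- weighted_gose6(g3[w], g12[w])
    source[w] <- "weighted"
  }
  f3 <- is.na(out) & !is.na(g3)
  if (any(f3)) {
    out[f3] <- g3[f3]
    source[f3] <- "gose3"
  }
  em_report <- NULL
  if (impute && any(is.na(out))) {
    fx <- extract_features(cohort)
    grade <- apply_grading(fx, "trondheim")
    marshall_num <- match(cohort$patients$marshall, .marshall_levels) - 1
    xm <- cbind(gose6 = out, age = cohort$patients$age,
                gcs = cohort$patients$gcs, marshall = marshall_num,
                trondheim = grade,
                log_vol_flair = log1p(fx$vol_tai_flair_cm3))
    em <- em_impute_gose(xm)
    source[is.na(out)] <- "imputed"
    out <- em$completed
    em_report <- em[c("n_imputed", "iterations", "loglik")]
  }
  source[is.na(out)] <- "missing"
  res <- data.frame(patient_id = ids, gose6 = as.integer(out),
                    gose6_source = source,
                    response_ordinal = as.integer(9 - out),
                    stringsAsFactors = FALSE)
  attr(res, "em") <- em_report
  res
}
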