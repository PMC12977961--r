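# check the fixed-effect design for rank deficiency before handing it to
# lme4, so the offending columns are named instead of silently dropped
check_full_rank <- function(formula_fixed, data) {
  X <- stats::model.matrix(formula_fixed, data)
  qrX <- qr(X)
  if (qrX$rank < ncol(X)) {
    bad <- colnames(X)[qrX$pivot[-seq_len(qrX$rank)]]
    stop("fixed-effect design is rank deficient; collinear columns: ",
         paste(bad, collapse = ", "), call. = FALSE)
  }
  invisible(TRUE)
}

new_model_fit <- function(fit, n_obs, n_subjects, converged, kind) {
  sm <- summary(fit)
  coefs <- stats::coef(sm)
  re_var <- as.data.frame(lme4::VarCorr(fit))
  ri <- re_var$vcov[which(re_var$grp != "Residual" &
                            !is.na(re_var$var1) &
                            re_var$var1 == "(Intercept)")][1]
  structure(list(coefficients = coefs,
                 ranef_variance = unname(ri),
                 logLik = as.numeric(stats::logLik(fit)),
                 n_fixed = nrow(coefs),
                 n_obs = stats::nobs(fit),
                 n_subjects = n_subjects,
                 converged = converged,
                 kind = kind,
                 model = fit),
            class = "model_fit")
}

#' @export
print.model_fit <- function(x, ...) {
  cat(sprintf("<model_fit> %s: n_obs = %d, n_subjects = %d, logLik = %.3f%s\n",
              x$kind, x$n_obs, x$n_subjects, x$logLik,
              if (!x$converged) " [NOT CONVERGED]" else ""))
  print(x$coefficients)
  cat("random-intercept variance:", format(x$ranef_variance), "\n")
  invisible(x)
}

lme4_converged <- function(fit) {
  msgs <- fit@optinfo$conv$lme4$messages
  warns <- fit@optinfo$warnings
  !(length(msgs) > 0 &&
      any(grepl("failed to converge", unlist(msgs), ignore.case = TRUE))) &&
    !(length(warns) > 0 &&
        any(grepl("failed to converge", unlist(warns), ignore.case = TRUE)))
}

#' Linear mixed model for longitudinal memory change
#'
#' Fits the change-from-baseline z-score on timepoint (factor, 3-month
#' reference), age at surgery, age at epilepsy onset, normalized resection
#' volume and the preoperative z-score, optionally plus one tract
#' disconnection term, with a random intercept per subject. Estimation is by
#' maximum likelihood (not REML) so that nested fits can be compared with
#' [likelihood_ratio_test()]. Rows with a missing outcome are dropped;
#' subjects contributing a single timepoint are retained.
#'
#' @param data long-format data.frame with columns `subject_id`, `timepoint`
#'   (values "3m"/"12m"), `change_z`, `age_surgery`, `age_onset`,
#'   `resection_volume`, `pre_z` and any tract columns.
#' @param tract_term optional name of one tract-measure column (e.g.
#'   `"transection"`); `NULL` fits the confound-only model.
#' @param covariates names of the confound columns.
#' @return a `model_fit` (coefficients, random-intercept variance, ML
#'   log-likelihood, convergence flag, the underlying `lmerMod`).
#' @export
fit_change_lmm <- function(data,
                           tract_term = NULL,
                           covariates = c("age_surgery", "age_onset",
                                          "resection_volume", "pre_z")) {
  need <- c("subject_id", "timepoint", "change_z", covariates, tract_term)
  miss <- setdiff(need, names(data))
  if (length(miss))
    stop("data lacks columns: ", paste(miss, collapse = ", "), call. = FALSE)
  d <- data[!is.na(data$change_z), , drop = FALSE]
  d$timepoint <- factor(d$timepoint, levels = c("3m", "12m"))
  rhs <- c("timepoint", covariates, tract_term)
  fixed <- stats::reformulate(rhs, response = "change_z")
  check_full_rank(fixed, d)
  form <- stats::as.formula(paste("change_z ~", paste(rhs, collapse = " + "),
                                  "+ (1 | subject_id)"))
  fit <- withCallingHandlers(
    lme4::lmer(form, data = d, REML = FALSE),
    message = function(m) invokeRestart("muffleMessage"),
    warning = function(w) {
      if (grepl("singular|converg", conditionMessage(w)))
        invokeRestart("muffleWarning")
    })
  new_model_fit(fit, nrow(d), length(unique(d$subject_id)),
                lme4_converged(fit), "lmm")
}

#' Logistic mixed model for binary outcome vs tract disconnection
#'
#' Fits a logistic random-intercept model of a binary outcome (RCI decline
#' or seizure freedom) on a disconnection indicator plus covariates
#' (resection type and normalized resection volume by default). Complete
#' separation is detected on the fixed-effect part; when found the fit is
#' flagged (`separation = TRUE`) and a Firth bias-reduced logistic
#' regression without the random intercept is used as a penalized-likelihood
#' fallback.
#'
#' @param data long-format data.frame (one row per subject-timepoint).
#' @param outcome name of the 0/1 outcome column.
#' @param predictor name of the 0/1 disconnection column.
#' @param covariates covariate column names.
#' @param subject grouping column for the random intercept.
#' @return a `model_fit` with log-odds estimates; field `separation`
#'   indicates the fallback.
#' @export
fit_binary_glmm <- function(data, outcome, predictor = "disconnected",
                            covariates = c("resection_type",
                                           "resection_volume"),
                            subject = "subject_id") {
  need <- c(subject, outcome, predictor, covariates)
  miss <- setdiff(need, names(data))
  if (length(miss))
    stop("data lacks columns: ", paste(miss, collapse = ", "), call. = FALSE)
  d <- data[!is.na(data[[outcome]]), , drop = FALSE]
  y <- d[[outcome]]
  if (!all(y %in% c(0, 1)))
    stop("outcome '", outcome, "' must be coded 0/1", call. = FALSE)
  if (length(unique(y)) < 2L)
    stop("outcome '", outcome, "' is degenerate: all values are ", y[1L],
         call. = FALSE)
  rhs <- c(predictor, covariates)
  fixed <- stats::reformulate(rhs, response = outcome)
  check_full_rank(fixed, d)

  sep <- detect_separation(fixed, d)
  if (sep) {
    fit <- firth_logistic(stats::model.matrix(fixed, d), y)
    out <- structure(list(coefficients = fit$coefficients,
                          ranef_variance = NA_real_,
                          logLik = fit$logLik,
                          n_fixed = nrow(fit$coefficients),
                          n_obs = nrow(d),
                          n_subjects = length(unique(d[[subject]])),
                          converged = fit$converged,
                          kind = "firth_logistic",
                          separation = TRUE,
                          model = fit),
                     class = "model_fit")
    warning("complete separation detected; penalized-likelihood (Firth) ",
            "fallback applied without the random intercept")
    return(out)
  }
  form <- stats::as.formula(paste(outcome, "~", paste(rhs, collapse = " + "),
                                  "+ (1 |", subject, ")"))
  fit <- withCallingHandlers(
    lme4::glmer(form, data = d, family = stats::binomial()),
    message = function(m) invokeRestart("muffleMessage"),
    warning = function(w) {
      if (grepl("singular|converg", conditionMessage(w)))
        invokeRestart("muffleWarning")
    })
  out <- new_model_fit(fit, nrow(d), length(unique(d[[subject]])),
                       lme4_converged(fit), "glmm")
  out$separation <- FALSE
  out
}

# a plain glm whose fitted probabilities collapse to 0/1 signals separation
detect_separation <- function(fixed, data) {
  fit <- suppressWarnings(stats::glm(fixed, data = data,
                                     family = stats::binomial()))
  eps <- 1e-8
  p <- fit$fitted.values
  y <- fit$y
  all(p[y == 1] > 1 - eps) && all(p[y == 0] < eps)
}

# Firth bias-reduced logistic regression: Newton steps on the modified
# score U*(b) = X'(y - p + h (1/2 - p)), h the hat-matrix diagonal
firth_logistic <- function(X, y, maxit = 100L, tol = 1e-8) {
  b <- rep(0, ncol(X))
  converged <- FALSE
  for (it in seq_len(maxit)) {
    eta <- drop(X %*% b)
    p <- stats::plogis(eta)
    w <- p * (1 - p)
    XW <- X * sqrt(w)
    I <- crossprod(XW)
    h <- rowSums((XW %*% solve(I)) * XW)
    U <- drop(crossprod(X, y - p + h * (0.5 - p)))
    step <- solve(I, U)
    b <- b + step
    if (max(abs(step)) < tol) { converged <- TRUE; break }
  }
  eta <- drop(X %*% b); p <- stats::plogis(eta)
  w <- p * (1 - p)
  I <- crossprod(X * sqrt(w))
  se <- sqrt(diag(solve(I)))
  ll <- sum(y * log(p) + (1 - y) * log1p(-p)) + 0.5 * determinant(I)$modulus
  co <- cbind(Estimate = b, `Std. Error` = se, `z value` = b / se)
  rownames(co) <- colnames(X)
  list(coefficients = co, logLik = as.numeric(ll), converged = converged)
}

#' Likelihood ratio test between nested ML fits
#'
#' chi^2 = 2 (logLik_full - logLik_null), degrees of freedom the difference
#' in fixed-effect count, p-value from the chi-squared distribution. Small
#' negative statistics from numerical noise at the boundary are clamped to
#' zero. Both fits must be on the same rows and by maximum likelihood.
#'
#' @param null_fit,full_fit `model_fit` objects, `null_fit` nested in
#'   `full_fit`.
#' @return an `lrt_result`: list with `chi_sq`, `df`, `p`.
#' @export
likelihood_ratio_test <- function(null_fit, full_fit) {
  stopifnot(inherits(null_fit, "model_fit"), inherits(full_fit, "model_fit"))
  if (null_fit$n_obs != full_fit$n_obs)
    stop("fits use different data: ", null_fit$n_obs, " vs ",
         full_fit$n_obs, " rows", call. = FALSE)
  df <- full_fit$n_fixed - null_fit$n_fixed
  if (df < 1L && full_fit$n_fixed != null_fit$n_fixed)
    stop("full model has fewer fixed effects than the null", call. = FALSE)
  chi <- max(0, 2 * (full_fit$logLik - null_fit$logLik))
  p <- if (df >= 1L) stats::pchisq(chi, df, lower.tail = FALSE) else 1
  structure(list(chi_sq = chi, df = max(df, 0L), p = p), class = "lrt_result")
}

#' @export
print.lrt_result <- function(x, ...) {
  cat(sprintf("<lrt_result> chi^2(%d) = %.4f, p = %.4g\n",
              x$df, x$chi_sq, x$p))
  invisible(x)
}

#' Binarize an ILAE seizure-outcome class
#'
#' Class 1 (complete seizure freedom) maps to 1; every class above 1 maps
#' to 0 (non-seizure-freedom).
#'
#' @param ilae integer ILAE class(es), >= 1.
#' @return 0/1 integer vector; `NA` propagates.
#' @export
binarize_ilae <- function(ilae) {
  bad <- !is.na(ilae) & (ilae < 1 | ilae != round(ilae))
  if (any(bad))
    stop("invalid ILAE class: ", paste(unique(ilae[bad]), collapse = ", "),
         " (classes are integers >= 1)", call. = FALSE)
  as.integer(ilae == 1)
}
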