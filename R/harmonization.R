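#' Welch two-sample t-test
#'
#' Unequal-variance t-test with Welch-Satterthwaite degrees of freedom,
#' two-sided. Used to screen tract metrics for scanner-batch differences
#' before harmonization.
#'
#' @param a,b numeric samples (each n >= 2 after removing `NA`s).
#' @return a `welch_result`: list with `t`, `df` (real-valued), `p`,
#'   `mean_a`, `mean_b`.
#' @export
welch_t_test <- function(a, b) {
  a <- a[!is.na(a)]; b <- b[!is.na(b)]
  if (length(a) < 2L || length(b) < 2L)
    stop("each sample needs at least 2 non-missing values", call. = FALSE)
  if (stats::var(a) == 0 && stats::var(b) == 0)
    stop("both samples have zero variance; t statistic undefined",
         call. = FALSE)
  ht <- stats::t.test(a, b, var.equal = FALSE)
  structure(list(t = unname(ht$statistic), df = unname(ht$parameter),
                 p = ht$p.value,
                 mean_a = mean(a), mean_b = mean(b)),
            class = "welch_result")
}

#' @export
print.welch_result <- function(x, ...) {
  cat(sprintf("<welch_result> t(%.3f) = %.4f, p = %.4g\n", x$df, x$t, x$p))
  invisible(x)
}

# method-of-moments inverse-gamma hyperparameters for the scale prior
aprior <- function(d) { m <- mean(d); s2 <- stats::var(d); (2 * s2 + m^2) / s2 }
bprior <- function(d) { m <- mean(d); s2 <- stats::var(d); (m * s2 + m^3) / s2 }

postmean <- function(g_hat, g_bar, n, d_star, t2)
  (t2 * n * g_hat + d_star * g_bar) / (t2 * n + d_star)
postvar <- function(ss, n, a, b) (0.5 * ss + b) / (n / 2 + a - 1)

# EB shrinkage for one batch: iterate the conditional posterior means of the
# additive (gamma) and multiplicative (delta) batch effects to convergence
eb_solve <- function(Z_b, g_hat, d_hat, conv = 1e-4, maxit = 200L) {
  n <- nrow(Z_b)
  g_bar <- mean(g_hat); t2 <- stats::var(g_hat)
  a <- aprior(d_hat); b <- bprior(d_hat)
  g_old <- g_hat; d_old <- d_hat
  for (it in seq_len(maxit)) {
    g_new <- postmean(g_hat, g_bar, n, d_old, t2)
    ss <- colSums((Z_b - matrix(g_new, n, length(g_new), byrow = TRUE))^2)
    d_new <- postvar(ss, n, a, b)
    change <- max(abs(g_new - g_old) / abs(g_old + 1e-12),
                  abs(d_new - d_old) / abs(d_old + 1e-12))
    g_old <- g_new; d_old <- d_new
    if (change < conv) break
  }
  list(gamma = g_old, delta = d_old)
}

#' ComBat-style location-scale batch harmonization
#'
#' Removes per-batch additive (location) and multiplicative (scale) effects
#' from a subjects-by-features table while preserving covariate effects:
#' features are standardized on covariate-adjusted data, per-batch
#' location/scale parameters are estimated — with parametric empirical-Bayes
#' shrinkage across features when `eb = TRUE` (normal prior on locations,
#' inverse-gamma on scales, method-of-moments hyperparameters) — and
#' removed, then the covariate fit is restored. With `eb = FALSE` the
#' adjustment reduces to exact per-batch alignment of residual means and
#' variances.
#'
#' @param features numeric matrix or data.frame, subjects x features.
#' @param batch factor (or coercible) of batch labels, >= 2 levels with >= 2
#'   subjects each.
#' @param covariates optional numeric matrix of biological covariates to
#'   preserve (subjects x q), no intercept column.
#' @param eb logical; empirical-Bayes shrinkage of batch parameters across
#'   features (needs >= 2 features; silently disabled for a single feature).
#' @return a `batch_adjustment`: list with `adjusted` (same shape as
#'   `features`), `gamma_hat`, `delta_hat`, `gamma_star`, `delta_star`
#'   (batches x features), `var_pooled`, `batch` and `eb`.
#' @export
combat_adjust <- function(features, batch, covariates = NULL, eb = TRUE) {
  Y <- as.matrix(features)
  if (!is.numeric(Y)) stop("features must be numeric", call. = FALSE)
  batch <- factor(batch)
  n <- nrow(Y); p <- ncol(Y)
  if (length(batch) != n)
    stop("batch labels (", length(batch), ") do not match subjects (", n, ")",
         call. = FALSE)
  if (nlevels(batch) < 2L)
    stop("need at least 2 batches", call. = FALSE)
  nb <- table(batch)
  if (any(nb < 2L))
    stop("batch '", names(nb)[which(nb < 2L)[1L]],
         "' has fewer than 2 subjects", call. = FALSE)
  if (eb && p < 2L) eb <- FALSE

  B <- stats::model.matrix(~ batch - 1)
  X <- B
  if (!is.null(covariates)) {
    C <- as.matrix(covariates)
    if (nrow(C) != n) stop("covariates rows do not match subjects", call. = FALSE)
    X <- cbind(B, C)
  }
  if (qr(X)$rank < ncol(X))
    stop("batch + covariate design is rank deficient (a covariate is ",
         "confounded with batch)", call. = FALSE)

  Bhat <- solve(crossprod(X), crossprod(X, Y))       # (nbatch+q) x p
  nbk <- as.numeric(nb)
  grand <- (nbk / n) %*% Bhat[seq_len(nlevels(batch)), , drop = FALSE]
  stand_mean <- matrix(grand, n, p, byrow = TRUE)
  if (!is.null(covariates))
    stand_mean <- stand_mean +
      X[, -seq_len(nlevels(batch)), drop = FALSE] %*%
      Bhat[-seq_len(nlevels(batch)), , drop = FALSE]
  resid_full <- Y - X %*% Bhat
  var_pooled <- colSums(resid_full^2) / n
  if (any(var_pooled <= 0))
    stop("a feature has zero residual variance; cannot standardize",
         call. = FALSE)
  sdv <- matrix(sqrt(var_pooled), n, p, byrow = TRUE)
  Z <- (Y - stand_mean) / sdv

  lv <- levels(batch)
  gamma_hat <- delta_hat <- matrix(NA_real_, length(lv), p,
                                   dimnames = list(lv, colnames(Y)))
  for (k in seq_along(lv)) {
    Zk <- Z[batch == lv[k], , drop = FALSE]
    gamma_hat[k, ] <- colMeans(Zk)
    delta_hat[k, ] <- apply(Zk, 2L, stats::var)
  }
  gamma_star <- gamma_hat; delta_star <- delta_hat
  if (eb) {
    for (k in seq_along(lv)) {
      sol <- eb_solve(Z[batch == lv[k], , drop = FALSE],
                      gamma_hat[k, ], delta_hat[k, ])
      gamma_star[k, ] <- sol$gamma
      delta_star[k, ] <- sol$delta
    }
  }

  adj <- Z
  for (k in seq_along(lv)) {
    rows <- batch == lv[k]
    adj[rows, ] <- sweep(sweep(Z[rows, , drop = FALSE], 2L,
                               gamma_star[k, ], "-"),
                         2L, sqrt(delta_star[k, ]), "/")
  }
  adjusted <- adj * sdv + stand_mean
  dimnames(adjusted) <- dimnames(Y)
  structure(list(adjusted = adjusted,
                 gamma_hat = gamma_hat, delta_hat = delta_hat,
                 gamma_star = gamma_star, delta_star = delta_star,
                 var_pooled = var_pooled, batch = batch, eb = eb),
            class = "batch_adjustment")
}

#' Welch-gated harmonization of a feature table
#'
#' Each feature is screened for a batch difference with a Welch two-sample
#' t-test (two batches); only features significant at `alpha` are
#' harmonized with [combat_adjust()], the rest pass through untouched.
#'
#' @param features subjects x features numeric matrix or data.frame.
#' @param batch batch labels, exactly 2 levels for the Welch gate.
#' @param covariates optional covariates preserved during adjustment.
#' @param alpha gate significance level (default 0.05).
#' @param eb empirical-Bayes shrinkage flag passed to [combat_adjust()].
#' @return list with `adjusted` table, `p_values` per feature,
#'   `harmonized_features` (names of adjusted columns) and the
#'   `batch_adjustment` (or `NULL` when nothing passed the gate).
#' @export
harmonize_features <- function(features, batch, covariates = NULL,
                               alpha = 0.05, eb = TRUE) {
  Y <- as.matrix(features)
  batch <- factor(batch)
  if (nlevels(batch) != 2L)
    stop("the Welch gate is defined for exactly 2 batches; got ",
         nlevels(batch), call. = FALSE)
  lv <- levels(batch)
  pv <- apply(Y, 2L, function(col)
    welch_t_test(col[batch == lv[1L]], col[batch == lv[2L]])$p)
  sig <- which(pv < alpha)
  adjusted <- Y
  adjustment <- NULL
  if (length(sig)) {
    adjustment <- combat_adjust(Y[, sig, drop = FALSE], batch,
                                covariates = covariates, eb = eb)
    adjusted[, sig] <- adjustment$adjusted
  }
  list(adjusted = adjusted, p_values = pv,
       harmonized_features = colnames(Y)[sig],
       adjustment = adjustment)
}
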