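#' Read a normative table for age-adjusted z-scoring
#'
#' A normative table gives, per task and age band, the mean and SD of the
#' raw score in a normative population. Columns: `task`, `age_low`,
#' `age_high`, `mean`, `sd`. Bands are inclusive at both ends.
#'
#' @param path CSV file path.
#' @return a data.frame normative table.
#' @export
read_normative_table <- function(path) {
  tab <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("task", "age_low", "age_high", "mean", "sd")
  miss <- setdiff(need, names(tab))
  if (length(miss))
    stop("normative table lacks columns: ", paste(miss, collapse = ", "),
         call. = FALSE)
  tab
}

#' Synthetic normative table shipped with the package
#'
#' Plausible list-learning norms for a verbal encoding task (raw maximum 75)
#' and a delayed retrieval task (raw maximum 15), in four adult age bands.
#' These are synthetic values for demonstration and testing; real analyses
#' should supply their instrument's published norms via
#' [read_normative_table()].
#'
#' @return a data.frame normative table.
#' @export
default_normative_table <- function() {
  read_normative_table(system.file("extdata", "normative_table_synthetic.csv",
                                   package = "disconnectr", mustWork = TRUE))
}

#' Age-adjusted z-score from a raw score
#'
#' z = (raw - mean) / sd using the normative band containing `age`.
#'
#' @param raw raw score(s); `NA` propagates.
#' @param age age(s) in years at assessment.
#' @param table normative table (see [read_normative_table()]).
#' @param task task name matching the table's `task` column.
#' @return z-score(s).
#' @export
z_transform <- function(raw, age, table, task) {
  rows <- table[table$task == task, , drop = FALSE]
  if (!nrow(rows))
    stop("task '", task, "' not present in normative table", call. = FALSE)
  mapply(function(r, a) {
    band <- rows[rows$age_low <= a & a <= rows$age_high, , drop = FALSE]
    if (!nrow(band))
      stop("age ", a, " is outside the normative table's range for task '",
           task, "'", call. = FALSE)
    band <- band[1L, ]
    if (!is.finite(band$sd) || band$sd <= 0)
      stop("normative SD must be positive (task '", task, "', age ", a, ")",
           call. = FALSE)
    (r - band$mean) / band$sd
  }, raw, age)
}

#' Pre-to-post change score
#'
#' Postoperative minus preoperative z-score. If either timepoint is missing
#' the change is missing (`NA`), never zero; the record itself is retained.
#'
#' @param pre_z,post_z numeric z-scores.
#' @return `post_z - pre_z`, with `NA` where either input is `NA`.
#' @export
change_score <- function(pre_z, post_z) {
  post_z - pre_z
}

#' MM-estimate robust linear regression
#'
#' High-breakdown S-type initial scale followed by a redescending bisquare
#' M-step tuned to 95% Gaussian efficiency (delegated to
#' [MASS::rlm()] with `method = "MM"`). The internal subsampling of the
#' initial estimator is seeded locally, so the fit is deterministic given
#' the data; the caller's RNG state is untouched. Rows with missing values
#' are dropped from the fit. Data that an ordinary least-squares fit already
#' interpolates exactly (zero residuals) are returned as that exact fit with
#' scale 0, which the MM iteration cannot represent.
#'
#' @param formula model formula.
#' @param data data.frame with the model variables.
#' @return a `robust_fit`: list with `coefficients`, `scale` (robust
#'   residual scale), `residuals`, `fitted`, `n` and the row indices used.
#' @export
robust_fit <- function(formula, data) {
  mf <- stats::model.frame(formula, data, na.action = stats::na.omit)
  X <- stats::model.matrix(attr(mf, "terms"), mf)
  y <- stats::model.response(mf)
  if (nrow(X) <= ncol(X))
    stop("need more observations (", nrow(X), ") than predictors (",
         ncol(X), ")", call. = FALSE)
  qrX <- qr(X)
  if (qrX$rank < ncol(X)) {
    bad <- colnames(X)[-seq_len(qrX$rank)]
    stop("design matrix is rank deficient; collinear columns: ",
         paste(bad, collapse = ", "), call. = FALSE)
  }
  used <- seq_len(nrow(data))
  na <- attr(mf, "na.action")
  if (!is.null(na)) used <- used[-na]

  ols <- stats::lm.fit(X, y)
  tol <- 1e-8 * max(1, max(abs(y)))
  if (max(abs(ols$residuals)) < tol) {
    co <- ols$coefficients
    return(structure(list(coefficients = co, scale = 0,
                          residuals = as.numeric(ols$residuals),
                          fitted = as.numeric(ols$fitted.values),
                          n = nrow(X), used = used),
                     class = "robust_fit"))
  }

  old_seed <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (is.null(old_seed)) {
      if (exists(".Random.seed", globalenv())) rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old_seed, envir = globalenv())
  })
  set.seed(760111L) # determinism of the S-estimate's subsampling
  fit <- MASS::rlm(X, y, method = "MM", maxit = 100)
  structure(list(coefficients = stats::coef(fit), scale = fit$s,
                 residuals = as.numeric(y - X %*% stats::coef(fit)),
                 fitted = as.numeric(X %*% stats::coef(fit)),
                 n = nrow(X), used = used),
            class = "robust_fit")
}

#' @export
print.robust_fit <- function(x, ...) {
  cat("<robust_fit> MM regression, n =", x$n, "\n")
  print(x$coefficients)
  cat("robust scale:", format(x$scale), "\n")
  invisible(x)
}

#' Reliable change classification from regression residuals
#'
#' A subject shows unexpected decline (-1) when their residual change score
#' falls below the lower limit of a `confidence`-level interval centred on
#' the expected change; otherwise the change is as predicted (0). With the
#' default normal-theory construction the lower limit is
#' `-qnorm(1 - (1 - confidence)/2) * scale` — at 80% confidence, about
#' -1.2816 robust-scale units (the 10th percentile of a two-sided interval).
#' The `empirical` method instead uses the `(1 - confidence)/2` quantile of
#' the fit's own residuals.
#'
#' @param fit a [robust_fit()] with positive scale.
#' @param confidence interval coverage in (0, 1); default 0.80.
#' @param method `"normal"` (default) or `"empirical"` lower-limit
#'   construction.
#' @return data.frame with `residual` and `classification` (-1 or 0) per
#'   observation used in the fit; the lower limit is attached as attribute
#'   `lower_limit`.
#' @export
rci_classify <- function(fit, confidence = 0.80,
                         method = c("normal", "empirical")) {
  stopifnot(inherits(fit, "robust_fit"))
  method <- match.arg(method)
  if (!is.numeric(confidence) || confidence <= 0 || confidence >= 1)
    stop("confidence must lie strictly between 0 and 1", call. = FALSE)
  if (!is.finite(fit$scale) || fit$scale <= 0)
    stop("robust scale must be positive to form a confidence interval",
         call. = FALSE)
  lower <- if (method == "normal") {
    -stats::qnorm(1 - (1 - confidence) / 2) * fit$scale
  } else {
    stats::quantile(fit$residuals, probs = (1 - confidence) / 2,
                    names = FALSE, type = 7)
  }
  out <- data.frame(residual = fit$residuals,
                    classification = ifelse(fit$residuals < lower, -1L, 0L))
  attr(out, "lower_limit") <- lower
  attr(out, "confidence") <- confidence
  out
}
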