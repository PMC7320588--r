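#' Ordinary least squares with coefficient t-tests
#'
#' Fits y on X with an intercept and returns classical coefficient
#' inference: standard errors, t = beta/SE, and two-sided p-values from the
#' t distribution with n - p - 1 degrees of freedom.
#'
#' @param y numeric response vector.
#' @param X numeric matrix or data.frame of predictors (no intercept
#'   column; one is added).
#' @return object of class \code{"ols_fit"}: list with
#'   \code{coefficients}, \code{se}, \code{t}, \code{p}, \code{residuals},
#'   \code{fitted}, \code{n}, \code{df}, \code{sigma}.
#' @export
fit_ols <- function(y, X) {
  X <- as.matrix(X)
  if (is.null(colnames(X))) colnames(X) <- paste0("x", seq_len(ncol(X)))
  n <- length(y)
  p <- ncol(X)
  if (n <= p + 1) stop("need n > p + 1 observations", call. = FALSE)
  Xi <- cbind("(Intercept)" = 1, X)
  qr_x <- qr(Xi)
  if (qr_x$rank < ncol(Xi))
    stop("singular design: predictors are collinear", call. = FALSE)
  fit <- stats::lm.fit(Xi, y)
  df <- n - p - 1
  res <- fit$residuals
  sigma2 <- sum(res^2) / df
  xtx_inv <- chol2inv(qr.R(qr_x))
  se <- sqrt(sigma2 * diag(xtx_inv))
  coefs <- fit$coefficients
  tval <- coefs / se
  structure(list(
    coefficients = coefs, se = se, t = tval,
    p = 2 * stats::pt(abs(tval), df, lower.tail = FALSE),
    residuals = res, fitted = fit$fitted.values,
    n = n, df = df, sigma = sqrt(sigma2)),
    class = "ols_fit")
}

#' @export
print.ols_fit <- function(x, ...) {
  cat("OLS fit: n =", x$n, ", residual df =", x$df, "\n")
  print(data.frame(estimate = x$coefficients, se = x$se,
                   t = x$t, p = x$p))
  invisible(x)
}

# Leave-one-out residuals via the hat-matrix identity e_i = r_i/(1 - h_ii),
# exact for OLS and O(n p^2) instead of n refits.
loocv_residuals <- function(y, X) {
  X <- as.matrix(X)
  n <- length(y)
  if (n <= ncol(X) + 2) stop("need n > p + 2 observations", call. = FALSE)
  Xi <- cbind(1, X)
  qr_x <- qr(Xi)
  if (qr_x$rank < ncol(Xi))
    stop("singular design: predictors are collinear", call. = FALSE)
  r <- qr.resid(qr_x, y)
  h <- rowSums(qr.Q(qr_x)[, seq_len(qr_x$rank), drop = FALSE]^2)
  if (any(h >= 1 - 1e-12))
    stop("leave-one-out fit singular at index ",
         which(h >= 1 - 1e-12)[1], call. = FALSE)
  r / (1 - h)
}

#' Bias-corrected leave-one-out cross-validation RMSE
#'
#' Each observation is predicted from a model fit on the remaining n - 1;
#' the bias-corrected RMSE is the standard deviation of those out-of-sample
#' residuals, sqrt(mean(e^2) - mean(e)^2), i.e. the plain LOOCV RMSE with
#' the mean-bias component removed.
#'
#' @inheritParams fit_ols
#' @param bias_corrected if FALSE, return the plain LOOCV RMSE
#'   sqrt(mean(e^2)).
#' @return non-negative scalar.
#' @export
loocv_rmse <- function(y, X, bias_corrected = TRUE) {
  e <- loocv_residuals(y, X)
  ms <- mean(e^2)
  if (bias_corrected) sqrt(max(ms - mean(e)^2, 0)) else sqrt(ms)
}

#' Exhaustive predictor-subset regression selected by LOOCV
#'
#' Scores every nonempty subset of the candidate predictors by the
#' bias-corrected leave-one-out RMSE and selects the subset with the
#' smallest value; ties go to the smaller subset, then to lexicographic
#' order of the joined predictor names. The selected model is refit on the
#' full data for coefficient inference.
#'
#' @param formula model formula naming the outcome and the candidate
#'   predictors, e.g. \code{wml ~ cardio + cognitive + age + gender}.
#' @param data data.frame containing the variables (factors and logicals
#'   are expanded to numeric contrasts before subsetting, so a candidate is
#'   a model term).
#' @param ... unused.
#' @return object of class \code{"loocv_select"} with components
#'   \code{comparison} (data.frame of all 2^p - 1 subsets with their
#'   bias-corrected and plain LOOCV RMSEs, sorted by the selection
#'   criterion), \code{selected} (character vector of predictor names),
#'   \code{criterion} (the winning bias-corrected RMSE), \code{fit} (the
#'   full-data \code{\link{fit_ols}} on the selected subset), \code{call},
#'   \code{y}, \code{X}.
#' @seealso methods \code{print}, \code{summary}, \code{coef},
#'   \code{predict}, \code{residuals}, \code{plot}.
#' @examples
#' set.seed(1)
#' d <- data.frame(x1 = rnorm(60), x2 = rnorm(60))
#' d$y <- 2 * d$x1 + rnorm(60)
#' m <- loocv_select(y ~ x1 + x2, d)
#' m$selected
#' @export
loocv_select <- function(formula, data, ...) {
  mf <- stats::model.frame(formula, data)
  y <- stats::model.response(mf)
  X <- stats::model.matrix(attr(mf, "terms"), mf)
  X <- X[, colnames(X) != "(Intercept)", drop = FALSE]
  p <- ncol(X)
  if (p < 1 || p > 12)
    stop("need between 1 and 12 candidate predictors", call. = FALSE)
  cand <- colnames(X)

  subsets <- lapply(seq_len(2^p - 1), function(code)
    cand[bitwAnd(code, 2^(seq_len(p) - 1)) > 0])
  rmse_bc <- numeric(length(subsets))
  rmse_plain <- numeric(length(subsets))
  for (i in seq_along(subsets)) {
    e <- loocv_residuals(y, X[, subsets[[i]], drop = FALSE])
    ms <- mean(e^2)
    rmse_plain[i] <- sqrt(ms)
    rmse_bc[i] <- sqrt(max(ms - mean(e)^2, 0))
  }
  labels <- vapply(subsets, paste, "", collapse = " + ")
  ord <- order(rmse_bc, lengths(subsets), labels)
  comparison <- data.frame(
    predictors = labels[ord],
    k = lengths(subsets)[ord],
    loocv_rmse_bc = rmse_bc[ord],
    loocv_rmse = rmse_plain[ord],
    stringsAsFactors = FALSE)
  sel <- subsets[[ord[1]]]

  structure(list(
    comparison = comparison,
    selected = sel,
    criterion = rmse_bc[ord[1]],
    fit = fit_ols(y, X[, sel, drop = FALSE]),
    call = match.call(), y = y, X = X),
    class = "loocv_select")
}

#' @export
print.loocv_select <- function(x, ...) {
  cat("Exhaustive subset regression selected by LOOCV bias-corrected RMSE\n")
  cat("Call: ", deparse(x$call), "\n", sep = "")
  cat(sprintf("Candidates: %d terms, %d subsets evaluated\n",
              ncol(x$X), nrow(x$comparison)))
  cat(sprintf("Selected: %s (RMSE = %.4g)\n",
              paste(x$selected, collapse = " + "), x$criterion))
  invisible(x)
}

#' @export
summary.loocv_select <- function(object, n_show = 10, ...) {
  print(object)
  cat("\nTop subsets by bias-corrected LOOCV RMSE:\n")
  print(utils::head(object$comparison, n_show), row.names = FALSE)
  cat("\nFull-data fit of the selected model:\n")
  print(object$fit)
  invisible(object)
}

#' @export
coef.loocv_select <- function(object, ...) object$fit$coefficients

#' @export
residuals.loocv_select <- function(object, ...) object$fit$residuals

#' @export
predict.loocv_select <- function(object, newdata = NULL, ...) {
  if (is.null(newdata)) return(object$fit$fitted)
  Xn <- as.matrix(newdata[, object$selected, drop = FALSE])
  drop(cbind(1, Xn) %*% object$fit$coefficients)
}

#' @export
plot.loocv_select <- function(x, ...) {
  cmp <- x$comparison
  plot(cmp$k, cmp$loocv_rmse_bc, xlab = "subset size",
       ylab = "bias-corrected LOOCV RMSE",
       main = "Subset comparison", ...)
  best <- cmp[1, ]
  graphics::points(best$k, best$loocv_rmse_bc, pch = 19, col = 2)
  invisible(x)
}

#' Spearman rank correlation with t-approximation p-value
#'
#' Pearson correlation of mid-ranks (average ranks for ties); the p-value
#' uses the t approximation t = r sqrt((n-2)/(1-r^2)) on n - 2 degrees of
#' freedom, adequate at cohort-scale n.
#'
#' @param x,y numeric vectors of equal length, n >= 3.
#' @return list of class \code{"cor_result"}: \code{method},
#'   \code{estimate}, \code{p}, \code{n} (and \code{covariates} for partial
#'   correlations).
#' @export
spearman_cor <- function(x, y) {
  n <- length(x)
  if (n < 3) stop("need n >= 3", call. = FALSE)
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    stop("undefined correlation: constant input", call. = FALSE)
  r <- stats::cor(x, y, method = "spearman")
  cor_result("spearman", r, n, df = n - 2)
}

cor_result <- function(method, r, n, df, covariates = NULL) {
  p <- if (abs(r) >= 1) 0 else {
    tt <- r * sqrt(df / (1 - r^2))
    2 * stats::pt(abs(tt), df, lower.tail = FALSE)
  }
  structure(list(method = method, estimate = r, p = p, n = n,
                 covariates = covariates),
            class = "cor_result")
}

#' @export
print.cor_result <- function(x, ...) {
  cat(sprintf("%s correlation: r = %.3f, p = %.3g, n = %d\n",
              x$method, x$estimate, x$p, x$n))
  if (!is.null(x$covariates))
    cat("controlling for:", paste(x$covariates, collapse = ", "), "\n")
  invisible(x)
}

#' Partial Pearson correlation via residualisation
#'
#' Correlates the residuals of x and y after regressing each on the
#' covariates (with intercept); the p-value uses t with n - q - 2 degrees
#' of freedom for q covariates.
#'
#' @param x,y numeric vectors.
#' @param covariates numeric vector, matrix or data.frame of q covariates.
#' @return a \code{"cor_result"} (see \code{\link{spearman_cor}}).
#' @export
partial_cor <- function(x, y, covariates) {
  Z <- as.matrix(covariates)
  n <- length(x)
  q <- ncol(Z)
  if (n <= q + 2) stop("need n > q + 2", call. = FALSE)
  rx <- residualize(x, Z)
  ry <- residualize(y, Z)
  if (stats::sd(rx) < 1e-12 * max(1, stats::sd(x)) ||
      stats::sd(ry) < 1e-12 * max(1, stats::sd(y)))
    stop("undefined correlation: residuals are constant", call. = FALSE)
  r <- stats::cor(rx, ry)
  cor_result("partial_pearson", r, n, df = n - q - 2,
             covariates = colnames(Z))
}

#' Residualise a variable on covariates
#'
#' Returns y minus its OLS fit on the covariates (with intercept); the
#' residuals have mean zero and are orthogonal to every covariate.
#'
#' @param y numeric vector.
#' @param covariates numeric vector, matrix or data.frame.
#' @return numeric vector of residuals.
#' @export
residualize <- function(y, covariates) {
  Z <- cbind(1, as.matrix(covariates))
  qr_z <- qr(Z)
  if (qr_z$rank < ncol(Z))
    stop("singular covariate design", call. = FALSE)
  qr.resid(qr_z, y)
}

#' Median split into low and high groups
#'
#' Splits at the mid-rank median: low = score <= median, high = score >
#' median. With integer risk scores whose median is 1 this reproduces the
#' "no or one risk factor" versus "more than one" partition.
#'
#' @param scores numeric vector, n >= 2.
#' @return list: \code{group} (factor with levels low/high), \code{cut}
#'   (the realised median), \code{n_low}, \code{n_high}.
#' @export
median_split <- function(scores) {
  if (length(scores) < 2) stop("need n >= 2", call. = FALSE)
  med <- stats::median(scores)
  grp <- factor(ifelse(scores <= med, "low", "high"),
                levels = c("low", "high"))
  if (any(table(grp) == 0))
    stop("degenerate split: all scores on one side of the median",
         call. = FALSE)
  list(group = grp, cut = med,
       n_low = sum(grp == "low"), n_high = sum(grp == "high"))
}

#' Two-sample t-test (pooled by default)
#'
#' Student's pooled-variance t-test with df = n_a + n_b - 2; Welch's
#' unequal-variance version is available behind a flag.
#'
#' @param a,b numeric vectors, each of length >= 2.
#' @param welch if TRUE use Welch's correction.
#' @return list: \code{t}, \code{df}, \code{p} (two-sided),
#'   \code{mean_a}, \code{mean_b}.
#' @export
two_sample_t <- function(a, b, welch = FALSE) {
  if (length(a) < 2 || length(b) < 2)
    stop("each group needs n >= 2", call. = FALSE)
  if (stats::var(a) + stats::var(b) == 0)
    stop("zero pooled variance", call. = FALSE)
  ht <- stats::t.test(a, b, var.equal = !welch)
  list(t = unname(ht$statistic), df = unname(ht$parameter),
       p = ht$p.value, mean_a = mean(a), mean_b = mean(b))
}

#' Holm step-down multiplicity correction
#'
#' Adjusted p-values follow the step-down rule: sort ascending, multiply
#' the j-th smallest by (m - j + 1), enforce monotonicity by a running
#' maximum and cap at 1. Rejections at level alpha are exactly the tests
#' with adjusted p <= alpha, a down-set of the sorted raw p-values.
#'
#' @param p numeric vector of raw p-values in [0, 1].
#' @param alpha family-wise error level in (0, 1).
#' @param family optional label carried through to the output.
#' @return data.frame: \code{p_raw}, \code{p_holm}, \code{reject},
#'   \code{family} (in the input order).
#' @examples
#' holm_adjust(c(0.01, 0.03, 0.04), alpha = 0.05)  # rejects only the first
#' @export
holm_adjust <- function(p, alpha = 0.05, family = NA_character_) {
  if (any(p < 0 | p > 1 | is.na(p)))
    stop("p-values must lie in [0, 1]", call. = FALSE)
  if (alpha <= 0 || alpha >= 1) stop("alpha must be in (0, 1)", call. = FALSE)
  adj <- stats::p.adjust(p, method = "holm")
  data.frame(p_raw = p, p_holm = adj, reject = adj <= alpha,
             family = family, stringsAsFactors = FALSE)
}
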