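#' Calibration statistics
#'
#' The statistics reported for a calibration set: RSQ (squared Pearson
#' correlation of reference and fitted), SEC (standard error of
#' calibration, `sqrt(sum(e^2) / (n - A - 1))` with `A` the number of
#' factors), SECV (standard error of cross-validation,
#' `sqrt(sum(e_cv^2) / n)`), 1-VR (one minus variance ratio,
#' `1 - sum(e_cv^2) / sum((ref - mean)^2)`), SD (sample standard
#' deviation of the reference values, n-1 denominator), the reference
#' mean, and the slope of reference on fitted.
#'
#' @param ref Reference values.
#' @param fitted Fitted (training) values from the final model.
#' @param cv_residuals Held-out residuals from cross-validation
#'   (same length as `ref`).
#' @param n_factors Number of latent factors A in the model.
#' @return List with `mean`, `rsq`, `slope`, `sd`, `sec`, `secv`,
#'   `one_minus_vr`.
#' @export
calibration_stats <- function(ref, fitted, cv_residuals, n_factors) {
  ref <- as.numeric(ref); fitted <- as.numeric(fitted)
  cv_residuals <- as.numeric(cv_residuals)
  n <- length(ref)
  if (length(fitted) != n || length(cv_residuals) != n)
    stop("ref, fitted and cv_residuals must have equal length")
  if (n < 3L) stop("need at least 3 samples")
  if (stats::var(ref) == 0) stop("zero-variance reference values")
  e <- ref - fitted
  sec <- sqrt(sum(e^2) / max(1L, n - n_factors - 1L))
  secv <- sqrt(sum(cv_residuals^2) / n)
  css <- sum((ref - mean(ref))^2)
  rsq <- if (stats::var(fitted) == 0) 0 else stats::cor(ref, fitted)^2
  slope <- if (stats::var(fitted) == 0) NA_real_ else
    stats::cov(ref, fitted) / stats::var(fitted)
  list(mean = mean(ref), rsq = rsq, slope = slope,
       sd = stats::sd(ref), sec = sec, secv = secv,
       one_minus_vr = 1 - sum(cv_residuals^2) / css)
}

#' External validation statistics
#'
#' The statistics reported for an independent validation set:
#' \describe{
#'   \item{RSQ}{squared Pearson correlation of reference and predicted.}
#'   \item{bias}{`mean(pred) - mean(ref)`; positive for an
#'     overestimating model, negative for an underestimating one.}
#'   \item{slope}{regression slope of reference on predicted,
#'     `cov(ref, pred) / var(pred)` (direction switchable via
#'     `slope_direction`).}
#'   \item{SEP}{bias-corrected standard error of performance,
#'     `sqrt(sum((e - mean(e))^2) / (n - 1))` with `e = pred - ref`;
#'     also reported as `sep_c`. The raw root-mean-square error of
#'     prediction is reported as `rmsep`.}
#'   \item{RPD}{ratio of performance to deviation, `sd(ref) / SEP`,
#'     with its qualitative band (see [rpd()]). Reported as `Inf` when
#'     SEP is zero (perfect prediction).}
#' }
#'
#' @param ref Reference values (nonzero variance).
#' @param pred Predicted values.
#' @param slope_direction `"ref-on-pred"` (default) or `"pred-on-ref"`.
#' @return An object of class `"validation_report"`: list with `n`,
#'   `range`, `mean`, `rsq`, `slope`, `bias`, `sd`, `sep`, `sep_c`,
#'   `rmsep`, `rpd`, `rpd_band`.
#' @export
external_validation <- function(ref, pred,
                                slope_direction = c("ref-on-pred",
                                                    "pred-on-ref")) {
  slope_direction <- match.arg(slope_direction)
  ref <- as.numeric(ref); pred <- as.numeric(pred)
  n <- length(ref)
  if (length(pred) != n) stop("ref and pred must have equal length")
  if (n < 3L) stop("need at least 3 samples")
  if (stats::var(ref) == 0) stop("zero-variance reference values")
  e <- pred - ref
  bias <- mean(e)
  sep <- sqrt(sum((e - bias)^2) / (n - 1L))
  rmsep <- sqrt(mean(e^2))
  sd_ref <- stats::sd(ref)
  if (stats::var(pred) == 0) {
    if (slope_direction == "ref-on-pred")
      stop("zero-variance predictions: slope undefined")
    slope <- 0; rsq <- 0
  } else {
    rsq <- stats::cor(ref, pred)^2
    slope <- if (slope_direction == "ref-on-pred")
      stats::cov(ref, pred) / stats::var(pred)
    else stats::cov(ref, pred) / stats::var(ref)
  }
  rp <- if (sep == 0) list(value = Inf, band = "excellent")
        else rpd(sd_ref, sep)
  structure(list(n = n, range = c(min(ref), max(ref)), mean = mean(ref),
                 rsq = rsq, slope = slope, bias = bias, sd = sd_ref,
                 sep = sep, sep_c = sep, rmsep = rmsep,
                 rpd = rp$value, rpd_band = rp$band),
            class = "validation_report")
}

#' @export
print.validation_report <- function(x, ...) {
  cat("<validation_report> N=", x$n, ", RSQ=", round(x$rsq, 3),
      ", slope=", round(x$slope, 3), ", bias=", signif(x$bias, 3),
      ", SEP=", signif(x$sep, 3), ", RPD=", round(x$rpd, 2),
      " (", x$rpd_band, ")\n", sep = "")
  invisible(x)
}

#' Ratio of performance to deviation (RPD)
#'
#' `RPD = SD(reference) / SEP`, with the conventional quality bands:
#' below 1.5 the model is unreliable; 1.5-2.0 it can separate high from
#' low values (screening); 2.0-2.5 approximate quantitative prediction;
#' 2.5-3.0 good quantitative prediction; 3.0 and above excellent. Band
#' boundaries are assigned upward (an RPD of exactly 2.5 is "good",
#' exactly 3.0 is "excellent").
#'
#' @param sd_ref Standard deviation of the reference values (> 0).
#' @param sep Standard error of performance (> 0).
#' @return List with `value` (the ratio) and `band` (one of
#'   `"unreliable"`, `"screen"`, `"approximate"`, `"good"`,
#'   `"excellent"`).
#' @export
rpd <- function(sd_ref, sep) {
  if (!is.finite(sep) || sep <= 0) stop("SEP must be positive")
  v <- sd_ref / sep
  list(value = v, band = rpd_band(v))
}

#' @rdname rpd
#' @param value An RPD value.
#' @export
rpd_band <- function(value) {
  cuts <- c(1.5, 2.0, 2.5, 3.0)
  bands <- c("unreliable", "screen", "approximate", "good", "excellent")
  bands[findInterval(value, cuts, left.open = FALSE) + 1L]
}

#' Paired t-test between reference and predicted values
#'
#' One-sample t-test on the differences `d = ref - pred` at the given
#' confidence level: `t = mean(d) / (sd(d) / sqrt(n))` with `df = n - 1`
#' and a two-sided p-value. A non-significant p indicates agreement
#' between laboratory and model.
#'
#' @param ref,pred Equal-length vectors (n >= 2).
#' @param conf Confidence level, default 0.95.
#' @return An object of class `"paired_t_result"`: list with
#'   `mean_diff`, `sd_diff`, `sem`, `ci_low`, `ci_high`, `t_value`,
#'   `df`, `p_value`, `conf`.
#' @export
paired_t <- function(ref, pred, conf = 0.95) {
  ref <- as.numeric(ref); pred <- as.numeric(pred)
  n <- length(ref)
  if (length(pred) != n) stop("ref and pred must have equal length")
  if (n < 2L) stop("need at least 2 pairs")
  d <- ref - pred
  if (stats::sd(d) == 0) stop("zero-variance differences: t undefined")
  ht <- stats::t.test(ref, pred, paired = TRUE, conf.level = conf)
  structure(list(mean_diff = mean(d), sd_diff = stats::sd(d),
                 sem = stats::sd(d) / sqrt(n),
                 ci_low = unname(ht$conf.int[1L]),
                 ci_high = unname(ht$conf.int[2L]),
                 t_value = unname(ht$statistic),
                 df = unname(ht$parameter),
                 p_value = ht$p.value, conf = conf),
            class = "paired_t_result")
}

#' @export
print.paired_t_result <- function(x, ...) {
  cat("<paired_t> mean diff=", signif(x$mean_diff, 3), ", t=",
      round(x$t_value, 3), ", df=", x$df, ", p=", signif(x$p_value, 3),
      "\n", sep = "")
  invisible(x)
}

#' Pearson correlation with significance
#'
#' Sample Pearson correlation plus the two-sided p-value from the usual
#' t transform (`stats::cor.test`).
#'
#' @param x,y Equal-length numeric vectors (n >= 3), both nonconstant.
#' @return List with `r`, `p_value`, `n`.
#' @export
pearson_r <- function(x, y) {
  x <- as.numeric(x); y <- as.numeric(y)
  if (length(x) != length(y)) stop("x and y must have equal length")
  if (length(x) < 3L) stop("need at least 3 pairs")
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    stop("constant input: correlation undefined")
  ct <- stats::cor.test(x, y)
  list(r = unname(ct$estimate), p_value = ct$p.value, n = length(x))
}

#' Strictly parallel reliability of a predicted/laboratory pair
#'
#' Maximum-likelihood reliability of a k-item scale under the strictly
#' parallel measurement model: every item measures the same true score
#' with one common item mean, one true-score variance `sigma_T^2` and
#' one error variance `sigma_e^2`; differences between item means are
#' charged to error. For the usual case the two "items" are the model
#' prediction and the laboratory value of each sample.
#'
#' Writing `M` for the (n-denominator) second-moment matrix of the items
#' about the common fitted mean, `m1 = 1'M1/k` for its component along
#' the unit vector and `m2 = (tr(M) - m1)/(k - 1)` for the rest, the ML
#' estimates are `sigma_e^2 = m2`, `k sigma_T^2 = m1 - m2`, and the
#' reliability of the k-item scale is `1 - m2/m1` (closed form; a
#' numerical likelihood maximisation gives the same value).
#'
#' @param pred Predicted values (item 1), or an n x k matrix of items.
#' @param lab Laboratory values (item 2); ignored when `pred` is a
#'   matrix.
#' @return An object of class `"reliability_result"`: list with
#'   `n_pairs`, `k`, `mean_pred`, `mean_lab`, `sd_pred`, `sd_lab`,
#'   `pearson_r` (pairs only), `reliability`, `common_mean`,
#'   `true_score_var`, `error_var`, `loglik`.
#' @export
strict_parallel_reliability <- function(pred, lab = NULL) {
  X <- if (is.matrix(pred)) pred else cbind(pred = as.numeric(pred),
                                            lab = as.numeric(lab))
  n <- nrow(X); k <- ncol(X)
  if (n < 3L) stop("need at least 3 rows")
  if (any(apply(X, 2L, stats::sd) == 0)) stop("zero-variance item")
  mu <- mean(X)
  Dev <- X - mu
  M <- crossprod(Dev) / n
  ones <- rep(1, k)
  m1 <- as.numeric(ones %*% M %*% ones) / k
  m2 <- (sum(diag(M)) - m1) / (k - 1)
  if (m1 <= 0) stop("degenerate input")
  rel <- 1 - m2 / m1
  # log-likelihood at the ML solution, for cross-checks
  ll <- -n / 2 * (k * log(2 * pi) + log(m1) + (k - 1) * log(m2) + k)
  out <- list(n_pairs = n, k = k,
              mean_pred = mean(X[, 1L]),
              mean_lab = if (k >= 2L) mean(X[, 2L]) else NA_real_,
              sd_pred = stats::sd(X[, 1L]),
              sd_lab = if (k >= 2L) stats::sd(X[, 2L]) else NA_real_,
              pearson_r = if (k == 2L) stats::cor(X[, 1L], X[, 2L])
                          else NA_real_,
              reliability = rel, common_mean = mu,
              true_score_var = (m1 - m2) / k, error_var = m2,
              loglik = ll)
  structure(out, class = "reliability_result")
}

#' @export
print.reliability_result <- function(x, ...) {
  cat("<reliability> n=", x$n_pairs, ", r=",
      if (is.na(x$pearson_r)) "NA" else round(x$pearson_r, 3),
      ", strict-parallel reliability=", round(x$reliability, 3), "\n",
      sep = "")
  invisible(x)
}
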