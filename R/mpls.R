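#' Fit a modified PLS (MPLS) regression
#'
#' Modified partial least squares in the Shenk-Westerhaus sense: before
#' each latent factor is extracted, the current spectral residual is
#' standardised per wavelength, so noisy or dead regions do not dominate
#' the covariance with the trait. Concretely, with centred `X` and `y`:
#' for each factor `a`, compute the per-wavelength SD `s_a` of the
#' current X-residual (SDs below `eps` are replaced by 1); the loading
#' weight is `w_a = (X_res' y_res) / s_a`, normalised to unit length;
#' scores `t_a = X_res w_a`; loadings `p_a = X_res' t_a / (t_a' t_a)` and
#' `q_a = y_res' t_a / (t_a' t_a)`; both residuals are then deflated.
#' Predictions accumulate `y_mean + sum_a q_a t_a`. With the per-factor
#' scaling disabled (`scale = FALSE`) the algorithm reduces exactly to
#' standard PLS1 (NIPALS).
#'
#' @param X Numeric matrix, n samples x p wavelengths (treated spectra).
#' @param y Numeric response vector, length n.
#' @param n_factors Number of latent factors A (0 allowed: mean model).
#' @param scale Use the per-factor wavelength standardisation (TRUE =
#'   MPLS; FALSE = standard PLS1).
#' @param eps Floor under which a wavelength SD is treated as 1.
#' @return An object of class `"mpls_model"` with elements `x_mean`,
#'   `y_mean`, `weights` (p x A), `x_loadings` (p x A), `y_loadings`
#'   (length A), `scalings` (p x A), `n_factors`, `fitted`, plus slots
#'   `wavelengths`, `treatment`, `trait` filled by [calibrate_trait()].
#' @export
fit_mpls <- function(X, y, n_factors, scale = TRUE, eps = 1e-12) {
  X <- as.matrix(X)
  y <- as.numeric(y)
  n <- nrow(X); p <- ncol(X)
  A <- as.integer(n_factors)
  if (length(y) != n) stop("length(y) != nrow(X)")
  if (anyNA(X) || anyNA(y)) stop("missing values are not allowed")
  if (A < 0L) stop("n_factors must be >= 0")
  if (A > 0L && n < A + 2L)
    stop("need at least n_factors + 2 samples (n = ", n, ", A = ", A, ")")
  if (stats::var(y) == 0 && A > 0L) stop("zero-variance response")
  x_mean <- colMeans(X)
  y_mean <- mean(y)
  E <- sweep(X, 2L, x_mean)
  f <- y - y_mean
  W <- P <- S <- matrix(0, p, A)
  q <- numeric(A)
  for (a in seq_len(A)) {
    s <- if (scale) {
      sa <- sqrt(colMeans(sweep(E, 2L, colMeans(E))^2))
      ifelse(sa < eps, 1, sa)
    } else rep(1, p)
    w <- as.vector(crossprod(E, f)) / s
    nw <- sqrt(sum(w^2))
    if (nw < eps)
      stop("residual covariance vanished at factor ", a,
           ": n_factors exceeds the rank of the problem")
    w <- w / nw
    t_a <- as.vector(E %*% w)
    tt <- sum(t_a^2)
    p_a <- as.vector(crossprod(E, t_a)) / tt
    q_a <- sum(f * t_a) / tt
    E <- E - tcrossprod(t_a, p_a)
    f <- f - q_a * t_a
    W[, a] <- w; P[, a] <- p_a; S[, a] <- s; q[a] <- q_a
  }
  model <- structure(list(x_mean = x_mean, y_mean = y_mean,
                          weights = W, x_loadings = P, y_loadings = q,
                          scalings = S, n_factors = A, scale = scale,
                          wavelengths = NULL, treatment = NULL,
                          trait = NULL),
                     class = "mpls_model")
  model$fitted <- predict(model, X)
  model
}

#' Predict from an MPLS model
#'
#' Deterministic and linear in the (centred) new spectra; a row equal to
#' the training mean spectrum predicts exactly `y_mean`, and a model
#' with 0 factors predicts `y_mean` for any input.
#'
#' @param object An `mpls_model`.
#' @param newdata Matrix of treated spectra on the model's grid, or a
#'   [spectra_set()] (its grid is checked against the model's when the
#'   model records one).
#' @param ... Unused.
#' @return Numeric vector of predictions (named by sample id when
#'   `newdata` is a spectra set).
#' @export
predict.mpls_model <- function(object, newdata, ...) {
  nms <- NULL
  if (inherits(newdata, "spectra_set")) {
    if (!is.null(object$wavelengths)) {
      if (length(newdata$wavelengths_nm) != length(object$wavelengths) ||
          any(newdata$wavelengths_nm != object$wavelengths))
        stop("grid mismatch: new spectra are not on the model's grid")
    }
    nms <- sample_ids(newdata)
    newdata <- newdata$absorbance
  }
  X <- as.matrix(newdata)
  if (ncol(X) != length(object$x_mean))
    stop("newdata has ", ncol(X), " wavelengths; model expects ",
         length(object$x_mean))
  E <- sweep(X, 2L, object$x_mean)
  pred <- rep(object$y_mean, nrow(X))
  for (a in seq_len(object$n_factors)) {
    t_a <- as.vector(E %*% object$weights[, a])
    pred <- pred + object$y_loadings[a] * t_a
    E <- E - tcrossprod(t_a, object$x_loadings[, a])
  }
  names(pred) <- nms
  pred
}

#' @export
print.mpls_model <- function(x, ...) {
  cat("<mpls_model> ", x$n_factors, " factors, ", length(x$x_mean),
      " wavelengths",
      if (!is.null(x$trait)) paste0(", trait '", x$trait, "'"), "\n", sep = "")
  invisible(x)
}

#' Choose the number of factors by cross-validation
#'
#' Samples are assigned to `n_groups` systematic cross-validation groups
#' by index modulo `n_groups` (deterministic, WinISI-style). For each
#' candidate factor count `a = 1..A_max` the standard error of
#' cross-validation is `SECV(a) = sqrt(sum(held-out errors^2) / n)`; the
#' chosen A attains the minimum SECV, ties going to the smaller A.
#'
#' @inheritParams fit_mpls
#' @param A_max Largest factor count to consider.
#' @param n_groups Number of CV groups (default 4).
#' @return An object of class `"cv_record"`: list with `secv` (named
#'   vector over a = 1..A_max), `chosen` (A), `groups` (assignment) and
#'   `cv_residuals` (held-out residuals, y - prediction, at the chosen A).
#' @export
choose_factors_cv <- function(X, y, A_max, n_groups = 4L, scale = TRUE) {
  X <- as.matrix(X); y <- as.numeric(y)
  n <- nrow(X)
  A_max <- as.integer(A_max)
  if (A_max < 1L) stop("A_max must be >= 1")
  if (n < 2L * n_groups) stop("need at least 2 samples per CV group")
  groups <- ((seq_len(n) - 1L) %% n_groups) + 1L
  # cap so every training fold can support A_max factors
  min_train <- min(tabulate(groups, n_groups))
  A_max <- min(A_max, n - min_train - 2L)
  if (A_max < 1L) stop("too few samples for cross-validation")
  res <- matrix(NA_real_, n, A_max)
  A_eff <- A_max
  for (a in seq_len(A_max)) {
    if (a > A_eff) break
    for (gkeep in seq_len(n_groups)) {
      hold <- groups == gkeep
      fit <- tryCatch(
        fit_mpls(X[!hold, , drop = FALSE], y[!hold], a, scale = scale),
        error = function(e) NULL)
      if (is.null(fit)) { # rank exhausted in this fold: stop growing
        A_eff <- a - 1L
        break
      }
      res[hold, a] <- y[hold] - predict(fit, X[hold, , drop = FALSE])
    }
  }
  if (A_eff < 1L) stop("cross-validation failed at a single factor")
  res <- res[, seq_len(A_eff), drop = FALSE]
  secv <- sqrt(colSums(res^2) / n)
  names(secv) <- seq_len(A_eff)
  chosen <- which.min(secv) # which.min takes the first (smallest A) on ties
  structure(list(secv = secv, chosen = as.integer(chosen), groups = groups,
                 cv_residuals = res[, chosen]),
            class = "cv_record")
}

#' @export
print.cv_record <- function(x, ...) {
  cat("<cv_record> chosen A =", x$chosen, "; SECV =",
      format(x$secv[x$chosen], digits = 4), "\n")
  invisible(x)
}

#' Calibrate with residual-outlier elimination
#'
#' The calibration loop used in practice: fit with the CV-chosen factor
#' count, standardise residuals by the SEC (`t_i = e_i / SEC`), drop all
#' samples with `|t_i| > t_crit` (largest first, at most `cap` in total
#' over the whole run — mirroring the "fewer than 10 outliers" practice
#' of routine NIRS calibration), refit, and repeat for at most
#' `max_passes` removal rounds. Leverage (GH, Mahalanobis distance of
#' the score vector relative to the calibration cloud) is reported for
#' every removed sample but never triggers removal by itself.
#'
#' @inheritParams choose_factors_cv
#' @param ids Optional sample ids (default row names / indices).
#' @param t_crit Standardised-residual threshold (default 2.5).
#' @param max_passes Maximum removal rounds (default 2).
#' @param cap Maximum number of samples removed in total (default 10).
#' @param A_max Largest factor count for CV; default
#'   `min(16, floor(n/6))`.
#' @return List with `model` (final [fit_mpls()] model), `cv` (final
#'   `cv_record`), `report` (class `"outlier_report"`: data frame of
#'   `sample_id`, `t`, `gh`, `pass`), `kept` (logical over input rows)
#'   and `passes` executed.
#' @export
eliminate_outliers <- function(X, y, ids = NULL, t_crit = 2.5,
                               max_passes = 2L, cap = 10L,
                               A_max = NULL, n_groups = 4L, scale = TRUE) {
  X <- as.matrix(X); y <- as.numeric(y)
  n0 <- nrow(X)
  if (is.null(ids)) ids <- rownames(X) %||% as.character(seq_len(n0))
  keep <- rep(TRUE, n0)
  removed <- data.frame(sample_id = character(0), t = numeric(0),
                        gh = numeric(0), pass = integer(0),
                        stringsAsFactors = FALSE)
  passes <- 0L
  repeat {
    n <- sum(keep)
    Amx <- if (is.null(A_max)) max(1L, min(16L, floor(n / 6))) else A_max
    cv <- choose_factors_cv(X[keep, , drop = FALSE], y[keep], Amx,
                            n_groups = n_groups, scale = scale)
    model <- fit_mpls(X[keep, , drop = FALSE], y[keep], cv$chosen,
                      scale = scale)
    if (passes >= max_passes || nrow(removed) >= cap) break
    e <- y[keep] - model$fitted
    sec <- sqrt(sum(e^2) / max(1L, n - cv$chosen - 1L))
    if (sec == 0) break
    t_i <- e / sec
    flag <- which(abs(t_i) > t_crit)
    if (length(flag) == 0L) break
    flag <- flag[order(-abs(t_i[flag]))]
    room <- cap - nrow(removed)
    flag <- flag[seq_len(min(length(flag), room))]
    if (n - length(flag) < 3L * cv$chosen)
      stop("outlier removal would leave fewer than 3 x chosen factors (",
           3L * cv$chosen, ") samples")
    # leverage of the flagged samples in the current score space
    Tsc <- scores_mpls(model, X[keep, , drop = FALSE])
    Sinv <- solve(crossprod(Tsc) / n)
    gh <- rowSums((Tsc %*% Sinv) * Tsc) / cv$chosen
    idx <- which(keep)[flag]
    removed <- rbind(removed, data.frame(sample_id = ids[idx],
                                         t = t_i[flag], gh = gh[flag],
                                         pass = passes + 1L,
                                         stringsAsFactors = FALSE))
    keep[idx] <- FALSE
    passes <- passes + 1L
  }
  class(removed) <- c("outlier_report", "data.frame")
  list(model = model, cv = cv, report = removed, kept = keep,
       passes = passes + 1L)
}

# score matrix of X under a fitted model (n x A)
scores_mpls <- function(object, X) {
  E <- sweep(as.matrix(X), 2L, object$x_mean)
  A <- object$n_factors
  Tsc <- matrix(0, nrow(E), A)
  for (a in seq_len(A)) {
    t_a <- as.vector(E %*% object$weights[, a])
    Tsc[, a] <- t_a
    E <- E - tcrossprod(t_a, object$x_loadings[, a])
  }
  Tsc
}

#' Full single-trait calibration chain
#'
#' Pretreatment, outlier elimination with cross-validated factor choice,
#' and calibration statistics for one trait: the function behind each
#' row of a calibration summary table (N, outliers, range, math
#' treatment, mean, RSQ, slope, SD, SECV, 1-VR, SEC).
#'
#' @param spectra A [spectra_set()] of raw spectra.
#' @param refs Reference data frame (see [read_reference_table()]).
#' @param trait Trait column name in `refs`.
#' @param treatment A [math_treatment()] or a code string like
#'   `"2,4,6,1"` (parsed with scatter `"snv-dt"`).
#' @param min_n Minimum number of reference-valued samples (default 20).
#' @param ... Passed to [eliminate_outliers()] (`t_crit`, `cap`,
#'   `A_max`, `n_groups`, ...).
#' @return An object of class `"calibration_result"`: list with the
#'   table fields (`trait`, `n`, `outliers_removed`, `range`,
#'   `treatment`, `mean`, `rsq`, `slope`, `sd`, `sec`, `secv`,
#'   `one_minus_vr`, `n_factors`) plus `model`, `cv`, `outlier_report`
#'   and `calibration_ids`.
#' @export
calibrate_trait <- function(spectra, refs, trait, treatment, min_n = 20L,
                            ...) {
  if (is.character(treatment))
    treatment <- parse_math_treatment(treatment, scatter = "snv-dt")
  refs <- validate_reference_table(refs)
  if (!trait %in% names(refs)) stop("unknown trait '", trait, "'")
  have <- refs$sample_id[!is.na(refs[[trait]])]
  have <- have[have %in% sample_ids(spectra)]
  if (length(have) < min_n)
    stop("only ", length(have), " samples with spectra and '", trait,
         "' values; need >= ", min_n)
  treated <- apply_pretreatment(subset_spectra(spectra, have), treatment)
  y <- refs[[trait]][match(have, refs$sample_id)]
  out <- eliminate_outliers(treated$absorbance, y, ids = have, ...)
  kept_ids <- have[out$kept]
  y_kept <- y[out$kept]
  stats <- calibration_stats(ref = y_kept, fitted = out$model$fitted,
                             cv_residuals = out$cv$cv_residuals,
                             n_factors = out$cv$chosen)
  model <- out$model
  model$wavelengths <- treated$wavelengths_nm
  model$treatment <- treatment
  model$trait <- trait
  structure(c(list(trait = trait, n = length(y_kept),
                   outliers_removed = nrow(out$report),
                   range = c(min(y_kept), max(y_kept)),
                   treatment = format(treatment)),
              stats,
              list(n_factors = out$cv$chosen, model = model, cv = out$cv,
                   outlier_report = out$report, calibration_ids = kept_ids)),
            class = "calibration_result")
}

#' @export
print.calibration_result <- function(x, ...) {
  cat("<calibration_result> ", x$trait, ": N=", x$n, " (-", x$outliers_removed,
      " outliers), \"", x$treatment, "\", A=", x$n_factors,
      ", RSQ=", round(x$rsq, 3), ", SECV=", signif(x$secv, 3), "\n", sep = "")
  invisible(x)
}

#' Serialize / restore an MPLS model
#'
#' Models are stored as versioned JSON holding the grid, treatment,
#' means and per-factor vectors at full double precision, so predictions
#' are reproducible from the file alone.
#'
#' @param model An `mpls_model`.
#' @param path JSON path.
#' @return `path` invisibly (write); an `mpls_model` (read).
#' @export
write_mpls_model <- function(model, path) {
  stopifnot(inherits(model, "mpls_model"))
  payload <- list(
    format = "nirscal-mpls-model", version = 1L,
    trait = model$trait,
    treatment = if (!is.null(model$treatment))
      list(code = format(model$treatment), scatter = model$treatment$scatter),
    wavelengths = model$wavelengths,
    x_mean = model$x_mean, y_mean = model$y_mean,
    weights = model$weights, x_loadings = model$x_loadings,
    y_loadings = model$y_loadings, scalings = model$scalings,
    n_factors = model$n_factors, scale = model$scale)
  jsonlite::write_json(payload, path, digits = NA, auto_unbox = TRUE)
  invisible(path)
}

#' @rdname write_mpls_model
#' @export
read_mpls_model <- function(path) {
  pl <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (!identical(pl$format, "nirscal-mpls-model"))
    stop("not an MPLS model file: ", path)
  as_mat <- function(m, p, A) matrix(as.numeric(m), p, A)
  p <- length(pl$x_mean); A <- as.integer(pl$n_factors)
  model <- structure(list(
    x_mean = as.numeric(pl$x_mean), y_mean = as.numeric(pl$y_mean),
    weights = as_mat(pl$weights, p, A),
    x_loadings = as_mat(pl$x_loadings, p, A),
    y_loadings = as.numeric(pl$y_loadings),
    scalings = as_mat(pl$scalings, p, A),
    n_factors = A, scale = isTRUE(pl$scale),
    wavelengths = if (!is.null(pl$wavelengths)) as.numeric(pl$wavelengths),
    treatment = if (!is.null(pl$treatment))
      parse_math_treatment(pl$treatment$code, pl$treatment$scatter),
    trait = pl$trait), class = "mpls_model")
  model
}
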