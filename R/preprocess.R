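#' WinISI-style math treatment
#'
#' Pretreatments are coded by four digits "d,g,s1,s2": derivative order,
#' gap in data points, and the lengths (data points) of a first and
#' second running-mean smoothing. `"0,0,1,1"` is the identity. A scatter
#' correction (none, SNV, or SNV followed by detrend) is applied before
#' the derivative.
#'
#' @param derivative Non-negative integer derivative order `d`.
#' @param gap Non-negative integer gap `g` in data points; must be >= 1
#'   when `derivative >= 1`.
#' @param smooth1,smooth2 Positive integer smoothing segment lengths
#'   (1 = no smoothing).
#' @param scatter One of `"none"`, `"snv"`, `"snv-dt"`.
#' @return An object of class `"math_treatment"`.
#' @export
math_treatment <- function(derivative = 0L, gap = 0L, smooth1 = 1L,
                           smooth2 = 1L, scatter = c("none", "snv", "snv-dt")) {
  scatter <- match.arg(tolower(scatter), c("none", "snv", "snv-dt"))
  d <- as.integer(derivative); g <- as.integer(gap)
  s1 <- as.integer(smooth1); s2 <- as.integer(smooth2)
  if (any(is.na(c(d, g, s1, s2))) || d < 0L || g < 0L)
    stop("treatment digits must be non-negative integers")
  if (s1 < 1L || s2 < 1L)
    stop("smoothing segments must be >= 1 (1 = no smoothing)")
  if (d >= 1L && g < 1L)
    stop("a derivative of order ", d, " needs gap >= 1")
  structure(list(derivative = d, gap = g, smooth1 = s1, smooth2 = s2,
                 scatter = scatter),
            class = "math_treatment")
}

#' Parse a four-digit math-treatment code
#'
#' @param code Text like `"2,4,6,1"`: derivative, gap, first and second
#'   smoothing segment, comma separated.
#' @param scatter Scatter-correction mode, as in [math_treatment()].
#' @return A [math_treatment()].
#' @examples
#' parse_math_treatment("2,4,6,1", scatter = "snv-dt")
#' @export
parse_math_treatment <- function(code, scatter = c("none", "snv", "snv-dt")) {
  scatter <- match.arg(tolower(scatter), c("none", "snv", "snv-dt"))
  parts <- strsplit(trimws(code), "\\s*,\\s*")[[1L]]
  if (length(parts) != 4L)
    stop("treatment code must have four comma-separated digits, got '",
         code, "'")
  nums <- suppressWarnings(as.integer(parts))
  if (any(is.na(nums)) || any(nums < 0L))
    stop("treatment digits must be non-negative integers, got '", code, "'")
  math_treatment(nums[1L], nums[2L], nums[3L], nums[4L], scatter)
}

#' @export
format.math_treatment <- function(x, ...)
  paste(x$derivative, x$gap, x$smooth1, x$smooth2, sep = ",")

#' @export
print.math_treatment <- function(x, ...) {
  cat("<math_treatment> \"", format(x), "\" scatter=", x$scatter, "\n",
      sep = "")
  invisible(x)
}

#' Standard normal variate (SNV)
#'
#' Centres a spectrum to zero mean and scales it to unit standard
#' deviation (population convention, n denominator), removing
#' multiplicative scatter and additive offsets: `snv(a*x + b) = snv(x)`
#' for any `a > 0`.
#'
#' @param x A [spectrum()], numeric vector, or spectra matrix
#'   (rows = samples).
#' @return Same shape as the input.
#' @export
snv <- function(x) UseMethod("snv")

#' @export
snv.default <- function(x) {
  if (length(x) < 2L) stop("SNV needs at least 2 points")
  s <- sqrt(mean((x - mean(x))^2))
  if (s < .Machine$double.eps * max(1, abs(mean(x))) * 100)
    stop("zero-variance (constant) spectrum: SNV undefined")
  (x - mean(x)) / s
}

#' @export
snv.spectrum <- function(x) {
  spectrum(x$sample_id, x$wavelengths_nm, snv.default(x$absorbance))
}

#' @export
snv.matrix <- function(x) t(apply(x, 1L, snv.default))

#' @export
snv.spectra_set <- function(x)
  spectra_set(snv.matrix(x$absorbance), x$wavelengths_nm, sample_ids(x))

#' Detrend: remove a low-order polynomial baseline
#'
#' Subtracts the least-squares polynomial fit (default quadratic) of
#' absorbance on wavelength. The residual is orthogonal to the
#' polynomial basis `1, lambda, ..., lambda^degree`.
#'
#' @param x A [spectrum()] or numeric vector of absorbances.
#' @param wavelengths Wavelength grid (required for the vector method).
#' @param degree Polynomial degree, default 2.
#' @return Same shape as the input.
#' @export
detrend <- function(x, wavelengths = NULL, degree = 2L) UseMethod("detrend")

#' @export
detrend.default <- function(x, wavelengths = NULL, degree = 2L) {
  if (is.null(wavelengths)) stop("`wavelengths` required")
  n <- length(x)
  if (n <= degree) stop("need more points (", n, ") than degree (", degree, ")")
  if (anyDuplicated(wavelengths))
    stop("degenerate design: repeated wavelengths")
  # orthogonal polynomial basis keeps the normal equations well conditioned
  basis <- cbind(1, stats::poly(wavelengths, degree = degree))
  x - basis %*% qr.coef(qr(basis), x)
}

#' @export
detrend.spectrum <- function(x, wavelengths = NULL, degree = 2L) {
  spectrum(x$sample_id, x$wavelengths_nm,
           as.vector(detrend.default(x$absorbance, x$wavelengths_nm, degree)))
}

#' SNV-detrend scatter correction
#'
#' SNV, then subtraction of the quadratic wavelength baseline, then
#' re-standardisation to zero mean and unit SD. The final
#' re-standardisation makes the correction exactly invariant to a
#' per-sample multiplicative gain, additive offset and linear tilt: two
#' spectra differing only by such nuisance terms map to the same output.
#'
#' @inheritParams detrend
#' @return Same shape as the input.
#' @export
snv_detrend <- function(x, wavelengths = NULL, degree = 2L) {
  if (inherits(x, "spectrum"))
    return(spectrum(x$sample_id, x$wavelengths_nm,
                    snv_detrend(x$absorbance, x$wavelengths_nm, degree)))
  snv.default(as.vector(detrend.default(snv.default(x), wavelengths, degree)))
}

# Effective (odd) boxcar width for a smoothing segment: even segments
# are rounded up to the next odd width; 1 means no smoothing.
effective_width <- function(s) if (s <= 1L) 1L else s + (s %% 2L == 0L)

boxcar <- function(x, s) {
  w <- effective_width(s)
  if (w == 1L) return(x)
  if (length(x) < w) stop("spectrum shorter than smoothing window (", w, ")")
  k <- (w - 1L) / 2L
  sm <- stats::filter(x, rep(1 / w, w), sides = 2)
  as.numeric(sm[(k + 1L):(length(x) - k)])
}

gap_difference <- function(x, g) {
  h <- as.integer(ceiling(g / 2))
  if (length(x) < 2L * h + 1L)
    stop("spectrum shorter than derivative support (", 2L * h + 1L, ")")
  idx <- (h + 1L):(length(x) - h)
  x[idx + h] - x[idx - h]
}

#' Number of points removed by a treatment at each edge
#'
#' A treatment "d,g,s1,s2" shortens the grid deterministically: each
#' boxcar of effective odd width `w` removes `(w-1)/2` points per edge
#' (even segments round up to the next odd width), and each application
#' of the central gap difference removes `ceiling(g/2)` points per edge.
#' The output length is therefore
#' `n - 2*((w1-1)/2) - 2*d*ceiling(g/2) - 2*((w2-1)/2)`.
#'
#' @param treatment A [math_treatment()].
#' @return Integer: points dropped at each edge.
#' @export
treatment_margin <- function(treatment) {
  stopifnot(inherits(treatment, "math_treatment"))
  k1 <- (effective_width(treatment$smooth1) - 1L) / 2L
  k2 <- (effective_width(treatment$smooth2) - 1L) / 2L
  h <- if (treatment$derivative >= 1L) as.integer(ceiling(treatment$gap / 2)) else 0L
  as.integer(k1 + treatment$derivative * h + k2)
}

#' Gap-segment derivative
#'
#' The derivative stage of a WinISI-style math treatment: running-mean
#' smoothing with segment `s1`, then `d` applications of the central gap
#' difference `D[x]_i = x[i + ceiling(g/2)] - x[i - ceiling(g/2)]`, then
#' running-mean smoothing with segment `s2`. Edges without full support
#' are dropped (no padding), so the output grid is the valid interior;
#' see [treatment_margin()] for the exact length bookkeeping.
#'
#' @param x A [spectrum()] or numeric vector.
#' @param treatment A [math_treatment()] (its scatter field is ignored
#'   here; see [apply_pretreatment()] for the full chain).
#' @param wavelengths Grid for the vector method.
#' @return A [spectrum()] on the shortened grid, or a list with
#'   `absorbance` and `wavelengths` for the vector method.
#' @export
gap_segment_derivative <- function(x, treatment, wavelengths = NULL) {
  stopifnot(inherits(treatment, "math_treatment"))
  if (inherits(x, "spectrum")) {
    out <- gap_segment_derivative(x$absorbance, treatment, x$wavelengths_nm)
    return(spectrum(x$sample_id, out$wavelengths, out$absorbance))
  }
  if (is.null(wavelengths)) wavelengths <- seq_along(x)
  m <- treatment_margin(treatment)
  if (length(x) <= 2L * m)
    stop("spectrum (", length(x), " points) shorter than treatment support (",
         2L * m + 1L, ")")
  y <- boxcar(x, treatment$smooth1)
  if (treatment$derivative >= 1L)
    for (i in seq_len(treatment$derivative))
      y <- gap_difference(y, treatment$gap)
  y <- boxcar(y, treatment$smooth2)
  grid <- wavelengths[(m + 1L):(length(wavelengths) - m)]
  list(absorbance = y, wavelengths = grid)
}

#' Apply a full pretreatment to a spectra set
#'
#' Per spectrum: scatter correction (none, SNV, or SNV-detrend) followed
#' by the gap-segment derivative of the treatment code. All outputs share
#' one (possibly shortened) grid.
#'
#' @param set A [spectra_set()].
#' @param treatment A [math_treatment()] (or a code string, parsed with
#'   scatter `"snv-dt"` — the usual choice for seed flours).
#' @return A [spectra_set()] of treated spectra.
#' @export
apply_pretreatment <- function(set, treatment) {
  stopifnot(inherits(set, "spectra_set"))
  if (is.character(treatment))
    treatment <- parse_math_treatment(treatment, scatter = "snv-dt")
  stopifnot(inherits(treatment, "math_treatment"))
  X <- set$absorbance
  grid <- set$wavelengths_nm
  corrected <- switch(treatment$scatter,
    "none" = X,
    "snv" = t(apply(X, 1L, snv.default)),
    "snv-dt" = t(apply(X, 1L, snv_detrend, wavelengths = grid)))
  m <- treatment_margin(treatment)
  out_grid <- grid[(m + 1L):(length(grid) - m)]
  out <- t(apply(corrected, 1L, function(row)
    gap_segment_derivative(row, treatment, grid)$absorbance))
  if (nrow(X) == 1L) out <- matrix(out, nrow = 1L)
  spectra_set(out, out_grid, sample_ids(set))
}
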