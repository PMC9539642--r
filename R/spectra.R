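#' Single NIR spectrum
#'
#' A spectrum is a vector of absorbance values, `log(1/R)` where R is
#' reflectance, on a strictly increasing wavelength grid in nanometres.
#'
#' @param sample_id Character scalar identifying the sample.
#' @param wavelengths_nm Numeric vector of wavelengths (nm), strictly
#'   increasing.
#' @param absorbance Numeric vector of `log(1/R)` values, same length as
#'   `wavelengths_nm`; all values must be finite.
#' @return An object of class `"spectrum"`: a list with elements
#'   `sample_id`, `wavelengths_nm`, `absorbance`.
#' @examples
#' sp <- spectrum("acc1", seq(400, 2498, by = 2), rep(0.5, 1050))
#' length(sp$wavelengths_nm)
#' @export
spectrum <- function(sample_id, wavelengths_nm, absorbance) {
  if (!is.character(sample_id) || length(sample_id) != 1L || is.na(sample_id))
    stop("`sample_id` must be a single non-missing character string")
  wavelengths_nm <- as.numeric(wavelengths_nm)
  absorbance <- as.numeric(absorbance)
  if (length(wavelengths_nm) != length(absorbance))
    stop("`absorbance` length (", length(absorbance),
         ") differs from wavelength grid length (", length(wavelengths_nm), ")")
  if (length(wavelengths_nm) == 0L)
    stop("a spectrum needs at least one point")
  if (any(!is.finite(wavelengths_nm)) || any(diff(wavelengths_nm) <= 0))
    stop("wavelengths must be finite and strictly increasing")
  if (any(!is.finite(absorbance)))
    stop("non-finite absorbance in sample '", sample_id, "' at wavelength ",
         wavelengths_nm[which(!is.finite(absorbance))[1L]], " nm")
  structure(list(sample_id = sample_id,
                 wavelengths_nm = wavelengths_nm,
                 absorbance = absorbance),
            class = "spectrum")
}

#' @export
print.spectrum <- function(x, ...) {
  cat("<spectrum> sample '", x$sample_id, "': ", length(x$wavelengths_nm),
      " points, ", min(x$wavelengths_nm), "-", max(x$wavelengths_nm), " nm\n",
      sep = "")
  invisible(x)
}

#' Collection of spectra on one shared wavelength grid
#'
#' The basic multi-sample container of the pipeline: an n-by-p absorbance
#' matrix plus the shared grid. Rows are samples, columns are wavelengths.
#'
#' @param absorbance Numeric matrix (samples x wavelengths), or a list of
#'   [spectrum()] objects sharing one grid.
#' @param wavelengths_nm Shared wavelength grid; ignored when `absorbance`
#'   is a list of spectra.
#' @param sample_ids Character vector of unique sample ids (row names);
#'   ignored when `absorbance` is a list of spectra.
#' @return An object of class `"spectra_set"`: list with `absorbance`
#'   (matrix with sample ids as row names) and `wavelengths_nm`.
#' @export
spectra_set <- function(absorbance, wavelengths_nm = NULL, sample_ids = NULL) {
  if (is.list(absorbance) && !is.data.frame(absorbance)) {
    spectra <- absorbance
    if (length(spectra) == 0L) stop("empty spectra list")
    ok <- vapply(spectra, inherits, logical(1), "spectrum")
    if (!all(ok)) stop("all list elements must be `spectrum` objects")
    grid <- spectra[[1L]]$wavelengths_nm
    for (sp in spectra) {
      if (length(sp$wavelengths_nm) != length(grid) ||
          any(sp$wavelengths_nm != grid))
        stop("grid mismatch: sample '", sp$sample_id,
             "' is not on the shared wavelength grid")
    }
    absorbance <- do.call(rbind, lapply(spectra, `[[`, "absorbance"))
    sample_ids <- vapply(spectra, `[[`, character(1), "sample_id")
    wavelengths_nm <- grid
  }
  absorbance <- as.matrix(absorbance)
  storage.mode(absorbance) <- "double"
  if (is.null(wavelengths_nm))
    stop("`wavelengths_nm` required when `absorbance` is a matrix")
  wavelengths_nm <- as.numeric(wavelengths_nm)
  if (ncol(absorbance) != length(wavelengths_nm))
    stop("matrix has ", ncol(absorbance), " columns but grid has ",
         length(wavelengths_nm), " wavelengths")
  if (any(diff(wavelengths_nm) <= 0))
    stop("wavelengths must be strictly increasing")
  if (is.null(sample_ids)) sample_ids <- rownames(absorbance)
  if (is.null(sample_ids))
    stop("`sample_ids` required (or row names on the matrix)")
  sample_ids <- as.character(sample_ids)
  if (length(sample_ids) != nrow(absorbance))
    stop("number of sample ids differs from number of rows")
  if (anyDuplicated(sample_ids))
    stop("duplicate sample_id: '",
         sample_ids[duplicated(sample_ids)][1L], "'")
  if (any(!is.finite(absorbance))) {
    bad <- which(!is.finite(absorbance), arr.ind = TRUE)[1L, ]
    stop("non-finite absorbance for sample '", sample_ids[bad[1L]],
         "' at wavelength ", wavelengths_nm[bad[2L]], " nm")
  }
  rownames(absorbance) <- sample_ids
  colnames(absorbance) <- wavelengths_nm
  structure(list(absorbance = absorbance, wavelengths_nm = wavelengths_nm),
            class = "spectra_set")
}

#' @export
print.spectra_set <- function(x, ...) {
  cat("<spectra_set> ", nrow(x$absorbance), " spectra x ",
      length(x$wavelengths_nm), " wavelengths (",
      min(x$wavelengths_nm), "-", max(x$wavelengths_nm), " nm)\n", sep = "")
  invisible(x)
}

#' @export
as.matrix.spectra_set <- function(x, ...) x$absorbance

#' @export
length.spectra_set <- function(x) nrow(x$absorbance)

#' Sample ids of a spectra set
#' @param set A [spectra_set()].
#' @return Character vector of sample ids.
#' @export
sample_ids <- function(set) {
  stopifnot(inherits(set, "spectra_set"))
  rownames(set$absorbance)
}

#' Extract one spectrum from a set
#' @param set A [spectra_set()].
#' @param id Sample id or integer index.
#' @return A [spectrum()].
#' @export
get_spectrum <- function(set, id) {
  stopifnot(inherits(set, "spectra_set"))
  if (is.numeric(id)) id <- sample_ids(set)[id]
  if (!id %in% sample_ids(set)) stop("unknown sample id '", id, "'")
  spectrum(id, set$wavelengths_nm, set$absorbance[id, ])
}

#' Subset a spectra set by sample id
#' @param set A [spectra_set()].
#' @param ids Character vector of sample ids (or integer indices).
#' @return A [spectra_set()] restricted to `ids`, in the given order.
#' @export
subset_spectra <- function(set, ids) {
  stopifnot(inherits(set, "spectra_set"))
  if (is.numeric(ids)) ids <- sample_ids(set)[ids]
  missing <- setdiff(ids, sample_ids(set))
  if (length(missing))
    stop("unknown sample ids: ", paste(missing, collapse = ", "))
  spectra_set(set$absorbance[ids, , drop = FALSE], set$wavelengths_nm, ids)
}

#' Average repeated scans of one sample
#'
#' Instruments record an averaged spectrum from many repeat scans (32 on
#' the monochromators this pipeline emulates). This is the pointwise
#' arithmetic mean over scans; the sample id is taken from the first scan.
#'
#' @param scans A list of [spectrum()] objects, or a [spectra_set()],
#'   all on one shared grid.
#' @return A single [spectrum()].
#' @export
average_scans <- function(scans) {
  if (inherits(scans, "spectra_set")) {
    id <- sample_ids(scans)[1L]
    return(spectrum(id, scans$wavelengths_nm, colMeans(scans$absorbance)))
  }
  if (!is.list(scans) || length(scans) == 0L)
    stop("`scans` must be a non-empty list of spectra or a spectra_set")
  grid <- scans[[1L]]$wavelengths_nm
  for (sp in scans) {
    if (!inherits(sp, "spectrum")) stop("all scans must be `spectrum` objects")
    if (length(sp$wavelengths_nm) != length(grid) ||
        any(sp$wavelengths_nm != grid))
      stop("grid mismatch between scans")
  }
  acc <- Reduce(`+`, lapply(scans, `[[`, "absorbance"))
  spectrum(scans[[1L]]$sample_id, grid, acc / length(scans))
}

#' Default wavelength grid
#'
#' Visible plus near-infrared grid of scanning monochromators used for
#' seed-flour work: 400-2498 nm at 2 nm steps, 1050 points. Any strictly
#' increasing grid is accepted elsewhere; this is only the generator
#' default.
#'
#' @return Numeric vector of wavelengths in nm.
#' @export
default_grid <- function() seq(400, 2498, by = 2)
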