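#' Read a spectra table
#'
#' Reads NIR spectra from one of three on-disk dialects into a
#' [spectra_set()]:
#' \describe{
#'   \item{`wide-csv`}{first column `sample_id`, remaining column headers
#'     are wavelengths in nm as plain numbers, one row per sample.}
#'   \item{`long-csv`}{columns `sample_id`, `wavelength`, `absorbance`;
#'     every sample must cover the same grid.}
#'   \item{`jcamp-dx`}{a single-block JCAMP-DX file with
#'     `##XYDATA=(X++(Y..Y))` absorbance data (read-only; one spectrum
#'     per file).}
#' }
#'
#' @param path File to read.
#' @param dialect One of `"wide-csv"`, `"long-csv"`, `"jcamp-dx"`.
#' @return A [spectra_set()] on one validated grid.
#' @export
read_spectra_table <- function(path,
                               dialect = c("wide-csv", "long-csv", "jcamp-dx")) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) stop("file not found: ", path)
  switch(dialect,
         "wide-csv" = read_spectra_wide(path),
         "long-csv" = read_spectra_long(path),
         "jcamp-dx" = read_spectra_jcamp(path))
}

read_spectra_wide <- function(path) {
  df <- utils::read.csv(path, check.names = FALSE, colClasses = "character")
  if (ncol(df) < 2L) stop("wide CSV needs a sample_id column plus wavelengths")
  if (names(df)[1L] != "sample_id")
    stop("first column of a wide spectra CSV must be 'sample_id', got '",
         names(df)[1L], "'")
  grid <- suppressWarnings(as.numeric(names(df)[-1L]))
  if (any(is.na(grid)))
    stop("non-numeric wavelength header: '",
         names(df)[-1L][which(is.na(grid))[1L]], "'")
  ids <- df[[1L]]
  if (anyDuplicated(ids))
    stop("duplicate sample_id: '", ids[duplicated(ids)][1L], "'")
  mat <- matrix(NA_real_, nrow(df), length(grid))
  for (j in seq_along(grid)) {
    v <- suppressWarnings(as.numeric(df[[j + 1L]]))
    bad <- which(is.na(v) & !is.na(df[[j + 1L]]) & nzchar(df[[j + 1L]]))
    if (length(bad) == 0L) bad <- which(is.na(v))
    if (any(is.na(v)))
      stop("non-numeric absorbance in sample '", ids[bad[1L]],
           "' at wavelength ", grid[j], " nm (value '", df[[j + 1L]][bad[1L]],
           "')")
    mat[, j] <- v
  }
  spectra_set(mat, grid, ids)
}

read_spectra_long <- function(path) {
  df <- utils::read.csv(path, check.names = FALSE)
  need <- c("sample_id", "wavelength", "absorbance")
  if (!all(need %in% names(df)))
    stop("long CSV needs columns: ", paste(need, collapse = ", "))
  if (!is.numeric(df$wavelength))
    stop("non-numeric wavelength value '", df$wavelength[1L], "'")
  if (!is.numeric(df$absorbance)) {
    bad <- which(is.na(suppressWarnings(as.numeric(df$absorbance))))[1L]
    stop("non-numeric absorbance in sample '", df$sample_id[bad],
         "' at wavelength ", df$wavelength[bad], " nm (value '",
         df$absorbance[bad], "')")
  }
  ids <- unique(as.character(df$sample_id))
  first <- df[df$sample_id == ids[1L], ]
  grid <- sort(first$wavelength)
  mat <- matrix(NA_real_, length(ids), length(grid))
  for (i in seq_along(ids)) {
    sub <- df[df$sample_id == ids[i], ]
    sub <- sub[order(sub$wavelength), ]
    if (nrow(sub) != length(grid) || any(sub$wavelength != grid))
      stop("grid mismatch: sample '", ids[i],
           "' is not on the shared wavelength grid")
    mat[i, ] <- sub$absorbance
  }
  spectra_set(mat, grid, ids)
}

# Minimal JCAMP-DX reader: single block, ##XYDATA=(X++(Y..Y)), AFFN
# (plain decimal) values only. Anything else is rejected outright.
read_spectra_jcamp <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- trimws(lines)
  get_field <- function(name) {
    hit <- grep(paste0("^##", name, "\\s*="), lines, ignore.case = TRUE,
                value = TRUE)
    if (length(hit) == 0L) return(NULL)
    trimws(sub("^##[^=]*=", "", hit[1L]))
  }
  if (sum(grepl("^##TITLE", lines, ignore.case = TRUE)) > 1L)
    stop("multi-block JCAMP-DX files are not supported")
  xy <- get_field("XYDATA")
  if (is.null(xy))
    stop("no ##XYDATA record; only XYDATA=(X++(Y..Y)) JCAMP-DX is supported")
  if (gsub("\\s", "", xy) != "(X++(Y..Y))")
    stop("unsupported XYDATA form '", xy,
         "'; only (X++(Y..Y)) is supported")
  xfac <- as.numeric(get_field("XFACTOR") %||% "1")
  yfac <- as.numeric(get_field("YFACTOR") %||% "1")
  title <- get_field("TITLE") %||% "jcamp"
  start <- grep("^##XYDATA", lines, ignore.case = TRUE)[1L]
  stop_at <- grep("^##END", lines, ignore.case = TRUE)
  stop_at <- if (length(stop_at)) stop_at[stop_at > start][1L] else length(lines) + 1L
  if (is.na(stop_at)) stop_at <- length(lines) + 1L
  data_lines <- lines[seq(start + 1L, stop_at - 1L)]
  data_lines <- data_lines[nzchar(data_lines) & !grepl("^##", data_lines)]
  if (length(data_lines) == 0L) stop("empty XYDATA block")
  if (any(grepl("[^0-9eE+., \t-]", data_lines)))
    stop("compressed (SQZ/DIF/DUP) JCAMP-DX data is not supported; ",
         "only plain AFFN values")
  x <- numeric(0); y <- numeric(0)
  for (ln in data_lines) {
    vals <- as.numeric(strsplit(ln, "[ \t,]+")[[1L]])
    vals <- vals[!is.na(vals)]
    if (length(vals) < 2L) stop("malformed XYDATA line: '", ln, "'")
    x <- c(x, vals[1L])
    y <- c(y, vals[-1L])
  }
  npt <- as.numeric(get_field("NPOINTS") %||% length(y))
  if (npt != length(y))
    stop("NPOINTS (", npt, ") disagrees with number of Y values (",
         length(y), ")")
  firstx <- as.numeric(get_field("FIRSTX") %||% (x[1L] * xfac))
  lastx <- as.numeric(get_field("LASTX") %||% NA)
  if (is.na(lastx)) {
    deltax <- as.numeric(get_field("DELTAX") %||% NA)
    if (is.na(deltax)) stop("need LASTX or DELTAX to build the grid")
    lastx <- firstx + deltax * (npt - 1)
  }
  grid <- seq(firstx, lastx, length.out = npt)
  spectra_set(matrix(y * yfac, nrow = 1L), grid, title)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Write a spectra table
#'
#' Writes a [spectra_set()] to CSV so that [read_spectra_table()] recovers
#' the same values (full double precision, 15 significant digits).
#'
#' @param set A non-empty [spectra_set()].
#' @param path Output file.
#' @param dialect `"wide-csv"` or `"long-csv"` (JCAMP-DX is read-only).
#' @return `path`, invisibly.
#' @export
write_spectra_table <- function(set, path, dialect = c("wide-csv", "long-csv")) {
  dialect <- match.arg(dialect)
  stopifnot(inherits(set, "spectra_set"))
  if (nrow(set$absorbance) == 0L) stop("refusing to write an empty spectra set")
  fmt <- function(x) formatC(x, digits = 15, format = "g")
  if (dialect == "wide-csv") {
    df <- data.frame(sample_id = sample_ids(set),
                     apply(set$absorbance, 2L, fmt),
                     check.names = FALSE, stringsAsFactors = FALSE)
    if (nrow(set$absorbance) == 1L) { # apply drops to vector
      df <- data.frame(sample_id = sample_ids(set),
                       t(fmt(set$absorbance[1L, ])),
                       check.names = FALSE, stringsAsFactors = FALSE)
    }
    names(df) <- c("sample_id", set$wavelengths_nm)
    utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  } else {
    df <- data.frame(
      sample_id = rep(sample_ids(set), each = length(set$wavelengths_nm)),
      wavelength = rep(set$wavelengths_nm, times = nrow(set$absorbance)),
      absorbance = fmt(as.vector(t(set$absorbance))),
      stringsAsFactors = FALSE)
    utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  }
  invisible(path)
}

#' Read a reference (wet-chemistry) table
#'
#' A reference table maps sample ids to laboratory trait values
#' (concentrations in g/100 g; total phenolics in gallic-acid-equivalent
#' g/100 g). Missing values are allowed per trait: each trait is modelled
#' on its non-missing subset.
#'
#' @param path CSV file with column `sample_id` plus one numeric column
#'   per trait.
#' @return A `data.frame` with `sample_id` (character) and numeric trait
#'   columns; all present values are validated non-negative, ids unique.
#' @export
read_reference_table <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  df <- utils::read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
  validate_reference_table(df)
}

#' Validate a reference table held in memory
#' @param df Data frame with `sample_id` plus numeric trait columns.
#' @return The validated data frame (ids coerced to character).
#' @export
validate_reference_table <- function(df) {
  if (!"sample_id" %in% names(df))
    stop("reference table needs a 'sample_id' column")
  df$sample_id <- as.character(df$sample_id)
  if (anyDuplicated(df$sample_id))
    stop("duplicate sample_id: '",
         df$sample_id[duplicated(df$sample_id)][1L], "'")
  traits <- setdiff(names(df), "sample_id")
  if (length(traits) == 0L) stop("reference table has no trait columns")
  for (tr in traits) {
    if (!is.numeric(df[[tr]]))
      stop("trait column '", tr, "' is not numeric")
    v <- df[[tr]]
    if (any(v[!is.na(v)] < 0))
      stop("negative value in trait '", tr, "' for sample '",
           df$sample_id[which(v < 0)[1L]], "'")
  }
  df
}

#' Write a reference table
#' @param df Reference data frame (validated by [validate_reference_table()]).
#' @param path Output CSV.
#' @return `path`, invisibly.
#' @export
write_reference_table <- function(df, path) {
  df <- validate_reference_table(df)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
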