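#' Published cowpea multi-trait NIRS study: summary tables
#'
#' Bundled fixture data from a multi-trait cowpea (*Vigna unguiculata*)
#' seed-flour NIRS calibration campaign (121 accessions split 81/40,
#' five traits), used throughout the package's examples and tests to
#' check that the validation statistics reproduce a published analysis
#' from its printed summaries alone.
#'
#' `cowpea_calibration_table()` — per-trait calibration statistics
#' (N, outliers removed, range, math-treatment code, mean, RSQ, slope,
#' SD, SECV).
#'
#' `cowpea_validation_table()` — external validation statistics over 40
#' accessions (range, mean, RSQ, slope, bias, SD, SEP, RPD).
#'
#' `cowpea_paired_t_table()` — paired t-tests (reference minus
#' predicted) over the validation set: mean difference, SD, SEM, 95% CI,
#' t, DF, p.
#'
#' `cowpea_reliability_table()` — applicability check on a 19-sample
#' verification subset: means and SDs of predicted vs laboratory values,
#' strict-parallel reliability and Pearson correlation.
#'
#' @return A `data.frame`; one row per trait.
#' @name cowpea_tables
NULL

#' @rdname cowpea_tables
#' @export
cowpea_calibration_table <- function() {
  data.frame(
    trait = c("protein", "starch", "tdf", "phenols", "phytate"),
    n = 81L,
    outliers = c(4L, 7L, 5L, 4L, 5L),
    range_min = c(20.0, 26.7, 12.2, 0.08, 0.583),
    range_max = c(27.8, 38.7, 22.4, 0.545, 1.62),
    treatment = c("2,4,6,1", "2,8,8,1", "2,4,4,1", "3,4,4,1", "2,8,8,1"),
    mean = c(23.9, 32.7, 17.3, 0.251, 1.10),
    rsq = c(0.800, 0.997, 0.934, 0.719, 0.985),
    slope = c(1.000, 1.004, 0.954, 1.000, 0.997),
    sd = c(1.29, 2.00, 1.70, 0.098, 0.173),
    secv = c(1.23, 0.063, 1.11, 0.085, 0.266),
    stringsAsFactors = FALSE)
}

#' @rdname cowpea_tables
#' @export
cowpea_validation_table <- function() {
  data.frame(
    trait = c("protein", "starch", "tdf", "phenols", "phytate"),
    n = 40L,
    range_min = c(19.3, 28.1, 14.5, 0.03, 0.866),
    range_max = c(26.5, 42.7, 20.3, 0.496, 1.40),
    treatment = c("2,4,6,1", "2,8,8,1", "2,4,4,1", "3,4,4,1", "2,8,8,1"),
    mean = c(24.2, 32.4, 17.2, 0.247, 1.12),
    rsq = c(0.903, 0.997, 0.901, 0.706, 0.955),
    slope = c(1.122, 1.028, 0.954, 1.179, 0.929),
    bias = c(0.197, 0.029, -0.026, 0.003, 0.009),
    sd = c(1.67, 2.81, 1.49, 0.114, 0.147),
    sep = c(0.598, 0.528, 0.454, 0.064, 0.033),
    rpd = c(2.80, 5.32, 3.28, 1.78, 4.45),
    stringsAsFactors = FALSE)
}

#' @rdname cowpea_tables
#' @export
cowpea_paired_t_table <- function() {
  data.frame(
    trait = c("protein", "starch", "tdf", "phenols", "phytate"),
    mean_diff = c(0.135, 0.0179, 0.0350, 0.00506, 0.00850),
    sem = c(0.0934, 0.0270, 0.0736, 0.0107, 0.00526),
    ci_low = c(-0.0549, -0.0368, -0.114, -0.0167, -0.00214),
    ci_high = c(0.325, 0.0725, 0.184, 0.0268, 0.0191),
    t_value = c(1.44, 0.662, 0.475, 0.473, 1.62),
    df = 40L,
    p_value = c(0.158, 0.512, 0.637, 0.639, 0.114),
    stringsAsFactors = FALSE)
}

#' @rdname cowpea_tables
#' @export
cowpea_reliability_table <- function() {
  data.frame(
    trait = c("protein", "starch", "tdf", "phenols", "phytate"),
    n = 19L,
    mean_pred = c(23.7, 32.4, 20.1, 0.24, 1.45),
    mean_lab = c(24.5, 33.2, 20.5, 0.27, 1.46),
    sd_pred = c(1.18, 2.00, 1.69, 0.037, 0.121),
    sd_lab = c(1.43, 2.91, 1.79, 0.051, 0.171),
    reliability = c(0.91, 0.92, 0.97, 0.64, 0.87),
    r = c(0.97, 0.93, 0.95, 0.55, 0.77),
    stringsAsFactors = FALSE)
}

#' Verification subset: predicted and laboratory values
#'
#' The 19-accession verification subset of the bundled cowpea study
#' (every 11th of 202 rank-ordered predictions sent back to wet
#' chemistry), with predicted (`*_pred`) and laboratory (`*_val`)
#' values for all five traits. The source data behind
#' [cowpea_reliability_table()].
#'
#' @return A `data.frame` with 19 rows: `sample_id` plus
#'   `{trait}_pred` / `{trait}_val` columns for tdf, phytate, phenols,
#'   protein and starch.
#' @export
cowpea_verification_pairs <- function() {
  data.frame(
    sample_id = c("NIC23093", "IC52099", "IC140239", "IC209139", "EC240841",
                  "EC241015", "IC257430", "IC265570", "IC326996", "IC341244",
                  "IC372718", "IC397907", "IC426824", "IC488259", "IC546253",
                  "EC724421", "IC91521A", "EC240917", "IC724382"),
    tdf_pred = c(21.0, 21.9, 24.6, 20.4, 17.8, 20.9, 18.7, 19.6, 18.4, 21.0,
                 19.2, 18.2, 17.5, 19.9, 20.0, 20.2, 20.9, 21.4, 21.5),
    tdf_val = c(20.6, 22.2, 25.1, 21.3, 18.8, 21.0, 19.4, 18.5, 18.7, 21.7,
                19.2, 18.7, 18.1, 20.0, 20.1, 20.2, 21.5, 22.5, 22.6),
    phytate_pred = c(1.51, 1.28, 1.60, 1.33, 1.34, 1.44, 1.27, 1.44, 1.46,
                     1.55, 1.35, 1.46, 1.47, 1.33, 1.49, 1.59, 1.53, 1.75,
                     1.45),
    phytate_val = c(1.54, 1.31, 1.63, 1.26, 1.45, 1.34, 1.22, 1.40, 1.62,
                    1.88, 1.23, 1.34, 1.45, 1.39, 1.45, 1.62, 1.56, 1.66,
                    1.40),
    phenols_pred = c(0.251, 0.215, 0.157, 0.204, 0.288, 0.228, 0.259, 0.274,
                     0.24, 0.246, 0.262, 0.276, 0.297, 0.282, 0.275, 0.24,
                     0.284, 0.20, 0.194),
    phenols_val = c(0.354, 0.345, 0.134, 0.311, 0.263, 0.211, 0.288, 0.3,
                    0.23, 0.248, 0.258, 0.287, 0.32, 0.313, 0.266, 0.288,
                    0.301, 0.244, 0.228),
    protein_pred = c(24.3, 23.7, 21.4, 24.1, 24.0, 23.4, 24.4, 25.6, 23.4,
                     22.7, 23.9, 26.0, 23.1, 24.9, 23.5, 24.4, 24.6, 22.8,
                     21.5),
    protein_val = c(25.3, 24.6, 21.7, 25.0, 24.6, 24.1, 25.3, 26.1, 24.2,
                    23.5, 24.6, 27.3, 24.2, 25.3, 24.4, 25.5, 25.6, 23.5,
                    21.0),
    starch_pred = c(32.0, 30.9, 36.7, 32.4, 31.6, 32.3, 31.2, 30.0, 34.1,
                    34.0, 30.5, 30.1, 33.5, 29.7, 32.9, 31.9, 31.1, 35.2,
                    35.7),
    starch_val = c(30.9, 31.1, 40.1, 35.7, 32.4, 33.4, 32.1, 30.1, 33.9,
                   34.1, 31.2, 30.1, 33.6, 30.0, 33.2, 31.7, 31.6, 36.9,
                   39.0),
    stringsAsFactors = FALSE)
}
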