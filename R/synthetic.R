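#' Gaussian absorption band of one constituent
#'
#' Under Beer-Lambert linearity each constituent contributes
#' `amplitude * exp(-(lambda - center)^2 / (2 width^2))` absorbance per
#' unit concentration at each of its bands.
#'
#' @param center_nm Band centre (nm).
#' @param width_nm Gaussian SD of the band (nm), > 0.
#' @param amplitude Absorbance per unit concentration at the centre.
#' @return An object of class `"component_band"`.
#' @export
component_band <- function(center_nm, width_nm, amplitude) {
  if (!is.finite(width_nm) || width_nm <= 0) stop("width must be > 0")
  if (!is.finite(amplitude)) stop("amplitude must be finite")
  structure(list(center_nm = center_nm, width_nm = width_nm,
                 amplitude = amplitude), class = "component_band")
}

#' Trait specification for the generator
#'
#' A trait is a truncated-normal concentration distribution (mean, SD,
#' bounds, all g/100 g) plus the absorption bands through which it shows
#' up in the spectrum.
#'
#' @param name Trait name.
#' @param mean,sd,min,max Truncated-normal parameters; must satisfy
#'   `min <= mean <= max` and `sd > 0`.
#' @param bands List of [component_band()] objects.
#' @return An object of class `"trait_spec"`.
#' @export
trait_spec <- function(name, mean, sd, min, max, bands) {
  if (!(min <= mean && mean <= max)) stop("need min <= mean <= max")
  if (sd <= 0) stop("sd must be > 0")
  if (!length(bands) || !all(vapply(bands, inherits, logical(1),
                                    "component_band")))
    stop("`bands` must be a non-empty list of component_band objects")
  structure(list(name = name, mean = mean, sd = sd, min = min, max = max,
                 bands = bands), class = "trait_spec")
}

#' Default trait specifications: cowpea seed flour
#'
#' Five nutritional traits with the concentration distributions observed
#' across a diverse cowpea germplasm panel (g/100 g; phenols in GAE
#' g/100 g): protein 24.0 +/- 1.54 in [19.4, 27.9], starch 32.6 +/- 2.27
#' in [27.5, 42.7], total dietary fiber 17.3 +/- 1.71 in [13.7, 21.1],
#' phytate 1.11 +/- 0.163 in [0.690, 1.88] and phenols 0.272 +/- 0.139
#' in [0.03, 0.832]. Band positions follow the usual NIR assignments for
#' seed flours: protein C-O/N-H combination bands in the 2000-2222 nm
#' region; polysaccharide (starch) O-H/C-O-O bands at 1934 and
#' 2083-2100 nm plus the long-wave band near 2482 nm; fiber C-H bands at
#' 1196 (methyl symmetric stretch), 1736 and 2310 nm; the phenol O-H
#' first overtone at 1430-1470 nm; the phytate O-H region at
#' 1560-1640 nm. Widths (Gaussian SD, 16-28 nm) are typical of
#' combination-region bands; amplitudes are scaled so clean absorbance
#' stays within the usual log(1/R) range of about 0-1.5.
#'
#' @return Named list of five [trait_spec()] objects.
#' @export
default_trait_specs <- function() {
  specs <- list(
    trait_spec("protein", mean = 24.0, sd = 1.54, min = 19.4, max = 27.9,
               bands = list(component_band(2055, 28, 0.012),
                            component_band(2180, 24, 0.009))),
    trait_spec("starch", mean = 32.6, sd = 2.27, min = 27.5, max = 42.7,
               bands = list(component_band(1934, 24, 0.010),
                            component_band(2100, 26, 0.008),
                            component_band(2482, 20, 0.005))),
    trait_spec("tdf", mean = 17.3, sd = 1.71, min = 13.7, max = 21.1,
               bands = list(component_band(1196, 22, 0.008),
                            component_band(1736, 24, 0.009),
                            component_band(2310, 24, 0.006))),
    trait_spec("phenols", mean = 0.272, sd = 0.139, min = 0.03, max = 0.832,
               bands = list(component_band(1450, 18, 0.5))),
    trait_spec("phytate", mean = 1.11, sd = 0.163, min = 0.690, max = 1.88,
               bands = list(component_band(1600, 24, 0.25),
                            component_band(1468, 16, 0.10))))
  names(specs) <- vapply(specs, `[[`, character(1), "name")
  specs
}

#' Default matrix (remainder) bands
#'
#' Seed flour is mostly constituents the calibration does not target
#' (moisture, soluble carbohydrates, lipids, ash). The generator closes
#' the composition to a 100 g/100 g basis: the remainder concentration
#' `100 - sum(traits)` absorbs through these broad water/carbohydrate
#' bands (O-H at 1450 and 1934 nm, C-O near 2100 nm, a weak C-H shoulder
#' near 1790 nm). Closure matters: it is what ties absolute
#' concentrations to band-intensity ratios once SNV has removed the
#' overall intensity scale, exactly as in real flour spectra.
#'
#' @return List of [component_band()] objects.
#' @export
default_matrix_bands <- function() {
  list(component_band(1450, 40, 0.004),
       component_band(1934, 35, 0.005),
       component_band(2100, 45, 0.002),
       component_band(1790, 60, 0.0015))
}

#' Configuration of the synthetic study
#'
#' Bundles everything the generator needs: sample count, seed, grid,
#' trait specifications and the nuisance model. Observed spectra are
#' `alpha_i * clean_i(lambda) + beta_i + delta_i * (lambda - mid)/range
#' + noise`, with per-sample multiplicative gain `alpha ~ N(1,
#' scatter_mult_sd)`, additive offset `beta ~ N(0, baseline_offset_sd)`,
#' linear tilt `delta ~ N(0, baseline_tilt_sd)` and iid point noise
#' `N(0, noise_sd)` — exactly the nuisance family that SNV-detrend is
#' designed to remove.
#'
#' @param n_samples Number of samples.
#' @param seed Integer seed; mandatory for any stochastic call.
#' @param grid Wavelength grid, default [default_grid()].
#' @param traits List of [trait_spec()]s, default [default_trait_specs()].
#' @param scatter_mult_sd SD of the multiplicative gain (default 0.05).
#' @param baseline_offset_sd SD of the additive offset (default 0.02).
#' @param baseline_tilt_sd SD of the linear tilt amplitude (default 0.02).
#' @param noise_sd SD of iid point noise; `NULL` (default) means 2% of
#'   the median clean absorbance, resolved at simulation time.
#' @param matrix_bands Bands of the remainder constituent closing the
#'   composition to `total_concentration`; default
#'   [default_matrix_bands()], `NULL` for no matrix constituent.
#' @param total_concentration Compositional basis (default 100 g/100 g).
#' @param trait_correlation Optional between-trait correlation matrix
#'   (default identity = independent traits).
#' @return An object of class `"synthetic_config"`.
#' @export
synthetic_config <- function(n_samples, seed, grid = default_grid(),
                             traits = default_trait_specs(),
                             scatter_mult_sd = 0.05,
                             baseline_offset_sd = 0.02,
                             baseline_tilt_sd = 0.02,
                             noise_sd = NULL,
                             matrix_bands = default_matrix_bands(),
                             total_concentration = 100,
                             trait_correlation = NULL) {
  if (n_samples < 1L) stop("n_samples must be >= 1")
  if (missing(seed) || is.null(seed)) stop("a seed is mandatory")
  sds <- c(scatter_mult_sd, baseline_offset_sd, baseline_tilt_sd,
           noise_sd %||% 0)
  if (any(sds < 0)) stop("all noise SDs must be >= 0")
  structure(list(n_samples = as.integer(n_samples), seed = as.integer(seed),
                 grid = grid, traits = traits,
                 scatter_mult_sd = scatter_mult_sd,
                 baseline_offset_sd = baseline_offset_sd,
                 baseline_tilt_sd = baseline_tilt_sd,
                 noise_sd = noise_sd,
                 matrix_bands = matrix_bands,
                 total_concentration = total_concentration,
                 trait_correlation = trait_correlation),
            class = "synthetic_config")
}

# one truncated-normal draw by rejection; cap guards infeasible bounds
rtruncnorm1 <- function(n, mean, sd, lo, hi, cap = 1000L) {
  out <- numeric(n)
  for (i in seq_len(n)) {
    for (tries in seq_len(cap)) {
      v <- stats::rnorm(1L, mean, sd)
      if (v >= lo && v <= hi) { out[i] <- v; break }
      if (tries == cap)
        stop("truncated-normal rejection failed after ", cap,
             " tries; check [min, max] against mean/sd")
    }
  }
  out
}

#' Simulate trait concentrations
#'
#' Truncated-normal draws per trait (rejection sampling, capped at 1000
#' tries per draw). With a non-identity `correlation`, correlated normal
#' deviates are drawn first and rows falling outside any trait's bounds
#' are redrawn.
#'
#' @param n Number of samples.
#' @param specs List of [trait_spec()]s.
#' @param seed Integer seed, or `NULL` to use the current RNG state.
#' @param correlation Optional between-trait correlation matrix.
#' @param ids Sample ids (default `S001`, `S002`, ...).
#' @return A reference data frame (`sample_id` + one column per trait).
#' @export
simulate_concentrations <- function(n, specs = default_trait_specs(),
                                    seed = NULL, correlation = NULL,
                                    ids = NULL) {
  if (n < 1L) stop("n must be >= 1")
  if (!is.null(seed)) set.seed(seed)
  if (is.null(ids)) ids <- sprintf("S%03d", seq_len(n))
  k <- length(specs)
  if (is.null(correlation)) {
    vals <- lapply(specs, function(sp)
      rtruncnorm1(n, sp$mean, sp$sd, sp$min, sp$max))
  } else {
    if (!all(dim(correlation) == c(k, k)))
      stop("correlation must be ", k, " x ", k)
    L <- chol(correlation)
    mat <- matrix(NA_real_, n, k)
    means <- vapply(specs, `[[`, numeric(1), "mean")
    sds <- vapply(specs, `[[`, numeric(1), "sd")
    los <- vapply(specs, `[[`, numeric(1), "min")
    his <- vapply(specs, `[[`, numeric(1), "max")
    for (i in seq_len(n)) {
      for (tries in seq_len(1000L)) {
        z <- as.vector(crossprod(L, stats::rnorm(k)))
        v <- means + sds * z
        if (all(v >= los & v <= his)) { mat[i, ] <- v; break }
        if (tries == 1000L)
          stop("correlated truncated sampling failed after 1000 tries")
      }
    }
    vals <- lapply(seq_len(k), function(j) mat[, j])
  }
  names(vals) <- vapply(specs, `[[`, character(1), "name")
  df <- data.frame(sample_id = ids, vals, stringsAsFactors = FALSE,
                   check.names = FALSE)
  validate_reference_table(df)
}

# constituent response matrix: traits x wavelengths
band_matrix <- function(specs, grid) {
  B <- t(vapply(specs, function(sp) {
    resp <- numeric(length(grid))
    for (b in sp$bands)
      resp <- resp + b$amplitude *
        exp(-(grid - b$center_nm)^2 / (2 * b$width_nm^2))
    resp
  }, numeric(length(grid))))
  rownames(B) <- vapply(specs, `[[`, character(1), "name")
  B
}

#' Simulate NIR spectra from reference concentrations
#'
#' Clean spectra are Beer-Lambert mixtures,
#' `clean_i = sum_t c_it * response_t(lambda)`, with each trait's
#' response the sum of its Gaussian bands. When the config carries
#' matrix bands, the remainder constituent
#' `total_concentration - sum_t c_it` contributes through them, closing
#' the composition. The observed spectrum adds the per-sample
#' gain/offset/tilt nuisance and iid noise of the [synthetic_config()].
#' Deterministic under the config seed.
#'
#' @param refs Reference data frame with a column for every trait in
#'   `config$traits`.
#' @param config A [synthetic_config()].
#' @param seed Override seed; `NULL` uses `config$seed`; `NA` uses the
#'   current RNG state (for callers that seeded already).
#' @return A [spectra_set()] on `config$grid`.
#' @export
simulate_spectra <- function(refs, config, seed = NULL) {
  stopifnot(inherits(config, "synthetic_config"))
  refs <- validate_reference_table(refs)
  traits <- vapply(config$traits, `[[`, character(1), "name")
  missing <- setdiff(traits, names(refs))
  if (length(missing))
    stop("refs lacks trait columns: ", paste(missing, collapse = ", "))
  if (is.null(seed)) seed <- config$seed
  if (!is.na(seed)) set.seed(seed)
  grid <- config$grid
  C <- as.matrix(refs[, traits, drop = FALSE])
  B <- band_matrix(config$traits, grid)
  clean <- C %*% B
  if (!is.null(config$matrix_bands)) {
    remainder <- config$total_concentration - rowSums(C)
    if (any(remainder < 0))
      stop("trait concentrations exceed the compositional basis of ",
           config$total_concentration, " g/100 g")
    resp <- numeric(length(grid))
    for (b in config$matrix_bands)
      resp <- resp + b$amplitude *
        exp(-(grid - b$center_nm)^2 / (2 * b$width_nm^2))
    clean <- clean + outer(remainder, resp)
  }
  n <- nrow(clean); p <- ncol(clean)
  noise_sd <- config$noise_sd %||% (0.02 * stats::median(clean))
  alpha <- stats::rnorm(n, 1, config$scatter_mult_sd)
  beta <- stats::rnorm(n, 0, config$baseline_offset_sd)
  delta <- stats::rnorm(n, 0, config$baseline_tilt_sd)
  tilt <- (grid - (min(grid) + max(grid)) / 2) / (max(grid) - min(grid))
  obs <- clean * alpha +
    matrix(beta, n, p) +
    outer(delta, tilt) +
    matrix(stats::rnorm(n * p, 0, noise_sd), n, p)
  spectra_set(obs, grid, refs$sample_id)
}

#' Simulate a full calibration study
#'
#' Packages the whole design at any scale: simulate `n_samples`
#' accessions (concentrations and spectra), optionally pick a diverse
#' subset by [ward_select_diverse()] (emulating the scan-then-select
#' stage of germplasm work), and rank-order split per trait into
#' calibration and validation sets. Fully deterministic under the
#' config seed.
#'
#' @param config A [synthetic_config()].
#' @param n_select Subset size carried to wet chemistry; `NULL` keeps
#'   all samples (no clustering stage).
#' @param n_clusters Clusters for the selection stage (default 10 when
#'   selecting).
#' @return List with `spectra` (the selected subset), `refs` (reference
#'   table of the subset), `splits` (named list of [rank_order_split()]
#'   plans, one per trait), `all_spectra`, `all_refs` and `selection`
#'   (the [ward_select_diverse()] output, or NULL).
#' @export
make_study <- function(config, n_select = NULL, n_clusters = 10L) {
  stopifnot(inherits(config, "synthetic_config"))
  set.seed(config$seed)
  refs <- simulate_concentrations(config$n_samples, config$traits,
                                  seed = NULL,
                                  correlation = config$trait_correlation)
  spectra <- simulate_spectra(refs, config, seed = NA)
  selection <- NULL
  sel_spectra <- spectra
  sel_refs <- refs
  if (!is.null(n_select) && n_select < config$n_samples) {
    selection <- ward_select_diverse(spectra, n_select,
                                     n_clusters = n_clusters)
    sel_spectra <- subset_spectra(spectra, selection$ids)
    sel_refs <- refs[match(selection$ids, refs$sample_id), , drop = FALSE]
    rownames(sel_refs) <- NULL
  }
  traits <- vapply(config$traits, `[[`, character(1), "name")
  splits <- lapply(traits, function(tr) rank_order_split(sel_refs, tr))
  names(splits) <- traits
  list(spectra = sel_spectra, refs = sel_refs, splits = splits,
       all_spectra = spectra, all_refs = refs, selection = selection)
}
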