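#' Pipeline configuration
#'
#' Bundles the parameters of a full calibration run: file paths, the
#' per-trait math-treatment codes, scatter mode, split / CV / outlier
#' parameters and the seed. The interactive interface of the package is
#' its functions; `run_stage()` strings them into the standard workflow
#' (simulate, select, split, calibrate, validate, predict, verify,
#' report) and writes each stage's artifacts as CSV so that runs are
#' scriptable and auditable.
#'
#' @param output_dir Directory for stage artifacts (created if needed).
#' @param spectra_path,reference_path Input files (wide CSV spectra,
#'   reference CSV); filled in by the `simulate` stage when generating.
#' @param treatments Named character vector/list: trait -> treatment
#'   code, e.g. `c(protein = "2,4,6,1")`.
#' @param scatter Scatter mode for all traits (default `"snv-dt"`).
#' @param seed Integer seed.
#' @param n_samples,n_select Generator sizes for the `simulate` /
#'   `select` stages.
#' @param verification_step Stride of the `verify` stage (default 11).
#' @param t_crit,outlier_cap,max_passes Outlier-elimination parameters.
#' @param cv_groups Cross-validation groups (default 4).
#' @return An object of class `"pipeline_config"` (a list).
#' @export
pipeline_config <- function(output_dir,
                            spectra_path = NULL, reference_path = NULL,
                            treatments = c(protein = "2,4,6,1",
                                           starch = "2,8,8,1",
                                           tdf = "2,4,4,1",
                                           phenols = "3,4,4,1",
                                           phytate = "2,8,8,1"),
                            scatter = "snv-dt", seed = 1L,
                            n_samples = 121L, n_select = NULL,
                            verification_step = 11L,
                            t_crit = 2.5, outlier_cap = 10L,
                            max_passes = 2L, cv_groups = 4L) {
  structure(list(output_dir = output_dir, spectra_path = spectra_path,
                 reference_path = reference_path,
                 treatments = as.list(treatments), scatter = scatter,
                 seed = as.integer(seed), n_samples = as.integer(n_samples),
                 n_select = n_select,
                 verification_step = as.integer(verification_step),
                 t_crit = t_crit, outlier_cap = as.integer(outlier_cap),
                 max_passes = as.integer(max_passes),
                 cv_groups = as.integer(cv_groups)),
            class = "pipeline_config")
}

#' Load a pipeline configuration from YAML
#' @param path YAML file whose keys match the [pipeline_config()]
#'   arguments.
#' @return A `pipeline_config`.
#' @export
load_pipeline_config <- function(path) {
  raw <- yaml::read_yaml(path)
  known <- names(formals(pipeline_config))
  unknown <- setdiff(names(raw), known)
  if (length(unknown))
    stop("unknown config keys: ", paste(unknown, collapse = ", "))
  do.call(pipeline_config, raw)
}

stage_log <- function(...) message("[nirscal] ", ...)

stage_path <- function(config, ...) file.path(config$output_dir, ...)

write_provenance <- function(config, stage) {
  cfg <- unclass(config)
  jsonlite::write_json(
    list(stage = stage, package = "nirscal",
         version = as.character(utils::packageVersion("nirscal")),
         config = cfg),
    stage_path(config, paste0(stage, "_provenance.json")),
    auto_unbox = TRUE, null = "null", digits = NA)
}

#' Run one pipeline stage
#'
#' Stages mirror the standard NIRS modeling workflow:
#' \describe{
#'   \item{simulate}{generate synthetic spectra + reference CSVs.}
#'   \item{select}{Ward-cluster the spectra and keep a diverse subset.}
#'   \item{split}{rank-order split per trait (writes one split CSV per
#'     trait).}
#'   \item{calibrate}{per-trait MPLS calibration on the calibration
#'     split; writes a calibration summary CSV and one model JSON per
#'     trait.}
#'   \item{validate}{predict the validation split and write the external
#'     validation summary.}
#'   \item{predict}{apply stored models to a spectra file.}
#'   \item{verify}{rank-order pick every k-th prediction, compare with
#'     laboratory values where available: correlation + reliability.}
#'   \item{report}{collect the calibration and validation summaries
#'     side by side.}
#' }
#' Each stage writes its artifacts under `config$output_dir` together
#' with a provenance JSON (config echo + package version); logs go to
#' the message stream.
#'
#' @param stage One of `"simulate"`, `"select"`, `"split"`,
#'   `"calibrate"`, `"validate"`, `"predict"`, `"verify"`, `"report"`.
#' @param config A [pipeline_config()].
#' @param trait Restrict `calibrate`/`validate`/`verify` to one trait
#'   (default: all configured traits).
#' @return Invisible named list of artifact paths.
#' @export
run_stage <- function(stage = c("simulate", "select", "split", "calibrate",
                                "validate", "predict", "verify", "report"),
                      config, trait = NULL) {
  stage <- match.arg(stage)
  stopifnot(inherits(config, "pipeline_config"))
  traits <- names(config$treatments)
  if (!is.null(trait)) {
    if (!trait %in% traits)
      stop("configuration error: trait '", trait,
           "' has no treatment configured")
    traits <- trait
  }
  if (length(traits) == 0L) stop("configuration error: no treatments")
  dir.create(config$output_dir, showWarnings = FALSE, recursive = TRUE)
  out <- switch(stage,
    simulate = stage_simulate(config),
    select = stage_select(config),
    split = stage_split(config, traits),
    calibrate = stage_calibrate(config, traits),
    validate = stage_validate(config, traits),
    predict = stage_predict(config, traits),
    verify = stage_verify(config, traits),
    report = stage_report(config))
  write_provenance(config, stage)
  invisible(out)
}

load_inputs <- function(config) {
  sp <- config$spectra_path %||% stage_path(config, "spectra.csv")
  rp <- config$reference_path %||% stage_path(config, "reference.csv")
  if (!file.exists(sp)) stop("missing input: spectra file ", sp)
  if (!file.exists(rp)) stop("missing input: reference file ", rp)
  list(spectra = read_spectra_table(sp, "wide-csv"),
       refs = read_reference_table(rp))
}

stage_simulate <- function(config) {
  specs <- default_trait_specs()
  traits <- names(config$treatments)
  unknown <- setdiff(traits, names(specs))
  if (length(unknown))
    stop("configuration error: no trait specification for ",
         paste(unknown, collapse = ", "))
  cfg <- synthetic_config(config$n_samples, config$seed,
                          traits = specs[traits])
  set.seed(cfg$seed)
  refs <- simulate_concentrations(cfg$n_samples, cfg$traits, seed = NULL)
  spectra <- simulate_spectra(refs, cfg, seed = NA)
  sp <- stage_path(config, "spectra.csv")
  rp <- stage_path(config, "reference.csv")
  write_spectra_table(spectra, sp)
  write_reference_table(refs, rp)
  stage_log("simulate: ", cfg$n_samples, " samples, seed ", cfg$seed)
  list(spectra = sp, reference = rp)
}

stage_select <- function(config) {
  inp <- load_inputs(config)
  n_sel <- config$n_select %||% length(inp$spectra)
  sel <- ward_select_diverse(inp$spectra, n_sel)
  path <- stage_path(config, "selected_ids.csv")
  utils::write.csv(data.frame(sample_id = sel$ids), path, row.names = FALSE,
                   quote = FALSE)
  stage_log("select: ", length(sel$ids), " of ", length(inp$spectra),
            " samples across ", max(sel$clusters), " clusters")
  list(selected = path)
}

stage_split <- function(config, traits) {
  inp <- load_inputs(config)
  paths <- list()
  for (tr in traits) {
    plan <- rank_order_split(inp$refs, tr)
    p <- stage_path(config, paste0("split_", tr, ".csv"))
    write_split_plan(plan, p)
    stage_log("split ", tr, ": ", length(plan$calibration_ids), " cal / ",
              length(plan$validation_ids), " val")
    paths[[tr]] <- p
  }
  paths
}

stage_calibrate <- function(config, traits) {
  inp <- load_inputs(config)
  rows <- list(); paths <- list()
  for (tr in traits) {
    plan <- read_split_plan(stage_path(config, paste0("split_", tr, ".csv")),
                            trait = tr)
    cal_refs <- inp$refs[inp$refs$sample_id %in% plan$calibration_ids, ]
    res <- calibrate_trait(subset_spectra(inp$spectra, plan$calibration_ids),
                           cal_refs, tr,
                           parse_math_treatment(config$treatments[[tr]],
                                                config$scatter),
                           t_crit = config$t_crit, cap = config$outlier_cap,
                           max_passes = config$max_passes,
                           n_groups = config$cv_groups)
    mp <- stage_path(config, paste0("model_", tr, ".json"))
    write_mpls_model(res$model, mp)
    stage_log("calibrate ", tr, ": N=", res$n, ", A=", res$n_factors,
              ", outliers=", res$outliers_removed,
              ", RSQ=", round(res$rsq, 3), ", SECV=", signif(res$secv, 3))
    rows[[tr]] <- data.frame(
      trait = tr, n = res$n, outliers = res$outliers_removed,
      range_min = res$range[1L], range_max = res$range[2L],
      treatment = res$treatment, mean = res$mean, rsq = res$rsq,
      slope = res$slope, sd = res$sd, secv = res$secv, sec = res$sec,
      one_minus_vr = res$one_minus_vr, n_factors = res$n_factors,
      stringsAsFactors = FALSE)
    paths[[tr]] <- mp
  }
  summary_path <- stage_path(config, "calibration_summary.csv")
  utils::write.csv(do.call(rbind, rows), summary_path, row.names = FALSE)
  c(paths, list(summary = summary_path))
}

stage_validate <- function(config, traits) {
  inp <- load_inputs(config)
  rows <- list()
  for (tr in traits) {
    plan <- read_split_plan(stage_path(config, paste0("split_", tr, ".csv")),
                            trait = tr)
    model <- read_mpls_model(stage_path(config, paste0("model_", tr, ".json")))
    treated <- apply_pretreatment(subset_spectra(inp$spectra,
                                                 plan$validation_ids),
                                  model$treatment)
    pred <- predict(model, treated)
    ref <- inp$refs[[tr]][match(plan$validation_ids, inp$refs$sample_id)]
    keep <- !is.na(ref)
    rep_ <- external_validation(ref[keep], pred[keep])
    tt <- paired_t(ref[keep], pred[keep])
    stage_log("validate ", tr, ": N=", rep_$n, ", RSQ=", round(rep_$rsq, 3),
              ", SEP=", signif(rep_$sep, 3), ", RPD=", round(rep_$rpd, 2),
              " (", rep_$rpd_band, "), paired-t p=", signif(tt$p_value, 3))
    rows[[tr]] <- data.frame(
      trait = tr, n = rep_$n, range_min = rep_$range[1L],
      range_max = rep_$range[2L], treatment = format(model$treatment),
      mean = rep_$mean, rsq = rep_$rsq, slope = rep_$slope, bias = rep_$bias,
      sd = rep_$sd, sep = rep_$sep, rpd = rep_$rpd, rpd_band = rep_$rpd_band,
      t_value = tt$t_value, p_value = tt$p_value,
      stringsAsFactors = FALSE)
  }
  path <- stage_path(config, "validation_summary.csv")
  utils::write.csv(do.call(rbind, rows), path, row.names = FALSE)
  list(summary = path)
}

stage_predict <- function(config, traits) {
  sp <- config$spectra_path %||% stage_path(config, "spectra.csv")
  if (!file.exists(sp)) stop("missing input: spectra file ", sp)
  spectra <- read_spectra_table(sp, "wide-csv")
  out <- data.frame(sample_id = sample_ids(spectra),
                    stringsAsFactors = FALSE)
  for (tr in traits) {
    model <- read_mpls_model(stage_path(config, paste0("model_", tr, ".json")))
    treated <- apply_pretreatment(spectra, model$treatment)
    out[[tr]] <- unname(predict(model, treated))
  }
  path <- stage_path(config, "predictions.csv")
  utils::write.csv(out, path, row.names = FALSE)
  stage_log("predict: ", nrow(out), " samples x ", length(traits), " traits")
  list(predictions = path)
}

stage_verify <- function(config, traits) {
  pp <- stage_path(config, "predictions.csv")
  if (!file.exists(pp)) stop("missing input: predictions file ", pp)
  preds <- utils::read.csv(pp, stringsAsFactors = FALSE)
  rp <- config$reference_path %||% stage_path(config, "reference.csv")
  if (!file.exists(rp)) stop("missing input: reference file ", rp)
  refs <- read_reference_table(rp)
  rows <- list()
  for (tr in traits) {
    v <- preds[[tr]]; names(v) <- preds$sample_id
    picked <- select_verification_subset(v, config$verification_step)
    lab <- refs[[tr]][match(picked, refs$sample_id)]
    keep <- !is.na(lab)
    rel <- strict_parallel_reliability(v[picked][keep], lab[keep])
    pr <- pearson_r(v[picked][keep], lab[keep])
    stage_log("verify ", tr, ": ", sum(keep), " pairs, r=",
              round(pr$r, 2), ", reliability=", round(rel$reliability, 2))
    rows[[tr]] <- data.frame(
      trait = tr, n = rel$n_pairs, mean_pred = rel$mean_pred,
      mean_lab = rel$mean_lab, sd_pred = rel$sd_pred, sd_lab = rel$sd_lab,
      reliability = rel$reliability, r = pr$r, p_value = pr$p_value,
      stringsAsFactors = FALSE)
  }
  path <- stage_path(config, "verification_summary.csv")
  utils::write.csv(do.call(rbind, rows), path, row.names = FALSE)
  list(summary = path)
}

stage_report <- function(config) {
  parts <- c("calibration_summary.csv", "validation_summary.csv",
             "verification_summary.csv")
  found <- parts[file.exists(stage_path(config, parts))]
  if (length(found) == 0L)
    stop("missing inputs: no stage summaries found in ", config$output_dir)
  combined <- lapply(found, function(f) {
    df <- utils::read.csv(stage_path(config, f), stringsAsFactors = FALSE)
    df$section <- sub("_summary.csv", "", f)
    df
  })
  path <- stage_path(config, "report.csv")
  all_cols <- unique(unlist(lapply(combined, names)))
  combined <- lapply(combined, function(df) {
    for (cl in setdiff(all_cols, names(df))) df[[cl]] <- NA
    df[all_cols]
  })
  utils::write.csv(do.call(rbind, combined), path, row.names = FALSE)
  stage_log("report: ", paste(found, collapse = " + "))
  list(report = path)
}
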