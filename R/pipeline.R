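# End-to-end orchestration: simulate/load -> exclusions -> features -> stratified
# split -> train (Cohort I) -> calibrate (Cohort II) -> blind test (Cohort III)
# -> high-risk clustering; plus the prospective mode that scores a new cohort
# with a frozen model and never refits. One structured log line per stage with
# row counts in and out.

#' Assemble a pipeline run configuration
#'
#' @param population An `hie_population`, or `NULL` if `synth` or `tables_dir`
#'   is given.
#' @param synth A [synthetic_config()] used to generate the population.
#' @param tables_dir Directory of CSV tables to read via [read_hie_tables()].
#' @param out_dir Output directory for run artifacts.
#' @param keep_n Variance-filter budget ([variance_filter()]); `NULL` disables
#'   the filter.
#' @param model_params Model tuning list (see [train_risk_model()]).
#' @param min_cell Calibration knot minimum ([fit_calibration()]).
#' @param thresholds PPV-table index thresholds.
#' @param cluster_k,variance_target,highrisk_threshold High-risk clustering
#'   settings.
#' @param seed Global seed, fanned out to per-stage seeds by fixed offsets.
#' @return A `run_config` list.
#' @export
run_config <- function(population = NULL, synth = NULL, tables_dir = NULL,
                       out_dir = tempfile("edrun"), keep_n = NULL,
                       model_params = list(), min_cell = 50L,
                       thresholds = c(30, 50, 70, 80), cluster_k = 6L,
                       variance_target = 0.8, highrisk_threshold = 70,
                       seed = 1L) {
  if (is.null(population) && is.null(synth) && is.null(tables_dir))
    stop("one of population, synth or tables_dir is required", call. = FALSE)
  if (!is.null(synth) && !inherits(synth, "synthetic_config"))
    stop("synth must be a 'synthetic_config'", call. = FALSE)
  if (!is.null(tables_dir) && !dir.exists(tables_dir))
    stop("tables_dir does not exist: ", tables_dir, call. = FALSE)
  structure(list(population = population, synth = synth,
                 tables_dir = tables_dir, out_dir = out_dir, keep_n = keep_n,
                 model_params = model_params, min_cell = min_cell,
                 thresholds = thresholds, cluster_k = cluster_k,
                 variance_target = variance_target,
                 highrisk_threshold = highrisk_threshold,
                 seed = as.integer(seed)),
            class = "run_config")
}

stage_log <- function(stage, n_in, n_out, quiet) {
  if (!quiet)
    message(sprintf("[%s] in=%d out=%d", stage, n_in, n_out))
}

resolve_population <- function(config, quiet) {
  if (!is.null(config$population)) return(config$population)
  if (!is.null(config$synth)) {
    pop <- generate_population(config$synth)
    stage_log("simulate", config$synth$n_patients, nrow(pop$patients), quiet)
    return(pop)
  }
  pop <- read_hie_tables(config$tables_dir)
  stage_log("load", NA_integer_, nrow(pop$patients), quiet)
  pop
}

manifest_for <- function(config, mode, extra = list()) {
  cfg <- config
  cfg$population <- NULL  # data, not configuration
  cfg$out_dir <- NULL     # filesystem location, not science: keeps the
  cfg$tables_dir <- NULL  # manifest hash a function of the run conditions only
  syn <- cfg$synth
  if (!is.null(syn)) {
    syn$index_date <- format(syn$index_date)
    syn$hazard_coefficients <- as.list(syn$hazard_coefficients)
    cfg$synth <- unclass(syn)
  }
  c(list(mode = mode,
         package_version = as.character(utils::packageVersion("edcasefinder")),
         config = unclass(cfg)),
    extra)
}

write_manifest <- function(manifest, out_dir) {
  json <- jsonlite::toJSON(manifest, auto_unbox = TRUE, digits = NA,
                           null = "null", pretty = TRUE)
  tmp <- tempfile()
  writeLines(json, tmp)
  hash <- unname(tools::md5sum(tmp))
  unlink(tmp)
  manifest$manifest_hash <- hash
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, null = "null",
                       pretty = TRUE)
  hash
}

evaluation_to_json <- function(ev, cluster_res, hash, path) {
  doc <- list(
    manifest_hash = hash,
    n = ev$n,
    auc = ev$auc,
    ppv_table = ev$ppv_table,
    logrank = ev$logrank,
    mean_ed_by_group = as.list(ev$mean_ed_by_group),
    km_curves = ev$km_curves,
    shrunken = list(features = rownames(ev$shrunken),
                    classes = colnames(ev$shrunken),
                    values = apply(ev$shrunken, 2L, identity, simplify = FALSE)),
    cluster_profiles = if (is.null(cluster_res)) NULL else cluster_res$profiles,
    cluster_explained_variance = if (is.null(cluster_res)) NULL else
      cluster_res$explained_variance)
  jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = NA,
                       null = "null", pretty = TRUE)
}

#' Run the retrospective modeling pipeline
#'
#' Executes exclusions, feature construction, the six-stratum balanced split,
#' training on Cohort I, PPV calibration on Cohort II, the blind-test report on
#' Cohort III, and high-risk clustering; writes the model JSON, per-patient
#' assessments, the evaluation report, cluster profiles, cohort assignments,
#' the exclusion log and a run manifest into `config$out_dir`.
#'
#' @param config A [run_config()].
#' @param quiet Suppress per-stage log lines.
#' @return Invisibly, a list with the fitted `model`, `calibration`,
#'   blind-test `evaluation`, `clusters`, `split`, `features`, and the artifact
#'   directory `out_dir`.
#' @export
run_retrospective <- function(config, quiet = FALSE) {
  stopifnot(inherits(config, "run_config"))
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  pop <- resolve_population(config, quiet)

  ex <- apply_exclusions(pop)
  stage_log("exclusions", nrow(pop$patients), nrow(ex$population$patients), quiet)
  write.csv(ex$exclusion_log, file.path(config$out_dir, "exclusions.csv"),
            row.names = FALSE)

  fm <- build_pivot_table(ex$population)
  if (!is.null(config$keep_n)) fm <- variance_filter(fm, config$keep_n)
  stage_log("features", nrow(ex$population$patients), ncol(fm$X), quiet)

  stratum <- stratify_six_subgroups(fm)
  split <- split_cohorts(fm$patient_id, stratum, fm$outcome,
                         seed = config$seed + 1L)
  write.csv(split, file.path(config$out_dir, "cohorts.csv"), row.names = FALSE)
  stage_log("split", length(stratum), length(unique(split$cohort)), quiet)

  rows_I <- which(split$cohort == "I")
  rows_II <- which(split$cohort == "II")
  rows_III <- which(split$cohort == "III")

  model <- train_risk_model(fm, rows_I, params = config$model_params,
                            seed = config$seed + 2L)
  stage_log("train", length(rows_I), length(model$submodels), quiet)

  scores_II <- score_patients(model, fm, rows_II)
  map <- fit_calibration(scores_II, fm$outcome[rows_II],
                         min_cell = config$min_cell)
  stage_log("calibrate", length(rows_II), nrow(map$knots), quiet)
  save_risk_model(model, file.path(config$out_dir, "model.json"),
                  calibration = map)

  scores_III <- score_patients(model, fm, rows_III)
  fm_III <- fm_subset(fm, rows_III)
  ev <- evaluate_risk(fm_III, scores_III, map, thresholds = config$thresholds)
  stage_log("evaluate", length(rows_III), nrow(ev$ppv_table), quiet)

  assess <- risk_assessment(fm_III$patient_id, scores_III, map)
  write.csv(assess, file.path(config$out_dir, "assessments.csv"),
            row.names = FALSE)

  clusters <- cluster_highrisk(fm_III, ev$risk_index, k = config$cluster_k,
                               variance_target = config$variance_target,
                               threshold = config$highrisk_threshold,
                               seed = config$seed + 3L)
  stage_log("cluster", sum(ev$risk_index >= config$highrisk_threshold),
            if (is.null(clusters)) 0L else nrow(clusters$profiles), quiet)
  if (!is.null(clusters))
    write.csv(clusters$profiles, file.path(config$out_dir, "profiles.csv"),
              row.names = FALSE)

  hash <- write_manifest(manifest_for(config, "retrospective"), config$out_dir)
  evaluation_to_json(ev, clusters, hash,
                     file.path(config$out_dir, "evaluation.json"))
  write.csv(ev$ppv_table, file.path(config$out_dir, "ppv_table.csv"),
            row.names = FALSE)

  invisible(list(model = model, calibration = map, evaluation = ev,
                 clusters = clusters, split = split, features = fm,
                 out_dir = config$out_dir))
}

#' Score a new cohort with a frozen model (prospective mode)
#'
#' Loads a persisted model and calibration map, validates the feature schema
#' (an error lists any selected feature missing from the new cohort's
#' matrix), scores every patient, and emits the same report family as the
#' retrospective run. Never refits and never mutates the model file.
#'
#' @param config A [run_config()] describing the prospective cohort.
#' @param frozen_model_path Path to a model JSON from a prior run.
#' @param quiet Suppress per-stage log lines.
#' @return Invisibly, a list with `evaluation`, `assessments`, `clusters`,
#'   `features` and `out_dir`.
#' @export
run_prospective <- function(config, frozen_model_path, quiet = FALSE) {
  stopifnot(inherits(config, "run_config"))
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  frozen <- load_risk_model(frozen_model_path)
  if (is.null(frozen$calibration))
    stop("frozen model document lacks a calibration map", call. = FALSE)
  pop <- resolve_population(config, quiet)
  ex <- apply_exclusions(pop)
  stage_log("exclusions", nrow(pop$patients), nrow(ex$population$patients), quiet)
  fm <- build_pivot_table(ex$population)
  stage_log("features", nrow(ex$population$patients), ncol(fm$X), quiet)

  needed <- unique(unlist(lapply(frozen$model$submodels, `[[`, "features")))
  missing <- setdiff(needed, colnames(fm$X))
  if (length(missing))
    stop("feature schema mismatch; missing feature(s): ",
         paste(missing, collapse = ", "), call. = FALSE)

  scores <- score_patients(frozen$model, fm, strict = TRUE)
  map <- frozen$calibration
  ev <- evaluate_risk(fm, scores, map, thresholds = config$thresholds)
  stage_log("evaluate", length(scores), nrow(ev$ppv_table), quiet)
  assess <- risk_assessment(fm$patient_id, scores, map)
  write.csv(assess, file.path(config$out_dir, "assessments.csv"),
            row.names = FALSE)
  clusters <- cluster_highrisk(fm, ev$risk_index, k = config$cluster_k,
                               variance_target = config$variance_target,
                               threshold = config$highrisk_threshold,
                               seed = config$seed + 3L)
  if (!is.null(clusters))
    write.csv(clusters$profiles, file.path(config$out_dir, "profiles.csv"),
              row.names = FALSE)
  hash <- write_manifest(
    manifest_for(config, "prospective",
                 extra = list(frozen_model = basename(frozen_model_path))),
    config$out_dir)
  evaluation_to_json(ev, clusters, hash,
                     file.path(config$out_dir, "evaluation.json"))
  invisible(list(evaluation = ev, assessments = assess, clusters = clusters,
                 features = fm, out_dir = config$out_dir))
}
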