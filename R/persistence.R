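# Model persistence: a versioned JSON document holding the partition rule, the
# per-subgroup feature lists and serialized trees, the hyperparameters and
# seeds, and (optionally) the calibration map.

tree_to_list <- function(m) {
  lapply(setNames(colnames(m), colnames(m)), function(cc) unname(m[, cc]))
}

tree_from_list <- function(l) {
  m <- do.call(cbind, lapply(l, function(x) as.numeric(unlist(x))))
  colnames(m) <- names(l)
  m
}

#' Save / load a risk model (with optional calibration map) as JSON
#'
#' @param model A `risk_model`.
#' @param path File path for the JSON document.
#' @param calibration Optional `calibration_map` stored alongside the model.
#' @return `save_risk_model()` returns `path` invisibly; `load_risk_model()`
#'   returns a list with elements `model` and `calibration` (NULL if absent).
#' @export
save_risk_model <- function(model, path, calibration = NULL) {
  stopifnot(inherits(model, "risk_model"))
  doc <- list(
    format = "edcasefinder-risk-model",
    format_version = 1L,
    package_version = as.character(utils::packageVersion("edcasefinder")),
    partition_rule = "prior_ed_count>0 x chronic_flag>0",
    horizon = model$horizon,
    seed = model$seed,
    params = model$params,
    feature_names = model$feature_names,
    submodels = lapply(model$submodels, function(m) {
      list(subgroup_id = m$subgroup_id,
           features = m$features,
           hyperparams = m$hyperparams,
           seed = m$seed,
           horizon = m$horizon,
           constant = m$constant,
           trees = if (is.null(m$trees)) NULL else lapply(m$trees, tree_to_list))
    }),
    calibration = if (is.null(calibration)) NULL else list(
      knots = calibration$knots,
      t_medium = calibration$t_medium,
      t_high = calibration$t_high,
      n_calibration = calibration$n_calibration)
  )
  jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = NA, null = "null")
  invisible(path)
}

#' @rdname save_risk_model
#' @export
load_risk_model <- function(path) {
  ## no auto-simplification: the tree arrays must keep their exact shape
  doc <- jsonlite::read_json(path, simplifyVector = FALSE)
  if (!identical(doc$format, "edcasefinder-risk-model"))
    stop("not an edcasefinder risk-model document: ", path, call. = FALSE)
  num1 <- function(x) if (is.null(x)) NULL else as.numeric(x)
  submodels <- lapply(doc$submodels, function(m) {
    structure(list(subgroup_id = m$subgroup_id,
                   features = as.character(unlist(m$features)),
                   hyperparams = lapply(m$hyperparams, function(x) x),
                   seed = as.integer(m$seed),
                   horizon = as.integer(m$horizon),
                   constant = num1(m$constant),
                   trees = if (is.null(m$trees)) NULL else
                     lapply(m$trees, tree_from_list)),
              class = "subgroup_model")
  })
  model <- structure(list(submodels = submodels,
                          feature_names = as.character(unlist(doc$feature_names)),
                          params = lapply(doc$params, function(x) x),
                          seed = as.integer(doc$seed),
                          horizon = as.integer(doc$horizon),
                          frozen = TRUE),
                     class = "risk_model")
  calibration <- NULL
  if (!is.null(doc$calibration)) {
    kn <- doc$calibration$knots
    knots <- data.frame(
      raw_score = vapply(kn, function(r) as.numeric(r$raw_score), 0),
      index = vapply(kn, function(r) as.numeric(r$index), 0))
    calibration <- structure(list(knots = knots,
                                  t_medium = as.numeric(doc$calibration$t_medium),
                                  t_high = as.numeric(doc$calibration$t_high),
                                  n_calibration =
                                    as.integer(doc$calibration$n_calibration)),
                             class = "calibration_map")
  }
  list(model = model, calibration = calibration)
}
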