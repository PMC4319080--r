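# The active case-finding learner. Two empirical features (any prior-year ED
# visit, any chronic diagnosis) drive a deterministic 2x2 partition into four
# subgroups; within each subgroup a minimal feature set is selected under a PPV
# constraint and a bagged survival-tree forest (log-rank splitting, leaf =
# within-horizon event fraction) produces the raw score. The forest mean is a
# posterior probability of an ED visit inside the outcome horizon.

subgroup_ids <- function() {
  c("EDpos_CHRpos", "EDpos_CHRneg", "EDneg_CHRpos", "EDneg_CHRneg")
}

#' Deterministic 2x2 partition on the empirical features
#'
#' @param prior_ed_count Prior-year ED visit counts.
#' @param chronic_flag Binary chronic-diagnosis flags.
#' @return Character vector of subgroup ids (`EDpos_CHRpos`, `EDpos_CHRneg`,
#'   `EDneg_CHRpos`, `EDneg_CHRneg`); a total function, so the four subgroups
#'   partition any cohort.
#' @export
#' @examples
#' partition_subgroup(c(3, 0), c(0, 1))
partition_subgroup <- function(prior_ed_count, chronic_flag) {
  if (anyNA(prior_ed_count) || anyNA(chronic_flag))
    stop("prior_ed_count and chronic_flag must be non-missing", call. = FALSE)
  paste0(ifelse(prior_ed_count > 0, "EDpos", "EDneg"), "_",
         ifelse(chronic_flag > 0, "CHRpos", "CHRneg"))
}

# out-of-fold logistic scores for a candidate feature set (columns of X)
oof_logistic_scores <- function(X, y, cols, folds) {
  n <- length(y)
  scores <- numeric(n)
  Xc <- cbind(1, X[, cols, drop = FALSE])
  for (f in sort(unique(folds))) {
    test <- folds == f
    fit <- suppressWarnings(
      glm.fit(Xc[!test, , drop = FALSE], y[!test], family = binomial()))
    beta <- fit$coefficients
    beta[is.na(beta)] <- 0
    scores[test] <- drop(Xc[test, , drop = FALSE] %*% beta)
  }
  scores
}

top_slice_metrics <- function(scores, y, review_fraction) {
  n <- length(y)
  ntop <- max(1L, ceiling(review_fraction * n))
  top <- order(-scores)[seq_len(ntop)]
  pos <- sum(y)
  list(sens = if (pos > 0) sum(y[top]) / pos else 0,
       ppv = mean(y[top]))
}

#' Greedy minimal feature selection under a PPV constraint
#'
#' Forward selection: at each step the feature that maximizes out-of-fold
#' sensitivity within the top `review_fraction` of scored patients is added,
#' restricted to candidates meeting `ppv_target` in that slice whenever any
#' candidate attains it. Candidate sets are scored with seeded 5-fold
#' out-of-fold logistic scores (fast, and avoids optimistic in-sample PPV).
#' Selection stops when the marginal sensitivity gain falls below `tol` or
#' `max_features` is reached. Ties prefer the lexicographically smaller
#' feature name.
#'
#' @param X Numeric matrix (patients x features) with column names.
#' @param y Binary outcome vector.
#' @param review_fraction Fraction of the subgroup reviewed (flagged) when
#'   measuring sensitivity and PPV, in (0,1).
#' @param ppv_target Required PPV in the reviewed slice, in (0,1).
#' @param seed Seed for the fold assignment.
#' @param max_features Cap on the number of selected features.
#' @param tol Minimum sensitivity gain to keep adding features.
#' @param n_folds Number of cross-validation folds.
#' @return Character vector of selected feature names, in selection order.
#' @export
select_features <- function(X, y, review_fraction = 0.2, ppv_target = 0.7,
                            seed = 1L, max_features = 12L, tol = 0.002,
                            n_folds = 5L) {
  stopifnot(is.matrix(X), !is.null(colnames(X)))
  if (review_fraction <= 0 || review_fraction >= 1)
    stop("review_fraction must be in (0,1)", call. = FALSE)
  if (ppv_target <= 0 || ppv_target >= 1)
    stop("ppv_target must be in (0,1)", call. = FALSE)
  if (length(unique(y)) < 2L)
    stop("subgroup must contain both cases and controls", call. = FALSE)
  folds <- withr::with_seed(seed,
    sample(rep_len(seq_len(n_folds), length(y))))
  candidates <- sort(colnames(X))
  selected <- character(0)
  best_sens <- review_fraction  # random-flagging baseline for the empty set
  repeat {
    remaining <- setdiff(candidates, selected)
    if (length(remaining) == 0L || length(selected) >= max_features) break
    sens <- ppv <- setNames(numeric(length(remaining)), remaining)
    for (f in remaining) {
      sc <- oof_logistic_scores(X, y, c(selected, f), folds)
      m <- top_slice_metrics(sc, y, review_fraction)
      sens[f] <- m$sens
      ppv[f] <- m$ppv
    }
    pool <- if (any(ppv >= ppv_target)) names(ppv)[ppv >= ppv_target]
            else remaining
    pick <- pool[order(-sens[pool], pool)][1L]
    gain <- sens[pick] - best_sens
    if (gain < tol) {
      if (length(selected) == 0L) {
        warning("no feature improves over the empty set; returning the single ",
                "best feature", call. = FALSE)
        selected <- pick
      }
      break
    }
    selected <- c(selected, pick)
    best_sens <- sens[pick]
  }
  selected
}

#' Default forest hyperparameters
#'
#' 100 trees on bootstrap resamples of 80% of the subgroup, depth capped at 8,
#' at least 25 patients per leaf, log-rank splitting.
#'
#' @return A named list: `n_trees`, `max_depth`, `min_leaf`,
#'   `bootstrap_fraction`, `split_rule` (`"logrank"` or `"gini"`).
#' @export
default_hyperparams <- function() {
  list(n_trees = 100L, max_depth = 8L, min_leaf = 25L,
       bootstrap_fraction = 0.8, split_rule = "logrank")
}

#' Fit a subgroup survival-tree forest
#'
#' Fits `n_trees` trees on seeded bootstrap resamples of the subgroup. The
#' split criterion is the two-sample log-rank statistic on
#' (`time_to_event`, `event`) restricted to the horizon; each leaf predicts its
#' empirical within-horizon event fraction and the forest score is the mean
#' over trees. A plain classification mode (Gini splitting on the event
#' indicator) is available via `split_rule = "gini"`. A degenerate subgroup
#' (single outcome class) yields a constant model emitting its event fraction.
#'
#' @param X Numeric feature matrix with column names.
#' @param day Integer days to event or censoring, in `1..horizon`.
#' @param event Binary event indicators.
#' @param selected_features Feature names used for splitting.
#' @param hyperparams List overriding [default_hyperparams()]:
#'   `n_trees`, `max_depth`, `min_leaf`, `bootstrap_fraction`, `split_rule`.
#' @param seed Integer seed for the bootstrap resamples.
#' @param horizon Restriction horizon in days (default the max of `day`).
#' @param subgroup_id Label stored with the model.
#' @return An object of class `subgroup_model`.
#' @export
train_subgroup_model <- function(X, day, event, selected_features,
                                 hyperparams = list(), seed = 1L,
                                 horizon = max(day), subgroup_id = "subgroup") {
  hp <- utils::modifyList(default_hyperparams(), hyperparams)
  base <- list(subgroup_id = subgroup_id, features = selected_features,
               hyperparams = hp, seed = as.integer(seed),
               horizon = as.integer(horizon))
  if (length(unique(event)) < 2L || length(selected_features) == 0L) {
    base$constant <- mean(event)
    base$trees <- NULL
    return(structure(base, class = "subgroup_model"))
  }
  missing <- setdiff(selected_features, colnames(X))
  if (length(missing))
    stop("features not in X: ", paste(missing, collapse = ", "), call. = FALSE)
  Xs <- X[, selected_features, drop = FALSE]
  storage.mode(Xs) <- "double"
  trees <- fit_forest_cpp(Xs, as.integer(day), as.integer(event),
                          as.integer(horizon), as.integer(hp$n_trees),
                          as.integer(hp$max_depth), as.integer(hp$min_leaf),
                          hp$bootstrap_fraction,
                          if (hp$split_rule == "gini") 1L else 0L,
                          as.integer(seed))
  base$constant <- NULL
  base$trees <- trees
  structure(base, class = "subgroup_model")
}

predict_subgroup_model <- function(model, X, strict = FALSE) {
  n <- nrow(X)
  if (!is.null(model$constant)) return(rep(model$constant, n))
  missing <- setdiff(model$features, colnames(X))
  if (length(missing) && strict)
    stop("feature schema mismatch; missing feature(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  Xs <- matrix(0, n, length(model$features),
               dimnames = list(NULL, model$features))
  have <- intersect(model$features, colnames(X))
  Xs[, have] <- X[, have, drop = FALSE]
  storage.mode(Xs) <- "double"
  predict_forest_cpp(model$trees, Xs)
}

#' Train the full hybrid risk model
#'
#' Routes the training rows through the deterministic partition, then per
#' subgroup runs [select_features()] followed by [train_subgroup_model()].
#'
#' @param fm An `ed_feature_matrix`.
#' @param rows Logical or integer index of training rows (Cohort I); default
#'   all rows.
#' @param params List of tuning values: `review_fraction`, `ppv_target`,
#'   `max_features`, `tol` for selection, plus the hyperparameters of
#'   [default_hyperparams()].
#' @param seed Integer seed (fanned out per subgroup by fixed offsets).
#' @return An object of class `risk_model` with one `subgroup_model` per
#'   partition cell.
#' @export
train_risk_model <- function(fm, rows = NULL, params = list(), seed = 1L) {
  stopifnot(inherits(fm, "ed_feature_matrix"))
  if (is.null(rows)) rows <- seq_along(fm$patient_id)
  tr <- fm_subset(fm, rows)
  sel_par <- list(review_fraction = params$review_fraction %||% 0.2,
                  ppv_target = params$ppv_target %||% 0.7,
                  max_features = params$max_features %||% 12L,
                  tol = params$tol %||% 0.002)
  hp <- params[intersect(names(params), names(default_hyperparams()))]
  sg <- partition_subgroup(tr$prior_ed_count, tr$chronic_flag)
  submodels <- list()
  for (k in seq_along(subgroup_ids())) {
    id <- subgroup_ids()[k]
    i <- sg == id
    sub_seed <- seed + 1000L * k
    if (!any(i)) {
      submodels[[id]] <- structure(
        list(subgroup_id = id, features = character(0),
             hyperparams = utils::modifyList(default_hyperparams(), hp),
             seed = sub_seed, horizon = fm$horizon, constant = mean(tr$event),
             trees = NULL),
        class = "subgroup_model")
      next
    }
    Xi <- tr$X[i, , drop = FALSE]
    yi <- tr$outcome[i]
    feats <- if (length(unique(yi)) < 2L) character(0) else
      select_features(Xi, yi,
                      review_fraction = sel_par$review_fraction,
                      ppv_target = sel_par$ppv_target,
                      seed = sub_seed,
                      max_features = sel_par$max_features,
                      tol = sel_par$tol)
    submodels[[id]] <- train_subgroup_model(
      Xi, tr$time_to_event[i], tr$event[i], feats,
      hyperparams = hp, seed = sub_seed, horizon = fm$horizon,
      subgroup_id = id)
  }
  structure(list(submodels = submodels,
                 feature_names = colnames(fm$X),
                 params = params, seed = as.integer(seed),
                 horizon = fm$horizon),
            class = "risk_model")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Score patients with a fitted risk model
#'
#' Routes each row through the deterministic partition and the matching
#' subgroup forest. Features are matched by name; a feature absent from the
#' input is treated as 0 unless `strict = TRUE`, in which case a schema error
#' names the missing features.
#'
#' @param model A `risk_model`.
#' @param fm An `ed_feature_matrix` (or any list with elements `X`,
#'   `prior_ed_count`, `chronic_flag`).
#' @param rows Optional row index to score (default all).
#' @param strict Error on missing feature columns instead of filling 0.
#' @return Numeric vector of raw scores in `[0, 1]`.
#' @export
score_patients <- function(model, fm, rows = NULL, strict = FALSE) {
  if (!inherits(model, "risk_model"))
    stop("model is not a fitted 'risk_model'", call. = FALSE)
  if (!is.null(rows)) fm <- fm_subset(fm, rows)
  sg <- partition_subgroup(fm$prior_ed_count, fm$chronic_flag)
  out <- numeric(length(sg))
  for (id in subgroup_ids()) {
    i <- sg == id
    if (!any(i)) next
    out[i] <- predict_subgroup_model(model$submodels[[id]],
                                     fm$X[i, , drop = FALSE], strict = strict)
  }
  pmin(pmax(out, 0), 1)
}

#' @export
predict.risk_model <- function(object, newdata, ...) {
  score_patients(object, newdata, ...)
}

#' @export
print.risk_model <- function(x, ...) {
  cat("Hybrid ED risk model (2x2 empirical partition + survival forests)\n")
  for (id in names(x$submodels)) {
    m <- x$submodels[[id]]
    if (!is.null(m$constant))
      cat(sprintf("  %-13s constant model, event fraction %.3f\n", id, m$constant))
    else
      cat(sprintf("  %-13s %d trees on %d features: %s\n", id,
                  length(m$trees), length(m$features),
                  paste(m$features, collapse = ", ")))
  }
  invisible(x)
}
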