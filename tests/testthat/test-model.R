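test_that("the 2x2 empirical partition is total and matches its definition", {
  expect_equal(partition_subgroup(3, 0), "EDpos_CHRneg")
  expect_equal(partition_subgroup(0, 1), "EDneg_CHRpos")
  grid <- expand.grid(ed = c(0, 2), chr = c(0, 1))
  got <- partition_subgroup(grid$ed, grid$chr)
  expect_setequal(got, c("EDpos_CHRpos", "EDpos_CHRneg",
                         "EDneg_CHRpos", "EDneg_CHRneg"))
  expect_equal(length(unique(got)), 4L)
})

test_that("a perfect predictor is selected alone with PPV 1", {
  set.seed(21)
  n <- 300
  y <- rbinom(n, 1, 0.3)
  X <- cbind(exact = y, matrix(rnorm(n * 8), n, 8,
                               dimnames = list(NULL, sprintf("noise%d", 1:8))))
  sel <- select_features(X, y, review_fraction = mean(y), ppv_target = 0.7,
                         seed = 1)
  expect_equal(sel, "exact")
  ## PPV in the reviewed slice is 1: all flagged patients are cases
  folds <- withr::with_seed(1, sample(rep_len(1:5, n)))
  sc <- edcasefinder:::oof_logistic_scores(X, y, "exact", folds)
  m <- edcasefinder:::top_slice_metrics(sc, y, mean(y))
  expect_equal(m$ppv, 1)
})

test_that("all-noise features stop at the cap with near-baseline sensitivity", {
  set.seed(31)
  n <- 400
  y <- rbinom(n, 1, 0.3)
  X <- matrix(rnorm(n * 15), n, 15,
              dimnames = list(NULL, sprintf("noise%02d", 1:15)))
  sel <- suppressWarnings(
    select_features(X, y, review_fraction = 0.3, ppv_target = 0.7,
                    seed = 2, max_features = 3, tol = 0))
  expect_lte(length(sel), 3L)
  expect_gte(length(sel), 1L)
  folds <- withr::with_seed(2, sample(rep_len(1:5, n)))
  sc <- edcasefinder:::oof_logistic_scores(X, y, sel, folds)
  m <- edcasefinder:::top_slice_metrics(sc, y, 0.3)
  expect_lt(abs(m$sens - 0.3), 0.12)
})

test_that("degenerate subgroups produce constant models", {
  X <- cbind(a = rnorm(40))
  all_case <- train_subgroup_model(X, day = sample(1:180, 40, TRUE),
                                   event = rep(1L, 40),
                                   selected_features = "a", horizon = 180)
  expect_equal(edcasefinder:::predict_subgroup_model(all_case, X),
               rep(1, 40))
  mixed_rate <- train_subgroup_model(X, day = rep(180L, 40),
                                     event = rep(0L, 40),
                                     selected_features = "a", horizon = 180)
  expect_equal(edcasefinder:::predict_subgroup_model(mixed_rate, X),
               rep(0, 40))
})

test_that("forest refit with the same data and seed is identical", {
  set.seed(41)
  n <- 500
  X <- cbind(x1 = rpois(n, 2), x2 = rnorm(n))
  p <- plogis(-2 + 0.8 * X[, "x1"])
  event <- rbinom(n, 1, p)
  day <- ifelse(event == 1, sample(1:180, n, TRUE), 180L)
  m1 <- train_subgroup_model(X, day, event, c("x1", "x2"),
                             hyperparams = list(n_trees = 20), seed = 7,
                             horizon = 180)
  m2 <- train_subgroup_model(X, day, event, c("x1", "x2"),
                             hyperparams = list(n_trees = 20), seed = 7,
                             horizon = 180)
  expect_identical(m1$trees, m2$trees)
  m3 <- train_subgroup_model(X, day, event, c("x1", "x2"),
                             hyperparams = list(n_trees = 20), seed = 8,
                             horizon = 180)
  expect_false(identical(m1$trees, m3$trees))
})

test_that("forest scores rise across tertiles of a planted risk driver", {
  set.seed(43)
  n <- 3000
  X <- cbind(driver = rnorm(n), junk = rnorm(n))
  p <- plogis(-2 + 1.5 * X[, "driver"])
  event <- rbinom(n, 1, p)
  day <- ifelse(event == 1, pmax(1L, as.integer(180 * runif(n)^(1 + p))), 180L)
  m <- train_subgroup_model(X, day, event, c("driver", "junk"),
                            hyperparams = list(n_trees = 50), seed = 3,
                            horizon = 180)
  sc <- edcasefinder:::predict_subgroup_model(m, X)
  tert <- cut(X[, "driver"], quantile(X[, "driver"], c(0, 1/3, 2/3, 1)),
              include.lowest = TRUE)
  means <- tapply(sc, tert, mean)
  expect_true(all(diff(means) > 0))
  expect_true(all(sc >= 0 & sc <= 1))
})

test_that("a depth-1 tree predicts exactly what manual traversal gives", {
  set.seed(47)
  n <- 200
  X <- cbind(x = rnorm(n))
  event <- as.integer(X[, "x"] > 0.2)
  day <- ifelse(event == 1, 20L, 180L)
  m <- train_subgroup_model(X, day, event, "x",
                            hyperparams = list(n_trees = 1, max_depth = 1,
                                               min_leaf = 5,
                                               bootstrap_fraction = 1),
                            seed = 11, horizon = 180)
  tree <- m$trees[[1]]
  expect_equal(nrow(tree), 3L)     # root + two leaves
  thr <- tree[1, "thr"]
  manual <- ifelse(X[, "x"] <= thr, tree[tree[1, "left"], "value"],
                   tree[tree[1, "right"], "value"])
  expect_equal(edcasefinder:::predict_subgroup_model(m, X), unname(manual))
})

test_that("the split log-rank statistic agrees with survival::survdiff", {
  set.seed(53)
  for (rep in 1:5) {
    n <- 120
    day <- sample(1:180, n, replace = TRUE)
    event <- rbinom(n, 1, 0.6)
    group <- rbinom(n, 1, 0.5)
    if (length(unique(group)) < 2) next
    ours <- edcasefinder:::logrank_stat_cpp(as.integer(day),
                                            as.integer(event),
                                            as.integer(group), 180L)
    ref <- survival::survdiff(survival::Surv(day, event) ~ group)
    expect_equal(ours, unname(ref$chisq), tolerance = 1e-8)
  }
})

test_that("scoring routes by feature name, not column position", {
  cohort <- shared_cohort()
  fm <- cohort$fm
  rows <- seq_len(2000)
  model <- suppressWarnings(
    train_risk_model(fm, rows,
                     params = list(n_trees = 20, max_features = 4), seed = 5))
  sc1 <- score_patients(model, fm, 2001:2500)
  fm_perm <- fm
  perm <- rev(seq_len(ncol(fm$X)))
  fm_perm$X <- fm$X[, perm]
  fm_perm$feature_meta <- fm$feature_meta[perm, ]
  sc2 <- score_patients(model, fm_perm, 2001:2500)
  expect_identical(sc1, sc2)
  expect_true(all(sc1 >= 0 & sc1 <= 1))
})

test_that("strict scoring reports missing features by name", {
  cohort <- shared_cohort()
  fm <- cohort$fm
  model <- suppressWarnings(
    train_risk_model(fm, seq_len(1500),
                     params = list(n_trees = 5, max_features = 3), seed = 5))
  used <- unlist(lapply(model$submodels, `[[`, "features"))
  drop <- used[1]
  fm2 <- fm
  keep <- setdiff(colnames(fm$X), drop)
  fm2$X <- fm$X[, keep]
  expect_error(score_patients(model, fm2, strict = TRUE), drop, fixed = TRUE)
  ## non-strict treats the absent feature as zero and still scores
  sc <- score_patients(model, fm2)
  expect_true(all(sc >= 0 & sc <= 1))
})

test_that("models survive a JSON round trip with identical scores", {
  cohort <- shared_cohort()
  fm <- cohort$fm
  model <- suppressWarnings(
    train_risk_model(fm, seq_len(1500),
                     params = list(n_trees = 10, max_features = 3), seed = 6))
  sc_mem <- score_patients(model, fm, 1501:2000)
  map <- fit_calibration(sc_mem, fm$outcome[1501:2000], min_cell = 10)
  path <- withr::local_tempfile(fileext = ".json")
  save_risk_model(model, path, calibration = map)
  back <- load_risk_model(path)
  sc_disk <- score_patients(back$model, fm, 1501:2000)
  expect_equal(sc_disk, sc_mem, tolerance = 1e-12)
  expect_equal(back$calibration$knots, map$knots, tolerance = 1e-12)
})
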