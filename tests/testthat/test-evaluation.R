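brute_force_auc <- function(scores, labels) {
  cases <- scores[labels == 1]
  controls <- scores[labels == 0]
  tot <- 0
  for (a in cases) tot <- tot + sum(a > controls) + 0.5 * sum(a == controls)
  tot / (length(cases) * length(controls))
}

test_that("AUC handles perfect ranking and complete ties", {
  expect_equal(roc_auc(c(0.9, 0.1), c(1, 0))$auc, 1.0)
  expect_equal(roc_auc(rep(0.5, 10), rep(c(0, 1), 5))$auc, 0.5)
  expect_error(roc_auc(c(0.1, 0.9), c(1, 1)), "both classes")
})

test_that("trapezoid AUC equals brute-force pair counting with ties", {
  set.seed(81)
  for (rep in 1:20) {
    n <- sample(20:200, 1)
    scores <- sample(round(runif(n), 2))  # plenty of ties
    labels <- rbinom(n, 1, 0.4)
    if (length(unique(labels)) < 2) next
    expect_equal(roc_auc(scores, labels)$auc, brute_force_auc(scores, labels),
                 tolerance = 1e-12)
  }
})

test_that("the PPV table reproduces printed-count arithmetic", {
  ## 16,727 flagged at threshold 50 of whom 9,459 are true -> 56.55% / 43.45%
  idx <- c(rep(60, 16727), rep(10, 5000))
  lab <- c(rep(1, 9459), rep(0, 16727 - 9459), rep(0, 5000))
  tab <- ppv_table(idx, lab, thresholds = 50)
  expect_equal(tab$n_flagged, 16727)
  expect_equal(round(tab$ppv, 2), 56.55)
  expect_equal(round(tab$false_flag_rate, 2), 43.45)
  ## 3,780 flagged with 839 non-events -> false-flag 22.20%
  idx2 <- c(rep(75, 3780), rep(10, 1000))
  lab2 <- c(rep(1, 3780 - 839), rep(0, 839), rep(1, 1000))
  tab2 <- ppv_table(idx2, lab2, thresholds = 70)
  expect_equal(round(tab2$false_flag_rate, 2), 22.20)
  ## threshold 0 flags everyone: PPV equals prevalence
  tab3 <- ppv_table(idx2, lab2, thresholds = 0)
  expect_equal(tab3$ppv, 100 * mean(lab2))
  ## internal consistency and the empty-flag marker
  expect_equal(tab2$n_true + tab2$n_false, tab2$n_flagged)
  tab4 <- ppv_table(c(10, 20), c(1, 0), thresholds = 90)
  expect_true(is.na(tab4$ppv))
  expect_equal(tab4$n_flagged, 0L)
})

test_that("KM without censoring equals the empirical survival function", {
  set.seed(83)
  t <- sample(1:50, 60, replace = TRUE)
  km <- km_curve(t, rep(1L, 60), rep("all", 60))$all
  for (i in seq_len(nrow(km)))
    expect_equal(km$survival[i], mean(t > km$day[i]))
})

test_that("KM matches the hand-computed product limit on the toy table", {
  ## times 2, 3, 3, 5 with events 1, 1, 0, 1:
  ## S(2) = 3/4; at t=3 risk 3, one event -> 3/4 * 2/3 = 1/2; at t=5 -> 0
  km <- km_curve(c(2, 3, 3, 5), c(1, 1, 0, 1), rep("g", 4))$g
  expect_equal(km$day, c(2, 3, 5))
  expect_equal(km$survival, c(0.75, 0.5, 0), tolerance = 1e-12)
  ## curves are non-increasing and bounded by 1
  expect_true(all(diff(km$survival) <= 0))
  expect_true(all(km$survival <= 1))
})

test_that("a group with no events stays at survival 1", {
  km <- km_curve(c(10, 20, 180), c(0, 0, 0), rep("quiet", 3))$quiet
  expect_true(all(km$survival == 1))
})

test_that("log-rank statistic matches the hand worksheet and is symmetric", {
  ## worksheet: A times (1, 2) both events, B times (2, 3) both events
  ## day 1: Y=4, Ya=2, d=1 (A): E_A = 0.5,  V = 1*2*2*3/(16*3) = 0.25
  ## day 2: Y=3, Ya=1, d=2:     E_A = 2/3,  V = 2*1*2*1/(9*2)  = 2/9
  ## day 3: Ya=0: no contribution
  ## O_A = 2, E_A = 7/6, V = 17/36 -> chi2 = (5/6)^2 / (17/36) = 25/17
  lr <- logrank_test(c(1, 2, 2, 3), c(1, 1, 1, 1), c("A", "A", "B", "B"))
  expect_equal(lr$statistic, 25 / 17, tolerance = 1e-9)
  expect_equal(lr$df, 1L)
  expect_equal(lr$p_value, pchisq(25 / 17, 1, lower.tail = FALSE))

  ## identical event-time multisets give statistic 0
  lr0 <- logrank_test(c(3, 7, 9, 3, 7, 9), c(1, 1, 0, 1, 1, 0),
                      rep(c("x", "y"), each = 3))
  expect_equal(lr0$statistic, 0, tolerance = 1e-12)

  ## invariant to renaming the groups
  set.seed(87)
  t <- sample(1:180, 90, TRUE); e <- rbinom(90, 1, 0.5)
  g <- sample(c("low", "medium", "high"), 90, TRUE)
  g2 <- c(low = "g3", medium = "g1", high = "g2")[g]
  expect_equal(logrank_test(t, e, g)$statistic,
               logrank_test(t, e, g2)$statistic, tolerance = 1e-12)
  expect_error(logrank_test(t, e, rep("one", 90)), "2 non-empty groups")
})

test_that("per-group ED means are plain arithmetic means", {
  m <- mean_ed_by_group(c(0, 2, 4, 1, 1), c("a", "a", "a", "b", "b"))
  expect_equal(unname(m["a"]), 2.0)
  expect_equal(unname(m["b"]), 1.0)
  expect_equal(unname(mean_ed_by_group(rep(0, 5), rep("z", 5))["z"]), 0)
  expect_error(mean_ed_by_group(c(-1, 2), c("a", "b")), "non-negative")
})

test_that("risk groups separate in time-to-event and utilization on synthetic data", {
  cohort <- shared_cohort()
  fm <- cohort$fm
  s <- stratify_six_subgroups(fm)
  sp <- split_cohorts(fm$patient_id, s, fm$outcome, seed = 61)
  r1 <- which(sp$cohort == "I"); r2 <- which(sp$cohort == "II")
  r3 <- which(sp$cohort == "III")
  model <- suppressWarnings(
    train_risk_model(fm, r1, params = list(n_trees = 40, max_features = 5),
                     seed = 62))
  map <- fit_calibration(score_patients(model, fm, r2), fm$outcome[r2],
                         min_cell = 25)
  fm3 <- edcasefinder:::fm_subset(fm, r3)
  ev <- suppressWarnings(evaluate_risk(fm3, score_patients(model, fm, r3), map))
  ## higher-risk groups visit the ED earlier ...
  expect_lt(ev$logrank$p_value, 0.001)
  ## ... and more often
  m <- ev$mean_ed_by_group[c("low", "medium", "high")]
  m <- m[!is.na(m)]
  expect_true(all(diff(m) > 0))
  ## and KM curves are valid survival curves
  for (g in names(ev$km_curves)) {
    expect_true(all(diff(ev$km_curves[[g]]$survival) <= 1e-12))
    expect_true(all(ev$km_curves[[g]]$survival >= 0 &
                      ev$km_curves[[g]]$survival <= 1))
  }
})

test_that("shrunken differences match direct formula evaluation", {
  ## two balanced classes, means 0 and 1, within-class SS of 50 each:
  ## pooled s = sqrt(100/98); s0 = s (single feature);
  ## m_k = sqrt(1/50 + 1/100); d_0 = (0 - 0.5) / (m_k * 2 s)
  x <- c(rep(c(-1, 1), 25), rep(c(0, 2), 25))
  cls <- rep(c("c0", "c1"), each = 50)
  X <- cbind(feat = x)
  d <- shrunken_difference(X, cls)
  s <- sqrt(100 / 98)
  mk <- sqrt(1 / 50 + 1 / 100)
  expect_equal(unname(d["feat", "c0"]), (0 - 0.5) / (mk * 2 * s),
               tolerance = 1e-12)
  expect_equal(unname(d["feat", "c1"]), (1 - 0.5) / (mk * 2 * s),
               tolerance = 1e-12)

  ## a feature identical across classes scores 0 everywhere
  X2 <- cbind(flat = rep(c(1, 2), 50), feat = x)
  d2 <- shrunken_difference(X2, cls)
  expect_equal(unname(d2["flat", ]), c(c0 = 0, c1 = 0), ignore_attr = TRUE)

  ## shrinkage beyond max |d| zeroes the matrix
  d3 <- shrunken_difference(X, cls, shrinkage = max(abs(d)) + 1)
  expect_true(all(d3 == 0))

  ## monotone in effect size at fixed SD and n
  x_small <- c(rep(c(-1, 1), 25), rep(c(-0.5, 1.5), 25))
  d_small <- shrunken_difference(cbind(feat = x_small), cls)
  expect_lt(max(abs(d_small)), max(abs(d)))
})
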