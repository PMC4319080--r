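test_that("pivot table computes outcome, censoring and prior ED from the right windows", {
  fm <- build_pivot_table(manual_population())
  i1 <- which(fm$patient_id == "P1")
  i2 <- which(fm$patient_id == "P2")
  i3 <- which(fm$patient_id == "P3")
  expect_equal(fm$prior_ed_count[i1], 3)
  expect_equal(fm$outcome[i1], 1L)
  expect_equal(fm$time_to_event[i1], 42L)

  expect_equal(fm$outcome[i2], 0L)
  expect_equal(fm$time_to_event[i2], 180L)
  expect_equal(fm$event[i2], 0L)

  ## new patient: no observation-window records, all-zero features, retained
  expect_equal(unname(fm$X[i3, setdiff(colnames(fm$X),
                                       c("age_19_34", "age_35_49", "age_0_18",
                                         "age_50_", "gender_female",
                                         "zip_income", "zip_education"))]),
               rep(0, ncol(fm$X) - 7))
  expect_equal(fm$outcome[i3], 1L)
  expect_equal(fm$time_to_event[i3], 1L)

  ## chronic structure: P2 carries diabetes (endocrine) + hypertension
  ## (circulatory) + heart failure (circulatory)
  expect_equal(fm$chronic_flag, c(0L, 1L, 0L))
  expect_equal(unname(fm$X[i2, "n_chronic_categories"]), 2)
  expect_equal(unname(fm$X[i2, "chronic_endocrine_immune"]), 1)
  expect_equal(unname(fm$X[i2, "chronic_circulatory"]), 1)

  ## no missing values anywhere
  expect_false(anyNA(fm$X))
})

test_that("windows must not overlap", {
  pop <- manual_population()
  expect_error(
    build_pivot_table(pop,
                      observation_window = as.Date(c("2012-01-01", "2013-01-10")),
                      outcome_window = as.Date(c("2013-01-01", "2013-06-29"))),
    "overlap")
})

test_that("dummy column sums recount the raw records", {
  cohort <- shared_cohort()
  fm <- cohort$fm
  pop <- cohort$excluded$population
  idx <- pop$config$index_date
  enc <- pop$encounters
  obs <- enc[enc$date < idx & enc$date >= idx - pop$config$observation_days, ]
  ## brute-force recount of observation-window ED encounters
  expect_equal(sum(fm$X[, "enc_ED"]), sum(obs$kind == "ED"))
  expect_equal(sum(fm$X[, "enc_inpatient"]), sum(obs$kind == "inpatient"))
  ## exclusive age dummies sum to exactly 1 per row
  age_cols <- grep("^age_", colnames(fm$X), value = TRUE)
  expect_equal(unname(rowSums(fm$X[, age_cols])), rep(1, nrow(fm$X)))
})

test_that("outcome-window records never leak into features", {
  pop <- manual_population()
  fm0 <- build_pivot_table(pop)
  ## delete all outcome-window records
  idx <- pop$config$index_date
  pop2 <- pop
  pop2$encounters <- pop$encounters[pop$encounters$date < idx, , drop = FALSE]
  fm1 <- build_pivot_table(pop2)
  expect_identical(fm0$X, fm1$X)
  ## and permuting outcome-window rows changes nothing either
  pop3 <- pop
  out_rows <- which(pop$encounters$date >= idx)
  pop3$encounters <- rbind(pop$encounters[-out_rows, ],
                           pop$encounters[rev(out_rows), ])
  fm2 <- build_pivot_table(pop3)
  expect_identical(fm0$X, fm2$X)
})

test_that("age groups bin on inclusive lower edges and reject negatives", {
  expect_equal(assign_age_group(c(0, 18, 19, 34, 35, 49, 50, 90)),
               c("0-18", "0-18", "19-34", "19-34", "35-49", "35-49",
                 "50+", "50+"))
  expect_error(assign_age_group(-1), "non-negative")
})

test_that("chronic dichotomy follows the lookup with a conservative default", {
  expect_equal(flag_chronic("250"), "chronic")        # diabetes
  expect_equal(flag_chronic("845"), "non_chronic")    # sprain
  expect_warning(out <- flag_chronic("V99"), "V99")
  expect_equal(out, "non_chronic")
  expect_equal(suppressWarnings(flag_chronic(c("250", "zzz", "845"))),
               c("chronic", "non_chronic", "non_chronic"))
})

test_that("variance filter keeps the top-variance features", {
  set.seed(5)
  X <- cbind(matrix(rnorm(200), 20, 10))
  colnames(X) <- sprintf("f%02d", 1:10)
  fm <- make_fm(X)
  ## brute force: min-max scale each column, rank variances
  scaled <- apply(X, 2, function(col) (col - min(col)) / (max(col) - min(col)))
  expected <- names(sort(apply(scaled, 2, var), decreasing = TRUE))[1:3]
  got <- variance_filter(fm, 3)
  expect_setequal(colnames(got$X), expected)

  ## constant column is always dropped first
  Xc <- cbind(X, constant = 5)
  fmc <- make_fm(Xc)
  expect_false("constant" %in% colnames(variance_filter(fmc, 10)$X))

  ## ties break lexicographically
  Xt <- cbind(bbb = c(0, 1, 0, 1), aaa = c(1, 0, 1, 0), ccc = c(0, 0, 0, 1))
  fmt <- make_fm(Xt)
  expect_true("aaa" %in% colnames(variance_filter(fmt, 1)$X))

  ## idempotence and the keep_n >= p identity
  once <- variance_filter(fm, 4)
  expect_identical(variance_filter(once, 4), once)
  expect_identical(variance_filter(fm, 99), fm)
})

test_that("empirical routing features survive the variance filter", {
  X <- cbind(noise1 = rnorm(50), noise2 = rnorm(50),
             prior_ed_count = rep(0, 50), chronic_flag = rep(0, 50))
  fm <- make_fm(X)
  got <- variance_filter(fm, 1)
  expect_true(all(c("prior_ed_count", "chronic_flag") %in% colnames(got$X)))
})
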