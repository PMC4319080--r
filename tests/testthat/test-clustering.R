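adjusted_rand <- function(a, b) {
  tab <- table(a, b)
  n <- sum(tab)
  sum_comb <- function(x) sum(choose(x, 2))
  sij <- sum_comb(tab)
  si <- sum_comb(rowSums(tab))
  sj <- sum_comb(colSums(tab))
  expected <- si * sj / choose(n, 2)
  (sij - expected) / ((si + sj) / 2 - expected)
}

test_that("rank-1 data reduces to one component explaining everything", {
  v <- rnorm(5)
  X <- outer(seq_len(40), v)   # every row a multiple of v
  red <- reduce_dimensions(X, variance_target = 0.8)
  expect_equal(red$n_components, 1L)
  expect_equal(sum(red$explained_variance), 1.0, tolerance = 1e-9)
})

test_that("variance target 1 retains the numeric rank", {
  set.seed(91)
  B <- matrix(rnorm(100 * 3), 100, 3)
  X <- cbind(B, B[, 1] + B[, 2])  # rank 3 in 4 columns
  red <- reduce_dimensions(X, variance_target = 1.0)
  expect_equal(red$n_components, 3L)
})

test_that("explained variance agrees with direct eigen-decomposition", {
  set.seed(93)
  X <- matrix(rnorm(100 * 10), 100, 10)
  red <- reduce_dimensions(X, variance_target = 1.0)
  ev_eigen <- eigen(cov(scale(X)), symmetric = TRUE)$values
  ev_eigen <- ev_eigen / sum(ev_eigen)
  expect_equal(red$explained_variance, ev_eigen[seq_len(red$n_components)],
               tolerance = 1e-9)
  ## non-increasing by construction
  expect_true(all(diff(red$explained_variance) <= 1e-12))
  expect_error(reduce_dimensions(X[1, , drop = FALSE]), "2 patients")
})

test_that("k = 1 reduces to the total centered sum of squares", {
  set.seed(95)
  Z <- matrix(rnorm(60 * 2), 60, 2)
  km <- kmeans_cluster(Z, k = 1, seed = 1, restarts = 3)
  expect_equal(km$wcss, sum(scale(Z, scale = FALSE)^2), tolerance = 1e-9)
  expect_equal(unique(km$assignments), 1L)
  expect_error(kmeans_cluster(Z, k = 61), "must not exceed")
})

test_that("clustering is deterministic under a fixed seed", {
  set.seed(97)
  Z <- matrix(rnorm(200 * 3), 200, 3)
  k1 <- kmeans_cluster(Z, k = 4, seed = 5, restarts = 10)
  k2 <- kmeans_cluster(Z, k = 4, seed = 5, restarts = 10)
  expect_identical(k1$assignments, k2$assignments)
})

test_that("clusterings from different seeds agree on well-structured data", {
  set.seed(99)
  centers <- matrix(rnorm(6 * 4, sd = 6), 6, 4)
  truth <- rep(1:6, each = 80)
  Z <- centers[truth, ] + matrix(rnorm(480 * 4), 480, 4)
  a1 <- kmeans_cluster(Z, k = 6, seed = 1, restarts = 10)$assignments
  a2 <- kmeans_cluster(Z, k = 6, seed = 2, restarts = 10)$assignments
  expect_gte(adjusted_rand(a1, a2), 0.8)
})

test_that("cluster profiles report exact n/N prevalences", {
  ## a cluster of 795 patients, 590 with the endocrine/immune chronic category
  n <- 795 + 1028
  X <- cbind(chronic_endocrine_immune = c(rep(1, 590), rep(0, 795 - 590),
                                          rep(1, 245), rep(0, 1028 - 245)),
             age_19_34 = 1,
             gender_female = rbinom(n, 1, 0.5),
             lab_glucose = rpois(n, 2),
             rad_xray = rpois(n, 1),
             n_medications = rpois(n, 3))
  fm <- make_fm(X, category = "chronic")
  fm$feature_meta$category <- c("chronic", "age_group", "ses", "lab",
                                "radiology", "medication")
  assignments <- rep(c(2L, 1L), c(795, 1028))
  prof <- profile_clusters(assignments, fm)
  ## ordered by size: cluster 1 is the 1028-patient group
  expect_equal(prof$n, c(1028, 795))
  expect_equal(prof$prev_endocrine_immune,
               c(245 / 1028, 590 / 795), tolerance = 1e-12)
  expect_equal(round(100 * prof$prev_endocrine_immune, 2), c(23.83, 74.21))
  expect_equal(prof$n_endocrine_immune, c(245, 590))
  ## numerators never exceed denominators, sizes sum to the population
  expect_true(all(prof$n_endocrine_immune <= prof$n))
  expect_equal(sum(prof$n), n)
})

test_that("a single-patient cluster with no chronic codes reports zero prevalence", {
  X <- cbind(chronic_circulatory = c(1, 1, 0),
             lab_glucose = c(2, 3, 0))
  fm <- make_fm(X)
  fm$feature_meta$category <- c("chronic", "lab")
  prof <- profile_clusters(c(1L, 1L, 2L), fm)
  solo <- prof[prof$n == 1, ]
  expect_equal(solo$prev_circulatory, 0)
  expect_equal(solo$mean_lab_count, 0)
})

test_that("the high-risk gate is inclusive at the threshold", {
  cohort <- shared_cohort()
  fm <- cohort$fm
  idx <- c(rep(70, 20), rep(10, length(fm$patient_id) - 20))
  res <- cluster_highrisk(fm, idx, k = 3, seed = 1, restarts = 5)
  expect_equal(res$n_highrisk, 20L)
  expect_equal(sum(res$profiles$n), 20L)
  expect_equal(length(res$assignments), 20L)
})
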