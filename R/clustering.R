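# High-risk phenotyping: standardize, project onto leading principal
# components, K-means (K = 6 by default) with greedy farthest-point seeding and
# restarts, then cluster prevalence / resource-consumption profiles.

#' Project features onto leading principal components
#'
#' Centers and unit-scales each feature (constant features are dropped), then
#' keeps the fewest leading components whose cumulative explained variance
#' reaches `variance_target`.
#'
#' @param X Numeric matrix (patients x features), at least two rows.
#' @param variance_target Cumulative explained-variance target in (0, 1].
#' @return A list with `projected` (patients x components), `loadings`
#'   (feature x component weights), `explained_variance` (per retained
#'   component, non-increasing), and `n_components`.
#' @export
reduce_dimensions <- function(X, variance_target = 0.8) {
  if (nrow(X) < 2L)
    stop("at least 2 patients required", call. = FALSE)
  if (variance_target <= 0 || variance_target > 1)
    stop("variance_target must be in (0, 1]", call. = FALSE)
  sdev0 <- apply(X, 2L, sd)
  keep <- sdev0 > 0
  Xs <- scale(X[, keep, drop = FALSE])
  pc <- prcomp(Xs, center = FALSE, scale. = FALSE)
  ev <- pc$sdev^2 / sum(pc$sdev^2)
  ## numeric rank: components with non-degenerate variance
  nz <- pc$sdev^2 > max(pc$sdev^2) * 1e-10
  ncomp <- min(which(cumsum(ev) >= variance_target - 1e-12))
  ncomp <- min(ncomp, sum(nz))
  list(projected = pc$x[, seq_len(ncomp), drop = FALSE],
       loadings = pc$rotation[, seq_len(ncomp), drop = FALSE],
       explained_variance = ev[seq_len(ncomp)],
       n_components = ncomp)
}

farthest_point_centers <- function(Z, k, first) {
  centers <- matrix(NA_real_, k, ncol(Z))
  centers[1L, ] <- Z[first, ]
  mind <- rowSums(sweep(Z, 2L, centers[1L, ], "-")^2)
  if (k > 1L) for (j in 2:k) {
    nxt <- which.max(mind)
    centers[j, ] <- Z[nxt, ]
    d <- rowSums(sweep(Z, 2L, centers[j, ], "-")^2)
    mind <- pmin(mind, d)
  }
  centers
}

#' Seeded K-means with farthest-point initialization
#'
#' Greedy farthest-point seeding: the first center is a seeded random row,
#' each further center the point farthest from those already chosen; the best
#' of `restarts` runs (lowest within-cluster sum of squares) is kept.
#' Deterministic given the seed.
#'
#' @param projected Numeric matrix of projected coordinates.
#' @param k Number of clusters (at most the number of rows).
#' @param seed Integer seed.
#' @param restarts Number of restarts (each with a different first center).
#' @return A list with `assignments` (integer vector), `centers`, `wcss`
#'   (total within-cluster sum of squares), `k`, `seed`.
#' @export
kmeans_cluster <- function(projected, k = 6L, seed = 1L, restarts = 25L) {
  n <- nrow(projected)
  if (k > n) stop("k must not exceed the number of patients", call. = FALSE)
  best <- NULL
  withr::with_seed(seed, {
    firsts <- sample.int(n, min(restarts, n))
    for (f in firsts) {
      centers <- farthest_point_centers(projected, k, f)
      centers <- unique(centers)
      km <- suppressWarnings(
        kmeans(projected, centers = centers, iter.max = 100L))
      if (is.null(best) || km$tot.withinss < best$tot.withinss) best <- km
    }
  })
  list(assignments = as.integer(best$cluster),
       centers = best$centers,
       wcss = best$tot.withinss,
       k = nrow(best$centers),
       seed = as.integer(seed))
}

#' Profile clusters of high-risk patients
#'
#' Per cluster: size, age-band and gender composition, prevalence of each
#' chronic diagnosis-chapter category (with numerator and denominator), and
#' mean lab / radiology / prescription counts. Clusters are ordered by size,
#' largest first, and relabeled 1..k in that order.
#'
#' @param assignments Integer cluster assignment per row of `fm`.
#' @param fm An `ed_feature_matrix` restricted to the profiled (high-risk)
#'   patients.
#' @return A data.frame, one row per cluster.
#' @export
profile_clusters <- function(assignments, fm) {
  stopifnot(inherits(fm, "ed_feature_matrix"),
            length(assignments) == length(fm$patient_id))
  X <- fm$X
  meta <- fm$feature_meta
  sizes <- table(assignments)
  new_order <- as.integer(names(sort(sizes, decreasing = TRUE)))
  relabel <- match(assignments, new_order)
  fam_cols <- paste0("chronic_", dx_families())
  fam_cols <- intersect(fam_cols, colnames(X))
  age_cols <- grep("^age_", colnames(X), value = TRUE)
  count_cols <- list(
    mean_lab_count = meta$name[meta$category == "lab" &
                                 !grepl("^lababn_", meta$name)],
    mean_radiology_count = meta$name[meta$category == "radiology"],
    mean_medication_count = intersect("n_medications", colnames(X)))
  rows <- lapply(seq_along(new_order), function(j) {
    i <- relabel == j
    N <- sum(i)
    row <- data.frame(cluster = j, n = N)
    for (ac in age_cols)
      row[[paste0("share_", ac)]] <- if (N > 0) mean(X[i, ac]) else NA_real_
    row$share_female <- if (N > 0 && "gender_female" %in% colnames(X))
      mean(X[i, "gender_female"]) else NA_real_
    for (fc in fam_cols) {
      num <- if (N > 0) sum(X[i, fc] > 0) else 0L
      row[[paste0("prev_", sub("^chronic_", "", fc))]] <-
        if (N > 0) num / N else NA_real_
      row[[paste0("n_", sub("^chronic_", "", fc))]] <- num
    }
    for (nm in names(count_cols)) {
      cc <- count_cols[[nm]]
      row[[nm]] <- if (N > 0 && length(cc))
        mean(rowSums(X[i, cc, drop = FALSE])) else NA_real_
    }
    row
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Cluster the high-risk population
#'
#' Convenience wrapper: selects patients with risk index at or above the
#' high-risk threshold, reduces dimensions, runs seeded K-means, and profiles
#' the clusters.
#'
#' @param fm An `ed_feature_matrix`.
#' @param indices Risk indices for the rows of `fm`.
#' @param k Number of clusters.
#' @param variance_target Cumulative explained-variance target for the
#'   projection.
#' @param threshold High-risk gate on the index scale (inclusive).
#' @param seed Integer seed.
#' @param restarts K-means restarts.
#' @return A list with `assignments` (named by patient id), `profiles`,
#'   `explained_variance`, `loadings`, `n_highrisk`, `seed`; `NULL` if fewer
#'   than `k` high-risk patients exist.
#' @export
cluster_highrisk <- function(fm, indices, k = 6L, variance_target = 0.8,
                             threshold = 70, seed = 1L, restarts = 25L) {
  hi <- which(indices >= threshold)
  if (length(hi) < k) {
    warning("fewer than k high-risk patients; clustering skipped", call. = FALSE)
    return(NULL)
  }
  fm_hi <- fm_subset(fm, hi)
  red <- reduce_dimensions(fm_hi$X, variance_target)
  km <- kmeans_cluster(red$projected, k = k, seed = seed, restarts = restarts)
  ## relabel by size, largest first, to match the profile ordering
  sizes <- table(km$assignments)
  new_order <- as.integer(names(sort(sizes, decreasing = TRUE)))
  relabeled <- match(km$assignments, new_order)
  profiles <- profile_clusters(km$assignments, fm_hi)
  list(assignments = setNames(relabeled, fm_hi$patient_id),
       profiles = profiles,
       explained_variance = red$explained_variance,
       loadings = red$loadings,
       n_highrisk = length(hi),
       seed = seed)
}
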