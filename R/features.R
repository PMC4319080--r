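# Patient-level pivot table: encounter-level records aggregated into one numeric
# row per patient. Count features for encounter types, diagnoses, labs,
# radiology and medications; indicator features for age group, gender and
# chronic diagnosis categories. Absence is encoded as 0, never NA. All feature
# values come from the observation window only; outcome and time-to-event come
# from the outcome window only (temporal hygiene).

#' Assign one of four age groups
#'
#' @param age_years Numeric vector of ages in years.
#' @return Character vector with levels `0-18`, `19-34`, `35-49`, `50+`
#'   (boundaries inclusive on the lower edge).
#' @export
#' @examples
#' assign_age_group(c(18, 19, 49, 50))
assign_age_group <- function(age_years) {
  if (anyNA(age_years) || any(age_years < 0))
    stop("age must be non-negative", call. = FALSE)
  cut(age_years, breaks = c(-Inf, 18, 34, 49, Inf),
      labels = age_group_levels(), right = TRUE) |> as.character()
}

#' Dichotomize diagnosis codes as chronic or non-chronic
#'
#' Looks codes up in the bundled lookup ([dx_lookup()]). Codes absent from the
#' lookup default to `non_chronic` with a warning (a conservative choice that
#' avoids inflating the chronic stratum).
#'
#' @param dx_code Character vector of diagnosis codes.
#' @return Character vector of `"chronic"` / `"non_chronic"`.
#' @export
flag_chronic <- function(dx_code) {
  lk <- dx_lookup()
  m <- match(dx_code, lk$code)
  unknown <- unique(dx_code[is.na(m) & !is.na(dx_code) & nzchar(dx_code)])
  if (length(unknown))
    warning("unknown diagnosis code(s) treated as non_chronic: ",
            paste(unknown, collapse = ", "), call. = FALSE)
  out <- ifelse(!is.na(m) & lk$chronic[m], "chronic", "non_chronic")
  out[is.na(dx_code)] <- "non_chronic"
  out
}

# counts of feat per patient, aligned to pid_levels; returns n x k matrix
count_matrix <- function(pid_levels, pid, feat, prefix) {
  if (!is.factor(feat)) feat <- factor(feat)
  if (length(pid) == 0L && nlevels(feat) == 0L)
    return(matrix(0, length(pid_levels), 0))
  tab <- table(factor(pid, levels = pid_levels), feat)
  m <- matrix(as.numeric(tab), nrow = length(pid_levels))
  colnames(m) <- paste0(prefix, colnames(tab))
  m
}

split_secondary <- function(pid, secondary_dx) {
  keep <- !is.na(secondary_dx) & nzchar(secondary_dx)
  if (!any(keep)) return(list(pid = character(0), code = character(0)))
  parts <- strsplit(secondary_dx[keep], ";", fixed = TRUE)
  list(pid = rep(pid[keep], lengths(parts)), code = unlist(parts))
}

#' Build the patient x feature pivot table
#'
#' One row per patient in the population. Count and indicator features are
#' computed only from records dated inside the observation window; the binary
#' outcome (any ED visit) and the day of the first ED visit are computed only
#' from the outcome window. Patients with no observation-window records are
#' retained with all-zero features (the new-patient case).
#'
#' @param population An `hie_population` (ideally after [apply_exclusions()]).
#' @param observation_window,outcome_window Optional `Date` vectors of length 2
#'   (inclusive start/end). Defaults derive from the population's config: the
#'   observation window ends the day before the index date, the outcome window
#'   starts at the index date. The outcome window must start after the
#'   observation window ends.
#' @return An object of class `ed_feature_matrix`: patient ids, a numeric
#'   feature matrix `X`, per-feature metadata (`feature_meta` with `name`,
#'   `category`, `source`), the outcome label, time to first outcome-window ED
#'   visit (censored at the window length), the event indicator, the
#'   outcome-window ED visit count, plus `prior_ed_count` and `chronic_flag`.
#' @export
build_pivot_table <- function(population, observation_window = NULL,
                              outcome_window = NULL) {
  if (!inherits(population, "hie_population"))
    stop("population must be an 'hie_population'", call. = FALSE)
  cfg <- population$config
  if (is.null(observation_window)) {
    if (is.null(cfg)) stop("observation_window required when the population has no config",
                           call. = FALSE)
    observation_window <- c(cfg$index_date - cfg$observation_days,
                            cfg$index_date - 1L)
  }
  if (is.null(outcome_window)) {
    if (is.null(cfg)) stop("outcome_window required when the population has no config",
                           call. = FALSE)
    outcome_window <- c(cfg$index_date, cfg$index_date + cfg$outcome_days - 1L)
  }
  if (outcome_window[1L] <= observation_window[2L])
    stop("windows overlap: the outcome window must start after the observation window ends",
         call. = FALSE)

  pats <- population$patients
  ids <- pats$patient_id
  n <- length(ids)
  horizon <- as.integer(outcome_window[2L] - outcome_window[1L]) + 1L

  in_win <- function(d, w) !is.na(d) & d >= w[1L] & d <= w[2L]
  enc <- population$encounters
  obs_enc <- enc[in_win(enc$date, observation_window), , drop = FALSE]
  out_ed <- enc[enc$kind == "ED" & in_win(enc$date, outcome_window), , drop = FALSE]

  ## ---- outcome ----
  out_day <- as.integer(out_ed$date - outcome_window[1L]) + 1L
  first_day <- tapply(out_day, factor(out_ed$patient_id, levels = ids), min)
  ed_count <- tapply(rep(1L, nrow(out_ed)), factor(out_ed$patient_id, levels = ids),
                     sum)
  outcome <- as.integer(!is.na(first_day))
  outcome_ed_count <- ifelse(is.na(ed_count), 0L, as.integer(ed_count))
  time_to_event <- ifelse(outcome == 1L, as.integer(first_day), horizon)
  event <- outcome

  ## ---- observation-window features ----
  visits <- obs_enc[obs_enc$kind %in% c("ED", "inpatient", "outpatient"), ,
                    drop = FALSE]
  enc_counts <- count_matrix(ids, visits$patient_id, visits$encounter_type_code,
                             "enc_")
  pdx <- visits[!is.na(visits$primary_dx) & nzchar(visits$primary_dx), ,
                drop = FALSE]
  pdx_counts <- count_matrix(ids, pdx$patient_id, pdx$primary_dx, "pdx_")
  sdx <- split_secondary(visits$patient_id, visits$secondary_dx)
  sdx_counts <- count_matrix(ids, sdx$pid, sdx$code, "sdx_")

  ## chronic categories from all observation-window diagnoses
  lk <- dx_lookup()
  all_dx_pid <- c(pdx$patient_id, sdx$pid)
  all_dx_code <- c(pdx$primary_dx, sdx$code)
  mi <- match(all_dx_code, lk$code)
  is_chr <- !is.na(mi) & lk$chronic[mi]
  chr_fam_counts <- count_matrix(ids, all_dx_pid[is_chr],
                                 factor(lk$family[mi[is_chr]],
                                        levels = dx_families()),
                                 "chronic_")
  if (ncol(chr_fam_counts) == 0L)
    chr_fam_counts <- matrix(0, n, length(dx_families()),
                             dimnames = list(NULL, paste0("chronic_", dx_families())))
  chr_ind <- 1 * (chr_fam_counts > 0)
  n_chronic_categories <- rowSums(chr_ind)
  chronic_flag <- as.integer(n_chronic_categories > 0)

  labs <- population$labs
  labs <- labs[in_win(labs$date, observation_window), , drop = FALSE]
  lab_counts <- count_matrix(ids, labs$patient_id, labs$lab_name, "lab_")
  lab_abn <- labs[labs$result == "abnormal", , drop = FALSE]
  lab_abn_counts <- count_matrix(ids, lab_abn$patient_id, lab_abn$lab_name,
                                 "lababn_")
  rad <- population$radiology
  rad <- rad[in_win(rad$date, observation_window), , drop = FALSE]
  rad_counts <- count_matrix(ids, rad$patient_id, rad$modality, "rad_")
  med <- population$medications
  med <- med[in_win(med$date, observation_window), , drop = FALSE]
  med_counts <- count_matrix(ids, med$patient_id, med$med_class, "med_")
  n_medications <- rowSums(med_counts)

  age_group <- assign_age_group(pats$age)
  age_dummies <- count_matrix(ids, ids, factor(age_group,
                                               levels = age_group_levels()),
                              "age_")
  colnames(age_dummies) <- paste0("age_", gsub("[-+]", "_", age_group_levels()))
  gender_female <- as.numeric(pats$gender == "F")

  prior_ed_count <- if (ncol(enc_counts) && "enc_ED" %in% colnames(enc_counts))
    as.numeric(enc_counts[, "enc_ED"]) else numeric(n)

  blocks <- list(
    list(m = age_dummies, category = "age_group"),
    list(m = cbind(gender_female = gender_female,
                   zip_income = pats$zip_income,
                   zip_education = pats$zip_education), category = "ses"),
    list(m = enc_counts, category = "encounter_type"),
    list(m = pdx_counts, category = "primary_dx"),
    list(m = sdx_counts, category = "secondary_dx"),
    list(m = cbind(chr_ind,
                   n_chronic_categories = n_chronic_categories,
                   chronic_flag = chronic_flag), category = "chronic"),
    list(m = cbind(lab_counts, lab_abn_counts), category = "lab"),
    list(m = rad_counts, category = "radiology"),
    list(m = cbind(med_counts, n_medications = n_medications),
         category = "medication"),
    list(m = cbind(prior_ed_count = prior_ed_count), category = "encounter_type")
  )
  X <- do.call(cbind, lapply(blocks, `[[`, "m"))
  meta <- data.frame(
    name = colnames(X),
    category = unlist(lapply(blocks, function(b)
      rep(b$category, ncol(b$m)))),
    source = colnames(X),
    stringsAsFactors = FALSE)
  if (anyDuplicated(meta$name))
    stop("internal error: duplicate feature names", call. = FALSE)
  X[is.na(X)] <- 0
  storage.mode(X) <- "double"
  rownames(X) <- NULL

  structure(list(patient_id = ids,
                 X = X,
                 feature_meta = meta,
                 outcome = outcome,
                 time_to_event = as.integer(time_to_event),
                 event = as.integer(event),
                 outcome_ed_count = outcome_ed_count,
                 prior_ed_count = prior_ed_count,
                 chronic_flag = chronic_flag,
                 horizon = horizon),
            class = "ed_feature_matrix")
}

#' @export
print.ed_feature_matrix <- function(x, ...) {
  cat("ED feature matrix:", length(x$patient_id), "patients x",
      ncol(x$X), "features\n")
  cat("  outcome incidence:",
      sprintf("%.2f%%", 100 * mean(x$outcome)), "\n")
  invisible(x)
}

# subset rows of a feature matrix by logical/integer index
fm_subset <- function(fm, i) {
  out <- fm
  out$patient_id <- fm$patient_id[i]
  out$X <- fm$X[i, , drop = FALSE]
  for (f in c("outcome", "time_to_event", "event", "outcome_ed_count",
              "prior_ed_count", "chronic_flag"))
    out[[f]] <- fm[[f]][i]
  out
}

#' Keep the highest-variance features
#'
#' Each column is min-max scaled to `[0, 1]` before its variance is measured so
#' counts and indicators compete on one scale; the `keep_n` highest-variance
#' features are retained (ties broken by feature name), and the empirical
#' routing features `prior_ed_count` and `chronic_flag` are always retained.
#' Filtering an already-filtered matrix with the same `keep_n` is the identity.
#'
#' @param fm An `ed_feature_matrix`.
#' @param keep_n Number of features to keep; if it is not smaller than the
#'   number of features the matrix is returned unchanged.
#' @return A reduced `ed_feature_matrix`.
#' @export
variance_filter <- function(fm, keep_n) {
  stopifnot(inherits(fm, "ed_feature_matrix"))
  if (length(keep_n) != 1L || is.na(keep_n) || keep_n < 1)
    stop("keep_n must be a positive count", call. = FALSE)
  p <- ncol(fm$X)
  if (keep_n >= p) return(fm)
  rng_lo <- apply(fm$X, 2L, min)
  rng_hi <- apply(fm$X, 2L, max)
  span <- rng_hi - rng_lo
  scaled <- sweep(fm$X, 2L, rng_lo, "-")
  nz <- span > 0
  scaled[, nz] <- sweep(scaled[, nz, drop = FALSE], 2L, span[nz], "/")
  v <- apply(scaled, 2L, var)
  v[!nz] <- 0
  ord <- order(-v, colnames(fm$X))
  keep_names <- colnames(fm$X)[ord[seq_len(keep_n)]]
  keep_names <- union(keep_names,
                      intersect(c("prior_ed_count", "chronic_flag"),
                                colnames(fm$X)))
  keep_idx <- which(colnames(fm$X) %in% keep_names)
  out <- fm
  out$X <- fm$X[, keep_idx, drop = FALSE]
  out$feature_meta <- fm$feature_meta[keep_idx, , drop = FALSE]
  rownames(out$feature_meta) <- NULL
  out
}
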