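# Synthetic HIE-style encounter generator. Emulates the structure of a statewide
# health information exchange extract: demographics, dated encounters with
# diagnosis codes and dispositions, labs, medications, radiology, plus a latent
# per-patient 6-month ED event probability (ground truth, never fed to models).

#' Configuration for the synthetic HIE population generator
#'
#' Defaults encode the study conditions the generator is meant to emulate: a
#' ~11.5% marginal 6-month ED incidence, strong ED-visit recurrence (most
#' patients with two or more historical ED visits revisit within the 6-month
#' outcome window), and chronic disease as a major risk driver.
#'
#' @param n_patients Number of patients to simulate.
#' @param index_date Date separating the 12-month observation window (before)
#'   from the 6-month outcome window (from this date on).
#' @param observation_days Length of the history window in days.
#' @param outcome_days Length of the outcome window in days.
#' @param target_incidence Marginal probability of at least one outcome-window
#'   ED visit; the generator calibrates its logistic intercept so the population
#'   mean latent hazard equals this value.
#' @param hazard_coefficients Named log-odds weights for the risk drivers
#'   `prior_ed_count` (capped at 4), `chronic_flag`, `age_group` (ordinal band
#'   0-3), `n_medications` (capped at 10), and `n_chronic_categories`.
#' @param chronic_prevalence Fraction of patients carrying at least one chronic
#'   diagnosis.
#' @param death_rate Fraction of patients given an encounter with disposition
#'   `expired` (these are later excluded by [apply_exclusions()]).
#' @param transfer_rate Fraction of ED visits that get a same-day paired ED
#'   record with disposition `transfer_from_ed` (an ED-to-ED transfer, later
#'   merged into one visit).
#' @param seed Integer seed; identical configurations produce identical output.
#' @return An object of class `synthetic_config`.
#' @export
synthetic_config <- function(n_patients,
                             index_date = as.Date("2013-01-01"),
                             observation_days = 365L,
                             outcome_days = 180L,
                             target_incidence = 0.115,
                             hazard_coefficients = c(prior_ed_count = 2.4,
                                                     chronic_flag = 0.9,
                                                     age_group = 0.3,
                                                     n_medications = 0.1,
                                                     n_chronic_categories = 0.25),
                             chronic_prevalence = 0.35,
                             death_rate = 0.005,
                             transfer_rate = 0.02,
                             seed = 1L) {
  check_count <- function(x, field) {
    if (!is.numeric(x) || length(x) != 1L || is.na(x) || x <= 0 || x != round(x))
      stop("invalid configuration field '", field, "': must be a positive count",
           call. = FALSE)
  }
  check_frac <- function(x, field, open = FALSE) {
    ok <- is.numeric(x) && length(x) == 1L && !is.na(x) &&
      (if (open) x > 0 && x < 1 else x >= 0 && x <= 1)
    if (!ok)
      stop("invalid configuration field '", field, "': must be a fraction in ",
           if (open) "(0,1)" else "[0,1]", call. = FALSE)
  }
  check_count(n_patients, "n_patients")
  check_count(observation_days, "observation_days")
  check_count(outcome_days, "outcome_days")
  check_frac(target_incidence, "target_incidence", open = TRUE)
  check_frac(chronic_prevalence, "chronic_prevalence")
  check_frac(death_rate, "death_rate")
  check_frac(transfer_rate, "transfer_rate")
  if (!inherits(index_date, "Date") || length(index_date) != 1L || is.na(index_date))
    stop("invalid configuration field 'index_date': must be a single Date",
         call. = FALSE)
  needed <- c("prior_ed_count", "chronic_flag", "age_group", "n_medications",
              "n_chronic_categories")
  if (!is.numeric(hazard_coefficients) ||
      !all(needed %in% names(hazard_coefficients)) ||
      anyNA(hazard_coefficients[needed]))
    stop("invalid configuration field 'hazard_coefficients': must be a named ",
         "numeric vector with entries ", paste(needed, collapse = ", "),
         call. = FALSE)
  if (!is.numeric(seed) || length(seed) != 1L || is.na(seed))
    stop("invalid configuration field 'seed': must be a single integer",
         call. = FALSE)
  structure(list(n_patients = as.integer(n_patients),
                 index_date = index_date,
                 observation_days = as.integer(observation_days),
                 outcome_days = as.integer(outcome_days),
                 target_incidence = target_incidence,
                 hazard_coefficients = hazard_coefficients[needed],
                 chronic_prevalence = chronic_prevalence,
                 death_rate = death_rate,
                 transfer_rate = transfer_rate,
                 seed = as.integer(seed)),
            class = "synthetic_config")
}

#' Generate a synthetic HIE population
#'
#' Draws a seeded population of patient histories spanning the observation and
#' outcome windows. Each patient's latent 6-month ED event probability
#' (`truth_hazard`) is a logistic function of the configured drivers; the
#' intercept is calibrated by root finding so the population mean equals
#' `target_incidence`. Event days are drawn so that higher-risk patients tend
#' to visit earlier in the outcome window.
#'
#' @param config A [synthetic_config()] object.
#' @return An object of class `hie_population`: a list of tables `patients`,
#'   `encounters`, `labs`, `medications`, `radiology`, `ground_truth`, plus the
#'   generating `config`. `ground_truth` carries `truth_hazard`, `event_flag`
#'   and `event_day` and is generator bookkeeping only.
#' @export
#' @examples
#' pop <- generate_population(synthetic_config(n_patients = 200, seed = 7))
#' nrow(pop$patients)
generate_population <- function(config) {
  if (!inherits(config, "synthetic_config"))
    stop("config must be a 'synthetic_config' object", call. = FALSE)
  withr::with_seed(config$seed, generate_population_impl(config))
}

generate_population_impl <- function(cfg) {
  n <- cfg$n_patients
  idx <- cfg$index_date
  lk <- dx_lookup()
  chronic_codes_by_family <- split(lk$code[lk$chronic], lk$family[lk$chronic])
  acute_codes <- lk$code[!lk$chronic]
  fams <- dx_families()

  pid <- sprintf("P%07d", seq_len(n))

  ## demographics
  band <- sample(0:3, n, replace = TRUE, prob = c(0.22, 0.22, 0.21, 0.35))
  age <- integer(n)
  lo <- c(0, 19, 35, 50)[band + 1]
  hi <- c(18, 34, 49, 90)[band + 1]
  age <- lo + floor(runif(n) * (hi - lo + 1))
  gender <- sample(c("F", "M"), n, replace = TRUE, prob = c(0.55, 0.45))
  zip_income <- round(exp(rnorm(n, mean = log(48000), sd = 0.35)))
  zip_education <- sample(1:5, n, replace = TRUE, prob = c(0.1, 0.25, 0.3, 0.25, 0.1))

  ## chronic disease structure
  chronic <- rbinom(n, 1L, cfg$chronic_prevalence)
  n_chrcat <- ifelse(chronic == 1L, 1L + rbinom(n, 3L, 0.35), 0L)
  chronic_codes <- vector("list", n)
  chr_idx <- which(chronic == 1L)
  for (i in chr_idx) {
    f <- sample(fams[fams != "other"], n_chrcat[i])
    chronic_codes[[i]] <- vapply(chronic_codes_by_family[f],
                                 function(cc) cc[sample.int(length(cc), 1L)], "")
  }

  ## utilization intensity (shared frailty correlates history across tables)
  frailty <- rgamma(n, shape = 2, rate = 2)
  prior_ed <- rpois(n, 0.16 * frailty * exp(0.7 * chronic + 0.15 * band))
  n_outpt <- rpois(n, 0.9 + 0.9 * chronic + 0.5 * frailty)
  n_inpt <- rpois(n, 0.05 + 0.12 * chronic)
  n_med <- rpois(n, 0.5 + 1.3 * chronic + 0.25 * n_chrcat + 0.2 * band)
  n_lab <- rpois(n, 1.2 + 1.3 * chronic + 0.6 * frailty)
  n_rad <- rpois(n, 0.25 + 0.3 * chronic + 0.15 * frailty)

  ## latent outcome model
  hc <- cfg$hazard_coefficients
  lp <- hc[["prior_ed_count"]] * pmin(prior_ed, 4L) +
    hc[["chronic_flag"]] * chronic +
    hc[["age_group"]] * band +
    hc[["n_medications"]] * pmin(n_med, 10L) +
    hc[["n_chronic_categories"]] * n_chrcat
  intercept <- stats::uniroot(function(b) mean(plogis(b + lp)) - cfg$target_incidence,
                              interval = c(-25, 15), tol = 1e-10)$root
  hazard <- plogis(intercept + lp)
  event <- rbinom(n, 1L, hazard)
  ## earlier events for higher-risk patients (risk-ordered time-to-event)
  eday <- rep(NA_integer_, n)
  ev_idx <- which(event == 1L)
  eday[ev_idx] <- pmax(1L, as.integer(ceiling(
    cfg$outcome_days * runif(length(ev_idx)) ^ (1 + 2 * hazard[ev_idx]))))
  extra_out_ed <- integer(n)
  extra_out_ed[ev_idx] <- rpois(length(ev_idx), 1.6 * hazard[ev_idx])

  ## helper: sample a primary diagnosis for visit rows of given patients
  sample_primary_dx <- function(patients_row) {
    m <- length(patients_row)
    if (m == 0L) return(character(0))
    dx <- sample(acute_codes, m, replace = TRUE)
    cc <- chronic_codes[patients_row]
    has_chr <- lengths(cc) > 0L
    use_chr <- has_chr & runif(m) < 0.6
    if (any(use_chr)) {
      ccu <- cc[use_chr]
      pick <- floor(runif(sum(use_chr)) * lengths(ccu)) + 1L
      dx[use_chr] <- vapply(seq_along(ccu), function(j) ccu[[j]][[pick[j]]], "")
    }
    dx
  }
  ## secondary codes: acute by default; chronic patients may carry one of
  ## their own chronic codes as a comorbidity (keeps the coded chronic flag
  ## aligned with the latent chronic status)
  sample_secondary_dx <- function(patients_row) {
    m <- length(patients_row)
    if (m == 0L) return(character(0))
    k <- rbinom(m, 2L, 0.25)
    out <- character(m)
    nz <- which(k > 0L)
    if (length(nz)) {
      codes <- sample(acute_codes, sum(k[nz]), replace = TRUE)
      out[nz] <- vapply(split(codes, rep(seq_along(nz), k[nz])),
                        paste, "", collapse = ";")
    }
    cc <- chronic_codes[patients_row]
    add_chr <- lengths(cc) > 0L & runif(m) < 0.3
    if (any(add_chr)) {
      w <- which(add_chr)
      pick <- floor(runif(length(w)) * lengths(cc[w])) + 1L
      extra <- vapply(seq_along(w), function(j) cc[[w[j]]][[pick[j]]], "")
      out[w] <- ifelse(nzchar(out[w]), paste(out[w], extra, sep = ";"), extra)
    }
    out
  }
  obs_date <- function(m) idx - 1L - floor(runif(m) * cfg$observation_days)

  visit_block <- function(patients_row, date, kind, type_code) {
    m <- length(patients_row)
    if (m == 0L)
      return(data.frame(patient_id = character(0), date = idx[0],
                        kind = character(0), encounter_type_code = character(0),
                        disposition = character(0), primary_dx = character(0),
                        secondary_dx = character(0), stringsAsFactors = FALSE))
    data.frame(patient_id = pid[patients_row],
               date = date,
               kind = kind,
               encounter_type_code = type_code,
               disposition = ifelse(runif(m) < 0.05, "other", "routine"),
               primary_dx = sample_primary_dx(patients_row),
               secondary_dx = sample_secondary_dx(patients_row),
               stringsAsFactors = FALSE)
  }

  ## observation-window visits
  p_ed <- rep(seq_len(n), prior_ed)
  enc_ed <- visit_block(p_ed, obs_date(length(p_ed)), "ED", "ED")
  p_ip <- rep(seq_len(n), n_inpt)
  enc_ip <- visit_block(p_ip, obs_date(length(p_ip)), "inpatient", "inpatient")
  p_op <- rep(seq_len(n), n_outpt)
  op_codes <- sample(setdiff(encounter_type_codes(), c("ED", "inpatient")),
                     length(p_op), replace = TRUE)
  enc_op <- visit_block(p_op, obs_date(length(p_op)), "outpatient", op_codes)

  ## outcome-window ED visits: first at event day, extras later in the window
  p_out1 <- ev_idx
  enc_out1 <- visit_block(p_out1, idx + eday[p_out1] - 1L, "ED", "ED")
  p_outx <- rep(ev_idx, extra_out_ed[ev_idx])
  d_outx <- integer(0)
  if (length(p_outx)) {
    first <- eday[p_outx]
    d_outx <- first + floor(runif(length(p_outx)) * (cfg$outcome_days - first + 1L))
  }
  enc_outx <- visit_block(p_outx, idx + d_outx - 1L, "ED", "ED")

  encounters <- rbind(enc_ed, enc_ip, enc_op, enc_out1, enc_outx)

  ## deaths: an inpatient encounter with disposition 'expired'
  n_dead <- round(cfg$death_rate * n)
  if (n_dead > 0L) {
    dead <- sample.int(n, n_dead)
    enc_dead <- visit_block(dead, obs_date(n_dead), "inpatient", "inpatient")
    enc_dead$disposition <- "expired"
    encounters <- rbind(encounters, enc_dead)
  }
  ## ED-to-ED transfers: same-day paired ED record on a fraction of ED visits
  ed_rows <- which(encounters$kind == "ED")
  n_tr <- round(cfg$transfer_rate * length(ed_rows))
  if (n_tr > 0L) {
    src <- encounters[sample(ed_rows, n_tr), , drop = FALSE]
    src$disposition <- "transfer_from_ed"
    encounters <- rbind(encounters, src)
  }
  encounters <- encounters[order(encounters$patient_id, encounters$date,
                                 encounters$kind, encounters$disposition), ]
  rownames(encounters) <- NULL

  ## labs / medications / radiology
  p_lab <- rep(seq_len(n), n_lab)
  p_abn <- pmin(0.2 + 0.3 * chronic[p_lab] + 0.08 * pmin(frailty[p_lab], 3), 0.9)
  labs <- data.frame(patient_id = pid[p_lab],
                     date = obs_date(length(p_lab)),
                     lab_name = sample(lab_names(), length(p_lab), replace = TRUE),
                     result = ifelse(runif(length(p_lab)) < p_abn,
                                     "abnormal", "normal"),
                     stringsAsFactors = FALSE)
  p_medr <- rep(seq_len(n), n_med)
  medications <- data.frame(patient_id = pid[p_medr],
                            date = obs_date(length(p_medr)),
                            med_class = sample(med_classes(), length(p_medr),
                                               replace = TRUE),
                            stringsAsFactors = FALSE)
  p_radr <- rep(seq_len(n), n_rad)
  radiology <- data.frame(patient_id = pid[p_radr],
                          date = obs_date(length(p_radr)),
                          modality = sample(radiology_modalities(), length(p_radr),
                                            replace = TRUE),
                          stringsAsFactors = FALSE)
  for (nm in c("labs", "medications", "radiology")) {
    tb <- get(nm)
    tb <- tb[order(tb$patient_id, tb$date, tb[[3L]]), ]
    rownames(tb) <- NULL
    assign(nm, tb)
  }

  patients <- data.frame(patient_id = pid,
                         age = as.integer(age),
                         gender = gender,
                         zip_income = zip_income,
                         zip_education = zip_education,
                         stringsAsFactors = FALSE)
  ground_truth <- data.frame(patient_id = pid,
                             truth_hazard = hazard,
                             event_flag = event,
                             event_day = eday,
                             stringsAsFactors = FALSE)

  structure(list(patients = patients,
                 encounters = encounters,
                 labs = labs,
                 medications = medications,
                 radiology = radiology,
                 ground_truth = ground_truth,
                 config = cfg),
            class = "hie_population")
}

#' @export
print.hie_population <- function(x, ...) {
  cat("Synthetic HIE population:", nrow(x$patients), "patients,",
      nrow(x$encounters), "encounters\n")
  cat("  index date:", format(x$config$index_date),
      "| observation:", x$config$observation_days, "d",
      "| outcome:", x$config$outcome_days, "d\n")
  invisible(x)
}

population_tables <- function() {
  c("patients", "encounters", "labs", "medications", "radiology", "ground_truth")
}

#' Write / read an HIE population as CSV tables
#'
#' `write_hie_tables()` persists the population as plain CSV files
#' (`patients.csv`, `encounters.csv`, `labs.csv`, `medications.csv`,
#' `radiology.csv`, and the generator bookkeeping `ground_truth.csv`), dates in
#' ISO-8601. `read_hie_tables()` reverses it; `read(write(x))` reproduces all
#' clinical tables exactly (ground truth rides in a separate file and is not
#' part of the round-trip contract).
#'
#' @param population An `hie_population`.
#' @param directory Directory to write to / read from (created if needed).
#' @return `write_hie_tables()` returns the file paths invisibly;
#'   `read_hie_tables()` returns an `hie_population` (without a config).
#' @export
write_hie_tables <- function(population, directory) {
  if (!inherits(population, "hie_population"))
    stop("population must be an 'hie_population'", call. = FALSE)
  dir.create(directory, recursive = TRUE, showWarnings = FALSE)
  paths <- character(0)
  for (nm in population_tables()) {
    tb <- population[[nm]]
    path <- file.path(directory, paste0(nm, ".csv"))
    data.table::fwrite(tb, path, dateTimeAs = "ISO")
    paths <- c(paths, path)
  }
  invisible(paths)
}

#' @rdname write_hie_tables
#' @export
read_hie_tables <- function(directory) {
  read_one <- function(nm, date_col = "date") {
    path <- file.path(directory, paste0(nm, ".csv"))
    if (!file.exists(path)) stop("missing table file: ", path, call. = FALSE)
    tb <- as.data.frame(data.table::fread(path, colClasses = list(
      character = "patient_id")))
    if (date_col %in% names(tb) && nrow(tb) > 0) {
      d <- as.Date(as.character(tb[[date_col]]), format = "%Y-%m-%d")
      bad <- which(is.na(d) & !is.na(tb[[date_col]]) & nzchar(tb[[date_col]]))
      if (length(bad))
        stop("parse error in '", basename(path), "', row ", bad[1L],
             ": invalid date '", tb[[date_col]][bad[1L]], "'", call. = FALSE)
      tb[[date_col]] <- d
    }
    tb
  }
  out <- list(patients = read_one("patients", date_col = NA),
              encounters = read_one("encounters"),
              labs = read_one("labs"),
              medications = read_one("medications"),
              radiology = read_one("radiology"),
              ground_truth = read_one("ground_truth", date_col = NA),
              config = NULL)
  ## character columns that fread may have typed otherwise on empty input
  for (nm in population_tables()) {
    ref_chr <- switch(nm,
      patients = c("patient_id", "gender"),
      encounters = c("patient_id", "kind", "encounter_type_code", "disposition",
                     "primary_dx", "secondary_dx"),
      labs = c("patient_id", "lab_name", "result"),
      medications = c("patient_id", "med_class"),
      radiology = c("patient_id", "modality"),
      ground_truth = "patient_id")
    for (cc in intersect(ref_chr, names(out[[nm]])))
      out[[nm]][[cc]] <- as.character(out[[nm]][[cc]])
    if (nrow(out[[nm]]) == 0) rownames(out[[nm]]) <- NULL
  }
  structure(out, class = "hie_population")
}
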