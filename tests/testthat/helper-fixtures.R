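# Shared fixtures, all generated in code. Heavy cohorts are memoized so several
# test files can share one simulation.

.fixture_cache <- new.env(parent = emptyenv())

memo <- function(key, builder) {
  if (!exists(key, envir = .fixture_cache)) {
    assign(key, builder(), envir = .fixture_cache)
  }
  get(key, envir = .fixture_cache)
}

# a mid-sized population with its feature matrix, shared across files
shared_cohort <- function() {
  memo("cohort5k", function() {
    pop <- generate_population(synthetic_config(n_patients = 5000, seed = 301))
    ex <- apply_exclusions(pop)
    fm <- build_pivot_table(ex$population)
    list(pop = pop, excluded = ex, fm = fm)
  })
}

# the full 20,000-patient study used by the acceptance suite
acceptance_study <- function() {
  memo("study20k", function() {
    cfg <- run_config(synth = synthetic_config(n_patients = 20000, seed = 2024),
                      seed = 2024, out_dir = file.path(tempdir(), "accept20k"))
    suppressWarnings(run_retrospective(cfg, quiet = TRUE))
  })
}

# minimal hand-rolled feature matrix for unit tests of downstream modules
make_fm <- function(X, outcome = NULL, time_to_event = NULL, event = NULL,
                    outcome_ed_count = NULL, prior_ed_count = NULL,
                    chronic_flag = NULL, category = "lab", horizon = 180L) {
  n <- nrow(X)
  if (is.null(colnames(X))) colnames(X) <- sprintf("f%02d", seq_len(ncol(X)))
  if (is.null(outcome)) outcome <- integer(n)
  if (is.null(event)) event <- outcome
  if (is.null(time_to_event)) time_to_event <- ifelse(event == 1L, 30L, horizon)
  if (is.null(outcome_ed_count)) outcome_ed_count <- outcome
  if (is.null(prior_ed_count)) prior_ed_count <-
      if ("prior_ed_count" %in% colnames(X)) X[, "prior_ed_count"] else numeric(n)
  if (is.null(chronic_flag)) chronic_flag <-
      if ("chronic_flag" %in% colnames(X)) X[, "chronic_flag"] else integer(n)
  structure(list(patient_id = sprintf("T%05d", seq_len(n)),
                 X = X,
                 feature_meta = data.frame(name = colnames(X),
                                           category = rep_len(category, ncol(X)),
                                           source = colnames(X),
                                           stringsAsFactors = FALSE),
                 outcome = as.integer(outcome),
                 time_to_event = as.integer(time_to_event),
                 event = as.integer(event),
                 outcome_ed_count = as.integer(outcome_ed_count),
                 prior_ed_count = as.numeric(prior_ed_count),
                 chronic_flag = as.integer(chronic_flag),
                 horizon = as.integer(horizon)),
            class = "ed_feature_matrix")
}

# small hand-constructed population with fully known records
manual_population <- function() {
  idx <- as.Date("2013-01-01")
  enc <- function(pid, date, kind, type, dispo = "routine", pdx = "486",
                  sdx = "") {
    data.frame(patient_id = pid, date = as.Date(date), kind = kind,
               encounter_type_code = type, disposition = dispo,
               primary_dx = pdx, secondary_dx = sdx, stringsAsFactors = FALSE)
  }
  encounters <- rbind(
    # P1: three observation-window ED visits, outcome ED at day 42
    enc("P1", "2012-03-01", "ED", "ED"),
    enc("P1", "2012-06-15", "ED", "ED", pdx = "845"),
    enc("P1", "2012-11-02", "ED", "ED"),
    enc("P1", "2013-02-11", "ED", "ED"),                 # day 42 of outcome
    # P2: chronic outpatient history, no outcome-window ED visit
    enc("P2", "2012-05-10", "outpatient", "office_visit", pdx = "250",
        sdx = "401"),
    enc("P2", "2012-08-20", "outpatient", "specialist", pdx = "428"),
    # P3: no observation-window records at all, outcome ED at day 1
    enc("P3", "2013-01-01", "ED", "ED", pdx = "780")
  )
  patients <- data.frame(
    patient_id = c("P1", "P2", "P3"),
    age = c(25L, 60L, 40L),
    gender = c("F", "M", "F"),
    zip_income = c(40000, 52000, 47000),
    zip_education = c(3L, 4L, 2L),
    stringsAsFactors = FALSE)
  labs <- data.frame(patient_id = "P2", date = as.Date("2012-07-01"),
                     lab_name = "glucose", result = "abnormal",
                     stringsAsFactors = FALSE)
  medications <- data.frame(patient_id = "P2", date = as.Date("2012-07-01"),
                            med_class = "insulin", stringsAsFactors = FALSE)
  radiology <- data.frame(patient_id = "P1", date = as.Date("2012-06-15"),
                          modality = "xray", stringsAsFactors = FALSE)
  ground_truth <- data.frame(patient_id = patients$patient_id,
                             truth_hazard = c(0.8, 0.2, 0.4),
                             event_flag = c(1L, 0L, 1L),
                             event_day = c(42L, NA, 1L),
                             stringsAsFactors = FALSE)
  structure(list(patients = patients, encounters = encounters, labs = labs,
                 medications = medications, radiology = radiology,
                 ground_truth = ground_truth,
                 config = synthetic_config(n_patients = 3,
                                           index_date = idx, seed = 1)),
            class = "hie_population")
}
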