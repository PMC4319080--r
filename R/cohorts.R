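# Cohort construction: exclusions (deaths, ED-to-ED transfers), the six-stratum
# decomposition on chronic history x prior ED band, and the balanced
# training / calibrating / blind-testing split.

#' Apply population exclusions
#'
#' Removes patients who died during the study frame (any encounter with
#' disposition `expired`) and merges ED-to-ED transfers: an ED record with
#' disposition `transfer_from_ed` that shares its patient and day with another
#' ED record is dropped, so the pair counts as one ED visit. Surviving
#' patients' non-ED records are never modified.
#'
#' @param population An `hie_population`.
#' @return A list with the filtered `population` and an `exclusion_log`
#'   data.frame (`patient_id`, `action`, `reason`, `date`).
#' @export
apply_exclusions <- function(population) {
  stopifnot(inherits(population, "hie_population"))
  enc <- population$encounters
  log <- data.frame(patient_id = character(0), action = character(0),
                    reason = character(0), date = as.Date(character(0)),
                    stringsAsFactors = FALSE)

  ## deaths
  dead_rows <- which(enc$disposition == "expired")
  dead_ids <- unique(enc$patient_id[dead_rows])
  if (length(dead_ids)) {
    first_row <- dead_rows[!duplicated(enc$patient_id[dead_rows])]
    log <- rbind(log, data.frame(patient_id = enc$patient_id[first_row],
                                 action = "remove_patient",
                                 reason = "disposition_expired",
                                 date = enc$date[first_row],
                                 stringsAsFactors = FALSE))
  }

  ## ED-to-ED transfer merge: drop the transfer row when a same-day ED pair exists
  is_tr <- enc$kind == "ED" & enc$disposition == "transfer_from_ed"
  key <- paste(enc$patient_id, enc$date)
  ed_plain_keys <- unique(key[enc$kind == "ED" & !is_tr])
  merge_rows <- which(is_tr & key %in% ed_plain_keys)
  if (length(merge_rows)) {
    log <- rbind(log, data.frame(patient_id = enc$patient_id[merge_rows],
                                 action = "merge_ed_visit",
                                 reason = "transfer_from_ed_same_day",
                                 date = enc$date[merge_rows],
                                 stringsAsFactors = FALSE))
  }

  keep_rows <- setdiff(seq_len(nrow(enc)), merge_rows)
  enc <- enc[keep_rows, , drop = FALSE]
  out <- population
  out$encounters <- enc
  if (length(dead_ids)) {
    for (nm in population_tables()) {
      tb <- out[[nm]]
      out[[nm]] <- tb[!(tb$patient_id %in% dead_ids), , drop = FALSE]
      rownames(out[[nm]]) <- NULL
    }
  } else {
    rownames(out$encounters) <- NULL
  }
  list(population = out, exclusion_log = log)
}

#' Six-subgroup stratification
#'
#' Crosses the chronic-disease flag (absent / present) with the prior-year ED
#' visit band (0, 1, 2 or more) into six strata; every patient receives
#' exactly one label.
#'
#' @param fm An `ed_feature_matrix`.
#' @return Character vector of stratum labels, e.g. `"chronic0_ed1"`,
#'   `"chronic1_ed2plus"`.
#' @export
stratify_six_subgroups <- function(fm) {
  stopifnot(inherits(fm, "ed_feature_matrix"))
  band <- cut(fm$prior_ed_count, breaks = c(-Inf, 0, 1, Inf),
              labels = c("ed0", "ed1", "ed2plus"))
  paste0("chronic", fm$chronic_flag, "_", as.character(band))
}

#' Split patients into training, calibrating and blind-testing cohorts
#'
#' Within every stratum, cases (at least one outcome-window ED visit) and
#' controls are separately shuffled under the seed and dealt round-robin to
#' Cohorts I, II and III, so case/control ratios and stratum composition are
#' balanced across the cohorts: per stratum and arm the three cohort counts
#' differ pairwise by at most one.
#'
#' @param patient_id Character vector of patient ids.
#' @param stratum Stratum label per patient (see [stratify_six_subgroups()]).
#' @param outcome Binary outcome per patient.
#' @param seed Integer seed for the shuffles.
#' @return An object of class `cohort_split`: a data.frame with columns
#'   `patient_id`, `stratum`, `outcome`, `cohort` (`"I"`, `"II"`, `"III"`),
#'   with the seed as an attribute.
#' @export
split_cohorts <- function(patient_id, stratum, outcome, seed = 1L) {
  if (length(patient_id) != length(stratum) ||
      length(patient_id) != length(outcome))
    stop("patient_id, stratum and outcome must have equal length", call. = FALSE)
  cohort <- character(length(patient_id))
  withr::with_seed(seed, {
    for (s in sort(unique(stratum))) {
      for (arm in c(1L, 0L)) {
        rows <- which(stratum == s & outcome == arm)
        if (length(rows) == 0L) next
        if (length(rows) < 3L)
          warning("stratum ", s, " has fewer than 3 ",
                  if (arm == 1L) "cases" else "controls",
                  "; dealing as far as possible", call. = FALSE)
        rows <- rows[sample.int(length(rows))]
        cohort[rows] <- c("I", "II", "III")[((seq_along(rows) - 1L) %% 3L) + 1L]
      }
    }
  })
  out <- data.frame(patient_id = patient_id, stratum = stratum,
                    outcome = outcome, cohort = cohort,
                    stringsAsFactors = FALSE)
  attr(out, "seed") <- seed
  class(out) <- c("cohort_split", class(out))
  out
}
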