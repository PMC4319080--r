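# Bundled clinical vocabularies for the synthetic generator and the feature
# builder. The diagnosis lookup is a deliberately small stand-in keyed to ICD-9
# chapter families, each code flagged chronic or non-chronic in the spirit of
# the AHRQ Chronic Condition Indicator dichotomy; it is synthetic, not the real
# CCI table.

#' Bundled diagnosis-code lookup
#'
#' A small fixed vocabulary of ICD-9-style three-digit diagnosis codes, each
#' assigned to a chapter family (endocrine/immune, circulatory, nervous system
#' and sense organs, respiratory, digestive, or other) and flagged chronic or
#' non-chronic. The table is a synthetic stand-in for the AHRQ Chronic
#' Condition Indicator used to dichotomize ICD-9-CM codes.
#'
#' @return A data.frame with columns `code`, `label`, `family`, `chronic`.
#' @export
#' @examples
#' head(dx_lookup())
dx_lookup <- function() {
  data.frame(
    code = c("250", "272", "279", "244",
             "401", "428", "427", "414",
             "345", "365", "332", "382",
             "493", "496", "486", "462",
             "571", "555", "558", "530",
             "715", "290", "780", "845", "599", "959"),
    label = c("diabetes", "lipid_disorder", "immune_disorder", "hypothyroidism",
              "hypertension", "heart_failure", "arrhythmia", "ischemic_heart",
              "epilepsy", "glaucoma", "parkinsons", "otitis_media",
              "asthma", "copd", "pneumonia", "pharyngitis",
              "chronic_liver", "crohns", "gastroenteritis", "reflux",
              "osteoarthritis", "dementia", "general_symptoms", "sprain",
              "uti", "injury_other"),
    family = c(rep("endocrine_immune", 4),
               rep("circulatory", 4),
               rep("nervous_sense", 4),
               rep("respiratory", 4),
               rep("digestive", 4),
               rep("other", 6)),
    chronic = c(TRUE, TRUE, TRUE, TRUE,
                TRUE, TRUE, TRUE, TRUE,
                TRUE, TRUE, TRUE, FALSE,
                TRUE, TRUE, FALSE, FALSE,
                TRUE, TRUE, FALSE, TRUE,
                TRUE, TRUE, FALSE, FALSE, FALSE, FALSE),
    stringsAsFactors = FALSE
  )
}

dx_families <- function() {
  c("endocrine_immune", "circulatory", "nervous_sense",
    "respiratory", "digestive", "other")
}

# encounter type codes: one for ED, one for inpatient, six outpatient flavours
encounter_type_codes <- function() {
  c("ED", "inpatient", "office_visit", "specialist", "urgent_care",
    "telehealth", "day_surgery", "behavioral_health")
}

lab_names <- function() {
  c("glucose", "hemoglobin", "creatinine", "sodium",
    "potassium", "wbc", "alt", "tsh")
}

med_classes <- function() {
  c("antihypertensive", "statin", "insulin", "oral_hypoglycemic",
    "bronchodilator", "corticosteroid", "opioid", "antidepressant",
    "anticoagulant", "ppi", "antibiotic", "nsaid")
}

radiology_modalities <- function() {
  c("xray", "ct", "mri")
}

age_group_levels <- function() {
  c("0-18", "19-34", "35-49", "50+")
}
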