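# Controlled vocabularies for the screening instrument. Enum tokens are
# UPPER_SNAKE and are the only values accepted in screening-record columns.

#' Controlled vocabularies of the screening instrument
#'
#' Named list of the legal tokens for every categorical column of a
#' screening-record table: the three journals, the nine study types, the
#' availability-statement levels, the claimed-availability modes, tri-state
#' accessibility answers, pre-registration/protocol aspects, and the
#' conflict-of-interest, funding and open-access statement levels.
#'
#' @return A named list of character vectors.
#' @export
#' @examples
#' screening_vocab()$journal
screening_vocab <- function() {
  list(
    journal = c("CIRCULATION", "EHJ", "JACC"),
    study_type = c(
      "CLINICAL_TRIAL", "CLINICAL_OBSERVATIONAL", "CLINICAL_INTERVENTION",
      "CASE_STUDY_OR_SERIES", "LAB_ANIMAL", "LAB_CELL_MOLECULAR",
      "META_ANALYSIS_SYSTEMATIC_REVIEW", "NONCLINICAL_SECONDARY_DATA",
      "NON_EMPIRICAL"
    ),
    statement = c("YES_AVAILABLE", "NO_STATEMENT", "STATES_UNAVAILABLE",
                  "NOT_APPLICABLE"),
    mode = c("REPOSITORY", "PERSONAL_OR_INSTITUTIONAL_PAGE", "SUPPLEMENT",
             "UPON_REQUEST", "NONE"),
    tristate = c("YES", "NO", "NOT_APPLICABLE"),
    yes_no = c("YES", "NO"),
    aspect = c("HYPOTHESES", "METHODS", "ANALYSIS_PLAN"),
    coi = c("HAS_COI", "NO_COI", "ABSENT"),
    funding = c("PRIVATE", "PUBLIC", "BOTH", "NO_FUNDING", "ABSENT"),
    open_access = c("YES_OA_BUTTON", "YES_OTHER", "NO")
  )
}

# Study types that, by the nature of the research, cannot have shareable
# materials; the two materials criteria are dropped from their denominator.
materials_incapable_types <- function() {
  c("META_ANALYSIS_SYSTEMATIC_REVIEW", "NONCLINICAL_SECONDARY_DATA")
}

empirical_study_types <- function() {
  setdiff(screening_vocab()$study_type, "NON_EMPIRICAL")
}

# Canonical column order of a screening-record table.
record_columns <- function() {
  c("article_id", "journal", "study_type", "study_type_stated",
    "materials_statement", "materials_mode", "materials_accessible",
    "data_statement", "data_mode", "data_accessible",
    "data_documented", "data_complete",
    "scripts_statement", "scripts_mode", "scripts_accessible",
    "prereg_statement", "prereg_accessible", "prereg_aspects",
    "protocol_linked", "protocol_aspects",
    "coi_statement", "funding_statement", "open_access", "country")
}

# column -> vocabulary name, for the enum-valued columns
record_enum_map <- function() {
  c(journal = "journal", study_type = "study_type",
    materials_statement = "statement", materials_mode = "mode",
    materials_accessible = "tristate",
    data_statement = "statement", data_mode = "mode",
    data_accessible = "tristate", data_documented = "tristate",
    data_complete = "tristate",
    scripts_statement = "statement", scripts_mode = "mode",
    scripts_accessible = "tristate",
    prereg_statement = "yes_no", prereg_accessible = "tristate",
    coi_statement = "coi", funding_statement = "funding",
    open_access = "open_access")
}

record_logical_columns <- function() {
  c("study_type_stated", "protocol_linked")
}

record_aspect_columns <- function() {
  c("prereg_aspects", "protocol_aspects")
}

# Split a semicolon-joined aspect cell into its tokens ("" -> character(0)).
split_aspects <- function(x) {
  if (length(x) == 0) return(list())
  x <- as.character(x)
  strsplit(ifelse(is.na(x) | x == "", "", x), ";", fixed = TRUE)
}
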