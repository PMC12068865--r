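# The scoring instrument: 17 equally weighted criteria, one per row of the
# coding form. The two materials criteria are dropped for study types that
# cannot have shareable materials (meta-analyses / systematic reviews and
# non-clinical secondary-data analyses), giving those types a denominator of
# 15 instead of 17.

#' The accessibility criteria
#'
#' One row per criterion of the screening instrument: identifier `C1`..`C17`,
#' a short label, and whether the criterion is one of the two materials items
#' that are omitted for study types without shareable materials.
#'
#' @return A tibble with columns `criterion_id`, `label`, `materials_item`.
#' @export
criteria_table <- function() {
  tibble::tribble(
    ~criterion_id, ~label,                                   ~materials_item,
    "C1",  "study type clearly stated",                      FALSE,
    "C2",  "materials stated available",                     TRUE,
    "C3",  "materials files accessible",                     TRUE,
    "C4",  "data stated available",                          FALSE,
    "C5",  "data files accessible",                          FALSE,
    "C6",  "data files documented",                          FALSE,
    "C7",  "data files complete (all raw data)",             FALSE,
    "C8",  "analysis scripts stated available",              FALSE,
    "C9",  "analysis script files accessible",               FALSE,
    "C10", "pre-registration stated",                        FALSE,
    "C11", "pre-registration accessible",                    FALSE,
    "C12", "pre-registration has all three aspects",         FALSE,
    "C13", "protocol linked",                                FALSE,
    "C14", "protocol has all three aspects",                 FALSE,
    "C15", "conflict-of-interest statement present",         FALSE,
    "C16", "funding statement present",                      FALSE,
    "C17", "article open access",                            FALSE
  )
}

#' Criteria applicable to a study type
#'
#' Returns the identifiers of the criteria that enter the accessibility-score
#' denominator for a study type: all 17 for materials-capable types, 15
#' (materials statement and accessibility omitted) for meta-analyses /
#' systematic reviews and non-clinical secondary-data analyses. Non-empirical
#' articles are not screened for accessibility criteria and cannot be scored.
#'
#' @param study_type A single study-type token.
#' @return Character vector of criterion identifiers.
#' @export
#' @examples
#' length(applicable_criteria("CLINICAL_TRIAL"))                  # 17
#' length(applicable_criteria("META_ANALYSIS_SYSTEMATIC_REVIEW")) # 15
applicable_criteria <- function(study_type) {
  stopifnot(length(study_type) == 1)
  if (!study_type %in% screening_vocab()$study_type) {
    stop("unknown study type: ", study_type, call. = FALSE)
  }
  if (study_type == "NON_EMPIRICAL") {
    stop("non-empirical articles are not screened for accessibility ",
         "criteria and have no applicable set", call. = FALSE)
  }
  crit <- criteria_table()
  if (study_type %in% materials_incapable_types()) {
    crit <- crit[!crit$materials_item, ]
  }
  crit$criterion_id
}

# Satisfaction of every criterion for every record, as a logical matrix in
# record order; gating is already encoded in the record invariants (e.g. an
# inaccessible or unstated resource can never have accessible = YES).
criterion_satisfaction <- function(records) {
  all3 <- function(col) {
    vapply(split_aspects(records[[col]]),
           function(t) all(screening_vocab()$aspect %in% t), logical(1))
  }
  tibble::tibble(
    C1 = isTRUE_vec(records$study_type_stated),
    C2 = records$materials_statement == "YES_AVAILABLE",
    C3 = records$materials_accessible == "YES",
    C4 = records$data_statement == "YES_AVAILABLE",
    C5 = records$data_accessible == "YES",
    C6 = records$data_documented == "YES",
    C7 = records$data_complete == "YES",
    C8 = records$scripts_statement == "YES_AVAILABLE",
    C9 = records$scripts_accessible == "YES",
    C10 = records$prereg_statement == "YES",
    C11 = records$prereg_accessible == "YES",
    C12 = all3("prereg_aspects"),
    C13 = isTRUE_vec(records$protocol_linked),
    C14 = all3("protocol_aspects"),
    C15 = records$coi_statement %in% c("HAS_COI", "NO_COI"),
    C16 = records$funding_statement != "ABSENT",
    C17 = records$open_access %in% c("YES_OA_BUTTON", "YES_OTHER")
  )
}

#' Evaluate the accessibility criteria for each record
#'
#' Maps every empirical screening record to one verdict per applicable
#' criterion. Conditional (gated) criteria stay in the applicable set even
#' when their parent statement is negative — they are simply unsatisfied —
#' so the denominator depends only on the study type. `NOT_APPLICABLE`
#' answers on gated items count as unsatisfied, never as satisfied.
#'
#' @param records A valid screening-record tibble containing only empirical
#'   study types.
#' @return A long tibble with columns `article_id`, `criterion_id`,
#'   `applicable`, `satisfied`; one row per record x applicable criterion.
#' @export
evaluate_criteria <- function(records) {
  assert_valid_records(records)
  if (nrow(records) == 0) stop("no records to evaluate", call. = FALSE)
  if (any(records$study_type == "NON_EMPIRICAL")) {
    stop("non-empirical articles cannot be scored; filter them out first",
         call. = FALSE)
  }
  sat <- criterion_satisfaction(records)
  crit <- criteria_table()
  long <- tidyr::pivot_longer(
    dplyr::bind_cols(
      tibble::tibble(article_id = records$article_id,
                     study_type = records$study_type),
      sat
    ),
    cols = dplyr::all_of(crit$criterion_id),
    names_to = "criterion_id", values_to = "satisfied"
  )
  drop_mat <- long$study_type %in% materials_incapable_types() &
    long$criterion_id %in% crit$criterion_id[crit$materials_item]
  long <- long[!drop_mat, ]
  tibble::tibble(
    article_id = long$article_id,
    criterion_id = long$criterion_id,
    applicable = TRUE,
    satisfied = long$satisfied
  )
}

#' Per-article accessibility scores
#'
#' The accessibility score of an article is the fraction of its applicable
#' criteria that are satisfied: `numerator / denominator`, where the
#' denominator is 17 for materials-capable study types and 15 otherwise.
#'
#' @param records A valid screening-record tibble of empirical articles.
#' @return A tibble with one row per article: `article_id`, `journal`,
#'   `study_type`, `numerator`, `denominator`, `score`.
#' @export
#' @examples
#' recs <- generate_records(default_config(n_articles = 50, seed = 7))
#' accessibility_score(dplyr::filter(recs, study_type != "NON_EMPIRICAL"))
accessibility_score <- function(records) {
  res <- evaluate_criteria(records)
  per <- dplyr::summarise(
    dplyr::group_by(res, .data$article_id),
    numerator = sum(.data$satisfied),
    denominator = sum(.data$applicable),
    .groups = "drop"
  )
  out <- dplyr::left_join(
    tibble::tibble(article_id = records$article_id,
                   journal = records$journal,
                   study_type = records$study_type),
    per, by = "article_id"
  )
  out$score <- out$numerator / out$denominator
  out
}

#' Pre-registration completeness
#'
#' Counts how many of the three pre-registerable aspects (hypotheses,
#' methods, analysis plan) each article's pre-registration contains; 0 when
#' no accessible pre-registration exists.
#'
#' @param records A valid screening-record tibble.
#' @return A tibble with columns `article_id`, `n_aspects` (0--3).
#' @export
prereg_completeness <- function(records) {
  assert_valid_records(records)
  n_asp <- lengths(split_aspects(records$prereg_aspects))
  n_asp[records$prereg_accessible != "YES"] <- 0L
  tibble::tibble(article_id = records$article_id, n_aspects = as.integer(n_asp))
}
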