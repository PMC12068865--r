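test_that("applicable criteria sets depend only on study type", {
  expect_length(applicable_criteria("CLINICAL_TRIAL"), 17)
  expect_length(applicable_criteria("LAB_ANIMAL"), 17)
  for (st in c("META_ANALYSIS_SYSTEMATIC_REVIEW", "NONCLINICAL_SECONDARY_DATA")) {
    ids <- applicable_criteria(st)
    expect_length(ids, 15)
    expect_false(any(c("C2", "C3") %in% ids))
  }
  expect_error(applicable_criteria("NON_EMPIRICAL"), "not screened")
  expect_error(applicable_criteria("EDITORIAL"), "unknown study type")
})

test_that("criterion satisfaction follows the coding-form mapping", {
  res <- evaluate_criteria(full_positive_record())
  expect_identical(nrow(res), 17L)
  expect_true(all(res$satisfied))

  res <- evaluate_criteria(all_negative_record())
  expect_identical(nrow(res), 17L)
  expect_false(any(res$satisfied))

  # full data chain satisfies C4-C7
  r <- all_negative_record()
  r$data_statement <- "YES_AVAILABLE"; r$data_mode <- "REPOSITORY"
  r$data_accessible <- "YES"; r$data_documented <- "YES"
  r$data_complete <- "YES"
  res <- evaluate_criteria(r)
  expect_setequal(res$criterion_id[res$satisfied], c("C4", "C5", "C6", "C7"))

  # two of three pre-registered aspects do not satisfy C12
  r <- full_positive_record()
  r$prereg_aspects <- "METHODS;HYPOTHESES"
  res <- evaluate_criteria(r)
  expect_false(res$satisfied[res$criterion_id == "C12"])
  expect_true(res$satisfied[res$criterion_id == "C11"])

  expect_error(evaluate_criteria(new_records("n", "EHJ", "NON_EMPIRICAL")),
               "[Nn]on-empirical")
})

test_that("accessibility score is the satisfied fraction of the applicable set", {
  sc <- accessibility_score(full_positive_record())
  expect_identical(sc$numerator, 17L)
  expect_identical(sc$denominator, 17L)
  expect_identical(sc$score, 1)

  sc <- accessibility_score(all_negative_record())
  expect_identical(sc$score, 0)

  # meta-analysis with exactly 3 of its 15 criteria satisfied scores 0.2
  r <- new_records("m1", "JACC", "META_ANALYSIS_SYSTEMATIC_REVIEW",
                   coi_statement = "NO_COI", funding_statement = "PUBLIC",
                   open_access = "YES_OTHER")
  sc <- accessibility_score(r)
  expect_identical(sc$numerator, 3L)
  expect_identical(sc$denominator, 15L)
  expect_equal(sc$score, 0.2)
})

test_that("scores stay in [0,1], denominators are constant within study type", {
  recs <- generate_records(default_config(n_articles = 500, seed = 99))
  emp <- dplyr::filter(recs, study_type != "NON_EMPIRICAL")
  sc <- accessibility_score(emp)
  expect_true(all(sc$score >= 0 & sc$score <= 1))
  expect_true(all(sc$numerator <= sc$denominator))
  per_type <- dplyr::summarise(dplyr::group_by(sc, study_type),
                               k = dplyr::n_distinct(denominator),
                               d = denominator[1], .groups = "drop")
  expect_true(all(per_type$k == 1))
  expect_setequal(unique(per_type$d), c(15L, 17L))
  expect_identical(
    sort(per_type$study_type[per_type$d == 15]),
    sort(intersect(per_type$study_type,
                   c("META_ANALYSIS_SYSTEMATIC_REVIEW",
                     "NONCLINICAL_SECONDARY_DATA")))
  )
})

test_that("satisfying one more criterion never decreases the score", {
  recs <- generate_records(default_config(n_articles = 120, seed = 17))
  emp <- dplyr::filter(recs, study_type != "NON_EMPIRICAL")
  base <- accessibility_score(emp)$score
  flips <- list(
    function(r) { r$study_type_stated <- TRUE; r },
    function(r) { r$protocol_linked <- TRUE; r },
    function(r) { r$coi_statement <- "HAS_COI"; r },
    function(r) { r$funding_statement <- "PUBLIC"; r },
    function(r) { r$open_access <- "YES_OTHER"; r }
  )
  for (flip in flips) {
    flipped <- accessibility_score(flip(emp))$score
    expect_true(all(flipped >= base))
  }
})

test_that("pre-registration completeness counts aspects of accessible preregs", {
  r <- full_positive_record()
  expect_identical(prereg_completeness(r)$n_aspects, 3L)
  r$prereg_aspects <- "METHODS"
  expect_identical(prereg_completeness(r)$n_aspects, 1L)
  expect_identical(prereg_completeness(all_negative_record())$n_aspects, 0L)
})
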