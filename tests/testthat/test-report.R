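test_that("percentages round half away from zero at the requested precision", {
  expect_identical(percent(56, 393), "14%")
  expect_identical(percent(125, 393, 1), "31.8%")
  expect_identical(percent(43, 393, 1), "10.9%")
  expect_identical(percent(7, 393), "2%")
  expect_identical(percent(0, 100), "0%")
  # .5 cases round away from zero, not to even
  expect_identical(percent_value(25, 1000, 0), 3)
  expect_identical(percent_value(35, 1000, 0), 4)
  expect_error(percent(1, 0), "positive")
  expect_error(percent(5, 4), "numerator")
})

test_that("score histogram uses left-closed width-0.1 bins with 1.0 in the top bin", {
  h <- score_histogram(c(0, 0.05, 0.25, 0.299, 0.3, 1))
  expect_identical(sum(h$count), 6L)
  expect_identical(h$count[h$bin == "0.00-0.09"], 2L)
  expect_identical(h$count[h$bin == "0.20-0.29"], 2L)
  expect_identical(h$count[h$bin == "0.30-0.39"], 1L)
  expect_identical(h$count[h$bin == "0.90-1.00"], 1L)
  expect_error(score_histogram(c(0.5, 1.2)), "\\[0, 1\\]")
  expect_error(score_histogram(c(0.5, NA)), "\\[0, 1\\]")
})

test_that("corpus summary reproduces its percentages from the tallied counts", {
  recs <- generate_records(default_config(n_articles = 639, seed = 44))
  s <- summarize_records(recs, run_battery = FALSE)
  expect_identical(s$corpus$n_total, 639L)
  oa <- s$corpus$open_access
  expect_identical(sum(oa$count), 639L)
  expect_equal(oa$pct_1dp, percent_value(oa$count, 639, 1))
  expect_equal(oa$pct_0dp, percent_value(oa$count, 639, 0))
  # availability chains are non-increasing: stated >= accessible >= documented
  av <- s$availability
  expect_true(all(av$n_stated_available >= av$n_accessible))
  d <- av[av$resource == "data", ]
  expect_true(d$n_accessible >= d$n_documented)
  expect_true(d$n_documented >= d$n_complete)
  expect_identical(sum(s$histogram$count), s$corpus$n_empirical)
  expect_identical(sum(s$repeatability$replicable), s$corpus$n_empirical)
})

test_that("a corpus with 605 of 639 articles open access reports 94.7% and >=90%", {
  recs <- new_records(sprintf("a%03d", 1:639), "EHJ", "NON_EMPIRICAL",
                      open_access = c(rep("YES_OTHER", 605), rep("NO", 34)))
  s <- summarize_records(recs, run_battery = FALSE)
  oa <- s$corpus$open_access
  n_open <- sum(oa$count[oa$level != "NO"])
  expect_identical(n_open, 605L)
  expect_identical(percent(n_open, 639, 1), "94.7%")
  expect_gte(percent_value(n_open, 639, 0), 90)
})

test_that("summaries are pure functions of the records", {
  recs <- generate_records(default_config(n_articles = 200, seed = 66))
  expect_identical(summarize_records(recs), summarize_records(recs))
})

test_that("edge corpora summarise sensibly", {
  expect_error(summarize_records(full_positive_record()[0, ]), "empty")

  # every empirical article with methods+data+scripts: 100% fully reproducible
  n <- 20L
  recs <- new_records(sprintf("r%02d", 1:n), "JACC", "CLINICAL_TRIAL",
                      data_statement = "YES_AVAILABLE", data_mode = "SUPPLEMENT",
                      data_accessible = "NO",
                      scripts_statement = "YES_AVAILABLE",
                      scripts_mode = "SUPPLEMENT", scripts_accessible = "NO",
                      protocol_linked = TRUE)
  s <- summarize_records(recs, run_battery = FALSE)
  rp <- s$repeatability_pct
  expect_identical(rp$count[rp$quantity == "fully_reproducible"], n)
  expect_equal(rp$pct_1dp[rp$quantity == "fully_reproducible"], 100)

  # singleton corpus: report exists, group SDs are absent
  s1 <- summarize_records(full_positive_record(), run_battery = FALSE)
  expect_identical(s1$corpus$n_total, 1L)
  expect_true(is.na(s1$by_study_type$sd))
})

test_that("summary JSON export round-trips its headline counts", {
  recs <- generate_records(default_config(n_articles = 150, seed = 10))
  s <- summarize_records(recs, run_battery = FALSE)
  parsed <- jsonlite::fromJSON(summary_to_json(s))
  expect_identical(parsed$corpus$n_total, s$corpus$n_total)
  expect_identical(nrow(parsed$histogram), 10L)
})

test_that("plot builders return ggplot objects", {
  recs <- generate_records(default_config(n_articles = 300, seed = 21))
  s <- summarize_records(recs, min_n = 10)
  expect_s3_class(autoplot(s), "ggplot")
  expect_s3_class(autoplot(s, type = "repeatability"), "ggplot")
  if (!is.null(s$battery)) {
    expect_s3_class(autoplot(s, type = "availability"), "ggplot")
  }
  expect_s3_class(plot_score_histogram(s$scores), "ggplot")
})
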