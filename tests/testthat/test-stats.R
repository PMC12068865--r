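test_that("group summaries report n, mean and sample SD", {
  d <- tibble::tibble(g = c("a", "b", "b"), v = c(0.4, 0.2, 0.4))
  s <- group_summary(d, g, v)
  expect_identical(s$n, c(1L, 2L))
  expect_equal(s$mean, c(0.4, 0.3))
  expect_true(is.na(s$sd[1]))
  expect_equal(s$sd[2], sqrt(0.02), tolerance = 1e-12)  # ~0.1414
  expect_error(group_summary(d[0, ], g, v), "no observations")
})

test_that("two-way ANOVA matches the textbook balanced decomposition", {
  set.seed(404)
  d <- tidyr::expand_grid(a = c("a1", "a2"), b = c("b1", "b2"),
                          rep = 1:3)
  cell_mean <- c(a1b1 = 0.2, a1b2 = 0.4, a2b1 = 0.5, a2b2 = 0.3)
  d$v <- cell_mean[paste0(d$a, d$b)] + round(rnorm(nrow(d), sd = 0.05), 3)
  oracle <- anova_balanced_oracle(d$v, d$a, d$b)
  fit <- two_way_anova(d, v, a, b)
  tab <- tidy(fit)
  expect_equal(tab$statistic, unname(oracle$F), tolerance = 1e-10)
  expect_equal(tab$df, unname(oracle$df[1:3]))
  expect_equal(tab$df_residual, rep(unname(oracle$df["e"]), 3))
  expect_equal(tab$p_raw,
               pf(unname(oracle$F), oracle$df[1:3], oracle$df["e"],
                  lower.tail = FALSE),
               tolerance = 1e-10)
})

test_that("ANOVA handles constant responses and degenerate factors", {
  d <- tidyr::expand_grid(a = c("x", "y"), b = c("p", "q"), rep = 1:2)
  d$v <- 0.3
  tab <- tidy(two_way_anova(d, v, a, b))
  expect_equal(tab$statistic, c(0, 0, 0))
  expect_equal(tab$p_raw, c(1, 1, 1))

  d$b <- "p"
  expect_error(two_way_anova(d, v, a, b), "fewer than 2 levels")
})

test_that("glance on an ANOVA fit reports fit-level statistics", {
  scores <- accessibility_score(
    dplyr::filter(generate_records(default_config(300, seed = 12)),
                  study_type != "NON_EMPIRICAL"))
  fit <- two_way_anova(scores, score, study_type, journal)
  g <- glance(fit)
  expect_identical(g$nobs, nrow(scores))
  expect_true(g$r.squared >= 0 && g$r.squared <= 1)
})

test_that("chi-squared homogeneity uses margin-derived expected counts", {
  r <- chi2_homogeneity(rbind(c(10, 10), c(10, 10)))
  expect_equal(r$statistic, 0)
  expect_equal(r$p_raw, 1)

  r <- chi2_homogeneity(rbind(c(20, 80), c(40, 60)))
  expect_equal(r$statistic, 200 / 21, tolerance = 1e-12)  # ~9.524
  expect_identical(r$df, 1)
  expect_identical(r$method, "CHI2")

  expect_error(chi2_homogeneity(rbind(c(0, 0), c(5, 5))), "zero row total")
  expect_error(chi2_homogeneity(rbind(c(0, 5), c(0, 5))), "zero column total")
  expect_error(chi2_homogeneity(rbind(c(1, -1), c(2, 2))), "nonnegative")
})

test_that("chi-squared agrees with stats::chisq.test and the 2x2 z-squared form", {
  set.seed(2024)
  for (i in 1:25) {
    k <- sample(2:5, 1)
    m <- matrix(rpois(2 * k, 12) + 1, ncol = 2)
    r <- chi2_homogeneity(m)
    ref <- suppressWarnings(chisq.test(m, correct = FALSE))
    expect_equal(r$statistic, unname(ref$statistic), tolerance = 1e-12)
    expect_equal(r$p_raw, ref$p.value, tolerance = 1e-12)
    # invariance under row permutation
    perm <- m[sample(nrow(m)), , drop = FALSE]
    expect_equal(chi2_homogeneity(perm)$statistic, r$statistic,
                 tolerance = 1e-12)
  }
  # 2x2 statistic equals the two-proportion z^2 without correction
  m <- rbind(c(20, 80), c(40, 60))
  p1 <- 20 / 100; p2 <- 40 / 100; pp <- 60 / 200
  z <- (p1 - p2) / sqrt(pp * (1 - pp) * (1 / 100 + 1 / 100))
  expect_equal(chi2_homogeneity(m)$statistic, z^2, tolerance = 1e-12)
})

test_that("Fisher's exact test follows the two-sided point-probability rule", {
  expect_equal(fisher_exact_2x2(rbind(c(1, 1), c(1, 1)))$p_raw, 1)
  r <- fisher_exact_2x2(rbind(c(0, 5), c(5, 0)))
  expect_equal(r$p_raw, 2 / 252, tolerance = 1e-12)
  expect_identical(r$method, "FISHER")

  m <- rbind(c(5, 0), c(1, 4))
  expect_equal(fisher_exact_2x2(m)$p_raw, fisher_brute(m), tolerance = 1e-12)

  set.seed(7)
  for (i in 1:200) {
    m <- matrix(sample(0:10, 4, replace = TRUE), 2)
    if (sum(m) == 0) next
    p <- fisher_exact_2x2(m)$p_raw
    expect_equal(p, fisher_brute(m), tolerance = 1e-12)
    expect_equal(p, fisher.test(m)$p.value, tolerance = 1e-7)
  }
})

test_that("Bonferroni multiplies by the family size and caps at 1", {
  expect_identical(bonferroni_adjust(0.3, m = 6), 1)
  expect_equal(bonferroni_adjust(0.01, m = 4), 0.04)
  expect_identical(bonferroni_adjust(0), 0)
  set.seed(5)
  for (i in 1:20) {
    p <- runif(sample(1:8, 1))
    m <- length(p) + sample(0:5, 1)
    adj <- bonferroni_adjust(p, m)
    expect_true(all(adj <= 1))
    expect_true(all(adj >= p))
    expect_identical(order(adj), order(pmin(1, p * m)))
    expect_equal(adj, p.adjust(p, method = "bonferroni", n = m),
                 tolerance = 1e-15)
  }
  expect_error(bonferroni_adjust(1.2), "\\[0, 1\\]")
  expect_error(bonferroni_adjust(c(0.1, 0.2), m = 1), "at least")
})

test_that("resource battery emits omnibus and all pairwise tests with Fisher on zero cells", {
  recs <- dplyr::bind_rows(
    records_with_pattern("CLINICAL_TRIAL", 12, 40, "data", prefix = "ct"),
    records_with_pattern("CLINICAL_OBSERVATIONAL", 8, 40, "data", prefix = "co"),
    records_with_pattern("LAB_ANIMAL", 20, 40, "data", prefix = "la"),
    records_with_pattern("CASE_STUDY_OR_SERIES", 2, 40, "data", prefix = "cs")
  )
  # lab animal alone shares scripts; all other types have a zero cell there
  idx <- which(recs$study_type == "LAB_ANIMAL")[1:10]
  recs$scripts_statement[idx] <- "YES_AVAILABLE"
  recs$scripts_mode[idx] <- "REPOSITORY"
  recs$scripts_accessible[idx] <- "NO"
  b <- resource_battery(recs, min_n = 15)
  expect_identical(nrow(b$pairwise), 24L)                 # C(4,2) * 4
  expect_identical(as.integer(table(b$pairwise$resource)[c("data", "scripts")]),
                   c(6L, 6L))
  scripts_la <- b$pairwise$resource == "scripts" &
    (b$pairwise$type_a == "LAB_ANIMAL" | b$pairwise$type_b == "LAB_ANIMAL")
  expect_true(all(b$pairwise$method[scripts_la] == "FISHER"))
  expect_true(all(b$pairwise$p_adjusted >= b$pairwise$p_raw))
  expect_identical(nrow(b$omnibus), 4L)
  g <- glance(b)
  expect_identical(g$n_pairwise, 24L)
  expect_gt(g$n_fisher, 0L)
})

test_that("identical groups give p = 1 before and after adjustment", {
  recs <- dplyr::bind_rows(
    records_with_pattern("CLINICAL_TRIAL", 10, 30, "data", prefix = "ct"),
    records_with_pattern("LAB_ANIMAL", 10, 30, "data", prefix = "la")
  )
  b <- resource_battery(recs, min_n = 15)
  row <- b$pairwise[b$pairwise$resource == "data", ]
  expect_equal(row$p_raw, 1)
  expect_equal(row$p_adjusted, 1)
})

test_that("small study types are excluded and under-powered sets refuse to run", {
  recs <- dplyr::bind_rows(
    records_with_pattern("CLINICAL_TRIAL", 10, 30, "data", prefix = "ct"),
    records_with_pattern("LAB_ANIMAL", 10, 30, "data", prefix = "la"),
    records_with_pattern("LAB_CELL_MOLECULAR", 1, 5, "data", prefix = "lc")
  )
  b <- resource_battery(recs, min_n = 15)
  expect_setequal(b$settings$eligible_types,
                  c("CLINICAL_TRIAL", "LAB_ANIMAL"))
  expect_error(resource_battery(recs, min_n = 50), "fewer than 2")
})

test_that("materials comparisons skip study types that cannot share materials", {
  recs <- dplyr::bind_rows(
    records_with_pattern("CLINICAL_TRIAL", 10, 30, "data", prefix = "ct"),
    records_with_pattern("LAB_ANIMAL", 10, 30, "data", prefix = "la"),
    records_with_pattern("META_ANALYSIS_SYSTEMATIC_REVIEW", 10, 30, "data",
                         prefix = "ma")
  )
  b <- resource_battery(recs, min_n = 15)
  mat <- b$counts[b$counts$resource == "materials", ]
  expect_false("META_ANALYSIS_SYSTEMATIC_REVIEW" %in% mat$study_type)
  expect_identical(sum(b$pairwise$resource == "materials"), 1L)  # C(2,2)=1 pair
  expect_identical(sum(b$pairwise$resource == "data"), 3L)
})
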