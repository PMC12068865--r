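# The comparison battery: group summaries, unbalanced two-way ANOVA of the
# accessibility score on study type and journal, k x 2 chi-squared tests of
# homogeneity, Fisher's exact fallback for tables with empty cells, and
# Bonferroni correction with a ceiling at 1.

new_test_result <- function(method, statistic, df, p_raw, p_adjusted = NA_real_) {
  tibble::tibble(method = method, statistic = statistic, df = df,
                 p_raw = p_raw, p_adjusted = p_adjusted)
}

#' Per-group summaries of a score
#'
#' @param data A data frame.
#' @param group,value Columns (unquoted) holding the group label and the
#'   numeric value.
#' @return A tibble with one row per group: `group`, `n`, `mean`, `sd`
#'   (sample SD; `NA` for singleton groups).
#' @export
#' @examples
#' group_summary(accessibility_score(
#'   dplyr::filter(generate_records(default_config(200, seed = 3)),
#'                 study_type != "NON_EMPIRICAL")),
#'   study_type, score)
group_summary <- function(data, group, value) {
  stopifnot(is.data.frame(data))
  if (nrow(data) == 0) stop("no observations to summarise", call. = FALSE)
  dplyr::summarise(
    dplyr::group_by(data, group = {{ group }}),
    n = dplyr::n(),
    mean = mean({{ value }}),
    sd = ifelse(dplyr::n() > 1, stats::sd({{ value }}), NA_real_),
    .groups = "drop"
  )
}

#' Two-way ANOVA of a score on two factors
#'
#' Fits `value ~ a * b` by least squares and tests both main effects and the
#' interaction. Designs are typically unbalanced (study types are not evenly
#' represented across journals), so main effects use Type II sums of squares
#' via [car::Anova()]; the interaction is tested from the full model. An
#' effect whose sum of squares is exactly zero (e.g. a constant response) is
#' reported as F = 0, p = 1.
#'
#' @param data A data frame.
#' @param value,a,b Columns (unquoted): numeric response and the two factors.
#' @return An object of class `transcreen_anova`; see [tidy()] and
#'   [glance()] methods, or `$table` for the effect-level results.
#' @export
#' @examples
#' scores <- accessibility_score(
#'   dplyr::filter(generate_records(default_config(400, seed = 11)),
#'                 study_type != "NON_EMPIRICAL"))
#' fit <- two_way_anova(scores, score, study_type, journal)
#' tidy(fit)
two_way_anova <- function(data, value, a, b) {
  stopifnot(is.data.frame(data))
  df <- tibble::tibble(
    value = dplyr::pull(data, {{ value }}),
    a = factor(dplyr::pull(data, {{ a }})),
    b = factor(dplyr::pull(data, {{ b }}))
  )
  df <- droplevels(df[stats::complete.cases(df), ])
  name_a <- rlang::as_name(rlang::enquo(a))
  name_b <- rlang::as_name(rlang::enquo(b))
  for (f in c("a", "b")) {
    if (nlevels(df[[f]]) < 2) {
      stop("factor '", if (f == "a") name_a else name_b,
           "' has fewer than 2 levels", call. = FALSE)
    }
  }
  fit <- stats::lm(value ~ a * b, data = df)
  rows <- c("a", "b", "a:b")
  if (stats::var(df$value) < .Machine$double.eps) {
    # constant response: every effect is absent (0/0 read as F = 0)
    an1 <- suppressWarnings(stats::anova(fit))
    df1 <- an1[rows, "Df"]
    df2 <- an1["Residuals", "Df"]
    fstat <- rep(0, 3)
    pval <- rep(1, 3)
  } else {
    an <- car::Anova(fit, type = 2, singular.ok = TRUE)
    ss <- an[rows, "Sum Sq"]
    df1 <- an[rows, "Df"]
    df2 <- an["Residuals", "Df"]
    fstat <- an[rows, "F value"]
    pval <- an[rows, "Pr(>F)"]
    # an individual zero effect is absent, not undefined
    zero <- !is.na(ss) & ss < .Machine$double.eps * max(1, sum(an$`Sum Sq`))
    fstat[zero] <- 0
    pval[zero] <- 1
  }
  table <- tibble::tibble(
    term = c(name_a, name_b, paste0(name_a, ":", name_b)),
    method = "ANOVA_F",
    df = df1, df_residual = df2,
    statistic = fstat, p_raw = pval, p_adjusted = NA_real_
  )
  structure(list(table = table, fit = fit,
                 factors = c(name_a, name_b)),
            class = "transcreen_anova")
}

#' @export
print.transcreen_anova <- function(x, ...) {
  cat("Two-way ANOVA (Type II):", x$factors[1], "*", x$factors[2], "\n")
  print(x$table, ...)
  invisible(x)
}

#' Chi-squared test of homogeneity for a k x 2 table
#'
#' Pearson's statistic `sum((O - E)^2 / E)` with expected counts from the
#' row/column margins, `k - 1` degrees of freedom, and no continuity
#' correction. Every row total and both column totals must be positive; for
#' sparse 2 x 2 tables use [fisher_exact_2x2()] instead.
#'
#' @param counts A k x 2 matrix (or data frame) of nonnegative integers,
#'   columns = (yes, no), rows = groups; row names label the groups.
#' @return A one-row tibble: `method` (`"CHI2"`), `statistic`, `df`, `p_raw`,
#'   `p_adjusted` (`NA`).
#' @export
#' @examples
#' chi2_homogeneity(rbind(c(20, 80), c(40, 60)))  # statistic ~ 9.524
chi2_homogeneity <- function(counts) {
  counts <- as.matrix(counts)
  if (ncol(counts) != 2 || nrow(counts) < 2) {
    stop("counts must be a k x 2 table with k >= 2", call. = FALSE)
  }
  if (any(counts < 0) || any(counts != round(counts))) {
    stop("counts must be nonnegative integers", call. = FALSE)
  }
  rt <- rowSums(counts)
  ct <- colSums(counts)
  if (any(rt == 0)) stop("zero row total: every group needs observations",
                         call. = FALSE)
  if (any(ct == 0)) {
    stop("zero column total: no variation in the outcome; ",
         "use fisher_exact_2x2() for sparse 2 x 2 tables", call. = FALSE)
  }
  n <- sum(counts)
  expected <- outer(rt, ct) / n
  statistic <- sum((counts - expected)^2 / expected)
  df <- nrow(counts) - 1
  new_test_result("CHI2", statistic, df,
                  stats::pchisq(statistic, df, lower.tail = FALSE))
}

#' Fisher's exact test for a 2 x 2 table
#'
#' Two-sided exact test with margins fixed. The p-value follows the
#' point-probability rule: the sum of hypergeometric point probabilities of
#' all tables (with the observed margins) no more probable than the observed
#' one. The `statistic` column carries the observed table's point
#' probability.
#'
#' @param counts A 2 x 2 matrix of nonnegative integers.
#' @return A one-row tibble: `method` (`"FISHER"`), `statistic`, `df` (`NA`),
#'   `p_raw`, `p_adjusted` (`NA`).
#' @export
#' @examples
#' fisher_exact_2x2(rbind(c(0, 5), c(5, 0)))  # p = 2/252
fisher_exact_2x2 <- function(counts) {
  counts <- as.matrix(counts)
  if (!all(dim(counts) == c(2, 2))) stop("counts must be 2 x 2", call. = FALSE)
  if (any(counts < 0) || any(counts != round(counts))) {
    stop("counts must be nonnegative integers", call. = FALSE)
  }
  r1 <- sum(counts[1, ]); r2 <- sum(counts[2, ]); c1 <- sum(counts[, 1])
  if (r1 + r2 == 0) return(new_test_result("FISHER", 1, NA_real_, 1))
  support <- max(0, c1 - r2):min(r1, c1)
  dens <- stats::dhyper(support, r1, r2, c1)
  d_obs <- dens[support == counts[1, 1]]
  # relative tolerance guards against ties broken by floating-point noise
  p <- sum(dens[dens <= d_obs * (1 + 1e-7)])
  new_test_result("FISHER", d_obs, NA_real_, min(p, 1))
}

#' Bonferroni correction with a ceiling at 1
#'
#' Multiplies each raw p-value by the number of tests in the family and
#' truncates values above 1 to exactly 1 (a probability cannot exceed 1).
#'
#' @param p Numeric vector of raw p-values in \[0, 1\].
#' @param m Family size; defaults to `length(p)` and must be at least that.
#' @return Adjusted p-values, in input order.
#' @export
#' @examples
#' bonferroni_adjust(0.3, m = 6)  # 1
bonferroni_adjust <- function(p, m = length(p)) {
  if (any(is.na(p)) || any(p < 0) || any(p > 1)) {
    stop("p-values must lie in [0, 1]", call. = FALSE)
  }
  if (m < length(p)) stop("m must be at least length(p)", call. = FALSE)
  pmin(1, m * p)
}

# yes/no counts per (resource, group) from an availability table
resource_counts <- function(avail, groups, resources) {
  purrr::map_dfr(resources, function(res) {
    tb <- dplyr::summarise(
      dplyr::group_by(tibble::tibble(group = groups, yes = avail[[res]]),
                      .data$group),
      yes = sum(.data$yes), n = dplyr::n(), .groups = "drop"
    )
    tibble::tibble(resource = res, study_type = as.character(tb$group),
                   yes = as.integer(tb$yes), no = as.integer(tb$n - tb$yes))
  })
}

#' Resource-sharing comparison battery
#'
#' For each of the four resource categories (materials, methods, data,
#' analysis scripts), compares sharing proportions across study types:
#' first an omnibus k x 2 chi-squared test of homogeneity across all
#' eligible study types, then every pairwise 2 x 2 comparison. A pairwise
#' table with an empty cell falls back to Fisher's exact test (optionally
#' any expected count below 5 via `fallback = "expected"`). Bonferroni
#' correction is applied per family: the omnibus family spans the resources,
#' the pairwise family spans all pairwise tests across resources; both
#' family sizes can be overridden. Study types with fewer than `min_n`
#' articles are excluded, and study types that cannot have shareable
#' materials are excluded from the materials comparisons.
#'
#' @param records A valid screening-record tibble; non-empirical articles
#'   are ignored.
#' @param min_n Minimum articles per study type for inclusion (default 15).
#' @param basis Availability basis passed to [resource_availability()].
#' @param fallback `"zero-cell"` (default): Fisher's exact test whenever a
#'   pairwise table has an observed 0; `"expected"`: also whenever any
#'   expected count is below 5.
#' @param m_omnibus,m_pairwise Bonferroni family sizes; default to the
#'   number of omnibus and pairwise tests actually performed.
#' @param alpha Significance threshold applied to adjusted p-values
#'   (default 0.05).
#' @return An object of class `resource_battery`: a list with tibbles
#'   `counts` (per resource x study type yes/no), `omnibus` and `pairwise`,
#'   plus the settings used. [tidy()] returns the pairwise table,
#'   [glance()] a one-row summary.
#' @export
resource_battery <- function(records, min_n = 15,
                             basis = c("statement", "accessible"),
                             fallback = c("zero-cell", "expected"),
                             m_omnibus = NULL, m_pairwise = NULL,
                             alpha = 0.05) {
  basis <- match.arg(basis)
  fallback <- match.arg(fallback)
  emp <- records[records$study_type != "NON_EMPIRICAL", , drop = FALSE]
  avail <- resource_availability(emp, basis = basis)
  type_n <- table(emp$study_type)
  eligible <- names(type_n)[type_n >= min_n]
  if (length(eligible) < 2) {
    stop("fewer than 2 study types with at least ", min_n,
         " articles; cannot compare", call. = FALSE)
  }
  keep <- emp$study_type %in% eligible
  avail <- avail[keep, , drop = FALSE]
  groups <- emp$study_type[keep]
  resources <- c("materials", "methods", "data", "scripts")
  counts <- resource_counts(avail, groups, resources)
  # meta-analyses etc. cannot share materials: drop them from that resource
  counts <- counts[!(counts$resource == "materials" &
                       counts$study_type %in% materials_incapable_types()), ]

  omnibus <- purrr::map_dfr(resources, function(res) {
    tb <- counts[counts$resource == res, ]
    m <- as.matrix(tb[, c("yes", "no")])
    rownames(m) <- tb$study_type
    r <- tryCatch(chi2_homogeneity(m), error = function(e) {
      new_test_result("CHI2", NA_real_, NA_real_, NA_real_)
    })
    dplyr::bind_cols(tibble::tibble(resource = res, n_types = nrow(tb)), r)
  })
  pairwise <- purrr::map_dfr(resources, function(res) {
    tb <- counts[counts$resource == res, ]
    if (nrow(tb) < 2) return(NULL)
    pairs <- utils::combn(seq_len(nrow(tb)), 2)
    purrr::map_dfr(seq_len(ncol(pairs)), function(j) {
      i1 <- pairs[1, j]; i2 <- pairs[2, j]
      m <- rbind(c(tb$yes[i1], tb$no[i1]), c(tb$yes[i2], tb$no[i2]))
      use_fisher <- any(m == 0)
      if (!use_fisher && fallback == "expected") {
        expected <- outer(rowSums(m), colSums(m)) / sum(m)
        use_fisher <- any(expected < 5)
      }
      r <- if (use_fisher) fisher_exact_2x2(m) else chi2_homogeneity(m)
      dplyr::bind_cols(
        tibble::tibble(resource = res,
                       type_a = tb$study_type[i1], type_b = tb$study_type[i2],
                       yes_a = tb$yes[i1], no_a = tb$no[i1],
                       yes_b = tb$yes[i2], no_b = tb$no[i2]),
        r
      )
    })
  })
  m_om <- if (is.null(m_omnibus)) nrow(omnibus) else m_omnibus
  m_pw <- if (is.null(m_pairwise)) nrow(pairwise) else m_pairwise
  ok <- !is.na(omnibus$p_raw)
  omnibus$p_adjusted[ok] <- bonferroni_adjust(omnibus$p_raw[ok], m = m_om)
  pairwise$p_adjusted <- bonferroni_adjust(pairwise$p_raw, m = m_pw)
  pairwise$significant <- pairwise$p_adjusted < alpha
  structure(
    list(counts = counts, omnibus = omnibus, pairwise = pairwise,
         settings = list(min_n = min_n, basis = basis, fallback = fallback,
                         m_omnibus = m_om, m_pairwise = m_pw, alpha = alpha,
                         eligible_types = sort(eligible))),
    class = "resource_battery"
  )
}

#' @export
print.resource_battery <- function(x, ...) {
  cat("Resource-sharing battery over study types:",
      paste(x$settings$eligible_types, collapse = ", "), "\n\n")
  cat("Omnibus tests (Bonferroni m =", x$settings$m_omnibus, "):\n")
  print(x$omnibus, ...)
  cat("\nPairwise tests (Bonferroni m =", x$settings$m_pairwise, "):\n")
  print(x$pairwise, ...)
  invisible(x)
}
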