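# Corpus-level summary: tallies and percentages for every screened item,
# the accessibility-score distribution, repeatability counts, and the
# comparison battery. Percentages are rounded half away from zero, the
# convention under which 7/393 prints as 2% and 56/393 as 14%.

round_half_away <- function(x, digits = 0) {
  f <- 10^digits
  sign(x) * floor(abs(x) * f + 0.5) / f
}

#' Percentage with half-away-from-zero rounding
#'
#' `percent_value()` returns the numeric percentage rounded half away from
#' zero to `decimals` places; `percent()` formats it with a `%` suffix.
#'
#' @param numerator,denominator Nonnegative counts, `numerator <=
#'   denominator`, `denominator > 0`. Vectorised.
#' @param decimals Decimal places (default 0).
#' @return `percent_value()`: numeric; `percent()`: character.
#' @export
#' @examples
#' percent(56, 393)        # "14%"
#' percent(125, 393, 1)    # "31.8%"
percent_value <- function(numerator, denominator, decimals = 0) {
  if (any(denominator <= 0)) stop("denominator must be positive",
                                  call. = FALSE)
  if (any(numerator < 0 | numerator > denominator)) {
    stop("numerator must lie in [0, denominator]", call. = FALSE)
  }
  round_half_away(100 * numerator / denominator, decimals)
}

#' @rdname percent_value
#' @export
percent <- function(numerator, denominator, decimals = 0) {
  v <- percent_value(numerator, denominator, decimals)
  paste0(formatC(v, format = "f", digits = decimals), "%")
}

#' Histogram of accessibility scores
#'
#' Bins scores into ten left-closed bins of width 0.1 (`0.00-0.09`,
#' `0.10-0.19`, ..., `0.90-1.00`); a score of exactly 1 falls in the top
#' bin. Counts sum to the number of scores.
#'
#' @param scores Numeric vector of scores in \[0, 1\].
#' @return A tibble with columns `bin`, `lower`, `upper`, `count`.
#' @export
#' @examples
#' score_histogram(c(0, 0.25, 0.25, 1))
score_histogram <- function(scores) {
  if (any(is.na(scores)) || any(scores < 0 | scores > 1)) {
    stop("scores must lie in [0, 1]", call. = FALSE)
  }
  lower <- seq(0, 0.9, by = 0.1)
  idx <- pmin(floor(scores * 10), 9) + 1
  tibble::tibble(
    bin = sprintf("%.2f-%.2f", lower, c(lower[-1] - 0.01, 1)),
    lower = lower,
    upper = c(lower[-1], 1),
    count = as.integer(tabulate(idx, nbins = 10))
  )
}

count_pct <- function(x, levels, denominator = length(x)) {
  cnt <- as.integer(table(factor(x, levels = levels)))
  tibble::tibble(
    level = levels, count = cnt, denominator = denominator,
    pct_0dp = percent_value(cnt, denominator, 0),
    pct_1dp = percent_value(cnt, denominator, 1)
  )
}

availability_chain <- function(records, res) {
  st <- records[[paste0(res, "_statement")]]
  acc <- records[[paste0(res, "_accessible")]]
  out <- tibble::tibble(
    resource = res,
    n = nrow(records),
    n_stated_available = sum(st == "YES_AVAILABLE"),
    n_states_unavailable = sum(st == "STATES_UNAVAILABLE"),
    n_no_statement = sum(st == "NO_STATEMENT"),
    n_not_applicable = sum(st == "NOT_APPLICABLE"),
    n_accessible = sum(acc == "YES")
  )
  if (res == "data") {
    out$n_documented <- sum(records$data_documented == "YES")
    out$n_complete <- sum(records$data_complete == "YES")
  }
  out
}

#' Summarise a screening corpus
#'
#' Produces the full tabular summary of a screened record set: corpus
#' composition (journal and study-type mix, study-type clarity), items
#' screened for all articles (conflict-of-interest, funding, open access),
#' resource-availability chains and claimed-availability modes for
#' empirical articles, pre-registration and protocol aspect tallies,
#' accessibility-score distribution and per-group summaries, potential
#' repeatability counts, and (optionally) the resource-sharing comparison
#' battery. A pure function of its inputs: repeated calls on the same
#' records give identical reports.
#'
#' @param records A valid screening-record tibble.
#' @param run_battery Run [resource_battery()] (default `TRUE`; skipped with
#'   a note when fewer than two study types are eligible).
#' @param min_n Minimum per-type sample size for the battery.
#' @return An object of class `screening_summary` (a list of tibbles and
#'   counts) with `print()` and [autoplot()] methods, and
#'   [summary_to_json()] for machine-readable export.
#' @export
#' @examples
#' s <- summarize_records(generate_records(default_config(200, seed = 5)))
#' s$repeatability
summarize_records <- function(records, run_battery = TRUE, min_n = 15) {
  assert_valid_records(records)
  if (nrow(records) == 0) stop("empty record set", call. = FALSE)
  vocab <- screening_vocab()
  emp <- records[records$study_type != "NON_EMPIRICAL", , drop = FALSE]
  n_total <- nrow(records)
  n_emp <- nrow(emp)

  corpus <- list(
    n_total = n_total,
    n_empirical = n_emp,
    n_non_empirical = n_total - n_emp,
    journals = count_pct(records$journal, vocab$journal),
    study_types = count_pct(records$study_type, vocab$study_type),
    clarity = count_pct(ifelse(records$study_type_stated, "STATED",
                               "INFERRED"), c("STATED", "INFERRED")),
    coi = count_pct(records$coi_statement, vocab$coi),
    funding = count_pct(records$funding_statement, vocab$funding),
    open_access = count_pct(records$open_access, vocab$open_access)
  )

  availability <- NULL; modes <- NULL; prereg <- NULL; scores <- NULL
  histogram <- NULL; by_type <- NULL; by_journal <- NULL
  repeatability <- NULL; battery <- NULL; battery_note <- NULL
  if (n_emp > 0) {
    availability <- dplyr::bind_rows(
      availability_chain(emp, "materials"),
      availability_chain(emp, "data"),
      availability_chain(emp, "scripts")
    )
    modes <- purrr::map_dfr(c("materials", "data", "scripts"), function(res) {
      stated <- emp[emp[[paste0(res, "_statement")]] == "YES_AVAILABLE", ]
      if (nrow(stated) == 0) return(NULL)
      dplyr::bind_cols(tibble::tibble(resource = res),
                       count_pct(stated[[paste0(res, "_mode")]],
                                 setdiff(vocab$mode, "NONE")))
    })
    comp <- prereg_completeness(emp)
    prereg <- list(
      n_stated = sum(emp$prereg_statement == "YES"),
      n_accessible = sum(emp$prereg_accessible == "YES"),
      n_protocol_linked = sum(emp$protocol_linked),
      completeness = tibble::tibble(
        n_aspects = 0:3,
        count = as.integer(tabulate(comp$n_aspects + 1L, nbins = 4))
      )
    )
    scores <- accessibility_score(emp)
    histogram <- score_histogram(scores$score)
    by_type <- group_summary(scores, study_type, score)
    by_journal <- group_summary(scores, journal, score)
    cls <- classify_repeatability(resource_availability(emp))
    tally3 <- function(x) {
      c(NONE = sum(x == "NONE"), PARTIAL = sum(x == "PARTIAL"),
        FULL = sum(x == "FULL"))
    }
    repeatability <- tibble::tibble(
      status = c("NONE", "PARTIAL", "FULL"),
      replicable = as.integer(tally3(cls$replicable)),
      reproducible = as.integer(tally3(cls$reproducible))
    )
    repeat_pct <- tibble::tibble(
      quantity = c("not_partially_replicable", "not_partially_reproducible",
                   "partially_repeatable", "fully_replicable",
                   "fully_reproducible"),
      count = c(sum(cls$replicable == "NONE"),
                sum(cls$reproducible == "NONE"),
                sum(cls$partially_repeatable),
                sum(cls$replicable == "FULL"),
                sum(cls$reproducible == "FULL")),
      denominator = n_emp
    )
    repeat_pct$pct_1dp <- percent_value(repeat_pct$count, n_emp, 1)
    if (run_battery) {
      battery <- tryCatch(resource_battery(records, min_n = min_n),
                          error = function(e) {
                            battery_note <<- conditionMessage(e)
                            NULL
                          })
    }
  } else {
    repeat_pct <- NULL
  }

  structure(
    list(provenance = attr(records, "provenance") %||% "unspecified",
         corpus = corpus, availability = availability, modes = modes,
         prereg = prereg, scores = scores, histogram = histogram,
         by_study_type = by_type, by_journal = by_journal,
         repeatability = repeatability, repeatability_pct = repeat_pct,
         battery = battery, battery_note = battery_note),
    class = "screening_summary"
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.screening_summary <- function(x, ...) {
  c0 <- x$corpus
  cat("## Screening summary (", c0$n_total, " articles, ",
      c0$n_empirical, " empirical)\n", sep = "")
  cat("provenance: ", x$provenance, "\n\n", sep = "")
  cat("### Corpus composition\n")
  print(c0$journals); cat("\n")
  print(c0$study_types); cat("\n")
  cat("### Conflict of interest / funding / open access (all articles)\n")
  print(c0$coi); print(c0$funding); print(c0$open_access); cat("\n")
  if (!is.null(x$availability)) {
    cat("### Resource availability (empirical articles)\n")
    print(x$availability); cat("\n")
    cat("### Accessibility scores\n")
    print(x$histogram)
    cat("\nby study type:\n"); print(x$by_study_type)
    cat("\nby journal:\n"); print(x$by_journal); cat("\n")
    cat("### Potential repeatability\n")
    print(x$repeatability)
    print(x$repeatability_pct); cat("\n")
    if (!is.null(x$battery)) print(x$battery)
    if (!is.null(x$battery_note)) {
      cat("battery skipped:", x$battery_note, "\n")
    }
  }
  invisible(x)
}

#' Export a screening summary as JSON
#'
#' @param summary A `screening_summary` from [summarize_records()].
#' @param path Optional output file; if `NULL` the JSON string is returned.
#' @return JSON string (invisibly when written to a file).
#' @export
summary_to_json <- function(summary, path = NULL) {
  stopifnot(inherits(summary, "screening_summary"))
  x <- unclass(summary)
  x$battery <- if (!is.null(x$battery)) unclass(x$battery)[c(
    "counts", "omnibus", "pairwise", "settings")]
  js <- jsonlite::toJSON(x, dataframe = "rows", na = "null",
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  if (is.null(path)) return(js)
  writeLines(js, path)
  invisible(js)
}
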