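# Potential replicability / reproducibility of an article, inferred from
# which of four resource categories it makes available:
#   replicable   triple: materials, analysis scripts, methods
#   reproducible triple: data,      analysis scripts, methods
# "Methods" means an accessible pre-registration or a linked protocol.
# PARTIAL = at least one of the triple, FULL = all three. The classifier
# captures the *potential* for repetition only; nothing is re-executed.

#' Resource availability per article
#'
#' Reduces each empirical record to four booleans: are materials, data and
#' analysis scripts stated available, and are methods present (an accessible
#' pre-registration or a linked protocol).
#'
#' @param records A valid screening-record tibble of empirical articles.
#' @param basis `"statement"` (default) takes an availability statement at
#'   its word; `"accessible"` additionally requires that the screener could
#'   access, download and open the files.
#' @param require_methods_aspect If `TRUE`, "methods" additionally requires
#'   that the pre-registration or protocol actually contains the METHODS
#'   aspect; by default mere presence suffices.
#' @return A tibble with columns `article_id`, `materials`, `data`,
#'   `scripts`, `methods` (logical).
#' @export
resource_availability <- function(records, basis = c("statement", "accessible"),
                                  require_methods_aspect = FALSE) {
  basis <- match.arg(basis)
  assert_valid_records(records)
  if (any(records$study_type == "NON_EMPIRICAL")) {
    stop("resource availability is defined for empirical articles only",
         call. = FALSE)
  }
  if (basis == "statement") {
    materials <- records$materials_statement == "YES_AVAILABLE"
    data <- records$data_statement == "YES_AVAILABLE"
    scripts <- records$scripts_statement == "YES_AVAILABLE"
  } else {
    materials <- records$materials_accessible == "YES"
    data <- records$data_accessible == "YES"
    scripts <- records$scripts_accessible == "YES"
  }
  has_aspect <- function(col) {
    vapply(split_aspects(records[[col]]), function(t) "METHODS" %in% t,
           logical(1))
  }
  prereg_ok <- records$prereg_accessible == "YES"
  protocol_ok <- isTRUE_vec(records$protocol_linked)
  if (require_methods_aspect) {
    prereg_ok <- prereg_ok & has_aspect("prereg_aspects")
    protocol_ok <- protocol_ok & has_aspect("protocol_aspects")
  }
  tibble::tibble(
    article_id = records$article_id,
    materials = materials, data = data, scripts = scripts,
    methods = prereg_ok | protocol_ok
  )
}

status_from_triple <- function(a, b, c) {
  k <- a + b + c
  dplyr::case_when(k == 3 ~ "FULL", k >= 1 ~ "PARTIAL", TRUE ~ "NONE")
}

#' Classify potential replicability and reproducibility
#'
#' An article is partially replicable if any of materials, analysis scripts
#' or methods is available and fully replicable if all three are; partially /
#' fully reproducible uses data in place of materials. An article that is
#' either partially replicable or partially reproducible is partially
#' repeatable.
#'
#' @param avail A tibble with logical columns `materials`, `data`, `scripts`,
#'   `methods` (and optionally `article_id`), as from
#'   [resource_availability()].
#' @return `avail`'s identifier columns plus `replicable`, `reproducible`
#'   (each `"NONE"`, `"PARTIAL"` or `"FULL"`) and `partially_repeatable`.
#' @export
#' @examples
#' classify_repeatability(tibble::tibble(
#'   materials = FALSE, data = TRUE, scripts = TRUE, methods = TRUE))
classify_repeatability <- function(avail) {
  need <- c("materials", "data", "scripts", "methods")
  missing_cols <- setdiff(need, names(avail))
  if (length(missing_cols) > 0) {
    stop("missing availability column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  stopifnot(all(vapply(avail[need], is.logical, logical(1))))
  out <- tibble::as_tibble(avail)
  out$replicable <- status_from_triple(avail$materials, avail$scripts,
                                       avail$methods)
  out$reproducible <- status_from_triple(avail$data, avail$scripts,
                                         avail$methods)
  out$partially_repeatable <- out$replicable != "NONE" |
    out$reproducible != "NONE"
  out
}
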