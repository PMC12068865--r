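#' Build a screening-record table
#'
#' Assembles a tibble of screening records in canonical column order, filling
#' unspecified coding items with their neutral values (statements
#' `NOT_APPLICABLE`, modes `NONE`, tri-states `NOT_APPLICABLE`, aspect sets
#' empty, logicals `FALSE`). Useful for constructing small record sets in
#' tests and examples; bulk data normally arrives via [read_records()] or
#' [generate_records()].
#'
#' @param article_id Character vector of unique article identifiers
#'   (e.g. PMIDs or DOIs).
#' @param journal Journal token, one of `screening_vocab()$journal`.
#' @param study_type Study-type token, one of `screening_vocab()$study_type`.
#' @param ... Named record columns overriding the neutral defaults; each must
#'   be a valid column name (see `record_columns()`) and is recycled to the
#'   number of records.
#' @return A tibble with one row per article and the canonical columns.
#' @export
#' @examples
#' new_records("a1", "JACC", "CLINICAL_TRIAL",
#'             data_statement = "YES_AVAILABLE", data_mode = "REPOSITORY")
new_records <- function(article_id, journal, study_type, ...) {
  n <- length(article_id)
  base <- tibble::tibble(
    article_id = as.character(article_id),
    journal = rep_len(journal, n),
    study_type = rep_len(study_type, n),
    study_type_stated = FALSE,
    materials_statement = "NOT_APPLICABLE", materials_mode = "NONE",
    materials_accessible = "NOT_APPLICABLE",
    data_statement = "NOT_APPLICABLE", data_mode = "NONE",
    data_accessible = "NOT_APPLICABLE", data_documented = "NOT_APPLICABLE",
    data_complete = "NOT_APPLICABLE",
    scripts_statement = "NOT_APPLICABLE", scripts_mode = "NONE",
    scripts_accessible = "NOT_APPLICABLE",
    prereg_statement = "NO", prereg_accessible = "NOT_APPLICABLE",
    prereg_aspects = "",
    protocol_linked = FALSE, protocol_aspects = "",
    coi_statement = "ABSENT", funding_statement = "ABSENT",
    open_access = "NO", country = NA_character_
  )
  dots <- list(...)
  bad <- setdiff(names(dots), record_columns())
  if (length(bad) > 0) {
    stop("unknown record column(s): ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  for (nm in names(dots)) base[[nm]] <- rep_len(dots[[nm]], n)
  base[record_columns()]
}

#' Validate screening records
#'
#' Checks every record against the schema: known enum tokens in each
#' categorical column, logical coding flags, unique article identifiers, and
#' the gating invariants of the instrument — an accessibility answer is
#' `NOT_APPLICABLE` unless its parent availability statement is
#' `YES_AVAILABLE`; data documentation and completeness follow the chain
#' statement -> accessible -> documented -> complete; a claimed-availability
#' mode is `NONE` exactly when nothing is stated available;
#' pre-registration aspects may be nonempty only when the pre-registration is
#' accessible, and protocol aspects only when a protocol is linked.
#'
#' Violations are returned, not raised, so a screening session can be audited
#' wholesale.
#'
#' @param records A screening-record tibble (see [new_records()]).
#' @return A tibble with columns `row`, `article_id`, `field`, `message`;
#'   zero rows when all records are valid.
#' @export
#' @examples
#' r <- new_records("a1", "EHJ", "CLINICAL_TRIAL")
#' validate_records(r)          # 0 rows
#' r$materials_accessible <- "YES"
#' validate_records(r)          # names materials_accessible
validate_records <- function(records) {
  stopifnot(is.data.frame(records))
  missing_cols <- setdiff(record_columns(), names(records))
  if (length(missing_cols) > 0) {
    stop("missing required column(s): ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  }
  vocab <- screening_vocab()
  n <- nrow(records)
  out <- list()
  add <- function(rows, field, message) {
    if (length(rows) == 0) return(invisible(NULL))
    out[[length(out) + 1]] <<- tibble::tibble(
      row = rows,
      article_id = as.character(records$article_id[rows]),
      field = field, message = message
    )
  }

  dup <- duplicated(records$article_id)
  add(which(dup), "article_id", "duplicate article_id within the record set")
  add(which(is.na(records$article_id) | records$article_id == ""),
      "article_id", "article_id must be a nonempty string")

  enum_map <- record_enum_map()
  for (col in names(enum_map)) {
    legal <- vocab[[enum_map[[col]]]]
    bad <- which(!(records[[col]] %in% legal))
    add(bad, col, paste0("illegal token ",
                         ifelse(is.na(records[[col]][bad]), "<NA>",
                                paste0("'", records[[col]][bad], "'")),
                         " (expected one of: ",
                         paste(legal, collapse = ", "), ")"))
  }
  for (col in record_logical_columns()) {
    bad <- which(!is.logical(records[[col]]) | is.na(records[[col]]))
    add(bad, col, "must be TRUE or FALSE")
  }
  for (col in record_aspect_columns()) {
    toks <- split_aspects(records[[col]])
    bad <- which(vapply(toks, function(t) {
      any(!(t %in% vocab$aspect)) || anyDuplicated(t) > 0
    }, logical(1)))
    add(bad, col,
        "aspects must be distinct tokens from HYPOTHESES;METHODS;ANALYSIS_PLAN")
  }

  # gating invariants on the statement -> accessible chains
  for (res in c("materials", "data", "scripts")) {
    st <- records[[paste0(res, "_statement")]]
    acc <- records[[paste0(res, "_accessible")]]
    md <- records[[paste0(res, "_mode")]]
    gated_off <- st %in% c("NO_STATEMENT", "STATES_UNAVAILABLE",
                           "NOT_APPLICABLE")
    add(which(gated_off & acc != "NOT_APPLICABLE"),
        paste0(res, "_accessible"),
        "must be NOT_APPLICABLE when nothing is stated available")
    add(which(st == "YES_AVAILABLE" & !(acc %in% c("YES", "NO"))),
        paste0(res, "_accessible"),
        "must be YES or NO when availability is stated")
    add(which(gated_off & md != "NONE"), paste0(res, "_mode"),
        "must be NONE when nothing is stated available")
    add(which(st == "YES_AVAILABLE" & md == "NONE"), paste0(res, "_mode"),
        "a stated availability must claim a mode")
  }
  # data chain continues: accessible -> documented -> complete
  add(which(records$data_accessible != "YES" &
              records$data_documented != "NOT_APPLICABLE"),
      "data_documented",
      "must be NOT_APPLICABLE unless the data files are accessible")
  add(which(records$data_documented != "YES" &
              records$data_complete != "NOT_APPLICABLE"),
      "data_complete",
      "must be NOT_APPLICABLE unless the data files are documented")

  add(which(records$prereg_statement == "NO" &
              records$prereg_accessible != "NOT_APPLICABLE"),
      "prereg_accessible",
      "must be NOT_APPLICABLE when no pre-registration is stated")
  add(which(records$prereg_accessible != "YES" &
              records$prereg_aspects != ""),
      "prereg_aspects",
      "aspects require an accessible pre-registration")
  add(which(!isTRUE_vec(records$protocol_linked) &
              records$protocol_aspects != ""),
      "protocol_aspects", "aspects require a linked protocol")

  if (length(out) == 0) {
    tibble::tibble(row = integer(), article_id = character(),
                   field = character(), message = character())
  } else {
    dplyr::arrange(dplyr::bind_rows(out), .data$row, .data$field)
  }
}

isTRUE_vec <- function(x) !is.na(x) & x == TRUE

assert_valid_records <- function(records) {
  v <- validate_records(records)
  if (nrow(v) > 0) {
    stop("invalid screening records (", nrow(v), " violation(s)); first: row ",
         v$row[1], ", field ", v$field[1], ": ", v$message[1], call. = FALSE)
  }
  invisible(records)
}

#' Read screening records from CSV
#'
#' Reads a screening-record table written in the package's CSV dialect
#' (UTF-8, comma-separated, header row of snake_case column names,
#' UPPER_SNAKE enum tokens, aspect subsets as semicolon-joined tokens).
#'
#' @param path Path to a CSV file.
#' @param strict If `TRUE` (default), abort on the first invalid row; if
#'   `FALSE`, drop invalid rows with a message giving the counts.
#' @return A screening-record tibble; the `provenance` attribute records the
#'   source path.
#' @export
#' @seealso [write_records()], [validate_records()]
read_records <- function(path, strict = TRUE) {
  raw <- readr::read_csv(
    path,
    col_types = readr::cols(.default = readr::col_character()),
    progress = FALSE
  )
  missing_cols <- setdiff(record_columns(), names(raw))
  if (length(missing_cols) > 0) {
    stop("schema error: file lacks required column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  raw <- raw[record_columns()]
  for (col in record_logical_columns()) {
    val <- toupper(trimws(raw[[col]]))
    parsed <- ifelse(val %in% c("TRUE", "T", "1"), TRUE,
                     ifelse(val %in% c("FALSE", "F", "0"), FALSE, NA))
    raw[[col]] <- parsed
  }
  for (col in record_aspect_columns()) {
    raw[[col]][is.na(raw[[col]])] <- ""
  }
  v <- validate_records(raw)
  if (nrow(v) > 0) {
    if (strict) {
      stop("value error in ", basename(path), ", row ", v$row[1],
           ", column ", v$field[1], ": ", v$message[1], call. = FALSE)
    }
    bad_rows <- sort(unique(v$row))
    message("read_records: dropped ", length(bad_rows), " invalid row(s) of ",
            nrow(raw), " (", nrow(v), " violation(s))")
    raw <- raw[-bad_rows, , drop = FALSE]
  }
  attr(raw, "provenance") <- as.character(path)
  raw
}

#' Write screening records to CSV
#'
#' Writes the canonical CSV dialect; [read_records()] on the result
#' reproduces the records exactly (round trip is the identity on valid
#' record sets).
#'
#' @param records A valid screening-record tibble.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_records <- function(records, path) {
  assert_valid_records(records)
  readr::write_csv(records[record_columns()], path, na = "", progress = FALSE)
  invisible(path)
}

#' Export screening records as JSON
#'
#' @param records A valid screening-record tibble.
#' @param path Optional file path; if `NULL` the JSON string is returned.
#' @return The JSON string (invisibly when written to a file).
#' @export
records_to_json <- function(records, path = NULL) {
  assert_valid_records(records)
  js <- jsonlite::toJSON(records[record_columns()], dataframe = "rows",
                         na = "null", auto_unbox = FALSE, pretty = TRUE)
  if (is.null(path)) return(js)
  writeLines(js, path)
  invisible(js)
}
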