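# Delimiter sniffing: UKB gp_clinical / gp_scripts extracts are
# tab-delimited, but comma-delimited exports are common; accept both.
read_delim_auto <- function(path) {
  header <- readLines(path, n = 1L)
  if (length(header) == 0L) stop("empty file: ", path)
  sep <- if (grepl("\t", header, fixed = TRUE)) "\t" else ","
  utils::read.table(path, header = TRUE, sep = sep, quote = "\"",
                    colClasses = "character", stringsAsFactors = FALSE,
                    na.strings = character(), comment.char = "",
                    check.names = FALSE)
}

parse_iso_date <- function(x) {
  x <- trimws(as.character(x))
  d <- as.Date(rep(NA_integer_, length(x)), origin = "1970-01-01")
  ok <- grepl("^\\d{4}-\\d{2}-\\d{2}$", x)
  if (any(ok)) d[ok] <- as.Date(x[ok], format = "%Y-%m-%d")
  d
}

require_columns <- function(df, cols, path) {
  missing <- setdiff(cols, names(df))
  if (length(missing))
    stop("table ", path, " is missing mandatory column(s): ",
         paste(missing, collapse = ", "))
}

#' Read a primary-care clinical events table
#'
#' Expects a delimited table (tab or comma, header row) with the layout of a
#' UK general-practice clinical extract: columns `patient_id`, `event_dt`,
#' `read_2`, `read_3`. A row yields one event; when both code columns are
#' populated the Read v2 code is used (deterministic single-category
#' assignment). Rows with an unparseable or empty date, or with no code in
#' either column, are rejected and counted — the count is returned in the
#' result's attributes, never silently discarded.
#'
#' @param path path to the delimited file.
#' @param codelist a [codelist] used to assign diagnostic categories.
#' @return data.frame of clinical events with columns `patient_id`,
#'   `event_date` (Date), `code`, `code_system` ("READ2"/"CTV3"),
#'   `category`; attributes `n_rejected` (unparseable rows) and
#'   `n_unknown_codes` (codes mapped to the neutral category).
#' @export
read_clinical_table <- function(path, codelist) {
  df <- read_delim_auto(path)
  require_columns(df, c("patient_id", "event_dt"), path)
  if (!any(c("read_2", "read_3") %in% names(df)))
    stop("table ", path, " is missing mandatory column(s): read_2 or read_3")
  if (!"read_2" %in% names(df)) df$read_2 <- ""
  if (!"read_3" %in% names(df)) df$read_3 <- ""

  date <- parse_iso_date(df$event_dt)
  r2 <- trimws(df$read_2)
  r3 <- trimws(df$read_3)
  code <- ifelse(nzchar(r2), r2, r3)
  code_system <- ifelse(nzchar(r2), "READ2", "CTV3")
  keep <- !is.na(date) & nzchar(code)
  n_rejected <- sum(!keep)

  mapped <- map_diagnosis_codes(code[keep], codelist)
  out <- data.frame(
    patient_id = as.character(df$patient_id[keep]),
    event_date = date[keep],
    code = code[keep],
    code_system = code_system[keep],
    category = mapped$category,
    stringsAsFactors = FALSE
  )
  out <- out[order(out$patient_id, out$event_date, out$code), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "n_rejected") <- n_rejected
  attr(out, "n_unknown_codes") <- mapped$n_unknown
  out
}

#' Read a primary-care prescriptions table
#'
#' Expects columns `patient_id`, `issue_date`, `drug_name` and optionally
#' `raw_code`. Drug names are canonicalised case-insensitively against the
#' codelist's drug map ([canonicalise_drug]); unmapped products keep class
#' `OTHER` and are counted. Rows with an unparseable date or empty drug name
#' are rejected and counted.
#'
#' @inheritParams read_clinical_table
#' @return data.frame of prescription events with columns `patient_id`,
#'   `issue_date` (Date), `drug_id`, `drug_class`, `raw_code`; attributes
#'   `n_rejected` and `n_unmapped_drugs`.
#' @export
read_prescription_table <- function(path, codelist) {
  df <- read_delim_auto(path)
  require_columns(df, c("patient_id", "issue_date", "drug_name"), path)
  if (!"raw_code" %in% names(df)) df$raw_code <- ""

  date <- parse_iso_date(df$issue_date)
  name <- trimws(df$drug_name)
  keep <- !is.na(date) & nzchar(name)
  n_rejected <- sum(!keep)

  mapped <- canonicalise_drug(name[keep], codelist)
  out <- data.frame(
    patient_id = as.character(df$patient_id[keep]),
    issue_date = date[keep],
    drug_id = mapped$drug_id,
    drug_class = mapped$class,
    raw_code = as.character(df$raw_code[keep]),
    stringsAsFactors = FALSE
  )
  out <- out[order(out$patient_id, out$issue_date, out$drug_id), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "n_rejected") <- n_rejected
  attr(out, "n_unmapped_drugs") <- mapped$n_unmapped
  out
}

#' Write clinical events back to the on-disk table layout
#'
#' Inverse of [read_clinical_table]: events become rows with `patient_id`,
#' `event_dt` (ISO-8601), `read_2`, `read_3`, the code placed in the column
#' matching its code system. Reading the written file with the same codelist
#' reproduces the event multiset exactly.
#'
#' @param events data.frame as returned by [read_clinical_table].
#' @param path output path (tab-delimited).
#' @export
write_clinical_table <- function(events, path) {
  df <- data.frame(
    patient_id = events$patient_id,
    event_dt = format(events$event_date, "%Y-%m-%d"),
    read_2 = ifelse(events$code_system == "READ2", events$code, ""),
    read_3 = ifelse(events$code_system == "CTV3", events$code, ""),
    stringsAsFactors = FALSE
  )
  utils::write.table(df, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(events)
}

#' Write prescription events back to the on-disk table layout
#'
#' @param prescriptions data.frame as returned by [read_prescription_table].
#' @param path output path (tab-delimited).
#' @export
write_prescription_table <- function(prescriptions, path) {
  df <- data.frame(
    patient_id = prescriptions$patient_id,
    issue_date = format(prescriptions$issue_date, "%Y-%m-%d"),
    drug_name = prescriptions$drug_id,
    raw_code = prescriptions$raw_code,
    stringsAsFactors = FALSE
  )
  utils::write.table(df, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(prescriptions)
}
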