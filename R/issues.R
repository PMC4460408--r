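# Issue and report machinery shared by the structural checker, the schema
# validator and the cross-validator.

#' Validation issue codes
#'
#' The closed set of codes a cross-validation can emit. Additional codes used
#' only by schema-level XML checking are listed in
#' [XML_ISSUE_CODES]; `BAD_STEP_INDEX` can only arise for documents assembled
#' with the low-level constructors (the user-facing constructor re-indexes
#' steps).
#'
#' @format Character vector of code tokens.
#' @export
VALIDATION_CODES <- c(
  "VERSION_MISMATCH", "PROCESS_ID_MISMATCH", "MISSING_FILE_BINDING",
  "CARDINALITY_SINGLE_VIOLATED", "ORPHAN_AMD_KEY", "UNRESOLVED_PLACEHOLDER",
  "MISSING_PARAMETER", "BAD_SWITCH_VALUE", "MISSING_OUTPUT_FILE",
  "REFERENCE_INCONSISTENT", "CHAIN_BROKEN", "NAMING_CONVENTION",
  "DUPLICATE_IDENTIFIER", "BAD_QUANTITY", "MISSING_SECTION"
)

#' @rdname VALIDATION_CODES
#' @export
XML_ISSUE_CODES <- c(
  "MISSING_SECTION", "MISSING_ATTRIBUTE", "BAD_TYPE", "BAD_QUANTITY",
  "UNKNOWN_ELEMENT", "MALFORMED_XML"
)

STRUCTURE_CODES <- unique(c(VALIDATION_CODES, "BAD_STEP_INDEX"))

new_issue <- function(severity, code, location, message) {
  stopifnot(severity %in% c("error", "warning"))
  structure(
    list(severity = severity, code = code, location = location,
         message = message),
    class = "procamd_issue"
  )
}

#' Build a validation report from a list of issues
#'
#' A report is an ordered list of coded issues plus an `ok` flag that is
#' `TRUE` iff no issue has severity `"error"` (warnings do not fail a
#' report).
#'
#' @param issues list of issues as created internally by the validators.
#' @return An object of class `validation_report` with elements `issues`
#'   (list) and `ok` (logical scalar).
#' @export
validation_report <- function(issues = list()) {
  stopifnot(is.list(issues))
  sev <- vapply(issues, function(i) i$severity, character(1))
  structure(list(issues = issues, ok = !any(sev == "error")),
            class = "validation_report")
}

combine_reports <- function(...) {
  reps <- list(...)
  validation_report(do.call(c, lapply(reps, function(r) r$issues)))
}

#' @export
print.procamd_issue <- function(x, ...) {
  cat(sprintf("[%s] %s at %s: %s\n", toupper(x$severity), x$code,
              x$location, x$message))
  invisible(x)
}

#' @export
print.validation_report <- function(x, ...) {
  if (length(x$issues) == 0) {
    cat("OK: no issues\n")
    return(invisible(x))
  }
  cat(sprintf("%s: %d issue(s)\n", if (x$ok) "OK (warnings only)" else "FAIL",
              length(x$issues)))
  for (i in x$issues) print(i)
  invisible(x)
}

#' Report issue table
#'
#' @param x a `validation_report`.
#' @param ... unused.
#' @return data.frame with columns severity, code, location, message (zero
#'   rows for a clean report).
#' @export
as.data.frame.validation_report <- function(x, ...) {
  if (length(x$issues) == 0) {
    return(data.frame(severity = character(), code = character(),
                      location = character(), message = character(),
                      stringsAsFactors = FALSE))
  }
  do.call(rbind, lapply(x$issues, function(i) {
    data.frame(severity = i$severity, code = i$code, location = i$location,
               message = i$message, stringsAsFactors = FALSE)
  }))
}

report_codes <- function(report, severity = NULL) {
  df <- as.data.frame(report)
  if (!is.null(severity)) df <- df[df$severity %in% severity, , drop = FALSE]
  df$code
}

#' Render a report as JSON lines
#'
#' One JSON object per issue, suitable for machine consumption
#' (`--format jsonl` on the command line).
#'
#' @param report a `validation_report`.
#' @return character vector, one JSON document per element.
#' @export
report_jsonl <- function(report) {
  vapply(report$issues, function(i) {
    jsonlite::toJSON(i[c("severity", "code", "location", "message")],
                     auto_unbox = TRUE)
  }, character(1))
}

procamd_error <- function(message, class, ...) {
  stop(structure(
    class = c(class, "procamd_error", "error", "condition"),
    list(message = message, call = sys.call(-1), ...)
  ))
}
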