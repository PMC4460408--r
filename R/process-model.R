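# In-memory model of a Process document.
#
# A process describes one type of computational analysis in the abstract:
# who wrote it and when (header), what it does (free-text description),
# which files go in and come out (file listings with single/collection
# quantity tags) and which tools run in which order with which abstract
# command lines (steps). Concrete runs are recorded separately in AMD
# files; the two are related 1:N.

#' File entry of a process document
#'
#' @param identifier token unique across all sections of the document; used
#'   by command-template placeholders and as the AMD binding key.
#' @param section one of `"input"`, `"reference"`, `"output"`.
#' @param format free text naming the file format (e.g. "BAM", "BED").
#' @param comment free text; may be empty.
#' @param quantity `"single"` (exactly one file per run) or `"collection"`
#'   (one or more).
#' @return one-row data.frame; `process_document()` rbinds these.
#' @export
file_entry <- function(identifier, section, format = "", comment = "",
                       quantity = c("single", "collection")) {
  quantity <- if (length(quantity) > 1) quantity[1] else quantity
  data.frame(identifier = as.character(identifier),
             section = as.character(section),
             format = as.character(format),
             comment = as.character(comment),
             quantity = as.character(quantity),
             stringsAsFactors = FALSE)
}

#' Tool step of a process document
#'
#' One pipeline stage: the tool, its version, the abstract command line
#' with `{placeholder}` tokens, an optional loop tag and optional binary
#' switches.
#'
#' @param tool_name,tool_version free text; the version is compared
#'   verbatim by [compare_processes()].
#' @param command_template abstract command line; `{...}` placeholders,
#'   `*` wildcard allowed inside placeholders.
#' @param loop_over character vector of placeholder patterns. Empty means
#'   the step runs once over all bound files; non-empty means one
#'   invocation per file matched by the patterns.
#' @param switches named list; each element is `list(true = , false = )`
#'   giving the text emitted for an AMD value of True/False. A switch
#'   declared as `TRUE` uses the default mapping True -> `--<name>`,
#'   False -> `""`.
#' @param comment free text.
#' @param index 1-based position; normally assigned by
#'   [process_document()].
#' @return object of class `tool_step`.
#' @export
tool_step <- function(tool_name, tool_version, command_template,
                      loop_over = character(), switches = list(),
                      comment = "", index = NA_integer_) {
  stopifnot(is.character(command_template), length(command_template) == 1)
  if (length(switches) > 0) {
    stopifnot(!is.null(names(switches)), all(nzchar(names(switches))))
    switches <- lapply(stats::setNames(names(switches), names(switches)),
                       function(nm) {
      sw <- switches[[nm]]
      if (isTRUE(sw)) sw <- list(true = paste0("--", nm), false = "")
      stopifnot(is.list(sw), all(c("true", "false") %in% names(sw)))
      list(true = as.character(sw$true), false = as.character(sw$false))
    })
  }
  structure(
    list(index = as.integer(index),
         tool_name = as.character(tool_name),
         tool_version = as.character(tool_version),
         command_template = command_template,
         loop_over = as.character(loop_over),
         switches = switches,
         comment = as.character(comment)),
    class = "tool_step"
  )
}

#' Construct a process document
#'
#' @param process_id short token naming the process (e.g. `"CHP"`); no
#'   whitespace, no `{`, `}` or `*`.
#' @param version positive integer process version. Incrementing it is
#'   mandated by tool-version, step-series, default-parameter or
#'   file-listing changes — see [compare_processes()].
#' @param author_name,author_contact,date header fields; `date` is an
#'   ISO-8601 calendar date.
#' @param description free-text purpose of the process.
#' @param files data.frame of [file_entry()] rows (rbind them), in
#'   declaration order.
#' @param steps list of [tool_step()]s in execution order; indices are
#'   (re-)assigned 1..S here.
#' @return object of class `process_document`. The constructor is
#'   permissive beyond basic types: run [check_structure()] to obtain a
#'   coded report of invariant violations.
#' @examples
#' doc <- process_document(
#'   "WCP", 1, "A. Author", "a@example.org", "2015-01-01",
#'   "Count lines containing a word and compare to a reference count.",
#'   rbind(file_entry("input_file", "input", "TXT", quantity = "single"),
#'         file_entry("ref_counts", "reference", "TXT", quantity = "single"),
#'         file_entry("count_out", "output", "TXT", quantity = "single")),
#'   list(tool_step("grepcount", "1.0",
#'                  "grepcount -w {word1} {input_file} > {count_out}")))
#' check_structure(doc)
#' @export
process_document <- function(process_id, version, author_name,
                             author_contact, date, description, files,
                             steps) {
  steps <- lapply(seq_along(steps), function(i) {
    s <- steps[[i]]
    stopifnot(inherits(s, "tool_step"))
    s$index <- as.integer(i)
    s
  })
  new_process_document(
    header = list(process_id = as.character(process_id),
                  version = as.integer(version),
                  author_name = as.character(author_name),
                  author_contact = as.character(author_contact),
                  date = as.character(date)),
    description = if (is.null(description)) NULL else as.character(description),
    files = files,
    steps = steps
  )
}

# Low-level constructor: performs no checking or re-indexing, so that
# deliberately broken documents (missing sections, bad indices) can be
# represented and reported on by check_structure().
new_process_document <- function(header, description, files, steps) {
  structure(list(header = header, description = description,
                 files = files, steps = steps),
            class = "process_document")
}

#' @export
print.process_document <- function(x, ...) {
  cat(sprintf("<process %s v%s> %d file entries, %d steps\n",
              x$header$process_id, x$header$version,
              if (is.null(x$files)) 0L else nrow(x$files),
              length(x$steps)))
  invisible(x)
}

#' @export
format.tool_step <- function(x, ...) {
  sprintf("step %d: %s %s%s", x$index, x$tool_name, x$tool_version,
          if (length(x$loop_over)) paste0(" [loop: ",
                                          paste(x$loop_over, collapse = " "),
                                          "]") else "")
}

#' @export
print.tool_step <- function(x, ...) {
  cat(format(x), "\n  ", x$command_template, "\n", sep = "")
  invisible(x)
}

#' Retrieve file entries by section
#'
#' @param doc a `process_document`.
#' @param section `"input"`, `"reference"`, `"output"` or `"all"`. `"all"`
#'   returns the concatenation inputs, references, outputs, each in
#'   declaration order.
#' @return data.frame of file entries.
#' @export
find_entries <- function(doc, section = c("input", "reference", "output",
                                          "all")) {
  section <- match.arg(section)
  files <- doc$files
  if (is.null(files) || nrow(files) == 0) return(file_entry(character(0), character(0))[0, ])
  if (section == "all") {
    return(do.call(rbind, lapply(c("input", "reference", "output"),
                                 function(s) files[files$section == s, ,
                                                   drop = FALSE])))
  }
  files[files$section == section, , drop = FALSE]
}

valid_token <- function(x) {
  length(x) == 1 && !is.na(x) && nzchar(x) &&
    !grepl("[{}*[:space:]]", x)
}

#' Check the structural invariants of a process document
#'
#' Mirrors what the shipped XML schema enforces, plus model-level rules a
#' schema cannot express (identifier uniqueness across sections, loop
#' patterns resolving to input/reference entries, switch names occurring in
#' the template). Violations are report entries, never exceptions.
#'
#' @param doc a `process_document`.
#' @return a [validation_report()]; empty iff all invariants hold.
#' @export
check_structure <- function(doc) {
  issues <- list()
  add <- function(severity, code, location, message) {
    issues[[length(issues) + 1L]] <<- new_issue(severity, code, location,
                                               message)
  }
  h <- doc$header
  if (is.null(h)) {
    add("error", "MISSING_SECTION", "/process/header", "header is missing")
  } else {
    if (!valid_token(h$process_id)) {
      add("error", "BAD_TYPE", "/process/@id",
          "process id must be a non-empty token without whitespace, braces or '*'")
    }
    if (is.na(h$version) || h$version < 1) {
      add("error", "BAD_TYPE", "/process/@version",
          "version must be a positive integer")
    }
    if (is.na(suppressWarnings(as.Date(h$date, format = "%Y-%m-%d")))) {
      add("error", "BAD_TYPE", "/process/header/date",
          sprintf("'%s' is not an ISO-8601 date", h$date))
    }
  }
  if (is.null(doc$description)) {
    add("error", "MISSING_SECTION", "/process/description",
        "description section is missing")
  }
  files <- doc$files
  if (is.null(files) || nrow(files) == 0) {
    add("error", "MISSING_SECTION", "/process/inputs",
        "file listings are missing")
  } else {
    for (s in c("input", "output")) {
      if (!any(files$section == s)) {
        add("error", "MISSING_SECTION", sprintf("/process/%ss", s),
            sprintf("at least one %s entry is required", s))
      }
    }
    dup <- unique(files$identifier[duplicated(files$identifier)])
    for (d in dup) {
      add("error", "DUPLICATE_IDENTIFIER",
          sprintf("/process//file[@id='%s']", d),
          sprintf("identifier '%s' declared more than once", d))
    }
    bad_q <- which(!files$quantity %in% c("single", "collection"))
    for (i in bad_q) {
      add("error", "BAD_QUANTITY",
          sprintf("/process//file[@id='%s']/@quantity", files$identifier[i]),
          sprintf("quantity '%s' is not 'single' or 'collection'",
                  files$quantity[i]))
    }
    bad_id <- which(!vapply(files$identifier, valid_token, logical(1)))
    for (i in bad_id) {
      add("error", "BAD_TYPE", sprintf("/process//file[%d]/@id", i),
          "identifier must be a token without whitespace, braces or '*'")
    }
  }
  if (is.null(doc$steps) || length(doc$steps) == 0) {
    add("error", "MISSING_SECTION", "/process/steps",
        "steps section is missing or empty")
  } else {
    idx <- vapply(doc$steps, function(s) as.integer(s$index), integer(1))
    if (!identical(idx, seq_along(doc$steps))) {
      add("error", "BAD_STEP_INDEX", "/process/steps",
          sprintf("step indices (%s) are not the contiguous sequence 1..%d",
                  paste(idx, collapse = ","), length(doc$steps)))
    }
    loopable <- if (is.null(files)) character() else
      files$identifier[files$section %in% c("input", "reference")]
    for (s in doc$steps) {
      loc <- sprintf("/process/steps/step[%s]", s$index)
      phs <- tryCatch(template_placeholders(s$command_template),
                      procamd_grammar_error = function(e) {
                        add("error", "UNRESOLVED_PLACEHOLDER",
                            paste0(loc, "/command"),
                            paste("template grammar error:",
                                  conditionMessage(e)))
                        NULL
                      })
      for (pat in s$loop_over) {
        if (length(match_identifiers(pat, loopable)) == 0) {
          add("error", "UNRESOLVED_PLACEHOLDER", paste0(loc, "/loop"),
              sprintf("loop pattern '%s' matches no input or reference entry",
                      pat))
        }
      }
      if (!is.null(phs)) {
        for (nm in names(s$switches)) {
          if (!nm %in% phs) {
            add("warning", "UNRESOLVED_PLACEHOLDER", paste0(loc, "/switch"),
                sprintf("switch '%s' does not occur in the command template",
                        nm))
          }
        }
      }
    }
  }
  validation_report(issues)
}

#' Compare two versions of a process and decide on a version increment
#'
#' A process version must be incremented when (i) a tool version changed,
#' (ii) the series of steps changed (tools added, removed or reordered),
#' (iii) fixed default parameters in a command template changed, or (iv)
#' the input/reference/output file listings changed. Comment and
#' description edits never require an increment; neither does an updated
#' *content* of a reference file (that is an AMD-level fact, not a listing
#' change).
#'
#' Default-parameter changes are detected by comparing the whitespace
#' tokens of the command templates with all placeholders masked, so a
#' placeholder rename alone is not a default change.
#'
#' @param old,new `process_document`s sharing the same `process_id`.
#' @return object of class `increment_decision`: `increment_required`
#'   (logical), `reasons` (subset of `TOOL_VERSION_CHANGED`,
#'   `STEP_SERIES_CHANGED`, `DEFAULTS_CHANGED`, `FILE_LISTINGS_CHANGED`)
#'   and `ignorable_changes` (subset of `COMMENT_ONLY`,
#'   `DESCRIPTION_ONLY`).
#' @export
compare_processes <- function(old, new) {
  stopifnot(inherits(old, "process_document"),
            inherits(new, "process_document"))
  if (!identical(old$header$process_id, new$header$process_id)) {
    procamd_error(
      sprintf("documents describe different processes ('%s' vs '%s')",
              old$header$process_id, new$header$process_id),
      "procamd_incomparable")
  }
  reasons <- character()
  ignorable <- character()

  tools_old <- vapply(old$steps, `[[`, character(1), "tool_name")
  tools_new <- vapply(new$steps, `[[`, character(1), "tool_name")
  if (!identical(tools_old, tools_new)) {
    reasons <- c(reasons, "STEP_SERIES_CHANGED")
  } else {
    vers_old <- vapply(old$steps, `[[`, character(1), "tool_version")
    vers_new <- vapply(new$steps, `[[`, character(1), "tool_version")
    if (!identical(vers_old, vers_new)) {
      reasons <- c(reasons, "TOOL_VERSION_CHANGED")
    }
    masked <- function(steps) lapply(steps, function(s)
      masked_tokens(s$command_template))
    if (!identical(masked(old$steps), masked(new$steps))) {
      reasons <- c(reasons, "DEFAULTS_CHANGED")
    }
  }

  triples <- function(d) {
    f <- d$files
    if (is.null(f) || nrow(f) == 0) return(character())
    sort(paste(f$identifier, f$section, f$quantity, sep = "\r"))
  }
  if (!identical(triples(old), triples(new))) {
    reasons <- c(reasons, "FILE_LISTINGS_CHANGED")
  }

  comments <- function(d) {
    c(if (!is.null(d$files)) d$files$comment,
      vapply(d$steps, `[[`, character(1), "comment"))
  }
  if (!identical(comments(old), comments(new))) {
    ignorable <- c(ignorable, "COMMENT_ONLY")
  }
  if (!identical(old$description, new$description)) {
    ignorable <- c(ignorable, "DESCRIPTION_ONLY")
  }

  structure(list(increment_required = length(reasons) > 0,
                 reasons = reasons, ignorable_changes = ignorable),
            class = "increment_decision")
}

# Whitespace tokens of a template with every placeholder replaced by a
# fixed sentinel, so only literal (default-parameter) text is compared.
masked_tokens <- function(template) {
  tok <- tokenize_template(template)
  masked <- paste(ifelse(tok$kind == "placeholder", "\x01", tok$text),
                  collapse = "")
  strsplit(trimws(masked), "[[:space:]]+")[[1]]
}

#' @export
print.increment_decision <- function(x, ...) {
  if (x$increment_required) {
    cat("version increment REQUIRED:", paste(x$reasons, collapse = ", "),
        "\n")
  } else {
    cat("no version increment required\n")
  }
  if (length(x$ignorable_changes)) {
    cat("ignorable changes:", paste(x$ignorable_changes, collapse = ", "),
        "\n")
  }
  invisible(x)
}
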