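# Analysis Metadata (AMD) files.
#
# An AMD records one concrete execution of a process as a row-oriented
# key-value text file: a header-less general block (process id/version,
# analysis id, date), then [Inputs], [References], [Outputs] binding file
# identifiers to the actual filenames of the run, [Parameters] with the
# non-default/analysis-specific settings, and [Metrics] with free-form run
# statistics. Collections are expressed as repeated keys. The format is
# deliberately trivial so that readers/writers exist in any language.

AMD_BLOCKS <- c("Inputs", "References", "Outputs", "Parameters", "Metrics")
AMD_REQUIRED_GENERAL <- c("process_id", "process_version", "analysis_id",
                          "date")

amd_key_ok <- function(k) {
  nzchar(k) & !grepl("[{}=[:space:]]", k)
}

#' Construct an AMD document
#'
#' Blocks are named character vectors in which names may repeat (repeated
#' keys are how collections are written). The general block must contain
#' `process_id`, `process_version` (positive integer), `analysis_id` and
#' `date`; these are ordered first canonically.
#'
#' @param general named character vector with unique names.
#' @param inputs,references,outputs,parameters,metrics named character
#'   vectors (possibly empty; names may repeat).
#' @return object of class `amd_document`.
#' @export
amd_document <- function(general, inputs = character(),
                         references = character(), outputs = character(),
                         parameters = character(), metrics = character()) {
  general <- vapply(general, as.character, character(1))
  miss <- setdiff(AMD_REQUIRED_GENERAL, names(general))
  if (length(miss) > 0) {
    procamd_error(sprintf("MISSING_GENERAL: general block lacks %s",
                          paste(miss, collapse = ", ")),
                  "procamd_amd_error")
  }
  if (anyDuplicated(names(general))) {
    procamd_error("duplicate keys in the general block", "procamd_amd_error")
  }
  pv <- suppressWarnings(as.integer(general[["process_version"]]))
  if (is.na(pv) || pv < 1 ||
      as.character(pv) != general[["process_version"]]) {
    procamd_error("process_version must be a positive integer",
                  "procamd_amd_error")
  }
  if (!nzchar(general[["analysis_id"]])) {
    procamd_error("analysis_id must be non-empty", "procamd_amd_error")
  }
  # canonical general key order: the required four, then the rest as given
  ord <- c(AMD_REQUIRED_GENERAL,
           setdiff(names(general), AMD_REQUIRED_GENERAL))
  general <- general[ord]
  blocks <- list(inputs = inputs, references = references,
                 outputs = outputs, parameters = parameters,
                 metrics = metrics)
  blocks <- lapply(blocks, function(b) {
    b <- as.character(b) |> stats::setNames(names(b))
    # canonical empty block: plain unnamed character(0), as the parser
    # produces, so constructed and parsed documents compare identical
    if (length(b) == 0) return(character())
    if (is.null(names(b)) || !all(amd_key_ok(names(b)))) {
      procamd_error(
        "block keys must be non-empty and free of whitespace, braces and '='",
        "procamd_amd_error")
    }
    b
  })
  structure(c(list(general = general), blocks), class = "amd_document")
}

#' @export
print.amd_document <- function(x, ...) {
  cat(sprintf("<amd %s of %s v%s> %d inputs, %d references, %d outputs, %d parameters, %d metrics\n",
              x$general[["analysis_id"]], x$general[["process_id"]],
              x$general[["process_version"]],
              length(x$inputs), length(x$references), length(x$outputs),
              length(x$parameters), length(x$metrics)))
  invisible(x)
}

amd_version <- function(amd) as.integer(amd$general[["process_version"]])

#' Parse an AMD file
#'
#' Rows before the first `[Block]` header belong to the general block.
#' `key=value` rows split once at the first `=`; repeated keys append in
#' order. Blank lines and lines starting with `#` are ignored; trailing
#' whitespace and Windows line endings are normalized away.
#'
#' @param text AMD file content, a character scalar (or vector of lines).
#' @param strict reject unknown block headers (default). In lenient mode
#'   rows of unknown blocks are dropped with a warning.
#' @return an [amd_document()].
#' @export
parse_amd <- function(text, strict = TRUE) {
  lines <- if (length(text) == 1) strsplit(text, "\r?\n")[[1]] else text
  lines <- sub("[[:space:]]+$", "", lines)
  general <- character()
  blocks <- stats::setNames(vector("list", length(AMD_BLOCKS)), AMD_BLOCKS)
  for (b in AMD_BLOCKS) blocks[[b]] <- character()
  current <- NA_character_  # NA = general
  skipping <- FALSE
  for (i in seq_along(lines)) {
    line <- lines[i]
    if (!nzchar(line) || startsWith(line, "#")) next
    if (grepl("^\\[.*\\]$", line)) {
      name <- sub("^\\[(.*)\\]$", "\\1", line)
      if (!name %in% AMD_BLOCKS) {
        if (strict) {
          procamd_error(sprintf("line %d: unknown block [%s]", i, name),
                        "procamd_amd_error", line = i)
        }
        warning(sprintf("dropping unknown block [%s] (line %d)", name, i))
        skipping <- TRUE
        next
      }
      current <- name
      skipping <- FALSE
      next
    }
    if (skipping) next
    eq <- regexpr("=", line, fixed = TRUE)
    if (eq < 1) {
      procamd_error(sprintf("line %d: expected key=value, got '%s'", i, line),
                    "procamd_amd_error", line = i)
    }
    key <- substr(line, 1, eq - 1)
    value <- substr(line, eq + 1, nchar(line))
    if (grepl("=", value, fixed = TRUE)) {
      warning(sprintf("line %d: value of '%s' contains '='", i, key))
    }
    if (is.na(current)) {
      if (key %in% names(general)) {
        procamd_error(sprintf("line %d: duplicate general key '%s'", i, key),
                      "procamd_amd_error", line = i)
      }
      general[key] <- value
    } else {
      blocks[[current]] <- c(blocks[[current]], stats::setNames(value, key))
    }
  }
  amd_document(general,
               inputs = blocks$Inputs, references = blocks$References,
               outputs = blocks$Outputs, parameters = blocks$Parameters,
               metrics = blocks$Metrics)
}

#' Serialize an AMD document
#'
#' Canonical form: general rows first (required keys in fixed order), then
#' the `[Inputs]`, `[References]`, `[Outputs]`, `[Parameters]`, `[Metrics]`
#' blocks in that order, empty blocks omitted, one `key=value` per row and
#' one blank line before each block header. `parse_amd(serialize_amd(d))`
#' is `d`, and repeated serialization is byte-identical.
#'
#' @param amd an [amd_document()].
#' @return character scalar, the AMD file content (trailing newline).
#' @export
serialize_amd <- function(amd) {
  stopifnot(inherits(amd, "amd_document"))
  for (blk in c("inputs", "references", "outputs", "parameters", "metrics")) {
    b <- amd[[blk]]
    if (length(b) > 0 && !all(amd_key_ok(names(b)))) {
      procamd_error(sprintf("invalid key in %s block", blk),
                    "procamd_amd_error")
    }
  }
  out <- paste0(names(amd$general), "=", amd$general)
  headers <- stats::setNames(AMD_BLOCKS,
                             c("inputs", "references", "outputs",
                               "parameters", "metrics"))
  for (blk in names(headers)) {
    b <- amd[[blk]]
    if (length(b) == 0) next
    out <- c(out, "", paste0("[", headers[[blk]], "]"),
             paste0(names(b), "=", b))
  }
  paste0(paste(out, collapse = "\n"), "\n")
}

#' Look up bindings by key pattern
#'
#' @param amd an [amd_document()].
#' @param block `"inputs"`, `"references"`, `"outputs"`, `"parameters"` or
#'   `"metrics"`.
#' @param key_pattern glob pattern over keys (`*` wildcard only). The
#'   default returns the whole block.
#' @return data.frame with columns `key`, `value` in declaration order
#'   (zero rows when nothing matches).
#' @examples
#' a <- amd_document(c(process_id = "CHP", process_version = "1",
#'                     analysis_id = "run1", date = "2015-01-01"),
#'                   parameters = c(H3K4me3_median_fraglen = "180",
#'                                  Input_median_fraglen = "175"))
#' values_for(a, "parameters", "*_median_fraglen")
#' @export
values_for <- function(amd, block = c("inputs", "references", "outputs",
                                      "parameters", "metrics"),
                       key_pattern = "*") {
  block <- match.arg(block)
  b <- amd[[block]]
  hit <- grepl(glob_to_regex(key_pattern), names(b))
  data.frame(key = as.character(names(b)[hit]),
             value = as.character(b[hit]),
             stringsAsFactors = FALSE)
}

#' Read / write AMD files on disk
#'
#' Thin UTF-8 file wrappers around [parse_amd()] and [serialize_amd()].
#' AMD files conventionally use the `.amd` extension and embed the process
#' id and version in their name (e.g. `run1_CHPv1.amd`).
#'
#' @param path file path.
#' @param amd an [amd_document()].
#' @param strict passed to [parse_amd()].
#' @return `read_amd()` an `amd_document`; `write_amd()` the path,
#'   invisibly.
#' @export
read_amd <- function(path, strict = TRUE) {
  parse_amd(readChar(path, file.size(path), useBytes = TRUE), strict = strict)
}

#' @rdname read_amd
#' @export
write_amd <- function(amd, path) {
  writeLines(serialize_amd(amd), path, sep = "", useBytes = TRUE)
  invisible(path)
}
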