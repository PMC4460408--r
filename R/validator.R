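# Cross-validation of a Process document against AMD files.
#
# Checking that every declared file has a binding, that 'single' entries
# are bound exactly once, that every placeholder resolves and that switch
# values are explicit True/False is the precondition for turning the
# abstract command lines into executable ones; reference consistency,
# output-presence, chaining and naming checks catch the project-level
# slips that otherwise surface months later.

#' Cross-validate a process document against one AMD
#'
#' Checks, in order: (1) matching process id, (2) matching process
#' version, (3) every declared file entry bound at least once in the
#' corresponding AMD block, (4) `single` entries bound exactly once,
#' (5) no orphan AMD keys in the file blocks (warning), (6) every
#' placeholder of every step resolvable (file bindings, parameter keys —
#' including per-loop-element wildcard keys — and switches), (7) switch
#' values are exactly `True` or `False`.
#'
#' All findings are report entries; nothing throws. The inputs are never
#' mutated and the report order is deterministic (rule order, then
#' document order).
#'
#' @param doc a [process_document()].
#' @param amd an [amd_document()].
#' @return a [validation_report()].
#' @export
validate_pair <- function(doc, amd) {
  issues <- list()
  add <- function(severity, code, location, message) {
    issues[[length(issues) + 1L]] <<- new_issue(severity, code, location,
                                               message)
  }
  # (1) + (2)
  if (!identical(amd$general[["process_id"]], doc$header$process_id)) {
    add("error", "PROCESS_ID_MISMATCH", "amd:general/process_id",
        sprintf("AMD names process '%s' but the document is '%s'",
                amd$general[["process_id"]], doc$header$process_id))
  }
  if (amd_version(amd) != doc$header$version) {
    add("error", "VERSION_MISMATCH", "amd:general/process_version",
        sprintf("AMD names process version %d but the document is version %d",
                amd_version(amd), doc$header$version))
  }
  # (3) + (4)
  unbound <- character()
  files <- doc$files
  for (i in seq_len(if (is.null(files)) 0 else nrow(files))) {
    id <- files$identifier[i]
    blk <- section_block[[files$section[i]]]
    n <- sum(names(amd[[blk]]) == id)
    if (n == 0) {
      unbound <- c(unbound, id)
      add("error", "MISSING_FILE_BINDING", sprintf("amd:%s/%s", blk, id),
          sprintf("'%s' (%s, %s) has no binding in the AMD %s block",
                  id, files$section[i], files$quantity[i], blk))
    } else if (identical(files$quantity[i], "single") && n != 1) {
      add("error", "CARDINALITY_SINGLE_VIOLATED",
          sprintf("amd:%s/%s", blk, id),
          sprintf("'%s' is declared single but bound %d times", id, n))
    }
  }
  # (5)
  for (sec in c("input", "reference", "output")) {
    blk <- section_block[[sec]]
    ids <- if (is.null(files)) character() else
      files$identifier[files$section == sec]
    orphan <- setdiff(unique(names(amd[[blk]])), ids)
    for (k in orphan) {
      add("warning", "ORPHAN_AMD_KEY", sprintf("amd:%s/%s", blk, k),
          sprintf("key '%s' in the AMD %s block matches no declared %s entry",
                  k, blk, sec))
    }
  }
  # (6) + (7)
  for (s in doc$steps) {
    loc <- sprintf("/process/steps/step[%s]/command", s$index)
    phs <- tryCatch(template_placeholders(s$command_template),
                    procamd_grammar_error = function(e) NULL)
    if (is.null(phs)) next  # already reported by check_structure
    elements <- tryCatch(loop_elements(doc, amd, s),
                         procamd_materialize_error = function(e) list())
    labels <- vapply(elements, `[[`, character(1), "label")
    for (pat in unique(phs)) {
      cls <- classify_placeholder(pat, doc, s)
      ploc <- sprintf("%s{%s}", loc, pat)
      if (cls$klass == "file") {
        # bindings already covered by rule (3); nothing further unless every
        # matched identifier is unbound, which rule (3) reported
        next
      }
      if (cls$klass == "switch") {
        val <- unname(amd$parameters[names(amd$parameters) == pat])
        if (length(val) == 0) {
          add("error", "MISSING_PARAMETER", ploc,
              sprintf("switch '%s' has no [Parameters] binding", pat))
        } else if (!val[1] %in% c("True", "False")) {
          add("error", "BAD_SWITCH_VALUE", ploc,
              sprintf("switch '%s' is '%s'; the explicit form True/False is required",
                      pat, val[1]))
        }
        next
      }
      # parameter
      if (grepl("*", pat, fixed = TRUE)) {
        if (length(elements) > 0) {
          for (lab in unique(labels)) {
            key <- gsub("*", lab, pat, fixed = TRUE)
            if (!key %in% names(amd$parameters)) {
              add("error", "MISSING_PARAMETER", ploc,
                  sprintf("loop element '%s' needs parameter key '%s'",
                          lab, key))
            }
          }
        } else if (nrow(values_for(amd, "parameters", pat)) == 0) {
          add("error", "UNRESOLVED_PLACEHOLDER", ploc,
              sprintf("wildcard pattern '%s' matches no file identifier and no parameter key",
                      pat))
        }
      } else if (!pat %in% names(amd$parameters)) {
        add("error", "MISSING_PARAMETER", ploc,
            sprintf("parameter '%s' has no [Parameters] binding", pat))
      }
    }
  }
  validation_report(issues)
}

#' Check that all declared output files were produced
#'
#' Comparing the files present after a run against the `[Outputs]`
#' bindings is the cheap test for whether an analysis terminated
#' successfully. Extra present files are ignored.
#'
#' @param amd an [amd_document()].
#' @param present_files character vector of filenames found on disk (or
#'   from a directory listing).
#' @return a [validation_report()] with one `MISSING_OUTPUT_FILE` error
#'   per absent output binding. An empty `[Outputs]` block yields a lone
#'   warning (nothing to check is usually a documentation gap).
#' @export
check_outputs_present <- function(amd, present_files) {
  issues <- list()
  if (length(amd$outputs) == 0) {
    issues[[1]] <- new_issue("warning", "MISSING_OUTPUT_FILE",
                             "amd:outputs",
                             "[Outputs] block is empty; nothing to check")
    return(validation_report(issues))
  }
  for (i in seq_along(amd$outputs)) {
    fn <- unname(amd$outputs[i])
    if (!fn %in% present_files) {
      issues[[length(issues) + 1L]] <- new_issue(
        "error", "MISSING_OUTPUT_FILE",
        sprintf("amd:outputs/%s", names(amd$outputs)[i]),
        sprintf("declared output '%s' was not produced", fn))
    }
  }
  validation_report(issues)
}

#' Check reference consistency across compatible AMDs
#'
#' Reference files are static inputs for a given kind of analysis:
#' compatible AMDs (same process id and version, differing only in
#' sample-specific bindings) must list identical reference filenames —
#' two samples analysed under the same process against different genome
#' assemblies is a documentation error.
#'
#' @param amds list of [amd_document()]s.
#' @return a [validation_report()]. If the AMDs do not share process id
#'   and version, only `PROCESS_ID_MISMATCH`/`VERSION_MISMATCH` issues are
#'   reported and no reference comparison is attempted.
#' @export
check_reference_consistency <- function(amds) {
  issues <- list()
  if (length(amds) < 2) return(validation_report(issues))
  ids <- vapply(amds, function(a) a$general[["process_id"]], character(1))
  vers <- vapply(amds, amd_version, integer(1))
  aids <- vapply(amds, function(a) a$general[["analysis_id"]], character(1))
  if (length(unique(ids)) > 1) {
    issues[[length(issues) + 1L]] <- new_issue(
      "error", "PROCESS_ID_MISMATCH", "amd:general/process_id",
      sprintf("AMDs name different processes: %s",
              paste(unique(ids), collapse = ", ")))
  }
  if (length(unique(vers)) > 1) {
    issues[[length(issues) + 1L]] <- new_issue(
      "error", "VERSION_MISMATCH", "amd:general/process_version",
      sprintf("AMDs name different process versions: %s",
              paste(unique(vers), collapse = ", ")))
  }
  if (length(issues) > 0) return(validation_report(issues))
  keys <- unique(unlist(lapply(amds, function(a) names(a$references))))
  for (k in keys) {
    lists <- lapply(amds, function(a)
      unname(a$references[names(a$references) == k]))
    if (length(unique(lists)) > 1) {
      divergent <- aids[!vapply(lists, identical, logical(1), lists[[1]])]
      issues[[length(issues) + 1L]] <- new_issue(
        "error", "REFERENCE_INCONSISTENT", sprintf("amd:references/%s", k),
        sprintf("reference '%s' differs between compatible AMDs (%s diverge from %s)",
                k, paste(divergent, collapse = ", "), aids[1]))
    }
  }
  validation_report(issues)
}

#' Check the chaining of two processes
#'
#' In a pipeline, the outputs of an upstream run (e.g. an alignment
#' process producing BAM files) become the inputs of a downstream run
#' (e.g. peak calling). Every filename in the downstream `[Inputs]` block
#' must occur among the upstream `[Outputs]` values.
#'
#' @param upstream,downstream [amd_document()]s of consecutive pipeline
#'   stages.
#' @param strict report breaks as errors instead of warnings (renaming
#'   during inter-institute transfer can legitimately break filename
#'   chains, hence warning by default).
#' @return a [validation_report()] with one `CHAIN_BROKEN` issue per
#'   unmatched downstream input.
#' @export
check_chain <- function(upstream, downstream, strict = FALSE) {
  issues <- list()
  produced <- unname(upstream$outputs)
  for (i in seq_along(downstream$inputs)) {
    fn <- unname(downstream$inputs[i])
    if (!fn %in% produced) {
      issues[[length(issues) + 1L]] <- new_issue(
        if (strict) "error" else "warning", "CHAIN_BROKEN",
        sprintf("amd:inputs/%s", names(downstream$inputs)[i]),
        sprintf("input '%s' of analysis %s is not an output of upstream analysis %s",
                fn, downstream$general[["analysis_id"]],
                upstream$general[["analysis_id"]]))
    }
  }
  validation_report(issues)
}

#' Lint output filenames for the naming convention
#'
#' Embedding the process identifier in every filename links each file to
#' its process and keeps names short; this is best practice, not a format
#' rule, so violations are always warnings.
#'
#' @param amd an [amd_document()].
#' @return a [validation_report()] with one `NAMING_CONVENTION` warning
#'   per output filename lacking the process id as a substring.
#' @export
lint_naming <- function(amd) {
  pid <- amd$general[["process_id"]]
  issues <- list()
  for (i in seq_along(amd$outputs)) {
    fn <- unname(amd$outputs[i])
    if (!grepl(pid, basename(fn), fixed = TRUE)) {
      issues[[length(issues) + 1L]] <- new_issue(
        "warning", "NAMING_CONVENTION",
        sprintf("amd:outputs/%s", names(amd$outputs)[i]),
        sprintf("output '%s' does not contain the process id '%s'", fn, pid))
    }
  }
  validation_report(issues)
}
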