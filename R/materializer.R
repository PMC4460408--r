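# Materialization: abstract command templates + one AMD -> concrete,
# brace-free, executable command lines.
#
# Loop semantics:
#   * empty loop tag     -> one invocation; file placeholders expand to all
#                           bound filenames space-joined (the
#                           "process everything at once" pattern).
#   * non-empty loop tag -> one invocation per (identifier, filename)
#                           binding matched by the loop patterns, in
#                           pattern order then binding order. Placeholders
#                           matching a looped entry resolve to the current
#                           element only; placeholders outside the loop are
#                           held constant (the peak-caller pattern: loop
#                           over the signal files, keep the one control).
# Wildcard parameter placeholders like {*_median_fraglen} bind per loop
# element: `*` is replaced by the element's label and the resulting key is
# looked up in [Parameters]. Outside a loop they expand to all matching
# parameter values, space-joined in key order.

section_block <- c(input = "inputs", reference = "references",
                   output = "outputs")

entry_section <- function(doc, identifier) {
  doc$files$section[match(identifier, doc$files$identifier)]
}

bindings_of <- function(amd, doc, identifier) {
  blk <- section_block[[entry_section(doc, identifier)]]
  b <- amd[[blk]]
  unname(b[names(b) == identifier])
}

filename_stem <- function(f) sub("\\..*$", "", basename(f))

# The label of a loop element substitutes `*` in wildcard parameter
# patterns. Defaults: the text captured by `*` of the matching loop
# pattern when the identifier has exactly one binding and the capture is
# non-empty; otherwise the filename stem (basename up to the first dot).
# An AMD may override labels with the reserved parameter key
# "<identifier>_label" (repeated positionally for collections).
loop_elements <- function(doc, amd, step) {
  loopable <- doc$files$identifier[doc$files$section %in%
                                     c("input", "reference")]
  seen <- character()
  elements <- list()
  for (pat in step$loop_over) {
    for (id in setdiff(match_identifiers(pat, loopable), seen)) {
      seen <- c(seen, id)
      files <- bindings_of(amd, doc, id)
      override <- unname(amd$parameters[names(amd$parameters) ==
                                          paste0(id, "_label")])
      captured <- capture_star(pat, id)
      for (j in seq_along(files)) {
        label <- if (length(override) >= j) {
          override[j]
        } else if (length(files) == 1 && nzchar(captured)) {
          captured
        } else {
          filename_stem(files[j])
        }
        elements[[length(elements) + 1L]] <-
          list(identifier = id, filename = files[j], label = label,
               ordinal = length(elements))
      }
    }
  }
  labels <- vapply(elements, `[[`, character(1), "label")
  if (anyDuplicated(labels)) {
    procamd_error(
      sprintf("loop labels are not unique in step %d: %s (override with <identifier>_label parameter keys)",
              step$index,
              paste(unique(labels[duplicated(labels)]), collapse = ", ")),
      "procamd_materialize_error", code = "MATERIALIZE_LABEL_CLASH")
  }
  elements
}

materialize_error <- function(code, step, message) {
  procamd_error(sprintf("step %d: %s", step$index, message),
                "procamd_materialize_error", code = code)
}

#' Expand one tool step into concrete command invocations
#'
#' @param doc a [process_document()].
#' @param amd a matching [amd_document()]; the pair should first pass
#'   [validate_pair()] (enforced unless `validated = TRUE`).
#' @param step one of `doc$steps`.
#' @param shell_quote POSIX-quote resolved filenames and values
#'   ([shQuote()]); templates themselves are trusted text and never
#'   quoted.
#' @param validated skip re-running [validate_pair()] (used internally by
#'   [expand_process()]).
#' @return list of `command_invocation` objects: `step_index`, `iteration`
#'   (0-based; 0 when the loop is empty), `command_line` (brace-free) and
#'   `bound_outputs` (data.frame identifier/filename of output bindings
#'   consumed by the template).
#' @export
expand_step <- function(doc, amd, step, shell_quote = FALSE,
                        validated = FALSE) {
  if (!validated) {
    rep <- validate_pair(doc, amd)
    if (!rep$ok) {
      procamd_error(
        paste0("cannot materialize: the pair does not validate\n",
               paste(utils::capture.output(print(rep)), collapse = "\n")),
        "procamd_materialize_error", code = "MATERIALIZE_INVALID_PAIR",
        report = rep)
    }
  }
  quote_if <- function(x) if (shell_quote) vapply(x, shQuote, character(1)) else x
  tokens <- tokenize_template(step$command_template)
  elements <- loop_elements(doc, amd, step)
  loop_ids <- unique(vapply(elements, `[[`, character(1), "identifier"))
  n_iter <- if (length(elements) == 0) 1L else length(elements)
  looped <- length(elements) > 0

  # Pre-resolve which output identifiers each file placeholder touches so
  # positional consumption can be checked against the iteration count.
  out_ids_used <- character()
  for (pat in tokens$text[tokens$kind == "placeholder"]) {
    cls <- classify_placeholder(pat, doc, step)
    if (cls$klass == "file") {
      ids <- cls$matched_identifiers
      out_ids_used <- union(out_ids_used,
                            ids[entry_section(doc, ids) == "output"])
    }
  }
  for (oid in out_ids_used) {
    q <- doc$files$quantity[match(oid, doc$files$identifier)]
    nb <- length(bindings_of(amd, doc, oid))
    if (looped && identical(q, "collection") && nb < n_iter) {
      materialize_error("MATERIALIZE_OUTPUT_ARITY", step,
        sprintf("output '%s' is bound %d time(s) but the loop has %d iteration(s)",
                oid, nb, n_iter))
    }
  }

  resolve_file <- function(cls, element, k) {
    parts <- character()
    for (id in cls$matched_identifiers) {
      sec <- entry_section(doc, id)
      if (sec == "output") {
        q <- doc$files$quantity[match(id, doc$files$identifier)]
        b <- bindings_of(amd, doc, id)
        parts <- c(parts, if (identical(q, "single")) {
          b[1]
        } else if (looped) {
          b[k]  # positional by iteration ordinal
        } else {
          b     # single invocation consumes all bindings
        })
      } else if (!is.null(element) && id %in% loop_ids) {
        if (id == element$identifier) parts <- c(parts, element$filename)
        # other looped identifiers contribute nothing in this iteration
      } else {
        parts <- c(parts, bindings_of(amd, doc, id))
      }
    }
    paste(quote_if(parts), collapse = " ")
  }

  resolve_parameter <- function(pattern, element) {
    if (grepl("*", pattern, fixed = TRUE) && !is.null(element)) {
      key <- gsub("*", element$label, pattern, fixed = TRUE)
      vals <- unname(amd$parameters[names(amd$parameters) == key])
      if (length(vals) == 0) {
        materialize_error("MATERIALIZE_MISSING_KEY", step,
          sprintf("no parameter key '%s' for loop element '%s' (pattern {%s})",
                  key, element$label, pattern))
      }
    } else {
      hits <- values_for(amd, "parameters", pattern)
      if (nrow(hits) == 0) {
        materialize_error("MATERIALIZE_MISSING_KEY", step,
          sprintf("no parameter key matches {%s}", pattern))
      }
      vals <- hits$value
    }
    paste(quote_if(vals), collapse = " ")
  }

  resolve_switch <- function(pattern) {
    val <- unname(amd$parameters[names(amd$parameters) == pattern])
    if (length(val) == 0 || !val[1] %in% c("True", "False")) {
      materialize_error("MATERIALIZE_BAD_SWITCH", step,
        sprintf("switch {%s} needs an AMD parameter value True or False",
                pattern))
    }
    sw <- step$switches[[pattern]]
    if (is.null(sw)) sw <- list(true = paste0("--", pattern), false = "")
    if (val[1] == "True") sw$true else sw$false
  }

  invocations <- vector("list", n_iter)
  for (k in seq_len(n_iter)) {
    element <- if (looped) elements[[k]] else NULL
    bound <- list()
    pieces <- character(nrow(tokens))
    for (t in seq_len(nrow(tokens))) {
      if (tokens$kind[t] == "literal") {
        pieces[t] <- tokens$text[t]
        next
      }
      pat <- tokens$text[t]
      cls <- classify_placeholder(pat, doc, step)
      pieces[t] <- switch(cls$klass,
        file = {
          oids <- cls$matched_identifiers[
            entry_section(doc, cls$matched_identifiers) == "output"]
          for (oid in oids) {
            q <- doc$files$quantity[match(oid, doc$files$identifier)]
            b <- bindings_of(amd, doc, oid)
            fn <- if (identical(q, "single")) b[1]
                  else if (looped) b[k] else b
            bound[[length(bound) + 1L]] <-
              data.frame(identifier = oid, filename = fn,
                         stringsAsFactors = FALSE)
          }
          resolve_file(cls, element, k)
        },
        parameter = resolve_parameter(pat, element),
        switch = resolve_switch(pat))
    }
    cmd <- trimws(paste(pieces, collapse = ""))
    if (grepl("[{}]", cmd)) {
      # cannot happen: every placeholder class resolves to literal text
      stop("internal error: residual braces after expansion")
    }
    invocations[[k]] <- structure(
      list(step_index = step$index, iteration = k - 1L,
           command_line = cmd,
           bound_outputs = if (length(bound)) do.call(rbind, bound)
                           else data.frame(identifier = character(),
                                           filename = character(),
                                           stringsAsFactors = FALSE)),
      class = "command_invocation")
  }
  invocations
}

#' Expand a whole process into an executable command list
#'
#' Concatenates [expand_step()] over the steps in index order; the total
#' invocation count is the sum of the per-step loop cardinalities.
#'
#' @inheritParams expand_step
#' @return list of `command_invocation`s.
#' @export
expand_process <- function(doc, amd, shell_quote = FALSE) {
  rep <- validate_pair(doc, amd)
  if (!rep$ok) {
    procamd_error(
      paste0("cannot materialize: the pair does not validate\n",
             paste(utils::capture.output(print(rep)), collapse = "\n")),
      "procamd_materialize_error", code = "MATERIALIZE_INVALID_PAIR",
      report = rep)
  }
  if (length(doc$steps) == 0) {
    warning("process has no steps; nothing to materialize")
    return(list())
  }
  out <- list()
  for (s in doc$steps) {
    inv <- tryCatch(
      expand_step(doc, amd, s, shell_quote = shell_quote, validated = TRUE),
      procamd_materialize_error = function(e) {
        e$message <- sprintf("step %d: %s", s$index, conditionMessage(e))
        stop(e)
      })
    out <- c(out, inv)
  }
  out
}

#' @export
print.command_invocation <- function(x, ...) {
  cat(sprintf("[step %d, iteration %d] %s\n", x$step_index, x$iteration,
              x$command_line))
  invisible(x)
}

#' Render invocations as a plain-text script
#'
#' One command per line, preceded by a `#` comment header naming the
#' process, version and analysis id.
#'
#' @param invocations list of invocations from [expand_process()].
#' @param doc,amd the pair they came from (for the header).
#' @return character scalar of script text.
#' @export
render_script <- function(invocations, doc, amd) {
  header <- c(
    sprintf("# process %s v%d", doc$header$process_id, doc$header$version),
    sprintf("# analysis %s (%s)", amd$general[["analysis_id"]],
            amd$general[["date"]]))
  cmds <- vapply(invocations, `[[`, character(1), "command_line")
  paste0(paste(c(header, cmds), collapse = "\n"), "\n")
}
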