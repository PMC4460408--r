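# The placeholder grammar for abstract command templates.
#
# A template is plain text with placeholders in curly braces, e.g.
#   "peakcall -t {sig_*} -c {sig_ctl} --q 0.05 {wide}"
# Placeholder patterns may contain the glob wildcard `*` (and only `*`:
# question marks and character classes are deliberately not supported, to
# keep patterns human-readable). Braces never nest.

#' Tokenize an abstract command template
#'
#' Splits a template into literal and placeholder tokens. Concatenating the
#' token texts (re-bracing the placeholders) reconstructs the template
#' exactly.
#'
#' @param template character scalar; may be empty.
#' @return data.frame with columns `kind` (`"literal"` or `"placeholder"`),
#'   `text` (literal text, or the pattern between the braces) and `start`,
#'   `end` (1-based character offsets of the token in the template,
#'   including braces for placeholders). Zero rows for the empty template.
#' @examples
#' tokenize_template("count -w {word1} {input_file}")
#' @export
tokenize_template <- function(template) {
  stopifnot(is.character(template), length(template) == 1, !is.na(template))
  chars <- strsplit(template, "", fixed = TRUE)[[1]]
  n <- length(chars)
  toks <- list()
  i <- 1L
  lit_start <- 1L
  push_literal <- function(upto) {
    if (upto >= lit_start) {
      toks[[length(toks) + 1L]] <<- list(
        kind = "literal",
        text = substr(template, lit_start, upto),
        start = lit_start, end = upto)
    }
  }
  while (i <= n) {
    ch <- chars[i]
    if (ch == "}") {
      procamd_error(sprintf("unbalanced '}' at offset %d", i),
                    "procamd_grammar_error", offset = i)
    }
    if (ch == "{") {
      close <- NA_integer_
      j <- i + 1L
      while (j <= n) {
        if (chars[j] == "{") {
          procamd_error(sprintf("nested '{' at offset %d", j),
                        "procamd_grammar_error", offset = j)
        }
        if (chars[j] == "}") { close <- j; break }
        j <- j + 1L
      }
      if (is.na(close)) {
        procamd_error(sprintf("unbalanced '{' at offset %d", i),
                      "procamd_grammar_error", offset = i)
      }
      if (close == i + 1L) {
        procamd_error(sprintf("empty placeholder '{}' at offset %d", i),
                      "procamd_grammar_error", offset = i)
      }
      push_literal(i - 1L)
      toks[[length(toks) + 1L]] <- list(
        kind = "placeholder",
        text = substr(template, i + 1L, close - 1L),
        start = i, end = close)
      i <- close + 1L
      lit_start <- i
    } else {
      i <- i + 1L
    }
  }
  push_literal(n)
  if (length(toks) == 0) {
    return(data.frame(kind = character(), text = character(),
                      start = integer(), end = integer(),
                      stringsAsFactors = FALSE))
  }
  data.frame(
    kind = vapply(toks, `[[`, character(1), "kind"),
    text = vapply(toks, `[[`, character(1), "text"),
    start = vapply(toks, `[[`, integer(1), "start"),
    end = vapply(toks, `[[`, integer(1), "end"),
    stringsAsFactors = FALSE
  )
}

rejoin_tokens <- function(tokens) {
  if (nrow(tokens) == 0) return("")
  paste(ifelse(tokens$kind == "placeholder",
               paste0("{", tokens$text, "}"), tokens$text),
        collapse = "")
}

template_placeholders <- function(template) {
  tok <- tokenize_template(template)
  tok$text[tok$kind == "placeholder"]
}

# `*` is the only wildcard; everything else is literal.
glob_to_regex <- function(pattern) {
  esc <- gsub("([][{}()+^$|\\\\?.])", "\\\\\\1", pattern)
  paste0("^", gsub("*", ".*", esc, fixed = TRUE), "$")
}

#' Match a glob pattern against identifiers
#'
#' `*` matches any (possibly empty) run of characters; all other characters
#' match literally. This is the only wildcard the placeholder grammar
#' admits.
#'
#' @param pattern character scalar glob pattern.
#' @param identifiers character vector of unique identifiers.
#' @return the matching identifiers, in their original (declaration) order.
#' @examples
#' match_identifiers("GALvX_*", c("GALvX_histone", "GALvX_input", "genome_fa"))
#' @export
match_identifiers <- function(pattern, identifiers) {
  stopifnot(is.character(pattern), length(pattern) == 1)
  if (length(identifiers) == 0) return(character())
  identifiers[grepl(glob_to_regex(pattern), identifiers)]
}

# Text captured by the first `*` of `pattern` when matching `text`
# (greedy, i.e. the longest capture); "" when pattern has no `*` or no match.
capture_star <- function(pattern, text) {
  if (!grepl("*", pattern, fixed = TRUE)) return("")
  esc <- gsub("([][{}()+^$|\\\\?.])", "\\\\\\1", pattern)
  star <- regexpr("*", esc, fixed = TRUE)
  rx <- paste0("^",
               substr(esc, 1, star - 1), "(.*)",
               gsub("*", ".*", substr(esc, star + 1, nchar(esc)), fixed = TRUE),
               "$")
  m <- regmatches(text, regexec(rx, text))[[1]]
  if (length(m) < 2) "" else m[2]
}

#' Classify a placeholder pattern
#'
#' A pattern is a *file* placeholder when it matches at least one file
#' identifier declared in the process (inputs, references or outputs); else
#' a *switch* when it is wildcard-free and declared among the step's
#' switches; else a *parameter*, to be bound from the AMD `[Parameters]`
#' block. The precedence file > switch > parameter is total: every pattern
#' receives exactly one class.
#'
#' @param pattern placeholder pattern (content between the braces).
#' @param doc a [process_document()].
#' @param step one of `doc$steps` (switch declarations are per step).
#' @return list with elements `pattern`, `klass` (`"file"`, `"switch"` or
#'   `"parameter"`) and `matched_identifiers` (non-empty iff `klass ==
#'   "file"`).
#' @export
classify_placeholder <- function(pattern, doc, step) {
  ids <- doc$files$identifier
  matched <- match_identifiers(pattern, ids)
  if (length(matched) > 0) {
    return(list(pattern = pattern, klass = "file",
                matched_identifiers = matched))
  }
  if (!grepl("*", pattern, fixed = TRUE) &&
      pattern %in% names(step$switches)) {
    return(list(pattern = pattern, klass = "switch",
                matched_identifiers = character()))
  }
  list(pattern = pattern, klass = "parameter",
       matched_identifiers = character())
}
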