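# XML serialization of Process documents.
#
# Element vocabulary:
#   <process id="CHP" version="1">
#     <header><author/><contact/><date/></header>
#     <description/>
#     <inputs>   <file id format quantity><comment/></file> ... </inputs>
#     <references/> <outputs/>
#     <steps>
#       <step index="1">
#         <tool/><version/><command/><loop/>
#         <switch name true false/> ... <comment/>
#       </step>
#     </steps>
#   </process>
# <loop> holds whitespace-separated placeholder patterns (empty element =
# empty loop tag). The normative schema ships as inst/extdata/process.xsd;
# an equivalent internal structural checker backs it so validation also
# works where libxml2 lacks schema support.

#' Path to the shipped XML schema / stylesheet
#'
#' @return file path inside the installed package.
#' @export
process_schema_path <- function() {
  system.file("extdata", "process.xsd", package = "procamd",
              mustWork = TRUE)
}

#' @rdname process_schema_path
#' @export
process_css_path <- function() {
  system.file("extdata", "process.css", package = "procamd",
              mustWork = TRUE)
}

KNOWN_CHILDREN <- list(
  process = c("header", "description", "inputs", "references", "outputs",
              "steps"),
  header = c("author", "contact", "date"),
  file = "comment",
  step = c("tool", "version", "command", "loop", "switch", "comment")
)

xml_issue <- function(severity, code, xpath, message) {
  new_issue(severity, code, xpath, message)
}

#' Validate process XML text against the document structure
#'
#' Structural checker equivalent to the shipped XSD: required sections and
#' attributes, integer version/index types, ISO date, the single/collection
#' quantity enumeration and (in strict mode) unknown elements. Returns
#' issues, never throws for content problems.
#'
#' @param xml_text character scalar of XML, or an `xml2` document.
#' @param strict flag unknown elements as errors (default).
#' @return list of issues (empty iff the document conforms); each carries
#'   an XPath location. Malformed XML yields a single `MALFORMED_XML`
#'   issue.
#' @seealso [xsd_validate()] for validation through libxml2 against the
#'   normative `process.xsd`.
#' @export
validate_against_schema <- function(xml_text, strict = TRUE) {
  node <- tryCatch(as_xml(xml_text), error = function(e) e)
  if (inherits(node, "error")) {
    return(list(xml_issue("error", "MALFORMED_XML", "/",
                          conditionMessage(node))))
  }
  issues <- list()
  add <- function(severity, code, xpath, message) {
    issues[[length(issues) + 1L]] <<- xml_issue(severity, code, xpath,
                                                message)
  }
  root <- xml2::xml_root(node)
  if (xml2::xml_name(root) != "process") {
    add("error", "UNKNOWN_ELEMENT", "/",
        sprintf("root element is <%s>, expected <process>",
                xml2::xml_name(root)))
    return(issues)
  }
  check_int <- function(value, xpath, what) {
    v <- suppressWarnings(as.integer(value))
    if (is.na(v) || v < 1 || as.character(v) != value) {
      add("error", "BAD_TYPE", xpath,
          sprintf("%s '%s' is not a positive integer", what, value))
    }
  }
  for (att in c("id", "version")) {
    if (is.na(xml2::xml_attr(root, att))) {
      add("error", "MISSING_ATTRIBUTE", "/process",
          sprintf("required attribute '%s' is missing", att))
    }
  }
  if (!is.na(xml2::xml_attr(root, "version"))) {
    check_int(xml2::xml_attr(root, "version"), "/process/@version",
              "version")
  }
  kids <- xml2::xml_children(root)
  kid_names <- xml2::xml_name(kids)
  for (sec in c("header", "description", "inputs", "outputs", "steps")) {
    if (!sec %in% kid_names) {
      add("error", "MISSING_SECTION", paste0("/process/", sec),
          sprintf("section <%s> is missing", sec))
    }
  }
  if (strict) {
    unknown <- setdiff(kid_names, KNOWN_CHILDREN$process)
    for (u in unknown) {
      add("error", "UNKNOWN_ELEMENT", paste0("/process/", u),
          sprintf("unknown element <%s> under <process>", u))
    }
  }
  hdr <- xml2::xml_find_first(root, "./header")
  if (!inherits(hdr, "xml_missing")) {
    d <- xml2::xml_find_first(hdr, "./date")
    if (inherits(d, "xml_missing")) {
      add("error", "MISSING_SECTION", "/process/header/date",
          "<date> is missing from the header")
    } else if (is.na(suppressWarnings(
                 as.Date(xml2::xml_text(d), format = "%Y-%m-%d")))) {
      add("error", "BAD_TYPE", "/process/header/date",
          sprintf("'%s' is not an ISO-8601 date", xml2::xml_text(d)))
    }
  }
  for (sec in c("inputs", "references", "outputs")) {
    sec_node <- xml2::xml_find_first(root, paste0("./", sec))
    if (inherits(sec_node, "xml_missing")) next
    files <- xml2::xml_find_all(sec_node, "./file")
    for (k in seq_along(files)) {
      f <- files[[k]]
      xp <- sprintf("/process/%s/file[%d]", sec, k)
      for (att in c("id", "format", "quantity")) {
        if (is.na(xml2::xml_attr(f, att))) {
          add("error", "MISSING_ATTRIBUTE", xp,
              sprintf("required attribute '%s' is missing", att))
        }
      }
      q <- xml2::xml_attr(f, "quantity")
      if (!is.na(q) && !q %in% c("single", "collection")) {
        add("error", "BAD_QUANTITY", paste0(xp, "/@quantity"),
            sprintf("quantity '%s' is not 'single' or 'collection'", q))
      }
    }
  }
  steps_node <- xml2::xml_find_first(root, "./steps")
  if (!inherits(steps_node, "xml_missing")) {
    steps <- xml2::xml_find_all(steps_node, "./step")
    for (k in seq_along(steps)) {
      s <- steps[[k]]
      xp <- sprintf("/process/steps/step[%d]", k)
      if (is.na(xml2::xml_attr(s, "index"))) {
        add("error", "MISSING_ATTRIBUTE", xp, "attribute 'index' is missing")
      } else {
        check_int(xml2::xml_attr(s, "index"), paste0(xp, "/@index"), "index")
      }
      for (el in c("tool", "version", "command")) {
        if (inherits(xml2::xml_find_first(s, paste0("./", el)),
                     "xml_missing")) {
          add("error", "MISSING_SECTION", paste0(xp, "/", el),
              sprintf("<%s> is missing from the step", el))
        }
      }
      if (strict) {
        unknown <- setdiff(xml2::xml_name(xml2::xml_children(s)),
                           KNOWN_CHILDREN$step)
        for (u in unknown) {
          add("error", "UNKNOWN_ELEMENT", paste0(xp, "/", u),
              sprintf("unknown element <%s> under <step>", u))
        }
      }
    }
  }
  issues
}

as_xml <- function(x) {
  if (inherits(x, "xml_document") || inherits(x, "xml_node")) return(x)
  xml2::read_xml(x)
}

#' Validate process XML against the shipped XSD via libxml2
#'
#' @param xml_text character scalar of XML.
#' @return logical scalar; schema error messages attached as attribute
#'   `"errors"` (as returned by [xml2::xml_validate()]).
#' @export
xsd_validate <- function(xml_text) {
  schema <- xml2::read_xml(process_schema_path())
  xml2::xml_validate(as_xml(xml_text), schema)
}

#' Read a Process document from XML
#'
#' @param xml_text character scalar of XML text, or a path-like string is
#'   *not* accepted — read the file first (see [read_process_file()]).
#' @param strict reject unknown elements (default). In lenient mode
#'   unknown children of `<process>` are preserved as opaque annotations
#'   and re-emitted by [write_process()]; unknown elements elsewhere are
#'   dropped with a warning.
#' @return a [process_document()]. Malformed XML raises a parse error with
#'   line/column (from libxml2); schema-level violations raise a classed
#'   error (`procamd_schema_error`) carrying the issue list in field
#'   `issues`.
#' @export
read_process <- function(xml_text, strict = TRUE) {
  node <- xml2::read_xml(xml_text)
  issues <- validate_against_schema(node, strict = strict)
  sev <- vapply(issues, function(i) i$severity, character(1))
  if (any(sev == "error")) {
    procamd_error(
      paste0("process XML violates the schema:\n",
             paste(vapply(issues, function(i)
               sprintf("  %s at %s: %s", i$code, i$location, i$message),
               character(1)), collapse = "\n")),
      "procamd_schema_error", issues = issues)
  }
  root <- xml2::xml_root(node)
  text1 <- function(parent, el) {
    n <- xml2::xml_find_first(parent, paste0("./", el))
    if (inherits(n, "xml_missing")) "" else xml2::xml_text(n)
  }
  hdr <- xml2::xml_find_first(root, "./header")
  files <- list()
  for (sec in c("inputs", "references", "outputs")) {
    sec_node <- xml2::xml_find_first(root, paste0("./", sec))
    if (inherits(sec_node, "xml_missing")) next
    for (f in xml2::xml_find_all(sec_node, "./file")) {
      files[[length(files) + 1L]] <- file_entry(
        identifier = xml2::xml_attr(f, "id"),
        section = sub("s$", "", sec),
        format = xml2::xml_attr(f, "format"),
        comment = text1(f, "comment"),
        quantity = xml2::xml_attr(f, "quantity"))
    }
  }
  steps <- lapply(xml2::xml_find_all(root, "./steps/step"), function(s) {
    loop_text <- text1(s, "loop")
    loop <- if (nzchar(trimws(loop_text)))
      strsplit(trimws(loop_text), "[[:space:]]+")[[1]] else character()
    switches <- list()
    for (sw in xml2::xml_find_all(s, "./switch")) {
      switches[[xml2::xml_attr(sw, "name")]] <-
        list(true = xml2::xml_attr(sw, "true"),
             false = xml2::xml_attr(sw, "false"))
    }
    tool_step(tool_name = text1(s, "tool"),
              tool_version = text1(s, "version"),
              command_template = text1(s, "command"),
              loop_over = loop, switches = switches,
              comment = text1(s, "comment"),
              index = as.integer(xml2::xml_attr(s, "index")))
  })
  doc <- new_process_document(
    header = list(process_id = xml2::xml_attr(root, "id"),
                  version = as.integer(xml2::xml_attr(root, "version")),
                  author_name = text1(hdr, "author"),
                  author_contact = text1(hdr, "contact"),
                  date = text1(hdr, "date")),
    description = text1(root, "description"),
    files = if (length(files)) do.call(rbind, files) else NULL,
    steps = steps)
  if (!strict) {
    unknown <- xml2::xml_children(root)
    unknown <- unknown[!xml2::xml_name(unknown) %in% KNOWN_CHILDREN$process]
    if (length(unknown) > 0) {
      attr(doc, "unknown_elements") <-
        vapply(unknown, function(u) as.character(u), character(1))
    }
  }
  doc
}

#' Write a Process document as XML
#'
#' Deterministic element order (header, description, inputs, references,
#' outputs, steps); byte-identical across repeated calls; output validates
#' against the shipped schema. Structurally invalid documents are refused
#' with the embedded [check_structure()] report.
#'
#' @param doc a [process_document()].
#' @param css embed an `xml-stylesheet` processing instruction pointing at
#'   `process.css`, for readability when the file is opened in a web
#'   browser.
#' @return character scalar of UTF-8 XML text.
#' @export
write_process <- function(doc, css = FALSE) {
  rep <- check_structure(doc)
  if (!rep$ok) {
    procamd_error(
      paste0("refusing to serialize a structurally invalid document:\n",
             paste(utils::capture.output(print(rep)), collapse = "\n")),
      "procamd_structure_error", report = rep)
  }
  x <- xml2::xml_new_root("process",
                          id = doc$header$process_id,
                          version = as.character(doc$header$version))
  hdr <- xml2::xml_add_child(x, "header")
  xml2::xml_add_child(hdr, "author", doc$header$author_name)
  xml2::xml_add_child(hdr, "contact", doc$header$author_contact)
  xml2::xml_add_child(hdr, "date", doc$header$date)
  xml2::xml_add_child(x, "description", doc$description)
  for (sec in c("input", "reference", "output")) {
    sec_node <- xml2::xml_add_child(x, paste0(sec, "s"))
    entries <- doc$files[doc$files$section == sec, , drop = FALSE]
    for (i in seq_len(nrow(entries))) {
      f <- xml2::xml_add_child(sec_node, "file",
                               id = entries$identifier[i],
                               format = entries$format[i],
                               quantity = entries$quantity[i])
      if (nzchar(entries$comment[i])) {
        xml2::xml_add_child(f, "comment", entries$comment[i])
      }
    }
  }
  steps_node <- xml2::xml_add_child(x, "steps")
  for (s in doc$steps) {
    sn <- xml2::xml_add_child(steps_node, "step",
                              index = as.character(s$index))
    xml2::xml_add_child(sn, "tool", s$tool_name)
    xml2::xml_add_child(sn, "version", s$tool_version)
    xml2::xml_add_child(sn, "command", s$command_template)
    xml2::xml_add_child(sn, "loop", paste(s$loop_over, collapse = " "))
    for (nm in names(s$switches)) {
      xml2::xml_add_child(sn, "switch", name = nm,
                          true = s$switches[[nm]]$true,
                          false = s$switches[[nm]]$false)
    }
    if (nzchar(s$comment)) xml2::xml_add_child(sn, "comment", s$comment)
  }
  for (u in attr(doc, "unknown_elements")) {
    xml2::xml_add_child(x, xml2::xml_root(xml2::read_xml(u)))
  }
  txt <- as.character(x)
  if (css) {
    txt <- sub("\\?>\n",
               "?>\n<?xml-stylesheet type=\"text/css\" href=\"process.css\"?>\n",
               txt)
  }
  txt
}

#' Read / write Process XML files on disk
#'
#' @param path file path (`.xml`).
#' @param doc a [process_document()].
#' @param strict,css passed through to [read_process()] /
#'   [write_process()].
#' @return `read_process_file()` a `process_document`;
#'   `write_process_file()` the path, invisibly.
#' @export
read_process_file <- function(path, strict = TRUE) {
  read_process(readChar(path, file.size(path), useBytes = TRUE),
               strict = strict)
}

#' @rdname read_process_file
#' @export
write_process_file <- function(doc, path, css = FALSE) {
  writeLines(write_process(doc, css = css), path, sep = "", useBytes = TRUE)
  invisible(path)
}
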