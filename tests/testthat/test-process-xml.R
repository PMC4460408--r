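test_that("process XML round-trips through write and read", {
  docs <- list(
    minimal_doc(),
    chipseq_example()$process,
    generate_triple(fixture_config(seed = 2))$process,
    generate_triple(fixture_config(n_inputs = 5, n_references = 0,
                                   loop_profile = "full",
                                   seed = 9))$process)
  for (d in docs) {
    xml <- write_process(d)
    expect_identical(read_process(xml), d)
    # serialization is deterministic (byte-identical on repeat)
    expect_identical(write_process(d), xml)
    # output of the writer always satisfies both validation routes
    expect_length(validate_against_schema(xml), 0)
    expect_true(xsd_validate(xml))
  }
})

test_that("non-ASCII header fields survive the UTF-8 round trip", {
  d <- minimal_doc()
  d$header$author_name <- "Anaïs Müller"
  path <- withr::local_tempfile(fileext = ".xml")
  write_process_file(d, path)
  expect_identical(read_process_file(path)$header$author_name,
                   d$header$author_name)
})

test_that("a transcribed word-count process parses into all four sections", {
  xml <- '<?xml version="1.0" encoding="UTF-8"?>
<process id="WCP" version="1">
  <header><author>B. Writer</author><contact>b@example.org</contact>
    <date>2015-01-15</date></header>
  <description>Count lines in an input file that contain two specified
    words and compare the resulting number to the number of lines in a
    reference file.</description>
  <inputs>
    <file id="input_file" format="TXT" quantity="single"/>
  </inputs>
  <references>
    <file id="ref_counts" format="TXT" quantity="single"/>
  </references>
  <outputs>
    <file id="count_out" format="TXT" quantity="single"/>
  </outputs>
  <steps>
    <step index="1">
      <tool>grep</tool><version>2.16</version>
      <command>grep -c {word1} {input_file} &gt; {count_out}</command>
      <loop/>
    </step>
    <step index="2">
      <tool>diffcount</tool><version>0.2</version>
      <command>diffcount {count_out} {ref_counts}</command>
      <loop/>
    </step>
  </steps>
</process>'
  doc <- read_process(xml)
  expect_s3_class(doc, "process_document")
  expect_equal(doc$header$process_id, "WCP")
  expect_length(doc$steps, 2)
  expect_equal(nrow(doc$files), 3)
  expect_length(check_structure(doc)$issues, 0)
  # each placeholder's value lives in the AMD, not the process
  expect_true("word1" %in%
                template_placeholders(doc$steps[[1]]$command_template))
})

test_that("schema violations are coded and located", {
  good <- write_process(minimal_doc())

  no_steps <- sub("(?s)<steps>.*</steps>", "", good, perl = TRUE)
  issues <- validate_against_schema(no_steps)
  expect_true("MISSING_SECTION" %in%
                vapply(issues, `[[`, character(1), "code"))
  expect_false(xsd_validate(no_steps))

  bad_version <- sub('version="1"', 'version="one"', good)
  codes <- vapply(validate_against_schema(bad_version), `[[`,
                  character(1), "code")
  expect_true("BAD_TYPE" %in% codes)
  expect_false(xsd_validate(bad_version))

  no_id <- sub(' id="in_file"', "", good)
  codes <- vapply(validate_against_schema(no_id), `[[`,
                  character(1), "code")
  expect_true("MISSING_ATTRIBUTE" %in% codes)
  expect_false(xsd_validate(no_id))

  bad_quantity <- sub('quantity="single"', 'quantity="many"', good)
  codes <- vapply(validate_against_schema(bad_quantity), `[[`,
                  character(1), "code")
  expect_true("BAD_QUANTITY" %in% codes)
  expect_false(xsd_validate(bad_quantity))

  # every issue's xpath resolves in the document (prefix sanity)
  for (iss in validate_against_schema(bad_version)) {
    expect_match(iss$location, "^/")
  }

  # reading a violating document raises a classed error carrying issues
  expect_error(read_process(no_steps), class = "procamd_schema_error")
  err <- tryCatch(read_process(bad_version), condition = identity)
  expect_true(length(err$issues) >= 1)
})

test_that("strict mode rejects unknown elements, lenient mode keeps them", {
  good <- write_process(minimal_doc())
  extended <- sub("</process>", "<audit>by QA</audit></process>", good)
  expect_error(read_process(extended, strict = TRUE),
               class = "procamd_schema_error")
  doc <- read_process(extended, strict = FALSE)
  expect_s3_class(doc, "process_document")
  expect_match(attr(doc, "unknown_elements"), "audit")
  # the annotation is re-emitted on write
  expect_match(write_process(doc), "<audit>by QA</audit>")
})

test_that("the css option embeds a stylesheet reference", {
  xml <- write_process(minimal_doc(), css = TRUE)
  expect_match(xml, "xml-stylesheet", fixed = TRUE)
  expect_identical(read_process(xml), minimal_doc())
  expect_true(file.exists(process_css_path()))
})

test_that("writing a structurally invalid document is refused with a report", {
  bad <- minimal_doc()
  bad$files$quantity[1] <- "many"
  err <- tryCatch(write_process(bad), condition = identity)
  expect_s3_class(err, "procamd_structure_error")
  expect_true("BAD_QUANTITY" %in% issue_codes(err$report))
})
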