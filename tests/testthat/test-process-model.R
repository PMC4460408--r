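test_that("find_entries returns sections in declaration order", {
  ex <- chipseq_example()
  ins <- find_entries(ex$process, "input")
  expect_equal(ins$identifier, c("GALvX_histone", "GALvX_input"))
  # the control is listed separately as 'single'
  expect_equal(ins$quantity[ins$identifier == "GALvX_input"], "single")
  expect_equal(ins$quantity[ins$identifier == "GALvX_histone"],
               "collection")

  # no references at all -> empty data frame, not an error
  doc <- minimal_doc()
  expect_equal(nrow(find_entries(doc, "reference")), 0)

  # 'all' concatenates inputs -> references -> outputs
  doc2 <- process_document(
    "ORD", 1, "a", "b", "2015-01-01", "ordering fixture",
    rbind(file_entry("a", "input", quantity = "single"),
          file_entry("b", "output", quantity = "single"),
          file_entry("c", "reference", quantity = "single")),
    list(tool_step("t", "1", "t {a} {b}")))
  expect_equal(find_entries(doc2, "all")$identifier, c("a", "c", "b"))

  expect_error(find_entries(doc2, "bogus"))
})

test_that("check_structure reports coded violations and is side-effect free", {
  doc <- minimal_doc()
  expect_length(check_structure(doc)$issues, 0)

  # duplicate identifier across sections
  dup <- doc
  dup$files <- rbind(dup$files,
                     file_entry("in_file", "output", quantity = "single"))
  rep <- check_structure(dup)
  expect_true("DUPLICATE_IDENTIFIER" %in% issue_codes(rep, "error"))

  # quantity outside the single/collection enumeration
  badq <- doc
  badq$files$quantity[1] <- "many"
  expect_true("BAD_QUANTITY" %in% issue_codes(check_structure(badq),
                                              "error"))

  # missing sections
  nodesc <- doc
  nodesc$description <- NULL
  expect_true("MISSING_SECTION" %in% issue_codes(check_structure(nodesc)))
  nosteps <- doc
  nosteps$steps <- list()
  expect_true("MISSING_SECTION" %in% issue_codes(check_structure(nosteps)))

  # loop pattern that resolves to nothing
  badloop <- minimal_doc()
  badloop$steps[[1]]$loop_over <- "zz_*"
  expect_true("UNRESOLVED_PLACEHOLDER" %in%
                issue_codes(check_structure(badloop), "error"))

  # idempotent: checking twice yields identical reports, inputs unchanged
  snapshot <- unserialize(serialize(dup, NULL))
  r1 <- check_structure(dup)
  r2 <- check_structure(dup)
  expect_identical(r1, r2)
  expect_identical(dup, snapshot)
})

test_that("version increment rules classify the four required changes", {
  ex <- chipseq_example()
  base <- ex$process

  # (i) tool version update
  v <- base
  v$steps[[3]]$tool_version <- "2.1.0"
  dec <- compare_processes(base, v)
  expect_true(dec$increment_required)
  expect_equal(dec$reasons, "TOOL_VERSION_CHANGED")

  # (ii) step added / removed / reordered
  added <- base
  added$steps <- c(added$steps,
                   list(tool_step("bamCoverage", "1.5.9.1",
                                  "bamCoverage -b {GALvX_histone}",
                                  index = 4)))
  expect_true("STEP_SERIES_CHANGED" %in%
                compare_processes(base, added)$reasons)
  reordered <- base
  reordered$steps <- base$steps[c(2, 1, 3)]
  for (i in 1:3) reordered$steps[[i]]$index <- i
  expect_true("STEP_SERIES_CHANGED" %in%
                compare_processes(base, reordered)$reasons)

  # (iii) a fixed literal (default parameter) changed
  q <- base
  q$steps[[3]]$command_template <-
    sub("--qvalue 0.05", "--qvalue 0.01", q$steps[[3]]$command_template)
  expect_equal(compare_processes(base, q)$reasons, "DEFAULTS_CHANGED")

  # (iv) file listings changed
  f <- base
  f$files <- rbind(f$files,
                   file_entry("blacklist_bed", "reference", "BED",
                              quantity = "single"))
  expect_equal(compare_processes(base, f)$reasons, "FILE_LISTINGS_CHANGED")

  # quantity flip is a listing change too
  qf <- base
  qf$files$quantity[qf$files$identifier == "GALvX_input"] <- "collection"
  expect_equal(compare_processes(base, qf)$reasons, "FILE_LISTINGS_CHANGED")
})

test_that("comment and description edits never require an increment", {
  base <- chipseq_example()$process

  com <- base
  com$steps[[1]]$comment <- "rewritten remark"
  com$files$comment[1] <- "better wording"
  dec <- compare_processes(base, com)
  expect_false(dec$increment_required)
  expect_equal(dec$reasons, character(0))
  expect_equal(dec$ignorable_changes, "COMMENT_ONLY")

  des <- base
  des$description <- "rephrased purpose statement"
  dec2 <- compare_processes(base, des)
  expect_false(dec2$increment_required)
  expect_equal(dec2$ignorable_changes, "DESCRIPTION_ONLY")

  # placeholder rename alone is not a defaults change
  ren <- base
  ren$steps[[1]]$command_template <-
    gsub("\\{numproc\\}", "{n_cpu}", ren$steps[[1]]$command_template)
  expect_false("DEFAULTS_CHANGED" %in% compare_processes(base, ren)$reasons)
})

test_that("increment comparison is reflexive and symmetric", {
  docs <- list(chipseq_example()$process, minimal_doc(),
               generate_triple(fixture_config(seed = 5))$process)
  for (d in docs) {
    dec <- compare_processes(d, d)
    expect_false(dec$increment_required)
    expect_equal(dec$reasons, character(0))
  }
  base <- docs[[1]]
  v1 <- base; v1$steps[[2]]$tool_version <- "9.9"
  v2 <- base; v2$files <- base$files[-3, ]
  v3 <- base; v3$description <- "x"
  for (v in list(v1, v2, v3)) {
    expect_equal(compare_processes(base, v)$increment_required,
                 compare_processes(v, base)$increment_required)
  }
  # differing process ids are incomparable
  other <- minimal_doc(process_id = "OTH")
  expect_error(compare_processes(base, other),
               class = "procamd_incomparable")
})
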