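test_that("a consistent pair validates cleanly and inputs are not mutated", {
  ex <- chipseq_example()
  before <- unserialize(serialize(ex, NULL))
  rep <- validate_pair(ex$process, ex$amd)
  expect_true(rep$ok)
  expect_length(rep$issues, 0)
  expect_identical(ex, before)
  # deterministic report
  expect_identical(validate_pair(ex$process, ex$amd), rep)
})

test_that("identity, version, binding and cardinality rules fire in order", {
  ex <- chipseq_example()

  v <- ex$amd
  v$general[["process_version"]] <- "2"
  rep <- validate_pair(ex$process, v)
  expect_equal(issue_codes(rep, "error"), "VERSION_MISMATCH")

  p <- ex$amd
  p$general[["process_id"]] <- "GAL"
  expect_true("PROCESS_ID_MISMATCH" %in%
                issue_codes(validate_pair(ex$process, p), "error"))

  # exactly one input control is expected to match all histone files
  dup <- ex$amd
  dup$inputs <- c(dup$inputs,
                  stats::setNames("Input.GAL.2.bam", "GALvX_input"))
  expect_true("CARDINALITY_SINGLE_VIOLATED" %in%
                issue_codes(validate_pair(ex$process, dup), "error"))

  miss <- ex$amd
  miss$references <- character()
  expect_true("MISSING_FILE_BINDING" %in%
                issue_codes(validate_pair(ex$process, miss), "error"))

  orphan <- ex$amd
  orphan$inputs <- c(orphan$inputs,
                     stats::setNames("x.bam", "unknown_key"))
  rep <- validate_pair(ex$process, orphan)
  expect_true(rep$ok)  # orphan keys warn, they do not fail
  expect_true("ORPHAN_AMD_KEY" %in% issue_codes(rep, "warning"))
})

test_that("placeholder resolution rules catch missing parameters and bad switches", {
  ex <- chipseq_example()

  # {labels} is a non-file parameter and must be bound in [Parameters]
  nolabels <- ex$amd
  nolabels$parameters <-
    nolabels$parameters[names(nolabels$parameters) != "labels"]
  rep <- validate_pair(ex$process, nolabels)
  expect_true("MISSING_PARAMETER" %in% issue_codes(rep, "error"))
  expect_match(paste(as.data.frame(rep)$message, collapse = " "), "labels")

  # a per-loop-element wildcard key must exist for every element
  nofrag <- ex$amd
  nofrag$parameters <- nofrag$parameters[
    names(nofrag$parameters) != "H3K27me3_median_fraglen"]
  rep2 <- validate_pair(ex$process, nofrag)
  expect_true("MISSING_PARAMETER" %in% issue_codes(rep2, "error"))
  expect_match(paste(as.data.frame(rep2)$message, collapse = " "),
               "H3K27me3_median_fraglen")

  # the explicit True/False form is required for switches
  sw <- ex$amd
  sw$parameters[["broad"]] <- "yes"
  expect_true("BAD_SWITCH_VALUE" %in%
                issue_codes(validate_pair(ex$process, sw), "error"))
})

test_that("output presence check equals the set-difference oracle", {
  ex <- chipseq_example()
  expect_true(check_outputs_present(ex$amd, ex$present_files)$ok)

  for (drop in c(1, 3, length(ex$present_files))) {
    present <- ex$present_files[-drop]
    rep <- check_outputs_present(ex$amd, present)
    missing_oracle <- setdiff(unname(ex$amd$outputs), present)
    expect_equal(sum(issue_codes(rep, "error") == "MISSING_OUTPUT_FILE"),
                 length(missing_oracle))
  }
  # extra files on disk are fine
  expect_true(check_outputs_present(
    ex$amd, c(ex$present_files, "scratch.tmp"))$ok)
  # an empty Outputs block is a warning, not an error
  empty <- minimal_amd()
  empty$outputs <- character()
  rep <- check_outputs_present(amd_document(
    empty$general, inputs = empty$inputs), character())
  expect_true(rep$ok)
  expect_length(rep$issues, 1)
})

test_that("compatible AMDs must list identical references", {
  mk <- function(aid, genome = "hg19.GRCh37.fa") {
    amd_document(c(process_id = "CHP", process_version = "1",
                   analysis_id = aid, date = "2015-01-01"),
                 references = c(genome_fa = genome))
  }
  expect_true(check_reference_consistency(
    list(mk("r1"), mk("r2"), mk("r3")))$ok)
  rep <- check_reference_consistency(
    list(mk("r1"), mk("r2", "hg38.fa"), mk("r3")))
  expect_equal(issue_codes(rep, "error"), "REFERENCE_INCONSISTENT")
  expect_match(as.data.frame(rep)$message, "r2")
  # single AMD is vacuously consistent
  expect_true(check_reference_consistency(list(mk("r1")))$ok)
  # incompatible AMDs are not compared further
  other <- amd_document(c(process_id = "GAL", process_version = "1",
                          analysis_id = "g1", date = "2015-01-01"),
                        references = c(genome_fa = "hg38.fa"))
  rep2 <- check_reference_consistency(list(mk("r1"), other))
  expect_true("PROCESS_ID_MISMATCH" %in% issue_codes(rep2, "error"))
  expect_false("REFERENCE_INCONSISTENT" %in% issue_codes(rep2))
})

test_that("pipeline chaining matches downstream inputs to upstream outputs", {
  gal <- amd_document(c(process_id = "GAL", process_version = "1",
                        analysis_id = "align1", date = "2015-01-01"),
                      outputs = stats::setNames(
                        c("a.GAL.bam", "b.GAL.bam", "ctl.GAL.bam"),
                        c("bam_out", "bam_out", "bam_out")))
  chp <- amd_document(c(process_id = "CHP", process_version = "1",
                        analysis_id = "peaks1", date = "2015-01-02"),
                      inputs = stats::setNames(
                        c("a.GAL.bam", "b.GAL.bam", "ctl.GAL.bam"),
                        c("GALvX_histone", "GALvX_histone", "GALvX_input")))
  expect_true(check_chain(gal, chp)$ok)
  expect_length(check_chain(gal, chp)$issues, 0)

  renamed <- amd_document(chp$general,
                          inputs = stats::setNames("c.GAL.bam",
                                                   "GALvX_histone"))
  rep <- check_chain(gal, renamed)
  expect_true(rep$ok)  # warning by default
  expect_equal(issue_codes(rep, "warning"), "CHAIN_BROKEN")
  expect_false(check_chain(gal, renamed, strict = TRUE)$ok)

  empty_in <- amd_document(chp$general)
  expect_length(check_chain(gal, empty_in)$issues, 0)
})

test_that("naming lint flags outputs without the process identifier", {
  ok <- amd_document(c(process_id = "CHP", process_version = "1",
                       analysis_id = "r", date = "2015-01-01"),
                     outputs = c(peaks = "sample7.CHP.20150101.narrowPeak"))
  expect_length(lint_naming(ok)$issues, 0)
  bad <- amd_document(ok$general, outputs = c(peaks = "peaks.bed"))
  rep <- lint_naming(bad)
  expect_true(rep$ok)  # never an error
  expect_equal(issue_codes(rep, "warning"), "NAMING_CONVENTION")
  none <- amd_document(ok$general)
  expect_length(lint_naming(none)$issues, 0)
})
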