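test_that("the empty loop yields one invocation over all bound files", {
  ex <- chipseq_example()
  inv <- expand_step(ex$process, ex$amd, ex$process$steps[[1]])
  expect_length(inv, 1)
  cmd <- inv[[1]]$command_line
  # all three alignments are passed at once
  expect_match(cmd,
               "--bamfiles H3K4me3.GAL.bam H3K27me3.GAL.bam Input.GAL.bam",
               fixed = TRUE)
  # the fixed parameter is not dynamic
  expect_match(cmd, "--numberOfSamples 500000", fixed = TRUE)
  # single-quantity output irrespective of the number of inputs
  expect_match(cmd, "--plotFile sample7.CHP.20150101.fgpplot.png",
               fixed = TRUE)
  expect_equal(inv[[1]]$iteration, 0L)
})

test_that("the full loop emits one invocation per alignment with its own wildcard values", {
  ex <- chipseq_example()
  inv <- expand_step(ex$process, ex$amd, ex$process$steps[[2]])
  expect_length(inv, 3)  # two histone marks + the input control
  cmds <- vapply(inv, `[[`, character(1), "command_line")
  expect_match(cmds[1], "--bamfile H3K4me3.GAL.bam", fixed = TRUE)
  expect_match(cmds[1], "--fragmentLength 180", fixed = TRUE)
  expect_match(cmds[2], "--fragmentLength 200", fixed = TRUE)
  expect_match(cmds[3], "--bamfile Input.GAL.bam", fixed = TRUE)
  expect_match(cmds[3], "--fragmentLength 175", fixed = TRUE)
  # each iteration consumes its own pair of collection outputs
  expect_match(cmds[1], "H3K4me3.CHP.20150101.gcbfreq.txt", fixed = TRUE)
  expect_match(cmds[3], "Input.CHP.20150101.gcbplot.png", fixed = TRUE)
  expect_equal(vapply(inv, `[[`, integer(1), "iteration"), 0:2)
})

test_that("the partial loop holds the single control constant", {
  ex <- chipseq_example()
  inv <- expand_step(ex$process, ex$amd, ex$process$steps[[3]])
  expect_length(inv, 2)  # loops over histones, not the control
  cmds <- vapply(inv, `[[`, character(1), "command_line")
  ctl <- regmatches(cmds, regexpr("-c [^ ]+", cmds))
  expect_equal(ctl, rep("-c Input.GAL.bam", 2))
  expect_match(cmds[1], "-t H3K4me3.GAL.bam", fixed = TRUE)
  expect_match(cmds[2], "-t H3K27me3.GAL.bam", fixed = TRUE)
  expect_match(cmds[1], "--name H3K4me3.CHP.20150101", fixed = TRUE)
  expect_match(cmds[2], "--extsize 200", fixed = TRUE)
})

test_that("binary switches emit their True/False text", {
  on <- chipseq_example(broad = TRUE)
  off <- chipseq_example(broad = FALSE)
  cmd_on <- expand_step(on$process, on$amd,
                        on$process$steps[[3]])[[1]]$command_line
  cmd_off <- expand_step(off$process, off$amd,
                         off$process$steps[[3]])[[1]]$command_line
  expect_match(cmd_on, "--broad", fixed = TRUE)
  expect_false(grepl("broad", cmd_off, fixed = TRUE))
})

test_that("expand_process concatenates steps: counts follow the loop law", {
  for (n in c(1, 3)) {
    ex <- chipseq_example(marks = paste0("mark", seq_len(n)))
    inv <- expand_process(ex$process, ex$amd)
    per_step <- table(factor(vapply(inv, `[[`, integer(1), "step_index"),
                             levels = 1:3))
    expect_equal(as.integer(per_step), c(1L, n + 1L, n))
    expect_length(inv, 1 + (n + 1) + n)
  }
})

test_that("expansion is deterministic, brace-free and literal-preserving", {
  fixtures <- lapply(c(4, 14, 24), function(s)
    generate_triple(fixture_config(
      n_inputs = 1 + s %% 5,
      loop_profile = c("mixed", "full", "partial")[1 + s %% 3],
      seed = s)))
  fixtures <- c(fixtures, list(chipseq_example()))
  for (f in fixtures) {
    inv1 <- expand_process(f$process, f$amd)
    inv2 <- expand_process(f$process, f$amd)
    expect_identical(inv1, inv2)
    for (i in inv1) {
      expect_false(grepl("[{}]", i$command_line))
      # every literal chunk of the template survives into the command
      step <- f$process$steps[[i$step_index]]
      tok <- tokenize_template(step$command_template)
      for (lit in trimws(tok$text[tok$kind == "literal"])) {
        if (nzchar(lit)) expect_match(i$command_line, lit, fixed = TRUE)
      }
      # bound outputs are a subset of the AMD Outputs bindings
      if (nrow(i$bound_outputs) > 0) {
        expect_true(all(i$bound_outputs$filename %in%
                          unname(f$amd$outputs)))
      }
    }
  }
})

test_that("materialization refuses invalid pairs and impossible bindings", {
  ex <- chipseq_example()

  broken <- ex$amd
  broken$parameters <- broken$parameters[
    names(broken$parameters) != "genomesize"]
  expect_error(expand_process(ex$process, broken),
               class = "procamd_materialize_error")

  # a looped wildcard key missing only at expansion time
  amd2 <- ex$amd
  amd2$parameters <- amd2$parameters[
    names(amd2$parameters) != "H3K4me3_name_prefix"]
  err <- tryCatch(expand_process(ex$process, amd2), condition = identity)
  expect_s3_class(err, "procamd_materialize_error")

  # fewer collection-output bindings than loop iterations
  amd3 <- ex$amd
  drop <- which(names(amd3$outputs) == "sampleID.PROCESS.DATE.gcbfreq")[1]
  amd3$outputs <- amd3$outputs[-drop]
  err3 <- tryCatch(
    expand_step(ex$process, amd3, ex$process$steps[[2]], validated = TRUE),
    condition = identity)
  expect_s3_class(err3, "procamd_materialize_error")
  expect_equal(err3$code, "MATERIALIZE_OUTPUT_ARITY")
})

test_that("loop labels can be overridden by reserved parameter keys", {
  ex <- chipseq_example(marks = "H3K4me3")
  amd <- ex$amd
  # relabel the histone element; its wildcard keys must follow
  amd$parameters <- c(amd$parameters,
                      stats::setNames("K4", "GALvX_histone_label"),
                      stats::setNames("180", "K4_median_fraglen"),
                      stats::setNames("K4.CHP.20150101", "K4_name_prefix"))
  inv <- expand_step(ex$process, amd, ex$process$steps[[3]],
                     validated = TRUE)
  expect_match(inv[[1]]$command_line, "--name K4.CHP.20150101",
               fixed = TRUE)
})

test_that("a render of the expansion carries one command per line", {
  ex <- chipseq_example()
  inv <- expand_process(ex$process, ex$amd)
  script <- render_script(inv, ex$process, ex$amd)
  lines <- strsplit(script, "\n")[[1]]
  expect_equal(sum(!startsWith(lines, "#")), length(inv))
  expect_match(lines[1], "CHP v1", fixed = TRUE)
})
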