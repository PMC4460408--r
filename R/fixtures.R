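# Synthetic fixture generation.
#
# generate_triple() emits an internally consistent (process, AMD,
# file-listing) triple emulating the structures a real epigenomics
# pipeline exhibits: a collection of per-mark signal alignments plus
# exactly one control (quantity 'single'), shared reference files,
# per-file parameters keyed by a sample-dependent prefix, a binary
# switch, and the three loop variants (empty, full, partial). Tool names
# come from a fixed fake vocabulary — nothing generated here is meant to
# be executable. corrupt_triple() applies one minimal, targeted edit per
# validator code so the detection matrix is testable without downloads.

#' Fixture generator configuration
#'
#' @param n_inputs number of collection (signal) input files, >= 1; a
#'   single-quantity control input is always added on top.
#' @param n_references number of reference entries, >= 0.
#' @param n_steps number of tool steps, >= 1.
#' @param loop_profile `"none"` (all steps loop-free), `"full"` (all steps
#'   loop over signal and control), `"partial"` (all steps loop over the
#'   signal collection while holding the control constant) or `"mixed"`
#'   (cycle empty/full/partial — the default, covering all variants).
#' @param with_switch attach a binary True/False switch to the last step.
#' @param seed integer seed; the same configuration always yields the
#'   identical triple, byte for byte.
#' @return object of class `fixture_config`.
#' @export
fixture_config <- function(n_inputs = 2, n_references = 3, n_steps = 3,
                           loop_profile = c("mixed", "none", "full",
                                            "partial"),
                           with_switch = TRUE, seed = 1) {
  loop_profile <- match.arg(loop_profile)
  stopifnot(n_inputs >= 1, n_inputs <= 50, n_references >= 0,
            n_references <= 50, n_steps >= 1, n_steps <= 50)
  structure(list(n_inputs = as.integer(n_inputs),
                 n_references = as.integer(n_references),
                 n_steps = as.integer(n_steps),
                 loop_profile = loop_profile,
                 with_switch = isTRUE(with_switch),
                 seed = as.integer(seed)),
            class = "fixture_config")
}

with_local_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  force(expr)
}

FAKE_TOOLS <- c("fxplot", "fxscan", "fxpeak", "fxnorm", "fxtally")

#' Generate a consistent (process, AMD, file listing) triple
#'
#' By construction the triple is validation-clean: [validate_pair()],
#' [check_outputs_present()] and [lint_naming()] report no errors, the
#' serialized process XML satisfies the shipped schema, and the bundled
#' companions keep the cross-AMD checks clean too (a `peer` AMD of a
#' second sample with identical references, and a synthetic `upstream`
#' AMD whose outputs cover this run's inputs).
#'
#' @param cfg a [fixture_config()].
#' @param sample_token short token distinguishing compatible runs (the
#'   peer AMD uses a different one).
#' @return object of class `fixture_triple` with elements `process`,
#'   `amd`, `present_files`, `peer`, `upstream` and `config`.
#' @export
generate_triple <- function(cfg = fixture_config(), sample_token = "s1") {
  stopifnot(inherits(cfg, "fixture_config"))
  with_local_seed(cfg$seed, build_triple(cfg, sample_token))
}

build_triple <- function(cfg, sample_token) {
  pid <- "FXP"
  marks <- paste0(sample_token, "mark", seq_len(cfg$n_inputs))
  ctl <- paste0(sample_token, "ctl")
  sig_files <- paste0(marks, ".", pid, ".bam")
  ctl_file <- paste0(ctl, ".", pid, ".bam")

  files <- rbind(
    file_entry("smp_sig", "input", "BAM",
               comment = "one alignment per mark", quantity = "collection"),
    file_entry("smp_ctl", "input", "BAM",
               comment = "exactly one control matches all marks",
               quantity = "single"))
  ref_ids <- character()
  ref_files <- character()
  if (cfg$n_references > 0) {
    ref_ids <- paste0("ref_", seq_len(cfg$n_references))
    ref_fmt <- rep(c("FASTA", "BED"), length.out = cfg$n_references)
    ref_files <- paste0("ref", seq_len(cfg$n_references), ".", pid, ".",
                        tolower(ref_fmt))
    for (i in seq_len(cfg$n_references)) {
      files <- rbind(files, file_entry(ref_ids[i], "reference", ref_fmt[i],
                                       quantity = "single"))
    }
  }

  step_kind <- switch(cfg$loop_profile,
    none = rep("empty", cfg$n_steps),
    full = rep("full", cfg$n_steps),
    partial = rep("partial", cfg$n_steps),
    mixed = rep(c("empty", "full", "partial"), length.out = cfg$n_steps))

  labels <- c(marks, ctl)
  outputs <- character()   # named vector: identifier -> filenames
  steps <- list()
  params <- c(nproc = as.character(sample(2:16, 1)),
              gsize = sprintf("%.1fe9", stats::runif(1, 1, 3)),
              labels = paste(labels, collapse = " "),
              all_fraglen = "")
  fraglens <- sample(120:260, length(labels), replace = TRUE)
  params[["all_fraglen"]] <- paste(fraglens, collapse = " ")
  for (i in seq_along(labels)) {
    params[paste0(labels[i], "_fraglen")] <- as.character(fraglens[i])
  }
  for (m in marks) params[paste0(m, "_prefix")] <- paste0(m, ".", pid)
  # pin loop-element labels to the mark/control tokens regardless of how
  # many bindings each identifier has (reserved override keys)
  params <- c(params,
              stats::setNames(marks, rep("smp_sig_label", length(marks))),
              stats::setNames(ctl, "smp_ctl_label"))

  ref_arg <- if (length(ref_ids) > 0) " --ref {ref_1}" else ""
  for (i in seq_len(cfg$n_steps)) {
    kind <- step_kind[i]
    tool <- FAKE_TOOLS[(i - 1) %% length(FAKE_TOOLS) + 1]
    tver <- sprintf("%d.%d.%d", sample(1:3, 1), sample(0:9, 1),
                    sample(0:9, 1))
    if (kind == "empty") {
      oid <- sprintf("plot%d_out", i)
      ofn <- paste0("all.", pid, ".step", i, ".png")
      files <- rbind(files, file_entry(oid, "output", "PNG",
                                       quantity = "single"))
      outputs <- c(outputs, stats::setNames(ofn, oid))
      steps[[i]] <- tool_step(tool, tver, paste0(
        tool, " -p {nproc} --bamfiles {smp_*} --labels {labels}",
        " --frags {all_fraglen}", ref_arg, " --out {", oid, "}",
        " --bins 500"),
        comment = "all alignments processed at once")
    } else if (kind == "full") {
      oid <- sprintf("scan%d_out", i)
      ofns <- paste0(labels, ".", pid, ".step", i, ".txt")
      files <- rbind(files, file_entry(oid, "output", "TXT",
                                       quantity = "collection"))
      outputs <- c(outputs, stats::setNames(ofns, rep(oid, length(ofns))))
      steps[[i]] <- tool_step(tool, tver, paste0(
        tool, " --bam {smp_*} --frag {*_fraglen}", ref_arg,
        " --out {", oid, "}"),
        loop_over = "smp_*",
        comment = "one run per alignment, control included")
    } else {  # partial: loop over the collection, hold the control
      oid <- sprintf("peak%d_out", i)
      ofns <- paste0(marks, ".", pid, ".step", i, ".bed")
      files <- rbind(files, file_entry(oid, "output", "BED",
                                       comment = "named via the prefix parameter",
                                       quantity = "collection"))
      outputs <- c(outputs, stats::setNames(ofns, rep(oid, length(ofns))))
      sw <- i == cfg$n_steps && cfg$with_switch
      steps[[i]] <- tool_step(tool, tver, paste0(
        tool, " -t {smp_sig} -c {smp_ctl} --gsize {gsize}",
        " --name {*_prefix} --ext {*_fraglen} --q 0.05",
        if (sw) " {wide}" else ""),
        loop_over = "smp_sig",
        switches = if (sw) list(wide = TRUE) else list(),
        comment = "control held constant across iterations")
    }
  }
  if (cfg$with_switch && !any(step_kind == "partial")) {
    # no partial step got the switch: attach it to the last step instead
    last <- steps[[cfg$n_steps]]
    last$command_template <- paste0(last$command_template, " {wide}")
    last$switches <- list(wide = list(true = "--wide", false = ""))
    steps[[cfg$n_steps]] <- last
  }
  if (cfg$with_switch) {
    params[["wide"]] <- sample(c("True", "False"), 1)
  }

  process <- process_document(
    process_id = pid, version = 1L,
    author_name = "Fixture Author", author_contact = "fixtures@example.org",
    date = "2015-06-08",
    description = paste("Synthetic analysis process generated for",
                        "validation testing; tools are fake and the",
                        "command lines are not executable."),
    files = files, steps = steps)

  metrics <- c(frip = sprintf("%.3f", stats::runif(1, 0.05, 0.6)),
               peaks_total = as.character(sample(1000:90000, 1)))
  amd <- amd_document(
    general = c(process_id = pid, process_version = "1",
                analysis_id = paste0("run_", sample_token, "_", pid, "v1"),
                date = "2015-06-09"),
    inputs = c(stats::setNames(sig_files, rep("smp_sig", length(sig_files))),
               stats::setNames(ctl_file, "smp_ctl")),
    references = stats::setNames(ref_files, ref_ids),
    outputs = outputs,
    parameters = params,
    metrics = metrics)

  peer <- NULL
  if (sample_token == "s1") {
    peer_triple <- build_triple_peer(cfg, "s2", ref_files, ref_ids)
    peer <- peer_triple
  }
  upstream <- amd_document(
    general = c(process_id = "UPS", process_version = "1",
                analysis_id = paste0("ups_", sample_token, "_UPSv1"),
                date = "2015-06-08"),
    outputs = stats::setNames(c(sig_files, ctl_file),
                              rep("ups_bam", cfg$n_inputs + 1L)))

  structure(list(process = process, amd = amd,
                 present_files = unname(outputs),
                 peer = peer, upstream = upstream, config = cfg),
            class = "fixture_triple")
}

# Peer AMD of a second, compatible sample: same process and references,
# sample-specific bindings renamed consistently.
build_triple_peer <- function(cfg, sample_token, ref_files, ref_ids) {
  t2 <- build_triple(cfg, sample_token)
  t2$amd
}

#' @export
print.fixture_triple <- function(x, ...) {
  cat(sprintf("<fixture_triple seed=%d profile=%s> %d inputs, %d steps\n",
              x$config$seed, x$config$loop_profile, x$config$n_inputs,
              x$config$n_steps))
  invisible(x)
}

#' Run the full validation battery over a fixture triple
#'
#' Structure check, schema validation of the serialized XML (skipped when
#' the structure check already failed, as serialization refuses invalid
#' documents), pair cross-validation, output presence, reference
#' consistency against the peer AMD, chain check against the upstream
#' AMD, and the naming lint — combined into one ordered report.
#'
#' @param t a `fixture_triple`.
#' @return a [validation_report()].
#' @export
validate_triple <- function(t) {
  reps <- list(check_structure(t$process))
  if (reps[[1]]$ok) {
    xml_issues <- validate_against_schema(write_process(t$process))
    reps <- c(reps, list(validation_report(xml_issues)))
  }
  reps <- c(reps, list(
    validate_pair(t$process, t$amd),
    check_outputs_present(t$amd, t$present_files),
    if (!is.null(t$peer)) check_reference_consistency(list(t$amd, t$peer))
    else validation_report(),
    if (!is.null(t$upstream)) check_chain(t$upstream, t$amd)
    else validation_report(),
    lint_naming(t$amd)))
  do.call(combine_reports, reps)
}

#' Corrupt a fixture so that exactly one validator code fires
#'
#' Returns a minimally edited copy of the triple guaranteed to trigger at
#' least one issue with the requested code under [validate_triple()],
#' without introducing any other *error* code. The edit is recorded in
#' attribute `"corruption"`.
#'
#' @param t a clean `fixture_triple` from [generate_triple()].
#' @param code one of the codes in [VALIDATION_CODES].
#' @param seed integer used where the edit picks among equivalent targets.
#' @return the corrupted `fixture_triple`.
#' @export
corrupt_triple <- function(t, code, seed = 1) {
  stopifnot(inherits(t, "fixture_triple"))
  if (!code %in% VALIDATION_CODES) {
    procamd_error(sprintf("unknown corruption code '%s'", code),
                  "procamd_fixture_error")
  }
  log <- NULL
  amd <- t$amd
  proc <- t$process
  rebuild_amd <- function(a) {
    amd_document(a$general, inputs = a$inputs, references = a$references,
                 outputs = a$outputs, parameters = a$parameters,
                 metrics = a$metrics)
  }
  switch(code,
    VERSION_MISMATCH = {
      amd$general[["process_version"]] <-
        as.character(amd_version(amd) + 1L)
      log <- "incremented AMD process_version"
    },
    PROCESS_ID_MISMATCH = {
      amd$general[["process_id"]] <- "ZZZ"
      log <- "changed AMD process_id to ZZZ"
    },
    MISSING_FILE_BINDING = {
      # drop an output binding: leaves present_files untouched (extras
      # are ignored) and no other rule refers to the removed key
      oid <- names(amd$outputs)[1]
      keep <- names(amd$outputs) != oid
      removed <- unname(amd$outputs[!keep])
      amd$outputs <- amd$outputs[keep]
      t$present_files <- setdiff(t$present_files, removed)
      log <- sprintf("removed all bindings of output '%s'", oid)
    },
    CARDINALITY_SINGLE_VIOLATED = {
      # same stem as the existing control so loop labels stay resolvable
      extra <- sub("\\.bam$", ".dup.bam", unname(amd$inputs[
        names(amd$inputs) == "smp_ctl"][1]))
      extra <- sub("^([^.]*)\\.", "\\1.", extra)
      amd$inputs <- c(amd$inputs, stats::setNames(extra, "smp_ctl"))
      log <- "added a second binding to the single-quantity control"
    },
    ORPHAN_AMD_KEY = {
      amd$inputs <- c(amd$inputs,
                      stats::setNames("stray.FXP.bam", "stray_key"))
      log <- "added an undeclared key to [Inputs]"
    },
    UNRESOLVED_PLACEHOLDER = {
      # a loop-free step whose wildcard placeholder matches neither a file
      # identifier nor any parameter key
      ghost <- tool_step("fxghost", "0.0.1", "fxghost --x {zzq_*}",
                         index = length(proc$steps) + 1L)
      proc$steps <- c(proc$steps, list(ghost))
      log <- "added a step with a wildcard placeholder matching nothing"
    },
    MISSING_PARAMETER = {
      key <- referenced_parameter_key(proc, amd)
      amd$parameters <- amd$parameters[names(amd$parameters) != key]
      log <- sprintf("deleted parameter key '%s'", key)
    },
    BAD_SWITCH_VALUE = {
      if (!"wide" %in% names(amd$parameters)) {
        procamd_error("fixture has no switch; BAD_SWITCH_VALUE inapplicable",
                      "procamd_fixture_error")
      }
      amd$parameters[["wide"]] <- "maybe"
      log <- "set the switch parameter to a non-True/False value"
    },
    MISSING_OUTPUT_FILE = {
      t$present_files <- t$present_files[-1]
      log <- "removed one produced file from the listing"
    },
    REFERENCE_INCONSISTENT = {
      if (is.null(t$peer) || length(t$peer$references) == 0) {
        procamd_error("no peer AMD with references; inapplicable",
                      "procamd_fixture_error")
      }
      peer <- t$peer
      peer$references[1] <- paste0("other_", unname(peer$references[1]))
      t$peer <- rebuild_amd(peer)
      log <- "pointed the peer AMD at a different reference file"
    },
    CHAIN_BROKEN = {
      if (is.null(t$upstream)) {
        procamd_error("no upstream AMD; inapplicable",
                      "procamd_fixture_error")
      }
      ups <- t$upstream
      ups$outputs[1] <- paste0("renamed_", unname(ups$outputs[1]))
      t$upstream <- rebuild_amd(ups)
      log <- "renamed an upstream output so a downstream input dangles"
    },
    NAMING_CONVENTION = {
      i <- 1L
      old <- unname(amd$outputs[i])
      new <- gsub(paste0(".", proc$header$process_id), "", old,
                  fixed = TRUE)
      amd$outputs[i] <- new
      t$present_files[t$present_files == old] <- new
      log <- sprintf("stripped the process id from output '%s'", old)
    },
    DUPLICATE_IDENTIFIER = {
      proc$files <- rbind(proc$files,
                          file_entry("smp_sig", "input", "BAM",
                                     quantity = "collection"))
      log <- "declared the signal identifier twice"
    },
    BAD_QUANTITY = {
      i <- which(proc$files$section == "input")[1]
      proc$files$quantity[i] <- "many"
      log <- sprintf("set quantity of '%s' to 'many'",
                     proc$files$identifier[i])
    },
    MISSING_SECTION = {
      proc$description <- NULL
      log <- "removed the description section"
    })
  t$amd <- rebuild_amd(amd)
  t$process <- proc
  attr(t, "corruption") <- list(code = code, edit = log)
  t
}

# A [Parameters] key that some command template actually resolves:
# preferably a plain placeholder key, else the per-label instance of a
# wildcard pattern used inside a loop.
referenced_parameter_key <- function(proc, amd) {
  wildcard <- NULL
  for (s in proc$steps) {
    for (pat in template_placeholders(s$command_template)) {
      cls <- classify_placeholder(pat, proc, s)
      if (cls$klass != "parameter") next
      if (!grepl("*", pat, fixed = TRUE)) return(pat)
      if (length(s$loop_over) > 0 && is.null(wildcard)) wildcard <- pat
    }
  }
  if (!is.null(wildcard)) {
    lab <- unname(amd$parameters[names(amd$parameters) ==
                                   "smp_sig_label"])[1]
    return(gsub("*", lab, wildcard, fixed = TRUE))
  }
  procamd_error("no template references a parameter; inapplicable",
                "procamd_fixture_error")
}
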