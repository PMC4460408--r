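# Shared fixture builders (constructed in code; nothing is read from disk).

# Smallest structurally valid process: one input, one output, one step.
minimal_doc <- function(process_id = "MIN", version = 1,
                        template = "count {in_file} > {out_file}") {
  process_document(
    process_id = process_id, version = version,
    author_name = "A. Author", author_contact = "a@example.org",
    date = "2015-01-01",
    description = "Minimal process for unit testing.",
    files = rbind(
      file_entry("in_file", "input", "TXT", quantity = "single"),
      file_entry("out_file", "output", "TXT", quantity = "single")),
    steps = list(tool_step("counter", "1.0", template)))
}

minimal_amd <- function(process_id = "MIN", version = "1") {
  amd_document(
    general = c(process_id = process_id, process_version = version,
                analysis_id = "run1", date = "2015-01-02"),
    inputs = c(in_file = "sample.txt"),
    outputs = c(out_file = paste0("sample.", process_id, ".count.txt")))
}

issue_codes <- function(report, severity = NULL) {
  df <- as.data.frame(report)
  if (!is.null(severity)) df <- df[df$severity %in% severity, , drop = FALSE]
  df$code
}

# random identifier-ish tokens for property tests
random_tokens <- function(n, min_len = 1, max_len = 10) {
  alphabet <- c(letters[1:6], "_", ".", "0", "1")
  vapply(seq_len(n), function(i) {
    paste(sample(alphabet, sample(min_len:max_len, 1), replace = TRUE),
          collapse = "")
  }, character(1))
}

random_glob <- function() {
  base <- random_tokens(1, 0, 6)
  n_star <- sample(0:min(2, nchar(base) + 1), 1)
  if (n_star == 0) return(base)
  pos <- sort(sample(0:nchar(base), n_star))
  out <- ""
  prev <- 0
  for (p in pos) {
    out <- paste0(out, substr(base, prev + 1, p), "*")
    prev <- p
  }
  paste0(out, substr(base, prev + 1, nchar(base)))
}
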