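# The ChIP-seq peak-calling worked example (process id "CHP").
#
# A realistic high-level ChIP-seq analysis: quality-control fingerprint
# over all alignments at once, per-file GC-bias computation, and MACS2
# peak calling looping over the histone-mark alignments while reusing the
# one immunoprecipitation input control. It exercises every placeholder
# and loop variant the format defines: the empty loop (step 1), the full
# loop over histone and control alignments with per-file wildcard
# parameters (step 2), the partial loop holding the single-quantity
# control constant (step 3), and the broad/narrow binary switch.

#' Build the ChIP-seq example process and AMD pair
#'
#' @param marks character vector of histone-mark names; one BAM binding
#'   per mark. The filename stem of each BAM is the mark name, which is
#'   what keys the per-file `*_median_fraglen` / `*_name_prefix`
#'   parameters.
#' @param fraglens integer vector of median fragment lengths, one per
#'   mark.
#' @param control_fraglen median fragment length of the input control.
#' @param broad call broad (`TRUE`) or narrow (`FALSE`) peaks; the
#'   `{broad}` switch emits `--broad` or nothing.
#' @param run_date date token embedded in the output filenames.
#' @return list with elements `process` (a [process_document()]), `amd`
#'   (an [amd_document()]) and `present_files` (the declared outputs, for
#'   [check_outputs_present()]).
#' @examples
#' ex <- chipseq_example()
#' validate_pair(ex$process, ex$amd)
#' invs <- expand_process(ex$process, ex$amd)
#' invs[[length(invs)]]  # one MACS2 call per histone mark
#' @export
chipseq_example <- function(marks = c("H3K4me3", "H3K27me3"),
                            fraglens = seq(180, by = 20,
                                           length.out = length(marks)),
                            control_fraglen = 175, broad = TRUE,
                            run_date = "20150101") {
  stopifnot(length(marks) >= 1, length(fraglens) == length(marks))
  pid <- "CHP"
  stamp <- function(label, what, ext) {
    paste0(label, ".", pid, ".", run_date, ".", what, ".", ext)
  }
  files <- rbind(
    file_entry("GALvX_histone", "input", "BAM",
               comment = "one alignment per histone mark",
               quantity = "collection"),
    file_entry("GALvX_input", "input", "BAM",
               comment = "exactly one input control is expected to match all histone files",
               quantity = "single"),
    file_entry("genome_fa", "reference", "FASTA",
               comment = "genome assembly sequence", quantity = "single"),
    file_entry("samplesID.PROCESS.DATE.fgpplot", "output", "PNG",
               comment = "one fingerprint plot irrespective of the number of inputs",
               quantity = "single"),
    file_entry("sampleID.PROCESS.DATE.gcbfreq", "output", "TXT",
               comment = "one GC-bias frequency table per alignment",
               quantity = "collection"),
    file_entry("sampleID.PROCESS.DATE.gcbplot", "output", "PNG",
               comment = "one GC-bias plot per alignment",
               quantity = "collection"),
    file_entry("macs2_peaks", "output", "narrowPeak/broadPeak",
               comment = "Standard MACS2 output for narrow/broad marks; named via the --name prefix",
               quantity = "collection"))
  steps <- list(
    tool_step("bamFingerprint", "1.5.9.1",
      paste("bamFingerprint -p {numproc} --bamfiles {GALvX_*}",
            "--plotFile {samplesID.PROCESS.DATE.fgpplot} --labels {labels}",
            "--fragmentLength {all_median_fraglen} --numberOfSamples 500000"),
      comment = "empty loop: all BAM files are processed at once"),
    tool_step("computeGCBias", "1.5.9.1",
      paste("computeGCBias --bamfile {GALvX_*}",
            "--fragmentLength {*_median_fraglen}",
            "--GCbiasFrequenciesFile {sampleID.PROCESS.DATE.gcbfreq}",
            "--biasPlot {sampleID.PROCESS.DATE.gcbplot}"),
      loop_over = c("GALvX_histone", "GALvX_input"),
      comment = "loops over histone and control alignments alike"),
    tool_step("macs2", "2.0.10",
      paste("macs2 callpeak -t {GALvX_histone} -c {GALvX_input} -f BAM",
            "--gsize {genomesize} --keep-dup all --name {*_name_prefix}",
            "--nomodel --extsize {*_median_fraglen} --qvalue 0.05 {broad}"),
      loop_over = "GALvX_histone",
      switches = list(broad = TRUE),
      comment = "loops over the histone alignments but not the input control"))
  process <- process_document(
    process_id = pid, version = 1L,
    author_name = "Example Author",
    author_contact = "author@example.org", date = "2015-06-08",
    description = paste(
      "High-level ChIP-seq analysis: fingerprint quality control over all",
      "alignments, per-file GC-bias assessment and MACS2 peak calling per",
      "histone mark against a shared input control."),
    files = files, steps = steps)

  histone_bams <- paste0(marks, ".GAL.bam")
  control_bam <- "Input.GAL.bam"
  all_labels <- c(marks, "Input")
  peak_ext <- if (broad) "broadPeak" else "narrowPeak"
  gcb_freq <- stamp(all_labels, "gcbfreq", "txt")
  gcb_plot <- stamp(all_labels, "gcbplot", "png")
  peaks <- paste0(marks, ".", pid, ".", run_date, "_peaks.", peak_ext)
  fgpplot <- stamp("sample7", "fgpplot", "png")

  params <- c(
    numproc = "4",
    labels = paste(all_labels, collapse = " "),
    all_median_fraglen = paste(c(fraglens, control_fraglen),
                               collapse = " "),
    genomesize = "2.7e9",
    stats::setNames(as.character(fraglens),
                    paste0(marks, "_median_fraglen")),
    Input_median_fraglen = as.character(control_fraglen),
    stats::setNames(paste0(marks, ".", pid, ".", run_date),
                    paste0(marks, "_name_prefix")),
    broad = if (broad) "True" else "False")

  amd <- amd_document(
    general = c(process_id = pid, process_version = "1",
                analysis_id = paste0("run1_", pid, "v1"),
                date = "2015-01-01"),
    inputs = c(stats::setNames(histone_bams,
                               rep("GALvX_histone", length(marks))),
               stats::setNames(control_bam, "GALvX_input")),
    references = c(genome_fa = "hg19.GRCh37.fa"),
    outputs = c(stats::setNames(fgpplot, "samplesID.PROCESS.DATE.fgpplot"),
                stats::setNames(gcb_freq,
                                rep("sampleID.PROCESS.DATE.gcbfreq",
                                    length(gcb_freq))),
                stats::setNames(gcb_plot,
                                rep("sampleID.PROCESS.DATE.gcbplot",
                                    length(gcb_plot))),
                stats::setNames(peaks, rep("macs2_peaks", length(peaks)))),
    parameters = params,
    metrics = c(frip = "0.31", peaks_total = "23411"))

  list(process = process, amd = amd,
       present_files = unname(amd$outputs))
}
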