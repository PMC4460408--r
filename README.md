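# procamd

Process and Analysis Metadata for computational pipelines.

## The problem

Published bioinformatics results routinely cannot be re-derived from the
paper alone: the exact tool versions, parameter values and file-to-file
relationships of an analysis live in shell histories, cluster job scripts
and people's heads. `procamd` implements a deliberately small, human- and
machine-readable two-part documentation scheme for computational
analyses:

* A **process document** (XML) describes one *type* of analysis
  abstractly and is versioned: a header (process id, version, author,
  contact, date), a free-text description, listings of input, reference
  and output files (each with an identifier, format and a declared
  cardinality `single` or `collection`), and an ordered series of tool
  steps whose command lines are *templates* containing `{placeholder}`
  tokens rather than concrete filenames.
* An **analysis metadata (AMD) file** (plain-text `key=value` rows,
  grouped into `[Inputs]`, `[References]`, `[Outputs]`, `[Parameters]`
  and `[Metrics]` blocks) records one *concrete run* of that process:
  the actual filenames bound to each identifier, the non-default
  parameter values, and run statistics. Many AMD files refer to one
  process document (1:N).

Because both halves are structured, the pair can be checked and
*materialized*: the package validates an AMD against its process
(cross-checking file bindings, cardinalities, parameters, switches,
reference consistency across compatible runs, and chaining between
consecutive processes) and expands the abstract command templates back
into the exact, brace-free command lines that were — or should be — run.

Key semantics implemented here:

* Placeholders use a minimal glob grammar: `*` is the only wildcard
  (`{GALvX_*}` matches every file identifier with that prefix).
  Placeholders that match a file identifier are file references;
  declared switches come next; anything else is a `[Parameters]` key.
* Each step carries a **loop tag**. An empty loop means a single
  invocation over all bound files at once; a non-empty loop yields one
  invocation per matched file binding, with non-looped placeholders held
  constant (the classic "one peak-calling run per histone mark, always
  against the same input control" pattern). Wildcard parameter keys such
  as `{*_median_fraglen}` are resolved per loop element.
* Binary switches bind `True`/`False` in the AMD and emit fixed flag
  text (e.g. `--broad`) or nothing.
* A process version must be incremented when tool versions, the step
  series, fixed default arguments or the file listings change — but not
  for comment or description edits, and not when a reference *file's
  content* (an AMD-side value) changes. `compare_processes()` decides
  this mechanically.

## Worked example

`chipseq_example()` builds a complete ChIP-seq peak-calling process
("CHP") and a matching AMD for two histone marks plus one
immunoprecipitation input control. It exercises every loop variant and
the broad/narrow switch.

```r
library(procamd)
ex <- chipseq_example()
validate_pair(ex$process, ex$amd)
#> OK: no issues
cat(render_script(expand_process(ex$process, ex$amd), ex$process, ex$amd))
```

Actual output:

```
# process CHP v1
# analysis run1_CHPv1 (2015-01-01)
bamFingerprint -p 4 --bamfiles H3K4me3.GAL.bam H3K27me3.GAL.bam Input.GAL.bam --plotFile sample7.CHP.20150101.fgpplot.png --labels H3K4me3 H3K27me3 Input --fragmentLength 180 200 175 --numberOfSamples 500000
computeGCBias --bamfile H3K4me3.GAL.bam --fragmentLength 180 --GCbiasFrequenciesFile H3K4me3.CHP.20150101.gcbfreq.txt --biasPlot H3K4me3.CHP.20150101.gcbplot.png
computeGCBias --bamfile H3K27me3.GAL.bam --fragmentLength 200 --GCbiasFrequenciesFile H3K27me3.CHP.20150101.gcbfreq.txt --biasPlot H3K27me3.CHP.20150101.gcbplot.png
computeGCBias --bamfile Input.GAL.bam --fragmentLength 175 --GCbiasFrequenciesFile Input.CHP.20150101.gcbfreq.txt --biasPlot Input.CHP.20150101.gcbplot.png
macs2 callpeak -t H3K4me3.GAL.bam -c Input.GAL.bam -f BAM --gsize 2.7e9 --keep-dup all --name H3K4me3.CHP.20150101 --nomodel --extsize 180 --qvalue 0.05 --broad
macs2 callpeak -t H3K27me3.GAL.bam -c Input.GAL.bam -f BAM --gsize 2.7e9 --keep-dup all --name H3K27me3.CHP.20150101 --nomodel --extsize 200 --qvalue 0.05 --broad
```

Note the three loop behaviours: `bamFingerprint` runs once over all
three alignments (empty loop, single-quantity plot output);
`computeGCBias` runs once per alignment with its own fragment length
(full loop, collection outputs); `macs2` runs once per histone mark
while `-c Input.GAL.bam` stays bit-identical (partial loop). The fixed
literals `--numberOfSamples 500000` and `--qvalue 0.05` pass through
untouched, and `--broad` appears because the AMD binds `broad=True`.

The version-increment comparator:

```r
new <- ex$process
new$steps[[3]]$tool_version <- "2.1.0"
compare_processes(ex$process, new)
#> version increment REQUIRED: TOOL_VERSION_CHANGED
```

The first lines of the AMD, as serialized by `serialize_amd(ex$amd)`:

```
process_id=CHP
process_version=1
analysis_id=run1_CHPv1
date=2015-01-01

[Inputs]
GALvX_histone=H3K4me3.GAL.bam
GALvX_histone=H3K27me3.GAL.bam
GALvX_input=Input.GAL.bam
```

## Command-line interface

The installed script `exec/procamd` wraps the same functions:

```sh
procamd=$(Rscript -e 'cat(file.path(find.package("procamd"), "exec", "procamd"))')
Rscript "$procamd" gen-fixture demo --seed 9 --n-inputs 3
Rscript "$procamd" validate demo/process.xml demo/run1.amd --files demo/files.txt
Rscript "$procamd" materialize demo/process.xml demo/run1.amd
Rscript "$procamd" diff old.xml new.xml        # exit 3 if an increment is overdue
Rscript "$procamd" report demo                 # static HTML index of the directory
```

Exit codes: 0 ok, 1 validation failure, 2 I/O or parse failure, 3
version-increment violation.

## Scope

The normative XML schema ships in `inst/extdata/process.xsd` (validated
via libxml2 through `xml2::xml_validate`, with an equivalent internal
checker producing coded, located issues). Out of scope: executing the
materialized commands, cryptographic integrity of documents, and
branching/merging of process versions (versions only increment). See the
vignette `vignettes/process-amd-metadata.Rmd` for the model, the exact
validation rule set and the design decisions.
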