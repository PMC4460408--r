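---
title: "Documenting analyses with process documents and AMD files"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Documenting analyses with process documents and AMD files}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(procamd)
```

## The model

`procamd` implements a two-part documentation scheme for computational
analyses. The **process document** is the abstract, versioned half: it
says what an analysis of a given type looks like — which kinds of files
go in and come out, and which tools run in which order with which
command-line shape. The **AMD** (analysis metadata) file is the concrete
half: one file per run, recording the actual filenames, parameter values
and run statistics. The separation makes the abstract part reusable and
diffable while keeping per-run records tiny, and it makes both halves
checkable against each other.

The model makes a few deliberate assumptions:

* An analysis is a *linear* series of tool invocations. There is no
  branching or conditional execution inside a process; a genuinely
  different tool series is a different process (or a new version).
* File relationships are expressed through *identifiers*, not paths.
  An identifier is declared once in the process (with a section —
  input, reference or output — a format tag and a quantity) and bound
  to one or more filenames in the AMD.
* Quantity is binary: `single` (exactly one binding) or `collection`
  (one or more). This is enough to express the common "n signal files,
  one shared control" situation and keeps validation decidable.
* Reference files (genome assemblies, annotation) are *shared state*:
  all AMD files of the same process id and version must bind identical
  reference filenames, which is what `check_reference_consistency()`
  enforces.

## Placeholder grammar and the label rule

Command templates contain `{name}` placeholders. The grammar is
deliberately minimal: `*` is the only wildcard, there are no character
classes and no `?`, and braces cannot nest. `tokenize_template()`
rejects malformed templates with a character offset. Classification
precedence is fixed: a pattern that matches at least one declared file
identifier is a **file** placeholder; otherwise, if the step declares a
switch of that name, it is a **switch**; otherwise it is a
**parameter** looked up in `[Parameters]`.

Within a looped step, each loop element gets a **label** that keys
per-element wildcard parameters such as `{*_median_fraglen}`. The label
rule is: if the placeholder pattern captured text via `*` for a
single-binding identifier, that captured text is the label; otherwise
the label defaults to the filename stem (the basename up to the first
`.`). Both defaults can be overridden with reserved parameter keys named
`<identifier>_label` (repeated positionally for collections). The stem
default is a pragmatic choice — in practice sample files are named after
the sample — and the override exists precisely because that convention
is not universal.

## Loop semantics

Each step carries a loop tag, a list of placeholder patterns:

* **empty loop** — one invocation; file placeholders expand to all
  bound filenames joined by spaces.
* **full/partial loop** — one invocation per matched binding, in AMD
  declaration order. Placeholders *not* in the loop are held constant
  across iterations, which yields the peak-calling pattern: one `macs2`
  call per histone mark, each against the same single control.
* Collection outputs consumed inside a loop are bound positionally:
  the k-th iteration takes the k-th binding of the output identifier,
  and materialization refuses (rather than recycles) when the counts
  disagree.

This gives the loop-cardinality law asserted in the acceptance tests:
1 invocation for empty loops, n (plus any looped singles) otherwise.

## Validation

`validate_pair()` applies an ordered rule set and reports coded issues
rather than throwing: identity (`PROCESS_ID_MISMATCH`,
`VERSION_MISMATCH`), binding completeness (`MISSING_FILE_BINDING`),
cardinality (`CARDINALITY_SINGLE_VIOLATED`), undeclared keys
(`ORPHAN_AMD_KEY`, a warning), placeholder resolution
(`UNRESOLVED_PLACEHOLDER`, `MISSING_PARAMETER`, `BAD_SWITCH_VALUE`).
Separate checks cover produced files (`MISSING_OUTPUT_FILE`), cross-run
reference agreement (`REFERENCE_INCONSISTENT`), chaining of consecutive
processes (`CHAIN_BROKEN`, a warning by default), filename conventions
(`NAMING_CONVENTION`, a warning) and document structure
(`DUPLICATE_IDENTIFIER`, `BAD_QUANTITY`, `MISSING_SECTION`). The code
set is closed: the fixture generator's `corrupt_triple()` can produce a
minimal, targeted corruption for each of the fifteen codes, which is how
the detection matrix in the test suite is built. XML-level violations
get their own codes (`MALFORMED_XML`, `MISSING_ATTRIBUTE`, `BAD_TYPE`,
`UNKNOWN_ELEMENT`) from an internal checker that agrees with libxml2
validation against the shipped `process.xsd`.

## Version increments

`compare_processes()` demands an increment exactly when one of four
things changed: a tool version (`TOOL_VERSION_CHANGED`), the step
series including mere reordering (`STEP_SERIES_CHANGED`), a fixed
literal argument (`DEFAULTS_CHANGED`, detected by comparing template
tokens with placeholders masked, so renaming a placeholder is not a
default change), or the set of (identifier, section, quantity) triples
(`FILE_LISTINGS_CHANGED`). Comment and description edits are reported
as ignorable. Two open questions were settled as follows: removal and
addition of a listing entry are treated identically (both are
`FILE_LISTINGS_CHANGED`), and author/contact changes are ignorable —
they alter provenance of the document, not the analysis it describes.
A change in a reference file's *content* is an AMD-side fact and never
triggers an increment.

## The synthetic fixture generator

`generate_triple()` builds seeded, internally consistent
(process, AMD, produced-file listing) triples plus two companions: a
*peer* AMD (a second sample with identical references) and an
*upstream* AMD whose outputs cover the triple's inputs. Tool names come
from a fake vocabulary (`fxplot`, `fxscan`, ...) — nothing is meant to
execute. The generator's knobs (1–50 inputs/references/steps, four loop
profiles, optional switch) were chosen as *study conditions* covering
the structural space the format defines, not tuned to any test outcome.

What passing the suite does **not** show: that real pipelines are
faithfully describable (the generator emits well-formed metadata by
construction, not field-collected files), that the validator catches
*combinations* of corruptions (the matrix applies one edit at a time),
or that materialized commands are executable (no tool is ever run).
Problem sizes in the tests — up to 20 collection inputs for the
cardinality law, 100 clean fixtures, 200 round trips, 1200 glob cases —
are the package's own choices, sized to run in seconds while giving the
property checks reasonable coverage.

## Numerical and representational choices

All metadata values are strings; the package never coerces parameter
values to numbers, so `2.7e9` and `0.05` survive round trips verbatim.
AMD serialization is canonical (fixed block order, general keys first,
empty blocks omitted, trailing newline) and parsing normalizes CRLF and
trailing whitespace, giving byte-stable re-serialization. XML writing
is deterministic and omits empty optional elements so that
`read_process(write_process(d))` is the identity on valid documents.
Process versions are single positive integers: the scheme only ever
increments, never branches.

## Limitations

* Validation is static. An AMD can be internally consistent and still
  describe a run that never happened; `check_outputs_present()` only
  compares against a caller-supplied file listing.
* The `*`-only glob grammar cannot express alternations; identifiers
  must be named so that prefix/suffix matching suffices.
* Chain checking matches filenames exactly; moved or renamed files
  break the chain even when contents are identical.
* The HTML report is a flat, static index — it does not follow chains
  across directories.
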