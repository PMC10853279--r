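---
title: "How bidsmapr proposes, revises and assembles a BIDS mapping"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{How bidsmapr proposes, revises and assembles a BIDS mapping}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

bidsmapr turns a directory of dcm2niix-style outputs — NIfTI images paired
with JSON sidecars — into a Brain Imaging Data Structure (BIDS) dataset in
two phases. The **Propose** phase runs a fully automatic inference pipeline
and encodes its best guess in a single hierarchical descriptor (dataset
block → subjects → series → objects). The **Revise** phase applies a
user-supplied edit script to that descriptor, re-validates, and only then
does assembly write files. This vignette explains each stage's model and
assumptions, the parameters that matter, the numerical choices, and what
the synthetic fixtures do and do not demonstrate.

## The inference pipeline

### Subjects and sessions

Every image must receive a subject label. The precedence is:

1. an explicit `sub-` marker (case-insensitive; `sub_` and `sub ` dialects
   are also accepted in the patient fields) found in the file path,
   PatientID or PatientName — the following alphanumeric run is the label.
   When path and metadata disagree, the path wins: researchers who encode
   `sub-` into their directory layout did so deliberately, whereas patient
   fields are filled by the scanner operator.
2. otherwise, images are grouped by their (PatientID, PatientName,
   PatientBirthDate) triple and the groups numbered `01`, `02`, …
   chronologically by each triple's earliest AcquisitionDate+Time. Labels
   below 10 are zero-padded. Triples with no timestamp sort last, ordered
   by the triple text itself, so anonymized-but-dated and undated data mix
   deterministically.
3. fully anonymized images (all three patient fields absent) take their
   containing folder name, sanitized to `[A-Za-z0-9]`; if nothing
   survives sanitization, positional numbering continues past the used
   range.

Sessions cluster by **calendar AcquisitionDate only**. AcquisitionTime
orders images within a day and breaks ties, but never splits one date into
two sessions: same-day rescans hours apart are almost always one visit
clinically, and no principled intra-day threshold exists. A single date
cluster produces *no* session entity (per the BIDS recommendation);
two or more clusters are labelled `01`, `02`, … chronologically, with
undated images forming one trailing cluster. An explicit `ses-` marker
always wins for the image carrying it.

All ordering used anywhere in the pipeline is the tuple
(AcquisitionDate, AcquisitionTime, SeriesNumber, path), which makes every
label assignment invariant to input file order.

### Series grouping

Images are partitioned by the four-field key (SeriesDescription,
ImageType, RepetitionTime, EchoTime). Two deliberate softenings:

* a trailing `_RR` on the description — the marker scanners append after
  retroactive reconstruction — is stripped before comparison, since the
  reconstructed image is functionally identical to its siblings;
* TR and TE compare within **±0.0005 s (0.5 ms), inclusive**, absorbing
  the binary-to-ASCII float precision differences between converter
  builds (0.03 and 0.030001 are the same echo time).

Because ±tolerance similarity is not transitive, membership is
**anchor-based**: an image joins the first existing series whose *founding
member* matches; otherwise it founds a new series. Scanning happens in the
deterministic order above, so series ids (consecutive integers from 1)
are stable across runs and machines. The inclusive boundary is
implemented as `|Δ| ≤ 0.0005 s + 1e-12`; the epsilon is orders of
magnitude below any real TE difference and exists only so that a
difference of exactly 0.5 ms groups regardless of how the two doubles
were produced. ImageType comparison is order-sensitive exact equality of
the token sequence, and an absent TR/TE matches only an absent one —
structurally different acquisitions should never merge.

### Classification

Three heuristics run in strict order; the first that yields a full
datatype/suffix pair wins, and everything is validated against an embedded
snapshot of the BIDS schema (datatype → admissible suffixes), pinned to
BIDS `r "1.8.0"`:

1. **explicit** — a `<datatype>_<suffix>` identifier in the description
   (`anat_T1w`), or an unambiguous lone suffix token (`bold`). A lone
   datatype token (`anat_highres`) is remembered as partial information.
2. **keyphrase** — case-insensitive substring match against the lexicon
   of MRI protocol-name conventions (`tfl3d` and `mprage` denote T1w,
   `spinecho`/`topup` denote distortion-correction epi field maps, …).
   Highest priority wins; ties go to the longest pattern. The lexicon
   ships as an editable TSV (`inst/extdata/lexicon.tsv`, loadable with
   `read_lexicon()`); it is a maintained table, not a closed list.
3. **metadata** — `DIFFUSION` in ImageType ⇒ `dwi/dwi`; a known-anatomical
   series with no suffix cue and EchoTime **strictly greater than
   0.100 s** ⇒ `T2w` ("exceeding 100 ms" read literally). A
   phasediff-family lexicon hit is refined by ImageType `P`/`M` tokens and
   EchoNumber into phasediff vs magnitude1/magnitude2.

If no heuristic resolves a full pair the series is set to **exclude** and
left to the user — a deliberately conservative sink state that surfaces
uncertainty instead of hiding a misidentification. An anatomical whose
suffix cannot be resolved and whose EchoTime is ≤ 100 ms also lands there.
One convenience rule fills a gap the heuristics leave: a functional BOLD
series whose description mentions "rest" but carries no `_task-` token
receives `task-rest`, because BIDS requires the task entity and resting
scans almost never encode it explicitly.

### Entities and run numbering

Entity values are recovered by `_<key>-<value>` searches of the
normalized description for every key in the canonical entity table
(`sub, ses, task, acq, ce, rec, dir, run, mod, echo, flip, inv, mt,
part` — the rendering order). Metadata supplies what descriptions lack:
EchoNumber → `echo`; for spin-echo field maps, PhaseEncodingDirection →
`dir` via the RAS-axes table `i→LR, i-→RL, j→PA, j-→AP, k→IS, k-→SI`.
That table is orientation-dependent by construction — it is correct for
RAS-oriented exports and is exactly the assumption behind the
direction-mismatch warning.

Run labels are added **only on collision**: within one subject/session,
when two or more included images share datatype, suffix and all non-run
entities, they get `run-01`, `run-02`, … chronologically (zero-padded to
two digits, matching the subject convention). A lone image never gets a
gratuitous run entity. Once assigned, runs are **sticky**: excluding
run-01 leaves run-02 untouched, since silently renaming files that a
user may already have referenced is worse than a gap in numbering.
`renumber_runs()` reassigns from scratch on explicit request.

### Entity layering and the Revise phase

The descriptor stores entities in three layers: per-object automatic
entities, series-level edits (inherited by every member), and
object-level overrides (applied last, win). Every edit triggers a full
re-derivation — merge layers, re-assign missing runs, re-link events,
re-validate — so the descriptor is always internally consistent and an
empty edit script is the identity. Edits arrive as an `edit_script()`
(or its JSON form) and are applied in the documented page order: dataset
description, subject remapping, series mapping, events column map,
object-level review, metadata injection.

### Events

Timing files (`.csv .tsv .txt .out .xlsx`) need no specific internal
layout. For text formats the delimiter is sniffed in the order tab,
comma, semicolon, whitespace — the first that yields a consistent column
count wins; tab first because tab-delimited exports (including E-Prime's)
are the most common and the least ambiguous. Spreadsheets use their first
worksheet. All cells are kept as text until the column map converts them,
so `1500 ms ÷ 1000 = 1.5 s` exactly on any input with up to three decimal
places, and TSV serialization uses `%.10g` so no binary-rounding artifact
ever prints.

One column map (`events_column_map()`) applies to *every* timing file of
a session — the supported BIDS columns are `onset`, `duration`,
`trial_type`, `response_time`, `value`, `stim_file`, with a
seconds/milliseconds unit declared per time-based column. Linkage to BOLD
runs seeks convergence of the `sub`, `ses` (if applicable), `task` and
`run` hints extracted from the file path or single-valued synonym columns
("Subject", "Sub", "Subj", …), assumes a one-to-one mapping (a second
file resolving to a claimed BOLD is a validation error), excludes
rest-task images from linkage, and hands out per-entity placeholder
labels `sub-XX1`, `sub-XX2`, … (independent counters per entity) where it
cannot decide. Missing cells serialize as `n/a` per the BIDS TSV
convention.

### Validation

Issues are two-tiered. **Errors** block assembly (unless `force = TRUE`,
which deliberately permits writing a non-compliant tree for later
repair): a required entity missing (task on functional images; dir on
spin-echo field maps), entity values with non-alphanumeric characters
(`acq-0.8 mm`), two included objects rendering to one path, events
one-to-one violations, and guided-metadata violations — type rules (ASL
`BackgroundSuppression` must be boolean) and dependency rules
(`BolusCutOffTechnique` becomes required once `BolusCutOffFlag` is
*provided*, presence-triggered, not value-triggered). **Warnings** never
block: a user `dir` entity contradicting PhaseEncodingDirection (with the
implied label in the message), 4D functional series under the volume
threshold, and timing files whose matching BOLD was excluded.

The low-volume threshold defaults to **20 volumes** (`min_volumes`
argument): a functional run shorter than that (≈40 s at TR 2) carries too
few time points for analysis and is almost always an aborted scan. The
value is exposed because it is a judgment call, and affected series are
auto-excluded with a warning rather than silently — un-excluding keeps
the data and retains the warning. The rule engine is internal and a
documented subset of community validation, not a parity claim; the
assembled tree can always be handed to the external validator.

### Assembly, anonymization, templates

`write_bids()` copies (or symlinks) every included image to its rendered
path and writes beside it the source sidecar minus the identity strip
list — PatientID, PatientName, PatientBirthDate, AcquisitionDateTime,
plus anything in `strip_fields` — with injected fields overriding source
fields of the same name. Scan date and time-of-day survive; the combined
timestamp does not. `participants.tsv` holds one row per non-excluded
subject, with age taken from a PatientAge-style sidecar field when
present and never computed from the (stripped) birthdate. BIDSVersion is
pre-filled from the schema snapshot. Writing is deterministic: two runs
into fresh directories are byte-identical.

A session template captures, per series signature (normalized
description, ImageType, TR, TE), the stored assignment with entities
minus `sub`/`ses`/`run` — those are session-specific and always
re-inferred. Signature matching on replay reuses the grouping rule
*including* the ±0.5 ms tolerance, because cross-session TR/TE jitter is
precisely what the tolerance exists for. Two exported series whose
signatures fall within tolerance of each other are ambiguous and refuse
to export. Templates carry a version field; a major-version mismatch
refuses to load. Only series-level decisions replay; object-level
(single-image) edits are considered session-specific.

## The synthetic generator

`generate_session()` writes a dcm2niix-style tree as a pure function of
(spec, seed): one sidecar plus a minimal NIfTI (2×2×2×T int16 zeros —
only headers are ever read) per series instance, subjects a week apart,
sessions a month apart, series five minutes apart, SeriesNumber
increasing, optional TE jitter emulating converter float noise, optional
full anonymization, and timing tables (10 trials by default, onsets from
a seeded uniform inter-trial interval of 1.5–2.5 s) in any accepted
format including a minimal self-written `.xlsx`. The default menu of
eight series covers every classification heuristic and the exclude path.

What it does *not* emulate: vendor-specific metadata quirks beyond the
fields the heuristics consume, realistic image content, corrupted or
partially transferred files, multi-echo/multi-coil naming schemes, and
non-MRI modalities. A green test suite therefore demonstrates the
documented behavior of the inference rules, not robustness to every
scanner dialect; the lexicon and the edit script are the designed escape
hatches for real-world variation.

## Problem sizes and numerical choices

The test suite runs at desk scale by design: grouping oracles compare
against a brute-force partitioner on all permutations of 5–6 image
fixtures; the filename grammar round-trips 1000 random schema-valid
assignments; the tolerance boundary is probed on a 0.00001 s grid; the
propagation scenario uses 12 subjects with a 10-subject majority series.
Tie-breaks are fixed everywhere (chronology, then SeriesNumber, then
path), degenerate inputs have defined behavior (empty directories yield
empty bundles; header-only timing files parse; `n_subjects = 0` generates
an empty tree), and every randomized test runs under a fixed seed.

## Known limitations

MEG/EEG/PET/NIRS are out of scope; the keyphrase lexicon is a curated
default rather than an exhaustive protocol dictionary; the
direction-label table assumes RAS orientation; intra-day session splits
are not attempted; and the internal validator intentionally covers the
documented rule set only.
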