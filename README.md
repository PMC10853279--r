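# bidsmapr

Headless "Propose-and-Revise" curation of neuroimaging data into the Brain
Imaging Data Structure (BIDS).

Labs that convert scanner output with dcm2niix end up with piles of NIfTI
images and JSON sidecars whose organization lives only in protocol names and
DICOM-derived metadata. Getting from there to a BIDS dataset —
`sub-01/ses-01/anat/sub-01_ses-01_T1w.nii.gz`, `events.tsv` files next to
their BOLD runs, a valid `dataset_description.json` — is tedious and
error-prone. bidsmapr automates the best-guess mapping (**Propose**), lets
you correct it with a reviewable edit script (**Revise**), validates it, and
materializes the final tree. It is aimed at researchers and data curators
who want this workflow scriptable and reproducible rather than interactive.

## What the engine does

* **Subject/session identification** — an explicit `sub-`/`ses-` marker in
  the path or patient fields wins; otherwise distinct (PatientID,
  PatientName, PatientBirthDate) triples are numbered `01`, `02`, …
  chronologically by acquisition timestamp; fully anonymized images take
  their folder name. Sessions come from AcquisitionDate clusters, and no
  `ses-` entity is emitted for single-visit subjects.
* **Series grouping** — images sharing (SeriesDescription, ImageType,
  RepetitionTime, EchoTime) form one series. TR/TE compare within
  ±0.0005 s (0.5 ms, inclusive) of the series anchor to absorb
  float-to-text precision noise (0.03 vs 0.030001 group together), and a
  trailing `_RR` (retroactive reconstruction) on the description is
  normalized away. Series-level decisions propagate to every member.
* **Datatype/suffix classification** — three heuristics in strict order:
  an explicit `<datatype>_<suffix>` identifier in the description (e.g.
  `anat_T1w`); a keyphrase lexicon of protocol-name conventions (`tfl3d`,
  `mprage` → `anat/T1w`; editable TSV); metadata rules (`DIFFUSION` in
  ImageType → `dwi/dwi`; an anatomical with EchoTime > 100 ms → `T2w`).
  When everything fails the series is set to *exclude* rather than guessed.
* **Entities and runs** — `_<key>-<value>` tokens in the description,
  `echo` from EchoNumber, `dir` for spin-echo field maps from
  PhaseEncodingDirection, and run labels `01`, `02`, … assigned
  chronologically whenever two images would otherwise collide.
* **Events** — free-form timing files (`.csv .tsv .txt .out .xlsx`) are
  parsed, one global column map (with seconds/milliseconds units) converts
  them to `events.tsv`, and each file is linked to its BOLD run by
  convergence of the `sub`/`ses`/`task`/`run` hints, with `sub-XX1`-style
  placeholders where linkage fails.
* **Validation and assembly** — an error/warning rule engine (missing
  required entities, non-alphanumeric labels, duplicate paths, direction
  mismatches, low-volume 4D series, orphaned events files, guided-metadata
  type/dependency checks) gates `write_bids()`, which copies images,
  writes anonymized sidecars, `participants.tsv` and
  `dataset_description.json`.
* **Templates** — a finalized session exports `ezBIDS_template.json`;
  replaying it onto a similar later session re-applies every series-level
  decision by signature matching under the same grouping tolerance.

## Worked example

Everything below runs without any real scans: the packaged generator
synthesizes a dcm2niix-style session tree (sidecars + minimal NIfTI
headers + timing files).

```r
library(bidsmapr)

root <- generate_session(session_spec(n_subjects = 2, seed = 7), "demo_raw")
core <- propose(root)
core
#> <bids_core> /…/demo_raw
#>   subjects: 2 | series: 8 | objects: 18 (16 included)
#>   issues: 0 error(s), 0 warning(s)
```

Two subjects were found (distinct patient triples, numbered
chronologically), the 18 images collapse into 8 series, and 16 objects are
included — the two localizers matched no heuristic and were proposed as
*exclude*. The object-level view shows the inferred mapping:

```r
dplyr::select(tidy(core), subject, series_id, datatype, suffix, entities, bids_path)
#> # A tibble: 18 × 6
#>   subject series_id datatype suffix entities           bids_path
#> 1 01              1 anat     T1w    ""                 sub-01/anat/sub-01_T1w.nii.gz
#> 2 01              2 anat     T2w    ""                 sub-01/anat/sub-01_T2w.nii.gz
#> 3 01              3 func     bold   "task-bart_run-01" sub-01/func/sub-01_task-bart_run-01_bold.nii.gz
#> 4 01              3 func     bold   "task-bart_run-02" sub-01/func/sub-01_task-bart_run-02_bold.nii.gz
#> 5 01              4 func     bold   "task-rest"        sub-01/func/sub-01_task-rest_bold.nii.gz
#> 6 01              5 dwi      dwi    ""                 sub-01/dwi/sub-01_dwi.nii.gz
#> 7 01              6 fmap     epi    "dir-AP"           sub-01/fmap/sub-01_dir-AP_epi.nii.gz
#> # …
```

The T1w came from the `mprage` keyphrase, the T2w from the 120 ms EchoTime
rule, the two task runs were numbered automatically, and the field maps
derived their `dir` entities from PhaseEncodingDirection. A series-level
revision propagates to every member — here both subjects' T1w images:

```r
core <- apply_edits(core, edit_script(series = list(
  list(series_id = 1, entities = list(acq = "mprage"))
)))
write_bids(core, "demo_bids")
# -> sub-01/anat/sub-01_acq-mprage_T1w.nii.gz, sub-02/anat/…, events.tsv
#    next to each task run, participants.tsv, dataset_description.json
```

`autoplot(core)` draws the subject-by-series layout;
`validate_dataset(core)` returns the issue table; `export_template(core)`
captures the session's decisions for reuse. A thin CLI wrapping the same
functions lives in `exec/bidsmapr`
(`bidsmapr propose <root> --out core.json`, `revise`, `apply`, `template
export`, `fixture`).

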