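## Synthetic session generator: emits dcm2niix-style trees (JSON sidecars
## + minimal NIfTI images + timing files) as a pure function of
## (spec, seed), so every pipeline stage is testable without real scans.

#' Default series menu for synthetic sessions
#'
#' One row per scanning sequence in the emulated protocol. The default
#' menu exercises every classification heuristic: an explicit
#' datatype/suffix identifier (task BOLD), keyphrase hits (MPRAGE T1w,
#' rest fMRI, spin-echo field maps), metadata rules (DIFFUSION ImageType;
#' an anatomical with EchoTime above 100 ms), and a localizer that no
#' heuristic resolves (the exclude path).
#'
#' @return tibble with columns `description`, `image_type` (list),
#'   `tr`, `te` (seconds), `volume_count`, `n_runs`, `ped`, `events`.
#' @export
default_series_menu <- function() {
  tibble::tibble(
    description = c(
      "T1w_MPRAGE", "anat_highres", "func_task-bart_bold", "rest_fmri",
      "ep2d_advanced", "SpinEchoFieldMap_AP", "SpinEchoFieldMap_PA",
      "localizer"
    ),
    image_type = list(
      c("ORIGINAL", "PRIMARY", "M", "NORM"),
      c("ORIGINAL", "PRIMARY", "M"),
      c("ORIGINAL", "PRIMARY", "M", "MB"),
      c("ORIGINAL", "PRIMARY", "M", "MB"),
      c("ORIGINAL", "PRIMARY", "DIFFUSION", "NONE"),
      c("ORIGINAL", "PRIMARY", "M"),
      c("ORIGINAL", "PRIMARY", "M"),
      c("ORIGINAL", "PRIMARY", "M")
    ),
    tr = c(2.3, 9.0, 2.0, 2.0, 3.2, 8.0, 8.0, 0.009),
    te = c(0.00296, 0.12, 0.03, 0.03, 0.089, 0.066, 0.066, 0.004),
    volume_count = c(1L, 1L, 150L, 150L, 60L, 3L, 3L, 1L),
    n_runs = c(1L, 1L, 2L, 1L, 1L, 1L, 1L, 1L),
    ped = c(NA, NA, "j-", "j-", "j-", "j-", "j", NA),
    events = c(FALSE, FALSE, TRUE, FALSE, FALSE, FALSE, FALSE, FALSE)
  )
}

#' Specify a synthetic session set
#'
#' Declarative description of the tree [generate_session()] writes:
#' subject count, sessions per subject, the series menu, whether patient
#' identity fields are present, an optional EchoTime jitter (emulating
#' converter float-precision noise within the grouping tolerance), and
#' the seed making generation a pure function of the spec.
#'
#' @param n_subjects number of subjects (>= 0).
#' @param sessions_per_subject sessions per subject; dates advance by a
#'   month between sessions so date clustering recovers them.
#' @param series_menu series table (see [default_series_menu()]).
#' @param anonymize drop PatientID/PatientName/PatientBirthDate from every
#'   sidecar (folder-name subject inference then applies).
#' @param te_jitter half-width (seconds) of uniform EchoTime jitter added
#'   per image.
#' @param timing_units units for generated timing files (`"seconds"` or
#'   `"milliseconds"`).
#' @param timing_format format for generated timing files (`"csv"`,
#'   `"tsv"`, `"txt"`, `"out"`, `"xlsx"`).
#' @param seed integer seed.
#' @return a list of class `session_spec`.
#' @export
session_spec <- function(n_subjects = 2L, sessions_per_subject = 1L,
                         series_menu = default_series_menu(),
                         anonymize = FALSE, te_jitter = 0,
                         timing_units = "seconds", timing_format = "csv",
                         seed = 1L) {
  stopifnot(n_subjects >= 0, sessions_per_subject >= 1, te_jitter >= 0)
  structure(
    list(n_subjects = as.integer(n_subjects),
         sessions_per_subject = as.integer(sessions_per_subject),
         series_menu = series_menu, anonymize = anonymize,
         te_jitter = te_jitter, timing_units = timing_units,
         timing_format = timing_format, seed = as.integer(seed)),
    class = "session_spec"
  )
}

with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (is.null(old)) suppressWarnings(rm(".Random.seed", envir = globalenv()))
    else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

write_minimal_nifti <- function(path, volumes) {
  dims <- if (volumes > 1L) c(2L, 2L, 2L, volumes) else c(2L, 2L, 2L)
  RNifti::writeNifti(array(0L, dim = dims), path)
}

#' Generate a synthetic dcm2niix-style session tree
#'
#' Writes one JSON sidecar plus a minimal valid NIfTI image (2x2x2xT
#' int16 zeros; only headers are ever read downstream) per series
#' instance, with deterministic acquisition dates/times (subjects a week
#' apart, sessions a month apart, series five minutes apart) and
#' monotonically increasing SeriesNumbers. Task series marked `events`
#' also receive a timing file per run, named with explicit
#' `sub-/ses-/task-/run-` path tokens.
#'
#' @param spec a [session_spec()].
#' @param out output directory; must not already exist non-empty.
#' @return `out`, invisibly usable with [discover_inputs()].
#' @export
generate_session <- function(spec, out) {
  stopifnot(inherits(spec, "session_spec"))
  if (dir.exists(out) && length(list.files(out, all.files = TRUE, no.. = TRUE))) {
    stop("output directory is not empty: ", out)
  }
  dir.create(out, recursive = TRUE, showWarnings = FALSE)
  menu <- spec$series_menu

  with_seed(spec$seed, {
    for (i in seq_len(spec$n_subjects)) {
      sub_dir <- sprintf("P%03d", i)
      for (s in seq_len(spec$sessions_per_subject)) {
        ses_dir <- if (spec$sessions_per_subject > 1) file.path(sub_dir, sprintf("d%d", s)) else sub_dir
        dir.create(file.path(out, ses_dir), recursive = TRUE, showWarnings = FALSE)
        date <- as.Date("2023-03-01") + (i - 1L) * 7L + (s - 1L) * 30L
        minute <- 0L
        series_number <- 0L
        for (m in seq_len(nrow(menu))) {
          for (r in seq_len(menu$n_runs[[m]])) {
            series_number <- series_number + 1L
            te <- menu$te[[m]]
            if (spec$te_jitter > 0) te <- te + stats::runif(1, -spec$te_jitter, spec$te_jitter)
            sidecar <- list(
              Modality = "MR",
              MagneticFieldStrength = 3,
              SeriesDescription = menu$description[[m]],
              ImageType = as.list(menu$image_type[[m]]),
              RepetitionTime = menu$tr[[m]],
              EchoTime = te,
              AcquisitionDate = format(date, "%Y-%m-%d"),
              AcquisitionTime = sprintf("09:%02d:00", minute),
              SeriesNumber = series_number,
              PatientAge = 20 + i,
              PatientSex = if (i %% 2 == 0) "F" else "M"
            )
            if (!is.na(menu$ped[[m]])) sidecar$PhaseEncodingDirection <- menu$ped[[m]]
            if (!spec$anonymize) {
              sidecar$PatientID <- sprintf("S%03d", i)
              sidecar$PatientName <- sprintf("volunteer%03d", i)
              sidecar$PatientBirthDate <- sprintf("19%02d-06-15", 70 + i)
            }
            stem <- file.path(ses_dir, sprintf(
              "%03d_%s", series_number,
              gsub("[^A-Za-z0-9_-]", "", menu$description[[m]])
            ))
            jsonlite::write_json(sidecar, file.path(out, paste0(stem, ".json")),
                                 auto_unbox = TRUE, digits = NA, pretty = TRUE)
            write_minimal_nifti(file.path(out, paste0(stem, ".nii.gz")),
                                menu$volume_count[[m]])
            minute <- minute + 5L

            if (isTRUE(menu$events[[m]])) {
              task <- stringr::str_match(menu$description[[m]], "_task-([A-Za-z0-9]+)")[, 2]
              if (!is.na(task) && tolower(task) != "rest") {
                sub_lab <- if (spec$anonymize) sprintf("P%03d", i) else pad_label(i)
                ev_dir <- file.path(out, "events")
                dir.create(ev_dir, showWarnings = FALSE)
                ev_name <- paste0(
                  "sub-", sub_lab,
                  if (spec$sessions_per_subject > 1) paste0("_ses-", pad_label(s)),
                  "_task-", task,
                  if (menu$n_runs[[m]] > 1) paste0("_run-", pad_label(r)),
                  "_events.", spec$timing_format
                )
                generate_timing_table(
                  n_trials = 10L, units = spec$timing_units,
                  seed = spec$seed * 1000L + i * 100L + s * 10L + r,
                  format = spec$timing_format,
                  path = file.path(ev_dir, ev_name)
                )
              }
            }
          }
        }
      }
    }
  })
  invisible(out)
}

#' Generate a reproducible task-timing table
#'
#' Writes a timing file with onset, duration and trial-type columns for
#' `n_trials` trials, in the requested units and format. Identical
#' (arguments, seed) pairs yield byte-identical files; millisecond output
#' is exactly 1000 times the seconds output of the same seed. Millisecond
#' columns are named `onset_ms`/`duration_ms` so the column-map guesser
#' declares the right unit.
#'
#' @param n_trials number of trials (>= 0; 0 gives a header-only file).
#' @param units `"seconds"` or `"milliseconds"`.
#' @param seed integer seed.
#' @param format one of `"csv"`, `"tsv"`, `"txt"`, `"out"`, `"xlsx"`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
generate_timing_table <- function(n_trials, units = c("seconds", "milliseconds"),
                                  seed = 1L, format = c("csv", "tsv", "txt", "out", "xlsx"),
                                  path) {
  units <- match.arg(units)
  format <- match.arg(format)
  tab <- with_seed(seed, {
    onset <- round(cumsum(stats::runif(n_trials, 1.5, 2.5)), 3)
    duration <- round(stats::runif(n_trials, 0.5, 1.5), 3)
    trial_type <- sample(c("go", "stop"), n_trials, replace = TRUE)
    tibble::tibble(onset = onset, duration = duration, trial_type = trial_type)
  })
  if (units == "milliseconds") {
    tab$onset <- tab$onset * 1000
    tab$duration <- tab$duration * 1000
    names(tab)[1:2] <- c("onset_ms", "duration_ms")
  }
  chr <- lapply(tab, function(col) if (is.numeric(col)) sprintf("%.10g", col) else col)
  if (format == "xlsx") {
    write_minimal_xlsx(tibble::as_tibble(chr), path)
  } else {
    delim <- switch(format, csv = ",", tsv = "\t", out = "\t", txt = " ")
    lines <- c(paste(names(tab), collapse = delim),
               if (n_trials > 0) do.call(paste, c(chr, sep = delim)))
    writeLines(lines, path, useBytes = TRUE)
  }
  invisible(path)
}
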