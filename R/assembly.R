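## Assembly: materialize a core descriptor as a BIDS dataset on disk.

## Identity fields never written to output sidecars; the full acquisition
## timestamp is treated as identifying, scan date/time alone are not.
.IDENTITY_FIELDS <- c("PatientID", "PatientName", "PatientBirthDate",
                      "AcquisitionDateTime")

#' Inject user-supplied metadata into an object's output sidecar
#'
#' Fields the converter does not extract (for example
#' `BackgroundSuppression` on ASL sequences) can be supplied here; they
#' are checked against the guided-metadata type and dependency rules and,
#' if valid, written into the BIDS sidecar at assembly, overriding source
#' fields of the same name. Rule violations are refused with the
#' validation issue.
#'
#' @param core a `bids_core` descriptor.
#' @param fields named list of metadata fields to inject.
#' @param series_id inject into every member of this series, or
#' @param object_path inject into the single object with this NIfTI path.
#' @return the updated core descriptor.
#' @export
inject_metadata <- function(core, fields, series_id = NULL, object_path = NULL) {
  idx <- if (!is.null(series_id)) {
    which(core$objects$series_id == series_id)
  } else if (!is.null(object_path)) {
    which(core$objects$nifti_path == object_path)
  } else {
    stop("give either series_id or object_path")
  }
  if (!length(idx)) stop("no objects match the given target")
  for (i in idx) {
    merged <- utils::modifyList(core$objects$injected[[i]], fields)
    chk <- check_metadata_rules(core$objects$suffix[[i]], merged,
                                core$objects$nifti_path[[i]])
    if (any(chk$severity == "error")) {
      stop("injected metadata violates rules: ",
           paste(chk$message[chk$severity == "error"], collapse = "; "))
    }
    core$objects$injected[[i]] <- merged
  }
  refresh_core(core)
}

## Guess an events column map from a timing file header: exact
## (case-insensitive) matches of the BIDS column names, also accepting a
## `_ms`/`_s` unit suffix, which sets the declared unit.
guess_column_map <- function(tf) {
  header <- tf$header
  low <- tolower(header)
  assignments <- list()
  units <- list()
  for (target in .BIDS_EVENTS_COLUMNS) {
    hit <- which(low %in% c(target, paste0(target, "_s"), paste0(target, "_ms")))
    if (length(hit)) {
      assignments[[target]] <- header[[hit[[1]]]]
      if (target %in% c("onset", "duration", "response_time")) {
        units[[target]] <- if (endsWith(low[[hit[[1]]]], "_ms")) "milliseconds" else "seconds"
      }
    }
  }
  if (is.null(assignments$onset) || is.null(assignments$duration)) return(NULL)
  do.call(events_column_map, c(assignments, list(time_units = units)))
}

#' Write a core descriptor to disk as a BIDS dataset
#'
#' Copies every included image to its rendered BIDS path, writes an
#' anonymized sidecar beside it (source metadata minus identity fields,
#' plus injected fields), converts and places linked `events.tsv` files
#' next to their BOLD images, and writes `dataset_description.json`,
#' `participants.tsv` and a minimal `README` at the dataset root.
#' Blocking validation errors refuse assembly unless `force = TRUE`
#' (non-compliant output is then permitted, with the expectation that the
#' user resolves the issues afterwards).
#'
#' @param core a `bids_core` descriptor.
#' @param out_root output directory (created; must not already contain the
#'   target files).
#' @param force write despite validation errors.
#' @param symlink symlink images instead of copying.
#' @param strip_fields extra sidecar field names to strip beyond the
#'   identity fields.
#' @return (invisibly) a tibble of written paths with their kind.
#' @export
write_bids <- function(core, out_root, force = FALSE, symlink = FALSE,
                       strip_fields = character()) {
  errs <- core$issues[core$issues$severity == "error", ]
  if (nrow(errs) && !force) {
    stop("validation errors present (", nrow(errs),
         "); resolve them or use force = TRUE:\n  ",
         paste(errs$message, collapse = "\n  "))
  }
  dir.create(out_root, recursive = TRUE, showWarnings = FALSE)
  written <- list()
  note <- function(path, kind) written[[length(written) + 1L]] <<-
    tibble::tibble(path = path, kind = kind)

  obj <- core$objects
  paths <- rendered_paths(core)
  strip <- c(.IDENTITY_FIELDS, strip_fields)

  for (i in which(obj$include)) {
    if (is.na(paths[[i]])) {
      stop("object cannot be rendered to a valid path: ", obj$nifti_path[[i]])
    }
    dest <- file.path(out_root, paths[[i]])
    if (file.exists(dest)) stop("collision on disk: ", dest)
    if (!file.exists(obj$nifti_path[[i]])) {
      stop("missing source file: ", obj$nifti_path[[i]])
    }
    dir.create(dirname(dest), recursive = TRUE, showWarnings = FALSE)
    ok <- if (symlink) file.symlink(normalizePath(obj$nifti_path[[i]]), dest)
          else file.copy(obj$nifti_path[[i]], dest)
    if (!ok) stop("failed to write ", dest)
    note(dest, "image")

    meta <- jsonlite::fromJSON(obj$json_path[[i]], simplifyVector = TRUE)
    meta <- meta[setdiff(names(meta), strip)]
    if (length(obj$injected[[i]])) meta <- utils::modifyList(meta, obj$injected[[i]])
    side <- sub("\\.nii(\\.gz)?$", ".json", dest)
    jsonlite::write_json(meta, side, auto_unbox = TRUE, pretty = TRUE,
                         digits = NA, null = "null")
    note(side, "sidecar")
  }

  ## events.tsv beside each linked BOLD image
  if (!is.null(core$events)) {
    for (i in seq_len(nrow(core$events))) {
      link <- core$events$linked_nifti[[i]]
      if (is.na(link)) next
      j <- which(obj$nifti_path == link)[1]
      if (!obj$include[[j]] || is.na(paths[[j]])) next
      tf <- core$timing_files[[i]]
      cmap <- core$column_map %||% guess_column_map(tf)
      if (is.null(cmap)) {
        message("no events column map for ", tf$path, "; skipping events.tsv")
        next
      }
      events <- apply_column_map(tf, cmap)
      dest <- file.path(out_root, sub("_bold\\.nii(\\.gz)?$", "_events.tsv", paths[[j]]))
      write_events_tsv(events, dest)
      note(dest, "events")
    }
  }

  dd_path <- file.path(out_root, "dataset_description.json")
  jsonlite::write_json(core$dataset_description, dd_path, auto_unbox = TRUE,
                       pretty = TRUE, digits = NA, null = "null")
  note(dd_path, "dataset_description")

  keep <- core$subjects$subject %in% obj$subject[obj$include]
  part <- core$subjects[keep, ]
  p_lines <- c(
    "participant_id\tage\tsex",
    if (nrow(part)) paste(paste0("sub-", part$subject),
                          format_tsv_num(part$age),
                          ifelse(is.na(part$sex), "n/a", part$sex),
                          sep = "\t")
  )
  pt_path <- file.path(out_root, "participants.tsv")
  writeLines(p_lines, pt_path, useBytes = TRUE)
  note(pt_path, "participants")

  rd_path <- file.path(out_root, "README")
  writeLines(c(
    paste0("# ", core$dataset_description$Name),
    "",
    "This dataset was organized into the Brain Imaging Data Structure (BIDS)",
    "with bidsmapr. Edit this file to describe the study."
  ), rd_path)
  note(rd_path, "readme")

  invisible(dplyr::bind_rows(written))
}
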