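## The Revise phase, headless: an edit script stands in for the web
## interface's pages and is applied in the documented page order —
## Dataset Description, Subjects/Sessions, Series Mapping, Events,
## Dataset Review (object-level), metadata injection. Series-level edits
## propagate to every member object; object-level edits are applied last
## and win.

#' Build an edit script
#'
#' @param dataset_description named list merged into the dataset
#'   description block.
#' @param subject_strategy optional subject remap strategy
#'   (`"Numerical"`, `"PatientID"`, `"PatientName"`).
#' @param series list of series-level edits: each a list with
#'   `series_id` and any of `datatype`, `suffix`, `include`, `entities`
#'   (named list; a `NULL`/`NA` value removes the entity).
#' @param objects list of object-level edits: each a list with
#'   `nifti_path` and any of `include`, `entities`.
#' @param column_map an [events_column_map()] applied to every timing
#'   file.
#' @param inject list of metadata injections: each a list with `fields`
#'   and one of `series_id` / `object_path`.
#' @return an object of class `edit_script`.
#' @export
edit_script <- function(dataset_description = NULL, subject_strategy = NULL,
                        series = list(), objects = list(),
                        column_map = NULL, inject = list()) {
  structure(
    list(dataset_description = dataset_description,
         subject_strategy = subject_strategy,
         series = series, objects = objects,
         column_map = column_map, inject = inject),
    class = "edit_script"
  )
}

#' Read an edit script from JSON
#'
#' @param path JSON file mirroring the [edit_script()] fields.
#' @return an `edit_script`.
#' @export
read_edit_script <- function(path) {
  raw <- jsonlite::fromJSON(path, simplifyVector = FALSE)
  if (!is.null(raw$column_map)) {
    raw$column_map <- do.call(events_column_map,
                              c(raw$column_map$assignments,
                                list(time_units = raw$column_map$time_units)))
  }
  do.call(edit_script, raw[intersect(names(raw), names(formals(edit_script)))])
}

merge_entities <- function(current, edit) {
  for (k in names(edit)) {
    v <- edit[[k]]
    if (is.null(v) || (length(v) == 1 && is.na(v))) current[[k]] <- NULL
    else current[[k]] <- as.character(v)
  }
  current
}

#' Apply an edit script to a proposed mapping
#'
#' Edits are applied with propagation semantics: a series-level edit
#' reaches all member objects (before object-level overrides), and
#' re-validation runs afterwards. Applying an empty script is the
#' identity.
#'
#' @param core a `bids_core` descriptor.
#' @param edits an [edit_script()] (or path to its JSON form).
#' @return the revised `bids_core`.
#' @export
apply_edits <- function(core, edits) {
  if (is.character(edits)) edits <- read_edit_script(edits)
  stopifnot(inherits(edits, "edit_script"))

  if (!is.null(edits$dataset_description)) {
    core$dataset_description <- utils::modifyList(core$dataset_description,
                                                  edits$dataset_description)
  }
  if (!is.null(edits$subject_strategy)) {
    core <- remap_subjects(core, edits$subject_strategy)
    core$subject_strategy <- edits$subject_strategy
  }

  for (e in edits$series) {
    i <- which(core$series$series_id == (e$series_id %||% -1L))
    if (!length(i)) {
      stop("unknown series_id ", e$series_id %||% "<missing>",
           "; valid ids: ", paste(core$series$series_id, collapse = ", "))
    }
    if (!is.null(e$datatype)) core$series$datatype[[i]] <- e$datatype
    if (!is.null(e$suffix)) core$series$suffix[[i]] <- e$suffix
    if (!is.null(e$include)) core$series$include[[i]] <- isTRUE(e$include)
    if (!is.null(e$entities)) {
      core$series$edit_entities[[i]] <-
        merge_entities(core$series$edit_entities[[i]], e$entities)
    }
    if (!identical(core$series$datatype[[i]], "exclude") &&
        !is_valid_pair(core$series$datatype[[i]], core$series$suffix[[i]])) {
      stop("edit leaves schema-invalid datatype/suffix on series ",
           core$series$series_id[[i]], ": ",
           core$series$datatype[[i]], "/", core$series$suffix[[i]])
    }
  }

  if (!is.null(edits$column_map)) core$column_map <- edits$column_map

  for (e in edits$objects) {
    i <- which(core$objects$nifti_path == (e$nifti_path %||% ""))
    if (!length(i)) {
      stop("unknown object '", e$nifti_path %||% "<missing>",
           "'; objects are addressed by their source NIfTI path")
    }
    ov <- core$objects$overrides[[i]]
    if (!is.null(e$include)) ov$include <- isTRUE(e$include)
    if (!is.null(e$entities)) ov$entities <- merge_entities(ov$entities %||% list(), e$entities)
    core$objects$overrides[[i]] <- ov
  }

  core <- refresh_core(core)
  for (e in edits$inject) {
    core <- inject_metadata(core, e$fields,
                            series_id = e$series_id %||% NULL,
                            object_path = e$object_path %||% NULL)
  }
  core
}
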