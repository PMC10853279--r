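## Core-descriptor serialization: the whole proposed mapping round-trips
## through a single UTF-8 JSON document (the machine-readable product of
## the Propose phase). Derived fields (final entities, run numbers, events
## linkage, issues) are recomputed on load, so the document only stores
## the layers that cannot be re-derived.

row_list <- function(df, cols) {
  lapply(seq_len(nrow(df)), function(i) {
    stats::setNames(lapply(cols, function(c) df[[c]][[i]]), cols)
  })
}

#' Serialize and restore a core descriptor
#'
#' `write_core()` writes a `bids_core` as one JSON document;
#' `read_core()` restores it and recomputes every derived field
#' (entities, run labels, events linkage, validation issues), so
#' write-then-read is the identity on a freshly refreshed descriptor.
#'
#' @param core a `bids_core`.
#' @param path JSON file path.
#' @return `read_core()` a `bids_core`; `write_core()` the path,
#'   invisibly.
#' @export
write_core <- function(core, path) {
  stopifnot(inherits(core, "bids_core"))
  doc <- list(
    format = "bidsmapr_core",
    format_version = 1L,
    dataset_description = core$dataset_description,
    subject_strategy = core$subject_strategy %||% NULL,
    subjects = row_list(core$subjects, names(core$subjects)),
    series = lapply(seq_len(nrow(core$series)), function(i) {
      s <- core$series[i, ]
      list(
        series_id = s$series_id[[1]],
        description = s$description[[1]],
        image_type = as.list(s$image_type[[1]]),
        repetition_time = s$repetition_time[[1]],
        echo_time = s$echo_time[[1]],
        n_members = s$n_members[[1]],
        datatype = s$datatype[[1]],
        suffix = s$suffix[[1]],
        heuristic = s$heuristic[[1]],
        include = s$include[[1]],
        edit_entities = s$edit_entities[[1]]
      )
    }),
    objects = row_list(core$objects, setdiff(names(core$objects),
                                             c("entities", "datatype", "suffix", "include"))),
    timing_files = lapply(core$timing_files, function(tf) {
      list(path = tf$path, header = as.list(tf$header),
           rows = unname(lapply(seq_len(nrow(tf$rows)), function(i) {
             as.list(unname(unlist(tf$rows[i, ], use.names = FALSE)))
           })),
           entity_hints = tf$entity_hints)
    }),
    column_map = if (!is.null(core$column_map)) unclass(core$column_map) else NULL,
    options = core$options,
    root = core$root
  )
  jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = NA,
                       null = "null", na = "null", pretty = TRUE)
  invisible(path)
}

## Undo simplifyVector = FALSE for stored metadata values: unnamed lists
## of same-type scalars become vectors, matching how sidecars are parsed.
simplify_json_value <- function(x) {
  if (!is.list(x)) return(x)
  if (length(x) && is.null(names(x)) &&
      all(vapply(x, function(v) is.atomic(v) && length(v) == 1L, NA))) {
    types <- unique(vapply(x, function(v) class(v)[[1]], ""))
    if (length(types) == 1L) return(unlist(x))
  }
  lapply(x, simplify_json_value)
}

#' @rdname write_core
#' @export
read_core <- function(path) {
  doc <- jsonlite::fromJSON(path, simplifyVector = FALSE)
  if (!identical(doc$format, "bidsmapr_core")) {
    stop(path, " is not a bidsmapr core descriptor")
  }
  chr <- function(v) if (is.null(v)) NA_character_ else as.character(v)
  num <- function(v) if (is.null(v)) NA_real_ else as.numeric(v)
  int <- function(v) if (is.null(v)) NA_integer_ else as.integer(v)

  subjects <- dplyr::bind_rows(lapply(doc$subjects, function(s) {
    tibble::tibble(
      subject = chr(s$subject), patient_id = chr(s$patient_id),
      patient_name = chr(s$patient_name), patient_birthdate = chr(s$patient_birthdate),
      first_acquisition = chr(s$first_acquisition),
      age = num(s$age), sex = chr(s$sex)
    )
  }))

  series <- dplyr::bind_rows(lapply(doc$series, function(s) {
    tibble::tibble(
      series_id = int(s$series_id), description = chr(s$description),
      image_type = list(as.character(unlist(s$image_type))),
      repetition_time = num(s$repetition_time), echo_time = num(s$echo_time),
      n_members = int(s$n_members), datatype = chr(s$datatype),
      suffix = chr(s$suffix), heuristic = chr(s$heuristic),
      include = isTRUE(s$include),
      edit_entities = list(lapply(s$edit_entities, as.character))
    )
  }))

  objects <- dplyr::bind_rows(lapply(doc$objects, function(o) {
    ov <- o$overrides %||% list()
    if (!is.null(ov$entities)) ov$entities <- lapply(ov$entities, as.character)
    if (!is.null(ov$include)) ov$include <- isTRUE(ov$include)
    tibble::tibble(
      json_path = chr(o$json_path), nifti_path = chr(o$nifti_path),
      subject = chr(o$subject), session = chr(o$session),
      series_id = int(o$series_id),
      auto_entities = list(lapply(o$auto_entities, as.character)),
      auto_include = isTRUE(o$auto_include),
      overrides = list(ov),
      volume_count = int(o$volume_count), series_number = int(o$series_number),
      acquisition_date = chr(o$acquisition_date),
      acquisition_time = chr(o$acquisition_time),
      phase_encoding_direction = chr(o$phase_encoding_direction),
      patient_id = chr(o$patient_id), patient_name = chr(o$patient_name),
      patient_birthdate = chr(o$patient_birthdate),
      extra_metadata = list(simplify_json_value(o$extra_metadata)),
      injected = list(simplify_json_value(o$injected %||% list()))
    )
  }))

  timing_files <- lapply(doc$timing_files, function(tf) {
    header <- as.character(unlist(tf$header))
    rows <- if (length(tf$rows)) {
      tibble::as_tibble(
        stats::setNames(as.list(as.data.frame(
          matrix(as.character(unlist(tf$rows)), ncol = length(header), byrow = TRUE),
          stringsAsFactors = FALSE)), header),
        .name_repair = "minimal"
      )
    } else {
      tibble::as_tibble(stats::setNames(rep(list(character()), length(header)), header),
                        .name_repair = "minimal")
    }
    structure(list(path = as.character(tf$path), header = header, rows = rows,
                   entity_hints = lapply(tf$entity_hints, as.character)),
              class = "timing_file")
  })

  column_map <- if (!is.null(doc$column_map)) {
    do.call(events_column_map, c(doc$column_map$assignments,
                                 list(time_units = doc$column_map$time_units)))
  }

  core <- structure(
    list(
      dataset_description = doc$dataset_description,
      subjects = subjects,
      series = series,
      objects = objects,
      timing_files = timing_files,
      column_map = column_map,
      options = list(min_volumes = int(doc$options$min_volumes)),
      root = as.character(doc$root)
    ),
    class = "bids_core"
  )
  if (!is.null(doc$subject_strategy)) core$subject_strategy <- doc$subject_strategy
  refresh_core(core)
}
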