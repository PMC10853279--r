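## Session templates: capture a finalized session's mapping decisions
## (per-series signature -> assignment) and replay them onto a similar new
## session, so repeated uploads of the same protocol need no re-editing.

.TEMPLATE_VERSION <- "1.0"

#' Export a session template from a finalized mapping
#'
#' Captures everything needed to map a similar future session: the
#' dataset description block, one signature per series (normalized
#' SeriesDescription, ImageType, RepetitionTime, EchoTime) with its
#' stored assignment (datatype, suffix, entities minus `sub`/`ses`/`run`
#' — those are session-specific and always re-inferred), the events
#' column map, and the subject-mapping strategy if one was applied.
#' Duplicate signatures are an export error.
#'
#' @param core a `bids_core` descriptor.
#' @return an object of class `bids_template`.
#' @export
export_template <- function(core) {
  ser <- core$series
  sig_key <- vapply(seq_len(nrow(ser)), function(i) {
    paste(ser$description[[i]], paste(ser$image_type[[i]], collapse = "\r"), sep = "\r\r")
  }, "")
  ## TR/TE excluded from the duplicate check on purpose: two series whose
  ## signatures differ only within the matching tolerance are ambiguous
  dup <- duplicated(sig_key) &
    vapply(seq_len(nrow(ser)), function(i) {
      j <- match(sig_key[[i]], sig_key)
      j < i && tol_match(ser$repetition_time[[i]], ser$repetition_time[[j]]) &&
        tol_match(ser$echo_time[[i]], ser$echo_time[[j]])
    }, NA)
  if (any(dup)) {
    stop("cannot export template: series with indistinguishable signatures: ",
         paste(ser$description[dup], collapse = ", "))
  }

  anchor_obj <- match(ser$series_id, core$objects$series_id)
  series <- lapply(seq_len(nrow(ser)), function(i) {
    ent <- core$objects$entities[[anchor_obj[[i]]]]
    ent <- ent[setdiff(names(ent), c("sub", "ses", "run"))]
    list(
      description = ser$description[[i]],
      image_type = ser$image_type[[i]],
      repetition_time = ser$repetition_time[[i]],
      echo_time = ser$echo_time[[i]],
      datatype = ser$datatype[[i]],
      suffix = ser$suffix[[i]],
      include = ser$include[[i]],
      entities = ent
    )
  })

  structure(
    list(
      template_version = .TEMPLATE_VERSION,
      bids_version = core$dataset_description$BIDSVersion,
      dataset_description = core$dataset_description,
      subject_strategy = core$subject_strategy %||% NULL,
      series = series,
      column_map = if (!is.null(core$column_map)) unclass(core$column_map) else NULL
    ),
    class = "bids_template"
  )
}

#' Read and write session templates
#'
#' Templates serialize to UTF-8 JSON (`ezBIDS_template.json` style). A
#' template whose major version differs from the package's refuses to
#' load.
#'
#' @param template a `bids_template`.
#' @param path file path.
#' @return `read_template()` a `bids_template`; `write_template()` the
#'   path, invisibly.
#' @export
write_template <- function(template, path) {
  stopifnot(inherits(template, "bids_template"))
  jsonlite::write_json(unclass(template), path, auto_unbox = TRUE,
                       digits = NA, null = "null", pretty = TRUE)
  invisible(path)
}

#' @rdname write_template
#' @export
read_template <- function(path) {
  raw <- jsonlite::fromJSON(path, simplifyVector = FALSE)
  ver <- raw$template_version %||% "0"
  if (strsplit(as.character(ver), ".", fixed = TRUE)[[1]][[1]] !=
      strsplit(.TEMPLATE_VERSION, ".", fixed = TRUE)[[1]][[1]]) {
    stop("template version ", ver, " is incompatible with ", .TEMPLATE_VERSION)
  }
  raw$series <- lapply(raw$series, function(s) {
    s$image_type <- as.character(unlist(s$image_type))
    s$entities <- lapply(s$entities, as.character)
    s$repetition_time <- if (is.null(s$repetition_time)) NA_real_ else as.numeric(s$repetition_time)
    s$echo_time <- if (is.null(s$echo_time)) NA_real_ else as.numeric(s$echo_time)
    s
  })
  if (!is.null(raw$column_map)) {
    raw$column_map <- do.call(events_column_map,
                              c(raw$column_map$assignments,
                                list(time_units = raw$column_map$time_units)))
  }
  structure(raw, class = "bids_template")
}

## Replay stored assignments onto a freshly grouped series table. A new
## series matches a stored signature under the same anchor rule as series
## grouping (exact normalized description and ImageType, TR/TE within the
## +/- 0.5 ms tolerance); unmatched series keep their inferred
## classification.
apply_template_series <- function(template, series) {
  for (s in template$series) {
    hit <- which(vapply(seq_len(nrow(series)), function(i) {
      identical(series$description[[i]], s$description) &&
        identical(series$image_type[[i]], s$image_type) &&
        tol_match(series$repetition_time[[i]], s$repetition_time) &&
        tol_match(series$echo_time[[i]], s$echo_time)
    }, NA))
    for (i in hit) {
      series$datatype[[i]] <- s$datatype
      series$suffix[[i]] <- s$suffix
      series$include[[i]] <- isTRUE(s$include)
      series$edit_entities[[i]] <- s$entities
    }
  }
  series
}
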