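## The core descriptor: the single hierarchical document (dataset block ->
## subjects -> series -> objects) produced by the Propose phase, revised by
## edit scripts, and consumed by assembly. Entity information is layered:
## per-object automatic entities, series-level edits inherited by every
## member, then object-level overrides, with run numbering recomputed after
## every change.

default_dataset_description <- function() {
  list(
    Name = "Untitled",
    BIDSVersion = .BIDS_VERSION,
    Authors = list(),
    Acknowledgements = "",
    Funding = list(),
    License = "",
    HowToAcknowledge = "",
    DatasetType = "raw"
  )
}

#' Propose a BIDS mapping for a directory of converter outputs
#'
#' Runs the full inference pipeline — subject/session identification,
#' series grouping, datatype/suffix classification, entity extraction,
#' automatic low-volume exclusion, run numbering, timing-file parsing and
#' BOLD linkage, and validation — and returns the core descriptor that
#' encodes the proposed mapping. The descriptor is self-contained:
#' replaying [write_bids()] from the descriptor plus the source files is
#' deterministic.
#'
#' @param root input directory (or a `bids_bundle` from
#'   [discover_inputs()]).
#' @param lexicon keyphrase lexicon for classification.
#' @param template optional [session template][export_template()] (object
#'   or path) whose stored series assignments are replayed onto matching
#'   series before fresh inference handles the rest.
#' @param min_volumes 4D functional series with fewer volumes than this
#'   are auto-excluded (with a warning issue); default 20.
#' @param column_map optional [events_column_map()] applied to every
#'   timing file at assembly time.
#' @return an object of class `bids_core`.
#' @examples
#' root <- generate_session(session_spec(n_subjects = 1), tempfile())
#' core <- propose(root)
#' glance(core)
#' @export
propose <- function(root, lexicon = default_lexicon(), template = NULL,
                    min_volumes = 20L, column_map = NULL) {
  bundle <- if (inherits(root, "bids_bundle")) root else discover_inputs(root)
  if (!nrow(bundle$images)) stop("no NIfTI+sidecar pairs found under ", bundle$root)
  if (is.null(template) && !is.na(bundle$template_path)) {
    template <- read_template(bundle$template_path)
  }
  if (is.character(template)) template <- read_template(template)

  images <- bundle$images |>
    infer_subjects() |>
    infer_sessions() |>
    group_series() |>
    classify_series(lexicon) |>
    extract_entities()

  series <- series_anchors(images)
  cls_idx <- match(series$series_id, images$series_id)
  series$datatype <- images$datatype[cls_idx]
  series$suffix <- images$suffix[cls_idx]
  series$heuristic <- images$heuristic[cls_idx]
  series$include <- images$include[cls_idx]
  series$edit_entities <- rep(list(list()), nrow(series))

  if (!is.null(template)) {
    series <- apply_template_series(template, series)
  }

  ## automatic low-volume exclusion of 4D functional series
  auto_include <- rep(TRUE, nrow(images))
  low <- images$datatype == "func" & images$volume_count > 1L &
    images$volume_count < min_volumes
  auto_include[low] <- FALSE

  objects <- tibble::tibble(
    json_path = images$json_path,
    nifti_path = images$nifti_path,
    subject = images$subject,
    session = images$session,
    series_id = images$series_id,
    auto_entities = lapply(images$entities, function(e) e[setdiff(names(e), "run")]),
    auto_include = auto_include,
    overrides = rep(list(list()), nrow(images)),
    volume_count = images$volume_count,
    series_number = images$series_number,
    acquisition_date = images$acquisition_date,
    acquisition_time = images$acquisition_time,
    phase_encoding_direction = images$phase_encoding_direction,
    patient_id = images$patient_id,
    patient_name = images$patient_name,
    patient_birthdate = images$patient_birthdate,
    extra_metadata = images$extra_metadata,
    injected = rep(list(list()), nrow(images))
  )

  ord <- acq_order(images)
  subjects <- images[ord, ][!duplicated(images$subject[ord]), ] |>
    dplyr::transmute(
      subject = .data$subject,
      patient_id = .data$patient_id,
      patient_name = .data$patient_name,
      patient_birthdate = .data$patient_birthdate,
      first_acquisition = paste(
        ifelse(is.na(.data$acquisition_date), "9999-99-99", .data$acquisition_date),
        ifelse(is.na(.data$acquisition_time), "99:99:99", .data$acquisition_time)
      ),
      age = purrr::map_dbl(.data$extra_metadata, function(m) {
        a <- m$PatientAge %||% NA
        suppressWarnings(as.numeric(stringr::str_extract(as.character(a), "[0-9.]+")))
      }),
      sex = purrr::map_chr(.data$extra_metadata, function(m) {
        s <- as.character(m$PatientSex %||% NA_character_)
        if (s %in% c("M", "F", "O")) s else "n/a"
      })
    )

  tf <- lapply(bundle$timing_candidates, function(p) {
    tryCatch(parse_timing_file(p), error = function(e) {
      message("skipping unparseable timing file ", p, ": ", conditionMessage(e))
      NULL
    })
  })
  tf <- tf[!vapply(tf, is.null, NA)]

  core <- structure(
    list(
      dataset_description = if (!is.null(template)) {
        utils::modifyList(default_dataset_description(), template$dataset_description %||% list())
      } else {
        default_dataset_description()
      },
      subjects = subjects,
      series = series,
      objects = objects,
      timing_files = tf,
      column_map = column_map %||% (if (!is.null(template)) template$column_map else NULL),
      options = list(min_volumes = as.integer(min_volumes)),
      root = bundle$root
    ),
    class = "bids_core"
  )
  persist_runs(refresh_core(core))
}

## Run labels are sticky once assigned: they are copied into the automatic
## entity layer so that later edits or exclusions never silently renumber
## the remaining runs. Renumbering happens only on explicit request via
## renumber_runs().
persist_runs <- function(core) {
  core$objects$auto_entities <- lapply(seq_len(nrow(core$objects)), function(i) {
    ent <- core$objects$auto_entities[[i]]
    r <- core$objects$entities[[i]]$run
    if (!is.null(r) && is.null(ent$run)) ent$run <- r
    ent
  })
  core
}

#' Renumber run labels from scratch
#'
#' Run labels assigned during the Propose phase are sticky: excluding
#' run-01 leaves run-02 untouched. This strips every run entity (automatic
#' and overridden) and reassigns runs chronologically among the currently
#' included objects.
#'
#' @param core a `bids_core` descriptor.
#' @return the renumbered descriptor.
#' @export
renumber_runs <- function(core) {
  core$objects$auto_entities <- lapply(core$objects$auto_entities, function(e) {
    e$run <- NULL
    e
  })
  core$objects$overrides <- lapply(core$objects$overrides, function(ov) {
    if (!is.null(ov$entities)) ov$entities$run <- NULL
    ov
  })
  persist_runs(refresh_core(core))
}

## Recompute every derived field of a core descriptor from its layers:
## final include flags, merged entity maps, run numbers, events linkage and
## the validation issue list. Idempotent; called after any edit.
refresh_core <- function(core) {
  obj <- core$objects
  ser <- core$series
  sidx <- match(obj$series_id, ser$series_id)

  include <- ser$include[sidx] & obj$auto_include
  entities <- vector("list", nrow(obj))
  for (i in seq_len(nrow(obj))) {
    ent <- utils::modifyList(obj$auto_entities[[i]], ser$edit_entities[[sidx[[i]]]])
    ov <- obj$overrides[[i]]
    if (!is.null(ov$entities)) ent <- utils::modifyList(ent, ov$entities)
    if (!is.null(ov$include)) include[[i]] <- isTRUE(ov$include)
    entities[[i]] <- order_entities(ent)
  }
  obj$datatype <- ser$datatype[sidx]
  obj$suffix <- ser$suffix[sidx]
  obj$include <- include & obj$datatype != "exclude"
  obj$entities <- entities
  obj <- assign_runs(obj)
  core$objects <- obj

  core$events <- if (length(core$timing_files)) {
    link_events_to_bold(core$timing_files, core$objects)
  } else {
    NULL
  }
  core$issues <- validate_dataset(core)
  core
}

## Rendered relative BIDS path for every included object.
rendered_paths <- function(core) {
  obj <- core$objects
  vapply(seq_len(nrow(obj)), function(i) {
    if (!obj$include[[i]]) return(NA_character_)
    ext <- if (grepl("\\.nii\\.gz$", obj$nifti_path[[i]])) ".nii.gz" else ".nii"
    tryCatch(
      render_bids_path(obj$subject[[i]], obj$session[[i]], obj$datatype[[i]],
                       obj$suffix[[i]], obj$entities[[i]], ext),
      error = function(e) NA_character_
    )
  }, "")
}

#' @export
print.bids_core <- function(x, ...) {
  g <- glance(x)
  cat("<bids_core> ", x$root, "\n", sep = "")
  cat("  subjects: ", g$n_subjects, " | series: ", g$n_series,
      " | objects: ", g$n_objects, " (", g$n_included, " included)\n", sep = "")
  cat("  issues: ", g$n_errors, " error(s), ", g$n_warnings, " warning(s)\n", sep = "")
  invisible(x)
}

#' Tidy and summarize a proposed BIDS mapping
#'
#' `tidy()` returns one row per image object with its final subject,
#' session, classification, entity string and rendered BIDS path;
#' `glance()` returns a one-row summary of the proposal.
#'
#' @param x a `bids_core` descriptor.
#' @param ... unused.
#' @return a tibble.
#' @method tidy bids_core
#' @export
tidy.bids_core <- function(x, ...) {
  obj <- x$objects
  tibble::tibble(
    nifti_path = obj$nifti_path,
    subject = obj$subject,
    session = obj$session,
    series_id = obj$series_id,
    datatype = obj$datatype,
    suffix = obj$suffix,
    entities = vapply(obj$entities, function(e) {
      if (!length(e)) "" else paste(names(e), unlist(e), sep = "-", collapse = "_")
    }, ""),
    include = obj$include,
    volume_count = obj$volume_count,
    bids_path = rendered_paths(x)
  )
}

#' @rdname tidy.bids_core
#' @method glance bids_core
#' @export
glance.bids_core <- function(x, ...) {
  tibble::tibble(
    n_subjects = nrow(x$subjects),
    n_sessions = length(unique(stats::na.omit(x$objects$session))),
    n_series = nrow(x$series),
    n_objects = nrow(x$objects),
    n_included = sum(x$objects$include),
    n_timing_files = length(x$timing_files),
    n_errors = sum(x$issues$severity == "error"),
    n_warnings = sum(x$issues$severity == "warning"),
    bids_version = x$dataset_description$BIDSVersion
  )
}

#' Plot the layout of a proposed BIDS mapping
#'
#' Tile plot of subjects against series, colored by datatype, with
#' excluded objects greyed out — a quick visual check that grouping and
#' classification produced the expected study layout.
#'
#' @param object a `bids_core` descriptor.
#' @param ... unused.
#' @return a ggplot object.
#' @method autoplot bids_core
#' @export
autoplot.bids_core <- function(object, ...) {
  d <- tidy(object)
  d$series <- factor(d$series_id)
  d$fill <- ifelse(d$include, d$datatype, "excluded")
  ggplot2::ggplot(d, ggplot2::aes(x = .data$series, y = .data$subject,
                                  fill = .data$fill)) +
    ggplot2::geom_tile(color = "white", linewidth = 0.4) +
    ggplot2::labs(x = "series id", y = "subject", fill = "datatype",
                  title = "Proposed BIDS layout") +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
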