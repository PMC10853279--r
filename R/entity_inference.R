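## Entity-label inference, run numbering, and the BIDS filename grammar
## (render + inverse parser).

order_entities <- function(entities) {
  keys <- intersect(.BIDS_ENTITY_ORDER, names(entities))
  entities[keys]
}

entities_from_description <- function(desc) {
  out <- list()
  norm <- normalize_series_description(desc %||% "")
  for (key in setdiff(.BIDS_ENTITY_ORDER, c("sub", "ses"))) {
    m <- stringr::str_match(
      norm, stringr::regex(paste0("_", key, "-([A-Za-z0-9]+)"), ignore_case = TRUE)
    )[, 2]
    if (!is.na(m)) out[[key]] <- m
  }
  out
}

#' Extract entity labels for every image
#'
#' Entities are recovered from the normalized SeriesDescription through
#' `_<key>-<value>` search patterns (value = maximal alphanumeric run,
#' key matched case-insensitively) for every key in the embedded entity
#' table. Additional metadata supplies entities the description lacks: an
#' `EchoNumber` sidecar field adds the `echo` entity (dcm2niix writes it
#' for multi-echo acquisitions); spin-echo field maps (`fmap/epi`) derive
#' their required `dir` entity from `PhaseEncodingDirection`; a functional
#' BOLD series whose description mentions "rest" but carries no explicit
#' task token receives `task-rest`.
#'
#' @param images classified image-record tibble (see [classify_series()]).
#' @return `images` with an `entities` list-column (named character lists
#'   in canonical order, `sub`/`ses`/`run` excluded).
#' @export
extract_entities <- function(images) {
  stopifnot(all(c("datatype", "suffix") %in% names(images)))
  images$entities <- purrr::pmap(
    list(images$series_description, images$datatype, images$suffix,
         images$echo_number, images$phase_encoding_direction),
    function(desc, dt, suf, en, ped) {
      ent <- entities_from_description(desc)
      if (!is.na(en) && is.null(ent$echo)) ent$echo <- as.character(en)
      if (identical(dt, "fmap") && identical(suf, "epi") &&
          is.null(ent$dir) && !is.na(ped)) {
        lab <- ped_to_direction(ped)
        if (!is.na(lab)) ent$dir <- lab
      }
      if (identical(dt, "func") && suf %in% c("bold", "sbref", "cbv") &&
          is.null(ent$task) &&
          stringr::str_detect(tolower(desc %||% ""), "rest")) {
        ent$task <- "rest"
      }
      order_entities(ent)
    }
  )
  images
}

entity_class_key <- function(datatype, suffix, entities) {
  ent <- entities[setdiff(names(entities), "run")]
  if (length(ent)) ent <- ent[order(names(ent))]
  paste(datatype, suffix, paste(names(ent), unlist(ent), sep = "-", collapse = "_"),
        sep = "|")
}

#' Assign run numbers within each subject/session
#'
#' Within every collision class — identical datatype, suffix and non-run
#' entities for one subject/session — two or more included images receive
#' run labels `01`, `02`, ... ordered by (AcquisitionDate,
#' AcquisitionTime, SeriesNumber); a lone image gets no run entity. An
#' explicit `run` entity already present (e.g. parsed from the
#' description) is preserved.
#'
#' @param images image-record tibble with subject/session, classification
#'   and `entities` columns.
#' @return `images` with run entities inserted into `entities`.
#' @export
assign_runs <- function(images) {
  key_sub <- paste(images$subject, images$session %||% NA, sep = "\r")
  for (ks in unique(key_sub)) {
    idx <- which(key_sub == ks & images$include)
    if (!length(idx)) next
    cls <- vapply(idx, function(i) {
      entity_class_key(images$datatype[[i]], images$suffix[[i]], images$entities[[i]])
    }, "")
    for (cl in unique(cls)) {
      members <- idx[cls == cl]
      if (length(members) < 2) next
      if (any(vapply(members, function(i) !is.null(images$entities[[i]]$run), NA))) next
      ord <- members[acq_order(images[members, ])]
      for (r in seq_along(ord)) {
        ent <- images$entities[[ord[[r]]]]
        ent$run <- pad_label(r)
        images$entities[[ord[[r]]]] <- order_entities(ent)
      }
    }
  }
  images
}

#' Render and parse BIDS file paths
#'
#' `render_bids_path()` builds the relative path
#' `sub-<label>/[ses-<label>/]<datatype>/sub-<label>[_ses-<label>]
#' [_<entities in canonical order>]_<suffix><extension>` and refuses
#' schema-invalid input (unknown entity keys, non-alphanumeric labels,
#' invalid datatype/suffix pairs). `parse_bids_path()` is its exact
#' inverse.
#'
#' @param subject,session subject label and optional session label
#'   (`NA`/`NULL` for none).
#' @param datatype,suffix schema-valid datatype and suffix.
#' @param entities named list of entity values (without `sub`/`ses`).
#' @param extension file extension including the dot.
#' @return `render_bids_path()`: a relative path string.
#'   `parse_bids_path()`: a list with `subject`, `session`, `datatype`,
#'   `suffix`, `entities`, `extension`.
#' @examples
#' render_bids_path("01", "01", "anat", "T1w")
#' parse_bids_path("sub-01/anat/sub-01_acq-mprage_T1w.nii.gz")
#' @export
render_bids_path <- function(subject, session = NA, datatype, suffix,
                             entities = list(), extension = ".nii.gz") {
  if (!is_valid_pair(datatype, suffix)) {
    stop("schema-invalid datatype/suffix pair: ", datatype, "/", suffix)
  }
  unknown <- setdiff(names(entities), .BIDS_ENTITY_ORDER)
  if (length(unknown)) stop("unknown entity key(s): ", paste(unknown, collapse = ", "))
  labels <- c(subject, if (!is.na(session %||% NA)) session, unlist(entities))
  bad <- labels[!grepl("^[A-Za-z0-9]+$", labels)]
  if (length(bad)) {
    stop("entity values must be alphanumeric; offending value(s): ",
         paste(bad, collapse = ", "))
  }
  ent <- order_entities(entities)
  stem <- paste0(
    "sub-", subject,
    if (!is.na(session %||% NA)) paste0("_ses-", session),
    if (length(ent)) paste0("_", paste(names(ent), unlist(ent), sep = "-", collapse = "_")),
    "_", suffix
  )
  parts <- c(
    paste0("sub-", subject),
    if (!is.na(session %||% NA)) paste0("ses-", session),
    datatype,
    paste0(stem, extension)
  )
  paste(parts, collapse = "/")
}

#' @rdname render_bids_path
#' @param path a rendered relative BIDS path.
#' @export
parse_bids_path <- function(path) {
  fname <- basename(path)
  datatype <- basename(dirname(path))
  ext <- stringr::str_extract(fname, "\\..*$")
  stem <- stringr::str_remove(fname, "\\..*$")
  parts <- strsplit(stem, "_", fixed = TRUE)[[1]]
  suffix <- parts[[length(parts)]]
  kv <- parts[-length(parts)]
  m <- stringr::str_match(kv, "^([a-z]+)-([A-Za-z0-9]+)$")
  if (anyNA(m[, 1])) stop("unparseable entity token in ", fname)
  ent <- stats::setNames(as.list(m[, 3]), m[, 2])
  list(
    subject = ent$sub %||% NA_character_,
    session = ent$ses %||% NA_character_,
    datatype = datatype,
    suffix = suffix,
    entities = ent[setdiff(names(ent), c("sub", "ses"))],
    extension = ext
  )
}
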