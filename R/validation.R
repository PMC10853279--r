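## Validation rule engine: errors block finalization, warnings are
## guidance only and never preclude BIDS compliance.

issue_row <- function(severity, code, target, message) {
  tibble::tibble(severity = severity, code = code, target = target,
                 message = message)
}

empty_issues <- function() {
  tibble::tibble(severity = character(), code = character(),
                 target = character(), message = character())
}

## Sidecar metadata type requirements and dependency rules, keyed by
## suffix. Deliberately a documented subset of the specification's
## metadata tables, centred on the perfusion (ASL) rules.
.METADATA_TYPES <- tibble::tribble(
  ~suffix, ~field,                  ~type,
  "asl",   "BackgroundSuppression", "boolean",
  "asl",   "BolusCutOffFlag",       "boolean",
  "asl",   "BolusCutOffDelayTime",  "number",
  "asl",   "BolusCutOffTechnique",  "text",
  "asl",   "ArterialSpinLabelingType", "text"
)

.METADATA_DEPENDENCIES <- tibble::tribble(
  ~suffix, ~if_field,         ~then_field,
  "asl",   "BolusCutOffFlag", "BolusCutOffTechnique"
)

#' Check sidecar metadata against type and dependency rules
#'
#' Guided-metadata checks: certain fields must hold a specific value type
#' (for example `BackgroundSuppression` on ASL sequences must be boolean),
#' and certain fields become required when another is provided (providing
#' `BolusCutOffFlag` makes `BolusCutOffTechnique` required). Violations
#' are errors; satisfied rules produce no issue.
#'
#' @param suffix the classified suffix the fields belong to.
#' @param fields named list of sidecar metadata values.
#' @param target label used in issue reports (default the suffix).
#' @return an issues tibble (`severity`, `code`, `target`, `message`).
#' @examples
#' check_metadata_rules("asl", list(BackgroundSuppression = "yes"))
#' @export
check_metadata_rules <- function(suffix, fields, target = suffix) {
  issues <- list()
  types <- .METADATA_TYPES[.METADATA_TYPES$suffix == suffix, ]
  for (i in seq_len(nrow(types))) {
    val <- fields[[types$field[[i]]]]
    if (is.null(val)) next
    ok <- switch(types$type[[i]],
      boolean = is.logical(val) && length(val) == 1L && !is.na(val),
      number  = is.numeric(val) && length(val) == 1L && !is.na(val),
      text    = is.character(val) && length(val) == 1L && !is.na(val)
    )
    if (!ok) {
      issues[[length(issues) + 1L]] <- issue_row(
        "error", "metadata-type", target,
        paste0(types$field[[i]], " must contain a ", types$type[[i]],
               " value; got ", deparse(val))
      )
    }
  }
  deps <- .METADATA_DEPENDENCIES[.METADATA_DEPENDENCIES$suffix == suffix, ]
  for (i in seq_len(nrow(deps))) {
    if (!is.null(fields[[deps$if_field[[i]]]]) &&
        is.null(fields[[deps$then_field[[i]]]])) {
      issues[[length(issues) + 1L]] <- issue_row(
        "error", "metadata-dependency", target,
        paste0(deps$then_field[[i]], " is required because ",
               deps$if_field[[i]], " is provided")
      )
    }
  }
  dplyr::bind_rows(c(list(empty_issues()), issues))
}

#' Validate a proposed BIDS mapping
#'
#' Runs the error-and-warning rule engine over a core descriptor. Errors
#' (which block [write_bids()] unless forced): a required entity missing
#' (e.g. `func/bold` without `task`), entity values containing
#' non-alphanumeric characters (e.g. `acq-0.8 mm`), two included objects
#' rendering to the same path, and guided-metadata violations on injected
#' fields. Warnings (never blocking): a user `dir` entity contradicting
#' the direction implied by `PhaseEncodingDirection`, 4D functional series
#' under the volume threshold, and timing files whose matching BOLD image
#' was excluded.
#'
#' @param core a `bids_core` descriptor.
#' @return an issues tibble (`severity`, `code`, `target`, `message`),
#'   zero rows for a fully conformant dataset.
#' @export
validate_dataset <- function(core) {
  obj <- core$objects
  min_volumes <- core$options$min_volumes %||% 20L
  issues <- list()
  add <- function(...) issues[[length(issues) + 1L]] <<- issue_row(...)

  for (i in which(obj$include)) {
    target <- obj$nifti_path[[i]]
    ent <- obj$entities[[i]]
    req <- required_entities_for(obj$datatype[[i]], obj$suffix[[i]])
    for (k in setdiff(req, names(ent))) {
      add("error", "missing-required-entity", target,
          paste0("the ", k, " entity label is missing from the ",
                 obj$datatype[[i]], "/", obj$suffix[[i]],
                 " sequence, which is required by BIDS"))
    }
    labels <- c(sub = obj$subject[[i]],
                if (!is.na(obj$session[[i]])) c(ses = obj$session[[i]]),
                unlist(ent))
    bad <- labels[!grepl("^[A-Za-z0-9]+$", labels)]
    for (k in names(bad)) {
      add("error", "bad-entity-charset", target,
          paste0("entity ", k, " value '", bad[[k]],
                 "' contains non-alphanumeric characters"))
    }
    if (!is.null(ent$dir) && !is.na(obj$phase_encoding_direction[[i]])) {
      implied <- ped_to_direction(obj$phase_encoding_direction[[i]])
      if (!is.na(implied) && !identical(ent$dir, implied)) {
        add("warning", "dir-mismatch", target,
            paste0("dir entity is '", ent$dir, "' but PhaseEncodingDirection '",
                   obj$phase_encoding_direction[[i]], "' implies '", implied, "'"))
      }
    }
    if (obj$datatype[[i]] == "func" && obj$volume_count[[i]] > 1L &&
        obj$volume_count[[i]] < min_volumes) {
      add("warning", "low-volume", target,
          paste0("included 4D sequence has only ", obj$volume_count[[i]],
                 " volumes (threshold ", min_volumes, ")"))
    }
    meta <- check_metadata_rules(obj$suffix[[i]], obj$injected[[i]], target)
    if (nrow(meta)) issues[[length(issues) + 1L]] <- meta
  }

  ## auto-excluded low-volume series: surface the decision as guidance
  auto_low <- which(!obj$include & !obj$auto_include)
  for (i in auto_low) {
    add("warning", "low-volume", obj$nifti_path[[i]],
        paste0("4D sequence excluded automatically: ", obj$volume_count[[i]],
               " volumes is below the threshold of ", min_volumes))
  }

  paths <- rendered_paths(core)
  dup <- paths[!is.na(paths) & duplicated(paths)]
  for (p in unique(dup)) {
    add("error", "duplicate-path", p,
        paste0(sum(paths == p, na.rm = TRUE),
               " included objects render to the identical path ", p))
  }

  if (!is.null(core$events)) {
    ## one-to-one violations: two timing files resolving to one BOLD image
    for (i in which(core$events$collision)) {
      add("error", "events-collision", core$events$path[[i]],
          "timing file resolves to a BOLD image already claimed by another timing file (one-to-one mapping violated)")
    }
    ## timing files whose matching BOLD image is excluded
    excluded_bold <- obj[!obj$include & obj$datatype == "func" & obj$suffix == "bold", ]
    for (i in which(is.na(core$events$linked_nifti) & !core$events$collision)) {
      h <- core$timing_files[[i]]$entity_hints
      cand <- seq_len(nrow(excluded_bold))
      if (!is.null(h$sub)) cand <- cand[excluded_bold$subject[cand] == h$sub]
      if (!is.null(h$task)) {
        tk <- vapply(excluded_bold$entities[cand],
                     function(e) e$task %||% NA_character_, "")
        cand <- cand[!is.na(tk) & tk == h$task]
      }
      if (!is.null(h$run)) {
        rn <- vapply(excluded_bold$entities[cand],
                     function(e) e$run %||% NA_character_, "")
        cand <- cand[is.na(rn) | rn == h$run]
      }
      if (length(cand) >= 1L) {
        add("warning", "orphan-events", core$events$path[[i]],
            "timing file matches a functional BOLD image that is excluded from conversion")
      }
    }
  }

  dplyr::bind_rows(c(list(empty_issues()), issues))
}
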