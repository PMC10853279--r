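## Task-timing file pipeline: parse arbitrary delimited/spreadsheet timing
## files, apply one global column mapping with unit conversion, link each
## file to its functional BOLD run, and emit BIDS events.tsv content.

.BIDS_EVENTS_COLUMNS <- c("onset", "duration", "trial_type", "response_time",
                          "value", "stim_file")

.ENTITY_COLUMN_SYNONYMS <- list(
  sub  = c("subject", "sub", "subj"),
  ses  = c("session", "ses", "sess"),
  task = c("task", "taskname"),
  run  = c("run", "runnumber")
)

## Delimiter sniffing for free-form text timing files: tab, comma,
## semicolon, then generic whitespace; the first delimiter giving a
## consistent column count (> 1, or 1 as last resort) across rows wins.
sniff_delimited <- function(lines) {
  candidates <- c("\t", ",", ";", "[[:space:]]+")
  for (d in candidates) {
    counts <- vapply(lines, function(l) length(strsplit(l, d)[[1]]), 0L, USE.NAMES = FALSE)
    if (length(unique(counts)) == 1L && counts[[1]] > 1L) {
      return(lapply(lines, function(l) strsplit(l, d)[[1]]))
    }
  }
  lapply(lines, function(l) l)
}

#' Parse a task-timing file
#'
#' Accepts `.csv`, `.tsv`, `.txt`, `.out` and `.xlsx` files with no
#' required internal layout: the delimiter of text formats is sniffed
#' (tab, comma, semicolon, whitespace), spreadsheets use their first
#' worksheet, and all cells are kept as text so later unit conversion is
#' exact. Entity hints (`sub`, `ses`, `task`, `run`) are extracted from
#' the file path (`sub-01/ses-01/task-bart_run-01`) and from columns whose
#' names match the common synonyms ("Subject", "Sub", "Subj", ...) when
#' the column holds a single unique value.
#'
#' @param path timing file path.
#' @return an object of class `timing_file`: list with `path`, `header`,
#'   `rows` (character tibble) and `entity_hints`.
#' @export
parse_timing_file <- function(path) {
  ext <- tolower(tools::file_ext(path))
  if (!ext %in% .TIMING_EXTENSIONS) {
    stop("unsupported timing file extension .", ext,
         "; accepted: ", paste0(".", .TIMING_EXTENSIONS, collapse = ", "))
  }
  if (ext == "xlsx") {
    tab <- readxl::read_excel(path, sheet = 1, col_types = "text")
    tab <- tibble::as_tibble(lapply(tab, as.character))
  } else {
    lines <- readLines(path, warn = FALSE)
    lines <- lines[nzchar(trimws(lines))]
    if (!length(lines)) stop("empty timing file: ", path)
    cells <- sniff_delimited(lines)
    header <- trimws(cells[[1]])
    body <- cells[-1]
    if (length(body) && any(lengths(body) != length(header))) {
      stop("inconsistent column count in timing file: ", path)
    }
    tab <- tibble::as_tibble(
      stats::setNames(as.list(as.data.frame(
        matrix(trimws(unlist(body)), ncol = length(header), byrow = TRUE,
               dimnames = NULL),
        stringsAsFactors = FALSE
      )), header),
      .name_repair = "minimal"
    )
    if (!length(body)) {
      tab <- tibble::as_tibble(stats::setNames(rep(list(character()), length(header)), header),
                               .name_repair = "minimal")
    }
  }

  hints <- list()
  for (key in c("sub", "ses", "task", "run")) {
    m <- stringr::str_match(path, stringr::regex(paste0(key, "[-_]([A-Za-z0-9]+)"),
                                                 ignore_case = TRUE))[, 2]
    if (!is.na(m)) hints[[key]] <- m
  }
  for (key in names(.ENTITY_COLUMN_SYNONYMS)) {
    if (!is.null(hints[[key]])) next
    hit <- which(tolower(names(tab)) %in% .ENTITY_COLUMN_SYNONYMS[[key]])
    if (length(hit)) {
      vals <- unique(tab[[hit[[1]]]])
      vals <- vals[!is.na(vals)]
      if (length(vals) == 1L) hints[[key]] <- sanitize_label(vals)
    }
  }

  structure(
    list(path = path, header = names(tab), rows = tab, entity_hints = hints),
    class = "timing_file"
  )
}

#' Declare the global events column mapping
#'
#' One mapping is declared per session and applied to every timing file:
#' each BIDS events column (`onset`, `duration`, `trial_type`,
#' `response_time`, `value`, `stim_file`) is bound to a source column
#' name, and every time-based bound column declares its unit (`seconds`
#' or `milliseconds`). `onset` and `duration` must be assigned.
#'
#' @param ... `<bids column> = <source column name>` assignments.
#' @param time_units named character vector/list mapping time-based BIDS
#'   columns to `"seconds"` or `"milliseconds"`.
#' @return an object of class `events_column_map`.
#' @examples
#' events_column_map(onset = "onset_ms", duration = "dur_ms",
#'                   trial_type = "cond",
#'                   time_units = c(onset = "milliseconds",
#'                                  duration = "milliseconds"))
#' @export
events_column_map <- function(..., time_units = c(onset = "seconds",
                                                  duration = "seconds")) {
  assignments <- list(...)
  unknown <- setdiff(names(assignments), .BIDS_EVENTS_COLUMNS)
  if (length(unknown)) stop("unknown events column(s): ", paste(unknown, collapse = ", "))
  if (is.null(assignments$onset) || is.null(assignments$duration)) {
    stop("the events column map must assign both onset and duration")
  }
  time_units <- as.list(time_units)
  bad <- !unlist(time_units) %in% c("seconds", "milliseconds")
  if (any(bad)) stop("time units must be 'seconds' or 'milliseconds'")
  time_based <- intersect(names(assignments), c("onset", "duration", "response_time"))
  missing_units <- setdiff(time_based, names(time_units))
  if (length(missing_units)) {
    stop("no time unit declared for: ", paste(missing_units, collapse = ", "))
  }
  structure(list(assignments = assignments, time_units = time_units),
            class = "events_column_map")
}

#' Apply the column mapping to one timing file
#'
#' Produces the events table: mapped columns first in the order `onset`,
#' `duration`, then the other mapped columns, then every unmapped source
#' column preserved verbatim. Values of columns declared in milliseconds
#' are divided by 1000 (exact on inputs with up to three decimal places);
#' missing cells become `n/a` when serialized.
#'
#' @param tf a `timing_file` (see [parse_timing_file()]).
#' @param cmap an [events_column_map()].
#' @return a tibble holding the events table.
#' @export
apply_column_map <- function(tf, cmap) {
  stopifnot(inherits(tf, "timing_file"), inherits(cmap, "events_column_map"))
  src <- unlist(cmap$assignments)
  missing <- src[!src %in% tf$header]
  if (length(missing)) {
    stop("timing file ", tf$path, " lacks mapped column(s): ",
         paste(missing, collapse = ", "))
  }
  ordered_targets <- intersect(.BIDS_EVENTS_COLUMNS, names(cmap$assignments))
  out <- list()
  for (target in ordered_targets) {
    vals <- tf$rows[[cmap$assignments[[target]]]]
    if (target %in% names(cmap$time_units)) {
      num <- suppressWarnings(as.numeric(vals))
      if (identical(cmap$time_units[[target]], "milliseconds")) num <- num / 1000
      out[[target]] <- num
    } else {
      out[[target]] <- vals
    }
  }
  rest <- setdiff(tf$header, unname(src))
  for (col in rest) out[[col]] <- tf$rows[[col]]
  tibble::as_tibble(out, .name_repair = "minimal")
}

#' Link timing files to their functional BOLD images
#'
#' Each timing file is linked to the unique included, non-rest `func/bold`
#' object that agrees with every available entity hint (`sub`, `ses` if
#' applicable, `task`, `run`); one-to-one mapping is assumed, so two
#' timing files resolving to the same BOLD image is an error. A linked
#' file inherits the BOLD image's SeriesNumber. Hints that cannot be
#' resolved produce per-entity placeholder labels (`sub-XX1`, `sub-XX2`,
#' ..., counters independent per entity) for the user to correct. A
#' second timing file resolving to an already-claimed BOLD image is left
#' unlinked with `collision = TRUE`; the validator reports it as an
#' error.
#'
#' @param tfs list of `timing_file` objects.
#' @param objects the objects tibble of a proposed dataset (must carry
#'   `subject`, `session`, `datatype`, `suffix`, `entities`, `include`,
#'   `series_number`).
#' @return a tibble with one row per timing file: `path`, `subject`,
#'   `session`, `task`, `run`, `linked_nifti` (`NA` when unresolved),
#'   `series_number`, `placeholder` (logical).
#' @export
link_events_to_bold <- function(tfs, objects) {
  bold <- objects[objects$datatype == "func" & objects$suffix == "bold" &
                    objects$include, , drop = FALSE]
  task_of <- vapply(bold$entities, function(e) e$task %||% NA_character_, "")
  run_of <- vapply(bold$entities, function(e) e$run %||% NA_character_, "")
  eligible <- which(is.na(task_of) | tolower(task_of) != "rest")

  counters <- c(sub = 0L, ses = 0L, task = 0L, run = 0L)
  rows <- vector("list", length(tfs))
  used <- character()
  for (i in seq_along(tfs)) {
    tf <- tfs[[i]]
    h <- tf$entity_hints
    cand <- eligible
    if (!is.null(h$sub)) cand <- cand[bold$subject[cand] == h$sub]
    if (!is.null(h$ses)) cand <- cand[!is.na(bold$session[cand]) & bold$session[cand] == h$ses]
    if (!is.null(h$task)) cand <- cand[!is.na(task_of[cand]) & task_of[cand] == h$task]
    if (!is.null(h$run)) cand <- cand[is.na(run_of[cand]) | run_of[cand] == h$run]
    placeholder <- FALSE
    fill <- function(key) {
      if (!is.null(h[[key]])) return(h[[key]])
      counters[[key]] <<- counters[[key]] + 1L
      placeholder <<- TRUE
      paste0("XX", counters[[key]])
    }
    if (length(cand) == 1L && !bold$nifti_path[[cand]] %in% used) {
      j <- cand
      used <- c(used, bold$nifti_path[[j]])
      rows[[i]] <- tibble::tibble(
        path = tf$path,
        subject = bold$subject[[j]], session = bold$session[[j]],
        task = task_of[[j]], run = run_of[[j]],
        linked_nifti = bold$nifti_path[[j]],
        series_number = bold$series_number[[j]],
        placeholder = FALSE,
        collision = FALSE
      )
    } else {
      collided <- length(cand) == 1L # unique match already claimed
      rows[[i]] <- tibble::tibble(
        path = tf$path,
        subject = if (collided) h$sub %||% NA_character_ else fill("sub"),
        session = h$ses %||% NA_character_,
        task = if (collided) h$task %||% NA_character_ else fill("task"),
        run = h$run %||% NA_character_,
        linked_nifti = NA_character_,
        series_number = NA_integer_,
        placeholder = placeholder,
        collision = collided
      )
    }
  }
  dplyr::bind_rows(rows)
}

#' Write a BIDS events.tsv file
#'
#' Tab-separated, UTF-8, missing values serialized as `n/a`, numeric
#' values formatted without binary-rounding artifacts, and columns always
#' beginning with `onset`, `duration`.
#'
#' @param events events tibble (see [apply_column_map()]).
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_events_tsv <- function(events, path) {
  stopifnot(all(c("onset", "duration") %in% names(events)))
  events <- events[, c("onset", "duration",
                       setdiff(names(events), c("onset", "duration")))]
  cells <- lapply(events, function(col) {
    if (is.numeric(col)) format_tsv_num(col)
    else ifelse(is.na(col) | col == "", "n/a", as.character(col))
  })
  lines <- c(
    paste(names(events), collapse = "\t"),
    if (nrow(events)) do.call(paste, c(cells, sep = "\t"))
  )
  writeLines(lines, path, useBytes = TRUE)
  invisible(path)
}
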