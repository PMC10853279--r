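## Subject and session inference: every image receives a subject label and
## (when warranted) a session label before series grouping begins.

explicit_from_record <- function(images, key) {
  ## Path takes precedence over PatientID over PatientName when several
  ## carry a sub-/ses- marker.
  lab <- find_explicit_label(images$json_path, key)
  lab <- dplyr::coalesce(lab, find_explicit_label(images$patient_id, key))
  lab <- dplyr::coalesce(lab, find_explicit_label(images$patient_name, key))
  sanitize_label(lab)
}

#' Infer subject labels for a set of image records
#'
#' Implements the subject-identification stage. Precedence per image:
#' an explicit `sub-` marker in the file path, PatientID or PatientName
#' wins; otherwise images with distinct (PatientID, PatientName,
#' PatientBirthDate) triples receive numeric labels `01`, `02`, ...
#' ordered chronologically by earliest acquisition timestamp; fully
#' anonymized images (all three patient fields absent) take their
#' containing folder name, sanitized to alphanumeric. Label assignment is
#' invariant to input row order.
#'
#' @param images image-record tibble (from [discover_inputs()]).
#' @return `images` with a `subject` character column added.
#' @export
infer_subjects <- function(images) {
  stopifnot(nrow(images) > 0)
  subject <- explicit_from_record(images, "sub")

  triple_present <- !is.na(images$patient_id) | !is.na(images$patient_name) |
    !is.na(images$patient_birthdate)

  ## (b) distinct patient triples, numbered chronologically by each
  ## triple's earliest acquisition stamp; triples with no stamp sort last,
  ## tie-broken by the triple's own text for determinism
  idx <- which(is.na(subject) & triple_present)
  if (length(idx)) {
    key <- paste(images$patient_id[idx], images$patient_name[idx],
                 images$patient_birthdate[idx], sep = "\r")
    stamp <- paste(
      ifelse(is.na(images$acquisition_date[idx]), "9999-99-99", images$acquisition_date[idx]),
      ifelse(is.na(images$acquisition_time[idx]), "99:99:99", images$acquisition_time[idx])
    )
    gmin <- tapply(stamp, key, min)
    groups <- names(gmin)[order(unname(gmin), names(gmin), method = "radix")]
    subject[idx] <- pad_label(match(key, groups))
  }

  ## (c) anonymized: containing folder name
  idx <- which(is.na(subject) & !triple_present)
  if (length(idx)) {
    folder <- sanitize_label(basename(dirname(images$json_path[idx])))
    subject[idx] <- folder
    ## folder yielded nothing usable: positional numbering past the used range
    miss <- which(is.na(subject[idx]))
    if (length(miss)) {
      used <- suppressWarnings(max(0L, as.integer(subject[grepl("^[0-9]+$", subject)])))
      subject[idx[miss]] <- pad_label(used + seq_along(miss))
    }
  }
  images$subject <- subject
  images
}

#' Infer session labels within each subject
#'
#' An explicit `ses-` marker (path, PatientID, PatientName) always wins.
#' Otherwise images are clustered by calendar AcquisitionDate: a single
#' cluster yields no session label at all, while two or more clusters are
#' labelled `01`, `02`, ... chronologically. AcquisitionTime orders images
#' within a date but never splits one date into two sessions; images with
#' no date form a single trailing cluster.
#'
#' @param images image-record tibble carrying a `subject` column.
#' @return `images` with a `session` character column added (`NA` where no
#'   session label applies).
#' @export
infer_sessions <- function(images) {
  stopifnot("subject" %in% names(images))
  session <- explicit_from_record(images, "ses")
  for (sub in unique(images$subject)) {
    idx <- which(images$subject == sub & is.na(session))
    if (!length(idx)) next
    dates <- images$acquisition_date[idx]
    key <- ifelse(is.na(dates), "9999-99-99", dates)
    clusters <- sort(unique(key))
    if (length(clusters) >= 2) {
      session[idx] <- pad_label(match(key, clusters))
    }
  }
  images$session <- session
  images
}

#' Remap subject labels of a proposed dataset
#'
#' Applies one of the three reset strategies to a core descriptor:
#' `"PatientName"` and `"PatientID"` copy the (sanitized) metadata value of
#' each subject as its label; `"Numerical"` assigns chronological integers,
#' zero-padded below 10 (`01`, `02`, ..., `10`, `11`).
#'
#' @param core a `bids_core` descriptor (see [propose()]).
#' @param strategy one of `"PatientName"`, `"PatientID"`, `"Numerical"`.
#' @return the core descriptor with subject labels rewritten everywhere
#'   (subjects table and objects table).
#' @export
remap_subjects <- function(core, strategy = c("Numerical", "PatientID", "PatientName")) {
  strategy <- match.arg(strategy)
  subs <- core$subjects
  old <- subs$subject
  if (strategy == "Numerical") {
    ord <- order(ifelse(is.na(subs$first_acquisition), "9999", subs$first_acquisition),
                 subs$subject)
    new <- character(nrow(subs))
    new[ord] <- pad_label(seq_len(nrow(subs)))
  } else {
    field <- if (strategy == "PatientID") subs$patient_id else subs$patient_name
    missing <- subs$subject[is.na(field)]
    if (length(missing)) {
      stop("strategy ", strategy, " unavailable: subjects lacking the field: ",
           paste(missing, collapse = ", "))
    }
    new <- sanitize_label(field)
    if (anyNA(new)) stop("strategy ", strategy, " produced empty labels after sanitization")
  }
  if (anyDuplicated(new)) stop("strategy ", strategy, " produced duplicate subject labels")
  core$subjects$subject <- new
  core$objects$subject <- new[match(core$objects$subject, old)]
  refresh_core(core)
}
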