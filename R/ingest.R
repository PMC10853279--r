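## Sidecar keys parsed into typed columns; everything else is carried
## verbatim in extra_metadata. Names matched case-sensitively as emitted by
## dcm2niix.
.PARSED_KEYS <- c(
  "SeriesDescription", "ImageType", "RepetitionTime", "EchoTime",
  "EchoNumber", "PatientID", "PatientName", "PatientBirthDate",
  "AcquisitionDate", "AcquisitionTime", "AcquisitionDateTime",
  "SeriesNumber", "PhaseEncodingDirection"
)

.TIMING_EXTENSIONS <- c("csv", "tsv", "txt", "out", "xlsx")

.TEMPLATE_BASENAME <- "ezBIDS_template.json"

empty_images <- function() {
  tibble::tibble(
    json_path = character(), nifti_path = character(),
    series_description = character(), image_type = list(),
    repetition_time = double(), echo_time = double(),
    echo_number = integer(),
    patient_id = character(), patient_name = character(),
    patient_birthdate = character(),
    acquisition_date = character(), acquisition_time = character(),
    series_number = integer(), phase_encoding_direction = character(),
    volume_count = integer(), extra_metadata = list()
  )
}

#' Discover dcm2niix-style inputs under a directory
#'
#' Walks `root` and collects every JSON sidecar that has a sibling NIfTI
#' image of the same stem into one image record per pair, along with
#' task-timing file candidates (`.csv`, `.tsv`, `.txt`, `.out`, `.xlsx`)
#' and an optional session template (`ezBIDS_template.json`). Hidden files
#' and anything under a `derivatives` directory are ignored. Discovery
#' order is deterministic (lexicographic by relative path), so repeated
#' runs over the same tree yield identical bundles.
#'
#' @param root directory containing converter outputs.
#' @return an object of class `bids_bundle`: a list with `images` (tibble,
#'   one row per NIfTI+sidecar pair), `timing_candidates` (character paths),
#'   `template_path` (path or `NA`) and `root`.
#' @seealso [read_sidecar()], [extract_archive()], [propose()]
#' @export
discover_inputs <- function(root) {
  if (!dir.exists(root)) stop("input root does not exist or is unreadable: ", root)
  rel <- list.files(root, recursive = TRUE, all.files = FALSE, full.names = FALSE)
  keep <- !vapply(strsplit(rel, "/", fixed = TRUE), function(parts) {
    any(startsWith(parts, ".")) || any(tolower(parts[-length(parts)]) == "derivatives")
  }, logical(1))
  rel <- sort(rel[keep], method = "radix")
  full <- file.path(root, rel)

  is_json <- grepl("\\.json$", rel, ignore.case = TRUE)
  template_path <- full[is_json & basename(rel) == .TEMPLATE_BASENAME]
  template_path <- if (length(template_path)) template_path[[1]] else NA_character_

  ext <- tolower(tools::file_ext(rel))
  timing_candidates <- full[ext %in% .TIMING_EXTENSIONS]

  sidecars <- full[is_json & basename(rel) != .TEMPLATE_BASENAME]
  records <- vector("list", length(sidecars))
  for (i in seq_along(sidecars)) {
    jp <- sidecars[[i]]
    stem <- sub("\\.json$", "", jp, ignore.case = TRUE)
    nii <- c(paste0(stem, ".nii.gz"), paste0(stem, ".nii"))
    nii <- nii[file.exists(nii)]
    if (!length(nii)) {
      message("skipping sidecar without sibling NIfTI: ", jp)
      next
    }
    records[[i]] <- read_sidecar(jp, nii[[1]])
  }
  images <- dplyr::bind_rows(c(list(empty_images()), records))

  structure(
    list(
      images = images,
      timing_candidates = timing_candidates,
      template_path = template_path,
      root = normalizePath(root)
    ),
    class = "bids_bundle"
  )
}

#' @export
print.bids_bundle <- function(x, ...) {
  cat("<bids_bundle> ", x$root, "\n",
      "  images: ", nrow(x$images),
      " | timing candidates: ", length(x$timing_candidates),
      " | template: ", if (is.na(x$template_path)) "none" else basename(x$template_path),
      "\n", sep = "")
  invisible(x)
}

#' Read one NIfTI+sidecar pair into an image record
#'
#' Parses the sidecar's typed keys (SeriesDescription, ImageType,
#' RepetitionTime, EchoTime, EchoNumber, patient identity fields,
#' acquisition timestamps, SeriesNumber, PhaseEncodingDirection) into
#' columns and preserves every remaining key verbatim in `extra_metadata`.
#' The volume count is the image header's 4th dimension (1 for 3D images);
#' voxel data are never loaded. Missing sidecar keys yield `NA`, never a
#' default. A combined `AcquisitionDateTime` is split into date and time
#' when the separate fields are absent.
#'
#' @param json_path path to the JSON sidecar.
#' @param nifti_path path to the sibling `.nii`/`.nii.gz` image.
#' @return a one-row tibble in the image-record layout.
#' @export
read_sidecar <- function(json_path, nifti_path) {
  meta <- tryCatch(
    jsonlite::fromJSON(json_path, simplifyVector = TRUE),
    error = function(e) stop("malformed JSON sidecar ", json_path, ": ",
                             conditionMessage(e))
  )
  hdr <- tryCatch(
    RNifti::niftiHeader(nifti_path),
    error = function(e) stop("unreadable NIfTI header ", nifti_path, ": ",
                             conditionMessage(e))
  )
  dims <- hdr$dim
  vol <- if (dims[1] >= 4L) as.integer(dims[5]) else 1L

  num1 <- function(key) {
    v <- meta[[key]]
    if (is.null(v)) NA_real_ else as.numeric(v)[[1]]
  }
  chr1 <- function(key) {
    v <- meta[[key]]
    if (is.null(v)) NA_character_ else as.character(v)[[1]]
  }
  int1 <- function(key) {
    v <- meta[[key]]
    if (is.null(v)) NA_integer_ else as.integer(v)[[1]]
  }

  acq_date <- chr1("AcquisitionDate")
  acq_time <- chr1("AcquisitionTime")
  adt <- chr1("AcquisitionDateTime")
  if (!is.na(adt) && is.na(acq_date)) {
    parts <- stringr::str_match(adt, "^([0-9-]+)[T ]?([0-9:.]*)")
    acq_date <- parts[, 2]
    if (is.na(acq_time) && nzchar(parts[, 3])) acq_time <- parts[, 3]
  }

  tibble::tibble(
    json_path = json_path,
    nifti_path = nifti_path,
    series_description = chr1("SeriesDescription") %||% NA_character_,
    image_type = list(as.character(meta$ImageType %||% character())),
    repetition_time = num1("RepetitionTime"),
    echo_time = num1("EchoTime"),
    echo_number = int1("EchoNumber"),
    patient_id = chr1("PatientID"),
    patient_name = chr1("PatientName"),
    patient_birthdate = chr1("PatientBirthDate"),
    acquisition_date = acq_date,
    acquisition_time = acq_time,
    series_number = int1("SeriesNumber"),
    phase_encoding_direction = chr1("PhaseEncodingDirection"),
    volume_count = vol,
    extra_metadata = list(meta[setdiff(names(meta), .PARSED_KEYS)])
  )
}

#' Extract an archive of converter outputs
#'
#' Unpacks a supported archive into a fresh temporary directory suitable
#' for [discover_inputs()]. Mandatory formats: `.tar`, `.tar.gz`/`.tgz`,
#' `.tar.bz2`, `.tar.xz`, `.zip`, and single-file `.gz`/`.bz2`/`.xz`.
#' `.7z` and `.rar` are supported only when the `7z`/`unrar` system tools
#' are installed.
#'
#' @param path archive file.
#' @param exdir extraction directory (default: a new temporary directory).
#' @return the extraction directory path.
#' @export
extract_archive <- function(path, exdir = tempfile("bidsmapr_extract_")) {
  if (!file.exists(path)) stop("archive does not exist: ", path)
  dir.create(exdir, recursive = TRUE, showWarnings = FALSE)
  lower <- tolower(path)
  supported <- ".tar, .tar.gz, .tgz, .tar.bz2, .tar.xz, .zip, .gz, .bz2, .xz (plus .7z/.rar when system tools are installed)"

  if (grepl("\\.(tar|tar\\.gz|tgz|tar\\.bz2|tar\\.xz)$", lower)) {
    utils::untar(path, exdir = exdir)
  } else if (grepl("\\.zip$", lower)) {
    utils::unzip(path, exdir = exdir)
  } else if (grepl("\\.(gz|bz2|xz)$", lower)) {
    con <- switch(sub("^.*\\.", "", lower),
      gz = gzfile(path, "rb"), bz2 = bzfile(path, "rb"), xz = xzfile(path, "rb"))
    on.exit(close(con))
    raw <- readBin(con, "raw", n = file.size(path) * 50 + 1e6)
    writeBin(raw, file.path(exdir, sub("\\.(gz|bz2|xz)$", "", basename(path))))
  } else if (grepl("\\.7z$", lower)) {
    if (Sys.which("7z") == "") stop("7z tool not installed; supported formats: ", supported)
    system2("7z", c("x", shQuote(path), paste0("-o", shQuote(exdir))))
  } else if (grepl("\\.rar$", lower)) {
    if (Sys.which("unrar") == "") stop("unrar tool not installed; supported formats: ", supported)
    system2("unrar", c("x", shQuote(path), shQuote(exdir)))
  } else {
    stop("unsupported archive format for ", basename(path),
         "; supported formats: ", supported)
  }
  exdir
}
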