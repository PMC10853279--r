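## Series grouping: partition image records into series by the four-field
## key (SeriesDescription, ImageType, RepetitionTime, EchoTime), with a
## +/- 0.5 ms tolerance on the two timing fields and normalization of the
## retroactive-reconstruction suffix on the description.

## TR/TE values within +/- 0.0005 s (0.5 ms, inclusive) of a group's anchor
## count as the same acquisition; compensates for binary-to-ASCII
## floating-point precision differences between converters.
.SERIES_TOLERANCE_S <- 0.0005

#' Normalize a SeriesDescription for grouping
#'
#' Retroactively reconstructed images (re-derived on the scanner after a
#' failed reconstruction) typically carry a trailing `_RR` on their
#' SeriesDescription while being functionally identical to their
#' uncorrupted siblings. A trailing `_RR` (case-insensitive) is removed;
#' anything else, including an `RR` prefix or infix, is left untouched.
#'
#' @param x character vector of descriptions.
#' @return normalized character vector.
#' @examples
#' normalize_series_description("T1_MPRAGE_RR") # "T1_MPRAGE"
#' normalize_series_description("RR_T1")        # unchanged
#' @export
normalize_series_description <- function(x) {
  stringr::str_remove(x, stringr::regex("_RR$", ignore_case = TRUE))
}

## guard for the binary representation of the boundary itself, so a
## difference of exactly 0.5 ms still groups no matter how the two doubles
## were produced; orders of magnitude below any real TE difference
.TOLERANCE_EPS <- 1e-12

tol_match <- function(a, b) {
  (is.na(a) & is.na(b)) |
    (!is.na(a) & !is.na(b) & abs(a - b) <= .SERIES_TOLERANCE_S + .TOLERANCE_EPS)
}

#' Group image records into series
#'
#' Scans images in deterministic order (AcquisitionDate, AcquisitionTime,
#' SeriesNumber, path) and assigns each to the first existing series whose
#' anchor (founding member) matches: identical normalized description,
#' identical ordered ImageType token sequence, and RepetitionTime and
#' EchoTime within ±0.0005 s (inclusive) of the anchor. An absent TR or TE
#' matches only an absent value. Non-matching images found a new series.
#' Series ids are consecutive integers starting at 1 in order of first
#' appearance, so they are stable across runs and input orderings.
#'
#' @param images image-record tibble.
#' @return `images` with an integer `series_id` column added.
#' @export
group_series <- function(images) {
  stopifnot(nrow(images) > 0)
  ord <- acq_order(images)
  desc <- normalize_series_description(images$series_description)

  anchors <- list()
  series_id <- integer(nrow(images))
  for (i in ord) {
    assigned <- 0L
    for (g in seq_along(anchors)) {
      a <- anchors[[g]]
      if (identical(a$desc, desc[[i]]) &&
          identical(a$image_type, images$image_type[[i]]) &&
          tol_match(a$tr, images$repetition_time[[i]]) &&
          tol_match(a$te, images$echo_time[[i]])) {
        assigned <- g
        break
      }
    }
    if (assigned == 0L) {
      anchors[[length(anchors) + 1L]] <- list(
        desc = desc[[i]],
        image_type = images$image_type[[i]],
        tr = images$repetition_time[[i]],
        te = images$echo_time[[i]]
      )
      assigned <- length(anchors)
    }
    series_id[[i]] <- assigned
  }
  images$series_id <- series_id
  images
}

## Anchor table for a grouped image set: one row per series with the
## founding member's normalized description, ImageType and timing values.
series_anchors <- function(images) {
  stopifnot("series_id" %in% names(images))
  ord <- acq_order(images)
  first <- ord[!duplicated(images$series_id[ord])]
  first <- first[order(images$series_id[first])]
  tibble::tibble(
    series_id = images$series_id[first],
    description = normalize_series_description(images$series_description[first]),
    image_type = images$image_type[first],
    repetition_time = images$repetition_time[first],
    echo_time = images$echo_time[first],
    n_members = as.integer(table(images$series_id)[as.character(images$series_id[first])])
  )
}
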