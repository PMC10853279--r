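#' @importFrom rlang %||% .data
#' @importFrom generics tidy glance
#' @import tibble
NULL

#' @export
generics::tidy

#' @export
generics::glance

#' Sanitize a candidate BIDS label
#'
#' BIDS labels may contain only `[A-Za-z0-9]`. Strips every other character;
#' an empty result is returned as `NA` so callers can fall back to
#' positional numbering.
#'
#' @param x character vector of candidate labels.
#' @return character vector of sanitized labels (`NA` where nothing
#'   survives).
#' @examples
#' sanitize_label("XY-9")   # "XY9"
#' sanitize_label("0.8 mm") # "08mm"
#' @export
sanitize_label <- function(x) {
  out <- stringr::str_remove_all(as.character(x), "[^A-Za-z0-9]")
  out[!is.na(out) & out == ""] <- NA_character_
  out
}

## Zero-pad positional labels below 10 ("01", "02", ..., "10", "11").
pad_label <- function(i) {
  ifelse(i < 10, sprintf("%02d", i), as.character(i))
}

## Case-insensitive search for an explicit sub-/ses- marker. Accepts the
## canonical hyphen plus the underscore/space dialects seen in PatientID and
## PatientName fields; the label is the maximal alphanumeric run that
## follows.
find_explicit_label <- function(x, key = c("sub", "ses")) {
  key <- match.arg(key)
  pat <- stringr::regex(paste0(key, "[-_ ]([A-Za-z0-9]+)"), ignore_case = TRUE)
  m <- stringr::str_match(as.character(x), pat)
  m[, 2]
}

## Chronological sort key: AcquisitionDate + AcquisitionTime as a sortable
## string; missing stamps sort last. Ties resolved by SeriesNumber then path
## so that input order never matters.
acq_order <- function(df) {
  stamp <- paste(
    ifelse(is.na(df$acquisition_date), "9999-99-99", df$acquisition_date),
    ifelse(is.na(df$acquisition_time), "99:99:99", df$acquisition_time)
  )
  sn <- ifelse(is.na(df$series_number), .Machine$integer.max, df$series_number)
  order(stamp, sn, df$json_path)
}

is_scalar_string <- function(x) is.character(x) && length(x) == 1L && !is.na(x)

## Format a numeric value for TSV output without binary-rounding artifacts
## (1.5 stays "1.5", never "1.4999...").
format_tsv_num <- function(x) {
  ifelse(is.na(x), "n/a", vapply(x, function(v) sprintf("%.10g", v), ""))
}
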