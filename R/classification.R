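## Datatype/suffix classification: three heuristics tried strictly in
## order, falling through to exclude so that misidentifications are left
## to the user rather than silently guessed.

tokenize_description <- function(desc) {
  toks <- stringr::str_split(tolower(desc %||% ""), "[^a-z0-9]+")[[1]]
  toks[nzchar(toks)]
}

## Heuristic 1: explicit "<datatype>_<suffix>" identifiers in the
## description (e.g. "anat_T1w"). A lone unambiguous suffix token also
## counts; a lone datatype token is remembered as partial information for
## heuristic 3.
explicit_classification <- function(desc) {
  toks <- tokenize_description(desc)
  dt <- .BIDS_DATATYPES[match(toks, .BIDS_DATATYPES, nomatch = 0L)][1]
  if (!is.na(dt)) {
    sufs <- .BIDS_SUFFIXES[[dt]]
    hit <- sufs[match(toks, tolower(sufs), nomatch = 0L)][1]
    if (!is.na(hit)) return(list(datatype = dt, suffix = hit, partial = NA_character_))
    return(list(datatype = NA_character_, suffix = NA_character_, partial = dt))
  }
  ## no datatype token: a suffix token valid for exactly one datatype
  for (tok in toks) {
    owners <- names(.BIDS_SUFFIXES)[vapply(.BIDS_SUFFIXES, function(s) tok %in% tolower(s), NA)]
    if (length(owners) == 1L) {
      suf <- .BIDS_SUFFIXES[[owners]][tolower(.BIDS_SUFFIXES[[owners]]) == tok]
      return(list(datatype = owners, suffix = suf, partial = NA_character_))
    }
  }
  list(datatype = NA_character_, suffix = NA_character_, partial = NA_character_)
}

## Heuristic 2: case-insensitive keyphrase substring match, highest
## priority wins (ties: longest pattern, then table order). Entries whose
## datatype contradicts partial explicit information are skipped.
keyphrase_classification <- function(desc, lexicon, partial = NA_character_) {
  low <- tolower(desc %||% "")
  hit <- lexicon[stringr::str_detect(low, stringr::fixed(lexicon$pattern)), ]
  if (!is.na(partial)) hit <- hit[hit$datatype == partial, ]
  if (!nrow(hit)) return(NULL)
  hit <- hit[order(-hit$priority, -nchar(hit$pattern)), ]
  hit[1, ]
}

## phasediff-family field maps are disambiguated by ImageType P/M tokens
## and EchoNumber when the lexicon alone cannot tell phase from magnitude.
refine_fmap <- function(suffix, image_type, echo_number) {
  if (suffix != "phasediff") return(suffix)
  if ("P" %in% image_type) return("phasediff")
  if ("M" %in% image_type) {
    if (!is.na(echo_number) && echo_number >= 2L) return("magnitude2")
    return("magnitude1")
  }
  suffix
}

classify_one <- function(desc, image_type, echo_time, echo_number, lexicon) {
  excluded <- list(datatype = "exclude", suffix = "", heuristic = "none", include = FALSE)

  ex <- explicit_classification(desc)
  if (!is.na(ex$datatype)) {
    return(list(datatype = ex$datatype, suffix = ex$suffix,
                heuristic = "explicit", include = TRUE))
  }

  kp <- keyphrase_classification(desc, lexicon, ex$partial)
  if (!is.null(kp)) {
    suffix <- if (kp$datatype == "fmap") refine_fmap(kp$suffix, image_type, echo_number) else kp$suffix
    return(list(datatype = kp$datatype, suffix = suffix,
                heuristic = "keyphrase", include = TRUE))
  }

  ## Heuristic 3: metadata. "DIFFUSION" in ImageType marks diffusion data;
  ## an anatomical series with no suffix cue and an EchoTime exceeding
  ## 100 ms (strictly greater) is taken to be T2-weighted.
  if ("DIFFUSION" %in% image_type) {
    return(list(datatype = "dwi", suffix = "dwi", heuristic = "metadata", include = TRUE))
  }
  if (identical(ex$partial, "anat") && !is.na(echo_time) && echo_time > 0.100) {
    return(list(datatype = "anat", suffix = "T2w", heuristic = "metadata", include = TRUE))
  }
  excluded
}

#' Classify each series into a BIDS datatype and suffix
#'
#' Applies the three-heuristic chain to every series anchor, strictly in
#' order: (1) an explicit datatype/suffix identifier in the
#' SeriesDescription (e.g. `anat_T1w`); (2) a keyphrase lexicon match
#' (e.g. `tfl3d` denotes a T1w anatomical); (3) metadata rules —
#' `DIFFUSION` in ImageType implies `dwi/dwi`, and an anatomical series
#' with no suffix keyword and EchoTime strictly above 100 ms is assumed
#' T2w. When every heuristic fails the series is set to `exclude` and left
#' to the user, which limits silent misidentification.
#'
#' @param images image-record tibble carrying `series_id` (see
#'   [group_series()]).
#' @param lexicon keyphrase table (default [default_lexicon()]).
#' @return `images` with `datatype`, `suffix`, `heuristic` and logical
#'   `include` columns added (shared by all members of a series).
#' @export
classify_series <- function(images, lexicon = default_lexicon()) {
  anchors <- series_anchors(images)
  first_idx <- match(anchors$series_id, images$series_id)
  res <- purrr::pmap(
    list(anchors$description, anchors$image_type, anchors$echo_time,
         images$echo_number[first_idx]),
    function(d, it, te, en) classify_one(d, it, te, en, lexicon)
  )
  cls <- tibble::tibble(
    series_id = anchors$series_id,
    datatype = purrr::map_chr(res, "datatype"),
    suffix = purrr::map_chr(res, "suffix"),
    heuristic = purrr::map_chr(res, "heuristic"),
    include = purrr::map_lgl(res, "include")
  )
  dplyr::left_join(images, cls, by = "series_id")
}
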