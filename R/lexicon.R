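#' Keyphrase lexicon for datatype/suffix classification
#'
#' The second classification heuristic searches `SeriesDescription` for
#' keyphrases commonly used in MRI protocol names (for example `tfl3d` or
#' `mprage` denote a T1-weighted anatomical). The lexicon is a maintained,
#' editable table: each row maps a lowercase substring pattern to a
#' datatype/suffix pair with a priority (higher wins when several patterns
#' match).
#'
#' `default_lexicon()` loads the table shipped with the package;
#' `read_lexicon()` loads a user-maintained table from a tab-separated file
#' with columns `pattern`, `datatype`, `suffix`, `priority`.
#'
#' @param path path to a tab-separated lexicon file.
#' @return a tibble with columns `pattern`, `datatype`, `suffix`,
#'   `priority`, validated against the embedded schema snapshot.
#' @examples
#' default_lexicon()
#' @export
default_lexicon <- function() {
  read_lexicon(system.file("extdata", "lexicon.tsv", package = "bidsmapr"))
}

#' @rdname default_lexicon
#' @export
read_lexicon <- function(path) {
  lex <- readr::read_tsv(path, col_types = readr::cols(
    pattern = readr::col_character(),
    datatype = readr::col_character(),
    suffix = readr::col_character(),
    priority = readr::col_integer()
  ))
  lex$pattern <- tolower(lex$pattern)
  if (anyDuplicated(lex$pattern)) {
    stop("lexicon patterns must be unique: ",
         paste(unique(lex$pattern[duplicated(lex$pattern)]), collapse = ", "))
  }
  ok <- mapply(is_valid_pair, lex$datatype, lex$suffix)
  if (!all(ok)) {
    stop("lexicon rows with schema-invalid datatype/suffix: ",
         paste(lex$pattern[!ok], collapse = ", "))
  }
  lex
}
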