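#' @keywords internal
"_PACKAGE"

## Static snapshot of the BIDS specification schema used throughout the
## package: which suffixes each datatype admits, the canonical entity order,
## and the per-suffix entity requirements. Pinned to one BIDS version so that
## classification, filename rendering and validation agree with each other.

.BIDS_VERSION <- "1.8.0"

.BIDS_DATATYPES <- c("anat", "func", "fmap", "dwi", "perf")

.BIDS_SUFFIXES <- list(
  anat = c(
    "T1w", "T2w", "FLAIR", "PDw", "T2starw", "T1rho", "T1map", "T2map",
    "T2starmap", "PDmap", "MTRmap", "UNIT1", "MP2RAGE", "angio",
    "inplaneT1", "inplaneT2", "defacemask"
  ),
  func = c("bold", "sbref", "cbv", "phase"),
  fmap = c(
    "phasediff", "phase1", "phase2", "magnitude1", "magnitude2",
    "magnitude", "fieldmap", "epi"
  ),
  dwi  = c("dwi", "sbref"),
  perf = c("asl", "m0scan")
)

## Canonical entity ordering (subset of the specification's entity table that
## MRI datatypes use). sub first, ses second; the rest follow the mandated
## total order.
.BIDS_ENTITY_ORDER <- c(
  "sub", "ses", "task", "acq", "ce", "rec", "dir", "run",
  "mod", "echo", "flip", "inv", "mt", "part"
)

## Entities that MUST be present for a given datatype/suffix pair. Kept
## deliberately small: the rules the validation engine enforces.
.BIDS_REQUIRED_ENTITIES <- list(
  "func/bold"  = "task",
  "func/sbref" = "task",
  "func/cbv"   = "task",
  "fmap/epi"   = "dir"
)

## PhaseEncodingDirection token -> human direction label, assuming
## RAS-oriented axes. Orientation-dependent by construction; documented in
## the methods vignette.
.PED_DIRECTION <- c(
  "i" = "LR", "i-" = "RL",
  "j" = "PA", "j-" = "AP",
  "k" = "IS", "k-" = "SI"
)

#' BIDS schema snapshot tables
#'
#' Accessors for the embedded, version-pinned snapshot of the BIDS
#' specification schema: valid datatype/suffix pairs, the canonical entity
#' ordering used when rendering filenames, and the entity requirements the
#' validator enforces.
#'
#' @return `bids_schema_version()` a version string; `bids_suffixes()` a
#'   tibble with columns `datatype` and `suffix`; `bids_entity_order()` a
#'   character vector of entity keys in canonical order.
#' @examples
#' bids_schema_version()
#' bids_suffixes()
#' bids_entity_order()
#' @export
bids_schema_version <- function() .BIDS_VERSION

#' @rdname bids_schema_version
#' @export
bids_suffixes <- function() {
  tibble::tibble(
    datatype = rep(names(.BIDS_SUFFIXES), lengths(.BIDS_SUFFIXES)),
    suffix   = unlist(.BIDS_SUFFIXES, use.names = FALSE)
  )
}

#' @rdname bids_schema_version
#' @export
bids_entity_order <- function() .BIDS_ENTITY_ORDER

is_valid_pair <- function(datatype, suffix) {
  datatype %in% names(.BIDS_SUFFIXES) && suffix %in% .BIDS_SUFFIXES[[datatype]]
}

required_entities_for <- function(datatype, suffix) {
  .BIDS_REQUIRED_ENTITIES[[paste(datatype, suffix, sep = "/")]] %||% character()
}

#' Direction label implied by a PhaseEncodingDirection token
#'
#' Maps the sidecar `PhaseEncodingDirection` token (`i`, `i-`, `j`, `j-`,
#' `k`, `k-`) to the direction entity label it implies under RAS-oriented
#' axes (`LR`, `RL`, `PA`, `AP`, `IS`, `SI`).
#'
#' @param ped character vector of direction tokens.
#' @return character vector of direction labels; `NA` for unknown tokens.
#' @examples
#' ped_to_direction(c("j-", "j"))
#' @export
ped_to_direction <- function(ped) {
  out <- unname(.PED_DIRECTION[ped])
  out
}
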