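## In-memory image-record builder: most pipeline stages operate on the
## record tibble directly, so tests rarely need to touch disk.
make_image <- function(json_path = "s/img.json",
                       nifti_path = sub("\\.json$", ".nii.gz", json_path),
                       desc = "T1w_MPRAGE",
                       image_type = c("ORIGINAL", "PRIMARY", "M"),
                       tr = 2.3, te = 0.003,
                       echo_number = NA_integer_,
                       patient_id = NA_character_,
                       patient_name = NA_character_,
                       patient_birthdate = NA_character_,
                       date = "2023-03-01", time = "09:00:00",
                       series_number = 1L,
                       ped = NA_character_,
                       volumes = 1L,
                       extra = list()) {
  tibble::tibble(
    json_path = json_path, nifti_path = nifti_path,
    series_description = desc, image_type = list(image_type),
    repetition_time = tr, echo_time = te,
    echo_number = as.integer(echo_number),
    patient_id = patient_id, patient_name = patient_name,
    patient_birthdate = patient_birthdate,
    acquisition_date = date, acquisition_time = time,
    series_number = as.integer(series_number),
    phase_encoding_direction = ped,
    volume_count = as.integer(volumes), extra_metadata = list(extra)
  )
}

## A pair of otherwise-identical records whose EchoTime differs by `delta`.
te_pair <- function(delta, te = 0.03) {
  dplyr::bind_rows(
    make_image(json_path = "a.json", te = te, series_number = 1L),
    make_image(json_path = "b.json", te = te + delta, series_number = 2L,
               time = "09:05:00")
  )
}

## Independent brute-force partitioner for the grouping oracle: repeatedly
## take the first unassigned record (in deterministic scan order) as an
## anchor and collect everything that matches it. Shares only the matching
## *rule* with group_series, not its code path.
brute_force_partition <- function(images) {
  stamp <- paste(
    ifelse(is.na(images$acquisition_date), "9999-99-99", images$acquisition_date),
    ifelse(is.na(images$acquisition_time), "99:99:99", images$acquisition_time)
  )
  sn <- ifelse(is.na(images$series_number), .Machine$integer.max, images$series_number)
  ord <- order(stamp, sn, images$json_path)
  norm <- sub("_[Rr][Rr]$", "", images$series_description)
  same <- function(i, j) {
    near <- function(a, b) (is.na(a) && is.na(b)) ||
      (!is.na(a) && !is.na(b) && abs(a - b) <= 0.0005 + 1e-12)
    identical(norm[[i]], norm[[j]]) &&
      identical(images$image_type[[i]], images$image_type[[j]]) &&
      near(images$repetition_time[[i]], images$repetition_time[[j]]) &&
      near(images$echo_time[[i]], images$echo_time[[j]])
  }
  id <- rep(NA_integer_, nrow(images))
  g <- 0L
  for (i in ord) {
    if (!is.na(id[[i]])) next
    g <- g + 1L
    for (j in ord) if (is.na(id[[j]]) && same(i, j)) id[[j]] <- g
  }
  id
}

## All permutations of 1..n (n small).
permutations <- function(n) {
  if (n == 1L) return(list(1L))
  out <- list()
  for (p in permutations(n - 1L)) {
    for (k in seq_len(n)) {
      out[[length(out) + 1L]] <- append(p, n, after = k - 1L)
    }
  }
  out
}

## Partition signature keyed by path so series ids can be compared across
## input orderings.
partition_by_path <- function(paths, ids) {
  split(paths, ids) |> lapply(sort) |> (\(x) unname(x[order(vapply(x, `[[`, "", 1))]))()
}

## Run the propose pipeline directly on an in-memory image tibble.
propose_images <- function(images, ...) {
  bundle <- structure(
    list(images = images, timing_candidates = character(),
         template_path = NA_character_, root = "<memory>"),
    class = "bids_bundle"
  )
  propose(bundle, ...)
}

clean_session_root <- function(...) {
  generate_session(session_spec(...), tempfile("fixture_"))
}
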