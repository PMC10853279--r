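test_that("description normalization strips only a trailing _RR", {
  expect_equal(normalize_series_description("T1_MPRAGE_RR"), "T1_MPRAGE")
  expect_equal(normalize_series_description("T1_MPRAGE"), "T1_MPRAGE")
  expect_equal(normalize_series_description("RR_T1"), "RR_T1")
  expect_equal(normalize_series_description("T1_rr"), "T1")
})

test_that("the EchoTime tolerance boundary is +/- 0.0005 s inclusive", {
  ## the documented float-precision example pair groups together
  expect_equal(dplyr::n_distinct(group_series(te_pair(0.030001 - 0.03))$series_id), 1L)
  ## exactly at the boundary: one group; just beyond: two
  expect_equal(dplyr::n_distinct(group_series(te_pair(0.0005))$series_id), 1L)
  expect_equal(dplyr::n_distinct(group_series(te_pair(0.0006))$series_id), 2L)

  ## probe a fine delta grid against the brute-force partitioner
  for (delta in seq(0, 0.002, by = 0.0001)) {
    pair <- te_pair(delta)
    expect_equal(group_series(pair)$series_id, brute_force_partition(pair),
                 info = paste("delta =", delta))
  }
})

test_that("exactly the four key fields decide grouping", {
  base <- function(n = 2) dplyr::bind_rows(lapply(seq_len(n), function(i) {
    make_image(json_path = sprintf("img%d.json", i), series_number = i,
               extra = list(FlipAngle = 8))
  }))

  same <- base()
  expect_equal(dplyr::n_distinct(group_series(same)$series_id), 1L)

  p <- base(); p$series_description[[2]] <- "other_scan"
  expect_equal(dplyr::n_distinct(group_series(p)$series_id), 2L)
  p <- base(); p$image_type[[2]] <- c("DERIVED", "PRIMARY", "M")
  expect_equal(dplyr::n_distinct(group_series(p)$series_id), 2L)
  p <- base(); p$repetition_time[[2]] <- p$repetition_time[[2]] + 0.1
  expect_equal(dplyr::n_distinct(group_series(p)$series_id), 2L)
  p <- base(); p$echo_time[[2]] <- p$echo_time[[2]] + 0.1
  expect_equal(dplyr::n_distinct(group_series(p)$series_id), 2L)

  ## non-key metadata never splits a group
  p <- base(); p$extra_metadata[[2]] <- list(FlipAngle = 90)
  p$volume_count[[2]] <- 10L
  p$phase_encoding_direction[[2]] <- "j-"
  expect_equal(dplyr::n_distinct(group_series(p)$series_id), 1L)

  ## absent TR/TE matches only absent
  p <- base(); p$echo_time[[2]] <- NA_real_
  expect_equal(dplyr::n_distinct(group_series(p)$series_id), 2L)
})

test_that("_RR reconstructions join their parent series", {
  imgs <- dplyr::bind_rows(
    make_image(json_path = "a.json", desc = "T1_MPRAGE"),
    make_image(json_path = "b.json", desc = "T1_MPRAGE_RR", series_number = 2L)
  )
  expect_equal(dplyr::n_distinct(group_series(imgs)$series_id), 1L)
})

test_that("grouping equals the brute-force oracle on every permutation of a mixed fixture", {
  imgs <- dplyr::bind_rows(
    make_image(json_path = "a.json", desc = "scanA", te = 0.0300, series_number = 1L),
    make_image(json_path = "b.json", desc = "scanA", te = 0.0304, series_number = 2L),
    make_image(json_path = "c.json", desc = "scanA", te = 0.0308, series_number = 3L),
    make_image(json_path = "d.json", desc = "scanA_RR", te = 0.0300, series_number = 4L),
    make_image(json_path = "e.json", desc = "scanB", te = 0.0300, series_number = 5L),
    make_image(json_path = "f.json", desc = "scanA", te = 0.0300,
               image_type = c("DERIVED", "PRIMARY"), series_number = 6L)
  )
  ref <- partition_by_path(imgs$json_path, brute_force_partition(imgs))
  for (perm in permutations(6L)) {
    shuffled <- imgs[unlist(perm), ]
    got <- group_series(shuffled)
    expect_equal(partition_by_path(got$json_path, got$series_id), ref)
  }
  ## within-group TR/TE spread never exceeds twice the anchor tolerance
  got <- group_series(imgs)
  for (g in split(got, got$series_id)) {
    expect_lte(diff(range(g$echo_time)), 0.001)
    expect_lte(diff(range(g$repetition_time)), 0.001)
  }
})

test_that("series ids are consecutive from 1 in first-appearance order", {
  imgs <- dplyr::bind_rows(
    make_image(json_path = "a.json", desc = "first", series_number = 1L),
    make_image(json_path = "b.json", desc = "second", series_number = 2L),
    make_image(json_path = "c.json", desc = "first", series_number = 3L)
  )
  expect_equal(group_series(imgs)$series_id, c(1L, 2L, 1L))
})
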