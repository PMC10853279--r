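pipeline_to_entities <- function(imgs, lexicon = default_lexicon()) {
  imgs |> infer_subjects() |> infer_sessions() |> group_series() |>
    classify_series(lexicon) |> extract_entities()
}

test_that("entities are parsed from _key- tokens and metadata", {
  out <- pipeline_to_entities(make_image(desc = "func_task-bart_run-01_bold",
                                         volumes = 150L))
  expect_equal(out$entities[[1]]$task, "bart")
  expect_equal(out$entities[[1]]$run, "01")

  out <- pipeline_to_entities(make_image(desc = "anat_T1w", echo_number = 2L))
  expect_equal(out$entities[[1]]$echo, "2")

  out <- pipeline_to_entities(make_image(desc = "anat_T1w"))
  expect_equal(length(out$entities[[1]]), 0L)

  ## fmap/epi derives its dir entity from PhaseEncodingDirection
  out <- pipeline_to_entities(make_image(desc = "SpinEchoFieldMap", ped = "j-"))
  expect_equal(out$entities[[1]]$dir, "AP")

  ## rest bold without explicit task token gets task-rest
  out <- pipeline_to_entities(make_image(desc = "rest_fmri", volumes = 150L))
  expect_equal(out$entities[[1]]$task, "rest")
})

test_that("run numbering applies on collision, chronologically, tie-broken by SeriesNumber", {
  two_runs <- dplyr::bind_rows(
    make_image(json_path = "s/a.json", desc = "task-rest_bold", volumes = 150L,
               time = "10:00:00", series_number = 4L),
    make_image(json_path = "s/b.json", desc = "task-rest_bold", volumes = 150L,
               time = "10:10:00", series_number = 6L)
  )
  core <- propose_images(two_runs)
  runs <- vapply(core$objects$entities, function(e) e$run, "")
  expect_equal(runs[order(core$objects$acquisition_time)], c("01", "02"))

  ## identical times: lower SeriesNumber is run-01
  tie <- two_runs
  tie$acquisition_time <- "10:00:00"
  core2 <- propose_images(tie)
  runs2 <- vapply(core2$objects$entities, function(e) e$run, "")
  expect_equal(runs2[order(core2$objects$series_number)], c("01", "02"))

  ## a single image never receives a run entity
  single <- propose_images(make_image(desc = "anat_T1w"))
  expect_null(single$objects$entities[[1]]$run)
})

test_that("rendering follows the canonical grammar", {
  expect_equal(render_bids_path("01", "01", "anat", "T1w"),
               "sub-01/ses-01/anat/sub-01_ses-01_T1w.nii.gz")
  expect_equal(render_bids_path("01", NA, "anat", "T1w", list(acq = "mprage")),
               "sub-01/anat/sub-01_acq-mprage_T1w.nii.gz")
  ## entities rendered in canonical order regardless of supply order
  expect_equal(
    render_bids_path("01", NA, "func", "bold",
                     list(run = "02", task = "bart", acq = "mb")),
    "sub-01/func/sub-01_task-bart_acq-mb_run-02_bold.nii.gz"
  )
  expect_error(render_bids_path("01", NA, "anat", "T1w", list(acq = "0.8 mm")),
               "alphanumeric")
  expect_error(render_bids_path("01", NA, "anat", "T1w", list(banana = "x")),
               "unknown entity")
  expect_error(render_bids_path("01", NA, "anat", "bold"), "schema-invalid")
})

test_that("render/parse round-trips over random schema-valid assignments", {
  schema <- bids_suffixes()
  keys <- setdiff(bids_entity_order(), c("sub", "ses"))
  set.seed(11)
  rand_label <- function() {
    paste(sample(c(LETTERS, letters, 0:9), sample(1:8, 1), replace = TRUE),
          collapse = "")
  }
  for (i in 1:1000) {
    row <- schema[sample(nrow(schema), 1), ]
    subject <- rand_label()
    session <- if (runif(1) < 0.5) rand_label() else NA
    n_ent <- sample(0:4, 1)
    ent <- stats::setNames(
      lapply(seq_len(n_ent), function(j) rand_label()),
      sample(keys, n_ent)
    )
    path <- render_bids_path(subject, session, row$datatype, row$suffix, ent)
    back <- parse_bids_path(path)
    expect_equal(back$subject, subject)
    expect_equal(back$session, if (is.na(session)) NA_character_ else session)
    expect_equal(back$datatype, row$datatype)
    expect_equal(back$suffix, row$suffix)
    expect_equal(back$entities[order(names(back$entities))],
                 lapply(ent, as.character)[order(names(ent))])
  }
})

test_that("no two included objects of a proposed dataset share a rendered path", {
  core <- propose(clean_session_root(n_subjects = 3))
  paths <- tidy(core)$bids_path
  paths <- paths[!is.na(paths)]
  expect_equal(anyDuplicated(paths), 0L)
})
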