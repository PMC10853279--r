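test_that("a clean fixture dataset yields zero internal errors", {
  core <- propose(clean_session_root(n_subjects = 2))
  expect_equal(sum(core$issues$severity == "error"), 0L)
})

test_that("a bold series without a task entity is an error", {
  imgs <- make_image(desc = "fmri_scan", volumes = 150L) # bold via keyphrase, no task
  core <- propose_images(imgs)
  expect_true(any(core$issues$code == "missing-required-entity" &
                    core$issues$severity == "error"))
})

test_that("non-alphanumeric entity values are flagged as errors", {
  core <- propose(clean_session_root(n_subjects = 1))
  t1 <- core$series$series_id[core$series$suffix == "T1w"][[1]]
  core2 <- apply_edits(core, edit_script(series = list(
    list(series_id = t1, entities = list(acq = "0.8 mm"))
  )))
  bad <- core2$issues[core2$issues$code == "bad-entity-charset", ]
  expect_equal(unique(bad$severity), "error")
  expect_gte(nrow(bad), 1L)
  ## errors block assembly unless forced
  expect_error(write_bids(core2, tempfile()), "validation errors")
})

test_that("a dir entity contradicting PhaseEncodingDirection is a warning with the implied label", {
  menu <- tibble::tibble(
    description = "SpinEchoFieldMap_dir-PA",
    image_type = list(c("ORIGINAL", "PRIMARY", "M")),
    tr = 8, te = 0.066, volume_count = 3L, n_runs = 1L, ped = "j-", events = FALSE
  )
  root <- generate_session(session_spec(n_subjects = 1, series_menu = menu),
                           tempfile())
  core <- propose(root)
  w <- core$issues[core$issues$code == "dir-mismatch", ]
  expect_equal(nrow(w), 1L)
  expect_equal(w$severity, "warning")
  expect_match(w$message, "'AP'")
  ## warnings never block assembly
  expect_no_error(write_bids(core, tempfile()))
})

test_that("duplicate rendered paths are errors", {
  imgs <- dplyr::bind_rows(
    make_image(json_path = "s/a.json", desc = "anat_T1w", series_number = 1L),
    make_image(json_path = "s/b.json", desc = "anat_T1w_RR", series_number = 2L)
  )
  core <- propose_images(imgs)
  ## same series, two objects: run numbering keeps them apart; force a
  ## duplicate via object-level run overrides
  core2 <- apply_edits(core, edit_script(objects = list(
    list(nifti_path = "s/b.nii.gz", entities = list(run = "01")),
    list(nifti_path = "s/a.nii.gz", entities = list(run = "01"))
  )))
  expect_true(any(core2$issues$code == "duplicate-path" &
                    core2$issues$severity == "error"))
})

test_that("low-volume 4D functional series are auto-excluded with a warning", {
  imgs <- make_image(desc = "task-bart_bold", volumes = 10L)
  core <- propose_images(imgs)
  expect_false(core$objects$include[[1]])
  expect_true(any(core$issues$code == "low-volume"))
  expect_equal(unique(core$issues$severity[core$issues$code == "low-volume"]),
               "warning")

  ## threshold is configurable
  core5 <- propose_images(imgs, min_volumes = 5L)
  expect_true(core5$objects$include[[1]])

  ## un-excluding keeps the data but retains the warning
  core3 <- apply_edits(core, edit_script(objects = list(
    list(nifti_path = imgs$nifti_path[[1]], include = TRUE)
  )))
  expect_true(core3$objects$include[[1]])
  expect_true(any(core3$issues$code == "low-volume"))
})

test_that("excluding a BOLD image orphans its events file as a warning", {
  root <- clean_session_root(n_subjects = 1)
  core <- propose(root)
  bold <- core$objects$nifti_path[
    vapply(core$objects$entities, function(e) identical(e$task, "bart") &&
             identical(e$run, "01"), NA)]
  core2 <- apply_edits(core, edit_script(objects = list(
    list(nifti_path = bold, include = FALSE)
  )))
  expect_true(any(core2$issues$code == "orphan-events"))
  expect_equal(unique(core2$issues$severity[core2$issues$code == "orphan-events"]),
               "warning")
})

test_that("guided metadata rules enforce types and dependencies", {
  expect_equal(nrow(check_metadata_rules("asl", list(BackgroundSuppression = FALSE))), 0L)
  bad_type <- check_metadata_rules("asl", list(BackgroundSuppression = "yes"))
  expect_equal(bad_type$code, "metadata-type")
  expect_equal(bad_type$severity, "error")
  dep <- check_metadata_rules("asl", list(BolusCutOffFlag = TRUE))
  expect_equal(dep$code, "metadata-dependency")
  both <- check_metadata_rules("asl", list(BolusCutOffFlag = TRUE,
                                           BolusCutOffTechnique = "QUIPSSII"))
  expect_equal(nrow(both), 0L)
})

test_that("removing an object never creates new errors about the others", {
  core <- propose(clean_session_root(n_subjects = 2))
  baseline_err <- core$issues[core$issues$severity == "error", ]
  for (path in core$objects$nifti_path[core$objects$include][1:4]) {
    core2 <- apply_edits(core, edit_script(objects = list(
      list(nifti_path = path, include = FALSE)
    )))
    new_err <- core2$issues[core2$issues$severity == "error", ]
    expect_equal(nrow(new_err), nrow(baseline_err))
  }
})
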