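test_that("export/apply replays a session's decisions onto an identical session", {
  root_a <- clean_session_root(n_subjects = 1, seed = 1)
  core_a <- propose(root_a)
  t1 <- core_a$series$series_id[core_a$series$suffix == "T1w"][[1]]
  core_a <- apply_edits(core_a, edit_script(series = list(
    list(series_id = t1, entities = list(acq = "mprage"))
  )))
  tpl <- export_template(core_a)

  root_b <- clean_session_root(n_subjects = 1, seed = 2)
  core_b <- propose(root_b, template = tpl)

  ## assignments agree series-by-series (labels/paths are session-specific)
  key <- function(core) {
    ord <- order(core$series$description)
    s <- core$series[ord, ]
    paste(s$description, s$datatype, s$suffix, s$include,
          vapply(seq_len(nrow(s)), function(i) {
            ent <- core$objects$entities[[match(s$series_id[[i]], core$objects$series_id)]]
            ent <- ent[setdiff(names(ent), "run")]
            paste(names(ent), unlist(ent), sep = "-", collapse = ",")
          }, ""))
  }
  expect_equal(key(core_b), key(core_a))
  ## the captured series-level edit was replayed
  acq <- vapply(core_b$objects$entities[core_b$objects$series_id ==
                  core_b$series$series_id[core_b$series$suffix == "T1w"][[1]]],
                function(e) e$acq %||% "", "")
  expect_true(all(acq == "mprage"))
})

test_that("templates round-trip through JSON and refuse incompatible versions", {
  core <- propose(clean_session_root(n_subjects = 1))
  tpl <- export_template(core)
  path <- tempfile(fileext = ".json")
  write_template(tpl, path)
  back <- read_template(path)
  expect_equal(back$series, tpl$series)
  expect_equal(back$dataset_description, tpl$dataset_description)

  doc <- jsonlite::fromJSON(path, simplifyVector = FALSE)
  doc$template_version <- "99.0"
  jsonlite::write_json(doc, path, auto_unbox = TRUE, null = "null")
  expect_error(read_template(path), "incompatible")
})

test_that("TR/TE signature matching uses the grouping tolerance", {
  core <- propose_images(make_image(desc = "mystery_scan", te = 0.0300))
  core <- apply_edits(core, edit_script(series = list(
    list(series_id = 1L, datatype = "anat", suffix = "FLAIR", include = TRUE)
  )))
  tpl <- export_template(core)

  within <- propose_images(make_image(desc = "mystery_scan", te = 0.0304),
                           template = tpl)
  expect_equal(within$series$suffix, "FLAIR")

  beyond <- propose_images(make_image(desc = "mystery_scan", te = 0.0308),
                           template = tpl)
  expect_equal(beyond$series$datatype, "exclude")
})

test_that("unmatched series fall through to fresh inference", {
  core <- propose(clean_session_root(n_subjects = 1))
  tpl <- export_template(core)
  extra <- dplyr::bind_rows(
    discover_inputs(clean_session_root(n_subjects = 1))$images,
    make_image(json_path = "novel.json", desc = "anat_FLAIR", series_number = 99L,
               date = "2023-03-01", time = "12:00:00",
               patient_id = "S001", patient_name = "volunteer001",
               patient_birthdate = "1971-06-15")
  )
  core2 <- propose_images(extra, template = tpl)
  novel <- core2$series[core2$series$description == "anat_FLAIR", ]
  expect_equal(novel$suffix, "FLAIR")
  expect_equal(novel$heuristic, "explicit")
})

test_that("a template never overrides object-level excludes in the new session", {
  core <- propose(clean_session_root(n_subjects = 1))
  tpl <- export_template(core)
  core2 <- propose(clean_session_root(n_subjects = 1, seed = 5), template = tpl)
  target <- core2$objects$nifti_path[core2$objects$include][[1]]
  core3 <- apply_edits(core2, edit_script(objects = list(
    list(nifti_path = target, include = FALSE)
  )))
  expect_false(core3$objects$include[core3$objects$nifti_path == target])
})

test_that("indistinguishable series signatures refuse to export", {
  imgs <- dplyr::bind_rows(
    make_image(json_path = "a.json", desc = "dup_scan", te = 0.030, series_number = 1L),
    make_image(json_path = "b.json", desc = "dup_scan", te = 0.031, series_number = 2L)
  )
  core <- propose_images(imgs) # two series, TE 1 ms apart
  expect_equal(nrow(core$series), 2L)
  ## 1 ms apart is outside the matching tolerance: exportable
  expect_no_error(export_template(core))
  ## force the two signatures within tolerance of each other: ambiguous
  core$series$echo_time[[2]] <- core$series$echo_time[[1]] + 0.0002
  expect_error(export_template(core), "indistinguishable")
})
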