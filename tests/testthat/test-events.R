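test_that("timing files parse across formats with identical content", {
  tab_path <- function(fmt) {
    p <- tempfile(fileext = paste0(".", fmt))
    generate_timing_table(5, units = "seconds", seed = 3, format = fmt, path = p)
    p
  }
  ref <- parse_timing_file(tab_path("csv"))
  expect_equal(ref$header, c("onset", "duration", "trial_type"))
  expect_equal(nrow(ref$rows), 5L)
  for (fmt in c("tsv", "txt", "out", "xlsx")) {
    other <- parse_timing_file(tab_path(fmt))
    expect_equal(other$header, ref$header, info = fmt)
    expect_equal(as.data.frame(other$rows), as.data.frame(ref$rows), info = fmt)
  }
  expect_error(parse_timing_file(tempfile(fileext = ".docx")), "extension")
})

test_that("entity hints come from path tokens and subject-synonym columns", {
  dir <- tempfile(); dir.create(file.path(dir, "sub-01", "ses-01"), recursive = TRUE)
  p <- file.path(dir, "sub-01", "ses-01", "task-bart_run-01.tsv")
  writeLines(c("onset\tduration", "1\t0.5"), p)
  h <- parse_timing_file(p)$entity_hints
  expect_equal(h[c("sub", "ses", "task", "run")],
               list(sub = "01", ses = "01", task = "bart", run = "01"))

  p2 <- tempfile(fileext = ".csv")
  writeLines(c("Subject,onset,duration", "07,1.0,0.5", "07,2.0,0.5"), p2)
  expect_equal(parse_timing_file(p2)$entity_hints$sub, "07")
})

test_that("the column map converts milliseconds exactly and orders columns", {
  p <- tempfile(fileext = ".csv")
  writeLines(c("cond,onset_ms,dur_ms",
               "go,1500,500",
               "stop,2750,1250"), p)
  tf <- parse_timing_file(p)
  cmap <- events_column_map(
    onset = "onset_ms", duration = "dur_ms", trial_type = "cond",
    time_units = c(onset = "milliseconds", duration = "milliseconds")
  )
  ev <- apply_column_map(tf, cmap)
  expect_equal(names(ev), c("onset", "duration", "trial_type"))
  expect_identical(ev$onset, c(1.5, 2.75))
  expect_identical(ev$duration, c(0.5, 1.25))

  ## exactness on every 3-decimal millisecond input
  p3 <- tempfile(fileext = ".csv")
  vals <- c(1, 7, 123, 999, 1500, 86399999)
  writeLines(c("onset_ms,dur_ms", paste(vals, vals, sep = ",")), p3)
  ev3 <- apply_column_map(parse_timing_file(p3),
                          events_column_map(onset = "onset_ms", duration = "dur_ms",
                                            time_units = c(onset = "milliseconds",
                                                           duration = "milliseconds")))
  expect_identical(ev3$onset, vals / 1000)
  out <- tempfile(); write_events_tsv(ev3, out)
  expect_equal(readLines(out)[[2]], "0.001\t0.001")

  ## seconds pass through untouched; missing mapped column errors by name
  cmap_s <- events_column_map(onset = "onset", duration = "missing_col")
  tf_s <- parse_timing_file(p)
  expect_error(apply_column_map(tf_s, cmap_s), "onset")
  expect_error(events_column_map(onset = "a"), "duration")
})

test_that("unmapped source columns are preserved after the mapped ones", {
  p <- tempfile(fileext = ".csv")
  writeLines(c("onset,duration,extra1,extra2", "1,0.5,a,b"), p)
  ev <- apply_column_map(parse_timing_file(p),
                         events_column_map(onset = "onset", duration = "duration"))
  expect_equal(names(ev), c("onset", "duration", "extra1", "extra2"))
})

test_that("events files link one-to-one to BOLD runs via entity convergence", {
  root <- clean_session_root(n_subjects = 2)
  core <- propose(root)
  ev <- core$events
  expect_equal(nrow(ev), 4L) # 2 subjects x 2 task runs
  expect_true(all(!is.na(ev$linked_nifti)))
  expect_true(all(!ev$placeholder))
  ## a linked timing file inherits the BOLD image's SeriesNumber
  j <- match(ev$linked_nifti, core$objects$nifti_path)
  expect_identical(ev$series_number, core$objects$series_number[j])
  ## agreement on every available entity
  for (i in seq_len(nrow(ev))) {
    h <- core$timing_files[[i]]$entity_hints
    expect_equal(ev$subject[[i]], h$sub)
    expect_equal(ev$task[[i]], h$task)
    if (!is.null(h$run)) expect_equal(ev$run[[i]], h$run)
  }
  ## rest BOLD images never receive events files
  rest <- vapply(core$objects$entities,
                 function(e) identical(e$task, "rest"), NA)
  expect_false(any(ev$linked_nifti %in% core$objects$nifti_path[rest]))
})

test_that("unresolvable hints yield per-entity placeholders", {
  root <- clean_session_root(n_subjects = 2)
  core <- propose(root)
  ## a timing file with no subject hint in a 2-subject dataset is ambiguous
  tf <- core$timing_files[[1]]
  tf$path <- "task-bart_run-01.csv"
  tf$entity_hints$sub <- NULL
  links <- link_events_to_bold(list(tf), core$objects)
  expect_equal(links$subject, "XX1")
  expect_true(links$placeholder)
  expect_true(is.na(links$linked_nifti))

  ## two files resolving to the same BOLD violate the one-to-one mapping
  dup <- core$timing_files[c(1, 1)]
  links2 <- link_events_to_bold(dup, core$objects)
  expect_false(links2$collision[[1]])
  expect_true(links2$collision[[2]])
  expect_true(is.na(links2$linked_nifti[[2]]))
  core_dup <- core
  core_dup$timing_files <- dup
  core_dup <- bidsmapr:::refresh_core(core_dup)
  expect_true(any(core_dup$issues$code == "events-collision" &
                    core_dup$issues$severity == "error"))
})
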