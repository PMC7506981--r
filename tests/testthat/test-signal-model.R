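test_that("signal and record constructors enforce their invariants", {
  expect_error(emg_signal(matrix(c(1, NA), 2), 100), "non-finite")
  expect_error(emg_signal(matrix(1), 0), "fs")
  expect_s3_class(emg_signal(1:5, 10), "emg_signal")
  x <- make_signal()
  expect_error(emg_record(x, "s1", gesture = 0, repetition = 1,
                          origin = "real", lineage = "gn"), "lineage")
  expect_error(emg_record(x, "s1", gesture = 0, repetition = 1,
                          origin = "augmented", lineage = character()), "lineage")
  expect_error(emg_record(x, "s1", gesture = -1, repetition = 1), "gesture")
})

test_that("datasets reject mixed rates and channel counts", {
  r1 <- make_record(fs = 100)
  r2 <- make_record(fs = 200)
  expect_error(emg_dataset(list(r1, r2)), "sampling rate")
  r3 <- make_record(c = 3)
  expect_error(emg_dataset(list(r1, r3)), "channel count")
  expect_true(is.na(emg_dataset()$fs))
})

test_that("repetition split partitions the dataset with no leakage", {
  recs <- list()
  for (rep in 1:10) for (g in 0:1)
    recs[[length(recs) + 1]] <- make_record(seed = rep * 10 + g, gesture = g,
                                            repetition = rep)
  ds <- emg_dataset(recs)
  parts <- split_by_repetition(ds, train_reps = setdiff(1:10, 4:5),
                               val_reps = 4, test_reps = 5)
  expect_equal(n_records(parts$train) + n_records(parts$val) + n_records(parts$test),
               n_records(ds))
  # every repetition-5 record routed to test only
  expect_true(all(dataset_meta(parts$test)$repetition == 5))
  expect_false(any(dataset_meta(parts$train)$repetition %in% 4:5))
  expect_false(any(dataset_meta(parts$val)$repetition == 5))
})

test_that("augmented records follow their source repetition through the split", {
  ds <- emg_dataset(list(make_record(repetition = 1), make_record(repetition = 5, seed = 2)))
  aug <- build_augmented_dataset(ds, gn_spec(), R = 2, seed = 1)
  parts <- split_by_repetition(aug, train_reps = 1, val_reps = integer(), test_reps = 5)
  expect_equal(n_records(parts$test), 3)
  expect_true(all(dataset_meta(parts$test)$repetition == 5))
})

test_that("split rejects overlapping and uncovered repetition sets", {
  ds <- emg_dataset(list(make_record(repetition = 1), make_record(repetition = 2, seed = 2)))
  expect_error(split_by_repetition(ds, 1:2, 2, integer()), "overlap")
  err <- tryCatch(split_by_repetition(ds, 1, integer(), integer()), error = identity)
  expect_s3_class(err, "emgaug_config_error")
  expect_match(conditionMessage(err), "2")  # names the uncovered repetition
  # empty train set is legal when everything is covered
  parts <- split_by_repetition(ds, integer(), 1, 2)
  expect_equal(n_records(parts$train), 0)
  # a repetition absent from the data may appear in a set without error
  expect_silent(split_by_repetition(ds, 1, 2, 3))
})

test_that("dataset round-trips losslessly through manifest + CSV", {
  ds <- emg_dataset(list(make_record(n = 37, c = 3, seed = 5),
                         make_record(n = 37, c = 3, seed = 6, gesture = 1,
                                     repetition = 2)))
  dir <- tempfile("ds")
  man <- write_dataset(ds, dir)
  back <- read_dataset(man)
  expect_equal(n_records(back), 2)
  for (i in 1:2) {
    expect_identical(unname(back$records[[i]]$signal$samples),
                     unname(ds$records[[i]]$signal$samples))
    expect_equal(back$records[[i]][c("subject", "gesture", "repetition", "origin")],
                 ds$records[[i]][c("subject", "gesture", "repetition", "origin")])
  }
  unlink(dir, recursive = TRUE)
})

test_that("manifest I/O reports distinct, named failures", {
  dir <- tempfile("bad"); dir.create(dir)
  # empty manifest is a valid empty dataset
  jsonlite::write_json(list(fs_hz = 100, records = list()),
                       file.path(dir, "empty.json"), auto_unbox = TRUE)
  expect_equal(n_records(read_dataset(file.path(dir, "empty.json"))), 0)
  # missing record file
  jsonlite::write_json(
    list(fs_hz = 100, records = list(list(path = "nope.csv", subject = "s",
                                          gesture = 0, repetition = 1))),
    file.path(dir, "missing.json"), auto_unbox = TRUE)
  expect_error(read_dataset(file.path(dir, "missing.json")), "not found",
               class = "emgaug_io_error")
  # per-record rate contradicting the manifest names both rates
  writeLines(c("ch1", "1", "2"), file.path(dir, "r.csv"))
  jsonlite::write_json(
    list(fs_hz = 100, records = list(list(path = "r.csv", fs_hz = 200,
                                          subject = "s", gesture = 0,
                                          repetition = 1))),
    file.path(dir, "mismatch.json"), auto_unbox = TRUE)
  err <- tryCatch(read_dataset(file.path(dir, "mismatch.json")), error = identity)
  expect_s3_class(err, "emgaug_io_error")
  expect_match(conditionMessage(err), "100")
  expect_match(conditionMessage(err), "200")
  unlink(dir, recursive = TRUE)
})
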