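test_that("label encoding follows the canonical 9-class order", {
  expect_identical(unname(encode_labels("Normal")),
                   c(1L, 0L, 0L, 0L, 0L, 0L, 0L, 0L, 0L))
  v <- encode_labels(c("AF", "PVC"))
  expect_identical(unname(which(v == 1L)), c(2L, 7L))
  expect_length(v, 9L)
  expect_error(encode_labels(character(0)), "non-empty")
})

test_that("segmentation yields floor(duration / 10 s) non-overlapping segments", {
  seg6 <- segment_recording(generate_recording("Normal", 60, seed = 1))
  expect_length(seg6, 6L)
  expect_length(segment_recording(generate_recording("Normal", 9, seed = 1)), 0L)
  rec25 <- generate_recording("Normal", 25, seed = 2)
  segs <- segment_recording(rec25)
  expect_length(segs, 2L)
  expect_identical(segs[[1]], rec25$signal[, 1:5000])
  expect_identical(segs[[2]], rec25$signal[, 5001:10000])
  bad <- generate_recording("Normal", 10, fs = 250, seed = 1)
  expect_error(segment_recording(bad), "500 Hz")
})

test_that("each segment yields 4 standard records that partition it", {
  rec <- generate_recording(c("AF", "PVC"), 10, seed = 3)
  seg <- segment_recording(rec)[[1]]
  srs <- build_standard_records(seg, encode_labels(rec$labels))
  expect_length(srs, 4L)
  # shared long lead = the segment's full lead II
  for (w in 1:4) expect_identical(srs[[w]]$long, seg[2, ])
  # windows partition the segment columns exactly
  expect_identical(do.call(cbind, lapply(srs, `[[`, "short")), seg)
  expect_identical(vapply(srs, `[[`, integer(1), "window_index"), 0:3)
  # multi-label vector copied unchanged to every sibling
  for (w in 1:4) expect_identical(sum(srs[[w]]$labels), 2L)
  expect_error(build_standard_records(seg[, 1:4999], encode_labels("AF")),
               "12 x 5000")
})

test_that("record count conservation: 4 * sum(floor(d_i/10)) records", {
  recs <- list(generate_recording("Normal", 10, seed = 1),
               generate_recording("AF", 27, seed = 2),
               generate_recording("STE", 9, seed = 3),
               generate_recording("PAC", 60, seed = 4))
  srs <- standard_records_from_recordings(recs)
  expect_length(srs, 4L * (1L + 2L + 0L + 6L))
})

test_that("HDF5 store round-trips and validates", {
  ds <- fix_small_dataset()
  path <- withr::local_tempfile(fileext = ".h5")
  write_dataset(ds, path)
  rt <- read_dataset(path)
  expect_identical(rt$n, ds$n)
  expect_identical(rt$labels, ds$labels)
  expect_identical(rt$patient_id, ds$patient_id)
  # samples stored as float32: equal within float32 resolution, and a
  # second write/read cycle is bit-exact
  expect_lt(max(abs(rt$short - ds$short)), 2^-20)
  write_dataset(rt, path)
  rt2 <- read_dataset(path)
  expect_identical(rt2$short, rt$short)
  expect_identical(rt2$long, rt$long)
  # empty store is valid with R = 0
  p2 <- withr::local_tempfile(fileext = ".h5")
  write_dataset(list(), p2)
  expect_identical(read_dataset(p2)$n, 0L)
  expect_error(read_dataset(withr::local_tempfile(fileext = ".h5")), "no such")
})

test_that("corrupt or mis-shaped stores are rejected with clear signals", {
  path <- withr::local_tempfile(fileext = ".h5")
  rhdf5::h5createFile(path)
  rhdf5::h5write(matrix(1, 3, 3), path, "short")
  rhdf5::h5closeAll()
  expect_error(read_dataset(path), "missing dataset")
  txt <- withr::local_tempfile(fileext = ".h5")
  writeLines("not hdf5", txt)
  expect_error(read_dataset(txt))
})

test_that("patient-disjoint split honors fractions and determinism", {
  ds <- fix_small_dataset()
  sp <- split_by_patient(ds$patient_id, seed = 1)
  expect_identical(levels(sp), c("train", "validation", "holdout"))
  expect_length(sp, ds$n)
  for (a in levels(sp)) for (b in setdiff(levels(sp), a))
    expect_length(intersect(ds$patient_id[sp == a], ds$patient_id[sp == b]), 0L)
  expect_identical(sp, split_by_patient(ds$patient_id, seed = 1))
  expect_false(identical(sp, split_by_patient(ds$patient_id, seed = 2)))
  expect_error(split_by_patient(rep("P1", 5)), "2 patients")
  expect_error(split_by_patient(ds$patient_id, holdout = 1.2), "fractions")
})

test_that("achieved split fractions track targets with many patients", {
  # 300 patients x 4 records each, uniform record counts
  pids <- rep(sprintf("P%04d", 1:300), each = 4)
  sp <- split_by_patient(pids, holdout = 0.17, validation = 0.05, seed = 3)
  hold_frac <- mean(sp == "holdout")
  expect_gte(hold_frac, 0.15); expect_lte(hold_frac, 0.19)
  val_frac <- sum(sp == "validation") / sum(sp != "holdout")
  expect_lt(abs(val_frac - 0.05), 0.02)
})
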