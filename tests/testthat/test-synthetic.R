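test_that("recording shape, sampling and amplitude contracts hold", {
  rec <- generate_recording("Normal", duration = 10, fs = 500, seed = 1)
  expect_identical(dim(rec$signal), c(12L, 5000L))
  expect_identical(rownames(rec$signal), ECG_LEADS)
  expect_equal(rec$fs, 500)
  expect_true(all(abs(rec$signal) <= 5))          # amplitude sanity, mV
  # non-default sampling rate and duration
  rec2 <- generate_recording("STD", duration = 7, fs = 250, seed = 2)
  expect_identical(ncol(rec2$signal), 7L * 250L)
})

test_that("identical arguments give bit-identical signals", {
  a <- generate_recording("AF", duration = 12, seed = 42)
  b <- generate_recording("AF", duration = 12, seed = 42)
  expect_identical(a$signal, b$signal)
  expect_identical(a$beats, b$beats)
  c <- generate_recording("AF", duration = 12, seed = 43)
  expect_false(identical(a$signal, c$signal))
})

test_that("invalid condition sets and arguments are rejected", {
  expect_error(generate_recording(character(0)), "non-empty")
  expect_error(generate_recording(c("Normal", "AF")), "mutually exclusive")
  expect_error(generate_recording("BadName"), "unknown")
  expect_error(generate_recording("AF", duration = 0.5), "duration")
  expect_error(generate_recording("AF", fs = 50), "fs")
})

test_that("AF recordings have absent P waves and irregular RR intervals", {
  rec <- generate_recording("AF", duration = 10, seed = 2)
  expect_identical(unname(encode_labels(rec$labels)), c(0L, 1L, rep(0L, 7)))
  expect_equal(measure_recording(rec)$p_amp, 0)
  # empirical RR CV from the generator's own beat times, long recording
  long <- generate_recording("AF", duration = 60, seed = 3)
  rr <- diff(long$beats$time)
  expect_gte(sd(rr) / mean(rr), 0.15)
})

test_that("every class expresses its defining feature in all generated records", {
  for (cl in ECG_CLASSES) {
    for (seed in 1:5) {
      rec <- generate_recording(cl, duration = 10, seed = seed)
      expect_true(all(check_label_features(rec)),
                  info = sprintf("class %s seed %d", cl, seed))
    }
  }
  # the measurable features behind those checks
  iavb <- measure_recording(generate_recording("I-AVB", 10, seed = 7))
  expect_gte(iavb$pr, 0.21)
  bbb <- measure_recording(generate_recording("LBBB", 10, seed = 7))
  expect_gte(bbb$qrs, 0.12)
  pvc <- measure_recording(generate_recording("PVC", 30, seed = 7))
  expect_gte(pvc$n_pvc, 1)
  expect_true(pvc$pvc_inverted)
  std <- measure_recording(generate_recording("STD", 10, seed = 7))
  expect_gte(std$n_st_dep, 2)
  expect_lte(std$st_min, -0.1)
})

test_that("multi-label recordings compose disease effects", {
  rec <- generate_recording(c("AF", "PVC"), duration = 30, seed = 9)
  expect_true(all(check_label_features(rec)))
  expect_equal(sum(encode_labels(rec$labels)), 2L)
})

test_that("cohorts have distinct patients, reproducibility and mix control", {
  co <- generate_cohort(10, duration_range = c(10, 10), seed = 0)
  expect_length(co, 10L)
  expect_length(unique(vapply(co, function(r) r$patient_id, character(1))), 10L)
  co2 <- generate_cohort(10, duration_range = c(10, 10), seed = 0)
  expect_identical(lapply(co, `[[`, "signal"), lapply(co2, `[[`, "signal"))
  af_only <- generate_cohort(30, class_mix = c(AF = 1), seed = 1)
  expect_true(all(vapply(af_only, function(r) identical(r$labels, "AF"),
                         logical(1))))
  expect_error(generate_cohort(5, class_mix = numeric(0)), "class_mix")
})

test_that("cohort class fractions track the requested mix", {
  mix <- c(Normal = 0.30, AF = 0.25, RBBB = 0.25, STD = 0.20)
  co <- generate_cohort(1000, class_mix = mix, seed = 2)
  labs <- vapply(co, function(r) r$labels[1], character(1))
  frac <- table(factor(labs, levels = names(mix))) / length(co)
  expect_true(all(abs(frac - mix) <= 0.03))
})

test_that("one patient profile is reused across that patient's recordings", {
  co <- generate_cohort(3, duration_range = c(10, 10), seed = 5,
                        recordings_per_patient = 3)
  pids <- vapply(co, function(r) r$patient_id, character(1))
  for (p in unique(pids)) {
    mine <- co[pids == p]
    prs <- vapply(mine, function(r) r$profile$pr, numeric(1))
    expect_equal(length(unique(prs)), 1L)     # same template draw
    expect_false(identical(mine[[1]]$signal, mine[[2]]$signal))
  }
})
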