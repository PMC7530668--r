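# Shared fixtures, built once per test run and cached.

.fixtures <- new.env(parent = emptyenv())

fixture <- function(name, builder) {
  if (is.null(.fixtures[[name]])) .fixtures[[name]] <- builder()
  .fixtures[[name]]
}

# one Normal standard record (first window of a 10-s recording)
fix_standard_record <- function() fixture("std_rec", function() {
  rec <- generate_recording("Normal", duration = 10, seed = 101)
  build_standard_records(segment_recording(rec)[[1]],
                         encode_labels("Normal"))[[1]]
})

# all-zero standard record (baseline-only rendering)
fix_zero_record <- function() {
  r <- fix_standard_record()
  r$short[] <- 0; r$long[] <- 0
  r
}

# small mixed cohort dataset: 12 patients, 1 x 10-20 s recording each
fix_small_dataset <- function() fixture("small_ds", function() {
  recs <- generate_cohort(12, duration_range = c(10, 20), seed = 202)
  dataset_from_records(standard_records_from_recordings(recs))
})

# rendered plot of the Normal record
fix_rendered <- function() fixture("rendered", function() {
  render_record(fix_standard_record())
})

# brute-force per-record counting oracle for the metric formulas
oracle_metrics <- function(pred, truth) {
  tp <- tn <- fp <- fn <- 0L
  for (i in seq_along(pred)) {
    if (truth[i] == 1L && pred[i] == 1L) tp <- tp + 1L
    else if (truth[i] == 1L && pred[i] == 0L) fn <- fn + 1L
    else if (truth[i] == 0L && pred[i] == 1L) fp <- fp + 1L
    else tn <- tn + 1L
  }
  safe <- function(num, den) if (den > 0) num / den else NA_real_
  list(TPR = safe(tp, tp + fn), TNR = safe(tn, tn + fp),
       PPV = safe(tp, tp + fp), NPV = safe(tn, tn + fn),
       ACC = safe(tp + tn, tp + tn + fp + fn),
       F1 = safe(2 * tp, 2 * tp + fp + fn))
}

# exhaustive pairwise-concordance AUC oracle
oracle_auc <- function(P, truth) {
  pos <- P[truth == 1]; neg <- P[truth == 0]
  tot <- 0
  for (a in pos) for (b in neg) tot <- tot + (a > b) + 0.5 * (a == b)
  tot / (length(pos) * length(neg))
}
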