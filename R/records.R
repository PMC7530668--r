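# Standard-record construction: 10-s segmentation, 4 windows per
# segment (2.5 s of all 12 leads + the segment's full 10 s of lead II),
# length-9 one-hot labels, patient-disjoint splitting.

SEG_SAMPLES <- 5000L    # 10 s @ 500 Hz
WIN_SAMPLES <- 1250L    # 2.5 s @ 500 Hz

#' Encode a condition set as a length-9 one-hot label vector
#'
#' Label order is fixed by [ECG_CLASSES]: (1) Normal, (2) AF, (3) I-AVB,
#' (4) LBBB, (5) RBBB, (6) PAC, (7) PVC, (8) STD, (9) STE. An entry is 1
#' iff the condition is present; several entries may be set.
#'
#' @param conditions Character vector of class names (non-empty).
#' @return Named integer vector of length 9 with values in \{0, 1\}.
#' @examples
#' encode_labels(c("AF", "PVC"))
#' @export
encode_labels <- function(conditions) {
  validate_conditions(conditions)
  setNames(as.integer(ECG_CLASSES %in% conditions), ECG_CLASSES)
}

#' Split a recording into non-overlapping 10-s segments
#'
#' Recordings are cut into consecutive 10-s segments with no overlap; a
#' trailing remainder shorter than 10 s is discarded, and recordings
#' shorter than 10 s yield zero segments (they are omitted).
#'
#' @param rec An `ecg_recording` sampled at 500 Hz with 12 leads.
#' @return List of 12 x 5000 matrices (possibly empty).
#' @export
segment_recording <- function(rec) {
  stopifnot(inherits(rec, "ecg_recording"))
  if (nrow(rec$signal) != 12L) stopf("recording must have exactly 12 leads")
  if (rec$fs != 500) stopf("recording must be sampled at 500 Hz")
  n_seg <- floor(ncol(rec$signal) / SEG_SAMPLES)
  if (n_seg == 0L) return(list())
  lapply(seq_len(n_seg), function(s) {
    rec$signal[, ((s - 1L) * SEG_SAMPLES + 1L):(s * SEG_SAMPLES), drop = FALSE]
  })
}

#' Build the four standard records of a 10-s segment
#'
#' Each 10-s segment yields four standard records: record w (w = 0..3)
#' takes samples \[1250 w, 1250 (w + 1)) of every lead as its 2.5-s
#' short block, and all four share the segment's full 10 s of lead II
#' as the long lead.
#'
#' @param segment 12 x 5000 numeric matrix (mV).
#' @param labels Length-9 binary label vector (see [encode_labels()]).
#' @param patient_id,recording_id Provenance strings.
#' @param segment_index Integer segment index within the recording.
#' @return List of 4 `standard_record` objects, each with fields
#'   `short` (12 x 1250), `long` (length 5000, lead II), `labels`,
#'   `patient_id`, `recording_id`, `segment_index`, `window_index`.
#' @export
build_standard_records <- function(segment, labels, patient_id = "P00001",
                                   recording_id = "R000001",
                                   segment_index = 1L) {
  if (!is.matrix(segment) || nrow(segment) != 12L || ncol(segment) != SEG_SAMPLES)
    stopf("segment must be a 12 x %d matrix", SEG_SAMPLES)
  labels <- as.integer(labels)
  if (length(labels) != 9L || !all(labels %in% c(0L, 1L)) || sum(labels) < 1L)
    stopf("labels must be a length-9 binary vector with at least one 1")
  long <- segment[LEAD_II, ]
  lapply(0:3, function(w) {
    structure(list(
      short = segment[, (w * WIN_SAMPLES + 1L):((w + 1L) * WIN_SAMPLES), drop = FALSE],
      long = long,
      labels = setNames(labels, ECG_CLASSES),
      patient_id = patient_id, recording_id = recording_id,
      segment_index = as.integer(segment_index), window_index = w),
      class = "standard_record")
  })
}

#' Convert raw recordings into a flat list of standard records
#'
#' Applies [segment_recording()] and [build_standard_records()] to every
#' recording. The total count is 4 * sum(floor(duration_i / 10 s)).
#'
#' @param recordings List of `ecg_recording` objects.
#' @return List of `standard_record` objects.
#' @export
standard_records_from_recordings <- function(recordings) {
  out <- list()
  for (i in seq_along(recordings)) {
    rec <- recordings[[i]]
    segs <- segment_recording(rec)
    labs <- encode_labels(rec$labels)
    rid <- sprintf("%s-%03d", rec$patient_id, i)
    for (s in seq_along(segs)) {
      out <- c(out, build_standard_records(segs[[s]], labs, rec$patient_id,
                                           rid, s))
    }
  }
  out
}

#' Patient-disjoint split of standard records
#'
#' Shuffles patients under `seed` and assigns whole patients greedily to
#' the holdout partition until its record fraction is reached, then
#' splits the remaining development records into training and internal
#' validation the same way. No patient contributes records to more than
#' one partition. Achieved fractions track the targets up to whole-
#' patient granularity.
#'
#' @param patient_ids Character vector, one patient id per record (or a
#'   list of `standard_record`s, or an `ecg_dataset`).
#' @param holdout Target holdout fraction of records (default 0.17).
#' @param validation Target validation fraction of the development
#'   records (default 0.05).
#' @param seed Integer seed.
#' @return Factor of length R with levels `train`, `validation`,
#'   `holdout`.
#' @export
split_by_patient <- function(patient_ids, holdout = 0.17, validation = 0.05,
                             seed = 1L) {
  if (is.list(patient_ids) && !is.null(patient_ids$patient_id))
    patient_ids <- patient_ids$patient_id
  else if (is.list(patient_ids))
    patient_ids <- vapply(patient_ids, function(r) r$patient_id, character(1))
  if (holdout <= 0 || holdout >= 1 || validation <= 0 || validation >= 1)
    stopf("fractions must lie in (0, 1)")
  pats <- unique(patient_ids)
  if (length(pats) < 2L) stopf("need at least 2 patients to split")
  R <- length(patient_ids)
  counts <- table(patient_ids)
  assign_greedy <- function(pool, target_n) {
    taken <- character(0); n <- 0
    for (p in pool) {
      if (n >= target_n) break
      taken <- c(taken, p); n <- n + counts[[p]]
    }
    taken
  }
  with_seed(seed, {
    shuffled <- sample(pats)
    hold_pats <- assign_greedy(shuffled, holdout * R)
    dev_pats <- setdiff(shuffled, hold_pats)
    if (length(dev_pats) == 0L) stopf("holdout fraction leaves no development patients")
    n_dev <- sum(counts[dev_pats])
    val_pats <- assign_greedy(dev_pats, validation * n_dev)
    out <- rep("train", R)
    out[patient_ids %in% hold_pats] <- "holdout"
    out[patient_ids %in% val_pats] <- "validation"
    factor(out, levels = c("train", "validation", "holdout"))
  })
}
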