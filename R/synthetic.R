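# Synthetic 12-lead ECG generator.
#
# Beat morphology is a sum of Gaussian bumps (P, Q, R, S, T) on a shared
# time base, projected onto the 12 leads by fixed per-lead gain vectors.
# Each condition class is expressed by construction rules on the template
# and rhythm (PR interval, QRS duration and polarity pattern, RR
# variability, ectopic insertion, ST plateau offset, fibrillatory
# baseline), so classes are separable by design. This is a stand-in for
# clinical recordings, not a physiological forward model.

#' Validate a condition set
#'
#' A condition set is a non-empty subset of [ECG_CLASSES]. "Normal" is
#' mutually exclusive with every disease class.
#'
#' @param conditions Character vector of class names.
#' @return The validated character vector (invisibly unchanged).
#' @export
validate_conditions <- function(conditions) {
  if (length(conditions) == 0L) stopf("condition set must be non-empty")
  bad <- setdiff(conditions, ECG_CLASSES)
  if (length(bad)) stopf("unknown condition(s): %s", paste(bad, collapse = ", "))
  if ("Normal" %in% conditions && length(conditions) > 1L)
    stopf("'Normal' is mutually exclusive with disease classes")
  if (anyDuplicated(conditions)) stopf("duplicated condition names")
  conditions
}

# fixed per-lead projection gains for the P/T axis (canonical lead order)
.base_gains <- c(0.7, 1.0, 0.45, -0.85, 0.3, 0.7,
                 -0.5, -0.25, 0.35, 0.85, 1.0, 0.8)

# Draw one patient's beat template + rhythm spec for a condition set.
# Everything downstream (all of that patient's recordings) reuses this
# profile, so patient-disjoint splitting is meaningful.
patient_profile <- function(conditions, seed) {
  validate_conditions(conditions)
  with_seed(seed, {
    gains <- .base_gains * runif(12, 0.9, 1.1)
    prof <- list(
      conditions  = conditions,
      gains       = gains,          # P and T projection
      qrs_gain    = gains,          # QRS projection (modified by BBB)
      pvc_gain    = gains,          # ectopic-QRS projection (PVC inverts)
      p_amp       = runif(1, 0.12, 0.18),   # mV
      r_amp       = runif(1, 1.0, 1.4),
      t_amp       = runif(1, 0.25, 0.40),
      pr          = runif(1, 0.14, 0.19),   # s, P onset to QRS onset
      qrs         = runif(1, 0.07, 0.09),   # s
      ect_qrs     = runif(1, 0.07, 0.09),   # ectopic QRS duration
      st_offset   = rep(0, 12),             # mV per lead
      rr_mean     = runif(1, 0.7, 1.0),     # s
      rr_cv       = runif(1, 0.02, 0.05),
      rhythm      = "sinus",
      ect_rate    = 0,
      ect_types   = character(0),
      fib         = FALSE)

    if ("AF" %in% conditions) {
      prof$rhythm <- "af"
      prof$rr_cv  <- runif(1, 0.20, 0.30)   # i.i.d. RR, CV >= 0.15
      prof$p_amp  <- 0
      prof$fib    <- TRUE
    }
    if ("I-AVB" %in% conditions) prof$pr <- runif(1, 0.22, 0.28)
    if ("LBBB" %in% conditions) {
      prof$qrs <- runif(1, 0.13, 0.15)
      g <- abs(prof$qrs_gain)
      # dominant positive deflection lateral (I, aVL, V5, V6),
      # negative right-precordial (V1-V3)
      prof$qrs_gain[c(1, 5, 11, 12)] <- 1.2 * g[c(1, 5, 11, 12)]
      prof$qrs_gain[7:9] <- -g[7:9]
    }
    if ("RBBB" %in% conditions) {
      prof$qrs <- runif(1, 0.13, 0.15)
      g <- abs(prof$qrs_gain)
      # opposite pattern: positive right-precordial, negative lateral
      prof$qrs_gain[7:8] <- 1.2 * g[7:8]
      prof$qrs_gain[c(1, 5, 11, 12)] <- -0.8 * g[c(1, 5, 11, 12)]
    }
    if ("PAC" %in% conditions) {
      prof$ect_rate <- 0.15
      prof$ect_types <- c(prof$ect_types, "pac")
    }
    if ("PVC" %in% conditions) {
      prof$ect_rate <- 0.15
      prof$ect_types <- c(prof$ect_types, "pvc")
      prof$ect_qrs <- runif(1, 0.13, 0.15)
      # amplitude-inverted, widened ectopic complexes in the inferior leads
      prof$pvc_gain <- prof$qrs_gain
      prof$pvc_gain[c(2, 3, 6)] <- -1.3 * abs(prof$pvc_gain[c(2, 3, 6)])
    }
    if ("STD" %in% conditions) prof$st_offset[c(2, 11, 12)] <- runif(1, -0.20, -0.12)
    if ("STE" %in% conditions) prof$st_offset[7:9] <- runif(1, 0.12, 0.25)
    prof
  })
}

# add a Gaussian bump to a signal vector (evaluated on +/- 4 sd support)
add_bump <- function(v, fs, center, amp, width) {
  n <- length(v)
  i0 <- max(1L, floor((center - 4 * width) * fs) + 1L)
  i1 <- min(n, ceiling((center + 4 * width) * fs) + 1L)
  if (i0 > i1 || i1 < 1L || i0 > n) return(v)
  t <- (seq.int(i0, i1) - 1) / fs
  v[i0:i1] <- v[i0:i1] + amp * exp(-(t - center)^2 / (2 * width^2))
  v
}

# smooth plateau (raised-cosine edges) used for the ST segment window
add_plateau <- function(v, fs, from, to, edge = 0.02) {
  n <- length(v)
  i0 <- max(1L, floor((from - edge) * fs) + 1L)
  i1 <- min(n, ceiling((to + edge) * fs) + 1L)
  if (i0 > i1 || i1 < 1L || i0 > n) return(v)
  t <- (seq.int(i0, i1) - 1) / fs
  w <- rep(1, length(t))
  w[t < from] <- 0.5 * (1 + cos(pi * (from - t[t < from]) / edge))
  w[t > to]   <- 0.5 * (1 + cos(pi * (t[t > to] - to) / edge))
  v[i0:i1] <- v[i0:i1] + w
  v
}

# draw the beat schedule (R-peak times and per-beat annotations)
draw_beats <- function(prof, duration) {
  rr_mean <- prof$rr_mean
  t <- stats::runif(1, 0.25, 0.45)
  times <- numeric(0); types <- character(0); rrs <- numeric(0)
  prev_rr <- rr_mean
  while (t < duration + rr_mean) {
    times <- c(times, t); types <- c(types, "sinus"); rrs <- c(rrs, prev_rr)
    if (prof$ect_rate > 0 && length(prof$ect_types) &&
        stats::runif(1) < prof$ect_rate && t > 1) {
      # ectopic beat at ~0.6 x mean RR coupling, then a compensatory pause
      etype <- if (length(prof$ect_types) == 1L) prof$ect_types else
        sample(prof$ect_types, 1L)
      rr_e <- 0.6 * rr_mean
      t <- t + rr_e
      times <- c(times, t); types <- c(types, etype); rrs <- c(rrs, rr_e)
      prev_rr <- 1.3 * rr_mean
      t <- t + prev_rr
    } else {
      prev_rr <- if (prof$rhythm == "af") {
        sdl <- sqrt(log(1 + prof$rr_cv^2))
        rr_mean * exp(stats::rnorm(1, -sdl^2 / 2, sdl))
      } else {
        rr_mean * (1 + prof$rr_cv * max(-2.5, min(2.5, stats::rnorm(1))))
      }
      t <- t + prev_rr
    }
  }
  keep <- times < duration - 0.05
  data.frame(time = times[keep], type = types[keep], rr_prev = rrs[keep],
             stringsAsFactors = FALSE)
}

# synthesize the 12 x N signal for a profile + beat schedule
synth_signal <- function(prof, beats, duration, fs) {
  n <- round(duration * fs)
  v_p <- v_qrs <- v_t <- v_ect <- v_ett <- v_st <- numeric(n)
  qw <- prof$qrs; ew <- prof$ect_qrs
  for (i in seq_len(nrow(beats))) {
    tc <- beats$time[i]; type <- beats$type[i]
    is_pvc <- type == "pvc"
    d <- if (is_pvc) ew else qw
    if (!is_pvc && prof$p_amp > 0) {
      # P centred before QRS onset (QRS onset at tc - d/2)
      v_p <- add_bump(v_p, fs, tc - d / 2 - prof$pr + 0.04, prof$p_amp, 0.025)
    }
    tgt_q <- if (is_pvc) "ect" else "qrs"
    wq <- d / 7                       # bump widths scale with QRS duration
    bump <- function(v) {
      v <- add_bump(v, fs, tc - 0.3 * d, -0.18 * prof$r_amp, wq * 0.8)
      v <- add_bump(v, fs, tc,            prof$r_amp,        wq)
      add_bump(v, fs, tc + 0.3 * d,      -0.22 * prof$r_amp, wq * 0.8)
    }
    if (is_pvc) v_ect <- bump(v_ect) else v_qrs <- bump(v_qrs)
    tw <- if (is_pvc) 0.08 else 0.06
    tb <- function(v) add_bump(v, fs, tc + d / 2 + 0.22, prof$t_amp *
                                 (if (is_pvc) -1 else 1), tw)
    if (is_pvc) v_ett <- tb(v_ett) else v_t <- tb(v_t)
    v_st <- add_plateau(v_st, fs, tc + d / 2 + 0.02, tc + d / 2 + 0.16)
  }
  sig <- outer(prof$gains, v_p + v_t) +
    outer(prof$qrs_gain, v_qrs) +
    outer(prof$pvc_gain, v_ect + v_ett) +
    outer(prof$st_offset, v_st)
  if (prof$fib) {
    # fibrillatory baseline: sum of sinusoids in the 4-9 Hz band, ~0.05 mV
    t <- (seq_len(n) - 1) / fs
    for (l in 1:12) {
      f <- stats::runif(8, 4, 9); ph <- stats::runif(8, 0, 2 * pi)
      w <- vapply(1:8, function(k) sin(2 * pi * f[k] * t + ph[k]), numeric(n))
      sig[l, ] <- sig[l, ] + 0.05 * rowSums(w) / sqrt(4)
    }
  }
  sig <- sig + matrix(stats::rnorm(12L * n, 0, 0.008), 12L, n)
  rownames(sig) <- ECG_LEADS
  sig
}

#' Generate one labeled synthetic 12-lead ECG recording
#'
#' Draws a patient beat template and rhythm for the requested condition
#' set, then synthesizes the signal. Condition signatures follow the
#' usual clinical definitions: AF has i.i.d. RR intervals (CV >= 0.15),
#' absent P waves and a 4-9 Hz fibrillatory baseline; I-AVB a PR
#' interval >= 0.21 s; LBBB/RBBB a QRS >= 0.12 s with opposite dominant
#' deflection in lateral versus right-precordial leads; PAC/PVC early
#' ectopic beats (coupling ~0.6 x mean RR) with/without a P wave and
#' narrow/wide QRS; STD/STE an ST-segment offset of at least 0.1 mV in
#' magnitude in >= 2 leads. Identical arguments (including `seed`) give
#' bit-identical output.
#'
#' @param conditions Character vector: subset of [ECG_CLASSES]
#'   ("Normal" must appear alone).
#' @param duration Recording length in seconds (>= 1).
#' @param fs Sampling rate in Hz (>= 100); default 500.
#' @param seed Integer seed.
#' @param patient_id Optional patient identifier string.
#' @return An object of class `ecg_recording`: list with `patient_id`,
#'   `fs`, `duration`, `signal` (12 x N matrix, mV, rows in [ECG_LEADS]
#'   order), `labels` (character), plus the internal `beats` annotation
#'   table and generating `profile` (used by [measure_recording()]).
#' @examples
#' rec <- generate_recording("AF", duration = 10, seed = 2)
#' dim(rec$signal)
#' @export
generate_recording <- function(conditions, duration = 10, fs = 500,
                               seed = 1L, patient_id = "P00001") {
  validate_conditions(conditions)
  assert_scalar_num(duration, "duration"); assert_scalar_num(fs, "fs")
  if (duration < 1) stopf("duration must be >= 1 s")
  if (fs < 100) stopf("fs must be >= 100 Hz")
  prof <- patient_profile(conditions, child_seed(seed, 1L))
  synth_recording(prof, duration, fs, child_seed(seed, 2L), patient_id)
}

# synthesize one recording from an existing patient profile
synth_recording <- function(prof, duration, fs, seed, patient_id) {
  with_seed(seed, {
    beats <- draw_beats(prof, duration)
    sig <- synth_signal(prof, beats, duration, fs)
    structure(list(patient_id = patient_id, fs = fs, duration = duration,
                   signal = sig, labels = prof$conditions,
                   beats = beats, profile = prof),
              class = "ecg_recording")
  })
}

#' @export
print.ecg_recording <- function(x, ...) {
  cat(sprintf("<ecg_recording> patient %s: %.0f s @ %g Hz, labels: %s\n",
              x$patient_id, x$duration, x$fs, paste(x$labels, collapse = "+")))
  invisible(x)
}

#' Generate a multi-patient synthetic cohort
#'
#' Each patient gets one template + rhythm draw, reused across all of
#' that patient's recordings, so patient-disjoint splitting is
#' meaningful. Condition sets are drawn per patient from `class_mix`.
#'
#' @param n_patients Number of synthetic patients (>= 1).
#' @param class_mix Named numeric vector of sampling weights over (a
#'   subset of) [ECG_CLASSES]; normalized internally. Default uniform
#'   over all 9 classes.
#' @param duration_range Length-2 numeric, seconds; each recording's
#'   duration is drawn uniformly (integer seconds) in this range.
#' @param seed Integer seed; all randomness flows from it through
#'   per-patient substreams.
#' @param fs Sampling rate, Hz.
#' @param recordings_per_patient Recordings per patient (default 1).
#' @param multi_label_rate Probability that a disease patient receives a
#'   second, compatible disease label (default 0).
#' @return List of [generate_recording()] objects.
#' @export
generate_cohort <- function(n_patients, class_mix = NULL,
                            duration_range = c(10, 10), seed = 1L,
                            fs = 500, recordings_per_patient = 1L,
                            multi_label_rate = 0) {
  if (n_patients < 1) stopf("n_patients must be >= 1")
  if (is.null(class_mix))
    class_mix <- setNames(rep(1, 9), ECG_CLASSES)
  if (length(class_mix) == 0L || sum(class_mix) <= 0)
    stopf("class_mix must be a non-empty set of positive weights")
  bad <- setdiff(names(class_mix), ECG_CLASSES)
  if (length(bad)) stopf("unknown class in class_mix: %s", paste(bad, collapse = ", "))
  probs <- class_mix / sum(class_mix)
  recs <- list()
  for (i in seq_len(n_patients)) {
    pid <- sprintf("P%05d", i)
    ps <- child_seed(seed, i)
    conds <- with_seed(ps, {
      primary <- sample(names(probs), 1L, prob = probs)
      conds <- primary
      if (primary != "Normal" && multi_label_rate > 0 &&
          runif(1) < multi_label_rate) {
        extra <- setdiff(ECG_CLASSES[-1], primary)
        conds <- c(primary, sample(extra, 1L))
      }
      conds
    })
    prof <- patient_profile(conds, child_seed(ps, 1L))
    for (r in seq_len(recordings_per_patient)) {
      rs <- child_seed(ps, 100L + r)
      dur <- with_seed(child_seed(ps, 200L + r), {
        if (duration_range[1] == duration_range[2]) duration_range[1]
        else sample(seq(duration_range[1], duration_range[2]), 1L)
      })
      recs[[length(recs) + 1L]] <- synth_recording(prof, dur, fs, rs, pid)
    }
  }
  recs
}

#' Measure the defining features of a recording from its annotations
#'
#' Rule-based measurer that reads the generator's internal beat
#' annotations and profile (not the raw signal) and reports the features
#' that define each class: PR interval, QRS durations, RR coefficient of
#' variation, ST offsets, P amplitude and ectopic composition.
#'
#' @param rec An `ecg_recording`.
#' @return List of measured features.
#' @export
measure_recording <- function(rec) {
  stopifnot(inherits(rec, "ecg_recording"))
  b <- rec$beats; p <- rec$profile
  sinus_rr <- diff(b$time[b$type == "sinus"])
  list(
    pr = p$pr,
    qrs = p$qrs,
    ect_qrs = p$ect_qrs,
    p_amp = p$p_amp,
    rr_cv = if (length(sinus_rr) > 2) sd(sinus_rr) / mean(sinus_rr) else NA_real_,
    param_rr_cv = p$rr_cv,
    st_min = min(p$st_offset), st_max = max(p$st_offset),
    n_st_dep = sum(p$st_offset <= -0.1), n_st_ele = sum(p$st_offset >= 0.1),
    n_pac = sum(b$type == "pac"), n_pvc = sum(b$type == "pvc"),
    pvc_inverted = any(sign(p$pvc_gain) != sign(p$qrs_gain) &
                         abs(p$qrs_gain) > 1e-9),
    n_beats = nrow(b))
}

#' Check that a recording's signal construction matches its labels
#'
#' Confirms, from the internal annotations, the defining feature of each
#' label carried by the recording (e.g. PR >= 0.21 s for I-AVB,
#' RR CV >= 0.15 for AF, QRS >= 0.12 s for bundle branch block).
#'
#' @param rec An `ecg_recording`.
#' @return Named logical vector, one entry per label on the recording.
#' @export
check_label_features <- function(rec) {
  m <- measure_recording(rec)
  vapply(rec$labels, function(cl) switch(cl,
    "Normal" = m$pr < 0.20 && m$qrs < 0.12 &&
      max(abs(c(m$st_min, m$st_max))) < 0.05,
    "AF"     = m$p_amp == 0 && m$param_rr_cv >= 0.15,
    "I-AVB"  = m$pr >= 0.21,
    "LBBB"   = m$qrs >= 0.12,
    "RBBB"   = m$qrs >= 0.12,
    "PAC"    = m$n_pac >= 1,
    "PVC"    = m$n_pvc >= 1 && m$ect_qrs >= 0.12 && m$pvc_inverted,
    "STD"    = m$n_st_dep >= 2,
    "STE"    = m$n_st_ele >= 2,
    FALSE), logical(1))
}
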