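# ECG preprocessing: filtering/resampling, median-beat construction,
# QRS-duration measurement and broad-QRS cohort selection.

#' The eight analysis leads
#'
#' Leads aVL, aVR, aVF and III are linear combinations of leads I and II and
#' carry no independent information, so median beats keep only these eight.
#' @export
LEADS8 <- c("I", "II", "V1", "V2", "V3", "V4", "V5", "V6")

#' Construct an ECG record
#'
#' A lightweight container for a multi-lead rhythm strip or any multi-lead
#' waveform segment, together with its sampling rate and per-record metadata.
#'
#' @param signal numeric matrix, leads x samples, in millivolts.
#' @param fs sampling rate in Hz.
#' @param lead_names character vector naming the rows of `signal`.
#' @param meta named list of per-record metadata. Recognised entries include
#'   `id`, `age`, `sex`, `heart_rate`, `qrs_ms`, `qtc_ms`, `morphology`
#'   (one of `"LBBB"`, `"RBBB"`, `"NSIVCD"`), `paced_flag`, `cied_flag`,
#'   `chb_flag`.
#' @return an object of class `ecg_record`.
#' @export
ecg_record <- function(signal, fs, lead_names = rownames(signal), meta = list()) {
  signal <- as.matrix(signal)
  if (is.null(lead_names)) stopf("lead_names must be supplied")
  if (length(lead_names) != nrow(signal)) stopf("lead_names must match rows of signal")
  if (anyDuplicated(lead_names)) stopf("lead_names must be unique")
  if (!is.numeric(fs) || length(fs) != 1L || fs <= 0) stopf("fs must be a positive scalar")
  rownames(signal) <- lead_names
  structure(list(signal = signal, fs = fs, lead_names = lead_names, meta = meta),
            class = "ecg_record")
}

#' @export
print.ecg_record <- function(x, ...) {
  cat(sprintf("<ecg_record> %d leads x %d samples @ %g Hz (%.1f s)\n",
              nrow(x$signal), ncol(x$signal), x$fs, ncol(x$signal) / x$fs))
  invisible(x)
}

#' Construct a median-beat object
#'
#' @param beats 8 x T numeric matrix (mV) at 400 Hz, rows ordered as
#'   [LEADS8]; one representative cardiac cycle.
#' @param fs sampling rate in Hz (400 by convention).
#' @param fiducial_index sample index of the R-peak alignment point.
#' @param source_id identifier of the originating record.
#' @return an object of class `median_beat`.
#' @export
median_beat <- function(beats, fs = 400, fiducial_index = NULL, source_id = NA_character_) {
  beats <- as.matrix(beats)
  if (nrow(beats) != 8L) stopf("a median beat has exactly 8 leads, got %d", nrow(beats))
  if (!all(is.finite(beats))) stopf("median beat contains non-finite values")
  rownames(beats) <- LEADS8
  structure(list(beats = beats, fs = fs,
                 fiducial_index = fiducial_index %||% (ncol(beats) %/% 3L),
                 source_id = source_id),
            class = "median_beat")
}

#' @export
print.median_beat <- function(x, ...) {
  cat(sprintf("<median_beat> 8 x %d @ %g Hz, fiducial at sample %d [%s]\n",
              ncol(x$beats), x$fs, x$fiducial_index, x$source_id))
  invisible(x)
}

#' Band-pass, notch-filter and resample an ECG record
#'
#' Applies a zero-phase (forward-backward) Butterworth band-pass and a
#' band-stop notch, then resamples to `target_fs`. Zero-phase filtering is
#' used so the R-peak fiducial is not shifted by group delay.
#'
#' @param rec an [ecg_record()].
#' @param band numeric length-2, band-pass corner frequencies in Hz.
#' @param notch_hz notch (mains) frequency in Hz; `NA` disables the notch.
#' @param target_fs output sampling rate in Hz.
#' @param notch_halfwidth_hz half-width of the band-stop notch in Hz.
#' @return an `ecg_record` at `target_fs` with the same leads and metadata.
#'   The output length is `round(n_in * target_fs / fs)`.
#' @export
filter_and_resample <- function(rec, band = c(0.5, 100), notch_hz = 60,
                                target_fs = 400, notch_halfwidth_hz = 2) {
  stopifnot(inherits(rec, "ecg_record"))
  fs <- rec$fs
  if (!(band[1] > 0 && band[1] < band[2])) stopf("need 0 < low < high band edges")
  if (fs <= 2 * band[2])
    stopf("sampling rate %g Hz too low for a %g Hz band edge (need fs > %g)",
          fs, band[2], 2 * band[2])
  nyq <- fs / 2
  bp <- signal::butter(2, band / nyq, type = "pass")
  filt1 <- function(x) signal::filtfilt(bp, x)
  if (!is.na(notch_hz) && notch_hz < nyq) {
    bs <- signal::butter(2, c(notch_hz - notch_halfwidth_hz,
                              notch_hz + notch_halfwidth_hz) / nyq, type = "stop")
    filt2 <- function(x) signal::filtfilt(bs, x)
  } else filt2 <- identity
  filtered <- t(apply(rec$signal, 1, function(x) filt2(filt1(x))))

  n_in <- ncol(filtered)
  n_out <- round(n_in * target_fs / fs)
  if (abs(fs - target_fs) < 1e-9) {
    out <- filtered
  } else {
    fr <- round(fs)
    tr <- round(target_fs)
    g <- gcd_int(tr, fr)
    out <- t(apply(filtered, 1, function(x) signal::resample(x, tr / g, fr / g)))
    # polyphase resampling can differ by a sample at the boundary
    if (ncol(out) > n_out) out <- out[, seq_len(n_out), drop = FALSE]
    if (ncol(out) < n_out) out <- cbind(out, out[, rep(ncol(out), n_out - ncol(out)), drop = FALSE])
  }
  if (!all(is.finite(out))) stopf("non-finite samples after filtering")
  ecg_record(out, fs = target_fs, lead_names = rec$lead_names, meta = rec$meta)
}

gcd_int <- function(a, b) if (b == 0) a else gcd_int(b, a %% b)

#' Detect R peaks on one lead
#'
#' Squared-amplitude envelope peak picking with a refractory period; simple
#' but adequate for median-beat alignment on filtered strips.
#'
#' @param y numeric vector, one lead.
#' @param fs sampling rate in Hz.
#' @param min_rr_s refractory period between accepted peaks, seconds.
#' @param thr_frac detection threshold as a fraction of the envelope maximum.
#' @return integer vector of peak sample indices, sorted.
#' @export
detect_r_peaks <- function(y, fs, min_rr_s = 0.3, thr_frac = 0.3) {
  e <- smooth_ma(y^2, round(0.02 * fs))
  if (max(e) <= 0) return(integer(0))
  thr <- thr_frac * max(e)
  n <- length(e)
  is_max <- e >= thr &
    e >= c(-Inf, e[-n]) &
    e > c(e[-1], -Inf)
  cand <- which(is_max)
  cand <- cand[order(e[cand], decreasing = TRUE)]
  accepted <- integer(0)
  min_gap <- round(min_rr_s * fs)
  for (p in cand) {
    if (!length(accepted) || all(abs(accepted - p) >= min_gap)) accepted <- c(accepted, p)
  }
  sort(accepted)
}

#' Collapse a rhythm strip into an 8-lead median beat
#'
#' R peaks are detected on a reference lead (lead II by default), a fixed
#' window is cut around each fiducial, and the per-sample, per-lead median
#' across beats is taken. Only the eight independent leads are retained, in
#' the fixed order [LEADS8].
#'
#' @param rec an [ecg_record()]; must contain at least the leads in [LEADS8].
#' @param ref_lead lead used for R-peak detection.
#' @param window numeric length-2: seconds before and after the fiducial
#'   (default 0.4 s before, 0.8 s after: a 1.2 s beat window).
#' @param min_beats minimum number of fully-contained beats required.
#' @return a [median_beat()]; errors with condition class
#'   `phenotree_too_few_beats` when fewer than `min_beats` beats are found,
#'   so callers can flag and exclude the record.
#' @export
build_median_beat <- function(rec, ref_lead = "II", window = c(0.4, 0.8),
                              min_beats = 3L) {
  stopifnot(inherits(rec, "ecg_record"))
  missing_leads <- setdiff(LEADS8, rec$lead_names)
  if (length(missing_leads))
    stopf("record is missing required leads: %s", paste(missing_leads, collapse = ", "))
  fs <- rec$fs
  peaks <- detect_r_peaks(rec$signal[ref_lead, ], fs)
  pre <- round(window[1] * fs)
  post <- round(window[2] * fs) - 1L
  peaks <- peaks[peaks - pre >= 1L & peaks + post <= ncol(rec$signal)]
  if (length(peaks) < min_beats) {
    stop(structure(class = c("phenotree_too_few_beats", "error", "condition"),
                   list(message = sprintf("only %d usable beat(s) detected (need >= %d)",
                                          length(peaks), min_beats),
                        call = NULL)))
  }
  Tn <- pre + post + 1L
  sig <- rec$signal[LEADS8, , drop = FALSE]
  stack <- array(NA_real_, c(8L, Tn, length(peaks)))
  for (b in seq_along(peaks)) {
    stack[, , b] <- sig[, (peaks[b] - pre):(peaks[b] + post)]
  }
  med <- apply(stack, c(1, 2), median)
  median_beat(med, fs = fs, fiducial_index = pre + 1L,
              source_id = as.character(rec$meta$id %||% NA_character_))
}

# Shared envelope-width rule: multi-lead RMS envelope, moving-average
# smoothing, onset/offset where the envelope crosses a fraction of its peak
# in the contiguous region around the envelope maximum.
envelope_width_ms <- function(mat, fs, smooth_ms = 20, threshold_frac = 0.1) {
  env <- sqrt(colMeans(mat^2))
  env <- smooth_ma(env, round(smooth_ms / 1000 * fs))
  pk <- max(env)
  if (pk <= 0) return(NA_real_)
  thr <- threshold_frac * pk
  ipk <- which.max(env)
  below_before <- which(env[seq_len(ipk)] < thr)
  onset <- if (length(below_before)) max(below_before) + 1L else 1L
  after <- seq(ipk, length(env))
  below_after <- after[env[after] < thr]
  offset <- if (length(below_after)) min(below_after) - 1L else length(env)
  (offset - onset) / fs * 1000
}

#' Measure QRS duration from a median beat
#'
#' Onset and offset are taken where a smoothed multi-lead RMS envelope
#' crosses a fraction of its peak (default 10% after 20 ms smoothing),
#' scanning outwards from the envelope maximum so that P and T waves in
#' separate envelope lobes do not inflate the measurement.
#'
#' @param beat a [median_beat()].
#' @param smooth_ms envelope smoothing window, ms.
#' @param threshold_frac onset/offset threshold as a fraction of envelope peak.
#' @return QRS duration in milliseconds.
#' @export
measure_qrs_duration <- function(beat, smooth_ms = 20, threshold_frac = 0.1) {
  stopifnot(inherits(beat, "median_beat"))
  w <- envelope_width_ms(beat$beats, beat$fs, smooth_ms, threshold_frac)
  if (is.na(w))
    stop(structure(class = c("phenotree_flat_signal", "error", "condition"),
                   list(message = "flat-line beat: QRS duration undefined", call = NULL)))
  w
}

#' Apply broad-QRS cohort selection
#'
#' Keeps records with QRS duration strictly greater than 120 ms and with no
#' pacing, cardiac implantable electronic device (CIED) or complete heart
#' block (CHB) flag, and reports per-rule exclusion counts mirroring a
#' selection flow chart. Rules are applied in a fixed order and each record
#' is attributed to the first rule it fails, so the counts telescope.
#'
#' @param records a data.frame of per-record metadata (columns `qrs_ms`,
#'   `paced_flag`, `cied_flag`, `chb_flag`) or a list of [ecg_record()]s
#'   whose `meta` carries those fields.
#' @param use_metadata_qrs if `FALSE`, a `measured_qrs_ms` column is used in
#'   place of `qrs_ms`.
#' @param qrs_threshold_ms records must exceed this duration (strict `>`).
#' @return a list with `records` (the surviving subset, same type as the
#'   input), `kept_ids` and `counts` (tibble: rule, excluded, remaining).
#' @export
apply_selection <- function(records, use_metadata_qrs = TRUE, qrs_threshold_ms = 120) {
  as_df <- is.data.frame(records)
  meta <- if (as_df) records else {
    do.call(rbind, lapply(records, function(r) {
      m <- r$meta
      data.frame(id = as.character(m$id %||% NA_character_),
                 qrs_ms = as.numeric(m$qrs_ms %||% NA_real_),
                 measured_qrs_ms = as.numeric(m$measured_qrs_ms %||% NA_real_),
                 paced_flag = isTRUE(m$paced_flag),
                 cied_flag = isTRUE(m$cied_flag),
                 chb_flag = isTRUE(m$chb_flag),
                 stringsAsFactors = FALSE)
    }))
  }
  qrs_col <- if (use_metadata_qrs) "qrs_ms" else "measured_qrs_ms"
  if (!qrs_col %in% names(meta)) stopf("metadata lacks column '%s'", qrs_col)
  qrs <- meta[[qrs_col]]
  flag <- function(col) if (col %in% names(meta)) isTRUE_vec(meta[[col]]) else rep(FALSE, nrow(meta))
  rules <- list(
    `QRS <= threshold or missing` = !(is.finite(qrs) & qrs > qrs_threshold_ms),
    `paced rhythm`                = flag("paced_flag"),
    `CIED present`                = flag("cied_flag"),
    `complete heart block`        = flag("chb_flag")
  )
  alive <- rep(TRUE, nrow(meta))
  excluded <- integer(length(rules))
  remaining <- integer(length(rules))
  for (j in seq_along(rules)) {
    hit <- alive & rules[[j]]
    excluded[j] <- sum(hit)
    alive <- alive & !hit
    remaining[j] <- sum(alive)
  }
  counts <- tibble::tibble(rule = names(rules), excluded = excluded, remaining = remaining)
  kept <- if (as_df) records[alive, , drop = FALSE] else records[alive]
  ids <- if ("id" %in% names(meta)) meta$id[alive] else which(alive)
  list(records = kept, kept_ids = ids, counts = counts)
}

isTRUE_vec <- function(x) {
  x <- as.logical(x)
  x[is.na(x)] <- FALSE
  x
}
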