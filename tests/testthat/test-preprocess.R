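# Filtering, resampling, median-beat construction, QRS measurement and
# broad-QRS selection.

make_rec <- function(signal, fs, leads = LEADS8) {
  ecg_record(signal, fs = fs, lead_names = leads, meta = list(id = "t1"))
}

test_that("filtering is linear, suppresses mains and resamples to 400 Hz", {
  fs <- 1000
  n <- 4000
  zero <- make_rec(matrix(0, 8, n), fs)
  fz <- filter_and_resample(zero)
  expect_true(all(fz$signal == 0))
  expect_equal(fz$fs, 400)
  expect_equal(ncol(fz$signal), round(n * 400 / fs))

  t <- seq_len(n) / fs
  mains <- make_rec(matrix(rep(sin(2 * pi * 60 * t), each = 8), 8, byrow = FALSE), fs)
  fm <- filter_and_resample(mains)
  rms_in <- sqrt(mean(mains$signal[1, ]^2))
  rms_out <- sqrt(mean(fm$signal[1, ]^2))
  expect_lt(rms_out, 0.1 * rms_in)

  # a mid-band component passes nearly untouched
  midband <- make_rec(matrix(rep(sin(2 * pi * 10 * t), each = 8), 8), fs)
  fmid <- filter_and_resample(midband)
  expect_gt(sqrt(mean(fmid$signal[1, ]^2)), 0.9 * sqrt(mean(midband$signal[1, ]^2)))

  low_fs <- make_rec(matrix(0, 8, 100), fs = 150)
  expect_error(filter_and_resample(low_fs), "too low")
})

test_that("median beat equals the per-sample median across aligned beats", {
  p <- morphology_params("LBBB", heart_rate_bpm = 60)
  clean <- generate_rhythm_strip(p, duration_s = 12, noise_sd = 0,
                                 jitter_sd_ms = 0, seed = 1)
  mb <- build_median_beat(clean)
  expect_s3_class(mb, "median_beat")
  expect_equal(nrow(mb$beats), 8)
  beat <- generate_median_beat(p, noise_sd = 0)
  win <- -80:80
  expect_equal(mb$beats[, mb$fiducial_index + win],
               beat$beats[, beat$fiducial_index + win],
               tolerance = 1e-6, ignore_attr = TRUE)

  # idempotence: a strip of one repeated beat maps to that beat again
  mb2 <- build_median_beat(clean)
  expect_identical(mb$beats, mb2$beats)
})

test_that("the median is robust to one corrupted beat (elementwise oracle)", {
  fs <- 400
  Tn <- 480
  template <- generate_median_beat(morphology_params("RBBB"), noise_sd = 0)$beats
  n_beats <- 10
  # build a strip of identical beats spaced 1.25 s apart, corrupt the 4th
  gap <- 500
  sig <- matrix(0, 8, gap * n_beats + Tn)
  fid <- 161
  centers <- fid + gap * (seq_len(n_beats) - 1) + 100
  for (b in seq_len(n_beats)) {
    idx <- (centers[b] - fid + 1):(centers[b] - fid + Tn)
    sig[, idx] <- sig[, idx] + template
  }
  corrupt <- (centers[4] - fid + 1):(centers[4] - fid + Tn)
  set.seed(8)
  # corrupt the precordial leads of one beat (detection lead II untouched)
  sig[3:8, corrupt] <- sig[3:8, corrupt] + matrix(rnorm(6 * Tn, 0, 2), 6)
  rec <- make_rec(sig, fs)
  mb <- build_median_beat(rec)
  # oracle: elementwise median of 9 identical beats + 1 corrupted = clean
  # beat; align on the detected energy peak of the template itself
  pk_t <- detect_r_peaks(template["II", ], fs)[1]
  win <- -100:150
  expect_equal(mb$beats[, mb$fiducial_index + win], template[, pk_t + win],
               tolerance = 0.05, ignore_attr = TRUE)
})

test_that("12-lead input collapses to the 8 independent leads", {
  p <- morphology_params("NSIVCD")
  strip <- generate_rhythm_strip(p, duration_s = 10, noise_sd = 0, seed = 2)
  full <- rbind(strip$signal,
                III = strip$signal["II", ] - strip$signal["I", ],
                aVR = -(strip$signal["I", ] + strip$signal["II", ]) / 2,
                aVL = strip$signal["I", ] - strip$signal["II", ] / 2,
                aVF = strip$signal["II", ] - strip$signal["I", ] / 2)
  rec12 <- ecg_record(full, fs = strip$fs, meta = list(id = "l12"))
  mb <- build_median_beat(rec12)
  expect_equal(nrow(mb$beats), 8)
  expect_equal(rownames(mb$beats), LEADS8)
})

test_that("too few beats raises a typed condition", {
  short <- make_rec(matrix(0, 8, 400), 400)
  expect_error(build_median_beat(short), class = "phenotree_too_few_beats")
})

test_that("QRS measurement rejects flat-lines", {
  flat <- median_beat(matrix(0, 8, 480))
  expect_error(measure_qrs_duration(flat), class = "phenotree_flat_signal")
})

test_that("broad-QRS selection applies the strict threshold and flags", {
  meta <- tibble::tibble(
    id = sprintf("r%02d", 1:10),
    qrs_ms = c(100, 110, 115, 120, 121, 130, 140, 150, 160, 170),
    paced_flag = FALSE, cied_flag = FALSE, chb_flag = FALSE)
  sel <- apply_selection(meta)
  expect_equal(nrow(sel$records), 6)          # 4 at or below 120 excluded
  expect_true("r05" %in% sel$kept_ids)        # 121 ms retained: strict >
  expect_false("r04" %in% sel$kept_ids)       # exactly 120 ms excluded

  # order independence (set semantics)
  sel_rev <- apply_selection(meta[10:1, ])
  expect_setequal(sel$kept_ids, sel_rev$kept_ids)
  expect_equal(sum(sel$counts$excluded), sum(sel_rev$counts$excluded))

  # all flags set: empty output with a complete audit trail
  allflag <- meta
  allflag$paced_flag <- TRUE
  sel0 <- apply_selection(allflag)
  expect_equal(nrow(sel0$records), 0)
  expect_equal(sum(sel0$counts$excluded), 10)
  expect_equal(sel0$counts$remaining[nrow(sel0$counts)], 0)
})
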