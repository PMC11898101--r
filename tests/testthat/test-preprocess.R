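make_rec <- function(n_s, fs = 250, ann = NULL, seed = 1) {
  withr::with_seed(seed, sig <- matrix(rnorm(19 * n_s), 19, n_s))
  eeg_recording(sig, fs, MONTAGE_1020,
                if (is.null(ann)) eegkan:::empty_annotations() else ann)
}

test_that("segmentation counts and labels follow the window arithmetic", {
  expect_equal(count_windows(400 * 3600, 12), 120000L)
  expect_equal(count_windows(12, 12), 1L)
  expect_equal(count_windows(11.9, 12), 0L)
  # 30 s with a seizure at [5, 9]: two full windows, labels sz/bg
  rec <- make_rec(30 * 250,
                  ann = data.frame(onset_s = 5, offset_s = 9,
                                   label = "seizure"))
  s <- segment_recording(rec)
  expect_length(s$segments, 2L)
  expect_equal(s$labels, c("seizure", "background"))
  expect_equal(dim(s$segments[[1]]), c(19L, 3000L))
  # sample conservation: windows * length + remainder = total
  expect_equal(length(s$segments) * 3000 + (30 * 250 - 2 * 3000),
               ncol(rec$signals))
  # single-window recording
  expect_length(segment_recording(make_rec(3000))$segments, 1L)
  # too-short recording gives an empty list
  expect_length(segment_recording(make_rec(1000))$segments, 0L)
})

test_that("the overlap-fraction labeling rule is honored", {
  ann <- data.frame(onset_s = 11, offset_s = 13, label = "seizure")
  rec <- make_rec(24 * 250, ann = ann)
  any_overlap <- segment_recording(rec, label_rule = 0)
  expect_equal(any_overlap$labels, c("seizure", "seizure"))
  # 1 s overlap out of 12 s = 8.3%: a 25% rule drops both
  quarter <- segment_recording(rec, label_rule = 0.25)
  expect_equal(quarter$labels, c("background", "background"))
})

test_that("STFT obeys the 23-frame, 125-bin shape contract", {
  fx <- stft_features(make_rec(3000)$signals)
  expect_equal(dim(fx), c(19L, 23L, 125L))
  expect_equal(stft_n_frames(3000), 23L)
  expect_equal(stft_n_freqs(), 125L)
  expect_equal(stft_n_frames(1000), 7L)
  expect_true(all(is.finite(fx)))
  # zero in, zero out (log1p(0) = 0)
  expect_equal(max(abs(stft_features(matrix(0, 19, 3000)))), 0)
  expect_error(stft_features(matrix(0, 19, 100)), "longer than")
  # a pure 10 Hz tone peaks in the 10 Hz bin (1 Hz resolution, DC dropped)
  tone <- matrix(sin(2 * pi * 10 * (0:2999) / 250), 1)
  ft <- stft_features(tone, stft_config(window_function = "rectangular"))
  expect_equal(which.max(ft[1, 5, ]), 10L)
})

test_that("standardization is exact on the training split and reusable", {
  withr::with_seed(51, x <- matrix(rnorm(600, 5, 3), 30, 20))
  st <- feature_stats(x)
  z <- standardize_features(x, st)
  expect_lt(max(abs(colMeans(z))), 1e-6)
  expect_lt(max(abs(apply(z, 2, var) - 1)), 1e-6)
  # constant feature maps to zero via the epsilon floor
  xc <- cbind(x, 7)
  zc <- standardize_features(xc, feature_stats(xc))
  expect_equal(zc[, 21], rep(0, 30))
  # the transform is a fixed affine map: applying it twice rescales twice
  expect_false(isTRUE(all.equal(standardize_features(z, st), z)))
  expect_error(standardize_features(x[, 1:5], st), "match")
})

test_that("band/time pooling averages into the requested shape", {
  fx <- array(1, dim = c(19, 23, 125))
  p <- pool_features(fx)
  expect_equal(dim(p), c(19L, 4L, 6L))
  expect_equal(max(abs(p - 1)), 0)   # mean of ones is one
  flat <- flatten_features(p)
  expect_equal(dim(flat), c(1L, 19L * 4L * 6L))
})

test_that("flattening is channel-major with frequency fastest", {
  fx <- array(0, dim = c(2, 3, 4))
  fx[1, 1, ] <- 1:4        # channel 1, frame 1 occupies the first 4 slots
  fx[2, 1, 1] <- 99        # channel 2 block starts at 3*4 offset
  v <- flatten_features(fx)[1, ]
  expect_equal(v[1:4], 1:4)
  expect_equal(v[12 + 1], 99)
})

test_that("montage conforming reorders, drops surplus, rejects missing", {
  rec <- make_rec(3000)
  shuffled <- eeg_recording(rec$signals[c(19:1), ], 250,
                            MONTAGE_1020[19:1])
  conf <- conform_recording(shuffled)
  expect_equal(conf$channel_names, MONTAGE_1020)
  expect_equal(conf$signals, rec$signals)
  extra <- eeg_recording(rbind(rec$signals, 0), 250,
                         c(MONTAGE_1020, "ECG"))
  expect_equal(nrow(conform_recording(extra)$signals), 19L)
  missing <- eeg_recording(rec$signals[-1, ], 250, MONTAGE_1020[-1])
  expect_error(conform_recording(missing), "FP1")
})

test_that("off-rate recordings are resampled to 250 Hz", {
  withr::with_seed(53, sig <- matrix(rnorm(19 * 2000), 19, 2000))
  rec <- eeg_recording(sig, 200, MONTAGE_1020)   # 10 s at 200 Hz
  conf <- conform_recording(rec)
  expect_equal(conf$fs, 250)
  expect_equal(ncol(conf$signals), 2500L)
})
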