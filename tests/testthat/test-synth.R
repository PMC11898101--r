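test_that("generation is a pure function of config and seed", {
  cfg <- sim_config(duration_s = 10)
  r1 <- gen_recording(cfg, seed = 81)
  r2 <- gen_recording(cfg, seed = 81)
  expect_identical(r1$signals, r2$signals)
  expect_identical(r1$annotations, r2$annotations)
  r3 <- gen_recording(cfg, seed = 82)
  expect_false(identical(r1$signals, r3$signals))
})

test_that("background spectral slope tracks the configured exponent", {
  for (expo in c(0.5, 1, 1.5)) {
    cfg <- sim_config(noise_exponent = expo, alpha_amp_uv = 0)
    rec <- gen_background(cfg, 60, seed = 83)
    x <- rec$signals[5, ]
    p <- Mod(stats::fft(x))^2
    f <- (seq_along(x) - 1) * 250 / length(x)
    sel <- f >= 2 & f <= 100
    slope <- -coef(lm(log(p[sel]) ~ log(f[sel])))[[2]]
    expect_lt(abs(slope - expo), 0.3)
  }
})

test_that("the alpha rhythm is posterior-dominant", {
  rec <- gen_background(sim_config(), 60, seed = 84)
  o_alpha <- band_power(rec$signals[match("O1", rec$channel_names), ],
                        250, 8, 12)
  f_alpha <- band_power(rec$signals[match("FP1", rec$channel_names), ],
                        250, 8, 12)
  expect_gt(o_alpha, f_alpha)
})

test_that("zero seizure rate is the identity with empty annotations", {
  cfg <- sim_config(seizure_rate = 0)
  rec <- gen_background(cfg, 20, seed = 85)
  out <- inject_seizures(rec, cfg, seed = 86)
  expect_identical(out$signals, rec$signals)
  expect_equal(nrow(out$annotations), 0L)
})

test_that("seizure bursts dominate the fundamental band inside annotations", {
  cfg <- sim_config(duration_s = 300)
  bg <- gen_background(cfg, 300, seed = 87)
  rec <- inject_seizures(bg, cfg, seed = 88)
  ann <- rec$annotations
  expect_gt(nrow(ann), 0L)
  ratios <- vapply(seq_len(nrow(ann)), function(i) {
    idx <- (round(ann$onset_s[i] * 250) + 1):(round(ann$offset_s[i] * 250))
    mean(vapply(1:19, function(ch) {
      band_power(rec$signals[ch, idx], 250, 2, 5) /
        band_power(bg$signals[ch, idx], 250, 2, 5)
    }, numeric(1)))
  }, numeric(1))
  expect_gte(mean(ratios), 3)
})

test_that("annotated occupancy tracks the configured ictal fraction", {
  cfg <- sim_config(duration_s = 3600)
  rec <- gen_recording(cfg, seed = 89, blinks = FALSE)
  frac <- sum(rec$annotations$offset_s - rec$annotations$onset_s) / 3600
  expect_lt(abs(frac - 0.25) / 0.25, 0.2)   # within 20% of target
})

test_that("zero blink rate is the identity; blinks are frontal-dominant", {
  cfg0 <- sim_config(blink_rate = 0)
  rec <- gen_background(cfg0, 20, seed = 90)
  expect_identical(inject_blinks(rec, cfg0, seed = 91)$signals, rec$signals)
  cfg <- sim_config()
  rec60 <- gen_background(cfg, 60, seed = 92)
  out <- inject_blinks(rec60, cfg, seed = 93)
  blink <- attr(out, "blink_train")
  expect_gte(abs(cor(out$signals[1, ], blink)), 0.3)
  added <- (out$signals - rec60$signals)^2
  front_var <- mean(added[1, ])
  post <- match(eegkan:::POSTERIOR_CHANNELS, out$channel_names)
  expect_lt(max(rowMeans(added[post, , drop = FALSE])), 0.05 * front_var)
})

test_that("datasets hit the requested label ratio and honor edge cases", {
  ds <- make_dataset(sim_config(), n_windows = 80, ictal_fraction = 0.25,
                     seed = 94, pool = list())
  expect_equal(sum(ds$y), 20L)       # exact by construction
  expect_equal(dim(ds$x), c(80L, 19L * 4L * 6L))
  expect_equal(ds$manifest$achieved_fraction, 0.25)
  ds0 <- make_dataset(sim_config(), n_windows = 20, ictal_fraction = 0,
                      seed = 95, pool = list())
  expect_true(all(ds0$labels == "background"))
})

test_that("full-resolution windows have the contract shape", {
  ds <- make_dataset(sim_config(), n_windows = 3, seed = 96)
  expect_equal(dim(ds$features[[1]]), c(19L, 23L, 125L))
  expect_equal(ncol(ds$x), 19L * 23L * 125L)
})

test_that("a zero shift reproduces the in-distribution dataset exactly", {
  cfg <- sim_config()
  zero <- ood_shift(seizure_freq_hz = cfg$seizure_freq_hz,
                    channel_gain_jitter = c(1, 1),
                    noise_exponent_delta = 0)
  d1 <- make_dataset(cfg, 12, seed = 97, pool = list())
  d2 <- make_ood_dataset(cfg, zero, 12, seed = 97, pool = list())
  expect_identical(d1$x, d2$x)
  expect_identical(d1$y, d2$y)
  d3 <- make_ood_dataset(cfg, ood_shift(), 12, seed = 97, pool = list())
  expect_false(identical(d1$x, d3$x))
  expect_identical(d3$manifest$shift$seizure_freq_hz, c(5.5, 7.5))
})

test_that("the OOD shift moves the seizure spectral peak out of band", {
  cfg <- sim_config(noise_amp_uv = c(5, 8), seizure_amp_uv = c(60, 80))
  peak_freq <- function(shift, seed) {
    ds <- make_dataset(cfg, 1, ictal_fraction = 1, seed = seed,
                       shift = shift)
    # average spectrum over channels/frames at full resolution
    spec <- apply(ds$features[[1]], 3, mean)
    which.max(spec)   # bin k is k Hz
  }
  in_peaks <- vapply(1:4, function(s) peak_freq(NULL, s), integer(1))
  ood_peaks <- vapply(1:4, function(s) peak_freq(ood_shift(), s), integer(1))
  expect_true(all(in_peaks >= 2 & in_peaks <= 5))
  expect_true(all(ood_peaks >= 5 & ood_peaks <= 8))
  expect_gt(mean(ood_peaks), mean(in_peaks))
})
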