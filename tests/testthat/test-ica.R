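test_that("Pearson helper matches the textbook formula", {
  expect_equal(pearson_r(c(1, 2, 3, 4), c(2, 4, 6, 8)), 1)
  withr::with_seed(61, {
    for (rep in 1:20) {
      a <- rnorm(30); b <- rnorm(30)
      expect_equal(pearson_r(a, b), oracle_pearson(a, b), tolerance = 1e-12)
    }
  })
  expect_warning(z <- pearson_r(rep(1, 10), rnorm(10)), "zero-variance")
  expect_equal(z, 0)
})

test_that("a 19-channel recording decomposes into 19 components", {
  rec <- gen_recording(sim_config(duration_s = 20), seed = 62)
  dec <- run_ica(rec, n_components = 19, seed = 1)
  expect_equal(ncol(dec$M), 19L)
  expect_equal(dim(dec$A), c(19L, 19L))
  expect_lt(dec$residual, 1e-6)
  expect_error(run_ica(rec, n_components = 25), "exceeds")
})

test_that("ICA is deterministic given the seed", {
  rec <- gen_recording(sim_config(duration_s = 15), seed = 63)
  d1 <- run_ica(rec, seed = 7)
  d2 <- run_ica(rec, seed = 7)
  expect_identical(d1$M, d2$M)
  expect_identical(d1$A, d2$A)
})

test_that("a single broadcast source concentrates in one component", {
  withr::with_seed(64, {
    src <- rnorm(3000)
    topo <- runif(19, 0.5, 2)
  })
  rec <- eeg_recording(outer(topo, src), 250, MONTAGE_1020)
  # rank-1 data cannot support 19 components
  expect_error(run_ica(rec, n_components = 19), "rank-deficient")
  dec <- run_ica(rec, n_components = 1, seed = 2)
  # that one component carries essentially all variance
  recon <- dec$M %*% dec$A
  tot <- sum((rec$signals - rowMeans(rec$signals))^2)
  expect_gt(1 - sum((t(recon) - (rec$signals - rowMeans(rec$signals)))^2) /
              tot, 0.99)
})

test_that("eye scoring finds planted frontal sources, misses orthogonal ones", {
  n <- 3000
  withr::with_seed(65, {
    src <- matrix(rnorm(3 * n), n, 3)
    mix <- matrix(runif(3 * 19, -1, 1), 3, 19)
  })
  rec <- eeg_recording(t(src %*% mix), 250, MONTAGE_1020)
  dec <- run_ica(rec, n_components = 3, seed = 3)
  dec <- score_eye_components(dec, rec)
  # a component equal to FP1 itself scores 1
  dec_self <- dec
  dec_self$M[, 1] <- rec$signals[1, ]
  s <- score_eye_components(dec_self, rec)
  expect_equal(s$eye_scores[1], 1)
  # fresh independent noise is near-orthogonal to both frontal channels
  withr::with_seed(66, dec_self$M[, 2] <- rnorm(n))
  s2 <- score_eye_components(dec_self, rec)
  expect_lt(s2$eye_scores[2], 0.05)
})

test_that("no component above threshold leaves the round-trip intact", {
  rec <- gen_recording(sim_config(duration_s = 15, blink_rate = 0),
                       seed = 67, blinks = FALSE)
  dec <- score_eye_components(run_ica(rec, seed = 4), rec)
  cleaned <- remove_components(dec, rec, threshold = 1)
  expect_length(attr(cleaned, "rejected"), 0L)
  rel <- sqrt(sum((cleaned$signals - rec$signals)^2) / sum(rec$signals^2))
  expect_lt(rel, 1e-6)
  expect_identical(cleaned$fs, rec$fs)
  expect_identical(cleaned$channel_names, rec$channel_names)
})

test_that("rejecting everything is refused", {
  rec <- gen_recording(sim_config(duration_s = 15), seed = 68)
  dec <- score_eye_components(run_ica(rec, seed = 5), rec)
  dec$eye_scores[] <- 0.99
  expect_error(remove_components(dec, rec, threshold = 0.5), "all-zero")
  expect_error(remove_components(dec, rec, threshold = 1.5), "threshold")
})

test_that("planted blinks are removed while posterior variance survives", {
  # the canonical eye-artifact experiment, one seed (the acceptance suite
  # runs the 5-seed version)
  cfg <- sim_config()
  base <- gen_background(cfg, 60, seed = 71)
  rec <- inject_blinks(base, cfg, seed = 171)
  blink <- attr(rec, "blink_train")
  expect_gte(abs(pearson_r(rec$signals[1, ], blink)), 0.3)
  cleaned <- clean_eye_artifacts(rec, seed = 71)
  expect_lt(abs(pearson_r(cleaned$signals[1, ], blink)), 0.1)
  post <- match(eegkan:::POSTERIOR_CHANNELS, rec$channel_names)
  ratio <- vapply(post, function(c)
    var(cleaned$signals[c, ]) / var(rec$signals[c, ]), numeric(1))
  expect_gt(min(ratio), 0.9)
})
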