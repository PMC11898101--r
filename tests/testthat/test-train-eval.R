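small_sep_data <- function(n, seed, d = 6) {
  # two well-separated Gaussian classes in d dimensions
  withr::with_seed(seed, {
    y <- sample(0:1, n, replace = TRUE)
    x <- matrix(rnorm(n * d, sd = 0.4), n, d) + outer(y, rep(0.8, d))
    list(x = x, y = y)
  })
}

test_that("split assembly hits the ratio with disjoint, seeded parts", {
  withr::with_seed(111, {
    x <- matrix(rnorm(500 * 4), 500, 4)
    y <- c(rep(1L, 100), rep(0L, 400))
  })
  sp <- assemble_splits(x, y, class_ratio = c(75, 25), seed = 7)
  kept <- unlist(sp$indices)
  expect_equal(length(kept), length(unique(kept)))   # disjoint
  yk <- y[kept]
  expect_equal(sum(yk == 1L), 100L)                  # all seizure kept
  expect_equal(sum(yk == 0L), 300L)                  # subsampled to 75:25
  # with exactly 300 bg + 100 sz available, everything is used
  sub <- c(sample(which(y == 0), 300), which(y == 1))
  sp2 <- assemble_splits(x[sub, ], y[sub], seed = 8)
  expect_equal(length(unlist(sp2$indices)), 400L)
  # reproducible
  sp3 <- assemble_splits(x, y, seed = 7)
  expect_identical(sp$indices, sp3$indices)
  expect_error(assemble_splits(x, rep(1L, 500)), "each class")
})

test_that("training is deterministic and rejects bad configs", {
  d <- small_sep_data(120, seed = 112)
  v <- small_sep_data(60, seed = 113)
  run <- function() {
    m <- kan_model("I-4-O", 6, 2, seed = 21)
    train_kan(m, d$x, d$y, v$x, v$y,
              cfg = train_config(epochs = 3, batch_size = 32, seed = 22))
  }
  f1 <- run(); f2 <- run()
  expect_identical(f1$history, f2$history)
  expect_identical(eegkan:::model_params(f1$model),
                   eegkan:::model_params(f2$model))
  expect_error(train_config(epochs = 0), "epochs")
  expect_error(train_config(epochs = 5, early_stop = 9), "patience")
  expect_error(train_kan(kan_model("I-3-O", 4, 2, seed = 1), d$x, d$y),
               "input_dim")
})

test_that("a separable problem trains to high validation AUROC", {
  d <- small_sep_data(240, seed = 114)
  v <- small_sep_data(120, seed = 115)
  m <- kan_model("I-6-O", 6, 2, seed = 23)
  fit <- train_kan(m, d$x, d$y, v$x, v$y,
                   cfg = train_config(epochs = 12, batch_size = 32,
                                      seed = 24, early_stop = 12))
  expect_gte(max(fit$history$auroc), 0.95)
  expect_equal(fit$selected_epoch, select_weights(fit$history$auroc,
                                                  patience = 12))
  s <- fit_summary(fit)
  expect_equal(s$selected_epoch, fit$selected_epoch)
})

test_that("evaluating the selected model on the training set is consistent", {
  d <- small_sep_data(160, seed = 116)
  v <- small_sep_data(80, seed = 117)
  st <- feature_stats(d$x)
  m <- kan_model("I-4-O", 6, 2, seed = 25)
  fit <- train_kan(m, standardize_features(d$x, st), d$y,
                   standardize_features(v$x, st), v$y,
                   cfg = train_config(epochs = 4, seed = 26))
  rep_v <- cross_dataset_eval(fit, v$x, v$y, st)
  expect_equal(rep_v$auroc, fit$history$auroc[fit$selected_epoch],
               tolerance = 1e-12)
  expect_identical(attr(rep_v, "stats_provenance"),
                   "training-split feature_stats")
})

test_that("feature sets round-trip through the directory layout", {
  d <- small_sep_data(60, seed = 118)
  dir <- withr::local_tempdir()
  splits <- list(train = list(x = d$x[1:40, ], y = d$y[1:40]),
                 val = list(x = d$x[41:60, ], y = d$y[41:60]))
  write_feature_set(splits, dir, manifest = list(note = "fixture"))
  back <- read_feature_set(dir)
  expect_equal(back$train$x, splits$train$x)
  expect_equal(back$val$y, splits$val$y)
  expect_equal(back$manifest$note, "fixture")
})
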