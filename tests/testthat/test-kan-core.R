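test_that("single-edge layer reduces to the edge activation", {
  withr::with_seed(1, {
    l <- kan_layer(1, 1)
    x <- runif(1, -1, 1)
  })
  expect_equal(layer_forward(l, x),
               edge_activation(x, edge_coeffs(l, 1, 1), l$base_weight[1, 1],
                               l$spline_scale[1, 1], l$cfg),
               tolerance = 1e-12)
})

test_that("layer and model forward match scalar nested-loop oracles", {
  withr::with_seed(11, {
    for (rep in 1:25) {
      in_d <- sample(1:5, 1); out_d <- sample(1:5, 1); hid <- sample(1:5, 1)
      m <- kan_model(sprintf("I-%d-O", hid), in_d, out_d)
      x <- runif(in_d, -1.3, 1.3)   # includes out-of-grid values
      expect_equal(model_forward(m, x), oracle_model_forward(m, x),
                   tolerance = 1e-8)
      l <- m$layers[[1]]
      expect_equal(as.numeric(layer_forward(l, x)),
                   oracle_layer_forward(l, x), tolerance = 1e-8)
    }
  })
})

test_that("batched forward equals per-sample forward", {
  m <- kan_model("I-4-O", 3, 2, seed = 5)
  withr::with_seed(6, X <- matrix(runif(30, -1, 1), 10, 3))
  Y <- model_forward(m, X)
  for (i in 1:10) {
    expect_equal(Y[i, ], model_forward(m, X[i, ]), tolerance = 1e-12)
  }
})

test_that("permuting inputs with the matching edge slices leaves output fixed", {
  withr::with_seed(3, {
    l <- kan_layer(4, 3)
    x <- runif(4, -1, 1)
    perm <- sample(4)
  })
  lp <- l
  lp$coef <- l$coef[, perm, , drop = FALSE]
  lp$base_weight <- l$base_weight[perm, , drop = FALSE]
  lp$spline_scale <- l$spline_scale[perm, , drop = FALSE]
  expect_equal(layer_forward(lp, x[perm]), layer_forward(l, x),
               tolerance = 1e-12)
})

test_that("identity second layer composes to the first layer alone", {
  cfg_id <- spline_config(base_function = "identity")
  m <- kan_model("I-3-O", 2, 3, cfg = cfg_id, seed = 9)
  # second layer: pass-through built from zero splines + identity base
  id_layer <- kan_layer(3, 3, cfg_id, init = "zero")
  id_layer$base_weight <- diag(3)
  m2 <- m
  m2$layers <- c(m$layers[1], list(id_layer))
  withr::with_seed(10, x <- runif(2, -1, 1))
  expect_equal(model_forward(m2, x),
               as.numeric(layer_forward(m$layers[[1]], x)),
               tolerance = 1e-12)
})

test_that("the exact representation form uses widths n, 2n+1, 1", {
  m <- kan_exact_form(2, seed = 1)
  widths <- c(m$input_dim, vapply(m$layers, `[[`, integer(1), "out_dim"))
  expect_equal(widths, c(2L, 5L, 1L))
  expect_length(m$layers, 2L)
})

test_that("dimension mismatches raise shape errors naming both sizes", {
  m <- kan_model("I-4-O", 3, 2, seed = 2)
  expect_error(model_forward(m, c(1, 2)), "2.*3|3.*2")
  expect_error(layer_forward(m$layers[[1]], runif(5)), "in_dim")
})

test_that("spec strings parse, round-trip, and reject malformed tokens", {
  expect_equal(eegkan:::parse_arch_spec("I-32-16-O"), c(32L, 16L))
  expect_equal(eegkan:::parse_arch_spec("I-O"), integer(0))
  m <- kan_model("I-7-4-O", 6, 2, seed = 1)
  expect_identical(m$spec, "I-7-4-O")
  widths <- vapply(m$layers, `[[`, integer(1), "out_dim")
  expect_equal(widths, c(7L, 4L, 2L))
  expect_error(eegkan:::parse_arch_spec("I-32-x-O"), "x")
  expect_error(eegkan:::parse_arch_spec("32-16"), "malformed")
  expect_error(arch_stats("I--O"), "malformed|bad")
})

test_that("architecture accounting reproduces the published reduction column", {
  expect_equal(arch_stats("I-32-32-O",
                          baseline = "I-764-256-O")$neuron_reduction_pct,
               6.27)
  expect_equal(arch_stats("I-32-16-O",
                          baseline = "I-764-256-O")$neuron_reduction_pct,
               4.71)
  self <- arch_stats("I-764-256-O", baseline = "I-764-256-O")
  expect_equal(self$neuron_reduction_pct, 100)
  expect_equal(self$param_reduction_pct, 100)
  expect_equal(arch_stats("I-32-32-O")$hidden_neurons, 64L)
})

test_that("parameter count increases with width, grid size, and order", {
  base <- arch_stats("I-16-8-O")$n_parameters
  expect_gt(arch_stats("I-17-8-O")$n_parameters, base)
  expect_gt(arch_stats("I-16-9-O")$n_parameters, base)
  expect_gt(arch_stats("I-16-8-O",
                       cfg = spline_config(grid_size = 6))$n_parameters, base)
  expect_gt(arch_stats("I-16-8-O",
                       cfg = spline_config(spline_order = 4))$n_parameters,
            base)
})

test_that("checkpoints round-trip bit-exactly and byte-stably", {
  m <- kan_model("I-5-3-O", 4, 2, seed = 21)
  p1 <- withr::local_tempfile(fileext = ".rds")
  p2 <- withr::local_tempfile(fileext = ".rds")
  save_kan(m, p1); save_kan(m, p2)
  expect_identical(unname(tools::md5sum(p1)), unname(tools::md5sum(p2)))
  m2 <- load_kan(p1)
  withr::with_seed(22, X <- matrix(runif(400, -1.5, 1.5), 100, 4))
  expect_identical(model_forward(m, X), model_forward(m2, X))
})

test_that("loading rejects empty, foreign, and wrong-version files", {
  empty <- withr::local_tempfile(fileext = ".rds")
  file.create(empty)
  expect_error(load_kan(empty), "empty")
  foreign <- withr::local_tempfile(fileext = ".rds")
  saveRDS(list(a = 1), foreign)
  expect_error(load_kan(foreign), "not an eegkan checkpoint")
  versioned <- withr::local_tempfile(fileext = ".rds")
  saveRDS(list(format = "eegkan-checkpoint", version = 99L), versioned)
  expect_error(load_kan(versioned), "version")
  expect_error(load_kan(tempfile()), "missing")
})
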