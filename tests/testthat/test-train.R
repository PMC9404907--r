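make_tiny_pairs <- function(n = 2, size = 32, amplitude = 3, seed = 50) {
  suite <- synth_suite(n, size = size, amplitude = amplitude, smoothness = 6,
                       n_trees = 2, branch_depth = 2,
                       vessel_width = c(1.2, 2.2), degrade = NULL, seed = seed)
  lapply(suite$pairs, function(p) list(ref = segment_vessels(p$i_ref),
                                       mov = segment_vessels(p$i_mov)))
}

test_that("zero learning rate leaves the weights unchanged", {
  pairs <- make_tiny_pairs(1)
  mod <- build_model(net_config(input_size = 32, depth = 2, base_filters = 4),
                     seed = 1)
  out <- train_model(mod, pairs, train_config(epochs = 1, batch_size = 1,
                                              learning_rate = 0, seed = 2))
  expect_identical(out$params, mod$params)
  expect_length(out$training_curve, 1)
})

test_that("training is deterministic given the seed", {
  pairs <- make_tiny_pairs(2)
  mod <- build_model(net_config(input_size = 32, depth = 2, base_filters = 4),
                     seed = 1)
  cfg <- train_config(epochs = 5, batch_size = 2, seed = 7)
  a <- train_model(mod, pairs, cfg)
  b <- train_model(mod, pairs, cfg)
  expect_identical(a$training_curve, b$training_curve)
  expect_identical(a$params, b$params)
})

test_that("training rejects empty or mismatched datasets", {
  mod <- build_model(net_config(input_size = 32, depth = 2, base_filters = 4))
  expect_error(train_model(mod, list()), class = "fundusreg_config_error")
  bad <- list(list(ref = matrix(runif(16 * 16), 16, 16),
                   mov = matrix(runif(16 * 16), 16, 16)))
  expect_error(train_model(mod, bad, train_config(epochs = 1)),
               class = "fundusreg_shape_error")
})

test_that("a short run improves the fitness on its own training pair", {
  pairs <- make_tiny_pairs(2, seed = 60)
  mod <- build_model(net_config(input_size = 32, depth = 2, base_filters = 4),
                     seed = 3)
  out <- train_model(mod, pairs,
                     train_config(epochs = 40, batch_size = 2,
                                  learning_rate = 1e-3, seed = 4))
  cv <- out$training_curve
  expect_length(cv, 40)
  expect_gt(cv[40], cv[1])
})

test_that("register_pair with an untrained model returns the moving map", {
  sp <- phantom_spec(size = 64, n_trees = 2, branch_depth = 3,
                     vessel_width = c(1.2, 2.6), seed = 70)
  pr <- make_pair(sp, deform = NULL, degrade = NULL)
  mod <- build_model(net_config(input_size = 64, depth = 2, base_filters = 4),
                     seed = 1)
  res <- register_pair(mod, pr$i_ref, pr$i_mov)
  # zero-initialized head -> identity transform -> BWarp == BMov
  expect_identical(res$b_warp$soft, res$b_mov$soft)
  expect_identical(dim(res$grid), c(64L, 64L, 2L))
  expect_true(all(res$grid == 0))
})

test_that("periodic checkpointing writes a loadable model", {
  pairs <- make_tiny_pairs(1)
  mod <- build_model(net_config(input_size = 32, depth = 2, base_filters = 4),
                     seed = 1)
  ck <- tempfile(fileext = ".rds")
  out <- train_model(mod, pairs,
                     train_config(epochs = 4, batch_size = 1, seed = 5,
                                  checkpoint_every = 2, checkpoint_path = ck))
  expect_true(file.exists(ck))
  saved <- load_model(ck)
  expect_s3_class(saved, "registration_model")
  expect_length(saved$training_curve, 4)
  expect_identical(saved$params, out$params)
})
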