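test_that("forward pass produces a full-resolution 2-channel field", {
  mod <- build_model(net_config(input_size = 64, depth = 2, base_filters = 8),
                     seed = 1)
  zero_in <- matrix(0, 64, 64)
  one_in <- matrix(runif(64 * 64), 64, 64)
  d <- forward_grid(mod, vessel_map(one_in), vessel_map(zero_in))
  expect_identical(dim(d), c(64L, 64L, 2L))
  expect_true(all(is.finite(d)))
})

test_that("a fresh model starts at the identity transform (zero head)", {
  mod <- build_model(net_config(input_size = 32, depth = 2, base_filters = 4),
                     seed = 5)
  expect_true(all(mod$params$final_W == 0))
  d <- forward_grid(mod, matrix(runif(1024), 32, 32),
                    matrix(runif(1024), 32, 32))
  expect_true(all(d == 0))
})

test_that("model building is deterministic in the seed", {
  cfg <- net_config(input_size = 32, depth = 2, base_filters = 4)
  a <- build_model(cfg, seed = 7)
  b <- build_model(cfg, seed = 7)
  c <- build_model(cfg, seed = 8)
  expect_identical(a$params, b$params)
  expect_false(identical(a$params, c$params))
})

test_that("configuration invariants are enforced", {
  expect_error(net_config(input_size = 50, depth = 2),
               class = "fundusreg_config_error")
  expect_error(net_config(depth = 0), class = "fundusreg_config_error")
  expect_error(net_config(kernel_size = 4), class = "fundusreg_config_error")
  mod <- build_model(net_config(input_size = 32, depth = 2, base_filters = 4))
  expect_error(forward_grid(mod, matrix(0.5, 16, 16), matrix(0.5, 16, 16)),
               class = "fundusreg_shape_error")
})

test_that("parameter count formula matches the built model", {
  for (cfg in list(net_config(input_size = 32, depth = 2, base_filters = 4),
                   net_config(input_size = 64, depth = 3, base_filters = 8),
                   net_config(input_size = 16, depth = 1, base_filters = 6))) {
    mod <- build_model(cfg, seed = 1)
    expect_identical(count_parameters(cfg),
                     sum(vapply(mod$params, length, integer(1))))
  }
})

test_that("the network is fully convolutional across input sizes", {
  cfg <- net_config(input_size = 16, depth = 2, base_filters = 4)
  mod <- build_model(cfg, seed = 2)
  for (sz in c(16L, 32L)) {
    m2 <- mod
    m2$config$input_size <- sz
    d <- forward_grid(m2, matrix(runif(sz^2), sz, sz),
                      matrix(runif(sz^2), sz, sz))
    expect_identical(dim(d), c(sz, sz, 2L))
  }
})

test_that("backpropagation matches central finite differences", {
  set.seed(11)
  cfg <- net_config(input_size = 16, depth = 2, base_filters = 4)
  mod <- build_model(cfg, seed = 3)
  mod$params$final_W[] <- rnorm(length(mod$params$final_W), sd = 0.01)
  x <- array(runif(16 * 16 * 2 * 2), c(16, 16, 2, 2))
  G <- array(rnorm(16 * 16 * 2 * 2), c(16, 16, 2, 2))
  fw <- fundusreg:::net_forward(mod, x, training = TRUE, keep_cache = TRUE)
  bk <- fundusreg:::net_backward(mod, fw$caches, G)
  lossat <- function(m) sum(fundusreg:::net_forward(m, x, training = TRUE)$out * G)
  eps <- 1e-6
  for (nm in c("enc0_c1_W", "enc1_c2_W", "dec2_t_W", "dec1_c1_g",
               "enc2_c1_be", "final_W")) {
    i <- sample(length(mod$params[[nm]]), 1)
    mp <- mod; mp$params[[nm]][i] <- mp$params[[nm]][i] + eps
    mm <- mod; mm$params[[nm]][i] <- mm$params[[nm]][i] - eps
    num <- (lossat(mp) - lossat(mm)) / (2 * eps)
    expect_lt(abs(num - bk$grads[[nm]][i]) / max(abs(num), 1e-4), 1e-3,
              label = sprintf("gradient for %s", nm))
  }
  # gradient of the mean output w.r.t. one input pixel
  i <- sample(length(x), 1)
  xp <- x; xp[i] <- xp[i] + eps
  xm <- x; xm[i] <- xm[i] - eps
  num <- (sum(fundusreg:::net_forward(mod, xp, training = TRUE)$out * G) -
            sum(fundusreg:::net_forward(mod, xm, training = TRUE)$out * G)) /
    (2 * eps)
  expect_lt(abs(num - bk$dx[i]) / max(abs(num), 1e-4), 1e-3)
})

test_that("checkpoints round-trip bit-exactly", {
  mod <- build_model(net_config(input_size = 32, depth = 2, base_filters = 4),
                     seed = 9)
  f <- tempfile(fileext = ".rds")
  save_model(mod, f)
  back <- load_model(f)
  expect_identical(back$params, mod$params)
  expect_identical(back$config, mod$config)
  expect_error(load_model(tempfile()), class = "fundusreg_io_error")
})
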