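test_that("MSE matches its hand-evaluated examples", {
  m <- matrix(runif(64), 8, 8)
  expect_equal(mse(m, m), 0)
  expect_equal(mse(matrix(0, 5, 7), matrix(1, 5, 7)), 1)
  a <- matrix(c(0, 1, 0.5, 0), 2, 2)
  b <- matrix(c(0, 0.5, 0, 0), 2, 2)
  expect_equal(mse(a, b), 0.125)
  expect_equal(mse(a, b), mse(b, a))
  expect_error(mse(a, matrix(0, 3, 3)), class = "fundusreg_shape_error")
})

test_that("SSIM is 1 exactly for identical images in both modes", {
  set.seed(31)
  m <- matrix(runif(32 * 32), 32, 32)
  expect_equal(ssim(m, m), 1.0, tolerance = 1e-12)
  expect_equal(ssim(m, m, ssim_params(mode = "global")), 1.0,
               tolerance = 1e-12)
})

test_that("global SSIM matches the direct formula, including negative values", {
  set.seed(32)
  m <- matrix(runif(24 * 24), 24, 24)
  m <- m - mean(m) + 0.5  # zero-mean around 0.5
  m <- pmin(pmax(m, 0), 1)
  inv <- 1 - m
  got <- ssim(m, inv, ssim_params(mode = "global"))
  mu1 <- mean(m); mu2 <- mean(inv)
  v1 <- mean(m^2) - mu1^2; v2 <- mean(inv^2) - mu2^2
  cv <- mean(m * inv) - mu1 * mu2
  c1 <- 1e-4; c2 <- 9e-4
  direct <- ((2 * mu1 * mu2 + c1) * (2 * cv + c2)) /
    ((mu1^2 + mu2^2 + c1) * (v1 + v2 + c2))
  expect_equal(got, direct, tolerance = 1e-12)
  expect_lt(got, 0)  # anti-correlated images score below zero, reported as-is
})

test_that("windowed SSIM agrees with the brute-force window oracle", {
  set.seed(33)
  for (rep in 1:3) {
    x <- matrix(runif(32 * 32), 32, 32)
    y <- pmin(pmax(x + rnorm(32 * 32, sd = 0.1), 0), 1)
    expect_equal(ssim(x, y), oracle_ssim_windowed(x, y), tolerance = 1e-8)
  }
})

test_that("Dice follows the stated overlap contract", {
  m <- mask_with_sizes(c(6, 9))
  expect_equal(dice(m, m), 1.0)
  a <- matrix(0, 6, 6); a[1:2, 1:2] <- 1
  b <- matrix(0, 6, 6); b[5:6, 5:6] <- 1
  expect_equal(dice(a, b), 0)
  # |A| = |B| = 4, |A and B| = 2
  b2 <- matrix(0, 6, 6); b2[1:2, 2:3] <- 1
  expect_equal(dice(a, b2), 0.5)
  expect_equal(dice(b2, a), 0.5)
  expect_equal(dice(matrix(0, 4, 4), matrix(0, 4, 4)), 1)  # degenerate
})

test_that("Dice is monotone in the intersection at fixed mask sizes", {
  base <- matrix(0, 8, 8); base[1:4, 1:4] <- 1
  prev <- -1
  for (shift in 3:0) {
    mv <- matrix(0, 8, 8); mv[1:4, (1 + shift):(4 + shift)] <- 1
    cur <- dice(base, mv)
    expect_gt(cur, prev)
    prev <- cur
  }
})

test_that("gain coefficient compares post- to pre-registration overlap", {
  r <- matrix(0, 8, 8); r[3:6, 3:6] <- 1
  m <- matrix(0, 8, 8); m[3:4, 3:6] <- 1    # overlap 8
  w <- matrix(0, 8, 8); w[3:6, 3:4] <- 1    # overlap 8
  expect_equal(gain_coefficient(r, m, m), 1.0)
  expect_equal(gain_coefficient(r, m, w), 1.0)
  w2 <- r  # overlap 16 = 2x
  expect_equal(gain_coefficient(r, m, w2), 2.0)
  expect_equal(gain_coefficient(r, m, matrix(0, 8, 8)), 0)
  expect_error(gain_coefficient(r, matrix(0, 8, 8), w),
               class = "fundusreg_undefined_baseline_error")
})

test_that("evaluate_all composes the four metrics consistently", {
  set.seed(34)
  soft <- matrix(runif(32 * 32), 32, 32)
  vm <- vessel_map(soft, threshold = 0.6)
  rep_ <- evaluate_all(vm, vm, vm)
  expect_equal(rep_$mse, 0)
  expect_equal(rep_$ssim, 1.0, tolerance = 1e-12)
  expect_equal(rep_$dice, 1.0)
  expect_equal(rep_$gc, 1.0)

  other <- vessel_map(matrix(runif(32 * 32), 32, 32), threshold = 0.4)
  r2 <- evaluate_all(vm, other, other)
  expect_identical(r2$mse, mse(vm$binary, other$binary))
  expect_identical(r2$ssim, ssim(vm$binary, other$binary))
  expect_identical(r2$dice, dice(vm, other))
  expect_identical(r2$gc, gain_coefficient(vm, other, other))
  expect_true(all(vapply(unclass(r2), is.finite, logical(1))))
})
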