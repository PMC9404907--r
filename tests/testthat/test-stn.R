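test_that("identity grid holds 0-based (row, col) coordinates", {
  g <- identity_grid(2, 2)
  expect_equal(g[, , 1], matrix(c(0, 1, 0, 1), 2, 2))
  expect_equal(g[, , 2], matrix(c(0, 0, 1, 1), 2, 2))
})

test_that("warping with the identity grid is exact", {
  set.seed(1)
  m <- matrix(runif(15 * 17), 15, 17)
  expect_identical(bilinear_warp(m, identity_grid(15, 17)), m)
  disp0 <- array(0, c(15, 17, 2))
  expect_identical(warp_displacement(m, disp0), m)
})

test_that("unit column shift matches the right-neighbour rule with clamping", {
  ramp <- matrix(rep(0:3, each = 4) / 3, 4, 4)
  grid <- identity_grid(4, 4)
  grid[, , 2] <- grid[, , 2] + 1
  out <- bilinear_warp(ramp, grid)
  expect_equal(out[, 1:3], ramp[, 2:4])
  expect_equal(out[, 4], ramp[, 4])  # clamped border
  expect_equal(out, oracle_bilinear(ramp, grid))
})

test_that("half-pixel shift interpolates midpoints", {
  row <- matrix(c(0, 1, 0), 1, 3)
  m <- rbind(row, row)  # 2 x 3 so bilinear is well-defined
  grid <- identity_grid(2, 3)
  grid[, , 2] <- grid[, , 2] + 0.5
  out <- bilinear_warp(m, grid)
  expect_equal(out[1, ], c(0.5, 0.5, 0))
  expect_equal(out, oracle_bilinear(m, grid))
})

test_that("sampler agrees with the brute-force oracle on random grids", {
  set.seed(33)
  for (rep in 1:100) {
    m <- matrix(runif(16 * 16), 16, 16)
    coords <- array(runif(16 * 16 * 2, -2, 17), c(16, 16, 2))
    expect_lt(max(abs(bilinear_warp(m, coords) - oracle_bilinear(m, coords))),
              1e-6)
  }
})

test_that("warped output stays inside the input intensity range", {
  set.seed(5)
  m <- matrix(runif(20 * 20, 0.2, 0.9), 20, 20)
  coords <- array(runif(20 * 20 * 2, -5, 25), c(20, 20, 2))
  out <- bilinear_warp(m, coords)
  expect_gte(min(out), min(m))
  expect_lte(max(out), max(m))
})

test_that("coordinate gradients pass a finite-difference check", {
  set.seed(9)
  m <- matrix(runif(12 * 12), 12, 12)
  # keep coordinates away from integer kinks and borders
  coords <- array(runif(12 * 12 * 2, 1.3, 9.7), c(12, 12, 2))
  coords <- coords + 0.41 - (coords %% 1) * 0  # arbitrary fractional parts
  dout <- matrix(rnorm(12 * 12), 12, 12)
  bw <- bilinear_warp_backward(m, coords, dout, want_image = TRUE)
  eps <- 1e-6
  for (k in 1:2) for (pick in c(7, 53, 101)) {
    cp <- coords; cp[, , k][pick] <- cp[, , k][pick] + eps
    cm <- coords; cm[, , k][pick] <- cm[, , k][pick] - eps
    num <- (sum(bilinear_warp(m, cp) * dout) -
              sum(bilinear_warp(m, cm) * dout)) / (2 * eps)
    ana <- bw$d_coords[, , k][pick]
    expect_lt(abs(num - ana) / max(abs(num), 1e-6), 1e-3)
  }
  # image-value gradient is exact (sampling is linear in the image)
  ip <- sample(144, 3)
  for (i in ip) {
    mp <- m; mp[i] <- mp[i] + eps
    num <- (sum(bilinear_warp(mp, coords) * dout) -
              sum(bilinear_warp(m, coords) * dout)) / eps
    expect_lt(abs(num - bw$d_image[i]) / max(abs(num), 1e-6), 1e-3)
  }
})

test_that("sampler rejects bad grids", {
  m <- matrix(runif(64), 8, 8)
  expect_error(bilinear_warp(m, identity_grid(9, 8)),
               class = "fundusreg_shape_error")
  bad <- identity_grid(8, 8)
  bad[1, 1, 1] <- NaN
  expect_error(bilinear_warp(m, bad), class = "fundusreg_value_error")
})

test_that("grids serialize bit-exactly", {
  g <- identity_grid(9, 9) + array(rnorm(9 * 9 * 2), c(9, 9, 2))
  f <- tempfile(fileext = ".rds")
  save_grid(g, f)
  expect_identical(load_grid(f), g)
})
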