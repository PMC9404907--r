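test_that("phantoms are deterministic per seed and well-ranged", {
  sp <- phantom_spec(size = 64, n_trees = 2, branch_depth = 3,
                     vessel_width = c(1.2, 2.6), seed = 17)
  a <- vessel_phantom(sp)
  b <- vessel_phantom(sp)
  expect_identical(a$pixels, b$pixels)
  expect_gte(min(a$pixels), 0)
  expect_lte(max(a$pixels), 1)
  c_ <- vessel_phantom(phantom_spec(size = 64, n_trees = 2, branch_depth = 3,
                                    vessel_width = c(1.2, 2.6), seed = 18))
  expect_false(identical(a$pixels, c_$pixels))
})

test_that("default phantom has a plausible vessel pixel fraction", {
  frac <- sapply(1:3, function(s) {
    ph <- vessel_phantom(phantom_spec(seed = s))
    mean(attr(ph, "vessel_mask"))
  })
  expect_true(all(frac >= 0.02 & frac <= 0.25))
})

test_that("deformation fields honour amplitude and zero-mean scaling", {
  z <- smooth_deformation(deformation_spec(amplitude = 0), 32, 32)
  expect_true(all(z == 0))
  for (amp in c(2, 6)) {
    d <- smooth_deformation(deformation_spec(amplitude = amp, seed = 3), 48, 48)
    mag <- sqrt(d[, , 1]^2 + d[, , 2]^2)
    expect_equal(max(mag), amp, tolerance = 1e-6)
  }
  d1 <- smooth_deformation(deformation_spec(seed = 5), 32, 32)
  d2 <- smooth_deformation(deformation_spec(seed = 5), 32, 32)
  expect_identical(d1, d2)
})

test_that("field correlation length grows with the smoothness parameter", {
  # empirical lag-1 autocorrelation of the row-displacement field
  ac1 <- function(sm) {
    d <- smooth_deformation(deformation_spec(amplitude = 4, smoothness = sm,
                                             seed = 9), 64, 64)
    f <- d[, , 1]
    stats::cor(as.vector(f[-1, ]), as.vector(f[-64, ]))
  }
  vals <- sapply(c(1, 4, 12), ac1)
  expect_true(all(diff(vals) > 0))
})

test_that("make_pair is the identity without deformation or degradation", {
  sp <- phantom_spec(size = 64, n_trees = 2, branch_depth = 3,
                     vessel_width = c(1.2, 2.6), seed = 4)
  pr <- make_pair(sp, deform = NULL, degrade = NULL)
  expect_identical(pr$i_mov$pixels, pr$i_ref$pixels)
  expect_true(all(pr$true_grid == 0))
})

test_that("segmentation overlap decays as deformation amplitude grows", {
  sp <- phantom_spec(size = 64, n_trees = 2, branch_depth = 3,
                     vessel_width = c(1.2, 2.6), seed = 12)
  dices <- sapply(c(0, 4, 8), function(amp) {
    pr <- make_pair(sp, deformation_spec(amplitude = amp, smoothness = 8,
                                         seed = 13), degrade = NULL)
    dice(segment_vessels(pr$i_ref), segment_vessels(pr$i_mov))
  })
  expect_true(all(diff(dices) < 0))
  expect_equal(dices[1], 1.0)
})

test_that("negating a small smooth field approximately inverts the warp", {
  sp <- phantom_spec(size = 64, n_trees = 2, branch_depth = 3,
                     vessel_width = c(1.2, 2.6), seed = 20)
  pr <- make_pair(sp, deformation_spec(amplitude = 0.25, smoothness = 12,
                                       seed = 21), degrade = NULL)
  back <- warp_displacement(pr$i_mov$pixels, -pr$true_grid)
  expect_lt(mse(back, pr$i_ref$pixels), 1e-3)
})

test_that("degradations dim, blur and occlude the moving image", {
  sp <- phantom_spec(size = 64, n_trees = 2, branch_depth = 3,
                     vessel_width = c(1.2, 2.6), seed = 30)
  clean <- make_pair(sp, deform = NULL, degrade = NULL)
  deg <- make_pair(sp, deform = NULL, degrade = degrade_options(seed = 31))
  expect_lt(mean(deg$i_mov$pixels), mean(clean$i_mov$pixels))
  expect_false(identical(deg$i_mov$pixels, clean$i_mov$pixels))
})

test_that("a synthetic suite is reproducible from its manifest", {
  s1 <- synth_suite(3, size = 64, amplitude = 4, n_trees = 2,
                    branch_depth = 3, vessel_width = c(1.2, 2.6), seed = 40)
  s2 <- synth_suite(3, size = 64, amplitude = 4, n_trees = 2,
                    branch_depth = 3, vessel_width = c(1.2, 2.6), seed = 40)
  expect_identical(s1$manifest, s2$manifest)
  for (i in 1:3)
    expect_identical(s1$pairs[[i]]$i_mov$pixels, s2$pairs[[i]]$i_mov$pixels)
})

test_that("degenerate fixtures exercise the metric failure paths", {
  # constant image -> undefined NCC
  expect_error(ncc(matrix(0.3, 16, 16), matrix(0.3, 16, 16)),
               class = "fundusreg_undefined_correlation_error")
  # disjoint masks -> undefined gain-coefficient baseline
  a <- matrix(0, 8, 8); a[1, 1] <- 1
  b <- matrix(0, 8, 8); b[8, 8] <- 1
  expect_error(gain_coefficient(a, b, b),
               class = "fundusreg_undefined_baseline_error")
})
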