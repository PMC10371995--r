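adiab <- boundarySpec("adiabatic", "adiabatic", "adiabatic", "adiabatic",
                      "adiabatic", "adiabatic")

test_that("stability bound follows the explicit-scheme formula", {
  cube <- buildToyScene("homogeneous-cube", pitch = 0.1, size = 2,
                        k_th = 0.5, c_v = 4000, rho = 1000)
  # rho c dx^2 / (6 k) x safety, dx = 1e-4 m
  expect_equal(stabilityDt(cube), 0.5 * 4e6 * 1e-8 / (0.5 * 6),
               tolerance = 1e-12)
  expect_equal(stabilityDt(cube), 6.7e-3, tolerance = 1e-2)
  half <- buildToyScene("homogeneous-cube", pitch = 0.05, size = 2,
                        k_th = 0.5, c_v = 4000, rho = 1000)
  expect_equal(stabilityDt(half), stabilityDt(cube) / 4)
  expect_equal(stabilityDt(cube, safety = 1), 2 * stabilityDt(cube))
  expect_error(runHeat(cube, NULL, t_end = 1, dt = 1), "stability")
})

test_that("uniform field with no source is an equilibrium", {
  cube <- buildToyScene("homogeneous-cube", pitch = 0.5, size = 5)
  r <- runHeat(cube, NULL, t_end = 5, T_init = 37, bc = adiab)
  expect_equal(range(r$T_final), c(37, 37))
  # fixed-temperature boundaries at the same value are also neutral
  r2 <- runHeat(cube, NULL, t_end = 5, T_init = 37,
                bc = boundarySpec(value = 37))
  expect_equal(range(r2$T_final), c(37, 37), tolerance = 1e-9)
})

test_that("harmonic-mean stencil reduces to the plain Laplacian for equal k", {
  cube <- buildToyScene("homogeneous-cube", pitch = 0.5, size = 5,
                        k_th = 0.4, c_v = 3000, rho = 1100)
  set.seed(31)
  T0 <- array(37 + rnorm(prod(dim(cube$label))), dim(cube$label))
  dt <- stabilityDt(cube)
  T1 <- heatStep(cube, T0, dt = dt, bc = adiab)
  # manual 6-neighbor Laplacian with conductance k (interior voxel)
  kmm <- 0.4 / 1000; rhoc <- 1100 * 3000 / 1e9; p <- 0.5
  i <- c(5, 5, 5)
  nb <- T0[4, 5, 5] + T0[6, 5, 5] + T0[5, 4, 5] + T0[5, 6, 5] +
    T0[5, 5, 4] + T0[5, 5, 6]
  expected <- T0[5, 5, 5] + dt / rhoc * kmm * (nb - 6 * T0[5, 5, 5]) / p^2
  expect_equal(T1[5, 5, 5], expected, tolerance = 1e-12)
})

test_that("point release matches the analytic heat kernel", {
  cube <- buildToyScene("homogeneous-cube", pitch = 0.2, size = 8,
                        k_th = 0.5, c_v = 4000, rho = 1000)
  rhoc <- 4e6 / 1e9
  alpha <- 5e-4 / rhoc                       # mm^2/s
  T0 <- array(0, dim(cube$label))
  T0[20, 20, 20] <- 100
  tend <- 2                                  # kernel sigma spans ~5 voxels
  r <- runHeat(cube, NULL, t_end = tend, T_init = T0, bc = adiab)
  cc <- voxelCenters(cube)
  ctr <- c(cc$x[20], cc$y[20], cc$z[20])
  E <- 100 * rhoc * cube$pitch^3
  Tref <- array(0, dim(cube$label))
  for (k in seq_len(cube$nz)) {
    Tref[, , k] <- outer(cc$x, cc$y, function(a, b)
      E / (rhoc * (4 * pi * alpha * tend)^1.5) *
        exp(-((a - ctr[1])^2 + (b - ctr[2])^2 + (cc$z[k] - ctr[3])^2) /
              (4 * alpha * tend)))
  }
  rmse <- sqrt(mean((r$T_final - Tref)^2))
  expect_lt(rmse / max(Tref), 0.02)
})

test_that("constant volumetric heating raises an adiabatic cube linearly", {
  cube <- buildToyScene("homogeneous-cube", pitch = 0.5, size = 5)
  q <- array(2e-3, dim(cube$label))          # W/mm^3
  r <- runHeat(cube, q, t_end = 8, T_init = 0, bc = adiab,
               record_stride = 2)
  rhoc <- 1000 * 4000 / 1e9
  expect_equal(mean(r$T_final), 2e-3 * 8 / rhoc, tolerance = 1e-9)
  rises <- colMeans(r$snapshots)
  expect_equal(rises, 2e-3 * r$times / rhoc, tolerance = 1e-9,
               ignore_attr = TRUE)
})

test_that("maximum principle holds without sources", {
  cube <- buildToyScene("homogeneous-cube", pitch = 0.5, size = 5)
  set.seed(8)
  T0 <- array(runif(prod(dim(cube$label)), 20, 60), dim(cube$label))
  r <- runHeat(cube, NULL, t_end = 10, T_init = T0, bc = adiab,
               record_stride = 2)
  expect_gte(min(r$snapshots), min(T0) - 1e-9)
  expect_lte(max(r$snapshots), max(T0) + 1e-9)
})

test_that("temperature rise is linear in the source power", {
  cube <- buildToyScene("homogeneous-cube", pitch = 0.5, size = 6)
  set.seed(9)
  q <- array(runif(prod(dim(cube$label))) * 1e-3, dim(cube$label))
  r1 <- runHeat(cube, q, t_end = 5, T_init = 37)
  r2 <- runHeat(cube, 3 * q, t_end = 5, T_init = 37)
  expect_equal(r2$T_final - 37, 3 * (r1$T_final - 37), tolerance = 1e-9)
})

test_that("inert voxels insulate and stay at their initial temperature", {
  scene <- suppressWarnings(buildSkinScene(pitch = 0.5))
  q <- array(0, dim(scene$label))
  q[20, 20, 2] <- 0.05
  r <- runHeat(scene, q, t_end = 20, T_init = 37)
  expect_equal(range(r$T_final[scene$label == 0L]), c(37, 37))
  expect_gt(max(r$T_final), 37)
})

test_that("validation phantom heats monotonically at the tumor center", {
  ph <- buildValidationPhantom(pitch = 1.5)
  g <- runPhotons(ph$scene, ph$beam, n = 2e4, seed = 17)
  q <- toHeatSource(g, ph$beam$power)
  ctr_idx <- which.max(q)                    # hottest voxel (tumor)
  r <- runHeat(ph$scene, q, t_end = 120, T_init = ph$T_init,
               bc = boundarySpec(value = 0), record_stride = 10,
               record_idx = ctr_idx)
  trace <- r$snapshots[1, ]
  expect_true(all(diff(trace) > 0))
  expect_gt(trace[length(trace)], ph$T_init)
})
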