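test_that("skin layer table matches the study's property sheet", {
  tab <- skinLayerTable()
  expect_equal(nrow(tab), 5)
  # four skin layers fill the 10 mm domain depth
  expect_equal(sum(tab$thickness[-1]), 10)
  expect_equal(tab$mu_abs[tab$material == "tumor"], 0.047)
  expect_true(all(tab$k_th > 0 & tab$c_v > 0 & tab$rho > 0))
})

test_that("skin scene lays out layers, tumor and inert exterior", {
  scene <- suppressWarnings(buildSkinScene(pitch = 0.1))
  expect_equal(scene$nz, 100)
  expect_equal(scene$nx, 200)
  cc <- voxelCenters(scene)
  # tumor: 4 mm diameter x 2 mm deep cylinder at the surface
  tm <- tumorMask(scene)
  vtum <- sum(tm) * scene$pitch^3
  expect_lt(abs(vtum - pi * 2^2 * 2) / (pi * 2^2 * 2), 0.05)
  ztum <- range(cc$z[apply(tm, 3, any)])
  expect_lt(ztum[2], 2.05)
  # outside-cylinder voxels are inert
  r <- sqrt(outer(cc$x^2, cc$y^2, `+`))
  expect_true(all(scene$label[, , 50][r > 10.1] == 0L))
  # layer order along the central column below the tumor
  col <- scene$label[5, 100, ]               # off-center: no tumor here
  labs <- unique(col[col != 0])
  expect_equal(labs, c(2L, 3L, 4L, 5L))
  # sub-pitch epidermis warns at coarse pitch
  expect_warning(buildSkinScene(pitch = 0.2), "thinnest layer")
})

test_that("scene rebuilds are deterministic", {
  s1 <- suppressWarnings(buildSkinScene(pitch = 0.2))
  s2 <- suppressWarnings(buildSkinScene(pitch = 0.2))
  expect_identical(s1$label, s2$label)
})

test_that("injection radius conserves total distributed volume", {
  expect_equal(injectionRadius(1, 1), 1)
  expect_equal(injectionRadius(7, 1), 7^(-1 / 3), tolerance = 1e-12)
  expect_equal(injectionRadius(7, 1), 0.523, tolerance = 1e-3)
  expect_equal(injectionRadius(1, 0.2), 0.2)
  # n (4/3) pi r^3 independent of n, scaling as phi^3
  v <- function(n, phi) n * 4 / 3 * pi * injectionRadius(n, phi)^3
  expect_equal(v(1, 1), v(7, 1))
  expect_equal(v(3, 0.6), v(5, 0.6))
  expect_equal(v(4, 0.5) / v(4, 1), 0.5^3)
})

test_that("injection layouts stay inside the tumor without overlap", {
  for (n in 1:7) {
    for (phi in c(0.2, 0.6, 1)) {
      plan <- placeInjections(n, phi)
      r <- plan$radius
      ctr <- plan$centers
      expect_equal(nrow(ctr), n)
      # entirely inside the tumor cylinder (radius 2, depth 0..2)
      rad <- sqrt(ctr[, 1]^2 + ctr[, 2]^2)
      expect_true(all(rad + r <= 2 + 1e-9))
      expect_true(all(ctr[, 3] - r >= -1e-9 & ctr[, 3] + r <= 2 + 1e-9))
      if (n > 1) {
        dmat <- as.matrix(dist(ctr))
        expect_true(all(dmat[upper.tri(dmat)] >= 2 * r - 1e-9))
      }
    }
  }
  expect_equal(placeInjections(1, 1)$centers, matrix(c(0, 0, 1), 1))
})

test_that("voxelized injection volume is conserved across injection counts", {
  eff <- opticalEfficiencies(C_abs = 10 * pi * 11^2, C_sca = 2 * pi * 11^2,
                             r_eff = 11)
  vols <- vapply(c(1, 3, 7), function(n) {
    scene <- suppressWarnings(buildSkinScene(pitch = 0.1))
    scene <- applyInjections(scene, placeInjections(n, 0.8), eff)
    gnp <- which(scene$materials$material == "tumor_gnp")
    sum(scene$label == gnp) * scene$pitch^3
  }, 0)
  expect_lt(diff(range(vols)) / mean(vols), 0.02)
  expect_equal(mean(vols), 4 / 3 * pi * 0.8^3, tolerance = 0.02)
})

test_that("particle-laden voxels get the combined optical properties", {
  eff <- opticalEfficiencies(C_abs = 10 * pi * 11^2, C_sca = 2 * pi * 11^2,
                             r_eff = 11)
  scene <- suppressWarnings(buildSkinScene(pitch = 0.2))
  scene <- applyInjections(scene, placeInjections(1, 1), eff)
  mats <- scene$materials
  gnp <- mats[mats$material == "tumor_gnp", ]
  f_v <- scene$meta$injections$f_v
  expect_equal(f_v, (4 / 3 * pi) / (pi * 4 * 2))
  expect_equal(gnp$mu_abs, 0.047 + 0.75 * f_v * 10 / 11e-6)
  # thermal properties inherited from the tumor
  expect_equal(gnp$k_th, mats$k_th[1])
  expect_equal(gnp$rho, mats$rho[1])
})

test_that("validation phantom geometry and beam follow the stated setup", {
  ph <- buildValidationPhantom(pitch = 0.5)
  vt <- sum(ph$scene$label == 1L) * 0.5^3
  expect_lt(abs(vt - 4 / 3 * pi * 125) / (4 / 3 * pi * 125), 0.05)
  expect_equal(ph$beam$power, 1 * pi * 1.5^2)  # 1 W/cm^2 x beam area
  expect_equal(ph$beam$profile, "top-hat")
  expect_equal(ph$beam$radius, 15)
  expect_equal(ph$T_init, 0)
})

test_that("toy scenes give single-material analytic fixtures", {
  slab <- buildToyScene("absorbing-slab", mu_abs = 1, mu_sca = 5)
  expect_equal(slab$materials$mu_sca, 0)   # purely absorbing by definition
  cube <- buildToyScene("homogeneous-cube", pitch = 0.5, size = 5)
  expect_true(all(cube$label == 1L))
  expect_equal(dim(cube$label), c(10, 10, 10))
})
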