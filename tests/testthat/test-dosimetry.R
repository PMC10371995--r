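test_that("band fractions partition any masked field", {
  # toy field with known counts: 3 below, 5 in band, 2 necrotic
  temps <- c(40, 42, 43, 44, 45, 46, 49, 49.9, 50, 55)
  bf <- bandFractions(temps)
  expect_equal(unname(bf), c(0.3, 0.5, 0.2))
  expect_equal(sum(bf), 1)
  expect_equal(unname(bandFractions(rep(45, 7))["apoptosis"]), 1)
  expect_equal(unname(bandFractions(rep(55, 7))["necrosis"]), 1)
  # boundary conventions: 43 and 50 are outside the apoptosis band
  expect_equal(unname(bandFractions(c(43, 50))["apoptosis"]), 0)
  set.seed(4)
  for (i in 1:10) {
    bf <- bandFractions(runif(50, 30, 70))
    expect_equal(sum(bf), 1)
  }
})

test_that("apoptosis retention ratio averages the in-band tumor fraction", {
  # 10-voxel toy mask over 4 snapshots
  allin <- matrix(45, nrow = 10, ncol = 4)
  expect_equal(thetaA(allin), 1)
  noneever <- matrix(30, nrow = 10, ncol = 4)
  expect_equal(thetaA(noneever), 0)
  half <- rbind(matrix(45, 5, 4), matrix(30, 5, 4))
  expect_equal(thetaA(half), 0.5)
  # time-varying: in-band only half the time
  flip <- cbind(matrix(45, 10, 2), matrix(55, 10, 2))
  expect_equal(thetaA(flip), 0.5)
  expect_error(thetaA(matrix(numeric(0), 0, 4)), "empty")
})

test_that("hazard retention weights the shell band occupancy", {
  w <- hazardWeights()
  cold <- matrix(40, 8, 3)
  expect_equal(thetaH(cold, w), 0)
  hot <- matrix(55, 8, 3)                    # single band of weight 0.75
  expect_equal(thetaH(hot, w), 0.75)
  # two-band toy: 60% of shell at weight 0.5, rest at weight 0
  mixed <- rbind(matrix(45, 6, 3), matrix(40, 4, 3))
  expect_equal(thetaH(mixed, w), 0.30)
  full <- thetaH(matrix(65, 5, 2), w)        # weight-1 band
  expect_equal(full, 1)
  expect_error(hazardWeights(w = c(0, 2, 0.5, 1)), "<= 1")
})

test_that("effective ratio is the quotient with degenerate sentinels", {
  expect_equal(thetaEff(0.6, 0.3), 2)
  expect_equal(thetaEff(0, 0.3), 0)
  expect_equal(thetaEff(0, 0), 0)
  inf <- thetaEff(0.5, 0)
  expect_equal(as.numeric(inf), Inf)
  expect_true(attr(inf, "degenerate"))
  expect_equal(thetaEff(0.3 * 2, 0.1 * 2), thetaEff(0.3, 0.1))
})

test_that("metrics stay within their theoretical bounds", {
  set.seed(6)
  for (i in 1:10) {
    snaps <- matrix(runif(60, 30, 80), nrow = 12)
    tA <- thetaA(snaps)
    tH <- thetaH(snaps)
    expect_gte(tA, 0); expect_lte(tA, 1)
    expect_gte(tH, 0); expect_lte(tH, 1)
    expect_gte(as.numeric(thetaEff(tA, tH)), 0)
  }
})

test_that("normal shell hugs the tumor without including it", {
  scene <- suppressWarnings(buildSkinScene(pitch = 0.1))
  sh <- normalShell(scene)
  tm <- tumorMask(scene)
  expect_equal(sum(sh & tm), 0)
  expect_equal(sum(sh & scene$label == 0L), 0)
  # thickness along +z under the tumor: 1 mm (half the tumor length)
  cc <- voxelCenters(scene)
  colz <- sh[100, 100, ]                      # on-axis column
  zrange <- range(cc$z[colz])
  expect_equal(zrange[1], 2.05, tolerance = 0.06)
  expect_equal(zrange[2], 3 - 0.05, tolerance = 0.06)
  # volume close to the analytic dilated-minus-tumor cylinder
  vol <- sum(sh) * scene$pitch^3
  vref <- pi * 3^2 * 3 - pi * 2^2 * 2
  # voxel shell uses Euclidean distance, so corners are rounded: the
  # analytic band is an upper bound and the rounded shell a bit smaller
  expect_lt(vol, vref)
  vref_round <- vref - (pi * 3^2 - pi * 2^2 * 1 - pi * 1^2 * 2) +
    (2 * pi * 2 * (pi * 1^2 / 4)) + pi * 1^2 * 1  # torus quarter + cap
  expect_gt(vol, 0.6 * vref)
})

test_that("sub-tumor peak reads the hottest voxel under the tumor", {
  scene <- suppressWarnings(buildSkinScene(pitch = 0.5))
  Tf <- array(37, dim(scene$label))
  cc <- voxelCenters(scene)
  kz <- which(cc$z > 2)[1]
  Tf[20, 20, kz] <- 44                        # under the tumor footprint
  Tf[2, 2, kz] <- 60                          # outside the footprint
  expect_equal(subTumorPeak(scene, Tf), 44)
})
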