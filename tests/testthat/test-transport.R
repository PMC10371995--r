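test_that("free-path sampling inverts the attenuation law", {
  expect_equal(sampleStep(1, exp(-1)), 1)
  expect_equal(sampleStep(2, exp(-1)), 0.5)
  expect_equal(sampleStep(1, 1), 0)
  expect_equal(sampleStep(0, 0.5), Inf)    # ballistic convention
  set.seed(11)
  s <- sampleStep(2.5, runif(1e5))
  expect_lt(abs(mean(s) - 1 / 2.5), 3 * sd(s) / sqrt(1e5))
})

test_that("direction sampling: isotropic closed form and HG mean", {
  expect_equal(sampleDirection(0, 0.75, 0)$cos_theta, 0.5)
  expect_equal(sampleDirection(0, 0.5, 0.5)$psi, pi)
  set.seed(12)
  d <- sampleDirection(0.9, runif(1e5), runif(1e5))
  # the HG mean cosine equals g
  expect_lt(abs(mean(d$cos_theta) - 0.9),
            3 * sd(d$cos_theta) / sqrt(1e5))
  expect_true(all(d$cos_theta >= -1 & d$cos_theta <= 1))
})

test_that("beam launch positions follow the stated profiles", {
  th <- laserBeam("top-hat", power = 1, radius = 2)
  set.seed(13)
  r_th <- vapply(runif(1e4), function(u) {
    p <- launchPhoton(th, u, 0.3)
    sqrt(sum(p$position[1:2]^2))
  }, 0)
  expect_true(all(r_th <= 2))
  ga <- laserBeam("gaussian", power = 1, radius = 2)
  r_ga <- vapply(runif(1e5), function(u) {
    p <- launchPhoton(ga, u, 0.3)
    sqrt(sum(p$position[1:2]^2))
  }, 0)
  # fraction inside r_l for the 1/e^2 Gaussian
  expect_equal(mean(r_ga <= 2), 1 - exp(-2), tolerance = 0.01)
  p <- launchPhoton(ga, 0.5, 0.25)
  expect_equal(p$direction, c(0, 0, 1))
  expect_equal(p$weight, 1)
})

test_that("weight deposition follows the albedo split", {
  expect_equal(depositWeight(1, 0.5, 1)$dW, 0.5)
  expect_equal(depositWeight(1, 0, 1)$dW, 0)
  # repeated interactions leave (1 - mu_abs/mu_ext)^k
  W <- 1
  for (i in 1:5) W <- depositWeight(W, 0.3, 1)$W
  expect_equal(W, 0.7^5)
})

test_that("roulette is unbiased and leaves healthy packets alone", {
  expect_equal(roulettePhoton(0.5, 0.99), 0.5)
  set.seed(14)
  w0 <- 5e-5
  post <- vapply(runif(1e5), function(u) roulettePhoton(w0, u), 0)
  expect_true(all(post %in% c(0, w0 * 10)))
  se <- sd(post) / sqrt(length(post))
  expect_lt(abs(mean(post) - w0), 3 * se)
})

test_that("energy is conserved and runs are seed-deterministic", {
  scene <- buildToyScene("homogeneous-cube", pitch = 0.5, size = 10,
                         mu_abs = 0.1, mu_sca = 2, g = 0.8)
  beam <- laserBeam("gaussian", power = 1, radius = 2)
  g1 <- runPhotons(scene, beam, n = 2e4, seed = 99)
  expect_lt(abs(g1$absorbed_total + g1$escaped - 1), 1e-3)
  expect_equal(sum(g1$absorbed), g1$absorbed_total, tolerance = 1e-12)
  g2 <- runPhotons(scene, beam, n = 2e4, seed = 99)
  expect_identical(g1$absorbed, g2$absorbed)
  g3 <- runPhotons(scene, beam, n = 2e4, seed = 100)
  expect_false(identical(g1$absorbed, g3$absorbed))
})

test_that("depth profile bookkeeping matches the total absorbed weight", {
  scene <- buildToyScene("absorbing-slab", pitch = 0.2, size = 10,
                         mu_abs = 0.5)
  beam <- laserBeam("top-hat", power = 1, radius = 1)
  g <- runPhotons(scene, beam, n = 2e4, seed = 5, record_cyl = TRUE)
  dp <- depthProfile(g)
  expect_equal(sum(dp$phi_z) * scene$pitch, g$absorbed_total,
               tolerance = 1e-10)
  g2 <- runPhotons(scene, beam, n = 100, seed = 5)
  expect_error(depthProfile(g2), "record")
})

test_that("absorbed fractions convert linearly to a heat source", {
  scene <- buildToyScene("absorbing-slab", pitch = 0.2, size = 6)
  beam <- laserBeam("top-hat", power = 1, radius = 1)
  g <- runPhotons(scene, beam, n = 5e3, seed = 3)
  q0 <- toHeatSource(g, 0)
  expect_true(all(q0 == 0))
  q1 <- toHeatSource(g, 1)
  q2 <- toHeatSource(g, 2)
  expect_equal(q2, 2 * q1)
  # sum(q V) = P x absorbed fraction
  expect_equal(sum(q1) * scene$pitch^3, g$absorbed_total, tolerance = 1e-12)
})

test_that("isotropic scattering keeps absorption rotation-symmetric", {
  scene <- buildToyScene("homogeneous-cube", pitch = 0.5, size = 10,
                         mu_abs = 0.2, mu_sca = 2, g = 0)
  beam <- laserBeam("top-hat", power = 1, radius = 0.25)
  g <- runPhotons(scene, beam, n = 1e5, seed = 21)
  a <- g$absorbed
  # quadrant totals around the beam axis, excluding the central columns
  n <- dim(a)[1]
  h <- n / 2
  q1 <- sum(a[1:h, 1:h, ]); q2 <- sum(a[(h + 1):n, 1:h, ])
  q3 <- sum(a[1:h, (h + 1):n, ]); q4 <- sum(a[(h + 1):n, (h + 1):n, ])
  counts <- c(q1, q2, q3, q4) * g$n
  chi2 <- sum((counts - mean(counts))^2 / mean(counts))
  expect_lt(chi2, qchisq(0.99, df = 3))
})

test_that("halving the packet count scales the Monte Carlo error by sqrt(2)", {
  scene <- buildToyScene("homogeneous-cube", pitch = 0.5, size = 10,
                         mu_abs = 0.5, mu_sca = 1, g = 0.5)
  beam <- laserBeam("gaussian", power = 1, radius = 1)
  probe <- function(n, seed) {
    g <- runPhotons(scene, beam, n = n, seed = seed)
    g$absorbed[10, 10, 3]
  }
  lo <- vapply(1:12, function(s) probe(2000, s), 0)
  hi <- vapply(1:12, function(s) probe(8000, 100 + s), 0)
  ratio <- sd(lo) / sd(hi)
  expect_gt(ratio, 1.2)                      # expect ~2 with wide noise band
  expect_lt(ratio, 3.5)
})
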