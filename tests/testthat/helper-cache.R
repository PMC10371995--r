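# shared fixtures for expensive computations, built once per test run

.cache <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (!exists(key, envir = .cache)) assign(key, force(expr), envir = .cache)
  get(key, envir = .cache)
}

# gold sphere DDA vs Mie at 1064 nm, shape-adapted prescription with the
# filtered kernel; key sized by lattice spacing (nm)
gold_sphere_dda <- function(spacing) {
  cached(paste0("gold_sphere_", spacing), {
    m <- refractiveIndex(goldDielectric(), 1064)
    k <- 2 * pi / 1064
    lat <- buildDipoleLattice(nanoparticleSpec("sphere", 20), spacing)
    al <- prescribedAlphaInv(lat, m, k, "filtered")
    s <- solveDipoleSystem(lat, al, k, kernel = "filtered")
    list(N = lat$N, eff = crossSections(s), residual = s$residual,
         mie = mieEfficiencies(20, m, 1064))
  })
}

# particle efficiencies stand-in for pipeline tests (calibrated-rod scale)
rod_eff <- function() {
  opticalEfficiencies(C_abs = 12 * pi * 11^2, C_sca = 1.2 * pi * 11^2,
                      r_eff = 11)
}

# one desk-preset distribution case, shared across sweep-shape checks
sweep_case <- function(phi, n, t_end = 600, seed = NULL) {
  if (is.null(seed)) seed <- 1000 + round(100 * phi) + n
  cached(sprintf("case_%g_%d_%g", phi, n, t_end), {
    suppressWarnings(runDistributionCase(phi, n, rod_eff(), preset = "desk",
                                         t_end = t_end, seed = seed))
  })
}
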