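#' Parametric study grid
#'
#' The study's sweep: distribution radius ratio 0.2-1.0 in steps of 0.2,
#' 1-7 injections, laser power 0-100 mW in steps of 2 mW (5 x 7 x 51 =
#' 1785 cases; 35 distribution cases).
#'
#' @param phi_drr Distribution radius ratios.
#' @param n_inj Injection counts.
#' @param power_mW Laser powers (mW).
#' @return A `SweepGrid`.
#' @export
sweepGrid <- function(phi_drr = seq(0.2, 1, by = 0.2), n_inj = 1:7,
                      power_mW = seq(0, 100, by = 2)) {
  stopifnot(length(phi_drr) >= 1, length(n_inj) >= 1, length(power_mW) >= 1)
  structure(list(phi_drr = phi_drr, n_inj = n_inj, power_mW = power_mW),
            class = "SweepGrid")
}

#' Enumerate sweep cases in deterministic order
#'
#' @param grid A [sweepGrid()].
#' @return data.frame of all (phi_drr, n, P_l) combinations, ordered by
#'   phi_drr, then injections, then power; attribute
#'   `n_distribution_cases` carries the count of (phi_drr, n) pairs.
#' @export
enumerateCases <- function(grid) {
  stopifnot(inherits(grid, "SweepGrid"))
  cases <- expand.grid(P_l = grid$power_mW, n = grid$n_inj,
                       phi_drr = grid$phi_drr,
                       KEEP.OUT.ATTRS = FALSE)[, c("phi_drr", "n", "P_l")]
  cases <- cases[order(cases$phi_drr, cases$n, cases$P_l), ]
  rownames(cases) <- NULL
  attr(cases, "n_distribution_cases") <-
    length(grid$phi_drr) * length(grid$n_inj)
  cases
}

#' Preset problem sizes
#'
#' `"desk"`: 0.2 mm pitch, 1e5 photon packets, 5 s snapshot stride --
#' sized so a distribution case runs in about a minute. `"paper"`: 0.1 mm
#' pitch, 1e6 packets, 1 s stride (full-fidelity settings).
#'
#' @param preset `"desk"` or `"paper"`.
#' @return List with `pitch`, `nphotons`, `stride`.
#' @export
presetOptions <- function(preset = c("desk", "paper")) {
  preset <- match.arg(preset)
  if (preset == "desk") list(pitch = 0.2, nphotons = 1e5, stride = 5)
  else list(pitch = 0.1, nphotons = 1e6, stride = 1)
}

#' Simulate one nanoparticle-distribution case at unit power
#'
#' Builds the skin + tumor scene with the requested injection layout, runs
#' Monte Carlo transport once, and integrates the heat equation with a
#' 1 W source. Because conduction with temperature-independent properties
#' is linear in the source, the temperature rise at any laser power is the
#' recorded unit-power rise scaled by the power; the 51-power sweep
#' reuses this single run.
#'
#' @param phi_drr Distribution radius ratio.
#' @param n_inj Number of injections.
#' @param eff Particle `OpticalEfficiencies` (see
#'   [defaultConverterEfficiencies()]).
#' @param preset `"desk"` or `"paper"` ([presetOptions()]).
#' @param t_end Irradiation time (s), default 600.
#' @param seed RNG seed for the transport run.
#' @param beam Beam description; default 1064 nm Gaussian, 2 mm radius
#'   (power field is ignored: the run is normalized per watt).
#' @param T_init Baseline temperature (degrees C).
#' @param bc Heat boundary conditions.
#' @param mode Transport attenuation convention (see [runPhotons()]).
#' @param fv_mode Volume-fraction semantics (see [applyInjections()]).
#' @return A `DistributionCase`: scene, absorption summary, per-watt
#'   temperature-rise snapshots `dT` (masked voxels x times) with row
#'   masks `is_tumor`/`is_shell`, per-watt final rise field `dT_final`
#'   (3-D), snapshot `times`, and provenance.
#' @export
runDistributionCase <- function(phi_drr, n_inj, eff, preset = "desk",
                                t_end = 600, seed = 1,
                                beam = laserBeam("gaussian", power = 1,
                                                 radius = 2,
                                                 wavelength = 1064),
                                T_init = 37, bc = boundarySpec(value = T_init),
                                mode = "reduced", fv_mode = "literal") {
  opt <- presetOptions(preset)
  scene <- buildSkinScene(pitch = opt$pitch)
  plan <- placeInjections(n_inj, phi_drr)
  scene <- applyInjections(scene, plan, eff, fv_mode = fv_mode)
  grid <- runPhotons(scene, beam, n = opt$nphotons, seed = seed, mode = mode)
  q <- toHeatSource(grid, P_l = 1)             # 1 W normalized source
  tmask <- tumorMask(scene)
  smask <- normalShell(scene)
  idx <- which(tmask | smask)
  run <- runHeat(scene, source = q, t_end = t_end, T_init = T_init, bc = bc,
                 record_stride = opt$stride, record_idx = idx)
  structure(list(phi_drr = phi_drr, n_inj = n_inj, scene = scene,
                 absorbed_total = grid$absorbed_total,
                 escaped = grid$escaped,
                 dT = run$snapshots - T_init,
                 dT_final = run$T_final - T_init,
                 times = run$times, idx = idx,
                 is_tumor = tmask[idx], is_shell = smask[idx],
                 provenance = list(seed = seed, nphotons = opt$nphotons,
                                   pitch = opt$pitch, stride = opt$stride,
                                   mode = mode, fv_mode = fv_mode,
                                   t_end = t_end, T_init = T_init,
                                   beam = beam)),
            class = "DistributionCase")
}

#' Dosimetry metrics of a distribution case across laser powers
#'
#' Scales the unit-power temperature rise to each requested power and
#' evaluates theta_A*, theta_H* and theta_eff*.
#'
#' @param case A `DistributionCase`.
#' @param power_mW Laser powers (mW).
#' @param band An [apoptosisBand()].
#' @param weights A [hazardWeights()].
#' @return data.frame: one row per power with `phi_drr`, `n`, `P_l`,
#'   `theta_A`, `theta_H`, `theta_eff`.
#' @export
caseMetrics <- function(case, power_mW, band = apoptosisBand(),
                        weights = hazardWeights()) {
  stopifnot(inherits(case, "DistributionCase"))
  T_init <- case$provenance$T_init
  tum <- case$dT[case$is_tumor, , drop = FALSE]
  sh <- case$dT[case$is_shell, , drop = FALSE]
  rows <- lapply(power_mW, function(P) {
    Twatts <- P / 1000
    tA <- thetaA(T_init + tum * Twatts, band)
    tH <- thetaH(T_init + sh * Twatts, weights)
    data.frame(phi_drr = case$phi_drr, n = case$n_inj, P_l = P,
               theta_A = tA, theta_H = tH,
               theta_eff = as.numeric(thetaEff(tA, tH)))
  })
  do.call(rbind, rows)
}

#' Run the full parametric sweep
#'
#' One transport + unit-power heat run per (phi_drr, n) distribution case,
#' metrics for every power by linear scaling.
#'
#' @param grid A [sweepGrid()].
#' @param eff Particle `OpticalEfficiencies`.
#' @param seed Base seed; case i uses `seed + i`.
#' @param progress Print one line per distribution case.
#' @param ... Passed to [runDistributionCase()].
#' @inheritParams caseMetrics
#' @return data.frame of metrics for every case in the grid.
#' @export
runSweep <- function(grid, eff, seed = 1, band = apoptosisBand(),
                     weights = hazardWeights(), progress = FALSE, ...) {
  stopifnot(inherits(grid, "SweepGrid"))
  combos <- expand.grid(n = grid$n_inj, phi_drr = grid$phi_drr,
                        KEEP.OUT.ATTRS = FALSE)
  out <- vector("list", nrow(combos))
  for (i in seq_len(nrow(combos))) {
    if (progress)
      message(sprintf("distribution case %d/%d: phi_drr = %g, n = %d",
                      i, nrow(combos), combos$phi_drr[i], combos$n[i]))
    case <- runDistributionCase(combos$phi_drr[i], combos$n[i], eff,
                                seed = seed + i, ...)
    out[[i]] <- caseMetrics(case, grid$power_mW, band, weights)
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Locate the optimal case
#'
#' Argmax of the chosen metric with deterministic tie-breaking: lowest
#' power first, then fewest injections, then smallest phi_drr. An `Inf`
#' metric (zero hazard with nonzero apoptosis) ranks above any finite
#' value.
#'
#' @param results Metrics data.frame from [runSweep()]/[caseMetrics()].
#' @param metric `"theta_eff"` or `"theta_A"`.
#' @return The winning row of `results`.
#' @export
findOptimum <- function(results, metric = c("theta_eff", "theta_A")) {
  metric <- match.arg(metric)
  if (nrow(results) == 0) stop("empty results")
  v <- results[[metric]]
  best <- which(v == max(v))
  cand <- results[best, ]
  cand <- cand[order(cand$P_l, cand$n, cand$phi_drr), ]
  cand[1, ]
}

#' Write sweep metrics as delimited text
#'
#' One row per case (phi_drr, n, P_l, theta_A, theta_H, theta_eff) plus
#' provenance columns for the seed and the hazard-band table used.
#'
#' @param metrics Metrics data.frame from [runSweep()]/[caseMetrics()].
#' @param file Output path (tab-separated).
#' @param seed Seed recorded with every row (NA when unknown).
#' @param weights The [hazardWeights()] the metrics were computed with;
#'   recorded as a compact band signature.
#' @return The path, invisibly.
#' @export
writeMetrics <- function(metrics, file, seed = NA,
                         weights = hazardWeights()) {
  sig <- paste(sprintf("%g:%g", weights$upper, weights$w), collapse = ",")
  out <- cbind(metrics, seed = seed, bands = sig)
  utils::write.table(out, file, sep = "\t", row.names = FALSE,
                     quote = FALSE)
  invisible(file)
}

#' Peak temperature directly beneath the tumor
#'
#' Maximum temperature over non-tumor voxels in the column under the
#' tumor's bottom face (lateral position within the tumor footprint,
#' depth below the tumor).
#'
#' @param scene A skin `VoxelScene`.
#' @param temperature 3-D temperature array on the scene grid.
#' @return Peak temperature (degrees C).
#' @export
subTumorPeak <- function(scene, temperature) {
  tum <- scene$meta$tumor
  if (is.null(tum)) stop("scene has no tumor")
  cc <- voxelCenters(scene)
  infoot <- outer(cc$x^2, cc$y^2, `+`) <= (tum$diameter / 2)^2
  below <- cc$z > tum$depth_offset + tum$length
  sel <- array(FALSE, dim(scene$label))
  for (k in which(below)) sel[, , k] <- infoot
  sel <- sel & !tumorMask(scene) & scene$label != 0L
  max(temperature[sel])
}
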