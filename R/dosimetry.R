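#' Apoptosis temperature band
#'
#' Programmed cell death is taken to occur strictly between the two
#' bounds; at or above the upper bound the tissue is counted as necrotic.
#'
#' @param lower,upper Band bounds in degrees C (both exclusive).
#' @return An `ApoptosisBand`.
#' @export
apoptosisBand <- function(lower = 43, upper = 50) {
  stopifnot(lower < upper)
  structure(list(lower = lower, upper = upper), class = "ApoptosisBand")
}

#' Thermal-hazard band weights
#'
#' Ordered, non-overlapping temperature bands with hazard weights in
#' [0, 1], used to grade damage phenomena (protein denaturation,
#' carbonization, ...) in the normal-tissue shell. The defaults are a
#' package assumption (the grading literature's exact weights are not
#' fixed here); every headline metric records the band table used.
#'
#' @param lower,upper Band bounds (degrees C); bands are `[lower, upper)`.
#' @param w Weights in [0, 1], one per band.
#' @return A `HazardWeights` object.
#' @export
hazardWeights <- function(lower = c(-Inf, 43, 50, 60),
                          upper = c(43, 50, 60, Inf),
                          w = c(0, 0.5, 0.75, 1)) {
  stopifnot(length(lower) == length(upper), length(w) == length(lower),
            all(lower < upper), all(w >= 0), all(w <= 1))
  if (any(lower[-1] < upper[-length(upper)]))
    stop("hazard bands must be ascending and non-overlapping")
  structure(list(lower = lower, upper = upper, w = w),
            class = "HazardWeights")
}

#' Normal-tissue shell around the tumor
#'
#' Non-tumor tissue voxels within a fixed distance of the tumor boundary
#' (default: 50% of the tumor length, i.e. 1 mm for the 2 mm tumor), the
#' region over which thermal hazard is scored.
#'
#' @param scene A skin `VoxelScene` (cylindrical tumor recorded in
#'   `meta$tumor`).
#' @param thickness Shell thickness (mm); defaults to half the tumor
#'   length.
#' @return Logical 3-D array, TRUE on shell voxels (never tumor, never
#'   outside-cylinder voxels).
#' @export
normalShell <- function(scene, thickness = NULL) {
  tum <- scene$meta$tumor
  if (is.null(tum)) stop("scene has no tumor")
  if (is.null(thickness)) thickness <- tum$length / 2
  cc <- voxelCenters(scene)
  Rt <- tum$diameter / 2
  z0 <- tum$depth_offset
  z1 <- tum$depth_offset + tum$length
  r <- sqrt(outer(cc$x^2, cc$y^2, `+`))
  dr <- pmax(r - Rt, 0)
  shell <- array(FALSE, dim(scene$label))
  for (k in seq_along(cc$z)) {
    dz <- max(z0 - cc$z[k], cc$z[k] - z1, 0)
    shell[, , k] <- sqrt(dr^2 + dz^2) <= thickness
  }
  shell & !tumorMask(scene) & scene$label != 0L
}

#' Temperature-band volume fractions over a mask
#'
#' @param temps Temperatures of the masked voxels (vector) or a full 3-D
#'   array with `mask` selecting voxels.
#' @param mask Optional logical array/vector.
#' @param band An [apoptosisBand()] (necrosis is at/above its upper
#'   bound).
#' @return Named vector of fractions `below`, `apoptosis`, `necrosis`
#'   summing to 1 over the mask.
#' @export
bandFractions <- function(temps, mask = NULL, band = apoptosisBand()) {
  v <- if (is.null(mask)) as.numeric(temps) else as.numeric(temps[mask])
  if (length(v) == 0) stop("empty mask")
  c(below = mean(v <= band$lower),
    apoptosis = mean(v > band$lower & v < band$upper),
    necrosis = mean(v >= band$upper))
}

#' Apoptosis retention ratio
#'
#' Time average (rectangle rule over uniformly spaced snapshots) of the
#' tumor-volume fraction strictly inside the apoptosis band.
#'
#' @param snapshots Matrix of temperatures, masked voxels x snapshot
#'   times (uniform spacing assumed).
#' @param band An [apoptosisBand()].
#' @return theta_A* in [0, 1].
#' @export
thetaA <- function(snapshots, band = apoptosisBand()) {
  snapshots <- as.matrix(snapshots)
  if (nrow(snapshots) == 0) stop("empty tumor mask")
  inband <- snapshots > band$lower & snapshots < band$upper
  mean(colMeans(inband))
}

#' Thermal hazard retention value
#'
#' Time average of the weighted in-band volume fractions of the
#' normal-tissue shell: at each snapshot,
#' `sum_j (shell fraction in band j) w_j`.
#'
#' @param snapshots Matrix of shell-voxel temperatures x snapshot times.
#' @param weights A [hazardWeights()].
#' @return theta_H* in [0, 1].
#' @export
thetaH <- function(snapshots, weights = hazardWeights()) {
  snapshots <- as.matrix(snapshots)
  if (nrow(snapshots) == 0) stop("empty shell mask")
  per_snap <- vapply(seq_len(ncol(snapshots)), function(j) {
    v <- snapshots[, j]
    sum(vapply(seq_along(weights$w), function(b) {
      mean(v >= weights$lower[b] & v < weights$upper[b]) * weights$w[b]
    }, 0))
  }, 0)
  mean(per_snap)
}

#' Effective apoptosis retention ratio
#'
#' The ratio theta_A* / theta_H*. A zero hazard with nonzero apoptosis
#' yields `Inf` with a flag attribute (`attr(x, "degenerate")`); zero
#' apoptosis yields 0.
#'
#' @param theta_A,theta_H The two retention values.
#' @return theta_eff* (>= 0, possibly `Inf`).
#' @export
thetaEff <- function(theta_A, theta_H) {
  if (theta_A == 0) return(0)
  if (theta_H == 0) {
    out <- Inf
    attr(out, "degenerate") <- TRUE
    return(out)
  }
  theta_A / theta_H
}
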