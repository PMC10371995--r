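#' Describe the irradiating laser beam
#'
#' @param profile `"gaussian"` or `"top-hat"`.
#' @param power Total beam power P_l (W).
#' @param radius Beam radius r_l (mm): the 1/e^2 radius for a Gaussian
#'   profile, the hard edge for a top-hat.
#' @param wavelength Wavelength (nm), carried as metadata.
#' @param center Lateral beam center (mm), default on-axis.
#' @return A `Beam` object. Incidence is normal to the surface (+z).
#' @export
laserBeam <- function(profile = c("gaussian", "top-hat"), power, radius,
                      wavelength = 1064, center = c(0, 0)) {
  profile <- match.arg(profile)
  stopifnot(power >= 0, radius > 0)
  structure(list(profile = profile, power = power, radius = radius,
                 wavelength = wavelength, center = center),
            class = "Beam")
}

#' Sample a free-path step length
#'
#' `S = -ln(xi) / mu_ext`. A vanishing attenuation coefficient returns
#' `Inf`, the ballistic-to-boundary convention used by the transport core.
#'
#' @param mu_ext Total attenuation coefficient (mm^-1).
#' @param xi Uniform(0, 1] random draw(s).
#' @return Step length(s) in mm.
#' @export
sampleStep <- function(mu_ext, xi) {
  stopifnot(mu_ext >= 0, all(xi > 0), all(xi <= 1))
  if (mu_ext == 0) return(rep(Inf, length(xi)))
  -log(xi) / mu_ext
}

#' Sample a scattering deflection
#'
#' Henyey-Greenstein inverse transform for `g > 0`; isotropic
#' `cos(theta) = 2 xi - 1` for `g = 0`. Azimuth `psi = 2 pi xi`.
#'
#' @param g Anisotropy factor, `0 <= g < 1`.
#' @param xi_theta,xi_psi Uniform(0, 1) draws.
#' @return List with `cos_theta` and `psi` (radians).
#' @export
sampleDirection <- function(g, xi_theta, xi_psi) {
  stopifnot(g >= 0, g < 1)
  if (g < 1e-6) {
    ct <- 2 * xi_theta - 1
  } else {
    tmp <- (1 - g^2) / (1 - g + 2 * g * xi_theta)
    ct <- (1 + g^2 - tmp^2) / (2 * g)
    ct <- pmin(1, pmax(-1, ct))
  }
  list(cos_theta = ct, psi = 2 * pi * xi_psi)
}

#' Launch a photon packet from a beam
#'
#' Radial position sampled from the beam profile (Gaussian:
#' `r = r_l sqrt(-ln(xi)/2)`; top-hat: `r = r_l sqrt(xi)`), direction +z,
#' weight 1.
#'
#' @param beam A [laserBeam()].
#' @param xi_r,xi_phi Uniform(0, 1) draws for radius and azimuth.
#' @return List with `position` (x, y, z = 0), `direction` (0, 0, 1) and
#'   `weight` (1).
#' @export
launchPhoton <- function(beam, xi_r, xi_phi) {
  stopifnot(inherits(beam, "Beam"))
  r <- if (beam$profile == "gaussian") {
    beam$radius * sqrt(-log(xi_r) / 2)
  } else {
    beam$radius * sqrt(xi_r)
  }
  phi <- 2 * pi * xi_phi
  list(position = c(beam$center[1] + r * cos(phi),
                    beam$center[2] + r * sin(phi), 0),
       direction = c(0, 0, 1), weight = 1)
}

#' Absorb part of a packet's weight at an interaction
#'
#' `Delta W = W mu_abs / mu_ext`; the packet keeps the remainder.
#'
#' @param W Packet weight.
#' @param mu_abs,mu_ext Absorption and stepping attenuation (mm^-1).
#' @return List with `dW` (deposited) and `W` (remaining weight).
#' @export
depositWeight <- function(W, mu_abs, mu_ext) {
  stopifnot(mu_ext > 0, mu_abs >= 0, mu_abs <= mu_ext)
  dW <- W * mu_abs / mu_ext
  list(dW = dW, W = W - dW)
}

#' Russian-roulette termination
#'
#' Below the weight threshold the packet survives with probability `1/m`
#' carrying weight `m W` (expected weight preserved), otherwise it is
#' terminated.
#'
#' @param W Packet weight.
#' @param xi Uniform(0, 1) draw.
#' @param threshold Weight threshold (default 1e-4).
#' @param m Survival multiplier (default 10).
#' @return The post-roulette weight (0 when terminated).
#' @export
roulettePhoton <- function(W, xi, threshold = 1e-4, m = 10) {
  if (W >= threshold) return(W)
  if (xi < 1 / m) W * m else 0
}

# per-material stepping attenuation for the chosen convention
.transport_props <- function(scene, mode) {
  mats <- scene$materials
  mu_red <- mats$mu_sca * (1 - mats$g)
  mu_ext <- if (mode == "reduced") mats$mu_abs + mu_red
            else mats$mu_abs + mats$mu_sca
  list(mu_abs = c(0, mats$mu_abs), mu_ext = c(0, mu_ext), g = c(0, mats$g))
}

#' Monte Carlo photon transport through a voxel scene
#'
#' Traces `n` photon packets from the beam through the scene, depositing
#' `Delta W = W mu_abs / mu_ext` at each interaction, Henyey-Greenstein
#' scattering, step-splitting at voxel boundaries, and Russian roulette.
#' Boundaries are refractive-index matched: packets leaving the grid or
#' entering an inert (label 0) voxel are counted as escaped.
#'
#' @param scene A `VoxelScene`.
#' @param beam A [laserBeam()].
#' @param n Number of photon packets.
#' @param seed Integer seed (applied via `set.seed`); `NULL` leaves the
#'   RNG state alone.
#' @param mode Stepping-attenuation convention: `"reduced"` (default)
#'   takes `mu_ext = mu_abs + mu_sca (1 - g)` while direction sampling
#'   still uses the tabulated g; `"full"` uses `mu_ext = mu_abs + mu_sca`.
#' @param record_cyl Record the cylindrical absorption histogram
#'   `phi_rz` (needed by [depthProfile()]).
#' @param dr Radial bin width for the cylindrical record (mm); defaults to
#'   the voxel pitch.
#' @param w_threshold,roulette_m Roulette parameters.
#' @return An `AbsorptionGrid`: `absorbed` (3-D array, absorbed fraction
#'   per voxel per launched packet), `escaped` and `absorbed_total`
#'   (fractions), `n`, `seed`, the beam, and the cylindrical record.
#' @export
runPhotons <- function(scene, beam, n, seed = NULL,
                       mode = c("reduced", "full"), record_cyl = FALSE,
                       dr = scene$pitch, w_threshold = 1e-4,
                       roulette_m = 10) {
  stopifnot(inherits(scene, "VoxelScene"), inherits(beam, "Beam"), n >= 1)
  mode <- match.arg(mode)
  if (!is.null(seed)) set.seed(seed)
  pr <- .transport_props(scene, mode)
  nr <- ceiling(sqrt((scene$nx * scene$pitch)^2 +
                       (scene$ny * scene$pitch)^2) / dr) + 1
  res <- mc_transport(as.integer(scene$label), scene$nx, scene$ny, scene$nz,
                      scene$pitch, scene$xmin, scene$ymin,
                      pr$mu_abs, pr$mu_ext, pr$g,
                      profile = if (beam$profile == "gaussian") 0L else 1L,
                      rl = beam$radius, x0 = beam$center[1],
                      y0 = beam$center[2], nphotons = as.integer(n),
                      w_threshold = w_threshold, roulette_m = roulette_m,
                      record_cyl = record_cyl, dr = dr, nr = as.integer(nr))
  structure(list(absorbed = array(res$absorbed / n,
                                  c(scene$nx, scene$ny, scene$nz)),
                 escaped = res$escaped / n,
                 absorbed_total = res$total_absorbed / n,
                 n = n, seed = seed, mode = mode, beam = beam,
                 pitch = scene$pitch,
                 phi_rz = if (record_cyl) res$phi_rz else NULL,
                 dr = if (record_cyl) dr else NULL),
            class = "AbsorptionGrid")
}

#' @export
print.AbsorptionGrid <- function(x, ...) {
  cat(sprintf(
    "AbsorptionGrid: %d packets, absorbed %.4f, escaped %.4f (mode %s)\n",
    x$n, x$absorbed_total, x$escaped, x$mode))
  invisible(x)
}

#' Depth profile of absorbed energy
#'
#' Collapses the cylindrical record onto depth:
#' `phi_z[i_z] = sum_{i_r} phi_rz[i_r, i_z] 2 pi (i_r + 0.5) (dr)^2`,
#' with `phi_rz` the absorbed probability density per unit volume
#' (weight / (N 2 pi (i_r + 0.5) dr^2 dz)), so `phi_z` is the absorbed
#' fraction per unit depth and `sum(phi_z) dz` recovers the total
#' absorbed fraction.
#'
#' @param grid An `AbsorptionGrid` produced with `record_cyl = TRUE`.
#' @return data.frame with `z` (mm, bin centers) and `phi_z` (mm^-1).
#' @export
depthProfile <- function(grid) {
  if (is.null(grid$phi_rz))
    stop("cylindrical record absent: rerun runPhotons(record_cyl = TRUE)")
  dz <- grid$pitch
  # raw weights -> density, then the ring-area weighted sum telescopes
  phi_z <- colSums(grid$phi_rz) / (grid$n * dz)
  data.frame(z = (seq_along(phi_z) - 0.5) * dz, phi_z = phi_z)
}

#' Convert absorbed fractions to a volumetric heat source
#'
#' `q_voxel = P_l x (absorbed fraction) / (voxel volume)`, so that
#' `sum(q V)` equals `P_l` times the total absorbed fraction.
#'
#' @param grid An `AbsorptionGrid`.
#' @param P_l Laser power (W).
#' @return 3-D array of power density (W/mm^3).
#' @export
toHeatSource <- function(grid, P_l) {
  stopifnot(P_l >= 0)
  grid$absorbed * P_l / grid$pitch^3
}
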