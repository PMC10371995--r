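#' Skin-layer and tumor property table
#'
#' Thermal and optical properties of the squamous-cell-carcinoma scenario:
#' tumor plus four skin layers (epidermis, papillary dermis, reticular
#' dermis, subcutaneous fat). Thermal conductivity in W/(m K), specific
#' heat in J/(kg K), density in kg/m^3, thickness in mm, optical
#' coefficients in mm^-1 at 1064 nm. The four skin-layer thicknesses sum
#' to the 10 mm domain depth.
#'
#' @return A data.frame, one row per material, in label order (label 1 =
#'   tumor, 2-5 = skin layers top to bottom).
#' @export
skinLayerTable <- function() {
  data.frame(
    material = c("tumor", "epidermis", "papillary_dermis",
                 "reticular_dermis", "subcutaneous_fat"),
    k_th = c(0.495, 0.235, 0.445, 0.445, 0.19),
    c_v = c(3421, 3589, 3300, 3300, 2500),
    rho = c(1070, 1200, 1200, 1200, 1000),
    thickness = c(2, 0.08, 0.5, 0.6, 8.82),
    mu_abs = c(0.047, 0.4, 0.38, 0.48, 0.43),
    mu_sca = c(0.883, 45, 30, 25, 5),
    g = c(0.8, 0.8, 0.9, 0.8, 0.75))
}

#' Construct a voxel scene
#'
#' @param label 3-D integer array of material labels (0 = inert/outside).
#' @param pitch Voxel pitch (mm), isotropic.
#' @param materials data.frame with one row per label (1..max) and columns
#'   `material`, `k_th` (W/mK), `c_v` (J/kgK), `rho` (kg/m^3), `mu_abs`,
#'   `mu_sca` (mm^-1), `g`.
#' @param xmin,ymin Lateral coordinates of the grid corner (mm); depth z
#'   starts at 0 (irradiated surface).
#' @param meta Free-form provenance list (tumor geometry, injections, ...).
#' @return A `VoxelScene`.
#' @export
voxelScene <- function(label, pitch, materials, xmin, ymin, meta = list()) {
  stopifnot(length(dim(label)) == 3, pitch > 0)
  lab <- as.integer(label)
  if (any(is.na(lab)) || any(lab < 0))
    stop("every voxel must carry a non-negative label")
  if (max(lab) > nrow(materials))
    stop("label table incomplete: label ", max(lab), " has no material row")
  needed <- c("material", "k_th", "c_v", "rho", "mu_abs", "mu_sca", "g")
  stopifnot(all(needed %in% names(materials)))
  structure(list(label = array(lab, dim(label)), pitch = pitch,
                 nx = dim(label)[1], ny = dim(label)[2], nz = dim(label)[3],
                 materials = materials, xmin = xmin, ymin = ymin,
                 meta = meta),
            class = "VoxelScene")
}

#' @export
print.VoxelScene <- function(x, ...) {
  cat(sprintf("VoxelScene: %d x %d x %d voxels at %.3g mm (%g x %g x %g mm)\n",
              x$nx, x$ny, x$nz, x$pitch, x$nx * x$pitch, x$ny * x$pitch,
              x$nz * x$pitch))
  tab <- table(factor(x$label, levels = 0:nrow(x$materials),
                      labels = c("outside", x$materials$material)))
  print(tab)
  invisible(x)
}

#' Voxel-center coordinates of a scene
#'
#' @param scene A `VoxelScene`.
#' @return List of vectors `x`, `y`, `z` (mm) giving voxel centers along
#'   each axis.
#' @export
voxelCenters <- function(scene) {
  p <- scene$pitch
  list(x = scene$xmin + (seq_len(scene$nx) - 0.5) * p,
       y = scene$ymin + (seq_len(scene$ny) - 0.5) * p,
       z = (seq_len(scene$nz) - 0.5) * p)
}

#' Build the layered-skin + tumor scene
#'
#' A 20 mm diameter x 10 mm deep skin cylinder embedded in a rectangular
#' voxel grid: four skin layers stacked in depth (epidermis, papillary
#' dermis, reticular dermis, subcutaneous fat) with a cylindrical
#' squamous-cell-carcinoma tumor (4 mm diameter x 2 mm long by default)
#' centered laterally and anchored at the irradiated surface. Voxels
#' outside the cylinder are labeled 0 (inert). Layers thinner than the
#' pitch are merged into their neighbors by nearest-layer assignment of
#' each voxel center (with a warning).
#'
#' @param pitch Voxel pitch (mm).
#' @param domain_diameter,domain_depth Skin cylinder size (mm).
#' @param tumor_diameter,tumor_length Tumor cylinder size (mm).
#' @param tumor_depth_offset Depth of the tumor's top face (mm); 0 places
#'   the tumor at the surface.
#' @return A `VoxelScene`; `meta$tumor` records the tumor geometry.
#' @export
buildSkinScene <- function(pitch = 0.2, domain_diameter = 20,
                           domain_depth = 10, tumor_diameter = 4,
                           tumor_length = 2, tumor_depth_offset = 0) {
  stopifnot(pitch > 0,
            tumor_depth_offset + tumor_length <= domain_depth,
            tumor_diameter <= domain_diameter)
  mats <- skinLayerTable()
  nx <- ny <- round(domain_diameter / pitch)
  nz <- round(domain_depth / pitch)
  xmin <- ymin <- -domain_diameter / 2
  xc <- xmin + (seq_len(nx) - 0.5) * pitch
  zc <- (seq_len(nz) - 0.5) * pitch
  bounds <- cumsum(c(0, mats$thickness[-1]))   # skin layer interfaces
  if (pitch > min(mats$thickness[-1]))
    warning("pitch ", pitch, " mm exceeds the thinnest layer (",
            min(mats$thickness[-1]),
            " mm): sub-pitch layers merge into neighbors by nearest-layer assignment")
  zlab <- findInterval(zc, bounds, rightmost.closed = FALSE)  # 1..4
  zlab <- pmin(zlab, 4L) + 1L                                  # labels 2..5
  lab <- array(0L, c(nx, ny, nz))
  r2 <- outer(xc^2, xc^2, `+`)                                 # lateral r^2
  incyl <- r2 <= (domain_diameter / 2)^2
  for (k in seq_len(nz)) lab[, , k] <- ifelse(incyl, zlab[k], 0L)
  intumor <- r2 <= (tumor_diameter / 2)^2
  ktum <- which(zc >= tumor_depth_offset &
                  zc <= tumor_depth_offset + tumor_length)
  for (k in ktum) lab[, , k][intumor] <- 1L
  voxelScene(lab, pitch, mats, xmin, ymin,
             meta = list(tumor = list(diameter = tumor_diameter,
                                      length = tumor_length,
                                      depth_offset = tumor_depth_offset,
                                      center = c(0, 0)),
                         domain = list(diameter = domain_diameter,
                                       depth = domain_depth)))
}

#' Per-injection distribution-sphere radius
#'
#' The total distributed volume is held constant across injection counts:
#' `r = phi_drr * base_radius * n^(-1/3)`, so `n (4/3) pi r^3` is
#' independent of `n` and scales as `phi_drr^3`.
#'
#' @param n Number of injections (1-7).
#' @param phi_drr Distribution radius ratio, in (0, 1].
#' @param base_radius Basis radius (mm): the single-injection,
#'   `phi_drr = 1` sphere radius (1 mm).
#' @return Sphere radius in mm.
#' @export
injectionRadius <- function(n, phi_drr, base_radius = 1) {
  stopifnot(n >= 1, n <= 7, phi_drr > 0, phi_drr <= 1)
  phi_drr * base_radius * n^(-1 / 3)
}

#' Lay out injection-sphere centers inside the tumor
#'
#' One sphere at the tumor centroid plus `n - 1` centers equally spaced on
#' a circle at the tumor's mid-depth plane, with the ring radius taken as
#' large as the tumor wall allows. When the center + ring layout cannot
#' satisfy pairwise non-overlap (small `n` with large spheres), all `n`
#' spheres go on the ring instead.
#'
#' @param n Number of injections.
#' @param phi_drr Distribution radius ratio.
#' @param tumor_diameter,tumor_length,tumor_depth_offset Tumor geometry
#'   (mm), matching [buildSkinScene()].
#' @param base_radius Basis radius (mm).
#' @return An `InjectionPlan`: list with `centers` (n x 3 matrix, mm),
#'   `radius` (mm), `n`, `phi_drr`.
#' @export
placeInjections <- function(n, phi_drr, tumor_diameter = 4, tumor_length = 2,
                            tumor_depth_offset = 0, base_radius = 1) {
  r <- injectionRadius(n, phi_drr, base_radius)
  Rt <- tumor_diameter / 2
  zmid <- tumor_depth_offset + tumor_length / 2
  if (r > tumor_length / 2 || r > Rt)
    stop("infeasible packing: sphere radius ", signif(r, 4),
         " mm does not fit inside the tumor")
  if (n == 1) {
    centers <- matrix(c(0, 0, zmid), 1)
  } else {
    ringR <- Rt - r
    ring_ok <- function(m, ringR) {
      # adjacent ring spheres must not overlap
      m < 2 || 2 * ringR * sin(pi / m) >= 2 * r - 1e-12
    }
    if (ringR >= 2 * r - 1e-12 && ring_ok(n - 1, ringR)) {
      ang <- 2 * pi * (seq_len(n - 1) - 1) / (n - 1)
      centers <- rbind(c(0, 0, zmid),
                       cbind(ringR * cos(ang), ringR * sin(ang), zmid))
    } else if (ring_ok(n, ringR)) {
      ang <- 2 * pi * (seq_len(n) - 1) / n
      centers <- cbind(ringR * cos(ang), ringR * sin(ang), zmid)
    } else {
      stop("infeasible packing: ", n, " spheres of radius ", signif(r, 4),
           " mm cannot be placed without overlap inside a ",
           tumor_diameter, " mm tumor")
    }
  }
  structure(list(centers = centers, radius = r, n = n, phi_drr = phi_drr,
                 base_radius = base_radius),
            class = "InjectionPlan")
}

#' Label nanoparticle-laden voxels and set their optical properties
#'
#' Marks the voxels inside the injection spheres with a new material label
#' whose optical coefficients are the host tumor's plus the
#' effective-medium particle addenda ([npCoefficients()],
#' [combineOptical()]); thermal properties remain the tumor's. The volume
#' fraction is, per injection, the distribution-sphere volume over the
#' tumor volume (the literal definition; `fv_mode = "dose"` switches to a
#' fixed total particle volume split across the spheres).
#'
#' @param scene A skin `VoxelScene` from [buildSkinScene()].
#' @param plan An `InjectionPlan` from [placeInjections()].
#' @param eff `OpticalEfficiencies` of the particle (default: the packaged
#'   calibrated gold nanorod via [defaultConverterEfficiencies()] is
#'   expensive; pass a precomputed one where possible).
#' @param fv_mode `"literal"` or `"dose"` (see [volumeFraction()]).
#' @param gnp_volume Total particle volume (mm^3) for `fv_mode = "dose"`.
#' @return The scene with an added `tumor_gnp` material row, relabeled
#'   voxels, and `meta$injections` recording the plan and coefficients.
#' @export
applyInjections <- function(scene, plan, eff, fv_mode = c("literal", "dose"),
                            gnp_volume = NULL) {
  stopifnot(inherits(scene, "VoxelScene"), inherits(plan, "InjectionPlan"))
  fv_mode <- match.arg(fv_mode)
  tum <- scene$meta$tumor
  if (is.null(tum)) stop("scene has no tumor to inject into")
  Vtumor <- pi * (tum$diameter / 2)^2 * tum$length
  Vsph <- 4 / 3 * pi * plan$radius^3
  f_v <- volumeFraction(Vsph, Vtumor, mode = fv_mode,
                        gnp_volume = gnp_volume, n_injections = plan$n)
  host <- scene$materials[1, ]
  tissue <- opticalProperties(host$mu_abs, host$mu_sca, host$g)
  np <- npCoefficients(f_v, eff)
  comb <- combineOptical(tissue, np)
  newlab <- nrow(scene$materials) + 1L
  row <- host
  row$material <- "tumor_gnp"
  row$mu_abs <- comb$mu_abs
  # store the full scattering consistent with the reduced bookkeeping
  row$mu_sca <- comb$mu_sca_red / (1 - host$g)
  scene$materials <- rbind(scene$materials, row)
  cc <- voxelCenters(scene)
  lab <- scene$label
  for (i in seq_len(plan$n)) {
    ctr <- plan$centers[i, ]
    dx2 <- (cc$x - ctr[1])^2
    dy2 <- (cc$y - ctr[2])^2
    dz2 <- (cc$z - ctr[3])^2
    for (k in which(dz2 <= plan$radius^2)) {
      inside <- outer(dx2, dy2, `+`) + dz2[k] <= plan$radius^2
      slab <- lab[, , k]
      slab[inside & slab == 1L] <- newlab
      lab[, , k] <- slab
    }
  }
  scene$label <- lab
  scene$meta$injections <- list(plan = plan, f_v = f_v, eff = eff,
                                np_part = np, combined = comb,
                                fv_mode = fv_mode)
  scene
}

#' Build the validation phantom
#'
#' A 5 mm radius spherical tumor embedded on-axis at 10 mm depth in a
#' 30 mm radius x 30 mm deep tissue cylinder, irradiated from the top by a
#' 805 nm top-hat beam of 15 mm radius at 1 W/cm^2 for 600 s, from a
#' uniform 0 degree C initial temperature. The phantom's material
#' properties are synthetic water-like stand-ins (the source study's
#' values are not part of this package); the fixture supports qualitative
#' heating-curve checks only.
#'
#' @param pitch Voxel pitch (mm); 1 mm keeps the 60 x 60 x 30 mm grid small.
#' @return List: `scene` (`VoxelScene`), `beam` ([laserBeam()], power =
#'   intensity x area = 1 W/cm^2 x pi 1.5^2 cm^2), `t_end` (600 s),
#'   `T_init` (0).
#' @export
buildValidationPhantom <- function(pitch = 1) {
  stopifnot(pitch > 0)
  mats <- data.frame(
    material = c("phantom_tumor", "phantom_tissue"),
    k_th = c(0.5, 0.5), c_v = c(4000, 4000), rho = c(1000, 1000),
    thickness = NA,
    mu_abs = c(0.4, 0.02), mu_sca = c(10, 10), g = c(0.9, 0.9))
  R <- 30; depth <- 30
  nx <- ny <- round(2 * R / pitch)
  nz <- round(depth / pitch)
  xmin <- ymin <- -R
  xc <- xmin + (seq_len(nx) - 0.5) * pitch
  zc <- (seq_len(nz) - 0.5) * pitch
  r2 <- outer(xc^2, xc^2, `+`)
  incyl <- r2 <= R^2
  lab <- array(0L, c(nx, ny, nz))
  for (k in seq_len(nz)) lab[, , k] <- ifelse(incyl, 2L, 0L)
  ctr <- c(0, 0, 10); rt <- 5
  for (k in which((zc - ctr[3])^2 <= rt^2)) {
    inside <- r2 + (zc[k] - ctr[3])^2 <= rt^2
    slab <- lab[, , k]
    slab[inside & slab == 2L] <- 1L
    lab[, , k] <- slab
  }
  scene <- voxelScene(lab, pitch, mats, xmin, ymin,
                      meta = list(tumor_sphere = list(center = ctr,
                                                      radius = rt)))
  beam <- laserBeam("top-hat", power = 1 * pi * 1.5^2, radius = 15,
                    wavelength = 805)
  list(scene = scene, beam = beam, t_end = 600, T_init = 0)
}

#' Single-material analytic test scenes
#'
#' @param kind `"absorbing-slab"` (purely absorbing, Beer-Lambert
#'   reference) or `"homogeneous-cube"` (uniform medium for heat-kernel and
#'   equilibrium checks).
#' @param pitch Voxel pitch (mm).
#' @param size Edge length (mm); the scene is a cube.
#' @param mu_abs,mu_sca,g Optical properties of the material.
#' @param k_th,c_v,rho Thermal properties (W/mK, J/kgK, kg/m^3).
#' @return A `VoxelScene` with every voxel labeled 1.
#' @export
buildToyScene <- function(kind = c("absorbing-slab", "homogeneous-cube"),
                          pitch = 0.2, size = 10, mu_abs = 1, mu_sca = 0,
                          g = 0, k_th = 0.5, c_v = 4000, rho = 1000) {
  kind <- match.arg(kind)
  if (kind == "absorbing-slab") mu_sca <- 0
  n <- round(size / pitch)
  lab <- array(1L, c(n, n, n))
  mats <- data.frame(material = kind, k_th = k_th, c_v = c_v, rho = rho,
                     thickness = NA, mu_abs = mu_abs, mu_sca = mu_sca, g = g)
  voxelScene(lab, pitch, mats, xmin = -size / 2, ymin = -size / 2,
             meta = list(kind = kind))
}

#' Tumor voxel mask
#'
#' @param scene A `VoxelScene` built by [buildSkinScene()] (tumor label 1,
#'   particle-laden tumor voxels labeled `tumor_gnp`).
#' @return Logical 3-D array: TRUE on tumor voxels (with or without
#'   particles).
#' @export
tumorMask <- function(scene) {
  labs <- c(1L, which(scene$materials$material == "tumor_gnp"))
  array(scene$label %in% labs, dim(scene$label))
}
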