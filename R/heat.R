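#' Boundary conditions for the heat solver
#'
#' @param xminus,xplus,yminus,yplus,zminus,zplus Per-face condition:
#'   `"adiabatic"` or `"fixed"`.
#' @param value Fixed-face temperature (degrees C), recycled per face.
#' @return A `BoundarySpec`. The default matches the skin study: the
#'   irradiated surface (`zminus`) adiabatic, all far faces clamped to
#'   body temperature.
#' @export
boundarySpec <- function(xminus = "fixed", xplus = "fixed",
                         yminus = "fixed", yplus = "fixed",
                         zminus = "adiabatic", zplus = "fixed",
                         value = 37) {
  faces <- c(xminus, xplus, yminus, yplus, zminus, zplus)
  stopifnot(all(faces %in% c("adiabatic", "fixed")))
  structure(list(type = as.integer(faces == "fixed"),
                 value = rep_len(value, 6), faces = faces),
            class = "BoundarySpec")
}

# per-material thermal vectors in mm units (W/(mm K), J/(mm^3 K));
# label 0 = inert: zero conductivity
.thermal_props <- function(scene) {
  mats <- scene$materials
  list(k = c(0, mats$k_th / 1000),
       rhoc = c(1, mats$rho * mats$c_v / 1e9))
}

#' Largest stable explicit time step
#'
#' `dt = safety x min over materials of rho c_v / (2 k (1/dx^2 + 1/dy^2 +
#' 1/dz^2))` for the isotropic-pitch grid.
#'
#' @param scene A `VoxelScene`.
#' @param safety Safety factor (default 0.5).
#' @return Time step in seconds.
#' @export
stabilityDt <- function(scene, safety = 0.5) {
  mats <- scene$materials
  stopifnot(all(mats$k_th > 0), all(mats$rho > 0), all(mats$c_v > 0))
  dx <- scene$pitch / 1000                      # m
  safety * min(mats$rho * mats$c_v / (2 * mats$k_th * 3 / dx^2))
}

#' Run the explicit heat-diffusion solver
#'
#' Explicit six-neighbor finite differences with harmonic-mean interface
#' conductivities on the voxel scene. Inert (label 0) voxels neither
#' conduct nor update, so the embedded tissue cylinder has adiabatic side
#' walls automatically.
#'
#' @param scene A `VoxelScene`.
#' @param source 3-D array of volumetric heating (W/mm^3), e.g. from
#'   [toHeatSource()]; `NULL` for no source.
#' @param t_end Simulated duration (s).
#' @param T_init Initial temperature: scalar or 3-D array (degrees C).
#' @param bc A [boundarySpec()].
#' @param dt Time step (s); defaults to [stabilityDt()] rounded down so
#'   that `record_stride` is an integer number of steps. Must not exceed
#'   the stability bound.
#' @param record_stride Snapshot interval (s); 0 disables snapshots.
#' @param record_idx Integer voxel indices (1-based, into the flattened
#'   array) whose temperatures are recorded at each snapshot; defaults to
#'   all voxels for small grids (< 2e5 voxels), otherwise required.
#' @param safety Stability safety factor when `dt` is derived.
#' @return A `TemperatureRun`: `T_final` (3-D array), `snapshots` (matrix,
#'   voxels x times), `times`, `dt`, `record_idx`.
#' @export
runHeat <- function(scene, source = NULL, t_end, T_init = 37,
                    bc = boundarySpec(), dt = NULL, record_stride = 0,
                    record_idx = NULL, safety = 0.5) {
  stopifnot(inherits(scene, "VoxelScene"), t_end > 0)
  ntot <- scene$nx * scene$ny * scene$nz
  dtmax <- stabilityDt(scene, safety = 1)
  if (is.null(dt)) {
    dt <- stabilityDt(scene, safety = safety)
    if (record_stride > 0) dt <- record_stride / ceiling(record_stride / dt)
  }
  if (dt > dtmax * (1 + 1e-9))
    stop("dt = ", dt, " s exceeds the stability bound ", dtmax, " s")
  nsteps <- ceiling(t_end / dt - 1e-9)
  record_every <- if (record_stride > 0) round(record_stride / dt) else 0L
  if (record_stride > 0 && abs(record_every * dt - record_stride) >
        1e-6 * record_stride)
    stop("record_stride must be an integer multiple of dt")
  if (is.null(record_idx)) {
    record_idx <- if (record_stride > 0 && ntot < 2e5) seq_len(ntot)
                  else integer(0)
  }
  q <- if (is.null(source)) numeric(ntot) else as.numeric(source)
  stopifnot(length(q) == ntot)
  T0 <- if (length(T_init) == 1) rep(T_init, ntot) else as.numeric(T_init)
  th <- .thermal_props(scene)
  res <- heat_run(as.integer(scene$label), scene$nx, scene$ny, scene$nz,
                  scene$pitch, th$k, th$rhoc, q, T0, dt,
                  as.integer(nsteps), bc$type, bc$value,
                  as.integer(record_every),
                  as.integer(record_idx - 1L))
  ns <- res$nsnap
  structure(list(T_final = array(res$T, c(scene$nx, scene$ny, scene$nz)),
                 snapshots = if (ns > 0) res$snapshots[, seq_len(ns),
                                                       drop = FALSE],
                 times = if (ns > 0) res$times[seq_len(ns)],
                 dt = dt, nsteps = nsteps, record_idx = record_idx,
                 bc = bc),
            class = "TemperatureRun")
}

#' @export
print.TemperatureRun <- function(x, ...) {
  cat(sprintf(
    "TemperatureRun: %d steps of %.4g s; final T in [%.2f, %.2f] C; %d snapshots\n",
    x$nsteps, x$dt, min(x$T_final), max(x$T_final),
    if (is.null(x$snapshots)) 0L else ncol(x$snapshots)))
  invisible(x)
}

#' Advance a temperature field by one explicit step
#'
#' Single-step wrapper around the same compiled kernel as [runHeat()];
#' useful for stencil-level checks.
#'
#' @inheritParams runHeat
#' @param T Current 3-D temperature array.
#' @return The updated 3-D temperature array.
#' @export
heatStep <- function(scene, T, source = NULL, dt, bc = boundarySpec()) {
  dtmax <- stabilityDt(scene, safety = 1)
  if (dt > dtmax * (1 + 1e-9))
    stop("dt = ", dt, " s exceeds the stability bound ", dtmax, " s")
  ntot <- scene$nx * scene$ny * scene$nz
  q <- if (is.null(source)) numeric(ntot) else as.numeric(source)
  th <- .thermal_props(scene)
  res <- heat_run(as.integer(scene$label), scene$nx, scene$ny, scene$nz,
                  scene$pitch, th$k, th$rhoc, q, as.numeric(T), dt, 1L,
                  bc$type, bc$value, 0L, integer(0))
  array(res$T, c(scene$nx, scene$ny, scene$nz))
}
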