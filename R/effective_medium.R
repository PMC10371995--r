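#' Tissue optical-property bundle
#'
#' @param mu_abs Absorption coefficient (mm^-1).
#' @param mu_sca Scattering coefficient (mm^-1); optional if `mu_sca_red`
#'   is given.
#' @param g Scattering anisotropy (mean cosine), in [-1, 1].
#' @param mu_sca_red Reduced scattering `mu_sca * (1 - g)` (mm^-1);
#'   computed when omitted.
#' @return An `OpticalProperties` list with `mu_abs`, `mu_sca`,
#'   `mu_sca_red`, `g`, and `mu_ext_reduced = mu_abs + mu_sca_red` /
#'   `mu_ext_full = mu_abs + mu_sca` (the two stepping conventions, see
#'   [runPhotons()]).
#' @export
opticalProperties <- function(mu_abs, mu_sca = NULL, g = 0,
                              mu_sca_red = NULL) {
  stopifnot(mu_abs >= 0, g >= -1, g <= 1)
  if (is.null(mu_sca_red)) {
    stopifnot(!is.null(mu_sca), mu_sca >= 0)
    mu_sca_red <- mu_sca * (1 - g)
  } else if (is.null(mu_sca)) {
    mu_sca <- if (g < 1) mu_sca_red / (1 - g) else 0
  }
  stopifnot(mu_sca_red >= 0)
  structure(list(mu_abs = mu_abs, mu_sca = mu_sca, mu_sca_red = mu_sca_red,
                 g = g, mu_ext_reduced = mu_abs + mu_sca_red,
                 mu_ext_full = mu_abs + mu_sca),
            class = "OpticalProperties")
}

#' Nanoparticle contribution to tissue optical coefficients
#'
#' Effective-medium relations for a dilute suspension of particles:
#' `mu_abs_np = 0.75 f_v Q_abs / r_eff` and likewise for scattering, with
#' `r_eff` converted to mm so the coefficients come out in mm^-1.
#'
#' @param f_v Volume fraction occupied by the particle-laden region
#'   (dimensionless, in [0, 1]).
#' @param eff An `OpticalEfficiencies` for the particle.
#' @param r_eff_nm Particle effective radius (nm); defaults to the one in
#'   `eff`.
#' @return An `OpticalProperties` carrying only the particle part, with
#'   `g = 0` (particles this small scatter nearly isotropically; the
#'   host tissue's g drives direction sampling, see [combineOptical()]).
#' @export
npCoefficients <- function(f_v, eff, r_eff_nm = eff$r_eff) {
  if (f_v < 0 || f_v > 1) stop("f_v must lie in [0, 1]")
  stopifnot(r_eff_nm > 0)
  r_eff_mm <- r_eff_nm * 1e-6
  opticalProperties(mu_abs = 0.75 * f_v * eff$Q_abs / r_eff_mm,
                    mu_sca = 0.75 * f_v * eff$Q_sca / r_eff_mm, g = 0)
}

#' Reduced scattering of the particle part
#'
#' @param mu_sca_np Particle scattering coefficient (mm^-1).
#' @param g Anisotropy used for the similarity reduction (the host
#'   tissue's g; see the methods vignette for why).
#' @return `mu_sca_np * (1 - g)` (mm^-1).
#' @export
reduceScattering <- function(mu_sca_np, g) {
  stopifnot(g >= -1, g <= 1)
  mu_sca_np * (1 - g)
}

#' Combine host-tissue and particle optical properties
#'
#' Component-wise sums of absorption and reduced scattering; the host's
#' anisotropy is retained for direction sampling (the reduced-scattering
#' bookkeeping leaves no separate particle g to mix in).
#'
#' @param tissue Host `OpticalProperties`.
#' @param np_part Particle-part `OpticalProperties` (from
#'   [npCoefficients()]); its reduced scattering is formed with the host g.
#' @return Combined `OpticalProperties`.
#' @export
combineOptical <- function(tissue, np_part) {
  stopifnot(inherits(tissue, "OpticalProperties"),
            inherits(np_part, "OpticalProperties"))
  np_red <- reduceScattering(np_part$mu_sca, tissue$g)
  opticalProperties(mu_abs = tissue$mu_abs + np_part$mu_abs,
                    mu_sca = tissue$mu_sca + np_part$mu_sca,
                    g = tissue$g,
                    mu_sca_red = tissue$mu_sca_red + np_red)
}

#' Volume fraction of the particle-laden region
#'
#' The study's literal definition: the ratio of the volume of one
#' injection's distribution sphere to the whole tumor volume (per
#' injection). An alternative dose-conserving mode divides a fixed total
#' particle volume across the distribution spheres instead.
#'
#' @param dist_volume Distribution-sphere volume of one injection (mm^3).
#' @param tumor_volume Total tumor volume (mm^3).
#' @param mode `"literal"` (default) or `"dose"`.
#' @param gnp_volume Total injected particle volume (mm^3); required for
#'   `mode = "dose"`.
#' @param n_injections Number of injections (for `mode = "dose"`).
#' @return Dimensionless volume fraction.
#' @export
volumeFraction <- function(dist_volume, tumor_volume, mode = c("literal", "dose"),
                           gnp_volume = NULL, n_injections = 1) {
  mode <- match.arg(mode)
  stopifnot(dist_volume > 0, tumor_volume > 0)
  if (dist_volume > tumor_volume)
    stop("distribution volume exceeds tumor volume")
  if (mode == "literal") return(dist_volume / tumor_volume)
  stopifnot(!is.null(gnp_volume), gnp_volume > 0)
  gnp_volume / (n_injections * dist_volume)
}
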