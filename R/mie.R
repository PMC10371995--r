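#' Lorenz-Mie efficiencies of a homogeneous sphere
#'
#' Standard Lorenz-Mie series for a sphere of complex refractive index `m`
#' (relative to the surrounding medium) at the given vacuum wavelength.
#' Used throughout the test suite as the independent oracle for the DDA
#' solver on spherical targets.
#'
#' @param radius Sphere radius (nm).
#' @param m Complex refractive index of the sphere relative to the host.
#' @param wavelength Wavelength in the host medium (nm).
#' @return An `OpticalEfficiencies` object (see [opticalEfficiencies()])
#'   with cross sections in nm^2 and dimensionless efficiencies.
#' @details The series is truncated at the standard Wiscombe rule
#'   `nmax = x + 4 x^(1/3) + 2`; the logarithmic derivative is computed by
#'   downward recurrence for numerical stability at large `|m| x`.
#' @export
mieEfficiencies <- function(radius, m, wavelength) {
  stopifnot(radius > 0, wavelength > 0)
  x <- 2 * pi * radius / wavelength
  if (identical(as.complex(m), as.complex(1))) {
    return(opticalEfficiencies(C_abs = 0, C_sca = 0, r_eff = radius))
  }
  nmax <- ceiling(x + 4 * x^(1/3) + 2)
  mx <- m * x
  # logarithmic derivative D_n(mx), downward recurrence
  nstart <- nmax + 15
  D <- complex(length.out = nstart + 1)
  for (n in nstart:1) {
    D[n] <- (n + 1) / mx - 1 / (D[n + 1] + (n + 1) / mx)
  }
  # Riccati-Bessel via upward recurrence on psi, chi (stable for moderate x)
  psi0 <- sin(x); psi1 <- sin(x) / x - cos(x)
  chi0 <- cos(x); chi1 <- cos(x) / x + sin(x)
  xi0 <- complex(real = psi0, imaginary = -chi0)
  xi1 <- complex(real = psi1, imaginary = -chi1)
  qext <- 0; qsca <- 0
  psim <- psi0; psin <- psi1
  xim <- xi0; xin <- xi1
  for (n in 1:nmax) {
    if (n > 1) {
      psi2 <- (2 * n - 1) / x * psin - psim
      xi2 <- (2 * n - 1) / x * xin - xim
      psim <- psin; psin <- psi2
      xim <- xin; xin <- xi2
    }
    Dn <- D[n]
    an <- ((Dn / m + n / x) * psin - psim) / ((Dn / m + n / x) * xin - xim)
    bn <- ((Dn * m + n / x) * psin - psim) / ((Dn * m + n / x) * xin - xim)
    qext <- qext + (2 * n + 1) * Re(an + bn)
    qsca <- qsca + (2 * n + 1) * (Mod(an)^2 + Mod(bn)^2)
  }
  Qext <- 2 / x^2 * qext
  Qsca <- 2 / x^2 * qsca
  area <- pi * radius^2
  opticalEfficiencies(C_abs = (Qext - Qsca) * area, C_sca = Qsca * area,
                      r_eff = radius)
}

#' Bundle optical cross sections and efficiencies
#'
#' Constructs the cross-section/efficiency bundle with the extinction
#' identity `C_ext = C_abs + C_sca` enforced by construction and
#' efficiencies `Q = C / (pi r_eff^2)`.
#'
#' @param C_abs,C_sca Absorption and scattering cross sections (nm^2).
#' @param r_eff Effective (volume-equivalent) radius (nm).
#' @param tol Relative tolerance below which a small negative cross section
#'   (numerical round-off) is clipped to zero; a larger negative value errors.
#' @return An `OpticalEfficiencies` object.
#' @export
opticalEfficiencies <- function(C_abs, C_sca, r_eff, tol = 1e-6) {
  scale <- max(abs(C_abs), abs(C_sca), 1e-300)
  if (C_abs < -tol * scale || C_sca < -tol * scale)
    stop("negative cross section beyond tolerance (unconverged solve?): ",
         "C_abs=", C_abs, " C_sca=", C_sca)
  C_abs <- max(C_abs, 0)
  C_sca <- max(C_sca, 0)
  area <- pi * r_eff^2
  structure(list(C_abs = C_abs, C_sca = C_sca, C_ext = C_abs + C_sca,
                 Q_abs = C_abs / area, Q_sca = C_sca / area,
                 Q_ext = (C_abs + C_sca) / area, r_eff = r_eff),
            class = "OpticalEfficiencies")
}

#' Write efficiencies as a delimited text row
#'
#' @param eff An `OpticalEfficiencies`.
#' @param file Output path (tab-separated; header written when the file
#'   does not yet exist, rows appended otherwise).
#' @param wavelength Wavelength (nm) recorded with the row.
#' @return The path, invisibly.
#' @export
writeEfficiencies <- function(eff, file, wavelength) {
  row <- data.frame(wavelength = wavelength, Q_abs = eff$Q_abs,
                    Q_sca = eff$Q_sca, Q_ext = eff$Q_ext,
                    r_eff = eff$r_eff)
  new <- !file.exists(file)
  utils::write.table(row, file, sep = "\t", row.names = FALSE,
                     col.names = new, append = !new, quote = FALSE)
  invisible(file)
}

#' @export
print.OpticalEfficiencies <- function(x, ...) {
  cat(sprintf(
    "OpticalEfficiencies (r_eff = %.3g nm): Q_abs = %.4g, Q_sca = %.4g, Q_ext = %.4g\n",
    x$r_eff, x$Q_abs, x$Q_sca, x$Q_ext))
  invisible(x)
}
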