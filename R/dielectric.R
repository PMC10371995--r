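#' Tabulated complex refractive index of gold
#'
#' Loads the packaged bulk-gold optical-constants table (400--1400 nm,
#' transcribed from Johnson & Christy 1972) as a `DielectricTable`.
#'
#' @param file Path to a tab-separated table with columns
#'   `wavelength_nm`, `n`, `k`. Defaults to the packaged gold table.
#' @return A `DielectricTable`: list with `wavelength` (nm, strictly
#'   increasing), `m` (complex refractive index) and the interpolation rule
#'   identifier (`"log-linear"`).
#' @export
goldDielectric <- function(file = system.file("extdata", "gold_nk.tsv",
                                              package = "pttsim")) {
  tab <- utils::read.table(file, header = TRUE, sep = "\t", comment.char = "#")
  dielectricTable(tab$wavelength_nm, complex(real = tab$n, imaginary = tab$k))
}

#' Construct a dielectric table
#'
#' @param wavelength Wavelengths in nm, strictly increasing.
#' @param m Complex refractive index at each wavelength; `Im(m) >= 0`
#'   (passive material convention, exp(-i omega t)).
#' @param interp Interpolation rule identifier; only `"log-linear"`
#'   (linear in log-wavelength) is implemented.
#' @return A `DielectricTable` object.
#' @export
dielectricTable <- function(wavelength, m, interp = "log-linear") {
  stopifnot(length(wavelength) == length(m), length(wavelength) >= 2)
  if (any(diff(wavelength) <= 0))
    stop("wavelengths must be strictly increasing")
  if (any(Im(m) < 0))
    stop("Im(m) must be >= 0 for a passive material")
  structure(list(wavelength = as.numeric(wavelength), m = as.complex(m),
                 interp = match.arg(interp, "log-linear")),
            class = "DielectricTable")
}

#' Interpolate a dielectric table
#'
#' @param table A `DielectricTable`.
#' @param wavelength Query wavelength(s) in nm; must lie inside the table's
#'   range (no extrapolation).
#' @return Complex refractive index at each query wavelength.
#' @export
refractiveIndex <- function(table, wavelength) {
  stopifnot(inherits(table, "DielectricTable"))
  rng <- range(table$wavelength)
  if (any(wavelength < rng[1] | wavelength > rng[2]))
    stop("wavelength outside tabulated range [", rng[1], ", ", rng[2], "] nm")
  lx <- log(table$wavelength)
  lq <- log(wavelength)
  re <- stats::approx(lx, Re(table$m), xout = lq)$y
  im <- stats::approx(lx, Im(table$m), xout = lq)$y
  complex(real = re, imaginary = im)
}

#' @export
print.DielectricTable <- function(x, ...) {
  cat("DielectricTable:", length(x$wavelength), "points,",
      min(x$wavelength), "-", max(x$wavelength), "nm,", x$interp,
      "interpolation\n")
  invisible(x)
}
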