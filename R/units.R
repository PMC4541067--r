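#' Physical constants used throughout the package
#'
#' All electro-optic algebra in this package is done in the field's customary
#' mixed units (debye, cubic angstrom, MV/cm, wavenumber), glued together by a
#' single set of conversion constants derived from CODATA values of
#' \eqn{h}, \eqn{c}, \eqn{e} and \eqn{\varepsilon_0} via Gaussian-cgs algebra:
#'
#' \describe{
#'   \item{`mvcm_per_d_a3`}{299.792458 --- field in MV/cm equivalent to a
#'     dipole-per-polarizability ratio of 1 D/\eqn{\AA^3}. Follows from
#'     1 D = 1e-18 esu cm, 1 \eqn{\AA^3} = 1e-24 cm\eqn{^3},
#'     1 statvolt = 299.792458 V.}
#'   \item{`kappa_cm`}{16.79201 --- Stark-shift coefficient
#'     \eqn{1\,\mathrm{D} \times 1\,\mathrm{MV/cm} / hc} in cm\eqn{^{-1}};
#'     the linear Stark shift of a 1 D dipole in a 1 MV/cm field.}
#'   \item{`curvature_to_a3`}{2517.058 --- product of the parabola curvature
#'     \eqn{A} (cm\eqn{^{-1}}D\eqn{^{-2}}) and \eqn{|\Delta\alpha|}
#'     (\eqn{\AA^3}); equals \eqn{10^{-12}/(2hc)} in cgs.}
#'   \item{`kcoul_v_ang`}{14.39965 --- Coulomb constant
#'     \eqn{e/(4\pi\varepsilon_0 \cdot 1\,\AA)} in volts; the potential of a
#'     unit charge at 1 angstrom.}
#'   \item{`mu2_from_extinction`}{9.185931e-3 --- constant in
#'     \eqn{|\mu|^2[\mathrm{D}^2] = 9.186\times10^{-3}\int(\varepsilon/\bar\nu)\,d\bar\nu};
#'     equals \eqn{3000\ln 10\, hc/(8\pi^3 N_A)} scaled to D\eqn{^2}.}
#'   \item{`c2pa_gm`}{52.56000 --- prefactor of the degenerate two-level
#'     two-photon cross section,
#'     \eqn{\sigma_2[\mathrm{GM}] = 52.56\, (f_{opt}^4/n^2)\,
#'     \frac{2\cos^2\gamma + 1}{15}\, \mu^2 \Delta\mu^2 / w}
#'     with \eqn{\mu,\Delta\mu} in D and \eqn{w} (Gaussian SD) in
#'     cm\eqn{^{-1}}; equals \eqn{4\pi^2 \times 10^{-22}/(\sqrt{2\pi}\,\hbar^2 c^3)}.}
#' }
#'
#' @return Named list of the constants above.
#' @examples
#' stark_constants()$mvcm_per_d_a3
#' @export
stark_constants <- function() {
  list(
    mvcm_per_d_a3      = 299.792458,
    kappa_cm           = 16.7920053797441,
    curvature_to_a3    = 2517.05828377135,
    kcoul_v_ang        = 14.3996454784257,
    mu2_from_extinction = 9.18593077628759e-3,
    c2pa_gm            = 52.5600018861580
  )
}

# internal shorthands
.mvcm_per_d_a3 <- 299.792458
.kappa_cm <- 16.7920053797441
.curvature_to_a3 <- 2517.05828377135
.kcoul_v_ang <- 14.3996454784257
.mu2_ext_const <- 9.18593077628759e-3
.c2pa_const <- 52.5600018861580

# linear field-unit conversion factors, all relative to MV/cm
# (1 statvolt/cm = 299.792458 V/cm)
.field_units <- c(
  "MV/cm"       = 1,
  "V/cm"        = 1e-6,
  "V/m"         = 1e-8,
  "V/A"         = 100,
  "statvolt/cm" = 299.792458e-6
)

#' Convert between the units used in the Stark analysis
#'
#' Exact linear conversions between electric-field units, plus the documented
#' compound conversions that appear in the Stark algebra. Field units:
#' `"MV/cm"`, `"V/cm"`, `"V/m"`, `"V/A"`, `"statvolt/cm"`. The compound pair
#' `"D/A3" -> "MV/cm"` (and back) applies the 299.792458 factor that links a
#' dipole-per-polarizability ratio to a field.
#'
#' @param value numeric vector to convert.
#' @param from,to unit names (character scalars).
#' @return converted numeric vector.
#' @examples
#' convert_units(1, "D/A3", "MV/cm")   # 299.792458
#' convert_units(1, "V/A", "MV/cm")    # 100
#' @export
convert_units <- function(value, from, to) {
  stopifnot(is.numeric(value), length(from) == 1L, length(to) == 1L)
  if (identical(from, to)) return(value)
  fu <- names(.field_units)
  if (from %in% fu && to %in% fu) {
    return(value * .field_units[[from]] / .field_units[[to]])
  }
  key <- paste(from, to, sep = "->")
  switch(key,
    "D/A3->MV/cm" = value * .mvcm_per_d_a3,
    "MV/cm->D/A3" = value / .mvcm_per_d_a3,
    stop("unsupported unit conversion: ", from, " -> ", to, call. = FALSE)
  )
}
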