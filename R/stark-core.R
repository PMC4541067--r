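#' Electro-optic reference parameters of the chromophore
#'
#' Bundles the three constants of the quadratic Stark model: the
#' field-independent dipole-moment change of the reference state
#' (`dmu_ref`, debye; the vacuum value \eqn{\Delta\mu_0} or a hydrogen-bonded
#' cluster value \eqn{\Delta\mu_{HB}}), the polarizability change on
#' excitation (`dalpha`, \eqn{\AA^3}; negative for the anionic GFP
#' chromophore), and the vacuum 0--0 transition wavenumber (`nu_vac`,
#' cm\eqn{^{-1}}).
#'
#' @param dmu_ref reference dipole difference, debye (>= 0).
#' @param dalpha polarizability change, cubic angstrom (non-zero).
#' @param nu_vac vacuum 0--0 wavenumber, cm^-1 (> 0).
#' @param reference `"vacuum"` when `dmu_ref` is the vacuum value (fields
#'   derived with it are *total* effective fields) or `"cluster"` when it is a
#'   hydrogen-bonded cluster value (fields are *long-range*).
#' @return object of class `stark_params`.
#' @examples
#' stark_params(4.47, -35, 20725)
#' @export
stark_params <- function(dmu_ref = 4.47, dalpha = -35, nu_vac = 20725,
                         reference = c("vacuum", "cluster")) {
  reference <- match.arg(reference)
  stopifnot(
    is.numeric(dmu_ref), length(dmu_ref) == 1L, is.finite(dmu_ref), dmu_ref >= 0,
    is.numeric(dalpha), length(dalpha) == 1L, is.finite(dalpha), dalpha != 0,
    is.numeric(nu_vac), length(nu_vac) == 1L, is.finite(nu_vac), nu_vac > 0
  )
  structure(
    list(dmu_ref = dmu_ref, dalpha = dalpha, nu_vac = nu_vac,
         reference = reference),
    class = "stark_params"
  )
}

#' @export
print.stark_params <- function(x, ...) {
  cat("Stark parameters (", x$reference, " reference)\n", sep = "")
  cat(sprintf("  dmu_ref: %.3f D\n  dalpha:  %.2f A^3\n  nu_vac:  %.0f cm^-1\n",
              x$dmu_ref, x$dalpha, x$nu_vac))
  invisible(x)
}

#' A projected internal-field estimate
#'
#' A field projection on the \eqn{\Delta\mu_0} axis in MV/cm (positive along
#' the imidazolinone-to-phenolate, +x, direction) together with its
#' provenance.
#'
#' @param value field, MV/cm.
#' @param kind one of `"total"`, `"long_range"`, `"reaction"`, `"structural"`.
#' @param sd optional standard deviation, MV/cm (>= 0).
#' @return object of class `field_estimate`.
#' @export
field_estimate <- function(value, kind, sd = NA_real_) {
  kind <- match.arg(kind, c("total", "long_range", "reaction", "structural"))
  stopifnot(is.numeric(value), length(value) == 1L, is.finite(value))
  if (!is.na(sd)) stopifnot(is.numeric(sd), sd >= 0)
  structure(list(value = value, sd = sd, kind = kind), class = "field_estimate")
}

#' @export
print.field_estimate <- function(x, ...) {
  cat(sprintf("%s field: %+.2f MV/cm", gsub("_", "-", x$kind), x$value))
  if (!is.na(x$sd)) cat(sprintf(" (sd %.2f)", x$sd))
  cat("\n")
  invisible(x)
}

#' Dipole-moment change in a given field
#'
#' The point-dipole linear response
#' \eqn{\Delta\mu(E) = \Delta\mu_{ref} + \Delta\alpha E}: the permanent
#' dipole difference acquires a field-induced part through the polarizability
#' change. The \eqn{\Delta\alpha E} product (\eqn{\AA^3 \times} MV/cm) is
#' converted to debye with the 299.792458 factor.
#'
#' @param field field projection on the dipole axis, MV/cm (vector ok).
#' @param params [stark_params()].
#' @return dipole difference in debye.
#' @examples
#' delta_mu_of_field(0, stark_params())          # 4.47
#' delta_mu_of_field(25.4395, stark_params())    # ~1.5 (citrine)
#' @export
delta_mu_of_field <- function(field, params = stark_params()) {
  stopifnot(inherits(params, "stark_params"), is.numeric(field), all(is.finite(field)))
  params$dmu_ref + params$dalpha * field / .mvcm_per_d_a3
}

#' Internal field from a measured dipole-moment change
#'
#' Inverts [delta_mu_of_field()]:
#' \eqn{E = (\Delta\mu - \Delta\mu_{ref})/\Delta\alpha}, reported in MV/cm.
#' With a vacuum reference the result is the total effective field; with a
#' cluster reference it is the long-range field.
#'
#' @param dmu measured dipole difference, debye (scalar).
#' @param params [stark_params()].
#' @param sd_dmu optional standard deviation of `dmu`, debye, propagated
#'   linearly to the field.
#' @return a [field_estimate()].
#' @examples
#' field_of_delta_mu(3.6, stark_params())  # +7.45 MV/cm (EGFP)
#' @export
field_of_delta_mu <- function(dmu, params = stark_params(), sd_dmu = NA_real_) {
  stopifnot(inherits(params, "stark_params"),
            is.numeric(dmu), length(dmu) == 1L, is.finite(dmu))
  value <- (dmu - params$dmu_ref) / params$dalpha * .mvcm_per_d_a3
  sd <- if (is.na(sd_dmu)) NA_real_ else abs(sd_dmu / params$dalpha) * .mvcm_per_d_a3
  kind <- if (params$reference == "vacuum") "total" else "long_range"
  field_estimate(value, kind, sd)
}

#' 0--0 transition wavenumber as a function of the dipole change
#'
#' The second-order Stark shift written in the measurable coordinates: a
#' parabola
#' \eqn{\bar\nu(\Delta\mu) = \bar\nu_{vac} -
#'  (\Delta\mu^2 - \Delta\mu_{ref}^2) / (2hc\Delta\alpha) = A\Delta\mu^2 + C}
#' with curvature \eqn{A = -1/(2hc\Delta\alpha)} (positive for
#' \eqn{\Delta\alpha < 0}, extremum at \eqn{\Delta\mu = 0}) and intercept
#' \eqn{C = \bar\nu_{vac} - A\,\Delta\mu_{ref}^2}.
#'
#' @param dmu dipole difference, debye (vector ok).
#' @param params [stark_params()].
#' @return wavenumber, cm^-1.
#' @examples
#' nu_of_delta_mu(4.47, stark_params())  # 20725: zero net shift at the vacuum value
#' @export
nu_of_delta_mu <- function(dmu, params = stark_params()) {
  stopifnot(inherits(params, "stark_params"), is.numeric(dmu), all(is.finite(dmu)))
  a <- -.curvature_to_a3 / params$dalpha
  a * dmu^2 + (params$nu_vac - a * params$dmu_ref^2)
}

.parabola_fit <- function(A, B, C, param_sd, chi2, n) {
  structure(list(A = A, B = B, C = C, param_sd = param_sd, chi2 = chi2, n = n),
            class = "parabola_fit")
}

#' @export
print.parabola_fit <- function(x, ...) {
  cat(sprintf("parabola fit (n = %d): nu = A*dmu^2 %s+ C\n", x$n,
              if (x$B != 0) "+ B*dmu " else ""))
  cat(sprintf("  A = %.2f +/- %.2f cm^-1 D^-2\n", x$A, x$param_sd[["A"]]))
  if (x$B != 0 || !is.na(x$param_sd[["B"]]))
    cat(sprintf("  B = %.2f +/- %.2f cm^-1 D^-1\n", x$B, x$param_sd[["B"]]))
  cat(sprintf("  C = %.0f +/- %.0f cm^-1\n  chi2 = %.4g\n",
              x$C, x$param_sd[["C"]], x$chi2))
  invisible(x)
}

#' Fit the Stark parabola across a protein ensemble
#'
#' Least-squares fit of the 0--0 wavenumber against the dipole change over an
#' ensemble of proteins sharing one chromophore. With
#' `constrain_extremum = TRUE` (the global-ensemble convention) the model is
#' \eqn{\bar\nu = A\Delta\mu^2 + C}, the extremum pinned at
#' \eqn{\Delta\mu = 0}; otherwise a free quadratic
#' \eqn{A\Delta\mu^2 + B\Delta\mu + C} is used. From the constrained fit the
#' electro-optic constants are derived as
#' \eqn{\Delta\alpha = -2517.058/A} (\eqn{\AA^3}) and
#' \eqn{\Delta\mu_0 = \sqrt{(\bar\nu_{vac} - C)/A}} (debye), with standard
#' errors propagated from the coefficient covariance by the delta method.
#'
#' @param dmu,nu numeric vectors (>= 3 points): dipole differences (D) and
#'   0--0 wavenumbers (cm^-1).
#' @param nu_vac vacuum wavenumber used to extract `dmu0`, cm^-1.
#' @param constrain_extremum force B = 0 (default TRUE).
#' @param weights optional per-point weights (1/sd^2); unweighted by default.
#' @return list with `fit` (a `parabola_fit`) and `params` (a
#'   [stark_params()] carrying the derived `dmu_ref`/`dalpha`, plus fields
#'   `dalpha_sd` and `dmu0_sd`). If \eqn{(\bar\nu_{vac} - C)/A < 0} the
#'   derived parameters are reported as `NA` with a warning.
#' @examples
#' p <- stark_params()
#' dmu <- seq(1, 7, length.out = 10)
#' f <- fit_stark_parabola(dmu, nu_of_delta_mu(dmu, p), nu_vac = 20725)
#' f$params$dalpha  # -35
#' @export
fit_stark_parabola <- function(dmu, nu, nu_vac = 20725,
                               constrain_extremum = TRUE, weights = NULL) {
  stopifnot(is.numeric(dmu), is.numeric(nu), length(dmu) == length(nu),
            length(dmu) >= 3L, all(is.finite(dmu)), all(is.finite(nu)))
  if (length(unique(dmu)) < (if (constrain_extremum) 2L else 3L))
    stop("design is rank deficient: too few distinct dmu values", call. = FALSE)
  d2 <- dmu^2
  fml <- if (constrain_extremum) nu ~ d2 else nu ~ d2 + dmu
  fit <- stats::lm(fml, weights = weights)
  cf <- stats::coef(fit)
  # exact synthetic data give zero residuals; summary.lm's "essentially
  # perfect fit" warning is expected there and carries no information
  vc <- suppressWarnings(stats::vcov(fit))
  A <- cf[["d2"]]
  C <- cf[["(Intercept)"]]
  B <- if (constrain_extremum) 0 else cf[["dmu"]]
  se <- sqrt(diag(vc))
  param_sd <- c(A = se[["d2"]],
                B = if (constrain_extremum) NA_real_ else se[["dmu"]],
                C = se[["(Intercept)"]])
  chi2 <- sum(stats::residuals(fit)^2 * (if (is.null(weights)) 1 else weights))
  pf <- .parabola_fit(A, B, C, param_sd, chi2, length(dmu))

  dalpha <- -.curvature_to_a3 / A
  dalpha_sd <- .curvature_to_a3 / A^2 * param_sd[["A"]]
  disc <- (nu_vac - C) / A
  if (disc < 0) {
    warning("(nu_vac - C)/A < 0: no real dmu0; derived parameters set to NA",
            call. = FALSE)
    params <- NULL
    dmu0 <- NA_real_
    dmu0_sd <- NA_real_
  } else {
    dmu0 <- sqrt(disc)
    # delta method on dmu0^2 = (nu_vac - C)/A; d/dA = -dmu0/(2A), d/dC = -1/(2 A dmu0)
    g <- c(-dmu0 / (2 * A), -1 / (2 * A * dmu0))
    S <- vc[c("d2", "(Intercept)"), c("d2", "(Intercept)")]
    dmu0_sd <- sqrt(drop(t(g) %*% S %*% g))
    params <- stark_params(dmu0, dalpha, nu_vac, reference = "vacuum")
    params$dalpha_sd <- dalpha_sd
    params$dmu0_sd <- dmu0_sd
  }
  list(fit = pf, params = params,
       derived = c(dalpha = dalpha, dalpha_sd = dalpha_sd,
                   dmu0 = dmu0, dmu0_sd = dmu0_sd))
}

#' Unconstrained quadratic fit for a hydrogen-bond class subset
#'
#' Free quadratic \eqn{\bar\nu = A\Delta\mu^2 + B\Delta\mu + C} for a subset
#' of proteins sharing one hydrogen-bonding class (e.g. the 5-HB cluster
#' proteins). Coefficient extraction only; no attempt is made to back-solve
#' the resonance-model parameters from (A, B, C).
#'
#' @inheritParams fit_stark_parabola
#' @param subset_label optional tag recorded with the fit.
#' @return a `parabola_fit` (with attribute `subset`).
#' @export
fit_subset_quadratic <- function(dmu, nu, subset_label = NULL, weights = NULL) {
  res <- fit_stark_parabola(dmu, nu, constrain_extremum = FALSE,
                            weights = weights)$fit
  attr(res, "subset") <- subset_label
  res
}

#' Field-fluctuation broadening of the 0--0 band
#'
#' Total Gaussian linewidth (SD) of the 0--0 transition when the internal
#' field fluctuates normally with SD `deltaE` about its mean: the linear Stark
#' effect turns field noise into frequency noise proportional to
#' \eqn{|\Delta\mu|}, added in quadrature to a field-independent vibrational
#' floor \eqn{\gamma}:
#' \deqn{w = \sqrt{(\kappa |\Delta\mu|\, \delta E)^2 + \gamma^2},\quad
#'       \kappa = 16.792\ \mathrm{cm^{-1} (D\, MV/cm)^{-1}}.}
#'
#' @param dmu dipole difference, debye (vector ok).
#' @param deltaE field-fluctuation SD, MV/cm (>= 0).
#' @param gamma field-independent width, cm^-1 (>= 0).
#' @return width (Gaussian SD), cm^-1.
#' @examples
#' linewidth_model(4, 5, 270)  # ~431 cm^-1
#' @export
linewidth_model <- function(dmu, deltaE, gamma) {
  stopifnot(is.numeric(dmu), all(is.finite(dmu)),
            is.numeric(deltaE), deltaE >= 0, is.numeric(gamma), gamma >= 0)
  sqrt((.kappa_cm * abs(dmu) * deltaE)^2 + gamma^2)
}

#' Fit the broadening model across an ensemble
#'
#' Ordinary least squares of \eqn{w^2} on \eqn{\Delta\mu^2}; the slope gives
#' the field-fluctuation SD \eqn{\delta E = \sqrt{slope}/\kappa} and the
#' intercept the vibrational floor \eqn{\gamma = \sqrt{intercept}}. Standard
#' errors follow by the delta method. A negative fitted intercept (or slope)
#' is reported as 0 with `degenerate = TRUE`.
#'
#' @param dmu,w numeric vectors (>= 3 points): dipole differences (D) and
#'   0--0 Gaussian widths (cm^-1).
#' @return object of class `broadening_fit`: `deltaE` (MV/cm), `gamma`
#'   (cm^-1), `deltaE_se`, `gamma_se`, `slope`, `intercept`, `slope_se`,
#'   `intercept_se`, `degenerate`.
#' @examples
#' dmu <- c(1, 3, 5, 7)
#' fit_broadening(dmu, linewidth_model(dmu, 5, 270))
#' @export
fit_broadening <- function(dmu, w) {
  stopifnot(is.numeric(dmu), is.numeric(w), length(dmu) == length(w),
            length(dmu) >= 2L, all(is.finite(dmu)), all(is.finite(w)),
            all(w >= 0))
  x <- dmu^2
  y <- w^2
  fit <- stats::lm(y ~ x)
  cf <- stats::coef(fit)
  se <- if (length(dmu) > 2L)
    sqrt(diag(suppressWarnings(stats::vcov(fit)))) else c(0, 0)
  slope <- cf[[2]]
  icept <- cf[[1]]
  degenerate <- slope < 0 || icept < 0
  if (degenerate)
    warning("negative slope or intercept in w^2 vs dmu^2 regression; ",
            "degenerate fit, parameter floored at 0", call. = FALSE)
  deltaE <- if (slope > 0) sqrt(slope) / .kappa_cm else 0
  gamma <- if (icept > 0) sqrt(icept) else 0
  deltaE_se <- if (slope > 0) se[[2]] / (2 * .kappa_cm^2 * deltaE) else NA_real_
  gamma_se <- if (icept > 0) se[[1]] / (2 * gamma) else NA_real_
  structure(
    list(deltaE = deltaE, gamma = gamma,
         deltaE_se = deltaE_se, gamma_se = gamma_se,
         slope = slope, intercept = icept,
         slope_se = se[[2]], intercept_se = se[[1]],
         degenerate = degenerate, n = length(dmu)),
    class = "broadening_fit"
  )
}

#' @export
print.broadening_fit <- function(x, ...) {
  cat(sprintf("broadening fit (n = %d): deltaE = %.2f +/- %.2f MV/cm, gamma = %.0f +/- %.0f cm^-1\n",
              x$n, x$deltaE, x$deltaE_se, x$gamma, x$gamma_se))
  if (x$degenerate) cat("  (degenerate: negative slope or intercept)\n")
  invisible(x)
}

#' Reaction field from a field-induced dipole change
#'
#' In a polarizable solvent the reaction field induces a dipole change
#' \eqn{\Delta\mu_{ind} = \Delta\alpha E_R}; inverting gives
#' \eqn{E_R = \Delta\mu_{ind}/\Delta\alpha} (MV/cm).
#'
#' @param dmu_ind induced dipole difference, debye.
#' @param dalpha polarizability change, cubic angstrom (non-zero).
#' @return a [field_estimate()] of kind `"reaction"`.
#' @examples
#' reaction_field_induced(2.1, -35)  # about -18 MV/cm
#' @export
reaction_field_induced <- function(dmu_ind, dalpha) {
  stopifnot(is.numeric(dmu_ind), length(dmu_ind) == 1L, is.finite(dmu_ind),
            is.numeric(dalpha), length(dalpha) == 1L, is.finite(dalpha),
            dalpha != 0)
  field_estimate(dmu_ind / dalpha * .mvcm_per_d_a3, "reaction")
}

#' Polarizable spherical-cavity (Onsager-type) model
#'
#' Parameters of the classical dielectric model of the solvent reaction
#' field: a solute of ground-state dipole `mu_g` (debye, signed projection)
#' and polarizability `alpha_g` (\eqn{\AA^3}) in a spherical cavity of radius
#' `a` (\eqn{\AA}) with internal dielectric constant `eps_in`, immersed in a
#' solvent of dielectric constant `eps`.
#'
#' @param mu_g,alpha_g,a,eps,eps_in see description.
#' @return object of class `cavity_model`.
#' @export
cavity_model <- function(mu_g, alpha_g, a, eps, eps_in = 2) {
  stopifnot(is.numeric(mu_g), is.finite(mu_g),
            is.numeric(alpha_g), alpha_g >= 0,
            is.numeric(a), a > 0,
            is.numeric(eps), is.numeric(eps_in),
            eps >= eps_in, eps_in >= 1)
  m <- structure(list(mu_g = mu_g, alpha_g = alpha_g, a = a,
                      eps = eps, eps_in = eps_in),
                 class = "cavity_model")
  f <- .cavity_factor(m)
  if (1 - f * alpha_g <= 0)
    stop("polarization catastrophe: 1 - f*alpha_g <= 0", call. = FALSE)
  m
}

.cavity_factor <- function(m) {
  2 * (m$eps - m$eps_in) / (m$eps_in * (2 * m$eps + m$eps_in) * m$a^3)
}

#' Solvent reaction field from the polarizable-cavity model
#'
#' Evaluates the cavity factor
#' \eqn{f = 2(\varepsilon - \varepsilon_{in}) /
#'      [\varepsilon_{in}(2\varepsilon + \varepsilon_{in})\,a^3]}
#' and the self-consistent reaction field of the polarizable dipole,
#' \eqn{E_R = f\mu_g / (1 - f\alpha_g)}, converted to MV/cm. The functional
#' form of `f` (internal-dielectric-screened Onsager factor) is validated in
#' the test suite against the known water/HBDI parameter set.
#'
#' @param model a [cavity_model()].
#' @return a [field_estimate()] of kind `"reaction"`.
#' @examples
#' reaction_field_cavity(cavity_model(-11, 22, 4.7, 79, 2))  # about -17 MV/cm
#' @export
reaction_field_cavity <- function(model) {
  stopifnot(inherits(model, "cavity_model"))
  f <- .cavity_factor(model)
  er <- f * model$mu_g / (1 - f * model$alpha_g)  # D/A^3
  field_estimate(er * .mvcm_per_d_a3, "reaction")
}
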