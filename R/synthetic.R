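# seeded evaluation without touching the caller's RNG state
.with_seed <- function(seed, code) {
  if (is.null(seed)) stop("a seed is mandatory for synthetic generation",
                          call. = FALSE)
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

#' Specification of a synthetic protein ensemble
#'
#' States the world the generator emulates: an ensemble of GFP-type mutants
#' whose internal fields are normally distributed protein-to-protein
#' (`field_mean`, `field_sd`), while within each protein the field fluctuates
#' with SD `deltaE`, broadening the 0--0 band on top of the vibrational floor
#' `gamma`. Dipole changes, transition frequencies, widths and two-photon
#' cross sections all follow from the forward Stark and two-level models
#' under `stark`, `mu` and `cfg`. Defaults are the experimentally fitted
#' constants, so synthetic ensembles land in the observed ranges
#' (dipole changes ~1.5--6.5 D, fields ~-18..+25 MV/cm).
#'
#' @param n_proteins ensemble size (>= 3; default 26).
#' @param field_mean,field_sd protein-to-protein field distribution, MV/cm.
#' @param deltaE within-protein field-fluctuation SD, MV/cm.
#' @param stark a [stark_params()].
#' @param gamma field-independent width, cm^-1.
#' @param mu transition dipole, debye.
#' @param cfg a [two_level_config()].
#' @param noise_nu,noise_dmu,noise_w measurement-noise SDs added to the
#'   observed wavenumber (cm^-1), dipole change (D) and width (cm^-1).
#' @param seed mandatory RNG seed.
#' @return object of class `ensemble_spec`.
#' @export
ensemble_spec <- function(n_proteins = 26L, field_mean = 4, field_sd = 10,
                          deltaE = 5, stark = stark_params(), gamma = 270,
                          mu = 6.9, cfg = two_level_config(),
                          noise_nu = 70, noise_dmu = 0.1, noise_w = 20,
                          seed = NULL) {
  stopifnot(n_proteins >= 3L, field_sd >= 0, deltaE >= 0, gamma >= 0,
            mu > 0, noise_nu >= 0, noise_dmu >= 0, noise_w >= 0,
            inherits(stark, "stark_params"),
            inherits(cfg, "two_level_config"))
  if (is.null(seed)) stop("seed is mandatory", call. = FALSE)
  structure(list(n_proteins = as.integer(n_proteins),
                 field_mean = field_mean, field_sd = field_sd,
                 deltaE = deltaE, stark = stark, gamma = gamma, mu = mu,
                 cfg = cfg, noise_nu = noise_nu, noise_dmu = noise_dmu,
                 noise_w = noise_w, seed = as.integer(seed)),
            class = "ensemble_spec")
}

#' Generate a synthetic protein ensemble with known ground truth
#'
#' Draws per-protein fields \eqn{E_i \sim N(\mu_E, \sigma_E)}, pushes them
#' through the forward models -- dipole change
#' \eqn{\Delta\mu_i = \Delta\mu_0 + \Delta\alpha E_i}, transition frequency
#' (Stark parabola), width (fluctuation broadening with `deltaE`), 0--0
#' extinction from the transition dipole, and two-photon cross section
#' (two-level model) -- then adds seeded Gaussian measurement noise to the
#' observables. The noiseless truth is attached as `attr(, "truth")`.
#'
#' @param spec an [ensemble_spec()].
#' @return data.frame with columns `name`, `hb_class`, `dmu`, `nu00`, `w`,
#'   `eps00`, `sigma2_00`, `mu`; attribute `truth` holds `field`,
#'   `dmu_true`, `nu_true`, `w_true`, `sigma2_true`, `eps00_true`.
#' @examples
#' ens <- gen_protein_ensemble(ensemble_spec(seed = 42))
#' fit_stark_parabola(ens$dmu, ens$nu00)$params
#' @export
gen_protein_ensemble <- function(spec) {
  stopifnot(inherits(spec, "ensemble_spec"))
  .with_seed(spec$seed, {
    n <- spec$n_proteins
    field <- stats::rnorm(n, spec$field_mean, spec$field_sd)
    dmu_true <- delta_mu_of_field(field, spec$stark)
    nu_true <- nu_of_delta_mu(dmu_true, spec$stark)
    w_true <- linewidth_model(dmu_true, spec$deltaE, spec$gamma)
    eps00_true <- spec$mu^2 * nu_true /
      (.mu2_ext_const * w_true * sqrt(2 * pi))
    sigma2_true <- two_photon_cross_section(dmu_true, spec$mu, w_true,
                                            spec$cfg)
    out <- data.frame(
      name = sprintf("syn%02d", seq_len(n)),
      hb_class = "5HB",
      dmu = abs(dmu_true + stats::rnorm(n, 0, spec$noise_dmu)),
      nu00 = nu_true + stats::rnorm(n, 0, spec$noise_nu),
      w = abs(w_true + stats::rnorm(n, 0, spec$noise_w)),
      eps00 = eps00_true,
      sigma2_00 = sigma2_true,
      mu = spec$mu
    )
    attr(out, "truth") <- data.frame(
      field = field, dmu_true = dmu_true, nu_true = nu_true,
      w_true = w_true, sigma2_true = sigma2_true, eps00_true = eps00_true)
    out
  })
}

#' Specification of a synthetic vibronic spectrum pair
#'
#' A shared-width Gaussian vibronic progression: band j sits
#' `(j-1) * spacing` above the 0--0 origin with relative 1PA amplitude
#' `rel_amp_1pa[j]` (2PA: `rel_amp_2pa[j]`). Defaults emulate the GFP-type
#' chromophore: ~1250 cm^-1 effective vibronic spacing and a decaying
#' progression.
#'
#' @param n_bands bands in the progression (3..5).
#' @param spacing vibronic spacing, cm^-1.
#' @param rel_amp_1pa,rel_amp_2pa relative band amplitudes (first entry, the
#'   0--0 band, must be 1).
#' @param grid_step grid spacing, cm^-1.
#' @param pad grid padding beyond the outer bands, in units of the width.
#' @param noise_sd multiplicative noise SD (0.01 = 1%).
#' @param seed mandatory RNG seed.
#' @return object of class `spectrum_spec`.
#' @export
spectrum_spec <- function(n_bands = 4L, spacing = 1250,
                          rel_amp_1pa = c(1, 0.65, 0.3, 0.1, 0.04)[1:n_bands],
                          rel_amp_2pa = c(1, 0.8, 0.45, 0.18, 0.07)[1:n_bands],
                          grid_step = 25, pad = 3.5, noise_sd = 0,
                          seed = NULL) {
  stopifnot(n_bands %in% 3:5, spacing > 0,
            length(rel_amp_1pa) == n_bands, length(rel_amp_2pa) == n_bands,
            rel_amp_1pa[1] == 1, rel_amp_2pa[1] == 1,
            grid_step > 0, pad >= 3, noise_sd >= 0)
  if (is.null(seed)) stop("seed is mandatory", call. = FALSE)
  structure(list(n_bands = as.integer(n_bands), spacing = spacing,
                 rel_amp_1pa = rel_amp_1pa, rel_amp_2pa = rel_amp_2pa,
                 grid_step = grid_step, pad = pad, noise_sd = noise_sd,
                 seed = as.integer(seed)),
            class = "spectrum_spec")
}

#' Generate a paired 1PA/2PA spectrum for one protein record
#'
#' Synthesises both spectra from a protein's photophysics (`nu00`, `eps00`,
#' `sigma2_00`, `w` -- e.g. one row of [gen_protein_ensemble()]) as sums of
#' shared-width Gaussians, the 0--0 amplitudes equal to `eps00` /
#' `sigma2_00` and the vibronic satellites scaled by the progression of the
#' [spectrum_spec()]. Multiplicative noise is seeded; ground truth is
#' attached as `attr(, "truth")`.
#'
#' @param record list or one-row data.frame with `nu00`, `eps00`,
#'   `sigma2_00`, `w`.
#' @param spec a [spectrum_spec()].
#' @return list with `one_photon` and `two_photon` `fp_spectrum` objects and
#'   attribute `truth` (centers, amplitudes, width).
#' @export
gen_spectra <- function(record, spec) {
  stopifnot(inherits(spec, "spectrum_spec"),
            all(c("nu00", "eps00", "sigma2_00", "w") %in% names(record)))
  nu00 <- record$nu00; w <- record$w
  centers <- nu00 + (seq_len(spec$n_bands) - 1) * spec$spacing
  amps1 <- record$eps00 * spec$rel_amp_1pa
  amps2 <- record$sigma2_00 * spec$rel_amp_2pa
  grid <- seq(nu00 - spec$pad * w,
              max(centers) + spec$pad * w, by = spec$grid_step)
  shape <- .band_matrix(grid, centers, w)
  v1 <- as.numeric(shape %*% amps1)
  v2 <- as.numeric(shape %*% amps2)
  .with_seed(spec$seed, {
    if (spec$noise_sd > 0) {
      v1 <- v1 * (1 + stats::rnorm(length(v1), 0, spec$noise_sd))
      v2 <- v2 * (1 + stats::rnorm(length(v2), 0, spec$noise_sd))
    }
    out <- list(one_photon = fp_spectrum(grid, pmax(v1, 0), "one_photon"),
                two_photon = fp_spectrum(grid, pmax(v2, 0), "two_photon"))
    attr(out, "truth") <- list(centers = centers, amp_1pa = amps1,
                               amp_2pa = amps2, width = w)
    out
  })
}

#' Generate a parallel-plate charge system with an analytic interior field
#'
#' Builds two square grids of point charges (+q at the low-x plate, -q at
#' the high-x plate for a positive requested field) enclosing a dummy
#' 5-atom chromophore chain (CE2, CD2, CG2, CB2, CA2 along +x, zero
#' charges, registered as selection `"chromophore"`). The charge magnitude
#' is set from the infinite-plate relation
#' \eqn{E = \sigma_s/\varepsilon_0} and then trimmed numerically -- by a
#' two-point potential difference across the chromophore span -- so the
#' interior field matches the request to better than 1%. The requested
#' field is stored as `attr(, "truth_field")`.
#'
#' @param field requested interior field along +x, MV/cm.
#' @param span chromophore chain length, angstrom.
#' @param separation plate separation, angstrom (>= 10 x span).
#' @param plate_side plate edge length, angstrom.
#' @param grid_spacing charge-grid spacing, angstrom.
#' @return a [charge_system()] with one snapshot.
#' @examples
#' sys <- gen_uniform_field_system(5)
#' axis_field(sys, exclude = "chromophore")$mean  # ~5 MV/cm
#' @export
gen_uniform_field_system <- function(field, span = 5, separation = 60,
                                     plate_side = 240, grid_spacing = 3) {
  stopifnot(is.numeric(field), length(field) == 1L, is.finite(field),
            span > 0, plate_side > 0, grid_spacing > 0)
  if (separation < 10 * span)
    stop("plate separation must be >= 10x the chromophore span",
         call. = FALSE)
  g <- seq(-plate_side / 2, plate_side / 2, by = grid_spacing)
  yz <- expand.grid(y = g, z = g)
  npl <- nrow(yz)
  # infinite-plate estimate: E[V/A] = 4 pi k_C sigma_s, sigma_s = q / s^2
  q0 <- (abs(field) / 100) * grid_spacing^2 / (4 * pi * .kcoul_v_ang)
  sgn <- if (field >= 0) 1 else -1
  plate_x <- c(rep(-separation / 2, npl), rep(separation / 2, npl))
  plate_q <- c(rep(sgn * q0, npl), rep(-sgn * q0, npl))
  chain_names <- c("CE2", "CD2", "CG2", "CB2", "CA2")
  chain_x <- seq(span / 2, -span / 2, length.out = 5)
  atoms <- data.frame(
    name = c(chain_names, sprintf("Q%05d", seq_along(plate_q))),
    resname = c(rep("CRO", 5), rep("PLT", length(plate_q))),
    resid = c(rep(1L, 5), rep(2L, length(plate_q))),
    chain = "",
    charge = c(rep(0, 5), plate_q)
  )
  xyz <- rbind(
    cbind(chain_x, 0, 0),
    cbind(plate_x, rep(yz$y, 2), rep(yz$z, 2))
  )
  dimnames(xyz) <- NULL
  sys <- charge_system(atoms, list(xyz),
                       selections = list(chromophore = 1:5))
  if (field != 0) {
    # numeric trim: two-point potential difference across the chain span
    va <- potential_at(c(-span / 2, 0, 0), sys, exclude = "chromophore")
    vb <- potential_at(c(span / 2, 0, 0), sys, exclude = "chromophore")
    measured <- (va - vb) / span * 100  # MV/cm along +x
    sys$atoms$charge <- sys$atoms$charge * (field / measured)
  }
  attr(sys, "truth_field") <- field
  sys
}

#' Read / write the per-protein photophysics table
#'
#' Tab-separated table of per-protein observables (`name`, `hb_class`,
#' `dmu` \[D\], `nu00` \[cm^-1\], `w` \[cm^-1\], and optionally `eps00`,
#' `sigma2_00`, `mu`, per-observable `*_sd` columns). When `truth` is
#' attached to the data.frame, [write_protein_table()] emits it alongside as
#' a JSON sidecar `<path>.truth.json`.
#'
#' @param path table path.
#' @return [read_protein_table()] returns a data.frame (with `truth`
#'   attribute when the sidecar exists).
#' @export
read_protein_table <- function(path) {
  out <- utils::read.delim(path, sep = "\t", strip.white = TRUE)
  stopifnot(all(c("name", "dmu", "nu00") %in% names(out)))
  sidecar <- paste0(path, ".truth.json")
  if (file.exists(sidecar))
    attr(out, "truth") <- as.data.frame(jsonlite::read_json(
      sidecar, simplifyVector = TRUE))
  out
}

#' @rdname read_protein_table
#' @param records data.frame of protein records.
#' @export
write_protein_table <- function(records, path) {
  utils::write.table(records, path, sep = "\t", row.names = FALSE,
                     quote = FALSE)
  truth <- attr(records, "truth")
  if (!is.null(truth))
    jsonlite::write_json(truth, paste0(path, ".truth.json"),
                         auto_unbox = TRUE, digits = NA)
  invisible(path)
}
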