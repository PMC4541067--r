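test_that("delta_mu_of_field matches hand-converted values", {
  # zero-field identity
  expect_equal(delta_mu_of_field(0, p_vac), 4.47)
  # 4.47 + 35 * 8.6 / 299.792458 = 5.4740279... (hand unit conversion)
  expect_equal(delta_mu_of_field(-8.6, p_vac), 5.47402792654644,
               tolerance = 1e-12)
  # the citrine field maps back to its dipole change
  expect_equal(delta_mu_of_field(25.4395314, p_vac), 1.5, tolerance = 1e-6)
  expect_error(delta_mu_of_field(NaN, p_vac))
})

test_that("field_of_delta_mu reproduces printed fields and tags provenance", {
  egfp <- field_of_delta_mu(3.6, p_vac)
  expect_equal(egfp$value, 7.4, tolerance = 0.01)  # printed +7.4 MV/cm
  expect_identical(egfp$kind, "total")
  citrine <- field_of_delta_mu(1.5, p_vac)
  expect_equal(citrine$value, 25.4, tolerance = 0.002)  # printed +25.4
  p_hb <- stark_params(1.76, -49, 20725, reference = "cluster")
  lr <- field_of_delta_mu(1.5, p_hb)
  expect_equal(lr$value, 1.6, tolerance = 0.01)  # printed ~1.6
  expect_identical(lr$kind, "long_range")
  expect_equal(field_of_delta_mu(4.47, p_vac)$value, 0)
  # sd propagation is linear
  expect_equal(field_of_delta_mu(3.6, p_vac, sd_dmu = 0.35)$sd,
               0.35 / 35 * 299.792458)
  expect_error(stark_params(4.47, 0, 20725))
})

test_that("field/dipole maps are exact inverses and monotone", {
  withr::with_seed(7, {
    for (p in list(p_vac, stark_params(1.76, -49, 20725, "cluster"))) {
      E <- runif(50, -40, 40)
      back <- vapply(delta_mu_of_field(E, p), function(d)
        field_of_delta_mu(d, p)$value, numeric(1))
      expect_equal(back, E, tolerance = 1e-10)
    }
  })
  # for dalpha < 0 the field decreases strictly in dmu
  dmu <- seq(0, 7, by = 0.5)
  E <- vapply(dmu, function(d) field_of_delta_mu(d, p_vac)$value, numeric(1))
  expect_true(all(diff(E) < 0))
})

test_that("nu_of_delta_mu is the documented parabola", {
  # zero net shift at the vacuum dipole value
  expect_equal(nu_of_delta_mu(4.47, p_vac), 20725)
  # intercept at dmu = 0 lands on the fitted C within its printed error
  expect_equal(nu_of_delta_mu(0, p_vac), 19300, tolerance = 70 / 19300)
  # even in dmu, and equals A dmu^2 + C
  A <- stark_constants()$curvature_to_a3 / 35
  C <- 20725 - A * 4.47^2
  withr::with_seed(11, {
    d <- runif(20, -8, 8)
    expect_equal(nu_of_delta_mu(d, p_vac), A * d^2 + C, tolerance = 1e-12)
    expect_equal(nu_of_delta_mu(d, p_vac), nu_of_delta_mu(-d, p_vac))
  })
  # vanishing curvature limit
  p_flat <- stark_params(4.47, -1e9, 20725)
  expect_equal(nu_of_delta_mu(c(0, 5, 10), p_flat), rep(20725, 3),
               tolerance = 1e-6)
})

test_that("fit_stark_parabola recovers exact and printed parameters", {
  dmu <- seq(1, 7, length.out = 12)
  fit <- fit_stark_parabola(dmu, nu_of_delta_mu(dmu, p_vac), nu_vac = 20725)
  expect_equal(fit$derived[["dalpha"]], -35, tolerance = 1e-6)
  expect_equal(fit$derived[["dmu0"]], 4.47, tolerance = 1e-6)
  expect_equal(fit$fit$B, 0)
  # the printed curvature A = 72 gives dalpha = -35 +/- 2 (computed -34.96)
  expect_equal(-stark_constants()$curvature_to_a3 / 72, -35, tolerance = 0.05)
  # printed (A, C, nu_vac) give dmu0 ~ 4.45, inside 4.47 +/- 0.16
  expect_equal(sqrt((20725 - 19300) / 72), 4.47, tolerance = 0.16 / 4.47)
})

test_that("fit_stark_parabola handles degenerate and failing inputs", {
  expect_error(fit_stark_parabola(rep(2, 5), rnorm(5)), "rank deficient")
  # C above nu_vac with positive A: no real dmu0
  expect_warning(
    res <- fit_stark_parabola(c(1, 2, 3, 4), 21000 + 72 * c(1, 4, 9, 16),
                              nu_vac = 20725),
    "no real dmu0")
  expect_true(is.na(res$derived[["dmu0"]]))
})

test_that("noisy parabola fits recover truth within 3 SE almost always", {
  hits <- withr::with_seed(202, {
    vapply(1:200, function(r) {
      dmu <- abs(rnorm(26, 4, 1.2))
      nu <- nu_of_delta_mu(dmu, p_vac) + rnorm(26, 0, 70)
      f <- fit_stark_parabola(dmu, nu, nu_vac = 20725)
      abs(f$derived[["dalpha"]] + 35) <= 3 * f$derived[["dalpha_sd"]] &&
        abs(f$derived[["dmu0"]] - 4.47) <= 3 * f$derived[["dmu0_sd"]]
    }, logical(1))
  })
  expect_gte(mean(hits), 0.95)
})

test_that("fit_subset_quadratic extracts free quadratic coefficients", {
  x <- seq(-2, 4, length.out = 9)
  f <- fit_subset_quadratic(x, 2 * x^2 - 3 * x + 5, subset_label = "5HB")
  expect_equal(c(f$A, f$B, f$C), c(2, -3, 5), tolerance = 1e-9)
  expect_identical(attr(f, "subset"), "5HB")
  # constrained parabola data yield B = 0 in the free fit
  dmu <- seq(1, 7, length.out = 9)
  f2 <- fit_subset_quadratic(dmu, nu_of_delta_mu(dmu, p_vac))
  expect_equal(f2$B, 0, tolerance = 1e-9)
  # noisy 5-HB subset: coefficients within 3 SE of truth
  hits <- withr::with_seed(303, {
    vapply(1:100, function(r) {
      d <- runif(15, 1, 7)
      nu <- 70 * d^2 - 20 * d + 19500 + rnorm(15, 0, 70)
      f <- fit_subset_quadratic(d, nu)
      all(abs(c(f$A - 70, f$B + 20, f$C - 19500)) <= 3 * f$param_sd)
    }, logical(1))
  })
  expect_gte(mean(hits), 0.95)
})

test_that("linewidth_model has the documented floor, scale and symmetry", {
  expect_equal(linewidth_model(0, 5, 270), 270)
  # sqrt((16.792 * 4 * 5)^2 + 270^2) = 430.92, the documented ~431
  expect_equal(linewidth_model(4, 5, 270), 430.92, tolerance = 1e-4)
  expect_equal(linewidth_model(-4, 5, 270), linewidth_model(4, 5, 270))
  w <- linewidth_model(seq(0, 8, by = 1), 5, 270)
  expect_true(all(diff(w) > 0))
  expect_true(linewidth_model(4, 6, 270) > linewidth_model(4, 5, 270))
  expect_true(linewidth_model(4, 5, 280) > linewidth_model(4, 5, 270))
  expect_error(linewidth_model(4, -1, 270))
})

test_that("fit_broadening inverts the linewidth model", {
  dmu <- c(0.5, 2, 3.5, 5, 6.5)
  fit <- fit_broadening(dmu, linewidth_model(dmu, 5, 270))
  expect_equal(fit$deltaE, 5, tolerance = 1e-6)
  expect_equal(fit$gamma, 270, tolerance = 1e-6)
  expect_false(fit$degenerate)
  # two points: exact interpolation
  f2 <- fit_broadening(c(2, 5), linewidth_model(c(2, 5), 5, 270))
  expect_equal(c(f2$deltaE, f2$gamma), c(5, 270), tolerance = 1e-9)
  # decreasing w^2 with dmu^2 flags a degenerate fit
  expect_warning(fd <- fit_broadening(c(1, 3, 5), c(500, 400, 300)),
                 "degenerate")
  expect_identical(fd$deltaE, 0)
  # seeded noisy ensembles recover truth within 3 SE
  hits <- withr::with_seed(404, {
    vapply(1:100, function(r) {
      d <- abs(rnorm(26, 4, 1.2))
      w <- linewidth_model(d, 5, 270) + rnorm(26, 0, 20)
      f <- fit_broadening(d, w)
      abs(f$deltaE - 5) <= 3 * f$deltaE_se &&
        abs(f$gamma - 270) <= 3 * f$gamma_se
    }, logical(1))
  })
  expect_gte(mean(hits), 0.95)
})

test_that("reaction fields from induced dipoles match printed values", {
  expect_equal(reaction_field_induced(2.1, -35)$value, -18, tolerance = 0.001)
  expect_equal(reaction_field_induced(1.3, -35)$value, -11.1, tolerance = 0.01)
  expect_identical(reaction_field_induced(0, -35)$value, 0)
  expect_identical(reaction_field_induced(2.1, -35)$kind, "reaction")
  expect_error(reaction_field_induced(2.1, 0))
})

test_that("cavity reaction field reproduces the water estimate and limits", {
  m <- cavity_model(mu_g = -11, alpha_g = 22, a = 4.7, eps = 79, eps_in = 2)
  expect_equal(reaction_field_cavity(m)$value, -17, tolerance = 0.05)
  # no dielectric contrast: zero field
  m0 <- cavity_model(-11, 22, 4.7, eps = 2, eps_in = 2)
  expect_equal(reaction_field_cavity(m0)$value, 0)
  # rigid-dipole limit: E_R = f mu_g exactly
  mr <- cavity_model(-11, 0, 4.7, 79, 2)
  f <- 2 * (79 - 2) / (2 * (2 * 79 + 2) * 4.7^3)
  expect_equal(reaction_field_cavity(mr)$value, f * -11 * 299.792458,
               tolerance = 1e-12)
  # odd in mu_g
  mp <- cavity_model(11, 22, 4.7, 79, 2)
  expect_equal(reaction_field_cavity(mp)$value,
               -reaction_field_cavity(m)$value)
  # vanishes as the cavity grows
  mbig <- cavity_model(-11, 22, 470, 79, 2)
  expect_lt(abs(reaction_field_cavity(mbig)$value), 1e-4)
  expect_error(cavity_model(-11, 5000, 1.0, 79, 2), "catastrophe")
})
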