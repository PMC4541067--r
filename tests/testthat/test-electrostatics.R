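test_that("PQR fixtures parse with charges as written", {
  path <- withr::local_tempfile(fileext = ".pqr")
  write_pqr_fixture(path)
  sys <- read_pqr(path)
  expect_equal(nrow(sys$atoms), 2L)
  expect_equal(sys$atoms$charge, c(1, -1))
  expect_equal(sys$snapshots[[1]][2, 1], 2)
  expect_identical(sys$atoms$name, c("NA", "CL"))
})

test_that("multi-model PDB files become snapshots with mapped charges", {
  path <- withr::local_tempfile(fileext = ".pdb")
  write_pdb_fixture(path)
  sys <- read_pdb_charges(path, ion_charge_table)
  expect_length(sys$snapshots, 3L)
  expect_equal(sys$atoms$charge, c(1, -1))
  expect_equal(sys$snapshots[[3]][1, 1], 0.2)
  # a missing mapping names the offending atom
  expect_error(read_pdb_charges(path, ion_charge_table[1, ]),
               "no charge mapping.*ION CL")
})

test_that("potential_at matches the Coulomb constant and basic geometry", {
  sys <- point_charges(rbind(c(0, 0, 0)), 1)
  expect_equal(potential_at(c(1, 0, 0), sys), 14.3996, tolerance = 1e-5)
  # opposite charges symmetric about the midpoint cancel
  dip <- point_charges(rbind(c(-1, 0, 0), c(1, 0, 0)), c(1, -1))
  expect_equal(potential_at(c(0, 0, 0), dip), 0)
  # excluding everything gives zero
  expect_identical(potential_at(c(5, 5, 5), dip, exclude = 1:2), 0)
  # clash detection
  expect_error(potential_at(c(1, 0, 0), point_charges(rbind(c(1, 0, 0)), 1)),
               "1e-6")
})

test_that("potentials superpose, scale and respect exclusion algebra", {
  withr::with_seed(21, {
    xyz <- matrix(runif(30, -10, 10), ncol = 3)
    q <- runif(10, -1, 1)
    pt <- c(12, 3, -4)
    sysA <- point_charges(xyz[1:4, ], q[1:4])
    sysB <- point_charges(xyz[5:10, ], q[5:10])
    sysAB <- point_charges(xyz, q, selections = list(first4 = 1:4))
    vA <- potential_at(pt, sysA)
    vB <- potential_at(pt, sysB)
    expect_equal(potential_at(pt, sysAB), vA + vB, tolerance = 1e-12)
    # doubling charges doubles the potential
    sys2 <- point_charges(xyz, 2 * q)
    expect_equal(potential_at(pt, sys2), 2 * (vA + vB), tolerance = 1e-12)
    # excluding S equals total minus S alone
    expect_equal(potential_at(pt, sysAB, exclude = "first4"),
                 (vA + vB) - vA, tolerance = 1e-12)
  })
})

test_that("project_chain returns signed axis coordinates and projections", {
  # chain listed along the axis direction: distances 0, 1, 2, ...
  names5 <- c("CA2", "CB2", "CG2", "CD2", "CE2")
  xyz <- rbind(cbind(0:4, 0, 0), c(10, 0, 0))
  sys <- charge_system(
    data.frame(name = c(names5, "Q1"), resname = c(rep("CRO", 5), "ION"),
               resid = c(rep(1L, 5), 2L), chain = "",
               charge = c(rep(0, 5), 1)),
    list(unname(xyz)), selections = list(chromophore = 1:5))
  pc <- project_chain(sys, chain_atoms = names5, exclude = "chromophore")
  expect_equal(pc$distance, 0:4)
  # potentials are the hand Coulomb values from the +1 charge at x = 10
  expect_equal(pc$potential, 14.3996454784257 / (10 - 0:4), tolerance = 1e-9)
  # displacing an atom perpendicular to the axis leaves its projection put
  xyz2 <- xyz
  xyz2[3, 2] <- 2.5
  sys2 <- charge_system(sys$atoms, list(unname(xyz2)),
                        selections = sys$selections)
  pc2 <- project_chain(sys2, chain_atoms = names5, exclude = "chromophore")
  expect_equal(pc2$distance, 0:4)
  # default chain order (CE2 first) gives descending signed coordinates
  pc3 <- project_chain(sys, exclude = "chromophore")
  expect_equal(pc3$distance, c(0, -1, -2, -3, -4))
})

test_that("axis_field recovers a distant point-charge field analytically", {
  # +1 e on the axis at 50 A from the chain midpoint
  sys <- chain_system(extra_xyz = rbind(c(50, 0, 0)), extra_q = 1)
  af <- axis_field(sys, exclude = "chromophore")
  # V(x) = kq/(50 - x) rises toward the charge, so the +x projection of the
  # field at the chain is -kq/r^2
  analytic <- -14.3996454784257 / 50^2 * 100  # MV/cm
  expect_equal(af$mean, analytic, tolerance = 0.05)
  expect_gt(af$r2[1], 0.99)
})

test_that("axis_field handles zero charge and degenerate geometry", {
  sys <- chain_system(extra_xyz = rbind(c(50, 0, 0)), extra_q = 0)
  af <- axis_field(sys, exclude = "chromophore")
  expect_equal(af$mean, 0)
  expect_true(is.na(af$r2[1]))
  # all chain atoms projecting onto one axis point is degenerate
  names5 <- c("CE2", "CD2", "CG2", "CB2", "CA2")
  xyz <- rbind(cbind(0, seq(0, 4), 0), c(0, 0, 10), c(1, 0, 0))
  sys2 <- charge_system(
    data.frame(name = c(names5, "Q1", "AX"),
               resname = c(rep("CRO", 5), "ION", "ION"),
               resid = c(rep(1L, 5), 2L, 3L), chain = "",
               charge = c(rep(0, 5), 1, 0)),
    list(unname(xyz)), selections = list(chromophore = 1:5))
  expect_error(axis_field(sys2, exclude = "chromophore", axis_from = "CE2",
                          axis_to = "AX"),
               "degenerate")
})

test_that("the projected field is invariant under rigid motions", {
  sys <- chain_system(extra_xyz = rbind(c(40, 3, -2), c(-35, -8, 6)),
                      extra_q = c(0.7, -0.4))
  f0 <- axis_field(sys, exclude = "chromophore")$mean
  R <- rotation_matrix(c(1, 2, 3), 1.1)
  shift <- c(15, -7, 22)
  moved <- charge_system(
    sys$atoms,
    list(sweep(sys$snapshots[[1]] %*% t(R), 2, -shift)),
    selections = sys$selections)
  f1 <- axis_field(moved, exclude = "chromophore")$mean
  expect_equal(f1, f0, tolerance = 1e-8)
})

test_that("snapshot statistics use the population standard deviation", {
  res <- structure(list(mean = 2, sd = 0, per_snapshot = c(1, 2, 3),
                        r2 = rep(1, 3), intercept = 0, n_frames = 3L,
                        axis = c(from = "CA2", to = "CE2")),
                   class = "axis_field")
  st <- snapshot_statistics(res)
  expect_equal(st$mean, 2)
  expect_equal(st$sd, sqrt(2 / 3))
  # identical frames: zero fluctuation
  sys <- chain_system(extra_xyz = rbind(c(50, 0, 0)), extra_q = 1,
                      frames = 4L)
  expect_equal(snapshot_statistics(axis_field(sys,
                                              exclude = "chromophore"))$sd, 0)
})

test_that("frame jitter reproduces the analytic field fluctuation", {
  # a +1 e charge whose axial distance jitters ~N(50, 1): to first order the
  # field SD is |dE/dr| sigma_r = 2 k q / r^3 * sigma_r
  r0 <- 50
  sigma_r <- 1
  shifts <- withr::with_seed(77, rnorm(500, 0, sigma_r))
  sys <- chain_system(
    extra_xyz = rbind(c(r0, 0, 0)), extra_q = 1, frames = 500L,
    jitter_fun = function(base, k) {
      base[6, 1] <- base[6, 1] + shifts[k]
      base
    })
  st <- snapshot_statistics(axis_field(sys, exclude = "chromophore"))
  analytic_sd <- 2 * 14.3996454784257 / r0^3 * 100 * sigma_r
  expect_equal(st$sd, analytic_sd, tolerance = 0.1)
})
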