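# Force-displacement reduction: stress/strain closed forms, bilinear
# (bio-yield) parameter recovery, bulk density, material library.

test_that("stress-strain reduction follows the engineering closed forms", {
  # zero load and the F/S, dL/L closed form
  r0 <- force_displacement_record(0, 0, length = 10, area = 100)
  c0 <- compute_stress_strain(r0)
  expect_identical(c0$stress, 0)
  expect_identical(c0$strain, 0)

  r1 <- force_displacement_record(c(0, 10), c(0, 1), length = 10, area = 100)
  c1 <- compute_stress_strain(r1)
  expect_equal(c1$stress, c(0, 0.1))
  expect_equal(c1$strain, c(0, 0.1))

  # linear record with k = 15.7 N/mm recovers E = kL/S = 1.57 MPa
  dl <- seq(0, 2, length.out = 50)
  rl <- force_displacement_record(15.7 * dl, dl, length = 10, area = 100)
  cl <- compute_stress_strain(rl)
  fit <- fit_bilinear_params(cl, density = 1030, poisson_ratio = 0.4)
  expect_equal(fit$young_modulus, 1.57, tolerance = 1e-9)
  expect_null(fit$tangent_modulus)
  expect_null(fit$yield_stress)
})

test_that("stress is scale-consistent: doubling F and S leaves sigma fixed", {
  set.seed(42)
  for (i in 1:20) {
    n <- sample(5:40, 1)
    dl <- sort(runif(n, 0, 3))
    f <- cumsum(runif(n, 0, 2))
    s <- runif(1, 10, 300)
    a <- compute_stress_strain(force_displacement_record(f, dl, 10, s))
    b <- compute_stress_strain(force_displacement_record(2 * f, dl, 10, 2 * s))
    expect_equal(a$stress, b$stress)
  }
})

test_that("invalid specimens are rejected", {
  expect_error(force_displacement_record(1, 1, length = 0, area = 10),
               "invalid specimen")
  expect_error(force_displacement_record(1, 1, length = 10, area = -1),
               "invalid specimen")
  expect_error(force_displacement_record(c(1, 2), c(1, 0.5), 10, 10),
               "non-decreasing")
})

test_that("bilinear generator + fit is the identity on (E, Et, sigma_y)", {
  # values from the flesh and core rows of the material table
  for (p in list(c(1.57, 0.92, 0.26), c(5.11, 0.83, 1.12))) {
    curve <- make_bilinear_curve(p[1], p[2], p[3], strain_max = 2.2 * p[3] / p[1])
    fit <- fit_bilinear_params(curve, density = 1030, poisson_ratio = 0.4)
    expect_equal(fit$young_modulus, p[1], tolerance = 1e-6)
    expect_equal(fit$tangent_modulus, p[2], tolerance = 1e-6)
    expect_equal(fit$yield_stress, p[3], tolerance = 1e-6)
  }
})

test_that("purely linear curves report no yield point", {
  curve <- make_bilinear_curve(3.1, NULL, NULL, strain_max = 0.2)
  fit <- fit_bilinear_params(curve, density = 1000, poisson_ratio = 0.3)
  expect_null(fit$tangent_modulus)
  expect_null(fit$yield_stress)
  expect_equal(fit$young_modulus, 3.1, tolerance = 1e-9)
})

test_that("bilinear recovery tolerates 1% Gaussian stress noise (100 reps)", {
  E <- 1.57; Et <- 0.92; sy <- 0.26
  max_err <- 0
  for (rep in 1:100) {
    set.seed(1000 + rep)
    curve <- make_bilinear_curve(E, Et, sy, strain_max = 0.35,
                                 noise_sd = 0.01 * (sy + Et * (0.35 - sy / E)))
    fit <- fit_bilinear_params(curve, density = 1030, poisson_ratio = 0.4)
    err <- max(abs(fit$young_modulus - E) / E,
               abs(fit$tangent_modulus - Et) / Et,
               abs(fit$yield_stress - sy) / sy)
    max_err <- max(max_err, err)
  }
  expect_lt(max_err, 0.05)
})

test_that("fit preconditions are enforced", {
  short <- make_bilinear_curve(1, NULL, NULL, strain_max = 0.1, n = 5)
  expect_error(fit_bilinear_params(short, 1000, 0.3), "underdetermined")
  bad <- structure(list(stress = c(0, 1, 2, 3, 4, 5),
                        strain = c(0, 0.1, 0.05, 0.2, 0.3, 0.4),
                        mode = "compression"), class = "stress_strain_curve")
  expect_error(fit_bilinear_params(bad, 1000, 0.3), "strictly increasing")
})

test_that("bulk density converts g/cm^3 to kg/m^3", {
  expect_equal(compute_density(bulk_sample(103, 100)), 1030)
  expect_equal(compute_density(bulk_sample(1, 1)), 1000)
  expect_equal(compute_density(bulk_sample(0.96, 1)), 960)
  expect_error(bulk_sample(1, 0))
})

test_that("CSV force-displacement records round-trip", {
  path <- withr::local_tempfile(fileext = ".csv")
  df <- data.frame(displacement_mm = c(0, 0.5, 1), force_N = c(0, 5, 10))
  write.csv(df, path, row.names = FALSE)
  rec <- read_force_displacement(path, length = 10, area = 100)
  expect_equal(rec$force, df$force_N)
  expect_equal(rec$displacement, df$displacement_mm)
  bad <- withr::local_tempfile(fileext = ".csv")
  write.csv(data.frame(x = 1, y = 2), bad, row.names = FALSE)
  expect_error(read_force_displacement(bad, 10, 100), "header")
})

test_that("the material library satisfies every constitutive invariant", {
  lib <- material_library()
  expect_setequal(names(lib),
                  c("skin", "flesh", "core", "steel", "pvc", "neoprene"))
  for (m in lib) {
    expect_s3_class(m, "material_params")  # constructor enforces invariants
    expect_gt(m$young_modulus, 0)
    expect_true(m$poisson_ratio > 0 && m$poisson_ratio < 0.5)
    if (!is.null(m$tangent_modulus))
      expect_lt(m$tangent_modulus, m$young_modulus)
  }
  expect_equal(material("flesh")$young_modulus, 1.57)
  expect_equal(material("core")$yield_stress, 1.12)
  # PVC density carried as tabulated even though implausible for bulk PVC
  expect_equal(material("pvc")$density, 60)
  expect_error(material("wood"), "unknown material")
})
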