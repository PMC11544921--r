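# Response-surface machinery: the published prediction polynomials, OLS
# quadratic fitting against a normal-equations oracle, rebound metrics, and
# the study drivers.

test_that("published polynomials reproduce their printed extrema", {
  # steel at (1 m, 90 deg) and neoprene at (0.25 m, 0 deg); the printed
  # extrema are 6716.07 and 1570.59 mm^3/J (direct evaluation of the printed
  # coefficients agrees to within a rounding unit)
  expect_lt(abs(evaluate_printed_model("steel", 1, 90) - 6716.07), 0.01)
  expect_lt(abs(evaluate_printed_model("neoprene", 0.25, 0) - 1570.59), 0.01)

  # the value at the origin is the printed intercept
  co <- printed_rsm_coefficients()
  for (m in names(co))
    expect_equal(evaluate_printed_model(m, 0, 0), unname(co[[m]]["b0"]))
  expect_error(evaluate_printed_model("glass", 1, 0), "unknown surface")
})

test_that("the printed extrema are extrema of their own polynomials", {
  mx <- rsm_extremum(printed_rsm_coefficients()$steel, maximum = TRUE)
  expect_equal(c(mx$X, mx$Y), c(1, 90))
  mn <- rsm_extremum(printed_rsm_coefficients()$neoprene, maximum = FALSE)
  expect_equal(c(mn$X, mn$Y), c(0.25, 0))
})

test_that("quadratic OLS recovers exact quadratics and matches the
           normal-equations oracle", {
  grid <- expand.grid(height_m = c(0.25, 0.5, 1), angle_deg = c(0, 45, 90))

  # exact quadratic data: coefficients recovered to 1e-8, R^2 = 1
  b_true <- c(12, -3, 0.5, 0.02, 4, -0.001)
  y <- cbind(1, grid$height_m, grid$angle_deg,
             grid$height_m * grid$angle_deg, grid$height_m^2,
             grid$angle_deg^2) %*% b_true
  d <- cbind(grid, bs_mm3_per_J = drop(y))
  fit <- fit_quadratic_surface(d, material = "test")
  expect_equal(unname(fit$coefficients), b_true, tolerance = 1e-8)
  expect_equal(fit$r_squared, 1, tolerance = 1e-10)

  # constant response: all non-intercept coefficients vanish
  dc <- cbind(grid, bs_mm3_per_J = 5)
  fitc <- fit_quadratic_surface(dc)
  expect_equal(unname(fitc$coefficients), c(5, 0, 0, 0, 0, 0),
               tolerance = 1e-10)

  # random responses: OLS equals the explicit normal-equations solve
  set.seed(21)
  for (i in 1:10) {
    dr <- cbind(grid, bs_mm3_per_J = rnorm(9, 1000, 300))
    f <- fit_quadratic_surface(dr)
    B <- cbind(1, grid$height_m, grid$angle_deg,
               grid$height_m * grid$angle_deg, grid$height_m^2,
               grid$angle_deg^2)
    beta_oracle <- solve(t(B) %*% B, t(B) %*% dr$bs_mm3_per_J)
    expect_equal(unname(f$coefficients), drop(beta_oracle), tolerance = 1e-10)
  }
})

test_that("fitting a printed model's own 3x3 evaluations recovers it", {
  grid <- expand.grid(height_m = c(0.25, 0.5, 1), angle_deg = c(0, 45, 90))
  for (m in c("steel", "pvc", "neoprene")) {
    y <- evaluate_printed_model(m, grid$height_m, grid$angle_deg)
    fit <- fit_quadratic_surface(cbind(grid, bs_mm3_per_J = y), material = m)
    expect_equal(unname(fit$coefficients),
                 unname(printed_rsm_coefficients()[[m]]), tolerance = 1e-6)
  }
})

test_that("rank-deficient designs are rejected with the confounded terms", {
  bad <- data.frame(height_m = c(0.25, 0.4, 0.5, 0.7, 0.9, 1),
                    angle_deg = 45, bs_mm3_per_J = rnorm(6))
  expect_error(fit_quadratic_surface(bad), "rank-deficient")
  few <- data.frame(height_m = c(0.25, 0.5), angle_deg = c(0, 45),
                    bs_mm3_per_J = 1:2)
  expect_error(fit_quadratic_surface(few), "distinct")
})

test_that("rebound metrics follow the closed forms", {
  # synthetic run: v0 = 3.13 m/s, rebound at half the impact speed
  fake <- structure(list(
    contact_force = c(0, 50, 100, 40, 0, 0, 0),
    com_velocity = c(-3.13, -1, 0, 1, 1.565, 1.5, 1.2),
    times = seq(0, 6e-3, by = 1e-3),
    scenario = drop_scenario(0.5, 0, "steel", v0 = 3.13)),
    class = "simulation_result")
  rb <- rebound_metrics(fake)
  expect_equal(rb$restitution, 0.5, tolerance = 1e-12)
  expect_equal(rb$rebound_height, (0.5 * 3.13)^2 / (2 * 9.8),
               tolerance = 1e-12)
  expect_true(rb$separated)

  # fully elastic sphere: restitution within 5% of one
  expect_equal(rebound_metrics(hertz_fixture()$result)$restitution, 1,
               tolerance = 0.05)
})

test_that("a nearly-zero-yield plastic sphere barely rebounds", {
  soft <- material_params("soft_plastic", 1.57, NULL, 0.005, 1030, 0.4)
  mesh <- make_fixture("elastic_sphere", radius = 10, element_size = 2.5)
  sc <- drop_scenario(0.05, 0, "steel", gravity = 0, duration = 0.01,
                      v0 = initial_velocity(0.05))
  res <- run_drop_simulation(mesh, list(flesh = soft, skin = soft), sc,
                             check_energy = FALSE)
  expect_lt(rebound_metrics(res)$restitution, 0.25)
})

test_that("the mesh sensitivity study reports one row per size", {
  st <- cached("mesh_study", mesh_sensitivity_study(
    sizes = c(4, 5, 6), scenario = drop_scenario(0.25, 0, "steel")))
  expect_identical(nrow(st$table), 3L)
  # element count strictly decreases as the mesh coarsens
  tab <- st$table[order(st$table$element_size_mm), ]
  expect_true(all(diff(tab$n_elements) < 0))
  expect_true(st$converged_size %in% c(4, 5, 6))
  expect_error(mesh_sensitivity_study(sizes = c(0.1, 2)), "0.5")
})

test_that("a degenerate zero-height sweep yields zero bruise everywhere", {
  g <- run_scenario_grid(heights = 0, angles = 0,
                         surfaces = c("steel", "neoprene"),
                         element_size = 6)
  expect_identical(nrow(g$cells), 2L)
  expect_false(any(g$cells$failed))
  expect_true(all(g$cells$bs_mm3_per_J == 0))
  expect_true(all(g$cells$vb_mm3 == 0))
})
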