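# Shared lazily-computed fixtures: expensive simulation runs are cached in a
# session-level environment so several test files can reuse them.

.fixture_cache <- new.env(parent = emptyenv())

cached <- function(name, expr) {
  if (!exists(name, envir = .fixture_cache)) {
    assign(name, force(expr), envir = .fixture_cache)
  }
  get(name, envir = .fixture_cache)
}

# Hertz benchmark: linear-elastic flesh-like sphere (r = 10 mm, nu = 0.3)
# dropped on a near-rigid foundation at 0.1 m/s. Low impact speed keeps the
# quasistatic Hertz closed form valid (the deviation grows ~ v^0.4 from
# stress-wave effects); 0.5 mm elements resolve the contact patch (a/l ~ 2.4).
hertz_fixture <- function() cached("hertz", {
  flesh <- material("flesh")
  el <- material_params("flesh_elastic", flesh$young_modulus, NULL, NULL,
                        flesh$density, 0.3)
  mesh <- make_fixture("elastic_sphere", radius = 10, element_size = 0.5,
                       skin_thickness = 0.01)
  surf <- material_params("near_rigid", el$young_modulus * 300, NULL, NULL,
                          1000, 0.3)
  v0 <- 0.1
  sc <- drop_scenario(v0^2 / (2 * 9.8), 0, surf, gravity = 0,
                      duration = 0.01, v0 = v0)
  res <- run_drop_simulation(mesh, list(flesh = el, skin = el), sc,
                             plasticity = FALSE,
                             geometric_nonlinearity = FALSE)
  E <- el$young_modulus * 1e6
  Estar <- E / (1 - el$poisson_ratio^2)
  R <- 0.01
  dmax <- (15 / 8 * 0.5 * res$mass_total * v0^2 / (Estar * sqrt(R)))^(2 / 5)
  list(result = res, scenario = sc, mesh = mesh,
       F_hertz = 4 / 3 * Estar * sqrt(R) * dmax^1.5, delta_max = dmax)
})

# baseline fruit drop: full multiscale fruit, steel surface, 0.5 m, 0 deg, at
# a coarse 4 mm mesh (fast; used for audit/impulse/damage checks)
fruit_run_fixture <- function() cached("fruit_run", {
  mesh <- generate_mesh(fruit_geometry(), 4)
  sc <- drop_scenario(0.5, 0, "steel")
  list(mesh = mesh, scenario = sc,
       result = run_drop_simulation(mesh, scenario = sc))
})

# full 27-cell factorial sweep at 3 mm (shared by the acceptance tests)
grid_fixture <- function() cached("grid27", {
  run_scenario_grid(element_size = 3, seed = 1L)
})
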