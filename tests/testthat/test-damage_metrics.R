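# Bruise extraction: threshold classification, volumes/areas against
# brute-force summation oracles, absorbed-energy definitions, BS = Vb/Et.

# a synthetic simulation_result over a small mesh with prescribed peak fields
fake_result <- function(mesh, tet_vm, skin_vm, energies = NULL) {
  structure(list(
    mesh = mesh, region = mesh$region,
    tet_peak_vm = tet_vm, skin_peak_vm = skin_vm,
    energies = energies %||% data.frame(
      time_s = c(0, 1e-3), ke_J = c(1, 0), ie_J = c(0, 0.5), ce_J = c(0, 0),
      plastic_J = c(0, 0.2), viscous_J = c(0, 0), contact_damping_J = c(0, 0),
      hourglass_J = c(0, 0), gravity_work_J = c(0, 0)),
    scenario = drop_scenario(0.5, 0, "steel"),
    mass_total = 0.1, initial_ke = 1,
    contact_force = c(0, 1, 0), com_velocity = c(-3, 0, 1),
    times = c(0, 5e-4, 1e-3)),
    class = "simulation_result")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

test_that("elements are bruised iff peak stress strictly exceeds threshold", {
  mesh <- make_fixture("unit_cube", n = 2)  # 48 tets, all flesh
  vm <- rep(0.1, 48)
  skin_vm <- rep(0.1, nrow(mesh$skin_tris))
  th <- damage_thresholds()

  # all below: empty mask
  m0 <- classify_bruised_elements(fake_result(mesh, vm, skin_vm), th)
  expect_false(any(m0$solid))
  expect_false(any(m0$skin))

  # exactly elements 3 and 7 above the flesh threshold
  vm2 <- vm
  vm2[c(3, 7)] <- 0.3
  m1 <- classify_bruised_elements(fake_result(mesh, vm2, skin_vm), th)
  expect_identical(which(m1$solid), c(3L, 7L))

  # a peak exactly at the threshold is NOT bruised (strict inequality)
  vm3 <- vm
  vm3[5] <- th$flesh
  m2 <- classify_bruised_elements(fake_result(mesh, vm3, skin_vm), th)
  expect_false(any(m2$solid))
})

test_that("bruised volume equals the brute-force subset sum", {
  mesh <- generate_mesh(fruit_geometry(), 5)
  vols <- tet_volumes(mesh$nodes, mesh$tets)
  n <- nrow(mesh$tets)

  expect_identical(bruise_volume(rep(FALSE, n), mesh), 0)
  expect_equal(bruise_volume(rep(TRUE, n), mesh), sum(vols))

  set.seed(3)
  mask <- runif(n) < 0.2
  oracle <- 0
  for (i in which(mask)) oracle <- oracle + vols[i]
  expect_equal(bruise_volume(mask, mesh), oracle, tolerance = 1e-12)
})

test_that("bruised skin area sums the triangle areas above threshold", {
  mesh <- make_fixture("elastic_sphere", radius = 10, element_size = 3)
  ns <- nrow(mesh$skin_tris)
  expect_identical(bruised_skin_area(rep(FALSE, ns), mesh), 0)
  # all above: total area ~ sphere surface within mesh tolerance
  tot <- bruised_skin_area(rep(TRUE, ns), mesh)
  expect_lt(abs(tot / (4 * pi * 100) - 1), 0.05)
  # single triangle: the cross-product closed form
  one <- rep(FALSE, ns)
  one[4] <- TRUE
  tri <- mesh$skin_tris[4, ]
  v1 <- mesh$nodes[tri[2], ] - mesh$nodes[tri[1], ]
  v2 <- mesh$nodes[tri[3], ] - mesh$nodes[tri[1], ]
  cr <- c(v1[2] * v2[3] - v1[3] * v2[2], v1[3] * v2[1] - v1[1] * v2[3],
          v1[1] * v2[2] - v1[2] * v2[1])
  expect_equal(bruised_skin_area(one, mesh), sqrt(sum(cr^2)) / 2,
               tolerance = 1e-12)
})

test_that("absorbed energy: peak internal energy captures the converted KE", {
  # elastic sphere run: at peak compression essentially all KE is internal
  hz <- hertz_fixture()
  expect_equal(absorbed_energy(hz$result) / hz$result$initial_ke, 1,
               tolerance = 0.05)
  # no-contact run absorbs nothing
  mesh <- make_fixture("elastic_sphere", radius = 10, element_size = 3)
  still <- run_drop_simulation(mesh, list(flesh = material("flesh"),
                                          skin = material("skin")),
                               drop_scenario(0, 0, "steel", gravity = 0,
                                             duration = 0.001))
  expect_lt(absorbed_energy(still), 1e-12)
})

test_that("plastic work of a perfectly plastic crush matches sigma_y*eps_p", {
  # elastic-perfectly-plastic uniaxial ramp: dissipation per unit volume is
  # sigma_y times the accumulated plastic strain
  epp <- material_params("epp", 1.57, NULL, 0.26, 1030, 0.4)
  resp <- uniaxial_response(epp, strain_max = 0.3, n_steps = 400)
  wp <- tail(resp$plastic_work_per_vol, 1)
  expect_gt(tail(resp$eps_p_bar, 1), 0)
  expect_equal(wp, 0.26 * tail(resp$eps_p_bar, 1), tolerance = 1e-6)
  # and the axial stress saturates at the yield stress
  expect_equal(tail(resp$stress, 1), 0.26, tolerance = 0.01)
})

test_that("bruise susceptibility is Vb/Et with a degenerate guard", {
  expect_identical(bruise_susceptibility(0, 0.5)$bs, 0)
  r <- bruise_susceptibility(100, 0.05)
  expect_equal(r$bs, 2000)
  expect_false(r$degenerate)
  expect_equal(bruise_susceptibility(200, 0.05)$bs, 2 * r$bs)
  d <- bruise_susceptibility(10, 0)
  expect_identical(d$bs, 0)
  expect_true(d$degenerate)
  expect_error(bruise_susceptibility(-1, 1), ">= 0")
})

test_that("bruised volume is monotone under threshold decrease", {
  mesh <- make_fixture("unit_cube", n = 2)
  set.seed(9)
  vm <- runif(48, 0, 0.6)
  skin_vm <- rep(0, nrow(mesh$skin_tris))
  vols <- numeric(0)
  for (thr in seq(0.5, 0.1, by = -0.1)) {
    th <- damage_thresholds(flesh_yield = thr)
    m <- classify_bruised_elements(fake_result(mesh, vm, skin_vm), th)
    vols <- c(vols, bruise_volume(m$solid, mesh))
  }
  expect_true(all(diff(vols) >= 0))
})

test_that("the damage report partitions Vb by region exactly", {
  fr <- fruit_run_fixture()
  rep_ <- damage_report(fr$result)
  expect_equal(sum(rep_$bruise_volume_by_region), rep_$bruise_volume)
  expect_gte(rep_$bruise_volume, 0)
  expect_gte(rep_$absorbed_energy, 0)
  expect_equal(rep_$bruise_susceptibility,
               rep_$bruise_volume / rep_$absorbed_energy)
  # all three absorbed-energy definitions are reported side by side
  expect_named(rep_$absorbed_energy_all,
               c("peak_internal", "plastic", "ke_loss"))
})
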