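# R interface to the explicit-dynamics core: scenario/config containers,
# stability estimate, constitutive single-point driver, contact model and the
# drop-simulation driver. The mesh lives in mm / MPa / N units; everything is
# converted to SI (m, kg, s, Pa) at the solver boundary.

#' Impact velocity of a free fall
#'
#' v0 = sqrt(2 g h), directed normal to the surface (downward). The fruit is
#' placed touching the surface and given this velocity, so the fall itself is
#' not simulated.
#'
#' @param height Drop height in m, >= 0.
#' @param gravity Gravitational acceleration (default 9.8 m s^-2).
#' @return Impact speed in m s^-1.
#' @export
initial_velocity <- function(height, gravity = 9.8) {
  if (!is_number(height) || height < 0) stopf("height must be >= 0")
  sqrt(2 * gravity * height)
}

#' Explicit solver configuration
#'
#' @param time_step_safety Fraction of the critical time step used (0, 1].
#' @param penalty_reference_thickness Reference foundation layer thickness
#'   h_ref in mm; contact pressure is `E_surf / h_ref * penetration`.
#' @param bulk_viscosity_linear Linear bulk viscosity coefficient.
#' @param contact_damping Viscous contact damping as a fraction of critical
#'   per penetrating node (suppresses penalty-spring ringing; its dissipation
#'   is tracked in the energy audit).
#' @param n_frames Number of output frames over the event.
#' @param contact_friction Coulomb friction coefficient (only 0, frictionless,
#'   is implemented).
#' @return Object of class `solver_config`.
#' @export
solver_config <- function(time_step_safety = 0.9,
                          penalty_reference_thickness = 10,
                          bulk_viscosity_linear = 0.06,
                          contact_damping = 0.1,
                          n_frames = 400L,
                          contact_friction = 0) {
  check_number(time_step_safety, "time_step_safety", 0, 1, strict_lower = TRUE)
  check_number(penalty_reference_thickness, "penalty_reference_thickness", 0,
               strict_lower = TRUE)
  check_number(bulk_viscosity_linear, "bulk_viscosity_linear", 0)
  check_number(contact_damping, "contact_damping", 0, 1)
  if (!identical(as.numeric(contact_friction), 0))
    stopf("only frictionless contact (contact_friction = 0) is implemented")
  structure(list(time_step_safety = time_step_safety,
                 penalty_reference_thickness = penalty_reference_thickness,
                 bulk_viscosity_linear = bulk_viscosity_linear,
                 contact_damping = contact_damping,
                 n_frames = as.integer(n_frames),
                 contact_friction = 0),
            class = "solver_config")
}

resolve_material <- function(x) {
  if (inherits(x, "material_params")) return(x)
  if (is.character(x) && length(x) == 1L) return(material(x))
  stopf("expected a material_params object or a library material name")
}

#' Drop scenario
#'
#' One cell of the factorial design: drop height, collision angle and contact
#' surface material. The collision angle is the angle between the fruit's
#' long (polar) axis and the contact plane: 0 deg is a side (equatorial)
#' impact with maximal contact area, 90 deg an end impact.
#'
#' @param height Drop height in m, >= 0.
#' @param angle Collision angle in degrees, within [0, 90].
#' @param surface Surface material: a [material_params()] or library name
#'   (`"steel"`, `"pvc"`, `"neoprene"`).
#' @param gravity Gravitational acceleration (m s^-2).
#' @param duration Simulated event time (s); 0.02 s covers contact and
#'   rebound.
#' @param element_size Target mesh element size in mm.
#' @param v0 Optional impact-speed override (m/s); defaults to the free-fall
#'   speed `sqrt(2 g h)`. Lets benchmark runs decouple impact speed from
#'   gravity.
#' @return Object of class `drop_scenario` with the impact speed `v0`.
#' @export
drop_scenario <- function(height, angle = 0, surface = "steel",
                          gravity = 9.8, duration = 0.02, element_size = 2,
                          v0 = NULL) {
  check_number(height, "height", 0)
  check_number(angle, "angle", 0, 90)
  check_number(duration, "duration", 0, strict_lower = TRUE)
  surface <- resolve_material(surface)
  structure(list(height = height, angle = angle, surface = surface,
                 gravity = gravity, duration = duration,
                 element_size = element_size,
                 v0 = v0 %||% initial_velocity(height, gravity)),
            class = "drop_scenario")
}

#' Default region materials from the built-in library
#' @return Named list with `flesh`, `core` and `skin` [material_params()].
#' @export
default_materials <- function() {
  lib <- material_library()
  list(flesh = lib$flesh, core = lib$core, skin = lib$skin)
}

hardening_modulus <- function(mat) {
  E <- mat$young_modulus
  Et <- mat$tangent_modulus
  if (is.null(Et) || Et == 0) return(0)
  if (Et >= E) stopf("tangent modulus must be < Young's modulus for %s",
                     mat$name)
  E * Et / (E - Et)
}

# per-tet material arrays (SI) from region labels
.tet_material_arrays <- function(mesh, materials, plasticity) {
  reg <- mesh$region
  pick <- function(field, default = NA_real_) {
    vapply(reg, function(r) {
      v <- materials[[r]][[field]]
      if (is.null(v)) default else v
    }, 0)
  }
  list(E = pick("young_modulus") * 1e6,
       nu = pick("poisson_ratio"),
       rho = pick("density"),
       sigy = pick("yield_stress") * 1e6,
       H = vapply(reg, function(r) hardening_modulus(materials[[r]]), 0) * 1e6,
       plastic = plasticity &
         !is.na(vapply(reg, function(r)
           materials[[r]]$yield_stress %||% NA_real_, 0)))
}

#' Stable explicit time step of a mesh
#'
#' Computes the critical time step as `safety * 2 / omega_max`, where
#' omega_max is the largest element eigenfrequency (per-element power
#' iteration on the assembled constant-strain stiffness against the lumped
#' mass). When a contact surface is given, the penalty spring frequency
#' of the skin nodes additionally bounds the step.
#'
#' @param mesh A `fruit_mesh`.
#' @param materials Named list of [material_params()] per region (`flesh`,
#'   `core`) plus `skin`; defaults to the built-in library.
#' @param config A [solver_config()].
#' @param surface Optional surface [material_params()] (or name) for the
#'   contact bound.
#' @return List with `dt` (s, the binding step), `dt_structural`,
#'   `dt_contact` (NA without a surface) and `omega_max` (rad/s).
#' @export
stable_time_step <- function(mesh, materials = default_materials(),
                             config = solver_config(), surface = NULL) {
  stopifnot(inherits(mesh, "fruit_mesh"))
  nodes_m <- mesh$nodes * 1e-3
  tm <- .tet_material_arrays(mesh, materials, plasticity = FALSE)
  om_tet <- cpp_max_tet_frequency(nodes_m, mesh$tets - 1L, tm$E, tm$nu, tm$rho)
  sk <- materials$skin %||% materials$flesh
  om_tri <- if (nrow(mesh$skin_tris) > 0)
    cpp_max_tri_frequency(nodes_m, mesh$skin_tris - 1L,
                          sk$young_modulus * 1e6, sk$poisson_ratio,
                          sk$density, mesh$skin_thickness * 1e-3)
  else 0
  om_s <- max(om_tet, om_tri)
  dt_struct <- config$time_step_safety * 2 / om_s
  dt_contact <- NA_real_
  om_c <- 0
  if (!is.null(surface)) {
    surface <- resolve_material(surface)
    trib <- rep(0, nrow(mesh$nodes))
    a0 <- tri_areas(mesh$nodes, mesh$skin_tris) * 1e-6
    for (k in 1:3) {
      tb <- tapply(rep(a0 / 3, 1), mesh$skin_tris[, k], sum)
      trib[as.integer(names(tb))] <- trib[as.integer(names(tb))] + tb
    }
    m <- .lumped_mass(mesh, materials)
    on <- which(trib > 0)
    k_c <- surface$young_modulus * 1e6 /
      (config$penalty_reference_thickness * 1e-3) * trib[on]
    om_c <- max(sqrt(k_c / m[on]))
    dt_contact <- config$time_step_safety * 2 / sqrt(om_s^2 + om_c^2)
  }
  list(dt = min(dt_struct, dt_contact, na.rm = TRUE),
       dt_structural = dt_struct, dt_contact = dt_contact,
       omega_max = om_s, omega_contact = om_c)
}

# lumped nodal mass (kg) of a mesh under the given materials
.lumped_mass <- function(mesh, materials) {
  m <- rep(0, nrow(mesh$nodes))
  vols <- tet_volumes(mesh$nodes, mesh$tets) * 1e-9
  rho <- vapply(mesh$region, function(r) materials[[r]]$density, 0)
  for (k in 1:4) {
    tb <- tapply(rho * vols / 4, mesh$tets[, k], sum)
    m[as.integer(names(tb))] <- m[as.integer(names(tb))] + tb
  }
  sk <- materials$skin %||% materials$flesh
  a0 <- tri_areas(mesh$nodes, mesh$skin_tris) * 1e-6
  for (k in 1:3) {
    tb <- tapply(sk$density * a0 * mesh$skin_thickness * 1e-3 / 3,
                 mesh$skin_tris[, k], sum)
    m[as.integer(names(tb))] <- m[as.integer(names(tb))] + tb
  }
  m
}

#' Single-point J2 radial-return update
#'
#' Elastic trial plus radial return with linear isotropic hardening
#' `H = E * Et / (E - Et)` (perfectly plastic when `Et` is absent or zero);
#' plasticity is active only when the material has a yield stress. Strain and
#' stress use Voigt order (xx, yy, zz, xy, yz, zx) with tensor (not
#' engineering) shear components. Units MPa.
#'
#' @param strain_increment Numeric(6) strain increment.
#' @param state List with `stress` (numeric(6), MPa) and `eps_p_bar`
#'   (accumulated equivalent plastic strain); defaults to a virgin state.
#' @param material A [material_params()].
#' @return List with `stress` (MPa), `eps_p_bar`, `dgamma` (plastic strain
#'   increment), `von_mises` (MPa) and `plastic_work_per_vol` (MPa = MJ/m^3).
#' @export
radial_return_update <- function(strain_increment, state = NULL, material) {
  if (is.null(state)) state <- list(stress = rep(0, 6), eps_p_bar = 0)
  has_yield <- !is.null(material$yield_stress)
  H <- hardening_modulus(material)
  out <- cpp_radial_return(as.numeric(strain_increment),
                           as.numeric(state$stress),
                           state$eps_p_bar,
                           material$young_modulus, material$poisson_ratio,
                           if (has_yield) material$yield_stress else 0,
                           H, has_yield)
  list(stress = out$stress, eps_p_bar = out$ebar, dgamma = out$dgamma,
       von_mises = out$von_mises, plastic_work_per_vol = out$wp_per_vol)
}

#' Uniaxial stress response of a material point
#'
#' Drives the J2 radial-return update through a monotonic uniaxial-stress
#' path: the axial strain is ramped to `strain_max` while the lateral strain
#' of each increment is solved (secant iteration) so the lateral stress stays
#' zero. Under the bilinear law the engineering stress-strain slope is E up
#' to the bio-yield stress and Et beyond, which this driver verifies and the
#' methods vignette illustrates.
#'
#' @param material A [material_params()].
#' @param strain_max Final axial strain.
#' @param n_steps Number of strain increments.
#' @return Data frame with `strain`, `stress` (MPa, axial), `eps_p_bar` and
#'   `plastic_work_per_vol` (MPa, cumulative).
#' @export
uniaxial_response <- function(material, strain_max = 0.3, n_steps = 300L) {
  state <- list(stress = rep(0, 6), eps_p_bar = 0)
  da <- strain_max / n_steps
  out <- matrix(0, n_steps + 1L, 4)
  wp <- 0
  dl <- -material$poisson_ratio * da  # initial guess: elastic lateral strain
  for (i in seq_len(n_steps)) {
    syy <- function(d) {
      r <- radial_return_update(c(da, d, d, 0, 0, 0), state, material)
      r$stress[2]
    }
    # secant iteration on the lateral strain increment
    d0 <- dl; d1 <- dl * 0.9 - 1e-8
    f0 <- syy(d0); f1 <- syy(d1)
    for (k in 1:60) {
      if (abs(f1) < 1e-10 * max(1, abs(material$young_modulus))) break
      d2 <- d1 - f1 * (d1 - d0) / (f1 - f0)
      d0 <- d1; f0 <- f1; d1 <- d2; f1 <- syy(d2)
    }
    dl <- d1
    res <- radial_return_update(c(da, dl, dl, 0, 0, 0), state, material)
    state <- list(stress = res$stress, eps_p_bar = res$eps_p_bar)
    wp <- wp + res$plastic_work_per_vol
    out[i + 1L, ] <- c(i * da, res$stress[1], res$eps_p_bar, wp)
  }
  data.frame(strain = out[, 1], stress = out[, 2], eps_p_bar = out[, 3],
             plastic_work_per_vol = out[, 4])
}

#' Elastic-foundation contact force
#'
#' For each node below the plane z = 0, the foundation applies the normal
#' pressure `E_surf / h_ref * penetration` over the node's tributary skin
#' area. Positions and areas in mm / mm^2, surface modulus in MPa; forces in
#' N, contact spring energy in J.
#'
#' @param node_positions Matrix (n x 3) of node positions (mm).
#' @param tributary_area Numeric(n) tributary areas (mm^2).
#' @param surface Surface [material_params()] (or library name).
#' @param config A [solver_config()].
#' @return List with `force` (numeric(n), upward normal force in N per node),
#'   `total_force` (N) and `contact_energy` (J).
#' @export
contact_force <- function(node_positions, tributary_area, surface,
                          config = solver_config()) {
  surface <- resolve_material(surface)
  z <- node_positions[, 3]
  pen <- pmax(-z, 0)
  k <- surface$young_modulus / config$penalty_reference_thickness *
    tributary_area  # N/mm per node
  fr <- k * pen
  list(force = fr, total_force = sum(fr),
       contact_energy = sum(0.5 * k * pen^2) * 1e-3)
}

# rotate mesh nodes so the polar (x) axis makes `angle` degrees with the
# plane, then drop the mesh so its lowest node touches z = 0
orient_mesh_nodes <- function(nodes, angle) {
  th <- angle * pi / 180
  R <- rbind(c(cos(th), 0, sin(th)), c(0, 1, 0), c(-sin(th), 0, cos(th)))
  out <- nodes %*% t(R)
  out[, 3] <- out[, 3] - min(out[, 3])
  out
}

#' Run the explicit drop-impact simulation
#'
#' Orients the fruit to the collision angle, places it touching the plane
#' z = 0, gives every node the free-fall impact velocity downward and
#' integrates the event with the central-difference scheme. Gravity acts
#' throughout. The result carries the full energy audit (kinetic, internal =
#' elastic + plastic stress work, plastic dissipation, contact spring energy,
#' bulk-viscosity dissipation, gravity work; hourglass energy is identically
#' zero for the fully integrated elements used here), the total contact force
#' and centre-of-mass velocity histories, and per-element peak Von Mises
#' stress and accumulated plastic strain.
#'
#' @param mesh A `fruit_mesh` (as generated, long axis along x).
#' @param materials Named list of region materials (`flesh`, `core`, `skin`);
#'   defaults to the built-in library. A mesh region lacking an entry is an
#'   error.
#' @param scenario A [drop_scenario()].
#' @param config A [solver_config()].
#' @param plasticity Set `FALSE` to run fully elastic (oracle benchmarks).
#' @param geometric_nonlinearity Update element geometry during integration
#'   (hypoelastic rate form on current coordinates, the default). `FALSE`
#'   switches to linear kinematics (reference-configuration gradients, no
#'   stress rotation), the regime of linear-elastic closed forms such as the
#'   Hertz contact benchmark.
#' @param check_energy Abort on energy growth beyond 5% of the impact kinetic
#'   energy (instability guard); default `TRUE`.
#' @return Object of class `simulation_result`.
#' @export
run_drop_simulation <- function(mesh, materials = default_materials(),
                                scenario, config = solver_config(),
                                plasticity = TRUE,
                                geometric_nonlinearity = TRUE,
                                check_energy = TRUE) {
  stopifnot(inherits(mesh, "fruit_mesh"), inherits(scenario, "drop_scenario"))
  for (r in unique(mesh$region))
    if (is.null(materials[[r]]))
      stopf("no material given for mesh region '%s'", r)
  nodes <- orient_mesh_nodes(mesh$nodes, scenario$angle) * 1e-3  # m
  tm <- .tet_material_arrays(mesh, materials, plasticity)
  sk <- materials$skin %||% materials$flesh
  om_tet <- cpp_max_tet_frequency(nodes, mesh$tets - 1L, tm$E, tm$nu, tm$rho)
  om_tri <- if (nrow(mesh$skin_tris) > 0)
    cpp_max_tri_frequency(nodes, mesh$skin_tris - 1L, sk$young_modulus * 1e6,
                          sk$poisson_ratio, sk$density,
                          mesh$skin_thickness * 1e-3)
  else 0
  sk_sigy <- sk$yield_stress
  res <- cpp_drop_sim(
    nodes, mesh$tets - 1L,
    tm$E, tm$nu, tm$rho,
    ifelse(is.na(tm$sigy), 0, tm$sigy), tm$H, tm$plastic,
    as.integer(mesh$region == "flesh"),
    mesh$skin_tris - 1L,
    sk$young_modulus * 1e6, sk$poisson_ratio, sk$density,
    if (is.null(sk_sigy)) 0 else sk_sigy * 1e6,
    plasticity && !is.null(sk_sigy),
    mesh$skin_thickness * 1e-3,
    scenario$v0, scenario$gravity, scenario$duration,
    scenario$surface$young_modulus * 1e6,
    config$penalty_reference_thickness * 1e-3,
    config$time_step_safety, config$bulk_viscosity_linear,
    config$contact_damping, config$n_frames, max(om_tet, om_tri),
    check_energy, geometric_nonlinearity)
  if (res$status != "ok")
    stopf("simulation aborted after %d steps at t = %.3g s: %s",
          as.integer(res$n_steps), max(res$times, 0), res$status)
  structure(list(
    times = res$times,
    contact_force = res$contact_force,
    com_velocity = res$com_vz,
    energies = data.frame(
      time_s = res$times, ke_J = res$ke, ie_J = res$ie, ce_J = res$ce,
      plastic_J = res$plastic, viscous_J = res$viscous,
      contact_damping_J = res$contact_damping,
      hourglass_J = rep(0, length(res$times)),
      gravity_work_J = res$gravity_work),
    tet_peak_vm = res$tet_peak_vm / 1e6,       # MPa
    vm_flesh_frame = res$vm_flesh_frame / 1e6,  # MPa, per output frame
    tet_eps_p = res$tet_eps_p,
    skin_peak_vm = res$tri_peak_vm / 1e6,      # MPa
    displacement = res$displacement * 1e3,     # mm
    initial_ke = res$initial_ke,
    mass_total = res$mass_total,
    dt = list(free = res$dt_free, contact = res$dt_contact),
    n_steps = as.integer(res$n_steps),
    mesh = mesh, scenario = scenario, config = config,
    region = mesh$region),
    class = "simulation_result")
}

#' @export
print.simulation_result <- function(x, ...) {
  cat(sprintf("<simulation_result> h=%g m, angle=%g deg, surface=%s\n",
              x$scenario$height, x$scenario$angle, x$scenario$surface$name))
  cat(sprintf("  %d steps (dt %.3g / %.3g s), peak contact force %.2f N\n",
              x$n_steps, x$dt$free, x$dt$contact, max(x$contact_force)))
  cat(sprintf("  peak flesh VM %.3f MPa, peak skin VM %.3f MPa\n",
              max(x$tet_peak_vm[x$region == "flesh"]),
              if (length(x$skin_peak_vm)) max(x$skin_peak_vm) else NA))
  invisible(x)
}

#' Time-series data frame of a simulation result
#'
#' @param result A `simulation_result`.
#' @return Data frame with columns `time_s`, `contact_force_N`,
#'   `com_velocity_mps`, `ke_J`, `ie_J`, `ce_J`, `plastic_J`, `hourglass_J`,
#'   `viscous_J`.
#' @export
as_timeseries <- function(result) {
  stopifnot(inherits(result, "simulation_result"))
  data.frame(time_s = result$times,
             contact_force_N = result$contact_force,
             com_velocity_mps = result$com_velocity,
             ke_J = result$energies$ke_J,
             ie_J = result$energies$ie_J,
             ce_J = result$energies$ce_J,
             plastic_J = result$energies$plastic_J,
             hourglass_J = result$energies$hourglass_J,
             viscous_J = result$energies$viscous_J)
}

#' Energy-audit closure error of a run
#'
#' Relative deviation of (KE + internal + contact + viscous) from
#' (initial KE + gravity work) at each output step, normalised by the impact
#' kinetic energy.
#'
#' @param result A `simulation_result`.
#' @return Numeric vector of relative closure errors per output frame.
#' @export
energy_audit <- function(result) {
  e <- result$energies
  total <- e$ke_J + e$ie_J + e$ce_J + e$viscous_J + e$contact_damping_J
  budget <- result$initial_ke + e$gravity_work_J
  (total - budget) / max(result$initial_ke, 1e-12)
}
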