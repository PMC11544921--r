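# Bruise extraction: Von Mises yield-threshold classification of elements,
# bruised volume and skin area, absorbed energy and the bruise-susceptibility
# index BS = Vb / Et (bruised volume per unit absorbed energy, mm^3/J).

#' Tissue damage thresholds
#'
#' Von Mises stress levels above which a region counts as bruised. Defaults:
#' flesh 0.26 MPa and skin 0.52 MPa (the values used in the damage analysis;
#' the tabulated skin yield 0.53 MPa is available via override), core 1.12
#' MPa.
#'
#' @param flesh_yield,skin_yield,core_yield Thresholds in MPa, > 0.
#' @return Object of class `damage_thresholds`.
#' @export
damage_thresholds <- function(flesh_yield = 0.26, skin_yield = 0.52,
                              core_yield = 1.12) {
  for (v in c(flesh_yield, skin_yield, core_yield))
    check_number(v, "threshold", 0, strict_lower = TRUE)
  structure(list(flesh = flesh_yield, skin = skin_yield, core = core_yield),
            class = "damage_thresholds")
}

#' Classify bruised elements
#'
#' An element is bruised iff its peak-over-time Von Mises stress strictly
#' exceeds its region's threshold (ties are not bruised).
#'
#' @param result A `simulation_result`.
#' @param thresholds A [damage_thresholds()].
#' @return List with logical vectors `solid` (per tetrahedron) and `skin`
#'   (per skin triangle).
#' @export
classify_bruised_elements <- function(result, thresholds = damage_thresholds()) {
  stopifnot(inherits(result, "simulation_result"))
  reg <- result$region
  th <- vapply(reg, function(r) {
    v <- thresholds[[r]]
    if (is.null(v)) stopf("no damage threshold for region '%s'", r)
    v
  }, 0)
  list(solid = unname(result$tet_peak_vm > th),
       skin = unname(result$skin_peak_vm > thresholds$skin))
}

#' Bruised volume
#'
#' Sum of undeformed volumes of the bruised solid (flesh + core) tetrahedra.
#'
#' @param mask Logical vector per tetrahedron (see
#'   [classify_bruised_elements()]).
#' @param mesh The `fruit_mesh` of the run.
#' @return Bruised volume in mm^3.
#' @export
bruise_volume <- function(mask, mesh) {
  if (length(mask) != nrow(mesh$tets))
    stopf("mask length %d does not match %d tetrahedra",
          length(mask), nrow(mesh$tets))
  sum(tet_volumes(mesh$nodes, mesh$tets)[mask])
}

#' Bruised skin area
#'
#' Sum of (undeformed) areas of skin triangles whose peak Von Mises stress
#' exceeds the skin threshold.
#'
#' @param mask_skin Logical vector per skin triangle.
#' @param mesh The `fruit_mesh` of the run.
#' @return Bruised skin area in mm^2.
#' @export
bruised_skin_area <- function(mask_skin, mesh) {
  if (length(mask_skin) != nrow(mesh$skin_tris))
    stopf("mask length %d does not match %d skin triangles",
          length(mask_skin), nrow(mesh$skin_tris))
  sum(tri_areas(mesh$nodes, mesh$skin_tris)[mask_skin])
}

#' Energy absorbed by the fruit during the collision
#'
#' The default definition is the maximum over time of the fruit's internal
#' energy (elastic strain energy plus plastic dissipation), i.e. the energy
#' taken up at peak compression. Alternatives: `"plastic"` (plastic
#' dissipation only, the irreversible part) and `"ke_loss"` (kinetic energy
#' lost between impact and rebound, 0.5 m (v0^2 - vr^2)).
#'
#' @param result A `simulation_result`.
#' @param method `"peak_internal"` (default), `"plastic"` or `"ke_loss"`.
#' @return Absorbed energy in J.
#' @export
absorbed_energy <- function(result,
                            method = c("peak_internal", "plastic", "ke_loss")) {
  method <- match.arg(method)
  e <- result$energies
  if (nrow(e) == 0) stopf("empty energy series")
  switch(method,
         peak_internal = max(e$ie_J),
         plastic = max(e$plastic_J),
         ke_loss = {
           rb <- rebound_metrics(result)
           v0 <- result$scenario$v0
           0.5 * result$mass_total * (v0^2 - rb$rebound_speed^2)
         })
}

#' Bruise susceptibility
#'
#' BS = Vb / Et in mm^3 J^-1. A run that absorbed no energy (Et = 0) returns
#' BS = 0 with a degenerate flag.
#'
#' @param bruise_volume Bruised volume Vb (mm^3), >= 0.
#' @param absorbed_energy Absorbed energy Et (J), >= 0.
#' @return List with `bs` (mm^3/J) and `degenerate` (logical).
#' @export
bruise_susceptibility <- function(bruise_volume, absorbed_energy) {
  if (bruise_volume < 0 || absorbed_energy < 0)
    stopf("bruise_volume and absorbed_energy must be >= 0")
  if (absorbed_energy == 0)
    return(list(bs = 0, degenerate = TRUE))
  list(bs = bruise_volume / absorbed_energy, degenerate = FALSE)
}

#' Full damage report of a simulation
#'
#' @param result A `simulation_result`.
#' @param thresholds A [damage_thresholds()].
#' @param energy_method Absorbed-energy definition, see [absorbed_energy()].
#' @return Object of class `damage_report`: bruise volume (mm^3, with
#'   per-region breakdown), bruised skin area (mm^2), absorbed energy (J,
#'   all three definitions), bruise susceptibility (mm^3/J) and the
#'   degenerate flag.
#' @export
damage_report <- function(result, thresholds = damage_thresholds(),
                          energy_method = "peak_internal") {
  masks <- classify_bruised_elements(result, thresholds)
  vols <- tet_volumes(result$mesh$nodes, result$mesh$tets)
  vb_region <- c(
    flesh = sum(vols[masks$solid & result$region == "flesh"]),
    core = sum(vols[masks$solid & result$region == "core"]))
  vb <- sum(vb_region)
  et_all <- c(peak_internal = absorbed_energy(result, "peak_internal"),
              plastic = absorbed_energy(result, "plastic"),
              ke_loss = tryCatch(absorbed_energy(result, "ke_loss"),
                                 error = function(e) NA_real_))
  et <- et_all[[energy_method]]
  bs <- bruise_susceptibility(vb, et)
  structure(list(bruise_volume = vb,
                 bruise_volume_by_region = vb_region,
                 bruised_skin_area = bruised_skin_area(masks$skin, result$mesh),
                 absorbed_energy = et,
                 absorbed_energy_all = et_all,
                 energy_method = energy_method,
                 bruise_susceptibility = bs$bs,
                 degenerate = bs$degenerate,
                 thresholds = thresholds),
            class = "damage_report")
}

#' @export
print.damage_report <- function(x, ...) {
  cat("<damage_report>\n")
  cat(sprintf("  bruise volume: %.1f mm^3 (flesh %.1f, core %.1f)\n",
              x$bruise_volume, x$bruise_volume_by_region[["flesh"]],
              x$bruise_volume_by_region[["core"]]))
  cat(sprintf("  bruised skin area: %.1f mm^2\n", x$bruised_skin_area))
  cat(sprintf("  absorbed energy (%s): %.4f J\n", x$energy_method,
              x$absorbed_energy))
  cat(sprintf("  bruise susceptibility: %.1f mm^3/J%s\n",
              x$bruise_susceptibility,
              if (x$degenerate) " (degenerate: no energy absorbed)" else ""))
  invisible(x)
}
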