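# Reduction of force-displacement tissue tests to constitutive parameters:
# engineering stress/strain, bilinear (bio-yield) fitting, bulk density, and
# the built-in material parameter library used by the impact solver.

#' Constitutive parameter record for a tissue or contact-surface material
#'
#' Holds the parameters of the bilinear elastic-plastic law used by the
#' explicit solver: Young's modulus `E`, optional tangent (post-yield) modulus
#' `Et`, optional bio-yield stress, density and Poisson's ratio. Units follow
#' the laboratory convention: MPa for moduli and stresses, kg m^-3 for
#' density.
#'
#' @param name Material name (character).
#' @param young_modulus Young's modulus E in MPa, > 0.
#' @param tangent_modulus Post-yield tangent modulus Et in MPa, `NULL` when the
#'   material fractured before a post-yield segment was observed (skin) or is
#'   treated as elastic / perfectly plastic; must satisfy `0 <= Et < E`.
#' @param yield_stress Bio-yield stress in MPa, `NULL` for purely elastic
#'   materials.
#' @param density Density in kg m^-3, > 0.
#' @param poisson_ratio Poisson's ratio, in (0, 0.5).
#' @param metadata Optional list of auxiliary data (e.g. measurement spreads).
#' @return An object of class `material_params`.
#' @export
material_params <- function(name, young_modulus, tangent_modulus = NULL,
                            yield_stress = NULL, density, poisson_ratio,
                            metadata = list()) {
  check_number(young_modulus, "young_modulus", lower = 0, strict_lower = TRUE)
  check_number(poisson_ratio, "poisson_ratio", lower = 0, upper = 0.5,
               strict_lower = TRUE, strict_upper = TRUE)
  check_number(density, "density", lower = 0, strict_lower = TRUE)
  if (!is.null(tangent_modulus)) {
    check_number(tangent_modulus, "tangent_modulus", lower = 0)
    if (tangent_modulus >= young_modulus)
      stopf("tangent_modulus (%g) must be < young_modulus (%g)",
            tangent_modulus, young_modulus)
  }
  if (!is.null(yield_stress))
    check_number(yield_stress, "yield_stress", lower = 0, strict_lower = TRUE)
  structure(list(name = as.character(name),
                 young_modulus = young_modulus,
                 tangent_modulus = tangent_modulus,
                 yield_stress = yield_stress,
                 density = density,
                 poisson_ratio = poisson_ratio,
                 metadata = metadata),
            class = "material_params")
}

#' @export
print.material_params <- function(x, ...) {
  cat(sprintf("<material_params> %s\n", x$name))
  cat(sprintf("  E  = %g MPa, nu = %g, rho = %g kg/m^3\n",
              x$young_modulus, x$poisson_ratio, x$density))
  if (!is.null(x$yield_stress))
    cat(sprintf("  sigma_y = %g MPa, Et = %s MPa\n", x$yield_stress,
                if (is.null(x$tangent_modulus)) "- (perfectly plastic)"
                else format(x$tangent_modulus)))
  invisible(x)
}

#' Built-in material parameter library
#'
#' Mean laboratory values for kiwifruit skin, flesh and core and for the three
#' contact-surface materials (steel, PVC, neoprene). Measurement spreads,
#' where reported, are carried as metadata (`*_sd` entries). Values are stored
#' as plain JSON under `inst/extdata/materials_table.json`.
#'
#' Note the PVC density is carried as tabulated (60 kg m^-3, physically
#' implausible for bulk PVC); it is unused because contact surfaces are
#' modelled as massless elastic foundations.
#'
#' @return Named list of [material_params()] objects.
#' @export
material_library <- function() {
  path <- system.file("extdata", "materials_table.json", package = "fruitdrop",
                      mustWork = TRUE)
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  out <- lapply(names(raw), function(nm) {
    r <- raw[[nm]]
    num_or_null <- function(v) if (is.null(v) || all(is.na(v))) NULL else as.numeric(v)
    material_params(
      name = nm,
      young_modulus = as.numeric(r$young_modulus),
      tangent_modulus = num_or_null(r$tangent_modulus),
      yield_stress = num_or_null(r$yield_stress),
      density = as.numeric(r$density),
      poisson_ratio = as.numeric(r$poisson_ratio),
      metadata = r[grepl("_sd$", names(r))])
  })
  names(out) <- names(raw)
  out
}

#' Look up one material from the built-in library
#'
#' @param name One of `"skin"`, `"flesh"`, `"core"`, `"steel"`, `"pvc"`,
#'   `"neoprene"` (case-insensitive).
#' @return A [material_params()] object.
#' @export
material <- function(name) {
  lib <- material_library()
  key <- tolower(name)
  if (!key %in% names(lib))
    stopf("unknown material '%s'; library has: %s", name,
          paste(names(lib), collapse = ", "))
  lib[[key]]
}

#' Force-displacement test record
#'
#' A single tension or compression test on a tissue specimen: load vs
#' crosshead displacement plus the specimen's initial gauge length and
#' cross-sectional area.
#'
#' @param force Load F in N (numeric vector, length >= 2).
#' @param displacement Displacement (elongation/compression) in mm,
#'   non-decreasing, same length as `force`.
#' @param length Initial specimen length L in mm, > 0.
#' @param area Cross-sectional area S in mm^2, > 0.
#' @param mode `"tension"` or `"compression"`.
#' @return Object of class `force_displacement_record`.
#' @export
force_displacement_record <- function(force, displacement, length, area,
                                      mode = c("compression", "tension")) {
  mode <- match.arg(mode)
  if (!is.numeric(force) || !is.numeric(displacement))
    stopf("force and displacement must be numeric vectors")
  if (length(force) != length(displacement) || length(force) < 1L)
    stopf("force and displacement must have equal length >= 1")
  if (any(diff(displacement) < 0))
    stopf("displacement must be non-decreasing")
  if (!is_number(length) || length <= 0)
    stopf("invalid specimen: initial length must be > 0 (got %s)", format(length))
  if (!is_number(area) || area <= 0)
    stopf("invalid specimen: cross-section area must be > 0 (got %s)", format(area))
  structure(list(force = as.numeric(force),
                 displacement = as.numeric(displacement),
                 length = length, area = area, mode = mode),
            class = "force_displacement_record")
}

#' Read a force-displacement record from CSV
#'
#' The file must have a header with columns `displacement_mm` and `force_N`.
#'
#' @param path CSV file path.
#' @inheritParams force_displacement_record
#' @return A [force_displacement_record()].
#' @export
read_force_displacement <- function(path, length, area,
                                    mode = c("compression", "tension")) {
  mode <- match.arg(mode)
  df <- utils::read.csv(path)
  need <- c("displacement_mm", "force_N")
  if (!all(need %in% names(df)))
    stopf("CSV must have header columns %s; found: %s",
          paste(need, collapse = ", "), paste(names(df), collapse = ", "))
  force_displacement_record(df$force_N, df$displacement_mm, length, area, mode)
}

#' Engineering stress-strain reduction of a test record
#'
#' Converts load and displacement to engineering stress and strain:
#' sigma_i = F_i / S (MPa for F in N and S in mm^2), eps_i = dL_i / L.
#'
#' @param record A [force_displacement_record()].
#' @return Object of class `stress_strain_curve` with fields `stress` (MPa),
#'   `strain` (dimensionless) and `mode`.
#' @export
compute_stress_strain <- function(record) {
  if (!inherits(record, "force_displacement_record"))
    stopf("record must be a force_displacement_record")
  structure(list(stress = record$force / record$area,
                 strain = record$displacement / record$length,
                 mode = record$mode),
            class = "stress_strain_curve")
}

#' Generate an exact bilinear stress-strain curve
#'
#' Synthetic-curve generator for validating the bilinear fit: elastic slope
#' `E` up to the yield point `sigma_y`, slope `Et` beyond. Optionally adds
#' Gaussian noise to the stresses.
#'
#' @param young_modulus Elastic slope E (MPa).
#' @param tangent_modulus Post-yield slope Et (MPa); `NULL` for a purely
#'   linear curve.
#' @param yield_stress Yield stress (MPa); `NULL` for a purely linear curve.
#' @param strain_max Final strain of the curve.
#' @param n Number of samples (uniform strain grid from 0).
#' @param noise_sd Gaussian noise standard deviation on stress, as an absolute
#'   value in MPa (0 for noiseless).
#' @return A `stress_strain_curve`.
#' @export
make_bilinear_curve <- function(young_modulus, tangent_modulus = NULL,
                                yield_stress = NULL, strain_max = 0.35,
                                n = 200L, noise_sd = 0) {
  strain <- seq(0, strain_max, length.out = n)
  if (is.null(yield_stress)) {
    stress <- young_modulus * strain
  } else {
    eps_y <- yield_stress / young_modulus
    et <- tangent_modulus %||% 0
    stress <- ifelse(strain <= eps_y,
                     young_modulus * strain,
                     yield_stress + et * (strain - eps_y))
  }
  if (noise_sd > 0) stress <- stress + stats::rnorm(n, 0, noise_sd)
  structure(list(stress = stress, strain = strain, mode = "compression"),
            class = "stress_strain_curve")
}

# Continuous two-segment piecewise-linear least squares at a fixed breakpoint.
# Basis: 1, eps, max(eps - bp, 0). Returns SSE and coefficients.
.pwl_fit <- function(strain, stress, bp) {
  x2 <- pmax(strain - bp, 0)
  X <- cbind(1, strain, x2)
  fit <- stats::lm.fit(X, stress)
  list(sse = sum(fit$residuals^2), beta = fit$coefficients)
}

#' Fit bilinear elastic-plastic parameters from a stress-strain curve
#'
#' Detects the bio-yield point as the breakpoint of a continuous two-segment
#' piecewise-linear least-squares fit (minimum-SSE breakpoint, grid over the
#' data followed by a 1-D polish). Reports the elastic slope `E`, the yield
#' stress at the breakpoint and the post-yield slope `Et`. A curve with no
#' detectable slope change (relative slope change < `linear_tol`) is reported
#' as purely linear: `Et` and `sigma_y` absent.
#'
#' @param curve A `stress_strain_curve` with monotone strain and >= 6 points.
#' @param density Material density (kg m^-3) carried into the result.
#' @param poisson_ratio Poisson's ratio carried into the result.
#' @param name Material name for the result.
#' @param smooth_window Optional odd moving-average window applied to stress
#'   before fitting (`NULL` = no smoothing, the default).
#' @param linear_tol Relative slope-change threshold below which the curve is
#'   declared purely linear (default 0.02).
#' @return A [material_params()] object; `tangent_modulus` and `yield_stress`
#'   are `NULL` for purely linear curves.
#' @export
fit_bilinear_params <- function(curve, density, poisson_ratio, name = "fitted",
                                smooth_window = NULL, linear_tol = 0.02) {
  if (!inherits(curve, "stress_strain_curve"))
    stopf("curve must be a stress_strain_curve")
  eps <- curve$strain
  sig <- curve$stress
  n <- length(eps)
  if (any(diff(eps) <= 0)) stopf("strain must be strictly increasing")
  if (n < 6L) stopf("underdetermined: need >= 6 points, got %d", n)
  if (!is.null(smooth_window)) {
    w <- as.integer(smooth_window)
    if (w %% 2L == 0L || w < 1L) stopf("smooth_window must be odd and >= 1")
    k <- rep(1 / w, w)
    pad <- (w - 1L) %/% 2L
    sig <- as.numeric(stats::filter(c(rep(sig[1], pad), sig, rep(sig[n], pad)),
                                    k, sides = 2))[(pad + 1L):(pad + n)]
  }

  # single-line fit (null model)
  X1 <- cbind(1, eps)
  lin <- stats::lm.fit(X1, sig)
  sse_lin <- sum(lin$residuals^2)
  slope_lin <- lin$coefficients[2]

  # breakpoint grid: keep >= 2 points strictly on each side
  cand <- eps[3:(n - 2)]
  sse_cand <- vapply(cand, function(bp) .pwl_fit(eps, sig, bp)$sse, 0)
  i <- which.min(sse_cand)
  lo <- cand[max(1L, i - 1L)]
  hi <- cand[min(length(cand), i + 1L)]
  bp <- if (hi > lo) {
    stats::optimize(function(b) .pwl_fit(eps, sig, b)$sse, c(lo, hi),
                    tol = .Machine$double.eps^0.5)$minimum
  } else cand[i]
  fit <- .pwl_fit(eps, sig, bp)
  beta <- fit$beta
  E <- unname(beta[2])
  Et <- unname(beta[2] + beta[3])
  sigma_y <- unname(beta[1] + beta[2] * bp)

  scale2 <- sum((sig - mean(sig))^2)
  is_linear <- (sse_lin <= 1e-18 * max(1, scale2)) ||
    (abs(beta[3]) < linear_tol * abs(E))
  if (is_linear) {
    return(material_params(name, unname(slope_lin), NULL, NULL,
                           density, poisson_ratio,
                           metadata = list(fit = list(linear = TRUE,
                                                      sse = sse_lin))))
  }
  if (E <= 0 || sigma_y <= 0)
    stopf("bilinear fit produced non-physical parameters (E=%g, sigma_y=%g)",
          E, sigma_y)
  # fracture-before-hardening curves: descending second segment => Et absent
  et_out <- if (Et < 0) NULL else Et
  material_params(name, E, et_out, sigma_y, density, poisson_ratio,
                  metadata = list(fit = list(linear = FALSE, sse = fit$sse,
                                             breakpoint_strain = bp)))
}

#' Bulk sample (mass and displaced volume)
#'
#' @param mass_g Sample mass in g, > 0.
#' @param volume_cm3 Sample volume in cm^3 (drainage method), > 0.
#' @return Object of class `bulk_sample`.
#' @export
bulk_sample <- function(mass_g, volume_cm3) {
  check_number(mass_g, "mass_g", lower = 0, strict_lower = TRUE)
  check_number(volume_cm3, "volume_cm3", lower = 0, strict_lower = TRUE)
  structure(list(mass_g = mass_g, volume_cm3 = volume_cm3),
            class = "bulk_sample")
}

#' Bulk density from mass and volume
#'
#' rho = m_a / v_a, converted from g cm^-3 to kg m^-3.
#'
#' @param sample A [bulk_sample()].
#' @return Density in kg m^-3.
#' @export
compute_density <- function(sample) {
  if (!inherits(sample, "bulk_sample")) stopf("sample must be a bulk_sample")
  1000 * sample$mass_g / sample$volume_cm3
}
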