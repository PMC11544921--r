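# Computational experiments and response-surface modelling: the 3x3x3
# scenario sweep, mesh sensitivity study, rebound analysis, quadratic
# response-surface fits of bruise susceptibility per surface material, and
# the published prediction polynomials.

#' Published response-surface coefficients
#'
#' Quadratic bruise-susceptibility prediction polynomials per contact surface
#' material, basis (1, X, Y, XY, X^2, Y^2) with X the drop height in m and Y
#' the collision angle in degrees; response in mm^3 J^-1.
#'
#' @return Named list (steel, pvc, neoprene) of numeric(6) coefficient
#'   vectors `b0, bX, bY, bXY, bX2, bY2`.
#' @export
printed_rsm_coefficients <- function() {
  list(
    steel    = c(b0 = 1419.5306, bX = 4039.4034, bY = 0.2218,
                 bXY = -4.4657, bX2 = 956.2515, bY2 = 0.0843),
    pvc      = c(b0 = 1021.1223, bX = 4839.5683, bY = 2.5997,
                 bXY = -2.1677, bX2 = 42.4485, bY2 = 0.0132),
    neoprene = c(b0 = -404.2321, bX = 8672.6431, bY = 0.3499,
                 bXY = -0.5917, bX2 = -3093.3563, bY2 = 0.0076))
}

quad_basis <- function(X, Y) cbind(1, X, Y, X * Y, X^2, Y^2)

#' Evaluate a published prediction polynomial
#'
#' Pure evaluation of the published quadratic bruise-susceptibility model for
#' the given surface material at drop height `X` (m) and collision angle `Y`
#' (degrees); no refitting.
#'
#' @param material `"steel"`, `"pvc"` or `"neoprene"` (case-insensitive).
#' @param X Drop height in m.
#' @param Y Collision angle in degrees.
#' @return Predicted bruise susceptibility in mm^3 J^-1 (vectorised over
#'   `X`, `Y`).
#' @export
evaluate_printed_model <- function(material, X, Y) {
  key <- tolower(material)
  coefs <- printed_rsm_coefficients()
  if (!key %in% names(coefs))
    stopf("unknown surface material '%s' (have: %s)", material,
          paste(names(coefs), collapse = ", "))
  drop(quad_basis(X, Y) %*% coefs[[key]])
}

#' Fit a quadratic response surface
#'
#' Ordinary least squares of the response on the basis
#' (1, X, Y, XY, X^2, Y^2) in raw factor units. Coefficient p-values come
#' from OLS t-statistics; with a 3x3 factorial and 6 parameters there are
#' only 3 residual degrees of freedom, so significance calls are low-powered
#' and reported as such. Standardised effects (|coefficient| * factor SD,
#' linear terms) support the height-vs-angle dominance comparison.
#'
#' @param data Data frame with columns `height_m`, `angle_deg` and the
#'   response column named by `response`.
#' @param response Name of the response column (default
#'   `"bs_mm3_per_J"`).
#' @param material Label carried into the model object.
#' @return Object of class `response_surface_model` with `coefficients`
#'   (b0, bX, bY, bXY, bX2, bY2), `r_squared`, `p_values`,
#'   `standardized_effects` (height, angle) and `source = "fitted"`.
#' @export
fit_quadratic_surface <- function(data, response = "bs_mm3_per_J",
                                  material = "unknown") {
  X <- data$height_m
  Y <- data$angle_deg
  y <- data[[response]]
  if (length(unique(paste(X, Y))) < 6)
    stopf("need >= 6 distinct (height, angle) points, got %d",
          length(unique(paste(X, Y))))
  B <- quad_basis(X, Y)
  qrB <- qr(B)
  if (qrB$rank < 6) {
    terms <- c("b0", "bX", "bY", "bXY", "bX2", "bY2")
    stopf("rank-deficient quadratic design (rank %d); confounded terms: %s",
          qrB$rank, paste(terms[-qrB$pivot[seq_len(qrB$rank)]], collapse = ", "))
  }
  beta <- qr.coef(qrB, y)
  fitted <- drop(B %*% beta)
  rss <- sum((y - fitted)^2)
  tss <- sum((y - mean(y))^2)
  r2 <- if (tss > 0) 1 - rss / tss else 1
  df <- length(y) - 6L
  pvals <- rep(NA_real_, 6)
  if (df > 0) {
    sigma2 <- rss / df
    XtXinv <- chol2inv(qr.R(qrB))
    se <- sqrt(pmax(diag(XtXinv) * sigma2, 0))
    tstat <- ifelse(se > 0, beta / se, Inf)
    pvals <- 2 * stats::pt(-abs(tstat), df)
  }
  names(beta) <- names(pvals) <- c("b0", "bX", "bY", "bXY", "bX2", "bY2")
  std_eff <- c(height = abs(beta[["bX"]]) * stats::sd(unique(X)),
               angle = abs(beta[["bY"]]) * stats::sd(unique(Y)))
  structure(list(material = material, coefficients = beta,
                 r_squared = r2, p_values = pvals, residual_df = df,
                 standardized_effects = std_eff, source = "fitted"),
            class = "response_surface_model")
}

#' Predict from a response-surface model
#' @param object A `response_surface_model`.
#' @param X Drop height (m).
#' @param Y Collision angle (deg).
#' @param ... Unused.
#' @export
predict.response_surface_model <- function(object, X, Y, ...) {
  drop(quad_basis(X, Y) %*% object$coefficients)
}

#' @export
print.response_surface_model <- function(x, ...) {
  cat(sprintf("<response_surface_model> %s (%s)\n", x$material, x$source))
  print(round(x$coefficients, 4))
  cat(sprintf("  R^2 = %.4f (df = %d)\n", x$r_squared, x$residual_df))
  invisible(x)
}

#' Extremum of a quadratic response surface on the factor box
#'
#' Closed-form stationary point of the quadratic, clipped against the box
#' [0.25, 1] m x [0, 90] deg, compared with a dense grid + polish over the
#' box edges and corners.
#'
#' @param coefficients Numeric(6) `(b0, bX, bY, bXY, bX2, bY2)`.
#' @param lower,upper Factor box bounds `(height, angle)`.
#' @param maximum Search for the maximum (default) or minimum.
#' @return List with `X`, `Y`, `value`.
#' @export
rsm_extremum <- function(coefficients, lower = c(0.25, 0), upper = c(1, 90),
                         maximum = TRUE) {
  b <- unname(coefficients)
  f <- function(X, Y) drop(quad_basis(X, Y) %*% b)
  # candidates: dense grid + unconstrained stationary point + corners
  Xs <- seq(lower[1], upper[1], length.out = 121)
  Ys <- seq(lower[2], upper[2], length.out = 121)
  grid <- expand.grid(X = Xs, Y = Ys)
  vals <- f(grid$X, grid$Y)
  A <- matrix(c(2 * b[5], b[4], b[4], 2 * b[6]), 2)
  if (abs(det(A)) > 1e-12) {
    st <- solve(A, -c(b[2], b[3]))
    if (all(st >= lower & st <= upper)) {
      grid <- rbind(grid, data.frame(X = st[1], Y = st[2]))
      vals <- c(vals, f(st[1], st[2]))
    }
  }
  i <- if (maximum) which.max(vals) else which.min(vals)
  list(X = grid$X[i], Y = grid$Y[i], value = vals[i])
}

#' Rebound metrics of a simulation
#'
#' Separation is the first time after peak contact at which the total contact
#' force returns to zero; the rebound speed is the maximum upward
#' centre-of-mass velocity after separation. Restitution e = v_rebound / v0;
#' rebound height = v_r^2 / (2 g).
#'
#' @param result A `simulation_result`.
#' @return Object of class `rebound_metrics`: `impact_speed`,
#'   `rebound_speed` (m/s), `restitution`, `rebound_height` (m), `separated`
#'   (logical; `FALSE` flags an incomplete event).
#' @export
rebound_metrics <- function(result) {
  stopifnot(inherits(result, "simulation_result"))
  fc <- result$contact_force
  v0 <- result$scenario$v0
  g <- result$scenario$gravity
  peak <- which.max(fc)
  sep <- which(fc[peak:length(fc)] <= 0)
  separated <- length(fc) > 0 && max(fc) > 0 && length(sep) > 0
  vr <- if (separated) {
    i0 <- peak + sep[1] - 1L
    max(c(0, result$com_velocity[i0:length(fc)]))
  } else 0
  e <- if (v0 > 0) vr / v0 else 0
  structure(list(impact_speed = v0, rebound_speed = vr, restitution = e,
                 rebound_height = vr^2 / (2 * g), separated = separated),
            class = "rebound_metrics")
}

#' Run the factorial scenario sweep
#'
#' Full factorial over drop heights, collision angles and surface materials
#' (default 3 x 3 x 3 = 27 scenarios). Each cell runs the explicit drop
#' simulation on the shared fruit mesh and is reduced to its damage report,
#' peak contact force, peak flesh Von Mises stress and rebound metrics. Cells
#' are cached as RDS files when `cache_dir` is given (resumable); a cell
#' whose integration goes unstable is marked failed and the sweep continues.
#'
#' @param heights Drop heights in m (default 0.25, 0.5, 1).
#' @param angles Collision angles in degrees (default 0, 45, 90).
#' @param surfaces Surface material names (default steel, pvc, neoprene).
#' @param element_size Mesh element size in mm for all runs.
#' @param geometry A [fruit_geometry()].
#' @param materials Region materials, defaults to the built-in library.
#' @param thresholds A [damage_thresholds()].
#' @param config A [solver_config()].
#' @param seed Mesh-generation seed.
#' @param cache_dir Optional directory for per-cell RDS caching.
#' @param verbose Print per-cell progress.
#' @return Object of class `scenario_grid`: tidy data frame `cells` (one row
#'   per scenario) plus the mesh and run metadata.
#' @export
run_scenario_grid <- function(heights = c(0.25, 0.5, 1),
                              angles = c(0, 45, 90),
                              surfaces = c("steel", "pvc", "neoprene"),
                              element_size = 3,
                              geometry = fruit_geometry(),
                              materials = default_materials(),
                              thresholds = damage_thresholds(),
                              config = solver_config(),
                              seed = 1L, cache_dir = NULL, verbose = FALSE) {
  mesh <- generate_mesh(geometry, element_size, seed = seed)
  design <- expand.grid(height_m = heights, angle_deg = angles,
                        surface = surfaces, stringsAsFactors = FALSE)
  rows <- vector("list", nrow(design))
  for (i in seq_len(nrow(design))) {
    d <- design[i, ]
    tag <- sprintf("cell_%s_h%g_a%g_s%g", d$surface, d$height_m, d$angle_deg,
                   element_size)
    cache <- if (!is.null(cache_dir)) file.path(cache_dir, paste0(tag, ".rds"))
    if (!is.null(cache) && file.exists(cache)) {
      rows[[i]] <- readRDS(cache)
      next
    }
    if (verbose) message(sprintf("[%2d/%d] %s h=%g m angle=%g", i,
                                 nrow(design), d$surface, d$height_m,
                                 d$angle_deg))
    row <- tryCatch({
      sc <- drop_scenario(d$height_m, d$angle_deg, d$surface,
                          element_size = element_size)
      res <- run_drop_simulation(mesh, materials, sc, config)
      rep_ <- damage_report(res, thresholds)
      rb <- rebound_metrics(res)
      data.frame(d, failed = FALSE,
                 vb_mm3 = rep_$bruise_volume,
                 skin_area_mm2 = rep_$bruised_skin_area,
                 et_J = rep_$absorbed_energy,
                 bs_mm3_per_J = rep_$bruise_susceptibility,
                 peak_force_N = max(res$contact_force),
                 peak_vm_flesh_MPa = max(res$tet_peak_vm[res$region == "flesh"]),
                 peak_vm_skin_MPa = if (length(res$skin_peak_vm))
                   max(res$skin_peak_vm) else NA_real_,
                 restitution = rb$restitution,
                 rebound_height_m = rb$rebound_height,
                 stringsAsFactors = FALSE)
    }, error = function(e) {
      data.frame(d, failed = TRUE, vb_mm3 = NA_real_,
                 skin_area_mm2 = NA_real_, et_J = NA_real_,
                 bs_mm3_per_J = NA_real_, peak_force_N = NA_real_,
                 peak_vm_flesh_MPa = NA_real_, peak_vm_skin_MPa = NA_real_,
                 restitution = NA_real_, rebound_height_m = NA_real_,
                 stringsAsFactors = FALSE)
    })
    if (!is.null(cache)) {
      dir.create(dirname(cache), showWarnings = FALSE, recursive = TRUE)
      saveRDS(row, cache)
    }
    rows[[i]] <- row
  }
  structure(list(cells = do.call(rbind, rows), element_size = element_size,
                 geometry = geometry, seed = seed),
            class = "scenario_grid")
}

#' @export
print.scenario_grid <- function(x, ...) {
  cat(sprintf("<scenario_grid> %d cells (%d failed), element size %g mm\n",
              nrow(x$cells), sum(x$cells$failed), x$element_size))
  invisible(x)
}

#' Fit per-surface response-surface models from a scenario grid
#'
#' @param grid A `scenario_grid`.
#' @param response Response column of the cells table.
#' @return Named list of `response_surface_model`, one per surface material.
#' @export
fit_grid_models <- function(grid, response = "bs_mm3_per_J") {
  cells <- grid$cells[!grid$cells$failed, ]
  out <- lapply(split(cells, cells$surface), function(d)
    fit_quadratic_surface(d, response = response, material = d$surface[1]))
  out[unique(cells$surface)]
}

#' Mesh sensitivity study
#'
#' Runs the reference scenario (steel surface, 0.5 m, 0 degrees by default)
#' at each element size and reports element count and peak flesh equivalent
#' stress, plus the coarsest size whose peak stress is within `tol` of the
#' finest size's value.
#'
#' @param sizes Element sizes in mm (default 1:5 as in the mesh table; pass a
#'   subset for quick studies).
#' @param scenario A [drop_scenario()] (element size taken from `sizes`).
#' @param geometry A [fruit_geometry()] or `NULL` to study the sphere
#'   fixture.
#' @param materials Region materials.
#' @param config Solver configuration.
#' @param tol Relative agreement tolerance with the finest mesh (default
#'   0.05).
#' @param seed Mesh seed.
#' @return List with `table` (data frame: element_size_mm, n_elements,
#'   n_nodes, peak_vm_MPa) and `converged_size` (coarsest within tolerance).
#' @export
mesh_sensitivity_study <- function(sizes = 1:5,
                                   scenario = drop_scenario(0.5, 0, "steel"),
                                   geometry = fruit_geometry(),
                                   materials = default_materials(),
                                   config = solver_config(),
                                   tol = 0.05, seed = 1L) {
  if (any(sizes < 0.5 | sizes > 10)) stopf("sizes must lie in [0.5, 10] mm")
  sizes <- sort(sizes, decreasing = TRUE)  # coarse to fine
  rows <- lapply(sizes, function(s) {
    mesh <- generate_mesh(geometry, s, seed = seed)
    res <- run_drop_simulation(mesh, materials, scenario, config)
    data.frame(element_size_mm = s, n_elements = nrow(mesh$tets),
               n_nodes = nrow(mesh$nodes),
               peak_vm_MPa = max(res$tet_peak_vm[res$region == "flesh"]),
               peak_force_N = max(res$contact_force))
  })
  tab <- do.call(rbind, rows)
  ref <- tab$peak_vm_MPa[nrow(tab)]  # finest
  ok <- abs(tab$peak_vm_MPa - ref) <= tol * abs(ref)
  converged <- if (any(ok)) max(tab$element_size_mm[ok]) else min(sizes)
  monotone <- all(diff(tab$peak_vm_MPa) >= 0) || all(diff(tab$peak_vm_MPa) <= 0)
  list(table = tab[order(tab$element_size_mm), ],
       converged_size = converged, monotone_convergence = monotone)
}
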