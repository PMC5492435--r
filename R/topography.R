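#' Clinical corneal topography analytics
#'
#' Sagittal (axial) curvature, zone keratometry, astigmatism, best-fit-sphere
#' elevation, pachymetry and anterior-corneal wavefront aberrations, computed
#' from Zernike surface representations.
#'
#' Sagittal curvature uses the keratometric convention
#' \eqn{C_S = (n - 1)/R} with \eqn{n = 1.3375} and \eqn{R} the distance (mm,
#' converted to m) from the surface point to the central axis measured along
#' the surface normal.
#'
#' @name topography
NULL

#' @export
KERATOMETRIC_INDEX <- 1.3375

#' Polar analysis grid used by the map analytics
#' @inheritParams polar_grid
#' @export
analysis_grid <- function(diameter = 9, nr = 90, na = 180) {
  polar_grid(diameter = diameter, nr = nr, na = na)
}

#' Sagittal curvature map
#'
#' Per-node axial radius \eqn{R = \rho \sqrt{1+|\nabla z|^2} / \partial_\rho z}
#' (the distance along the surface normal from the point to the central axis),
#' converted to diopters with the keratometric index. Nodes whose normal is
#' (numerically) parallel to the axis get curvature 0 and are flagged.
#'
#' @param surface a `zernike_surface` (anterior corneal surface, sag
#'   convention) or an `elevation_pair` (its anterior surface is used).
#' @param grid polar analysis grid; defaults to a 9-mm, 1-degree grid covering
#'   the clinical zones.
#' @return a `curvature_map`: `values` (D, nr x na), `grid`, `R_mm`, `flags`.
#' @export
sagittal_curvature <- function(surface, grid = NULL) {
  if (inherits(surface, "elevation_pair")) {
    surface <- fit_zernike_pair(surface)$anterior
  }
  stopifnot(inherits(surface, "zernike_surface"))
  if (is.null(grid)) {
    grid <- analysis_grid(diameter = min(9, surface$zone_diameter))
  }
  xy <- grid_xy(grid)
  ev <- eval_zernike(surface, as.vector(xy$x), as.vector(xy$y), deriv = TRUE)
  zx <- matrix(ev$zx, grid$nr, grid$na)
  zy <- matrix(ev$zy, grid$nr, grid$na)
  ct <- matrix(cos(grid$theta), grid$nr, grid$na, byrow = TRUE)
  st <- matrix(sin(grid$theta), grid$nr, grid$na, byrow = TRUE)
  zr <- zx * ct + zy * st                       # radial slope
  rho <- matrix(grid$r, grid$nr, grid$na)
  Nn <- sqrt(1 + zx^2 + zy^2)
  flat <- abs(zr) < 1e-9
  R_mm <- ifelse(flat, Inf, rho * Nn / zr)
  values <- ifelse(flat, 0, (KERATOMETRIC_INDEX - 1) / (R_mm / 1000))
  structure(list(values = values, R_mm = R_mm, grid = grid, flags = flat,
                 n_keratometric = KERATOMETRIC_INDEX),
            class = "curvature_map")
}

#' @export
print.curvature_map <- function(x, ...) {
  v <- x$values[is.finite(x$values) & !x$flags]
  cat(sprintf("Sagittal curvature map (%d x %d): %.2f-%.2f D, mean %.2f D\n",
              x$grid$nr, x$grid$na, min(v), max(v), mean(v)))
  invisible(x)
}

region_weights <- function(map, r_min, r_max) {
  stopifnot(inherits(map, "curvature_map"))
  if (r_max > max(map$grid$r) + map$grid$dr / 2) {
    stop(sprintf("region extends to %.2f mm but map covers only %.2f mm",
                 r_max, max(map$grid$r) + map$grid$dr / 2))
  }
  w <- grid_cell_area(map$grid)
  sel <- map$grid$r >= r_min & map$grid$r <= r_max
  if (!any(sel)) stop("empty region")
  w[!sel, ] <- 0
  w
}

#' Area-weighted mean curvature over a disk or annulus
#'
#' Clinical zone keratometry: `region = c(0, 2)` is the central 2.0-mm-radius
#' disk, `c(2, 3.5)` the paracentral annulus.
#'
#' @param map a `curvature_map`.
#' @param region `c(r_min, r_max)` in mm (a disk when `r_min = 0`).
#' @return mean power, D.
#' @export
zone_mean_curvature <- function(map, region) {
  stopifnot(length(region) == 2, region[2] > region[1])
  w <- region_weights(map, region[1], region[2])
  sum(w * map$values) / sum(w)
}

#' Keratometric astigmatism from a curvature map
#'
#' Meridional powers are computed by area-weighted averaging over the annulus
#' in each meridian bin (opposite semi-meridians combined), then fitted with a
#' sinusoid \eqn{c_0 + c_2\cos 2\phi + s_2\sin 2\phi}; cylinder = steep - flat
#' = twice the fitted amplitude, axis = the steep meridian. This reduces to
#' the exact steep/flat difference on toric surfaces and is robust to noise.
#'
#' @param map a `curvature_map`.
#' @param annulus `c(r_min, r_max)` mm; clinical default 0.5-2.5 mm radius
#'   (a 0.5-2.0-mm annulus is the common alternative convention).
#' @return an `astigmatism_result`: `cylinder` (D, >= 0), `axis_deg` in
#'   [0, 180), `steep`, `flat` (D), `zero_cylinder` flag.
#' @export
astigmatism <- function(map, annulus = c(0.5, 2.5)) {
  w <- region_weights(map, annulus[1], annulus[2])
  na <- map$grid$na
  if (na %% 2 != 0) stop("astigmatism needs an even angular sample count")
  half <- na / 2
  # meridional power: combine theta and theta + pi
  wm <- w[, 1:half] + w[, half + 1:half]
  pm <- (w[, 1:half] * map$values[, 1:half] +
           w[, half + 1:half] * map$values[, half + 1:half])
  M <- colSums(pm) / colSums(wm)
  phi <- map$grid$theta[1:half]
  X <- cbind(1, cos(2 * phi), sin(2 * phi))
  cf <- stats::lm.fit(X, M)$coefficients
  amp <- sqrt(cf[2]^2 + cf[3]^2)
  cylinder <- 2 * amp
  zero <- cylinder < 1e-4
  axis <- if (zero) 0 else (atan2(cf[3], cf[2]) / 2) %% pi
  structure(list(cylinder = as.numeric(cylinder),
                 axis_deg = as.numeric(axis * 180 / pi),
                 steep = as.numeric(cf[1] + amp), flat = as.numeric(cf[1] - amp),
                 mean_power = as.numeric(cf[1]),
                 zero_cylinder = zero, annulus = annulus),
            class = "astigmatism_result")
}

#' @export
print.astigmatism_result <- function(x, ...) {
  cat(sprintf("Astigmatism: %.2f D @ %.1f deg (steep %.2f / flat %.2f D, annulus %.1f-%.1f mm)\n",
              x$cylinder, x$axis_deg, x$steep, x$flat, x$annulus[1], x$annulus[2]))
  invisible(x)
}

#' Best-fit sphere and elevation map
#'
#' Fits the apex-anchored sphere (center on the optical axis at (0,0,R),
#' radius free: a one-parameter, unconditionally stable fit) to the surface
#' over the central zone, by least squares on the radial distance residual.
#' Elevation is the signed normal distance surface - sphere, positive when
#' the surface lies anterior to the reference.
#'
#' @param surface a `zernike_surface`.
#' @param zone_diameter fit zone, mm (clinical default 8.0).
#' @param grid optional polar sampling grid for the fit/map.
#' @return list: `radius_mm`, `elevation_um` (nr x na), `grid`, `rms_um`.
#' @export
best_fit_sphere <- function(surface, zone_diameter = 8, grid = NULL) {
  stopifnot(inherits(surface, "zernike_surface"))
  if (is.null(grid)) grid <- polar_grid(diameter = zone_diameter, nr = 64, na = 96)
  if (max(grid$r) > zone_diameter / 2 + 1e-9) {
    grid <- polar_grid(diameter = zone_diameter, nr = grid$nr, na = grid$na)
  }
  xy <- grid_xy(grid)
  z <- matrix(eval_zernike(surface, as.vector(xy$x), as.vector(xy$y)),
              grid$nr, grid$na)
  rho2 <- matrix(grid$r^2, grid$nr, grid$na)
  dist_to_center <- function(R) sqrt(rho2 + (z - R)^2)
  obj <- function(R) sum((dist_to_center(R) - R)^2)
  # apical curvature seed from the innermost ring
  R0 <- mean((grid$r[2]^2 + z[2, ]^2) / (2 * pmax(z[2, ], 1e-9)))
  if (!is.finite(R0) || R0 < 3 || R0 > 30) R0 <- 7.8
  opt <- stats::optimize(obj, interval = c(max(2, R0 / 3), min(40, R0 * 3)))
  R <- opt$minimum
  elev <- (dist_to_center(R) - R) * 1000
  if (!is.finite(R) || R <= 0) stop("degenerate best-fit sphere")
  list(radius_mm = R, elevation_um = elev, grid = grid,
       rms_um = sqrt(mean(elev^2)))
}

#' Fit both surfaces of an elevation pair
#'
#' @param pair an `elevation_pair`.
#' @param order Zernike order.
#' @param zone_diameter fit zone, mm.
#' @return list with `anterior`, `posterior` `zernike_surface` objects.
#' @export
fit_zernike_pair <- function(pair, order = 12, zone_diameter = 8) {
  stopifnot(inherits(pair, "elevation_pair"))
  xy <- grid_xy(pair$grid)
  list(anterior = fit_zernike(as.vector(xy$x), as.vector(xy$y),
                              as.vector(pair$z_ant), order, zone_diameter),
       posterior = fit_zernike(as.vector(xy$x), as.vector(xy$y),
                               as.vector(pair$z_post), order, zone_diameter))
}

#' Pachymetry map
#'
#' Corneal thickness as the distance from each anterior-surface node along the
#' anterior surface normal to the posterior surface, in micrometers. Solved by
#' a vectorized Newton iteration on the ray-surface intersection; nodes whose
#' normal fails to intersect the posterior surface within the zone are
#' flagged (NA).
#'
#' @param anterior,posterior `zernike_surface` objects (sag convention).
#' @param grid polar map grid (kept inside both fit zones).
#' @return list: `thickness_um` (nr x na), `grid`, `flags`.
#' @export
pachymetry <- function(anterior, posterior, grid = NULL) {
  stopifnot(inherits(anterior, "zernike_surface"),
            inherits(posterior, "zernike_surface"))
  if (is.null(grid)) {
    d <- 0.8 * min(anterior$zone_diameter, posterior$zone_diameter)
    grid <- polar_grid(diameter = d, nr = 48, na = 96)
  }
  xy <- grid_xy(grid)
  x <- as.vector(xy$x); y <- as.vector(xy$y)
  ea <- eval_zernike(anterior, x, y, deriv = TRUE)
  Nn <- sqrt(1 + ea$zx^2 + ea$zy^2)
  nx <- -ea$zx / Nn; ny <- -ea$zy / Nn; nz <- 1 / Nn   # posterior-pointing
  t <- eval_zernike(posterior, x, y) - ea$z             # vertical-gap seed
  ok <- rep(TRUE, length(x))
  for (it in 1:30) {
    px <- x + t * nx; py <- y + t * ny
    inside <- px^2 + py^2 <= (posterior$zone_diameter / 2)^2
    ok <- ok & inside
    ep <- eval_zernike(posterior, pmin(pmax(px, -1e3), 1e3), py, deriv = TRUE)
    g <- (ea$z + t * nz) - ep$z
    dg <- nz - (ep$zx * nx + ep$zy * ny)
    step <- g / dg
    t <- t - ifelse(ok, step, 0)
    if (max(abs(step[ok]), 0) < 1e-10) break
  }
  t[!ok] <- NA
  flags <- !ok | t <= 1e-12              # non-intersecting or degenerate gap
  structure(list(thickness_um = matrix(t * 1000, grid$nr, grid$na),
                 grid = grid, flags = matrix(flags, grid$nr, grid$na)),
            class = "pachymetry_map")
}

#' Anterior corneal wavefront aberration indices
#'
#' The anterior-surface wavefront error over a central pupil:
#' \eqn{W = (n - 1)(z_{ref} - z_{surf})} with the keratometric index and the
#' best-fit sphere over the pupil as reference, expanded in OSA Zernike terms.
#' Named indices aggregate same-order terms by root-sum-square (spherical is
#' the signed Z(4,0) coefficient); `rms_hoa` covers radial orders >= 4.
#'
#' @param surface anterior `zernike_surface`.
#' @param pupil_diameter mm (clinical default 6.0).
#' @param order expansion order for the wavefront fit.
#' @return a `wavefront_indices` list, all values in micrometers.
#' @export
wavefront_coefficients <- function(surface, pupil_diameter = 6, order = 8) {
  stopifnot(inherits(surface, "zernike_surface"))
  if (pupil_diameter > surface$zone_diameter + 1e-9) {
    stop("wavefront pupil exceeds the surface's fitted zone")
  }
  grid <- polar_grid(diameter = pupil_diameter, nr = 48, na = 96)
  bfs <- best_fit_sphere(surface, zone_diameter = pupil_diameter, grid = grid)
  xy <- grid_xy(grid)
  z <- eval_zernike(surface, as.vector(xy$x), as.vector(xy$y))
  z_ref <- bfs$radius_mm - sqrt(pmax(bfs$radius_mm^2 - grid_xy(grid)$x^2 -
                                       grid_xy(grid)$y^2, 0))
  W_um <- (KERATOMETRIC_INDEX - 1) * (as.vector(z_ref) - z) * 1000
  fit <- fit_zernike(as.vector(xy$x), as.vector(xy$y), W_um,
                     order = order, zone_diameter = pupil_diameter)
  cf <- fit$coefficients; n <- fit$n; m <- fit$m
  pick <- function(nn, mm) {
    v <- cf[n == nn & m %in% mm]
    if (length(v) == 0) 0 else v
  }
  rss <- function(v) sqrt(sum(v^2))
  structure(list(
    spherical = as.numeric(pick(4, 0)),
    astigmatic = rss(pick(2, c(-2, 2))),
    coma = rss(pick(3, c(-1, 1))),
    trefoil = rss(pick(3, c(-3, 3))),
    tetrafoil = rss(pick(4, c(-4, 4))),
    rms_hoa = rss(cf[n >= 4]),
    pupil_diameter = pupil_diameter,
    coefficients_um = cf, n = n, m = m),
    class = "wavefront_indices")
}

#' @export
print.wavefront_indices <- function(x, ...) {
  cat(sprintf(
    "Wavefront (%.1f-mm pupil, um): sph %.3f, ast %.3f, coma %.3f, trefoil %.3f, tetrafoil %.3f, RMS-HOA %.3f\n",
    x$pupil_diameter, x$spherical, x$astigmatic, x$coma, x$trefoil,
    x$tetrafoil, x$rms_hoa))
  invisible(x)
}
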