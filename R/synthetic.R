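#' Synthetic Scheimpflug-like corneal tomography
#'
#' Generates anterior/posterior corneal elevation pairs on a polar grid,
#' emulating the maps a Scheimpflug tomographer exports: smooth biconic/toric
#' anterior surfaces with configurable apical radii and asphericities, a
#' radially interpolated thickness profile for the posterior surface, optional
#' Gaussian measurement noise, and a parameterized nasal pterygium footprint.
#'
#' Conventions: corneal apex at the origin, optical axis = z, heights stored as
#' sag (z increases posteriorly, into the eye). Right-eye (OD) laterality by
#' default: the nasal 0-degree meridian points toward -x.
#'
#' @name synthetic_data
NULL

#' Specify a synthetic cornea
#'
#' Defaults target a normal prolate cornea whose central (2.0-mm radius disk)
#' mean sagittal power is about 44.15 D and paracentral (2.0-3.5 mm annulus)
#' mean about 43.28 D, with 512 um central pachymetry.
#'
#' @param Rx,Ry apical radii of curvature of the anterior surface, mm.
#' @param Qx,Qy asphericities (Q = 0 gives a sphere; Q < 0 prolate).
#' @param central_thickness,peripheral_thickness pachymetry, um; the thickness
#'   profile interpolates quadratically in radius from center to the corneal
#'   edge (smooth at the apex).
#' @param corneal_diameter mm (must cover the 8-mm analysis zone).
#' @param noise_sd measurement noise standard deviation, um (0 = noiseless).
#' @param seed integer seed driving all stochastic draws for this spec.
#' @return a `synthetic_cornea_spec` list.
#' @export
synthetic_cornea_spec <- function(Rx = 7.59, Ry = 7.59, Qx = -0.39, Qy = -0.39,
                                  central_thickness = 512,
                                  peripheral_thickness = 660,
                                  corneal_diameter = 11.5,
                                  noise_sd = 0, seed = 1L) {
  stopifnot(Rx > 0, Ry > 0, central_thickness > 0,
            peripheral_thickness >= central_thickness,
            corneal_diameter >= 8.0, noise_sd >= 0)
  structure(list(Rx = Rx, Ry = Ry, Qx = Qx, Qy = Qy,
                 central_thickness = central_thickness,
                 peripheral_thickness = peripheral_thickness,
                 corneal_diameter = corneal_diameter,
                 noise_sd = noise_sd, seed = as.integer(seed)),
            class = "synthetic_cornea_spec")
}

#' Polar sampling grid for elevation maps
#'
#' @param diameter map extent, mm (default 10, a Pentacam-like 10-mm zone).
#' @param nr,na radial and angular sample counts. Radii sit at cell centers
#'   (no pole node, no edge node).
#' @export
polar_grid <- function(diameter = 10, nr = 60, na = 96) {
  stopifnot(diameter > 0, nr >= 4, na >= 8)
  rmax <- diameter / 2
  r <- (seq_len(nr) - 0.5) * rmax / nr
  theta <- (seq_len(na) - 1) * 2 * pi / na
  structure(list(type = "polar", diameter = diameter, nr = nr, na = na,
                 r = r, theta = theta,
                 dr = rmax / nr, dtheta = 2 * pi / na),
            class = "polar_grid")
}

grid_xy <- function(grid) {
  x <- outer(grid$r, cos(grid$theta))
  y <- outer(grid$r, sin(grid$theta))
  list(x = x, y = y)
}

## cell areas of the polar grid (mm^2), nr x na
grid_cell_area <- function(grid) {
  matrix(grid$r * grid$dr * grid$dtheta, grid$nr, grid$na)
}

#' Biconic sag and slopes
#'
#' z = (x^2/Rx + y^2/Ry) / (1 + sqrt(1 - (1+Qx) x^2/Rx^2 - (1+Qy) y^2/Ry^2)),
#' with analytic first derivatives.
#' @keywords internal
biconic_sag <- function(x, y, Rx, Ry, Qx, Qy, deriv = FALSE) {
  arg <- 1 - (1 + Qx) * x^2 / Rx^2 - (1 + Qy) * y^2 / Ry^2
  if (any(arg < 0)) {
    bad <- sqrt(x^2 + y^2)[arg < 0]
    stop(sprintf(
      "biconic undefined at radius %.3f mm: square-root argument negative (Rx=%.3f, Ry=%.3f)",
      min(bad), Rx, Ry))
  }
  S <- sqrt(arg)
  num <- x^2 / Rx + y^2 / Ry
  z <- num / (1 + S)
  if (!deriv) return(z)
  Sx <- -(1 + Qx) * x / Rx^2 / S
  Sy <- -(1 + Qy) * y / Ry^2 / S
  zx <- (2 * x / Rx * (1 + S) - num * Sx) / (1 + S)^2
  zy <- (2 * y / Ry * (1 + S) - num * Sy) / (1 + S)^2
  list(z = z, zx = zx, zy = zy)
}

with_seed <- function(seed, code) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())), add = TRUE)
  }
  set.seed(seed)
  force(code)
}

#' Generate a synthetic corneal elevation pair
#'
#' The anterior surface is the biconic of the spec sampled on `grid`; the
#' posterior surface is obtained by offsetting the anterior surface along its
#' local normal by the radially interpolated thickness profile (meridian-wise;
#' the small azimuthal component of the normal is neglected for toric
#' surfaces) and resampling onto the same grid. Gaussian noise of sd
#' `noise_sd` um is then added independently to both height maps when
#' `noise_sd > 0`. Identical spec + seed gives bit-identical output.
#'
#' @param spec a [synthetic_cornea_spec()].
#' @param grid a [polar_grid()]; its extent must lie inside the biconic domain.
#' @return an `elevation_pair`: matrices `z_ant`, `z_post` (mm, nr x na),
#'   the grid, and the generating spec.
#' @export
make_synthetic_cornea <- function(spec, grid = polar_grid()) {
  stopifnot(inherits(spec, "synthetic_cornea_spec"), inherits(grid, "polar_grid"))
  xy <- grid_xy(grid)
  ant <- biconic_sag(xy$x, xy$y, spec$Rx, spec$Ry, spec$Qx, spec$Qy, deriv = TRUE)
  z_ant <- ant$z

  # thickness profile, mm: quadratic in radius from center to the corneal
  # edge (smooth at the apex -- a linear-in-radius profile has a cone
  # singularity there that neither real pachymetry nor a polynomial surface
  # expansion supports), clamped beyond the edge
  t_of_r <- function(r) {
    tc <- spec$central_thickness / 1000
    tp <- spec$peripheral_thickness / 1000
    re <- spec$corneal_diameter / 2
    tc + (tp - tc) * pmin(r / re, 1)^2
  }

  # meridian-wise normal offset, then respline onto the grid radii
  z_post <- matrix(NA_real_, grid$nr, grid$na)
  for (j in seq_len(grid$na)) {
    ct <- cos(grid$theta[j]); st <- sin(grid$theta[j])
    dzdr <- ant$zx[, j] * ct + ant$zy[, j] * st
    Nn <- sqrt(1 + ant$zx[, j]^2 + ant$zy[, j]^2)
    tt <- t_of_r(grid$r)
    r_off <- grid$r - tt * dzdr / Nn
    z_off <- z_ant[, j] + tt / Nn
    z_post[, j] <- stats::spline(r_off, z_off, xout = grid$r, method = "natural")$y
  }

  if (spec$noise_sd > 0) {
    with_seed(spec$seed, {
      s <- spec$noise_sd / 1000
      z_ant <- z_ant + matrix(stats::rnorm(length(z_ant), 0, s), grid$nr, grid$na)
      z_post <- z_post + matrix(stats::rnorm(length(z_post), 0, s), grid$nr, grid$na)
    })
  }

  if (any(z_post <= z_ant)) stop("degenerate synthetic cornea: non-positive thickness")
  structure(list(z_ant = z_ant, z_post = z_post, grid = grid, spec = spec,
                 apex_origin = TRUE),
            class = "elevation_pair")
}

#' @export
print.elevation_pair <- function(x, ...) {
  cat(sprintf("Elevation pair on %d x %d polar grid, %.1f-mm zone\n",
              x$grid$nr, x$grid$na, x$grid$diameter))
  cat(sprintf("  central anterior sag %.4f mm, central pachymetry ~%.0f um\n",
              x$z_ant[1, 1], 1000 * (x$z_post[1, 1] - x$z_ant[1, 1])))
  invisible(x)
}

#' Specify a pterygium footprint
#'
#' A limbus-anchored circular-sector wedge with a rounded (circular-arc)
#' central apex: points with planar radius between `apex_distance` and the
#' limbus, within `angular_width` of the footprint meridian.
#'
#' @param meridian_angle degrees; 0 = nasal (toward -x for a right eye).
#' @param apex_distance mm from corneal center to the footprint's most central
#'   point.
#' @param angular_width full angular width at the limbus, degrees (0, 180).
#' @param laterality `"OD"` (right eye, nasal toward -x) or `"OS"`.
#' @export
pterygium_footprint <- function(meridian_angle = 0, apex_distance = 2.0,
                                angular_width = 30, laterality = "OD") {
  if (!(angular_width > 0)) stop("angular_width must be positive")
  if (angular_width >= 180) stop("angular_width must be < 180 degrees")
  stopifnot(apex_distance > 0, laterality %in% c("OD", "OS"))
  structure(list(meridian_angle = meridian_angle, apex_distance = apex_distance,
                 angular_width = angular_width, laterality = laterality),
            class = "pterygium_footprint")
}

## direction of the footprint's central meridian in map coordinates (radians)
footprint_direction <- function(fp) {
  sgn <- if (fp$laterality == "OD") 1 else -1
  pi + sgn * fp$meridian_angle * pi / 180
}

angdiff <- function(a, b) {
  d <- (a - b) %% (2 * pi)
  ifelse(d > pi, d - 2 * pi, d)
}

#' Pterygium footprint mask on an elevation grid
#'
#' @param fp a [pterygium_footprint()].
#' @param pair an `elevation_pair` (or a `polar_grid`).
#' @param limbus_radius mm; defaults to the generating spec's corneal radius,
#'   clamped to the grid extent.
#' @return list with logical `mask` (nr x na), planar `area_mm2`, and the
#'   analytic sector area for reference.
#' @export
footprint_mask <- function(fp, pair, limbus_radius = NULL) {
  stopifnot(inherits(fp, "pterygium_footprint"))
  grid <- if (inherits(pair, "polar_grid")) pair else pair$grid
  if (is.null(limbus_radius)) {
    limbus_radius <- if (!inherits(pair, "polar_grid") && !is.null(pair$spec)) {
      min(pair$spec$corneal_diameter / 2, grid$diameter / 2)
    } else grid$diameter / 2
  }
  if (fp$apex_distance >= limbus_radius) {
    stop("footprint apex_distance must be inside the limbus radius")
  }
  if (limbus_radius > max(grid$r) + grid$dr / 2 + 1e-9) {
    stop(sprintf("grid extent (%.2f mm) does not cover the limbus radius (%.2f mm)",
                 max(grid$r) + grid$dr / 2, limbus_radius))
  }
  dir <- footprint_direction(fp)
  half <- fp$angular_width / 2 * pi / 180
  inr <- grid$r >= fp$apex_distance & grid$r <= limbus_radius
  inth <- abs(angdiff(grid$theta, dir)) <= half
  mask <- outer(inr, inth) > 0
  if (!any(mask)) {
    stop("pterygium footprint does not intersect the grid (empty mask)")
  }
  area <- sum(grid_cell_area(grid)[mask])
  analytic <- fp$angular_width / 360 * pi * (limbus_radius^2 - fp$apex_distance^2)
  list(mask = mask, area_mm2 = area, analytic_area_mm2 = analytic,
       limbus_radius = limbus_radius)
}

#' Cartesian export of an elevation pair
#'
#' @param pair an `elevation_pair`.
#' @return data.frame with columns `x_mm`, `y_mm`, `z_anterior_mm`,
#'   `z_posterior_mm`, one row per grid node.
#' @export
elevation_as_cartesian <- function(pair) {
  stopifnot(inherits(pair, "elevation_pair"))
  xy <- grid_xy(pair$grid)
  data.frame(x_mm = as.vector(xy$x), y_mm = as.vector(xy$y),
             z_anterior_mm = as.vector(pair$z_ant),
             z_posterior_mm = as.vector(pair$z_post))
}

#' Build an elevation pair by sampling Zernike surfaces
#'
#' Evaluates fitted anterior/posterior surfaces on a polar grid, e.g. to turn
#' a simulated postoperative shape into tomography-like follow-up data.
#'
#' @param anterior,posterior `zernike_surface` objects.
#' @param grid a [polar_grid()] inside both zones.
#' @export
elevation_pair_from_surfaces <- function(anterior, posterior,
                                         grid = polar_grid(diameter = 8)) {
  xy <- grid_xy(grid)
  za <- matrix(eval_zernike(anterior, as.vector(xy$x), as.vector(xy$y)),
               grid$nr, grid$na)
  zp <- matrix(eval_zernike(posterior, as.vector(xy$x), as.vector(xy$y)),
               grid$nr, grid$na)
  structure(list(z_ant = za, z_post = zp, grid = grid, spec = NULL,
                 apex_origin = TRUE),
            class = "elevation_pair")
}
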