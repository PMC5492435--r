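#' Corneal finite-element mesh
#'
#' Builds a spherical-cap template mesh of the cornea plus a 4-mm scleral rim
#' from 8-node hexahedra, layered through the thickness. The cross-section is
#' an O-grid (a central structured square block blended into concentric
#' rings), which avoids the polar-axis degeneracy of a naive spherical mesh.
#' The template is later warped so that its anterior and posterior boundary
#' nodes lie on patient-specific Zernike surfaces, with interior nodes
#' following by linear through-thickness interpolation.
#'
#' @name geometry
NULL

## --- O-grid cross-section layout in a unit parameter disk --------------------
## Returns parameter coordinates (tau = radial fraction in [0,1], phi) for all
## cross-section nodes plus quad connectivity. Rings at tau >= t0 are exact
## circles, so the limbus ring and rim annulus are circular.
ogrid_section <- function(m, n_circ_cornea, n_circ_rim, t_limbus, t0 = 0.35,
                          n_trans = NULL) {
  stopifnot(m >= 2, n_circ_cornea >= 2, n_circ_rim >= 2, t_limbus > t0)
  if (is.null(n_trans)) n_trans <- max(2, round(m / 2))
  a <- 0.5 * t0
  nper <- 4 * m

  # core block nodes (m+1)^2
  u <- seq(-a, a, length.out = m + 1)
  core <- expand.grid(u = u, v = u)
  core_id <- matrix(seq_len((m + 1)^2), m + 1, m + 1)  # [i_u, i_v]

  # perimeter of the core, counterclockwise from corner (-a,-a)
  per_iu <- c(1:(m + 1), rep(m + 1, m - 1), (m + 1):1, rep(1, m - 1))
  per_iv <- c(rep(1, m + 1), 2:m, rep(m + 1, m + 1), m:2)
  stopifnot(length(per_iu) == nper)
  per_ids <- core_id[cbind(per_iu, per_iv)]
  pu <- core$u[per_ids]; pv <- core$v[per_ids]
  phi_sq <- atan2(pv, pu)
  phi_sq <- phi_sq - phi_sq[1]           # unwrap from the starting corner
  phi_sq <- phi_sq %% (2 * pi)
  phi_sq[1] <- 0
  phi_sq <- cummax(phi_sq)               # enforce monotone perimeter angles
  phi0 <- atan2(-a, -a)
  phi_unif <- 2 * pi * (seq_len(nper) - 1) / nper

  nodes_u <- core$u; nodes_v <- core$v
  ring_ids <- list(); ring_ids[[1]] <- per_ids

  # transition rings: square boundary -> circle at t0
  for (j in seq_len(n_trans)) {
    s <- j / n_trans
    rad <- (1 - s) * sqrt(pu^2 + pv^2) + s * t0
    ph <- (1 - s) * phi_sq + s * phi_unif
    nodes_u <- c(nodes_u, rad * cos(phi0 + ph))
    nodes_v <- c(nodes_v, rad * sin(phi0 + ph))
    ring_ids[[j + 1]] <- length(nodes_u) - nper + seq_len(nper)
  }

  # circular rings: t0 -> t_limbus -> 1
  tau_rings <- c(seq(t0, t_limbus, length.out = n_circ_cornea + 1)[-1],
                 seq(t_limbus, 1, length.out = n_circ_rim + 1)[-1])
  for (tr in tau_rings) {
    nodes_u <- c(nodes_u, tr * cos(phi0 + phi_unif))
    nodes_v <- c(nodes_v, tr * sin(phi0 + phi_unif))
    ring_ids[[length(ring_ids) + 1]] <- length(nodes_u) - nper + seq_len(nper)
  }

  # quad connectivity: core block
  quads <- matrix(0L, 0, 4)
  for (i in 1:m) for (j in 1:m) {
    quads <- rbind(quads, c(core_id[i, j], core_id[i + 1, j],
                            core_id[i + 1, j + 1], core_id[i, j + 1]))
  }
  # ring quads
  for (rg in seq_len(length(ring_ids) - 1)) {
    inner <- ring_ids[[rg]]; outer <- ring_ids[[rg + 1]]
    k2 <- c(seq_len(nper)[-1], 1)
    quads <- rbind(quads, cbind(inner, outer, outer[k2], inner[k2]))
  }

  tau <- sqrt(nodes_u^2 + nodes_v^2)
  phi <- atan2(nodes_v, nodes_u)
  n_rings_limbus <- 1 + n_trans + n_circ_cornea      # index into ring_ids
  list(u = nodes_u, v = nodes_v, tau = tau, phi = phi, quads = quads,
       limbus_ring = ring_ids[[n_rings_limbus]],
       outer_ring = ring_ids[[length(ring_ids)]],
       nper = nper)
}

#' Build the spherical template mesh (cornea + scleral rim)
#'
#' @param radial_res number of circular element rings from the O-grid core to
#'   the outer rim edge (split between cornea and rim in proportion to arc
#'   length; at least 2 rings in the rim).
#' @param circumferential_res number of circumferential element divisions
#'   (rounded to a multiple of 4, minimum 8).
#' @param n_layers through-thickness element layers (>= 2; the depth-dependent
#'   fiber distribution needs at least two).
#' @param corneal_diameter mm; the limbus ring sits at this diameter.
#' @param rim_width scleral rim width along the surface, mm (default 4).
#' @param template_radius anterior radius of the spherical template, mm.
#' @param corneal_thickness uniform template corneal thickness, mm.
#' @param scleral_thickness rim thickness at the outer edge, mm (linear ramp
#'   from the corneal thickness across the rim).
#' @return a `cornea_mesh`: `nodes` (N x 3, mm, apex at origin, sag +z),
#'   hex connectivity `hex` (ne x 8), face sets, node sets, layer and region
#'   tags, and the column parameterization used for warping.
#' @export
build_template_mesh <- function(radial_res = 20, circumferential_res = 32,
                                n_layers = 4, corneal_diameter = 9,
                                rim_width = 4, template_radius = 7.5,
                                corneal_thickness = 0.55,
                                scleral_thickness = 0.75) {
  if (n_layers < 2) stop("n_layers must be >= 2 (depth-dependent fiber weighting)")
  if (circumferential_res < 8) stop("circumferential_res must be >= 8")
  if (radial_res < 4) stop("radial_res must be >= 4")
  m <- max(2L, as.integer(round(circumferential_res / 4)))
  R <- template_radius
  r_c <- corneal_diameter / 2
  if (r_c >= R) stop("corneal radius must be smaller than the template radius")
  a_cornea <- asin(r_c / R)
  a_max <- a_cornea + rim_width / R
  if (a_max >= pi / 2 * 0.98) stop("rim extends too far around the template sphere")
  t_limbus <- a_cornea / a_max

  t0 <- 0.35
  n_rim <- max(2L, round(radial_res * (1 - t_limbus) / (1 - t0)))
  n_cor <- max(2L, radial_res - n_rim)
  sec <- ogrid_section(m, n_cor, n_rim, t_limbus, t0 = t0)

  ns <- length(sec$tau)                 # nodes per cross-section
  alpha <- sec$tau * a_max
  thick <- rim_thickness(alpha, a_cornea, a_max, corneal_thickness,
                         scleral_thickness)
  # anterior anchors on the sphere (sag convention: z = R (1 - cos alpha))
  ax <- R * sin(alpha) * cos(sec$phi)
  ay <- R * sin(alpha) * sin(sec$phi)
  az <- R * (1 - cos(alpha))
  # inward (posterior-pointing) unit normal of the sphere
  nx <- -sin(alpha) * cos(sec$phi)
  ny <- -sin(alpha) * sin(sec$phi)
  nz <- cos(alpha)
  px <- ax + thick * nx; py <- ay + thick * ny; pz <- az + thick * nz

  nl <- n_layers
  zeta <- (0:nl) / nl                   # 0 = posterior, 1 = anterior
  nodes <- matrix(0, ns * (nl + 1), 3)
  for (l in 0:nl) {
    idx <- l * ns + seq_len(ns)
    w <- zeta[l + 1]
    nodes[idx, 1] <- px + w * (ax - px)
    nodes[idx, 2] <- py + w * (ay - py)
    nodes[idx, 3] <- pz + w * (az - pz)
  }

  # layer stacking runs posterior -> anterior (decreasing z at the apex), so
  # reverse the in-plane winding to keep the hexahedra right-handed
  sec$quads <- sec$quads[, c(1, 4, 3, 2)]
  nq <- nrow(sec$quads)
  hex <- matrix(0L, nq * nl, 8)
  elem_layer <- integer(nq * nl)
  for (l in seq_len(nl)) {
    bot <- (l - 1) * ns; top <- l * ns
    rows <- (l - 1) * nq + seq_len(nq)
    hex[rows, ] <- cbind(sec$quads + bot, sec$quads + top)
    elem_layer[rows] <- l
  }

  # element cross-section centers (parameter space) and region tags
  qtau <- rowMeans(matrix(sec$tau[sec$quads], nq, 4))
  qphi <- atan2(rowMeans(matrix(sec$v[sec$quads], nq, 4)),
                rowMeans(matrix(sec$u[sec$quads], nq, 4)))
  elem_tau <- rep(qtau, nl)
  elem_phi <- rep(qphi, nl)
  elem_region <- ifelse(elem_tau * a_max <= a_cornea, "cornea", "rim")

  # boundary face sets (local node ids within the hex rows)
  top_rows <- which(elem_layer == nl)
  bot_rows <- which(elem_layer == 1)
  anterior_faces <- cbind(hex[top_rows, 5:8], elem = top_rows)
  posterior_faces <- cbind(hex[bot_rows, 4:1], elem = bot_rows)

  mesh <- structure(list(
    nodes = nodes, hex = hex, n_layers = nl, ns = ns,
    elem_layer = elem_layer, elem_region = elem_region,
    elem_tau = elem_tau, elem_phi = elem_phi,
    anterior_faces = anterior_faces, posterior_faces = posterior_faces,
    limbus_nodes = nl * ns + sec$limbus_ring,
    rim_edge_nodes = as.integer(outer(sec$outer_ring, (0:nl) * ns, `+`)),
    section = list(tau = sec$tau, phi = sec$phi), zeta = zeta,
    params = list(template_radius = R, corneal_diameter = corneal_diameter,
                  rim_width = rim_width, corneal_thickness = corneal_thickness,
                  scleral_thickness = scleral_thickness,
                  a_cornea = a_cornea, a_max = a_max, t_limbus = t_limbus)),
    class = "cornea_mesh")
  q <- mesh_quality(mesh)
  if (q$min_jacobian <= 0) {
    stop(sprintf("template mesh has non-positive Jacobians (min %.3g, element %d); increase resolution",
                 q$min_jacobian, q$worst_element))
  }
  mesh
}

#' @export
print.cornea_mesh <- function(x, ...) {
  cat(sprintf("Corneal FE mesh: %d nodes, %d hexahedra (%d layers), cornea %.1f mm + %.1f-mm rim\n",
              nrow(x$nodes), nrow(x$hex), x$n_layers,
              x$params$corneal_diameter, x$params$rim_width))
  invisible(x)
}

## trilinear hex shape-function derivatives at a reference point
hex_dN <- function(xi, eta, ze) {
  s <- matrix(c(-1, -1, -1,  1, -1, -1,  1, 1, -1, -1, 1, -1,
                -1, -1,  1,  1, -1,  1,  1, 1,  1, -1, 1,  1),
              8, 3, byrow = TRUE)
  dN <- matrix(0, 8, 3)
  for (a in 1:8) {
    dN[a, 1] <- s[a, 1] * (1 + s[a, 2] * eta) * (1 + s[a, 3] * ze) / 8
    dN[a, 2] <- s[a, 2] * (1 + s[a, 1] * xi) * (1 + s[a, 3] * ze) / 8
    dN[a, 3] <- s[a, 3] * (1 + s[a, 1] * xi) * (1 + s[a, 2] * eta) / 8
  }
  dN
}

#' Mesh quality metrics
#'
#' Jacobian determinants of the trilinear map at the 2x2x2 Gauss points of
#' each hexahedron, scaled Jacobians (det / product of Jacobian row norms),
#' and the worst element.
#'
#' @param mesh a `cornea_mesh` (or any list with `nodes`, `hex`).
#' @return list: `min_jacobian` (mm^3 scale), `min_scaled_jacobian`,
#'   `mean_scaled_jacobian`, `worst_element`.
#' @export
mesh_quality <- function(mesh) {
  nodes <- mesh$nodes; hex <- mesh$hex
  ne <- nrow(hex)
  g <- 1 / sqrt(3)
  gp <- expand.grid(xi = c(-g, g), eta = c(-g, g), ze = c(-g, g))
  X <- matrix(nodes[hex, 1], ne, 8)
  Y <- matrix(nodes[hex, 2], ne, 8)
  Z <- matrix(nodes[hex, 3], ne, 8)
  minJ <- rep(Inf, ne); minSJ <- rep(Inf, ne); sumSJ <- rep(0, ne)
  for (k in seq_len(nrow(gp))) {
    dN <- hex_dN(gp$xi[k], gp$eta[k], gp$ze[k])
    J11 <- X %*% dN[, 1]; J12 <- X %*% dN[, 2]; J13 <- X %*% dN[, 3]
    J21 <- Y %*% dN[, 1]; J22 <- Y %*% dN[, 2]; J23 <- Y %*% dN[, 3]
    J31 <- Z %*% dN[, 1]; J32 <- Z %*% dN[, 2]; J33 <- Z %*% dN[, 3]
    det <- J11 * (J22 * J33 - J23 * J32) - J12 * (J21 * J33 - J23 * J31) +
      J13 * (J21 * J32 - J22 * J31)
    r1 <- sqrt(J11^2 + J21^2 + J31^2)
    r2 <- sqrt(J12^2 + J22^2 + J32^2)
    r3 <- sqrt(J13^2 + J23^2 + J33^2)
    sj <- det / pmax(r1 * r2 * r3, 1e-300)
    minJ <- pmin(minJ, det)
    minSJ <- pmin(minSJ, sj)
    sumSJ <- sumSJ + sj
  }
  list(min_jacobian = min(minJ), min_scaled_jacobian = min(minSJ),
       mean_scaled_jacobian = mean(sumSJ / nrow(gp)),
       worst_element = which.min(minSJ))
}

#' Warp the template mesh to patient-specific Zernike surfaces
#'
#' Anterior and posterior boundary nodes of the corneal region are moved
#' (axially) onto the respective Zernike surfaces; interior nodes follow by
#' linear through-thickness interpolation of the two boundary displacements.
#' Scleral-rim nodes keep the template geometry, with the corneal-edge
#' displacement blended smoothly to zero across the rim (the rim acts only as
#' a boundary frame). Element inversion after warping is an error.
#'
#' @param template a `cornea_mesh` from [build_template_mesh()].
#' @param anterior,posterior `zernike_surface` objects whose zones cover the
#'   corneal footprint of the template.
#' @return the warped `cornea_mesh`.
#' @export
warp_mesh <- function(template, anterior, posterior) {
  stopifnot(inherits(template, "cornea_mesh"),
            inherits(anterior, "zernike_surface"),
            inherits(posterior, "zernike_surface"))
  p <- template$params
  if (anterior$zone_diameter < p$corneal_diameter - 1e-9) {
    stop("anterior surface zone does not cover the corneal footprint")
  }
  ns <- template$ns; nl <- template$n_layers
  ant_idx <- nl * ns + seq_len(ns)
  post_idx <- seq_len(ns)
  A <- template$nodes[ant_idx, , drop = FALSE]
  P <- template$nodes[post_idx, , drop = FALSE]

  tau <- template$section$tau; phi <- template$section$phi
  t_l <- p$t_limbus
  r_c <- p$corneal_diameter / 2
  corneal <- tau <= t_l + 1e-12

  r_post <- max(sqrt(P[corneal, 1]^2 + P[corneal, 2]^2))
  if (posterior$zone_diameter < 2 * r_post - 1e-9) {
    stop("posterior surface zone does not cover the corneal footprint")
  }
  # corneal columns: axial displacement bringing the anchors onto the target
  # surfaces (relative to the current anchor heights, so warps compose and
  # invert exactly)
  dz_a <- rep(0, ns); dz_p <- rep(0, ns)
  dz_a[corneal] <- eval_zernike(anterior, A[corneal, 1], A[corneal, 2]) -
    A[corneal, 3]
  dz_p[corneal] <- eval_zernike(posterior, P[corneal, 1], P[corneal, 2]) -
    P[corneal, 3]

  # rim columns: the surfaces are patient-specific only over the cornea; carry
  # the limbus-ring displacement (same angular index on the circular rings)
  # outward, tapered smoothly to zero at the rim edge
  limbus_sec <- which(abs(tau - t_l) < 1e-9)
  rim <- which(!corneal)
  if (length(rim) > 0) {
    match_l <- limbus_sec[apply(abs(outer(phi[rim], phi[limbus_sec], angdiff)),
                                1, which.min)]
    w <- (1 + cos(pi * pmin(1, (tau[rim] - t_l) / (1 - t_l)))) / 2
    dz_a[rim] <- dz_a[match_l] * w
    dz_p[rim] <- dz_p[match_l] * w
  }

  nodes <- template$nodes
  for (l in 0:nl) {
    zf <- template$zeta[l + 1]          # 0 posterior, 1 anterior
    idx <- l * ns + seq_len(ns)
    nodes[idx, 3] <- nodes[idx, 3] + (1 - zf) * dz_p + zf * dz_a
  }
  out <- template
  out$nodes <- nodes
  q <- mesh_quality(out)
  if (q$min_jacobian <= 0) {
    stop(sprintf("warp produced a distorted element (worst element %d, min Jacobian %.3g)",
                 q$worst_element, q$min_jacobian))
  }
  out
}

## thickness vs polar angle: uniform over the cornea, smoothstep ramp (C1 at
## the limbus, so the posterior template stays polynomial-representable)
## across the rim
rim_thickness <- function(alpha, a_cornea, a_max, t_cornea, t_sclera) {
  s <- pmin(pmax((alpha - a_cornea) / (a_max - a_cornea), 0), 1)
  t_cornea + (t_sclera - t_cornea) * s^2 * (3 - 2 * s)
}

#' Template surfaces of a mesh as Zernike fits
#'
#' Fits the template's own (spherical) anterior and posterior surfaces, e.g.
#' to express an identity warp or to warp a patient mesh back to the
#' template.
#' @param mesh a `cornea_mesh`.
#' @param zone_diameter,order fit parameters.
#' @export
template_surfaces <- function(mesh, zone_diameter = 9.5, order = 12) {
  p <- mesh$params
  R <- p$template_radius
  # dense parametric sampling of the analytic template geometry
  alpha <- seq(1e-4, p$a_max, length.out = 160)
  phi <- seq(0, 2 * pi, length.out = 49)[-49]
  A <- expand.grid(alpha = alpha, phi = phi)
  thick <- rim_thickness(A$alpha, p$a_cornea, p$a_max, p$corneal_thickness,
                         p$scleral_thickness)
  ax <- R * sin(A$alpha) * cos(A$phi)
  ay <- R * sin(A$alpha) * sin(A$phi)
  az <- R * (1 - cos(A$alpha))
  rp <- (R - thick) * sin(A$alpha)
  zp <- R - (R - thick) * cos(A$alpha)
  list(anterior = fit_zernike(ax, ay, az, order, zone_diameter),
       posterior = fit_zernike(rp * cos(A$phi), rp * sin(A$phi), zp, order,
                               zone_diameter))
}

#' Pterygium footprint faces on a mesh
#'
#' Anterior-surface faces of the corneal region whose centroid lies inside the
#' footprint wedge (planar radius between `apex_distance` and the limbus,
#' within the angular width of the footprint meridian).
#'
#' @param fp a [pterygium_footprint()].
#' @param mesh a `cornea_mesh`.
#' @return integer row indices into `mesh$anterior_faces`.
#' @export
footprint_faces <- function(fp, mesh) {
  stopifnot(inherits(fp, "pterygium_footprint"), inherits(mesh, "cornea_mesh"))
  fc <- mesh$anterior_faces[, 1:4]
  cx <- rowMeans(matrix(mesh$nodes[fc, 1], nrow(fc), 4))
  cy <- rowMeans(matrix(mesh$nodes[fc, 2], nrow(fc), 4))
  r <- sqrt(cx^2 + cy^2)
  th <- atan2(cy, cx)
  r_lim <- mesh$params$corneal_diameter / 2
  if (fp$apex_distance >= r_lim) {
    stop("footprint apex_distance lies outside the mesh limbus")
  }
  dir <- footprint_direction(fp)
  half <- fp$angular_width / 2 * pi / 180
  sel <- which(r >= fp$apex_distance & r <= r_lim + 1e-9 &
                 abs(angdiff(th, dir)) <= half)
  if (length(sel) == 0) stop("pterygium footprint does not intersect the mesh (empty face set)")
  sel
}

#' Single-hexahedron test mesh
#'
#' A unit cube (mm) as a `cornea_mesh`-compatible object, used for
#' constitutive patch tests of the solver.
#' @param L edge length, mm.
#' @export
unit_hex_mesh <- function(L = 1) {
  nodes <- matrix(c(0, 0, 0, L, 0, 0, L, L, 0, 0, L, 0,
                    0, 0, L, L, 0, L, L, L, L, 0, L, L),
                  8, 3, byrow = TRUE)
  structure(list(nodes = nodes,
                 hex = matrix(1:8, 1, 8),
                 n_layers = 1L, ns = 4L,
                 elem_layer = 1L, elem_region = "cornea",
                 elem_tau = 0, elem_phi = 0,
                 anterior_faces = matrix(c(5:8, 1), 1, 5),
                 posterior_faces = matrix(c(4:1, 1), 1, 5),
                 limbus_nodes = integer(0), rim_edge_nodes = integer(0),
                 section = list(tau = rep(0, 4), phi = rep(0, 4)),
                 zeta = c(0, 1),
                 params = list(template_radius = Inf, corneal_diameter = 2 * L,
                               rim_width = 0, corneal_thickness = L,
                               scleral_thickness = L, a_cornea = 0, a_max = 0,
                               t_limbus = 1)),
            class = "cornea_mesh")
}
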