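#' Quasi-static nonlinear finite-element solver
#'
#' Total-Lagrangian Newton solution of the corneal model: internal forces and
#' consistent tangent from the fiber-reinforced tissue model (mean-dilatation
#' near-incompressibility), intraocular pressure as a follower load on the
#' deformed posterior surface (with its load-stiffness term), tangential
#' surface tractions, Dirichlet fixation of the scleral rim edge, load
#' stepping with adaptive cutback, and fixed-point recovery of the stress-free
#' configuration.
#'
#' Internal unit system: mm - N - MPa. Pressure conversion:
#' 1 mmHg = 133.32 Pa (so the physiologic 15 mmHg is 1999.8 Pa).
#'
#' @name solver
NULL

#' @export
MMHG_TO_MPA <- 133.32e-6

#' Load case for a static solve
#'
#' @param iop_mmhg intraocular pressure, mmHg (applied as a follower pressure
#'   on the posterior surface).
#' @param traction optional traction force vector (length 3N, Newtons) as
#'   produced by [apply_surface_traction()], applied as a dead load.
#' @param fixed_nodes node indices with all displacement components fixed;
#'   defaults to the scleral rim edge when `NULL`.
#' @param fixed_dofs optional explicit DOF indices (into the 3N displacement
#'   vector, x1 y1 z1 x2 ...) overriding `fixed_nodes`.
#' @param prescribed displacement values (mm) for `fixed_dofs` (ramped with
#'   the load factor); default zero.
#' @export
load_case <- function(iop_mmhg = 15, traction = NULL, fixed_nodes = NULL,
                      fixed_dofs = NULL, prescribed = NULL) {
  stopifnot(iop_mmhg >= 0)
  if (!is.null(prescribed)) stopifnot(length(prescribed) == length(fixed_dofs))
  structure(list(iop_mmhg = iop_mmhg, traction = traction,
                 fixed_nodes = fixed_nodes, fixed_dofs = fixed_dofs,
                 prescribed = prescribed),
            class = "load_case")
}

#' Solver options
#'
#' @param tol_rel Newton convergence on the residual norm relative to the
#'   external force norm.
#' @param tol_abs absolute residual floor, N.
#' @param max_newton Newton iterations per load step.
#' @param n_steps initial number of load steps.
#' @param max_cutbacks step-halving limit on divergence.
#' @param n_theta fiber angular quadrature order.
#' @export
solver_options <- function(tol_rel = 1e-8, tol_abs = 1e-12, max_newton = 30,
                           n_steps = 5, max_cutbacks = 8, n_theta = 32) {
  list(tol_rel = tol_rel, tol_abs = tol_abs, max_newton = max_newton,
       n_steps = n_steps, max_cutbacks = max_cutbacks, n_theta = n_theta)
}

## per-element fiber frame (reference config) and angular weights
fiber_setup <- function(mesh, fd, n_theta) {
  ne <- nrow(mesh$hex)
  nodes <- mesh$nodes
  # through-thickness (posterior -> anterior) direction per element
  cen <- function(cols, d) rowMeans(matrix(nodes[mesh$hex[, cols], d], ne, 4))
  nx <- cen(5:8, 1) - cen(1:4, 1)
  ny <- cen(5:8, 2) - cen(1:4, 2)
  nz <- cen(5:8, 3) - cen(1:4, 3)
  nn <- sqrt(nx^2 + ny^2 + nz^2)
  nx <- nx / nn; ny <- ny / nn; nz <- nz / nn
  # e1: global x projected into the tangent plane
  e1x <- 1 - nx * nx; e1y <- -nx * ny; e1z <- -nx * nz
  e1n <- sqrt(e1x^2 + e1y^2 + e1z^2)
  e1 <- cbind(e1x / e1n, e1y / e1n, e1z / e1n)
  e2 <- cbind(ny * e1[, 3] - nz * e1[, 2],
              nz * e1[, 1] - nx * e1[, 3],
              nx * e1[, 2] - ny * e1[, 1])
  if (fd$type == "single") {
    thetas <- fd$single_angle
    phi <- matrix(1, ne, 1)
  } else {
    thetas <- theta_grid(n_theta)
    cx <- rowMeans(matrix(nodes[mesh$hex, 1], ne, 8))
    cy <- rowMeans(matrix(nodes[mesh$hex, 2], ne, 8))
    depth <- 1 - (mesh$elem_layer - 0.5) / mesh$n_layers   # 0 ant, 1 post
    phi <- matrix(0, ne, n_theta)
    for (el in seq_len(ne)) {
      # fiber angles are measured in the element frame; express the angular
      # density in that frame by shifting by the frame's meridian offset
      phi[el, ] <- fiber_weight(fd, c(cx[el], cy[el], 0), depth[el], thetas)
    }
  }
  list(e1 = e1, e2 = e2, phi = phi, thetas = thetas)
}

matpar_vec <- function(params) {
  c(params$C10, params$gamma_m, params$mu_m, params$gamma_k, params$mu_k,
    params$penalty_bulk)
}

## ensure quad faces are ordered with x_,xi x x_,eta pointing out of the solid
orient_faces <- function(mesh, faces) {
  nd <- mesh$nodes
  f <- faces[, 1:4, drop = FALSE]
  el <- faces[, 5]
  fcx <- matrix(nd[f, 1], nrow(f), 4)
  fcy <- matrix(nd[f, 2], nrow(f), 4)
  fcz <- matrix(nd[f, 3], nrow(f), 4)
  d1 <- cbind(fcx[, 3] - fcx[, 1], fcy[, 3] - fcy[, 1], fcz[, 3] - fcz[, 1])
  d2 <- cbind(fcx[, 4] - fcx[, 2], fcy[, 4] - fcy[, 2], fcz[, 4] - fcz[, 2])
  nrm <- cbind(d1[, 2] * d2[, 3] - d1[, 3] * d2[, 2],
               d1[, 3] * d2[, 1] - d1[, 1] * d2[, 3],
               d1[, 1] * d2[, 2] - d1[, 2] * d2[, 1])
  ecx <- rowMeans(matrix(nd[mesh$hex[el, ], 1], length(el), 8))
  ecy <- rowMeans(matrix(nd[mesh$hex[el, ], 2], length(el), 8))
  ecz <- rowMeans(matrix(nd[mesh$hex[el, ], 3], length(el), 8))
  outward <- cbind(rowMeans(fcx) - ecx, rowMeans(fcy) - ecy, rowMeans(fcz) - ecz)
  flip <- rowSums(nrm * outward) < 0
  f[flip, ] <- f[flip, c(1, 4, 3, 2)]
  cbind(f, el)
}

#' Tangential limbus-ward surface traction
#'
#' Builds the nodal force vector for the retracting pterygium's pull: each
#' face of the footprint receives a traction directed from its centroid
#' toward the nearest limbus-ring point along the footprint's central
#' meridian, projected onto the face tangent plane (zero normal component by
#' construction), with magnitudes proportional to face area and scaled so the
#' resultant force equals `total_force_mN`.
#'
#' @param mesh a `cornea_mesh`.
#' @param face_rows row indices into `mesh$anterior_faces` (from
#'   [footprint_faces()]).
#' @param total_force_mN total pulling force, mN.
#' @param fp the [pterygium_footprint()] (for the central-meridian anchor).
#' @return list: `force` (length 3N, Newtons), `resultant_N`,
#'   `n_faces`, `excluded`.
#' @export
apply_surface_traction <- function(mesh, face_rows, total_force_mN, fp) {
  stopifnot(total_force_mN >= 0)
  if (length(face_rows) == 0) stop("empty traction face set")
  nd <- mesh$nodes
  faces <- mesh$anterior_faces[face_rows, , drop = FALSE]
  nf <- nrow(faces)
  f <- numeric(3 * nrow(nd))
  if (total_force_mN == 0) {
    return(list(force = f, resultant_N = 0, n_faces = nf, excluded = 0L))
  }
  # anchor: limbus-ring node nearest the footprint's central meridian
  dir <- footprint_direction(fp)
  ln <- mesh$limbus_nodes
  lth <- atan2(nd[ln, 2], nd[ln, 1])
  anchor <- nd[ln[which.min(abs(angdiff(lth, dir)))], ]

  fc <- faces[, 1:4, drop = FALSE]
  px <- matrix(nd[fc, 1], nf, 4); py <- matrix(nd[fc, 2], nf, 4)
  pz <- matrix(nd[fc, 3], nf, 4)
  cx <- rowMeans(px); cy <- rowMeans(py); cz <- rowMeans(pz)
  d1 <- cbind(px[, 3] - px[, 1], py[, 3] - py[, 1], pz[, 3] - pz[, 1])
  d2 <- cbind(px[, 4] - px[, 2], py[, 4] - py[, 2], pz[, 4] - pz[, 2])
  nrm <- cbind(d1[, 2] * d2[, 3] - d1[, 3] * d2[, 2],
               d1[, 3] * d2[, 1] - d1[, 1] * d2[, 3],
               d1[, 1] * d2[, 2] - d1[, 2] * d2[, 1])
  area <- 0.5 * sqrt(rowSums(nrm^2))
  nrm <- nrm / sqrt(rowSums(nrm^2))
  d0 <- cbind(anchor[1] - cx, anchor[2] - cy, anchor[3] - cz)
  dt <- d0 - rowSums(d0 * nrm) * nrm            # tangent-plane projection
  dn <- sqrt(rowSums(dt^2))
  ok <- dn > 1e-8 * sqrt(rowSums(d0^2))
  if (any(!ok)) {
    warning(sprintf("%d traction faces with degenerate tangent direction excluded",
                    sum(!ok)))
  }
  if (!any(ok)) stop("no usable traction faces")
  dt <- dt[ok, , drop = FALSE] / dn[ok]
  fface <- dt * area[ok]
  resultant <- sqrt(sum(colSums(fface)^2))
  fface <- fface * (total_force_mN / 1000) / resultant
  fco <- fc[ok, , drop = FALSE]
  for (a in 1:4) {
    idx <- fco[, a]
    f[3 * (idx - 1) + 1] <- f[3 * (idx - 1) + 1] + fface[, 1] / 4
    f[3 * (idx - 1) + 2] <- f[3 * (idx - 1) + 2] + fface[, 2] / 4
    f[3 * (idx - 1) + 3] <- f[3 * (idx - 1) + 3] + fface[, 3] / 4
  }
  list(force = f, resultant_N = sqrt(sum(c(sum(fface[, 1]), sum(fface[, 2]),
                                           sum(fface[, 3]))^2)),
       n_faces = sum(ok), excluded = sum(!ok),
       directions = dt, faces_used = which(ok))
}

#' Static equilibrium solve
#'
#' @param mesh a `cornea_mesh` (its nodes are the reference configuration).
#' @param params a [material_params()].
#' @param load a [load_case()].
#' @param fd a [fiber_distribution()].
#' @param opts [solver_options()].
#' @param u_init optional displacement warm start (3N); when supplied the
#'   solver first attempts the full load in one step from it, falling back to
#'   load stepping from zero.
#' @return a `deformed_state`: displacement field `u` (3N, mm), deformed
#'   nodes, per-Gauss-point stress/strain (`gp`), convergence log, and the
#'   setup used.
#' @export
solve_static <- function(mesh, params, load = load_case(),
                         fd = fiber_distribution(), opts = solver_options(),
                         u_init = NULL) {
  stopifnot(inherits(mesh, "cornea_mesh"), inherits(params, "material_params"),
            inherits(load, "load_case"))
  N <- nrow(mesh$nodes)
  if (!is.null(load$fixed_dofs)) {
    fixed_dof <- load$fixed_dofs
    u_pre <- if (is.null(load$prescribed)) numeric(length(fixed_dof)) else
      load$prescribed
  } else {
    fixed <- load$fixed_nodes
    if (is.null(fixed)) fixed <- mesh$rim_edge_nodes
    fixed_dof <- as.vector(outer(1:3, 3 * (fixed - 1), `+`))
    u_pre <- numeric(length(fixed_dof))
  }
  free <- setdiff(seq_len(3 * N), fixed_dof)

  fs <- fiber_setup(mesh, fd, opts$n_theta)
  mp <- matpar_vec(params)
  has_pressure <- load$iop_mmhg > 0 && nrow(mesh$posterior_faces) > 0
  pfaces <- if (has_pressure) orient_faces(mesh, mesh$posterior_faces) else NULL
  p_full <- load$iop_mmhg * MMHG_TO_MPA
  f_trac <- if (is.null(load$traction)) numeric(3 * N) else load$traction
  has_load <- has_pressure || any(f_trac != 0) || any(u_pre != 0)

  u <- numeric(3 * N)
  log <- list()
  if (!has_load) {
    gp <- fem_stress(mesh$nodes, mesh$hex, u, mp, fs$e1, fs$e2, fs$phi, fs$thetas)
    return(new_deformed_state(mesh, u, gp, data.frame(), params, fd, opts))
  }

  s_done <- 0; ds <- 1 / opts$n_steps; cutbacks <- 0
  if (!is.null(u_init)) {
    u <- u_init
    ds <- 1                              # try the full load from the warm start
  }
  u_last <- numeric(3 * N)
  while (s_done < 1 - 1e-12) {
    s <- min(1, s_done + ds)
    converged <- FALSE
    res0 <- NA
    u[fixed_dof] <- s * u_pre
    for (it in seq_len(opts$max_newton)) {
      asm <- fem_assemble(mesh$nodes, mesh$hex, u, mp, fs$e1, fs$e2,
                          fs$phi, fs$thetas)
      if (!isTRUE(asm$ok)) break
      if (has_pressure) {
        pres <- fem_pressure(mesh$nodes, pfaces[, 1:4, drop = FALSE], u,
                             s * p_full)
        f_ext <- pres$f_ext + s * f_trac
      } else {
        pres <- NULL
        f_ext <- s * f_trac
      }
      r <- asm$f_int - f_ext
      rn <- sqrt(sum(r[free]^2))
      if (it == 1) res0 <- rn
      fext_norm <- max(sqrt(sum(f_ext[free]^2)), res0, opts$tol_abs)
      log[[length(log) + 1]] <- data.frame(step = s, iter = it, residual = rn,
                                           rel = rn / fext_norm)
      if (rn <= opts$tol_rel * fext_norm || rn <= opts$tol_abs) {
        converged <- TRUE; break
      }
      if (!is.finite(rn) || (it > 6 && rn > 1e3 * res0)) break
      if (has_pressure) {
        K <- Matrix::sparseMatrix(i = c(asm$i, pres$i), j = c(asm$j, pres$j),
                                  x = c(asm$v, -pres$v), dims = c(3 * N, 3 * N))
      } else {
        K <- Matrix::sparseMatrix(i = asm$i, j = asm$j, x = asm$v,
                                  dims = c(3 * N, 3 * N))
      }
      Kff <- K[free, free, drop = FALSE]
      # the tangent is symmetric up to the (conservative, for a pressure
      # surface with fixed boundary) follower-load term; factor the
      # symmetrized matrix by sparse Cholesky, falling back to LU
      Ks <- Matrix::forceSymmetric((Kff + Matrix::t(Kff)) / 2)
      # an indefinite excursion (early Newton iterate) falls back to LU;
      # CHOLMOD's not-positive-definite warning is that expected signal
      du <- suppressWarnings(tryCatch(
        as.numeric(Matrix::solve(Matrix::Cholesky(Ks, LDL = FALSE,
                                                  super = TRUE), r[free])),
        error = function(e) as.numeric(Matrix::solve(Kff, r[free]))))
      u[free] <- u[free] - du
    }
    if (converged) {
      s_done <- s; u_last <- u
    } else {
      cutbacks <- cutbacks + 1
      if (cutbacks > opts$max_cutbacks) {
        stop(sprintf("Newton divergence at load fraction %.3f after %d cutbacks",
                     s, cutbacks - 1))
      }
      ds <- if (!is.null(u_init) && cutbacks == 1) 1 / opts$n_steps else ds / 2
      u <- u_last
    }
  }
  gp <- fem_stress(mesh$nodes, mesh$hex, u, mp, fs$e1, fs$e2, fs$phi, fs$thetas)
  new_deformed_state(mesh, u, gp, do.call(rbind, log), params, fd, opts)
}

new_deformed_state <- function(mesh, u, gp, log, params, fd, opts) {
  def <- mesh$nodes + matrix(u, ncol = 3, byrow = TRUE)
  structure(list(mesh = mesh, u = u, nodes_def = def, gp = gp,
                 convergence_log = log, params = params, fd = fd, opts = opts),
            class = "deformed_state")
}

#' @export
print.deformed_state <- function(x, ...) {
  umax <- max(sqrt(rowSums(matrix(x$u, ncol = 3, byrow = TRUE)^2)))
  cat(sprintf("Deformed state: max |u| = %.2f um, J in [%.5f, %.5f], mean von Mises %.2f kPa\n",
              1000 * umax, min(x$gp$J), max(x$gp$J),
              1000 * sum(x$gp$von_mises * x$gp$weight) / sum(x$gp$weight)))
  invisible(x)
}

#' Recover the stress-free configuration
#'
#' The tomography measures the cornea under intraocular pressure, so the
#' unloaded shape is unknown. Fixed-point iteration on the reference
#' geometry: inflate the current guess under the IOP and subtract the
#' discrepancy to the measured node positions,
#' \eqn{x_0 \leftarrow x_0 - \omega\,(\mathrm{inflate}(x_0) - x_{meas})},
#' until re-inflation reproduces the measured nodes to `tol`.
#'
#' @param mesh the measured-configuration `cornea_mesh`.
#' @param params,fd,opts as in [solve_static()].
#' @param iop_mmhg intraocular pressure, mmHg.
#' @param tol maximum nodal error, mm (default 1e-3 = 1 um).
#' @param max_iter fixed-point iteration limit.
#' @param relax relaxation factor omega in (0, 1].
#' @return list: `mesh0` (stress-free configuration), `state` (the inflation
#'   of `mesh0`, i.e. the preoperative loaded state), `errors` (max nodal
#'   error per iteration, mm), `iterations`.
#' @export
find_stress_free_config <- function(mesh, params, iop_mmhg = 15,
                                    fd = fiber_distribution(),
                                    opts = solver_options(),
                                    tol = 1e-3, max_iter = 30, relax = 1) {
  stopifnot(iop_mmhg >= 0, relax > 0, relax <= 1)
  if (iop_mmhg == 0) {
    state <- solve_static(mesh, params, load_case(iop_mmhg = 0), fd, opts)
    return(list(mesh0 = mesh, state = state, errors = 0, iterations = 0L))
  }
  x_meas <- mesh$nodes
  mesh0 <- mesh
  errors <- numeric(0)
  lc <- load_case(iop_mmhg = iop_mmhg)
  u_ws <- NULL
  for (k in seq_len(max_iter)) {
    state <- solve_static(mesh0, params, lc, fd, opts, u_init = u_ws)
    u_ws <- state$u
    gap <- state$nodes_def - x_meas
    err <- max(sqrt(rowSums(gap^2)))
    errors <- c(errors, err)
    if (err < tol) {
      return(list(mesh0 = mesh0, state = state, errors = errors,
                  iterations = k))
    }
    mesh0$nodes <- mesh0$nodes - relax * gap
  }
  stop(sprintf(
    "stress-free configuration did not converge in %d iterations (errors: %s mm)",
    max_iter, paste(signif(errors, 3), collapse = ", ")))
}
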