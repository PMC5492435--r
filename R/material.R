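#' Anisotropic fiber-reinforced corneal tissue model
#'
#' Strain energy per unit reference volume (MPa):
#' \deqn{\Psi = U(J) + \bar\Psi_m(C_{10}) +
#'   \frac{1}{\pi}\int_0^\pi \Phi(\theta)\,[\bar\Psi_{f1}(\gamma_m,\mu_m) +
#'   \bar\Psi_{f2}(\gamma_k,\mu_k)]\, d\theta}
#' with a volumetric penalty \eqn{U = \kappa/2 (J-1)^2} enforcing near
#' incompressibility, a (compressible) neo-Hookean matrix
#' \eqn{\bar\Psi_m = C_{10}(I_1 - 3 - 2\ln J)} for the proteoglycan ground
#' substance, and two in-plane fiber families -- main collagen lamellae and
#' cross-links -- with the Markert power-law potential
#' \eqn{\psi_f(\lambda) = \frac{\mu}{\gamma}(\lambda^\gamma - 1) - \mu\ln\lambda}
#' per direction, active in tension only (\eqn{\lambda > 1}; collagen cannot
#' sustain compression). The angular distribution \eqn{\Phi \ge 0} is a
#' probability weighting over in-plane fiber angles,
#' \eqn{\frac{1}{\pi}\int_0^\pi \Phi\,d\theta = 1}, so the integral is a
#' weighted average over directions; it varies with corneal position
#' (orthogonal nasal-temporal/superior-inferior peaks centrally blending into
#' a circumferential limbal annulus) and with normalized depth.
#'
#' Default constants (MPa / dimensionless): C10 = 0.06, gamma_m = 0.13,
#' mu_m = 24.0, gamma_k = 0.08, mu_k = 95.0 -- the human-cornea preset.
#'
#' @name material
NULL

#' Material parameters
#'
#' @param C10 neo-Hookean matrix constant, MPa.
#' @param gamma_m,mu_m main collagen fiber family (dimensionless exponent, MPa).
#' @param gamma_k,mu_k collagen cross-link family.
#' @param penalty_bulk volumetric penalty modulus kappa, MPa. The default
#'   (60 MPa, three decades above C10) keeps |J - 1| below 1e-3 at
#'   physiologic corneal wall stress while leaving Newton systems well
#'   conditioned.
#' @export
material_params <- function(C10 = 0.06, gamma_m = 0.13, mu_m = 24.0,
                            gamma_k = 0.08, mu_k = 95.0, penalty_bulk = 60) {
  stopifnot(C10 >= 0, mu_m >= 0, mu_k >= 0, penalty_bulk > 0)
  structure(list(C10 = C10, gamma_m = gamma_m, mu_m = mu_m,
                 gamma_k = gamma_k, mu_k = mu_k, penalty_bulk = penalty_bulk),
            class = "material_params")
}

#' Matrix-only variant (fiber moduli zero), for oracle tests
#' @inheritParams material_params
#' @export
matrix_only_params <- function(C10 = 0.06, penalty_bulk = 60) {
  material_params(C10 = C10, mu_m = 0, mu_k = 0, penalty_bulk = penalty_bulk)
}

#' In-plane collagen fiber angular distribution
#'
#' Mixture of an isotropic floor and pi-periodic von Mises peaks: orthogonal
#' peaks at 0 and 90 degrees in the central cornea, blending with planar
#' radius (logistic transition) into a single circumferential peak near the
#' limbus. The anisotropic fraction grows linearly with normalized depth
#' (0 = anterior surface, 1 = posterior), reflecting the stronger lamellar
#' alignment of the posterior stroma seen in X-ray scattering. Each von Mises
#' component exp(b cos 2(theta - mu))/I0(b) integrates to 1 under
#' (1/pi) \\int_0^pi d theta, so the mixture is analytically normalized.
#'
#' @param type `"physiologic"` (default), `"uniform"` (isotropy limit,
#'   Phi = 1), or `"single"` (one discrete direction; the angular
#'   integral degenerates to evaluation at `single_angle`).
#' @param concentration von Mises concentration b.
#' @param f_aniso_anterior,f_aniso_posterior anisotropic mixture fraction at
#'   the anterior/posterior surface.
#' @param transition_radius,transition_width mm; center of and width of the
#'   central-to-limbal blend.
#' @param single_angle radians, for `type = "single"`.
#' @export
fiber_distribution <- function(type = c("physiologic", "uniform", "single"),
                               concentration = 2,
                               f_aniso_anterior = 0.3, f_aniso_posterior = 0.7,
                               transition_radius = 4.0, transition_width = 1.0,
                               single_angle = 0) {
  type <- match.arg(type)
  stopifnot(concentration > 0, f_aniso_anterior >= 0, f_aniso_anterior <= 1,
            f_aniso_posterior >= 0, f_aniso_posterior <= 1)
  structure(list(type = type, concentration = concentration,
                 f_aniso_anterior = f_aniso_anterior,
                 f_aniso_posterior = f_aniso_posterior,
                 transition_radius = transition_radius,
                 transition_width = transition_width,
                 single_angle = single_angle),
            class = "fiber_distribution")
}

#' Fiber angular weight Phi at a material point
#'
#' @param fd a [fiber_distribution()].
#' @param point length-3 position, mm (planar radius and meridian are used).
#' @param depth normalized depth in [0, 1], 0 = anterior surface.
#' @param theta in-plane fiber angles, radians in [0, pi).
#' @return Phi values (same length as `theta`), satisfying
#'   (1/pi) integral Phi d theta = 1.
#' @export
fiber_weight <- function(fd, point, depth, theta) {
  stopifnot(inherits(fd, "fiber_distribution"))
  if (fd$type == "single") {
    stop("a single-direction fiber configuration has no angular density")
  }
  if (fd$type == "uniform") return(rep(1, length(theta)))
  b <- fd$concentration
  vm <- function(mu) exp(b * cos(2 * (theta - mu))) / besselI(b, 0)
  r <- sqrt(point[1]^2 + point[2]^2)
  g <- stats::plogis((fd$transition_radius - r) /
                       (fd$transition_width / 4))       # 1 central, 0 limbal
  fa <- fd$f_aniso_anterior +
    (fd$f_aniso_posterior - fd$f_aniso_anterior) * depth
  th_circ <- atan2(point[2], point[1]) + pi / 2
  (1 - fa) + fa * (g * (0.5 * vm(0) + 0.5 * vm(pi / 2)) + (1 - g) * vm(th_circ))
}

## Markert fiber potential and derivatives (tension-only)
fiber_psi <- function(lam, mu, gam) {
  ifelse(lam > 1, mu / gam * (lam^gam - 1) - mu * log(lam), 0)
}
fiber_g <- function(lam, mu, gam) {      # (1/lambda) d psi / d lambda
  ifelse(lam > 1, mu * (lam^(gam - 2) - lam^-2), 0)
}
fiber_gp <- function(lam, mu, gam) {     # d g / d lambda
  ifelse(lam > 1, mu * ((gam - 2) * lam^(gam - 3) + 2 * lam^-3), 0)
}

theta_grid <- function(n_theta) (seq_len(n_theta) - 0.5) * pi / n_theta

fiber_dirs <- function(theta, basis) {
  # unit reference directions a(theta) = cos(theta) e1 + sin(theta) e2
  outer(cos(theta), basis[, 1]) + outer(sin(theta), basis[, 2])
}

default_basis <- cbind(c(1, 0, 0), c(0, 1, 0))

check_state <- function(F) {
  J <- det(F)
  if (!is.finite(J) || J <= 0) stop("invalid deformation state: det F <= 0")
  J
}

phi_at <- function(fd, point, depth, theta) {
  if (fd$type == "single") rep(1, length(theta)) else
    fiber_weight(fd, point, depth, theta)
}

eff_thetas <- function(fd, n_theta) {
  if (fd$type == "single") fd$single_angle else theta_grid(n_theta)
}

#' Strain energy density
#'
#' @param F 3x3 deformation gradient (det F > 0).
#' @param params a [material_params()].
#' @param fd a [fiber_distribution()] (default uniform).
#' @param point,depth material-point position (mm) and normalized depth.
#' @param basis 3x2 matrix of in-plane unit vectors spanning the fiber plane.
#' @param n_theta angular quadrature order (midpoint rule on the pi-periodic
#'   integrand: spectrally convergent for smooth Phi).
#' @return energy, MPa (= mJ/mm^3).
#' @export
strain_energy <- function(F, params, fd = fiber_distribution("uniform"),
                          point = c(0, 0, 0), depth = 0.5,
                          basis = default_basis, n_theta = 32) {
  J <- check_state(F)
  C <- crossprod(F)
  I1 <- sum(diag(C))
  W <- params$penalty_bulk / 2 * (J - 1)^2 +
    params$C10 * (I1 - 3 - 2 * log(J))
  th <- eff_thetas(fd, n_theta)
  A <- fiber_dirs(th, basis)
  lam <- sqrt(rowSums((A %*% C) * A))
  phi <- phi_at(fd, point, depth, th)
  W + mean(phi * (fiber_psi(lam, params$mu_m, params$gamma_m) +
                    fiber_psi(lam, params$mu_k, params$gamma_k)))
}

#' Second Piola-Kirchhoff stress
#'
#' \eqn{S = 2\,\partial\Psi/\partial C}, MPa.
#' @inheritParams strain_energy
#' @export
pk2_stress <- function(F, params, fd = fiber_distribution("uniform"),
                       point = c(0, 0, 0), depth = 0.5,
                       basis = default_basis, n_theta = 32) {
  J <- check_state(F)
  C <- crossprod(F)
  Ci <- solve(C)
  S <- 2 * params$C10 * (diag(3) - Ci) +
    params$penalty_bulk * (J - 1) * J * Ci
  th <- eff_thetas(fd, n_theta)
  A <- fiber_dirs(th, basis)
  lam <- sqrt(rowSums((A %*% C) * A))
  phi <- phi_at(fd, point, depth, th)
  g <- phi * (fiber_g(lam, params$mu_m, params$gamma_m) +
                fiber_g(lam, params$mu_k, params$gamma_k))
  Sf <- crossprod(A * g, A) / length(th)      # mean over angles of g a (x) a
  (S + (Sf + t(Sf)) / 2)
}

#' Material tangent (fourth-order elasticity tensor)
#'
#' Returns \eqn{\mathbb{C}} with \eqn{dS = \mathbb{C} : dE}, as a
#' 3x3x3x3 array (major and minor symmetric), MPa.
#' @inheritParams strain_energy
#' @export
material_tangent <- function(F, params, fd = fiber_distribution("uniform"),
                             point = c(0, 0, 0), depth = 0.5,
                             basis = default_basis, n_theta = 32) {
  J <- check_state(F)
  C <- crossprod(F)
  Ci <- solve(C)
  CC <- array(0, c(3, 3, 3, 3))
  # symmetrized open products
  odot <- function(A) {
    out <- array(0, c(3, 3, 3, 3))
    for (i in 1:3) for (j in 1:3) for (k in 1:3) for (l in 1:3) {
      out[i, j, k, l] <- (A[i, k] * A[j, l] + A[i, l] * A[j, k]) / 2
    }
    out
  }
  oxo <- function(A, B) {
    out <- array(0, c(3, 3, 3, 3))
    for (i in 1:3) for (j in 1:3) out[i, j, , ] <- A[i, j] * B
    out
  }
  kap <- params$penalty_bulk
  CC <- CC + 4 * params$C10 * odot(Ci)
  CC <- CC + kap * ((2 * J - 1) * J * oxo(Ci, Ci) - 2 * (J^2 - J) * odot(Ci))
  th <- eff_thetas(fd, n_theta)
  A <- fiber_dirs(th, basis)
  lam <- sqrt(rowSums((A %*% C) * A))
  phi <- phi_at(fd, point, depth, th)
  gp <- phi * (fiber_gp(lam, params$mu_m, params$gamma_m) +
                 fiber_gp(lam, params$mu_k, params$gamma_k)) / lam
  for (k in seq_along(th)) {
    if (gp[k] == 0) next
    aa <- tcrossprod(A[k, ])
    CC <- CC + (gp[k] / length(th)) * oxo(aa, aa)
  }
  CC
}

#' Cauchy stress from a deformation state
#' @inheritParams strain_energy
#' @return 3x3 Cauchy stress, MPa.
#' @export
cauchy_stress <- function(F, params, fd = fiber_distribution("uniform"),
                          point = c(0, 0, 0), depth = 0.5,
                          basis = default_basis, n_theta = 32) {
  S <- pk2_stress(F, params, fd, point, depth, basis, n_theta)
  F %*% S %*% t(F) / det(F)
}

#' Von Mises equivalent of a stress tensor
#' @param sig 3x3 symmetric stress tensor.
#' @export
von_mises <- function(sig) {
  s <- sig - diag(mean(diag(sig)), 3)
  sqrt(3 / 2 * sum(s^2))
}

#' Closed-form incompressible neo-Hookean uniaxial Cauchy stress
#'
#' \eqn{\sigma = 2 C_{10} (\lambda^2 - 1/\lambda)}, MPa.
#' @param lambda axial stretch.
#' @param C10 MPa.
#' @export
uniaxial_cauchy_incompressible <- function(lambda, C10 = 0.06) {
  2 * C10 * (lambda^2 - 1 / lambda)
}

#' Uniaxial stress response of the (penalty-compressible) material
#'
#' Solves the lateral stretch so that lateral Cauchy stresses vanish for
#' \eqn{F = diag(\lambda, s, s)}, and returns the axial Cauchy stress. With
#' fibers off and a large penalty modulus this converges to the closed
#' incompressible form.
#'
#' @inheritParams strain_energy
#' @param lambda axial stretch (along the first basis vector).
#' @return list: `sigma_axial` (MPa), `lateral_stretch`.
#' @export
uniaxial_response <- function(lambda, params,
                              fd = fiber_distribution("uniform"),
                              point = c(0, 0, 0), depth = 0.5, n_theta = 32) {
  s <- 1 / sqrt(lambda)
  for (it in 1:60) {
    Fm <- diag(c(lambda, s, s))
    sig <- cauchy_stress(Fm, params, fd, point, depth, n_theta = n_theta)
    g <- (sig[2, 2] + sig[3, 3]) / 2
    h <- 1e-7 * s
    sig2 <- cauchy_stress(diag(c(lambda, s + h, s + h)), params, fd, point,
                          depth, n_theta = n_theta)
    dg <- ((sig2[2, 2] + sig2[3, 3]) / 2 - g) / h
    step <- g / dg
    s <- s - step
    if (abs(step) < 1e-14 * s) break
  }
  Fm <- diag(c(lambda, s, s))
  sig <- cauchy_stress(Fm, params, fd, point, depth, n_theta = n_theta)
  list(sigma_axial = sig[1, 1], lateral_stretch = s)
}
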