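#' Zernike surface representation
#'
#' Corneal surfaces are represented as height fields expanded in Zernike
#' polynomials over a circular zone, the standard clinical decomposition of
#' corneal elevation. The basis follows the OSA/ANSI double-index convention
#' with unit-RMS normalization: term \eqn{(n, m)} is
#' \eqn{N_n^m R_n^{|m|}(\rho)\cos(m\theta)} for \eqn{m \ge 0} and
#' \eqn{N_n^m R_n^{|m|}(\rho)\sin(|m|\theta)} for \eqn{m < 0}, with
#' \eqn{N_n^m = \sqrt{2(n+1)/(1+\delta_{m0})}} and \eqn{\rho = 2r/}
#' `zone_diameter`.
#'
#' @name zernike
#' @keywords internal
NULL

## Index table and radial polynomial coefficients for OSA ordering, n <= order.
## Radial polynomials are stored as coefficient vectors over powers rho^0..rho^n
## so evaluation and analytic derivatives reduce to a power-matrix product.
zernike_index_table <- function(order) {
  stopifnot(order >= 0, order <= 12)
  n <- integer(0); m <- integer(0)
  for (nn in 0:order) {
    for (mm in seq(-nn, nn, by = 2)) {
      n <- c(n, nn); m <- c(m, mm)
    }
  }
  j <- (n * (n + 2) + m) / 2
  ord <- order(j)
  list(n = n[ord], m = m[ord], j = j[ord])
}

zernike_radial_coefs <- function(n, m_abs, max_pow) {
  # R_n^{|m|}(rho) = sum_k (-1)^k (n-k)! / (k! ((n+|m|)/2-k)! ((n-|m|)/2-k)!) rho^(n-2k)
  co <- numeric(max_pow + 1)
  for (k in 0:((n - m_abs) / 2)) {
    v <- (-1)^k * factorial(n - k) /
      (factorial(k) * factorial((n + m_abs) / 2 - k) * factorial((n - m_abs) / 2 - k))
    co[n - 2 * k + 1] <- co[n - 2 * k + 1] + v
  }
  co
}

zernike_norm <- function(n, m) sqrt(2 * (n + 1) / (1 + (m == 0)))

#' Evaluate the Zernike design matrix (and optionally its gradient)
#'
#' @param r,theta polar coordinates of sample points; `r` in the same length
#'   unit as the surface heights, `theta` in radians.
#' @param order maximum radial order.
#' @param zone_diameter diameter of the unit-disk zone, mm.
#' @param deriv if `TRUE`, also return matrices of \eqn{\partial Z/\partial x}
#'   and \eqn{\partial Z/\partial y} (per mm).
#' @return matrix `npts x nterms`, or a list `Z`, `Zx`, `Zy` when `deriv`.
#' @keywords internal
zernike_basis <- function(r, theta, order = 12, zone_diameter = 8, deriv = FALSE) {
  idx <- zernike_index_table(order)
  nt <- length(idx$n)
  rho <- 2 * r / zone_diameter
  P <- outer(rho, 0:order, `^`)                       # npts x (order+1)
  Z <- matrix(0, length(r), nt)
  if (deriv) {
    # d/d rho uses power-shifted coefficients; chain rule back to x, y in mm
    Pd <- cbind(0 * rho, outer(rho, 0:(order - 1), `^`) *
                  rep(1:order, each = length(rho)))
    Zr <- matrix(0, length(r), nt)  # dZ/d rho
    Zt <- matrix(0, length(r), nt)  # dZ/d theta
  }
  for (k in seq_len(nt)) {
    n <- idx$n[k]; m <- idx$m[k]; ma <- abs(m)
    co <- zernike_radial_coefs(n, ma, order)
    R <- drop(P %*% co)
    N <- zernike_norm(n, m)
    ang <- if (m >= 0) cos(m * theta) else sin(ma * theta)
    Z[, k] <- N * R * ang
    if (deriv) {
      Rd <- drop(Pd %*% co)
      angd <- if (m >= 0) -m * sin(m * theta) else ma * cos(ma * theta)
      Zr[, k] <- N * Rd * ang
      Zt[, k] <- N * R * angd
    }
  }
  if (!deriv) return(Z)
  # x = r cos t, y = r sin t;  dZ/dx = cos t dZ/dr - sin t / r dZ/dt, etc.
  s <- 2 / zone_diameter                 # d rho / d r
  rr <- pmax(r, 1e-9)                    # guard the pole; callers avoid r = 0
  Zx <- cos(theta) * Zr * s - sin(theta) / rr * Zt
  Zy <- sin(theta) * Zr * s + cos(theta) / rr * Zt
  list(Z = Z, Zx = Zx, Zy = Zy)
}

#' Fit a Zernike surface to scattered height samples
#'
#' Least-squares fit of heights `z` at points `(x, y)` (all mm) over a circular
#' zone. Points outside the zone are dropped. The fit is solved by QR; a large
#' condition number of the design (clustered or rank-deficient sampling) is an
#' error.
#'
#' @param x,y,z sample coordinates and heights, mm.
#' @param order maximum radial order (default 12).
#' @param zone_diameter zone diameter, mm (clinical default 8.0).
#' @param max_condition conditioning guard on the design matrix.
#' @return an object of class `zernike_surface`: coefficients (mm, OSA order),
#'   index vectors `n`, `m`, `zone_diameter`, `normalization`, and the fit
#'   residual `rms` (mm).
#' @export
fit_zernike <- function(x, y, z, order = 12, zone_diameter = 8,
                        max_condition = 1e8) {
  stopifnot(length(x) == length(y), length(x) == length(z))
  r <- sqrt(x^2 + y^2)
  keep <- r <= zone_diameter / 2 + 1e-12
  if (!any(keep)) stop("no sample points inside the fit zone")
  r <- r[keep]; th <- atan2(y[keep], x[keep]); zz <- z[keep]
  idx <- zernike_index_table(order)
  if (length(zz) < length(idx$n)) {
    stop(sprintf("need at least %d points inside the zone, got %d",
                 length(idx$n), length(zz)))
  }
  Z <- zernike_basis(r, th, order, zone_diameter)
  qrZ <- qr(Z)
  if (qrZ$rank < ncol(Z)) {
    stop("rank-deficient Zernike design matrix (clustered samples)")
  }
  Rd <- abs(diag(qr.R(qrZ)))
  cond <- max(Rd) / min(Rd)
  if (cond > max_condition) {
    stop(sprintf("ill-conditioned Zernike design (condition number %.3g)", cond))
  }
  coef <- qr.coef(qrZ, zz)
  res <- zz - drop(Z %*% coef)
  structure(list(coefficients = coef, n = idx$n, m = idx$m,
                 zone_diameter = zone_diameter, normalization = "OSA/ANSI unit-RMS",
                 order = order, rms = sqrt(mean(res^2))),
            class = "zernike_surface")
}

#' Evaluate a Zernike surface
#'
#' @param surface a `zernike_surface`.
#' @param x,y evaluation points, mm.
#' @param deriv if `TRUE` return a list with `z`, `zx`, `zy` (slopes per mm).
#' @export
eval_zernike <- function(surface, x, y, deriv = FALSE) {
  stopifnot(inherits(surface, "zernike_surface"))
  r <- sqrt(x^2 + y^2); th <- atan2(y, x)
  B <- zernike_basis(r, th, surface$order, surface$zone_diameter, deriv = deriv)
  if (!deriv) return(drop(B %*% surface$coefficients))
  list(z  = drop(B$Z %*% surface$coefficients),
       zx = drop(B$Zx %*% surface$coefficients),
       zy = drop(B$Zy %*% surface$coefficients))
}

#' Construct a Zernike surface from a coefficient vector
#' @param coefficients numeric vector in OSA ordering (length must match the
#'   number of terms of `order`), mm.
#' @inheritParams fit_zernike
#' @export
zernike_surface <- function(coefficients, order = 12, zone_diameter = 8) {
  idx <- zernike_index_table(order)
  stopifnot(length(coefficients) == length(idx$n))
  structure(list(coefficients = as.numeric(coefficients), n = idx$n, m = idx$m,
                 zone_diameter = zone_diameter, normalization = "OSA/ANSI unit-RMS",
                 order = order, rms = 0),
            class = "zernike_surface")
}

#' @export
print.zernike_surface <- function(x, ...) {
  cat(sprintf("Zernike surface: order %d (%d terms), zone %.1f mm, %s\n",
              x$order, length(x$coefficients), x$zone_diameter, x$normalization))
  cat(sprintf("  fit residual RMS: %.4g um\n", x$rms * 1000))
  invisible(x)
}

#' Zernike fit with automatic order reduction
#'
#' As [fit_zernike()], but reduces the order (in steps of 2, down to 4) when
#' the sampling cannot support the requested order (rank deficiency or
#' ill conditioning) -- e.g. surface nodes of a coarse mesh with few distinct
#' meridians.
#' @inheritParams fit_zernike
#' @export
fit_zernike_auto <- function(x, y, z, order = 12, zone_diameter = 8,
                             max_condition = 1e8) {
  for (o in seq(order, 4, by = -2)) {
    res <- tryCatch(fit_zernike(x, y, z, o, zone_diameter, max_condition),
                    error = function(e) e)
    if (!inherits(res, "error")) return(res)
  }
  stop(res)
}
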