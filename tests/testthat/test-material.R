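table1 <- material_params()

test_that("fiber distribution is a normalized angular density everywhere", {
  fd <- fiber_distribution()
  th_dense <- (seq_len(20000) - 0.5) * pi / 20000
  for (pt in list(c(0, 0, 0), c(2, 1, 0), c(-4.2, 0.5, 0), c(0, 4.6, 0))) {
    for (depth in c(0, 0.5, 1)) {
      w <- fiber_weight(fd, pt, depth, th_dense)
      expect_true(all(w >= 0))
      expect_lt(abs(mean(w) - 1), 1e-8)   # (1/pi) integral Phi = 1
    }
  }
  expect_equal(fiber_weight(fiber_distribution("uniform"), c(0, 0, 0), 0.5,
                            th_dense[1:5]), rep(1, 5))
})

test_that("central distribution peaks on the orthogonal meridians", {
  fd <- fiber_distribution()
  th <- seq(0, pi, length.out = 361)[-361]
  w <- fiber_weight(fd, c(0, 0, 0), 0.8, th)
  peaks <- th[w > max(w) * 0.999]
  expect_true(all(pmin(abs(peaks - 0), abs(peaks - pi / 2),
                       abs(peaks - pi)) < 0.02))
  # near the limbus the peak turns circumferential
  wl <- fiber_weight(fd, c(4.6, 0, 0), 0.8, th)
  expect_lt(abs(th[which.max(wl)] - pi / 2), 0.02)  # tangent at (4.6, 0)
})

test_that("energy vanishes exactly at the reference and under rotation", {
  expect_equal(strain_energy(diag(3), table1), 0)
  th <- 0.7
  Q <- matrix(c(cos(th), -sin(th), 0, sin(th), cos(th), 0, 0, 0, 1), 3,
              byrow = TRUE)
  expect_lt(abs(strain_energy(Q, table1)), 1e-14)
  expect_lt(max(abs(pk2_stress(diag(3), table1))), 1e-14)
  expect_error(strain_energy(diag(c(1, 1, -1)), table1), "det F")
})

test_that("angular quadrature converges spectrally and matches a dense oracle", {
  F <- diag(c(1.05, 1.05, 1 / 1.05^2))
  fd <- fiber_distribution()
  W32 <- strain_energy(F, table1, fd, point = c(1, 0.5, 0), n_theta = 32)
  W64 <- strain_energy(F, table1, fd, point = c(1, 0.5, 0), n_theta = 64)
  W512 <- strain_energy(F, table1, fd, point = c(1, 0.5, 0), n_theta = 512)
  expect_lt(abs(W64 / W32 - 1), 1e-8)
  expect_lt(abs(W32 / W512 - 1), 1e-8)
})

test_that("stress and tangent are consistent with the energy by finite differences", {
  set.seed(10)
  fd <- fiber_distribution()
  sqrtm <- function(C) {
    e <- eigen(C); e$vectors %*% diag(sqrt(e$values)) %*% t(e$vectors)
  }
  for (k in 1:10) {
    F <- diag(c(1.03, 1.03, 0.98)) + matrix(rnorm(9, 0, 0.005), 3)
    if (det(F) <= 0) next
    C <- crossprod(F)
    S <- pk2_stress(F, table1, fd)
    h <- 1e-6
    Sfd <- matrix(0, 3, 3)
    for (i in 1:3) for (j in 1:3) {
      dC <- matrix(0, 3, 3); dC[i, j] <- dC[i, j] + h / 2
      dC[j, i] <- dC[j, i] + h / 2
      Sfd[i, j] <- (strain_energy(sqrtm(C + dC), table1, fd) -
                      strain_energy(sqrtm(C - dC), table1, fd)) / h
    }
    expect_lt(max(abs(S - Sfd)) / max(abs(S)), 1e-6)
  }
  # tangent vs finite differences of the stress, at 3 states; the base is a
  # biaxial-tension state so no fiber direction sits on the tension-only
  # switch (where the tangent is legitimately discontinuous)
  for (k in 1:3) {
    F <- diag(c(1.03, 1.03, 0.98)) + matrix(rnorm(9, 0, 0.002), 3)
    if (det(F) <= 0) next
    C <- crossprod(F)
    CC <- material_tangent(F, table1, fd)
    dE <- matrix(rnorm(9), 3); dE <- (dE + t(dE)) / 2
    h <- 1e-6
    # dS = CC : dE with dC = 2 dE, so step C by 2h dE
    dS_fd <- (pk2_stress(sqrtm(C + 2 * h * dE), table1, fd) -
                pk2_stress(sqrtm(C - 2 * h * dE), table1, fd)) / (2 * h)
    dS <- matrix(0, 3, 3)
    for (i in 1:3) for (j in 1:3) dS[i, j] <- sum(CC[i, j, , ] * dE)
    expect_lt(max(abs(dS - dS_fd)) / max(abs(dS)), 1e-5)
  }
})

test_that("matrix-only uniaxial response approaches 2 C10 (lambda^2 - 1/lambda)", {
  mo <- matrix_only_params(penalty_bulk = 1e5)
  for (lam in c(1.01, 1.05, 1.1)) {
    r <- uniaxial_response(lam, mo)
    expect_equal(r$sigma_axial, uniaxial_cauchy_incompressible(lam),
                 tolerance = 1e-6)
  }
  # spot value: lambda = 1.1 gives 36.1 kPa
  expect_equal(1000 * uniaxial_cauchy_incompressible(1.1, 0.06), 36.1,
               tolerance = 0.05)
})

test_that("small-strain moduli recover 2 C10 in shear and 6 C10 uniaxial", {
  mo <- matrix_only_params(penalty_bulk = 1e5)
  # simple shear: sigma_12 / gamma -> mu = 2 C10
  g <- 1e-4
  F <- diag(3); F[1, 2] <- g
  sig <- cauchy_stress(F, mo)
  expect_equal(sig[1, 2] / g, 2 * 0.06, tolerance = 1e-3)
  # uniaxial slope d sigma / d lambda -> E = 6 C10 = 0.36 MPa
  dl <- 1e-4
  r <- uniaxial_response(1 + dl, mo)
  expect_equal(r$sigma_axial / dl, 6 * 0.06, tolerance = 1e-2)
})

test_that("fibers are tension-only", {
  # single fiber along x, axial compression: no fiber stress at all
  fs <- fiber_distribution("single", single_angle = 0)
  F <- diag(c(0.95, 1, 1))
  with_f <- pk2_stress(F, table1, fs)
  without <- pk2_stress(F, matrix_only_params(C10 = table1$C10,
                                              penalty_bulk = table1$penalty_bulk),
                        fs)
  expect_equal(with_f, without, tolerance = 1e-14)
  # under tension the fiber contributes
  Ft <- diag(c(1.05, 1, 1))
  expect_gt(pk2_stress(Ft, table1, fs)[1, 1],
            pk2_stress(Ft, matrix_only_params(C10 = table1$C10,
                                              penalty_bulk = table1$penalty_bulk),
                       fs)[1, 1] + 0.1)
})

test_that("uniform fiber distribution gives an in-plane isotropic response", {
  fd <- fiber_distribution("uniform")
  # all in-plane directions in tension, away from the tension-only switch
  # (the integrand kink at the switch would degrade the midpoint quadrature)
  F <- diag(c(1.04, 1.01, 0.95))
  th <- 0.41
  Q <- matrix(c(cos(th), -sin(th), 0, sin(th), cos(th), 0, 0, 0, 1), 3,
              byrow = TRUE)
  W1 <- strain_energy(F, table1, fd, n_theta = 256)
  W2 <- strain_energy(F %*% Q, table1, fd, n_theta = 256)  # in-plane rotation
  expect_lt(abs(W1 / W2 - 1), 1e-8)
})
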