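test_that("an unloaded body stays exactly at rest", {
  mesh <- build_template_mesh(radial_res = 10, circumferential_res = 16,
                              n_layers = 2)
  st <- solve_static(mesh, material_params(), load_case(iop_mmhg = 0))
  expect_true(all(st$u == 0))
  expect_lt(max(st$gp$von_mises), 1e-14)
})

test_that("single-element patch test reproduces the constitutive response", {
  # matrix-only against the constitutive uniaxial solve at the same penalty
  mo <- matrix_only_params()
  st <- uniaxial_patch_solve(1.1, mo)
  ref <- uniaxial_response(1.1, mo)
  sig <- st$gp$cauchy[, 1]
  expect_lt(diff(range(sig)), 1e-12)               # homogeneous state
  expect_equal(mean(sig), ref$sigma_axial, tolerance = 1e-8)
  # lateral stresses vanish
  expect_lt(max(abs(st$gp$cauchy[, 2:3])), 1e-10)
})

test_that("traction resultant, tangency and degenerate cases", {
  mesh <- build_template_mesh(radial_res = 12, circumferential_res = 24,
                              n_layers = 3)
  fp <- pterygium_footprint()
  fset <- footprint_faces(fp, mesh)
  tr <- apply_surface_traction(mesh, fset, 30, fp)
  # resultant equals 30 mN to machine precision
  f <- matrix(tr$force, ncol = 3, byrow = TRUE)
  expect_equal(sqrt(sum(colSums(f)^2)), 30e-3, tolerance = 1e-13)
  # per-face tangency: traction direction has no normal component
  fc <- mesh$anterior_faces[fset[tr$faces_used], 1:4, drop = FALSE]
  px <- matrix(mesh$nodes[fc, 1], nrow(fc), 4)
  py <- matrix(mesh$nodes[fc, 2], nrow(fc), 4)
  pz <- matrix(mesh$nodes[fc, 3], nrow(fc), 4)
  d1 <- cbind(px[, 3] - px[, 1], py[, 3] - py[, 1], pz[, 3] - pz[, 1])
  d2 <- cbind(px[, 4] - px[, 2], py[, 4] - py[, 2], pz[, 4] - pz[, 2])
  nrm <- cbind(d1[, 2] * d2[, 3] - d1[, 3] * d2[, 2],
               d1[, 3] * d2[, 1] - d1[, 1] * d2[, 3],
               d1[, 1] * d2[, 2] - d1[, 2] * d2[, 1])
  nrm <- nrm / sqrt(rowSums(nrm^2))
  expect_lt(max(abs(rowSums(tr$directions * nrm))), 1e-12)
  # zero force gives the zero vector
  tr0 <- apply_surface_traction(mesh, fset, 0, fp)
  expect_true(all(tr0$force == 0))
  expect_error(apply_surface_traction(mesh, integer(0), 30, fp), "empty")
})

test_that("the solution is objective under rigid rotation of the problem", {
  mesh <- build_template_mesh(radial_res = 10, circumferential_res = 16,
                              n_layers = 2)
  mo <- matrix_only_params()
  opts <- solver_options(n_steps = 2, tol_rel = 1e-11)
  st <- solve_static(mesh, mo, load_case(iop_mmhg = 15),
                     fd = fiber_distribution("uniform"), opts = opts)
  th <- 0.5
  Q <- matrix(c(1, 0, 0,
                0, cos(th), -sin(th),
                0, sin(th), cos(th)), 3, byrow = TRUE)
  mesh_r <- mesh
  mesh_r$nodes <- mesh$nodes %*% t(Q)
  st_r <- solve_static(mesh_r, mo, load_case(iop_mmhg = 15),
                       fd = fiber_distribution("uniform"), opts = opts)
  U <- matrix(st$u, ncol = 3, byrow = TRUE)
  Ur <- matrix(st_r$u, ncol = 3, byrow = TRUE)
  expect_lt(max(abs(Ur - U %*% t(Q))) / max(abs(U)), 1e-8)
})

test_that("internal and external virtual work balance at equilibrium", {
  lap <- cached_laplace_shell()
  st <- lap$pf$state
  mesh <- st$mesh
  fs <- corneafem:::fiber_setup(mesh, st$fd, st$opts$n_theta)
  asm <- corneafem:::fem_assemble(mesh$nodes, mesh$hex, st$u,
                                  corneafem:::matpar_vec(st$params),
                                  fs$e1, fs$e2, fs$phi, fs$thetas)
  pfaces <- corneafem:::orient_faces(mesh, mesh$posterior_faces)
  pres <- corneafem:::fem_pressure(mesh$nodes, pfaces[, 1:4], st$u,
                                   15 * MMHG_TO_MPA)
  fixed <- as.vector(outer(1:3, 3 * (mesh$rim_edge_nodes - 1), `+`))
  free <- setdiff(seq_len(length(st$u)), fixed)
  set.seed(1)
  dv <- rnorm(length(free), 0, 1e-3)
  ivw <- sum(asm$f_int[free] * dv)
  evw <- sum(pres$f_ext[free] * dv)
  expect_lt(abs(ivw - evw) / abs(evw), 1e-7)
})

test_that("stress-free recovery is the identity without load and self-consistent with it", {
  mesh <- build_template_mesh(radial_res = 10, circumferential_res = 16,
                              n_layers = 2)
  pf0 <- find_stress_free_config(mesh, material_params(), iop_mmhg = 0)
  expect_identical(pf0$mesh0$nodes, mesh$nodes)
  expect_equal(pf0$iterations, 0L)

  cases <- cached_prestress_cases()
  for (cs in cases) {
    err <- cs$pf$errors
    expect_lt(err[length(err)] * 1000, 1)          # < 1 um
    expect_true(all(diff(err) < 0))                # monotone decrease
    # re-inflating the recovered configuration reproduces the measurement
    gap <- cs$pf$state$nodes_def - cs$mesh$nodes
    expect_lt(max(sqrt(rowSums(gap^2))) * 1000, 1)
  }
})

test_that("follower pressure inflates the shell anteriorly with quadratic Newton tails", {
  lap <- cached_laplace_shell()
  st <- lap$pf$state
  # apex (node nearest the axis on the anterior surface) moves anteriorly
  ns <- st$mesh$ns; nl <- st$mesh$n_layers
  ant <- nl * ns + seq_len(ns)
  apex <- ant[which.min(st$mesh$section$tau)]
  expect_lt(st$nodes_def[apex, 3], st$mesh$nodes[apex, 3])
  # each load step ends far below the relative tolerance
  log <- st$convergence_log
  final <- tapply(log$rel, log$step, min)
  expect_true(all(final < 1e-8))
})
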