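test_that("default template mesh has desk-scale counts and valid Jacobians", {
  m <- build_template_mesh()
  expect_gt(nrow(m$hex), 2000)
  expect_lt(nrow(m$hex), 8000)
  q <- mesh_quality(m)
  expect_gt(q$min_jacobian, 0)
  expect_gt(q$min_scaled_jacobian, 0.3)
})

test_that("clinical-scale resolution reaches 35k+ elements with positive Jacobians", {
  m <- build_template_mesh(radial_res = 44, circumferential_res = 64,
                           n_layers = 10)
  expect_gte(nrow(m$hex), 35000)
  expect_gte(nrow(m$nodes), 35000)
  expect_gt(mesh_quality(m)$min_jacobian, 0)
})

test_that("mesh construction validates its resolution arguments", {
  expect_error(build_template_mesh(n_layers = 1), "n_layers")
  expect_error(build_template_mesh(circumferential_res = 4), "circumferential")
  expect_error(build_template_mesh(radial_res = 2), "radial_res")
})

test_that("rim geometry: limbus ring at the corneal diameter, 4-mm rim arc", {
  m <- build_template_mesh()
  lr <- sqrt(rowSums(m$nodes[m$limbus_nodes, 1:2]^2))
  expect_lt(max(abs(lr - m$params$corneal_diameter / 2)), 1e-9)
  expect_equal(m$params$a_max - m$params$a_cornea,
               m$params$rim_width / m$params$template_radius)
})

test_that("warping is interpolatory: boundary nodes land on the target surfaces", {
  m <- build_template_mesh(radial_res = 12, circumferential_res = 24,
                           n_layers = 3)
  s <- fit_zernike_pair(make_synthetic_cornea(toric_spec()),
                        zone_diameter = 9.5)
  mw <- warp_mesh(m, s$anterior, s$posterior)
  ns <- m$ns; nl <- m$n_layers
  corneal <- m$section$tau <= m$params$t_limbus + 1e-12
  ant <- mw$nodes[nl * ns + seq_len(ns), ][corneal, ]
  post <- mw$nodes[seq_len(ns), ][corneal, ]
  da <- eval_zernike(s$anterior, ant[, 1], ant[, 2]) - ant[, 3]
  dp <- eval_zernike(s$posterior, post[, 1], post[, 2]) - post[, 3]
  expect_lt(max(abs(da)) * 1000, 0.5)
  expect_lt(max(abs(dp)) * 1000, 0.5)
  expect_gt(mesh_quality(mw)$min_jacobian, 0)
})

test_that("warps compose exactly and invert back to the template", {
  m <- build_template_mesh(radial_res = 10, circumferential_res = 16,
                           n_layers = 2)
  s <- fit_zernike_pair(make_synthetic_cornea(toric_spec()),
                        zone_diameter = 9.5)
  ts <- template_surfaces(m)
  mw <- warp_mesh(m, s$anterior, s$posterior)
  # warping an already-warped mesh to a target equals warping the template
  direct <- warp_mesh(m, ts$anterior, ts$posterior)
  via <- warp_mesh(mw, ts$anterior, ts$posterior)
  expect_lt(max(abs(via$nodes - direct$nodes)), 1e-9)
  # and the template surfaces bring the nodes back to the template
  expect_lt(max(abs(via$nodes - m$nodes)) * 1000, 0.5)
})

test_that("identity warp to the template's own surfaces moves nothing", {
  m <- build_template_mesh(radial_res = 10, circumferential_res = 16,
                           n_layers = 2)
  ts <- template_surfaces(m)
  mi <- warp_mesh(m, ts$anterior, ts$posterior)
  expect_lt(max(abs(mi$nodes - m$nodes)) * 1000, 0.5)
})

test_that("an extreme warp that inverts elements is rejected", {
  m <- build_template_mesh(radial_res = 10, circumferential_res = 16,
                           n_layers = 2)
  s <- fit_zernike_pair(make_synthetic_cornea(synthetic_cornea_spec()),
                        zone_diameter = 9.5)
  # posterior target above the anterior target: negative thickness
  expect_error(warp_mesh(m, s$posterior, s$anterior), "distorted element")
})

test_that("mesh_quality flags an inverted cell", {
  m <- unit_hex_mesh()
  m$hex <- m$hex[, c(5:8, 1:4), drop = FALSE]   # flip handedness
  q <- mesh_quality(m)
  expect_lt(q$min_jacobian, 0)
  expect_equal(q$worst_element, 1)
})

test_that("corneal shell volume is near the analytic spherical-shell value", {
  m <- build_template_mesh(radial_res = 16, circumferential_res = 32,
                           n_layers = 4)
  q <- corneafem:::fiber_setup(m, fiber_distribution("uniform"), 4)
  gp <- corneafem:::fem_stress(m$nodes, m$hex, numeric(3 * nrow(m$nodes)),
                               corneafem:::matpar_vec(matrix_only_params()),
                               q$e1, q$e2, q$phi, q$thetas)
  corneal <- m$elem_region[gp$elem] == "cornea"
  vol <- sum(gp$weight[corneal])
  p <- m$params
  Rm <- p$template_radius - p$corneal_thickness / 2
  analytic <- 2 * pi * Rm^2 * (1 - cos(p$a_cornea)) * p$corneal_thickness
  expect_lt(abs(vol / analytic - 1), 0.1)
})

test_that("footprint faces select the nasal wedge", {
  m <- build_template_mesh(radial_res = 12, circumferential_res = 24,
                           n_layers = 3)
  fp <- pterygium_footprint(meridian_angle = 0, apex_distance = 2,
                            angular_width = 30)
  fset <- footprint_faces(fp, m)
  expect_gt(length(fset), 0)
  fc <- m$anterior_faces[fset, 1:4]
  cx <- rowMeans(matrix(m$nodes[fc, 1], length(fset), 4))
  expect_true(all(cx < 0))   # nasal = -x for a right eye
  expect_error(footprint_faces(pterygium_footprint(meridian_angle = 90,
                                                   apex_distance = 4.4,
                                                   angular_width = 1),
                               build_template_mesh(radial_res = 10,
                                                   circumferential_res = 16,
                                                   n_layers = 2)),
               "empty face set|does not intersect")
})
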