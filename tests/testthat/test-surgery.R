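test_that("region statistics: constant fields, partition identity, validation", {
  # homogeneous single-element state: sd = 0, mean = the value
  st <- uniaxial_patch_solve(1.05, matrix_only_params())
  rg <- region_stress_strain(st, region_central(radius = 10))
  expect_equal(rg$sd_stress_kPa, 0, tolerance = 1e-9)
  expect_equal(rg$mean_stress_kPa, 1000 * mean(st$gp$von_mises),
               tolerance = 1e-9)

  # disjoint layer regions recombine to the full-footprint mean
  sim <- cached_sphere_sim()
  fp <- simulation_config()$footprint
  full <- region_stress_strain(sim$states$post, region_footprint(fp, "full"))
  ant <- region_stress_strain(sim$states$post, region_footprint(fp, "anterior"))
  pos <- region_stress_strain(sim$states$post, region_footprint(fp, "posterior"))
  # middle layer = full minus the two surface layers
  vol_mid <- full$volume_mm3 - ant$volume_mm3 - pos$volume_mm3
  sum_mid <- full$mean_stress_kPa * full$volume_mm3 -
    ant$mean_stress_kPa * ant$volume_mm3 -
    pos$mean_stress_kPa * pos$volume_mm3
  recombined <- (ant$mean_stress_kPa * ant$volume_mm3 +
                   pos$mean_stress_kPa * pos$volume_mm3 + sum_mid) /
    full$volume_mm3
  expect_equal(recombined, full$mean_stress_kPa, tolerance = 1e-12)
  expect_gt(vol_mid, 0)

  expect_error(region_stress_strain(sim$states$post,
                                    region_central(radius = 1e-6)), "empty")
})

test_that("zero pulling force predicts zero change, reproducibly", {
  pair <- make_synthetic_cornea(sphere_spec())
  cfg <- fast_config(pulling_force_mN = 0)
  r1 <- simulate_treatment(pair, cfg)
  expect_identical(r1$states$pre$u, r1$states$post$u)
  expect_equal(r1$changes$delta_cylinder_D, 0, tolerance = 1e-10)
  expect_equal(r1$changes$delta_central_D, 0, tolerance = 1e-10)
  expect_equal(r1$changes$pachymetry_change_pct, 0, tolerance = 1e-8)
  # determinism: a fresh run gives bit-identical displacements
  r2 <- simulate_treatment(pair, cfg)
  expect_identical(r1$states$post$u, r2$states$post$u)
  expect_identical(rlang::hash(r1$changes), rlang::hash(r2$changes))
})

test_that("nasal traction induces cylinder, flattens the pulled meridian, spares pachymetry", {
  sim <- cached_sphere_sim()
  expect_gt(sim$changes$delta_cylinder_D, 0)
  expect_lt(sim$changes$delta_central_D, 0)          # central flattening
  # steep axis ends up orthogonal to the (horizontal) pull meridian
  expect_lt(abs(sim$predicted$astigmatism$axis_deg - 90), 15)
  # pulled-meridian zone curvature drops relative to the orthogonal meridian
  cm <- sim$predicted$curvature_map
  cm0 <- sim$preop$curvature_map
  horiz <- abs(cos(cm$grid$theta)) > cos(pi / 8)
  vert <- abs(sin(cm$grid$theta)) > cos(pi / 8)
  ann <- cm$grid$r >= 0.5 & cm$grid$r <= 2.5
  dpull <- mean(cm$values[ann, horiz]) - mean(cm0$values[ann, horiz])
  dorth <- mean(cm$values[ann, vert]) - mean(cm0$values[ann, vert])
  expect_lt(dpull, dorth)
  # anterior-surface stress under the footprint increases; pachymetry stable
  expect_gt(sim$regions$footprint_anterior$post$mean_stress_kPa,
            sim$regions$footprint_anterior$pre$mean_stress_kPa)
  expect_lt(abs(sim$changes$pachymetry_change_pct), 1)
})

test_that("preoperative indices reproduce the synthetic cornea", {
  sim <- cached_sphere_sim()
  # sphere R = 7.66 mm: 337.5/7.66 = 44.06 D everywhere
  expect_equal(sim$preop$central_D, 337.5 / 7.66, tolerance = 2e-3)
  expect_lt(sim$preop$astigmatism$cylinder, 0.01)
  expect_equal(sim$preop$pachymetry_central_um, 512, tolerance = 2)
})

test_that("induced cylinder grows with force through the clinical range, then saturates", {
  sim30 <- cached_sphere_sim()
  sim15 <- cached_sphere_sim_15()
  sim60 <- cached_sphere_sim_60()
  # ascending branch: half the clinical force gives strictly less cylinder
  expect_gt(sim15$delta_cylinder_D, 0)
  expect_gt(sim30$changes$delta_cylinder_D, sim15$delta_cylinder_D)
  # central flattening keeps growing with force even past the cylinder peak
  expect_lt(sim60$predicted$central_D, sim30$predicted$central_D)
})

test_that("axis differences wrap modulo 180 degrees", {
  expect_equal(corneafem:::axis_difference(179, 1), 2)
  expect_equal(corneafem:::axis_difference(0, 179), 1)
  expect_equal(corneafem:::axis_difference(90, 90), 0)
})

test_that("follow-up comparison against the prediction itself is null", {
  sim <- cached_sphere_sim()
  cfg <- simulation_config()
  observed <- elevation_pair_from_surfaces(
    sim$surfaces$predicted_anterior, sim$surfaces$predicted_posterior,
    polar_grid(diameter = 8, nr = 50, na = 72))
  cmp <- compare_to_followup(sim, observed, cfg)
  expect_lt(abs(cmp$delta_cylinder_D), 1e-6)
  expect_lt(abs(cmp$delta_central_D), 1e-6)
  expect_lt(max(abs(cmp$wavefront$difference_um)), 1e-4)
  # against the preop shape it recovers the simulated change
  obs_pre <- elevation_pair_from_surfaces(
    sim$surfaces$pre_anterior, sim$surfaces$pre_posterior,
    polar_grid(diameter = 8, nr = 50, na = 72))
  cmp2 <- compare_to_followup(sim, obs_pre, cfg)
  expect_equal(cmp2$delta_cylinder_D, sim$changes$delta_cylinder_D,
               tolerance = 1e-4)
  expect_error(compare_to_followup(sim,
                                   make_synthetic_cornea(sphere_spec(),
                                                         polar_grid(diameter = 6)),
                                   cfg),
               "analysis zone")
})
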