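#' End-to-end pterygium traction simulation
#'
#' Orchestrates the full treatment pipeline: tomography (elevation pair) ->
#' Zernike surfaces -> warped patient-specific mesh -> stress-free
#' configuration under IOP -> tangential limbus-ward traction on the
#' pterygium footprint -> clinical topography analytics and region-averaged
#' tissue stress/strain on the pre- and post-traction states.
#'
#' @name surgery
NULL

#' Simulation configuration
#'
#' @param params a [material_params()] (human-cornea constants by default).
#' @param fd a [fiber_distribution()].
#' @param iop_mmhg intraocular pressure, mmHg.
#' @param pulling_force_mN total tangential pull of the retracting pterygium,
#'   mN (the calibrated clinical value is 30 mN).
#' @param footprint a [pterygium_footprint()].
#' @param astig_annulus astigmatism annulus radii, mm (`c(0.5, 2.5)`;
#'   `c(0.5, 2.0)` is the alternative clinical convention).
#' @param central_radius central-keratometry disk radius, mm.
#' @param paracentral paracentral annulus radii, mm.
#' @param mesh_radial,mesh_circ,mesh_layers template mesh resolution.
#' @param zernike_order expansion order for all surface fits.
#' @param analysis_zone clinical analysis zone diameter, mm.
#' @param warp_zone zone diameter for the mesh-warping surface fits, mm
#'   (must cover the corneal mesh footprint).
#' @param opts [solver_options()].
#' @param prestress_tol stress-free recovery tolerance, mm.
#' @param seed integer seed recorded in the provenance.
#' @export
simulation_config <- function(params = material_params(),
                              fd = fiber_distribution(),
                              iop_mmhg = 15, pulling_force_mN = 30,
                              footprint = pterygium_footprint(),
                              astig_annulus = c(0.5, 2.5),
                              central_radius = 2.0,
                              paracentral = c(2.0, 3.5),
                              mesh_radial = 14, mesh_circ = 24,
                              mesh_layers = 3,
                              zernike_order = 12, analysis_zone = 8,
                              warp_zone = 9.5,
                              opts = solver_options(n_steps = 3),
                              prestress_tol = 1e-3, seed = 1L) {
  stopifnot(pulling_force_mN >= 0, iop_mmhg >= 0,
            inherits(footprint, "pterygium_footprint"))
  structure(list(params = params, fd = fd, iop_mmhg = iop_mmhg,
                 pulling_force_mN = pulling_force_mN, footprint = footprint,
                 astig_annulus = astig_annulus,
                 central_radius = central_radius, paracentral = paracentral,
                 mesh_radial = mesh_radial, mesh_circ = mesh_circ,
                 mesh_layers = mesh_layers, zernike_order = zernike_order,
                 analysis_zone = analysis_zone, warp_zone = warp_zone,
                 opts = opts, prestress_tol = prestress_tol,
                 seed = as.integer(seed)),
            class = "simulation_config")
}

#' Fit the corneal surfaces of a deformed state
#'
#' Least-squares Zernike fit to the deformed anterior/posterior boundary
#' nodes of the corneal region.
#'
#' @param state a `deformed_state`.
#' @param which `"anterior"` or `"posterior"`.
#' @param order,zone_diameter fit parameters.
#' @export
surface_from_state <- function(state, which = c("anterior", "posterior"),
                               order = 12, zone_diameter = 8) {
  which <- match.arg(which)
  mesh <- state$mesh
  ns <- mesh$ns; nl <- mesh$n_layers
  idx <- if (which == "anterior") nl * ns + seq_len(ns) else seq_len(ns)
  corneal <- mesh$section$tau <= mesh$params$t_limbus + 1e-12
  nd <- state$nodes_def[idx, , drop = FALSE][corneal, , drop = FALSE]
  fit_zernike_auto(nd[, 1], nd[, 2], nd[, 3], order = order,
                   zone_diameter = zone_diameter)
}

## clinical index bundle from a fitted anterior (+ posterior) surface
topography_indices <- function(ant, post, config) {
  cmap <- sagittal_curvature(ant)
  ast <- astigmatism(cmap, config$astig_annulus)
  pach <- pachymetry(ant, post,
                     grid = polar_grid(diameter = 5, nr = 24, na = 48))
  list(curvature_map = cmap,
       central_D = zone_mean_curvature(cmap, c(0, config$central_radius)),
       paracentral_D = zone_mean_curvature(cmap, config$paracentral),
       astigmatism = ast,
       pachymetry_central_um = mean(pach$thickness_um[1, ], na.rm = TRUE),
       bfs = best_fit_sphere(ant, zone_diameter = config$analysis_zone),
       wavefront = wavefront_coefficients(ant))
}

#' Region-averaged stress and strain
#'
#' Volume-weighted mean and standard deviation (over reference-volume Gauss
#' weights) of the scalar stress measure (von Mises Cauchy stress, kPa) and
#' scalar strain measure (maximum principal Green-Lagrange strain) over a
#' mesh region.
#'
#' @param state a `deformed_state`.
#' @param region one of `region_central(radius)`,
#'   `region_footprint(fp, layer)`.
#' @return list: `mean_stress_kPa`, `sd_stress_kPa`, `mean_strain`,
#'   `sd_strain`, `n_gp`, `volume_mm3`.
#' @export
region_stress_strain <- function(state, region) {
  stopifnot(inherits(state, "deformed_state"))
  sel <- region_select(state, region)
  if (!any(sel)) stop(sprintf("empty region '%s' on this mesh", region$name))
  w <- state$gp$weight[sel]
  wm <- function(x) sum(w * x) / sum(w)
  wsd <- function(x) sqrt(sum(w * (x - wm(x))^2) / sum(w))
  s <- 1000 * state$gp$von_mises[sel]
  e <- state$gp$strain_max[sel]
  list(mean_stress_kPa = wm(s), sd_stress_kPa = wsd(s),
       mean_strain = wm(e), sd_strain = wsd(e),
       n_gp = sum(sel), volume_mm3 = sum(w))
}

#' @rdname region_stress_strain
#' @param radius central-zone radius, mm (1.5 = the clinical 3.0-mm zone).
#' @export
region_central <- function(radius = 1.5) {
  list(type = "central", radius = radius,
       name = sprintf("central %.1f-mm zone", 2 * radius))
}

#' @rdname region_stress_strain
#' @param fp a [pterygium_footprint()].
#' @param layer `"anterior"`, `"posterior"` (outermost/innermost element
#'   layer under the footprint) or `"full"` (full thickness).
#' @export
region_footprint <- function(fp, layer = c("full", "anterior", "posterior")) {
  layer <- match.arg(layer)
  list(type = "footprint", fp = fp, layer = layer,
       name = sprintf("footprint (%s)", layer))
}

region_select <- function(state, region) {
  mesh <- state$mesh
  gp <- state$gp
  if (region$type == "central") {
    return(sqrt(gp$gp_x[, 1]^2 + gp$gp_x[, 2]^2) < region$radius)
  }
  if (region$type == "footprint") {
    fp <- region$fp
    r <- sqrt(gp$gp_x[, 1]^2 + gp$gp_x[, 2]^2)
    th <- atan2(gp$gp_x[, 2], gp$gp_x[, 1])
    half <- fp$angular_width / 2 * pi / 180
    sel <- r >= fp$apex_distance & r <= mesh$params$corneal_diameter / 2 &
      abs(angdiff(th, footprint_direction(fp))) <= half
    lay <- mesh$elem_layer[gp$elem]
    if (region$layer == "anterior") sel <- sel & lay == mesh$n_layers
    if (region$layer == "posterior") sel <- sel & lay == 1
    return(sel)
  }
  stop("unknown region type")
}

#' Simulate the pterygium traction treatment
#'
#' Runs the three-stage pipeline on a preoperative elevation pair: (i) warp
#' the spherical template mesh to the patient's Zernike surfaces; (ii)
#' recover the stress-free configuration under the IOP; (iii) apply the
#' tangential limbus-ward pulling force on the pterygium footprint and solve
#' the treated equilibrium. Clinical maps and indices are computed from the
#' (IOP-loaded) preoperative and (IOP + traction) predicted states.
#'
#' @param preop an `elevation_pair` covering the analysis zone.
#' @param config a [simulation_config()].
#' @return a `simulation_result` with elements `preop`/`predicted` (index
#'   bundles), `changes`, `regions` (stress/strain summaries pre/post),
#'   `states`, `mesh0`, `prestress`, and `provenance`.
#' @export
simulate_treatment <- function(preop, config = simulation_config()) {
  stopifnot(inherits(preop, "elevation_pair"),
            inherits(config, "simulation_config"))
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop(sprintf("stage '%s' failed: %s", name, conditionMessage(e)),
           call. = FALSE)
    })
  }
  surfs <- stage("fit_zernike", fit_zernike_pair(
    preop, order = config$zernike_order, zone_diameter = config$warp_zone))
  template <- stage("template_mesh", build_template_mesh(
    radial_res = config$mesh_radial, circumferential_res = config$mesh_circ,
    n_layers = config$mesh_layers))
  mesh <- stage("warp_mesh", warp_mesh(template, surfs$anterior,
                                       surfs$posterior))
  pf <- stage("prestress", find_stress_free_config(
    mesh, config$params, iop_mmhg = config$iop_mmhg, fd = config$fd,
    opts = config$opts, tol = config$prestress_tol))
  pre_state <- pf$state

  faces <- stage("footprint", footprint_faces(config$footprint, pf$mesh0))
  trac <- stage("traction", apply_surface_traction(
    pf$mesh0, faces, config$pulling_force_mN, config$footprint))
  post_state <- stage("traction_solve", solve_static(
    pf$mesh0, config$params,
    load_case(iop_mmhg = config$iop_mmhg, traction = trac$force),
    fd = config$fd, opts = config$opts, u_init = pre_state$u))

  zo <- config$zernike_order; az <- config$analysis_zone
  pre_ant <- surface_from_state(pre_state, "anterior", zo, az)
  pre_post <- surface_from_state(pre_state, "posterior", zo, az)
  prd_ant <- surface_from_state(post_state, "anterior", zo, az)
  prd_post <- surface_from_state(post_state, "posterior", zo, az)
  pre_ix <- topography_indices(pre_ant, pre_post, config)
  prd_ix <- topography_indices(prd_ant, prd_post, config)

  regions <- list(
    central = list(pre = region_stress_strain(pre_state, region_central()),
                   post = region_stress_strain(post_state, region_central())),
    footprint_full = list(
      pre = region_stress_strain(pre_state,
                                 region_footprint(config$footprint, "full")),
      post = region_stress_strain(post_state,
                                  region_footprint(config$footprint, "full"))),
    footprint_anterior = list(
      pre = region_stress_strain(pre_state,
                                 region_footprint(config$footprint, "anterior")),
      post = region_stress_strain(post_state,
                                  region_footprint(config$footprint, "anterior"))),
    footprint_posterior = list(
      pre = region_stress_strain(pre_state,
                                 region_footprint(config$footprint, "posterior")),
      post = region_stress_strain(post_state,
                                  region_footprint(config$footprint, "posterior"))))

  changes <- list(
    delta_cylinder_D = prd_ix$astigmatism$cylinder - pre_ix$astigmatism$cylinder,
    delta_central_D = prd_ix$central_D - pre_ix$central_D,
    delta_paracentral_D = prd_ix$paracentral_D - pre_ix$paracentral_D,
    axis_change_deg = axis_difference(prd_ix$astigmatism$axis_deg,
                                      pre_ix$astigmatism$axis_deg),
    pachymetry_change_pct = 100 *
      (prd_ix$pachymetry_central_um / pre_ix$pachymetry_central_um - 1),
    stress_change_pct = lapply(regions, function(rg) {
      100 * (rg$post$mean_stress_kPa / rg$pre$mean_stress_kPa - 1)
    }))

  structure(list(
    preop = pre_ix, predicted = prd_ix, changes = changes, regions = regions,
    states = list(pre = pre_state, post = post_state),
    mesh0 = pf$mesh0, prestress = pf[c("errors", "iterations")],
    surfaces = list(pre_anterior = pre_ant, pre_posterior = pre_post,
                    predicted_anterior = prd_ant,
                    predicted_posterior = prd_post),
    traction = trac[c("resultant_N", "n_faces", "excluded")],
    provenance = list(config_hash = rlang::hash(config),
                      package_version =
                        as.character(utils::packageVersion("corneafem")),
                      seed = config$seed)),
    class = "simulation_result")
}

#' @export
print.simulation_result <- function(x, ...) {
  cat("Pterygium traction simulation\n")
  cat(sprintf("  preop:     K central %.2f D, paracentral %.2f D, cyl %.2f D @ %.0f deg\n",
              x$preop$central_D, x$preop$paracentral_D,
              x$preop$astigmatism$cylinder, x$preop$astigmatism$axis_deg))
  cat(sprintf("  predicted: K central %.2f D, paracentral %.2f D, cyl %.2f D @ %.0f deg\n",
              x$predicted$central_D, x$predicted$paracentral_D,
              x$predicted$astigmatism$cylinder,
              x$predicted$astigmatism$axis_deg))
  cat(sprintf("  delta cyl %+0.2f D, delta central %+0.2f D, pachymetry %+0.2f%%\n",
              x$changes$delta_cylinder_D, x$changes$delta_central_D,
              x$changes$pachymetry_change_pct))
  rg <- x$regions
  cat(sprintf("  stress central 3-mm: %.1f -> %.1f kPa; footprint anterior: %.1f -> %.1f kPa (%+.1f%%)\n",
              rg$central$pre$mean_stress_kPa, rg$central$post$mean_stress_kPa,
              rg$footprint_anterior$pre$mean_stress_kPa,
              rg$footprint_anterior$post$mean_stress_kPa,
              x$changes$stress_change_pct$footprint_anterior))
  invisible(x)
}

axis_difference <- function(a, b) {
  d <- abs(a - b) %% 180
  min(d, 180 - d)
}

#' Compare a simulation prediction to follow-up tomography
#'
#' Computes the clinical indices of an observed (e.g. postoperative
#' follow-up) elevation pair with the same conventions as the simulation and
#' reports the differences: curvature and cylinder deltas, axis difference
#' (mod 180 degrees), and per-index wavefront differences with percentage
#' errors.
#'
#' @param result a `simulation_result`.
#' @param observed an `elevation_pair`.
#' @param config the [simulation_config()] used (analysis conventions).
#' @export
compare_to_followup <- function(result, observed,
                                config = simulation_config()) {
  stopifnot(inherits(result, "simulation_result"),
            inherits(observed, "elevation_pair"))
  if (observed$grid$diameter < config$analysis_zone) {
    stop("observed map does not cover the analysis zone")
  }
  obs_s <- fit_zernike_pair(observed, order = config$zernike_order,
                            zone_diameter = config$analysis_zone)
  obs <- topography_indices(obs_s$anterior, obs_s$posterior, config)
  prd <- result$predicted
  wf_names <- c("spherical", "astigmatic", "coma", "trefoil", "tetrafoil",
                "rms_hoa")
  wf_pred <- unlist(prd$wavefront[wf_names])
  wf_obs <- unlist(obs$wavefront[wf_names])
  list(
    delta_cylinder_D = prd$astigmatism$cylinder - obs$astigmatism$cylinder,
    delta_central_D = prd$central_D - obs$central_D,
    delta_paracentral_D = prd$paracentral_D - obs$paracentral_D,
    axis_difference_deg = axis_difference(prd$astigmatism$axis_deg,
                                          obs$astigmatism$axis_deg),
    wavefront = data.frame(
      index = wf_names, predicted_um = wf_pred, observed_um = wf_obs,
      difference_um = wf_pred - wf_obs,
      percent_error = 100 * (wf_pred - wf_obs) / ifelse(wf_obs == 0, NA,
                                                        wf_obs),
      row.names = NULL),
    observed = obs)
}

#' Re-run the traction stage of a simulation at a different force
#'
#' Reuses the recovered stress-free configuration of an existing result and
#' solves the traction stage only (e.g. for dose-response studies).
#'
#' @param result a `simulation_result`.
#' @param config its [simulation_config()].
#' @param pulling_force_mN new total force, mN.
#' @return list with the new `state`, index bundle `predicted`, and
#'   `delta_cylinder_D` relative to the result's preop state.
#' @export
rerun_traction <- function(result, config, pulling_force_mN) {
  mesh0 <- result$mesh0
  faces <- footprint_faces(config$footprint, mesh0)
  trac <- apply_surface_traction(mesh0, faces, pulling_force_mN,
                                 config$footprint)
  st <- solve_static(mesh0, config$params,
                     load_case(iop_mmhg = config$iop_mmhg,
                               traction = trac$force),
                     fd = config$fd, opts = config$opts,
                     u_init = result$states$post$u)
  ant <- surface_from_state(st, "anterior", config$zernike_order,
                            config$analysis_zone)
  post <- surface_from_state(st, "posterior", config$zernike_order,
                             config$analysis_zone)
  ix <- topography_indices(ant, post, config)
  list(state = st, predicted = ix,
       delta_cylinder_D = ix$astigmatism$cylinder -
         result$preop$astigmatism$cylinder)
}
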