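vnorm_test <- function(v) sqrt(sum(v^2))

test_that("generated femur is watertight with exact noise-free head geometry", {
  fem <- fx_femur_clean()
  v <- mesh_validate(fem$mesh)
  expect_true(v$watertight)
  expect_true(v$outward)
  expect_identical(v$n_degenerate_faces, 0L)
  expect_equal(v$genus, 0)
  # head vertices sit exactly on the truth sphere (outside the fovea dimple)
  r <- sqrt(rowSums(sweep(fem$mesh$vertices, 2, fem$truth$head_center)^2))
  on_sphere <- abs(r - fem$truth$head_radius) < 1e-9
  expect_gt(mean(on_sphere), 0.3)
  hs <- fit_head_sphere(fem$mesh, seed = 11)
  expect_equal(hs$radius, 24, tolerance = 1e-6)
  expect_lt(vnorm_test(hs$center - fem$truth$head_center), 1e-6)
})

test_that("identical parameters and seed give bit-identical meshes", {
  a <- generate_femur(femur_params(seed = 9, target_edge = 2))
  b <- generate_femur(femur_params(seed = 9, target_edge = 2))
  expect_identical(a$mesh$vertices, b$mesh$vertices)
  expect_identical(a$mesh$faces, b$mesh$faces)
  c_ <- generate_femur(femur_params(seed = 10, target_edge = 2))
  expect_false(identical(a$mesh$vertices, c_$mesh$vertices))
})

test_that("CCD angle and anteversion are realized exactly over random draws", {
  pool <- list(ccd = c(120, 125, 127, 130, 135), av = c(0, 5, 10, 15, 20))
  for (k in 1:20) {
    ccd <- pool$ccd[(k %% 5) + 1]
    av <- pool$av[((k + 2) %% 5) + 1]
    side <- if (k %% 2 == 0) "left" else "right"
    fem <- generate_femur(femur_params(ccd_angle = ccd, anteversion = av,
                                       side = side, seed = 100 + k,
                                       noise_sd = 0, target_edge = 2.5))
    got <- angle_between(fem$truth$neck_axis$direction,
                         fem$truth$shaft_axis$direction)
    expect_equal(got, 180 - ccd, tolerance = 0.01)
    # anteversion: axial-plane angle between neck projection and medial
    fr <- fem$truth$frame
    proj <- project_onto_plane(fem$truth$neck_axis$direction, fr$superior)
    expect_equal(angle_between(proj, fr$medial), av, tolerance = 0.01)
  }
})

test_that("impossible parameter combinations raise generation errors", {
  expect_error(femur_params(neck_radii = c(23, 20)),
               class = "sraguide_geometry_error")
  expect_error(femur_params(bend_radius = 10),
               class = "sraguide_geometry_error")
  expect_error(femur_params(cartilage_thickness = 30),
               class = "sraguide_invalid_input")
  expect_error(femur_params(head_radius = -1),
               class = "sraguide_invalid_input")
})

test_that("osteophytes displace the surface without touching the truth", {
  fem <- generate_femur(femur_params(n_osteophytes = 3, noise_sd = 0,
                                     seed = 5, target_edge = 2))
  base <- generate_femur(femur_params(n_osteophytes = 0, noise_sd = 0,
                                      seed = 5, target_edge = 2))
  expect_true(mesh_validate(fem$mesh)$watertight)
  expect_identical(fem$truth$head_center, base$truth$head_center)
  expect_gt(max(abs(fem$mesh$vertices - base$mesh$vertices)), 0.4)
})

test_that("simulated post-op scan carries the injected deviation exactly", {
  fem <- fx_femur_clean()
  plan <- fx_plan()
  scan <- simulate_postop_scan(fem, plan, angular_error = 0, entry_shift = c(0, 0),
                               pose = identity_transform(), noise_sd = 0,
                               seed = 3, voxel = 0.6)
  expect_equal(angle_between(scan$achieved_axis_truth$direction,
                             plan$axis$direction), 0, tolerance = 1e-9)
  scan2 <- simulate_postop_scan(fem, plan, angular_error = 2.9,
                                error_plane_azimuth = 120, entry_shift = c(1.5, -1),
                                pose = identity_transform(), noise_sd = 0,
                                seed = 3, voxel = 0.6)
  expect_equal(angle_between(scan2$achieved_axis_truth$direction,
                             plan$axis$direction), 2.9, tolerance = 1e-9)
  # the channel makes the resected head a genus-1 solid
  v <- mesh_validate(scan2$head_mesh)
  expect_true(v$watertight)
  expect_equal(v$genus, 1)
  expect_gt(scan2$partial_overlap_fraction, 0.5)
  expect_error(simulate_postop_scan(fem, plan, channel_radius = 14),
               class = "sraguide_geometry_error")
})
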