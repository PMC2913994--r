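test_that("Procrustes solves exact correspondences to machine precision", {
  P <- random_units(300, 41) * 20
  Tk <- rigid_transform(rotation_about(c(1, -1, 2), 37), c(4, -6, 1))
  Q <- apply_transform(Tk, P)
  pr <- procrustes_rigid(P, Q)
  expect_lt(max(abs(pr$rotation - Tk$rotation)), 1e-12)
  expect_lt(max(abs(pr$translation - Tk$translation)), 1e-10)
})

test_that("ICP on identical points converges immediately to the identity", {
  fem <- fx_femur_clean()
  pts <- mesh_sample_surface(fem$mesh, 500, seed = 8)
  icp <- icp_register(pts, fem$mesh, init = identity_transform())
  expect_true(icp$converged)
  expect_lte(icp$n_iterations, 2L)
  expect_lt(icp$rmse, 1e-6)
  expect_lt(sraguide:::rotation_angle(icp$transform$rotation), 1e-6)
})

test_that("ICP recovers a known displacement with monotone error", {
  fem <- fx_femur_clean()
  pts <- mesh_sample_surface(fem$mesh, 1000, seed = 9)
  Tk <- rigid_transform(rotation_about(c(1, 2, -1), 10), c(3, -2, 2.5))
  icp <- icp_register(apply_transform(Tk, pts), fem$mesh,
                      init = identity_transform(), max_iter = 100, tol = 1e-9)
  Tinv <- invert_transform(Tk)
  rot_err <- sraguide:::rotation_angle(t(Tinv$rotation) %*% icp$transform$rotation)
  expect_lt(rot_err, 0.05)
  expect_lt(sqrt(sum((icp$transform$translation - Tinv$translation)^2)), 0.05)
  expect_true(all(diff(icp$trace) <= 1e-9))
  expect_lt(icp$rmse, 1e-3)
  expect_error(icp_register(pts[1:50, ], fem$mesh),
               class = "sraguide_registration_error")
})

test_that("trimmed ICP tolerates partial overlap and noise", {
  fem <- fx_femur_clean()
  # 60% crop keeping the mid band (head base, neck, bend, upper shaft);
  # trimmed ICP re-admits trimmed points only gradually, so the iteration
  # budget must allow the long convergence tail
  ok <- vapply(1:5, function(k) {
    old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
    on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
    set.seed(300 + k)
    pts <- mesh_sample_surface(fem$mesh, 2500, seed = 300 + k)
    keep <- pts[, 3] > quantile(pts[, 3], 0.2) & pts[, 3] < quantile(pts[, 3], 0.8)
    pts <- pts[keep, ] + matrix(rnorm(3 * sum(keep), 0, 0.1), sum(keep), 3)
    Tk <- rigid_transform(rotation_about(rnorm(3), 6), runif(3, -4, 4))
    icp <- icp_register(apply_transform(Tk, pts), fem$mesh,
                        init = identity_transform(), max_iter = 400,
                        trim_fraction = 0.3, tol = 1e-10)
    Tinv <- invert_transform(Tk)
    rot_err <- sraguide:::rotation_angle(t(Tinv$rotation) %*% icp$transform$rotation)
    tr_err <- sqrt(sum((icp$transform$translation - Tinv$translation)^2))
    rot_err < 0.3 && tr_err < 0.3
  }, logical(1))
  expect_true(all(ok))
})

test_that("cylinder fit recovers the drill axis at spec accuracy", {
  ax <- sraguide:::unitize(c(1, 0.5, 2))
  e1 <- sraguide:::unitize(project_onto_plane(c(1, 0, 0), ax))
  e2 <- sraguide:::cross3(ax, e1)
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(77)
  tt <- runif(500, -20, 20)
  ph <- runif(500, 0, 2 * pi)
  cyl <- sweep(outer(tt, ax) + 1.6 * (outer(cos(ph), e1) + outer(sin(ph), e2)),
               2, c(5, 6, 7), "+")
  f0 <- fit_drill_axis(cyl, 1.6)
  expect_lt(angle_between(f0$direction, ax), 1e-4)
  expect_equal(attr(f0, "radius"), 1.6, tolerance = 1e-6)
  # noisy walls over seeds
  errs <- vapply(1:20, function(k) {
    set.seed(900 + k)
    noisy <- cyl + matrix(rnorm(1500, 0, 0.05), 500, 3)
    angle_between(fit_drill_axis(noisy, 1.6)$direction, ax)
  }, numeric(1))
  expect_lt(max(errs), 0.1)
  # half-cylinder coverage (channel truncated by the osteotomy)
  half <- ph < pi
  set.seed(55)
  hpts <- cyl[half, ] + matrix(rnorm(3 * sum(half), 0, 0.05), sum(half), 3)
  expect_lt(angle_between(fit_drill_axis(hpts, 1.6)$direction, ax), 0.3)
  # sign alignment and error paths
  fa <- fit_drill_axis(cyl, 1.6, align_dir = -ax)
  expect_lt(sum(fa$direction * ax), 0)
  expect_error(fit_drill_axis(cyl[1:20, ], 1.6), class = "sraguide_fit_error")
  blob <- matrix(rnorm(300) * 10, 100, 3)
  expect_error(fit_drill_axis(blob, 1.6), class = "sraguide_fit_error")
})

test_that("deviation record reproduces a constructed maximal case", {
  fem <- fx_femur_clean()
  plan <- fx_plan()
  # identity: all zeros
  rec0 <- compute_deviation(plan, plan$axis, head_mesh = fem$mesh)
  expect_equal(rec0$true3d_angle, 0, tolerance = 1e-9)
  expect_equal(rec0$entry_distance, 0, tolerance = 1e-9)
  # the pilot's maxima used as a synthetic construction: 2.9 deg and 2.1 mm
  scan <- simulate_postop_scan(fem, plan, angular_error = 2.9,
                               error_plane_azimuth = 60,
                               entry_shift = c(2.1, 0),
                               pose = identity_transform(), noise_sd = 0,
                               seed = 6, voxel = 0.6)
  rec <- compute_deviation(plan, scan$achieved_axis_truth, head_mesh = fem$mesh)
  expect_equal(rec$true3d_angle, 2.9, tolerance = 0.05)
  expect_equal(rec$entry_distance, 2.1, tolerance = 0.05)
  expect_lte(rec$frontal, rec$true3d_angle + 1e-9)
  expect_lte(rec$axial, rec$true3d_angle + 1e-9)
  expect_lte(rec$sagittal, rec$true3d_angle + 1e-9)
})

test_that("simulation + evaluation round-trip recovers the generating rotation", {
  fem <- fx_femur_clean()
  plan <- fx_plan()
  # noise-free, identity pose: full-pipeline round trip at 0.05 deg / mm
  scan <- simulate_postop_scan(fem, plan, angular_error = 2.0,
                               error_plane_azimuth = 30, entry_shift = c(1.2, 0),
                               pose = identity_transform(), noise_sd = 0,
                               seed = 3, voxel = 0.55)
  ev <- evaluate_case(scan, fem, plan, seed = 4, case_id = "rt")
  expect_equal(ev$record$true3d_angle, 2.0, tolerance = 0.05)
  expect_equal(ev$record$entry_distance, 1.2, tolerance = 0.05)
  expect_gte(ev$n_channel_points, 50)
  # construction-level round trip over many random perturbations
  for (k in 1:40) {
    old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
    set.seed(1200 + k)
    ang <- runif(1, 0.2, 8)
    azi <- runif(1, 0, 360)
    sc <- simulate_postop_scan(fem, plan, angular_error = ang,
                               error_plane_azimuth = azi, entry_shift = c(0, 0),
                               pose = identity_transform(), noise_sd = 0,
                               seed = k, voxel = 2)  # geometry only, coarse
    rec <- compute_deviation(plan, sc$achieved_axis_truth, head_mesh = fem$mesh)
    expect_equal(rec$true3d_angle, ang, tolerance = 0.05)
    if (!is.null(old)) assign(".Random.seed", old, globalenv())
  }
})

test_that("deviation records are invariant to the arbitrary scan pose", {
  fem <- fx_femur_clean()
  plan <- fx_plan()
  recs <- lapply(1:4, function(k) {
    old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
    on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
    set.seed(40 + k)
    pose <- rigid_transform(rotation_about(rnorm(3), runif(1, 0, 15)),
                            runif(3, -20, 20))
    scan <- simulate_postop_scan(fem, plan, angular_error = 2.0,
                                 error_plane_azimuth = 30, entry_shift = c(1, 0),
                                 pose = pose, noise_sd = 0, seed = 3, voxel = 0.55)
    evaluate_case(scan, fem, plan, seed = 4)$record
  })
  m <- sapply(recs, function(r) c(r$true3d_angle, r$frontal, r$axial,
                                  r$sagittal, r$entry_distance))
  spreads <- apply(m, 1, function(x) diff(range(x)))
  expect_lt(max(spreads[1:4]), 0.1)
  expect_lt(spreads[5], 0.1)
})
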