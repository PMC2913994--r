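test_that("zero-adjustment plan reproduces the neck axis exactly", {
  an <- fx_anatomy()
  p0 <- make_plan(an$frame, an$neck, 0, 0)
  expect_equal(angle_between(p0$axis$direction, an$neck$axis$direction), 0,
               tolerance = 1e-12)
})

test_that("adjustment rotations decompose and compose as constructed", {
  an <- fx_anatomy()
  # pure valgus: deviation dominated by the frontal component (the minimal
  # rotation axis is perpendicular to both directions, so it is not exactly
  # the anterior axis unless the directions are too)
  p5 <- make_plan(an$frame, an$neck, 5, 0)
  d5 <- decompose_angle(an$neck$axis, p5$axis, an$frame)
  expect_gt(d5$frontal, d5$axial)
  expect_gt(d5$frontal, d5$sagittal)
  expect_equal(d5$frontal^2 + d5$axial^2 + d5$sagittal^2, d5$true3d^2,
               tolerance = 1e-9)
  expect_lt(d5$true3d, 5 + 1e-9)
  # valgus sign: the drilling direction closes on the distal shaft direction
  before <- angle_between(an$neck$axis$direction, -an$frame$superior)
  after <- angle_between(p5$axis$direction, -an$frame$superior)
  expect_lt(after, before)
  # pure version: deviation dominated by the axial component, anterior gain
  p4 <- make_plan(an$frame, an$neck, 0, 4)
  d4 <- decompose_angle(an$neck$axis, p4$axis, an$frame)
  expect_gt(d4$axial, d4$frontal)
  expect_gt(sum(-p4$axis$direction * an$frame$anterior),
            sum(-an$neck$axis$direction * an$frame$anterior))
  # (3, 4): matches a brute-force composition of the same two rotations
  p34 <- make_plan(an$frame, an$neck, 3, 4)
  d <- an$neck$axis$direction
  cand_v <- lapply(c(1, -1), function(s)
    as.numeric(rotation_about(an$frame$anterior, s * 3) %*% d))
  pick <- which.min(vapply(cand_v, function(v)
    angle_between(v, -an$frame$superior), numeric(1)))
  dv <- cand_v[[pick]]
  cand_w <- lapply(c(1, -1), function(s)
    as.numeric(rotation_about(an$frame$superior, s * 4) %*% dv))
  gain <- vapply(cand_w, function(v) sum(-v * an$frame$anterior), numeric(1))
  oracle_dir <- cand_w[[which.max(gain)]]
  expect_equal(angle_between(p34$axis$direction, oracle_dir), 0, tolerance = 1e-6)
  # bounds
  expect_error(make_plan(an$frame, an$neck, 25, 0), class = "sraguide_invalid_plan")
})

test_that("entry point matches the analytic ray-sphere solution", {
  fem <- fx_femur_clean()
  # through the head centre along the drilling axis: |entry| = head radius
  ep <- compute_entry_point(fem$mesh, fem$truth$neck_axis)
  expect_equal(sqrt(sum(ep^2)), 24, tolerance = 0.01)
  # offset vertical ray: closed-form ray-sphere intersection
  ax <- axis3(c(10, 0.5, 0), c(0, 0, -1))
  ep2 <- compute_entry_point(fem$mesh, ax)
  expect_equal(ep2[3], sqrt(24^2 - 10^2 - 0.5^2), tolerance = 0.05)
  expect_equal(ep2[1:2], c(10, 0.5), tolerance = 0.01)
  # tangent miss
  expect_error(compute_entry_point(fem$mesh, axis3(c(90, 0, 0), c(0, 0, -1))),
               class = "sraguide_axis_misses_bone")
})

test_that("clearance margins match analytic values and a sampling oracle", {
  feml <- generate_femur(femur_params(neck_radii = c(15, 15), noise_sd = 0,
                                     seed = 2, target_edge = 1.5))
  hs <- fit_head_sphere(feml$mesh, seed = 2)
  neck <- fit_neck_axis(feml$mesh, hs)
  fr <- build_frame(hs, neck, feml$truth$shaft_axis, side = "left",
                    anterior_ref = c(0, 1, 0))
  plan0 <- make_plan(fr, neck, 0, 0, mesh = feml$mesh)
  # coaxial corridor r = 4.75 in an exact cylindrical neck r = 15
  cl <- check_clearance(feml$mesh, plan0, corridor_radius = 4.75)
  expect_equal(cl$min_superior, 10.25, tolerance = 0.1)
  expect_equal(cl$min_inferior, 10.25, tolerance = 0.1)
  expect_false(cl$notching)
  # margins are monotone non-increasing in corridor radius
  radii <- c(3, 4.75, 7, 10, 14)
  sups <- vapply(radii, function(r)
    check_clearance(feml$mesh, plan0, corridor_radius = r)$min_superior, numeric(1))
  expect_true(all(diff(sups) <= 1e-9))
  # sampling oracle on the default elliptic femur
  fem <- fx_femur_clean()
  plan <- fx_plan()
  cld <- check_clearance(fem$mesh, plan, corridor_radius = 4.75, seed = 5)
  pts <- mesh_sample_surface(fem$mesh, 1e5, seed = 99)
  dvec <- plan$axis$direction
  tau <- as.numeric(sweep(pts, 2, plan$frame$origin) %*% dvec)
  band <- sraguide:::find_neck_corridor(fem$mesh, plan$frame$origin, 24, dvec)
  keep <- tau >= band[1] & tau <= band[2]
  rel <- sweep(pts[keep, ], 2, plan$axis$point)
  t <- as.numeric(rel %*% dvec)
  radial <- rel - outer(t, dvec)
  rho <- sqrt(rowSums(radial^2))
  sup_dir <- sraguide:::unitize(project_onto_plane(plan$frame$superior, dvec))
  is_sup <- as.numeric(radial %*% sup_dir) > 0
  expect_equal(cld$min_superior, min(rho[is_sup]) - 4.75, tolerance = 0.1)
  expect_equal(cld$min_inferior, min(rho[!is_sup]) - 4.75, tolerance = 0.1)
  # a strongly tilted plan with a wide corridor breaches the cortex
  plan_v <- make_plan(fr, neck, -10, 0, mesh = feml$mesh)
  clv <- check_clearance(feml$mesh, plan_v, corridor_radius = 14)
  expect_true(clv$notching)
})
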