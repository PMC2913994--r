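test_that("sphere fit is exact on clean data and robust to outliers", {
  # exact points on a known sphere
  dirs <- random_units(2000, 31)
  P <- sweep(dirs * 24, 2, c(10, 20, 30), "+")
  f <- fit_head_sphere(P, method = "linear", seed = 1)
  expect_equal(f$center, c(10, 20, 30), tolerance = 1e-6)
  expect_equal(f$radius, 24, tolerance = 1e-6)
  # 20% outliers pushed 3 mm outward: ransac recovers and reports inliers
  P2 <- P
  P2[1:400, ] <- sweep(dirs[1:400, ] * 27, 2, c(10, 20, 30), "+")
  f2 <- fit_head_sphere(P2, method = "ransac", seed = 3)
  expect_equal(f2$inlier_fraction, 0.8, tolerance = 0.05)
  expect_equal(f2$radius, 24, tolerance = 0.1)
  # degenerate (planar) input
  flat <- cbind(matrix(rnorm(400), 200, 2), 0)
  expect_error(fit_head_sphere(flat, method = "linear", region_hint = c(0, 0, 0)),
               class = "sraguide_degenerate_fit")
})

test_that("sphere fit recovers radius within 0.1 mm from noisy hemispheres", {
  hits <- vapply(1:40, function(k) {
    old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
    on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
    set.seed(7000 + k)
    n <- 2000
    z <- runif(n)
    th <- runif(n, 0, 2 * pi)
    P <- cbind(sqrt(1 - z^2) * cos(th), sqrt(1 - z^2) * sin(th), z) * 24
    P <- sweep(P + matrix(rnorm(3 * n, 0, 0.2), n, 3), 2, c(10, 20, 30), "+")
    abs(fit_head_sphere(P, method = "linear", seed = k)$radius - 24) < 0.1
  }, logical(1))
  expect_gte(mean(hits), 0.95)
})

test_that("neck axis is recovered on a perfect cylinder-plus-head construction", {
  # elliptic neck with zero noise: the fitted axis must match the truth to
  # a small fraction of a degree, unaffected by ellipticity
  fem <- fx_femur_clean()
  an <- fx_anatomy()
  expect_true(an$neck$converged)
  expect_lt(angle_between(an$neck$axis$direction,
                          fem$truth$neck_axis$direction), 0.05)
  expect_gte(nrow(an$neck$slice_centroids), 5)
  # circular neck control: same accuracy
  femc <- generate_femur(femur_params(neck_radii = c(15, 15), noise_sd = 0,
                                      seed = 2, target_edge = 1.5))
  hc_ <- fit_head_sphere(femc$mesh, seed = 2)
  nc <- fit_neck_axis(femc$mesh, hc_)
  expect_lt(angle_between(nc$axis$direction, femc$truth$neck_axis$direction), 0.05)
})

test_that("neck axis recovery stays below 1 degree under surface noise", {
  errs <- vapply(1:12, function(k) {
    fem <- generate_femur(femur_params(noise_sd = 0.15, seed = 5000 + k))
    hs <- fit_head_sphere(fem$mesh, seed = k)
    neck <- fit_neck_axis(fem$mesh, hs)
    angle_between(neck$axis$direction, fem$truth$neck_axis$direction)
  }, numeric(1))
  expect_gte(mean(errs < 1), 0.95)
})

test_that("anatomy fits commute with rigid transforms", {
  fem <- fx_femur_clean()
  an <- fx_anatomy()
  Tr <- rigid_transform(rotation_about(c(2, -1, 0.5), 33), c(12, -8, 5))
  moved <- apply_transform(Tr, fem$mesh)
  hs2 <- fit_head_sphere(moved, seed = 2)
  expect_lt(sqrt(sum((hs2$center - apply_transform(Tr, an$head$center))^2)), 0.05)
  expect_lt(abs(hs2$radius - an$head$radius), 0.05)
  n2 <- fit_neck_axis(moved, hs2)
  expect_lt(angle_between(n2$axis$direction,
                          as.numeric(Tr$rotation %*% an$neck$axis$direction)), 0.05)
})

test_that("build_frame recovers anteversion and mirrors correctly", {
  fem <- fx_femur_clean()
  an <- fx_anatomy()
  fr <- an$frame
  # scanner-referenced frame: anteversion of the fitted neck axis
  proj <- project_onto_plane(an$neck$axis$direction, fr$superior)
  expect_equal(angle_between(proj, fr$medial), 15, tolerance = 0.2)
  # zero-anteversion femur: neck axis lies in the frontal plane
  fem0 <- generate_femur(femur_params(anteversion = 0, noise_sd = 0, seed = 3,
                                      target_edge = 2))
  hs0 <- fit_head_sphere(fem0$mesh, seed = 1)
  n0 <- fit_neck_axis(fem0$mesh, hs0)
  fr0 <- build_frame(hs0, n0, fem0$truth$shaft_axis, side = "left",
                     anterior_ref = c(0, 1, 0))
  expect_lt(abs(sum(n0$axis$direction * fr0$anterior)), 0.01)
  # fallback frame without an anterior reference also puts the neck in-plane
  frf <- build_frame(hs0, n0, fem0$truth$shaft_axis, side = "left")
  expect_lt(abs(sum(n0$axis$direction * frf$anterior)), 0.01)
  # mirrored right femur: medial flips, frame stays consistent with its side
  femR <- generate_femur(femur_params(side = "right", noise_sd = 0, seed = 3,
                                      target_edge = 2))
  hsR <- fit_head_sphere(femR$mesh, seed = 1)
  nR <- fit_neck_axis(femR$mesh, hsR)
  frR <- build_frame(hsR, nR, femR$truth$shaft_axis, side = "right",
                     anterior_ref = c(0, 1, 0))
  expect_lt(max(abs(frR$medial - c(-1, 0, 0))), 1e-9)
  expect_equal(det(cbind(frR$medial, frR$anterior, frR$superior)), -1,
               tolerance = 1e-9)
  # parallel axes are rejected
  fake_neck <- an$neck
  fake_neck$axis <- axis3(c(0, 0, 0), fem$truth$shaft_axis$direction)
  expect_error(build_frame(an$head, fake_neck, fem$truth$shaft_axis),
               class = "sraguide_degenerate_frame")
})
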