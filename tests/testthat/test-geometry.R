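test_that("angle_between matches the atan2 oracle and handles sign flips", {
  expect_equal(angle_between(c(0, 0, 1), c(0, 0, 1)), 0)
  expect_equal(angle_between(c(0, 0, 1), c(0, sin(pi / 18), cos(pi / 18))), 10,
               tolerance = 1e-12)
  u <- random_units(1000, 11)
  v <- random_units(1000, 12)
  for (i in seq_len(nrow(u))) {
    cr <- c(u[i, 2] * v[i, 3] - u[i, 3] * v[i, 2],
            u[i, 3] * v[i, 1] - u[i, 1] * v[i, 3],
            u[i, 1] * v[i, 2] - u[i, 2] * v[i, 1])
    oracle <- atan2(sqrt(sum(cr^2)), abs(sum(u[i, ] * v[i, ]))) * 180 / pi
    expect_equal(angle_between(u[i, ], v[i, ]), oracle, tolerance = 1e-9)
    expect_equal(angle_between(u[i, ], v[i, ]), angle_between(-u[i, ], v[i, ]))
    expect_equal(angle_between(u[i, ], v[i, ]), angle_between(v[i, ], u[i, ]))
  }
  expect_error(angle_between(c(0, 0, 0), c(1, 0, 0)), class = "sraguide_invalid_input")
})

test_that("angle_between is a metric on directions (triangle inequality)", {
  u <- random_units(200, 21); v <- random_units(200, 22); w <- random_units(200, 23)
  for (i in 1:200) {
    ab <- angle_between(u[i, ], v[i, ])
    bc <- angle_between(v[i, ], w[i, ])
    ac <- angle_between(u[i, ], w[i, ])
    expect_lte(ac, ab + bc + 1e-9)
  }
})

test_that("rigid transforms compose, invert and round-trip to 1e-9 mm", {
  T1 <- rigid_transform(rotation_about(c(0, 0, 1), 90), c(1, 2, 3))
  expect_equal(apply_transform(T1, c(1, 0, 0)), c(1, 3, 3), tolerance = 1e-12)
  pts <- matrix(rnorm(300), 100, 3) * 20
  for (k in 1:100) {
    ax <- random_units(1, 100 + k)
    Tk <- rigid_transform(rotation_about(ax, 360 * k / 101), rnorm(3) * 10)
    rt <- apply_transform(invert_transform(Tk), apply_transform(Tk, pts))
    expect_lt(max(abs(rt - pts)), 1e-9)
  }
  # associativity of composition
  A <- rigid_transform(rotation_about(c(1, 2, 3), 33), c(1, -1, 2))
  B <- rigid_transform(rotation_about(c(-1, 0, 1), 77), c(0, 5, -3))
  C <- rigid_transform(rotation_about(c(0, 1, 0), -15), c(2, 2, 2))
  lhs <- compose_transform(compose_transform(A, B), C)
  rhs <- compose_transform(A, compose_transform(B, C))
  expect_equal(lhs$rotation, rhs$rotation, tolerance = 1e-12)
  expect_equal(lhs$translation, rhs$translation, tolerance = 1e-12)
  # rotations preserve norms
  R <- rotation_about(c(3, -2, 1), 123.4)
  vs <- random_units(50, 7) * 5
  expect_equal(sqrt(rowSums((vs %*% t(R))^2)), sqrt(rowSums(vs^2)), tolerance = 1e-12)
  expect_error(rigid_transform(matrix(1:9, 3, 3), c(0, 0, 0)),
               class = "sraguide_invalid_transform")
})

test_that("transforms serialize as 4x4 homogeneous matrices", {
  Tk <- rigid_transform(rotation_about(c(1, 1, 0), 40), c(-2, 3, 7))
  M <- transform_to_matrix(Tk)
  expect_equal(dim(M), c(4L, 4L))
  T2 <- transform_from_matrix(M)
  expect_equal(T2$rotation, Tk$rotation)
  expect_equal(T2$translation, Tk$translation)
})

test_that("anatomical frames validate orthonormality and handedness", {
  fr <- anatomical_frame(c(0, 0, 0), c(1, 0, 0), c(0, 1, 0), c(0, 0, 1))
  expect_s3_class(fr, "anatomical_frame")
  expect_error(anatomical_frame(c(0, 0, 0), c(1, 0, 0), c(1, 0, 0), c(0, 0, 1)),
               class = "sraguide_invalid_frame")
  # right-side frame carries det -1
  frR <- anatomical_frame(c(0, 0, 0), c(-1, 0, 0), c(0, 1, 0), c(0, 0, 1),
                          side = "right")
  expect_identical(frR$side, "right")
  expect_error(anatomical_frame(c(0, 0, 0), c(-1, 0, 0), c(0, 1, 0), c(0, 0, 1),
                                side = "left"),
               class = "sraguide_invalid_frame")
})

test_that("decompose_angle matches the quaternion oracle on random cases", {
  fr0 <- anatomical_frame(c(0, 0, 0), c(1, 0, 0), c(0, 1, 0), c(0, 0, 1))
  # pure in-plane rotation about the anterior axis: frontal component is the
  # whole angle (the paper-grade worst case magnitude)
  u <- c(0, 0, 1)
  v <- as.numeric(rotation_about(c(0, 1, 0), 2.9) %*% u)
  d <- decompose_angle(axis3(c(0, 0, 0), u), axis3(c(0, 0, 0), v), fr0)
  expect_equal(d$true3d, 2.9, tolerance = 1e-9)
  expect_equal(d$frontal, 2.9, tolerance = 1e-9)
  expect_equal(d$axial, 0, tolerance = 1e-9)
  expect_equal(d$sagittal, 0, tolerance = 1e-9)
  # identity
  d0 <- decompose_angle(u, u, fr0)
  expect_true(d0$degenerate)
  expect_equal(c(d0$frontal, d0$axial, d0$sagittal), c(0, 0, 0))
  # random frames and direction pairs vs the independent oracle
  for (i in 1:500) {
    fr <- random_frame(3000 + i)
    uv <- random_units(2, 6000 + i)
    got <- decompose_angle(uv[1, ], uv[2, ], fr)
    want <- oracle_decompose(uv[1, ], uv[2, ], fr)
    expect_equal(got$true3d, unname(want["true3d"]), tolerance = 1e-9)
    expect_equal(got$frontal, unname(want["frontal"]), tolerance = 1e-9)
    expect_equal(got$axial, unname(want["axial"]), tolerance = 1e-9)
    expect_equal(got$sagittal, unname(want["sagittal"]), tolerance = 1e-9)
  }
})

test_that("decomposition components never exceed the true-3D angle and sum in squares", {
  zero_count <- 0L
  for (i in 1:300) {
    fr <- random_frame(400 + i)
    uv <- random_units(2, 800 + i)
    d <- decompose_angle(uv[1, ], uv[2, ], fr)
    expect_lte(d$frontal, d$true3d + 1e-9)
    expect_lte(d$axial, d$true3d + 1e-9)
    expect_lte(d$sagittal, d$true3d + 1e-9)
    expect_equal(d$frontal^2 + d$axial^2 + d$sagittal^2, d$true3d^2,
                 tolerance = 1e-9)
    if (d$frontal + d$axial + d$sagittal < 1e-12) zero_count <- zero_count + 1L
  }
  expect_identical(zero_count, 0L)  # random pairs are never parallel
})
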