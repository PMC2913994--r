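# The jig fixture (fx_jig) is generated once and shared by every block.

test_that("generated jig satisfies its geometric contract", {
  jig <- fx_jig()
  fem <- fx_femur_clean()
  plan <- fx_plan()
  ct <- jig_contract(jig, fem, plan)
  expect_true(ct$watertight)
  expect_true(ct$outward)
  expect_true(ct$parts_watertight)
  expect_identical(sort(names(jig$parts)),
                   sort(c("cage", "neck_support", paste0("knife_", 1:4), "cylinder")))
  # drill axis collinear with the plan
  expect_lt(ct$axis_angle_dev_deg, 1e-6)
  expect_lt(ct$axis_offset_mm, 1e-3)
  # through-bore patency: the drill path crosses no jig geometry
  expect_identical(ct$bore_crossings, 0L)
  # contact-surface offset realized on the cage
  expect_equal(ct$cage_standoff_mm, 0.5, tolerance = 0.1)
  # knife tips on the bone sphere, blades reaching the bone surface
  expect_lt(ct$knife_tip_dev_mm, 0.1)
  expect_lt(ct$knife_min_dist_mm, 0.1)
})

test_that("jig generation is deterministic and rigid-transform equivariant", {
  jig <- fx_jig()
  an <- fx_anatomy()
  fem <- fx_femur_clean()
  plan <- fx_plan()
  jig2 <- generate_jig(fem, plan, jig_params(voxel = 0.45), head = an$head,
                       neck = an$neck$axis)
  expect_identical(jig$mesh$vertices, jig2$mesh$vertices)
  # transform the whole scene; the jig must follow within 1e-6 mm
  Tr <- rigid_transform(rotation_about(c(1, -2, 0.7), 28), c(6, -11, 4))
  fem_t <- fem
  fem_t$mesh <- apply_transform(Tr, fem$mesh)
  head_t <- an$head
  head_t$center <- apply_transform(Tr, an$head$center)
  neck_t <- sraguide:::transform_axis(Tr, an$neck$axis)
  frame_t <- anatomical_frame(apply_transform(Tr, an$frame$origin),
                              as.numeric(Tr$rotation %*% an$frame$medial),
                              as.numeric(Tr$rotation %*% an$frame$anterior),
                              as.numeric(Tr$rotation %*% an$frame$superior))
  plan_t <- plan
  plan_t$axis <- sraguide:::transform_axis(Tr, plan$axis)
  plan_t$entry_point <- apply_transform(Tr, plan$entry_point)
  plan_t$frame <- frame_t
  jig_t <- generate_jig(fem_t, plan_t, jig_params(voxel = 0.45), head = head_t,
                        neck = neck_t)
  back <- apply_transform(invert_transform(Tr), jig_t$mesh)
  expect_identical(nrow(back$vertices), nrow(jig$mesh$vertices))
  expect_lt(max(abs(back$vertices - jig$mesh$vertices)), 1e-6)
})

test_that("snap fit has a unique seating with the designed stability split", {
  fem <- fx_femur_clean()
  jig <- fx_jig()
  snap <- validate_snap_fit(fem, jig, n_starts = 20L, seed = 5)
  # cost is exactly zero at the design pose
  expect_lt(snap$design_cost, 1e-6)
  # unique snap-fit position (the qualitative checklist's "1")
  expect_true(snap$unique_minimum)
  expect_identical(snap$n_possible_positions, 1L)
  st <- snap$stiffness
  # AP and ML stiffness dominated by the knives...
  expect_gt(st$ap$knives, st$ap$neck_support)
  expect_gt(st$ml$knives, st$ml$neck_support)
  # ...removing the support barely changes AP...
  expect_lt(1 - st$ap$knives / st$ap$total, 0.10)
  # ...while varus-valgus is dominated by the neck support
  expect_gt(st$varus_valgus$neck_support / st$varus_valgus$total, 0.5)
})

test_that("jig STL export round-trips and respects watertightness", {
  jig <- fx_jig()
  tmp <- tempfile(fileext = ".stl")
  export_stl(jig, tmp)
  back <- read_stl(tmp)
  expect_identical(nrow(back$faces), nrow(jig$mesh$faces))
  expect_equal(mesh_volume(back), mesh_volume(jig$mesh), tolerance = 1e-3)
  unlink(tmp)
})

test_that("jig parameter validation rejects impossible designs", {
  expect_error(jig_params(cage_polar_extent = 85), class = "sraguide_invalid_input")
  expect_error(jig_params(cage_polar_extent = 130), class = "sraguide_invalid_input")
  expect_error(jig_params(knife_positions = c(0, 10, 20)),
               class = "sraguide_invalid_input")
  an <- fx_anatomy()
  plan_nobore <- make_plan(an$frame, an$neck, 0, 0, wire_diameter = 3.2)
  expect_error(generate_jig(fx_femur_clean(), plan_nobore),
               class = "sraguide_design_error")  # no entry point
})
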