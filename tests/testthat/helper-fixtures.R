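# Shared fixtures, built lazily and cached for the whole test run. All
# fixtures are generated in code from fixed seeds; nothing is read from disk.

.fixtures <- new.env(parent = emptyenv())

fx <- function(name, build) {
  if (is.null(.fixtures[[name]])) .fixtures[[name]] <- build()
  .fixtures[[name]]
}

fx_femur_clean <- function() {
  fx("femur_clean", function() generate_femur(femur_params(noise_sd = 0, seed = 1)))
}

fx_femur_noisy <- function() {
  fx("femur_noisy", function() generate_femur(femur_params(seed = 42)))
}

fx_anatomy <- function() {
  fx("anatomy", function() {
    fem <- fx_femur_clean()
    head <- fit_head_sphere(fem$mesh, seed = 2)
    neck <- fit_neck_axis(fem$mesh, head)
    frame <- build_frame(head, neck, fem$truth$shaft_axis, side = "left",
                         anterior_ref = c(0, 1, 0))
    list(head = head, neck = neck, frame = frame)
  })
}

fx_plan <- function() {
  fx("plan", function() {
    an <- fx_anatomy()
    make_plan(an$frame, an$neck, valgus_adjust = 3, version_adjust = 0,
              mesh = fx_femur_clean()$mesh)
  })
}

# one jig, reused by the whole jig test file (slightly coarser lattice than
# the production default to keep the run short)
fx_jig <- function() {
  fx("jig", function() {
    an <- fx_anatomy()
    generate_jig(fx_femur_clean(), fx_plan(), jig_params(voxel = 0.45),
                 head = an$head, neck = an$neck$axis)
  })
}

random_units <- function(n, seed) {
  withr_seed <- seed  # local RNG without touching global state
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(withr_seed)
  m <- matrix(stats::rnorm(3 * n), n, 3)
  m / sqrt(rowSums(m^2))
}

random_frame <- function(seed) {
  u <- random_units(2, seed)
  m <- u[1, ]
  a <- u[2, ] - sum(u[2, ] * m) * m
  a <- a / sqrt(sum(a^2))
  s <- c(m[2] * a[3] - m[3] * a[2], m[3] * a[1] - m[1] * a[3], m[1] * a[2] - m[2] * a[1])
  anatomical_frame(c(0, 0, 0), m, a, s, side = "left")
}

# independent decomposition oracle: quaternion route (the package uses the
# cross/dot route), components of the minimal rotation vector along the
# anatomical plane normals
oracle_decompose <- function(u, v, frame) {
  u <- u / sqrt(sum(u^2)); v <- v / sqrt(sum(v^2))
  if (sum(u * v) < 0) v <- -v
  w <- c(1 + sum(u * v),
         u[2] * v[3] - u[3] * v[2],
         u[3] * v[1] - u[1] * v[3],
         u[1] * v[2] - u[2] * v[1])
  w <- w / sqrt(sum(w^2))           # unit quaternion taking u to v
  vec <- w[2:4]
  s <- sqrt(sum(vec^2))
  theta <- 2 * atan2(s, w[1]) * 180 / pi
  if (s < 1e-12) return(c(true3d = 0, frontal = 0, axial = 0, sagittal = 0))
  ax <- vec / s
  c(true3d = theta,
    frontal = theta * abs(sum(ax * frame$anterior)),
    axial = theta * abs(sum(ax * frame$superior)),
    sagittal = theta * abs(sum(ax * frame$medial)))
}
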