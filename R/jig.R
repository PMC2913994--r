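# Parametric generation of the custom neck jig: a slightly
# more-than-hemispherical cage over the anterior femoral head, an anterior
# neck support bridged to the cage rim, four knives on the central arch whose
# edges land on the segmented bone surface (cutting through cartilage in the
# physical situation), and a drill-guide cylinder on the planned axis with
# the bore subtracted through all parts.
#
# CSG strategy: every part is an analytic signed field (the neck support uses
# a radial surface profile measured from the bone mesh by ray casting), the
# union is the pointwise minimum, and the solid is meshed by marching
# tetrahedra on a lattice anchored to the jig's local frame. This yields a
# watertight manifold mesh unconditionally and makes the construction
# rigid-transform equivariant.

#' Jig design parameters
#'
#' @param contact_offset stand-off of cage and neck support from the bone
#'   model (mm); compensates cartilage and manufacturing tolerance.
#' @param cage_polar_extent angular extent of the cage from its pole (deg);
#'   must be in (90, 120] — more than a hemisphere on the anterior side.
#' @param cage_thickness cage shell thickness (mm).
#' @param knife_penetration how far the knife edges reach beyond the cage
#'   inner surface (mm). The default equals `contact_offset`, so edges land
#'   exactly on the segmented bone surface.
#' @param knife_width blade width at the back of the wedge (mm).
#' @param knife_edge_land blade thickness at the cutting edge (mm).
#' @param knife_edge_angle included wedge angle of the blade (deg).
#' @param knife_positions arch angles of the four knives from the cage pole
#'   (deg; positive toward anterior).
#' @param knife_edge_arc angular length of each knife edge along the arch
#'   (deg).
#' @param neck_support_wrap circumferential extent of the anterior neck
#'   support (deg, centred on anterior).
#' @param neck_support_length extent of the neck support along the neck axis
#'   (mm), beyond the head-neck transition.
#' @param neck_support_thickness shell thickness of the neck support (mm).
#' @param cylinder_bore drill-guide bore diameter (mm); default wire + 0.2.
#' @param cylinder_outer guide-cylinder outer diameter (mm); default bore + 4.
#' @param cylinder_length guide-cylinder length beyond the cage (mm).
#' @param voxel lattice spacing for surface extraction (mm).
#' @return a `jig_params` list.
#' @export
jig_params <- function(contact_offset = 0.5, cage_polar_extent = 100,
                       cage_thickness = 3, knife_penetration = 0.5,
                       knife_width = 1.5, knife_edge_land = 0.6,
                       knife_edge_angle = 20,
                       knife_positions = c(-45, -15, 15, 45),
                       knife_edge_arc = 16,
                       neck_support_wrap = 160, neck_support_length = 25,
                       neck_support_thickness = 3,
                       cylinder_bore = NULL, cylinder_outer = NULL,
                       cylinder_length = 30, voxel = 0.35) {
  p <- as.list(environment())
  if (cage_polar_extent <= 90 || cage_polar_extent > 120)
    stop_invalid("cage_polar_extent must be in (90, 120] degrees")
  if (length(knife_positions) != 4L)
    stop_invalid("the jig carries exactly four knives")
  if (any(c(cage_thickness, knife_width, neck_support_thickness,
            cylinder_length, voxel, contact_offset) <= 0))
    stop_invalid("jig thicknesses, lengths and voxel must be positive")
  class(p) <- "jig_params"
  p
}

# bilinear interpolation on the (tau, phi) radial profile
profile_interp <- function(prof, tau, phi) {
  tau <- pmin(max(prof$tau), pmax(min(prof$tau), tau))
  phi <- pmin(max(prof$phi), pmax(min(prof$phi), phi))
  it <- pmax(1L, pmin(length(prof$tau) - 1L, findInterval(tau, prof$tau)))
  ip <- pmax(1L, pmin(length(prof$phi) - 1L, findInterval(phi, prof$phi)))
  wt <- (tau - prof$tau[it]) / (prof$tau[it + 1L] - prof$tau[it])
  wp <- (phi - prof$phi[ip]) / (prof$phi[ip + 1L] - prof$phi[ip])
  r00 <- prof$r[cbind(it, ip)]
  r10 <- prof$r[cbind(it + 1L, ip)]
  r01 <- prof$r[cbind(it, ip + 1L)]
  r11 <- prof$r[cbind(it + 1L, ip + 1L)]
  (1 - wt) * ((1 - wp) * r00 + wp * r01) + wt * ((1 - wp) * r10 + wp * r11)
}

#' Generate the custom neck jig for a planned drill axis
#'
#' @param femur a `femur_model` (or any list with `mesh` and `truth`).
#' @param plan a `drill_plan` with a computed entry point.
#' @param params a [jig_params()].
#' @param head optional [fit_head_sphere()] result; defaults to the femur's
#'   ground-truth head sphere.
#' @param neck optional neck [axis3()]; defaults to the femur's ground-truth
#'   neck axis.
#' @return a `jig_model`: `mesh` (watertight union), `parts` (named list of
#'   part meshes: cage, neck_support, knife_1..4, cylinder), `drill_axis`
#'   (collinear with the plan axis by construction), `contact_points`
#'   (knife tips on the bone sphere; neck-support rim patch on the bone
#'   surface), `params`, `head`, and the local design frame.
#' @export
generate_jig <- function(femur, plan, params = jig_params(), head = NULL,
                         neck = NULL) {
  stopifnot(inherits(plan, "drill_plan"))
  if (!inherits(params, "jig_params")) params <- do.call(jig_params, params)
  mesh <- femur$mesh
  if (is.null(head)) {
    if (is.null(femur$truth))
      stop_invalid("need a head sphere fit (or femur ground truth)")
    head <- list(center = femur$truth$head_center, radius = femur$truth$head_radius)
  }
  if (is.null(neck)) neck <- femur$truth$neck_axis
  hc <- head$center
  R <- head$radius
  if (is.null(plan$entry_point))
    stop_with("sraguide_design_error", "plan has no entry point; pass mesh to make_plan")

  # local design frame: z = from head centre through the entry point
  p_hat <- -plan$axis$direction
  ent_z <- sum((plan$entry_point - hc) * p_hat)
  if (ent_z < 0.5 * R)
    stop_with("sraguide_design_error", "plan axis does not exit through the cage region")
  y_loc <- project_onto_plane(plan$frame$anterior, p_hat)
  if (vnorm(y_loc) < 1e-6)
    stop_with("sraguide_design_error", "plan axis parallel to anterior; cage bias undefined")
  y_loc <- unitize(y_loc)
  x_loc <- cross3(y_loc, p_hat)
  B <- cbind(x_loc, y_loc, p_hat)  # local -> world rotation

  pr <- params
  bore_d <- pr$cylinder_bore %||% (plan$wire_diameter + 0.2)
  if (bore_d <= plan$wire_diameter)
    stop_invalid("cylinder bore must exceed the wire diameter")
  outer_d <- pr$cylinder_outer %||% (bore_d + 4)
  Ri <- R + pr$contact_offset
  Ro <- Ri + pr$cage_thickness
  ext <- deg2rad(pr$cage_polar_extent)
  R_tip <- Ri - pr$knife_penetration
  half_arc <- deg2rad(pr$knife_edge_arc) / 2
  wedge_slope <- 2 * tan(deg2rad(pr$knife_edge_angle) / 2)
  wrap_half <- deg2rad(pr$neck_support_wrap) / 2

  # neck coordinates (local)
  dn_l <- as.numeric(t(B) %*% neck$direction)
  A1 <- project_onto_plane(plan$frame$anterior, neck$direction)
  if (vnorm(A1) < 1e-6) stop_with("sraguide_design_error", "neck axis parallel to anterior")
  A1 <- unitize(A1)
  A2 <- cross3(neck$direction, A1)
  A1_l <- as.numeric(t(B) %*% A1)
  A2_l <- as.numeric(t(B) %*% A2)

  tau_lo <- 3
  tau0 <- 0.42 * R
  tau_hi <- tau0 + pr$neck_support_length

  # measured radial surface profile around the neck axis (bone surface the
  # support offsets); rays from the axis outward
  prof_tau <- seq(tau_lo - 2, tau_hi + 2, by = 1.25)
  prof_phi <- seq(-(wrap_half + deg2rad(15)), wrap_half + deg2rad(15),
                  length.out = 49)
  og <- expand.grid(tau = prof_tau, phi = prof_phi)
  origins <- sweep(outer(og$tau, neck$direction), 2, hc, "+")
  dirs <- outer(cos(og$phi), A1) + outer(sin(og$phi), A2)
  hit <- mesh_ray(mesh, origins, dirs, tmax = 3 * R)
  rr <- hit$t
  if (anyNA(rr)) rr[is.na(rr)] <- stats::median(rr, na.rm = TRUE)
  prof <- list(tau = prof_tau, phi = prof_phi,
               r = matrix(rr, length(prof_tau), length(prof_phi)))

  z_t1 <- ent_z + pr$cage_thickness + pr$cylinder_length

  f_cage <- function(p) {
    r <- sqrt(rowSums(p^2))
    polar <- acos(pmin(1, pmax(-1, p[, 3] / pmax(r, 1e-9))))
    keep <- pmax(r * (polar - ext), pmin(r * (polar - pi / 2), -p[, 2]))
    pmax(Ri - r, r - Ro, keep)
  }
  f_tube <- function(p) {
    rho <- sqrt(p[, 1]^2 + p[, 2]^2)
    pmax(rho - outer_d / 2, Ri - p[, 3], p[, 3] - z_t1)
  }
  f_knife <- function(p, alpha_deg) {
    a <- deg2rad(alpha_deg)
    rho_a <- sqrt(p[, 2]^2 + p[, 3]^2)
    beta <- atan2(p[, 2], p[, 3])
    w <- pmin(pr$knife_width,
              pr$knife_edge_land + wedge_slope * pmax(0, rho_a - R_tip))
    pmax(R_tip - rho_a, rho_a - Ro, rho_a * (abs(beta - a) - half_arc),
         abs(p[, 1]) - w / 2)
  }
  f_support <- function(p) {
    tau <- as.numeric(p %*% dn_l)
    c1 <- as.numeric(p %*% A1_l)
    c2 <- as.numeric(p %*% A2_l)
    rho <- sqrt(c1^2 + c2^2)
    phi <- atan2(c2, c1)
    surf <- profile_interp(prof, tau, phi)
    pmax(surf + pr$contact_offset - rho,
         rho - (surf + pr$contact_offset + pr$neck_support_thickness),
         tau_lo - tau, tau - tau_hi,
         rho * (abs(phi) - wrap_half))
  }
  f_bore <- function(p) bore_d / 2 - sqrt(p[, 1]^2 + p[, 2]^2)

  f_union <- function(p) {
    v <- pmin(f_cage(p), f_tube(p), f_support(p))
    for (a in pr$knife_positions) v <- pmin(v, f_knife(p, a))
    pmax(v, f_bore(p))
  }

  margin <- 2
  s_ext <- max(prof$r) + pr$contact_offset + pr$neck_support_thickness
  xy_ext <- max(Ro, s_ext + tau_hi * sqrt(dn_l[1]^2 + dn_l[2]^2)) + margin
  z_support_min <- min(tau_hi * dn_l[3], tau_lo * dn_l[3], 0) - s_ext
  lower <- c(-xy_ext, -xy_ext, min(-1, z_support_min) - margin)
  upper <- c(xy_ext, xy_ext, z_t1 + margin)

  mesh_local <- implicit_mesh(f_union, lower, upper, voxel = pr$voxel)
  to_world <- function(m) {
    m$vertices <- sweep(m$vertices %*% t(B), 2, hc, "+")
    m
  }
  jig_mesh <- to_world(mesh_local)

  part_field <- list(
    cage = function(p) pmax(f_cage(p), f_bore(p)),
    neck_support = f_support,
    knife_1 = function(p) f_knife(p, pr$knife_positions[1]),
    knife_2 = function(p) f_knife(p, pr$knife_positions[2]),
    knife_3 = function(p) f_knife(p, pr$knife_positions[3]),
    knife_4 = function(p) f_knife(p, pr$knife_positions[4]),
    cylinder = function(p) pmax(f_tube(p), f_bore(p))
  )
  parts <- lapply(part_field, function(ff)
    to_world(implicit_mesh(ff, lower, upper, voxel = pr$voxel)))

  # contact points: knife edge midpoints on the bone sphere; neck-support rim
  # patch on the measured bone surface (the gripping lips of the snap fit)
  tips_l <- t(vapply(pr$knife_positions, function(adeg) {
    a <- deg2rad(adeg)
    R * c(0, sin(a), cos(a))
  }, numeric(3)))
  tips <- sweep(tips_l %*% t(B), 2, hc, "+")
  rim_tau <- seq(tau0 + 6, tau_hi - 1, length.out = 10)
  rim_phi <- c(seq(0.92 * wrap_half, 0.995 * wrap_half, length.out = 6),
               seq(-0.995 * wrap_half, -0.92 * wrap_half, length.out = 6))
  rg <- expand.grid(tau = rim_tau, phi = rim_phi)
  rsurf <- profile_interp(prof, rg$tau, rg$phi)
  patch <- sweep(outer(rg$tau, neck$direction) +
                   rsurf * (outer(cos(rg$phi), A1) + outer(sin(rg$phi), A2)),
                 2, hc, "+")
  # snap the patch exactly onto the bone surface (the profile is an
  # interpolant); the snap-fit cost is then exactly zero at the design pose
  patch <- mesh_closest_point(mesh, patch)$points
  rim_normals <- outer(cos(rg$phi), A1) + outer(sin(rg$phi), A2)

  knife_frames <- lapply(pr$knife_positions, function(adeg) {
    a <- deg2rad(adeg)
    list(radial = as.numeric(B %*% c(0, sin(a), cos(a))),
         tangent = as.numeric(B %*% c(0, cos(a), -sin(a))),
         normal = x_loc)
  })

  structure(list(mesh = jig_mesh, parts = parts, drill_axis = plan$axis,
                 params = pr,
                 contact_points = list(knife_tips = tips, neck_patch = patch,
                                       neck_patch_normals = rim_normals),
                 knife_frames = knife_frames,
                 head = list(center = hc, radius = R),
                 frame = plan$frame, local_basis = B, origin = hc,
                 bore_diameter = bore_d, entry_point = plan$entry_point),
            class = "jig_model")
}

#' @export
print.jig_model <- function(x, ...) {
  cat(sprintf("jig_model: %d parts, bore %.1f mm; ", length(x$parts), x$bore_diameter))
  print(x$mesh)
  invisible(x)
}

#' Verify the geometric contract of a generated jig
#'
#' Measures the invariants the design promises: watertightness (and per-part
#' watertightness), collinearity of the drill axis with the plan, patency of
#' the bore (a ray along the drill axis passes the jig without crossing it),
#' cage stand-off from the bone, and knife-tip placement on the head sphere.
#'
#' @param jig a `jig_model`.
#' @param femur the `femur_model` it was designed for.
#' @param plan the `drill_plan` used.
#' @param n_cage_samples cage-surface samples for the stand-off measurement.
#' @return list of named measurements.
#' @export
jig_contract <- function(jig, femur, plan, n_cage_samples = 4000L) {
  v <- mesh_validate(jig$mesh)
  axis_dev <- angle_between(jig$drill_axis$direction, plan$axis$direction)
  axis_off <- {
    rel <- jig$drill_axis$point - plan$axis$point
    vnorm(rel - sum(rel * plan$axis$direction) * plan$axis$direction)
  }
  # patency: walk the drill axis from well outside the guide tube down to the
  # bone entry point; an open bore is crossed zero times
  d <- plan$axis$direction
  far <- plan$entry_point - (jig$params$cylinder_length + jig$params$cage_thickness +
                               jig$head$radius + 10) * d
  seg_len <- vnorm(plan$entry_point - far) - 0.5
  pat <- mesh_ray(jig$mesh, far, d, tmax = seg_len)
  cage_pts <- mesh_sample_surface(jig$parts$cage, n_cage_samples, seed = 4L)
  standoff <- min(mesh_closest_point(femur$mesh, cage_pts)$dist)
  tip_dev <- abs(sqrt(rowSums(sweep(jig$contact_points$knife_tips, 2,
                                    jig$head$center)^2)) - jig$head$radius)
  # knife blades must actually reach the bone: the knife part surface comes
  # within (voxel-resolution of) the penetration depth of the bone surface
  knife_reach <- vapply(1:4, function(i) {
    kp <- jig$parts[[paste0("knife_", i)]]
    min(mesh_closest_point(femur$mesh, kp$vertices)$dist)
  }, numeric(1))
  list(watertight = v$watertight, outward = v$outward,
       volume = v$volume,
       parts_watertight = all(vapply(jig$parts,
                                     function(m) mesh_validate(m)$watertight,
                                     logical(1))),
       axis_angle_dev_deg = axis_dev, axis_offset_mm = axis_off,
       bore_crossings = pat$count[1],
       cage_standoff_mm = standoff,
       knife_tip_dev_mm = max(tip_dev),
       knife_min_dist_mm = max(knife_reach))
}

# pose parameter: 6-vector (tx, ty, tz, rx, ry, rz); rotation = rotation
# vector in degrees applied about the head centre, then translation
apply_pose6 <- function(p6, pts, center) {
  ang <- sqrt(sum(p6[4:6]^2))
  moved <- if (ang > 1e-12) {
    sweep(sweep(pts, 2, center) %*% t(rotation_about(p6[4:6], ang)), 2, center, "+")
  } else pts
  sweep(moved, 2, p6[1:3], "+")
}

#' Validate the snap fit of a jig on its femur
#'
#' Quantifies the paper-grade qualitative checklist on the synthetic
#' analogue. The fit cost of a jig pose combines the two contact families of
#' the design: the four knife edges are treated as embedded point constraints
#' (a blade seated in its cut resists displacement in every direction), and
#' the neck support grips through its superior and inferior rim lips, modelled
#' as point-to-surface springs (free to slide, resisting normal motion). The
#' design pose has zero cost; the validator (a) searches the +/- `trans_range`
#' mm / `rot_range` deg pose neighbourhood from random restarts for competing
#' zero-cost seatings ("number of possible positions"), and (b) probes
#' direction-resolved stiffness: cost increase for unit anteroposterior (AP)
#' and mediolateral (ML) translations and for a unit varus-valgus rotation,
#' with per-contact-family attribution obtained by zeroing each family.
#'
#' @param femur the `femur_model`.
#' @param jig the `jig_model` designed for it.
#' @param trans_range,rot_range half-widths of the searched pose box (mm, deg).
#' @param n_starts random restarts for the minimum search.
#' @param seed search seed.
#' @param seat_tol cost (mm^2) below which a local minimum counts as a
#'   seated pose.
#' @return a fit report: `unique_minimum`, `n_possible_positions`,
#'   `design_cost`, `stiffness` (per direction: total and per contact
#'   family), and the table of located minima.
#' @export
validate_snap_fit <- function(femur, jig, trans_range = 5, rot_range = 10,
                              n_starts = 30L, seed = 1L, seat_tol = 0.05) {
  stopifnot(inherits(jig, "jig_model"))
  tips <- jig$contact_points$knife_tips
  patch <- jig$contact_points$neck_patch
  if (nrow(tips) < 1L || nrow(patch) < 1L)
    stop_with("sraguide_invalid_jig", "jig has no contact points")
  hc <- jig$head$center
  mesh <- femur$mesh
  bone_idx <- mesh_index(mesh)

  knife_cost <- function(p6) {
    moved <- apply_pose6(p6, tips, hc)
    mean(rowSums((moved - tips)^2))
  }
  support_cost <- function(p6) {
    moved <- apply_pose6(p6, patch, hc)
    mean(mesh_closest_point(mesh, moved, index = bone_idx)$dist^2)
  }
  total_cost <- function(p6) knife_cost(p6) + support_cost(p6)

  design_cost <- total_cost(rep(0, 6))

  probe <- function(costf, dir6) {
    (costf(dir6) + costf(-dir6)) / 2
  }
  frame <- jig$frame
  dirs <- list(ap = c(frame$anterior, 0, 0, 0),
               ml = c(frame$medial, 0, 0, 0),
               varus_valgus = c(0, 0, 0, frame$anterior))
  stiffness <- lapply(dirs, function(d6) {
    list(total = probe(total_cost, d6),
         knives = probe(knife_cost, d6),
         neck_support = probe(support_cost, d6))
  })

  starts <- with_seed(seed, {
    matrix(c(stats::runif(3L * n_starts, -trans_range, trans_range),
             stats::runif(3L * n_starts, -rot_range, rot_range)),
           ncol = 6)[, c(1, 3, 5, 2, 4, 6), drop = FALSE]
  })
  minima <- lapply(seq_len(n_starts), function(i) {
    o <- stats::optim(starts[i, ], total_cost, method = "Nelder-Mead",
                      control = list(maxit = 600, reltol = 1e-10))
    list(par = o$par, value = o$value)
  })
  vals <- vapply(minima, `[[`, numeric(1), "value")
  # cluster in cost order so each cluster is anchored at its best-converged
  # (deepest) representative; greedy clustering is otherwise sensitive to
  # which sloppily-converged run happens to come first
  ord <- order(vals)
  seated <- minima[ord[vals[ord] < seat_tol]]
  clusters <- list()
  for (m in seated) {
    placed <- FALSE
    for (j in seq_along(clusters)) {
      ctr <- clusters[[j]]
      if (vnorm(m$par[1:3] - ctr[1:3]) < 0.5 && vnorm(m$par[4:6] - ctr[4:6]) < 1) {
        placed <- TRUE
        break
      }
    }
    if (!placed) clusters[[length(clusters) + 1L]] <- m$par
  }
  n_pos <- max(1L, length(clusters))  # the design pose itself always seats
  at_design <- length(clusters) == 0L ||
    all(vapply(clusters, function(ctr)
      vnorm(ctr[1:3]) < 0.5 && vnorm(ctr[4:6]) < 1, logical(1)))
  list(unique_minimum = at_design && length(clusters) <= 1L,
       n_possible_positions = n_pos,
       design_cost = design_cost,
       stiffness = stiffness,
       minima = data.frame(value = vals, t(vapply(minima, `[[`, numeric(6), "par"))))
}

#' Export a jig (or any mesh) to STL
#'
#' @param jig a `jig_model` or [mesh3()].
#' @param path output path.
#' @param ascii write the ASCII dialect.
#' @return `path`, invisibly.
#' @export
export_stl <- function(jig, path, ascii = FALSE) {
  mesh <- if (inherits(jig, "jig_model")) jig$mesh else jig
  write_stl(mesh, path, ascii = ascii)
}
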