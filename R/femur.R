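# Synthetic proximal femur with exact ground truth, plus a simulated
# post-operative scan of the resected head with a drill channel.
#
# The bone is composed analytically: a spherical head, an elliptic neck with
# a mild symmetric flare (waist mid-neck), a circular-arc bend realizing the
# CCD angle, and a shaft stub. The surface is generated as a single swept
# grid (sections perpendicular to the skeleton, per-section radius = union of
# the analytic primitives), so it is watertight by construction and the head
# centre, neck axis, CCD and anteversion are exact. Surface noise is applied
# along vertex normals after ground truth is recorded. The mesh models the
# bone surface as segmented from CT; articular cartilage is not visible on CT
# and is carried only as metadata used by the jig's knife design.

#' Parameters of the synthetic proximal femur
#'
#' Defaults describe an adult femur at the scale of the pilot anatomy: head
#' radius 24 mm, elliptic neck 16 x 13 mm (superoinferior x anteroposterior),
#' CCD angle 127 deg, anteversion 15 deg.
#'
#' @param head_radius femoral head radius (mm).
#' @param cartilage_thickness nominal cartilage thickness over the head polar
#'   cap (mm); metadata only — CT-segmented bone models do not contain
#'   cartilage, which is why the jig knives are sized to cut through it.
#' @param neck_length head centre to neck-shaft junction (mm).
#' @param neck_radii length-2: superoinferior and anteroposterior neck
#'   semi-axes at the waist (mm).
#' @param ccd_angle caput-collum-diaphyseal angle (deg) between neck axis and
#'   shaft axis.
#' @param anteversion axial-plane forward tilt of the neck axis (deg).
#' @param shaft_radius,shaft_length proximal shaft stub dimensions (mm).
#' @param neck_flare strength of the trochanteric flare at the distal end of
#'   the neck (dimensionless). The flare is a radial scaling of the centred
#'   elliptic section, so section centroids stay exactly on the neck axis.
#' @param bend_radius radius of the neck-to-shaft bend arc (mm); must exceed
#'   the largest section radius to keep the sweep embedded.
#' @param fovea_radius,fovea_depth,fovea_offset size (mm), depth (mm) and
#'   angular offset from the head apex (deg, toward posteroinferior) of the
#'   fovea capitis, modelled as a subtracted spherical dimple. The fovea is
#'   the main rotational landmark of the otherwise near-symmetric head and is
#'   what makes scan-to-model registration well-posed; set
#'   `fovea_depth = 0` to disable.
#' @param noise_sd Gaussian surface noise along vertex normals (mm).
#' @param n_osteophytes number of osteophyte bumps near the head-neck
#'   transition.
#' @param side `"left"` or `"right"`.
#' @param seed RNG seed for noise and osteophytes.
#' @param target_edge target mesh edge length (mm).
#' @return a `femur_params` list.
#' @export
femur_params <- function(head_radius = 24, cartilage_thickness = 2,
                         neck_length = 35, neck_radii = c(16, 13),
                         ccd_angle = 127, anteversion = 15,
                         shaft_radius = 15, shaft_length = 60,
                         neck_flare = 0.5, bend_radius = 25,
                         fovea_radius = 6, fovea_depth = 2,
                         fovea_offset = 25,
                         noise_sd = 0.15, n_osteophytes = 0,
                         side = "left", seed = 1L, target_edge = 1.0) {
  p <- list(head_radius = head_radius, cartilage_thickness = cartilage_thickness,
            neck_length = neck_length, neck_radii = as.numeric(neck_radii),
            ccd_angle = ccd_angle, anteversion = anteversion,
            shaft_radius = shaft_radius, shaft_length = shaft_length,
            neck_flare = neck_flare, bend_radius = bend_radius,
            fovea_radius = fovea_radius, fovea_depth = fovea_depth,
            fovea_offset = fovea_offset,
            noise_sd = noise_sd, n_osteophytes = n_osteophytes,
            side = match.arg(side, c("left", "right")), seed = as.integer(seed),
            target_edge = target_edge)
  lens <- c(p$head_radius, p$neck_length, p$neck_radii, p$shaft_radius,
            p$shaft_length, p$bend_radius, p$target_edge)
  if (any(!is.finite(lens)) || any(lens <= 0))
    stop_invalid("all femur dimensions must be positive and finite")
  if (p$cartilage_thickness < 0 || p$cartilage_thickness >= p$head_radius)
    stop_invalid("cartilage_thickness must be in [0, head_radius)")
  if (p$noise_sd < 0) stop_invalid("noise_sd must be non-negative")
  if (p$fovea_depth < 0 || (p$fovea_depth > 0 && p$fovea_depth >= p$fovea_radius))
    stop_invalid("fovea_depth must be in [0, fovea_radius)")
  g_end <- 1 + p$neck_flare * (0.05 / 0.15)^2
  if (max(p$neck_radii) * g_end >= 0.95 * p$head_radius)
    stop_geometry("neck is wider than the head: the composed solid would self-intersect")
  if (max(max(p$neck_radii) * g_end, p$shaft_radius) >= p$bend_radius)
    stop_geometry("bend_radius must exceed the largest section radius (sweep would fold over)")
  class(p) <- "femur_params"
  p
}

# in-section elliptic radius, angle measured from the first basis vector
ellipse_radius <- function(theta, r1, r2) {
  r1 * r2 / sqrt((r2 * cos(theta))^2 + (r1 * sin(theta))^2)
}

neck_flare_factor <- function(u, p) {
  # u measured from the head apex along the neck axis. The neck is a constant
  # elliptic cylinder over its waist plateau and flares quadratically toward
  # the trochanter from 95% of the neck length — this is the "section area
  # starts increasing" saddle that bounds the neck corridor distally.
  onset <- p$head_radius + 0.95 * p$neck_length
  scale <- 0.15 * p$neck_length
  1 + p$neck_flare * (pmax(0, u - onset) / scale)^2
}

smoothstep <- function(x) {
  x <- pmin(1, pmax(0, x))
  x * x * (3 - 2 * x)
}

#' Generate a synthetic proximal femur with known ground truth
#'
#' @param params a [femur_params()].
#' @return a `femur_model`: list with `mesh` (watertight [mesh3()]) and
#'   `truth` (head centre/radius, neck axis, shaft axis, anatomical frame —
#'   all exact, recorded before surface noise), plus the generating `params`.
#' @examples
#' fem <- generate_femur(femur_params(noise_sd = 0, target_edge = 2))
#' fem$truth$head_radius
#' @export
generate_femur <- function(params = femur_params()) {
  if (!inherits(params, "femur_params")) params <- do.call(femur_params, params)
  p <- params
  R <- p$head_radius
  th <- deg2rad(180 - p$ccd_angle)
  av <- deg2rad(p$anteversion)
  # neck direction from head centre toward medial-superior(-anterior)
  d <- c(sin(th) * cos(av), sin(th) * sin(av), cos(th))
  dn <- -d                        # drilling direction: apex -> lateral
  hc <- c(0, 0, 0)
  Jn <- hc + p$neck_length * dn   # neck-shaft junction
  t1 <- dn
  t2 <- c(0, 0, -1)               # shaft distal direction
  phi_max <- acos(pmin(1, pmax(-1, sum(t1 * t2))))
  w_axis <- unitize(cross3(t1, t2))
  m_hat <- cross3(w_axis, t1)
  Cb <- Jn + p$bend_radius * m_hat

  te <- p$target_edge
  ncol_ <- max(24L, as.integer(ceiling(2 * pi * R / te)))
  thetas <- (0:(ncol_ - 1)) * 2 * pi / ncol_

  # station list: along-path position, tangent, section basis, radius function
  stations <- list()
  add_station <- function(pos, E1, E2, radii) {
    stations[[length(stations) + 1L]] <<- list(pos = pos, E1 = E1, E2 = E2, r = radii)
  }

  E1_0 <- unitize(c(0, 0, 1) - sum(c(0, 0, 1) * t1) * t1)  # superior-ish in section
  E2_0 <- cross3(t1, E1_0)

  # fovea capitis: subtracted spherical dimple offset from the apex toward
  # posteroinferior; shallow, so the surface stays star-shaped per section
  # and the swept mesh and the implicit scan field describe the same solid
  fovea <- NULL
  if (p$fovea_depth > 0) {
    w <- project_onto_plane(c(0, -0.55, -0.84), d)
    if (vnorm(w) < 1e-6) w <- E1_0
    w <- unitize(w)
    off <- deg2rad(p$fovea_offset)
    f_dir <- cos(off) * d + sin(off) * w
    fovea <- list(center = hc + (R + p$fovea_radius - p$fovea_depth) * f_dir,
                  radius = p$fovea_radius)
  }

  sec_radius_headneck <- function(u) {
    delta <- u - R
    rs <- if (abs(delta) < R) sqrt(R^2 - delta^2) else 0
    rn <- if (u > R) ellipse_radius(thetas, p$neck_radii[1], p$neck_radii[2]) *
      neck_flare_factor(u, p) else 0
    r <- pmax(rs, rn)
    if (!is.null(fovea)) {
      P <- apex + u * dn
      vhat <- outer(cos(thetas), E1_0) + outer(sin(thetas), E2_0)
      rel <- P - fovea$center
      b <- 2 * as.numeric(vhat %*% rel)
      cc <- sum(rel^2) - fovea$radius^2
      disc <- b^2 - 4 * cc
      ok <- disc > 0
      t_in <- ifelse(ok, (-b - sqrt(pmax(disc, 0))) / 2, Inf)
      t_out <- ifelse(ok, (-b + sqrt(pmax(disc, 0))) / 2, -Inf)
      clip <- ok & t_in > 0 & t_in < r & r < t_out
      r <- ifelse(clip, t_in, r)
    }
    r
  }

  # head cap: polar-angle spacing for uniform arc length
  dpsi <- te / R
  psis <- seq(dpsi, pi / 2, by = dpsi)
  apex <- hc - R * dn       # dn points from apex into the neck
  for (ps in psis) {
    u <- R * (1 - cos(ps))
    add_station(apex + u * dn, E1_0, E2_0, sec_radius_headneck(u))
  }
  u_head_end <- R * (1 - cos(psis[length(psis)]))
  u_junction <- R + p$neck_length
  for (u in seq(u_head_end + te, u_junction, by = te)) {
    add_station(apex + u * dn, E1_0, E2_0, sec_radius_headneck(u))
  }
  r_neck_end <- ellipse_radius(thetas, p$neck_radii[1], p$neck_radii[2]) *
    neck_flare_factor(u_junction, p)
  # bend arc
  dphi <- te / p$bend_radius
  for (ph in seq(dphi, phi_max, by = dphi)) {
    Rb <- rotation_about(w_axis, rad2deg(ph))
    pos <- Cb - p$bend_radius * as.numeric(Rb %*% m_hat)
    wb <- smoothstep(ph / phi_max)
    add_station(pos, as.numeric(Rb %*% E1_0), as.numeric(Rb %*% E2_0),
                (1 - wb) * r_neck_end + wb * p$shaft_radius)
  }
  Rb <- rotation_about(w_axis, rad2deg(phi_max))
  bend_end <- Cb - p$bend_radius * as.numeric(Rb %*% m_hat)
  E1_s <- as.numeric(Rb %*% E1_0); E2_s <- as.numeric(Rb %*% E2_0)
  for (s in seq(te, p$shaft_length, by = te)) {
    add_station(bend_end + s * t2, E1_s, E2_s, rep(p$shaft_radius, ncol_))
  }

  nst <- length(stations)
  verts <- matrix(0, 1L + nst * ncol_ + 1L, 3)
  verts[1, ] <- apex
  ct <- cos(thetas); st <- sin(thetas)
  for (i in seq_len(nst)) {
    stn <- stations[[i]]
    ring <- outer(stn$r * ct, stn$E1) + outer(stn$r * st, stn$E2)
    verts[1L + (i - 1L) * ncol_ + seq_len(ncol_), ] <- sweep(ring, 2, stn$pos, "+")
  }
  end_center <- stations[[nst]]$pos
  verts[nrow(verts), ] <- end_center

  ring_idx <- function(i) 1L + (i - 1L) * ncol_ + seq_len(ncol_)
  faces <- vector("list", nst + 1L)
  r1 <- ring_idx(1)
  nxt <- c(2:ncol_, 1L)
  faces[[1]] <- cbind(1L, r1, r1[nxt])
  for (i in seq_len(nst - 1L)) {
    a <- ring_idx(i); b <- ring_idx(i + 1L)
    faces[[i + 1L]] <- rbind(cbind(a, b, b[nxt]), cbind(a, b[nxt], a[nxt]))
  }
  rn_ <- ring_idx(nst)
  faces[[nst + 1L]] <- cbind(nrow(verts), rn_[nxt], rn_)
  faces <- do.call(rbind, faces)
  mesh <- mesh3(verts, faces)
  if (mesh_volume(mesh) < 0) mesh$faces <- mesh$faces[, c(1, 3, 2)]

  # mirror for right side (through the sagittal x = 0 plane)
  mirror <- p$side == "right"
  if (mirror) {
    mesh$vertices[, 1] <- -mesh$vertices[, 1]
    mesh$faces <- mesh$faces[, c(1, 3, 2)]
    d <- d * c(-1, 1, 1); dn <- dn * c(-1, 1, 1)
    if (!is.null(fovea)) fovea$center <- fovea$center * c(-1, 1, 1)
  }

  side_sign <- if (mirror) -1 else 1
  truth <- list(
    head_center = hc,
    head_radius = R,
    neck_axis = axis3(hc, dn),
    shaft_axis = axis3(if (mirror) Jn * c(-1, 1, 1) else Jn, t2),
    frame = anatomical_frame(hc, c(side_sign, 0, 0), c(0, 1, 0), c(0, 0, 1),
                             side = p$side),
    cartilage_thickness = p$cartilage_thickness,
    fovea = fovea
  )

  # osteophytes: smooth bumps near the head-neck transition
  if (p$n_osteophytes > 0) {
    vdist <- sqrt(rowSums(mesh$vertices^2))
    band <- which(vdist > 1.0 * R & vdist < 1.45 * R)
    vn <- mesh_vertex_normals(mesh)
    bump <- with_seed(p$seed + 7919L, {
      centers <- sample(band, p$n_osteophytes, replace = length(band) < p$n_osteophytes)
      amps <- stats::runif(p$n_osteophytes, 0.5, 1.5)
      list(centers = centers, amps = amps)
    })
    disp <- numeric(nrow(mesh$vertices))
    for (i in seq_len(p$n_osteophytes)) {
      cpt <- mesh$vertices[bump$centers[i], ]
      dd2 <- rowSums(sweep(mesh$vertices, 2, cpt)^2)
      disp <- disp + bump$amps[i] * exp(-dd2 / (2 * 3^2))
    }
    mesh$vertices <- mesh$vertices + disp * vn
  }

  if (p$noise_sd > 0) {
    vn <- mesh_vertex_normals(mesh)
    eps <- with_seed(p$seed, stats::rnorm(nrow(mesh$vertices), 0, p$noise_sd))
    mesh$vertices <- mesh$vertices + eps * vn
  }

  structure(list(mesh = mesh, truth = truth, params = p), class = "femur_model")
}

#' @export
print.femur_model <- function(x, ...) {
  cat(sprintf("femur_model (%s): head r=%.1f mm, CCD %.1f deg, anteversion %.1f deg; ",
              x$params$side, x$params$head_radius, x$params$ccd_angle,
              x$params$anteversion))
  print(x$mesh)
  invisible(x)
}

# analytic signed field of the head + proximal neck solid (planning frame),
# shared by the post-op scan simulator; matches the swept surface
femur_headneck_field <- function(p, hc, dn, E1n, E2n, fovea = NULL) {
  force(p); force(hc); force(dn); force(E1n); force(E2n); force(fovea)
  function(pts) {
    rel <- sweep(pts, 2, hc)
    tau <- as.numeric(rel %*% dn)
    f_sph <- sqrt(rowSums(rel^2)) - p$head_radius
    q <- rel - outer(tau, dn)
    rho <- sqrt(rowSums(q^2))
    theta <- atan2(as.numeric(q %*% E2n), as.numeric(q %*% E1n))
    rell <- ellipse_radius(theta, p$neck_radii[1], p$neck_radii[2]) *
      neck_flare_factor(tau + p$head_radius, p)
    f_neck <- pmax(rho - rell, -tau)
    f <- pmin(f_sph, f_neck)
    if (!is.null(fovea))
      f <- pmax(f, fovea$radius - sqrt(rowSums(sweep(pts, 2, fovea$center)^2)))
    f
  }
}

#' Simulate a post-operative optical scan of the resected femoral head
#'
#' Builds the resected head + neck-stump solid with a cylindrical drill
#' channel along the *achieved* axis — the planned axis perturbed by a known
#' angular error (about a perpendicular axis at a chosen azimuth) and a known
#' tangential entry-point shift — then meshes it, adds surface noise, and
#' expresses it in an arbitrary scan frame. The perturbation and pose are
#' recorded as ground truth so the evaluation pipeline can be validated
#' end-to-end.
#'
#' @param model a `femur_model` (with truth).
#' @param planned planned drill axis ([axis3()] or a `drill_plan`).
#' @param angular_error injected angular deviation (deg, >= 0).
#' @param error_plane_azimuth azimuth (deg) of the perpendicular rotation
#'   axis, measured from the anterior direction around the planned axis.
#' @param entry_shift length-2 tangential entry shift (mm) in the
#'   (anterior-ish, lateral-ish) tangent basis at the entry point.
#' @param pose a [rigid_transform()] mapping planning to scan frame, or
#'   `"random"` for a seeded random pose (rotation up to 15 deg, translation
#'   up to 20 mm — the residual misalignment left after the coarse manual
#'   pre-alignment that precedes ICP in scan-processing software).
#' @param noise_sd scan noise along vertex normals (mm).
#' @param seed RNG seed.
#' @param channel_radius drill-channel radius (mm); default 1.6 (3.2 mm wire).
#' @param cut_fraction osteotomy position as a fraction of neck length from
#'   the head centre.
#' @param voxel lattice spacing for meshing the resected solid (mm).
#' @return a `postop_scan`: list with `head_mesh` (scan frame),
#'   `applied_pose` (planning -> scan), `achieved_axis_truth` (planning
#'   frame), `planned_axis`, `channel_radius`, `partial_overlap_fraction`,
#'   `noise_sd`.
#' @export
simulate_postop_scan <- function(model, planned, angular_error = 0,
                                 error_plane_azimuth = 0,
                                 entry_shift = c(0, 0), pose = identity_transform(),
                                 noise_sd = 0, seed = 1L,
                                 channel_radius = 1.6, cut_fraction = 0.85,
                                 voxel = 0.4) {
  stopifnot(inherits(model, "femur_model"))
  if (inherits(planned, "drill_plan")) planned <- planned$axis
  if (!inherits(planned, "axis3")) stop_invalid("planned must be an axis3 or drill_plan")
  if (angular_error < 0) stop_invalid("angular_error must be >= 0")
  p <- model$params
  if (channel_radius >= min(p$neck_radii))
    stop_geometry("channel radius >= neck minor radius: degenerate channel")

  dpl <- planned$direction
  anterior <- model$truth$frame$anterior
  e1 <- project_onto_plane(anterior, dpl)
  if (vnorm(e1) < 1e-6) e1 <- project_onto_plane(c(1, 0, 0), dpl)
  e1 <- unitize(e1)
  e2 <- cross3(dpl, e1)

  az <- deg2rad(error_plane_azimuth)
  rot_axis <- cos(az) * e1 + sin(az) * e2
  achieved_dir <- if (angular_error > 0)
    as.numeric(rotation_about(rot_axis, angular_error) %*% dpl) else dpl

  entry <- compute_entry_point(model$mesh, planned)
  shifted <- entry + entry_shift[1] * e1 + entry_shift[2] * e2
  hit <- mesh_ray(model$mesh, shifted - 3 * p$head_radius * achieved_dir, achieved_dir)
  if (is.na(hit$t[1])) stop_geometry("achieved axis misses the bone")
  entry_achieved <- shifted - 3 * p$head_radius * achieved_dir + hit$t[1] * achieved_dir
  achieved <- axis3(entry_achieved, achieved_dir)

  hc <- model$truth$head_center
  dn <- model$truth$neck_axis$direction
  E1n <- unitize(project_onto_plane(c(0, 0, 1), dn))
  E2n <- cross3(dn, E1n)
  bone_field <- femur_headneck_field(p, hc, dn, E1n, E2n,
                                     fovea = model$truth$fovea)
  tau_cut <- cut_fraction * p$neck_length
  f <- function(pts) {
    rel <- sweep(pts, 2, hc)
    tau <- as.numeric(rel %*% dn)
    fb <- bone_field(pts)
    fch <- channel_radius - {
      rel2 <- sweep(pts, 2, achieved$point)
      tt <- as.numeric(rel2 %*% achieved$direction)
      qq <- rel2 - outer(tt, achieved$direction)
      sqrt(rowSums(qq^2))
    }
    pmax(fb, tau - tau_cut, fch)
  }
  rmax <- max(p$neck_radii) * neck_flare_factor(p$head_radius + tau_cut, p)
  corners <- rbind(hc - (p$head_radius + 2), hc + (p$head_radius + 2),
                   hc + tau_cut * dn - (rmax + 2), hc + tau_cut * dn + (rmax + 2))
  lower <- apply(corners, 2, min); upper <- apply(corners, 2, max)
  scan_mesh <- implicit_mesh(f, lower, upper, voxel = voxel)

  ov_pts <- mesh_sample_surface(scan_mesh, 1000, seed = seed + 13L)
  ov <- mesh_closest_point(model$mesh, ov_pts)
  partial_overlap <- mean(ov$dist < 0.5)

  if (noise_sd > 0) {
    vn <- mesh_vertex_normals(scan_mesh)
    eps <- with_seed(seed, stats::rnorm(nrow(scan_mesh$vertices), 0, noise_sd))
    scan_mesh$vertices <- scan_mesh$vertices + eps * vn
  }

  if (identical(pose, "random")) {
    pose <- with_seed(seed + 101L, {
      ax <- unitize(stats::rnorm(3))
      ang <- stats::runif(1, 0, 15)
      tr <- stats::runif(3, -20, 20)
      rigid_transform(rotation_about(ax, ang), tr)
    })
  }
  stopifnot(inherits(pose, "rigid_transform"))
  scan_mesh <- apply_transform(pose, scan_mesh)

  structure(list(head_mesh = scan_mesh, applied_pose = pose,
                 achieved_axis_truth = achieved, planned_axis = planned,
                 channel_radius = channel_radius,
                 partial_overlap_fraction = partial_overlap,
                 noise_sd = noise_sd, cut_fraction = cut_fraction),
            class = "postop_scan")
}

#' @export
print.postop_scan <- function(x, ...) {
  cat(sprintf("postop_scan: channel r=%.2f mm, overlap %.2f; ",
              x$channel_radius, x$partial_overlap_fraction))
  print(x$head_mesh)
  invisible(x)
}
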