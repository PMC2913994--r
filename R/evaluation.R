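# Post-operative accuracy analysis: rigid ICP registration of the (simulated)
# optical scan onto the planning model, drill-channel axis extraction by
# cylinder fitting, and deviation metrics between planned and achieved drill
# axes (true-3D angle, anatomical-plane components, insertion-point distance).

#' Closed-form optimal rigid alignment (Procrustes / Kabsch)
#'
#' Least-squares rigid transform mapping the rows of `P` onto the rows of
#' `Q` (same length, in correspondence), via the SVD of the cross-covariance
#' with a reflection guard.
#'
#' @param P,Q n x 3 matrices in correspondence.
#' @return a [rigid_transform()] `T` minimizing `sum |T(P) - Q|^2`.
#' @export
procrustes_rigid <- function(P, Q) {
  pbar <- colMeans(P)
  qbar <- colMeans(Q)
  H <- crossprod(sweep(P, 2, pbar), sweep(Q, 2, qbar))
  sv <- svd(H)
  d <- sign(det(sv$v %*% t(sv$u)))
  R <- sv$v %*% diag(c(1, 1, d)) %*% t(sv$u)
  rigid_transform(R, qbar - as.numeric(R %*% pbar))
}

# PCA pre-alignment of two point clouds: centroids + principal axes with the
# 4 proper sign-flip combinations, disambiguated by post-alignment residual
pca_align <- function(moving, target_pts, n_eval = 500L, seed = 1L) {
  pm <- colMeans(moving)
  pt <- colMeans(target_pts)
  Em <- svd(crossprod(sweep(moving, 2, pm)) / nrow(moving))$u
  Et <- svd(crossprod(sweep(target_pts, 2, pt)) / nrow(target_pts))$u
  if (det(Em) < 0) Em[, 3] <- -Em[, 3]
  if (det(Et) < 0) Et[, 3] <- -Et[, 3]
  flips <- list(c(1, 1, 1), c(1, -1, -1), c(-1, 1, -1), c(-1, -1, 1))
  sub <- moving[with_seed(seed, sample.int(nrow(moving), min(n_eval, nrow(moving)))), ,
                drop = FALSE]
  best <- NULL
  for (fl in flips) {
    R <- Et %*% diag(fl) %*% t(Em)
    tr <- rigid_transform(R, pt - as.numeric(R %*% pm))
    X <- apply_transform(tr, sub)
    # nearest-target-point residual proxy
    d2 <- vapply(seq_len(nrow(X)), function(i)
      min(rowSums(sweep(target_pts, 2, X[i, ])^2)), numeric(1))
    sc <- stats::median(d2)
    if (is.null(best) || sc < best$score) best <- list(score = sc, tr = tr)
  }
  best$tr
}

#' Iterative closest point rigid registration
#'
#' Classic point-to-point ICP: nearest-point correspondences against the
#' target mesh surface (exact closest point on triangles, grid-accelerated),
#' closed-form optimal rigid update per iteration ([procrustes_rigid()]),
#' optional trimming of the worst residual fraction for partial-overlap
#' robustness. The trimmed RMS error is non-increasing; a safeguard stops and
#' reverts if it ever rises.
#'
#' @param moving n x 3 point matrix or a [mesh3()] (vertices are used).
#' @param target target [mesh3()].
#' @param init initial [rigid_transform()], `"pca"` for PCA pre-alignment, or
#'   `NULL` for identity.
#' @param max_iter iteration cap.
#' @param tol convergence threshold on the RMSE change (mm).
#' @param trim_fraction fraction of worst correspondences discarded each
#'   iteration (0 to 0.5).
#' @param n_sample optional random subsample size of the moving points.
#' @param seed seed for subsampling.
#' @param index optional [mesh_index()] of the target.
#' @return an `icp_result`: `transform` (moving -> target), `rmse`,
#'   `n_iterations`, `converged`, `inlier_fraction`, `trace` (per-iteration
#'   RMSE).
#' @export
icp_register <- function(moving, target, init = NULL, max_iter = 100L,
                         tol = 1e-6, trim_fraction = 0, n_sample = NULL,
                         seed = 1L, index = NULL) {
  if (inherits(moving, "mesh3")) moving <- moving$vertices
  moving <- as.matrix(moving)
  if (nrow(moving) < 100L)
    stop_with("sraguide_registration_error", "need at least 100 moving points")
  if (trim_fraction < 0 || trim_fraction > 0.5)
    stop_invalid("trim_fraction must be in [0, 0.5]")
  if (!is.null(n_sample) && n_sample < nrow(moving)) {
    moving <- moving[with_seed(seed, sample.int(nrow(moving), n_sample)), ,
                     drop = FALSE]
  }
  Tcur <- if (is.null(init)) {
    identity_transform()
  } else if (identical(init, "pca")) {
    pca_align(moving, target$vertices, seed = seed)
  } else {
    stopifnot(inherits(init, "rigid_transform"))
    init
  }
  if (is.null(index)) index <- mesh_index(target)
  n_keep <- max(3L, floor(nrow(moving) * (1 - trim_fraction)))
  trace <- numeric(0)
  converged <- FALSE
  rmse_prev <- Inf
  for (it in seq_len(max_iter)) {
    X <- apply_transform(Tcur, moving)
    cp <- mesh_closest_point(target, X, index = index)
    ord <- order(cp$dist)
    keep <- ord[seq_len(n_keep)]
    dT <- procrustes_rigid(X[keep, , drop = FALSE], cp$points[keep, , drop = FALSE])
    Tnew <- compose_transform(dT, Tcur)
    resid <- apply_transform(dT, X[keep, , drop = FALSE]) - cp$points[keep, , drop = FALSE]
    rmse <- sqrt(mean(rowSums(resid^2)))
    if (rmse > rmse_prev + 1e-12) {
      converged <- TRUE  # safeguard: revert and stop at the previous optimum
      break
    }
    Tcur <- Tnew
    trace <- c(trace, rmse)
    if (is.finite(rmse_prev) && abs(rmse_prev - rmse) < tol) {
      converged <- TRUE
      rmse_prev <- rmse
      break
    }
    rmse_prev <- rmse
  }
  structure(list(transform = Tcur, rmse = rmse_prev,
                 n_iterations = length(trace), converged = converged,
                 inlier_fraction = 1 - trim_fraction, trace = trace),
            class = "icp_result")
}

#' @export
print.icp_result <- function(x, ...) {
  cat(sprintf("icp_result: rmse %.5f mm after %d iterations (%s)\n",
              x$rmse, x$n_iterations,
              if (x$converged) "converged" else "not converged"))
  invisible(x)
}

#' Extract drill-channel wall points from a registered scan mesh
#'
#' Channel-wall candidates are vertices close to the expected axis whose
#' outward normals point back toward the axis (the wall of a drilled tunnel
#' faces inward).
#'
#' @param mesh registered scan [mesh3()] (planning frame).
#' @param approx_axis an [axis3()] near the channel (e.g. the planned axis).
#' @param radius expected channel radius (mm).
#' @param radial_window candidates within `radial_window * radius` of the
#'   axis are considered.
#' @param normals optional precomputed vertex normals of `mesh`.
#' @return matrix of channel wall points.
#' @export
extract_channel_points <- function(mesh, approx_axis, radius,
                                   radial_window = 2.2, normals = NULL) {
  rel <- sweep(mesh$vertices, 2, approx_axis$point)
  t <- as.numeric(rel %*% approx_axis$direction)
  radial <- rel - outer(t, approx_axis$direction)
  rho <- sqrt(rowSums(radial^2))
  vn <- normals %||% mesh_vertex_normals(mesh)
  inward <- rowSums(vn * radial / pmax(rho, 1e-9))
  keep <- rho < radial_window * radius & inward < -0.5
  mesh$vertices[keep, , drop = FALSE]
}

#' Fit a cylinder axis to drill-channel points
#'
#' Initializes with the principal axis of the point set and refines by least
#' squares on `sum((distance-to-axis - r)^2)` over axis orientation, axis
#' position and radius. The returned direction is sign-aligned with
#' `align_dir` when given (conventionally: into the bone).
#'
#' @param points n x 3 channel-wall points (>= 50).
#' @param expected_radius nominal channel radius (mm); used as the initial
#'   radius and for the residual sanity bound.
#' @param align_dir optional direction for the sign convention.
#' @return an [axis3()] through the channel centroid, with attributes
#'   `radius` and `rms_residual`.
#' @export
fit_drill_axis <- function(points, expected_radius, align_dir = NULL) {
  P <- as.matrix(points)
  if (nrow(P) < 50L)
    stop_with("sraguide_fit_error", "need at least 50 channel-wall points")
  ctr <- colMeans(P)
  Pc <- sweep(P, 2, ctr)
  d0 <- svd(crossprod(Pc) / nrow(Pc))$u[, 1]
  # orthonormal complement for the 2-dof axis offset
  basis <- function(d) {
    e1 <- unitize(project_onto_plane(if (abs(d[1]) < 0.9) c(1, 0, 0) else c(0, 1, 0), d))
    cbind(e1, cross3(d, e1))
  }
  obj <- function(par) {
    # par: 2 rotation offsets (rad) of the direction, 2 in-plane offsets, radius
    Bd <- basis(d0)
    d <- unitize(d0 + par[1] * Bd[, 1] + par[2] * Bd[, 2])
    Bp <- basis(d)
    pt <- ctr + par[3] * Bp[, 1] + par[4] * Bp[, 2]
    rel <- sweep(P, 2, pt)
    tt <- as.numeric(rel %*% d)
    rho <- sqrt(pmax(rowSums(rel^2) - tt^2, 0))
    sum((rho - par[5])^2)
  }
  o <- stats::optim(c(0, 0, 0, 0, expected_radius), obj, method = "BFGS",
                    control = list(maxit = 300, reltol = 1e-14))
  Bd <- basis(d0)
  d <- unitize(d0 + o$par[1] * Bd[, 1] + o$par[2] * Bd[, 2])
  Bp <- basis(d)
  pt <- ctr + o$par[3] * Bp[, 1] + o$par[4] * Bp[, 2]
  rms <- sqrt(o$value / nrow(P))
  if (rms > 0.5 * expected_radius)
    stop_with("sraguide_fit_error",
              sprintf("points are not cylinder-like (rms %.3f mm)", rms))
  if (!is.null(align_dir) && sum(d * align_dir) < 0) d <- -d
  ax <- axis3(pt, d)
  attr(ax, "radius") <- o$par[5]
  attr(ax, "rms_residual") <- rms
  ax
}

#' Deviation between planned and achieved drill axes
#'
#' The paper-grade per-case record: true-3D angular deviation between the
#' directions, its frontal / axial / sagittal components
#' ([decompose_angle()]), and the 3D distance between the insertion points of
#' the two axes into the femoral head of the planning model.
#'
#' @param plan a `drill_plan` (with entry point) or planned [axis3()].
#' @param achieved_axis achieved [axis3()] in the planning frame.
#' @param frame an [anatomical_frame()]; defaults to the plan's frame.
#' @param head_mesh planning-model [mesh3()] used for the insertion points.
#' @param case_id optional label.
#' @param registration_rmse optional RMSE of the scan registration (mm).
#' @return a `deviation_record`: `case_id`, `true3d_angle`, `frontal`,
#'   `axial`, `sagittal` (deg), `entry_distance` (mm), `registration_rmse`.
#' @export
compute_deviation <- function(plan, achieved_axis, frame = NULL, head_mesh = NULL,
                              case_id = NA_character_, registration_rmse = NA_real_) {
  if (inherits(plan, "drill_plan")) {
    frame <- frame %||% plan$frame
    planned_axis <- plan$axis
    planned_entry <- plan$entry_point
  } else {
    planned_axis <- plan
    planned_entry <- NULL
  }
  if (is.null(frame)) stop_invalid("an anatomical frame is required")
  dec <- decompose_angle(planned_axis, achieved_axis, frame)
  entry_distance <- NA_real_
  if (!is.null(head_mesh)) {
    if (is.null(planned_entry)) planned_entry <- compute_entry_point(head_mesh, planned_axis)
    achieved_entry <- compute_entry_point(head_mesh, achieved_axis)
    entry_distance <- vnorm(achieved_entry - planned_entry)
  }
  structure(list(case_id = case_id,
                 true3d_angle = dec$true3d,
                 frontal = dec$frontal, axial = dec$axial, sagittal = dec$sagittal,
                 entry_distance = entry_distance,
                 registration_rmse = registration_rmse),
            class = "deviation_record")
}

#' @export
print.deviation_record <- function(x, ...) {
  cat(sprintf(
    "deviation_record [%s]: true-3D %.2f deg (frontal %.2f, axial %.2f, sagittal %.2f), entry %.2f mm\n",
    x$case_id, x$true3d_angle, x$frontal, x$axial, x$sagittal, x$entry_distance))
  invisible(x)
}

#' Evaluate a simulated post-operative scan against its plan
#'
#' The full accuracy pipeline of a single case: (1) trimmed ICP registration
#' of the scan onto the planning bone model, initialized by aligning the
#' scan's RANSAC head-sphere centre with the planning head centre (the
#' residual pose after coarse pre-alignment); (2) drill-channel wall
#' extraction in the planning frame; (3) cylinder fit of the achieved axis;
#' (4) deviation record against the plan.
#'
#' @param scan a `postop_scan`.
#' @param femur the planning `femur_model`.
#' @param plan the `drill_plan`.
#' @param trim_fraction ICP trimming in the refinement stage (the cut face
#'   and channel have no counterpart in the planning model).
#' @param trim_low trimming in the first ICP stage. The resected head is
#'   dominated by the (rotation-indifferent) spherical head; aggressive
#'   trimming at large misalignment would discard the neck-stump points that
#'   carry all the rotational information together with the true outliers, so
#'   the first stage trims just past the outlier fraction.
#' @param n_sample moving points used by ICP.
#' @param seed seed (sampling).
#' @param case_id label for the record.
#' @return list with `record` (`deviation_record`), `icp` (`icp_result`),
#'   `achieved_axis`, `n_channel_points`.
#' @export
evaluate_case <- function(scan, femur, plan, trim_fraction = 0.25,
                          trim_low = 0.18, n_sample = 2000L, seed = 1L,
                          case_id = NA_character_) {
  stopifnot(inherits(scan, "postop_scan"), inherits(plan, "drill_plan"))
  pts <- mesh_sample_surface(scan$head_mesh, n_sample, seed = seed)
  scan_head <- fit_head_sphere(pts, seed = seed)
  plan_head_ctr <- plan$frame$origin

  # global initialization: the scan's own neck-stump direction (centroid of
  # points beyond the head sphere, seen from the scan head centre) is aligned
  # with the planned neck direction — fixing the tilt — and the remaining
  # twist about the neck axis is resolved by short trimmed-ICP runs from a
  # fan of twist candidates (the fovea and the elliptic stump disambiguate)
  dp <- plan$axis$direction
  stump <- pts[sqrt(rowSums(sweep(pts, 2, scan_head$center)^2)) >
                 scan_head$radius + 2, , drop = FALSE]
  R0 <- diag(3)
  if (nrow(stump) >= 20L) {
    ds <- unitize(colMeans(stump) - scan_head$center)
    w <- cross3(ds, dp)
    if (vnorm(w) > 1e-9)
      R0 <- rotation_about(w, rad2deg(atan2(vnorm(w), sum(ds * dp))))
  }
  # twist candidates are scored by the trimmed rmse plus a landmark term:
  # how well the planning model's fovea region is reproduced by the
  # registered scan. The elliptic stump alone is two-fold symmetric, and
  # trimming hides the few fovea points, so the landmark term is what breaks
  # the 180-degree twist ambiguity (exactly the feature a human operator
  # uses when coarsely aligning retrieval scans).
  landmark <- NULL
  if (!is.null(femur$truth$fovea)) {
    fv <- femur$truth$fovea
    near <- sqrt(rowSums(sweep(femur$mesh$vertices, 2, fv$center)^2)) < 1.2 * fv$radius
    if (sum(near) >= 10L) landmark <- femur$mesh$vertices[near, , drop = FALSE]
  }
  bone_idx <- mesh_index(femur$mesh)
  scan_idx <- mesh_index(scan$head_mesh)
  score_cand <- function(cand) {
    s <- cand$rmse^2
    if (!is.null(landmark)) {
      back <- apply_transform(invert_transform(cand$transform), landmark)
      s <- s + mean(mesh_closest_point(scan$head_mesh, back, index = scan_idx)$dist^2)
    }
    s
  }
  best <- NULL
  for (tw in seq(0, 345, by = 15)) {
    Rt <- rotation_about(dp, tw) %*% R0
    init <- rigid_transform(Rt, plan_head_ctr - as.numeric(Rt %*% scan_head$center))
    cand <- icp_register(pts, femur$mesh, init = init, max_iter = 15L,
                         tol = 1e-8, trim_fraction = trim_low, seed = seed,
                         index = bone_idx)
    sc <- score_cand(cand)
    if (is.null(best) || sc < best$score) {
      best <- cand
      best$score <- sc
    }
  }
  icp1 <- icp_register(pts, femur$mesh, init = best$transform, max_iter = 150L,
                       tol = 1e-8, trim_fraction = trim_low, seed = seed,
                       index = bone_idx)
  icp <- icp_register(pts, femur$mesh, init = icp1$transform, max_iter = 100L,
                      tol = 1e-8, trim_fraction = trim_fraction, seed = seed,
                      index = bone_idx)
  # twist lock: trimmed ICP carries no gradient in the twist about the
  # near-symmetric neck axis (the few fovea points are trimmed as apparent
  # outliers), so the residual twist is corrected in closed form from the
  # fovea itself — both fovea point clouds are identified intrinsically as
  # surface points lying well inside their head spheres (excluding the
  # drill-channel mouth near the planned axis), and the rotation about the
  # planned axis aligning their centroids is applied, followed by a trimmed
  # re-polish of the tilt (which cannot drift the twist back, for the same
  # reason the twist needed locking).
  dense <- mesh_sample_surface(scan$head_mesh, 8000L, seed = seed + 29L)
  rs <- sqrt(rowSums(sweep(dense, 2, scan_head$center)^2))
  in_band <- rs < scan_head$radius - 0.6 & rs > scan_head$radius - 3.5
  band_pts <- dense[in_band, , drop = FALSE]
  # absolute-threshold polish: fixed-fraction trimming always discards the
  # largest residuals — which on this geometry are exactly the informative
  # stump/fovea points — so the final refinement instead rejects only true
  # outliers (cut face and channel interior, residuals well above the
  # threshold) and keeps every surface point that is plausibly bone-on-bone
  polish_abs <- function(Tinit, thr = 0.8, iters = 150L) {
    Tcur <- Tinit
    for (it in seq_len(iters)) {
      X <- apply_transform(Tcur, pts)
      cp <- mesh_closest_point(femur$mesh, X, index = bone_idx)
      keep <- which(cp$dist < thr)
      if (length(keep) < 100L) break
      dT <- procrustes_rigid(X[keep, , drop = FALSE], cp$points[keep, , drop = FALSE])
      Tnew <- compose_transform(dT, Tcur)
      delta <- rotation_angle(dT$rotation) + vnorm(dT$translation)
      Tcur <- Tnew
      if (delta < 1e-8) break
    }
    Tcur
  }
  if (nrow(band_pts) >= 8L) {
    Tcur <- icp$transform
    twist_about <- function(ang_deg, Tbase) {
      Rtw <- rotation_about(dp, ang_deg)
      Ttw <- rigid_transform(Rtw, plan_head_ctr - as.numeric(Rtw %*% plan_head_ctr))
      compose_transform(Ttw, Tbase)
    }
    # channel-mouth points also lie inside the sphere; they are excluded
    # intrinsically in the scan frame: the fovea is at most ~2 mm deep, so
    # points deeper than the band can only be channel wall, and band points
    # adjacent to that deeper set belong to the channel mouth
    deep <- dense[rs < scan_head$radius - 3.5, , drop = FALSE]
    fov <- band_pts
    if (nrow(deep) > 0L) {
      near_deep <- vapply(seq_len(nrow(band_pts)), function(i)
        min(rowSums(sweep(deep, 2, band_pts[i, ])^2)), numeric(1))
      fov <- band_pts[near_deep > 9, , drop = FALSE]  # > 3 mm away
    }
    for (rep_ in 1:2) {
      if (nrow(fov) < 8L) break
      # distances are clamped so that any residual channel-mouth
      # contaminant (an interior point, many mm from the surface) saturates
      # instead of dominating the score
      tw_score <- function(a) {
        Xf <- apply_transform(twist_about(a, Tcur), fov)
        mean(pmin(mesh_closest_point(femur$mesh, Xf, index = bone_idx)$dist, 2)^2)
      }
      coarse <- seq(-9, 9, by = 0.75)
      sc <- vapply(coarse, tw_score, numeric(1))
      a0 <- coarse[which.min(sc)]
      fine <- seq(a0 - 0.7, a0 + 0.7, by = 0.14)
      a1 <- fine[which.min(vapply(fine, tw_score, numeric(1)))]
      Tcur <- twist_about(a1, Tcur)
      Tcur <- polish_abs(Tcur)
    }
    X <- apply_transform(Tcur, pts)
    cp <- mesh_closest_point(femur$mesh, X, index = bone_idx)
    n_keep <- max(3L, floor(nrow(pts) * (1 - trim_fraction)))
    keep <- order(cp$dist)[seq_len(n_keep)]
    icp$transform <- Tcur
    icp$rmse <- sqrt(mean((cp$dist[keep])^2))
  }
  reg_mesh <- apply_transform(icp$transform, scan$head_mesh)
  # extract-and-refit loop: seeding the wall search with the planned axis
  # truncates the (tilted) channel asymmetrically, which under scan noise
  # attenuates the fitted angle; re-centring the search on the fitted axis
  # restores complete wall rings and removes the bias
  achieved <- plan$axis
  scan_normals <- mesh_vertex_normals(reg_mesh)
  n_prev <- -1L
  for (k in 1:8) {
    ch <- extract_channel_points(reg_mesh, achieved, scan$channel_radius,
                                 normals = scan_normals)
    achieved <- fit_drill_axis(ch, scan$channel_radius,
                               align_dir = plan$axis$direction)
    # iterate until the recovered wall is complete (the point count stops
    # growing as the search window re-centres on the fitted axis)
    if (nrow(ch) <= n_prev * 1.002) break
    n_prev <- nrow(ch)
  }
  rec <- compute_deviation(plan, achieved, head_mesh = femur$mesh,
                           case_id = case_id, registration_rmse = icp$rmse)
  list(record = rec, icp = icp, achieved_axis = achieved,
       n_channel_points = nrow(ch))
}
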