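# Recovery of the femoral head sphere, the anatomical neck axis and the
# anatomical frame from a bone surface mesh.

sphere_lsq <- function(P) {
  # algebraic least squares: |p - c|^2 = r^2  <=>  2 p.c + (r^2 - |c|^2) = |p|^2
  A <- cbind(2 * P, 1)
  b <- rowSums(P^2)
  qrA <- qr(A)
  if (qrA$rank < 4L)
    stop_with("sraguide_degenerate_fit", "sphere fit is degenerate (planar or collinear points)")
  x <- qr.coef(qrA, b)
  ctr <- x[1:3]
  r2 <- x[4] + sum(ctr^2)
  if (!is.finite(r2) || r2 <= 0)
    stop_with("sraguide_degenerate_fit", "sphere fit produced a non-positive radius")
  list(center = as.numeric(ctr), radius = sqrt(r2))
}

#' Fit the femoral head sphere
#'
#' Recovers centre and radius of the femoral head from a proximal-femur mesh
#' or a raw point cloud. The `linear` method is the algebraic least-squares
#' sphere with iterative residual trimming (so neck points do not contaminate
#' the fit); `ransac` draws 4-point sphere hypotheses, keeps the largest
#' consensus at `inlier_threshold`, and refits linearly on the inliers —
#' robust to outliers and to partial (hemispherical) coverage.
#'
#' @param x a [mesh3()] or an n x 3 point matrix.
#' @param region_hint optional approximate head-centre seed point; when
#'   absent, a seeded RANSAC pass locates the dominant sphere.
#' @param method `"linear"` or `"ransac"`.
#' @param seed RANSAC seed.
#' @param radius_guess initial head-radius scale used with `region_hint`
#'   (candidate points within `1.3 * radius_guess` of the hint).
#' @param inlier_threshold RANSAC consensus band (mm).
#' @param ransac_iter number of RANSAC hypotheses.
#' @param radius_range admissible radius interval (mm) for hypotheses.
#' @return a `head_sphere_fit`: `center`, `radius`, `rms_residual`,
#'   `inlier_fraction`, `n_inliers`.
#' @export
fit_head_sphere <- function(x, region_hint = NULL,
                            method = c("ransac", "linear"), seed = 1L,
                            radius_guess = 25, inlier_threshold = 0.5,
                            ransac_iter = 500L, radius_range = c(8, 80)) {
  method <- match.arg(method)
  P <- if (inherits(x, "mesh3")) x$vertices else as.matrix(x)
  if (nrow(P) < 50L)
    stop_invalid("need at least 50 candidate points for the head-sphere fit")

  if (!is.null(region_hint)) {
    d <- sqrt(rowSums(sweep(P, 2, as.numeric(region_hint))^2))
    cand <- P[d < 1.3 * radius_guess, , drop = FALSE]
    if (nrow(cand) < 50L)
      stop_invalid("fewer than 50 points near region_hint")
    fit <- sphere_lsq(cand)
  } else {
    # RANSAC seeding (also used to localize the head for the linear method)
    n <- nrow(P)
    best <- NULL
    with_seed(seed, {
      draws <- matrix(sample.int(n, 4L * ransac_iter, replace = TRUE), ncol = 4L)
      for (it in seq_len(ransac_iter)) {
        idx <- draws[it, ]
        if (anyDuplicated(idx)) next
        hyp <- tryCatch(sphere_lsq(P[idx, , drop = FALSE]), error = function(e) NULL)
        if (is.null(hyp) || hyp$radius < radius_range[1] || hyp$radius > radius_range[2]) next
        res <- abs(sqrt(rowSums(sweep(P, 2, hyp$center)^2)) - hyp$radius)
        score <- sum(res < inlier_threshold)
        if (is.null(best) || score > best$score)
          best <- list(score = score, center = hyp$center, radius = hyp$radius)
      }
    })
    if (is.null(best))
      stop_with("sraguide_degenerate_fit", "RANSAC found no valid sphere hypothesis")
    res <- abs(sqrt(rowSums(sweep(P, 2, best$center)^2)) - best$radius)
    cand <- P[res < inlier_threshold, , drop = FALSE]
    if (nrow(cand) < 50L)
      stop_with("sraguide_degenerate_fit", "RANSAC consensus too small for a sphere fit")
    fit <- sphere_lsq(cand)
  }

  # trimmed refinement: the inclusion band shrinks with the core residual
  # scale, so head-neck crease points cannot bias the final estimate and a
  # noise-free sphere is recovered to machine precision
  for (k in 1:8) {
    res_all <- abs(sqrt(rowSums(sweep(P, 2, fit$center)^2)) - fit$radius)
    core <- res_all[res_all <= stats::quantile(res_all, 0.25)]
    thr <- max(1e-9, 3 * sqrt(mean(core^2)))
    keep <- res_all < thr
    if (sum(keep) < 50L) break
    fit_new <- sphere_lsq(P[keep, , drop = FALSE])
    moved <- vnorm(fit_new$center - fit$center) + abs(fit_new$radius - fit$radius)
    fit <- fit_new
    if (moved < 1e-10) break
  }
  res_all <- abs(sqrt(rowSums(sweep(P, 2, fit$center)^2)) - fit$radius)
  inliers <- res_all < inlier_threshold
  structure(list(center = fit$center, radius = fit$radius,
                 rms_residual = sqrt(mean(res_all[inliers]^2)),
                 inlier_fraction = mean(inliers),
                 n_inliers = sum(inliers)),
            class = "head_sphere_fit")
}

#' @export
print.head_sphere_fit <- function(x, ...) {
  cat(sprintf("head_sphere_fit: center (%.3f, %.3f, %.3f), r = %.3f mm, rms %.4f mm, inliers %.0f%%\n",
              x$center[1], x$center[2], x$center[3], x$radius,
              x$rms_residual, 100 * x$inlier_fraction))
  invisible(x)
}

# sweep the section perimeter profile along a trial axis and locate the neck
# corridor: from just past the head (1.05 R) to the saddle where the section
# starts growing toward the trochanter (distal-most point of the waist
# plateau, tolerance 1%)
find_neck_corridor <- function(mesh, center, radius, dir, step = 1.0) {
  u_safe <- 1.05 * radius   # always past the head sphere, whatever the neck
  us <- seq(0.7 * radius, u_safe + 1.2 * radius, by = step)
  stats_u <- vapply(seq_along(us), function(i) {
    s <- mesh_section(mesh, center + us[i] * dir, dir, max_radius = 1.3 * radius)
    if (is.null(s$segments)) return(c(0, NA_real_))
    mid <- (s$segments[, 1:3, drop = FALSE] + s$segments[, 4:6, drop = FALSE]) / 2
    c(s$perimeter, sqrt(max(rowSums(sweep(mid, 2, center + us[i] * dir)^2))))
  }, numeric(2))
  per <- stats_u[1, ]
  rmax <- stats_u[2, ]
  valid <- per > 0
  if (sum(valid & us >= u_safe) < 5L)
    stop_with("sraguide_insufficient_geometry",
              "could not sweep enough neck cross-sections (cropped mesh?)")
  sm <- stats::filter(per, rep(1 / 3, 3), sides = 2)
  sm[is.na(sm)] <- per[is.na(sm)]
  sm[!valid] <- Inf
  clean <- valid & us >= u_safe & us <= u_safe + 0.42 * radius
  level <- stats::median(sm[clean])
  # the corridor starts at the always-safe head-clearance bound; sections
  # proximal of it can still contain head sphere, whose centroids follow the
  # current slicing direction rather than the neck axis and would break the
  # contraction of the re-slicing iteration
  u_start <- u_safe
  # distal bound: perimeter rises 1.5% above the waist level (median-based,
  # robust to per-section jitter) — the trochanteric saddle; clamped inside
  # the anatomical neck
  rises <- which(sm > 1.015 * level & us > u_safe)
  u_end <- if (length(rises)) us[min(rises) - 1L] else max(us[valid])
  u_end <- min(u_end, u_safe + 0.42 * radius)
  if (u_end - u_start < 0.25 * radius) u_end <- u_start + 0.25 * radius
  c(u_start, u_end)
}

#' Fit the anatomical neck axis
#'
#' Morphometric definition of the anatomical femoral neck axis: the
#' total-least-squares 3D line through the centroids of neck cross-sections,
#' with the slicing direction re-aligned to the current axis estimate until
#' the direction is stable. Sections are taken perpendicular to the current
#' axis across the neck corridor (from just past the head to the trochanteric
#' saddle); section centroids are length-weighted boundary centroids, which
#' coincide with the section centre for the (possibly elliptic) neck, so
#' ellipticity does not bias the fit.
#'
#' @param mesh a [mesh3()] of the proximal femur.
#' @param head a [fit_head_sphere()] result.
#' @param shaft_hint optional [axis3()] of the shaft used to orient the
#'   initial search direction; by default the direction from the head centre
#'   toward the mesh centroid is used.
#' @param n_slices number of corridor sections per iteration.
#' @param max_iter iteration cap.
#' @param tol_deg convergence tolerance on the axis direction change (deg).
#' @return a `neck_axis_fit`: `axis` ([axis3()], direction pointing from the
#'   head into the neck), `n_slices`, `slice_centroids`, `converged`,
#'   `iterations`, `corridor` (distances from the head centre).
#' @export
fit_neck_axis <- function(mesh, head, shaft_hint = NULL, n_slices = 15L,
                          max_iter = 50L, tol_deg = 0.01) {
  stopifnot(inherits(head, "head_sphere_fit"))
  ctr <- head$center
  if (!is.null(shaft_hint)) {
    stopifnot(inherits(shaft_hint, "axis3"))
    q <- shaft_hint$point +
      sum((ctr - shaft_hint$point) * shaft_hint$direction) * shaft_hint$direction
    d <- unitize(q - ctr)
  } else {
    d <- unitize(colMeans(mesh$vertices) - ctr)
  }
  # bootstrap band close past the head: section centroids of the (possibly
  # obliquely cut) neck lie on the neck axis, so even a poor initial
  # direction yields a good axis after one pass; the corridor proper is then
  # detected along the refined axis
  corridor <- c(1.05, 1.4) * head$radius
  iterations <- 0L
  converged <- FALSE
  centroids <- NULL
  for (it in seq_len(max_iter)) {
    iterations <- it
    if (it == 2L) corridor <- find_neck_corridor(mesh, ctr, head$radius, d)
    us <- seq(corridor[1], corridor[2], length.out = n_slices)
    cl <- lapply(us, function(u) {
      s <- mesh_section(mesh, ctr + u * d, d, max_radius = 1.3 * head$radius)
      s$centroid
    })
    cl <- cl[!vapply(cl, is.null, logical(1))]
    if (length(cl) < 5L)
      stop_with("sraguide_insufficient_geometry",
                sprintf("only %d valid neck slices (need >= 5)", length(cl)))
    centroids <- do.call(rbind, cl)
    m <- colMeans(centroids)
    sv <- svd(sweep(centroids, 2, m))
    d_new <- sv$v[, 1]
    if (sum(d_new * d) < 0) d_new <- -d_new
    change <- angle_between(d, d_new)
    d <- d_new
    if (change < tol_deg && it >= 2L) {
      converged <- TRUE
      break
    }
  }
  m <- colMeans(centroids)
  anchor <- m + sum((ctr - m) * d) * d  # point on the line nearest the head centre
  structure(list(axis = axis3(anchor, d), n_slices = nrow(centroids),
                 slice_centroids = centroids, converged = converged,
                 iterations = iterations, corridor = corridor),
            class = "neck_axis_fit")
}

#' @export
print.neck_axis_fit <- function(x, ...) {
  cat(sprintf("neck_axis_fit: direction (%.4f, %.4f, %.4f), %d slices, %s in %d iterations\n",
              x$axis$direction[1], x$axis$direction[2], x$axis$direction[3],
              x$n_slices, if (x$converged) "converged" else "NOT converged",
              x$iterations))
  invisible(x)
}

#' Build the anatomical frame from fitted anatomy
#'
#' The superior axis opposes the (distally pointing) shaft direction. The
#' medial axis is taken perpendicular to superior: from the scanner/patient
#' anterior reference when one is available (CT planning data are acquired in
#' a patient-aligned frame, which is what published frontal/axial/sagittal
#' deviation components refer to), otherwise from the neck axis itself — in
#' that fallback the frontal plane contains the neck axis by construction and
#' the frame carries no anteversion information.
#'
#' @param head a [fit_head_sphere()] result (frame origin = head centre).
#' @param neck a [fit_neck_axis()] result.
#' @param shaft_axis [axis3()] of the femoral shaft, direction pointing
#'   distally.
#' @param side `"left"` or `"right"`.
#' @param anterior_ref optional anterior reference direction (e.g. the CT
#'   scanner's +y axis).
#' @return an [anatomical_frame()].
#' @export
build_frame <- function(head, neck, shaft_axis, side = "left", anterior_ref = NULL) {
  stopifnot(inherits(head, "head_sphere_fit"), inherits(neck, "neck_axis_fit"),
            inherits(shaft_axis, "axis3"))
  side <- match.arg(side, c("left", "right"))
  s <- unitize(-shaft_axis$direction)
  if (angle_between(neck$axis$direction, shaft_axis$direction) < 5)
    stop_with("sraguide_degenerate_frame",
              "neck and shaft axes are nearly parallel; frame is undefined")
  side_sign <- if (side == "left") 1 else -1
  if (!is.null(anterior_ref)) {
    m <- side_sign * cross3(unitize(anterior_ref), s)
  } else {
    # medial-ish: opposite the (head -> lateral) neck direction, in-plane
    m <- -project_onto_plane(neck$axis$direction, s)
  }
  if (vnorm(m) < 1e-6)
    stop_with("sraguide_degenerate_frame", "anterior reference parallel to superior axis")
  m <- unitize(m)
  a <- side_sign * cross3(s, m)
  anatomical_frame(head$center, m, a, s, side = side)
}
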