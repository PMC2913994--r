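# Core geometric primitives: rigid transforms, 3D axes, anatomical frames,
# unsigned angles and the per-plane decomposition of an angular deviation.

#' Rigid transform (rotation + translation)
#'
#' Represents a proper rigid motion `x -> R x + t` in millimetre coordinates.
#' The rotation must be orthonormal with determinant +1.
#'
#' @param rotation 3x3 orthonormal matrix (det +1).
#' @param translation length-3 numeric vector (mm).
#' @return an object of class `rigid_transform`.
#' @examples
#' T1 <- rigid_transform(rotation_about(c(0, 0, 1), 90), c(1, 2, 3))
#' apply_transform(T1, c(1, 0, 0))  # -> (1, 3, 3)
#' @export
rigid_transform <- function(rotation = diag(3), translation = c(0, 0, 0)) {
  rotation <- as.matrix(rotation)
  translation <- as.numeric(translation)
  if (!all(dim(rotation) == c(3L, 3L)) || length(translation) != 3L)
    stop_invalid("rigid_transform needs a 3x3 rotation and length-3 translation")
  err <- max(abs(crossprod(rotation) - diag(3)))
  if (err > 1e-9 || abs(det(rotation) - 1) > 1e-9)
    stop_with("sraguide_invalid_transform",
              sprintf("rotation is not orthonormal with det +1 (error %.3g)", err))
  structure(list(rotation = rotation, translation = translation),
            class = "rigid_transform")
}

#' @export
print.rigid_transform <- function(x, ...) {
  cat("rigid_transform\n")
  ang <- rotation_angle(x$rotation)
  cat(sprintf("  rotation: %.4f deg, translation: (%.3f, %.3f, %.3f) mm\n",
              ang, x$translation[1], x$translation[2], x$translation[3]))
  invisible(x)
}

#' Identity rigid transform
#' @return a `rigid_transform` with unit rotation and zero translation.
#' @export
identity_transform <- function() rigid_transform()

#' Compose two rigid transforms
#'
#' `compose_transform(a, b)` returns the transform applying `b` first, then
#' `a` (i.e. `x -> a(b(x))`).
#'
#' @param a,b `rigid_transform` objects.
#' @return a `rigid_transform`.
#' @export
compose_transform <- function(a, b) {
  stopifnot(inherits(a, "rigid_transform"), inherits(b, "rigid_transform"))
  rigid_transform(a$rotation %*% b$rotation,
                  as.numeric(a$rotation %*% b$translation) + a$translation)
}

#' Invert a rigid transform
#' @param x a `rigid_transform`.
#' @return the inverse `rigid_transform`.
#' @export
invert_transform <- function(x) {
  stopifnot(inherits(x, "rigid_transform"))
  Rt <- t(x$rotation)
  rigid_transform(Rt, -as.numeric(Rt %*% x$translation))
}

#' Apply a rigid transform to points or a mesh
#'
#' @param x a `rigid_transform`.
#' @param points an n x 3 matrix, a length-3 vector, or a [mesh3()] object.
#' @return transformed points (same shape as input) or mesh.
#' @export
apply_transform <- function(x, points) {
  stopifnot(inherits(x, "rigid_transform"))
  if (inherits(points, "mesh3")) {
    points$vertices <- apply_transform(x, points$vertices)
    return(points)
  }
  if (is.null(dim(points))) {
    return(as.numeric(x$rotation %*% points) + x$translation)
  }
  sweep(points %*% t(x$rotation), 2, x$translation, "+")
}

#' Rotation matrix about an axis
#'
#' Rodrigues rotation by `angle_deg` degrees about the (not necessarily unit)
#' axis `axis`.
#'
#' @param axis length-3 vector.
#' @param angle_deg rotation angle in degrees.
#' @return 3x3 rotation matrix.
#' @export
rotation_about <- function(axis, angle_deg) {
  k <- unitize(axis, "rotation axis")
  th <- deg2rad(angle_deg)
  K <- matrix(c(0, -k[3], k[2],
                k[3], 0, -k[1],
                -k[2], k[1], 0), 3, 3, byrow = TRUE)
  diag(3) + sin(th) * K + (1 - cos(th)) * (K %*% K)
}

# rotation angle (deg) of a rotation matrix
rotation_angle <- function(R) {
  c_ <- (sum(diag(R)) - 1) / 2
  rad2deg(acos(pmin(1, pmax(-1, c_))))
}

# axis-angle (rotation vector, degrees) of a rotation matrix via the log map
rotation_log <- function(R) {
  c_ <- (sum(diag(R)) - 1) / 2
  th <- acos(pmin(1, pmax(-1, c_)))
  if (th < 1e-12) return(c(0, 0, 0))
  w <- c(R[3, 2] - R[2, 3], R[1, 3] - R[3, 1], R[2, 1] - R[1, 2])
  if (sin(th) < 1e-8) {
    # near 180 deg: fall back to the symmetric part
    B <- (R + diag(3)) / 2
    ax <- sqrt(pmax(0, diag(B)))
    i <- which.max(ax)
    ax <- B[, i] / max(ax[i], 1e-12)
    return(rad2deg(th) * unitize(ax))
  }
  rad2deg(th) * w / (2 * sin(th))
}

#' Serialize / deserialize a rigid transform as a 4x4 homogeneous matrix
#'
#' The row-major 4x4 convention is used in JSON plan and report files.
#'
#' @param x a `rigid_transform` (for `transform_to_matrix`) or a 4x4 matrix
#'   (for `transform_from_matrix`).
#' @return a 4x4 matrix, or a `rigid_transform`.
#' @export
transform_to_matrix <- function(x) {
  stopifnot(inherits(x, "rigid_transform"))
  rbind(cbind(x$rotation, x$translation), c(0, 0, 0, 1))
}

#' @rdname transform_to_matrix
#' @export
transform_from_matrix <- function(x) {
  x <- as.matrix(x)
  if (!all(dim(x) == c(4L, 4L))) stop_invalid("expected a 4x4 matrix")
  rigid_transform(x[1:3, 1:3], x[1:3, 4])
}

# --- axes -------------------------------------------------------------------

#' 3D axis (line with direction)
#'
#' A line through `point` with unit `direction`. For drill and neck axes the
#' direction convention is the drilling direction: from the head-apex entry
#' into the femoral neck.
#'
#' @param point length-3 point on the line (mm).
#' @param direction length-3 direction (normalized internally).
#' @return an object of class `axis3`.
#' @export
axis3 <- function(point, direction) {
  point <- as.numeric(point)
  if (length(point) != 3L) stop_invalid("axis3 point must be length 3")
  structure(list(point = point, direction = unitize(as.numeric(direction), "axis direction")),
            class = "axis3")
}

#' @export
print.axis3 <- function(x, ...) {
  cat(sprintf("axis3: point (%.2f, %.2f, %.2f), direction (%.4f, %.4f, %.4f)\n",
              x$point[1], x$point[2], x$point[3],
              x$direction[1], x$direction[2], x$direction[3]))
  invisible(x)
}

transform_axis <- function(tr, ax) {
  axis3(apply_transform(tr, ax$point), as.numeric(tr$rotation %*% ax$direction))
}

# --- angles -----------------------------------------------------------------

#' Unsigned angle between two directions
#'
#' Angle between two directions treated as undirected lines, in degrees,
#' always in \[0, 90\]. Inputs are normalized internally; sign flips of either
#' argument do not change the result. This is the paper-grade "angular
#' deviation" between a planned and an achieved drill direction.
#'
#' @param u,v length-3 non-zero vectors.
#' @return angle in degrees in \[0, 90\].
#' @examples
#' angle_between(c(0, 0, 1), c(0, sin(pi / 18), cos(pi / 18)))  # 10 degrees
#' @export
angle_between <- function(u, v) {
  u <- unitize(as.numeric(u), "direction")
  v <- unitize(as.numeric(v), "direction")
  rad2deg(acos(pmin(1, pmax(0, abs(sum(u * v))))))
}

#' Project a vector onto a plane
#'
#' Removes the component along the plane normal. Used for in-plane angle
#' measurements such as anteversion.
#'
#' @param v length-3 vector.
#' @param normal plane normal (normalized internally).
#' @return the projected vector (not normalized; may be near zero).
#' @export
project_onto_plane <- function(v, normal) {
  n <- unitize(as.numeric(normal), "plane normal")
  v <- as.numeric(v)
  v - sum(v * n) * n
}

# --- anatomical frame -------------------------------------------------------

#' Anatomical coordinate frame
#'
#' Orthonormal medial / anterior / superior axes anchored at the femoral head
#' centre. The frontal (coronal) plane is spanned by medial and superior, the
#' axial (transverse) plane by medial and anterior, and the sagittal plane by
#' anterior and superior. For a left femur the triple is right-handed
#' (medial x anterior = superior); a right femur mirrors the medial axis, so
#' its triple has determinant -1 — both are accepted and the stored `side`
#' disambiguates. All plane-angle computations are unsigned and independent
#' of handedness.
#'
#' @param origin head centre (mm).
#' @param medial,anterior,superior unit axes (orthonormalized check only, not
#'   re-orthonormalized).
#' @param side `"left"` or `"right"`.
#' @return an object of class `anatomical_frame`.
#' @export
anatomical_frame <- function(origin, medial, anterior, superior, side = "left") {
  side <- match.arg(side, c("left", "right"))
  M <- cbind(medial, anterior, superior)
  if (max(abs(crossprod(M) - diag(3))) > 1e-9)
    stop_with("sraguide_invalid_frame", "frame axes are not orthonormal")
  d <- det(M)
  expected <- if (side == "left") 1 else -1
  if (abs(d - expected) > 1e-9)
    stop_with("sraguide_invalid_frame",
              sprintf("frame handedness (det %.6f) does not match side '%s'", d, side))
  structure(list(origin = as.numeric(origin),
                 medial = as.numeric(medial),
                 anterior = as.numeric(anterior),
                 superior = as.numeric(superior),
                 side = side),
            class = "anatomical_frame")
}

#' @export
print.anatomical_frame <- function(x, ...) {
  cat(sprintf("anatomical_frame (%s femur), origin (%.2f, %.2f, %.2f)\n",
              x$side, x$origin[1], x$origin[2], x$origin[3]))
  invisible(x)
}

frame_plane_normal <- function(frame, plane = c("frontal", "axial", "sagittal")) {
  plane <- match.arg(plane)
  switch(plane,
         frontal = frame$anterior,   # plane spanned by medial & superior
         axial = frame$superior,     # medial & anterior
         sagittal = frame$medial)    # anterior & superior
}

#' Decompose an angular deviation into anatomical-plane components
#'
#' Computes the minimal rotation carrying the planned drill direction onto the
#' achieved one and resolves its rotation vector along the three anatomical
#' plane normals: the frontal component is the part of the rotation taking
#' place within the frontal plane (rotation about the anterior axis), and
#' likewise for axial (about superior) and sagittal (about medial). Each
#' component is `theta * |axis . normal|` where `theta` is the true-3D angle,
#' so components never exceed the true-3D angle and their squares sum to its
#' square — matching the arithmetic of published deviation tables. The
#' achieved direction is sign-aligned with the planned one first.
#'
#' @param planned,achieved [axis3()] objects or length-3 directions.
#' @param frame an [anatomical_frame()].
#' @return list with `true3d`, `frontal`, `axial`, `sagittal` (degrees) and
#'   `degenerate` (TRUE when the directions are parallel to within 1e-9 so the
#'   rotation axis is undefined and all components are zero).
#' @export
decompose_angle <- function(planned, achieved, frame) {
  if (!inherits(frame, "anatomical_frame"))
    stop_with("sraguide_invalid_frame", "frame must be an anatomical_frame")
  u <- if (inherits(planned, "axis3")) planned$direction else unitize(as.numeric(planned))
  v <- if (inherits(achieved, "axis3")) achieved$direction else unitize(as.numeric(achieved))
  if (sum(u * v) < 0) v <- -v
  w <- cross3(u, v)
  s <- vnorm(w)
  th <- rad2deg(atan2(s, sum(u * v)))
  if (s < 1e-9) {
    return(list(true3d = th, frontal = 0, axial = 0, sagittal = 0,
                degenerate = TRUE))
  }
  wh <- w / s
  list(true3d = th,
       frontal = th * abs(sum(wh * frame_plane_normal(frame, "frontal"))),
       axial = th * abs(sum(wh * frame_plane_normal(frame, "axial"))),
       sagittal = th * abs(sum(wh * frame_plane_normal(frame, "sagittal"))),
       degenerate = FALSE)
}
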