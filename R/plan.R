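# Drill planning: the guide-wire axis is the anatomical neck axis plus the
# surgeon's valgus / version adjustments; the entry point is where the axis
# pierces the femoral head; the clearance check sweeps the implant corridor
# through the neck and reports superior / inferior cortex margins (notching).

#' Construct a drill plan from fitted anatomy
#'
#' Starts from the anatomical neck axis and applies the surgeon's
#' adjustments: `valgus_adjust` rotates the drilling direction within the
#' frontal plane (positive = valgus, i.e. the wire aligns closer to the shaft
#' axis), then `version_adjust` rotates it within the axial plane (positive =
#' more anteverted: the head-end of the wire tilts anteriorly). With both
#' adjustments zero the plan axis is exactly the neck axis.
#'
#' @param frame an [anatomical_frame()].
#' @param neck a [fit_neck_axis()] result (or an [axis3()] neck axis).
#' @param valgus_adjust,version_adjust adjustment angles in degrees, each
#'   within +/- 20.
#' @param wire_diameter guide-wire diameter (mm).
#' @param mesh optional [mesh3()]; when given, the entry point is computed
#'   immediately.
#' @param implant_stem_diameter corridor diameter used by implant-level
#'   clearance checks (mm).
#' @return a `drill_plan`: `axis` ([axis3()], drilling direction from the
#'   head apex into the neck), `entry_point` (or NULL), adjustment angles,
#'   `wire_diameter`, `implant_stem_diameter`, `frame`, `clearance` (NULL
#'   until [check_clearance()] is run).
#' @export
make_plan <- function(frame, neck, valgus_adjust = 0, version_adjust = 0,
                      wire_diameter = 3.2, mesh = NULL,
                      implant_stem_diameter = 9.5) {
  stopifnot(inherits(frame, "anatomical_frame"))
  ax <- if (inherits(neck, "neck_axis_fit")) neck$axis else neck
  if (!inherits(ax, "axis3")) stop_invalid("neck must be a neck_axis_fit or axis3")
  if (abs(valgus_adjust) > 20 || abs(version_adjust) > 20)
    stop_with("sraguide_invalid_plan", "adjustments must be within +/- 20 degrees")

  d <- ax$direction
  # valgus: in-frontal-plane rotation (about the anterior axis), sign chosen
  # so positive valgus tilts the drilling direction toward the distal shaft
  # direction (larger neck-shaft angle)
  if (valgus_adjust != 0) {
    distal <- -frame$superior
    cand <- lapply(c(1, -1), function(s)
      as.numeric(rotation_about(frame$anterior, s * abs(valgus_adjust)) %*% d))
    pick <- which.min(vapply(cand, function(v) angle_between(v, distal), numeric(1)))
    sgn <- c(1, -1)[pick]
    d <- as.numeric(rotation_about(frame$anterior, sgn * valgus_adjust) %*% d)
  }
  # version: axial-plane rotation (about the superior axis), positive =
  # the into-the-head direction (-d) gains an anterior component
  if (version_adjust != 0) {
    cand <- lapply(c(1, -1), function(s)
      as.numeric(rotation_about(frame$superior, s * abs(version_adjust)) %*% d))
    gain <- vapply(cand, function(v) sum(-v * frame$anterior), numeric(1))
    sgn <- c(1, -1)[which.max(gain)]
    d <- as.numeric(rotation_about(frame$superior, sgn * version_adjust) %*% d)
  }
  axis <- axis3(ax$point, d)
  entry <- if (!is.null(mesh)) compute_entry_point(mesh, axis) else NULL
  structure(list(axis = axis, entry_point = entry,
                 valgus_adjust = valgus_adjust, version_adjust = version_adjust,
                 wire_diameter = wire_diameter,
                 implant_stem_diameter = implant_stem_diameter,
                 frame = frame, clearance = NULL),
            class = "drill_plan")
}

#' @export
print.drill_plan <- function(x, ...) {
  cat(sprintf("drill_plan: valgus %+.1f deg, version %+.1f deg, wire %.1f mm\n",
              x$valgus_adjust, x$version_adjust, x$wire_diameter))
  if (!is.null(x$clearance))
    cat(sprintf("  clearance: superior %.2f mm, inferior %.2f mm%s\n",
                x$clearance$min_superior, x$clearance$min_inferior,
                if (x$clearance$notching) " [NOTCHING]" else ""))
  invisible(x)
}

#' Entry point of a drill axis on the bone surface
#'
#' First ray-mesh intersection walking along the drilling direction from
#' outside the bone — for the conventional apex-to-lateral drilling direction
#' this is the insertion point on the femoral head.
#'
#' @param mesh a [mesh3()].
#' @param axis an [axis3()] (or `drill_plan`).
#' @return length-3 entry point (mm).
#' @export
compute_entry_point <- function(mesh, axis) {
  if (inherits(axis, "drill_plan")) axis <- axis$axis
  stopifnot(inherits(axis, "axis3"))
  ext <- max(sqrt(rowSums(sweep(mesh$vertices, 2, axis$point)^2))) + 1
  orig <- axis$point - ext * axis$direction
  hit <- mesh_ray(mesh, orig, axis$direction)
  if (is.na(hit$t[1]))
    stop_with("sraguide_axis_misses_bone", "drill axis does not intersect the bone mesh")
  as.numeric(orig + hit$t[1] * axis$direction)
}

#' Cortex clearance (notching) check
#'
#' Sweeps the cylindrical corridor of radius `corridor_radius` along the plan
#' axis through the neck corridor and reports the minimal signed margin
#' between the corridor wall and the neck cortex on the superior and inferior
#' sides. A negative margin means the corridor breaches the cortex
#' (notching), the complication the planning is meant to avoid.
#'
#' @param mesh a [mesh3()] of the proximal femur.
#' @param plan a `drill_plan` (its frame supplies the superior direction and
#'   the head fit origin).
#' @param corridor_radius corridor radius (mm); defaults to the implant stem
#'   radius from the plan.
#' @param n_samples surface points sampled on the neck band for the margin
#'   search.
#' @param seed sampling seed.
#' @param band optional explicit neck band `c(min, max)` as distances from
#'   the frame origin along the plan axis, bypassing corridor detection.
#' @return a clearance record: `min_superior`, `min_inferior`, `notching`,
#'   `corridor_radius`, `n_points`. The record is also attached to the
#'   returned plan when assigned back by the caller.
#' @export
check_clearance <- function(mesh, plan, corridor_radius = NULL,
                            n_samples = 20000L, seed = 1L, band = NULL) {
  stopifnot(inherits(plan, "drill_plan"))
  corridor_radius <- corridor_radius %||% (plan$implant_stem_diameter / 2)
  frame <- plan$frame
  ctr <- frame$origin
  d <- plan$axis$direction
  # neck band along the plan axis, from past the head to the trochanteric rise
  corridor <- band
  if (is.null(corridor)) {
    head_r <- vnorm(compute_entry_point(mesh, plan$axis) - ctr)
    corridor <- tryCatch(find_neck_corridor(mesh, ctr, head_r, d),
                         error = function(e) stop_with("sraguide_insufficient_geometry",
                                                       conditionMessage(e)))
  }
  pts <- rbind(mesh$vertices, mesh_sample_surface(mesh, n_samples, seed = seed))
  rel <- sweep(pts, 2, plan$axis$point)
  t <- as.numeric(rel %*% d)
  tau <- as.numeric(sweep(pts, 2, ctr) %*% d)  # distance past the head centre
  band <- tau >= corridor[1] & tau <= corridor[2]
  if (sum(band) < 100L)
    stop_with("sraguide_insufficient_geometry", "no cortex points in the neck band")
  radial <- rel[band, , drop = FALSE] - outer(t[band], d)
  rho <- sqrt(rowSums(radial^2))
  margin <- rho - corridor_radius
  sup_comp <- as.numeric(radial %*% unitize(project_onto_plane(frame$superior, d)))
  is_sup <- sup_comp > 0
  rec <- list(min_superior = min(margin[is_sup]),
              min_inferior = min(margin[!is_sup]),
              corridor_radius = corridor_radius,
              n_points = sum(band))
  rec$notching <- rec$min_superior < 0 || rec$min_inferior < 0
  rec
}
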