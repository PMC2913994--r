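# Cohort reporting (machine-readable analogues of the qualitative checklist
# and the quantitative deviation table) and the end-to-end pipeline driver.

#' Qualitative fit checklist for one case
#'
#' Recordable schema mirroring the intraoperative surgeon checklist: number
#' of possible snap-fit positions, passive stability, full neck contact,
#' knife contact, guide failure, application complexity (1 = not complex to
#' 5 = very complex) and number of handling steps. Values come either from
#' [validate_snap_fit()] on the synthetic analogue or from manual entry.
#'
#' @param case_id case label.
#' @param n_possible_positions count of distinct seated poses.
#' @param passive_stability,full_neck_contact,all_knives_contact,guide_failure
#'   logical flags.
#' @param complexity_rating integer 1-5.
#' @param n_steps positive integer.
#' @return a `qualitative_checklist`.
#' @export
qualitative_checklist <- function(case_id, n_possible_positions = 1L,
                                  passive_stability = TRUE,
                                  full_neck_contact = TRUE,
                                  all_knives_contact = TRUE,
                                  guide_failure = FALSE,
                                  complexity_rating = 1L, n_steps = 1L) {
  if (!complexity_rating %in% 1:5) stop_invalid("complexity_rating must be 1..5")
  if (n_possible_positions < 1 || n_steps < 1)
    stop_invalid("counts must be >= 1")
  structure(list(case_id = case_id,
                 n_possible_positions = as.integer(n_possible_positions),
                 passive_stability = isTRUE(passive_stability),
                 full_neck_contact = isTRUE(full_neck_contact),
                 all_knives_contact = isTRUE(all_knives_contact),
                 guide_failure = isTRUE(guide_failure),
                 complexity_rating = as.integer(complexity_rating),
                 n_steps = as.integer(n_steps)),
            class = "qualitative_checklist")
}

#' Summarize a cohort of deviation records
#'
#' Exact per-metric minima and maxima over the per-case records — the
#' "overall min / max" columns of a quantitative deviation table.
#'
#' @param records list of `deviation_record`s (or a data frame with the
#'   metric columns).
#' @return a `cohort_summary`: `per_case` (data frame) and `overall`
#'   (data frame with `metric`, `min`, `max`).
#' @export
summarize_cohort <- function(records) {
  if (inherits(records, "deviation_record")) records <- list(records)
  if (is.data.frame(records)) {
    df <- records
  } else {
    if (!length(records)) stop_invalid("empty cohort")
    df <- do.call(rbind, lapply(records, function(r) {
      data.frame(case_id = r$case_id, true3d_angle = r$true3d_angle,
                 frontal = r$frontal, axial = r$axial, sagittal = r$sagittal,
                 entry_distance = r$entry_distance,
                 registration_rmse = r$registration_rmse,
                 stringsAsFactors = FALSE)
    }))
  }
  if (!nrow(df)) stop_invalid("empty cohort")
  metrics <- intersect(c("true3d_angle", "frontal", "axial", "sagittal",
                         "entry_distance", "registration_rmse"), names(df))
  rng <- function(m, f) {
    v <- df[[m]][is.finite(df[[m]])]
    if (!length(v)) return(NA_real_)
    f(v)
  }
  overall <- data.frame(
    metric = metrics,
    min = vapply(metrics, rng, numeric(1), f = min),
    max = vapply(metrics, rng, numeric(1), f = max),
    row.names = NULL, stringsAsFactors = FALSE)
  structure(list(per_case = df, overall = overall), class = "cohort_summary")
}

#' @export
print.cohort_summary <- function(x, ...) {
  cat(sprintf("cohort_summary: %d cases\n", nrow(x$per_case)))
  print(x$overall, row.names = FALSE)
  invisible(x)
}

#' Default pipeline configuration
#'
#' All tunables of the end-to-end study analogue, overridable per section.
#' `valgus_adjust` defaults to +3 deg: resurfacing guidance favours a slight
#' valgus wire position relative to the anatomical neck axis.
#'
#' @return nested list of defaults.
#' @export
default_config <- function() {
  list(
    cohort = list(n_cases = 5L, base_seed = 1L),
    femur = list(),          # femur_params() overrides
    plan = list(valgus_adjust = 3, version_adjust = 0, wire_diameter = 3.2),
    jig = list(enabled = FALSE),  # jig_params() overrides + enabled flag
    postop = list(angular_error_range = c(1.0, 3.0),
                  entry_shift_range = c(1.0, 2.2),
                  noise_sd = 0.1, pose = "random", voxel = 0.55),
    evaluate = list(trim_fraction = 0.35, n_sample = 1500L)
  )
}

merge_config <- function(base, override) {
  for (nm in names(override)) {
    if (is.list(base[[nm]]) && is.list(override[[nm]])) {
      base[[nm]] <- merge_config(base[[nm]], override[[nm]])
    } else {
      base[[nm]] <- override[[nm]]
    }
  }
  base
}

#' Load a pipeline configuration from YAML or JSON
#'
#' Missing entries fall back to [default_config()].
#'
#' @param path config file (`.yaml`/`.yml` or `.json`), or `NULL` for pure
#'   defaults.
#' @return configuration list.
#' @export
load_config <- function(path = NULL) {
  cfg <- default_config()
  if (is.null(path)) return(cfg)
  if (!file.exists(path))
    stop_with("sraguide_missing_file", sprintf("config file not found: %s", path))
  user <- if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::read_json(path, simplifyVector = TRUE)
  } else {
    yaml::read_yaml(path)
  }
  merge_config(cfg, user)
}

config_hash <- function(cfg) {
  tmp <- tempfile(fileext = ".json")
  on.exit(unlink(tmp))
  jsonlite::write_json(cfg, tmp, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  unname(tools::md5sum(tmp))
}

pipeline_log <- function(con, stage, msg) {
  line <- sprintf("[%s] %s", stage, msg)
  message(line)
  if (!is.null(con)) writeLines(line, con)
}

run_single_case <- function(cfg, case_seed, case_id, out_case, logcon) {
  log_ <- function(stage, ...) pipeline_log(logcon, paste0(case_id, "/", stage),
                                            sprintf(...))
  fp_args <- merge_config(list(seed = case_seed), cfg$femur)
  femur <- generate_femur(do.call(femur_params, fp_args))
  mv <- mesh_validate(femur$mesh)
  log_("synth", "femur mesh: %d faces, watertight=%s", nrow(femur$mesh$faces),
       mv$watertight)

  head <- fit_head_sphere(femur$mesh, seed = case_seed)
  neck <- fit_neck_axis(femur$mesh, head)
  frame <- build_frame(head, neck, femur$truth$shaft_axis, side = femur$params$side,
                       anterior_ref = femur$truth$frame$anterior)
  log_("fit-anatomy", "head r=%.3f mm; neck axis error vs truth %.3f deg",
       head$radius, angle_between(neck$axis$direction,
                                  femur$truth$neck_axis$direction))

  plan <- make_plan(frame, neck, valgus_adjust = cfg$plan$valgus_adjust,
                    version_adjust = cfg$plan$version_adjust,
                    wire_diameter = cfg$plan$wire_diameter, mesh = femur$mesh)
  log_("plan", "entry point (%.2f, %.2f, %.2f)", plan$entry_point[1],
       plan$entry_point[2], plan$entry_point[3])

  jig_report <- NULL
  if (isTRUE(cfg$jig$enabled)) {
    jp_over <- cfg$jig[setdiff(names(cfg$jig), "enabled")]
    jig <- generate_jig(femur, plan, do.call(jig_params, jp_over))
    export_stl(jig, file.path(out_case, "jig.stl"))
    snap <- validate_snap_fit(femur, jig, seed = case_seed)
    contract <- jig_contract(jig, femur, plan)
    jig_report <- list(contract = contract,
                       snap_fit = snap[c("unique_minimum", "n_possible_positions",
                                         "design_cost")])
    log_("design-jig", "watertight=%s, unique snap-fit=%s",
         contract$watertight, snap$unique_minimum)
  }

  inj <- with_seed(case_seed + 577L, list(
    angular_error = stats::runif(1, cfg$postop$angular_error_range[1],
                                 cfg$postop$angular_error_range[2]),
    azimuth = stats::runif(1, 0, 360),
    shift_angle = stats::runif(1, 0, 2 * pi),
    shift_mag = stats::runif(1, cfg$postop$entry_shift_range[1],
                             cfg$postop$entry_shift_range[2])))
  scan <- simulate_postop_scan(
    femur, plan, angular_error = inj$angular_error,
    error_plane_azimuth = inj$azimuth,
    entry_shift = inj$shift_mag * c(cos(inj$shift_angle), sin(inj$shift_angle)),
    pose = cfg$postop$pose, noise_sd = cfg$postop$noise_sd,
    seed = case_seed + 211L, voxel = cfg$postop$voxel)
  log_("simulate-postop", "injected %.2f deg / %.2f mm; overlap %.2f",
       inj$angular_error, inj$shift_mag, scan$partial_overlap_fraction)

  ev <- evaluate_case(scan, femur, plan, trim_fraction = cfg$evaluate$trim_fraction,
                      n_sample = cfg$evaluate$n_sample, seed = case_seed + 307L,
                      case_id = case_id)
  truth_dev <- compute_deviation(plan, scan$achieved_axis_truth,
                                 head_mesh = femur$mesh, case_id = case_id)
  log_("evaluate", "measured %.3f deg / %.3f mm (icp rmse %.4f mm)",
       ev$record$true3d_angle, ev$record$entry_distance, ev$icp$rmse)

  plan_json <- list(case_id = case_id,
                    axis = list(point = plan$axis$point,
                                direction = plan$axis$direction),
                    entry_point = plan$entry_point,
                    valgus_adjust = plan$valgus_adjust,
                    version_adjust = plan$version_adjust,
                    wire_diameter = plan$wire_diameter)
  jsonlite::write_json(plan_json, file.path(out_case, "plan.json"),
                       auto_unbox = TRUE, digits = NA)
  dev_json <- list(measured = unclass(ev$record),
                   injected = list(angular_error = inj$angular_error,
                                   entry_shift = inj$shift_mag),
                   truth = unclass(truth_dev),
                   icp = list(rmse = ev$icp$rmse, iterations = ev$icp$n_iterations,
                              converged = ev$icp$converged,
                              transform = transform_to_matrix(ev$icp$transform)),
                   jig = jig_report)
  jsonlite::write_json(dev_json, file.path(out_case, "deviation.json"),
                       auto_unbox = TRUE, digits = NA)
  list(record = ev$record, injected = inj, jig = jig_report,
       icp_rmse = ev$icp$rmse)
}

#' Run the end-to-end synthetic study analogue
#'
#' For each case: generate a synthetic femur, fit the anatomy, build the
#' drill plan, optionally generate and validate the jig, simulate the
#' post-operative scan with known injected deviations, run the evaluation
#' pipeline, and write per-case artifacts (plan JSON, jig STL, deviation
#' JSON) plus a cohort report. Identical configuration and seed give an
#' identical report.
#'
#' @param config a configuration list ([load_config()]/[default_config()]) or
#'   a path to a YAML/JSON config file.
#' @param out_dir output directory (created if needed).
#' @return the cohort report list, invisibly; also written to
#'   `cohort.json`.
#' @export
run_pipeline <- function(config = default_config(), out_dir = tempfile("sraguide_")) {
  cfg <- if (is.character(config)) load_config(config) else
    merge_config(default_config(), config)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  logcon <- file(file.path(out_dir, "pipeline.log"), "w")
  on.exit(close(logcon))
  writeLines(sprintf("# sraguide %s | config %s | started %s",
                     as.character(utils::packageVersion("sraguide")),
                     config_hash(cfg), format(Sys.time())), logcon)
  n <- cfg$cohort$n_cases
  results <- vector("list", n)
  for (i in seq_len(n)) {
    case_id <- sprintf("case_%02d", i)
    out_case <- file.path(out_dir, case_id)
    dir.create(out_case, showWarnings = FALSE)
    results[[i]] <- run_single_case(cfg, cfg$cohort$base_seed + 1000L * i,
                                    case_id, out_case, logcon)
  }
  summary <- summarize_cohort(lapply(results, `[[`, "record"))
  report <- list(
    software = paste0("sraguide ", as.character(utils::packageVersion("sraguide"))),
    config_hash = config_hash(cfg),
    base_seed = cfg$cohort$base_seed,
    n_cases = n,
    per_case = summary$per_case,
    overall = summary$overall,
    injected = data.frame(
      case_id = vapply(results, function(r) r$record$case_id, character(1)),
      angular_error = vapply(results, function(r) r$injected$angular_error, numeric(1)),
      entry_shift = vapply(results, function(r) r$injected$shift_mag, numeric(1)))
  )
  jsonlite::write_json(report, file.path(out_dir, "cohort.json"),
                       auto_unbox = TRUE, digits = NA, dataframe = "rows")
  invisible(list(report = report, summary = summary, out_dir = out_dir,
                 results = results))
}
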