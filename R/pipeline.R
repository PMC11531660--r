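# End-to-end per-specimen analysis and cohort assembly.

#' Analyze one specimen
#'
#' Runs the full chain: axis construction ([build_axes()]), anatomical frame
#' ([build_frame()]), per-plane rotational differences
#' ([rotational_difference()]), exit points and translational offsets
#' ([axis_exit_points()], [point_offsets()],
#' [axis_translational_offset()]). Frame orthogonality and the Pythagorean
#' identity of every offset record are asserted on every run.
#'
#' @param mesh a [bone_mesh()].
#' @param landmarks a [landmark_set()].
#' @param side anatomical side; defaults to the side recorded on the mesh.
#' @param reslice passed to [distal_humeral_axis()].
#' @return object of class `specimen_report`: `axes`, `frame`, `rotation`,
#'   `exits`, `medial`, `lateral`, `axis_offset`,
#'   `medial_intersection_point`, `diagnostics`.
#' @export
run_specimen <- function(mesh, landmarks, side = mesh$side, reslice = TRUE) {
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop(sprintf("[%s | specimen %s] %s", name, mesh$specimen_id,
                   conditionMessage(e)), call. = FALSE))
  }
  check_landmarks_on_surface(landmarks, mesh)
  axes <- stage("axis construction", build_axes(mesh, landmarks, reslice = reslice))
  frame <- stage("anatomical frame",
                 build_frame(axes$long_axis, axes$fe_axis, side = side))
  rotation <- stage("rotational difference", rotational_difference(frame, axes))
  exits <- stage("exit points", axis_exit_points(axes$fe_axis, mesh, frame))
  offs <- stage("point offsets",
                point_offsets(exits, axes$medial_epicondyle,
                              axes$lateral_epicondyle, frame))
  ax <- stage("axis offset",
              axis_translational_offset(axes$fe_axis, axes$lateral_epicondyle,
                                        axes$medial_epicondyle, mesh, frame))
  structure(list(specimen_id = mesh$specimen_id, side = side,
                 axes = axes, frame = frame, rotation = rotation,
                 exits = exits, medial = offs$medial, lateral = offs$lateral,
                 axis_offset = ax$record,
                 medial_intersection_point = ax$medial_intersection_point,
                 diagnostics = list(
                   circle_residual_range = range(axes$trochlear_circle$radial_residuals),
                   circle_converged = axes$trochlear_circle$converged,
                   circle_iterations = axes$trochlear_circle$iterations,
                   ellipse_rms = vapply(axes$shaft_ellipses, `[[`, numeric(1),
                                        "rms_residual"))),
            class = "specimen_report")
}

#' Flatten a specimen report (or ground-truth measurement) to one row
#'
#' @param report a `specimen_report` from [run_specimen()] or the result of
#'   [measure_ground_truth()].
#' @param specimen_id id for the row.
#' @return one-row data.frame with all scalar outputs (degrees / mm).
#' @export
report_row <- function(report, specimen_id = report$specimen_id %||% "specimen") {
  rot <- report$rotation
  rec <- function(r, prefix) {
    if (is.null(r))
      return(stats::setNames(rep(NA_real_, 4),
                             paste0(prefix, c("_abs", "_ap", "_ml", "_is"))))
    stats::setNames(c(r$absolute, r$anterior_posterior, r$medial_lateral,
                      r$inferior_superior),
                    paste0(prefix, c("_abs", "_ap", "_ml", "_is")))
  }
  vals <- c(alpha = rot$alpha, beta = rot$beta, absolute_diff = rot$absolute_diff,
            flexion_extension = rot$flexion_extension,
            varus_valgus = rot$varus_valgus,
            external_internal = rot$external_internal,
            rec(report$medial, "medial"), rec(report$lateral, "lateral"),
            rec(report$axis_offset, "axis"))
  cbind(data.frame(specimen = specimen_id), as.data.frame(as.list(vals)))
}

#' Analyze a cohort of specimens
#'
#' @param specimens list of `list(mesh, landmarks)` (or [generate_specimen()]
#'   outputs).
#' @param reslice passed to [run_specimen()].
#' @return list with `reports` and `table` (one row per specimen,
#'   [report_row()] columns).
#' @export
run_cohort <- function(specimens, reslice = TRUE) {
  reports <- lapply(seq_along(specimens), function(i) {
    s <- specimens[[i]]
    run_specimen(s$mesh, s$landmarks, reslice = reslice)
  })
  table <- do.call(rbind, lapply(reports, report_row))
  list(reports = reports, table = table)
}

#' Cohort table via the ground-truth fast path
#'
#' Computes [report_row()]s from `ground_truth` objects through
#' [measure_ground_truth()] (no meshes, no fitting). Used for statistical
#' calibration at scale.
#'
#' @param specimens list with `truth` elements (e.g. from
#'   [generate_cohort()] with `meshes = FALSE`).
#' @return data.frame, one row per specimen.
#' @export
truth_cohort_table <- function(specimens) {
  do.call(rbind, lapply(seq_along(specimens), function(i) {
    report_row(measure_ground_truth(specimens[[i]]$truth), specimen_id = i)
  }))
}

#' Compare a pipeline report against the specimen's ground truth
#'
#' The parameter-recovery check: absolute errors of every rotational
#' component (vs the realized ground truth) and every translational
#' component.
#'
#' @param report a `specimen_report`.
#' @param truth a `ground_truth`.
#' @return named numeric vector of absolute errors (degrees / mm).
#' @export
compare_to_truth <- function(report, truth) {
  m <- measure_ground_truth(truth)
  err <- c(
    flexion = abs(report$rotation$flexion_extension - m$rotation$flexion_extension),
    varus = abs(report$rotation$varus_valgus - m$rotation$varus_valgus),
    external = abs(report$rotation$external_internal - m$rotation$external_internal),
    alpha = abs(report$rotation$alpha - m$rotation$alpha),
    beta = abs(report$rotation$beta - m$rotation$beta))
  cmp_rec <- function(a, b, prefix) {
    if (is.null(a) || is.null(b))
      return(stats::setNames(rep(NA_real_, 4),
                             paste0(prefix, c("_ap", "_ml", "_is", "_abs"))))
    stats::setNames(c(abs(a$anterior_posterior - b$anterior_posterior),
                      abs(a$medial_lateral - b$medial_lateral),
                      abs(a$inferior_superior - b$inferior_superior),
                      abs(a$absolute - b$absolute)),
                    paste0(prefix, c("_ap", "_ml", "_is", "_abs")))
  }
  c(err, cmp_rec(report$medial, m$medial, "medial"),
    cmp_rec(report$lateral, m$lateral, "lateral"),
    cmp_rec(report$axis_offset, m$axis_offset, "axis"))
}

#' Write a cohort report to CSV and JSON
#'
#' The CSV mirrors the cohort table (one specimen per row); the JSON adds
#' the per-column summary and the medial-vs-lateral paired t-tests.
#'
#' @param table cohort table ([run_cohort()] or [truth_cohort_table()]).
#' @param dir output directory (created if needed).
#' @param stem file stem.
#' @return named character vector of the files written, invisibly.
#' @export
write_cohort_report <- function(table, dir, stem = "cohort") {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  csv <- file.path(dir, paste0(stem, ".csv"))
  utils::write.csv(table, csv, row.names = FALSE)
  if (nrow(table) >= 2) {
    summary <- cohort_summary(table[-1])
    tests <- list(
      absolute = t_test(table$medial_abs, table$lateral_abs, paired = TRUE),
      anterior_posterior = t_test(table$medial_ap, table$lateral_ap, paired = TRUE),
      medial_lateral = t_test(abs(table$medial_ml), abs(table$lateral_ml),
                              paired = TRUE),
      inferior_superior = t_test(table$medial_is, table$lateral_is, paired = TRUE))
    payload <- list(summary = summary, medial_vs_lateral = tests)
  } else {
    payload <- list(summary = NULL, medial_vs_lateral = NULL,
                    statistics = "unavailable: fewer than 2 specimens")
  }
  js <- file.path(dir, paste0(stem, ".json"))
  jsonlite::write_json(payload, js, digits = NA, auto_unbox = TRUE, na = "null")
  invisible(c(csv = csv, json = js))
}
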