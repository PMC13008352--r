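# File plumbing: fixed CSV dialect (comma, '.' decimal, UTF-8, mandatory
# header), JSON for scalar results, legacy-VTK text for fields, YAML for
# run configuration. Column dictionary: t_s, z_um, dx_um, length_um,
# dP_Pa, dt_s.

#' Read bead displacement traces from CSV
#'
#' Expects columns `t_s` and `z_um`; optional `dx_um` (distance to the
#' stimulus) and `trace_id` (multiple traces per file). Unknown extra
#' columns are accepted with a warning. Time must be strictly increasing
#' within each trace; violations are reported with their row numbers.
#'
#' @param path CSV file path.
#' @return A tibble of traces (grouping column `trace_id` always present).
#' @export
read_trace_csv <- function(path) {
  df <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  need <- c("t_s", "z_um")
  missing <- setdiff(need, names(df))
  if (length(missing) > 0L)
    abort(sprintf("Missing required column(s): %s.",
                  paste(missing, collapse = ", ")))
  extra <- setdiff(names(df), c(need, "dx_um", "trace_id"))
  if (length(extra) > 0L)
    warn(sprintf("Ignoring unknown column(s): %s.", paste(extra, collapse = ", ")))
  if (!"trace_id" %in% names(df)) df$trace_id <- 1L
  df$.row <- seq_len(nrow(df))
  bad <- df |>
    dplyr::group_by(.data$trace_id) |>
    dplyr::mutate(bad = c(FALSE, diff(.data$t_s) <= 0)) |>
    dplyr::ungroup() |>
    dplyr::filter(.data$bad)
  if (nrow(bad) > 0L)
    abort(sprintf("Non-monotone time: first offending row %d (trace %s).",
                  bad$.row[1], bad$trace_id[1]))
  df$.row <- NULL
  df
}

#' Read a pressure-step dataset from CSV
#'
#' Columns: `length_um`, `dt_s`, `dP_Pa`; optional `cell_id`.
#'
#' @param path CSV file path.
#' @return A tibble ready for [darcy_fit()] / [hyperbolic_lag_fit()].
#' @export
read_pressure_step_csv <- function(path) {
  df <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  need <- c("length_um", "dt_s", "dP_Pa")
  missing <- setdiff(need, names(df))
  if (length(missing) > 0L)
    abort(sprintf("Missing required column(s): %s.",
                  paste(missing, collapse = ", ")))
  df
}

config_hash <- function(x) {
  tf <- tempfile(fileext = ".json")
  on.exit(unlink(tf))
  jsonlite::write_json(x, tf, auto_unbox = TRUE, digits = NA, force = TRUE)
  unname(tools::md5sum(tf))
}

#' Read / write a run configuration
#'
#' Run configurations are flat-ish named lists (scenario and estimator
#' parameters, mesh resolution, tolerances, seed, output paths) stored as
#' YAML; they round-trip through file without loss.
#'
#' @param config Named list.
#' @param path YAML file path.
#' @return `read_config()` returns the named list; `write_config()` the
#'   path, invisibly.
#' @export
write_config <- function(config, path) {
  yaml::write_yaml(config, path)
  invisible(path)
}

#' @rdname write_config
#' @export
read_config <- function(path) {
  yaml::read_yaml(path)
}

#' Write an analysis result to disk
#'
#' Scalar results (`poro_fit`, `ring_calibration`) are written as JSON
#' with a config hash; series-bearing results (`surface_response`) get one
#' CSV per series (profile, probe traces, force, pressure) plus a JSON
#' sidecar. Existing files are never overwritten unless `force = TRUE`.
#'
#' @param result A `poro_fit`, `ring_calibration` or `surface_response`.
#' @param dir Output directory (created if needed).
#' @param force Overwrite existing files.
#' @return Character vector of files written, invisibly.
#' @export
write_result <- function(result, dir, force = FALSE) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  written <- character()
  emit_json <- function(obj, file) {
    p <- file.path(dir, file)
    if (file.exists(p) && !force)
      abort(sprintf("File exists: %s (use force = TRUE).", p))
    # 17 significant digits: doubles survive the decimal round trip bitwise
    jsonlite::write_json(obj, p, auto_unbox = TRUE, digits = I(17),
                         force = TRUE)
    written <<- c(written, p)
  }
  emit_csv <- function(df, file) {
    p <- file.path(dir, file)
    if (file.exists(p) && !force)
      abort(sprintf("File exists: %s (use force = TRUE).", p))
    readr::write_csv(df, p, progress = FALSE)
    written <<- c(written, p)
  }
  if (inherits(result, "poro_fit")) {
    payload <- list(E_Pa = result$E_Pa, D_um2_s = result$D_um2_s,
                    objective = result$objective,
                    convergence = result$convergence,
                    n_evaluations = nrow(result$trace),
                    warnings = result$warnings,
                    meta = result$meta)
    payload$config_hash <- config_hash(result$meta)
    emit_json(payload, "fit_result.json")
    emit_csv(result$trace, "fit_trace.csv")
  } else if (inherits(result, "ring_calibration")) {
    emit_json(unclass(result), "calibration.json")
  } else if (inherits(result, "surface_response")) {
    meta <- list(scenario = result$scenario, steady = result$steady)
    meta$config_hash <- config_hash(meta)
    emit_json(meta, "response.json")
    if (!is.null(result$profile)) emit_csv(result$profile, "profile.csv")
    if (!is.null(result$force)) emit_csv(result$force, "force.csv")
    if (!is.null(result$pressure)) emit_csv(result$pressure, "pressure.csv")
    if (!is.null(result$time_lags)) emit_csv(result$time_lags, "time_lags.csv")
    if (!is.null(result$probes)) {
      for (p_um in unique(result$probes$probe_um)) {
        emit_csv(result$probes[result$probes$probe_um == p_um, ],
                 sprintf("probe_%g.csv", p_um))
      }
    }
  } else abort("Unsupported result type.")
  invisible(written)
}

#' Read a fit result written by [write_result()]
#'
#' @param dir Directory containing `fit_result.json`.
#' @return Named list of the stored values.
#' @export
read_fit_result <- function(dir) {
  jsonlite::read_json(file.path(dir, "fit_result.json"), simplifyVector = TRUE)
}

#' Write a transient solution snapshot as legacy VTK text
#'
#' Writes the mesh (corner nodes, as VTK quads) with point data
#' `displacement` (3-vector, z in the third slot kept 0; axisymmetric
#' r-z components) and `pressure` at one stored time, plus a JSON sidecar
#' of run parameters.
#'
#' @param solution A `poro_solution`.
#' @param path Output `.vtk` path (sidecar written alongside).
#' @param time Snapshot time, s (default final).
#' @return `path`, invisibly.
#' @export
write_vtk <- function(solution, path, time = NULL) {
  idx <- time_index(solution, time)
  mesh <- solution$mesh
  pn <- mesh$pnode
  coords <- mesh$nodes[pn, , drop = FALSE]
  np <- length(pn)
  con <- matrix(match(mesh$conn[, 1:4], pn), ncol = 4L) - 1L
  lines <- c(
    "# vtk DataFile Version 3.0",
    "poroflow transient solution snapshot",
    "ASCII",
    "DATASET UNSTRUCTURED_GRID",
    sprintf("POINTS %d double", np),
    sprintf("%.10g %.10g 0", coords[, 1], coords[, 2]),
    sprintf("CELLS %d %d", nrow(con), 5L * nrow(con)),
    sprintf("4 %d %d %d %d", con[, 1], con[, 2], con[, 3], con[, 4]),
    sprintf("CELL_TYPES %d", nrow(con)),
    rep("9", nrow(con)),
    sprintf("POINT_DATA %d", np),
    "VECTORS displacement double",
    sprintf("%.10g %.10g 0",
            solution$U[2L * pn - 1L, idx], solution$U[2L * pn, idx]),
    "SCALARS pressure double 1",
    "LOOKUP_TABLE default",
    sprintf("%.10g", solution$P[, idx]))
  writeLines(lines, path)
  side <- list(time_s = solution$times[idx],
               materials = as.data.frame(solution$materials),
               initial_pressure = solution$initial_pressure)
  jsonlite::write_json(side, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA, force = TRUE)
  invisible(path)
}
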