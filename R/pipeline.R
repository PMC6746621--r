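#' Build and validate a study configuration
#'
#' Collects everything a full six-variant experiment needs: the mesh source,
#' pacing site, target QRS duration, truth substrate (for synthetic EAM),
#' candidate variants, EAM source and metric options. Validation happens
#' here, before any computation.
#'
#' @param mesh either a list of [generate_biventricular_mesh()] arguments
#'   (`type = "biventricular"`), a list with `type = "slab"` and
#'   [generate_slab_mesh()] arguments, or `list(file = <path>)`.
#' @param pacing `"rv_apex"` or a length-3 coordinate (mm); the stimulus is
#'   the nearest mesh node.
#' @param qrsd_ms target QRS duration (ms); `NULL` uses the truth model's
#'   total activation time (the self-consistent synthetic default).
#' @param truth list describing the ground-truth substrate for synthetic
#'   EAM: `variant`, `base_cv` and any [build_substrate()] parameter.
#' @param variants candidate substrate variants (non-empty subset of
#'   [SUBSTRATE_VARIANTS]).
#' @param eam either `list(file = <csv>)` or synthetic sampling parameters
#'   (`n_points`, `noise_sd_pct`, `spatial_jitter_sd_mm`, `n_veins`).
#' @param match_tol_pct isochrone matching tolerance (%QRS, default 0).
#' @param anisotropy_ratio transverse/longitudinal CV ratio (default 0.4).
#' @param calibration_tol_ms calibration tolerance (ms, default 5).
#' @param scar optional `list(center, radius_mm)`; when the SCAR variant is
#'   requested on an unlabeled synthetic mesh, a default posterior-wall
#'   scar sphere is added.
#' @param seed integer RNG seed; every random choice in the study flows
#'   from it.
#' @return A validated `StudyConfig`.
#' @export
study_config <- function(mesh = list(type = "biventricular"),
                         pacing = "rv_apex",
                         qrsd_ms = NULL,
                         truth = list(variant = "FEC", base_cv = 0.33),
                         variants = SUBSTRATE_VARIANTS,
                         eam = list(n_points = 50, noise_sd_pct = 5),
                         match_tol_pct = 0,
                         anisotropy_ratio = 0.4,
                         calibration_tol_ms = 5,
                         scar = NULL,
                         seed = 1L) {
  if (!is.null(qrsd_ms) && !(is.numeric(qrsd_ms) && qrsd_ms > 0))
    stop("qrsd_ms must be positive")
  if (!length(variants) || !all(variants %in% SUBSTRATE_VARIANTS))
    stop("variants must be a non-empty subset of SUBSTRATE_VARIANTS")
  if (is.null(truth$variant) || !truth$variant %in% SUBSTRATE_VARIANTS)
    stop("truth$variant must name a substrate variant")
  if (!is.list(mesh) || (is.null(mesh$type) && is.null(mesh$file)))
    stop("mesh must give a synthetic type or a file")
  if (!is.null(mesh$file) && !file.exists(paste0(mesh$file, ".pts")) &&
      !file.exists(mesh$file))
    stop("mesh file does not exist: ", mesh$file)
  if (!is.null(eam$file) && !file.exists(eam$file))
    stop("EAM file does not exist: ", eam$file)
  if (!is.numeric(seed) || length(seed) != 1L)
    stop("seed must be a single integer")
  structure(list(mesh = mesh, pacing = pacing, qrsd_ms = qrsd_ms,
                 truth = truth, variants = variants, eam = eam,
                 match_tol_pct = match_tol_pct,
                 anisotropy_ratio = anisotropy_ratio,
                 calibration_tol_ms = calibration_tol_ms,
                 scar = scar, seed = as.integer(seed)),
            class = "StudyConfig")
}

#' Load a study configuration from YAML
#'
#' @param path YAML file whose keys mirror [study_config()] arguments.
#' @return A validated `StudyConfig`.
#' @export
read_study_config <- function(path) {
  do.call(study_config, yaml::read_yaml(path))
}

build_study_mesh <- function(config) {
  ms <- config$mesh
  if (!is.null(ms$file)) {
    mesh <- read_mesh(ms$file)
  } else if (identical(ms$type, "slab")) {
    args <- ms[setdiff(names(ms), "type")]
    mesh <- do.call(generate_slab_mesh, args)
  } else {
    args <- ms[setdiff(names(ms), "type")]
    mesh <- do.call(generate_biventricular_mesh, args)
  }
  if ("SCAR" %in% c(config$variants, config$truth$variant) &&
      !any(mesh$region == "SCAR")) {
    sc <- config$scar
    if (is.null(sc)) {
      # default: mid-height scar sphere in the posterior LV free wall
      ctr <- element_centroids(mesh)
      post <- which(mesh$region == "LV_FREE_WALL_POST")
      if (!length(post)) stop("cannot place a default scar: no posterior LV wall")
      ab <- rowMeans(matrix(mesh$apex_base[mesh$elems], ncol = 4L))
      pick <- post[which.min(abs(ab[post] - 0.5))]
      sc <- list(center = ctr[pick, ], radius_mm = 8)
    }
    mesh <- add_scar_region(mesh, sc$center, sc$radius_mm)
  }
  mesh
}

substrate_args <- function(config, lst) {
  keep <- intersect(names(lst),
                    c("fec_ratio", "fec_thickness_mm", "fec_extent",
                      "septal_factor"))
  c(list(anisotropy_ratio = config$anisotropy_ratio), lst[keep])
}

#' Run the full six-variant study
#'
#' The experiment end to end: build (or read) the mesh, assign fibers,
#' simulate the ground truth, draw (or read) the EAM recording, then for
#' every candidate variant calibrate the bulk velocity to the QRS duration,
#' simulate, score temporal and distance errors at the EAM points, screen
#' the physiological constraints, and compare the variants statistically.
#' Variants whose calibration fails are reported as failed, never silently
#' included. Fully deterministic for a fixed config seed.
#'
#' @param config a [study_config()].
#' @param out_dir optional output directory; writes `summary.json`,
#'   `comparison.csv`, `eam.csv` and per-variant VTK activation maps.
#' @return A `StudyReport`: per-variant results, the comparison table, the
#'   EAM recording and the truth map.
#' @export
run_study <- function(config, out_dir = NULL) {
  stopifnot(inherits(config, "StudyConfig"))
  mesh <- build_study_mesh(config)
  fibers <- assign_fibers(mesh)
  stim <- if (identical(config$pacing, "rv_apex")) rv_apex_node(mesh)
          else nearest_node(mesh, config$pacing)
  pacing <- pacing_config(stim)

  truth_sub <- do.call(build_substrate,
                       c(list(mesh = mesh, variant = config$truth$variant,
                              base_cv = config$truth$base_cv %||% 0.33),
                         substrate_args(config, config$truth)))
  truth_map <- solve_eikonal(mesh, fibers, truth_sub, pacing)
  qrsd <- config$qrsd_ms %||%
    suppressWarnings(as.numeric(total_activation_time(truth_map)))

  if (!is.null(config$eam$file)) {
    eam <- read_eam(config$eam$file)
    proj <- project_points(mesh, eam)
    eam <- proj$eam
    proj_rms <- proj$rms_mm
  } else {
    eam <- sample_eam(mesh, truth_map,
                      n_points = config$eam$n_points %||% 50,
                      noise_sd_pct = config$eam$noise_sd_pct %||% 5,
                      seed = config$seed, qrsd_ms = qrsd,
                      n_veins = config$eam$n_veins %||% 4L,
                      spatial_jitter_sd_mm =
                        config$eam$spatial_jitter_sd_mm %||% 3)
    proj_rms <- 0
  }

  results <- list()
  for (v in config$variants) {
    res <- tryCatch({
      template <- do.call(build_substrate,
                          c(list(mesh = mesh, variant = v,
                                 base_cv = truth_sub$base_cv),
                            substrate_args(config, config$truth)))
      calib <- suppressWarnings(
        calibrate_cv(mesh, fibers, template, pacing, qrsd,
                     tolerance_ms = config$calibration_tol_ms))
      fitted <- scale_substrate(template, calib$fitted_cv / template$base_cv)
      map <- solve_eikonal(mesh, fibers, fitted, pacing)
      sim_lat <- normalized_lat(map, mesh, eam$points, qrsd)
      terr <- temporal_error(sim_lat, eam$lat_pct, qrsd)
      derr <- distance_error(map, mesh, eam$points, eam$lat_pct, qrsd,
                             config$match_tol_pct)
      site <- latest_activation_site(map, mesh)
      constraints <- check_constraints(calib, site$region)
      calibrated_ok <- calib$mismatch <= config$calibration_tol_ms
      list(variant = v, ok = TRUE, calibration = calib,
           calibrated_ok = calibrated_ok, map = map,
           report = error_report(v, terr, as.numeric(derr), proj_rms),
           latest_site = site, constraints = constraints)
    }, error = function(e) {
      list(variant = v, ok = FALSE, error = conditionMessage(e))
    })
    results[[v]] <- res
  }

  usable <- Filter(function(r) isTRUE(r$ok) && isTRUE(r$calibrated_ok), results)
  comparison <- if (length(usable) >= 2L)
    compare_variants(lapply(usable, `[[`, "report")) else NULL

  report <- structure(list(config = config, qrsd_ms = qrsd,
                           truth_map = truth_map, eam = eam,
                           results = results, comparison = comparison,
                           mesh = mesh, fibers = fibers, pacing = pacing),
                      class = "StudyReport")
  if (!is.null(out_dir)) write_study_report(report, out_dir)
  report
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.StudyReport <- function(x, ...) {
  cat(sprintf("StudyReport: truth %s, QRSd %.1f ms, %d EAM points\n",
              x$config$truth$variant, x$qrsd_ms, nrow(x$eam$points)))
  for (r in x$results) {
    if (!isTRUE(r$ok)) {
      cat(sprintf("  %-15s FAILED: %s\n", r$variant, r$error))
    } else {
      cat(sprintf("  %-15s cv %.3f m/s, dist %.2f mm, temp %+.2f ms, constraints %s\n",
                  r$variant, r$calibration$fitted_cv,
                  r$report$mean_distance_mm, r$report$mean_temporal_ms,
                  if (r$constraints$pass) "pass"
                  else paste("FAIL:", paste(r$constraints$reasons, collapse = "; "))))
    }
  }
  if (!is.null(x$comparison))
    cat("  ranking:", paste(x$comparison$ranking, collapse = " > "), "\n")
  invisible(x)
}

#' Serialize a study report
#'
#' Writes `summary.json` (deterministic for a fixed config seed),
#' `comparison.csv`, the EAM recording, and one VTK file per successful
#' variant carrying the activation map.
#'
#' @param report a `StudyReport`.
#' @param out_dir output directory (created if needed).
#' @return `out_dir`, invisibly.
#' @export
write_study_report <- function(report, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  summary <- list(
    qrsd_ms = report$qrsd_ms,
    truth_variant = report$config$truth$variant,
    seed = report$config$seed,
    n_eam_points = nrow(report$eam$points),
    variants = lapply(report$results, function(r) {
      if (!isTRUE(r$ok)) return(list(variant = r$variant, ok = FALSE,
                                     error = r$error))
      list(variant = r$variant, ok = TRUE,
           fitted_cv = round(r$calibration$fitted_cv, 10),
           calibration_mismatch_ms = round(r$calibration$mismatch, 10),
           mean_distance_mm = round(r$report$mean_distance_mm, 10),
           mean_temporal_ms = round(r$report$mean_temporal_ms, 10),
           latest_site_region = r$latest_site$region,
           constraints_pass = r$constraints$pass,
           constraint_failures = r$constraints$reasons)
    }),
    ranking = if (!is.null(report$comparison))
      as.list(report$comparison$ranking) else NULL)
  jsonlite::write_json(summary, file.path(out_dir, "summary.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       null = "null")
  write_eam(report$eam, file.path(out_dir, "eam.csv"))
  if (!is.null(report$comparison))
    write.table(report$comparison$table, file.path(out_dir, "comparison.csv"),
                sep = ",", row.names = FALSE, quote = FALSE)
  for (r in report$results) {
    if (isTRUE(r$ok))
      write_mesh(report$mesh,
                 file.path(out_dir, sprintf("activation_%s.vtk", tolower(r$variant))),
                 fibers = report$fibers, map = r$map)
  }
  invisible(out_dir)
}

#' Sweep the fast-endocardial-conduction ratio
#'
#' Runs the FEC candidate at each requested fold-increase and layer extent
#' against a fixed study (mesh, truth, EAM all from `config`), reporting
#' the mean distance error per cell. Ratio 1 with full extent degenerates
#' to the normal model. Ratios outside `[1, 10]` draw a warning but still
#' run.
#'
#' @param config a [study_config()]; the truth substrate and EAM are built
#'   once from it.
#' @param ratios numeric vector of FEC fold-increases (default 1:10).
#' @param extents layer extents to cross with the ratios
#'   (default both `"FULL"` and `"LOWER_THIRD"`).
#' @return data frame: `fec_ratio`, `fec_extent`, `fitted_cv`,
#'   `mean_distance_mm`, `mean_temporal_ms`, `calibrated_ok`.
#' @export
sweep_fec_ratio <- function(config, ratios = 1:10,
                            extents = c("FULL", "LOWER_THIRD")) {
  stopifnot(inherits(config, "StudyConfig"))
  if (any(ratios < 1 | ratios > 10))
    warning("FEC ratios outside [1, 10] are outside the studied range; running anyway")
  mesh <- build_study_mesh(config)
  fibers <- assign_fibers(mesh)
  stim <- if (identical(config$pacing, "rv_apex")) rv_apex_node(mesh)
          else nearest_node(mesh, config$pacing)
  pacing <- pacing_config(stim)
  truth_sub <- do.call(build_substrate,
                       c(list(mesh = mesh, variant = config$truth$variant,
                              base_cv = config$truth$base_cv %||% 0.33),
                         substrate_args(config, config$truth)))
  truth_map <- solve_eikonal(mesh, fibers, truth_sub, pacing)
  qrsd <- config$qrsd_ms %||%
    suppressWarnings(as.numeric(total_activation_time(truth_map)))
  if (!is.null(config$eam$file)) {
    eam <- project_points(mesh, read_eam(config$eam$file))$eam
  } else {
    eam <- sample_eam(mesh, truth_map,
                      n_points = config$eam$n_points %||% 50,
                      noise_sd_pct = config$eam$noise_sd_pct %||% 5,
                      seed = config$seed, qrsd_ms = qrsd,
                      n_veins = config$eam$n_veins %||% 4L,
                      spatial_jitter_sd_mm =
                        config$eam$spatial_jitter_sd_mm %||% 3)
  }

  rows <- list()
  for (ext in extents) {
    for (r in ratios) {
      template <- build_substrate(mesh, "FEC", base_cv = truth_sub$base_cv,
                                  anisotropy_ratio = config$anisotropy_ratio,
                                  fec_ratio = r, fec_extent = ext)
      calib <- suppressWarnings(
        calibrate_cv(mesh, fibers, template, pacing, qrsd,
                     tolerance_ms = config$calibration_tol_ms))
      fitted <- scale_substrate(template, calib$fitted_cv / template$base_cv)
      map <- solve_eikonal(mesh, fibers, fitted, pacing)
      sim_lat <- normalized_lat(map, mesh, eam$points, qrsd)
      derr <- distance_error(map, mesh, eam$points, eam$lat_pct, qrsd,
                             config$match_tol_pct)
      terr <- temporal_error(sim_lat, eam$lat_pct, qrsd)
      rows[[length(rows) + 1L]] <- data.frame(
        fec_ratio = r, fec_extent = ext, fitted_cv = calib$fitted_cv,
        mean_distance_mm = mean(as.numeric(derr), na.rm = TRUE),
        mean_temporal_ms = mean(terr, na.rm = TRUE),
        calibrated_ok = calib$mismatch <= config$calibration_tol_ms)
    }
  }
  do.call(rbind, rows)
}
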