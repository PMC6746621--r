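#' Electro-anatomical mapping recording
#'
#' Measurement points (mm, in mesh coordinates) with local activation times
#' normalized as a percentage of the QRS duration, plus the QRS duration
#' itself.
#'
#' @param points q x 3 numeric matrix of coordinates (mm).
#' @param lat_pct numeric vector of normalized LAT (% of QRS duration).
#' @param qrsd_ms QRS duration (ms), > 0.
#' @return An `EAMRecording`.
#' @export
eam_recording <- function(points, lat_pct, qrsd_ms) {
  points <- as.matrix(points)
  if (ncol(points) != 3L || nrow(points) < 1L)
    stop("points must be a non-empty q x 3 matrix")
  if (length(lat_pct) != nrow(points) || any(!is.finite(lat_pct)))
    stop("lat_pct must be finite with one value per point")
  if (!(qrsd_ms > 0)) stop("qrsd_ms must be positive")
  structure(list(points = points, lat_pct = as.numeric(lat_pct),
                 qrsd_ms = as.numeric(qrsd_ms)),
            class = "EAMRecording")
}

#' @export
print.EAMRecording <- function(x, ...) {
  cat(sprintf("EAMRecording: %d points, LAT %.1f-%.1f %%QRS, QRSd %.0f ms\n",
              nrow(x$points), min(x$lat_pct), max(x$lat_pct), x$qrsd_ms))
  invisible(x)
}

#' Project measurement points onto the epicardial surface
#'
#' Each point moves to its closest point on an `EPI`-labeled boundary face;
#' the root-mean-square displacement is reported, mirroring how
#' coronary-vein mapping points are registered to a model surface.
#'
#' @param mesh an `ActivationMesh` with `EPI` faces.
#' @param eam an `EAMRecording`.
#' @return list with `eam` (projected recording) and `rms_mm`.
#' @export
project_points <- function(mesh, eam) {
  epi <- mesh$surface_labels == "EPI"
  if (!any(epi)) stop("mesh has no EPI-labeled surface faces")
  tris <- mesh$surface_faces[epi, , drop = FALSE]
  cp <- .closest_triangle_cpp(eam$points, mesh$nodes, tris - 1L)
  out <- eam
  out$points <- cp$foot
  list(eam = out, rms_mm = sqrt(mean(cp$dist^2)))
}

#' Normalized local activation time at surface points
#'
#' Interpolates the activation map barycentrically within the nearest
#' epicardial triangle of each point and expresses it as a percentage of
#' the QRS duration. Values above 100% are legitimate (the simulated total
#' activation time may exceed the QRS duration by up to the calibration
#' tolerance). Points whose triangle touches unreachable tissue yield `NA`.
#'
#' @param map an `ActivationMap`.
#' @param mesh the mesh the map lives on.
#' @param points q x 3 matrix of (projected) points.
#' @param qrsd_ms QRS duration (ms).
#' @return numeric vector of LAT in %QRS (NA where unreachable).
#' @export
normalized_lat <- function(map, mesh, points, qrsd_ms) {
  points <- rbind(points)
  epi <- mesh$surface_labels == "EPI"
  if (!any(epi)) stop("mesh has no EPI-labeled surface faces")
  tris <- mesh$surface_faces[epi, , drop = FALSE]
  cp <- .closest_triangle_cpp(points, mesh$nodes, tris - 1L)
  t_ms <- vapply(seq_len(nrow(points)), function(i) {
    tri <- tris[cp$triangle[i], ]
    bc <- barycentric_weights(cp$foot[i, ], mesh$nodes[tri[1], ],
                              mesh$nodes[tri[2], ], mesh$nodes[tri[3], ])
    tv <- map$times[tri]
    if (any(!is.finite(tv))) return(NA_real_)
    sum(bc * tv)
  }, numeric(1))
  100 * (t_ms - map$pacing$onset_time) / qrsd_ms
}

barycentric_weights <- function(p, a, b, c3) {
  v0 <- b - a; v1 <- c3 - a; v2 <- p - a
  d00 <- sum(v0 * v0); d01 <- sum(v0 * v1); d11 <- sum(v1 * v1)
  d20 <- sum(v2 * v0); d21 <- sum(v2 * v1)
  den <- d00 * d11 - d01 * d01
  if (abs(den) < 1e-300) return(c(1, 0, 0))
  v <- (d11 * d20 - d01 * d21) / den
  w <- (d00 * d21 - d01 * d20) / den
  c(1 - v - w, v, w)
}

#' Temporal error between simulated and measured activation
#'
#' The relative LAT error (simulated minus measured, in %QRS) multiplied by
#' the QRS duration. Positive values mean the model activates later
#' (slower) than the measurement; negative values mean it activates faster.
#'
#' @param sim_lat_pct,meas_lat_pct LAT values in %QRS.
#' @param qrsd_ms QRS duration (ms).
#' @return temporal error in ms (vectorized).
#' @export
temporal_error <- function(sim_lat_pct, meas_lat_pct, qrsd_ms) {
  (sim_lat_pct - meas_lat_pct) / 100 * qrsd_ms
}

#' Isochrone distance error
#'
#' For each measurement, the minimum Euclidean distance from the projected
#' point to the simulated isochrone of the measured activation time: the
#' level set is located by linear interpolation along every mesh edge that
#' crosses the level (a band of half-width `match_tol_pct` when non-zero).
#' A point whose own simulated LAT matches within `match_tol_pct`
#' contributes 0. Measurements outside the simulated LAT range are flagged
#' and scored against the nearest extreme isochrone.
#'
#' @param map an `ActivationMap`.
#' @param mesh the mesh the map lives on.
#' @param points q x 3 matrix of projected points.
#' @param meas_lat_pct measured LAT (%QRS) per point.
#' @param qrsd_ms QRS duration (ms).
#' @param match_tol_pct tolerance (in %QRS) within which a simulated LAT
#'   "matches" the measurement (default 0: exact level-set crossing).
#' @return numeric vector of distances (mm) with logical attribute
#'   `out_of_range` per point.
#' @export
distance_error <- function(map, mesh, points, meas_lat_pct, qrsd_ms,
                           match_tol_pct = 0) {
  points <- rbind(points)
  stopifnot(length(meas_lat_pct) == nrow(points))
  fin <- is.finite(map$times)
  if (!any(fin)) stop("all nodes are unreachable from the stimulus")
  node_lat <- 100 * (map$times - map$pacing$onset_time) / qrsd_ms
  rng <- range(node_lat[fin])
  ed <- mesh_edges(mesh)
  both_fin <- fin[ed[, 1]] & fin[ed[, 2]]
  ed <- ed[both_fin, , drop = FALSE]
  la <- node_lat[ed[, 1]]; lb <- node_lat[ed[, 2]]
  pa <- mesh$nodes[ed[, 1], , drop = FALSE]
  pb <- mesh$nodes[ed[, 2], , drop = FALSE]
  sim_at_pt <- normalized_lat(map, mesh, points, qrsd_ms)

  level_points <- function(L) {
    hit <- (la - L) * (lb - L) <= 0
    if (!any(hit)) return(NULL)
    denom <- lb[hit] - la[hit]
    s <- ifelse(abs(denom) < 1e-12, 0.5, (L - la[hit]) / denom)
    pa[hit, , drop = FALSE] +
      (pb[hit, , drop = FALSE] - pa[hit, , drop = FALSE]) * s
  }
  min_dist <- function(p, iso) {
    if (is.null(iso)) return(Inf)
    sqrt(min((iso[, 1] - p[1])^2 + (iso[, 2] - p[2])^2 + (iso[, 3] - p[3])^2))
  }

  q <- nrow(points)
  out <- numeric(q)
  flag <- logical(q)
  for (i in seq_len(q)) {
    L <- meas_lat_pct[i]
    if (is.finite(sim_at_pt[i]) && abs(sim_at_pt[i] - L) <= match_tol_pct) {
      out[i] <- 0
      next
    }
    if (L < rng[1] - match_tol_pct || L > rng[2] + match_tol_pct) {
      flag[i] <- TRUE
      extreme <- if (L > rng[2]) which(fin & node_lat == rng[2])
                 else which(fin & node_lat == rng[1])
      ex <- mesh$nodes[extreme, , drop = FALSE]
      out[i] <- sqrt(min((ex[, 1] - points[i, 1])^2 + (ex[, 2] - points[i, 2])^2 +
                         (ex[, 3] - points[i, 3])^2))
      next
    }
    levels <- if (match_tol_pct > 0) c(L - match_tol_pct, L + match_tol_pct) else L
    d <- min(vapply(levels, function(l) min_dist(points[i, ], level_points(l)),
                    numeric(1)))
    if (match_tol_pct > 0) {
      # nodes strictly inside the band are part of the matching set too
      inb <- which(fin & abs(node_lat - L) <= match_tol_pct)
      if (length(inb)) {
        nb <- mesh$nodes[inb, , drop = FALSE]
        d <- min(d, sqrt(min((nb[, 1] - points[i, 1])^2 +
                             (nb[, 2] - points[i, 2])^2 +
                             (nb[, 3] - points[i, 3])^2)))
      }
    }
    if (!is.finite(d)) flag[i] <- TRUE
    out[i] <- if (is.finite(d)) d else NA_real_
  }
  structure(out, out_of_range = flag)
}

#' Physiological constraint screen
#'
#' A calibrated model is physiologically admissible when its fitted bulk
#' conduction velocity lies in the experimentally reported 0.07-0.75 m/s
#' range and its latest activated site is not septal (endocardial mapping
#' places the latest activation near the LV lateral wall).
#'
#' @param calib a `CalibrationResult`.
#' @param site_region region label of the latest activated site.
#' @param cv_range admissible velocity range in m/s (default `c(0.07, 0.75)`).
#' @return list with `pass` (logical) and `reasons` (character, empty on pass).
#' @export
check_constraints <- function(calib, site_region, cv_range = c(0.07, 0.75)) {
  reasons <- character(0)
  if (calib$fitted_cv < cv_range[1] || calib$fitted_cv > cv_range[2])
    reasons <- c(reasons,
                 sprintf("fitted conduction velocity %.3f m/s outside [%.2f, %.2f] m/s",
                         calib$fitted_cv, cv_range[1], cv_range[2]))
  if (identical(site_region, "SEPTUM"))
    reasons <- c(reasons, "latest activated site lies in the septum")
  list(pass = length(reasons) == 0L, reasons = reasons)
}

#' Per-variant error report
#'
#' @param variant substrate variant identifier.
#' @param temporal_error_ms,distance_error_mm per-point error vectors.
#' @param projection_rms_mm RMS of the EAM projection displacement (mm).
#' @return An `ErrorReport` with per-point values, means and standard errors.
#' @export
error_report <- function(variant, temporal_error_ms, distance_error_mm,
                         projection_rms_mm = NA_real_) {
  se <- function(x) stats::sd(x, na.rm = TRUE) / sqrt(sum(is.finite(x)))
  structure(list(
    variant = variant,
    temporal_error_ms = temporal_error_ms,
    distance_error_mm = distance_error_mm,
    mean_temporal_ms = mean(temporal_error_ms, na.rm = TRUE),
    se_temporal_ms = se(temporal_error_ms),
    mean_distance_mm = mean(distance_error_mm, na.rm = TRUE),
    se_distance_mm = se(distance_error_mm),
    projection_rms_mm = projection_rms_mm),
    class = "ErrorReport")
}

#' @export
print.ErrorReport <- function(x, ...) {
  cat(sprintf("ErrorReport [%s]: temporal %.1f +/- %.1f ms, distance %.1f +/- %.1f mm (n = %d)\n",
              x$variant, x$mean_temporal_ms, x$se_temporal_ms,
              x$mean_distance_mm, x$se_distance_mm,
              length(x$distance_error_mm)))
  invisible(x)
}

#' Compare substrate variants statistically
#'
#' One-way ANOVA across variants for the temporal and distance errors, with
#' all-pairs Tukey HSD post-hoc tests and a ranking by mean distance error
#' -- the comparison used to single out the fast-endocardial-conduction
#' model.
#'
#' @param reports a list of `ErrorReport`s (>= 2 variants, >= 2 points each).
#' @return A `VariantComparison`: `table` (per-variant means/SEs), `anova`
#'   (F and p per metric), `tukey` (adjusted p-value tables), `ranking`
#'   (variants by increasing mean distance error).
#' @export
compare_variants <- function(reports) {
  if (length(reports) < 2L) stop("need at least two variants to compare")
  for (r in reports) {
    if (!inherits(r, "ErrorReport")) stop("reports must be ErrorReport objects")
    if (sum(is.finite(r$distance_error_mm)) < 2L)
      stop("variant ", r$variant, " has fewer than two observations")
  }
  long <- do.call(rbind, lapply(reports, function(r)
    data.frame(variant = r$variant,
               temporal = r$temporal_error_ms,
               distance = r$distance_error_mm)))
  long$variant <- factor(long$variant)
  long <- long[is.finite(long$temporal) & is.finite(long$distance), ]

  one_way <- function(metric) {
    fit <- stats::aov(long[[metric]] ~ variant, data = long)
    an <- summary(fit)[[1]]
    tk <- stats::TukeyHSD(fit)$variant
    Fv <- an$`F value`[1]
    list(F = ifelse(is.na(Fv), 0, Fv), p = an$`Pr(>F)`[1], tukey = tk)
  }
  at <- one_way("temporal")
  ad <- one_way("distance")
  tab <- data.frame(
    variant = vapply(reports, `[[`, character(1), "variant"),
    n = vapply(reports, function(r) sum(is.finite(r$distance_error_mm)), integer(1)),
    mean_temporal_ms = vapply(reports, `[[`, numeric(1), "mean_temporal_ms"),
    se_temporal_ms = vapply(reports, `[[`, numeric(1), "se_temporal_ms"),
    mean_distance_mm = vapply(reports, `[[`, numeric(1), "mean_distance_mm"),
    se_distance_mm = vapply(reports, `[[`, numeric(1), "se_distance_mm"),
    row.names = NULL)
  tab <- tab[order(tab$mean_distance_mm), ]
  structure(list(table = tab,
                 anova = list(temporal = at[c("F", "p")],
                              distance = ad[c("F", "p")]),
                 tukey = list(temporal = at$tukey, distance = ad$tukey),
                 ranking = tab$variant),
            class = "VariantComparison")
}

#' @export
print.VariantComparison <- function(x, ...) {
  cat("VariantComparison (ranked by mean distance error):\n")
  print(x$table, row.names = FALSE, digits = 4)
  cat(sprintf("ANOVA distance: F = %.2f, p = %.3g; temporal: F = %.2f, p = %.3g\n",
              x$anova$distance$F, x$anova$distance$p,
              x$anova$temporal$F, x$anova$temporal$p))
  invisible(x)
}
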