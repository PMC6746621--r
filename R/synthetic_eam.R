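#' Sample a synthetic coronary-vein-like EAM recording
#'
#' Emulates intra-procedural coronary-vein mapping of the LV free-wall
#' epicardium: measurement sites are laid out along a few roughly
#' apex-to-base polylines ("veins") on LV free-wall epicardial faces, then
#' perturbed by Gaussian spatial jitter (re-projected onto the epicardium,
#' mimicking the registration error that mapping chains report as a
#' projection RMS) and by additive Gaussian noise on the normalized local
#' activation time.
#'
#' @param mesh an `ActivationMesh` with labeled LV free wall and `EPI` faces.
#' @param truth_map the ground-truth `ActivationMap` on `mesh`.
#' @param n_points number of measurement points (>= 1).
#' @param noise_sd_pct LAT noise standard deviation in %QRS (default 5).
#' @param seed RNG seed (mandatory: recordings are reproducible by design).
#' @param qrsd_ms QRS duration used for normalization; defaults to the
#'   truth map's total activation time.
#' @param n_veins number of vein polylines (default 4).
#' @param spatial_jitter_sd_mm spatial jitter SD in mm (default 3).
#' @return An [eam_recording()]; attribute `truth_lat_pct` carries the
#'   noiseless LAT at the sampled (jittered, re-projected) points.
#' @export
sample_eam <- function(mesh, truth_map, n_points, noise_sd_pct = 5, seed,
                       qrsd_ms = NULL, n_veins = 4L,
                       spatial_jitter_sd_mm = 3) {
  if (missing(seed)) stop("seed is mandatory for synthetic EAM sampling")
  if (n_points < 1L) stop("n_points must be >= 1")
  if (is.null(qrsd_ms))
    qrsd_ms <- suppressWarnings(as.numeric(total_activation_time(truth_map)))

  own <- surface_face_owners(mesh)
  lvfree <- mesh$surface_labels == "EPI" &
    mesh$region[own] %in% c("LV_FREE_WALL_ANT", "LV_FREE_WALL_POST")
  if (!any(lvfree)) stop("mesh has no LV free-wall EPI faces")
  faces <- mesh$surface_faces[lvfree, , drop = FALSE]
  fc <- (mesh$nodes[faces[, 1], , drop = FALSE] +
         mesh$nodes[faces[, 2], , drop = FALSE] +
         mesh$nodes[faces[, 3], , drop = FALSE]) / 3
  fab <- (mesh$apex_base[faces[, 1]] + mesh$apex_base[faces[, 2]] +
          mesh$apex_base[faces[, 3]]) / 3
  axis_xy <- colMeans(mesh$nodes[, 1:2, drop = FALSE])
  fang <- atan2(fc[, 2] - axis_xy[2], fc[, 1] - axis_xy[1])

  set.seed(as.integer(seed))
  # vein trunk angles spread over the angular span of the LV free wall;
  # work relative to the wall's circular mean so the +/- pi wrap (the free
  # wall faces away from the septum) cannot split the span
  amean <- atan2(mean(sin(fang)), mean(cos(fang)))
  rel <- ((fang - amean + pi) %% (2 * pi)) - pi
  qa <- stats::quantile(rel, c(0.1, 0.9))
  vein_ang <- amean + seq(qa[1], qa[2], length.out = n_veins) +
    stats::rnorm(n_veins, 0, 0.05)
  per_vein <- diff(round(seq(0, n_points, length.out = n_veins + 1L)))
  pts <- matrix(NA_real_, n_points, 3)
  i <- 0L
  for (v in seq_len(n_veins)) {
    if (per_vein[v] == 0L) next
    ab_targets <- seq(0.08, 0.95, length.out = per_vein[v])
    for (ab in ab_targets) {
      i <- i + 1L
      score <- (fab - ab)^2 + (0.25 * angdiff(fang, vein_ang[v]))^2
      pts[i, ] <- fc[which.min(score), ]
    }
  }
  pts <- pts + matrix(stats::rnorm(3L * n_points, 0, spatial_jitter_sd_mm),
                      n_points, 3)
  proj <- project_points(mesh, eam_recording(pts, rep(0, n_points), qrsd_ms))
  pts <- proj$eam$points

  truth_lat <- normalized_lat(truth_map, mesh, pts, qrsd_ms)
  if (anyNA(truth_lat))
    stop("ground-truth activation is not finite at sampled epicardial points")
  lat <- truth_lat + stats::rnorm(n_points, 0, noise_sd_pct)
  out <- eam_recording(pts, lat, qrsd_ms)
  attr(out, "truth_lat_pct") <- truth_lat
  out
}

angdiff <- function(a, b) {
  d <- (a - b) %% (2 * pi)
  pmin(d, 2 * pi - d)
}
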