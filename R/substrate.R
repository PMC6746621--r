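#' Substrate variants
#'
#' The six rule-based conduction substrates: normal homogeneous myocardium;
#' scar (complete block in scar-labeled elements); functional block of the
#' anterior or posterior LV free wall (complete block, transmural, full
#' apex-base extent); slow septal conduction (septal velocity scaled to 50%
#' of bulk); and a fast endocardial conduction (FEC) layer, a thin
#' endocardial shell with a six-fold longitudinal velocity acting as a
#' surrogate for the Purkinje system / fast sub-endocardial conduction.
#'
#' @export
SUBSTRATE_VARIANTS <- c("NORMAL", "SCAR", "ANTERIOR_BLOCK", "POSTERIOR_BLOCK",
                        "SLOW_SEPTUM", "FEC")

#' Build a conduction substrate
#'
#' Produces per-element longitudinal conduction velocities realizing one of
#' the six variants. Velocities are in m/s (numerically equal to mm/ms, the
#' solver's internal unit); 0 encodes complete block. The transverse
#' velocity is always `anisotropy_ratio` times the longitudinal one.
#'
#' FEC layer membership is by element-centroid distance to the nearest
#' endocardial (`LV_ENDO` or `RV_ENDO`) boundary face; on meshes coarser
#' than the layer thickness, the first element layer touching the
#' endocardial surface is used instead. With `fec_extent = "LOWER_THIRD"`
#' the layer is restricted to elements with mean apex-base coordinate below
#' 1/3.
#'
#' @param mesh a labeled `ActivationMesh`.
#' @param variant one of [SUBSTRATE_VARIANTS].
#' @param base_cv bulk longitudinal conduction velocity in m/s (default 0.5,
#'   mid-range of the physiologically plausible 0.07-0.75 m/s; usually
#'   overwritten by [calibrate_cv()]).
#' @param anisotropy_ratio transverse/longitudinal velocity ratio in (0, 1],
#'   default 0.4.
#' @param fec_ratio FEC fold-increase of the longitudinal velocity,
#'   default 6 (range 1-10).
#' @param fec_thickness_mm FEC layer thickness (mm), default 1.
#' @param fec_extent `"FULL"` (apex to base) or `"LOWER_THIRD"`.
#' @param septal_factor septal velocity multiplier in (0, 1], default 0.5.
#' @return A `SubstrateModel`.
#' @export
build_substrate <- function(mesh, variant,
                            base_cv = 0.5,
                            anisotropy_ratio = 0.4,
                            fec_ratio = 6,
                            fec_thickness_mm = 1,
                            fec_extent = c("FULL", "LOWER_THIRD"),
                            septal_factor = 0.5) {
  if (!variant %in% SUBSTRATE_VARIANTS)
    stop("unknown substrate variant: ", variant)
  fec_extent <- match.arg(fec_extent)
  if (!(base_cv > 0)) stop("base_cv must be positive")
  if (anisotropy_ratio <= 0 || anisotropy_ratio > 1)
    stop("anisotropy_ratio must be in (0, 1]")
  if (fec_ratio < 1) stop("fec_ratio must be >= 1")
  if (septal_factor <= 0 || septal_factor > 1)
    stop("septal_factor must be in (0, 1]")

  m <- n_elems(mesh)
  cv <- rep(base_cv, m)
  if (variant == "SCAR") {
    hit <- mesh$region == "SCAR"
    if (!any(hit)) stop("SCAR variant requires SCAR region labels on the mesh")
    cv[hit] <- 0
  } else if (variant == "ANTERIOR_BLOCK" || variant == "POSTERIOR_BLOCK") {
    lab <- if (variant == "ANTERIOR_BLOCK") "LV_FREE_WALL_ANT" else "LV_FREE_WALL_POST"
    hit <- mesh$region == lab
    if (!any(hit)) stop(variant, " requires ", lab, " region labels on the mesh")
    cv[hit] <- 0
  } else if (variant == "SLOW_SEPTUM") {
    hit <- mesh$region == "SEPTUM"
    if (!any(hit)) stop("SLOW_SEPTUM requires SEPTUM region labels on the mesh")
    cv[hit] <- septal_factor * base_cv
  } else if (variant == "FEC") {
    hit <- fec_layer_elements(mesh, fec_thickness_mm, fec_extent)
    cv[hit] <- fec_ratio * base_cv
  }

  structure(list(variant = variant, cv_long = cv,
                 anisotropy_ratio = anisotropy_ratio,
                 fec_ratio = fec_ratio, fec_thickness_mm = fec_thickness_mm,
                 fec_extent = fec_extent, septal_factor = septal_factor,
                 base_cv = base_cv),
            class = "SubstrateModel")
}

#' @export
print.SubstrateModel <- function(x, ...) {
  cat(sprintf("SubstrateModel: %s, base CV %.3f m/s, anisotropy %.2f, %d elements (%d blocked)\n",
              x$variant, x$base_cv, x$anisotropy_ratio, length(x$cv_long),
              sum(x$cv_long == 0)))
  invisible(x)
}

#' Elements belonging to the fast endocardial layer
#'
#' @inheritParams build_substrate
#' @return logical vector over elements.
#' @export
fec_layer_elements <- function(mesh, fec_thickness_mm = 1,
                               fec_extent = c("FULL", "LOWER_THIRD")) {
  fec_extent <- match.arg(fec_extent)
  endo <- mesh$surface_labels %in% c("LV_ENDO", "RV_ENDO")
  if (!any(endo)) stop("mesh has no endocardial surface faces")
  tris <- mesh$surface_faces[endo, , drop = FALSE]
  ctr <- element_centroids(mesh)
  d <- .closest_triangle_cpp(ctr, mesh$nodes, tris - 1L)$dist
  hit <- d <= fec_thickness_mm
  if (!any(hit)) {
    # mesh coarser than the layer: take the first element layer on the surface
    own <- surface_face_owners(mesh)
    hit <- seq_len(n_elems(mesh)) %in% own[endo]
  }
  if (fec_extent == "LOWER_THIRD") {
    ab <- rowMeans(matrix(mesh$apex_base[mesh$elems], ncol = ncol(mesh$elems)))
    hit <- hit & ab < 1 / 3
  }
  hit
}

# Owning element index for each stored boundary face.
surface_face_owners <- function(mesh) {
  bd <- derive_boundary_faces(mesh$elems)
  lut <- stats::setNames(bd$elem, face_key(bd$faces))
  own <- lut[face_key(mesh$surface_faces)]
  if (anyNA(own)) stop("stored surface faces are not boundary faces of the mesh")
  unname(own)
}

#' Scale a substrate's velocities
#'
#' Multiplies every longitudinal velocity (and the recorded base velocity)
#' by `alpha`. Blocked elements stay blocked and all regional ratios are
#' preserved, which is what makes single-parameter calibration possible.
#'
#' @param substrate a `SubstrateModel`.
#' @param alpha positive scale factor.
#' @return The scaled `SubstrateModel`.
#' @export
scale_substrate <- function(substrate, alpha) {
  if (!is.numeric(alpha) || length(alpha) != 1L || !(alpha > 0))
    stop("alpha must be a positive scalar")
  substrate$cv_long <- substrate$cv_long * alpha
  substrate$base_cv <- substrate$base_cv * alpha
  substrate
}
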