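#' Rule-based myofiber orientation
#'
#' Assigns a unit fiber direction to every element from the two anatomical
#' coordinates: the local circumferential direction (long-axis gradient
#' crossed with the transmural gradient) is rotated about the transmural
#' axis by a helix angle interpolated linearly in transmural depth, from
#' `endo_helix_deg` at the endocardium to `epi_helix_deg` at the epicardium.
#' This is the standard rule-based surrogate for DT-MRI fiber measurements;
#' the +60/-60 degree defaults are the conventional values for this family
#' of rules.
#'
#' Degenerate elements (apex region, where the circumferential direction is
#' undefined because the two gradients align) fall back to projecting a
#' fixed reference vector onto the plane normal to the transmural axis.
#'
#' @param mesh an `ActivationMesh` with `transmural` and `apex_base` fields.
#' @param endo_helix_deg helix angle at the endocardium (degrees, default +60).
#' @param epi_helix_deg helix angle at the epicardium (degrees, default -60).
#' @return A `FiberField`: list with `fiber_dir` (m x 3, unit rows).
#' @export
assign_fibers <- function(mesh, endo_helix_deg = 60, epi_helix_deg = -60) {
  if (is.null(mesh$transmural) || is.null(mesh$apex_base))
    stop("mesh lacks transmural/apex_base coordinate fields")
  if (ncol(mesh$elems) != 4L)
    stop("fiber assignment requires a tetrahedral mesh")
  gt <- element_gradients(mesh, mesh$transmural)
  gl <- element_gradients(mesh, mesh$apex_base)

  et <- normalize_rows(gt, fallback = c(0, 0, 1))
  # circumferential = long-axis x transmural
  ec <- row_cross(gl, et)
  nc <- sqrt(rowSums(ec^2))
  deg <- nc < 1e-8
  if (any(deg)) {
    # project reference vectors onto the plane normal to et
    for (ref in list(c(0, 1, 0), c(1, 0, 0))) {
      idx <- which(deg)
      if (!length(idx)) break
      r <- matrix(ref, length(idx), 3, byrow = TRUE)
      proj <- r - et[idx, , drop = FALSE] *
        rowSums(r * et[idx, , drop = FALSE])
      ok <- sqrt(rowSums(proj^2)) > 1e-8
      ec[idx[ok], ] <- proj[ok, , drop = FALSE]
      deg[idx[ok]] <- FALSE
    }
  }
  ec <- normalize_rows(ec, fallback = c(0, 1, 0))

  tbar <- rowMeans(matrix(mesh$transmural[mesh$elems], ncol = ncol(mesh$elems)))
  alpha <- (endo_helix_deg + (epi_helix_deg - endo_helix_deg) * tbar) * pi / 180
  # Rodrigues rotation of ec about et (orthogonal axes)
  f <- ec * cos(alpha) + row_cross(et, ec) * sin(alpha)
  fiber_field(normalize_rows(f, fallback = c(0, 1, 0)))
}

#' Constant (isotropic-use) fiber field
#'
#' A fixed unit vector on every element. Intended for use with anisotropy
#' ratio 1.0, where the conduction tensor is isotropic and the fiber axis is
#' immaterial; useful for solver verification.
#'
#' @param mesh an `ActivationMesh`.
#' @param direction length-3 vector (default +x); normalized internally.
#' @return A `FiberField`.
#' @export
isotropic_fibers <- function(mesh, direction = c(1, 0, 0)) {
  d <- direction / sqrt(sum(direction^2))
  fiber_field(matrix(d, n_elems(mesh), 3, byrow = TRUE))
}

fiber_field <- function(dirs) {
  dirs <- as.matrix(dirs)
  if (ncol(dirs) != 3L) stop("fiber_dir must be m x 3")
  nrm <- sqrt(rowSums(dirs^2))
  if (any(abs(nrm - 1) > 1e-9))
    stop("fiber directions must be unit vectors")
  structure(list(fiber_dir = dirs), class = "FiberField")
}

#' @export
print.FiberField <- function(x, ...) {
  cat(sprintf("FiberField: %d unit directions\n", nrow(x$fiber_dir)))
  invisible(x)
}

# Per-element gradient of a nodal scalar on linear tets, vectorized via the
# cross-product inverse of the edge matrix.
element_gradients <- function(mesh, values) {
  el <- mesh$elems
  p1 <- mesh$nodes[el[, 1], , drop = FALSE]
  a <- mesh$nodes[el[, 2], , drop = FALSE] - p1
  b <- mesh$nodes[el[, 3], , drop = FALSE] - p1
  c3 <- mesh$nodes[el[, 4], , drop = FALSE] - p1
  bc <- row_cross(b, c3); ca <- row_cross(c3, a); ab <- row_cross(a, b)
  det <- rowSums(a * bc)
  det[abs(det) < 1e-300] <- NA_real_
  dv1 <- values[el[, 2]] - values[el[, 1]]
  dv2 <- values[el[, 3]] - values[el[, 1]]
  dv3 <- values[el[, 4]] - values[el[, 1]]
  g <- (bc * dv1 + ca * dv2 + ab * dv3) / det
  g[!is.finite(g)] <- 0
  g
}

row_cross <- function(a, b) {
  cbind(a[, 2] * b[, 3] - a[, 3] * b[, 2],
        a[, 3] * b[, 1] - a[, 1] * b[, 3],
        a[, 1] * b[, 2] - a[, 2] * b[, 1])
}

normalize_rows <- function(m, fallback) {
  nrm <- sqrt(rowSums(m^2))
  bad <- nrm < 1e-12
  nrm[bad] <- 1
  out <- m / nrm
  if (any(bad)) out[bad, ] <- matrix(fallback, sum(bad), 3, byrow = TRUE)
  out
}
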