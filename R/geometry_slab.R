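#' Generate a regular tetrahedralized slab
#'
#' A box of myocardium on a regular lattice, split into six tetrahedra per
#' cube (Kuhn triangulation, conforming across cubes). The `z = 0` face is
#' labeled `LV_ENDO`, the `z = thickness` face `EPI`, the four side faces
#' `BASE`. The transmural coordinate is linear across the thickness (z), the
#' apex-to-base coordinate linear along the length (x). All elements start
#' labeled `LV_FREE_WALL_ANT`; use [relabel_elements()] or
#' [add_scar_region()] to carve out other regions.
#'
#' @param length_mm,width_mm,thickness_mm box dimensions (mm), > 0.
#' @param spacing_mm lattice spacing (mm); must divide each dimension.
#' @return An [activation_mesh()].
#' @export
generate_slab_mesh <- function(length_mm, width_mm, thickness_mm, spacing_mm) {
  dims <- c(length_mm, width_mm, thickness_mm)
  if (any(!is.finite(dims)) || any(dims <= 0) || spacing_mm <= 0)
    stop("slab dimensions and spacing must be positive")
  steps <- dims / spacing_mm
  if (any(abs(steps - round(steps)) > 1e-9))
    stop("spacing_mm must divide every slab dimension")
  nx <- as.integer(round(steps[1])) + 1L
  ny <- as.integer(round(steps[2])) + 1L
  nz <- as.integer(round(steps[3])) + 1L

  g <- expand.grid(i = 0:(nx - 1L), j = 0:(ny - 1L), k = 0:(nz - 1L))
  nodes <- cbind(g$i, g$j, g$k) * spacing_mm
  nid <- function(i, j, k) 1L + i + nx * (j + ny * k)  # matches expand.grid order

  elems <- kuhn_tets(nx, ny, nz, nid)
  bd <- derive_boundary_faces(elems)
  fc <- (nodes[bd$faces[, 1], ] + nodes[bd$faces[, 2], ] +
           nodes[bd$faces[, 3], ]) / 3
  lab <- rep("BASE", nrow(bd$faces))
  lab[abs(fc[, 3]) < 1e-9] <- "LV_ENDO"
  lab[abs(fc[, 3] - thickness_mm) < 1e-9] <- "EPI"

  activation_mesh(
    nodes = nodes, elems = elems,
    region = rep("LV_FREE_WALL_ANT", nrow(elems)),
    surface_faces = bd$faces, surface_labels = lab,
    apex_base = nodes[, 1] / length_mm,
    transmural = nodes[, 3] / thickness_mm)
}

# Kuhn (6-tet) triangulation of an (nx-1) x (ny-1) x (nz-1) cube lattice.
# Each tet follows a monotone vertex path 000 -> 111 given by an axis
# permutation; shared cube faces triangulate identically.
kuhn_tets <- function(nx, ny, nz, nid) {
  perms <- rbind(c(1, 2, 3), c(1, 3, 2), c(2, 1, 3),
                 c(2, 3, 1), c(3, 1, 2), c(3, 2, 1))
  ci <- expand.grid(i = 0:(nx - 2L), j = 0:(ny - 2L), k = 0:(nz - 2L))
  if (nrow(ci) == 0L) stop("slab must contain at least one lattice cube")
  out <- vector("list", 6L)
  for (p in 1:6) {
    off <- matrix(0L, 4L, 3L)
    for (s in 1:3) {
      off[s + 1L, ] <- off[s, ]
      off[s + 1L, perms[p, s]] <- 1L
    }
    out[[p]] <- cbind(
      nid(ci$i + off[1, 1], ci$j + off[1, 2], ci$k + off[1, 3]),
      nid(ci$i + off[2, 1], ci$j + off[2, 2], ci$k + off[2, 3]),
      nid(ci$i + off[3, 1], ci$j + off[3, 2], ci$k + off[3, 3]),
      nid(ci$i + off[4, 1], ci$j + off[4, 2], ci$k + off[4, 3]))
  }
  do.call(rbind, out)
}

#' Relabel a subset of elements
#'
#' @param mesh an `ActivationMesh`.
#' @param which integer or logical vector selecting elements.
#' @param label a single region label from `names(REGION_CODES)`.
#' @return The mesh with updated region labels.
#' @export
relabel_elements <- function(mesh, which, label) {
  if (!label %in% names(REGION_CODES))
    stop("unknown region label: ", label)
  mesh$region[which] <- label
  mesh
}
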