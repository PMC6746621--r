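#' @useDynLib cardioeik, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @importFrom stats aov sd rnorm runif TukeyHSD
#' @importFrom utils read.table write.table
NULL

#' Anatomical label vocabularies
#'
#' Region labels tag elements; surface labels tag boundary faces. The integer
#' codes are the on-disk representation in VTK cell-data arrays.
#'
#' @format Named integer vectors.
#' @name label_codes
#' @export
REGION_CODES <- c(
  LV_FREE_WALL_ANT  = 1L,
  LV_FREE_WALL_POST = 2L,
  SEPTUM            = 3L,
  RV_FREE_WALL      = 4L,
  SCAR              = 5L
)

#' @rdname label_codes
#' @export
SURFACE_CODES <- c(
  LV_ENDO = 1L,
  RV_ENDO = 2L,
  EPI     = 3L,
  BASE    = 4L
)

#' Construct an activation mesh
#'
#' The container every other component operates on: node coordinates (mm),
#' tetrahedral (or triangular) connectivity, per-element anatomical region
#' labels, per-boundary-face surface labels and the two normalized anatomical
#' coordinates (apex-to-base and endocardium-to-epicardium, both in
#' \eqn{[0,1]}). Node and element indices are 1-based throughout.
#'
#' @param nodes numeric matrix, n x 3, coordinates in mm.
#' @param elems integer matrix, m x 4 (tetrahedra) or m x 3 (triangles),
#'   1-based node indices.
#' @param region character vector of length m; values from
#'   `names(REGION_CODES)`.
#' @param surface_faces integer matrix, f x 3, the boundary faces (1-based).
#' @param surface_labels character vector of length f; values from
#'   `names(SURFACE_CODES)`.
#' @param apex_base,transmural numeric vectors of length n in `[0, 1]`
#'   (0 = apex / endocardium, 1 = base / epicardium).
#' @return An object of class `ActivationMesh`.
#' @export
activation_mesh <- function(nodes, elems, region, surface_faces,
                            surface_labels, apex_base, transmural) {
  nodes <- as.matrix(nodes)
  storage.mode(nodes) <- "double"
  elems <- as.matrix(elems)
  storage.mode(elems) <- "integer"
  dimnames(nodes) <- dimnames(elems) <- NULL
  if (ncol(nodes) != 3L) stop("nodes must be an n x 3 matrix")
  if (!ncol(elems) %in% c(3L, 4L))
    stop("elements must be triangles (3 cols) or tetrahedra (4 cols)")
  n <- nrow(nodes)
  if (any(elems < 1L) || any(elems > n))
    stop("element connectivity references invalid node indices")
  if (length(region) != nrow(elems))
    stop("region labels must have one entry per element")
  bad <- setdiff(unique(region), names(REGION_CODES))
  if (length(bad))
    stop("unknown region label(s): ", paste(bad, collapse = ", "))
  surface_faces <- as.matrix(surface_faces)
  storage.mode(surface_faces) <- "integer"
  dimnames(surface_faces) <- NULL
  if (nrow(surface_faces) > 0L && ncol(surface_faces) != 3L)
    stop("surface_faces must be an f x 3 matrix")
  if (length(surface_labels) != nrow(surface_faces))
    stop("surface_labels must have one entry per boundary face")
  bad <- setdiff(unique(surface_labels), names(SURFACE_CODES))
  if (length(bad))
    stop("unknown surface label(s): ", paste(bad, collapse = ", "))
  for (fld in list(apex_base = apex_base, transmural = transmural)) {
    if (length(fld) != n) stop("coordinate fields must have one value per node")
    if (anyNA(fld) || any(fld < -1e-9 | fld > 1 + 1e-9))
      stop("apex_base and transmural coordinates must lie in [0, 1]")
  }
  structure(
    list(nodes = nodes, elems = elems,
         region = as.character(region),
         surface_faces = surface_faces,
         surface_labels = as.character(surface_labels),
         apex_base = pmin(pmax(as.numeric(apex_base), 0), 1),
         transmural = pmin(pmax(as.numeric(transmural), 0), 1)),
    class = "ActivationMesh")
}

#' @export
print.ActivationMesh <- function(x, ...) {
  kind <- if (ncol(x$elems) == 4L) "tetrahedral" else "triangular"
  cat(sprintf("ActivationMesh: %d nodes, %d %s elements, %d boundary faces\n",
              nrow(x$nodes), nrow(x$elems), kind, nrow(x$surface_faces)))
  cat("  regions: ",
      paste(sprintf("%s (%d)", names(table(x$region)), table(x$region)),
            collapse = ", "), "\n", sep = "")
  cat("  surfaces: ",
      paste(sprintf("%s (%d)", names(table(x$surface_labels)),
                    table(x$surface_labels)), collapse = ", "), "\n", sep = "")
  invisible(x)
}

#' Number of nodes / elements
#' @param mesh an `ActivationMesh`.
#' @return integer count.
#' @export
n_nodes <- function(mesh) nrow(mesh$nodes)

#' @rdname n_nodes
#' @export
n_elems <- function(mesh) nrow(mesh$elems)

#' Element centroids
#' @param mesh an `ActivationMesh`.
#' @return m x 3 numeric matrix of centroids (mm).
#' @export
element_centroids <- function(mesh) {
  el <- mesh$elems
  k <- ncol(el)
  out <- matrix(0, nrow(el), 3)
  for (j in seq_len(k)) out <- out + mesh$nodes[el[, j], , drop = FALSE]
  out / k
}

# Order-independent string key per triangle face (vectorized).
face_key <- function(faces) {
  lo <- pmin(faces[, 1], faces[, 2], faces[, 3])
  hi <- pmax(faces[, 1], faces[, 2], faces[, 3])
  mid <- faces[, 1] + faces[, 2] + faces[, 3] - lo - hi
  paste(lo, mid, hi)
}

# All unique undirected element edges, as a 2-column 1-based index matrix.
mesh_edges <- function(mesh) {
  el <- mesh$elems
  if (ncol(el) == 4L) {
    pairs <- rbind(c(1, 2), c(1, 3), c(1, 4), c(2, 3), c(2, 4), c(3, 4))
  } else {
    pairs <- rbind(c(1, 2), c(1, 3), c(2, 3))
  }
  e <- do.call(rbind, lapply(seq_len(nrow(pairs)), function(k)
    cbind(el[, pairs[k, 1]], el[, pairs[k, 2]])))
  lo <- pmin(e[, 1], e[, 2]); hi <- pmax(e[, 1], e[, 2])
  key <- as.numeric(lo) * (max(hi) + 1) + hi
  keep <- !duplicated(key)
  cbind(lo[keep], hi[keep])
}

# Boundary faces of a tet mesh: triangle faces referenced by exactly one tet.
# Returns list(faces = f x 3 matrix with original orientation, elem = owning
# element index).
derive_boundary_faces <- function(elems) {
  if (ncol(elems) != 4L) stop("boundary faces are derived from tetrahedra")
  faceIdx <- rbind(c(1, 2, 3), c(1, 2, 4), c(1, 3, 4), c(2, 3, 4))
  m <- nrow(elems)
  faces <- do.call(rbind, lapply(1:4, function(k) elems[, faceIdx[k, ]]))
  owner <- rep(seq_len(m), 4L)
  key <- face_key(faces)
  keep <- !(key %in% key[duplicated(key)])
  list(faces = faces[keep, , drop = FALSE], elem = owner[keep])
}

#' Mark a spherical scar region
#'
#' Relabels every element whose centroid lies within `radius_mm` of `center`
#' as `SCAR`. A convenience for synthetic geometries; imported meshes may
#' carry scar labels directly.
#'
#' @param mesh an `ActivationMesh`.
#' @param center numeric length-3, sphere centre (mm).
#' @param radius_mm sphere radius (mm), > 0.
#' @return The mesh with updated region labels.
#' @export
add_scar_region <- function(mesh, center, radius_mm) {
  stopifnot(length(center) == 3L, radius_mm > 0)
  ctr <- element_centroids(mesh)
  d2 <- (ctr[, 1] - center[1])^2 + (ctr[, 2] - center[2])^2 +
        (ctr[, 3] - center[3])^2
  hit <- d2 <= radius_mm^2
  if (!any(hit)) warning("no elements within the scar sphere; labels unchanged")
  mesh$region[hit] <- "SCAR"
  mesh
}

#' Locate the mesh node nearest a coordinate
#'
#' Used to turn a physical pacing-lead position into a stimulus node.
#'
#' @param mesh an `ActivationMesh`.
#' @param coord numeric length-3 position (mm).
#' @return 1-based node index.
#' @export
nearest_node <- function(mesh, coord) {
  stopifnot(length(coord) == 3L)
  d2 <- (mesh$nodes[, 1] - coord[1])^2 + (mesh$nodes[, 2] - coord[2])^2 +
        (mesh$nodes[, 3] - coord[3])^2
  which.min(d2)
}

#' Find the RV apex node
#'
#' The RV-endocardial node with the smallest apex-to-base coordinate: the
#' conventional site of an RV pacing lead.
#'
#' @param mesh an `ActivationMesh` with `RV_ENDO` surface labels.
#' @return 1-based node index.
#' @export
rv_apex_node <- function(mesh) {
  idx <- unique(as.vector(mesh$surface_faces[mesh$surface_labels == "RV_ENDO", ,
                                             drop = FALSE]))
  if (!length(idx)) stop("mesh has no RV_ENDO surface faces")
  idx[which.min(mesh$apex_base[idx])]
}

#' Pacing configuration
#'
#' @param stimulus_nodes integer vector of 1-based node indices (non-empty).
#' @param onset_time stimulus onset in ms (default 0).
#' @return An object of class `PacingConfig`.
#' @export
pacing_config <- function(stimulus_nodes, onset_time = 0) {
  stimulus_nodes <- as.integer(stimulus_nodes)
  if (!length(stimulus_nodes)) stop("stimulus node set must be non-empty")
  if (anyNA(stimulus_nodes) || any(stimulus_nodes < 1L))
    stop("stimulus nodes must be positive indices")
  structure(list(stimulus_nodes = stimulus_nodes,
                 onset_time = as.numeric(onset_time)),
            class = "PacingConfig")
}
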