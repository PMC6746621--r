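#' Generate an idealized biventricular mesh
#'
#' Two truncated-ellipsoid shells sharing a septal wall, voxelized on a
#' regular lattice and split into tetrahedra. The long axis is z (apex at
#' negative z, base plane at `base_z_mm`); the right ventricle is offset
#' along +x, so the septum's outward direction defines the 0 degree
#' circumferential reference. This idealization stands in for segmented
#' patient anatomies: every downstream algorithm operates only on the labels
#' and coordinate fields, never on the ellipsoid parameters.
#'
#' Labeling rules:
#' * boundary faces: `BASE` on the base plane; otherwise the nearest of the
#'   LV cavity, RV cavity and outer surfaces decides `LV_ENDO` / `RV_ENDO` /
#'   `EPI`;
#' * `SEPTUM` elements are those whose centroid is within 1.5 x the combined
#'   wall thickness of *both* cavity surfaces (the wall between the cavities);
#' * the remaining LV wall is split into anterior (`y > 0`) and posterior
#'   (`y < 0`) halves by circumferential angle about the LV long axis, with
#'   the septal bisector at 0 degrees and anterior covering (0, 180) degrees
#'   under a right-handed convention;
#' * the rest of the RV shell is `RV_FREE_WALL`.
#'
#' The apex-to-base coordinate is the normalized long-axis position; the
#' transmural coordinate solves a discrete Laplace problem with endocardium
#' = 0 and epicardium = 1 (natural condition on the base), so it obeys the
#' discrete maximum principle.
#'
#' @param lv_radii_mm LV cavity semi-axes (x, y, z) in mm (default 20, 20, 40).
#' @param rv_radii_mm RV cavity semi-axes in mm (default 15, 22, 32).
#' @param wall_thickness_mm LV wall thickness in mm (default 10); the RV free
#'   wall uses half this value.
#' @param spacing_mm lattice spacing in mm (default 2).
#' @param base_z_mm base-plane height (mm, default 10); must be a multiple of
#'   `spacing_mm` and cut through both cavities.
#' @return An [activation_mesh()].
#' @export
generate_biventricular_mesh <- function(lv_radii_mm = c(20, 20, 40),
                                        rv_radii_mm = c(15, 22, 32),
                                        wall_thickness_mm = 10,
                                        spacing_mm = 2,
                                        base_z_mm = 10) {
  if (length(lv_radii_mm) != 3L || length(rv_radii_mm) != 3L)
    stop("cavity radii must be length-3 (x, y, z semi-axes)")
  if (wall_thickness_mm <= 0 || spacing_mm <= 0)
    stop("wall thickness and spacing must be positive")
  if (any(lv_radii_mm <= wall_thickness_mm) || any(rv_radii_mm <= wall_thickness_mm / 2))
    stop("geometrically impossible parameters: radii must exceed the wall thickness")
  if (abs(base_z_mm / spacing_mm - round(base_z_mm / spacing_mm)) > 1e-9)
    stop("base_z_mm must be a multiple of spacing_mm")
  if (base_z_mm >= min(lv_radii_mm[3], rv_radii_mm[3]))
    stop("geometrically impossible parameters: base plane must cut both cavities")

  rv_wall <- wall_thickness_mm / 2
  lv_c <- c(0, 0, 0)
  lv_out <- lv_radii_mm + wall_thickness_mm
  # RV cavity abuts the LV outer surface so the septal wall is one LV wall thick
  rv_c <- c(lv_radii_mm[1] + wall_thickness_mm + rv_radii_mm[1], 0,
            lv_radii_mm[3] - rv_radii_mm[3] - rv_wall + base_z_mm / 2)
  rv_out <- rv_radii_mm + rv_wall

  ell_val <- function(p, c0, r) {
    sqrt(((p[, 1] - c0[1]) / r[1])^2 + ((p[, 2] - c0[2]) / r[2])^2 +
         ((p[, 3] - c0[3]) / r[3])^2)
  }
  # first-order distance to the ellipsoid surface: (f - 1) / |grad f|
  ell_dist <- function(p, c0, r) {
    f <- ell_val(p, c0, r)
    g <- sqrt(((p[, 1] - c0[1]) / r[1]^2)^2 + ((p[, 2] - c0[2]) / r[2]^2)^2 +
              ((p[, 3] - c0[3]) / r[3]^2)^2) / pmax(f, 1e-12)
    (f - 1) / pmax(g, 1e-12)
  }
  in_solid <- function(p) {
    in_lv_out <- ell_val(p, lv_c, lv_out) <= 1
    in_rv_out <- ell_val(p, rv_c, rv_out) <= 1
    in_lv_cav <- ell_val(p, lv_c, lv_radii_mm) < 1
    in_rv_cav <- ell_val(p, rv_c, rv_radii_mm) < 1
    (in_lv_out | in_rv_out) & !in_lv_cav & !in_rv_cav & p[, 3] <= base_z_mm
  }

  h <- spacing_mm
  ix <- seq(floor((lv_c[1] - lv_out[1]) / h), ceiling((rv_c[1] + rv_out[1]) / h))
  iy <- seq(floor(min(lv_c[2] - lv_out[2], rv_c[2] - rv_out[2]) / h),
            ceiling(max(lv_c[2] + lv_out[2], rv_c[2] + rv_out[2]) / h))
  iz <- seq(floor(min(lv_c[3] - lv_out[3], rv_c[3] - rv_out[3]) / h),
            base_z_mm / h)
  nx <- length(ix); ny <- length(iy); nz <- length(iz)
  g <- expand.grid(i = seq_len(nx) - 1L, j = seq_len(ny) - 1L, k = seq_len(nz) - 1L)
  nodes_all <- cbind((g$i + ix[1]) * h, (g$j + iy[1]) * h, (g$k + iz[1]) * h)
  nid <- function(i, j, k) 1L + i + nx * (j + ny * k)

  elems_all <- kuhn_tets(nx, ny, nz, nid)
  # keep tets whose cube-center (= tet centroid's cube) is inside the solid;
  # use the tet centroid itself, which is robust to the Kuhn split
  ctr <- (nodes_all[elems_all[, 1], ] + nodes_all[elems_all[, 2], ] +
          nodes_all[elems_all[, 3], ] + nodes_all[elems_all[, 4], ]) / 4
  keep <- in_solid(ctr)
  elems <- elems_all[keep, , drop = FALSE]
  if (nrow(elems) == 0L) stop("geometrically impossible parameters: empty solid")

  # largest connected component over element-shared nodes
  ed <- unique(rbind(elems[, c(1, 2)], elems[, c(1, 3)], elems[, c(1, 4)],
                     elems[, c(2, 3)], elems[, c(2, 4)], elems[, c(3, 4)]))
  gr <- igraph::graph_from_edgelist(ed, directed = FALSE)
  cmp <- igraph::components(gr)
  main <- which.max(cmp$csize)
  node_ok <- rep(FALSE, nrow(nodes_all))
  node_ok[seq_along(cmp$membership)] <- cmp$membership == main
  elems <- elems[rowSums(matrix(node_ok[elems], ncol = 4)) == 4L, , drop = FALSE]

  used <- sort(unique(as.vector(elems)))
  remap <- integer(nrow(nodes_all)); remap[used] <- seq_along(used)
  nodes <- nodes_all[used, , drop = FALSE]
  elems <- matrix(remap[elems], ncol = 4L)

  ctr <- (nodes[elems[, 1], ] + nodes[elems[, 2], ] +
          nodes[elems[, 3], ] + nodes[elems[, 4], ]) / 4
  d_lvc <- abs(ell_dist(ctr, lv_c, lv_radii_mm))
  d_rvc <- abs(ell_dist(ctr, rv_c, rv_radii_mm))
  sep_tol <- 1.5 * (wall_thickness_mm + rv_wall)
  region <- rep("RV_FREE_WALL", nrow(elems))
  in_lv_shell <- ell_val(ctr, lv_c, lv_out) <= 1
  ang <- atan2(ctr[, 2] - lv_c[2], ctr[, 1] - lv_c[1])
  region[in_lv_shell & ang > 0] <- "LV_FREE_WALL_ANT"
  region[in_lv_shell & ang <= 0] <- "LV_FREE_WALL_POST"
  region[d_lvc <= sep_tol & d_rvc <= sep_tol] <- "SEPTUM"

  bd <- derive_boundary_faces(elems)
  fc <- (nodes[bd$faces[, 1], ] + nodes[bd$faces[, 2], ] +
         nodes[bd$faces[, 3], ]) / 3
  f_lvc <- abs(ell_dist(fc, lv_c, lv_radii_mm))
  f_rvc <- abs(ell_dist(fc, rv_c, rv_radii_mm))
  f_out <- pmin(abs(ell_dist(fc, lv_c, lv_out)), abs(ell_dist(fc, rv_c, rv_out)))
  lab <- c("LV_ENDO", "RV_ENDO", "EPI")[max.col(-cbind(f_lvc, f_rvc, f_out))]
  lab[abs(fc[, 3] - base_z_mm) < 1e-9] <- "BASE"

  zmin <- min(nodes[, 3])
  apex_base <- (nodes[, 3] - zmin) / (base_z_mm - zmin)

  endo_nodes <- unique(as.vector(bd$faces[lab %in% c("LV_ENDO", "RV_ENDO"), ]))
  epi_nodes <- unique(as.vector(bd$faces[lab == "EPI", ]))
  transmural <- laplace_coordinate(nodes, elems, endo_nodes, epi_nodes)

  activation_mesh(nodes = nodes, elems = elems, region = region,
                  surface_faces = bd$faces, surface_labels = lab,
                  apex_base = apex_base, transmural = transmural)
}

#' Harmonic coordinate between two node sets
#'
#' Solves the discrete Laplace equation on the mesh edge graph with
#' Dirichlet values 0 on `zero_nodes` and 1 on `one_nodes` (edge weights =
#' 1/length; natural condition elsewhere). With positive weights the
#' solution satisfies the discrete maximum principle, so it lies in
#' \eqn{[0,1]} with no interior extrema.
#'
#' @param nodes n x 3 coordinate matrix.
#' @param elems element connectivity matrix (1-based).
#' @param zero_nodes,one_nodes node index vectors for the two boundaries.
#' @return numeric vector of length n in `[0, 1]`.
#' @export
laplace_coordinate <- function(nodes, elems, zero_nodes, one_nodes) {
  n <- nrow(nodes)
  mesh_like <- list(elems = elems)
  ed <- mesh_edges(mesh_like)
  len <- sqrt(rowSums((nodes[ed[, 1], , drop = FALSE] -
                       nodes[ed[, 2], , drop = FALSE])^2))
  w <- 1 / pmax(len, 1e-12)
  W <- Matrix::sparseMatrix(i = c(ed[, 1], ed[, 2]), j = c(ed[, 2], ed[, 1]),
                            x = c(w, w), dims = c(n, n))
  d <- Matrix::rowSums(W)
  L <- Matrix::Diagonal(n, d) - W
  fixed <- rep(NA_real_, n)
  fixed[zero_nodes] <- 0
  fixed[one_nodes] <- 1
  free <- which(is.na(fixed))
  if (!length(free)) return(fixed)
  rhs <- -L[free, -free, drop = FALSE] %*% fixed[-free]
  sol <- Matrix::solve(L[free, free, drop = FALSE], rhs)
  fixed[free] <- as.numeric(sol)
  pmin(pmax(fixed, 0), 1)
}
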