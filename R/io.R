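#' Write an activation mesh to disk
#'
#' Two plain-text dialects:
#' * **VTK legacy ASCII** (`.vtk`): one unstructured grid holding the
#'   tetrahedra plus the boundary faces as triangle cells. Cell-data arrays
#'   `region` (codes in [REGION_CODES]; 0 on the face cells) and `surface`
#'   (codes in [SURFACE_CODES]; 0 on the tets), point-data arrays
#'   `apex_base` and `transmural`, optional cell vectors `fiber`, cell
#'   scalars `cv_long_m_per_s` and point scalars `activation_ms`.
#'   Connectivity on disk is 0-based as the format requires.
#' * **CARP-style text** (`format = "carp"`): `<base>.pts`, `<base>.elem`
#'   (`Tt` rows with region code), `<base>.surf` (`Tr` rows with surface
#'   code), `<base>.apex_base.dat`, `<base>.transmural.dat`, and optionally
#'   `<base>.lon`.
#'
#' @param mesh an `ActivationMesh`.
#' @param path output file (`.vtk`) or basename (carp).
#' @param format `"vtk"` (default, or inferred from a `.vtk` extension) or
#'   `"carp"`.
#' @param fibers optional `FiberField` to embed.
#' @param substrate optional `SubstrateModel`; writes `cv_long_m_per_s`.
#' @param map optional `ActivationMap`; writes `activation_ms`.
#' @return `path`, invisibly.
#' @export
write_mesh <- function(mesh, path, format = NULL, fibers = NULL,
                       substrate = NULL, map = NULL) {
  if (is.null(format))
    format <- if (grepl("\\.vtk$", path)) "vtk" else "carp"
  if (format == "vtk") {
    write_mesh_vtk(mesh, path, fibers, substrate, map)
  } else if (format == "carp") {
    write_mesh_carp(mesh, path, fibers)
  } else stop("unknown mesh format: ", format)
  invisible(path)
}

#' Read an activation mesh
#'
#' Accepts the two dialects written by [write_mesh()]. A round trip
#' preserves coordinates (to float precision), connectivity and every label
#' array exactly. Missing label arrays raise an error naming the missing
#' array; cell types other than tetrahedra and triangles are rejected.
#'
#' @param path a `.vtk` file or a carp basename (with `<base>.pts` present).
#' @return An `ActivationMesh`.
#' @export
read_mesh <- function(path) {
  if (grepl("\\.vtk$", path)) return(read_mesh_vtk(path))
  if (file.exists(paste0(path, ".pts"))) return(read_mesh_carp(path))
  stop("unknown mesh format (expected a .vtk file or a .pts/.elem basename): ",
       path)
}

code_of <- function(labels, codes) unname(codes[labels])
label_of <- function(x, codes) names(codes)[match(x, codes)]

write_mesh_vtk <- function(mesh, path, fibers = NULL, substrate = NULL,
                           map = NULL) {
  con <- file(path, "w")
  on.exit(close(con))
  n <- n_nodes(mesh); m <- n_elems(mesh); f <- nrow(mesh$surface_faces)
  wl <- function(...) writeLines(..., con = con)
  wl(c("# vtk DataFile Version 3.0", "cardioeik activation mesh", "ASCII",
       "DATASET UNSTRUCTURED_GRID"))
  wl(sprintf("POINTS %d float", n))
  wl(apply(format(mesh$nodes, digits = 9, trim = TRUE, scientific = FALSE),
           1L, paste, collapse = " "))
  is_tet <- ncol(mesh$elems) == 4L
  k <- ncol(mesh$elems)
  wl(sprintf("CELLS %d %d", m + f, m * (k + 1L) + f * 4L))
  wl(paste(k, apply(mesh$elems - 1L, 1L, paste, collapse = " ")))
  if (f > 0L)
    wl(paste(3L, apply(mesh$surface_faces - 1L, 1L, paste, collapse = " ")))
  wl(sprintf("CELL_TYPES %d", m + f))
  wl(as.character(c(rep(if (is_tet) 10L else 5L, m), rep(5L, f))))
  wl(sprintf("CELL_DATA %d", m + f))
  wl(c("SCALARS region int 1", "LOOKUP_TABLE default"))
  wl(as.character(c(code_of(mesh$region, REGION_CODES), rep(0L, f))))
  wl(c("SCALARS surface int 1", "LOOKUP_TABLE default"))
  wl(as.character(c(rep(0L, m), code_of(mesh$surface_labels, SURFACE_CODES))))
  if (!is.null(substrate)) {
    wl(c("SCALARS cv_long_m_per_s float 1", "LOOKUP_TABLE default"))
    wl(format(c(substrate$cv_long, rep(0, f)), digits = 9, trim = TRUE))
  }
  if (!is.null(fibers)) {
    wl("VECTORS fiber float")
    wl(apply(format(rbind(fibers$fiber_dir, matrix(0, f, 3)), digits = 9,
                    trim = TRUE, scientific = FALSE), 1L, paste, collapse = " "))
  }
  wl(sprintf("POINT_DATA %d", n))
  wl(c("SCALARS apex_base float 1", "LOOKUP_TABLE default"))
  wl(format(mesh$apex_base, digits = 9, trim = TRUE))
  wl(c("SCALARS transmural float 1", "LOOKUP_TABLE default"))
  wl(format(mesh$transmural, digits = 9, trim = TRUE))
  if (!is.null(map)) {
    wl(c("SCALARS activation_ms float 1", "LOOKUP_TABLE default"))
    wl(format(map$times, digits = 9, trim = TRUE))
  }
}

read_mesh_vtk <- function(path) {
  tok <- scan(path, what = "character", quiet = TRUE, comment.char = "",
              skip = 4L)
  pos <- 1L
  take <- function(k) { v <- tok[pos:(pos + k - 1L)]; pos <<- pos + k; v }
  expect <- function(word) {
    if (!identical(toupper(tok[pos]), word)) stop("malformed VTK file near '",
                                                  tok[pos], "' (expected ", word, ")")
    pos <<- pos + 1L
  }
  expect("POINTS")
  n <- as.integer(take(1L)); take(1L)  # dtype
  nodes <- matrix(as.numeric(take(3L * n)), ncol = 3L, byrow = TRUE)
  expect("CELLS")
  ncell <- as.integer(take(1L)); tot <- as.integer(take(1L))
  raw <- as.integer(take(tot))
  cells <- vector("list", ncell)
  p <- 1L
  for (i in seq_len(ncell)) {
    k <- raw[p]
    cells[[i]] <- raw[(p + 1L):(p + k)] + 1L
    p <- p + k + 1L
  }
  expect("CELL_TYPES")
  if (as.integer(take(1L)) != ncell) stop("malformed VTK file: cell count mismatch")
  ctype <- as.integer(take(ncell))
  if (!all(ctype %in% c(5L, 10L)))
    stop("unsupported cell types in VTK file (only tri/tet supported)")

  arrays_cell <- list(); arrays_point <- list(); vectors_cell <- list()
  mode <- NULL
  while (pos <= length(tok)) {
    w <- toupper(tok[pos])
    if (w == "CELL_DATA") { mode <- "cell"; pos <- pos + 2L }
    else if (w == "POINT_DATA") { mode <- "point"; pos <- pos + 2L }
    else if (w == "SCALARS") {
      nm <- tok[pos + 1L]; pos <- pos + 4L  # SCALARS name type 1
      if (toupper(tok[pos]) == "LOOKUP_TABLE") pos <- pos + 2L
      cnt <- if (mode == "cell") ncell else n
      vals <- as.numeric(take(cnt))
      if (mode == "cell") arrays_cell[[nm]] <- vals else arrays_point[[nm]] <- vals
    } else if (w == "VECTORS") {
      nm <- tok[pos + 1L]; pos <- pos + 3L
      cnt <- if (mode == "cell") ncell else n
      vectors_cell[[nm]] <- matrix(as.numeric(take(3L * cnt)), ncol = 3L,
                                   byrow = TRUE)
    } else stop("malformed VTK file near '", tok[pos], "'")
  }

  tets <- ctype == 10L
  if (any(tets)) {
    elems <- do.call(rbind, cells[tets])
    face_cells <- which(!tets)
  } else {
    elems <- do.call(rbind, cells)
    face_cells <- seq_len(ncell)
  }
  if (is.null(arrays_cell$surface))
    stop("mesh file is missing the 'surface_labels' array ('surface')")
  if (is.null(arrays_cell$region))
    stop("mesh file is missing the 'region_labels' array ('region')")
  if (is.null(arrays_point$apex_base))
    stop("mesh file is missing the 'apex_base' point array")
  if (is.null(arrays_point$transmural))
    stop("mesh file is missing the 'transmural' point array")
  surface_faces <- if (any(tets)) do.call(rbind, cells[face_cells])
                   else elems
  surf_codes <- arrays_cell$surface[face_cells]
  elem_cells <- if (any(tets)) which(tets) else seq_len(ncell)
  mesh <- activation_mesh(
    nodes = nodes, elems = elems,
    region = label_of(arrays_cell$region[elem_cells], REGION_CODES),
    surface_faces = surface_faces,
    surface_labels = label_of(surf_codes, SURFACE_CODES),
    apex_base = arrays_point$apex_base,
    transmural = arrays_point$transmural)
  if (!is.null(vectors_cell$fiber))
    attr(mesh, "fiber") <- vectors_cell$fiber[elem_cells, , drop = FALSE]
  if (!is.null(arrays_cell$cv_long_m_per_s))
    attr(mesh, "cv_long") <- arrays_cell$cv_long_m_per_s[elem_cells]
  if (!is.null(arrays_point$activation_ms))
    attr(mesh, "activation_ms") <- arrays_point$activation_ms
  mesh
}

write_mesh_carp <- function(mesh, base, fibers = NULL) {
  pts <- file(paste0(base, ".pts"), "w")
  writeLines(as.character(n_nodes(mesh)), pts)
  write.table(mesh$nodes, pts, row.names = FALSE, col.names = FALSE)
  close(pts)
  el <- file(paste0(base, ".elem"), "w")
  writeLines(as.character(n_elems(mesh)), el)
  tag <- if (ncol(mesh$elems) == 4L) "Tt" else "Tr"
  write.table(cbind(tag, mesh$elems - 1L, code_of(mesh$region, REGION_CODES)),
              el, row.names = FALSE, col.names = FALSE, quote = FALSE)
  close(el)
  sf <- file(paste0(base, ".surf"), "w")
  writeLines(as.character(nrow(mesh$surface_faces)), sf)
  write.table(cbind("Tr", mesh$surface_faces - 1L,
                    code_of(mesh$surface_labels, SURFACE_CODES)),
              sf, row.names = FALSE, col.names = FALSE, quote = FALSE)
  close(sf)
  writeLines(format(mesh$apex_base, digits = 9, trim = TRUE),
             paste0(base, ".apex_base.dat"))
  writeLines(format(mesh$transmural, digits = 9, trim = TRUE),
             paste0(base, ".transmural.dat"))
  if (!is.null(fibers)) {
    lon <- file(paste0(base, ".lon"), "w")
    writeLines("1", lon)
    write.table(fibers$fiber_dir, lon, row.names = FALSE, col.names = FALSE)
    close(lon)
  }
}

read_mesh_carp <- function(base) {
  nodes <- as.matrix(read.table(paste0(base, ".pts"), skip = 1L))
  ele <- read.table(paste0(base, ".elem"), skip = 1L,
                    colClasses = c("character", rep("integer", 5)))
  if (!all(ele[[1]] == "Tt") && !all(ele[[1]] == "Tr"))
    stop("mixed or unsupported element types (only tri/tet supported)")
  k <- if (ele[[1]][1] == "Tt") 4L else 3L
  elems <- as.matrix(ele[, 2:(1 + k)]) + 1L
  region <- label_of(ele[[2 + k]], REGION_CODES)
  surf_path <- paste0(base, ".surf")
  if (!file.exists(surf_path))
    stop("mesh is missing the 'surface_labels' file (", surf_path, ")")
  sf <- read.table(surf_path, skip = 1L,
                   colClasses = c("character", rep("integer", 4)))
  ab_path <- paste0(base, ".apex_base.dat")
  tm_path <- paste0(base, ".transmural.dat")
  if (!file.exists(ab_path)) stop("mesh is missing the 'apex_base' field file")
  if (!file.exists(tm_path)) stop("mesh is missing the 'transmural' field file")
  activation_mesh(
    nodes = nodes, elems = elems, region = region,
    surface_faces = as.matrix(sf[, 2:4]) + 1L,
    surface_labels = label_of(sf[[5]], SURFACE_CODES),
    apex_base = scan(ab_path, quiet = TRUE),
    transmural = scan(tm_path, quiet = TRUE))
}

#' Read / write EAM recordings as CSV
#'
#' Columns `x_mm, y_mm, z_mm, lat_pct`; the QRS duration travels in a
#' `# qrsd_ms=<value>` comment line above the header.
#'
#' @param path CSV file path.
#' @param eam an `EAMRecording` (for writing).
#' @return [eam_recording()] (reading) or `path` invisibly (writing).
#' @export
read_eam <- function(path) {
  first <- readLines(path, n = 1L)
  m <- regmatches(first, regexec("qrsd_ms\\s*=\\s*([0-9.]+)", first))[[1]]
  if (length(m) < 2L)
    stop("EAM file is missing the '# qrsd_ms=' header line: ", path)
  df <- read.table(path, sep = ",", header = TRUE, comment.char = "#")
  eam_recording(as.matrix(df[, c("x_mm", "y_mm", "z_mm")]), df$lat_pct,
                as.numeric(m[2]))
}

#' @rdname read_eam
#' @export
write_eam <- function(eam, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# qrsd_ms=%.6g", eam$qrsd_ms), con)
  writeLines("x_mm,y_mm,z_mm,lat_pct", con)
  writeLines(apply(cbind(eam$points, eam$lat_pct), 1L, function(r)
    paste(format(r, digits = 9, trim = TRUE, scientific = FALSE),
          collapse = ",")), con)
  invisible(path)
}
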