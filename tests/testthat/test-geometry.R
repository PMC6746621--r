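test_that("slab generation produces the expected lattice", {
  m <- generate_slab_mesh(60, 20, 10, 1)
  expect_equal(n_nodes(m), 61L * 21L * 11L)
  expect_true(all(abs(m$nodes - round(m$nodes)) < 1e-12))
  expect_true(all(m$nodes[, 1] >= 0 & m$nodes[, 1] <= 60))

  m2 <- generate_slab_mesh(10, 10, 10, 5)
  expect_equal(n_nodes(m2), 27L)
  expect_equal(n_elems(m2), 48L)  # 6 tets per cube x 8 cubes
})

test_that("degenerate slab parameters are rejected", {
  expect_error(generate_slab_mesh(60, 20, 0, 1), "positive")
  expect_error(generate_slab_mesh(-5, 20, 10, 1), "positive")
  expect_error(generate_slab_mesh(60, 20, 10, 0.7), "divide")
})

test_that("slab labels and coordinate fields follow the construction rules", {
  m <- slab_small()
  # label partition: every element exactly one region, every boundary face
  # exactly one surface label
  expect_equal(length(m$region), n_elems(m))
  expect_true(all(m$region %in% names(REGION_CODES)))
  expect_equal(length(m$surface_labels), nrow(m$surface_faces))
  bd <- cardioeik:::derive_boundary_faces(m$elems)
  expect_equal(nrow(bd$faces), nrow(m$surface_faces))
  # coordinates linear in x (apex-base) and z (transmural)
  expect_equal(m$apex_base, m$nodes[, 1] / 20)
  expect_equal(m$transmural, m$nodes[, 3] / 10)
  # endo/epi face placement
  fc <- (m$nodes[m$surface_faces[, 1], ] + m$nodes[m$surface_faces[, 2], ] +
         m$nodes[m$surface_faces[, 3], ]) / 3
  expect_true(all(abs(fc[m$surface_labels == "LV_ENDO", 3]) < 1e-9))
  expect_true(all(abs(fc[m$surface_labels == "EPI", 3] - 10) < 1e-9))
})

test_that("mesh generation is deterministic", {
  a <- generate_slab_mesh(20, 10, 10, 2)
  b <- generate_slab_mesh(20, 10, 10, 2)
  expect_identical(a, b)
  expect_identical(generate_biventricular_mesh(spacing_mm = 4, base_z_mm = 8),
                   generate_biventricular_mesh(spacing_mm = 4, base_z_mm = 8))
})

test_that("biventricular mesh satisfies its labeling contracts", {
  m <- biv_mesh()
  expect_setequal(unique(m$surface_labels),
                  c("LV_ENDO", "RV_ENDO", "EPI", "BASE"))
  expect_true(all(c("SEPTUM", "LV_FREE_WALL_ANT", "LV_FREE_WALL_POST",
                    "RV_FREE_WALL") %in% unique(m$region)))
  # LV_ENDO faces hug the inner ellipsoid (voxelized surface, so allow
  # about one lattice cell of slack)
  fc <- (m$nodes[m$surface_faces[, 1], ] + m$nodes[m$surface_faces[, 2], ] +
         m$nodes[m$surface_faces[, 3], ]) / 3
  lv <- m$surface_labels == "LV_ENDO"
  f <- sqrt((fc[lv, 1] / 20)^2 + (fc[lv, 2] / 20)^2 + (fc[lv, 3] / 40)^2)
  # normalized level 1 = on-surface; 2 mm spacing on a 20 mm radius ~ 0.1
  expect_true(all(abs(f - 1) < 0.2))
  # apex-base fraction below one third is strictly interior
  frac <- mean(m$apex_base < 1 / 3)
  expect_gt(frac, 0)
  expect_lt(frac, 1)
  # transmural coordinate: discrete maximum principle (bounded by its
  # boundary values 0 and 1) and correct boundary values
  expect_true(all(m$transmural >= 0 & m$transmural <= 1))
  endo_nodes <- unique(as.vector(
    m$surface_faces[m$surface_labels %in% c("LV_ENDO", "RV_ENDO"), ]))
  epi_nodes <- unique(as.vector(m$surface_faces[m$surface_labels == "EPI", ]))
  expect_true(all(m$transmural[setdiff(endo_nodes, epi_nodes)] < 1e-9))
  expect_true(all(m$transmural[setdiff(epi_nodes, endo_nodes)] > 1 - 1e-9))
})

test_that("septum label matches its defining rule", {
  m <- biv_mesh()
  # septal elements must be close to BOTH cavities; free-wall elements are
  # far from at least one
  ctr <- element_centroids(m)
  rv_c <- c(20 + 10 + 15, 0, 40 - 32 - 5 + 5)
  d_lv <- abs(sqrt((ctr[, 1] / 20)^2 + (ctr[, 2] / 20)^2 + (ctr[, 3] / 40)^2) - 1) * 20
  d_rv <- abs(sqrt(((ctr[, 1] - rv_c[1]) / 15)^2 + ((ctr[, 2] - rv_c[2]) / 22)^2 +
                   ((ctr[, 3] - rv_c[3]) / 32)^2) - 1) * 15
  sep <- m$region == "SEPTUM"
  # all septal centroids lie between the cavities (positive-x half, roughly
  # near both surfaces); crude but independent of the generator's internals
  expect_true(all(ctr[sep, 1] > 0))
  expect_lt(median(d_lv[sep] + d_rv[sep]), median(d_lv[!sep] + d_rv[!sep]))
})

test_that("impossible biventricular parameters are rejected", {
  expect_error(generate_biventricular_mesh(lv_radii_mm = c(5, 5, 5),
                                           wall_thickness_mm = 10),
               "impossible")
  expect_error(generate_biventricular_mesh(base_z_mm = 3, spacing_mm = 2),
               "multiple")
})

test_that("scar labeling marks exactly the elements inside the sphere", {
  m <- slab_small()
  ctr <- element_centroids(m)
  ms <- add_scar_region(m, c(10, 10, 5), 4)
  inside <- sqrt(rowSums(sweep(ctr, 2, c(10, 10, 5))^2)) <= 4
  expect_identical(ms$region == "SCAR", inside)
  expect_warning(add_scar_region(m, c(500, 0, 0), 1), "no elements")
})

test_that("laplace coordinate obeys the discrete maximum principle", {
  m <- slab_small()
  z0 <- which(m$nodes[, 3] == 0)
  z1 <- which(m$nodes[, 3] == 10)
  u <- laplace_coordinate(m$nodes, m$elems, z0, z1)
  # bounded by the Dirichlet data with no interior extrema beyond them
  expect_true(all(u >= 0 & u <= 1))
  expect_true(all(u[z0] == 0))
  expect_true(all(u[z1] == 1))
  interior <- setdiff(seq_len(n_nodes(m)), c(z0, z1))
  expect_true(all(u[interior] > 0 & u[interior] < 1))
  # in the lattice interior (away from the free side boundaries, whose
  # truncated stencils distort the graph-harmonic solution) it is close to
  # the linear transmural profile
  core <- m$nodes[, 1] >= 6 & m$nodes[, 1] <= 14 &
          m$nodes[, 2] >= 6 & m$nodes[, 2] <= 14
  expect_lt(max(abs(u[core] - m$nodes[core, 3] / 10)), 0.05)
})
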