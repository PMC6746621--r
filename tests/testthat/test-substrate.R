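test_that("NORMAL substrate is uniform at the base velocity", {
  m <- slab_small()
  s <- build_substrate(m, "NORMAL", base_cv = 0.5)
  expect_true(all(s$cv_long == 0.5))
})

test_that("FEC layer is exactly the 1 mm endocardial shell with six-fold velocity", {
  m <- slab_fine()  # LV_ENDO is the z = 0 face, 1 mm elements
  s <- build_substrate(m, "FEC", base_cv = 0.4)
  ctr <- element_centroids(m)
  in_layer <- ctr[, 3] < 1 + 1e-9  # independent geometric definition
  expect_identical(s$cv_long[in_layer], rep(6 * 0.4, sum(in_layer)))
  expect_identical(s$cv_long[!in_layer], rep(0.4, sum(!in_layer)))
  # layer-thickness invariant, computed from the slab's planar endo surface
  expect_lte(max(ctr[s$cv_long > 0.4, 3]), 1)
})

test_that("FEC falls back to the first element layer on coarse meshes", {
  m <- generate_slab_mesh(20, 20, 10, 5)  # 5 mm elements, layer 1 mm
  s <- build_substrate(m, "FEC", base_cv = 0.4)
  fast <- s$cv_long > 0.4
  expect_true(any(fast))
  own <- cardioeik:::surface_face_owners(m)
  endo_elems <- own[m$surface_labels == "LV_ENDO"]
  expect_setequal(which(fast), unique(endo_elems))
})

test_that("lower-third FEC is restricted by the apex-base coordinate", {
  m <- slab_fine()
  s <- build_substrate(m, "FEC", base_cv = 0.4, fec_extent = "LOWER_THIRD")
  fast <- s$cv_long > 0.4
  ab <- rowMeans(matrix(m$apex_base[m$elems], ncol = 4))
  expect_true(all(ab[fast] < 1 / 3))
  expect_true(any(fast))
})

test_that("slow septum scales exactly the septal elements by 50%", {
  m <- slab_septal()
  s <- build_substrate(m, "SLOW_SEPTUM", base_cv = 0.6)
  expect_identical(s$cv_long[m$region == "SEPTUM"],
                   rep(0.3, sum(m$region == "SEPTUM")))
  expect_identical(s$cv_long[m$region != "SEPTUM"],
                   rep(0.6, sum(m$region != "SEPTUM")))
})

test_that("scar and block variants zero exactly the labeled region", {
  m <- add_scar_region(slab_small(), c(10, 10, 5), 4)
  s <- build_substrate(m, "SCAR", base_cv = 0.5)
  expect_identical(s$cv_long == 0, m$region == "SCAR")
  b <- biv_mesh()
  sa <- build_substrate(b, "ANTERIOR_BLOCK", base_cv = 0.5)
  expect_identical(sa$cv_long == 0, b$region == "LV_FREE_WALL_ANT")
  sp <- build_substrate(b, "POSTERIOR_BLOCK", base_cv = 0.5)
  expect_identical(sp$cv_long == 0, b$region == "LV_FREE_WALL_POST")
})

test_that("invalid substrate requests are rejected", {
  m <- slab_small()
  expect_error(build_substrate(m, "SCAR"), "SCAR region labels")
  expect_error(build_substrate(m, "WILD"), "unknown substrate variant")
  expect_error(build_substrate(m, "NORMAL", base_cv = 0), "positive")
  expect_error(build_substrate(m, "NORMAL", anisotropy_ratio = 1.4), "0, 1")
})

test_that("scale_substrate preserves zeros and ratios", {
  m <- add_scar_region(slab_fine(), c(10, 10, 5), 4)
  s <- build_substrate(m, "FEC", base_cv = 0.4)
  expect_identical(scale_substrate(s, 1), s)
  s2 <- scale_substrate(s, 2)
  expect_equal(max(s2$cv_long) / min(s2$cv_long), s$fec_ratio)
  expect_equal(s2$base_cv, 0.8)
  sc <- build_substrate(m, "SCAR", base_cv = 0.4)
  expect_identical(scale_substrate(sc, 0.5)$cv_long == 0, sc$cv_long == 0)
  expect_error(scale_substrate(s, 0), "positive")
  expect_error(scale_substrate(s, -1), "positive")
})

test_that("raising the FEC ratio never slows any node down", {
  m <- generate_slab_mesh(20, 20, 6, 2)
  fib <- assign_fibers(m)
  pac <- pacing_config(nearest_node(m, c(0, 10, 0)))
  prev <- NULL
  for (r in c(1, 3, 6, 10)) {
    s <- build_substrate(m, "FEC", base_cv = 0.4, fec_ratio = r)
    t <- solve_eikonal(m, fib, s, pac)$times
    if (!is.null(prev)) expect_true(all(t <= prev + 1e-9))
    prev <- t
  }
})
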