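test_that("isotropic point-source times match the Euclidean closed form", {
  m <- slab_fine()
  fib <- isotropic_fibers(m)
  src <- c(20, 20, 0)
  pac <- pacing_config(nearest_node(m, src))
  s <- build_substrate(m, "NORMAL", base_cv = 1, anisotropy_ratio = 1)
  map <- solve_eikonal(m, fib, s, pac)
  d <- sqrt(rowSums(sweep(m$nodes, 2, src)^2))
  sel <- d > 3
  rel <- (map$times[sel] - d[sel]) / d[sel]
  expect_lt(max(rel), 0.03)
  expect_gt(min(rel), -1e-9)  # never undershoots the true time
})

test_that("anisotropic times match t = sqrt(x' G x) along and across fibers", {
  m <- slab_fine()
  fib <- isotropic_fibers(m, c(1, 0, 0))
  src <- c(20, 20, 0)
  pac <- pacing_config(nearest_node(m, src))
  s <- build_substrate(m, "NORMAL", base_cv = 1, anisotropy_ratio = 0.4)
  map <- solve_eikonal(m, fib, s, pac)
  # closed form with G = diag(1/vl^2, 1/vt^2, 1/vt^2)
  expect_equal(map$times[nearest_node(m, c(30, 20, 0))], 10, tolerance = 1e-6)
  expect_equal(map$times[nearest_node(m, c(20, 30, 0))], 25, tolerance = 1e-6)
  dd <- sweep(m$nodes, 2, src)
  ttrue <- sqrt(dd[, 1]^2 + (dd[, 2]^2 + dd[, 3]^2) / 0.16)
  sel <- sqrt(rowSums(dd^2)) > 3
  rel <- (map$times[sel] - ttrue[sel]) / ttrue[sel]
  expect_lt(max(rel), 0.03)
  expect_gt(min(rel), -1e-9)
})

test_that("edge-graph Dijkstra upper-bounds the solver on every test mesh", {
  cases <- list(
    list(m = slab_small(), aniso = 1, fib_dir = c(1, 0, 0), variant = "NORMAL"),
    list(m = slab_small(), aniso = 0.4, fib_dir = c(1, 1, 0), variant = "NORMAL"),
    list(m = slab_fine(), aniso = 0.4, fib_dir = c(1, 0, 0), variant = "FEC"))
  for (cs in cases) {
    fib <- isotropic_fibers(cs$m, cs$fib_dir)
    s <- build_substrate(cs$m, cs$variant, base_cv = 0.6,
                         anisotropy_ratio = cs$aniso)
    pac <- pacing_config(nearest_node(cs$m, c(0, 0, 0)))
    t_sol <- solve_eikonal(cs$m, fib, s, pac)$times
    t_dij <- edge_graph_times(cs$m, fib, s, pac)
    expect_true(all(t_sol <= t_dij + 1e-8))
  }
})

test_that("solution converges toward the closed form under refinement", {
  err_at <- function(h) {
    m <- generate_slab_mesh(20, 20, 4, h)
    fib <- isotropic_fibers(m)
    pac <- pacing_config(nearest_node(m, c(0, 0, 0)))
    s <- build_substrate(m, "NORMAL", base_cv = 1, anisotropy_ratio = 1)
    map <- solve_eikonal(m, fib, s, pac, init_radius_mm = 4)
    d <- sqrt(rowSums(m$nodes^2))
    sel <- d > 5
    max((map$times[sel] - d[sel]) / d[sel])
  }
  errs <- vapply(c(2, 1, 0.5), err_at, numeric(1))
  expect_true(all(diff(errs) <= 1e-9))  # non-increasing with refinement
  expect_lt(errs[2], 0.03)
})

test_that("activation around a blocked wall follows the detour geodesic", {
  m <- generate_slab_mesh(20, 20, 2, 1)
  fib <- isotropic_fibers(m)
  s <- build_substrate(m, "NORMAL", base_cv = 1, anisotropy_ratio = 1)
  ctr <- element_centroids(m)
  # transmural wall at x in (9, 10), open gap where y < 2
  s$cv_long[ctr[, 1] > 9 & ctr[, 1] < 10 & ctr[, 2] >= 2] <- 0
  pac <- pacing_config(nearest_node(m, c(0, 10, 1)))
  map <- solve_eikonal(m, fib, s, pac)
  t_target <- map$times[nearest_node(m, c(20, 10, 1))]
  # around-the-gap geodesic: source -> gap corner -> target
  t_geo <- sqrt(9^2 + 8^2) + 1 + sqrt(10^2 + 8^2)
  expect_rel_equal(t_target, t_geo, 0.05)
  t_dij <- edge_graph_times(m, fib, s, pac)
  expect_true(all(map$times <= t_dij + 1e-8))
})

test_that("the exact 1/alpha scaling law holds to float precision", {
  m <- slab_fine()
  fib <- assign_fibers(m)
  pac <- pacing_config(nearest_node(m, c(5, 20, 0)), onset_time = 3)
  s <- build_substrate(m, "FEC", base_cv = 0.4)
  t1 <- solve_eikonal(m, fib, s, pac)$times
  t2 <- solve_eikonal(m, fib, scale_substrate(s, 2), pac)$times
  rel <- abs((t2 - 3) - (t1 - 3) / 2) / pmax(t1 - 3, 1e-12)
  expect_lt(max(rel), 1e-9)
})

test_that("anisotropic front level sets are ellipses with the anisotropy ratio", {
  m <- slab_fine()
  fib <- isotropic_fibers(m, c(1, 0, 0))
  pac <- pacing_config(nearest_node(m, c(20, 20, 0)))
  s <- build_substrate(m, "NORMAL", base_cv = 1, anisotropy_ratio = 0.4)
  map <- solve_eikonal(m, fib, s, pac)
  # radius of the t = 15 ms level set along x vs along y on the endo face
  on_x <- which(m$nodes[, 2] == 20 & m$nodes[, 3] == 0 & m$nodes[, 1] > 20)
  on_y <- which(m$nodes[, 1] == 20 & m$nodes[, 3] == 0 & m$nodes[, 2] > 20)
  rx <- approx(map$times[on_x], m$nodes[on_x, 1] - 20, xout = 15)$y
  ry <- approx(map$times[on_y], m$nodes[on_y, 2] - 20, xout = 15)$y
  expect_rel_equal(ry / rx, 0.4, 0.03)
})

test_that("solver rejects inconsistent inputs", {
  m <- slab_small()
  fib <- isotropic_fibers(m)
  s <- build_substrate(m, "NORMAL", base_cv = 1)
  expect_error(solve_eikonal(m, isotropic_fibers(slab_fine()), s,
                             pacing_config(1L)), "does not match")
  expect_error(pacing_config(integer(0)), "non-empty")
  s0 <- s; s0$cv_long[] <- 0
  expect_error(solve_eikonal(m, fib, s0, pacing_config(1L)), "blocked")
  expect_error(fiber_field <- cardioeik:::fiber_field(matrix(c(1, 1, 0), 1)),
               "unit")
})

test_that("total activation time excludes unreachable tissue and reports it", {
  m <- slab_long()
  fib <- isotropic_fibers(m, c(1, 0, 0))
  s <- build_substrate(m, "NORMAL", base_cv = 1, anisotropy_ratio = 1)
  pac <- pace_x0(m)
  map <- solve_eikonal(m, fib, s, pac)
  tat <- total_activation_time(map)
  expect_equal(as.numeric(tat), 60, tolerance = 1e-9)
  expect_identical(attr(tat, "unreachable"), 0L)
  # onset translation leaves TAT unchanged
  pac10 <- pacing_config(pac$stimulus_nodes, onset_time = 10)
  map10 <- solve_eikonal(m, fib, s, pac10)
  expect_equal(as.numeric(total_activation_time(map10)), 60, tolerance = 1e-9)
  # sealed-off far end: unreachable nodes excluded with a warning
  ctr <- element_centroids(m)
  s$cv_long[ctr[, 1] > 50 & ctr[, 1] < 52] <- 0
  mapb <- solve_eikonal(m, fib, s, pac)
  expect_warning(tatb <- total_activation_time(mapb), "unreachable")
  expect_gt(attr(tatb, "unreachable"), 0L)
  expect_true(is.finite(tatb))
})

test_that("latest activation site and tie-breaking behave as documented", {
  m <- slab_long()
  fib <- isotropic_fibers(m, c(1, 0, 0))
  s <- build_substrate(m, "NORMAL", base_cv = 1, anisotropy_ratio = 1)
  map <- solve_eikonal(m, fib, s, pace_x0(m))
  site <- latest_activation_site(map, m)
  expect_equal(unname(site$coords[1]), 60)
  # all x = 60 nodes tie; the lowest index must win
  tied <- which(abs(map$times - max(map$times)) < 1e-12)
  expect_identical(site$node, min(tied))
  expect_false(site$is_septal)
  ms <- slab_septal()
  expect_identical(latest_activation_site(map, ms)$region, ms$region[1])
})

test_that("calibration hits the QRS target through the scaling law", {
  m <- slab_long()
  fib <- isotropic_fibers(m, c(1, 0, 0))
  s <- build_substrate(m, "NORMAL", base_cv = 0.3)
  pac <- pace_x0(m)
  cal <- calibrate_cv(m, fib, s, pac, 120)
  expect_equal(cal$fitted_cv, 0.5, tolerance = 1e-6)   # TAT = 60 mm / v
  expect_lte(cal$mismatch, 5)
  expect_lte(cal$n_evaluations, 3)
  cal2 <- calibrate_cv(m, fib, s, pac, 60)
  expect_equal(cal2$fitted_cv, 1.0, tolerance = 1e-6)
  # brute-force grid search agrees with the scaling shortcut
  calg <- calibrate_cv(m, fib, s, pac, 120, method = "grid")
  expect_lt(abs(calg$fitted_cv - 0.5), 0.01)
  expect_lte(calg$mismatch, 5)
})

test_that("calibration on an FEC substrate preserves the layer/bulk ratio", {
  m <- slab_fine()
  fib <- assign_fibers(m)
  s <- build_substrate(m, "FEC", base_cv = 0.4)
  pac <- pacing_config(nearest_node(m, c(0, 20, 0)))
  cal <- calibrate_cv(m, fib, s, pac, 80)
  fitted <- scale_substrate(s, cal$fitted_cv / s$base_cv)
  expect_equal(max(fitted$cv_long) / min(fitted$cv_long), 6, tolerance = 1e-12)
  expect_lte(cal$mismatch, 5)
})

test_that("unreachable calibration targets report the achievable range", {
  m <- slab_long()
  fib <- isotropic_fibers(m, c(1, 0, 0))
  s <- build_substrate(m, "NORMAL", base_cv = 0.3)
  expect_error(calibrate_cv(m, fib, s, pace_x0(m), 10),
               "achievable TAT range")
  expect_error(calibrate_cv(m, fib, s, pace_x0(m), 0), "positive")
})
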