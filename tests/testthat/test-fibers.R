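test_that("slab fibers follow the linear helix-angle rule", {
  m <- slab_small()  # apex-base along x, transmural along z
  fib <- assign_fibers(m, 60, -60)
  expect_equal(nrow(fib$fiber_dir), n_elems(m))
  # unit norm everywhere
  expect_lt(mean(abs(sqrt(rowSums(fib$fiber_dir^2)) - 1)), 1e-9)
  # midwall elements: helix angle 0, fiber along the circumferential (y) axis
  tbar <- rowMeans(matrix(m$transmural[m$elems], ncol = 4))
  mid <- abs(tbar - 0.5) < 1e-9
  expect_true(any(mid))
  expect_lt(max(abs(abs(fib$fiber_dir[mid, 2]) - 1)), 1e-9)
  # every element matches the predicted helix angle about the y axis:
  # fiber = (-sin(a), -cos(a), 0) up to sign, a = 60 - 120 * tbar degrees
  a <- (60 - 120 * tbar) * pi / 180
  pred <- cbind(sin(a), -cos(a), 0)
  dev <- abs(rowSums(fib$fiber_dir * pred))  # |cos| of angle to prediction
  expect_gt(min(dev), 1 - 1e-9)
})

test_that("zero helix angles give purely circumferential fibers", {
  m <- slab_small()
  fib <- assign_fibers(m, 0, 0)
  expect_lt(max(abs(abs(fib$fiber_dir[, 2]) - 1)), 1e-9)
  expect_lt(max(abs(fib$fiber_dir[, c(1, 3)])), 1e-9)
})

test_that("negating helix angles mirrors the in-plane component", {
  m <- slab_small()
  f1 <- assign_fibers(m, 60, -60)$fiber_dir
  f2 <- assign_fibers(m, -60, 60)$fiber_dir
  expect_lt(max(abs(f1[, 2] - f2[, 2])), 1e-9)  # circumferential part equal
  expect_lt(max(abs(f1[, 1] + f2[, 1])), 1e-9)  # longitudinal part negated
})

test_that("fiber angle is continuous across transmural depth", {
  m <- slab_small()
  fib <- assign_fibers(m)
  tbar <- rowMeans(matrix(m$transmural[m$elems], ncol = 4))
  ang <- atan2(fib$fiber_dir[, 1], -fib$fiber_dir[, 2]) * 180 / pi
  # angle difference bounded by angle span x depth difference (plus slack)
  o <- order(tbar)
  dd <- diff(tbar[o]); da <- abs(diff(ang[o]))
  expect_true(all(da <= 120 * dd + 1e-6))
})

test_that("mesh without coordinate fields is rejected", {
  m <- slab_small()
  m$transmural <- NULL
  expect_error(assign_fibers(m), "coordinate fields")
})

test_that("isotropic fibers realize an isotropic medium at ratio 1", {
  m <- slab_small()
  pac <- pacing_config(nearest_node(m, c(0, 0, 0)))
  s_iso <- build_substrate(m, "NORMAL", base_cv = 1, anisotropy_ratio = 1)
  fa <- isotropic_fibers(m, c(1, 0, 0))
  fb <- isotropic_fibers(m, c(0, 1, 1))
  expect_lt(max(abs(fa$fiber_dir[1, ] - fa$fiber_dir[n_elems(m), ])), 1e-15)
  ta <- solve_eikonal(m, fa, s_iso, pac)$times
  tb <- solve_eikonal(m, fb, s_iso, pac)$times
  expect_lt(max(abs(ta - tb)), 1e-9)
  # contrapositive: with anisotropy the fiber choice matters
  s_ani <- build_substrate(m, "NORMAL", base_cv = 1, anisotropy_ratio = 0.4)
  ta2 <- solve_eikonal(m, fa, s_ani, pac)$times
  tb2 <- solve_eikonal(m, fb, s_ani, pac)$times
  expect_gt(max(abs(ta2 - tb2)), 1)
})
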