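# A linear activation field on the long slab makes every metric
# hand-computable: plane-wave pacing at x = 0 with cv 1 mm/ms gives
# t(x) = x ms, and with QRSd = 60 ms, LAT(x) = x / 0.6 %.
linear_field <- function() {
  m <- slab_long()
  fib <- isotropic_fibers(m, c(1, 0, 0))
  s <- build_substrate(m, "NORMAL", base_cv = 1, anisotropy_ratio = 1)
  map <- solve_eikonal(m, fib, s, pace_x0(m))
  list(m = m, map = map, qrsd = 60)
}

test_that("epicardial projection reproduces plane-geometry answers", {
  m <- slab_long()  # EPI is the z = 10 plane
  pts <- rbind(c(10, 10, 10),    # already on the surface
               c(20, 10, 15),    # 5 mm above a flat facet
               c(40, 5, 13))     # 3 mm above
  eam <- eam_recording(pts, c(10, 20, 30), 60)
  pr <- project_points(m, eam)
  expect_equal(pr$eam$points[1, ], c(10, 10, 10), tolerance = 1e-12)
  expect_equal(pr$eam$points[2, ], c(20, 10, 10), tolerance = 1e-12)
  expect_equal(pr$rms_mm, sqrt(mean(c(0, 5, 3)^2)), tolerance = 1e-12)
  # constant offset: rms equals the offset
  eam3 <- eam_recording(sweep(pr$eam$points, 2, c(0, 0, 3), "+"),
                        c(10, 20, 30), 60)
  expect_equal(project_points(m, eam3)$rms_mm, 3, tolerance = 1e-12)
  m_noepi <- m
  m_noepi$surface_labels[m_noepi$surface_labels == "EPI"] <- "BASE"
  expect_error(project_points(m_noepi, eam), "EPI")
})

test_that("normalized LAT is the interpolated time as a percentage of QRSd", {
  lf <- linear_field()
  p <- rbind(c(30, 10, 10), c(0, 10, 10), c(45, 7, 10))
  lat <- normalized_lat(lf$map, lf$m, p, lf$qrsd)
  expect_equal(lat, c(50, 0, 75), tolerance = 1e-6)
  # values above 100% are permitted with a shorter QRSd
  expect_equal(normalized_lat(lf$map, lf$m, rbind(c(39, 10, 10)), 30),
               130, tolerance = 1e-6)
})

test_that("temporal error follows the sign convention and is linear in QRSd", {
  expect_equal(temporal_error(50, 40, 120), 12)
  expect_equal(temporal_error(42, 42, 100), 0)
  expect_equal(temporal_error(30, 40, 100), -10)  # model faster => negative
  sim <- c(10, 55, 80); meas <- c(20, 50, 90)
  expect_equal(temporal_error(sim, meas, 100),
               -temporal_error(meas, sim, 100))
  expect_equal(temporal_error(sim, meas, 200), 2 * temporal_error(sim, meas, 100))
})

test_that("distance error reproduces the hand-computed isochrone offset", {
  lf <- linear_field()
  # measured LAT 13.333% of 60 ms = 8 ms => isochrone plane x = 8;
  # point at x = 10 lies 2 mm away
  d <- distance_error(lf$map, lf$m, rbind(c(10, 10, 10)), 800 / 60, lf$qrsd)
  expect_equal(as.numeric(d), 2, tolerance = 1e-6)
  expect_false(attr(d, "out_of_range"))
  # brute-force cross-check over all edge crossings of the level set
  ed <- cardioeik:::mesh_edges(lf$m)
  lat <- 100 * lf$map$times / lf$qrsd
  L <- 800 / 60
  hit <- (lat[ed[, 1]] - L) * (lat[ed[, 2]] - L) <= 0
  a <- lf$m$nodes[ed[hit, 1], , drop = FALSE]
  b <- lf$m$nodes[ed[hit, 2], , drop = FALSE]
  den <- lat[ed[hit, 2]] - lat[ed[hit, 1]]
  s <- ifelse(abs(den) < 1e-12, 0, (L - lat[ed[hit, 1]]) / den)
  iso <- a + (b - a) * s
  brute <- sqrt(min(rowSums(sweep(iso, 2, c(10, 10, 10))^2)))
  expect_equal(as.numeric(d), brute, tolerance = 1e-9)
})

test_that("distance error is zero iff the point's LAT matches", {
  lf <- linear_field()
  p <- rbind(c(24, 10, 10))
  lat_here <- normalized_lat(lf$map, lf$m, p, lf$qrsd)
  expect_equal(as.numeric(distance_error(lf$map, lf$m, p, lat_here, lf$qrsd)),
               0)
  expect_gt(as.numeric(distance_error(lf$map, lf$m, p, lat_here + 5, lf$qrsd)),
            0)
})

test_that("out-of-range measurements are flagged against the extreme isochrone", {
  lf <- linear_field()
  p <- rbind(c(50, 10, 10))
  d <- distance_error(lf$map, lf$m, p, 150, lf$qrsd)  # later than all times
  expect_true(attr(d, "out_of_range"))
  # nearest latest-activated tissue is the x = 60 face, 10 mm away
  expect_equal(as.numeric(d), 10, tolerance = 1e-6)
})

test_that("distance error shrinks with the matching tolerance and is bounded", {
  lf <- linear_field()
  p <- rbind(c(10, 10, 10), c(30, 0, 10), c(55, 20, 10))
  meas <- c(5, 60, 95)
  tols <- c(0, 2, 5, 10)
  prev <- rep(Inf, 3)
  for (tl in tols) {
    d <- as.numeric(distance_error(lf$map, lf$m, p, meas, lf$qrsd,
                                   match_tol_pct = tl))
    expect_true(all(d <= prev + 1e-9))
    prev <- d
  }
  diam <- sqrt(sum((apply(lf$m$nodes, 2, max) - apply(lf$m$nodes, 2, min))^2))
  expect_true(all(prev <= diam))
})

test_that("physiological constraint screen enumerates failures", {
  cal <- function(cv) structure(list(fitted_cv = cv), class = "CalibrationResult")
  expect_true(check_constraints(cal(0.33), "LV_FREE_WALL_POST")$pass)
  r1 <- check_constraints(cal(0.80), "LV_FREE_WALL_POST")
  expect_false(r1$pass)
  expect_match(r1$reasons, "velocity")
  r2 <- check_constraints(cal(0.4), "SEPTUM")
  expect_false(r2$pass)
  expect_match(r2$reasons, "septum")
  r3 <- check_constraints(cal(0.05), "SEPTUM")
  expect_length(r3$reasons, 2L)
})

test_that("variant comparison matches the textbook ANOVA decomposition", {
  mk <- function(v, x) error_report(v, x, x)
  # identical groups: F = 0, Tukey p = 1
  r <- compare_variants(list(mk("A", c(1, 2, 3)), mk("B", c(1, 2, 3))))
  expect_equal(r$anova$distance$F, 0)
  expect_equal(unname(r$tukey$distance[, "p adj"]), 1)
  # hand-computable 2 x 3 fixture
  a <- c(1, 2, 3); b <- c(7, 9, 11)
  r2 <- compare_variants(list(mk("A", a), mk("B", b)))
  gm <- mean(c(a, b))
  ssb <- 3 * ((mean(a) - gm)^2 + (mean(b) - gm)^2)
  ssw <- sum((a - mean(a))^2) + sum((b - mean(b))^2)
  expect_equal(r2$anova$distance$F, (ssb / 1) / (ssw / 4), tolerance = 1e-12)
  # clear separation: significant pair, correct ranking
  set.seed(42)
  g1 <- abs(rnorm(3, 0, 1e-3)); g2 <- 10 + rnorm(3, 0, 1e-3)
  r3 <- compare_variants(list(mk("LOW", g1), mk("HIGH", g2)))
  expect_lt(r3$tukey$distance[, "p adj"], 0.001)
  expect_identical(r3$ranking, c("LOW", "HIGH"))
  expect_error(compare_variants(list(mk("A", a))), "two variants")
  expect_error(compare_variants(list(mk("A", a), mk("B", 5))), "two observations")
})
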