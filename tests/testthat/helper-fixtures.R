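# Shared fixtures, built once per test run and cached (mesh generation is
# deterministic, so caching cannot leak state between tests).

.fixture_cache <- new.env(parent = emptyenv())

fixture <- function(name, expr) {
  if (is.null(.fixture_cache[[name]]))
    assign(name, force(expr), envir = .fixture_cache)
  .fixture_cache[[name]]
}

slab_small <- function() fixture("slab_small", generate_slab_mesh(20, 20, 10, 2))

slab_fine <- function() fixture("slab_fine", generate_slab_mesh(40, 40, 10, 1))

slab_long <- function() fixture("slab_long", generate_slab_mesh(60, 20, 10, 2))

biv_mesh <- function() fixture("biv_mesh", generate_biventricular_mesh())

# slab with the middle third (along x) labeled SEPTUM
slab_septal <- function() fixture("slab_septal", {
  m <- generate_slab_mesh(60, 20, 10, 2)
  ctr <- element_centroids(m)
  relabel_elements(m, ctr[, 1] > 20 & ctr[, 1] < 40, "SEPTUM")
})

# plane-wave pacing: every node on the x = 0 face
pace_x0 <- function(mesh) pacing_config(which(mesh$nodes[, 1] == 0))

expect_rel_equal <- function(actual, expected, tol) {
  expect_lt(abs(actual - expected) / abs(expected), tol)
}
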