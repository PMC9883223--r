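# Shared fixtures: small analytic masks, cached phantom pipelines, and a
# ray-parity point-in-mesh oracle.

.fixture_cache <- new.env()

# Solid digital ball mask, not touching the boundary.
ball_mask <- function(d = 36, r = 13) {
  ctr <- (d + 1) / 2
  g <- expand.grid(x = 1:d, y = 1:d, z = 1:d)
  array((g$x - ctr)^2 + (g$y - ctr)^2 + (g$z - ctr)^2 <= r^2, c(d, d, d))
}

# Flat-topped step pyramid: stacked shrinking squares, top at z = levels + 1.5.
pyramid_mask <- function(base_half = 8, levels = 4) {
  d <- 2 * base_half + 5
  ctr <- base_half + 3
  m <- array(FALSE, c(d, d, levels + 3))
  for (k in seq_len(levels)) {
    r <- base_half - (k - 1) * 2
    m[(ctr - r):(ctr + r), (ctr - r):(ctr + r), k + 1] <- TRUE
  }
  m
}

# Full phantom pipeline (phantom -> mask -> mesh), cached per (seed, shape).
phantom_case <- function(seed = 1L, shape = 160L, ...) {
  key <- paste0("ph_", seed, "_", shape)
  if (is.null(.fixture_cache[[key]])) {
    ph <- generate_phantom(phantom_spec(shape = shape, seed = seed, ...))
    mask <- binarize_soft_tissue(ph$volume)
    mesh <- extract_isosurface(mask)
    .fixture_cache[[key]] <- list(truth = ph$truth, mask = mask, mesh = mesh)
  }
  .fixture_cache[[key]]
}

# Ray-parity inside test: casts a +z ray from each query point (slightly
# offset to dodge exact vertex hits) and counts triangle crossings.
# Independent of the marching-cubes tables: pure triangle geometry.
point_in_mesh <- function(mesh, pts) {
  v1 <- mesh$vertices[mesh$faces[, 1], , drop = FALSE]
  v2 <- mesh$vertices[mesh$faces[, 2], , drop = FALSE]
  v3 <- mesh$vertices[mesh$faces[, 3], , drop = FALSE]
  apply(pts, 1, function(p) {
    px <- p[1] + 1.1e-4; py <- p[2] + 2.3e-4
    d1 <- cbind(v1[, 1] - px, v1[, 2] - py)
    d2 <- cbind(v2[, 1] - px, v2[, 2] - py)
    d3 <- cbind(v3[, 1] - px, v3[, 2] - py)
    c1 <- d1[, 1] * d2[, 2] - d1[, 2] * d2[, 1]
    c2 <- d2[, 1] * d3[, 2] - d2[, 2] * d3[, 1]
    c3 <- d3[, 1] * d1[, 2] - d3[, 2] * d1[, 1]
    hit <- (c1 > 0 & c2 > 0 & c3 > 0) | (c1 < 0 & c2 < 0 & c3 < 0)
    if (!any(hit)) return(FALSE)
    w <- abs(c1[hit]) + abs(c2[hit]) + abs(c3[hit])
    zs <- (abs(c2[hit]) * v1[hit, 3] + abs(c3[hit]) * v2[hit, 3] +
             abs(c1[hit]) * v3[hit, 3]) / w
    sum(zs > p[3]) %% 2L == 1L
  })
}
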