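# Isosurface extraction, mesh topology, normals, smoothing, mesh I/O.

test_that("a single interior voxel meshes to the 6-vertex corner-clip solid", {
  m <- array(FALSE, c(3, 3, 3)); m[2, 2, 2] <- TRUE
  mesh <- extract_isosurface(m)
  # oracle: 8 surrounding cells each hold one inside corner -> one
  # triangle each (single-corner table entry); the 6 cut lattice edges
  # give 6 shared vertices
  expect_equal(nrow(mesh$vertices), 6L)
  expect_equal(nrow(mesh$faces), 8L)
  expect_true(mesh_is_watertight(mesh))
  expect_equal(euler_characteristic(mesh), 2L)
  expect_false(mesh$open_boundary)
  # all vertices at edge midpoints around voxel (2,2,2)
  expect_equal(sort(unique(round(rowSums(abs(sweep(mesh$vertices, 2,
                                                   c(2, 2, 2)))), 9))),
               0.5)
})

test_that("a digitized ball is watertight with Euler characteristic 2", {
  mesh <- extract_isosurface(ball_mask(44, 20))
  expect_true(mesh_is_watertight(mesh))
  expect_equal(euler_characteristic(mesh), 2L)
  expect_false(mesh$open_boundary)
  # outward normals: positive dot with the radial direction
  ctr <- colMeans(mesh$vertices)
  expect_true(all(rowSums(mesh$normals * sweep(mesh$vertices, 2, ctr)) > 0))
  # unit normals
  expect_equal(rowSums(mesh$normals^2), rep(1, nrow(mesh$normals)),
               tolerance = 1e-12)
})

test_that("inside voxels lie inside the mesh, outside voxels outside", {
  set.seed(5)
  for (rep in 1:3) {
    m <- array(FALSE, c(9, 9, 9))
    m[3:7, 3:7, 3:7] <- array(runif(125) < 0.55, c(5, 5, 5))
    m[5, 5, 5] <- TRUE
    m <- largest_connected_component(m)
    mesh <- extract_isosurface(m)
    pts <- as.matrix(expand.grid(x = 2:8, y = 2:8, z = 2:8))
    got <- point_in_mesh(mesh, pts)
    expect_identical(unname(got), unname(m[pts]))
  }
})

test_that("the complement mask yields the same vertices with flipped normals", {
  m <- array(FALSE, c(7, 7, 7))
  m[3:5, 3:6, 3:4] <- TRUE; m[4, 4, 5] <- TRUE
  a <- extract_isosurface(m)
  b <- extract_isosurface(!m)
  key <- function(v) apply(round(v * 2), 1, paste, collapse = ",")
  oa <- order(key(a$vertices)); ob <- order(key(b$vertices))
  expect_identical(key(a$vertices)[oa], key(b$vertices)[ob])
  expect_lt(max(abs(a$normals[oa, ] + b$normals[ob, ])), 1e-9)
})

test_that("integer mask shifts translate every vertex exactly", {
  base <- array(FALSE, c(12, 12, 12)); base[3:5, 3:6, 4:5] <- TRUE
  shifted <- array(FALSE, c(12, 12, 12)); shifted[6:8, 4:7, 6:7] <- TRUE
  a <- extract_isosurface(base)
  b <- extract_isosurface(shifted)
  key <- function(v) sort(apply(round(v * 2), 1, paste, collapse = ","))
  expect_identical(key(sweep(a$vertices, 2, -c(3, 1, 2))), key(b$vertices))
})

test_that("the step pyramid has a planar top plateau with +z normals", {
  mesh <- extract_isosurface(pyramid_mask())
  zmax <- max(mesh$vertices[, 3])
  top <- mesh$vertices[, 3] == zmax
  expect_gt(sum(top), 5)
  # interior plateau vertices (one vertex in from the rim): exact +z
  rng <- range(mesh$vertices[top, 1])
  inner <- top & mesh$vertices[, 1] > rng[1] & mesh$vertices[, 1] < rng[2] &
    mesh$vertices[, 2] > rng[1] & mesh$vertices[, 2] < rng[2]
  expect_gt(sum(inner), 0)
  expect_equal(mesh$normals[inner, ],
               matrix(rep(c(0, 0, 1), each = sum(inner)), ncol = 3),
               tolerance = 1e-12)
})

test_that("foreground touching the grid boundary flags an open mesh", {
  m <- array(FALSE, c(5, 5, 5)); m[1:3, 2:4, 2:4] <- TRUE
  mesh <- extract_isosurface(m)
  expect_true(mesh$open_boundary)
  expect_false(mesh_is_watertight(mesh))
  expect_error(extract_isosurface(array(FALSE, c(4, 4, 4))), "no foreground")
})

test_that("normal smoothing is the identity at 0 iterations and on plateaus", {
  mesh <- extract_isosurface(pyramid_mask(base_half = 10))
  expect_identical(smooth_preserving_plateaus(mesh, 0L), mesh)
  sm <- smooth_preserving_plateaus(mesh, 2L)
  expect_identical(sm$vertices, mesh$vertices)   # positions never move
  # plateau vertices whose 2-ring stays on the plateau are fixed points
  zmax <- max(mesh$vertices[, 3])
  ctr <- mean(range(mesh$vertices[mesh$vertices[, 3] == zmax, 1]))
  deep <- mesh$vertices[, 3] == zmax &
    abs(mesh$vertices[, 1] - ctr) <= 1 & abs(mesh$vertices[, 2] - ctr) <= 1
  expect_gt(sum(deep), 0)
  expect_equal(sm$normals[deep, ], mesh$normals[deep, ], tolerance = 1e-12)
})

test_that("smoothing pulls staircase-noise wall normals toward the wall", {
  w <- array(FALSE, c(8, 30, 30)); w[1:4, , ] <- TRUE
  set.seed(1)
  w[cbind(5, sample(5:26, 20), sample(5:26, 20))] <- TRUE
  mesh <- extract_isosurface(w)
  sm <- smooth_preserving_plateaus(mesh, 8L)
  wall <- mesh$vertices[, 1] == 4.5 &
    mesh$vertices[, 2] > 6 & mesh$vertices[, 2] < 24 &
    mesh$vertices[, 3] > 6 & mesh$vertices[, 3] < 24
  ang <- acos(pmin(1, sm$normals[wall, 1])) * 180 / pi
  expect_lt(max(ang), 10)
})

test_that("PLY and OBJ exports round-trip the mesh", {
  mesh <- extract_isosurface(ball_mask(20, 7))
  for (fmt in c("ascii", "binary")) {
    p <- file.path(tempdir(), paste0("m_", fmt, ".ply"))
    write_ply(mesh, p, format = fmt)
    back <- read_ply(p)
    expect_equal(back$vertices, mesh$vertices, tolerance = 1e-6)
    expect_identical(back$faces, mesh$faces)
    expect_equal(back$normals, mesh$normals, tolerance = 1e-6)
  }
  po <- file.path(tempdir(), "m.obj")
  write_obj(mesh, po)
  lines <- readLines(po)
  expect_equal(sum(startsWith(lines, "v ")), nrow(mesh$vertices))
  expect_equal(sum(startsWith(lines, "f ")), nrow(mesh$faces))
})
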