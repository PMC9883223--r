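# Landmark catalog, CC-point computation, coordinate conversion, and the
# perturbation-consistency examination.

# Flat rectangular sheet in the x-z plane at constant y, wound so vertex
# normals point along -y (anterior) -- a synthetic tabletop.
make_sheet <- function(xs, zs, y, flip = FALSE) {
  g <- expand.grid(x = xs, z = zs)
  verts <- cbind(g$x, y, g$z)
  nx <- length(xs)
  faces <- list()
  for (i in seq_len(nx - 1)) for (j in seq_len(length(zs) - 1)) {
    p1 <- (j - 1) * nx + i
    faces[[length(faces) + 1]] <- c(p1, p1 + 1, p1 + nx)
    faces[[length(faces) + 1]] <- c(p1 + 1, p1 + nx + 1, p1 + nx)
  }
  f <- do.call(rbind, faces)
  if (flip) f <- f[, c(1, 3, 2)]
  list(vertices = verts, faces = f)
}

sheets_mesh <- function(...) {
  parts <- list(...)
  verts <- do.call(rbind, lapply(parts, `[[`, "vertices"))
  off <- cumsum(c(0, vapply(parts, function(p) nrow(p$vertices), 0)))
  faces <- do.call(rbind, lapply(seq_along(parts), function(k)
    parts[[k]]$faces + off[k]))
  triangle_mesh(verts, faces)
}

test_that("the catalog carries the six fixed anatomical normals", {
  cat_ <- landmark_catalog()
  expect_named(cat_, c("Pn", "Co", "ULP", "LLP", "Ch_r", "Ch_l"))
  expect_equal(cat_$Pn$normal_raw, c(0, -0.5, 0))
  expect_equal(cat_$Co$normal_raw, c(0, -0.5, -0.5))
  expect_equal(cat_$ULP$normal_raw, c(0, -0.5, 0))
  expect_equal(cat_$LLP$normal_raw, c(0, -0.5, 0))
  expect_equal(cat_$Ch_r$normal_raw, c(-0.5, -0.5, 0))
  expect_equal(cat_$Ch_l$normal_raw, c(0.5, -0.5, 0))
  expect_equal(cat_$Co$normal_unit, c(0, -sqrt(2) / 2, -sqrt(2) / 2))
  for (lm in cat_)
    expect_equal(sum(lm$normal_unit^2), 1, tolerance = 1e-15)
})

test_that("snapping picks the nearest vertex with lowest-index ties", {
  mesh <- sheets_mesh(make_sheet(0:2, 0:2, 0))
  expect_equal(snap_to_surface(c(1, 0, 1), mesh),
               which(mesh$vertices[, 1] == 1 & mesh$vertices[, 3] == 1))
  # 0.4 px off a vertex with the nearest other vertex 1.0 px away
  expect_equal(snap_to_surface(c(0.4, 0, 0), mesh), 1L)
  # exact tie between vertices 1 and 2: lowest index wins
  expect_equal(snap_to_surface(c(0.5, 0, 0), mesh), 1L)
})

test_that("a coplanar plateau is returned in full", {
  mesh <- sheets_mesh(make_sheet(0:4, 0:4, 0))
  reg <- find_tabletop(mesh, c(2, 0, 2), "Pn")
  expect_s3_class(reg, "tabletop_region")
  expect_length(reg$members, 25L)
  # every member within the ball and the band
  s <- reg$start_point
  rel <- sweep(mesh$vertices[reg$members, ], 2, s)
  expect_true(all(rowSums(rel^2) <= 50^2))
  expect_true(all(abs(rel %*% c(0, -1, 0)) <= 1))
})

test_that("a disjoint same-height tabletop 30 px away is not merged", {
  mesh <- sheets_mesh(make_sheet(0:4, 0:4, 0), make_sheet(30:34, 0:4, 0))
  reg <- find_tabletop(mesh, c(2, 0, 2), "LLP")
  expect_length(reg$members, 25L)
  expect_true(all(mesh$vertices[reg$members, 1] <= 4))
})

test_that("a terrace 2 px lower along the normal is excluded by the band", {
  mesh <- sheets_mesh(make_sheet(0:4, 0:4, 0), make_sheet(5:9, 0:4, 2))
  reg <- find_tabletop(mesh, c(2, 0, 2), "Pn", band_px = 1)
  # oracle: explicit per-vertex band test
  keep <- abs(mesh$vertices[, 2] - 0) <= 1
  expect_setequal(reg$members, which(keep))
  expect_length(reg$members, 25L)
})

test_that("a back-facing start point is rejected", {
  mesh <- sheets_mesh(make_sheet(0:4, 0:4, 0, flip = TRUE))
  expect_error(find_tabletop(mesh, c(2, 0, 2), "Pn"),
               "not on the landmark-facing surface")
})

test_that("CC points are unweighted member centroids", {
  cat_ <- landmark_catalog()
  mk_region <- function(verts, members) {
    mesh <- triangle_mesh(verts, matrix(c(1, 2, 3), 1),
                          normals = matrix(rep(c(0, -1, 0), nrow(verts)),
                                           ncol = 3, byrow = TRUE))
    reg <- structure(list(landmark = cat_$Pn, start_index = members[1],
                          start_point = verts[members[1], ],
                          members = members, radius_px = 50, band_px = 1),
                     class = "tabletop_region")
    list(mesh = mesh, reg = reg)
  }
  one <- mk_region(rbind(c(100, 80, 120), c(101, 80, 120), c(100, 81, 120)),
                   1L)
  cc1 <- compute_cc_point(one$reg, one$mesh)
  expect_equal(cc1$voxel_coords, c(100, 80, 120))
  sq <- mk_region(rbind(c(10, 10, 10), c(12, 10, 10), c(10, 12, 10),
                        c(12, 12, 10)), 1:4)
  cc2 <- compute_cc_point(sq$reg, sq$mesh)
  expect_equal(cc2$voxel_coords, c(11, 11, 10))
  expect_equal(cc2$n_members, 4L)
  # 25-vertex plateau: equals the brute-force mean of the member list
  mesh <- sheets_mesh(make_sheet(0:4, 0:4, 0))
  reg <- find_tabletop(mesh, c(2, 0, 2), "Pn")
  cc3 <- compute_cc_point(reg, mesh)
  expect_equal(cc3$voxel_coords,
               colMeans(mesh$vertices[reg$members, ]))
})

test_that("voxel-to-mm conversion matches the reference constants exactly", {
  expect_equal(convert_voxel_to_mm(c(266.5, 266.5, 266)), c(0, 0, 0))
  expect_equal(convert_voxel_to_mm(c(276.5, 266.5, 266)), c(3, 0, 0))
  set.seed(11)
  for (i in 1:20) {
    p <- runif(3, 0, 533)
    expect_equal(convert_mm_to_voxel(convert_voxel_to_mm(p)), p,
                 tolerance = 1e-12)
  }
})

test_that("euclidean_d is the plain Euclidean norm", {
  expect_identical(euclidean_d(c(0, 0, 0)), 0)
  expect_identical(euclidean_d(c(3, 4, 0)), 5)
  expect_equal(euclidean_d(c(0.3, 0.3, 0.3)), 0.3 * sqrt(3))
})

test_that("perturbation directions span the normal's tangent plane", {
  for (ab in names(landmark_catalog())) {
    dirs <- perturbation_directions(ab)
    n <- landmark_catalog()[[ab]]$normal_unit
    expect_equal(unname(dirs %*% n), matrix(0, 4, 1), tolerance = 1e-12)
    expect_equal(rowSums(dirs^2), c(up = 1, down = 1, left = 1, right = 1))
    expect_equal(dirs["down", ], -dirs["up", ])
  }
  # anterior landmarks: up/down = +/-z, left/right = +/-x
  dirs <- perturbation_directions("Pn")
  expect_equal(dirs["up", ], c(x = 0, y = 0, z = 1))
  expect_equal(dirs["left", ], c(x = 1, y = 0, z = 0))
})

test_that("consistency is exact on a plateau and reports escapes honestly", {
  mesh <- sheets_mesh(make_sheet(0:10, 0:10, 0))
  reg <- find_tabletop(mesh, c(5, 0, 5), "Pn")
  g0 <- consistency_check(mesh, reg, offsets_px = 0)
  expect_true(all(g0$delta_d_px == 0))
  g <- consistency_check(mesh, reg)
  expect_equal(nrow(g), 32L)
  expect_true(all(g$delta_d_px == 0))
  # two terraces: a move beyond the small plateau snaps to the far one
  mesh2 <- sheets_mesh(make_sheet(0:2, 0:4, 0), make_sheet(5:13, 0:4, 2))
  regA <- find_tabletop(mesh2, c(1, 0, 2), "Pn")
  ccA <- compute_cc_point(regA, mesh2)
  g2 <- consistency_check(mesh2, regA)
  esc <- g2$direction == "left" & g2$offset_px == 4   # +x, towards terrace B
  expect_true(all(g2$delta_d_px[esc] > 0))
  # oracle: distance between the two terrace centroids
  regB <- find_tabletop(mesh2, c(9, 2, 2), "Pn")
  ccB <- compute_cc_point(regB, mesh2)
  expect_equal(g2$delta_d_px[esc],
               sqrt(sum((ccB$voxel_coords - ccA$voxel_coords)^2)))
})

test_that("two starts on one tabletop give identical CC points", {
  mesh <- sheets_mesh(make_sheet(0:8, 0:8, 0))
  cc1 <- compute_cc_point(find_tabletop(mesh, c(2.2, 0, 3.7), "ULP"), mesh)
  cc2 <- compute_cc_point(find_tabletop(mesh, c(6.1, 0, 4.9), "ULP"), mesh)
  expect_equal(cc1$voxel_coords, cc2$voxel_coords, tolerance = 1e-9)
})

test_that("translating the volume translates the CC point exactly", {
  base <- array(FALSE, c(24, 24, 24))
  g <- expand.grid(x = 1:24, y = 1:24, z = 1:24)
  blob <- (g$x - 12)^2 + (g$y - 14)^2 + (g$z - 12)^2 <= 49
  base[cbind(g$x, g$y, g$z)[blob, ]] <- TRUE
  shifted <- array(FALSE, c(24, 24, 24))
  shifted[cbind(g$x + 2, g$y + 1, g$z + 3)[blob & g$x <= 22 & g$y <= 23 &
                                             g$z <= 21, ]] <- TRUE
  m1 <- extract_isosurface(base)
  m2 <- extract_isosurface(shifted)
  cc1 <- compute_cc_point(find_tabletop(m1, c(12, 6, 12), "Pn"), m1)
  cc2 <- compute_cc_point(find_tabletop(m2, c(14, 7, 15), "Pn"), m2)
  expect_equal(cc2$voxel_coords, cc1$voxel_coords + c(2, 1, 3),
               tolerance = 1e-12)
})
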