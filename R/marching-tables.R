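# Cell-case dictionaries for marching squares (2D) and marching cubes (3D).
#
# Conventions (used everywhere in this package):
#   * Cube corner i (0..7) sits at (x, y, z) = (bit0(i), bit1(i), bit2(i))
#     of the unit cell; a configuration index is sum(2^i) over corners that
#     are inside the tissue.
#   * Square corner i (0..3) sits at (u, v) = (bit0(i), bit1(i)).
#   * For binary data at isovalue 0.5 every surface vertex is an edge
#     midpoint; that degeneracy is what produces the terraced "tabletop"
#     geometry downstream.
#   * Ambiguous (saddle) faces are resolved geometrically: the separated
#     diagonal is always the one through the face corner with minimal
#     coordinates along the face's two spanning axes.  The rule depends
#     only on geometry, never on which diagonal is inside, so the two
#     cells sharing a face always agree and complementary configurations
#     produce identical (orientation-flipped) surfaces.

.ccmark_cache <- new.env(parent = emptyenv())

#' Cube corner coordinates
#'
#' @return An 8 x 3 matrix; row `i` holds the unit-cell coordinates of
#'   corner `i - 1` under the package's bit-ordering convention.
#' @export
mc_corner_coords <- function() {
  i <- 0:7
  cbind(x = i %% 2L, y = (i %/% 2L) %% 2L, z = i %/% 4L)
}

#' Cube edge table
#'
#' The 12 cell edges, ordered axis-major (x edges, then y, then z).
#'
#' @return A data frame with columns `lo`, `hi` (0-based corner ids),
#'   `axis` (1 = x, 2 = y, 3 = z) and the midpoint coordinates
#'   `mx`, `my`, `mz`.
#' @export
mc_edge_table <- function() {
  if (!is.null(.ccmark_cache$edges)) return(.ccmark_cache$edges)
  pos <- mc_corner_coords()
  lo <- integer(0); hi <- integer(0); axis <- integer(0)
  for (a in 1:3) {
    bit <- 2L^(a - 1L)
    for (c0 in 0:7) {
      if (bitwAnd(c0, bit) == 0L) {
        lo <- c(lo, c0); hi <- c(hi, c0 + bit); axis <- c(axis, a)
      }
    }
  }
  mid <- (pos[lo + 1L, , drop = FALSE] + pos[hi + 1L, , drop = FALSE]) / 2
  out <- data.frame(lo = lo, hi = hi, axis = axis,
                    mx = mid[, 1], my = mid[, 2], mz = mid[, 3])
  .ccmark_cache$edges <- out
  out
}

# Edge id (1..12) for an unordered 0-based corner pair.
.mc_edge_id <- function(a, b) {
  et <- mc_edge_table()
  lo <- pmin(a, b); hi <- pmax(a, b)
  match(paste(lo, hi), paste(et$lo, et$hi))
}

# Directed marching-squares segments for one cell face.
#
# states: logical[4] in cycle order; pos2: 4 x 2 corner positions in cycle
# order; sep_cycle_pos: cycle position (1..4) of the corner whose diagonal
# is separated on a saddle.  Returns a list of directed segments, each an
# integer pair c(from, to) of cycle-midpoint slots (slot k = midpoint of
# the face edge between cycle corners k and k+1); direction keeps the
# inside region on the left in the (u, v) frame.
.ms_face_segments <- function(states, pos2, sep_cycle_pos = 1L) {
  n_in <- sum(states)
  if (n_in == 0L || n_in == 4L) return(list())
  nxt <- c(2L, 3L, 4L, 1L)
  prv <- c(4L, 1L, 2L, 3L)
  mid2 <- (pos2 + pos2[nxt, , drop = FALSE]) / 2   # slot k midpoint coords
  orient <- function(a_slot, b_slot, rep_pt) {
    A <- mid2[a_slot, ]; B <- mid2[b_slot, ]
    d <- B - A
    left <- c(-d[2], d[1])
    if (sum(left * (rep_pt - (A + B) / 2)) > 0) c(a_slot, b_slot) else c(b_slot, a_slot)
  }
  corner_cut <- function(k, rep_pt) orient(prv[k], k, rep_pt)
  segs <- list()
  if (n_in == 1L || n_in == 3L) {
    k <- if (n_in == 1L) which(states) else which(!states)
    rep_pt <- if (n_in == 1L) pos2[k, ] else c(0.5, 0.5)
    segs <- list(corner_cut(k, rep_pt))
  } else {
    ins <- which(states)
    if (any(nxt[ins[1]] == ins[2], nxt[ins[2]] == ins[1])) {
      k <- if (nxt[ins[1]] == ins[2]) ins[1] else ins[2]   # ins = {k, k+1}
      rep_pt <- (pos2[k, ] + pos2[nxt[k], ]) / 2
      segs <- list(orient(prv[k], nxt[k], rep_pt))
    } else {
      # saddle: cut off the designated corner and its diagonal mate
      j <- sep_cycle_pos
      j2 <- nxt[nxt[j]]
      rep_j  <- if (states[j])  pos2[j, ]  else c(0.5, 0.5)
      rep_j2 <- if (states[j2]) pos2[j2, ] else c(0.5, 0.5)
      segs <- list(corner_cut(j, rep_j), corner_cut(j2, rep_j2))
    }
  }
  segs
}

#' Marching-squares case dictionary
#'
#' All 16 configurations of a binary 2D cell, mapped to the contour
#' segments that separate inside from outside corners.  Segment endpoints
#' lie at edge midpoints (the binary-data degeneracy of linear
#' interpolation).  The two saddle cases are resolved by the fixed
#' geometric rule: the separated diagonal is the one through corner 0 at
#' (0, 0), whichever class that diagonal belongs to, so complementary
#' configurations map to identical segment sets.
#'
#' @return A list of 16 entries (names `"0"`..`"15"`).  Entry `i` holds
#'   `index`, `corner_states` (logical, corner k inside iff bit k of `i`),
#'   and `segments`: a list of 2 x 2 matrices, one endpoint (u, v) per row.
#' @export
marching_squares_table <- function() {
  if (!is.null(.ccmark_cache$ms_table)) return(.ccmark_cache$ms_table)
  cycle <- c(0L, 1L, 3L, 2L)                     # corner ids in cyclic order
  pos2 <- cbind(c(0, 1, 1, 0), c(0, 0, 1, 1))    # their (u, v) positions
  out <- vector("list", 16L)
  for (idx in 0:15) {
    st_bit <- bitwAnd(idx, 2L^(0:3)) > 0L        # by corner id
    st_cyc <- st_bit[cycle + 1L]
    segs <- .ms_face_segments(st_cyc, pos2, sep_cycle_pos = 1L)
    nxt <- c(2L, 3L, 4L, 1L)
    mid2 <- (pos2 + pos2[nxt, , drop = FALSE]) / 2
    seg_mats <- lapply(segs, function(s) {
      m <- mid2[s, , drop = FALSE]
      dimnames(m) <- list(NULL, c("u", "v"))
      # published table is undirected: order endpoints deterministically
      if (m[1, 1] > m[2, 1] || (m[1, 1] == m[2, 1] && m[1, 2] > m[2, 2]))
        m <- m[2:1, , drop = FALSE]
      m
    })
    out[[idx + 1L]] <- list(index = idx, corner_states = st_bit,
                            segments = seg_mats)
  }
  names(out) <- as.character(0:15)
  .ccmark_cache$ms_table <- out
  out
}

# The six cube faces with the metadata the table generator needs:
# corner ids in cycle order consistent with an outward right-handed
# (u, v, w) frame, the 2D corner positions, and the cycle position of the
# saddle-rule corner (minimal along both spanning axes).
.mc_faces <- function() {
  if (!is.null(.ccmark_cache$faces)) return(.ccmark_cache$faces)
  pos <- mc_corner_coords()
  cyc3 <- list(c(2L, 3L), c(3L, 1L), c(1L, 2L))  # +x->(y,z), +y->(z,x), +z->(x,y)
  faces <- list()
  pos2 <- cbind(c(0, 1, 1, 0), c(0, 0, 1, 1))
  for (a in 1:3) for (s in 0:1) {
    uv <- cyc3[[a]]
    if (s == 0L) uv <- rev(uv)                   # outward normal is -e_a
    corners <- integer(4)
    for (k in 1:4) {
      coords <- integer(3)
      coords[a] <- s
      coords[uv[1]] <- pos2[k, 1]
      coords[uv[2]] <- pos2[k, 2]
      corners[k] <- coords[1] + 2L * coords[2] + 4L * coords[3]
    }
    # saddle corner: minimal along both spanning axes (shared with the
    # neighbouring cell, so the resolution is globally consistent)
    span <- setdiff(1:3, a)
    sel <- pos[corners + 1L, span[1]] == 0L & pos[corners + 1L, span[2]] == 0L
    faces[[length(faces) + 1L]] <- list(corners = corners, pos2 = pos2,
                                        sep = which(sel))
  }
  .ccmark_cache$faces <- faces
  faces
}

# Internal: triangle table for all 256 cube configurations.
# Returns a list; element idx+1 is an n x 3 integer matrix of edge ids
# (1..12), triangles oriented so normals point from inside to outside.
.mc_tri_table <- function() {
  if (!is.null(.ccmark_cache$tri_table)) return(.ccmark_cache$tri_table)
  faces <- .mc_faces()
  nxt <- c(2L, 3L, 4L, 1L)
  # per face, per cycle slot: the cube edge id that midpoint slot maps to
  face_edge_ids <- lapply(faces, function(f)
    vapply(1:4, function(k) .mc_edge_id(f$corners[k], f$corners[nxt[k]]), 1L))
  tab <- vector("list", 256L)
  for (idx in 0:255) {
    st <- bitwAnd(idx, 2L^(0:7)) > 0L
    from <- integer(0); to <- integer(0)
    for (fi in seq_along(faces)) {
      f <- faces[[fi]]
      segs <- .ms_face_segments(st[f$corners + 1L], f$pos2, f$sep)
      for (s in segs) {
        from <- c(from, face_edge_ids[[fi]][s[1]])
        to <- c(to, face_edge_ids[[fi]][s[2]])
      }
    }
    if (length(from) == 0L) { tab[[idx + 1L]] <- matrix(0L, 0L, 3L); next }
    stopifnot(!anyDuplicated(from), !anyDuplicated(to))  # chainable
    succ <- integer(12L); succ[from] <- to
    used <- logical(12L)
    tris <- list()
    for (st_edge in from) {
      if (used[st_edge]) next
      loop <- st_edge; used[st_edge] <- TRUE
      e <- succ[st_edge]
      while (e != st_edge) { loop <- c(loop, e); used[e] <- TRUE; e <- succ[e] }
      loop <- rev(loop)  # emitted normals then point inside -> outside
      # anchor the fan at the smallest edge id so a complemented
      # configuration (reversed loop) triangulates with the same diagonals
      m <- which.min(loop)
      if (m > 1L) loop <- c(loop[m:length(loop)], loop[1:(m - 1L)])
      if (length(loop) >= 3L)
        for (k in 2:(length(loop) - 1L))
          tris[[length(tris) + 1L]] <- loop[c(1L, k, k + 1L)]
    }
    tab[[idx + 1L]] <- matrix(unlist(tris), ncol = 3L, byrow = TRUE)
  }
  # orientation sanity: corner 0 inside -> normal points away from corner 0
  t1 <- tab[[2L]]
  et <- mc_edge_table()
  v <- as.matrix(et[t1[1, ], c("mx", "my", "mz")])
  n <- crossprod_3(v[2, ] - v[1, ], v[3, ] - v[1, ])
  stopifnot(sum(n * c(1, 1, 1)) > 0)
  .ccmark_cache$tri_table <- tab
  tab
}

# 3-vector cross product.
crossprod_3 <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2],
    a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}

#' Marching-cubes case dictionary
#'
#' All 256 configurations of a binary cell mapped to oriented triangle
#' sets with vertices at edge midpoints.  The table is generated
#' programmatically: every face of the cell contributes its
#' marching-squares segments (saddles resolved by the geometric
#' minimal-corner rule, identically for the two cells sharing the face),
#' the directed segments are chained into closed loops on the cell
#' boundary, and each loop is fan-triangulated.  By construction the
#' surface in every cell separates inside from outside corners, meshes
#' assembled from it are watertight on closed components, and
#' complementary configurations yield the same triangles with opposite
#' orientation.
#'
#' @return A list of 256 entries (names `"0"`..`"255"`).  Entry `i` holds
#'   `index`, `corner_states` (logical[8]), `edges`: an n x 3 integer
#'   matrix of edge ids into [mc_edge_table()], and `triangles`: a list of
#'   3 x 3 coordinate matrices (one vertex per row, unit-cell
#'   coordinates), oriented with outward (inside-to-outside) normals.
#' @export
#' @examples
#' tab <- marching_cubes_table()
#' nrow(tab[["0"]]$edges)    # homogeneous cell: no triangles
#' nrow(tab[["1"]]$edges)    # one corner inside: one clipped triangle
marching_cubes_table <- function() {
  tab <- .mc_tri_table()
  et <- mc_edge_table()
  mids <- as.matrix(et[, c("mx", "my", "mz")])
  out <- lapply(0:255, function(idx) {
    e <- tab[[idx + 1L]]
    list(index = idx,
         corner_states = bitwAnd(idx, 2L^(0:7)) > 0L,
         edges = e,
         triangles = lapply(seq_len(nrow(e)), function(r) {
           m <- mids[e[r, ], , drop = FALSE]
           dimnames(m) <- list(NULL, c("x", "y", "z"))
           m
         }))
  })
  names(out) <- as.character(0:255)
  out
}

# The 24 rotations of the cube as permutations of corner ids 0..7
# (value at position i+1 = image of corner i).
.mc_rotations <- function() {
  if (!is.null(.ccmark_cache$rotations)) return(.ccmark_cache$rotations)
  pos <- mc_corner_coords()
  rot_x <- matrix(c(1, 0, 0, 0, 0, -1, 0, 1, 0), 3, 3, byrow = TRUE)
  rot_z <- matrix(c(0, -1, 0, 1, 0, 0, 0, 0, 1), 3, 3, byrow = TRUE)
  apply_rot <- function(R) {
    ctr <- pos - 0.5
    img <- t(R %*% t(ctr)) + 0.5
    perm <- integer(8)
    for (i in 1:8) {
      j <- which(colSums(abs(t(pos) - img[i, ])) < 1e-9)
      perm[i] <- j - 1L
    }
    perm
  }
  gens <- list(apply_rot(rot_x), apply_rot(rot_z))
  id <- 0:7
  seen <- list(id)
  keys <- paste(id, collapse = ",")
  queue <- list(id)
  while (length(queue) > 0) {
    p <- queue[[1]]; queue <- queue[-1]
    for (g in gens) {
      q <- g[p + 1L]          # compose: corner i -> p -> g
      k <- paste(q, collapse = ",")
      if (!(k %in% keys)) {
        keys <- c(keys, k); seen <- c(seen, list(q)); queue <- c(queue, list(q))
      }
    }
  }
  stopifnot(length(seen) == 24L)
  .ccmark_cache$rotations <- seen
  seen
}

#' Count marching-cubes equivalence classes
#'
#' Brute-force canonicalization of all 256 cube configurations under the
#' 24 rotations of the cube, optionally combined with inside/outside
#' complementation.  Under rotation plus complementation the count is the
#' classic 15 unique marching-cubes patterns.
#'
#' @param symmetry `"rotation"` or `"rotation+complement"`.
#' @return Integer: the number of distinct equivalence classes.
#' @export
#' @examples
#' count_cube_equivalence_classes("rotation+complement")  # 15
count_cube_equivalence_classes <- function(symmetry = c("rotation+complement",
                                                        "rotation")) {
  symmetry <- match.arg(symmetry)
  rots <- .mc_rotations()
  canon <- integer(256L)
  for (idx in 0:255) {
    st <- bitwAnd(idx, 2L^(0:7)) > 0L
    imgs <- vapply(rots, function(p) {
      # corner i of the rotated config is inside iff its preimage was
      sti <- logical(8); sti[p + 1L] <- st
      as.integer(sum(2^(0:7)[sti]))
    }, 1L)
    if (symmetry == "rotation+complement") imgs <- c(imgs, 255L - imgs)
    canon[idx + 1L] <- min(imgs)
  }
  length(unique(canon))
}

#' Burnside count of cube-configuration classes
#'
#' Independent arithmetic cross-check of
#' [count_cube_equivalence_classes()]: averages the number of fixed
#' configurations over the symmetry group using cycle structure only
#' (a pure rotation fixes `2^cycles` configurations; a rotation composed
#' with complementation fixes `2^cycles` when all corner cycles have even
#' length and none otherwise).
#'
#' @inheritParams count_cube_equivalence_classes
#' @return The Burnside (orbit-counting) class count.
#' @export
burnside_cube_classes <- function(symmetry = c("rotation+complement",
                                               "rotation")) {
  symmetry <- match.arg(symmetry)
  rots <- .mc_rotations()
  cycle_lengths <- function(p) {
    seen <- logical(8); out <- integer(0)
    for (i in 0:7) {
      if (seen[i + 1L]) next
      len <- 0L; j <- i
      repeat {
        seen[j + 1L] <- TRUE; len <- len + 1L; j <- p[j + 1L]
        if (j == i) break
      }
      out <- c(out, len)
    }
    out
  }
  fixed <- vapply(rots, function(p) 2^length(cycle_lengths(p)), 1)
  if (symmetry == "rotation") return(as.integer(round(mean(fixed))))
  fixed_c <- vapply(rots, function(p) {
    cl <- cycle_lengths(p)
    if (all(cl %% 2L == 0L)) 2^length(cl) else 0
  }, 1)
  as.integer(round(sum(c(fixed, fixed_c)) / 48))
}
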