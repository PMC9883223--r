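# Automatic soft-tissue segmentation: global Otsu threshold plus
# largest-component selection.

#' Otsu threshold
#'
#' Histogram-based threshold maximizing between-class variance, computed
#' on a fixed equal-width binning of the observed intensity range and an
#' exhaustive scan over all bin-boundary candidate thresholds.
#' Deterministic for a fixed binning; ties are broken toward the lower
#' threshold.
#'
#' @param x Numeric samples (vector or array), or a precomputed histogram
#'   given as a list with elements `counts` (length `nbins`) and `breaks`
#'   (length `nbins + 1`).
#' @param bins Number of histogram bins when `x` holds raw samples.
#' @return The threshold value `t`; intensities `<= t` form the lower
#'   class, intensities `> t` the upper class.
#' @export
#' @examples
#' otsu_threshold(c(rnorm(100, 30, 5), rnorm(100, 200, 5)))
otsu_threshold <- function(x, bins = 256L) {
  if (is.list(x) && !is.null(x$counts) && !is.null(x$breaks)) {
    counts <- as.numeric(x$counts)
    breaks <- as.numeric(x$breaks)
    stopifnot(length(breaks) == length(counts) + 1L)
  } else {
    v <- as.numeric(x)
    v <- v[is.finite(v)]
    if (length(unique(v)) < 2L) stop("degenerate histogram: need at least two distinct intensity values")
    rng <- range(v)
    breaks <- seq(rng[1], rng[2], length.out = bins + 1L)
    bin <- pmin(pmax(findInterval(v, breaks, rightmost.closed = TRUE), 1L), bins)
    counts <- as.numeric(tabulate(bin, nbins = bins))
  }
  if (sum(counts > 0) < 2L) stop("degenerate histogram: need at least two distinct intensity values")
  mids <- (breaks[-1] + breaks[-length(breaks)]) / 2
  w <- cumsum(counts)
  m <- cumsum(counts * mids)
  total_w <- w[length(w)]
  total_m <- m[length(m)]
  # candidate k: split after bin k (classes 1..k vs k+1..n)
  k <- seq_len(length(counts) - 1L)
  w0 <- w[k]; w1 <- total_w - w0
  valid <- w0 > 0 & w1 > 0
  bcv <- rep(-Inf, length(k))
  mu0 <- m[k][valid] / w0[valid]
  mu1 <- (total_m - m[k][valid]) / w1[valid]
  bcv[valid] <- w0[valid] * w1[valid] * (mu0 - mu1)^2
  best <- which.max(bcv)          # which.max takes the first (lowest) maximum
  breaks[best + 1L]               # boundary between bin `best` and `best + 1`
}

#' Binarize soft tissue
#'
#' Applies a single global Otsu threshold to the whole volume, labels the
#' tissue class as foreground, and keeps only the largest 26-connected
#' foreground component, discarding disconnected specks.
#'
#' @param volume A [cbct_volume()].
#' @param invert By default the lower-intensity class is treated as
#'   background (air); set `TRUE` when the contrast is inverted so that
#'   tissue is the darker class.  The paper-style display inversion of
#'   binarized slices is a presentation detail and does not change the
#'   mask.
#' @param bins Histogram bins for the Otsu scan.
#' @return An object of class `tissue_mask`: logical `data` grid of the
#'   same shape and spacing as the volume, plus `threshold_used`.
#' @export
binarize_soft_tissue <- function(volume, invert = FALSE, bins = 256L) {
  stopifnot(inherits(volume, "cbct_volume"))
  thr <- otsu_threshold(volume$data, bins = bins)
  fg <- if (invert) volume$data <= thr else volume$data > thr
  if (!any(fg)) stop("no tissue found: empty foreground after thresholding")
  fg <- largest_connected_component(fg)
  structure(list(data = fg, spacing = volume$spacing, threshold_used = thr),
            class = "tissue_mask")
}

#' @export
print.tissue_mask <- function(x, ...) {
  cat(sprintf("tissue_mask: %s voxels, %d foreground, threshold %.4g\n",
              paste(dim(x$data), collapse = " x "), sum(x$data),
              x$threshold_used))
  invisible(x)
}

#' Largest 26-connected component of a binary grid
#'
#' 26-connectivity (faces, edges and corners) avoids spurious
#' fragmentation of thin structures such as nostril rims.
#'
#' @param fg 3D logical array.
#' @return Logical array retaining only the largest component (ties
#'   broken toward the component discovered first in scan order).
#' @export
largest_connected_component <- function(fg) {
  stopifnot(is.logical(fg), length(dim(fg)) == 3L)
  d <- dim(fg)
  idx_fg <- which(fg)
  if (length(idx_fg) == 0L) stop("no tissue found: empty foreground")
  id_of <- integer(prod(d))
  id_of[idx_fg] <- seq_along(idx_fg)
  offsets <- as.matrix(expand.grid(dx = -1:1, dy = -1:1, dz = -1:1))
  offsets <- offsets[rowSums(abs(offsets)) > 0, , drop = FALSE]
  # keep each unordered neighbour pair once (lexicographically positive shift)
  pos <- offsets[offsets[, 1] > 0 |
                   (offsets[, 1] == 0 & offsets[, 2] > 0) |
                   (offsets[, 1] == 0 & offsets[, 2] == 0 & offsets[, 3] > 0), ,
                 drop = FALSE]
  edges <- vector("list", nrow(pos))
  for (r in seq_len(nrow(pos))) {
    o <- pos[r, ]
    xr <- max(1, 1 - o[1]):min(d[1], d[1] - o[1])
    yr <- max(1, 1 - o[2]):min(d[2], d[2] - o[2])
    zr <- max(1, 1 - o[3]):min(d[3], d[3] - o[3])
    a <- fg[xr, yr, zr, drop = FALSE]
    b <- fg[xr + o[1], yr + o[2], zr + o[3], drop = FALSE]
    both <- a & b
    if (!any(both)) next
    w <- which(both)
    sub <- arrayInd(w, dim(both))
    lin_a <- (sub[, 1] + xr[1] - 1) + (sub[, 2] + yr[1] - 2) * d[1] +
      (sub[, 3] + zr[1] - 2) * d[1] * d[2]
    lin_b <- lin_a + o[1] + o[2] * d[1] + o[3] * d[1] * d[2]
    edges[[r]] <- rbind(id_of[lin_a], id_of[lin_b])
  }
  ev <- unlist(edges, use.names = FALSE)
  g <- igraph::make_graph(if (is.null(ev)) integer(0) else ev,
                          n = length(idx_fg), directed = FALSE)
  comp <- igraph::components(g)
  keep <- which.max(comp$csize)
  out <- array(FALSE, d)
  out[idx_fg[comp$membership == keep]] <- TRUE
  out
}
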