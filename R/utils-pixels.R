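# Low-level pixel helpers shared across the imaging and skeleton code.
# Convention throughout: matrices are indexed (row, col), 1-based, origin at
# the image top-left, row increasing downwards.

SQRT2 <- sqrt(2)

#' @keywords internal
#' @noRd
.shiftMat <- function(m, dr, dc) {
  # Shift a matrix by (dr, dc) with replicated (clamped) borders.
  nr <- nrow(m); nc <- ncol(m)
  ri <- pmin(pmax(seq_len(nr) - dr, 1L), nr)
  ci <- pmin(pmax(seq_len(nc) - dc, 1L), nc)
  m[ri, ci, drop = FALSE]
}

#' @noRd
.pixelKey <- function(px, nr) {
  # Unique numeric key for (row, col) pairs given the number of rows.
  as.numeric(px[, 1L]) + (as.numeric(px[, 2L]) - 1) * as.numeric(nr)
}

# 8-neighbourhood offsets, row/col
.NBR8 <- cbind(
  dr = c(-1L, -1L, -1L, 0L, 0L, 1L, 1L, 1L),
  dc = c(-1L, 0L, 1L, -1L, 1L, -1L, 0L, 1L)
)

#' Geodesic (chamfer) length of a pixel polyline
#'
#' Sums 1 for orthogonal and sqrt(2) for diagonal steps between consecutive
#' pixels of an 8-connected pixel path.
#'
#' @param poly integer matrix with two columns (row, col); consecutive rows
#'   must be 8-neighbours.
#' @return numeric length in pixels (0 for a single pixel).
#' @export
chamferLength <- function(poly) {
  poly <- as.matrix(poly)
  if (nrow(poly) < 2L) return(0)
  dr <- abs(diff(poly[, 1L]))
  dc <- abs(diff(poly[, 2L]))
  if (any(dr > 1L | dc > 1L | (dr + dc) == 0L))
    stop("polyline steps must be between distinct 8-neighbouring pixels")
  sum(ifelse(dr == 1L & dc == 1L, SQRT2, 1))
}

#' Rasterize a straight segment between two pixels (Bresenham)
#'
#' @param p0,p1 integer (row, col) endpoints.
#' @return integer matrix of pixels from `p0` to `p1` inclusive.
#' @export
bresenhamLine <- function(p0, p1) {
  r0 <- as.integer(p0[1L]); c0 <- as.integer(p0[2L])
  r1 <- as.integer(p1[1L]); c1 <- as.integer(p1[2L])
  dr <- abs(r1 - r0); dc <- abs(c1 - c0)
  sr <- sign(r1 - r0); sc <- sign(c1 - c0)
  n <- max(dr, dc) + 1L
  out <- matrix(0L, n, 2L)
  err <- dc - dr
  r <- r0; c <- c0
  for (i in seq_len(n)) {
    out[i, ] <- c(r, c)
    if (r == r1 && c == c1) break
    e2 <- 2L * err
    if (e2 > -dr) { err <- err - dr; c <- c + sc }
    if (e2 < dc) { err <- err + dc; r <- r + sr }
  }
  out[seq_len(i), , drop = FALSE]
}

#' @noRd
.dedupePath <- function(px) {
  # Drop consecutive duplicate pixels from a pixel path.
  if (nrow(px) < 2L) return(px)
  keep <- c(TRUE, rowSums(abs(diff(px))) > 0L)
  px[keep, , drop = FALSE]
}

#' @noRd
.rasterizePolyline <- function(pts) {
  # Rasterize a polyline given real-valued vertices (n x 2, row/col):
  # round vertices, Bresenham-connect consecutive distinct pixels, dedupe.
  pix <- round(pts)
  pix <- .dedupePath(matrix(as.integer(pix), ncol = 2L))
  if (nrow(pix) == 1L) return(pix)
  segs <- vector("list", nrow(pix) - 1L)
  for (i in seq_len(nrow(pix) - 1L)) {
    seg <- bresenhamLine(pix[i, ], pix[i + 1L, ])
    segs[[i]] <- seg[-1L, , drop = FALSE]
  }
  .dedupePath(rbind(pix[1L, , drop = FALSE], do.call(rbind, segs)))
}

#' @noRd
.unionFind <- function(n) {
  parent <- seq_len(n)
  find <- function(x) {
    while (parent[x] != x) {
      parent[x] <<- parent[parent[x]]
      x <- parent[x]
    }
    x
  }
  union <- function(a, b) {
    ra <- find(a); rb <- find(b)
    if (ra != rb) parent[max(ra, rb)] <<- min(ra, rb)
  }
  list(find = find, union = union, roots = function() vapply(seq_len(n), find, 1L))
}
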