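# Morphological thinning and skeleton-pixel classification.

#' Thin a binary mask to a one-pixel-wide skeleton
#'
#' Iterative two-subfield thinning (Zhang-Suen) run to a fixpoint, so the
#' operation is idempotent: thinning an already thin structure returns it
#' unchanged. The result preserves 8-connectivity of each component.
#'
#' @param mask integer/logical matrix; nonzero = foreground.
#' @return integer 0/1 matrix of the same dimensions.
#' @export
thinMask <- function(mask) {
  p <- matrix(as.integer(mask != 0), nrow(mask), ncol(mask))
  nr <- nrow(p); nc <- ncol(p)
  # pad with a background frame so neighbour shifts never wrap
  pad <- matrix(0L, nr + 2L, nc + 2L)
  pad[2:(nr + 1L), 2:(nc + 1L)] <- p
  p <- pad
  nbr <- function(m, dr, dc) {
    m[(2:(nr + 1L)) + dr, (2:(nc + 1L)) + dc, drop = FALSE]
  }
  repeat {
    changed <- FALSE
    for (step in 1:2) {
      core <- p[2:(nr + 1L), 2:(nc + 1L), drop = FALSE]
      p2 <- nbr(p, -1L, 0L); p3 <- nbr(p, -1L, 1L); p4 <- nbr(p, 0L, 1L)
      p5 <- nbr(p, 1L, 1L); p6 <- nbr(p, 1L, 0L); p7 <- nbr(p, 1L, -1L)
      p8 <- nbr(p, 0L, -1L); p9 <- nbr(p, -1L, -1L)
      B <- p2 + p3 + p4 + p5 + p6 + p7 + p8 + p9
      A <- (p2 == 0L & p3 == 1L) + (p3 == 0L & p4 == 1L) +
        (p4 == 0L & p5 == 1L) + (p5 == 0L & p6 == 1L) +
        (p6 == 0L & p7 == 1L) + (p7 == 0L & p8 == 1L) +
        (p8 == 0L & p9 == 1L) + (p9 == 0L & p2 == 1L)
      if (step == 1L) {
        cond <- core == 1L & B >= 2L & B <= 6L & A == 1L &
          (p2 * p4 * p6) == 0L & (p4 * p6 * p8) == 0L
      } else {
        cond <- core == 1L & B >= 2L & B <= 6L & A == 1L &
          (p2 * p4 * p8) == 0L & (p2 * p6 * p8) == 0L
      }
      if (any(cond)) {
        changed <- TRUE
        core[cond] <- 0L
        p[2:(nr + 1L), 2:(nc + 1L)] <- core
      }
    }
    if (!changed) break
  }
  p[2:(nr + 1L), 2:(nc + 1L), drop = FALSE]
}

#' Skeletonize a segmented region
#'
#' Thins the region's pixel set to a one-pixel-wide, 8-connected skeleton
#' lying inside the region.
#'
#' @param region a [PlantRegion-class].
#' @return a [Skeleton-class].
#' @export
skeletonize <- function(region) {
  px <- region@pixels
  bb <- region@bbox
  h <- bb[3L] - bb[1L] + 1L
  w <- bb[4L] - bb[2L] + 1L
  m <- matrix(0L, h, w)
  m[cbind(px[, 1L] - bb[1L] + 1L, px[, 2L] - bb[2L] + 1L)] <- 1L
  sk <- thinMask(m)
  keep <- which(sk == 1L, arr.ind = TRUE)
  if (nrow(keep) < 2L)
    stop("too-small-object: skeleton has fewer than 2 pixels")
  out <- cbind(row = keep[, 1L] + bb[1L] - 1L, col = keep[, 2L] + bb[2L] - 1L)
  out <- out[order(out[, 1L], out[, 2L]), , drop = FALSE]
  new("Skeleton", pixels = matrix(as.integer(out), ncol = 2L,
                                  dimnames = list(NULL, c("row", "col"))),
      sourceRegionId = region@id)
}

#' @noRd
.skeletonAdjacency <- function(px) {
  # Neighbour lists (8-connectivity restricted to skeleton pixels).
  n <- nrow(px)
  nr <- max(px[, 1L]) + 2L
  keys <- .pixelKey(px, nr)
  ord <- order(keys)
  skeys <- keys[ord]
  from <- integer(0); to <- integer(0)
  for (k in seq_len(nrow(.NBR8))) {
    nk <- .pixelKey(cbind(px[, 1L] + .NBR8[k, 1L], px[, 2L] + .NBR8[k, 2L]), nr)
    hit <- match(nk, skeys)
    found <- which(!is.na(hit))
    from <- c(from, found)
    to <- c(to, ord[hit[found]])
  }
  unname(split(to, factor(from, levels = seq_len(n))))
}

#' Classify skeleton pixels
#'
#' Each skeleton pixel is a terminal node, a branching node, or an edge
#' point according to whether it has one, more than two, or exactly two
#' 8-neighbours within the skeleton.
#'
#' @param skel a [Skeleton-class] (or a pixel matrix).
#' @return character vector (`"terminal"`, `"edge"`, `"branching"`), one
#'   entry per skeleton pixel, in pixel order.
#' @export
classifySkeletonPixels <- function(skel) {
  px <- if (is(skel, "Skeleton")) skel@pixels else as.matrix(skel)
  if (nrow(px) < 2L) stop("too-small-object: need at least 2 skeleton pixels")
  deg <- lengths(.skeletonAdjacency(px))
  if (any(deg == 0L))
    stop("too-small-object: isolated skeleton pixel (0 neighbours)")
  ifelse(deg == 1L, "terminal", ifelse(deg == 2L, "edge", "branching"))
}
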