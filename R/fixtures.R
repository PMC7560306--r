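# Deterministic synthetic plate scans with exact per-organ ground truth.
#
# The generator emulates the imaging protocol the pipeline was designed
# for: dissected seedlings laid flat and non-overlapping on an agar plate,
# scanned in colour over a blue background, with a physical scale bar in a
# lower corner. Strokes are rendered without anti-aliasing so the
# foreground truth is exact; seeded salt noise is added only after the
# truth is captured. Ground-truth organ lengths are recorded as the digital
# (chamfer) arc length of the rasterized centerline - the quantity a
# skeleton geodesic measures - alongside the Euclidean arc length.

#' @noRd
.withSeed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else suppressWarnings(rm(".Random.seed", envir = globalenv()))
  })
  set.seed(seed)
  force(code)
}

#' @noRd
.curvePoints <- function(start, angle0, turn, length, step = 1.5) {
  # Constant-speed curve with linearly varying heading.
  # angle 0 = straight up (towards smaller rows); positive leans to +col.
  n <- max(2L, ceiling(length / step))
  s <- (seq_len(n) - 0.5) / n
  th <- angle0 + turn * s
  dl <- length / n
  pts <- cbind(start[1L] + cumsum(-cos(th) * dl),
               start[2L] + cumsum(sin(th) * dl))
  unname(rbind(matrix(start, 1L), pts))
}

#' @noRd
.endHeading <- function(angle0, turn) angle0 + turn

#' @noRd
.euclidLength <- function(pts) {
  sum(sqrt(rowSums(diff(pts)^2)))
}

#' Build one synthetic plant specification
#'
#' Lays out organ centerlines for a seedling with `nLeaves` open leaves:
#' a near-vertical internode, short culm segments between leaf junctions,
#' one hanging leaf per junction on alternating sides, and a terminal
#' blade continuing the main axis (the longest leaf, so the shoot top is
#' its tip). A plant with a single leaf is branchless: internode and blade
#' form one unbranched curve. Organ sizes default to the magnitudes of
#' 7-day-old rice seedlings at roughly 10 px/mm.
#'
#' @param nLeaves integer 1..4.
#' @param base numeric (row, col) of the shoot base.
#' @param startSide +1 or -1, side of the first hanging leaf.
#' @param strokeWidthPx rendered stroke width.
#' @param withTick draw a short plate grid-line tick crossing the internode
#'   near the base (creates two sub-threshold spurs, exercising pruning)?
#' @return a `plantSpec` list with `organs` (role, pts, width), `nLeaves`,
#'   `base`.
#' @export
randomPlantSpec <- function(nLeaves, base, startSide = 1,
                            strokeWidthPx = 3, withTick = TRUE) {
  stopifnot(nLeaves >= 1, nLeaves <= 4)
  organs <- list()
  a0 <- stats::runif(1, -0.06, 0.06)
  tw <- stats::runif(1, -0.08, 0.08)
  internodeLen <- stats::runif(1, 280, 330)
  intPts <- .curvePoints(base, a0, tw, internodeLen)
  organs[[1L]] <- list(role = "internode", pts = intPts, width = strokeWidthPx)
  cur <- intPts[nrow(intPts), ]
  curHead <- .endHeading(a0, tw)
  side <- startSide
  if (nLeaves == 1L) {
    bl <- .curvePoints(cur, curHead + stats::runif(1, -0.05, 0.05),
                       stats::runif(1, -0.15, 0.15), stats::runif(1, 200, 250))
    organs[[2L]] <- list(role = "blade", pts = bl, width = strokeWidthPx)
  } else {
    for (k in seq_len(nLeaves - 1L)) {
      hangLen <- stats::runif(1, 150, 195) * 0.95^(k - 1L)
      ha <- side * stats::runif(1, 0.8, 1.15)
      organs[[length(organs) + 1L]] <- list(
        role = "leaf", junction = k, width = strokeWidthPx,
        pts = .curvePoints(cur, ha, side * stats::runif(1, 0.05, 0.3), hangLen))
      side <- -side
      if (k < nLeaves - 1L) {
        culmLen <- stats::runif(1, 38, 55)
        ca <- curHead + stats::runif(1, -0.04, 0.04)
        ct <- stats::runif(1, -0.05, 0.05)
        cp <- .curvePoints(cur, ca, ct, culmLen)
        organs[[length(organs) + 1L]] <- list(role = "culm", junction = k,
                                              pts = cp, width = strokeWidthPx)
        cur <- cp[nrow(cp), ]
        curHead <- .endHeading(ca, ct)
      }
    }
    ta <- curHead + stats::runif(1, -0.05, 0.05)
    organs[[length(organs) + 1L]] <- list(
      role = "terminal", junction = nLeaves - 1L, width = strokeWidthPx,
      pts = .curvePoints(cur, ta, stats::runif(1, -0.08, 0.08),
                         stats::runif(1, 210, 250)))
  }
  if (withTick) {
    h <- stats::runif(1, 35, 58)  # arc height of the tick crossing
    idx <- max(2L, min(nrow(intPts), round(h / (internodeLen / (nrow(intPts) - 1L)))))
    ctr <- intPts[idx, ]
    lt <- stats::runif(1, 11, 20); rt <- stats::runif(1, 11, 20)
    organs[[length(organs) + 1L]] <- list(
      role = "tick", width = 2,
      pts = rbind(c(ctr[1L], ctr[2L] - lt), ctr, c(ctr[1L], ctr[2L] + rt)))
  }
  structure(list(organs = organs, nLeaves = nLeaves, base = base,
                 strokeWidthPx = strokeWidthPx),
            class = "plantSpec")
}

#' Scene specification for the synthetic generator
#'
#' @param canvasH,canvasW canvas size in pixels (`canvasW = NA` sizes the
#'   canvas from the number of plants).
#' @param backgroundRGB plate background colour (blue, as in the imaging
#'   protocol).
#' @param plantRGB stroke colour of plant tissue (green).
#' @param barWidthPx,barLengthMM scale-bar extent in pixels and physical
#'   length (2 cm by default).
#' @param barCorner `"left"` or `"right"` lower corner.
#' @param noiseLevel fraction of pixels replaced by white salt noise after
#'   truth capture.
#' @param seed integer seed fixing every random draw.
#' @return a `sceneSpec` list.
#' @export
sceneSpec <- function(canvasH = 800, canvasW = NA,
                      backgroundRGB = c(45, 75, 180),
                      plantRGB = c(60, 170, 80),
                      barWidthPx = 200, barLengthMM = 20,
                      barCorner = "left", noiseLevel = 0.01, seed = 1) {
  structure(list(canvasH = canvasH, canvasW = canvasW,
                 backgroundRGB = backgroundRGB, plantRGB = plantRGB,
                 barWidthPx = barWidthPx, barLengthMM = barLengthMM,
                 barCorner = barCorner, noiseLevel = noiseLevel, seed = seed),
            class = "sceneSpec")
}

#' @noRd
.stamp <- function(mask, chain, width) {
  r <- (width - 1) / 2
  offs <- expand.grid(dr = -ceiling(r):ceiling(r), dc = -ceiling(r):ceiling(r))
  offs <- offs[offs$dr^2 + offs$dc^2 <= (width / 2)^2 | (abs(offs$dr) <= r & abs(offs$dc) <= r), , drop = FALSE]
  nr <- nrow(mask); nc <- ncol(mask)
  for (i in seq_len(nrow(offs))) {
    rr <- chain[, 1L] + offs$dr[i]
    cc <- chain[, 2L] + offs$dc[i]
    ok <- rr >= 1L & rr <= nr & cc >= 1L & cc <= nc
    mask[cbind(rr[ok], cc[ok])] <- 1L
  }
  mask
}

#' @noRd
.sceneGeometry <- function(nPlants, scene, spacing = 360, sideMargin = 200) {
  barPadCols <- scene$barWidthPx + 24
  off <- barPadCols + sideMargin
  W <- if (is.na(scene$canvasW)) off + spacing * (nPlants - 1L) + sideMargin else scene$canvasW
  H <- scene$canvasH
  frac <- max((scene$barWidthPx + 24) / W, 72 / H)
  frac <- min(0.5, frac)
  baseCols <- off + spacing * (seq_len(nPlants) - 1L)
  if (scene$barCorner == "right") baseCols <- W - baseCols + 1
  list(H = H, W = W, cornerWindowFrac = frac, baseCols = baseCols,
       baseRow = H - 58)
}

#' @noRd
.renderScene <- function(specs, scene, H, W, frac, fgRGB, bgRGB, barRGB) {
  canvas <- array(0, dim = c(H, W, 3L))
  for (ch in 1:3) canvas[, , ch] <- bgRGB[ch]
  fgMask <- matrix(0L, H, W)
  chains <- vector("list", length(specs))
  for (i in seq_along(specs)) {
    sp <- specs[[i]]
    orgChains <- lapply(sp$organs, function(o) .rasterizePolyline(o$pts))
    chains[[i]] <- orgChains
    for (j in seq_along(sp$organs))
      fgMask <- .stamp(fgMask, orgChains[[j]], sp$organs[[j]]$width)
  }
  # scene validity: plants must fit and not touch each other
  if (length(specs) > 1L) {
    allPts <- lapply(seq_along(specs), function(i)
      do.call(rbind, chains[[i]]))
    for (i in seq_along(specs)) for (j in seq_along(specs)) {
      if (j <= i) next
      minGap <- specs[[i]]$strokeWidthPx + 3
      a <- allPts[[i]]; b <- allPts[[j]]
      # coarse check on subsampled points
      ai <- a[seq(1L, nrow(a), by = 2L), , drop = FALSE]
      bi <- b[seq(1L, nrow(b), by = 2L), , drop = FALSE]
      dmin <- min(vapply(seq_len(nrow(ai)), function(k)
        min(abs(bi[, 1L] - ai[k, 1L]) + abs(bi[, 2L] - ai[k, 2L])), 0))
      if (dmin < minGap)
        stop("invalid-scene: plant strokes overlap or touch")
    }
  }
  anyOut <- vapply(seq_along(specs), function(i) {
    p <- do.call(rbind, chains[[i]])
    any(p[, 1L] < 4 | p[, 1L] > H - 3 | p[, 2L] < 4 | p[, 2L] > W - 3)
  }, TRUE)
  if (any(anyOut)) stop("invalid-scene: plant does not fit on the canvas")
  for (ch in 1:3) {
    pl <- canvas[, , ch]
    pl[fgMask == 1L] <- fgRGB[ch]
    canvas[, , ch] <- pl
  }
  # scale bar in the configured lower corner
  barH <- 24L
  rows <- (H - 40L):(H - 40L + barH - 1L)
  cols <- if (scene$barCorner == "left") 12:(12 + scene$barWidthPx - 1L)
          else (W - 11L - scene$barWidthPx + 1L):(W - 11L)
  for (ch in 1:3) canvas[rows, cols, ch] <- barRGB[ch]
  list(canvas = canvas, fgMask = fgMask, chains = chains,
       barWidthPx = length(cols))
}

#' @noRd
.leafSplitLength <- function(sp, orgChains, leafIdx) {
  # Analytic skeletal length of a leaf rendered at stroke width w: the
  # medial axis of the union of two width-w strokes separates where their
  # centerlines are more than w apart, so the leaf's skeletal arc runs
  # from that split point to the tip. Computed on the rasterized
  # centerline chain against the sample points of all other organs.
  w <- sp$organs[[leafIdx]]$width
  chain <- orgChains[[leafIdx]]
  others <- do.call(rbind, lapply(seq_along(sp$organs)[-leafIdx], function(j) {
    p <- sp$organs[[j]]$pts
    # densify so centerline separation is sampled finely
    mid <- (p[-1L, , drop = FALSE] + p[-nrow(p), , drop = FALSE]) / 2
    rbind(p, mid)
  }))
  dmin <- vapply(seq_len(nrow(chain)), function(k)
    sqrt(min((others[, 1L] - chain[k, 1L])^2 + (others[, 2L] - chain[k, 2L])^2)),
    0)
  split <- which(dmin > w)
  from <- if (length(split)) split[1L] else 1L
  len <- chamferLength(chain[from:nrow(chain), , drop = FALSE])
  if (from > 1L) {
    # sub-pixel: interpolate the crossing inside the step before `from`
    step <- chamferLength(chain[(from - 1L):from, , drop = FALSE])
    f <- (w - dmin[from - 1L]) / max(dmin[from] - dmin[from - 1L], 1e-9)
    len <- len + step * (1 - min(max(f, 0), 1))
  }
  len
}

#' @noRd
.plantTruth <- function(sp, orgChains, mmpp) {
  roles <- vapply(sp$organs, `[[`, "", "role")
  chamf <- vapply(orgChains, chamferLength, 0)
  eucl <- vapply(sp$organs, function(o) .euclidLength(o$pts), 0)
  if (sp$nLeaves == 1L) {
    shootPx <- sum(chamf[roles %in% c("internode", "blade")])
    truthLeaves <- numeric(0)
    internodePx <- shootPx
    leafCount <- 0L
  } else {
    internodePx <- chamf[roles == "internode"]
    shootPx <- internodePx + sum(chamf[roles == "culm"]) +
      chamf[roles == "terminal"]
    nJ <- sp$nLeaves - 1L
    leafIdxs <- which(roles == "leaf")
    hangJ <- vapply(sp$organs[leafIdxs], `[[`, 0L, "junction")
    hangLen <- vapply(leafIdxs[order(hangJ)], function(j)
      .leafSplitLength(sp, orgChains, j), 0)
    termLen <- .leafSplitLength(sp, orgChains, which(roles == "terminal"))
    truthLeaves <- numeric(0)
    for (k in seq_len(nJ)) {
      atJ <- hangLen[k]
      if (k == nJ) {
        pair <- sort(c(atJ, termLen), decreasing = TRUE)
        truthLeaves <- c(truthLeaves, pair)
      } else {
        truthLeaves <- c(truthLeaves, atJ)
      }
    }
    leafCount <- sp$nLeaves
  }
  list(leafCount = leafCount,
       internodePx = unname(internodePx), shootPx = unname(shootPx),
       leafPx = unname(truthLeaves),
       internodeMM = unname(internodePx * mmpp),
       shootMM = unname(shootPx * mmpp),
       leafMM = unname(truthLeaves * mmpp),
       euclideanOrganPx = setNames(eucl, roles),
       base = round(sp$base))
}

#' Render a synthetic seedling scene with ground truth
#'
#' Renders the given plant specs over a blue background with a corner
#' scale bar, captures the exact foreground mask and per-organ ground-truth
#' lengths, then adds seeded salt noise. Identical specs and seed give
#' bit-identical images.
#'
#' @param specs list of `plantSpec`s (see [randomPlantSpec()]).
#' @param scene a [sceneSpec()].
#' @return list with `image` (raster array 0..255), `truth` (a
#'   [SceneTruth-class]) and `cornerWindowFrac` (the corner-window fraction
#'   that contains the rendered bar, for the analysis config).
#' @export
makeSeedlingScene <- function(specs, scene = sceneSpec()) {
  geom <- .sceneGeometry(length(specs), scene)
  .withSeed(scene$seed + 1543L, {
    rend <- .renderScene(specs, scene, geom$H, geom$W, geom$cornerWindowFrac,
                         fgRGB = scene$plantRGB, bgRGB = scene$backgroundRGB,
                         barRGB = c(10, 10, 10))
    mmpp <- scene$barLengthMM / rend$barWidthPx
    plants <- lapply(seq_along(specs), function(i)
      .plantTruth(specs[[i]], rend$chains[[i]], mmpp))
    img <- rend$canvas
    if (scene$noiseLevel > 0) {
      n <- round(scene$noiseLevel * geom$H * geom$W)
      idx <- sample.int(geom$H * geom$W, n)
      for (ch in 1:3) {
        pl <- img[, , ch]
        pl[idx] <- 255
        img[, , ch] <- pl
      }
    }
    truth <- new("SceneTruth", plants = plants, mask = rend$fgMask,
                 barWidthPx = as.numeric(rend$barWidthPx),
                 barLengthMM = scene$barLengthMM, seed = as.numeric(scene$seed))
    list(image = img, truth = truth, cornerWindowFrac = geom$cornerWindowFrac)
  })
}

#' Generate a fully random seedling scene
#'
#' Draws plant specs (leaf counts, organ lengths, angles, curvature) from
#' the given seed and renders them with [makeSeedlingScene()].
#'
#' @param nPlants number of plants.
#' @param leaves integer vector (recycled) of leaves per plant, 1..4.
#' @param scene a [sceneSpec()]; its seed drives every draw.
#' @param withTick draw artifact grid ticks crossing the internodes?
#' @return as [makeSeedlingScene()].
#' @export
randomSeedlingScene <- function(nPlants = 1, leaves = 2,
                                scene = sceneSpec(), withTick = TRUE) {
  leaves <- rep_len(leaves, nPlants)
  geom <- .sceneGeometry(nPlants, scene)
  specs <- .withSeed(scene$seed, lapply(seq_len(nPlants), function(i)
    randomPlantSpec(leaves[i], base = c(geom$baseRow, geom$baseCols[i]),
                    startSide = if (i %% 2L == 1L) 1 else -1,
                    withTick = withTick)))
  c(makeSeedlingScene(specs, scene), list(specs = specs))
}

#' Render a synthetic coleoptile scene with ground truth
#'
#' Coleoptiles are unbranched, so each spec is a single curved organ.
#' Strokes are pale on a dark plate, suited to grayscale Otsu segmentation;
#' the scale bar is rendered pale as well.
#'
#' @param specs list of `plantSpec`s with a single `coleoptile` organ (see
#'   [randomColeoptileScene()] for the generator).
#' @param scene a [sceneSpec()]; `backgroundRGB`/`plantRGB` default to a
#'   dark plate and pale tissue when left at the seedling defaults.
#' @return as [makeSeedlingScene()].
#' @export
makeColeoptileScene <- function(specs, scene = sceneSpec()) {
  bg <- if (identical(scene$backgroundRGB, c(45, 75, 180))) c(55, 55, 55) else scene$backgroundRGB
  fg <- if (identical(scene$plantRGB, c(60, 170, 80))) c(235, 232, 210) else scene$plantRGB
  geom <- .sceneGeometry(length(specs), scene, spacing = 130, sideMargin = 120)
  .withSeed(scene$seed + 2719L, {
    rend <- .renderScene(specs, scene, geom$H, geom$W, geom$cornerWindowFrac,
                         fgRGB = fg, bgRGB = bg, barRGB = c(240, 240, 240))
    mmpp <- scene$barLengthMM / rend$barWidthPx
    plants <- lapply(seq_along(specs), function(i) {
      ch <- rend$chains[[i]]
      px <- sum(vapply(ch, chamferLength, 0))
      list(leafCount = 0L, coleoptilePx = px, coleoptileMM = px * mmpp,
           base = round(specs[[i]]$base))
    })
    img <- rend$canvas
    if (scene$noiseLevel > 0) {
      n <- round(scene$noiseLevel * geom$H * geom$W)
      idx <- sample.int(geom$H * geom$W, n)
      for (chn in 1:3) {
        pl <- img[, , chn]
        pl[idx] <- 255
        img[, , chn] <- pl
      }
    }
    truth <- new("SceneTruth", plants = plants, mask = rend$fgMask,
                 barWidthPx = as.numeric(rend$barWidthPx),
                 barLengthMM = scene$barLengthMM, seed = as.numeric(scene$seed))
    list(image = img, truth = truth, cornerWindowFrac = geom$cornerWindowFrac)
  })
}

#' @rdname makeColeoptileScene
#' @param nPlants number of coleoptiles.
#' @param lengthRange arc-length range (px) coleoptile lengths are drawn
#'   from.
#' @export
randomColeoptileScene <- function(nPlants = 1, scene = sceneSpec(),
                                  lengthRange = c(180, 280)) {
  geom <- .sceneGeometry(nPlants, scene, spacing = 130, sideMargin = 120)
  specs <- .withSeed(scene$seed, lapply(seq_len(nPlants), function(i) {
    len <- stats::runif(1, lengthRange[1L], lengthRange[2L])
    pts <- .curvePoints(c(geom$baseRow, geom$baseCols[i]),
                        stats::runif(1, -0.12, 0.12),
                        stats::runif(1, -0.35, 0.35), len)
    structure(list(organs = list(list(role = "coleoptile", pts = pts,
                                      width = 3)),
                   nLeaves = 0L, base = c(geom$baseRow, geom$baseCols[i]),
                   strokeWidthPx = 3),
              class = "plantSpec")
  }))
  c(makeColeoptileScene(specs, scene), list(specs = specs))
}

#' Match ground-truth plants to detected regions
#'
#' Regions are numbered in reading order of their bounding boxes, which
#' need not equal the order plants were specified in. Matches each truth
#' plant to the region whose bounding box contains its base point.
#'
#' @param truth a [SceneTruth-class].
#' @param regions list of [PlantRegion-class] objects.
#' @return integer vector: for each truth plant, the matching region id
#'   (`NA` if undetected).
#' @export
matchTruthToRegions <- function(truth, regions) {
  vapply(truth@plants, function(p) {
    b <- p$base
    for (r in regions) {
      bb <- r@bbox
      if (b[1L] >= bb[1L] - 8 && b[1L] <= bb[3L] + 8 &&
          b[2L] >= bb[2L] - 8 && b[2L] <= bb[4L] + 8)
        return(r@id)
    }
    NA_integer_
  }, 0L)
}

#' Rasterize a skeleton test fixture from a tree specification
#'
#' Draws a one-pixel-wide tree whose nodes and edge polylines are given
#' explicitly, as a unit-test oracle for graph construction and pruning.
#' The realized edge lengths (chamfer metric) are returned as truth; the
#' rasterization is validated by rebuilding the graph and comparing node
#' kinds against the specification.
#'
#' @param treeSpec list with `nodes` (data.frame `id`, `row`, `col`,
#'   `kind`) and `edges` (list of `list(a, b, via = optional waypoint
#'   matrix)`).
#' @return list with `skeleton` (a [Skeleton-class]), `graph` (the built
#'   [PlantGraph-class]) and `edgeLengths` (chamfer truth per spec edge).
#' @export
makeSkeletonFixture <- function(treeSpec) {
  nd <- treeSpec$nodes
  chains <- lapply(treeSpec$edges, function(e) {
    pa <- unlist(nd[nd$id == e$a, c("row", "col")])
    pb <- unlist(nd[nd$id == e$b, c("row", "col")])
    pts <- rbind(pa, if (!is.null(e$via)) e$via, pb)
    .rasterizePolyline(pts)
  })
  px <- unique(do.call(rbind, chains))
  skel <- new("Skeleton",
              pixels = matrix(as.integer(px[order(px[, 1L], px[, 2L]), ]),
                              ncol = 2L, dimnames = list(NULL, c("row", "col"))),
              sourceRegionId = 1L)
  graph <- buildPlantGraph(skel)
  specCounts <- table(factor(nd$kind, levels = c("terminal", "branching")))
  gotCounts <- table(factor(graph@nodes$kind, levels = c("terminal", "branching")))
  if (!all(specCounts == gotCounts))
    stop("fixture error: rasterization created unintended adjacencies (",
         "expected ", specCounts[1L], "T/", specCounts[2L], "B, got ",
         gotCounts[1L], "T/", gotCounts[2L], "B)")
  list(skeleton = skel, graph = graph,
       edgeLengths = vapply(chains, chamferLength, 0))
}
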