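# Trait extraction from pruned plant graphs, calibration, statistics.

#' Anchor nodes of a plant graph
#'
#' The lowest node (greatest row coordinate) anchors the shoot base; the
#' highest node (smallest row) is the shoot top. Ties are broken towards
#' the smallest column.
#'
#' @param graph a [PlantGraph-class] with at least 2 nodes.
#' @return list with node ids `lowest` and `highest`.
#' @export
anchorNodes <- function(graph) {
  nd <- graph@nodes
  if (nrow(nd) < 2L) stop("measurement error: graph has fewer than 2 nodes")
  list(lowest = nd$id[order(-nd$row, nd$col)][1L],
       highest = nd$id[order(nd$row, nd$col)][1L])
}

#' Convert a pixel length to millimetres
#'
#' @param lengthPx length in pixels (>= 0).
#' @param bar a [ScaleBar-class].
#' @return length in millimetres: `lengthPx * lengthMM / widthPx`.
#' @export
pxToMM <- function(lengthPx, bar) {
  if (any(lengthPx < 0)) stop("negative length")
  lengthPx * bar@lengthMM / bar@widthPx
}

#' Measure a seedling from its pruned graph
#'
#' The main path runs from the lowest to the highest node (geodesic
#' shortest path). The total shoot length is the length of this path; the
#' internode is its basal segment up to the first branching node (the whole
#' path, with a warning, if the plant is branchless). Every off-path
#' subtree hanging from a junction on the main path is one leaf, measured
#' as the maximal geodesic distance from its junction into the subtree; the
#' terminal segment of the main path above the last junction is also a
#' leaf. Leaves are numbered by junction order from the base; two leaves
#' sharing a junction are ordered longest first. All lengths are calibrated
#' through the scale bar.
#'
#' @param graph a pruned, simplified [PlantGraph-class].
#' @param bar a [ScaleBar-class].
#' @param regionId region id recorded in the result.
#' @return a `traitRecord` list: `regionId`, `totalShootMM`,
#'   `internodeMM`, `leafMM` (ordered numeric vector), `coleoptileMM`
#'   (`NA` in seedling mode), `areaPx` (`NA` here, filled by the pipeline),
#'   plus pixel-scale equivalents and `leafPolylines` for overlays.
#' @export
measureSeedling <- function(graph, bar, regionId = graph@sourceRegionId) {
  nd <- graph@nodes
  if (nrow(nd) < 2L) stop("measurement error: graph has fewer than 2 nodes")
  anchors <- anchorNodes(graph)
  geo <- geodesicDistances(graph, anchors$lowest)
  totalPx <- geo$dist[as.character(anchors$highest)]
  # main path, base -> top
  path <- anchors$highest
  while (!is.na(geo$parent[as.character(path[1L])]))
    path <- c(geo$parent[as.character(path[1L])], path)
  deg <- nodeDegrees(graph)
  junctions <- path[deg[as.character(path)] >= 3L]
  leafPx <- numeric(0)
  leafPolys <- list()
  if (!length(junctions)) {
    warning("branchless plant: internode set to total shoot, no leaves")
    internodePx <- totalPx
  } else {
    internodePx <- geo$dist[as.character(junctions[1L])]
    lastJ <- junctions[length(junctions)]
    for (J in junctions) {
      geoJ <- geodesicDistances(graph, J)
      # branch identifier: first hop from J on the path to each node
      firstHop <- setNames(rep(NA_integer_, nrow(nd)), as.character(nd$id))
      for (v in nd$id) {
        if (v == J) next
        u <- v
        repeat {
          p <- geoJ$parent[as.character(u)]
          if (p == J) break
          u <- p
        }
        firstHop[as.character(v)] <- u
      }
      onPath <- intersect(unique(stats::na.omit(firstHop)), path)
      jLeaf <- numeric(0); jPoly <- list()
      for (hop in setdiff(unique(stats::na.omit(firstHop)), onPath)) {
        members <- nd$id[!is.na(firstHop) & firstHop == hop]
        jLeaf <- c(jLeaf, max(geoJ$dist[as.character(members)]))
        jPoly <- c(jPoly, list(.branchPolylines(graph, J, members)))
      }
      if (J == lastJ) {
        termLen <- totalPx - geo$dist[as.character(lastJ)]
        jLeaf <- c(jLeaf, termLen)
        # polyline of the terminal segment: edges of the path above lastJ
        above <- path[which(path == lastJ):length(path)]
        jPoly <- c(jPoly, list(.pathPolylines(graph, above)))
      }
      o <- order(-jLeaf)
      leafPx <- c(leafPx, jLeaf[o])
      leafPolys <- c(leafPolys, jPoly[o])
    }
  }
  rec <- list(regionId = regionId,
              totalShootMM = unname(pxToMM(totalPx, bar)),
              internodeMM = unname(pxToMM(internodePx, bar)),
              leafMM = unname(pxToMM(leafPx, bar)),
              coleoptileMM = NA_real_,
              totalShootPx = unname(totalPx),
              internodePx = unname(internodePx),
              leafPx = unname(leafPx),
              areaPx = NA_integer_,
              group = NA_character_,
              leafPolylines = leafPolys)
  class(rec) <- "traitRecord"
  rec
}

#' @noRd
.edgeBetween <- function(graph, a, b) {
  for (e in graph@edges)
    if ((e$a == a && e$b == b) || (e$a == b && e$b == a)) return(e)
  NULL
}

#' @noRd
.pathPolylines <- function(graph, nodeSeq) {
  polys <- list()
  for (i in seq_len(length(nodeSeq) - 1L)) {
    e <- .edgeBetween(graph, nodeSeq[i], nodeSeq[i + 1L])
    if (!is.null(e)) polys[[length(polys) + 1L]] <- e$polyline
  }
  polys
}

#' @noRd
.branchPolylines <- function(graph, J, members) {
  sel <- c(J, members)
  polys <- list()
  for (e in graph@edges)
    if (e$a %in% sel && e$b %in% sel && !(e$a == J && e$b == J))
      polys[[length(polys) + 1L]] <- e$polyline
  polys
}

#' Measure a coleoptile from its (unpruned) graph
#'
#' The only parameter of interest is the total length: the maximal geodesic
#' distance from the lowest node to any other node. Coleoptile graphs are
#' never pruned, so a short skeleton fork near the tip simply loses to the
#' longer branch in the maximum.
#'
#' @param graph an unpruned [PlantGraph-class].
#' @param bar a [ScaleBar-class].
#' @param regionId region id recorded in the result.
#' @return a `traitRecord` list with `coleoptileMM` set and seedling traits
#'   `NA`.
#' @export
measureColeoptile <- function(graph, bar, regionId = graph@sourceRegionId) {
  if (nrow(graph@nodes) < 2L)
    stop("measurement error: graph has fewer than 2 nodes")
  anchors <- anchorNodes(graph)
  geo <- geodesicDistances(graph, anchors$lowest)
  lenPx <- max(geo$dist)
  rec <- list(regionId = regionId,
              totalShootMM = NA_real_, internodeMM = NA_real_,
              leafMM = numeric(0),
              coleoptileMM = unname(pxToMM(lenPx, bar)),
              totalShootPx = NA_real_, internodePx = NA_real_,
              leafPx = numeric(0), coleoptilePx = unname(lenPx),
              areaPx = NA_integer_, group = NA_character_,
              leafPolylines = list())
  class(rec) <- "traitRecord"
  rec
}

#' Summary statistics of a trait
#'
#' @param values numeric vector, `n >= 2`.
#' @return list with `n`, `mean`, `sd` (sample, n-1 denominator) and
#'   `se = sd / sqrt(n)`.
#' @export
summarizeValues <- function(values) {
  values <- values[!is.na(values)]
  n <- length(values)
  if (n < 2L) stop("insufficient-sample: need at least 2 values")
  s <- stats::sd(values)
  list(n = n, mean = mean(values), sd = s, se = s / sqrt(n))
}

#' Group records and summarize each trait per group
#'
#' @param records list of `traitRecord`s.
#' @param labels optional named character vector mapping region id to group
#'   label; records without a label fall into `"ungrouped"`.
#' @return data.frame with columns `group`, `parameter`, `n`, `mean`, `sd`,
#'   `se`; one row per group x parameter with at least two values.
#' @export
groupAndSummarize <- function(records, labels = NULL) {
  ids <- vapply(records, function(r) as.integer(r$regionId), 0L)
  grp <- rep("ungrouped", length(records))
  if (!is.null(labels)) {
    labIds <- as.integer(names(labels))
    unknown <- setdiff(labIds, ids)
    if (length(unknown))
      stop("unknown-region: no region with id ", paste(unknown, collapse = ", "))
    grp[match(labIds, ids)] <- as.character(labels)
  }
  df <- recordsToDataFrame(records)
  df$group <- grp
  params <- setdiff(names(df), c("image", "region_id", "group", "area_px"))
  out <- list()
  for (g in unique(grp)) {
    sub <- df[df$group == g, , drop = FALSE]
    for (p in params) {
      v <- sub[[p]][!is.na(sub[[p]])]
      if (length(v) < 2L) next
      s <- summarizeValues(v)
      out[[length(out) + 1L]] <- data.frame(
        group = g, parameter = p, n = s$n, mean = s$mean, sd = s$sd,
        se = s$se, stringsAsFactors = FALSE)
    }
  }
  if (!length(out))
    return(data.frame(group = character(), parameter = character(),
                      n = integer(), mean = numeric(), sd = numeric(),
                      se = numeric(), stringsAsFactors = FALSE))
  do.call(rbind, out)
}

#' Merge segmented regions
#'
#' Unions the pixel sets of the named regions, so that a cut-off stem or
#' leaf fragment can be re-attached to its plant before re-analysis. If the
#' union is disconnected, the two nearest pixels between components are
#' joined by a rasterized straight bridge until the result is one
#' component. The merged region takes the smallest input id.
#'
#' @param regions list of [PlantRegion-class] objects.
#' @param ids integer vector (>= 2 distinct existing ids) to merge.
#' @return a single merged [PlantRegion-class].
#' @export
mergeRegions <- function(regions, ids) {
  ids <- unique(as.integer(ids))
  if (length(ids) < 2L) stop("mergeRegions needs at least 2 distinct ids")
  have <- vapply(regions, function(r) r@id, 0L)
  if (!all(ids %in% have)) stop("unknown id: ", paste(setdiff(ids, have), collapse = ", "))
  px <- unique(do.call(rbind, lapply(regions[match(ids, have)], function(r) r@pixels)))
  repeat {
    bb <- c(min(px[, 1L]), min(px[, 2L]), max(px[, 1L]), max(px[, 2L]))
    m <- matrix(0L, bb[3L] - bb[1L] + 1L, bb[4L] - bb[2L] + 1L)
    m[cbind(px[, 1L] - bb[1L] + 1L, px[, 2L] - bb[2L] + 1L)] <- 1L
    lab <- labelMask8(m)
    k <- max(lab)
    if (k == 1L) break
    # bridge the two closest components
    comp1 <- which(lab == 1L, arr.ind = TRUE)
    best <- NULL; bestD <- Inf
    for (other in 2:k) {
      comp2 <- which(lab == other, arr.ind = TRUE)
      for (i in seq_len(nrow(comp1))) {
        d2 <- (comp2[, 1L] - comp1[i, 1L])^2 + (comp2[, 2L] - comp1[i, 2L])^2
        j <- which.min(d2)
        if (d2[j] < bestD) { bestD <- d2[j]; best <- rbind(comp1[i, ], comp2[j, ]) }
      }
    }
    bridge <- bresenhamLine(best[1L, ], best[2L, ])
    bridge <- cbind(bridge[, 1L] + bb[1L] - 1L, bridge[, 2L] + bb[2L] - 1L)
    px <- unique(rbind(px, bridge))
  }
  # recompute contour on the final connected mask
  contours <- EBImage::ocontour(lab)
  ct <- contours[[1L]] + 1L
  ct <- cbind(ct[, 1L] + bb[1L] - 1L, ct[, 2L] + bb[2L] - 1L)
  px <- px[order(px[, 1L], px[, 2L]), , drop = FALSE]
  new("PlantRegion", id = min(ids),
      pixels = matrix(as.integer(px), ncol = 2L,
                      dimnames = list(NULL, c("row", "col"))),
      contour = matrix(as.integer(ct), ncol = 2L,
                       dimnames = list(NULL, c("row", "col"))),
      areaPx = nrow(px),
      bbox = as.integer(c(min(px[, 1L]), min(px[, 2L]),
                          max(px[, 1L]), max(px[, 2L]))))
}

#' Program-versus-manual comparison report
#'
#' Mirrors the validation protocol used to accept automated measurements
#' against manual ones: Shapiro-Wilk normality per list, an F test on the
#' variance ratio, then a pooled-variance two-sided Student t test on the
#' means.
#'
#' @param a,b numeric vectors of equal length, `n >= 3`.
#' @return list with `n`, `meanA`, `meanB`, `shapiroPA`, `shapiroPB`,
#'   `fTestP`, `tStat`, `tTestP`.
#' @export
compareMeasurements <- function(a, b) {
  if (length(a) != length(b)) stop("insufficient-sample: lists must have equal length")
  n <- length(a)
  if (n < 3L) stop("insufficient-sample: need n >= 3")
  shap <- function(x) {
    if (stats::sd(x) == 0) return(NA_real_)
    stats::shapiro.test(x)$p.value
  }
  if (stats::sd(a) == 0 && stats::sd(b) == 0) {
    same <- isTRUE(all.equal(mean(a), mean(b)))
    return(list(n = n, meanA = mean(a), meanB = mean(b),
                shapiroPA = NA_real_, shapiroPB = NA_real_,
                fTestP = NA_real_, tStat = if (same) 0 else Inf,
                tTestP = if (same) 1 else 0))
  }
  tt <- stats::t.test(a, b, var.equal = TRUE, alternative = "two.sided")
  list(n = n, meanA = mean(a), meanB = mean(b),
       shapiroPA = shap(a), shapiroPB = shap(b),
       fTestP = stats::var.test(a, b)$p.value,
       tStat = unname(tt$statistic),
       tTestP = tt$p.value)
}
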