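#' @import methods
NULL

#' Analysis configuration
#'
#' Holds every tunable of the measurement pipeline. The defaults mirror the
#' published screening protocol: a 20 mm scale bar, a minimum detection area
#' of 500 px (removes scanning noise), and a spur-pruning threshold of 50 px.
#'
#' @slot plantType `"seedling"` (HSV colour segmentation, pruning on) or
#'   `"coleoptile"` (grayscale Otsu segmentation, no pruning).
#' @slot scaleBarSide lower corner holding the bar, `"left"` or `"right"`.
#' @slot scaleBarLengthMM physical bar length in millimetres (default 20).
#' @slot minDetectionAreaPx smallest connected component kept as a plant,
#'   in pixels (default 500); components with area `>=` the value are kept.
#' @slot pruneThresholdPx terminal skeleton edges strictly shorter than this
#'   are pruned (default 50 px), except the basal edge below the lowest node.
#' @slot hsvBounds numeric of length 6, `c(hMin, hMax, sMin, sMax, vMin,
#'   vMax)`; hue in degrees (0-360, wrap-around allowed when `hMin > hMax`),
#'   saturation and value in `[0, 1]`. Bounds are inclusive.
#' @slot cornerWindowFrac fraction of image height and width scanned for the
#'   scale bar in the configured lower corner (default 0.15).
#' @slot medianKernelPx odd median-blur kernel width in pixels (default 3:
#'   the smallest kernel that removes isolated salt pixels while leaving
#'   organs a few pixels wide intact).
#' @slot bilateralD bilateral filter window diameter in pixels (default 5).
#' @slot bilateralSigmaColor bilateral range sigma, intensity units 0-255.
#' @slot bilateralSigmaSpace bilateral spatial sigma in pixels.
#' @seealso [analysisConfig()]
#' @export
setClass("AnalysisConfig", representation(
  plantType = "character",
  scaleBarSide = "character",
  scaleBarLengthMM = "numeric",
  minDetectionAreaPx = "numeric",
  pruneThresholdPx = "numeric",
  hsvBounds = "numeric",
  cornerWindowFrac = "numeric",
  medianKernelPx = "numeric",
  bilateralD = "numeric",
  bilateralSigmaColor = "numeric",
  bilateralSigmaSpace = "numeric"
))

setValidity("AnalysisConfig", function(object) {
  msg <- character()
  if (!object@plantType %in% c("seedling", "coleoptile"))
    msg <- c(msg, "plantType must be 'seedling' or 'coleoptile'")
  if (!object@scaleBarSide %in% c("left", "right"))
    msg <- c(msg, "scaleBarSide must be 'left' or 'right'")
  if (object@scaleBarLengthMM <= 0)
    msg <- c(msg, "scaleBarLengthMM must be positive")
  if (object@minDetectionAreaPx < 1)
    msg <- c(msg, "minDetectionAreaPx must be >= 1")
  if (object@pruneThresholdPx < 0)
    msg <- c(msg, "pruneThresholdPx must be >= 0")
  if (length(object@hsvBounds) != 6L)
    msg <- c(msg, "hsvBounds must have six values (hMin,hMax,sMin,sMax,vMin,vMax)")
  if (object@cornerWindowFrac <= 0 || object@cornerWindowFrac > 0.5)
    msg <- c(msg, "cornerWindowFrac must lie in (0, 0.5]")
  if (object@medianKernelPx < 1 || object@medianKernelPx %% 2 != 1)
    msg <- c(msg, "medianKernelPx must be a positive odd integer")
  if (length(msg)) msg else TRUE
})

#' Construct an AnalysisConfig
#'
#' @param plantType `"seedling"` or `"coleoptile"`.
#' @param scaleBarSide `"left"` or `"right"`.
#' @param scaleBarLengthMM physical scale-bar length, mm.
#' @param minDetectionAreaPx minimum region area kept, px.
#' @param pruneThresholdPx spur-pruning threshold, px.
#' @param hsvBounds inclusive HSV window `c(hMin, hMax, sMin, sMax, vMin,
#'   vMax)` for plant colour; the default window covers the green of healthy
#'   shoot tissue against a blue plate background.
#' @param cornerWindowFrac lower-corner window fraction for bar detection.
#' @param medianKernelPx odd median-blur kernel width, px.
#' @param bilateralD,bilateralSigmaColor,bilateralSigmaSpace bilateral
#'   filter window diameter (px), range sigma (intensity 0-255) and spatial
#'   sigma (px).
#' @return An [AnalysisConfig-class] object.
#' @examples
#' cfg <- analysisConfig()
#' cfg
#' @export
analysisConfig <- function(plantType = c("seedling", "coleoptile"),
                           scaleBarSide = c("left", "right"),
                           scaleBarLengthMM = 20,
                           minDetectionAreaPx = 500,
                           pruneThresholdPx = 50,
                           hsvBounds = c(70, 180, 0.2, 1, 0.15, 1),
                           cornerWindowFrac = 0.15,
                           medianKernelPx = 3,
                           bilateralD = 5,
                           bilateralSigmaColor = 30,
                           bilateralSigmaSpace = 3) {
  new("AnalysisConfig",
      plantType = match.arg(plantType),
      scaleBarSide = match.arg(scaleBarSide),
      scaleBarLengthMM = scaleBarLengthMM,
      minDetectionAreaPx = minDetectionAreaPx,
      pruneThresholdPx = pruneThresholdPx,
      hsvBounds = hsvBounds,
      cornerWindowFrac = cornerWindowFrac,
      medianKernelPx = medianKernelPx,
      bilateralD = bilateralD,
      bilateralSigmaColor = bilateralSigmaColor,
      bilateralSigmaSpace = bilateralSigmaSpace)
}

setMethod("show", "AnalysisConfig", function(object) {
  cat("AnalysisConfig:", object@plantType,
      "| bar:", object@scaleBarSide, sprintf("%g mm", object@scaleBarLengthMM),
      "| min area:", object@minDetectionAreaPx, "px",
      "| prune <", object@pruneThresholdPx, "px\n")
})

#' Detected scale bar
#'
#' The pixel width of the scanned reference bar together with its physical
#' length defines the mm-per-pixel calibration factor for every measurement.
#'
#' @slot widthPx bar extent along its long (column) axis, pixels (>= 10).
#' @slot lengthMM physical bar length, millimetres.
#' @slot corner `"left"` or `"right"` lower corner.
#' @seealso [detectScaleBar()], [mmPerPx()], [pxToMM()]
#' @export
setClass("ScaleBar", representation(
  widthPx = "numeric", lengthMM = "numeric", corner = "character"
))

setValidity("ScaleBar", function(object) {
  msg <- character()
  if (object@widthPx < 10) msg <- c(msg, "widthPx must be >= 10 (noise guard)")
  if (object@lengthMM <= 0) msg <- c(msg, "lengthMM must be positive")
  if (!object@corner %in% c("left", "right"))
    msg <- c(msg, "corner must be 'left' or 'right'")
  if (length(msg)) msg else TRUE
})

#' @rdname ScaleBar-class
#' @param widthPx,lengthMM,corner see slots.
#' @export
scaleBar <- function(widthPx, lengthMM = 20, corner = "left") {
  new("ScaleBar", widthPx = widthPx, lengthMM = lengthMM, corner = corner)
}

#' Millimetres per pixel of a scale bar
#' @param bar a [ScaleBar-class].
#' @return numeric scalar, `lengthMM / widthPx`.
#' @export
mmPerPx <- function(bar) {
  stopifnot(is(bar, "ScaleBar"))
  bar@lengthMM / bar@widthPx
}

setMethod("show", "ScaleBar", function(object) {
  cat(sprintf("ScaleBar: %g px = %g mm (%.5f mm/px), %s corner\n",
              object@widthPx, object@lengthMM, mmPerPx(object), object@corner))
})

#' Segmented plant region
#'
#' A maximal 8-connected foreground component that passed the minimum-area
#' filter, with its ordered outline contour.
#'
#' @slot id integer label (reading order of bounding-box top-left corners).
#' @slot pixels integer matrix (row, col) of member pixels.
#' @slot contour integer matrix (row, col), ordered outline pixels.
#' @slot areaPx number of member pixels.
#' @slot bbox integer `c(rowMin, colMin, rowMax, colMax)`, inclusive.
#' @export
setClass("PlantRegion", representation(
  id = "integer", pixels = "matrix", contour = "matrix",
  areaPx = "integer", bbox = "integer"
))

setValidity("PlantRegion", function(object) {
  if (object@areaPx != nrow(object@pixels))
    return("areaPx must equal the number of member pixels")
  TRUE
})

setMethod("show", "PlantRegion", function(object) {
  cat(sprintf("PlantRegion %d: %d px, bbox [%d,%d]-[%d,%d]\n", object@id,
              object@areaPx, object@bbox[1], object@bbox[2], object@bbox[3],
              object@bbox[4]))
})

#' One-pixel-wide skeleton of a region
#'
#' @slot pixels integer matrix (row, col) of skeleton pixels, 8-connected.
#' @slot sourceRegionId id of the [PlantRegion-class] it was thinned from.
#' @export
setClass("Skeleton", representation(
  pixels = "matrix", sourceRegionId = "integer"
))

setMethod("show", "Skeleton", function(object) {
  cat(sprintf("Skeleton of region %d: %d px\n", object@sourceRegionId,
              nrow(object@pixels)))
})

#' Skeleton graph of a plant
#'
#' Nodes are terminal (degree 1) or branching (degree >= 3) skeleton points;
#' edges carry the pixel polyline between them and its geodesic length
#' (1 per orthogonal, sqrt(2) per diagonal step).
#'
#' @slot nodes data.frame with columns `id`, `row`, `col`, `kind`
#'   (`"terminal"`/`"branching"`).
#' @slot edges list of lists with fields `a`, `b` (node ids), `lengthPx`,
#'   `polyline` (pixel matrix).
#' @slot sourceRegionId originating region id.
#' @export
setClass("PlantGraph", representation(
  nodes = "data.frame", edges = "list", sourceRegionId = "integer"
))

setValidity("PlantGraph", function(object) {
  msg <- character()
  nd <- object@nodes
  if (!all(c("id", "row", "col", "kind") %in% names(nd)))
    return("nodes must have columns id, row, col, kind")
  if (anyDuplicated(nd$id)) msg <- c(msg, "node ids must be unique")
  for (e in object@edges) {
    if (!all(c(e$a, e$b) %in% nd$id)) {
      msg <- c(msg, "edge endpoints must reference existing nodes")
      break
    }
    if (e$lengthPx <= 0) {
      msg <- c(msg, "edge lengths must be positive")
      break
    }
  }
  if (length(msg)) msg else TRUE
})

setMethod("show", "PlantGraph", function(object) {
  kinds <- table(object@nodes$kind)
  cat(sprintf(
    "PlantGraph (region %d): %d nodes (%d terminal, %d branching), %d edges, total length %.1f px\n",
    object@sourceRegionId, nrow(object@nodes),
    sum(object@nodes$kind == "terminal"), sum(object@nodes$kind == "branching"),
    length(object@edges), sum(vapply(object@edges, `[[`, 0, "lengthPx"))))
})

#' Graph accessors
#' @param graph a [PlantGraph-class].
#' @return `graphNodes()` the node data.frame; `graphEdges()` the edge list;
#'   `nodeDegrees()` a named integer vector of degrees by node id.
#' @export
graphNodes <- function(graph) graph@nodes

#' @rdname graphNodes
#' @export
graphEdges <- function(graph) graph@edges

#' @rdname graphNodes
#' @export
nodeDegrees <- function(graph) {
  deg <- setNames(integer(nrow(graph@nodes)), graph@nodes$id)
  for (e in graph@edges) {
    deg[as.character(e$a)] <- deg[as.character(e$a)] + 1L
    deg[as.character(e$b)] <- deg[as.character(e$b)] + 1L
  }
  deg
}

#' Ground truth of a synthetic scene
#'
#' @slot plants list of per-plant truth lists (organ arc lengths in px and
#'   mm, expected leaf count, base point).
#' @slot mask integer 0/1 matrix: exact rendered plant foreground before
#'   noise was added.
#' @slot barWidthPx rendered scale-bar width, px.
#' @slot barLengthMM physical bar length, mm.
#' @slot seed seed the scene was rendered with.
#' @export
setClass("SceneTruth", representation(
  plants = "list", mask = "matrix", barWidthPx = "numeric",
  barLengthMM = "numeric", seed = "numeric"
))

setMethod("show", "SceneTruth", function(object) {
  cat(sprintf("SceneTruth: %d plant(s), bar %g px / %g mm, seed %g\n",
              length(object@plants), object@barWidthPx, object@barLengthMM,
              object@seed))
})
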