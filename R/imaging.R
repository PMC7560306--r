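# Image I/O, preprocessing, segmentation and scale-bar detection.
#
# Raster images are numeric arrays height x width x 3 with 8-bit channel
# values in 0..255; grayscale images are height x width matrices in 0..255;
# binary masks are integer 0/1 matrices.

#' Read a raster image
#'
#' Reads PNG and TIFF through the png/tiff packages and JPEG through
#' EBImage. The result is a height x width x 3 array of 8-bit values
#' (0-255), rows running top to bottom.
#'
#' @param path image file path (`.png`, `.tif(f)`, `.jpg/.jpeg`).
#' @return numeric array `c(height, width, 3)` in 0..255.
#' @export
readRasterImage <- function(path) {
  ext <- tolower(tools::file_ext(path))
  if (ext == "png") {
    a <- png::readPNG(path)
  } else if (ext %in% c("tif", "tiff")) {
    a <- tiff::readTIFF(path)
  } else if (ext %in% c("jpg", "jpeg")) {
    img <- EBImage::readImage(path)
    a <- aperm(EBImage::imageData(img), c(2L, 1L, 3L)[seq_along(dim(img))])
  } else {
    stop("unsupported image format: ", ext)
  }
  if (length(dim(a)) == 2L) a <- array(rep(a, 3L), dim = c(dim(a), 3L))
  if (dim(a)[3L] > 3L) a <- a[, , 1:3, drop = FALSE]
  round(a * 255)
}

#' Write an RGB image or a binary mask as PNG
#'
#' Masks are written with foreground 255, background 0.
#'
#' @param img raster array (0..255) or 0/1 mask matrix.
#' @param path output `.png` path.
#' @return `path`, invisibly.
#' @export
writeImagePNG <- function(img, path) {
  png::writePNG(img / 255, path)
  invisible(path)
}

#' @rdname writeImagePNG
#' @param mask integer/logical 0-1 matrix.
#' @export
writeMaskPNG <- function(mask, path) {
  png::writePNG(matrix(as.numeric(mask != 0), nrow(mask), ncol(mask)), path)
  invisible(path)
}

#' Crop an image to the plate workspace
#'
#' The scan must be cropped to the plate holding the plants and the scale
#' bar before analysis; the rectangle is user-supplied. Coordinates are
#' 0-based and half-open, matching the `[row0, row1) x [col0, col1)`
#' convention, so the full image is `c(0, 0, height, width)`.
#'
#' @param img raster array.
#' @param rect numeric `c(row0, col0, row1, col1)`, 0-based half-open.
#' @return the cropped raster array of dimensions `(row1-row0, col1-col0)`.
#' @export
cropToWorkspace <- function(img, rect) {
  h <- dim(img)[1L]; w <- dim(img)[2L]
  r0 <- rect[1L]; c0 <- rect[2L]; r1 <- rect[3L]; c1 <- rect[4L]
  if (!(r0 >= 0 && r0 < r1 && r1 <= h && c0 >= 0 && c0 < c1 && c1 <= w))
    stop("invalid rectangle: must satisfy 0 <= row0 < row1 <= height, 0 <= col0 < col1 <= width")
  img[(r0 + 1):r1, (c0 + 1):c1, , drop = FALSE]
}

#' Convert RGB to grayscale (0-255)
#'
#' Uses the Rec. 601 luma weights (0.299, 0.587, 0.114).
#'
#' @param img raster array in 0..255.
#' @return matrix of rounded intensities 0..255.
#' @export
rgbToGray <- function(img) {
  round(0.299 * img[, , 1L] + 0.587 * img[, , 2L] + 0.114 * img[, , 3L])
}

#' Convert RGB to HSV
#'
#' @param img raster array in 0..255.
#' @return array `c(h, w, 3)` with hue in degrees (0-360), saturation and
#'   value in `[0, 1]`.
#' @export
rgbToHSV <- function(img) {
  d <- dim(img)
  m <- rbind(as.vector(img[, , 1L]), as.vector(img[, , 2L]), as.vector(img[, , 3L]))
  hsv <- grDevices::rgb2hsv(m, maxColorValue = 255)
  out <- array(0, dim = d)
  out[, , 1L] <- hsv[1L, ] * 360
  out[, , 2L] <- hsv[2L, ]
  out[, , 3L] <- hsv[3L, ]
  out
}

#' Median blur
#'
#' @param img raster array or grayscale matrix in 0..255.
#' @param kernelPx odd kernel width; 1 is a no-op.
#' @return blurred image, same dimensions and scale.
#' @export
medianBlur <- function(img, kernelPx = 5) {
  if (kernelPx %% 2 != 1 || kernelPx < 1)
    stop("config error: median kernel must be a positive odd integer")
  if (kernelPx == 1) return(img)
  r <- (kernelPx - 1) / 2
  median3x3 <- function(m) {
    # vectorized 3x3 median: 19-exchange median-of-9 network over the
    # nine shifted planes (replicated borders)
    p <- vector("list", 9L)
    k <- 0L
    for (dr in -1:1) for (dc in -1:1) {
      k <- k + 1L
      p[[k]] <- .shiftMat(m, dr, dc)
    }
    s <- function(i, j) {
      lo <- pmin(p[[i]], p[[j]])
      p[[j]] <<- pmax(p[[i]], p[[j]])
      p[[i]] <<- lo
    }
    s(2,3); s(5,6); s(8,9); s(1,2); s(4,5); s(7,8); s(2,3); s(5,6); s(8,9)
    s(1,4); s(6,9); s(5,8); s(4,7); s(2,5); s(3,6); s(5,8); s(5,3); s(7,5)
    s(5,3)
    p[[5L]]
  }
  blur1 <- function(m) {
    if (kernelPx == 3) median3x3(m) else EBImage::medianFilter(m / 255, r) * 255
  }
  if (length(dim(img)) == 2L) return(blur1(img))
  out <- img
  for (ch in seq_len(dim(img)[3L])) out[, , ch] <- blur1(img[, , ch])
  out
}

#' Bilateral filter
#'
#' Edge-preserving smoothing: each pixel is replaced by a weighted mean of
#' its neighbourhood where weights fall off with spatial distance
#' (`sigmaSpace`) and with luminance difference (`sigmaColor`), so organ
#' boundaries are preserved while plate texture is flattened. Range weights
#' are computed on luminance and applied to all channels.
#'
#' @param img raster array in 0..255.
#' @param d window diameter in pixels (odd).
#' @param sigmaColor range sigma in intensity units (0-255).
#' @param sigmaSpace spatial sigma in pixels.
#' @return filtered raster array.
#' @export
bilateralFilter <- function(img, d = 5, sigmaColor = 30, sigmaSpace = 3) {
  if (d %% 2 != 1 || d < 1) stop("config error: bilateral diameter must be odd")
  if (d == 1) return(img)
  r <- (d - 1) / 2
  lum <- round(0.299 * img[, , 1L] + 0.587 * img[, , 2L] + 0.114 * img[, , 3L])
  acc <- array(0, dim = dim(img))
  wsum <- matrix(0, nrow(lum), ncol(lum))
  rangeLUT <- exp(-((0:255)^2) / (2 * sigmaColor^2))  # range weight by |dL|
  for (dr in -r:r) for (dc in -r:r) {
    ws <- exp(-(dr^2 + dc^2) / (2 * sigmaSpace^2))
    shLum <- .shiftMat(lum, dr, dc)
    w <- ws * rangeLUT[abs(shLum - lum) + 1L]
    dim(w) <- dim(lum)
    wsum <- wsum + w
    for (ch in 1:3) acc[, , ch] <- acc[, , ch] + w * .shiftMat(img[, , ch], dr, dc)
  }
  for (ch in 1:3) acc[, , ch] <- acc[, , ch] / wsum
  acc
}

#' Preprocess a scan for segmentation
#'
#' Median blur (salt noise removal), bilateral filtering (edge-preserving
#' smoothing), then conversion to HSV, the colour space in which plant
#' green separates cleanly from the blue plate background.
#'
#' @param img raster array in 0..255.
#' @param cfg an [AnalysisConfig-class].
#' @return HSV array (`h` 0-360, `s`/`v` 0-1), same height and width.
#' @export
preprocessImage <- function(img, cfg = analysisConfig()) {
  sm <- medianBlur(img, cfg@medianKernelPx)
  sm <- bilateralFilter(sm, cfg@bilateralD, cfg@bilateralSigmaColor,
                        cfg@bilateralSigmaSpace)
  rgbToHSV(sm)
}

#' Segment plants by HSV colour thresholding
#'
#' A pixel is foreground iff all three channels lie inside the inclusive
#' HSV window of `cfg`. Hue wrap-around (window crossing 0/360) is
#' supported by giving `hMin > hMax`.
#'
#' @param hsvImg HSV array from [preprocessImage()].
#' @param cfg an [AnalysisConfig-class].
#' @return integer 0/1 mask matrix.
#' @export
segmentColor <- function(hsvImg, cfg = analysisConfig()) {
  b <- cfg@hsvBounds
  d <- dim(hsvImg)
  h <- matrix(hsvImg[, , 1L], d[1L], d[2L])
  s <- matrix(hsvImg[, , 2L], d[1L], d[2L])
  v <- matrix(hsvImg[, , 3L], d[1L], d[2L])
  hueOk <- if (b[1L] <= b[2L]) h >= b[1L] & h <= b[2L] else h >= b[1L] | h <= b[2L]
  mask <- hueOk & s >= b[3L] & s <= b[4L] & v >= b[5L] & v <= b[6L]
  matrix(as.integer(mask), d[1L], d[2L])
}

#' Otsu threshold of a grayscale image
#'
#' Scans every candidate threshold `t` in 1..255, splitting pixels into the
#' classes `I < t` and `I >= t`, and returns the `t` maximizing the
#' between-class variance (ties broken towards the smallest `t`).
#'
#' @param gray matrix of intensities 0..255.
#' @return integer threshold.
#' @export
otsuThreshold <- function(gray) {
  g <- as.integer(round(gray))
  counts <- tabulate(g + 1L, nbins = 256L)
  if (sum(counts > 0L) < 2L)
    stop("degenerate histogram: image has fewer than 2 distinct intensities")
  n <- sum(counts)
  lev <- 0:255
  cumN <- cumsum(counts)
  cumS <- cumsum(counts * lev)
  # class 0 = {I < t} for t in 1..255 -> prefix of length t
  n0 <- cumN[1:255]
  s0 <- cumS[1:255]
  n1 <- n - n0
  w0 <- n0 / n; w1 <- n1 / n
  mu0 <- ifelse(n0 > 0, s0 / n0, 0)
  mu1 <- ifelse(n1 > 0, (cumS[256L] - s0) / n1, 0)
  sigmaB <- w0 * w1 * (mu0 - mu1)^2
  which.max(sigmaB)  # threshold t; which.max picks the first (smallest) tie
}

#' Otsu segmentation with automatic polarity
#'
#' Thresholds the image with [otsuThreshold()], then decides which class is
#' the object: the class whose mean intensity differs most from the mean of
#' the image border (assumed background) becomes foreground. This works for
#' pale coleoptiles on dark plates and dark bars on pale plates alike.
#'
#' @param gray matrix of intensities 0..255.
#' @return list with `threshold` (integer), `mask` (0/1 matrix) and
#'   `foreground` (`"below"` or `"above"` the threshold).
#' @export
segmentOtsu <- function(gray) {
  t <- otsuThreshold(gray)
  lowMask <- gray < t
  border <- c(gray[1L, ], gray[nrow(gray), ], gray[, 1L], gray[, ncol(gray)])
  muBorder <- mean(border)
  muLow <- mean(gray[lowMask])
  muHigh <- mean(gray[!lowMask])
  fgLow <- abs(muLow - muBorder) >= abs(muHigh - muBorder)
  mask <- if (fgLow) lowMask else !lowMask
  list(threshold = t,
       mask = matrix(as.integer(mask), nrow(gray), ncol(gray)),
       foreground = if (fgLow) "below" else "above")
}

#' @noRd
.cornerWindowIndex <- function(h, w, cfg) {
  wh <- max(1L, floor(cfg@cornerWindowFrac * h))
  ww <- max(1L, floor(cfg@cornerWindowFrac * w))
  rows <- (h - wh + 1L):h
  cols <- if (cfg@scaleBarSide == "left") 1L:ww else (w - ww + 1L):w
  list(rows = rows, cols = cols)
}

#' 8-connected labelling of a binary mask
#'
#' @param mask integer/logical matrix.
#' @return integer matrix of labels (0 = background), 8-connectivity.
#' @export
labelMask8 <- function(mask) {
  m <- matrix(as.numeric(mask != 0), nrow(mask), ncol(mask))
  lab <- EBImage::imageData(EBImage::bwlabel(m))
  k <- max(lab)
  if (k <= 1L) return(matrix(as.integer(lab), nrow(m), ncol(m)))
  # bwlabel is 4-connected; merge labels touching diagonally
  nr <- nrow(lab); nc <- ncol(lab)
  a <- lab[-nr, -nc]; b <- lab[-1, -1]     # NW-SE diagonal pairs
  c_ <- lab[-nr, -1]; d <- lab[-1, -nc]    # NE-SW diagonal pairs
  p1 <- cbind(a[a > 0 & b > 0 & a != b], b[a > 0 & b > 0 & a != b])
  p2 <- cbind(c_[c_ > 0 & d > 0 & c_ != d], d[c_ > 0 & d > 0 & c_ != d])
  pairs <- unique(rbind(p1, p2))
  uf <- .unionFind(as.integer(k))
  if (nrow(pairs)) for (i in seq_len(nrow(pairs))) uf$union(pairs[i, 1L], pairs[i, 2L])
  roots <- uf$roots()
  newIds <- match(roots, sort(unique(roots)))
  out <- matrix(0L, nr, nc)
  nz <- lab > 0
  out[nz] <- newIds[lab[nz]]
  out
}

#' Extract plant regions from a segmentation mask
#'
#' The configured scale-bar corner window is excised first (the bar is
#' detected separately), then maximal 8-connected components with area at
#' least `minDetectionAreaPx` are kept. Regions are numbered 1..k in
#' reading order of their bounding-box top-left corners and carry their
#' ordered outline contour.
#'
#' @param mask integer 0/1 matrix from [segmentColor()] or [segmentOtsu()].
#' @param cfg an [AnalysisConfig-class].
#' @param excludeCorner zero out the scale-bar corner window first?
#' @return list of [PlantRegion-class] objects (possibly empty).
#' @export
extractRegions <- function(mask, cfg = analysisConfig(), excludeCorner = TRUE) {
  m <- matrix(as.integer(mask != 0), nrow(mask), ncol(mask))
  if (excludeCorner) {
    win <- .cornerWindowIndex(nrow(m), ncol(m), cfg)
    m[win$rows, win$cols] <- 0L
  }
  lab <- labelMask8(m)
  k <- max(lab)
  if (k == 0L) return(list())
  areas <- tabulate(lab[lab > 0L], nbins = k)
  keep <- which(areas >= cfg@minDetectionAreaPx)
  if (!length(keep)) return(list())
  # reading order of bbox top-left corners
  idx <- which(lab > 0L, arr.ind = TRUE)
  labv <- lab[lab > 0L]
  rowMin <- vapply(keep, function(l) min(idx[labv == l, 1L]), 0L)
  colMin <- vapply(keep, function(l) min(idx[labv == l, 2L]), 0L)
  keep <- keep[order(rowMin, colMin)]
  # relabel kept components 1..k' for contour extraction
  lab2 <- matrix(0L, nrow(lab), ncol(lab))
  for (i in seq_along(keep)) lab2[lab == keep[i]] <- i
  contours <- EBImage::ocontour(lab2)
  out <- vector("list", length(keep))
  for (i in seq_along(keep)) {
    px <- idx[labv == keep[i], , drop = FALSE]
    ct <- contours[[i]] + 1L  # ocontour is 0-based (row, col) for our layout
    out[[i]] <- new("PlantRegion",
                    id = i,
                    pixels = matrix(as.integer(px), ncol = 2L,
                                    dimnames = list(NULL, c("row", "col"))),
                    contour = matrix(as.integer(ct), ncol = 2L,
                                     dimnames = list(NULL, c("row", "col"))),
                    areaPx = nrow(px),
                    bbox = as.integer(c(min(px[, 1L]), min(px[, 2L]),
                                        max(px[, 1L]), max(px[, 2L]))))
  }
  out
}

#' Detect and calibrate the scale bar
#'
#' Looks in the configured lower corner window (a `cornerWindowFrac`
#' fraction of the image height and width). The window is converted to
#' grayscale and Otsu-thresholded with border-based polarity, and the
#' largest connected non-background component is taken as the bar; its
#' column extent is the bar width in pixels.
#'
#' @param img raster array in 0..255 (the uncropped working image).
#' @param cfg an [AnalysisConfig-class].
#' @return a [ScaleBar-class].
#' @export
detectScaleBar <- function(img, cfg = analysisConfig()) {
  win <- .cornerWindowIndex(dim(img)[1L], dim(img)[2L], cfg)
  sub <- img[win$rows, win$cols, , drop = FALSE]
  gray <- medianBlur(rgbToGray(sub), cfg@medianKernelPx)  # scrub salt noise
  seg <- tryCatch(segmentOtsu(gray), error = function(e) NULL)
  if (is.null(seg)) stop("bar-not-found: corner window has no contrast")
  lab <- labelMask8(seg$mask)
  k <- max(lab)
  if (k == 0L) stop("bar-not-found: no component in the corner window")
  areas <- tabulate(lab[lab > 0L], nbins = k)
  best <- which.max(areas)
  px <- which(lab == best, arr.ind = TRUE)
  widthPx <- max(px[, 2L]) - min(px[, 2L]) + 1L
  heightPx <- max(px[, 1L]) - min(px[, 1L]) + 1L
  # the bar is a solid rectangle; speckle from a barless window is not
  fill <- nrow(px) / (widthPx * heightPx)
  if (widthPx < 10 || fill < 0.5)
    stop("bar-not-found: no solid component at least 10 px wide")
  new("ScaleBar", widthPx = as.numeric(widthPx),
      lengthMM = cfg@scaleBarLengthMM, corner = cfg@scaleBarSide)
}
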